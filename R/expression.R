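# Expression-correlation contrast of function-enriched coregulation pairs
# against background, per condition (normal vs tumor), pooled across tissues.

#' Pearson product-moment correlation
#'
#' Direct summation formula with pairwise deletion of missing values.
#' Returns `NA_real_` (an undefined marker, not an error) when either vector
#' is constant or fewer than `min_obs` complete observation pairs remain.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_obs Minimum complete pairs (default 3).
#' @return Correlation in \[-1, 1\], or `NA_real_`.
#' @export
pearson_cc <- function(x, y, min_obs = 3) {
  if (length(x) != length(y))
    fc_domain_error("pearson_cc: length mismatch (%d vs %d)",
                    length(x), length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_obs) return(NA_real_)
  mx <- sum(x) / n; my <- sum(y) / n
  dx <- x - mx; dy <- y - my
  sxx <- sum(dx * dx); syy <- sum(dy * dy)
  if (sxx == 0 || syy == 0) return(NA_real_)
  r <- sum(dx * dy) / sqrt(sxx * syy)
  max(-1, min(1, r))
}

#' Expression profile of a regulator in one condition
#'
#' A TF maps to its own mRNA row; a miRNA family maps to the per-sample
#' aggregate (default mean, computed over non-missing values) of its member
#' mature miRNAs present in the dataset. Samples are restricted to the
#' condition, pooled across tissues, in stable dataset order.
#'
#' @param reg A [regulator()].
#' @param expr An `ExpressionDataset`.
#' @param condition `"normal"` or `"tumor"`.
#' @param aggregate `"mean"` (default) or `"max"` over family members.
#' @return Named numeric vector over condition samples, or `NULL` when no
#'   member of the regulator is measured (a lookup miss; callers skip and
#'   count the pair).
#' @export
regulator_expression <- function(reg, expr, condition = c("normal", "tumor"),
                                 aggregate = c("mean", "max")) {
  condition <- match.arg(condition)
  aggregate <- match.arg(aggregate)
  cols <- which(expr$sample_meta$condition == condition)
  rows <- intersect(if (reg$kind == "TF") reg$id else reg$members,
                    rownames(expr$values))
  if (length(rows) == 0) return(NULL)
  sub <- expr$values[rows, cols, drop = FALSE]
  if (length(rows) == 1) return(sub[1, ])
  f <- if (aggregate == "mean") function(v) mean(v, na.rm = TRUE)
       else function(v) max(v, na.rm = TRUE)
  out <- apply(sub, 2, function(v)
    if (all(is.na(v))) NA_real_ else f(v))
  out
}

pair_r <- function(reg_a, reg_b, reg_index, expr, condition, aggregate) {
  ra <- reg_index[[reg_a]]; rb <- reg_index[[reg_b]]
  if (is.null(ra) || is.null(rb)) return(NA_real_)
  xa <- regulator_expression(ra, expr, condition, aggregate)
  xb <- regulator_expression(rb, expr, condition, aggregate)
  if (is.null(xa) || is.null(xb)) return(NA_real_)
  pearson_cc(xa, xb)
}

#' Index the regulators of one or more networks
#' @param ... `RegulatorTargetNetwork` objects.
#' @return Named list of [regulator()] objects keyed by id.
#' @export
regulator_index <- function(...) {
  out <- list()
  for (net in list(...)) {
    for (i in seq_len(nrow(net$regulators))) {
      id <- net$regulators$id[i]
      out[[id]] <- regulator(id, net$regulators$kind[i],
                             members = net$members[[id]])
    }
  }
  out
}

#' Foreground vs background correlation distributions
#'
#' For each pair kind, computes Pearson correlations between the paired
#' regulators' expression profiles for the function-enriched pairs
#' (foreground) and for same-kind pairs not flagged enriched (background),
#' then compares the two distributions with a two-sample Kolmogorov-Smirnov
#' test (the minimal quantitative summary of the distribution plots; labelled
#' an addition in the run report). Pairs with unresolvable expression or
#' fewer than 3 complete observations are skipped and counted.
#'
#' @param enriched_pairs List of `CoregulationPair` flagged enriched.
#' @param all_pairs Candidate pair pool; background = same-kind members not
#'   in the enriched set.
#' @param expr An `ExpressionDataset`.
#' @param condition `"normal"` or `"tumor"`.
#' @param reg_index Named regulator list from [regulator_index()].
#' @param aggregate Family aggregation rule, see [regulator_expression()].
#' @param min_side Minimum values per side for the KS test (default 5;
#'   below it the summary is flagged `insufficient_n`).
#' @return Named list (one `CorrelationSummary` per pair kind): pair_kind,
#'   condition, foreground_r, background_r, ks_stat, ks_p, insufficient_n,
#'   n_pairs_used, n_pairs_skipped.
#' @export
correlation_distributions <- function(enriched_pairs, all_pairs, expr,
                                      condition, reg_index,
                                      aggregate = "mean", min_side = 5) {
  n_cond <- sum(expr$sample_meta$condition == condition)
  if (n_cond < 3)
    fc_domain_error("condition '%s' has %d samples; need >= 3",
                    condition, n_cond)
  key <- function(p) paste(p$reg_a, p$reg_b, sep = "|")
  enr_keys <- vapply(enriched_pairs, key, character(1))
  kinds_e <- vapply(enriched_pairs, `[[`, character(1), "pair_kind")
  kinds_a <- vapply(all_pairs, `[[`, character(1), "pair_kind")
  out <- list()
  for (k in sort(unique(kinds_e))) {
    fg <- enriched_pairs[kinds_e == k]
    bg <- all_pairs[kinds_a == k]
    bg <- bg[!vapply(bg, key, character(1)) %in% enr_keys]
    rs <- function(ps) vapply(ps, function(p)
      pair_r(p$reg_a, p$reg_b, reg_index, expr, condition, aggregate),
      numeric(1))
    fg_r <- rs(fg); bg_r <- rs(bg)
    skipped <- sum(is.na(fg_r)) + sum(is.na(bg_r))
    fg_r <- fg_r[!is.na(fg_r)]; bg_r <- bg_r[!is.na(bg_r)]
    if (length(fg_r) == 0)
      fc_domain_error("no foreground pair of kind %s has resolvable expression in %s",
                      k, condition)
    insufficient <- min(length(fg_r), length(bg_r)) < min_side
    if (!insufficient) {
      ks <- suppressWarnings(stats::ks.test(fg_r, bg_r))
      ks_stat <- unname(ks$statistic); ks_p <- ks$p.value
    } else {
      ks_stat <- NA_real_; ks_p <- NA_real_
    }
    out[[k]] <- structure(list(
      pair_kind = k, condition = condition,
      foreground_r = fg_r, background_r = bg_r,
      ks_stat = ks_stat, ks_p = ks_p, insufficient_n = insufficient,
      n_pairs_used = length(fg_r) + length(bg_r),
      n_pairs_skipped = skipped), class = "CorrelationSummary")
  }
  out
}

#' @export
print.CorrelationSummary <- function(x, ...) {
  cat(sprintf("<CorrelationSummary %s/%s: fg n=%d (mean r=%.3f), bg n=%d (mean r=%.3f), KS D=%s p=%s%s>\n",
              x$pair_kind, x$condition,
              length(x$foreground_r), mean(x$foreground_r),
              length(x$background_r),
              if (length(x$background_r)) mean(x$background_r) else NA,
              format(x$ks_stat, digits = 3), format(x$ks_p, digits = 3),
              if (x$insufficient_n) ", insufficient n" else ""))
  invisible(x)
}
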