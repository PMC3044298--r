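# Coregulation-pair enumeration and permutation-calibrated functional
# enrichment.
#
# The score: for a gene set with level-2 annotation counts c_k against
# genome-wide totals M_k (plus an unannotated pseudo-category),
#   L = sum_k ln C(M_k, c_k) - ln C(sum_k M_k, sum_k c_k),
# the log-likelihood of the observed profile under multivariate
# hypergeometric sampling of annotation instances. Because genes can carry
# several level-2 terms, L is used as a profile-surprise statistic only;
# calibration comes from an empirical null that redraws same-size GENE sets
# from the universe, which respects the annotation dependence.

#' Collapse mature miRNAs into family regulators
#'
#' Mature miRNAs sharing a seed are grouped into one family regulator whose
#' target set is the union of the member target sets. Matures missing from
#' the family map become singleton families under their own name (logged),
#' so no regulator is silently lost.
#'
#' @param mirna_edges data.frame with columns `mature`, `target`.
#' @param family_map data.frame with columns `mature`, `family`.
#' @return A [regulator_target_network()] of `MIRNA_FAMILY` regulators.
#' @export
collapse_families <- function(mirna_edges, family_map) {
  fam <- stats::setNames(family_map$family, family_map$mature)
  matures <- unique(mirna_edges$mature)
  unmapped <- setdiff(matures, names(fam))
  if (length(unmapped) > 0) {
    fc_log("collapse_families: %d unmapped mature miRNA(s) kept as singleton families",
           length(unmapped))
    fam <- c(fam, stats::setNames(unmapped, unmapped))
  }
  family_of <- fam[mirna_edges$mature]
  members <- split(family_map$mature, family_map$family)
  singletons <- stats::setNames(as.list(unmapped), unmapped)
  members <- c(members, singletons)
  used <- sort(unique(family_of))
  regs <- lapply(used, function(f)
    regulator(f, "MIRNA_FAMILY", members = unique(members[[f]] %||% f)))
  regulator_target_network(
    regs, data.frame(regulator_id = unname(family_of),
                     target = mirna_edges$target))
}

#' Propagate TF regulation of host genes to embedded miRNA families
#'
#' Embedded miRNA precursors share the transcription unit of their host
#' gene, so a TF targeting the host is taken to regulate the embedded
#' miRNA's family: for every TF -> host edge and precursor in that host,
#' emit TF -> family(precursor).
#'
#' @param tf_net TF [regulator_target_network()].
#' @param host_map data.frame with columns `precursor`, `host_gene`.
#' @param family_map data.frame mapping `mature` (precursor names accepted)
#'   to `family`.
#' @return data.frame of directed edges `source`, `dest`, `source_kind`.
#' @export
propagate_host_regulation <- function(tf_net, host_map, family_map) {
  fam <- stats::setNames(family_map$family, family_map$mature)
  out <- list(); skipped <- 0L
  hosts <- split(host_map$precursor, host_map$host_gene)
  tf_edges <- tf_net$edges[tf_net$edges$target %in% names(hosts), ,
                           drop = FALSE]
  for (i in seq_len(nrow(tf_edges))) {
    for (prec in hosts[[tf_edges$target[i]]]) {
      f <- fam[prec]
      if (is.na(f)) { skipped <- skipped + 1L; next }
      out[[length(out) + 1L]] <- c(tf_edges$regulator_id[i], unname(f))
    }
  }
  if (skipped > 0)
    fc_log("propagate_host_regulation: skipped %d precursor(s) with unknown family",
           skipped)
  if (length(out) == 0)
    return(data.frame(source = character(0), dest = character(0),
                      source_kind = character(0), stringsAsFactors = FALSE))
  m <- unique(do.call(rbind, out))
  data.frame(source = m[, 1], dest = m[, 2], source_kind = "TF",
             stringsAsFactors = FALSE)
}

pair_kind_of <- function(kind_a, kind_b) {
  if (kind_a == "TF" && kind_b == "TF") "TF_TF"
  else if (kind_a == "MIRNA_FAMILY" && kind_b == "MIRNA_FAMILY") "MIR_MIR"
  else "TF_MIR"
}

#' Enumerate coregulation pairs from shared targets
#'
#' All unordered regulator pairs (TF-TF, TF-miRNA, miRNA-miRNA) whose target
#' sets share at least `min_shared` genes, in canonical order (reg_a < reg_b
#' lexicographically; rows sorted by reg_a then reg_b).
#'
#' @param tf_net TF network.
#' @param mir_net miRNA-family network.
#' @param min_shared Minimum shared-target count (default 3; a 1-2 gene
#'   profile carries no usable functional signal).
#' @return A list of `CoregulationPair` objects: `reg_a`, `reg_b`,
#'   `pair_kind`, `shared` (character vector of shared target genes).
#' @export
enumerate_pairs <- function(tf_net, mir_net, min_shared = 3) {
  regs <- rbind(tf_net$regulators, mir_net$regulators)
  if (anyDuplicated(regs$id))
    fc_integrity_error("regulator ids overlap between TF and miRNA networks")
  edges <- rbind(tf_net$edges, mir_net$edges)
  genes <- sort(unique(edges$target))
  ids <- sort(regs$id)
  kind <- stats::setNames(regs$kind, regs$id)[ids]
  inc <- matrix(0L, nrow = length(ids), ncol = length(genes),
                dimnames = list(ids, genes))
  inc[cbind(match(edges$regulator_id, ids), match(edges$target, genes))] <- 1L
  shared_counts <- tcrossprod(inc)
  pairs <- list()
  for (i in seq_along(ids)) {
    js <- which(shared_counts[i, ] >= min_shared)
    js <- js[js > i]
    for (j in js) {
      shared <- genes[inc[i, ] == 1L & inc[j, ] == 1L]
      pairs[[length(pairs) + 1L]] <- structure(
        list(reg_a = ids[i], reg_b = ids[j],
             pair_kind = pair_kind_of(kind[i], kind[j]),
             shared = shared),
        class = "CoregulationPair")
    }
  }
  pairs
}

#' @export
print.CoregulationPair <- function(x, ...) {
  cat(sprintf("<CoregulationPair %s -- %s [%s], %d shared targets>\n",
              x$reg_a, x$reg_b, x$pair_kind, length(x$shared)))
  invisible(x)
}

#' Multivariate hypergeometric log-likelihood of a functional profile
#'
#' `L = sum_k ln C(M_k, c_k) - ln C(M_tot, n_inst)` over the level-2
#' categories plus the unannotated pseudo-category, where `M_tot = sum_k M_k`
#' and `n_inst = sum_k c_k`. Computed in log space (log-gamma), `L <= 0`.
#' Lower L means a more atypical (more function-concentrated) profile.
#'
#' @param profile A `FunctionalProfile`.
#' @param ann The `Level2Annotation` defining population counts.
#' @return Scalar log-likelihood (natural log).
#' @export
mvh_loglik <- function(profile, ann) {
  cc <- c(profile$counts, profile$unannotated)
  MM <- c(ann$population_counts, ann$unannotated_count)
  names(MM) <- c(names(ann$population_counts), UNANNOTATED)
  bad <- which(cc > MM)
  if (length(bad) > 0)
    fc_domain_error("profile count exceeds population for term %s (%d > %d)",
                    names(MM)[bad[1]], cc[bad[1]], MM[bad[1]])
  sum(lchoose(MM, cc)) - lchoose(sum(MM), sum(cc))
}

# vectorised score for a 0/1 instance matrix subset: rows = genes of one set
profile_loglik_from_counts <- function(cs, MM, lch_tot) {
  sum(lchoose(MM, cs)) - lch_tot[sum(cs) + 1L]
}

# draw n_perm null gene sets of size n and score them; lch_tot is a lookup
# of lchoose(M_tot, .) over all attainable instance totals
null_loglik_sample <- function(ann, n, n_perm) {
  inst <- ann$inst_matrix
  MM <- c(ann$population_counts, ann$unannotated_count)
  M_tot <- sum(MM)
  lch_tot <- lchoose(M_tot, 0:(n * ncol(inst)))
  vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nrow(inst), n)
    cs <- colSums(inst[idx, , drop = FALSE])
    profile_loglik_from_counts(cs, MM, lch_tot)
  }, numeric(1))
}

#' Permutation test of profile enrichment
#'
#' Draws `n_perm` gene sets of the same size uniformly without replacement
#' from the annotation universe, scores each with [mvh_loglik()], and
#' returns the empirical p-value `p = (1 + #{L_null <= L_obs}) / (1 +
#' n_perm)` (pseudocount convention; the minimum attainable p is
#' `1/(n_perm+1)`). Null samples depend only on the set size, so they can be
#' reused across same-size sets via `cache`.
#'
#' @param profile A `FunctionalProfile` with `set_size >= 1`.
#' @param ann A `Level2Annotation`.
#' @param n_perm Number of permutations (paper default 10000).
#' @param rng_seed Optional seed applied before drawing (ignored on a cache
#'   hit).
#' @param cache Optional environment used to memoise null samples by set
#'   size within a run.
#' @return List with `L_obs`, `p_perm`, `n_perm`.
#' @export
permutation_test <- function(profile, ann, n_perm = 10000, rng_seed = NULL,
                             cache = NULL) {
  n <- profile$set_size
  if (n < 1) fc_domain_error("permutation test needs a non-empty gene set")
  if (n > length(ann$universe))
    fc_domain_error("set size %d exceeds universe size %d",
                    n, length(ann$universe))
  if (n_perm < 1) fc_domain_error("n_perm must be >= 1")
  L_obs <- mvh_loglik(profile, ann)
  key <- as.character(n)
  nulls <- if (!is.null(cache) && !is.null(cache[[key]])) {
    cache[[key]]
  } else {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    nl <- null_loglik_sample(ann, n, n_perm)
    if (!is.null(cache)) cache[[key]] <- nl
    nl
  }
  list(L_obs = L_obs,
       p_perm = (1 + sum(nulls <= L_obs)) / (1 + length(nulls)),
       n_perm = length(nulls))
}

#' FDR adjustment: Benjamini-Hochberg step-up or Benjamini-Liu step-down
#'
#' BH: classic step-up with monotonicity enforcement. BL: the Benjamini-Liu
#' (1999) step-down procedure with critical constants
#' `c_i = 1 - (1 - min(1, m*alpha/(m-i+1)))^(1/(m-i+1))`; its adjusted
#' values are the step-down-monotone inversion of those constants. Ties are
#' broken by stable input order.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @param method `"BH"` or `"BL"`.
#' @param alpha FDR level used for the rejection flags (default 0.05).
#' @return List with `adjusted` (same order as input) and `reject` (logical).
#' @export
fdr_adjust <- function(pvalues, method = c("BH", "BL"), alpha = 0.05) {
  method <- match.arg(method)
  p <- as.numeric(pvalues)
  if (length(p) == 0)
    return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    fc_domain_error("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)  # stable: order() preserves input order on ties
  ps <- p[o]
  if (method == "BH") {
    adj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
    adj_sorted <- pmin(adj_sorted, 1)
    adjusted <- numeric(m); adjusted[o] <- adj_sorted
    reject <- adjusted <= alpha
  } else {
    i <- seq_len(m)
    mi <- m - i + 1
    # smallest alpha at which p_(i) passes constant c_i, then step-down max
    adj_sorted <- pmin(1, mi / m * (1 - (1 - ps)^mi))
    adj_sorted <- cummax(adj_sorted)
    adjusted <- numeric(m); adjusted[o] <- adj_sorted
    crit <- 1 - (1 - pmin(1, m * alpha / mi))^(1 / mi)
    pass <- ps <= crit
    k <- if (all(pass)) m else which(!pass)[1] - 1L
    reject_sorted <- seq_len(m) <= k
    reject <- logical(m); reject[o] <- reject_sorted
  }
  list(adjusted = adjusted, reject = reject)
}

#' Score all coregulation pairs and flag function-enriched ones
#'
#' Runs the permutation test on every pair's shared-target profile and
#' applies FDR control over all tested pairs pooled (optionally within each
#' pair kind). Deterministic given `rng_seed`: pairs are processed in
#' canonical order and null samples are drawn from a single seeded stream.
#'
#' @param pairs List of `CoregulationPair` (from [enumerate_pairs()]).
#' @param ann A `Level2Annotation`.
#' @param n_perm Permutations per set size (default 10000).
#' @param alpha FDR threshold (default 0.05).
#' @param rng_seed Integer seed.
#' @param fdr_method `"BH"` (default) or `"BL"`.
#' @param fdr_scope `"pooled"` (default) or `"by_kind"`.
#' @return data.frame with columns reg_a, reg_b, pair_kind, n_shared,
#'   loglik, p_perm, q, enriched; attribute `"shared"` holds the
#'   shared-target sets (named `reg_a|reg_b`).
#' @export
find_enriched_pairs <- function(pairs, ann, n_perm = 10000, alpha = 0.05,
                                rng_seed = 1L, fdr_method = "BH",
                                fdr_scope = c("pooled", "by_kind")) {
  fdr_scope <- match.arg(fdr_scope)
  if (length(pairs) == 0)
    fc_domain_error("no coregulation pairs to test")
  ord <- order(vapply(pairs, `[[`, character(1), "reg_a"),
               vapply(pairs, `[[`, character(1), "reg_b"))
  pairs <- pairs[ord]
  cache <- new.env(parent = emptyenv())
  set.seed(rng_seed)
  res <- lapply(pairs, function(pr) {
    prof <- functional_profile(pr$shared, ann)
    pt <- permutation_test(prof, ann, n_perm = n_perm, cache = cache)
    data.frame(reg_a = pr$reg_a, reg_b = pr$reg_b, pair_kind = pr$pair_kind,
               n_shared = length(pr$shared), loglik = pt$L_obs,
               p_perm = pt$p_perm, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  if (fdr_scope == "pooled") {
    adj <- fdr_adjust(tab$p_perm, method = fdr_method, alpha = alpha)
    tab$q <- adj$adjusted; tab$enriched <- adj$reject
  } else {
    tab$q <- NA_real_; tab$enriched <- NA
    for (k in unique(tab$pair_kind)) {
      sel <- tab$pair_kind == k
      adj <- fdr_adjust(tab$p_perm[sel], method = fdr_method, alpha = alpha)
      tab$q[sel] <- adj$adjusted; tab$enriched[sel] <- adj$reject
    }
  }
  attr(tab, "shared") <- stats::setNames(
    lapply(pairs, `[[`, "shared"),
    vapply(pairs, function(p) paste(p$reg_a, p$reg_b, sep = "|"),
           character(1)))
  tab
}
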