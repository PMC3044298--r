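# Upstream network motifs over coregulation pairs, with significance from
# resampled background pair sets. Because a coregulation pair shares targets
# by construction, any upstream A->B edge completes a feed-forward loop
# through every shared target; the catalog therefore tests upstream wiring
# only.

#' Build the directed upstream regulator network
#'
#' Union of: TF->TF edges (a TF whose gene sits in another TF's target set),
#' TF->family edges (predicted TF-miRNA regulation plus host-gene
#' propagation, see [propagate_host_regulation()]), and family->TF edges (a
#' TF gene inside a family's target set). Self-loops dropped, union
#' deduplicated.
#'
#' @param tf_net TF [regulator_target_network()].
#' @param tf_mir_edges data.frame `source` (TF), `dest` (family) of predicted
#'   TF->miRNA regulation; may be empty.
#' @param host_edges data.frame from [propagate_host_regulation()]; may be
#'   empty.
#' @param mir_net miRNA-family network.
#' @return An `UpstreamNetwork`: list with `edges` (data.frame `source`,
#'   `dest`, `source_kind`).
#' @export
build_upstream_network <- function(tf_net, tf_mir_edges = NULL,
                                   host_edges = NULL, mir_net = NULL) {
  tf_ids <- tf_net$regulators$id
  parts <- list()
  # TF -> TF: regulator's target set contains another TF's gene symbol
  tt <- tf_net$edges[tf_net$edges$target %in% tf_ids, , drop = FALSE]
  if (nrow(tt) > 0)
    parts$tt <- data.frame(source = tt$regulator_id, dest = tt$target,
                           source_kind = "TF", stringsAsFactors = FALSE)
  if (!is.null(tf_mir_edges) && nrow(tf_mir_edges) > 0)
    parts$tm <- data.frame(source = tf_mir_edges$source,
                           dest = tf_mir_edges$dest,
                           source_kind = "TF", stringsAsFactors = FALSE)
  if (!is.null(host_edges) && nrow(host_edges) > 0)
    parts$host <- data.frame(source = host_edges$source,
                             dest = host_edges$dest,
                             source_kind = "TF", stringsAsFactors = FALSE)
  if (!is.null(mir_net)) {
    mt <- mir_net$edges[mir_net$edges$target %in% tf_ids, , drop = FALSE]
    if (nrow(mt) > 0)
      parts$mt <- data.frame(source = mt$regulator_id, dest = mt$target,
                             source_kind = "MIRNA_FAMILY",
                             stringsAsFactors = FALSE)
  }
  edges <- if (length(parts) == 0)
    data.frame(source = character(0), dest = character(0),
               source_kind = character(0), stringsAsFactors = FALSE)
  else unique(do.call(rbind, parts))
  edges <- edges[edges$source != edges$dest, , drop = FALSE]
  edges <- edges[order(edges$source, edges$dest), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "UpstreamNetwork")
}

#' @export
print.UpstreamNetwork <- function(x, ...) {
  cat(sprintf("<UpstreamNetwork: %d directed edges (%d from TFs, %d from miRNA families)>\n",
              nrow(x$edges), sum(x$edges$source_kind == "TF"),
              sum(x$edges$source_kind == "MIRNA_FAMILY")))
  invisible(x)
}

# fast lookup context shared by all predicates
upstream_context <- function(upstream) {
  e <- upstream$edges
  list(
    edge_set = paste(e$source, e$dest, sep = ">"),
    parents = split(e$source, e$dest),
    parent_kind = split(e$source_kind, e$dest)
  )
}

has_edge <- function(ctx, a, b) paste(a, b, sep = ">") %in% ctx$edge_set

common_upstream <- function(ctx, a, b, kind) {
  pa <- ctx$parents[[a]]; pb <- ctx$parents[[b]]
  if (is.null(pa) || is.null(pb)) return(character(0))
  ka <- ctx$parent_kind[[a]]; kb <- ctx$parent_kind[[b]]
  setdiff(intersect(pa[ka == kind], pb[kb == kind]), c(a, b))
}

#' Default motif catalog
#'
#' Five patterns over a coregulation pair (A, B) and the upstream network:
#' `FFL_BIDIR` (A->B and B->A), `FFL_UNIDIR` (exactly one of the two),
#' `COMMON_UP_TF` (a third TF regulating both), `COMMON_UP_TF_AND_MIR`
#' (common upstream TF and a common upstream miRNA family), and
#' `UPSTREAM_CROSSTALK` (upstream regulators X of A and Y of B, outside the
#' pair, with X = Y or X and Y regulating one another). User catalogs are
#' named lists of `list(motif_id, predicate = function(a, b, ctx),
#' description)`.
#'
#' @return Named list of motif entries.
#' @export
default_motif_catalog <- function() {
  list(
    FFL_BIDIR = list(
      motif_id = "FFL_BIDIR",
      predicate = function(a, b, ctx)
        has_edge(ctx, a, b) && has_edge(ctx, b, a),
      description = "bidirectional feed-forward loop: A and B regulate each other (and their shared targets)"),
    FFL_UNIDIR = list(
      motif_id = "FFL_UNIDIR",
      predicate = function(a, b, ctx)
        xor(has_edge(ctx, a, b), has_edge(ctx, b, a)),
      description = "unidirectional feed-forward loop: exactly one of A->B, B->A"),
    COMMON_UP_TF = list(
      motif_id = "COMMON_UP_TF",
      predicate = function(a, b, ctx)
        length(common_upstream(ctx, a, b, "TF")) > 0,
      description = "a TF outside the pair regulates both members"),
    COMMON_UP_TF_AND_MIR = list(
      motif_id = "COMMON_UP_TF_AND_MIR",
      predicate = function(a, b, ctx)
        length(common_upstream(ctx, a, b, "TF")) > 0 &&
        length(common_upstream(ctx, a, b, "MIRNA_FAMILY")) > 0,
      description = "common upstream TF and common upstream miRNA family"),
    UPSTREAM_CROSSTALK = list(
      motif_id = "UPSTREAM_CROSSTALK",
      predicate = function(a, b, ctx) {
        pa <- setdiff(ctx$parents[[a]] %||% character(0), c(a, b))
        pb <- setdiff(ctx$parents[[b]] %||% character(0), c(a, b))
        if (length(pa) == 0 || length(pb) == 0) return(FALSE)
        if (length(intersect(pa, pb)) > 0) return(TRUE)
        for (x in pa) for (y in pb)
          if (has_edge(ctx, x, y) || has_edge(ctx, y, x)) return(TRUE)
        FALSE
      },
      description = "upstream regulators of A and B coincide or regulate one another")
  )
}

#' Count motif occurrences over coregulation pairs
#'
#' @param pairs List of `CoregulationPair` (or any list of objects with
#'   `reg_a`, `reg_b`).
#' @param upstream An `UpstreamNetwork`.
#' @param catalog Motif catalog (default [default_motif_catalog()]).
#' @return Named integer vector of observed counts per motif id.
#' @export
count_motifs <- function(pairs, upstream, catalog = default_motif_catalog()) {
  if (length(catalog) == 0) fc_config_error("motif catalog is empty")
  hits <- motif_hit_matrix(pairs, upstream, catalog)
  colSums(hits)
}

# pairs x motifs logical matrix of predicate outcomes
motif_hit_matrix <- function(pairs, upstream, catalog) {
  ctx <- upstream_context(upstream)
  ids <- vapply(catalog, `[[`, character(1), "motif_id")
  m <- matrix(FALSE, nrow = length(pairs), ncol = length(catalog),
              dimnames = list(NULL, ids))
  for (i in seq_along(pairs)) {
    a <- pairs[[i]]$reg_a; b <- pairs[[i]]$reg_b
    for (j in seq_along(catalog))
      m[i, j] <- isTRUE(catalog[[j]]$predicate(a, b, ctx))
  }
  m
}

#' Motif enrichment against resampled background pair sets
#'
#' For each pair kind separately, draws `n_resample` pair sets of the same
#' size as the function-enriched set uniformly without replacement from the
#' background pool (all pairs of that kind in the global network), counts
#' each motif, and reports `p_emp = (1 + #(null >= observed)) /
#' (1 + n_resample)` (over-representation only). A motif is significant when
#' `p_emp < alpha_motif` (paper threshold 0.001).
#'
#' @param enriched_pairs List of `CoregulationPair` flagged enriched.
#' @param all_pairs Background pool (the global network's pairs; must contain
#'   at least as many pairs per kind as the enriched set).
#' @param upstream An `UpstreamNetwork`.
#' @param catalog Motif catalog.
#' @param n_resample Number of background sets (paper default 10000).
#' @param rng_seed Integer seed.
#' @param alpha_motif Significance threshold on `p_emp` (default 0.001).
#' @return data.frame: motif_id, pair_kind, observed, fraction, null_mean,
#'   null_sd, null_max, p_emp, significant.
#' @export
motif_significance <- function(enriched_pairs, all_pairs, upstream,
                               catalog = default_motif_catalog(),
                               n_resample = 10000, rng_seed = 1L,
                               alpha_motif = 0.001) {
  if (length(enriched_pairs) == 0)
    fc_domain_error("enriched pair set is empty")
  set.seed(rng_seed)
  kinds_e <- vapply(enriched_pairs, `[[`, character(1), "pair_kind")
  kinds_a <- vapply(all_pairs, `[[`, character(1), "pair_kind")
  out <- list()
  for (k in sort(unique(kinds_e))) {
    enr <- enriched_pairs[kinds_e == k]
    pool <- all_pairs[kinds_a == k]
    if (length(pool) < length(enr))
      fc_domain_error("background pool for %s (%d) smaller than enriched set (%d)",
                      k, length(pool), length(enr))
    hits_pool <- motif_hit_matrix(pool, upstream, catalog)
    obs <- colSums(motif_hit_matrix(enr, upstream, catalog))
    n_set <- length(enr)
    null_counts <- matrix(0L, nrow = n_resample, ncol = ncol(hits_pool),
                          dimnames = list(NULL, colnames(hits_pool)))
    for (r in seq_len(n_resample)) {
      idx <- sample.int(length(pool), n_set)
      null_counts[r, ] <- colSums(hits_pool[idx, , drop = FALSE])
    }
    p_emp <- vapply(colnames(null_counts), function(mid)
      (1 + sum(null_counts[, mid] >= obs[mid])) / (1 + n_resample),
      numeric(1))
    out[[k]] <- data.frame(
      motif_id = colnames(null_counts), pair_kind = k,
      observed = as.integer(obs), fraction = obs / n_set,
      null_mean = colMeans(null_counts),
      null_sd = apply(null_counts, 2, stats::sd),
      null_max = apply(null_counts, 2, max),
      p_emp = p_emp, significant = p_emp < alpha_motif,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
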