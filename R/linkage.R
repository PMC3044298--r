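# Per-term functional linkages (Fisher's exact test + FDR) and coregulation
# multigraphs. A linkage (A, B, term) says: the GO level-2 term is
# over-represented among the shared targets of enriched pair (A, B).

#' One-sided Fisher (hypergeometric tail) term enrichment
#'
#' Upper-tail probability `P(X >= x)` for the 2x2 table (in set / not) x
#' (has term / not), with `x` the number of set genes carrying the term.
#' Computed by direct log-space summation of hypergeometric point masses.
#'
#' @param shared Character vector of gene ids (subset of the universe; genes
#'   outside it are dropped as in [functional_profile()]).
#' @param term A level-2 term id.
#' @param ann A `Level2Annotation`.
#' @return p-value in (0, 1].
#' @export
fisher_term_enrichment <- function(shared, term, ann) {
  if (!term %in% ann$level2_terms)
    fc_domain_error("term %s is not a level-2 term", term)
  shared <- intersect(unique(as.character(shared)), ann$universe)
  N <- length(ann$universe)
  K <- ann$population_counts[[term]]
  n <- length(shared)
  x <- sum(ann$inst_matrix[shared, term])
  hyper_upper_tail(x, N, K, n)
}

# P(X >= x) for X ~ Hypergeometric(N, K, n), log-space point-mass summation
hyper_upper_tail <- function(x, N, K, n) {
  if (x <= 0) return(1)
  hi <- min(K, n)
  if (x > hi) return(0)
  i <- x:hi
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' Build functional linkages from enriched pairs
#'
#' For every function-enriched pair, tests each level-2 term with a nonzero
#' count in the shared-target set by [fisher_term_enrichment()], then applies
#' FDR control pooled over all (pair, term) tests (Benjamini-Liu step-down by
#' default, matching the construction of high-specificity networks; BH
#' available). Zero-count terms cannot be enriched and are not tested.
#'
#' @param enriched_pairs Result of [find_enriched_pairs()]; only rows with
#'   `enriched == TRUE` are used.
#' @param ann A `Level2Annotation`.
#' @param alpha FDR level (default 0.05).
#' @param method `"BL"` (default) or `"BH"`.
#' @param scope `"pooled"` (default) or `"by_pair"` correction.
#' @return data.frame: reg_a, reg_b, pair_kind, term, p_fisher, q, passed.
#' @export
build_linkages <- function(enriched_pairs, ann, alpha = 0.05,
                           method = c("BL", "BH"),
                           scope = c("pooled", "by_pair")) {
  method <- match.arg(method); scope <- match.arg(scope)
  shared_sets <- attr(enriched_pairs, "shared")
  tab <- enriched_pairs[enriched_pairs$enriched %in% TRUE, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    key <- paste(tab$reg_a[i], tab$reg_b[i], sep = "|")
    shared <- shared_sets[[key]]
    prof <- functional_profile(shared, ann)
    for (term in names(prof$counts)[prof$counts > 0]) {
      rows[[length(rows) + 1L]] <- data.frame(
        reg_a = tab$reg_a[i], reg_b = tab$reg_b[i],
        pair_kind = tab$pair_kind[i], term = term,
        p_fisher = fisher_term_enrichment(shared, term, ann),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(reg_a = character(0), reg_b = character(0),
                      pair_kind = character(0), term = character(0),
                      p_fisher = numeric(0), q = numeric(0),
                      passed = logical(0), stringsAsFactors = FALSE))
  lk <- do.call(rbind, rows)
  if (scope == "pooled") {
    adj <- fdr_adjust(lk$p_fisher, method = method, alpha = alpha)
    lk$q <- adj$adjusted; lk$passed <- adj$reject
  } else {
    lk$q <- NA_real_; lk$passed <- NA
    for (key in unique(paste(lk$reg_a, lk$reg_b))) {
      sel <- paste(lk$reg_a, lk$reg_b) == key
      adj <- fdr_adjust(lk$p_fisher[sel], method = method, alpha = alpha)
      lk$q[sel] <- adj$adjusted; lk$passed[sel] <- adj$reject
    }
  }
  lk
}

#' Construct a coregulation multigraph
#'
#' @param nodes data.frame with columns `id`, `kind`.
#' @param edges data.frame with columns `reg_a`, `reg_b`, `term` (undirected;
#'   parallel edges differ in term).
#' @return A `CoregulationNetwork`.
#' @export
coregulation_network <- function(nodes, edges) {
  missing <- setdiff(c(edges$reg_a, edges$reg_b), nodes$id)
  if (length(missing) > 0)
    fc_integrity_error("edge endpoints missing from node table: %s",
                       paste(missing, collapse = ", "))
  cp <- canonical_pair(edges$reg_a, edges$reg_b)
  edges$reg_a <- cp$a; edges$reg_b <- cp$b
  edges <- edges[order(edges$reg_a, edges$reg_b, edges$term), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "CoregulationNetwork")
}

#' @export
print.CoregulationNetwork <- function(x, ...) {
  cat(sprintf("<CoregulationNetwork: %d regulators, %d term-edges over %d pairs>\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(paste(x$edges$reg_a, x$edges$reg_b)))))
  invisible(x)
}

#' Assemble a coregulation network from passing linkages
#'
#' Nodes are the regulators incident to at least one passing linkage; each
#' passing (pair, term) becomes one undirected edge, so parallel edges encode
#' distinct biological processes shared by the pair.
#'
#' @param linkages Output of [build_linkages()]; only `passed == TRUE` rows
#'   are used.
#' @param regulators data.frame `id`, `kind` covering all regulators (e.g.
#'   `rbind(tf_net$regulators, mir_net$regulators)`).
#' @param kind_filter Optional pair kind (`"TF_TF"`, `"TF_MIR"`, `"MIR_MIR"`)
#'   to restrict the view.
#' @return A [coregulation_network()].
#' @export
build_coregulation_network <- function(linkages, regulators,
                                       kind_filter = NULL) {
  lk <- linkages[linkages$passed %in% TRUE, , drop = FALSE]
  if (!is.null(kind_filter))
    lk <- lk[lk$pair_kind == kind_filter, , drop = FALSE]
  ids <- unique(c(lk$reg_a, lk$reg_b))
  nodes <- regulators[regulators$id %in% ids, c("id", "kind"), drop = FALSE]
  unknown <- setdiff(ids, nodes$id)
  if (length(unknown) > 0)
    fc_integrity_error("linkage regulators missing from regulator table: %s",
                       paste(unknown, collapse = ", "))
  coregulation_network(nodes,
                       lk[, c("reg_a", "reg_b", "term"), drop = FALSE])
}

#' Summary statistics of a coregulation network
#'
#' `links_per_pair`: total term-edges divided by distinct connected pairs
#' (coregulation density). `edge_types_per_regulator`: mean over nodes of
#' the number of distinct terms on incident edges (functional diversity).
#' `largest_component`: node count of the largest connected component.
#' An empty network yields `NA` markers, not an error.
#'
#' @param net A `CoregulationNetwork`.
#' @return List with the three statistics plus `n_nodes`, `n_edges`.
#' @export
network_stats <- function(net) {
  n_edges <- nrow(net$edges); n_nodes <- nrow(net$nodes)
  if (n_edges == 0)
    return(list(links_per_pair = NA_real_,
                edge_types_per_regulator = NA_real_,
                largest_component = if (n_nodes > 0) 1L else NA_integer_,
                n_nodes = n_nodes, n_edges = n_edges))
  pair_key <- paste(net$edges$reg_a, net$edges$reg_b, sep = "|")
  links_per_pair <- n_edges / length(unique(pair_key))
  types <- vapply(net$nodes$id, function(v) {
    inc <- net$edges$reg_a == v | net$edges$reg_b == v
    length(unique(net$edges$term[inc]))
  }, integer(1))
  g <- igraph::graph_from_data_frame(
    unique(net$edges[, c("reg_a", "reg_b")]), directed = FALSE,
    vertices = net$nodes$id)
  comp <- igraph::components(g)
  list(links_per_pair = links_per_pair,
       edge_types_per_regulator = mean(types),
       largest_component = as.integer(max(comp$csize)),
       n_nodes = n_nodes, n_edges = n_edges)
}
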