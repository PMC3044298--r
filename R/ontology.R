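# GO level-2 biological-process profiles.
#
# "Level 2" here means: direct is_a children of the biological_process root
# (GO:0008150). A gene carries a level-2 term when any of its raw annotations
# equals the term or reaches it through is_a (and, by default, part_of)
# ancestor edges. Genes may carry several level-2 terms; the enrichment
# stage treats the resulting counts as annotation instances.

#' Level-2 terms of a BP ontology
#'
#' All terms reachable from the biological_process root by exactly one
#' `is_a` edge, in stable lexicographic order.
#'
#' @param dag A `go_dag` from [read_ontology()].
#' @return Character vector of term ids.
#' @export
level2_terms <- function(dag) {
  root <- "GO:0008150"
  if (!root %in% dag$terms$id)
    fc_integrity_error("biological_process root %s missing from DAG", root)
  sort(unique(dag$is_a$child[dag$is_a$parent == root]))
}

# ancestor closure per term over is_a (+ part_of when enabled), memoised
term_ancestors <- function(dag, use_part_of = TRUE) {
  edges <- dag$is_a
  if (use_part_of && nrow(dag$part_of) > 0) edges <- rbind(edges, dag$part_of)
  parents <- split(edges$parent, edges$child)
  memo <- new.env(parent = emptyenv())
  anc <- function(term) {
    if (!is.null(memo[[term]])) return(memo[[term]])
    memo[[term]] <- character(0)  # guard against part_of cycles
    p <- parents[[term]]
    res <- if (is.null(p)) character(0)
           else unique(c(p, unlist(lapply(p, anc), use.names = FALSE)))
    memo[[term]] <- res
    res
  }
  stats::setNames(lapply(dag$terms$id, anc), dag$terms$id)
}

UNANNOTATED <- "__unannotated__"

#' Map raw annotations to level-2 BP terms
#'
#' @param annotations data.frame with columns `gene`, `term` (raw GO ids, as
#'   returned by [read_ontology()]).
#' @param dag A `go_dag`.
#' @param universe Gene universe for population counts; defaults to all genes
#'   in `annotations`. Genes in the universe with no level-2 term count as
#'   unannotated (they stay in the permutation background).
#' @param use_part_of Propagate across `part_of` edges too (default TRUE).
#' @return A `Level2Annotation`: list with `level2_terms`, `gene_terms`
#'   (named list gene -> level-2 term subset), `population_counts` (M_k),
#'   `unannotated_count`, `universe`, and `inst_matrix`, a genes x (K+1)
#'   0/1 matrix whose last column is the unannotated pseudo-category.
#' @export
map_to_level2 <- function(annotations, dag, universe = NULL,
                          use_part_of = TRUE) {
  l2 <- level2_terms(dag)
  universe <- sort(unique(c(universe, annotations$gene)))
  anc <- term_ancestors(dag, use_part_of)
  # raw term -> level-2 terms it maps to (itself if level-2, plus ancestors)
  raw_terms <- unique(annotations$term)
  raw_to_l2 <- lapply(raw_terms, function(t) intersect(c(t, anc[[t]]), l2))
  names(raw_to_l2) <- raw_terms
  mapped <- data.frame(
    gene = rep(annotations$gene,
               lengths(raw_to_l2[annotations$term])),
    term = unlist(raw_to_l2[annotations$term], use.names = FALSE),
    stringsAsFactors = FALSE)
  mapped <- unique(mapped)
  gene_terms <- stats::setNames(vector("list", length(universe)), universe)
  if (nrow(mapped) > 0) {
    by_gene <- split(mapped$term, mapped$gene)
    gene_terms[names(by_gene)] <- by_gene
  }
  gene_terms <- lapply(gene_terms, function(x) sort(x %||% character(0)))
  K <- length(l2)
  inst <- matrix(0, nrow = length(universe), ncol = K + 1L,
                 dimnames = list(universe, c(l2, UNANNOTATED)))
  if (nrow(mapped) > 0)
    inst[cbind(match(mapped$gene, universe), match(mapped$term, l2))] <- 1
  inst[rowSums(inst[, seq_len(K), drop = FALSE]) == 0, K + 1L] <- 1
  pop <- colSums(inst[, seq_len(K), drop = FALSE])
  structure(list(
    level2_terms = l2,
    gene_terms = gene_terms,
    population_counts = stats::setNames(as.integer(pop), l2),
    unannotated_count = as.integer(sum(inst[, K + 1L])),
    universe = universe,
    inst_matrix = inst
  ), class = "Level2Annotation")
}

#' @export
print.Level2Annotation <- function(x, ...) {
  cat(sprintf("<Level2Annotation: %d level-2 terms, %d genes (%d unannotated)>\n",
              length(x$level2_terms), length(x$universe),
              x$unannotated_count))
  invisible(x)
}

#' Functional profile of a gene set
#'
#' Per-level-2-term annotation counts c_k for a gene set -- the functional
#' fingerprint scored by the enrichment stage. Genes outside the annotation
#' universe are dropped with a logged count.
#'
#' @param genes Character vector of gene ids.
#' @param ann A `Level2Annotation`.
#' @return A `FunctionalProfile`: list with `counts` (named, over
#'   level-2 terms), `set_size`, `unannotated`, `n_dropped`.
#' @export
functional_profile <- function(genes, ann) {
  genes <- unique(as.character(genes))
  known <- genes %in% ann$universe
  if (any(!known))
    fc_log("functional_profile: dropped %d gene(s) outside universe",
           sum(!known))
  genes <- genes[known]
  K <- length(ann$level2_terms)
  if (length(genes) == 0) {
    cnt <- stats::setNames(integer(K), ann$level2_terms)
    return(structure(list(counts = cnt, set_size = 0L, unannotated = 0L,
                          n_dropped = sum(!known)),
                     class = "FunctionalProfile"))
  }
  sub <- ann$inst_matrix[genes, , drop = FALSE]
  cs <- colSums(sub)
  structure(list(
    counts = stats::setNames(as.integer(cs[seq_len(K)]), ann$level2_terms),
    set_size = length(genes),
    unannotated = as.integer(cs[K + 1L]),
    n_dropped = sum(!known)
  ), class = "FunctionalProfile")
}

#' @export
print.FunctionalProfile <- function(x, ...) {
  cat(sprintf("<FunctionalProfile: n=%d genes, %d annotation instances, %d unannotated>\n",
              x$set_size, sum(x$counts), x$unannotated))
  invisible(x)
}

#' Export a Level2Annotation as an audit TSV
#' @param ann A `Level2Annotation`.
#' @param path Output TSV (gene, pipe-joined level-2 terms).
#' @export
write_level2_tsv <- function(ann, path) {
  fc_write_tsv(data.frame(
    gene = names(ann$gene_terms),
    level2_terms = vapply(ann$gene_terms, paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE), path)
}
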