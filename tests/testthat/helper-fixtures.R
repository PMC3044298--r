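# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; nothing binary is read from disk.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# --- tiny ontology -----------------------------------------------------------

# root BP + K level-2 children T01..TK + one grandchild per level-2 term,
# written as OBO 1.2
write_toy_obo_file <- function(path, K = 3, part_of_child = FALSE) {
  l2 <- sprintf("GO:10%05d", seq_len(K))
  lines <- c("format-version: 1.2", "",
             "[Term]", "id: GO:0008150", "name: biological_process",
             "namespace: biological_process", "")
  for (i in seq_len(K)) {
    lines <- c(lines, "[Term]", paste0("id: ", l2[i]),
               sprintf("name: process %d", i),
               "namespace: biological_process",
               "is_a: GO:0008150 ! biological_process", "")
  }
  gc1 <- sprintf("GO:20%05d", seq_len(K))
  for (i in seq_len(K)) {
    rel <- if (part_of_child && i == 1)
      paste0("relationship: part_of ", l2[i])
    else paste0("is_a: ", l2[i])
    lines <- c(lines, "[Term]", paste0("id: ", gc1[i]),
               sprintf("name: subprocess %d", i),
               "namespace: biological_process", rel, "")
  }
  writeLines(lines, path)
  list(root = "GO:0008150", l2 = l2, children = gc1)
}

toy_dag <- function(K = 3, part_of_child = FALSE) {
  path <- tempfile(fileext = ".obo")
  info <- write_toy_obo_file(path, K, part_of_child)
  dag <- quiet(funcoreg:::build_bp_dag(funcoreg:::parse_obo(path)))
  list(dag = dag, info = info, path = path)
}

# in-code Level2Annotation from a named list gene -> level-2 term subset
ann_from_list <- function(gene_terms, l2, extra_unannotated = 0) {
  genes <- names(gene_terms)
  if (extra_unannotated > 0) {
    extra <- sprintf("u%03d", seq_len(extra_unannotated))
    gene_terms <- c(gene_terms,
                    stats::setNames(rep(list(character(0)), extra_unannotated),
                                    extra))
    genes <- names(gene_terms)
  }
  df <- data.frame(
    gene = rep(genes, lengths(gene_terms)),
    term = unlist(gene_terms, use.names = FALSE),
    stringsAsFactors = FALSE)
  td <- toy_dag(K = length(l2))
  # rename the toy level-2 ids to the requested ones via direct construction
  stopifnot(length(l2) <= length(td$info$l2))
  map <- stats::setNames(td$info$l2[seq_along(l2)], l2)
  df$term <- unname(map[df$term])
  ann <- map_to_level2(df, td$dag, universe = genes)
  # restore requested term names for readable assertions
  names(ann$population_counts) <- l2
  ann$level2_terms <- l2
  colnames(ann$inst_matrix) <- c(l2, funcoreg:::UNANNOTATED)
  ann$gene_terms <- lapply(ann$gene_terms, function(t)
    unname(stats::setNames(l2, td$info$l2[seq_along(l2)])[t]))
  ann
}

# uniformly random annotation universe over K terms (0..3 terms per gene)
random_ann <- function(n_genes, K, seed) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  l2 <- sprintf("T%02d", seq_len(K))
  gene_terms <- lapply(genes, function(g) sample(l2, sample(0:3, 1)))
  names(gene_terms) <- genes
  ann_from_list(gene_terms, l2)
}

# --- tiny regulator networks -------------------------------------------------

make_net <- function(kind, targets) {
  regs <- lapply(names(targets), function(i) regulator(i, kind))
  edges <- data.frame(
    regulator_id = rep(names(targets), lengths(targets)),
    target = unlist(targets, use.names = FALSE),
    stringsAsFactors = FALSE)
  regulator_target_network(regs, edges)
}

make_pair <- function(a, b, kind = "TF_MIR", shared = character(0)) {
  cp <- funcoreg:::canonical_pair(a, b)
  structure(list(reg_a = cp$a, reg_b = cp$b, pair_kind = kind,
                 shared = shared), class = "CoregulationPair")
}

# --- independent oracles -----------------------------------------------------

# exact-arithmetic multivariate hypergeometric log-likelihood: plain choose()
# products (exact in double for small arguments), log taken at the end
mvh_oracle <- function(cc, MM) {
  log(prod(choose(MM, cc)) / choose(sum(MM), sum(cc)))
}

# all compositions of n into K non-negative parts
compositions <- function(n, K) {
  if (K == 1) return(matrix(n, ncol = 1))
  out <- list()
  for (i in 0:n) {
    rest <- compositions(n - i, K - 1)
    out[[length(out) + 1]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}

# brute-force pair enumeration by double loop over regulators
enumerate_pairs_oracle <- function(tf_targets, mir_targets, min_shared) {
  all_t <- c(tf_targets, mir_targets)
  kind <- c(rep("TF", length(tf_targets)),
            rep("MIRNA_FAMILY", length(mir_targets)))
  names(kind) <- names(all_t)
  ids <- names(all_t)
  out <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    shared <- intersect(all_t[[ids[i]]], all_t[[ids[j]]])
    if (length(shared) >= min_shared) {
      cp <- funcoreg:::canonical_pair(ids[i], ids[j])
      out[[length(out) + 1]] <- list(
        reg_a = cp$a, reg_b = cp$b,
        pair_kind = funcoreg:::pair_kind_of(kind[[ids[i]]], kind[[ids[j]]]),
        n_shared = length(shared))
    }
  }
  out
}

# brute-force motif counting by explicit loops over candidate regulators
count_motifs_oracle <- function(pairs, edges) {
  ek <- paste(edges$source, edges$dest)
  has <- function(x, y) paste(x, y) %in% ek
  parents <- function(v) edges$source[edges$dest == v]
  kind_of <- stats::setNames(edges$source_kind, edges$source)
  counts <- c(FFL_BIDIR = 0, FFL_UNIDIR = 0, COMMON_UP_TF = 0,
              COMMON_UP_TF_AND_MIR = 0, UPSTREAM_CROSSTALK = 0)
  for (p in pairs) {
    a <- p$reg_a; b <- p$reg_b
    ab <- has(a, b); ba <- has(b, a)
    if (ab && ba) counts["FFL_BIDIR"] <- counts["FFL_BIDIR"] + 1
    if (xor(ab, ba)) counts["FFL_UNIDIR"] <- counts["FFL_UNIDIR"] + 1
    pa <- setdiff(parents(a), c(a, b)); pb <- setdiff(parents(b), c(a, b))
    common <- intersect(pa, pb)
    ctf <- any(kind_of[common] == "TF")
    cmir <- any(kind_of[common] == "MIRNA_FAMILY")
    if (ctf) counts["COMMON_UP_TF"] <- counts["COMMON_UP_TF"] + 1
    if (ctf && cmir)
      counts["COMMON_UP_TF_AND_MIR"] <- counts["COMMON_UP_TF_AND_MIR"] + 1
    cross <- length(common) > 0
    if (!cross) for (x in pa) for (y in pb)
      if (has(x, y) || has(y, x)) { cross <- TRUE; break }
    if (cross) counts["UPSTREAM_CROSSTALK"] <- counts["UPSTREAM_CROSSTALK"] + 1
  }
  counts
}

random_upstream <- function(n_reg, n_edge, seed) {
  set.seed(seed)
  ids <- c(sprintf("T%02d", seq_len(ceiling(n_reg / 2))),
           sprintf("F%02d", seq_len(floor(n_reg / 2))))
  src <- sample(ids, n_edge, replace = TRUE)
  dst <- sample(ids, n_edge, replace = TRUE)
  keep <- src != dst
  edges <- unique(data.frame(
    source = src[keep], dest = dst[keep],
    source_kind = ifelse(startsWith(src[keep], "T"), "TF", "MIRNA_FAMILY"),
    stringsAsFactors = FALSE))
  structure(list(edges = edges), class = "UpstreamNetwork")
}
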