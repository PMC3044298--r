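# Synthetic regulatory-system generator with planted ground truth.
#
# The generator states a small world with the statistical structure the
# pipeline assumes: a toy BP ontology (root, level-2 children, one deeper
# child per term to exercise ancestor propagation), genes annotated to 0-3
# level-2 terms, TF and miRNA-family target sets from independent edge coin
# flips, planted pairs whose shared targets are drawn coherently from a
# single level-2 term's gene pool, an upstream network that can carry a
# planted common-upstream-TF motif, and paired normal/tumour expression with
# planted correlation in one condition and decorrelation in the other.

#' Synthetic-scenario configuration
#'
#' Defaults are the package's stated default scenario: 2000 genes (the last
#' `n_tfs` of which are the TF genes themselves), 20 TFs, 20 miRNA families,
#' 12 level-2 terms of ~250 genes each, 10 planted term-coherent pairs with
#' 8 shared targets, background edge probability 0.02 (~40 targets per
#' regulator), and expression with correlation 0.7 planted in normal samples
#' and 0 in tumour samples, 16 samples per condition over 8 tissues.
#'
#' @param ... Overrides for any field.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_genes = 2000L, n_tfs = 20L, n_families = 20L,
    n_level2_terms = 12L, genes_per_term = 250L,
    n_planted_pairs = 10L, planted_overlap = 8L,
    background_edge_prob = 0.02,
    upstream_edge_prob = 0.05,
    plant_common_up_tf = FALSE,
    n_hosts = 8L,
    planted_rho_normal = 0.7, planted_rho_tumor = 0.0,
    n_samples_per_condition = 16L,
    member_noise_sd = 0.15,
    rng_seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    fc_config_error("unknown config field(s): %s",
                    paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "SyntheticConfig")
}

validate_synthetic_config <- function(cfg) {
  counts <- c("n_genes", "n_tfs", "n_families", "n_level2_terms",
              "genes_per_term", "n_samples_per_condition")
  for (f in counts) if (cfg[[f]] < 1)
    fc_config_error("%s must be positive", f)
  if (cfg$n_planted_pairs > min(cfg$n_tfs, cfg$n_families))
    fc_config_error("n_planted_pairs exceeds available TF/family count")
  if (cfg$background_edge_prob < 0 || cfg$background_edge_prob > 1)
    fc_config_error("background_edge_prob must be a probability")
  if (abs(cfg$planted_rho_normal) > 1 || abs(cfg$planted_rho_tumor) > 1)
    fc_config_error("planted correlations must lie in [-1, 1]")
  invisible(cfg)
}

synthetic_term_ids <- function(K) sprintf("GO:10%05d", seq_len(K))

write_toy_obo <- function(path, l2_ids, child_ids) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", "ontology: funcoreg-synthetic", ""),
             con)
  stanza <- function(id, name, isa = NULL) {
    writeLines(c("[Term]", paste0("id: ", id), paste0("name: ", name),
                 "namespace: biological_process",
                 if (!is.null(isa)) paste0("is_a: ", isa), ""), con)
  }
  stanza("GO:0008150", "biological_process")
  for (i in seq_along(l2_ids))
    stanza(l2_ids[i], sprintf("synthetic process %d", i), "GO:0008150")
  for (i in seq_along(child_ids))
    stanza(child_ids[i], sprintf("synthetic subprocess %d", i), l2_ids[i])
}

#' Generate a synthetic regulatory system bundle
#'
#' Writes, under `dir`: `ontology.obo`, `annotations.tsv` (gene TAB term;
#' a fixed fraction of instances point at a deeper child term so level-2
#' mapping is exercised), `tf_targets.tsv`, `mirna_targets.tsv` (mature
#' level), `family_map.tsv` (matures and precursors), `host_map.tsv`,
#' `tf_mir_edges.tsv` (predicted TF->family regulation), and `truth.json`.
#' Planted pair i couples TF i with family i through `planted_overlap`
#' shared targets drawn from one level-2 term's gene pool; background edges
#' are independent coin flips. Deterministic given `cfg$rng_seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created).
#' @return A `SyntheticTruth` list: `planted_pairs`, `planted_motifs`,
#'   `planted_correlations` data.frames, plus `files` (named paths).
#' @export
simulate_regulatory_system <- function(cfg, dir) {
  validate_synthetic_config(cfg)
  set.seed(cfg$rng_seed)
  K <- cfg$n_level2_terms
  l2 <- synthetic_term_ids(K)
  children <- sprintf("GO:20%05d", seq_len(K))
  tf_ids <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  fam_ids <- sprintf("FAM%02d", seq_len(cfg$n_families))
  genes <- c(sprintf("g%05d", seq_len(cfg$n_genes - cfg$n_tfs)), tf_ids)

  # annotations: n_terms per gene ~ Binomial(3, p) so that the mean term
  # size matches genes_per_term
  p_term <- min(1, K * cfg$genes_per_term / (3 * cfg$n_genes))
  n_terms <- stats::rbinom(length(genes), 3, p_term)
  ann <- data.frame(gene = rep(genes, n_terms),
                    term = unlist(lapply(n_terms, function(k)
                      if (k == 0) character(0) else sample(l2, k)),
                      use.names = FALSE),
                    stringsAsFactors = FALSE)
  term_pool <- split(ann$gene, ann$term)
  # feasibility before any file is written
  if (cfg$n_planted_pairs > 0) {
    planted_terms <- l2[(seq_len(cfg$n_planted_pairs) - 1L) %% K + 1L]
    small <- vapply(term_pool[planted_terms], length, integer(1)) <
      cfg$planted_overlap
    if (any(small))
      fc_config_error("term %s has fewer than planted_overlap=%d genes",
                      planted_terms[which(small)[1]], cfg$planted_overlap)
  } else planted_terms <- character(0)
  # a quarter of instances are recorded at the deeper child term
  deep <- stats::runif(nrow(ann)) < 0.25
  ann$term[deep] <- children[match(ann$term[deep], l2)]

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    obo = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    tf_targets = file.path(dir, "tf_targets.tsv"),
    mirna_targets = file.path(dir, "mirna_targets.tsv"),
    family_map = file.path(dir, "family_map.tsv"),
    host_map = file.path(dir, "host_map.tsv"),
    tf_mir_edges = file.path(dir, "tf_mir_edges.tsv"),
    truth = file.path(dir, "truth.json"))
  write_toy_obo(files["obo"], l2, children)
  ann <- ann[order(ann$gene, ann$term), ]
  writeLines(c("#gene\tterm",
               sprintf("%s\t%s", ann$gene, ann$term)), files["annotations"])

  # background target edges: independent coin flips
  flip_targets <- function(reg_ids) {
    hits <- which(matrix(stats::runif(length(reg_ids) * length(genes)) <
                           cfg$background_edge_prob,
                         nrow = length(reg_ids)), arr.ind = TRUE)
    data.frame(reg = reg_ids[hits[, 1]], target = genes[hits[, 2]],
               stringsAsFactors = FALSE)
  }
  tf_edges <- flip_targets(tf_ids)
  fam_edges <- flip_targets(fam_ids)

  # planted pairs: TF i -- FAM i share planted_overlap genes of one term
  planted <- list()
  for (i in seq_len(cfg$n_planted_pairs)) {
    pool <- setdiff(term_pool[[planted_terms[i]]], c(tf_ids[i]))
    shared <- sample(pool, cfg$planted_overlap)
    tf_edges <- rbind(tf_edges,
                      data.frame(reg = tf_ids[i], target = shared,
                                 stringsAsFactors = FALSE))
    fam_edges <- rbind(fam_edges,
                       data.frame(reg = fam_ids[i], target = shared,
                                  stringsAsFactors = FALSE))
    cp <- canonical_pair(tf_ids[i], fam_ids[i])
    planted[[i]] <- data.frame(reg_a = cp$a, reg_b = cp$b,
                               planted_term = planted_terms[i],
                               stringsAsFactors = FALSE)
  }
  planted_pairs <- if (length(planted) > 0) do.call(rbind, planted)
    else data.frame(reg_a = character(0), reg_b = character(0),
                    planted_term = character(0), stringsAsFactors = FALSE)

  # families: 1-4 mature members; family edges distributed over members
  n_members <- sample(1:4, cfg$n_families, replace = TRUE)
  fam_members <- lapply(seq_len(cfg$n_families), function(i)
    sprintf("miR-%02d%s", i, letters[seq_len(n_members[i])]))
  names(fam_members) <- fam_ids
  family_map <- data.frame(
    mature = unlist(fam_members, use.names = FALSE),
    family = rep(fam_ids, n_members), stringsAsFactors = FALSE)
  fam_edges <- unique(fam_edges)
  member_of_edge <- vapply(fam_edges$reg, function(f)
    sample(fam_members[[f]], 1), character(1))
  mirna_edges <- data.frame(mature = member_of_edge,
                            target = fam_edges$target,
                            stringsAsFactors = FALSE)

  # hosts: precursors embedded in ordinary genes
  precursors <- sprintf("pre-mir-%02d", seq_len(cfg$n_hosts))
  host_genes <- sample(setdiff(genes, tf_ids), cfg$n_hosts)
  prec_family <- sample(fam_ids, cfg$n_hosts, replace = TRUE)
  host_map <- data.frame(precursor = precursors, host_gene = host_genes,
                         stringsAsFactors = FALSE)
  family_map <- rbind(family_map,
                      data.frame(mature = precursors, family = prec_family,
                                 stringsAsFactors = FALSE))

  # predicted TF->family regulation, plus planted common-upstream-TF motif
  grid <- expand.grid(source = tf_ids, dest = fam_ids,
                      stringsAsFactors = FALSE)
  tf_mir <- grid[stats::runif(nrow(grid)) < cfg$upstream_edge_prob, ,
                 drop = FALSE]
  planted_motifs <- data.frame(reg_a = character(0), reg_b = character(0),
                               motif_id = character(0),
                               stringsAsFactors = FALSE)
  if (cfg$plant_common_up_tf && cfg$n_planted_pairs > 0) {
    # one dedicated upstream TF per planted pair, so the motif does not leak
    # to background pairs built from members of different planted pairs
    ups <- sprintf("TFUP%02d", seq_len(cfg$n_planted_pairs))
    tf_edges <- rbind(tf_edges,
                      data.frame(reg = ups,
                                 target = tf_ids[seq_len(cfg$n_planted_pairs)],
                                 stringsAsFactors = FALSE))
    tf_mir <- rbind(tf_mir,
                    data.frame(source = ups,
                               dest = fam_ids[seq_len(cfg$n_planted_pairs)],
                               stringsAsFactors = FALSE))
    planted_motifs <- data.frame(reg_a = planted_pairs$reg_a,
                                 reg_b = planted_pairs$reg_b,
                                 motif_id = "COMMON_UP_TF",
                                 stringsAsFactors = FALSE)
  }

  tf_tab <- unique(data.frame(regulator_id = tf_edges$reg,
                              regulator_kind = "TF",
                              target_gene = tf_edges$target,
                              stringsAsFactors = FALSE))
  tf_tab <- tf_tab[order(tf_tab$regulator_id, tf_tab$target_gene), ]
  fc_write_tsv(tf_tab, files["tf_targets"])
  mirna_edges <- unique(mirna_edges[order(mirna_edges$mature,
                                          mirna_edges$target), ])
  fc_write_tsv(mirna_edges, files["mirna_targets"])
  fc_write_tsv(family_map[order(family_map$mature), ], files["family_map"])
  fc_write_tsv(host_map[order(host_map$precursor), ], files["host_map"])
  tf_mir <- unique(tf_mir[order(tf_mir$source, tf_mir$dest), ])
  fc_write_tsv(tf_mir, files["tf_mir_edges"])

  planted_correlations <- if (nrow(planted_pairs) > 0)
    data.frame(planted_pairs[, c("reg_a", "reg_b")],
               rho_normal = cfg$planted_rho_normal,
               rho_tumor = cfg$planted_rho_tumor,
               stringsAsFactors = FALSE)
  else data.frame(reg_a = character(0), reg_b = character(0),
                  rho_normal = numeric(0), rho_tumor = numeric(0))
  truth <- structure(list(planted_pairs = planted_pairs,
                          planted_motifs = planted_motifs,
                          planted_correlations = planted_correlations,
                          config = unclass(cfg), files = files,
                          tf_ids = tf_ids, fam_ids = fam_ids,
                          fam_members = fam_members),
                     class = "SyntheticTruth")
  jsonlite::write_json(
    list(planted_pairs = planted_pairs, planted_motifs = planted_motifs,
         planted_correlations = planted_correlations,
         config = unclass(cfg)),
    files["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # post-write assertion: file-level shared-target counts hold
  if (nrow(planted_pairs) > 0) {
    tf_chk <- split(tf_tab$target_gene, tf_tab$regulator_id)
    fam_chk <- split(mirna_edges$target,
                     stats::setNames(family_map$family,
                                     family_map$mature)[mirna_edges$mature])
    for (i in seq_len(cfg$n_planted_pairs)) {
      ov <- length(intersect(tf_chk[[tf_ids[i]]], fam_chk[[fam_ids[i]]]))
      if (ov < cfg$planted_overlap)
        fc_integrity_error("planted pair %s/%s wrote only %d shared targets",
                           tf_ids[i], fam_ids[i], ov)
    }
  }
  truth
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("<SyntheticTruth: %d planted pairs, %d planted motifs, bundle at %s>\n",
              nrow(x$planted_pairs), nrow(x$planted_motifs),
              dirname(x$files[["truth"]])))
  invisible(x)
}

#' Generate paired normal/tumour expression for a synthetic system
#'
#' TF genes get one mRNA row each; mature miRNAs get one row each. For every
#' planted pair, the TF profile and the family's latent profile are drawn
#' from a bivariate normal with correlation `planted_rho_normal` in normal
#' samples and `planted_rho_tumor` in tumour samples (Cholesky
#' construction); family members are the latent profile plus small
#' independent noise, so the member mean tracks the latent signal. All other
#' regulators are independent standard normals. Eight tissue labels are
#' cycled across samples (decorative: no tissue effect is simulated).
#'
#' @param truth A `SyntheticTruth` from [simulate_regulatory_system()].
#' @param dir Output directory; writes `expression_matrix.tsv` and
#'   `sample_meta.tsv`.
#' @param rng_seed Seed (defaults to `config$rng_seed + 1` so the regulatory
#'   and expression streams are independent).
#' @return Named character vector of the two file paths.
#' @export
simulate_expression <- function(truth, dir,
                                rng_seed = truth$config$rng_seed + 1L) {
  cfg <- truth$config
  if (cfg$n_samples_per_condition < 3)
    fc_config_error("n_samples_per_condition must be >= 3")
  set.seed(rng_seed)
  ns <- cfg$n_samples_per_condition
  tissues <- c("colon", "pancreas", "kidney", "bladder", "prostate",
               "uterus", "lung", "breast")
  meta <- data.frame(
    sample_id = c(sprintf("N%02d", seq_len(ns)), sprintf("T%02d", seq_len(ns))),
    tissue = rep(tissues, length.out = 2 * ns),
    condition = rep(c("normal", "tumor"), each = ns),
    stringsAsFactors = FALSE)

  matures <- unlist(truth$fam_members, use.names = FALSE)
  entities <- c(truth$tf_ids, matures)
  kind <- c(rep("mRNA", length(truth$tf_ids)),
            rep("mature_miRNA", length(matures)))
  vals <- matrix(stats::rnorm(length(entities) * 2 * ns),
                 nrow = length(entities),
                 dimnames = list(entities, meta$sample_id))

  fam_of_pair <- function(a, b) if (startsWith(a, "FAM")) c(a, b) else c(b, a)
  for (i in seq_len(nrow(truth$planted_correlations))) {
    pc <- truth$planted_correlations[i, ]
    fb <- fam_of_pair(pc$reg_a, pc$reg_b)
    fam <- fb[1]; tf <- fb[2]
    for (cond in c("normal", "tumor")) {
      rho <- if (cond == "normal") pc$rho_normal else pc$rho_tumor
      cols <- which(meta$condition == cond)
      x <- stats::rnorm(length(cols))
      z <- rho * x + sqrt(1 - rho^2) * stats::rnorm(length(cols))
      vals[tf, cols] <- x
      for (m in truth$fam_members[[fam]])
        vals[m, cols] <- z + stats::rnorm(length(cols),
                                          sd = cfg$member_noise_sd)
    }
  }

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_path <- file.path(dir, "expression_matrix.tsv")
  meta_path <- file.path(dir, "sample_meta.tsv")
  df <- data.frame(entity_id = entities, entity_kind = kind,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(vals))) df[[meta$sample_id[j]]] <-
    sprintf("%.6f", vals[, j])
  fc_write_tsv(df, mat_path)
  fc_write_tsv(meta, meta_path)
  c(matrix = mat_path, meta = meta_path)
}
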