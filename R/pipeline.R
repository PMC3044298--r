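# End-to-end orchestration: pairs -> enrichment -> linkages -> networks ->
# motifs -> expression, with a run manifest and per-stage seeds derived from
# one global seed (so skipping a stage does not shift downstream streams).

#' Read a pipeline configuration file
#'
#' Flat key: value text (DCF). Unknown keys are rejected. See
#' [default_pipeline_config()] for keys and defaults.
#'
#' @param path Config file path.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) fc_io_error("config not found: %s", path)
  raw <- as.list(read.dcf(path)[1, ])
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    fc_config_error("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (k in names(raw)) {
    v <- raw[[k]]
    cfg[[k]] <- if (is.numeric(defaults[[k]])) as.numeric(v)
    else if (is.logical(defaults[[k]])) as.logical(v)
    else if (k == "skip") strsplit(v, ",\\s*")[[1]]
    else v
  }
  cfg
}

#' Default pipeline configuration
#'
#' Analysis defaults follow the published protocol: 10000 permutations,
#' FDR 0.05, 10000 motif resamples, motif alpha 0.001; `min_shared = 3` is a
#' package choice (settable to 1). `synthetic = TRUE` generates the default
#' synthetic bundle instead of reading input paths.
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    synthetic = TRUE,
    tf_targets = "", mirna_targets = "", family_map = "", host_map = "",
    tf_mir_edges = "", obo = "", annotations = "", annot_format = "TSV2",
    expression_matrix = "", sample_meta = "",
    permutations = 10000, resamples = 10000,
    fdr = 0.05, motif_alpha = 0.001, min_shared = 3,
    seed = 1, fdr_method = "BH", linkage_fdr_method = "BL",
    plant_common_up_tf = FALSE,
    out_dir = "funcoreg_out",
    skip = character(0))
}

stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 0L, enrich = 1L, motifs = 2L, expression = 3L)
  as.integer((as.integer(seed) * 7L + offsets[[stage]]) %% .Machine$integer.max)
}

#' Run the whole coregulation pipeline
#'
#' Executes pairs -> enrichment -> linkages -> networks -> motifs ->
#' expression in order, writing one TSV per stage plus GraphML networks, a
#' deterministic `manifest.json` (config, input digests, seeds, package
#' version, record counts) and a separate `timings.json` (wall-clock, not
#' part of the determinism contract). Stages named in `config$skip`
#' (`"linkages"`, `"network"`, `"motifs"`, `"expression"`) are skipped.
#'
#' @param config A config list, or path to a DCF config file.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  timings <- list(); t_stage <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  if (isTRUE(cfg$synthetic) || identical(cfg$synthetic, "TRUE")) {
    scfg <- synthetic_config(rng_seed = stage_seed(cfg$seed, "simulate"),
                             plant_common_up_tf = isTRUE(cfg$plant_common_up_tf))
    truth <- t_stage(simulate_regulatory_system(scfg, file.path(out, "bundle")),
                     "simulate")
    expr_files <- simulate_expression(truth, file.path(out, "bundle"))
    f <- truth$files
    cfg$tf_targets <- unname(f["tf_targets"])
    cfg$mirna_targets <- unname(f["mirna_targets"])
    cfg$family_map <- unname(f["family_map"])
    cfg$host_map <- unname(f["host_map"])
    cfg$tf_mir_edges <- unname(f["tf_mir_edges"])
    cfg$obo <- unname(f["obo"]); cfg$annotations <- unname(f["annotations"])
    cfg$annot_format <- "TSV2"
    cfg$expression_matrix <- unname(expr_files["matrix"])
    cfg$sample_meta <- unname(expr_files["meta"])
  }

  inputs <- c(cfg$tf_targets, cfg$mirna_targets, cfg$family_map,
              cfg$host_map, cfg$tf_mir_edges, cfg$obo, cfg$annotations,
              cfg$expression_matrix, cfg$sample_meta)
  inputs <- inputs[nzchar(inputs)]
  counts <- list()

  tf_net <- read_regulator_targets(cfg$tf_targets)
  mirna_raw <- fc_read_tsv(cfg$mirna_targets, c("mature", "target"))
  family_map <- fc_read_tsv(cfg$family_map, c("mature", "family"))
  mir_net <- collapse_families(mirna_raw, family_map)
  onto <- read_ontology(cfg$obo, cfg$annotations, cfg$annot_format)
  ann <- map_to_level2(onto$annotations, onto$dag,
                       universe = union(tf_net$universe, mir_net$universe))
  counts$tfs <- nrow(tf_net$regulators)
  counts$families <- nrow(mir_net$regulators)
  counts$genes <- length(ann$universe)

  pairs <- enumerate_pairs(tf_net, mir_net, min_shared = cfg$min_shared)
  counts$pairs <- length(pairs)

  enriched_tab <- t_stage(
    find_enriched_pairs(pairs, ann, n_perm = cfg$permutations,
                        alpha = cfg$fdr,
                        rng_seed = stage_seed(cfg$seed, "enrich"),
                        fdr_method = cfg$fdr_method),
    "enrich")
  fc_write_tsv(format_num_cols(enriched_tab), file.path(out, "pairs.tsv"))
  counts$enriched_pairs <- sum(enriched_tab$enriched)
  regs <- rbind(tf_net$regulators, mir_net$regulators)
  enr_keys <- paste(enriched_tab$reg_a, enriched_tab$reg_b, sep = "|")[
    enriched_tab$enriched]
  pair_keys <- vapply(pairs, function(p) paste(p$reg_a, p$reg_b, sep = "|"),
                      character(1))
  enr_pairs <- pairs[pair_keys %in% enr_keys]

  linkages <- NULL
  if (!"linkages" %in% cfg$skip) {
    term_names <- stats::setNames(onto$dag$terms$name, onto$dag$terms$id)
    linkages <- t_stage(
      build_linkages(enriched_tab, ann, alpha = cfg$fdr,
                     method = cfg$linkage_fdr_method),
      "linkages")
    lk_out <- linkages
    lk_out$term_name <- unname(term_names[lk_out$term])
    fc_write_tsv(format_num_cols(lk_out), file.path(out, "linkages.tsv"))
    counts$linkages <- sum(linkages$passed)
  }

  if (!"network" %in% cfg$skip && !is.null(linkages)) {
    net <- build_coregulation_network(linkages, regs)
    write_network(net, file.path(out, "network.graphml"), "GraphML")
    write_network(net, file.path(out, "network.sif"), "SIF")
    stats_all <- lapply(c(ALL = NA, TF_TF = "TF_TF", TF_MIR = "TF_MIR",
                          MIR_MIR = "MIR_MIR"), function(k) {
      n <- if (is.na(k)) net else build_coregulation_network(linkages, regs, k)
      network_stats(n)
    })
    jsonlite::write_json(stats_all, file.path(out, "network_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    counts$network_nodes <- nrow(net$nodes)
    counts$network_edges <- nrow(net$edges)
  }

  if (!"motifs" %in% cfg$skip && length(enr_pairs) > 0) {
    tf_mir <- fc_read_tsv(cfg$tf_mir_edges, c("source", "dest"))
    host_map <- fc_read_tsv(cfg$host_map, c("precursor", "host_gene"))
    host_edges <- propagate_host_regulation(tf_net, host_map, family_map)
    upstream <- build_upstream_network(tf_net, tf_mir, host_edges, mir_net)
    motifs <- t_stage(
      motif_significance(enr_pairs, pairs, upstream,
                         n_resample = cfg$resamples,
                         rng_seed = stage_seed(cfg$seed, "motifs"),
                         alpha_motif = cfg$motif_alpha),
      "motifs")
    fc_write_tsv(format_num_cols(motifs), file.path(out, "motifs.tsv"))
    counts$significant_motifs <- sum(motifs$significant)
  }

  if (!"expression" %in% cfg$skip && nzchar(cfg$expression_matrix) &&
      length(enr_pairs) > 0) {
    expr <- read_expression(cfg$expression_matrix, cfg$sample_meta)
    idx <- regulator_index(tf_net, mir_net)
    summaries <- list()
    for (cond in c("normal", "tumor"))
      summaries[[cond]] <- correlation_distributions(
        enr_pairs, pairs, expr, cond, idx)
    rows <- list(); vals <- list()
    for (cond in names(summaries)) for (k in names(summaries[[cond]])) {
      s <- summaries[[cond]][[k]]
      rows[[paste(cond, k)]] <- data.frame(
        pair_kind = k, condition = cond,
        n_foreground = length(s$foreground_r),
        n_background = length(s$background_r),
        mean_fg_r = mean(s$foreground_r), mean_bg_r = mean(s$background_r),
        ks_stat = s$ks_stat, ks_p = s$ks_p,
        insufficient_n = s$insufficient_n,
        n_pairs_skipped = s$n_pairs_skipped, stringsAsFactors = FALSE)
      vals[[paste(cond, k)]] <- data.frame(
        pair_kind = k, condition = cond,
        group = c(rep("foreground", length(s$foreground_r)),
                  rep("background", length(s$background_r))),
        r = c(s$foreground_r, s$background_r), stringsAsFactors = FALSE)
    }
    fc_write_tsv(format_num_cols(do.call(rbind, rows)),
                 file.path(out, "correlation_summary.tsv"))
    fc_write_tsv(format_num_cols(do.call(rbind, vals)),
                 file.path(out, "correlation_values.tsv"))
    counts$correlation_groups <- length(rows)
  }

  manifest <- list(
    tool = "funcoreg",
    version = as.character(utils::packageVersion("funcoreg")),
    config = cfg[order(names(cfg))],
    seeds = list(global = cfg$seed,
                 simulate = stage_seed(cfg$seed, "simulate"),
                 enrich = stage_seed(cfg$seed, "enrich"),
                 motifs = stage_seed(cfg$seed, "motifs"),
                 expression = stage_seed(cfg$seed, "expression")),
    input_digests = as.list(tools::md5sum(inputs)),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(timings, file.path(out, "timings.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

# fixed-width numeric formatting so identical runs write identical bytes
format_num_cols <- function(df) {
  for (j in seq_along(df)) if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
    df[[j]] <- sprintf("%.10g", df[[j]])
  df
}

#' Command-line entry point
#'
#' `funcoreg_cli(c("run", "--config", "cfg.dcf"))` etc. Subcommands:
#' `simulate` (write a synthetic bundle) and `run` (full pipeline). Flags
#' override config keys: `--permutations`, `--resamples`, `--fdr`,
#' `--motif-alpha`, `--min-shared`, `--seed`, `--fdr-method`, `--out-dir`,
#' `--skip`. Used by `inst/cli/funcoreg.R`.
#'
#' @param args Character vector of CLI arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
funcoreg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: funcoreg.R <simulate|run> [--config FILE] [--seed N] [--out-dir DIR]\n",
        "       [--permutations N] [--resamples N] [--fdr X] [--motif-alpha X]\n",
        "       [--min-shared N] [--fdr-method BH|BL] [--skip stages]\n")
    return(invisible(1L))
  }
  sub <- args[1]; rest <- args[-1]
  cfg <- default_pipeline_config()
  flag_key <- c("--config" = "config", "--seed" = "seed",
                "--out-dir" = "out_dir", "--permutations" = "permutations",
                "--resamples" = "resamples", "--fdr" = "fdr",
                "--motif-alpha" = "motif_alpha", "--min-shared" = "min_shared",
                "--fdr-method" = "fdr_method", "--skip" = "skip")
  i <- 1
  while (i <= length(rest)) {
    key <- flag_key[rest[i]]
    if (is.na(key)) fc_config_error("unknown flag: %s", rest[i])
    val <- rest[i + 1]
    if (key == "config") cfg <- utils::modifyList(cfg, read_pipeline_config(val))
    else if (key == "skip") cfg$skip <- strsplit(val, ",")[[1]]
    else cfg[[key]] <- if (is.numeric(cfg[[key]])) as.numeric(val) else val
    i <- i + 2
  }
  stage_skips <- list(
    pairs = c("linkages", "network", "motifs", "expression"),
    enrich = c("linkages", "network", "motifs", "expression"),
    linkages = c("network", "motifs", "expression"),
    network = c("motifs", "expression"),
    motifs = c("linkages", "network", "expression"),
    expression = c("linkages", "network", "motifs"))
  if (sub == "simulate") {
    truth <- simulate_regulatory_system(
      synthetic_config(rng_seed = stage_seed(cfg$seed, "simulate")),
      file.path(cfg$out_dir, "bundle"))
    simulate_expression(truth, file.path(cfg$out_dir, "bundle"))
  } else if (sub == "run") {
    run_pipeline(cfg)
  } else if (sub %in% names(stage_skips)) {
    cfg$skip <- union(cfg$skip, stage_skips[[sub]])
    run_pipeline(cfg)
  } else {
    fc_config_error("unknown subcommand: %s", sub)
  }
  invisible(0L)
}
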