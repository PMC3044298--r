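#' Construct a regulator
#'
#' A regulator is either a transcription factor (`"TF"`, whose single member
#' is its own gene symbol) or a miRNA family (`"MIRNA_FAMILY"`, whose members
#' are mature miRNA names sharing a seed).
#'
#' @param id Non-empty regulator identifier (opaque, case-sensitive).
#' @param kind One of `"TF"`, `"MIRNA_FAMILY"`.
#' @param members Character vector of member identifiers; defaults to `id`.
#' @return An object of class `Regulator`.
#' @export
regulator <- function(id, kind = c("TF", "MIRNA_FAMILY"), members = id) {
  kind <- match.arg(kind)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    fc_domain_error("regulator id must be a non-empty string")
  members <- unique(as.character(members))
  if (length(members) == 0L)
    fc_domain_error("regulator '%s' must have at least one member", id)
  structure(list(id = id, kind = kind, members = members),
            class = "Regulator")
}

#' @export
print.Regulator <- function(x, ...) {
  cat(sprintf("<Regulator %s [%s], %d member(s)>\n",
              x$id, x$kind, length(x$members)))
  invisible(x)
}

#' Construct a regulator-target network
#'
#' Bipartite network of regulator -> target-gene edges, the adjacency
#' structure underlying coregulation-pair enumeration. Duplicate edges are
#' collapsed; all edge regulators must be registered; every target is added
#' to the gene universe.
#'
#' @param regulators List of [regulator()] objects.
#' @param edges data.frame with columns `regulator_id`, `target`.
#' @param universe Optional character vector of gene ids; targets are always
#'   included.
#' @return An object of class `RegulatorTargetNetwork` with fields
#'   `regulators` (data.frame id/kind), `members` (named list),
#'   `edges` (data.frame), `universe` (character).
#' @export
regulator_target_network <- function(regulators, edges,
                                     universe = character(0)) {
  stopifnot(is.list(regulators))
  ids <- vapply(regulators, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    fc_integrity_error("duplicate regulator ids: %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", "))
  edges <- unique(data.frame(regulator_id = as.character(edges$regulator_id),
                             target = as.character(edges$target),
                             stringsAsFactors = FALSE))
  unknown <- setdiff(edges$regulator_id, ids)
  if (length(unknown) > 0)
    fc_integrity_error("edges reference unregistered regulator(s): %s",
                       paste(unknown, collapse = ", "))
  structure(list(
    regulators = data.frame(
      id = ids,
      kind = vapply(regulators, function(r) r$kind, character(1)),
      stringsAsFactors = FALSE),
    members = stats::setNames(lapply(regulators, function(r) r$members), ids),
    edges = edges,
    universe = sort(unique(c(as.character(universe), edges$target)))
  ), class = "RegulatorTargetNetwork")
}

#' @export
print.RegulatorTargetNetwork <- function(x, ...) {
  cat(sprintf("<RegulatorTargetNetwork: %d regulators (%d TF, %d miRNA family), %d edges, %d genes>\n",
              nrow(x$regulators), sum(x$regulators$kind == "TF"),
              sum(x$regulators$kind == "MIRNA_FAMILY"),
              nrow(x$edges), length(x$universe)))
  invisible(x)
}

#' Target set of one regulator
#' @param net A `RegulatorTargetNetwork`.
#' @param id Regulator id.
#' @return Character vector of target gene ids.
#' @export
targets_of <- function(net, id) {
  net$edges$target[net$edges$regulator_id == id]
}

#' Read regulator-target edges from TSV
#'
#' Expects header columns `regulator_id`, `target_gene` and a kind column
#' (default `regulator_kind`) with tokens `TF` or `MIRNA_FAMILY`
#' (case-insensitive). Duplicate rows are collapsed silently; the collapse
#' count is logged along with regulator/edge/target tallies.
#'
#' @param path TSV file path ('#' comment lines ignored).
#' @param kind_column Name of the column holding the regulator kind.
#' @return A [regulator_target_network()].
#' @export
read_regulator_targets <- function(path, kind_column = "regulator_kind") {
  df <- fc_read_tsv(path, required_cols = c("regulator_id", kind_column,
                                            "target_gene"))
  kind_raw <- toupper(df[[kind_column]])
  ok <- kind_raw %in% c("TF", "MIRNA_FAMILY")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    fc_format_error("%s: unknown regulator kind '%s' at data line %d",
                    path, df[[kind_column]][bad], bad)
  }
  if (nrow(df) == 0) {
    net <- regulator_target_network(list(),
                                    data.frame(regulator_id = character(0),
                                               target = character(0)))
    fc_log("read %s: 0 regulators, 0 edges, 0 targets", path)
    return(net)
  }
  kind_by_reg <- tapply(kind_raw, df$regulator_id, function(k) {
    u <- unique(k)
    if (length(u) > 1)
      fc_format_error("regulator appears with conflicting kinds: %s",
                      paste(u, collapse = "/"))
    u
  })
  regs <- lapply(names(kind_by_reg),
                 function(i) regulator(i, kind_by_reg[[i]]))
  n_raw <- nrow(df)
  net <- regulator_target_network(
    regs, data.frame(regulator_id = df$regulator_id, target = df$target_gene))
  fc_log("read %s: %d regulators, %d edges (%d duplicate rows collapsed), %d targets",
         path, nrow(net$regulators), nrow(net$edges),
         n_raw - nrow(net$edges), length(unique(net$edges$target)))
  net
}

# ---------------------------------------------------------------------------
# Ontology: minimal OBO 1.2 parser (id/name/namespace/is_a/part_of/obsolete)
# restricted to the biological_process namespace.

parse_obo <- function(path) {
  if (!file.exists(path)) fc_io_error("file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  term_starts <- which(lines == "[Term]")
  terms <- list(); n_obsolete <- 0L
  bounds <- c(term_starts, length(lines) + 1L)
  for (i in seq_along(term_starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    get1 <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      if (length(v) == 0) return(NA_character_)
      sub("\\s*!.*$", "", substring(v[1], nchar(key) + 3L))
    }
    getall <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      trimws(sub("\\s*!.*$", "", substring(v, nchar(key) + 3L)))
    }
    id <- get1("id")
    if (is.na(id)) next
    if (identical(get1("is_obsolete"), "true")) { n_obsolete <- n_obsolete + 1L; next }
    rel <- getall("relationship")
    part_of <- sub("^part_of\\s+", "", rel[startsWith(rel, "part_of ")])
    terms[[length(terms) + 1L]] <- list(
      id = trimws(id), name = get1("name") %||% NA_character_,
      namespace = get1("namespace"),
      is_a = getall("is_a"), part_of = part_of)
  }
  list(terms = terms, n_obsolete = n_obsolete)
}

build_bp_dag <- function(parsed) {
  keep <- Filter(function(t) identical(t$namespace, "biological_process"),
                 parsed$terms)
  ids <- vapply(keep, `[[`, character(1), "id")
  edge_df <- function(field) {
    do.call(rbind, c(list(data.frame(child = character(0), parent = character(0),
                                     stringsAsFactors = FALSE)),
      lapply(keep, function(t) {
        p <- intersect(t[[field]], ids)  # edges out of namespace dropped
        if (length(p) == 0) return(NULL)
        data.frame(child = t$id, parent = p, stringsAsFactors = FALSE)
      })))
  }
  is_a <- edge_df("is_a"); part_of <- edge_df("part_of")
  # cycle check on is_a via iterative leaf-stripping (Kahn)
  if (nrow(is_a) > 0) {
    remaining <- is_a
    repeat {
      sinks <- setdiff(remaining$parent, remaining$child)
      drop <- remaining$parent %in% sinks
      if (!any(drop)) {
        if (nrow(remaining) > 0)
          fc_integrity_error("is_a graph contains a cycle involving: %s",
                             paste(utils::head(unique(remaining$child), 5),
                                   collapse = ", "))
        break
      }
      remaining <- remaining[!drop, , drop = FALSE]
      if (nrow(remaining) == 0) break
    }
  }
  roots <- setdiff(ids, is_a$child)
  structure(list(
    terms = data.frame(
      id = ids,
      name = vapply(keep, function(t) t$name %||% NA_character_, character(1)),
      stringsAsFactors = FALSE),
    is_a = is_a, part_of = part_of,
    root = if ("GO:0008150" %in% ids) "GO:0008150"
           else if (length(roots) == 1) roots else roots
  ), class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag: %d biological_process terms, %d is_a edges, %d part_of edges, root %s>\n",
              nrow(x$terms), nrow(x$is_a), nrow(x$part_of),
              paste(x$root, collapse = ",")))
  invisible(x)
}

read_gaf <- function(path, exclude_evidence = character(0)) {
  if (!file.exists(path)) fc_io_error("file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0)
    return(data.frame(gene = character(0), term = character(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 9
  if (any(short))
    fc_format_error("%s: GAF row with < 9 columns at data line %d",
                    path, which(short)[1])
  gene <- vapply(fields, `[[`, character(1), 3)   # DB Object Symbol
  qual <- vapply(fields, `[[`, character(1), 4)
  term <- vapply(fields, `[[`, character(1), 5)
  evid <- vapply(fields, `[[`, character(1), 7)
  aspect <- vapply(fields, `[[`, character(1), 9)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual) & aspect == "P" &
    !(evid %in% exclude_evidence)
  data.frame(gene = gene[keep], term = term[keep], stringsAsFactors = FALSE)
}

#' Read an ontology and gene annotations
#'
#' Parses an OBO 1.2 file, restricts it to the `biological_process`
#' namespace (keeping `is_a` and `part_of` edges separately, dropping
#' obsolete terms with a warning count), and reads gene -> GO-term
#' annotations from either a GAF 2.x file (rows with a `NOT` qualifier or a
#' non-`P` aspect are excluded) or a two-column `gene<TAB>term` TSV.
#' Annotations to terms absent from the DAG are skipped and counted.
#'
#' @param obo_path OBO 1.2 file.
#' @param annot_path Annotation file.
#' @param annot_format `"GAF"` or `"TSV2"`.
#' @param exclude_evidence GAF evidence codes to drop (default none: all
#'   evidence including IEA is accepted).
#' @return List with elements `dag` (class `go_dag`), `annotations`
#'   (data.frame gene/term, deduplicated), `n_obsolete_dropped`,
#'   `n_unknown_term_skipped`.
#' @export
read_ontology <- function(obo_path, annot_path,
                          annot_format = c("GAF", "TSV2"),
                          exclude_evidence = character(0)) {
  annot_format <- match.arg(annot_format)
  parsed <- parse_obo(obo_path)
  dag <- build_bp_dag(parsed)
  if (parsed$n_obsolete > 0)
    warning(sprintf("dropped %d obsolete term(s) from %s",
                    parsed$n_obsolete, obo_path), call. = FALSE)
  ann <- if (annot_format == "GAF") {
    read_gaf(annot_path, exclude_evidence)
  } else {
    lines <- readLines(annot_path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(fields, length, integer(1)) < 2
    if (any(bad))
      fc_format_error("%s: two-column TSV row with < 2 fields at line %d",
                      annot_path, which(bad)[1])
    data.frame(gene = vapply(fields, `[[`, character(1), 1),
               term = vapply(fields, `[[`, character(1), 2),
               stringsAsFactors = FALSE)
  }
  known <- ann$term %in% dag$terms$id
  n_unknown <- sum(!known)
  if (n_unknown > 0)
    warning(sprintf("skipped %d annotation(s) to terms absent from the BP DAG",
                    n_unknown), call. = FALSE)
  ann <- unique(ann[known, , drop = FALSE])
  rownames(ann) <- NULL
  fc_log("ontology %s: %d BP terms; annotations %s: %d gene-term pairs (%d unknown-term rows skipped)",
         obo_path, nrow(dag$terms), annot_path, nrow(ann), n_unknown)
  list(dag = dag, annotations = ann,
       n_obsolete_dropped = parsed$n_obsolete,
       n_unknown_term_skipped = n_unknown)
}

# ---------------------------------------------------------------------------
# Expression

#' Read an expression matrix with sample metadata
#'
#' The matrix TSV has one row per entity: a leading `entity_id` column, an
#' optional `entity_kind` column (`mRNA` or `mature_miRNA`), then one numeric
#' column per sample (log-intensity scale). The metadata TSV has columns
#' `sample_id`, `tissue`, `condition` (`normal`/`tumor`). Samples are matched
#' by id; a matrix sample absent from the metadata is an integrity error.
#'
#' @param matrix_path Matrix TSV.
#' @param meta_path Metadata TSV.
#' @param na_token String representing missing values (default `"NA"`).
#' @return An `ExpressionDataset`: list with `values` (numeric matrix,
#'   entities x samples), `sample_meta` (data.frame), `entity_kind` (named
#'   character), `n_missing` (NA cell count).
#' @export
read_expression <- function(matrix_path, meta_path, na_token = "NA") {
  df <- fc_read_tsv(matrix_path, required_cols = "entity_id")
  meta <- fc_read_tsv(meta_path,
                      required_cols = c("sample_id", "tissue", "condition"))
  if (!all(meta$condition %in% c("normal", "tumor")))
    fc_format_error("%s: condition must be 'normal' or 'tumor'", meta_path)
  if (anyDuplicated(df$entity_id))
    fc_integrity_error("%s: duplicated entity ids: %s", matrix_path,
                       paste(unique(df$entity_id[duplicated(df$entity_id)]),
                             collapse = ", "))
  kind <- if ("entity_kind" %in% names(df)) df$entity_kind else
    rep(NA_character_, nrow(df))
  sample_cols <- setdiff(names(df), c("entity_id", "entity_kind"))
  unmatched <- setdiff(sample_cols, meta$sample_id)
  if (length(unmatched) > 0)
    fc_integrity_error("samples in matrix absent from metadata: %s",
                       paste(unmatched, collapse = ", "))
  meta <- meta[match(sample_cols, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  vals <- as.matrix(df[, sample_cols, drop = FALSE])
  vals[vals == na_token] <- NA
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- is.na(vals) & as.matrix(df[, sample_cols, drop = FALSE]) != na_token
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    fc_format_error("%s: non-numeric cell '%s' at entity %s, sample %s",
                    matrix_path,
                    df[idx[1], sample_cols[idx[2]]],
                    df$entity_id[idx[1]], sample_cols[idx[2]])
  }
  rownames(vals) <- df$entity_id
  n_missing <- sum(is.na(vals))
  fc_log("read %s: %d entities x %d samples, %d missing cells",
         matrix_path, nrow(vals), ncol(vals), n_missing)
  structure(list(values = vals, sample_meta = meta,
                 entity_kind = stats::setNames(kind, df$entity_id),
                 n_missing = n_missing),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("<ExpressionDataset: %d entities x %d samples (%d normal, %d tumor), %d missing>\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_meta$condition == "normal"),
              sum(x$sample_meta$condition == "tumor"), x$n_missing))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Network export / import

#' Write a coregulation network
#'
#' GraphML keeps parallel edges and records the GO term in a `go_term` edge
#' attribute plus the regulator kind in a `kind` node attribute; SIF uses the
#' GO term id as the interaction type; TSV is the raw edge table.
#'
#' @param net A `CoregulationNetwork` (see [build_coregulation_network()]).
#' @param path Output file path.
#' @param format `"GraphML"`, `"SIF"` or `"TSV"`.
#' @export
write_network <- function(net, path, format = c("GraphML", "SIF", "TSV")) {
  format <- match.arg(format)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "TSV") {
    fc_write_tsv(net$edges, path)
  } else if (format == "SIF") {
    lines <- if (nrow(net$edges) > 0)
      sprintf("%s\t%s\t%s", net$edges$reg_a, net$edges$term, net$edges$reg_b)
    else character(0)
    writeLines(lines, path, useBytes = TRUE)
  } else {
    doc <- xml2::xml_new_root(
      "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
    key1 <- xml2::xml_add_child(doc, "key", id = "d0", `for` = "node",
                                attr.name = "kind", attr.type = "string")
    key2 <- xml2::xml_add_child(doc, "key", id = "d1", `for` = "edge",
                                attr.name = "go_term", attr.type = "string")
    g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
    for (i in seq_len(nrow(net$nodes))) {
      nd <- xml2::xml_add_child(g, "node", id = net$nodes$id[i])
      d <- xml2::xml_add_child(nd, "data", key = "d0")
      xml2::xml_text(d) <- net$nodes$kind[i]
    }
    for (i in seq_len(nrow(net$edges))) {
      e <- xml2::xml_add_child(g, "edge",
                               source = net$edges$reg_a[i],
                               target = net$edges$reg_b[i])
      d <- xml2::xml_add_child(e, "data", key = "d1")
      xml2::xml_text(d) <- net$edges$term[i]
    }
    tryCatch(xml2::write_xml(doc, path),
             error = function(e) fc_io_error("cannot write %s: %s",
                                             path, conditionMessage(e)))
  }
  invisible(path)
}

#' Read a GraphML coregulation network written by [write_network()]
#' @param path GraphML file.
#' @return A `CoregulationNetwork`.
#' @export
read_network_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  node_df <- data.frame(
    id = xml2::xml_attr(nodes, "id"),
    kind = vapply(nodes, function(n)
      xml2::xml_text(xml2::xml_find_first(n, "./g:data[@key='d0']", ns)),
      character(1)),
    stringsAsFactors = FALSE)
  edge_df <- data.frame(
    reg_a = xml2::xml_attr(edges, "source"),
    reg_b = xml2::xml_attr(edges, "target"),
    term = vapply(edges, function(e)
      xml2::xml_text(xml2::xml_find_first(e, "./g:data[@key='d1']", ns)),
      character(1)),
    stringsAsFactors = FALSE)
  coregulation_network(node_df, edge_df)
}
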