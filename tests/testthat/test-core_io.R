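test_that("read_regulator_targets collapses duplicates and tallies counts", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("regulator_id\tregulator_kind\ttarget_gene",
               "A\tTF\tg1", "A\tTF\tg2", "A\tTF\tg1"), path)
  net <- quiet(read_regulator_targets(path))
  expect_equal(nrow(net$edges), 2)
  expect_equal(sort(targets_of(net, "A")), c("g1", "g2"))

  # header-only file -> empty network
  writeLines("regulator_id\tregulator_kind\ttarget_gene", path)
  net0 <- quiet(read_regulator_targets(path))
  expect_equal(nrow(net0$edges), 0)
  expect_equal(nrow(net0$regulators), 0)
})

test_that("read_regulator_targets counts match an independent line tally", {
  # toy fixture: 12 distinct edges over 3 TFs and 2 families
  rows <- c(sprintf("T%d\tTF\tg%d", rep(1:3, each = 3), c(1:3, 2:4, 3:5)),
            sprintf("F%d\tMIRNA_FAMILY\tg%d", rep(1:2, c(2, 1)), c(1, 6, 7)))
  path <- tempfile(fileext = ".tsv")
  writeLines(c("regulator_id\tregulator_kind\ttarget_gene", rows), path)
  net <- quiet(read_regulator_targets(path))
  # independent tally straight off the text lines
  fields <- strsplit(rows, "\t")
  expect_equal(nrow(net$edges), length(unique(rows)))
  expect_equal(nrow(net$regulators),
               length(unique(vapply(fields, `[[`, "", 1))))
  expect_equal(length(unique(net$edges$target)),
               length(unique(vapply(fields, `[[`, "", 3))))
})

test_that("read_regulator_targets reports format errors precisely", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("regulator_id\ttarget_gene", "A\tg1"), path)
  expect_error(read_regulator_targets(path),
               "regulator_kind", class = "funcoreg_format_error")
  writeLines(c("regulator_id\tregulator_kind\ttarget_gene",
               "A\tTF\tg1", "B\tPROTEIN\tg2"), path)
  expect_error(read_regulator_targets(path),
               "line 2", class = "funcoreg_format_error")
})

test_that("OBO parsing restricts to BP, drops obsolete, keeps part_of apart", {
  path <- tempfile(fileext = ".obo")
  td <- write_toy_obo_file(path, K = 2, part_of_child = TRUE)
  # append an obsolete term and a non-BP term
  cat("[Term]\nid: GO:9999999\nname: gone\nnamespace: biological_process\nis_obsolete: true\n\n",
      "[Term]\nid: GO:5555555\nname: mf\nnamespace: molecular_function\n\n",
      file = path, append = TRUE)
  ann_path <- tempfile(fileext = ".tsv")
  writeLines(sprintf("gene1\t%s", td$l2[1]), ann_path)
  expect_warning(res <- suppressMessages(read_ontology(path, ann_path, "TSV2")),
                 "obsolete")
  expect_equal(nrow(res$dag$terms), 5)  # root + 2 level-2 + 2 children
  expect_false("GO:5555555" %in% res$dag$terms$id)
  expect_equal(nrow(res$dag$part_of), 1)
  expect_equal(res$dag$part_of$child, td$children[1])
})

test_that("GAF reading drops NOT rows and unknown terms with counts", {
  obo <- tempfile(fileext = ".obo")
  td <- write_toy_obo_file(obo, K = 2)
  gaf <- tempfile(fileext = ".gaf")
  row <- function(gene, qual, term, aspect = "P")
    paste("DB", paste0("id_", gene), gene, qual, term, "PMID:1", "IEA", "",
          aspect, sep = "\t")
  writeLines(c("!gaf-version: 2.1",
               row("gA", "", td$l2[1]),
               row("gB", "NOT", td$l2[1]),
               row("gC", "", "GO:7777777"),
               row("gD", "", td$l2[2], aspect = "F")), gaf)
  res <- quiet(suppressWarnings(read_ontology(obo, gaf, "GAF")))
  expect_equal(res$annotations$gene, "gA")
  expect_equal(res$n_unknown_term_skipped, 1)
})

test_that("cyclic is_a graphs are rejected", {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000001", "name: a",
               "namespace: biological_process", "is_a: GO:0000002", "",
               "[Term]", "id: GO:0000002", "name: b",
               "namespace: biological_process", "is_a: GO:0000001", ""),
             path)
  expect_error(funcoreg:::build_bp_dag(funcoreg:::parse_obo(path)),
               "cycle", class = "funcoreg_integrity_error")
})

test_that("read_expression matches samples, counts NAs, rejects orphans", {
  mat <- tempfile(fileext = ".tsv"); meta <- tempfile(fileext = ".tsv")
  writeLines(c("entity_id\ts1\ts2\ts3\ts4\ts5\ts6",
               sprintf("e%d\t%s", 1:4,
                       apply(matrix(round(rnorm(24), 3), 4), 1, paste,
                             collapse = "\t"))), mat)
  writeLines(c("sample_id\ttissue\tcondition",
               sprintf("s%d\tcolon\t%s", 1:6,
                       rep(c("normal", "tumor"), each = 3))), meta)
  ds <- quiet(read_expression(mat, meta))
  expect_equal(ncol(ds$values), 6)
  expect_equal(nrow(ds$values), 4)

  # NA counting
  writeLines(c("entity_id\ts1\ts2", "e1\tNA\t1.0", "e2\tNA\tNA"), mat)
  writeLines(c("sample_id\ttissue\tcondition",
               "s1\tcolon\tnormal", "s2\tcolon\ttumor"), meta)
  expect_equal(quiet(read_expression(mat, meta))$n_missing, 3)

  # sample present in matrix, absent from metadata
  writeLines(c("entity_id\ts1\tsX", "e1\t1\t2"), mat)
  expect_error(quiet(read_expression(mat, meta)), "sX",
               class = "funcoreg_integrity_error")

  # non-numeric cell other than NA token
  writeLines(c("entity_id\ts1\ts2", "e1\t1.0\tabc"), mat)
  expect_error(quiet(read_expression(mat, meta)), "abc",
               class = "funcoreg_format_error")
})

test_that("GraphML round trip preserves nodes, edge multiset, attributes", {
  nodes <- data.frame(id = c("A", "B"), kind = c("TF", "MIRNA_FAMILY"))
  edges <- data.frame(reg_a = "A", reg_b = "B",
                      term = c("GO:1", "GO:2", "GO:1"))
  net <- coregulation_network(nodes, edges)
  path <- tempfile(fileext = ".graphml")
  write_network(net, path, "GraphML")
  doc <- xml2::read_xml(path)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")), 3)
  back <- read_network_graphml(path)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)

  # empty network -> valid document round trip
  empty <- coregulation_network(data.frame(id = character(0),
                                           kind = character(0)),
                                data.frame(reg_a = character(0),
                                           reg_b = character(0),
                                           term = character(0)))
  write_network(empty, path, "GraphML")
  expect_equal(nrow(read_network_graphml(path)$edges), 0)
})

test_that("SIF export uses the term as interaction type", {
  net <- coregulation_network(
    data.frame(id = c("A", "B"), kind = "TF"),
    data.frame(reg_a = "A", reg_b = "B", term = "GO:1"))
  path <- tempfile(fileext = ".sif")
  write_network(net, path, "SIF")
  expect_equal(readLines(path), "A\tGO:1\tB")
})

test_that("readers are pure functions of file content", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("regulator_id\tregulator_kind\ttarget_gene",
               "A\tTF\tg1", "B\tMIRNA_FAMILY\tg2"), path)
  expect_identical(quiet(read_regulator_targets(path)),
                   quiet(read_regulator_targets(path)))
})
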