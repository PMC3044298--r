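test_that("pearson_cc matches closed forms and flags degenerate input", {
  expect_equal(pearson_cc(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_cc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 3, 2)), 0.5, tolerance = 1e-12)
  expect_true(is.na(pearson_cc(c(1, 2, 3), c(5, 5, 5))))   # constant
  expect_true(is.na(pearson_cc(c(1, 2, NA), c(1, 2, 3))))  # < 3 complete
  expect_error(pearson_cc(1:3, 1:4), class = "funcoreg_domain_error")
})

test_that("pearson_cc equals direct summation on random vectors", {
  set.seed(50)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson_cc(x, y), stats::cor(x, y), tolerance = 1e-12)
  }
  # pairwise deletion agrees with cor(use = "pairwise")
  x <- c(1, NA, 3, 4, 5, 2); y <- c(2, 1, NA, 3, 8, 0)
  expect_equal(pearson_cc(x, y),
               stats::cor(x, y, use = "pairwise.complete.obs"),
               tolerance = 1e-12)
})

make_expr <- function(values, meta) {
  structure(list(values = values, sample_meta = meta,
                 entity_kind = stats::setNames(rep("mRNA", nrow(values)),
                                               rownames(values)),
                 n_missing = sum(is.na(values))),
            class = "ExpressionDataset")
}

test_that("regulator_expression aggregates family members and subsets condition", {
  meta <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                     tissue = "colon",
                     condition = c("normal", "normal", "tumor", "tumor"))
  vals <- rbind(TF1 = c(1, 2, 3, 4), a = c(2, 4, 6, 8), b = c(4, 6, 8, 10),
                c = c(1, NA, 1, 1))
  colnames(vals) <- meta$sample_id
  expr <- make_expr(vals, meta)
  tf <- regulator("TF1", "TF")
  expect_equal(unname(regulator_expression(tf, expr, "normal")), c(1, 2))
  fam <- regulator("F1", "MIRNA_FAMILY", members = c("a", "b"))
  expect_equal(unname(regulator_expression(fam, expr, "normal")), c(3, 5))
  solo <- regulator("F2", "MIRNA_FAMILY", members = c("b", "zz"))
  expect_equal(unname(regulator_expression(solo, expr, "tumor")), c(8, 10))
  # NA cells are ignored within the member mean
  fam3 <- regulator("F3", "MIRNA_FAMILY", members = c("a", "b", "c"))
  expect_equal(unname(regulator_expression(fam3, expr, "normal")),
               c(mean(c(2, 4, 1)), mean(c(4, 6))))
  # no member measured -> lookup miss
  expect_null(regulator_expression(
    regulator("F4", "MIRNA_FAMILY", members = "nope"), expr, "normal"))
})

test_that("relabelling samples consistently leaves correlations unchanged", {
  set.seed(51)
  meta <- data.frame(sample_id = sprintf("s%d", 1:10), tissue = "lung",
                     condition = rep(c("normal", "tumor"), 5))
  vals <- matrix(rnorm(30), nrow = 3,
                 dimnames = list(c("TF1", "TF2", "a"), meta$sample_id))
  expr <- make_expr(vals, meta)
  perm <- sample(10)
  expr2 <- make_expr(vals[, perm], meta[perm, ])
  for (cond in c("normal", "tumor")) {
    r1 <- pearson_cc(regulator_expression(regulator("TF1", "TF"), expr, cond),
                     regulator_expression(regulator("TF2", "TF"), expr, cond))
    x2 <- regulator_expression(regulator("TF1", "TF"), expr2, cond)
    y2 <- regulator_expression(regulator("TF2", "TF"), expr2, cond)
    expect_equal(pearson_cc(x2, y2), r1, tolerance = 1e-12)
  }
})

test_that("correlation_distributions contrasts planted against background", {
  set.seed(52)
  ns <- 16
  meta <- data.frame(sample_id = sprintf("s%d", seq_len(2 * ns)),
                     tissue = rep(c("colon", "lung"), ns),
                     condition = rep(c("normal", "tumor"), each = ns))
  n_pairs <- 40
  ids_tf <- sprintf("TF%02d", seq_len(2 * n_pairs))
  vals <- matrix(rnorm(2 * n_pairs * 2 * ns), nrow = 2 * n_pairs,
                 dimnames = list(ids_tf, meta$sample_id))
  # plant rho=0.8 in normal for the first n_pairs pairs (TF(2i-1), TF(2i))
  for (i in seq_len(n_pairs / 2)) {
    a <- 2 * i - 1; b <- 2 * i
    cols <- which(meta$condition == "normal")
    vals[b, cols] <- 0.8 * vals[a, cols] + sqrt(1 - 0.64) * rnorm(ns)
  }
  expr <- make_expr(vals, meta)
  idx <- stats::setNames(lapply(ids_tf, regulator, kind = "TF"), ids_tf)
  fg <- lapply(seq_len(n_pairs / 2), function(i)
    make_pair(ids_tf[2 * i - 1], ids_tf[2 * i], kind = "TF_TF"))
  bg <- lapply(seq_len(n_pairs / 2), function(i)
    make_pair(ids_tf[2 * i - 1], ids_tf[2 * (n_pairs / 2) + 2 * i],
              kind = "TF_TF"))
  res_n <- correlation_distributions(fg, c(fg, bg), expr, "normal", idx)
  res_t <- correlation_distributions(fg, c(fg, bg), expr, "tumor", idx)
  expect_lt(res_n$TF_TF$ks_p, 0.01)
  expect_gt(res_t$TF_TF$ks_p, 0.05)
  expect_gt(mean(res_n$TF_TF$foreground_r), 0.5)
  # background excludes the enriched pairs themselves
  expect_equal(length(res_n$TF_TF$background_r), length(bg))
})

test_that("degenerate and null correlation cases behave", {
  set.seed(53)
  meta <- data.frame(sample_id = sprintf("s%d", 1:12), tissue = "colon",
                     condition = rep(c("normal", "tumor"), each = 6))
  ids <- sprintf("TF%02d", 1:20)
  vals <- matrix(rnorm(20 * 12), nrow = 20,
                 dimnames = list(ids, meta$sample_id))
  expr <- make_expr(vals, meta)
  idx <- stats::setNames(lapply(ids, regulator, kind = "TF"), ids)
  all_pairs <- lapply(seq(1, 19, 2), function(i)
    make_pair(ids[i], ids[i + 1], kind = "TF_TF"))
  # same generator on both sides -> KS not significant
  res <- correlation_distributions(all_pairs[1:5], all_pairs, expr,
                                   "normal", idx)
  expect_gt(res$TF_TF$ks_p, 0.05)
  # single foreground pair -> flagged insufficient, no KS
  res1 <- correlation_distributions(all_pairs[1], all_pairs, expr,
                                    "normal", idx)
  expect_true(res1$TF_TF$insufficient_n)
  expect_true(is.na(res1$TF_TF$ks_stat))
  expect_length(res1$TF_TF$foreground_r, 1)
  # unresolvable foreground -> domain error naming the cause
  ghost <- list(make_pair("GH1", "GH2", kind = "TF_TF"))
  expect_error(correlation_distributions(ghost, all_pairs, expr,
                                         "normal", idx),
               "resolvable", class = "funcoreg_domain_error")
})
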