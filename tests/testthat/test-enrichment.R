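test_that("collapse_families unions member targets and keeps unmapped matures", {
  edges <- data.frame(mature = c("miR-a", "miR-b", "miR-b", "miR-x"),
                      target = c("g1", "g2", "g1", "g9"))
  fmap <- data.frame(mature = c("miR-a", "miR-b"), family = "F")
  net <- quiet(collapse_families(edges, fmap))
  expect_equal(sort(targets_of(net, "F")), c("g1", "g2"))  # union + dedup
  expect_equal(targets_of(net, "miR-x"), "g9")             # singleton family
  expect_equal(net$members[["F"]], c("miR-a", "miR-b"))
  expect_equal(nrow(net$regulators), 2)
})

test_that("host-gene regulation propagates TF edges to embedded families", {
  tf_net <- make_net("TF", list(X = c("H", "g1"), Y = "H", Z = "g2"))
  host_map <- data.frame(precursor = c("pre1", "pre2"),
                         host_gene = c("H", "H"))
  fmap <- data.frame(mature = c("pre1", "pre2"), family = c("F1", "F2"))
  out <- propagate_host_regulation(tf_net, host_map, fmap)
  # 2 TFs targeting H x 2 precursors of distinct families -> 4 edges
  expect_equal(nrow(out), 4)
  expect_setequal(paste(out$source, out$dest),
                  c("X F1", "X F2", "Y F1", "Y F2"))
  # host not targeted by any TF -> no edge
  out2 <- propagate_host_regulation(
    make_net("TF", list(X = "g1")), host_map, fmap)
  expect_equal(nrow(out2), 0)
  # unknown family -> logged skip
  out3 <- quiet(propagate_host_regulation(
    tf_net, data.frame(precursor = "preZ", host_gene = "H"), fmap))
  expect_equal(nrow(out3), 0)
})

test_that("enumerate_pairs intersects target sets above the threshold", {
  tf <- make_net("TF", list(TF1 = c("g1", "g2", "g3")))
  mir <- make_net("MIRNA_FAMILY", list(F1 = c("g2", "g3", "g4"),
                                       F2 = c("g8", "g9")))
  pairs <- enumerate_pairs(tf, mir, min_shared = 2)
  expect_length(pairs, 1)
  expect_equal(pairs[[1]]$pair_kind, "TF_MIR")
  expect_equal(sort(pairs[[1]]$shared), c("g2", "g3"))
  expect_length(enumerate_pairs(tf, make_net("MIRNA_FAMILY",
                                             list(F2 = c("g8", "g9"))),
                                min_shared = 1), 0)
})

test_that("enumerate_pairs equals the brute-force double loop", {
  for (seed in 1:5) {
    set.seed(seed)
    genes <- sprintf("g%02d", 1:30)
    tf_targets <- lapply(stats::setNames(nm = sprintf("T%d", 1:5)),
                         function(i) sample(genes, sample(3:12, 1)))
    mir_targets <- lapply(stats::setNames(nm = sprintf("F%d", 1:5)),
                          function(i) sample(genes, sample(3:12, 1)))
    got <- enumerate_pairs(make_net("TF", tf_targets),
                           make_net("MIRNA_FAMILY", mir_targets),
                           min_shared = 3)
    want <- enumerate_pairs_oracle(tf_targets, mir_targets, min_shared = 3)
    key <- function(p) paste(p$reg_a, p$reg_b, p$pair_kind,
                             if (!is.null(p$n_shared)) p$n_shared
                             else length(p$shared))
    expect_setequal(vapply(got, key, ""), vapply(want, key, ""))
  }
})

test_that("mvh_loglik matches closed forms", {
  ann1 <- list(population_counts = c(T1 = 10L), unannotated_count = 0L)
  prof1 <- list(counts = c(T1 = 4L), unannotated = 0L)
  expect_equal(mvh_loglik(prof1, ann1), 0)  # single category: C(M,n)/C(M,n)

  ann2 <- list(population_counts = c(T1 = 3L, T2 = 2L), unannotated_count = 0L)
  prof2 <- list(counts = c(T1 = 2L, T2 = 1L), unannotated = 0L)
  expect_equal(mvh_loglik(prof2, ann2), log(0.6), tolerance = 1e-12)

  expect_error(mvh_loglik(list(counts = c(T1 = 5L), unannotated = 0L),
                          list(population_counts = c(T1 = 3L),
                               unannotated_count = 0L)),
               "T1", class = "funcoreg_domain_error")
})

test_that("mvh_loglik agrees with the exact-rational oracle on all small instances", {
  MM <- c(7L, 5L, 6L, 8L)
  for (K in 1:4) for (n in 0:6) {
    cs <- compositions(n, K)
    for (r in seq_len(nrow(cs))) {
      cc <- cs[r, ]
      if (any(cc > MM[seq_len(K)])) next
      prof <- list(counts = stats::setNames(cc[-K] %||% integer(0),
                                            head(letters, K - 1)),
                   unannotated = cc[K])
      names(prof$counts) <- head(letters, K - 1)
      ann <- list(population_counts = stats::setNames(MM[seq_len(K)][-K] %||%
                                                        integer(0),
                                                      head(letters, K - 1)),
                  unannotated_count = MM[K])
      expect_equal(mvh_loglik(prof, ann), mvh_oracle(cc, MM[seq_len(K)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("permutation_test applies the pseudocount counting rule", {
  ann <- random_ann(60, K = 3, seed = 3)
  set.seed(4)
  genes <- sample(ann$universe, 6)
  prof <- functional_profile(genes, ann)
  L <- mvh_loglik(prof, ann)
  # inject null scores through the cache to pin the counting rule
  cache <- new.env()
  cache[["6"]] <- c(L + 1, L + 2, L + 3)      # L_obs below every null
  expect_equal(permutation_test(prof, ann, cache = cache)$p_perm, 1 / 4)
  cache[["6"]] <- c(L - 1, L + 1, L + 2)      # one null at or below
  expect_equal(permutation_test(prof, ann, cache = cache)$p_perm, 2 / 4)
  # bounds and errors
  pt <- permutation_test(prof, ann, n_perm = 9, rng_seed = 1)
  expect_gte(pt$p_perm, 1 / 10)
  expect_lte(pt$p_perm, 1)
  big <- list(counts = prof$counts, set_size = 10000L,
              unannotated = prof$unannotated)
  expect_error(permutation_test(structure(big, class = "FunctionalProfile"),
                                ann), class = "funcoreg_domain_error")
})

test_that("null cache is keyed by set size and reused", {
  ann <- random_ann(80, K = 3, seed = 5)
  set.seed(6)
  g1 <- sample(ann$universe, 5); g2 <- sample(ann$universe, 5)
  cache <- new.env()
  p1 <- permutation_test(functional_profile(g1, ann), ann, n_perm = 50,
                         rng_seed = 10, cache = cache)
  nulls_after <- cache[["5"]]
  p2 <- permutation_test(functional_profile(g2, ann), ann, n_perm = 50,
                         rng_seed = 99, cache = cache)  # seed ignored on hit
  expect_identical(cache[["5"]], nulls_after)
  expect_equal(p2$n_perm, 50)
})

test_that("fdr_adjust BH matches the hand-worked example and reference", {
  res <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04), "BH", alpha = 0.05)
  expect_true(all(res$reject))  # thresholds i*alpha/m = .0125,.025,.0375,.05
  expect_equal(res$adjusted, c(0.04, 0.04, 0.04, 0.04))

  all1 <- fdr_adjust(rep(1, 5), "BH")
  expect_false(any(all1$reject))
  expect_true(all(all1$adjusted == 1))

  set.seed(20)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_adjust(p, "BH")$adjusted,
                 stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2), "BH"),
               class = "funcoreg_domain_error")
})

test_that("fdr_adjust BL is step-down monotone and dominates Bonferroni", {
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(2:30, 1))
    res <- fdr_adjust(p, "BL", alpha = 0.05)
    expect_true(all(res$adjusted[order(p)] == cummax(res$adjusted[order(p)])))
    bonf <- p <= 0.05 / length(p)
    expect_true(all(res$reject[bonf]))
    # flags consistent with adjusted values at alpha
    expect_equal(res$reject, res$adjusted <= 0.05)
  }
})

test_that("find_enriched_pairs is deterministic and orders pairs canonically", {
  ann <- random_ann(200, K = 4, seed = 30)
  set.seed(31)
  tf <- make_net("TF", list(T1 = sample(ann$universe, 30),
                            T2 = sample(ann$universe, 30)))
  mir <- make_net("MIRNA_FAMILY", list(F1 = sample(ann$universe, 30),
                                       F2 = sample(ann$universe, 30)))
  pairs <- enumerate_pairs(tf, mir, min_shared = 3)
  expect_gt(length(pairs), 0)
  r1 <- find_enriched_pairs(pairs, ann, n_perm = 100, rng_seed = 42)
  r2 <- find_enriched_pairs(rev(pairs), ann, n_perm = 100, rng_seed = 42)
  expect_identical(r1, r2)  # order-invariant input, canonical output
  expect_true(all(r1$q >= r1$p_perm))
  expect_equal(r1$enriched, r1$q <= 0.05)
})
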