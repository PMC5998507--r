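test_that("sampling weights follow the frequency-ratio rule", {
  ## test pool: strata A (has DNA) and B (no other TE), 50/50
  test_prof <- make_profiles(10, counts = list(
    "SINE:ss" = rep(1, 10), "DNA:ss" = rep(c(1, 0), each = 5)))
  ## reference pool: 5 of A, 15 of B -> f_ref = 0.25/0.75
  ref_prof <- make_profiles(20, counts = list(
    "DNA:ss" = rep(c(1, 0), c(5, 15))), prefix = "r")
  pair <- structure(list(test_profiles = test_prof, ref_profiles = ref_prof,
                         focal_class = "SINE", focal_age = "ss",
                         universe = NULL, n_both_ages = 0L, usable = TRUE),
                    class = "te_gene_set_pair")
  w <- compute_sampling_weights(pair)
  expect_equal(sum(w), 1)
  ## per-gene weights proportional to 2 (stratum A) and 2/3 (stratum B)
  expect_equal(unname(w[1] / w[6]), 2 / (2 / 3))
  ## total mass per stratum reproduces the test-pool frequencies
  expect_equal(unname(sum(w[1:5])), 0.5)
  expect_equal(unname(sum(w[6:20])), 0.5)

  ## identical stratum frequencies give uniform weights
  ref_u <- make_profiles(20, counts = list(
    "DNA:ss" = rep(c(1, 0), each = 10)), prefix = "u")
  pair$ref_profiles <- ref_u
  wu <- compute_sampling_weights(pair)
  expect_equal(unname(wu), rep(1 / 20, 20), ignore_attr = TRUE)

  ## a stratum only present in the test pool is dropped with a warning
  test_c <- make_profiles(10, counts = list(
    "SINE:ss" = rep(1, 10),
    "DNA:ss" = rep(c(1, 0), each = 5),
    "LINE:ss" = rep(c(0, 1, 0), c(5, 2, 3))))
  pair$test_profiles <- test_c
  pair$ref_profiles <- ref_prof
  expect_warning(wc <- compute_sampling_weights(pair), "dropped")
  expect_equal(sum(wc), 1)
  expect_identical(attr(wc, "dropped_strata"), "LINE|L1")
})

test_that("matched set sizes follow the 1000-gene rule with a 600-gene floor", {
  mk_pair <- function(n_test, n_ref) {
    structure(list(test_profiles = make_profiles(n_test),
                   ref_profiles = make_profiles(n_ref, prefix = "r"),
                   focal_class = "SINE", focal_age = "ss",
                   universe = NULL, n_both_ages = 0L, usable = TRUE),
              class = "te_gene_set_pair")
  }
  cfg <- bootstrap_config()
  big <- mk_pair(5000, 5000)
  w <- rep(1 / 5000, 5000)
  s <- draw_matched_sets(big, w, cfg)
  expect_identical(s$n, 1000L)
  expect_length(s$test, 1000)
  expect_length(s$reference, 1000)

  mid <- mk_pair(700, 5000)
  s2 <- draw_matched_sets(mid, w, cfg)
  expect_identical(s2$n, 700L)

  small <- mk_pair(599, 5000)
  s3 <- draw_matched_sets(small, w, cfg)
  expect_identical(s3$status, "skipped_small_pool")
})

test_that("iteration statistics implement zero-omitted medians and expressed proportions", {
  s <- iteration_statistics(2^c(1, 2, 3), 2^c(0, 1, 2))
  expect_equal(unname(s["median_diff"]), 1.0)

  test_tpm <- c(rep(2, 8), 0, 0)
  ref_tpm <- c(rep(2, 6), 0, 0, 0, 0)
  s2 <- iteration_statistics(test_tpm, ref_tpm)
  expect_equal(unname(s2["prop_diff"]), 0.2)
  ## zeros omitted from the median: both medians use the non-zero values
  expect_equal(unname(s2["median_diff"]), 0)

  s3 <- iteration_statistics(c(1, 2, 4), c(1, 2, 4))
  expect_equal(unname(s3), c(0, 0))

  s4 <- iteration_statistics(c(0, 0), c(1, 2))
  expect_true(is.na(s4["median_diff"]))
})

test_that("percentile CIs match the quantile oracle and degrade gracefully", {
  ci <- ci_from_bootstrap(1:1000, alpha = 0.05, m = 1)
  expect_equal(ci, c(25.975, 975.025))

  ## the 1 - alpha/m level for m = 24: quantiles at 0.0010417 / 0.9989583
  set.seed(5)
  x <- rnorm(5000)
  ci24 <- ci_from_bootstrap(x, alpha = 0.05, m = 24)
  expect_equal(ci24, unname(quantile(x, c(0.05 / 48, 1 - 0.05 / 48), type = 7)))

  expect_equal(ci_from_bootstrap(rep(3.5, 100)), c(3.5, 3.5))

  expect_warning(ci_small <- ci_from_bootstrap(1:100, alpha = 0.05, m = 24),
                 "too few")
  expect_equal(ci_small, c(1, 100))
})

test_that("zero-crossing p-values use the add-one rule and tie on both sides", {
  expect_equal(pvalue_from_bootstrap(rep(1, 5000)), 2 / 5001)
  expect_equal(pvalue_from_bootstrap(c(-(1:50), 1:50)), 1)
  expect_equal(pvalue_from_bootstrap(c(rep(0, 50), 1:50)), 1)
  expect_equal(pvalue_from_bootstrap(c(-1, rep(1, 999))),
               2 * (1 + 1) / 1001)
})

test_that("BH adjustment equals the exhaustive step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(c(1, 1)), c(1, 1))
  set.seed(17)
  for (rep in 1:10) {
    p <- runif(sample(1:10, 1))
    expect_equal(adjust_bh(p), oracle_bh(p))
  }
  expect_error(adjust_bh(c(0.5, 0)), "0, 1")
})

test_that("log2 changes convert to percent changes", {
  expect_equal(log2_change_to_percent(1), 100)
  expect_equal(log2_change_to_percent(0), 0)
  expect_equal(log2_change_to_percent(-0.5), 100 * (2^-0.5 - 1))
  expect_equal(round(log2_change_to_percent(-0.5), 2), -29.29)
})

test_that("compiled and pure-R engines produce identical results under one seed", {
  cfg <- simulation_config(n_genes = 500, species = "spA",
                           tissues = "brain", seed = 19)
  ds <- simulate_te_dataset(cfg)
  prof <- te_profiles(ds)
  pair <- build_gene_set_pair(prof, "LINE", "ss")
  bcfg <- bootstrap_config(n_genes_per_set = 300, min_pool = 100,
                           n_iterations = 50, m = 4, seed = 77)
  a <- suppressWarnings(run_bootstrap(pair, ds$expression, "spA_brain", bcfg,
                                      engine = "cpp"))
  b <- suppressWarnings(run_bootstrap(pair, ds$expression, "spA_brain", bcfg,
                                      engine = "r"))
  expect_identical(a$iterations, b$iterations)
  expect_identical(a$median_diff, b$median_diff)

  ## and rerunning the compiled engine with the same seed is deterministic
  a2 <- suppressWarnings(run_bootstrap(pair, ds$expression, "spA_brain", bcfg,
                                       engine = "cpp"))
  expect_identical(a$iterations, a2$iterations)
})

test_that("a pool below the minimum is skipped, not an error", {
  prof <- make_profiles(800, counts = list(
    "SINE:ss" = rep(c(1, 0), c(100, 700))))
  pair <- build_gene_set_pair(prof, "SINE", "ss")
  expr <- make_expression(prof$gene_id, round(2^rnorm(800, 3, 1), 3))
  res <- run_bootstrap(pair, expr, "spA_brain", bootstrap_config())
  expect_identical(res$status, "skipped_small_pool")
  expect_null(res$median_diff)
})

test_that("p-values and CIs agree on significance up to one rank of slack", {
  set.seed(23)
  m <- 6; alpha <- 0.05
  for (mu in c(0, 0.05, 0.12, 0.3)) {
    for (rep in 1:5) {
      x <- rnorm(800, mu, 1)
      ci <- ci_from_bootstrap(x, alpha, m)
      p <- pvalue_from_bootstrap(x)
      sig_ci <- ci[1] > 0 || ci[2] < 0
      sig_p <- p < alpha / m
      ## agreement, or a boundary case where the zero-exceedance count sits
      ## within one rank of the CI's tail cutoff
      n_min <- min(sum(x <= 0), sum(x >= 0))
      cutoff <- length(x) * alpha / (2 * m)
      expect_true(sig_ci == sig_p || abs(n_min - cutoff) < 2)
    }
  }
})

test_that("all-positive iteration statistics give a positive CI and significance", {
  x <- abs(rnorm(5000)) + 0.01
  ci <- ci_from_bootstrap(x, 0.05, 24)
  expect_gt(ci[1], 0)
  expect_lt(pvalue_from_bootstrap(x), 0.05 / 24)
})
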