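## The core statistic: composition/length-matched weighted bootstrap of
## expression differences with FWER-adjusted percentile CIs, zero-crossing
## p-values and BH FDR.

#' Bootstrap configuration
#'
#' @param n_genes_per_set genes drawn per set each iteration (default 1000);
#'   pools smaller than this (but at least `min_pool`) use the pool size.
#' @param min_pool minimum pool size below which a comparison is skipped
#'   (default 600).
#' @param n_iterations bootstrap iterations B (default 5000).
#' @param alpha family-wise error level (default 0.05).
#' @param m number of tests in the family; CIs are taken at level
#'   `1 - alpha/m` (default 1; [teboot()] computes
#'   `m = n_tissues * n_classes` per family).
#' @param expressed_threshold TPM above which a gene counts as expressed for
#'   the proportion statistic (default 0, i.e. TPM > 0).
#' @param with_replacement draw with replacement (default TRUE, the true
#'   bootstrap); `FALSE` is available for sensitivity checks (R engine only).
#' @param seed optional RNG seed applied by [run_bootstrap()].
#' @return object of class `te_boot_config`.
#' @export
bootstrap_config <- function(n_genes_per_set = 1000L, min_pool = 600L,
                             n_iterations = 5000L, alpha = 0.05, m = 1L,
                             expressed_threshold = 0,
                             with_replacement = TRUE, seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (min_pool > n_genes_per_set)
    stop("min_pool must be <= n_genes_per_set")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (m < 1) stop("m must be >= 1")
  structure(list(n_genes_per_set = as.integer(n_genes_per_set),
                 min_pool = as.integer(min_pool),
                 n_iterations = as.integer(n_iterations),
                 alpha = alpha, m = as.integer(m),
                 expressed_threshold = expressed_threshold,
                 with_replacement = isTRUE(with_replacement),
                 seed = seed),
            class = "te_boot_config")
}

#' Reference-pool sampling weights
#'
#' For each stratum s — the set of co-occurring TE classes other than the
#' focal class, plus the gene-length bin (see [stratum_key()]) — a reference
#' gene in s gets weight proportional to `f_test(s) / f_ref(s)`, the ratio
#' of the stratum's frequency among test-pool genes to its frequency among
#' reference genes.  The weighted reference draw then matches the test
#' pool's stratum distribution in expectation.  Strata present in the test
#' pool but absent from the reference pool cannot be matched; they are
#' dropped from the target distribution (with a warning) and recorded in the
#' `dropped_strata` attribute.
#'
#' @param pair a `te_gene_set_pair` from [build_gene_set_pair()].
#' @return named numeric vector of weights over reference-pool gene IDs,
#'   summing to 1, with attributes `dropped_strata` and `n_effective`
#'   (`1 / sum(w^2)`, the effective reference sample size under the
#'   weights).
#' @export
compute_sampling_weights <- function(pair) {
  if (!inherits(pair, "te_gene_set_pair"))
    stop("'pair' must come from build_gene_set_pair()")
  if (nrow(pair$ref_profiles) == 0) stop("reference pool is empty")
  if (nrow(pair$test_profiles) == 0) stop("test pool is empty")
  st_test <- stratum_key(pair$test_profiles, pair$focal_class)
  st_ref <- stratum_key(pair$ref_profiles, pair$focal_class)
  f_test <- table(st_test) / length(st_test)
  f_ref <- table(st_ref) / length(st_ref)
  dropped <- setdiff(names(f_test), names(f_ref))
  if (length(dropped))
    warning(sprintf(
      "%d stratum/strata present only in the test pool dropped from the target distribution (mass %.3f)",
      length(dropped), sum(f_test[dropped])))
  w <- as.numeric(f_test[st_ref]) / as.numeric(f_ref[st_ref])
  w[is.na(w)] <- 0  # reference-only strata are never drawn
  if (sum(w) <= 0) stop("no matchable strata between test and reference pools")
  w <- w / sum(w)
  names(w) <- pair$ref_profiles$gene_id
  attr(w, "dropped_strata") <- dropped
  attr(w, "n_effective") <- 1 / sum(w^2)
  w
}

#' Draw one pair of matched gene sets
#'
#' The test sample is drawn uniformly with replacement from the test pool;
#' the reference sample (same size) is drawn with the matching weights.  The
#' set size is `min(n_genes_per_set, pool sizes)`; if either pool is smaller
#' than `min_pool` the comparison is skipped (a skip marker is returned, not
#' an error).
#'
#' @param pair a `te_gene_set_pair`.
#' @param weights reference weights from [compute_sampling_weights()].
#' @param cfg a [bootstrap_config()].
#' @return list with `test` and `reference` gene-ID vectors and `n`, or a
#'   list with `status = "skipped_small_pool"`.
#' @export
draw_matched_sets <- function(pair, weights, cfg = bootstrap_config()) {
  n_test <- nrow(pair$test_profiles)
  n_ref <- nrow(pair$ref_profiles)
  if (n_test < cfg$min_pool || n_ref < cfg$min_pool)
    return(list(status = "skipped_small_pool",
                n_test_pool = n_test, n_ref_pool = n_ref))
  n <- min(cfg$n_genes_per_set, n_test, n_ref)
  list(test = sample(pair$test_profiles$gene_id, n,
                     replace = cfg$with_replacement),
       reference = sample(pair$ref_profiles$gene_id, n,
                          replace = cfg$with_replacement, prob = weights),
       n = n, status = "ok")
}

#' Statistics of one bootstrap iteration
#'
#' `median_diff` is the difference of the two sets' median log2(TPM),
#' computed after omitting genes with zero TPM; it is `NA` when one set has
#' no expressed gene.  `prop_diff` is the difference in the proportions of
#' genes detected as expressed (TPM above `expressed_threshold`), computed
#' on all sampled genes including zeros.
#'
#' @param test_tpm,ref_tpm TPM values of the sampled gene sets.
#' @param expressed_threshold TPM threshold (default 0).
#' @return named numeric vector `c(median_diff, prop_diff)`.
#' @export
iteration_statistics <- function(test_tpm, ref_tpm, expressed_threshold = 0) {
  lt <- test_tpm[test_tpm > 0]
  lr <- ref_tpm[ref_tpm > 0]
  md <- if (length(lt) == 0 || length(lr) == 0) NA_real_
        else median(log2(lt)) - median(log2(lr))
  pd <- mean(test_tpm > expressed_threshold) -
        mean(ref_tpm > expressed_threshold)
  c(median_diff = md, prop_diff = pd)
}

#' Percentile bootstrap confidence interval at level 1 - alpha/m
#'
#' Empirical quantiles at `alpha/(2m)` and `1 - alpha/(2m)` with linear
#' interpolation between order statistics.  With fewer than `2m/alpha`
#' non-missing values the tails cannot be resolved: the interval falls back
#' to the sample range with a width warning.
#'
#' @param stats bootstrap statistics (NAs dropped).
#' @param alpha family-wise level (default 0.05).
#' @param m number of tests in the family (default 1).
#' @return numeric `c(low, high)`.
#' @export
ci_from_bootstrap <- function(stats, alpha = 0.05, m = 1) {
  x <- stats[!is.na(stats)]
  if (length(x) < 2) stop("need at least 2 non-missing bootstrap statistics")
  lo <- alpha / (2 * m)
  if (length(x) < 1 / lo) {
    warning("too few bootstrap statistics to resolve the ",
            sprintf("%.5f", lo), " tail; returning the sample range")
    return(range(x))
  }
  unname(quantile(x, c(lo, 1 - lo), type = 7, names = FALSE))
}

#' Two-sided bootstrap p-value from the zero crossing
#'
#' The smallest two-sided percentile level at which the confidence interval
#' touches zero, with add-one continuity so p is never 0:
#' `p = 2 * min((#\{stats <= 0\} + 1) / (B + 1), (#\{stats >= 0\} + 1) / (B + 1))`,
#' capped at 1.  Ties at exactly zero count on both sides.
#'
#' @param stats bootstrap statistics (NAs dropped).
#' @return p-value in (0, 1].
#' @export
pvalue_from_bootstrap <- function(stats) {
  x <- stats[!is.na(stats)]
  if (length(x) < 1) stop("need at least 1 non-missing bootstrap statistic")
  B <- length(x)
  p <- 2 * min((sum(x <= 0) + 1) / (B + 1), (sum(x >= 0) + 1) / (B + 1))
  min(1, p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment, returned in input order.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted q-values.
#' @export
adjust_bh <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    validation_error("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Convert a log2 expression change to a percent change
#'
#' `100 * (2^d - 1)`: a log2 difference of +1 is a +100 percent change in
#' median expression, -0.5 is about -29 percent.
#'
#' @param d log2 change(s).
#' @return percent change(s).
#' @export
log2_change_to_percent <- function(d) 100 * (2^d - 1)

## pure-R engine mirroring the C++ kernel draw-for-draw (same RNG stream):
## per iteration n uniform test draws, then n inverse-CDF reference draws
boot_engine_r <- function(vt, vr, w, n, B, thresh, with_replacement = TRUE) {
  nt <- length(vt); nr <- length(vr)
  md <- numeric(B); pd <- numeric(B)
  if (with_replacement) {
    cumw <- cumsum(w); tot <- cumw[nr]
    for (b in seq_len(B)) {
      it <- pmin(nt, as.integer(floor(runif(n) * nt)) + 1L)
      ir <- pmin(nr, findInterval(runif(n) * tot, cumw) + 1L)
      s <- iteration_statistics(vt[it], vr[ir], thresh)
      md[b] <- s[["median_diff"]]; pd[b] <- s[["prop_diff"]]
    }
  } else {
    for (b in seq_len(B)) {
      it <- sample.int(nt, n)
      ir <- sample.int(nr, n, prob = w)
      s <- iteration_statistics(vt[it], vr[ir], thresh)
      md[b] <- s[["median_diff"]]; pd[b] <- s[["prop_diff"]]
    }
  }
  list(median_diff = md, prop_diff = pd)
}

#' Run the weighted bootstrap for one comparison
#'
#' Executes B iterations of matched resampling for one focal element in one
#' expression sample and summarises both statistics: point estimates (mean
#' and median of the iteration statistics), percentile CIs at level
#' `1 - alpha/m`, and zero-crossing p-values.  Results are deterministic
#' given a seed.
#'
#' @param pair a `te_gene_set_pair`.
#' @param expr a `te_expression` object.
#' @param sample_id column of the expression matrix to analyse.
#' @param cfg a [bootstrap_config()].
#' @param engine `"cpp"` (compiled kernel, default) or `"r"` (pure R; same
#'   draws as the kernel under the same seed).
#' @param keep_iterations retain the per-iteration statistics (default TRUE).
#' @return object of class `te_bootstrap_result`; skipped comparisons (pool
#'   below `min_pool`) carry `status = "skipped_small_pool"` and no
#'   statistics.
#' @export
run_bootstrap <- function(pair, expr, sample_id, cfg = bootstrap_config(),
                          engine = c("cpp", "r"), keep_iterations = TRUE) {
  engine <- match.arg(engine)
  if (!cfg$with_replacement) engine <- "r"
  if (!sample_id %in% colnames(expr$values))
    validation_error(paste0("no expression sample: ", sample_id))
  meta <- expr$sample_meta[expr$sample_meta$sample_id == sample_id, ]

  base <- list(focal_class = pair$focal_class, focal_age = pair$focal_age,
               universe = pair$universe,
               species = meta$species, tissue = meta$tissue,
               sample_id = sample_id,
               n_test_pool = nrow(pair$test_profiles),
               n_ref_pool = nrow(pair$ref_profiles),
               alpha = cfg$alpha, m = cfg$m)

  if (base$n_test_pool < cfg$min_pool || base$n_ref_pool < cfg$min_pool) {
    return(structure(c(base, list(status = "skipped_small_pool")),
                     class = "te_bootstrap_result"))
  }

  vt <- expr$values[pair$test_profiles$gene_id, sample_id]
  vr <- expr$values[pair$ref_profiles$gene_id, sample_id]
  if (anyNA(vt) || anyNA(vr))
    validation_error("pool genes without expression values in this sample")

  w <- compute_sampling_weights(pair)
  n <- min(cfg$n_genes_per_set, length(vt), length(vr))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- if (engine == "cpp") {
    .boot_kernel(unname(vt), unname(vr), unname(w), n, cfg$n_iterations,
                 cfg$expressed_threshold)
  } else {
    boot_engine_r(unname(vt), unname(vr), unname(w), n, cfg$n_iterations,
                  cfg$expressed_threshold, cfg$with_replacement)
  }

  summarise <- function(x) {
    ok <- x[!is.na(x)]
    ci <- ci_from_bootstrap(x, cfg$alpha, cfg$m)
    list(estimate = mean(ok), estimate_median = median(ok),
         ci_low = ci[1], ci_high = ci[2],
         p = pvalue_from_bootstrap(x), n_iter_used = length(ok))
  }
  out <- c(base, list(
    status = "ok", n_sampled = n,
    median_diff = summarise(res$median_diff),
    prop_diff = summarise(res$prop_diff),
    dropped_strata = attr(w, "dropped_strata")))
  if (keep_iterations) out$iterations <- res
  structure(out, class = "te_bootstrap_result")
}

#' @export
print.te_bootstrap_result <- function(x, ...) {
  cat(sprintf("Weighted bootstrap: %s:%s, %s/%s\n", x$focal_class, x$focal_age,
              paste(x$species, collapse = ","), paste(x$tissue, collapse = ",")))
  if (x$status != "ok") {
    cat(sprintf("  %s (pools %d/%d, minimum not met)\n", x$status,
                x$n_test_pool, x$n_ref_pool))
    return(invisible(x))
  }
  cat(sprintf("  pools %d/%d, sets of %d\n", x$n_test_pool, x$n_ref_pool,
              x$n_sampled))
  with(x$median_diff, cat(sprintf(
    "  median log2(TPM) diff: %.3f [%0.3f, %0.3f] (level 1-%.3g/%d), p = %.3g\n",
    estimate, ci_low, ci_high, x$alpha, x$m, p)))
  with(x$prop_diff, cat(sprintf(
    "  expressed-proportion diff: %.4f [%0.4f, %0.4f], p = %.3g\n",
    estimate, ci_low, ci_high, p)))
  invisible(x)
}
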