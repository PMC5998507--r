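## The top-level fit: run the weighted bootstrap across every
## (species, universe, age, TE class, tissue) combination, with
## family-wise CI levels (m = tissues x classes per family) and BH FDR
## across the result set.

#' Fit TE-expression associations by weighted bootstrap
#'
#' For each species and gene universe (orthologs and non-orthologs, when the
#' profiles carry an `is_ortholog` flag), gene lengths are re-binned within
#' the universe, and for each focal (TE class, age group) element the genes
#' carrying it are compared against composition/length-matched resamples of
#' the remaining genes, in every tissue sample of that species.  Confidence
#' intervals are percentile bootstrap intervals at level `1 - alpha/m` with
#' `m = n_tissues * n_classes` computed per (species, universe, age) family
#' (overridable); p-values come from the CI zero crossing and are BH-adjusted
#' per statistic across all comparisons of the fit.
#'
#' @param expression a `te_expression` object.
#' @param profiles a profile table from [te_profiles()]/[build_profiles()].
#' @param te_classes TE classes to test (default all four).
#' @param ages age groups to test (default `c("ss", "ns")`).
#' @param B bootstrap iterations (default 5000).
#' @param n_genes_per_set,min_pool,alpha,m,expressed_threshold see
#'   [bootstrap_config()]; `m = NULL` computes `n_tissues * n_classes`.
#' @param n_bins gene-length bins per universe (default 10).
#' @param seed RNG seed for the whole fit (identical seeds give identical
#'   fits).
#' @param engine `"cpp"` (default) or `"r"`.
#' @return object of class `teboot`: list with `results` (one row per
#'   comparison x statistic), `config`, `call`, `seed`.
#' @examples
#' cfg <- simulation_config(n_genes = 800, species = "spA",
#'                          tissues = c("brain", "liver"), seed = 7)
#' ds <- simulate_te_dataset(cfg)
#' fit <- teboot(ds$expression, te_profiles(ds), B = 200, seed = 7)
#' fit
#' @export
teboot <- function(expression, profiles,
                   te_classes = TE_CLASSES, ages = AGE_GROUPS,
                   B = 5000, n_genes_per_set = 1000, min_pool = 600,
                   alpha = 0.05, m = NULL, expressed_threshold = 0,
                   n_bins = 10, seed = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!inherits(expression, "te_expression"))
    stop("'expression' must be a te_expression object")
  stopifnot(all(te_classes %in% TE_CLASSES), all(ages %in% AGE_GROUPS))
  if (!is.null(seed)) set.seed(seed)

  meta <- expression$sample_meta
  species <- intersect(unique(profiles$species), unique(meta$species))
  if (length(species) == 0)
    validation_error("no species shared between profiles and expression samples")

  has_universe <- "is_ortholog" %in% names(profiles) &&
    !anyNA(profiles$is_ortholog) &&
    length(unique(profiles$is_ortholog)) > 1

  rows <- list()
  for (sp in species) {
    sp_meta <- meta[meta$species == sp, , drop = FALSE]
    n_tissues <- length(unique(sp_meta$tissue))
    universes <- if (has_universe) c("ortholog", "non_ortholog") else "all"
    for (uni in universes) {
      prof_u <- profiles[profiles$species == sp, , drop = FALSE]
      if (uni == "ortholog") prof_u <- prof_u[prof_u$is_ortholog, , drop = FALSE]
      if (uni == "non_ortholog") prof_u <- prof_u[!prof_u$is_ortholog, , drop = FALSE]
      if (nrow(prof_u) == 0) next
      ## length bins are defined within the sampling universe
      prof_u$length_bin <- unname(assign_length_bins(
        setNames(prof_u$gene_length, prof_u$gene_id), n_bins))
      prof_u$composition_key <- composition_key(prof_u)
      for (age in ages) {
        m_fam <- if (is.null(m)) n_tissues * length(te_classes) else m
        cfg <- bootstrap_config(n_genes_per_set = n_genes_per_set,
                                min_pool = min_pool, n_iterations = B,
                                alpha = alpha, m = m_fam,
                                expressed_threshold = expressed_threshold)
        for (cls in te_classes) {
          pair <- build_gene_set_pair(prof_u, cls, age, universe = uni)
          skip <- nrow(pair$test_profiles) < cfg$min_pool ||
            nrow(pair$ref_profiles) < cfg$min_pool
          w <- if (!skip) compute_sampling_weights(pair) else NULL
          for (sid in sp_meta$sample_id) {
            res <- run_bootstrap(pair, expression, sid, cfg,
                                 engine = engine, keep_iterations = FALSE)
            rows[[length(rows) + 1L]] <- result_rows(res)
          }
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ## BH FDR per statistic across all testable comparisons
  results$fdr <- NA_real_
  for (st in unique(results$statistic)) {
    ok <- results$statistic == st & results$status == "ok"
    if (any(ok)) results$fdr[ok] <- adjust_bh(results$p[ok])
  }
  structure(list(results = results,
                 config = list(B = B, n_genes_per_set = n_genes_per_set,
                               min_pool = min_pool, alpha = alpha, m = m,
                               expressed_threshold = expressed_threshold,
                               n_bins = n_bins, te_classes = te_classes,
                               ages = ages, engine = engine),
                 seed = seed, call = match.call()),
            class = "teboot")
}

## flatten one te_bootstrap_result into two result rows (one per statistic)
result_rows <- function(res) {
  template <- data.frame(
    species = res$species, tissue = res$tissue, sample_id = res$sample_id,
    universe = if (is.null(res$universe)) "all" else res$universe,
    te_class = res$focal_class, age = res$focal_age,
    statistic = c("median_diff", "prop_diff"),
    estimate = NA_real_, estimate_median = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
    n_test_pool = res$n_test_pool, n_ref_pool = res$n_ref_pool,
    n_sampled = NA_integer_, n_iter_used = NA_integer_,
    m = res$m, status = res$status, stringsAsFactors = FALSE)
  if (res$status == "ok") {
    for (i in 1:2) {
      s <- res[[template$statistic[i]]]
      template$estimate[i] <- s$estimate
      template$estimate_median[i] <- s$estimate_median
      template$ci_low[i] <- s$ci_low
      template$ci_high[i] <- s$ci_high
      template$p[i] <- s$p
      template$n_iter_used[i] <- s$n_iter_used
    }
    template$n_sampled <- res$n_sampled
  }
  template
}

#' @export
print.teboot <- function(x, ...) {
  r <- x$results
  ok <- r$status == "ok"
  sig <- ok & (r$ci_low > 0 | r$ci_high < 0)
  cat("Weighted bootstrap TE-expression fit\n")
  cat(sprintf("  %d comparisons (%d statistics each), B = %d iterations\n",
              nrow(r) / 2L, 2L, x$config$B))
  cat(sprintf("  skipped (pool < %d): %d; significant at the 1-alpha/m level: %d (median), %d (proportion)\n",
              x$config$min_pool, sum(r$status != "ok") / 2L,
              sum(sig & r$statistic == "median_diff"),
              sum(sig & r$statistic == "prop_diff")))
  invisible(x)
}

#' @method summary teboot
#' @export
summary.teboot <- function(object, statistic = "median_diff", ...) {
  r <- object$results[object$results$statistic == statistic, , drop = FALSE]
  r$significant <- r$status == "ok" & (r$ci_low > 0 | r$ci_high < 0)
  r$percent_change <- if (statistic == "median_diff")
    log2_change_to_percent(r$estimate) else NA_real_
  structure(list(statistic = statistic, table = r,
                 alpha = object$config$alpha),
            class = "summary.teboot")
}

#' @export
print.summary.teboot <- function(x, ...) {
  cat(sprintf("Statistic: %s (alpha = %g, CI level 1-alpha/m)\n",
              x$statistic, x$alpha))
  r <- x$table
  sig <- r[which(r$significant), c("species", "tissue", "universe",
                                   "te_class", "age", "estimate",
                                   "ci_low", "ci_high", "p", "fdr")]
  if (nrow(sig)) {
    cat("Significant comparisons (CI excluding 0):\n")
    print(format(sig, digits = 3), row.names = FALSE)
  } else cat("No comparison significant at the family-wise level.\n")
  invisible(x)
}

#' @method coef teboot
#' @export
coef.teboot <- function(object, statistic = "median_diff", ...) {
  r <- object$results[object$results$statistic == statistic &
                        object$results$status == "ok", , drop = FALSE]
  setNames(r$estimate, paste(r$species, r$tissue, r$universe,
                             r$te_class, r$age, sep = ":"))
}

#' @method confint teboot
#' @export
confint.teboot <- function(object, parm, level, statistic = "median_diff", ...) {
  r <- object$results[object$results$statistic == statistic &
                        object$results$status == "ok", , drop = FALSE]
  out <- as.matrix(r[, c("ci_low", "ci_high")])
  rownames(out) <- paste(r$species, r$tissue, r$universe,
                         r$te_class, r$age, sep = ":")
  out
}

#' @method as.data.frame teboot
#' @export
as.data.frame.teboot <- function(x, ...) x$results

#' Write a results table as TSV
#' @param x a `teboot` fit or its results data.frame.
#' @param path output TSV path.
#' @export
write_te_results <- function(x, path) {
  r <- if (inherits(x, "teboot")) x$results else x
  write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Significance heatmap of bootstrap results
#'
#' Renders the results grid — tissues in rows, (species x TE class x age)
#' in columns — with cells coloured red for significantly increased
#' expression, blue for significantly decreased, white for non-significant
#' and grey for skipped comparisons (pool below the minimum).  Significance
#' follows the family-wise CI rule by default (CI at level 1-alpha/m
#' excluding 0); `criterion = "fdr"` uses the BH-adjusted p-values instead.
#'
#' @param x a `teboot` fit or results data.frame.
#' @param statistic which statistic to display (default `"median_diff"`).
#' @param universe restrict to one gene universe (default: all present).
#' @param criterion `"ci"` (default) or `"fdr"`.
#' @param fdr_threshold FDR cutoff when `criterion = "fdr"` (default 0.05).
#' @param draw draw the grid (default TRUE); with `FALSE` only the cell
#'   classification is returned.
#' @return invisibly, a character matrix of cell states (`"up"`, `"down"`,
#'   `"ns"`, `"skipped"`, `NA` for absent combinations).
#' @export
render_te_heatmap <- function(x, statistic = "median_diff", universe = NULL,
                              criterion = c("ci", "fdr"),
                              fdr_threshold = 0.05, draw = TRUE) {
  criterion <- match.arg(criterion)
  r <- if (inherits(x, "teboot")) x$results else x
  r <- r[r$statistic == statistic, , drop = FALSE]
  if (!is.null(universe)) r <- r[r$universe %in% universe, , drop = FALSE]
  if (nrow(r) == 0) validation_error("no results to render")

  sig <- r$status == "ok" & if (criterion == "ci") {
    r$ci_low > 0 | r$ci_high < 0
  } else {
    !is.na(r$fdr) & r$fdr < fdr_threshold
  }
  state <- ifelse(r$status != "ok", "skipped",
                  ifelse(sig & r$estimate > 0, "up",
                         ifelse(sig & r$estimate < 0, "down", "ns")))

  rows <- unique(r$tissue)
  cols <- unique(paste(r$species, r$universe, r$te_class, r$age, sep = "\n"))
  cell <- matrix(NA_character_, length(rows), length(cols),
                 dimnames = list(rows, cols))
  cell[cbind(match(r$tissue, rows),
             match(paste(r$species, r$universe, r$te_class, r$age,
                         sep = "\n"), cols))] <- state

  if (draw) {
    pal <- c(up = "#c0392b", down = "#2e6da4", ns = "white",
             skipped = "grey70")
    nr <- nrow(cell); nc <- ncol(cell)
    op <- graphics::par(mar = c(1, 6, 7, 1))
    on.exit(graphics::par(op))
    graphics::plot(NA, xlim = c(0, nc), ylim = c(0, nr), axes = FALSE,
                   xlab = "", ylab = "", asp = NA,
                   main = paste("TE association:", statistic))
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      col <- if (is.na(cell[i, j])) "grey90" else pal[[cell[i, j]]]
      graphics::rect(j - 1, nr - i, j, nr - i + 1, col = col,
                     border = "grey40")
    }
    graphics::axis(2, at = seq_len(nr) - 0.5, labels = rev(rownames(cell)),
                   las = 2, tick = FALSE)
    graphics::axis(3, at = seq_len(nc) - 0.5,
                   labels = gsub("\n", " ", colnames(cell)),
                   las = 2, tick = FALSE, cex.axis = 0.6)
  }
  invisible(cell)
}

#' @method plot teboot
#' @export
plot.teboot <- function(x, statistic = "median_diff", ...) {
  render_te_heatmap(x, statistic = statistic, ...)
}

#' End-to-end synthetic pipeline
#'
#' Simulates a dataset, builds TE composition profiles, fits the weighted
#' bootstrap, and optionally writes the dataset files and results TSV — the
#' full analysis chain in one call.  With a fixed seed the run (including
#' the written TSVs) is reproducible bit for bit.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory for dataset + results files.
#' @param seed RNG seed passed to [teboot()] (defaults to the simulation
#'   seed).
#' @param ... further arguments to [teboot()] (e.g. `B`, `ages`).
#' @return list with `dataset`, `profiles`, `fit`, and when written,
#'   `manifest` and `results_path`.
#' @export
run_te_pipeline <- function(config, out_dir = NULL, seed = config$seed, ...) {
  ds <- simulate_te_dataset(config)
  prof <- te_profiles(ds, flank = config$flank)
  fit <- teboot(ds$expression, prof, seed = seed, ...)
  out <- list(dataset = ds, profiles = prof, fit = fit)
  if (!is.null(out_dir)) {
    out$manifest <- write_te_dataset(ds, out_dir)
    out$results_path <- write_te_results(fit, file.path(out_dir, "results.tsv"))
  }
  out
}
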