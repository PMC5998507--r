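test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(ss_fraction = 1.2), "ss_fraction")
  expect_error(simulation_config(zero_rate = 1), "zero_rate")
  expect_error(simulation_config(te_class_rates = c(DNA = -1, `ERV/LTR` = 1,
                                                    LINE = 1, SINE = 1)),
               "te_class_rates")
  expect_error(simulation_config(te_class_rates = c(foo = 1)), "te_class_rates")
  expect_error(simulation_config(cooccurrence_dispersion = 0.5),
               "cooccurrence_dispersion")
  expect_error(simulation_config(planted_effects = data.frame(x = 1)),
               "planted_effects")
})

test_that("identical configs give byte-identical datasets", {
  cfg <- simulation_config(n_genes = 300, species = c("spA", "spB"),
                           tissues = c("brain", "liver"), seed = 11)
  a <- simulate_te_dataset(cfg)
  b <- simulate_te_dataset(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(a$te_insertions, b$te_insertions)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$orthologs, b$orthologs)
  expect_identical(a$truth, b$truth)
})

test_that("zero TE rates give an all-TE-free genome with empty pools", {
  cfg <- simulation_config(n_genes = 150, species = "spA",
                           tissues = "brain",
                           te_class_rates = c(DNA = 0, `ERV/LTR` = 0,
                                              LINE = 0, SINE = 0),
                           seed = 2)
  ds <- simulate_te_dataset(cfg)
  expect_identical(nrow(ds$te_insertions), 0L)
  prof <- te_profiles(ds)
  expect_true(all(grepl("^none\\|", prof$composition_key)))
  pair <- build_gene_set_pair(prof, "SINE", "ss")
  expect_identical(nrow(pair$test_profiles), 0L)
  expect_false(pair$usable)
})

test_that("genes do not overlap and insertions land near their genes", {
  cfg <- simulation_config(n_genes = 400, species = "spA",
                           tissues = "brain", seed = 5)
  ds <- simulate_te_dataset(cfg)
  g <- ds$genes[order(ds$genes$chrom, ds$genes$start), ]
  by_chrom <- split(g, g$chrom)
  for (gc in by_chrom) {
    expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }
  expect_true(all(ds$genes$start >= 0))
  expect_true(all(ds$te_insertions$start >= 0))
  expect_true(all(ds$te_insertions$end > ds$te_insertions$start))
})

test_that("the species-specific identity fraction converges to ss_fraction", {
  cfg <- simulation_config(n_genes = 2000, species = "spA",
                           tissues = "brain", seed = 8)
  ds <- simulate_te_dataset(cfg)
  ident <- ds$te_insertions$percent_identity
  expect_true(all(ident >= 50 & ident <= 100))
  phat <- mean(ident >= 94)
  se <- sqrt(0.3 * 0.7 / length(ident))
  expect_lt(abs(phat - 0.3), 4 * se)
})

test_that("TE class counts co-occur positively and multi-TE genes dominate", {
  cfg <- simulation_config(n_genes = 2000, species = "spA",
                           tissues = "brain", seed = 13)
  ds <- simulate_te_dataset(cfg)
  prof <- te_profiles(ds)
  cols <- teboot:::te_count_columns()
  per_class <- sapply(c("DNA", "ERVLTR", "LINE", "SINE"), function(tok)
    rowSums(prof[, grep(paste0("^n_", tok, "_"), names(prof)), drop = FALSE]))
  expect_gt(cor(per_class[, "SINE"], per_class[, "LINE"]), 0)
  expect_gt(cor(per_class[, "DNA"], per_class[, "ERVLTR"]), 0)
  total <- rowSums(prof[, cols])
  expect_lt(mean(total == 1), 0.5)   # single-TE genes are a minority
  expect_lt(mean(total == 0), 0.25)  # TE-free genes are rare
})

test_that("planted effects are recorded in truth and visible in expression", {
  pe <- data.frame(species = "spA", tissue = "brain", te_class = "SINE",
                   age_group = "ss", delta = 1, stringsAsFactors = FALSE)
  cfg <- simulation_config(n_genes = 2000, species = "spA",
                           tissues = c("brain", "liver"),
                           planted_effects = pe, seed = 21)
  ds <- simulate_te_dataset(cfg)
  expect_gt(nrow(ds$truth), 0)
  expect_true(all(ds$truth$tissue == "brain"))

  ## truth matches the pipeline's own carrier definition
  prof <- te_profiles(ds)
  carriers <- prof$gene_id[prof$n_SINE_ss > 0]
  expect_setequal(ds$truth$gene_id, carriers)

  ## mean log2 TPM difference carriers vs non-carriers ~ delta (3 SE)
  tpm <- ds$expression$values[, "spA_brain"]
  lx <- log2(tpm[tpm > 0])
  isc <- names(lx) %in% carriers
  diff <- mean(lx[isc]) - mean(lx[!isc])
  se <- sqrt(var(lx[isc]) / sum(isc) + var(lx[!isc]) / sum(!isc))
  expect_lt(abs(diff - 1), 3 * se)

  ## the untouched tissue shows no such shift
  tpm2 <- ds$expression$values[, "spA_liver"]
  ly <- log2(tpm2[tpm2 > 0])
  isc2 <- names(ly) %in% carriers
  diff2 <- mean(ly[isc2]) - mean(ly[!isc2])
  se2 <- sqrt(var(ly[isc2]) / sum(isc2) + var(ly[!isc2]) / sum(!isc2))
  expect_lt(abs(diff2), 4 * se2)
})
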