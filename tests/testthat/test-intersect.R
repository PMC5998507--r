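test_that("age classification is inclusive at the 94 percent boundary and monotone", {
  expect_identical(classify_te_age(94.0), "ss")
  expect_identical(classify_te_age(93.99), "ns")
  expect_identical(classify_te_age(100), "ss")
  ## raising the threshold never moves an insertion from ns to ss
  set.seed(1)
  ident <- runif(200, 50, 100)
  for (th in c(90, 94, 97)) {
    lo <- classify_te_age(ident, th)
    hi <- classify_te_age(ident, th + 2)
    expect_false(any(lo == "ns" & hi == "ss"))
  }
})

test_that("flanking extends both sides, clips at zero, and flank 0 is identity", {
  g <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                  start = c(5000L, 500L), end = c(6000L, 800L),
                  stringsAsFactors = FALSE)
  f <- flank_genes(g, 1000)
  expect_identical(f$start, c(4000L, 0L))
  expect_identical(f$end, c(7000L, 1800L))
  expect_identical(flank_genes(g, 0)[, c("start", "end")],
                   g[, c("start", "end")])
})

test_that("intersection follows half-open semantics at the boundary", {
  g <- data.frame(gene_id = "g", chrom = "chr1", start = 4000L, end = 7000L,
                  stringsAsFactors = FALSE)
  te1 <- data.frame(chrom = "chr1", start = 6999L, end = 7100L,
                    te_class = "SINE", family = "f", percent_identity = 95,
                    stringsAsFactors = FALSE)
  te2 <- te1; te2$start <- 7000L
  expect_identical(nrow(intersect_genes_tes(g, te1)), 1L)  # 1 bp shared
  expect_identical(nrow(intersect_genes_tes(g, te2)), 0L)  # abutting only
  te3 <- te1; te3$chrom <- "chrX"
  expect_warning(ov <- intersect_genes_tes(g, te3), "absent")
  expect_identical(nrow(ov), 0L)
})

test_that("intersection matches the brute-force all-pairs oracle", {
  set.seed(7)
  n_g <- 200; n_t <- 500
  g <- data.frame(gene_id = sprintf("g%03d", seq_len(n_g)),
                  chrom = sample(paste0("chr", 1:3), n_g, TRUE),
                  start = sample.int(50000, n_g), stringsAsFactors = FALSE)
  g$end <- g$start + sample.int(3000, n_g)
  te <- data.frame(chrom = sample(paste0("chr", 1:4), n_t, TRUE),
                   start = sample.int(52000, n_t),
                   te_class = sample(c("DNA", "SINE"), n_t, TRUE),
                   family = "f", percent_identity = 95,
                   stringsAsFactors = FALSE)
  te$end <- te$start + sample.int(1000, n_t)
  got <- suppressWarnings(intersect_genes_tes(g, te))
  want <- oracle_intersect(g, te)
  key <- function(d) sort(paste(d$gene_id, d$te_start, d$te_end))
  expect_identical(key(got), key(want))
})

test_that("length bins are equal-frequency with stable tie-breaks", {
  b <- assign_length_bins(stats::setNames(1:10, letters[1:10]), 10)
  expect_identical(unname(b), 1:10)

  expect_warning(b1 <- assign_length_bins(stats::setNames(rep(5, 8),
                                                          letters[1:8]), 10),
                 "identical")
  expect_true(all(b1 == 1L))

  set.seed(3)
  lens <- round(rlnorm(1000, 9, 1.2))
  b2 <- assign_length_bins(stats::setNames(lens, sprintf("g%04d", 1:1000)), 10)
  expect_identical(as.integer(table(b2)), rep(100L, 10))
  ## monotone: genes in a higher bin are never shorter
  expect_true(max(lens[b2 == 1]) <= min(lens[b2 == 10]))

  expect_error(assign_length_bins(numeric(0)), "empty")
})

test_that("profiles count elements per class and age with canonical keys", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                  start = c(0L, 10000L), end = c(5000L, 16000L),
                  stringsAsFactors = FALSE)
  ov <- data.frame(gene_id = c("g1", "g1", "g1"),
                   te_class = c("SINE", "SINE", "LINE"),
                   family = "f",
                   percent_identity = c(96, 99, 80),
                   te_start = 1L, te_end = 2L, stringsAsFactors = FALSE)
  prof <- build_profiles(g, ov, n_bins = 2)
  expect_identical(prof$n_SINE_ss, c(2L, 0L))
  expect_identical(prof$n_LINE_ns, c(1L, 0L))
  expect_match(prof$composition_key[1], "^LINE:ns\\+SINE:ss\\|L")
  expect_match(prof$composition_key[2], "^none\\|L")

  ## key is order-independent: permuting the overlap rows changes nothing
  prof2 <- build_profiles(g, ov[c(3, 1, 2), ], n_bins = 2)
  expect_identical(prof$composition_key, prof2$composition_key)
})

test_that("gene set pairs partition the universe with the focal element rule", {
  prof <- make_profiles(6, counts = list(
    "SINE:ss" = c(1, 2, 0, 0, 1, 0),
    "SINE:ns" = c(0, 0, 1, 0, 1, 0),
    "LINE:ns" = c(1, 0, 0, 1, 0, 0)))
  pair <- build_gene_set_pair(prof, "SINE", "ss")
  ids <- prof$gene_id
  expect_setequal(pair$test_profiles$gene_id, ids[c(1, 2, 5)])
  expect_setequal(pair$ref_profiles$gene_id, ids[c(3, 4, 6)])
  ## every gene in exactly one pool
  expect_length(intersect(pair$test_profiles$gene_id,
                          pair$ref_profiles$gene_id), 0)
  expect_setequal(c(pair$test_profiles$gene_id, pair$ref_profiles$gene_id), ids)
  ## gene 5 has both ages of the focal class and sits in the test pool
  expect_identical(pair$n_both_ages, 1L)
  ## a gene with only the other age is reference; a no-TE gene is reference
  expect_true(ids[3] %in% pair$ref_profiles$gene_id)
  expect_true(ids[6] %in% pair$ref_profiles$gene_id)
})

test_that("stratum keys ignore the focal class but track other classes and bins", {
  prof <- make_profiles(3, counts = list(
    "SINE:ss" = c(1, 0, 1),
    "SINE:ns" = c(0, 1, 0),
    "DNA:ss" = c(1, 1, 0),
    "LINE:ns" = c(0, 1, 0)))
  s <- stratum_key(prof, "SINE")
  expect_identical(s, c("DNA|L1", "DNA+LINE|L1", "none|L1"))
})
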