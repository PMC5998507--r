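# in-code fixtures shared across the suite

# minimal profile table: `counts` is a named list of count vectors keyed by
# element ("SINE:ss", ...); missing elements are zero everywhere
make_profiles <- function(n, counts = list(), lengths = NULL, n_bins = 1,
                          species = "spA", prefix = "g") {
  prof <- data.frame(gene_id = sprintf("%s%04d", prefix, seq_len(n)),
                     species = species, stringsAsFactors = FALSE)
  prof$gene_length <- if (is.null(lengths)) 1000L + seq_len(n) else lengths
  prof$length_bin <- unname(assign_length_bins(
    stats::setNames(prof$gene_length, prof$gene_id), n_bins))
  keys <- teboot:::te_element_keys()
  cols <- teboot:::te_count_columns()
  for (i in seq_along(keys)) {
    v <- counts[[keys[i]]]
    prof[[cols[i]]] <- if (is.null(v)) 0L else as.integer(v)
  }
  prof$composition_key <- composition_key(prof)
  prof
}

# expression table over the genes of a profile frame, one sample
make_expression <- function(gene_ids, tpm, sample_id = "spA_brain",
                            species = "spA", tissue = "brain") {
  values <- matrix(tpm, ncol = 1, dimnames = list(gene_ids, sample_id))
  expression_table(values, data.frame(sample_id = sample_id,
                                      species = species, tissue = tissue,
                                      stringsAsFactors = FALSE))
}

# brute-force all-pairs interval intersection oracle (half-open semantics)
oracle_intersect <- function(genes, tes) {
  hits <- lapply(seq_len(nrow(genes)), function(i) {
    j <- which(tes$chrom == genes$chrom[i] &
                 tes$start < genes$end[i] & genes$start[i] < tes$end)
    if (length(j)) data.frame(gene_id = genes$gene_id[i],
                              te_start = tes$start[j], te_end = tes$end[j],
                              stringsAsFactors = FALSE)
  })
  do.call(rbind, hits)
}

# exhaustive Benjamini-Hochberg definition: q_i = min over j with
# p_(j) >= p_(i) of p_(j) * n / rank(j), computed from first principles
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) p[o[j]] * n / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}
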