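## Synthetic datasets: gene annotations, TE landscapes, ortholog tables and
## TPM expression with known planted TE-associated effects.

config_error <- function(field, msg) {
  stop(structure(
    class = c("teboot_config_error", "error", "condition"),
    list(message = sprintf("invalid simulation config: field '%s' %s", field, msg),
         call = sys.call(-1))))
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  Defaults describe a genome in
#' which nearly every gene carries several TE insertions of multiple classes
#' (so genes with a single TE are a minority and TE-free genes are rare),
#' insertion identities straddle the 94 percent species-specificity boundary,
#' and log-normal-like TPM values carry optional additive shifts on log2(TPM)
#' planted on genes that contain a chosen (TE class, age group) element.
#'
#' @param n_genes number of genes per species.
#' @param n_chromosomes chromosomes genes are distributed over.
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene-length
#'   parameters in bp.
#' @param te_class_rates named vector, expected insertions per gene for each
#'   of the four TE classes (`DNA`, `ERV/LTR`, `LINE`, `SINE`); scaled per
#'   gene by the square root of relative gene length (longer genes carry
#'   more insertions) and by the co-occurrence frailty.
#' @param ss_fraction probability an insertion has identity >= 94 (i.e. is
#'   species-specific).
#' @param identity_dist_ss,identity_dist_ns functions `n -> n draws` of
#'   percent identity; draws must land in `[94, 100]` and `[50, 94)`
#'   respectively.
#' @param cooccurrence_dispersion overdispersion factor `>= 1`; per-gene gamma
#'   frailty (mean 1, variance dispersion - 1) multiplying all class rates,
#'   which makes counts of different classes positively correlated within a
#'   gene.  `1` disables the frailty.
#' @param tissues,species tissue and species names; one expression sample is
#'   generated per (species, tissue).
#' @param ortholog_fraction fraction of gene indices that belong to
#'   single-copy ortholog groups shared across all species.
#' @param baseline_log2tpm_mean,baseline_log2tpm_sd per-gene baseline
#'   log2(TPM), shared across species.
#' @param tissue_effect_sd sd of per-(gene, tissue) expression effects shared
#'   across species (drives tissue-level clustering).
#' @param species_effect_sd sd of per-(gene, species) effects.
#' @param noise_sd per-sample Gaussian noise sd on log2(TPM).
#' @param zero_rate probability a gene is unexpressed (TPM = 0) in a sample.
#' @param flank flank in bp used both for TE placement around genes and for
#'   deciding which genes carry a planted effect (must match the analysis
#'   flank).
#' @param planted_effects `NULL`, or a data.frame with columns `species`,
#'   `tissue`, `te_class`, `age_group`, `delta`: additive shifts on log2(TPM)
#'   applied to genes whose TE profile contains the (class, age) element.
#' @param seed integer RNG seed; identical configs give byte-identical
#'   datasets.
#' @return an object of class `te_sim_config`.
#' @seealso [simulate_te_dataset()]
#' @export
simulation_config <- function(n_genes = 3000L,
                              n_chromosomes = 5L,
                              gene_length_meanlog = 9.5,
                              gene_length_sdlog = 1.2,
                              te_class_rates = c("DNA" = 1.5, "ERV/LTR" = 2,
                                                 "LINE" = 3, "SINE" = 3),
                              ss_fraction = 0.3,
                              identity_dist_ss = function(n) runif(n, 94, 100),
                              identity_dist_ns = function(n) runif(n, 50, 94),
                              cooccurrence_dispersion = 1.5,
                              tissues = c("brain", "heart", "kidney",
                                          "liver", "testis", "ovary"),
                              species = c("spA", "spB"),
                              ortholog_fraction = 0.7,
                              baseline_log2tpm_mean = 3,
                              baseline_log2tpm_sd = 2,
                              tissue_effect_sd = 1,
                              species_effect_sd = 0.5,
                              noise_sd = 0.5,
                              zero_rate = 0.1,
                              flank = 1000L,
                              planted_effects = NULL,
                              seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    config_error("n_genes", "must be a positive count")
  if (!is.numeric(n_chromosomes) || n_chromosomes < 1)
    config_error("n_chromosomes", "must be a positive count")
  if (!is.numeric(gene_length_sdlog) || gene_length_sdlog < 0)
    config_error("gene_length_sdlog", "must be >= 0")
  if (is.null(names(te_class_rates)) ||
      !setequal(names(te_class_rates), TE_CLASSES))
    config_error("te_class_rates",
                 sprintf("must be named with exactly: %s",
                         paste(TE_CLASSES, collapse = ", ")))
  if (any(te_class_rates < 0))
    config_error("te_class_rates", "must all be >= 0")
  if (!is.numeric(ss_fraction) || ss_fraction < 0 || ss_fraction > 1)
    config_error("ss_fraction", "must lie in [0, 1]")
  if (!is.function(identity_dist_ss))
    config_error("identity_dist_ss", "must be a function(n)")
  if (!is.function(identity_dist_ns))
    config_error("identity_dist_ns", "must be a function(n)")
  if (!is.numeric(cooccurrence_dispersion) || cooccurrence_dispersion < 1)
    config_error("cooccurrence_dispersion", "must be >= 1")
  if (length(tissues) < 1 || anyDuplicated(tissues))
    config_error("tissues", "must be a non-empty set of unique names")
  if (length(species) < 1 || anyDuplicated(species))
    config_error("species", "must be a non-empty set of unique names")
  if (ortholog_fraction < 0 || ortholog_fraction > 1)
    config_error("ortholog_fraction", "must lie in [0, 1]")
  if (noise_sd < 0) config_error("noise_sd", "must be >= 0")
  if (!is.numeric(zero_rate) || zero_rate < 0 || zero_rate >= 1)
    config_error("zero_rate", "must lie in [0, 1)")
  if (flank < 0) config_error("flank", "must be >= 0")
  if (!is.null(planted_effects)) {
    need <- c("species", "tissue", "te_class", "age_group", "delta")
    if (!is.data.frame(planted_effects) ||
        !all(need %in% names(planted_effects)))
      config_error("planted_effects",
                   sprintf("must be a data.frame with columns: %s",
                           paste(need, collapse = ", ")))
    if (!all(planted_effects$te_class %in% TE_CLASSES))
      config_error("planted_effects", "te_class values must be one of the 4 classes")
    if (!all(planted_effects$age_group %in% AGE_GROUPS))
      config_error("planted_effects", "age_group values must be 'ss' or 'ns'")
    if (!all(planted_effects$species %in% species))
      config_error("planted_effects", "species not in the simulated species set")
    if (!all(planted_effects$tissue %in% tissues))
      config_error("planted_effects", "tissue not in the simulated tissue set")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    config_error("seed", "must be a single integer")

  structure(list(
    n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    gene_length_meanlog = gene_length_meanlog,
    gene_length_sdlog = gene_length_sdlog,
    te_class_rates = te_class_rates[TE_CLASSES],
    ss_fraction = ss_fraction,
    identity_dist_ss = identity_dist_ss,
    identity_dist_ns = identity_dist_ns,
    cooccurrence_dispersion = cooccurrence_dispersion,
    tissues = tissues,
    species = species,
    ortholog_fraction = ortholog_fraction,
    baseline_log2tpm_mean = baseline_log2tpm_mean,
    baseline_log2tpm_sd = baseline_log2tpm_sd,
    tissue_effect_sd = tissue_effect_sd,
    species_effect_sd = species_effect_sd,
    noise_sd = noise_sd,
    zero_rate = zero_rate,
    flank = as.integer(flank),
    planted_effects = planted_effects,
    seed = as.integer(seed)
  ), class = "te_sim_config")
}

#' @export
print.te_sim_config <- function(x, ...) {
  cat("Synthetic TE/expression simulation config\n")
  cat(sprintf("  genes: %d on %d chromosomes; species: %s; tissues: %s\n",
              x$n_genes, x$n_chromosomes,
              paste(x$species, collapse = ", "),
              paste(x$tissues, collapse = ", ")))
  cat(sprintf("  TE rates/gene: %s (ss fraction %.2f, dispersion %.1f)\n",
              paste(sprintf("%s=%.2g", names(x$te_class_rates), x$te_class_rates),
                    collapse = " "),
              x$ss_fraction, x$cooccurrence_dispersion))
  ne <- if (is.null(x$planted_effects)) 0L else nrow(x$planted_effects)
  cat(sprintf("  planted effects: %d; seed: %d\n", ne, x$seed))
  invisible(x)
}

## typical insertion length ranges (bp) per class
te_length_range <- function(cls) {
  switch(cls,
         "DNA"     = c(200, 1500),
         "ERV/LTR" = c(300, 5000),
         "LINE"    = c(500, 6000),
         "SINE"    = c(100, 400))
}

#' Simulate a TE/expression dataset with planted effects
#'
#' Places non-overlapping genes on chromosomes, drops TE insertions of four
#' classes into gene extents (plus flanks) and intergenic space, assigns each
#' insertion a percent identity, and generates per-sample TPM values whose
#' log2 means carry the configured planted shifts on genes that contain the
#' targeted (TE class, age group) element.  Carrier status is determined with
#' the same flank/intersection/age-classification machinery used by the
#' analysis, so the returned `truth` table records exactly which genes
#' received which shift.
#'
#' @param config a [simulation_config()] object.
#' @return an object of class `te_dataset`: a list with `genes`,
#'   `te_insertions`, `expression` (a `te_expression` object), `orthologs`
#'   (long table `group_id`, `species`, `gene_id`), `truth` (one row per
#'   affected gene x sample) and the `config`.
#' @examples
#' cfg <- simulation_config(n_genes = 200, species = "spA",
#'                          tissues = c("brain", "liver"), seed = 42)
#' ds <- simulate_te_dataset(cfg)
#' head(ds$genes)
#' @export
simulate_te_dataset <- function(config) {
  if (!inherits(config, "te_sim_config"))
    stop("'config' must be created by simulation_config()")
  set.seed(config$seed)
  n  <- config$n_genes
  nt <- length(config$tissues)

  ## quantities shared across species: lengths, baselines, tissue effects
  lens <- pmax(200L, as.integer(round(
    rlnorm(n, config$gene_length_meanlog, config$gene_length_sdlog))))
  mu <- rnorm(n, config$baseline_log2tpm_mean, config$baseline_log2tpm_sd)
  tissue_eff <- matrix(rnorm(n * nt, 0, config$tissue_effect_sd), n, nt,
                       dimnames = list(NULL, config$tissues))

  n_orth <- round(config$ortholog_fraction * n)
  is_orth <- seq_len(n) <= n_orth

  genes_all <- vector("list", length(config$species))
  tes_all   <- vector("list", length(config$species))
  expr_all  <- vector("list", length(config$species))
  truth_all <- list()

  for (si in seq_along(config$species)) {
    sp <- config$species[si]
    gene_id <- sprintf("%s_g%05d", sp, seq_len(n))

    ## place genes without overlap, round-robin over chromosomes
    chrom_idx <- rep(seq_len(config$n_chromosomes), length.out = n)
    start <- integer(n)
    for (ci in seq_len(config$n_chromosomes)) {
      on_c <- which(chrom_idx == ci)
      gaps <- 4000L + sample.int(4000L, length(on_c), replace = TRUE)
      ends <- cumsum(as.numeric(gaps) + as.numeric(lens[on_c]))
      start[on_c] <- as.integer(ends - lens[on_c])
    }
    genes <- data.frame(
      gene_id = gene_id, species = sp,
      chrom = paste0("chr", chrom_idx),
      start = start, end = start + lens,
      strand = sample(c("+", "-"), n, replace = TRUE),
      is_ortholog = is_orth,
      stringsAsFactors = FALSE)

    ## TE counts per gene x class: Poisson with a shared gamma frailty
    ## (co-occurrence across classes) and tempered length scaling (longer
    ## genes accumulate more insertions, sublinearly)
    disp <- config$cooccurrence_dispersion
    frailty <- if (disp > 1)
      rgamma(n, shape = 1 / (disp - 1), scale = disp - 1) else rep(1, n)
    rel_len <- sqrt(lens / mean(lens))
    lam <- outer(frailty * rel_len, config$te_class_rates)
    cnt <- matrix(rpois(length(lam), lam), n, length(TE_CLASSES))

    cnt_vec <- as.vector(cnt)            # column-major: class blocks
    gidx <- rep(rep(seq_len(n), times = length(TE_CLASSES)), cnt_vec)
    cls  <- rep(rep(TE_CLASSES, each = n), cnt_vec)
    m_genic <- length(gidx)

    ## a small intergenic background so not every TE touches a gene
    m_inter <- ceiling(0.05 * max(m_genic, 1)) * (m_genic > 0)
    m <- m_genic + m_inter
    if (m > 0) {
      cls <- c(cls, sample(TE_CLASSES, m_inter, replace = TRUE,
                           prob = config$te_class_rates + 1e-12))
      is_ss <- runif(m) < config$ss_fraction
      ident <- numeric(m)
      if (any(is_ss)) {
        ident[is_ss] <- config$identity_dist_ss(sum(is_ss))
        if (any(ident[is_ss] < 94 | ident[is_ss] > 100))
          config_error("identity_dist_ss", "produced draws outside [94, 100]")
      }
      if (any(!is_ss)) {
        ident[!is_ss] <- config$identity_dist_ns(sum(!is_ss))
        if (any(ident[!is_ss] < 0 | ident[!is_ss] >= 94))
          config_error("identity_dist_ns", "produced draws outside [0, 94)")
      }
      ident <- round(ident, 2)

      rng <- vapply(cls, te_length_range, numeric(2))
      telen <- as.integer(round(runif(m, rng[1, ], rng[2, ])))

      tstart <- integer(m)
      if (m_genic > 0) {
        gs <- pmax(0L, genes$start[gidx] - config$flank)
        ge <- genes$end[gidx] + config$flank
        tstart[seq_len(m_genic)] <-
          as.integer(gs + floor(runif(m_genic) * (ge - gs)))
      }
      if (m_inter > 0) {
        ic <- sample.int(config$n_chromosomes, m_inter, replace = TRUE)
        cmax <- vapply(seq_len(config$n_chromosomes), function(ci) {
          e <- genes$end[chrom_idx == ci]
          if (length(e)) max(e) + 50000 else 100000
        }, numeric(1))
        tstart[m_genic + seq_len(m_inter)] <-
          as.integer(floor(runif(m_inter) * cmax[ic]))
        tchrom_inter <- paste0("chr", ic)
      }
      tchrom <- character(m)
      if (m_genic > 0) tchrom[seq_len(m_genic)] <- genes$chrom[gidx]
      if (m_inter > 0) tchrom[m_genic + seq_len(m_inter)] <- tchrom_inter

      tes <- data.frame(
        species = sp, chrom = tchrom,
        start = tstart, end = tstart + telen,
        te_class = cls,
        family = paste0(te_class_token(cls), "-f",
                        sample.int(6L, m, replace = TRUE)),
        percent_identity = ident,
        stringsAsFactors = FALSE)
    } else {
      tes <- data.frame(species = character(), chrom = character(),
                        start = integer(), end = integer(),
                        te_class = character(), family = character(),
                        percent_identity = numeric(),
                        stringsAsFactors = FALSE)
    }

    ## expression: baseline + tissue + species effects + planted deltas
    sp_eff <- rnorm(n, 0, config$species_effect_sd)
    x <- mu + sp_eff + tissue_eff +
      matrix(rnorm(n * nt, 0, config$noise_sd), n, nt)
    colnames(x) <- config$tissues

    pe <- config$planted_effects
    if (!is.null(pe) && any(pe$species == sp)) {
      ## carrier status via the analysis pipeline itself
      prof <- build_profiles(
        genes, intersect_genes_tes(flank_genes(genes, config$flank), tes))
      for (r in which(pe$species == sp)) {
        col <- paste0("n_", te_class_token(pe$te_class[r]), "_", pe$age_group[r])
        carrier <- prof$gene_id[prof[[col]] > 0]
        ix <- match(carrier, genes$gene_id)
        if (length(ix) && pe$delta[r] != 0) {
          x[ix, pe$tissue[r]] <- x[ix, pe$tissue[r]] + pe$delta[r]
        }
        if (length(ix)) {
          truth_all[[length(truth_all) + 1L]] <- data.frame(
            gene_id = carrier, species = sp, tissue = pe$tissue[r],
            te_class = pe$te_class[r], age_group = pe$age_group[r],
            delta = pe$delta[r], stringsAsFactors = FALSE)
        }
      }
    }

    tpm <- round(2^x, 3)
    zero <- matrix(runif(n * nt) < config$zero_rate, n, nt)
    tpm[zero] <- 0
    rownames(tpm) <- gene_id
    colnames(tpm) <- paste(sp, config$tissues, sep = "_")

    genes_all[[si]] <- genes
    tes_all[[si]] <- tes
    expr_all[[si]] <- tpm
  }

  genes <- do.call(rbind, genes_all)
  tes <- do.call(rbind, tes_all)
  rownames(genes) <- rownames(tes) <- NULL

  ## combined matrix: rows = all genes, columns = all samples; a species'
  ## samples carry values only for its own genes
  all_ids <- genes$gene_id
  all_samples <- unlist(lapply(expr_all, colnames), use.names = FALSE)
  values <- matrix(NA_real_, length(all_ids), length(all_samples),
                   dimnames = list(all_ids, all_samples))
  for (si in seq_along(config$species)) {
    values[rownames(expr_all[[si]]), colnames(expr_all[[si]])] <- expr_all[[si]]
  }
  sample_meta <- data.frame(
    sample_id = all_samples,
    species = rep(config$species, each = nt),
    tissue = rep(config$tissues, times = length(config$species)),
    study = "synthetic", stringsAsFactors = FALSE)
  expression <- expression_table(values, sample_meta)

  orthologs <- data.frame(
    group_id = rep(sprintf("OG%05d", seq_len(n_orth)),
                   times = length(config$species)),
    species = rep(config$species, each = n_orth),
    gene_id = unlist(lapply(config$species, function(sp)
      sprintf("%s_g%05d", sp, seq_len(n_orth))), use.names = FALSE),
    stringsAsFactors = FALSE)

  truth <- if (length(truth_all)) do.call(rbind, truth_all) else
    data.frame(gene_id = character(), species = character(),
               tissue = character(), te_class = character(),
               age_group = character(), delta = numeric(),
               stringsAsFactors = FALSE)

  structure(list(genes = genes, te_insertions = tes,
                 expression = expression, orthologs = orthologs,
                 truth = truth, config = config),
            class = "te_dataset")
}

#' @export
print.te_dataset <- function(x, ...) {
  cat("Synthetic TE/expression dataset\n")
  cat(sprintf("  %d genes (%d species), %d TE insertions, %d samples\n",
              nrow(x$genes), length(unique(x$genes$species)),
              nrow(x$te_insertions), ncol(x$expression$values)))
  cat(sprintf("  ortholog groups: %d; truth rows: %d\n",
              length(unique(x$orthologs$group_id)), nrow(x$truth)))
  invisible(x)
}
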