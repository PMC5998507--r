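## Gene/TE intersection and per-gene TE composition profiles: flank genes by
## 1 kb, overlap with TE insertions under half-open semantics, classify
## insertions by age (>= 94 percent identity = species-specific), bin gene
## lengths into equal-frequency deciles, and derive the test/reference gene
## pools for a focal (class, age) element.

#' Classify TE insertions by age
#'
#' Species-specific ("ss") insertions are those with percent identity at or
#' above the threshold (boundary inclusive); all others are
#' non-species-specific ("ns").
#'
#' @param te numeric vector of percent identities, or a TE data.frame with a
#'   `percent_identity` column.
#' @param threshold identity threshold in percent (default 94).
#' @return character vector of `"ss"`/`"ns"`.
#' @export
classify_te_age <- function(te, threshold = 94) {
  ident <- if (is.data.frame(te)) te$percent_identity else te
  if (!is.numeric(ident)) validation_error("percent identity must be numeric")
  ifelse(ident >= threshold, "ss", "ns")
}

#' Flank gene extents
#'
#' Extends every gene by `flank` bp on both sides regardless of strand,
#' clipping at position 0 on the left.
#'
#' @param genes gene data.frame (`chrom`, `start`, `end`, ...).
#' @param flank flank size in bp (default 1000).
#' @return the same data.frame with extended `start`/`end`.
#' @export
flank_genes <- function(genes, flank = 1000) {
  if (flank < 0) validation_error("flank must be >= 0")
  genes$start <- pmax(0L, genes$start - as.integer(flank))
  genes$end <- genes$end + as.integer(flank)
  genes
}

#' Intersect gene intervals with TE insertions
#'
#' A TE overlaps a gene iff the two intervals share at least 1 bp under
#' 0-based half-open semantics on the same chromosome (and species, when
#' both inputs carry a `species` column).  A TE may be assigned to several
#' overlapping genes.
#'
#' @param genes gene intervals (typically [flank_genes()] output).
#' @param tes TE data.frame.
#' @return data.frame with one row per (gene, TE) overlap: `gene_id` plus the
#'   TE columns `te_class`, `family`, `percent_identity`, `te_start`,
#'   `te_end`.
#' @export
intersect_genes_tes <- function(genes, tes) {
  empty <- data.frame(gene_id = character(), te_class = character(),
                      family = character(), percent_identity = numeric(),
                      te_start = integer(), te_end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(genes) == 0 || nrow(tes) == 0) return(empty)
  gsp <- if ("species" %in% names(genes)) genes$species else ""
  tsp <- if ("species" %in% names(tes)) tes$species else ""
  gkey <- paste0(gsp, "#", genes$chrom)
  tkey <- paste0(tsp, "#", tes$chrom)
  stray <- setdiff(unique(tkey), unique(gkey))
  if (length(stray))
    warning("TE chromosomes absent from gene annotation: ",
            paste(sub("^#", "", sub("#", ":", stray)), collapse = ", "))
  lv <- union(unique(gkey), unique(tkey))
  ## half-open [s, e) == 1-based closed [s + 1, e]; >= 1 bp shared
  gr_g <- GenomicRanges::GRanges(factor(gkey, levels = lv),
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  gr_t <- GenomicRanges::GRanges(factor(tkey, levels = lv),
                                 IRanges::IRanges(tes$start + 1L, tes$end))
  hits <- GenomicRanges::findOverlaps(gr_t, gr_g)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  data.frame(gene_id = genes$gene_id[si],
             te_class = tes$te_class[qi],
             family = tes$family[qi],
             percent_identity = tes$percent_identity[qi],
             te_start = tes$start[qi], te_end = tes$end[qi],
             stringsAsFactors = FALSE)
}

#' Assign equal-frequency gene-length bins
#'
#' Lengths are split into `n_bins` equal-frequency bins (deciles by default)
#' within the supplied gene universe; ties are broken by stable gene-ID
#' order.  If every length is identical the binning is degenerate: all genes
#' land in bin 1 with a warning.
#'
#' @param genes gene data.frame (`start`/`end` or `gene_length`), a profile
#'   table, or a named numeric vector of lengths.
#' @param n_bins number of bins (default 10).
#' @return named integer vector of bins in `1..n_bins`.
#' @export
assign_length_bins <- function(genes, n_bins = 10) {
  if (is.data.frame(genes)) {
    lens <- if ("gene_length" %in% names(genes)) genes$gene_length
            else genes$end - genes$start
    ids <- genes$gene_id
  } else {
    lens <- as.numeric(genes)
    ids <- names(genes)
    if (is.null(ids)) ids <- as.character(seq_along(lens))
  }
  if (length(lens) == 0) validation_error("empty gene list")
  if (length(unique(lens)) == 1L && length(lens) > 1L) {
    warning("all gene lengths identical; every gene assigned to bin 1")
    return(setNames(rep(1L, length(lens)), ids))
  }
  ord <- order(lens, ids)
  bin <- integer(length(lens))
  bin[ord] <- as.integer(ceiling(seq_along(ord) * n_bins / length(ord)))
  setNames(bin, ids)
}

#' Build per-gene TE composition profiles
#'
#' One profile per gene: counts and presence per (TE class x age group),
#' gene length (flanks excluded), an equal-frequency length bin, and a
#' canonical composition key.  Genes with no overlapping TE are the "no TE"
#' set (all presence false).
#'
#' @param genes gene data.frame with original (unflanked) coordinates.
#' @param te_overlaps output of [intersect_genes_tes()].
#' @param n_bins length bins (default 10).
#' @param identity_threshold ss/ns identity boundary (default 94).
#' @return data.frame with columns `gene_id`, `species`, `is_ortholog` (when
#'   available), `gene_length`, `length_bin`, one `n_<class>_<age>` count
#'   column per element, and `composition_key`.
#' @export
build_profiles <- function(genes, te_overlaps, n_bins = 10,
                           identity_threshold = 94) {
  if (nrow(genes) == 0) validation_error("empty gene list")
  keys <- te_element_keys()
  if (nrow(te_overlaps)) {
    okey <- paste0(te_overlaps$te_class, ":",
                   classify_te_age(te_overlaps$percent_identity,
                                   identity_threshold))
    tab <- table(factor(te_overlaps$gene_id, levels = genes$gene_id),
                 factor(okey, levels = keys))
    counts <- matrix(as.integer(tab), nrow = nrow(genes),
                     dimnames = list(genes$gene_id, keys))
  } else {
    counts <- matrix(0L, nrow(genes), length(keys),
                     dimnames = list(genes$gene_id, keys))
  }
  prof <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  if ("species" %in% names(genes)) prof$species <- genes$species
  if ("is_ortholog" %in% names(genes)) prof$is_ortholog <- genes$is_ortholog
  prof$gene_length <- genes$end - genes$start
  prof$length_bin <- unname(assign_length_bins(
    setNames(prof$gene_length, prof$gene_id), n_bins))
  cc <- as.data.frame(counts)
  names(cc) <- te_count_columns()
  prof <- cbind(prof, cc)
  prof$composition_key <- composition_key(prof)
  rownames(prof) <- NULL
  prof
}

#' Canonical composition key of a profile
#'
#' Encodes the set of (class, age) elements present in a gene (sorted, hence
#' order-independent) together with its length bin, e.g.
#' `"LINE:ns+SINE:ss|L4"`; genes with no TEs get `"none|L<bin>"`.  With
#' `exclude`, the focal element is left out of the key — this is the stratum
#' used for sampling-weight matching.
#'
#' @param profiles a profile table from [build_profiles()].
#' @param exclude optional element key `"<class>:<age>"` to ignore.
#' @return character vector of keys, one per profile row.
#' @export
composition_key <- function(profiles, exclude = NULL) {
  keys <- te_element_keys()
  cols <- te_count_columns()
  keep <- rep(TRUE, length(keys))
  if (!is.null(exclude)) keep <- keys != exclude
  present <- as.matrix(profiles[, cols[keep], drop = FALSE]) > 0
  ord_keys <- sort(keys[keep])  # canonical order
  present <- present[, match(ord_keys, keys[keep]), drop = FALSE]
  body <- apply(present, 1L, function(p)
    if (any(p)) paste(ord_keys[p], collapse = "+") else "none")
  paste0(body, "|L", profiles$length_bin)
}

#' Matching stratum of each gene
#'
#' The stratum used for sampling-weight matching: the set of co-occurring TE
#' classes present in the gene other than the focal class (any age), plus
#' the gene-length bin — e.g. `"DNA+LINE|L4"`.  Classes (not class-age
#' elements) define the stratum so that stratum frequencies stay estimable:
#' with four classes and ten length bins there are at most 80 strata.
#'
#' @param profiles a profile table from [build_profiles()].
#' @param focal_class TE class whose presence is ignored.
#' @return character vector of stratum keys, one per profile row.
#' @export
stratum_key <- function(profiles, focal_class) {
  other <- setdiff(TE_CLASSES, focal_class)
  present <- vapply(other, function(cl) {
    cols <- paste0("n_", te_class_token(cl), "_", AGE_GROUPS)
    rowSums(as.matrix(profiles[, cols, drop = FALSE])) > 0
  }, logical(nrow(profiles)))
  present <- matrix(present, nrow = nrow(profiles))
  body <- apply(present, 1L, function(p)
    if (any(p)) paste(other[p], collapse = "+") else "none")
  paste0(body, "|L", profiles$length_bin)
}

#' Split a gene universe into test and reference pools
#'
#' The test pool holds the genes whose profile contains the focal
#' (class, age) element; the reference pool holds all other genes of the
#' universe (they may carry other classes, or the same class at the other
#' age, or no TE at all).  Genes carrying the focal class at both ages go to
#' the test pool; their number is recorded in `n_both_ages` so the choice
#' can be sensitivity-checked.
#'
#' @param profiles profile table restricted to one gene universe (one
#'   species, orthologs or non-orthologs).
#' @param focal_class one of `DNA`, `ERV/LTR`, `LINE`, `SINE`.
#' @param focal_age `"ss"` or `"ns"`.
#' @param universe optional label stored on the pair.
#' @return object of class `te_gene_set_pair` with elements
#'   `test_profiles`, `ref_profiles`, `focal_class`, `focal_age`,
#'   `universe`, `n_both_ages`, `usable`.
#' @export
build_gene_set_pair <- function(profiles, focal_class, focal_age,
                                universe = NULL) {
  if (!focal_class %in% TE_CLASSES)
    validation_error(paste0("unknown TE class: ", focal_class))
  if (!focal_age %in% AGE_GROUPS)
    validation_error(paste0("unknown age group: ", focal_age))
  col <- paste0("n_", te_class_token(focal_class), "_", focal_age)
  other <- paste0("n_", te_class_token(focal_class), "_",
                  setdiff(AGE_GROUPS, focal_age))
  in_test <- profiles[[col]] > 0
  structure(list(
    test_profiles = profiles[in_test, , drop = FALSE],
    ref_profiles = profiles[!in_test, , drop = FALSE],
    focal_class = focal_class, focal_age = focal_age,
    universe = universe,
    n_both_ages = sum(in_test & profiles[[other]] > 0),
    usable = any(in_test)
  ), class = "te_gene_set_pair")
}

#' @export
print.te_gene_set_pair <- function(x, ...) {
  cat(sprintf("Gene set pair, focal %s:%s%s\n", x$focal_class, x$focal_age,
              if (is.null(x$universe)) "" else paste0(" (", x$universe, ")")))
  cat(sprintf("  test pool: %d genes (%d with both ages); reference pool: %d genes\n",
              nrow(x$test_profiles), x$n_both_ages, nrow(x$ref_profiles)))
  invisible(x)
}

#' Convenience: profiles for every species of a dataset
#'
#' Flanks genes, intersects with the TE annotation, classifies insertion
#' ages and builds composition profiles, per species.
#'
#' @param genes gene data.frame (or a `te_dataset`, in which case `tes` is
#'   taken from it).
#' @param tes TE data.frame.
#' @param flank flank in bp (default 1000).
#' @param n_bins length bins (default 10).
#' @param identity_threshold ss/ns boundary (default 94).
#' @return profile table covering all species.
#' @export
te_profiles <- function(genes, tes = NULL, flank = 1000, n_bins = 10,
                        identity_threshold = 94) {
  if (inherits(genes, "te_dataset")) {
    tes <- genes$te_insertions
    genes <- genes$genes
  }
  sp <- unique(genes$species)
  out <- lapply(sp, function(s) {
    g <- genes[genes$species == s, , drop = FALSE]
    t <- tes[tes$species == s, , drop = FALSE]
    ov <- intersect_genes_tes(flank_genes(g, flank), t)
    build_profiles(g, ov, n_bins = n_bins,
                   identity_threshold = identity_threshold)
  })
  do.call(rbind, out)
}
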