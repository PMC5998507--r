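## Readers/writers for gene annotations (GFF3/GTF/BED), TE annotations
## (BED6+2 TSV), TPM expression matrices and ortholog tables.  Internal
## coordinates are uniformly 0-based half-open (BED convention); GFF3/GTF
## converters handle the 1-based inclusive representation.  Expression stays
## in TPM at I/O; any log transform happens downstream.

validation_error <- function(msg) {
  stop(structure(
    class = c("teboot_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))))
}

#' Construct and validate an expression table
#'
#' @param values numeric matrix of TPM, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs).  `NA` marks a gene/sample
#'   pair from different species.
#' @param sample_meta data.frame with columns `sample_id`, `species`,
#'   `tissue` (optionally `study`), one row per column of `values`.
#' @return object of class `te_expression`.
#' @export
expression_table <- function(values, sample_meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0)
    validation_error("expression matrix must have gene IDs as rownames")
  if (anyDuplicated(colnames(values)))
    validation_error("duplicate sample IDs in expression matrix")
  if (!all(c("sample_id", "species", "tissue") %in% names(sample_meta)))
    validation_error("sample_meta needs columns sample_id, species, tissue")
  missing_meta <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(missing_meta))
    validation_error(paste0("samples missing from metadata: ",
                            paste(missing_meta, collapse = ", ")))
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  if (any(is.na(sample_meta$species)) || any(is.na(sample_meta$tissue)))
    validation_error("every sample needs species and tissue")
  if (any(values < 0, na.rm = TRUE))
    validation_error("TPM values must be non-negative")
  structure(list(values = values, sample_meta = sample_meta,
                 gene_ids = rownames(values)),
            class = "te_expression")
}

#' @export
print.te_expression <- function(x, ...) {
  cat(sprintf("TPM expression table: %d genes x %d samples (%d species, %d tissues)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_meta$species)),
              length(unique(x$sample_meta$tissue))))
  invisible(x)
}

#' Read gene annotations
#'
#' GFF3/GTF `gene` features are converted from 1-based inclusive to 0-based
#' half-open coordinates; BED is taken as-is.  Gzipped files are accepted.
#'
#' @param path annotation file.
#' @param format one of `"gff3"`, `"gtf"`, `"bed"`.
#' @param species species label attached to every record.
#' @return data.frame with columns `gene_id`, `species`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `is_ortholog` (NA until an ortholog
#'   table is joined).
#' @export
read_genes <- function(path, format = c("gff3", "gtf", "bed"),
                       species = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) validation_error(paste0("no such file: ", path))
  if (format %in% c("gff3", "gtf")) {
    gr <- rtracklayer::import(path, format = format)
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[as.character(gr$type) == "gene"]
    ids <- if (format == "gff3") {
      if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    } else {
      as.character(gr$gene_id)
    }
    out <- data.frame(
      gene_id = ids, species = species,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # 1-based -> 0-based
      end = GenomicRanges::end(gr),
      strand = sub("\\*", "unknown", as.character(GenomicRanges::strand(gr))),
      is_ortholog = NA, stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    out <- data.frame(
      gene_id = as.character(gr$name), species = species,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # rtracklayer stores 1-based
      end = GenomicRanges::end(gr),
      strand = sub("\\*", "unknown", as.character(GenomicRanges::strand(gr))),
      is_ortholog = NA, stringsAsFactors = FALSE)
  }
  if (any(is.na(out$gene_id)) || any(out$gene_id == ""))
    validation_error("gene records without an ID")
  if (anyDuplicated(out$gene_id))
    validation_error(paste0("duplicate gene_id within species: ",
                            out$gene_id[duplicated(out$gene_id)][1]))
  if (any(out$end <= out$start))
    validation_error("gene with end <= start")
  rownames(out) <- NULL
  out
}

#' Write gene annotations
#'
#' @param genes gene data.frame as returned by [read_genes()].
#' @param path output file.
#' @param format `"gff3"` or `"bed"`.
#' @export
write_genes <- function(genes, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  strand <- sub("unknown", "*", genes$strand)
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = strand)
  if (format == "gff3") {
    gr$ID <- genes$gene_id
    gr$type <- "gene"
    gr$source <- "teboot"
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    gr$name <- genes$gene_id
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Default TE class alias table
#'
#' Maps common repeat-annotation labels onto the four canonical TE classes.
#' @return named character vector alias -> class.
#' @export
te_class_aliases <- function() {
  c("Alu" = "SINE", "MIR" = "SINE", "Retroposon" = "SINE", "tRNA" = "SINE",
    "L1" = "LINE", "L2" = "LINE", "CR1" = "LINE",
    "LTR" = "ERV/LTR", "ERV" = "ERV/LTR", "ERVL" = "ERV/LTR",
    "ERVK" = "ERV/LTR", "Gypsy" = "ERV/LTR",
    "hAT" = "DNA", "TcMar" = "DNA", "Helitron" = "DNA")
}

#' Read a TE annotation table
#'
#' BED-like TSV with header columns `chrom`, `start`, `end`, `family`,
#' `score`, `strand`, `te_class`, `percent_identity` (BED6 + 2).
#' Coordinates are 0-based half-open.
#'
#' @param path TSV file (optionally gzipped).
#' @param species species label attached to every record.
#' @param aliases optional named character vector mapping non-canonical
#'   `te_class` labels to the four classes (see [te_class_aliases()]);
#'   unknown labels not covered by an alias are rejected.
#' @return data.frame with columns `species`, `chrom`, `start`, `end`,
#'   `te_class`, `family`, `percent_identity`.
#' @export
read_te_annotation <- function(path, species = "unknown", aliases = NULL) {
  if (!file.exists(path)) validation_error(paste0("no such file: ", path))
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "te_class", "percent_identity")
  if (!all(need %in% names(d)))
    validation_error(paste0("TE table must have columns: ",
                            paste(need, collapse = ", ")))
  if (!"family" %in% names(d)) d$family <- d$te_class
  if (nrow(d)) {
    unknown <- !(d$te_class %in% TE_CLASSES)
    if (any(unknown) && !is.null(aliases)) {
      mapped <- aliases[d$te_class[unknown]]
      ok <- !is.na(mapped)
      d$te_class[unknown][ok] <- mapped[ok]
      unknown <- !(d$te_class %in% TE_CLASSES)
    }
    if (any(unknown))
      validation_error(paste0("unknown te_class values: ",
                              paste(unique(d$te_class[unknown]), collapse = ", ")))
    if (any(d$percent_identity < 0 | d$percent_identity > 100))
      validation_error("percent_identity outside [0, 100]")
    if (any(d$end <= d$start))
      validation_error("TE with end <= start")
  }
  out <- data.frame(species = rep(species, nrow(d)), chrom = d$chrom,
                    start = as.integer(d$start), end = as.integer(d$end),
                    te_class = d$te_class, family = d$family,
                    percent_identity = as.numeric(d$percent_identity),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a TE annotation table (BED6 + 2 TSV)
#' @param tes TE data.frame as returned by [read_te_annotation()].
#' @param path output TSV.
#' @export
write_te_annotation <- function(tes, path) {
  out <- data.frame(chrom = tes$chrom, start = tes$start, end = tes$end,
                    family = tes$family, score = rep(0L, nrow(tes)),
                    strand = rep(".", nrow(tes)),
                    te_class = tes$te_class,
                    percent_identity = tes$percent_identity,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix with sample metadata
#'
#' @param path TSV whose first column is `gene_id` and remaining columns are
#'   sample IDs holding TPM values.
#' @param meta_path TSV with columns `sample_id`, `species`, `tissue`
#'   (optionally `study`).
#' @param genes optional gene annotation (from [read_genes()]); expression
#'   rows absent from it are retained but listed in the `unannotated`
#'   attribute of the result.
#' @return a `te_expression` object (see [expression_table()]).
#' @export
read_expression <- function(path, meta_path, genes = NULL) {
  if (!file.exists(path)) validation_error(paste0("no such file: ", path))
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  if (names(d)[1] != "gene_id")
    validation_error("first expression column must be gene_id")
  values <- as.matrix(d[, -1, drop = FALSE])
  rownames(values) <- d$gene_id
  out <- expression_table(values, meta)
  if (!is.null(genes))
    attr(out, "unannotated") <- setdiff(d$gene_id, genes$gene_id)
  out
}

#' Write an expression matrix and its sample metadata
#' @param expr a `te_expression` object.
#' @param path,meta_path output TSVs.
#' @export
write_expression <- function(expr, path, meta_path) {
  d <- data.frame(gene_id = rownames(expr$values), expr$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(expr$sample_meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a single-copy ortholog table
#'
#' Long-format TSV with columns `group_id`, `species`, `gene_id`.  A group
#' with two genes for one species violates the single-copy constraint and is
#' rejected; groups missing some species are accepted and flagged in the
#' `incomplete_groups` attribute.
#'
#' @param path TSV file.
#' @return data.frame (`group_id`, `species`, `gene_id`) with attribute
#'   `incomplete_groups`.
#' @export
read_orthologs <- function(path) {
  if (!file.exists(path)) validation_error(paste0("no such file: ", path))
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (!all(c("group_id", "species", "gene_id") %in% names(d)))
    validation_error("ortholog table needs columns group_id, species, gene_id")
  if (anyDuplicated(d[, c("group_id", "species")]))
    validation_error("single-copy violated: a group has two genes for one species")
  if (anyDuplicated(d$gene_id))
    validation_error("a gene_id appears in more than one ortholog group")
  n_sp <- length(unique(d$species))
  per_group <- table(d$group_id)
  attr(d, "incomplete_groups") <- names(per_group)[per_group < n_sp]
  d
}

#' Write an ortholog table
#' @param orthologs long-format data.frame (`group_id`, `species`, `gene_id`).
#' @param path output TSV.
#' @export
write_orthologs <- function(orthologs, path) {
  write.table(orthologs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Emits per-species gene annotations as GFF3 and BED, TE annotations as
#' BED6+2 TSV, the expression matrix and sample metadata, the ortholog table
#' and the planted-effect truth table.  All files round-trip losslessly
#' through [read_te_dataset()].
#'
#' @param ds a `te_dataset` from [simulate_te_dataset()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a manifest data.frame (`file`, `md5`, `n_records`).
#' @export
write_te_dataset <- function(ds, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0); counts <- integer(0)
  add <- function(f, n) { files <<- c(files, f); counts <<- c(counts, n) }
  for (sp in unique(c(ds$genes$species, ds$te_insertions$species))) {
    g <- ds$genes[ds$genes$species == sp, , drop = FALSE]
    t <- ds$te_insertions[ds$te_insertions$species == sp, , drop = FALSE]
    fg <- file.path(out_dir, paste0("genes_", sp, ".gff3"))
    fb <- file.path(out_dir, paste0("genes_", sp, ".bed"))
    ft <- file.path(out_dir, paste0("te_", sp, ".tsv"))
    write_genes(g, fg, "gff3"); add(fg, nrow(g))
    write_genes(g, fb, "bed"); add(fb, nrow(g))
    write_te_annotation(t, ft); add(ft, nrow(t))
  }
  fe <- file.path(out_dir, "expression.tsv")
  fm <- file.path(out_dir, "samples.tsv")
  write_expression(ds$expression, fe, fm)
  add(fe, nrow(ds$expression$values)); add(fm, nrow(ds$expression$sample_meta))
  fo <- file.path(out_dir, "orthologs.tsv")
  write_orthologs(ds$orthologs, fo); add(fo, nrow(ds$orthologs))
  fr <- file.path(out_dir, "truth.tsv")
  write.table(ds$truth, fr, sep = "\t", quote = FALSE, row.names = FALSE)
  add(fr, nrow(ds$truth))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(files)),
                         n_records = counts, stringsAsFactors = FALSE)
  invisible(manifest)
}

#' Read a dataset directory written by [write_te_dataset()]
#'
#' @param dir dataset directory.
#' @return a `te_dataset` (without the generating config).
#' @export
read_te_dataset <- function(dir) {
  meta <- read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
  species <- unique(meta$species)
  orthologs <- read_orthologs(file.path(dir, "orthologs.tsv"))
  genes <- do.call(rbind, lapply(species, function(sp)
    read_genes(file.path(dir, paste0("genes_", sp, ".gff3")), "gff3", sp)))
  genes$is_ortholog <- genes$gene_id %in% orthologs$gene_id
  tes <- do.call(rbind, lapply(species, function(sp)
    read_te_annotation(file.path(dir, paste0("te_", sp, ".tsv")), sp)))
  expression <- read_expression(file.path(dir, "expression.tsv"),
                                file.path(dir, "samples.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path))
    read.delim(truth_path, stringsAsFactors = FALSE) else NULL
  if (!is.null(truth) && nrow(truth) == 0) {
    truth <- data.frame(gene_id = character(), species = character(),
                        tissue = character(), te_class = character(),
                        age_group = character(), delta = numeric(),
                        stringsAsFactors = FALSE)
  }
  structure(list(genes = genes, te_insertions = tes, expression = expression,
                 orthologs = orthologs, truth = truth, config = NULL),
            class = "te_dataset")
}

#' Map an expression matrix onto ortholog groups
#'
#' Builds a cross-species matrix with one row per ortholog group, taking for
#' each sample the value of that species' group member.  Used for clustering
#' samples from several species on a common gene universe.
#'
#' @param expr a `te_expression` object.
#' @param orthologs long-format ortholog table.
#' @param complete_only drop groups with missing values in any sample.
#' @return numeric matrix, ortholog groups x samples.
#' @export
ortholog_expression <- function(expr, orthologs, complete_only = TRUE) {
  groups <- unique(orthologs$group_id)
  out <- matrix(NA_real_, length(groups), ncol(expr$values),
                dimnames = list(groups, colnames(expr$values)))
  for (sp in unique(orthologs$species)) {
    cols <- expr$sample_meta$sample_id[expr$sample_meta$species == sp]
    if (!length(cols)) next
    o <- orthologs[orthologs$species == sp, ]
    present <- o$gene_id %in% rownames(expr$values)
    out[o$group_id[present], cols] <-
      expr$values[o$gene_id[present], cols, drop = FALSE]
  }
  if (complete_only) out <- out[complete.cases(out), , drop = FALSE]
  out
}
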