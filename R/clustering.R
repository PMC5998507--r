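## Expression-based sample clustering: pairwise distances on log2(TPM + 1)
## profiles, UPGMA / Ward.D2 dendrograms with fixed-k cuts, and PCA.

#' Pairwise distances between expression samples
#'
#' Distances are computed between sample vectors after a log2(TPM + 1)
#' transform (the pseudocount keeps unexpressed genes in the vectors;
#' the bootstrap statistic, by contrast, omits zeros and uses log2(TPM)).
#'
#' @param x numeric matrix genes x samples (e.g. [ortholog_expression()]
#'   output) or a `te_expression` object.
#' @param transform `"log2p1"` (default) or `"none"`.
#' @param metric `"euclidean"` (default) or `"spearman"`
#'   (1 - Spearman correlation).
#' @return a `dist` object over samples with attribute `metric`.
#' @export
expression_distance <- function(x, transform = c("log2p1", "none"),
                                metric = c("euclidean", "spearman")) {
  transform <- match.arg(transform)
  metric <- match.arg(metric)
  if (inherits(x, "te_expression")) x <- x$values
  if (ncol(x) < 2) validation_error("need at least 2 samples")
  if (any(colSums(x, na.rm = TRUE) == 0))
    warning("sample(s) with all-zero expression")
  if (transform == "log2p1") x <- log2(x + 1)
  d <- if (metric == "euclidean") {
    dist(t(x))
  } else {
    as.dist(1 - cor(x, method = "spearman"))
  }
  attr(d, "metric") <- metric
  d
}

#' Hierarchical clustering of samples
#'
#' UPGMA (average linkage, giving an ultrametric tree) or Ward's minimum
#' variance criterion in its D2 form, which expects unsquared Euclidean
#' distances and does the squared-distance bookkeeping internally.  The tree
#' is cut to exactly `k` clusters.
#'
#' @param d a `dist` from [expression_distance()].
#' @param method `"upgma"` or `"ward_d2"`.
#' @param k number of clusters to cut (defaults: 5 for UPGMA, 7 for
#'   Ward.D2).
#' @return object of class `te_clustering`: list with the `hclust` tree,
#'   `labels` (cluster of each sample), `method`, `k`.
#' @export
hierarchical_cluster <- function(d, method = c("upgma", "ward_d2"), k = NULL) {
  method <- match.arg(method)
  n <- attr(d, "Size")
  if (is.null(k)) k <- if (method == "upgma") 5L else 7L
  if (k > n) validation_error("k must not exceed the number of samples")
  h <- hclust(d, method = if (method == "upgma") "average" else "ward.D2")
  structure(list(hclust = h, labels = cutree(h, k = k),
                 method = method, k = as.integer(k),
                 metric = attr(d, "metric")),
            class = "te_clustering")
}

#' @export
print.te_clustering <- function(x, ...) {
  cat(sprintf("%s clustering of %d samples cut at k = %d\n",
              toupper(x$method), length(x$labels), x$k))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @method plot te_clustering
#' @export
plot.te_clustering <- function(x, ...) {
  plot(x$hclust, main = sprintf("%s dendrogram (k = %d)",
                                toupper(x$method), x$k),
       xlab = "", sub = "", ...)
  if (x$k > 1 && x$k < length(x$labels))
    stats::rect.hclust(x$hclust, k = x$k, border = "grey40")
  invisible(x)
}

#' Scatter plot of samples on two principal components
#'
#' @param p result of [pca_samples()].
#' @param dims two component indices (default first two).
#' @param labels optional point labels (e.g. tissue); defaults to sample IDs.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot_pca_samples <- function(p, dims = c(1, 2), labels = NULL, ...) {
  sc <- p$scores
  if (ncol(sc) < max(dims)) validation_error("not enough components")
  if (is.null(labels)) labels <- rownames(sc)
  vf <- round(100 * p$variance_fraction[dims], 1)
  graphics::plot(sc[, dims[1]], sc[, dims[2]],
                 xlab = sprintf("PC%d (%.1f%%)", dims[1], vf[1]),
                 ylab = sprintf("PC%d (%.1f%%)", dims[2], vf[2]),
                 pch = 19, col = "grey40", ...)
  graphics::text(sc[, dims[1]], sc[, dims[2]], labels, pos = 3, cex = 0.7)
  invisible(p)
}

#' Export a dendrogram as Newick
#' @param clustering a `te_clustering` (or `hclust`) object.
#' @param path output file.
#' @export
export_newick <- function(clustering, path) {
  h <- if (inherits(clustering, "te_clustering")) clustering$hclust
       else clustering
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Principal component analysis of expression samples
#'
#' Samples are projected onto the principal components of their
#' log2(TPM + 1) profiles after per-gene centering.  Variance fractions sum
#' to at most 1 and are non-increasing; a constant matrix yields all-zero
#' coordinates and fractions.
#'
#' @param x numeric matrix genes x samples or a `te_expression`.
#' @param n_components number of components to keep (default: all).
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return list with `scores` (samples x components), `variance_fraction`,
#'   and the fitted `prcomp` object.
#' @export
pca_samples <- function(x, n_components = NULL,
                        transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  if (inherits(x, "te_expression")) x <- x$values
  if (ncol(x) < 2) validation_error("need at least 2 samples")
  if (transform == "log2p1") x <- log2(x + 1)
  p <- prcomp(t(x), center = TRUE, scale. = FALSE)
  total <- sum(p$sdev^2)
  vf <- if (total > 0) p$sdev^2 / total else rep(0, length(p$sdev))
  k <- if (is.null(n_components)) length(vf)
       else min(n_components, length(vf))
  scores <- p$x[, seq_len(k), drop = FALSE]
  if (total == 0) scores[] <- 0
  list(scores = scores, variance_fraction = vf[seq_len(k)], prcomp = p)
}
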