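#' Principal component analysis of samples
#'
#' Singular value decomposition of the gene-centered log-expression matrix;
#' zero-variance genes are removed before centering. Sample scores and
#' explained-variance fractions are returned.
#'
#' @param logexpr genes x samples log-expression matrix.
#' @return list: `scores` (samples x components), `explained_variance`
#'   (fractions, non-increasing, summing to 1), `sdev`.
#' @export
pca_samples <- function(logexpr) {
  if (ncol(logexpr) < 2L) stop("need at least 2 samples")
  v <- apply(logexpr, 1L, var)
  x <- logexpr[v > 0, , drop = FALSE]
  x <- x - rowMeans(x)
  pc <- prcomp(t(x), center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained_variance = ev, sdev = pc$sdev)
}

#' Hierarchical clustering of samples on Pearson correlation
#'
#' Distance `1 - r` between sample expression profiles, agglomerated with
#' the selected linkage. Ties are broken deterministically by sample order.
#'
#' @param logexpr genes x samples log-expression matrix.
#' @param linkage `"average"` (default), `"complete"`, or `"single"`.
#' @return an `hclust` object.
#' @export
hcluster_samples <- function(logexpr, linkage = c("average", "complete",
                                                  "single")) {
  linkage <- match.arg(linkage)
  if (ncol(logexpr) < 2L) stop("need at least 2 samples")
  v <- apply(logexpr, 2L, var)
  if (any(v == 0))
    stop("zero-variance sample: ", colnames(logexpr)[v == 0][1L])
  d <- as.dist(1 - cor(logexpr))
  hclust(d, method = linkage)
}
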