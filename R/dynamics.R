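#' Catalogue of dynamic expression patterns
#'
#' All sequences of `{UP, DOWN, SAME}` over the `t - 1` consecutive-stage
#' transitions, minus the all-SAME sequence: `3^(t-1) - 1` patterns, in
#' lexicographic order of their labels.
#'
#' @param t number of time points (>= 2).
#' @return character vector of pattern labels such as `"UP.SAME"`.
#' @export
enumerate_patterns <- function(t) {
  if (t < 2L) stop("need at least 2 time points")
  moves <- c("DOWN", "SAME", "UP")
  grid <- do.call(expand.grid,
                  c(rep(list(moves), t - 1L), stringsAsFactors = FALSE))
  lab <- apply(grid, 1L, paste, collapse = ".")
  sort(lab[lab != paste(rep("SAME", t - 1L), collapse = ".")])
}

#' Assign a dynamic pattern from transition-wise DE results
#'
#' Each consecutive-stage transition (contrast later minus earlier, within
#' one genotype) is labeled UP if `q < fdr` and `log2fc >= lfc`, DOWN if
#' `q < fdr` and `log2fc <= -lfc`, else SAME. The all-SAME assignment is
#' reported as `"NONE"`.
#'
#' @param q,log2fc numeric vectors, one entry per transition in stage order.
#' @param fdr,lfc thresholds (defaults 0.05, 1).
#' @return pattern label or `"NONE"`.
#' @export
assign_pattern <- function(q, log2fc, fdr = 0.05, lfc = 1) {
  if (length(q) != length(log2fc) || !length(q))
    stop("need matched q and log2fc for every transition")
  if (anyNA(q) || anyNA(log2fc)) stop("missing transition statistics")
  lab <- ifelse(q < fdr & log2fc >= lfc, "UP",
                ifelse(q < fdr & log2fc <= -lfc, "DOWN", "SAME"))
  out <- paste(lab, collapse = ".")
  if (all(lab == "SAME")) "NONE" else out
}

#' Transition-wise DE within one genotype
#'
#' Reuses the moderated pipeline with contrasts later-stage minus
#' earlier-stage among the samples of a single genotype, then assigns every
#' gene a dynamic pattern.
#'
#' @param fpkm_mat FPKM matrix.
#' @param samples sample metadata.
#' @param genotype which genotype to analyze.
#' @param fdr,lfc pattern thresholds.
#' @param pseudocount log-transform pseudocount.
#' @return list: `patterns` (named character vector per gene),
#'   `transitions` (long data.frame gene/transition/log2fc/q), `rho`.
#' @export
run_transition_patterns <- function(fpkm_mat, samples, genotype,
                                    fdr = 0.05, lfc = 1, pseudocount = 0.5) {
  keep <- samples$genotype == genotype
  if (!any(keep)) stop("no samples for genotype ", genotype)
  sam <- samples[keep, , drop = FALSE]
  logexpr <- log_expression(fpkm_mat[, sam$sample_id, drop = FALSE],
                            pseudocount)
  stage <- factor(sam$stage, levels = sort(unique(sam$stage)))
  design <- model.matrix(~ 0 + stage)
  colnames(design) <- levels(stage)
  st <- levels(stage)
  cmat <- vapply(seq_len(length(st) - 1L), function(j) {
    v <- numeric(ncol(design)); v[j] <- -1; v[j + 1L] <- 1; v
  }, numeric(ncol(design)))
  colnames(cmat) <- paste0(st[-length(st)], "_to_", st[-1L])
  rownames(cmat) <- colnames(design)
  rho <- estimate_lane_correlation(logexpr, design, sam$lane)
  fit <- fit_contrasts(logexpr, design, cmat, rho, sam$lane)
  eb <- limma::eBayes(fit)
  trans <- do.call(rbind, lapply(seq_len(ncol(cmat)), function(j) {
    p <- eb$p.value[, j]
    data.frame(gene = rownames(logexpr), transition = colnames(cmat)[j],
               log2fc = eb$coefficients[, j], q = bh_adjust(p), p = p,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  qmat <- matrix(trans$q, ncol = ncol(cmat))
  fmat <- matrix(trans$log2fc, ncol = ncol(cmat))
  pats <- vapply(seq_len(nrow(logexpr)), function(g)
    assign_pattern(qmat[g, ], fmat[g, ], fdr, lfc), character(1L))
  list(patterns = setNames(pats, rownames(logexpr)), transitions = trans,
       rho = rho)
}

## k-means++ seeding: spread initial centers with probability proportional
## to squared distance from the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' K-means clustering of standardized expression profiles
#'
#' Per-gene profiles (z-scored mean log expression across stages) are
#' clustered by Lloyd's algorithm with k-means++ initialization and
#' multiple restarts, keeping the solution with the smallest within-cluster
#' sum of squares. Deterministic given the seed.
#'
#' @param profiles genes x stages matrix of standardized profiles
#'   (zero-variance genes must be excluded beforehand).
#' @param k number of clusters (default 8).
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts (default 25).
#' @return a `stats::kmeans` object.
#' @export
kmeans_profiles <- function(profiles, k = 8L, seed = 1L, restarts = 25L) {
  profiles <- as.matrix(profiles)
  if (k > nrow(profiles)) stop("k exceeds the number of genes")
  withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(profiles, k)
      centers <- centers + rnorm(length(centers), 0, 1e-9)  # break exact ties
      km <- suppressWarnings(
        kmeans(profiles, centers = centers, iter.max = 100L,
               algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
}

#' Standardized mean expression profiles
#'
#' Per gene: mean log expression per stage within one genotype, z-scored
#' across stages. Genes with zero variance across stages are dropped.
#'
#' @param fpkm_mat FPKM matrix.
#' @param samples sample metadata.
#' @param genotype genotype to profile.
#' @param pseudocount log-transform pseudocount.
#' @return genes x stages matrix.
#' @export
stage_profiles <- function(fpkm_mat, samples, genotype, pseudocount = 0.5) {
  keep <- samples$genotype == genotype
  logexpr <- log_expression(fpkm_mat[, samples$sample_id[keep], drop = FALSE],
                            pseudocount)
  stage <- factor(samples$stage[keep])
  means <- vapply(levels(stage), function(s)
    rowMeans(logexpr[, stage == s, drop = FALSE]), numeric(nrow(logexpr)))
  svec <- apply(means, 1L, sd)
  means <- means[svec > 0, , drop = FALSE]
  (means - rowMeans(means)) / apply(means, 1L, sd)
}

#' Compare dynamic patterns between genotypes
#'
#' @param wt,mut named pattern vectors (gene -> label, `"NONE"` allowed)
#'   from [run_transition_patterns()].
#' @return list: `tally` (pattern x genotype counts over the shared
#'   catalogue), `overlap_genes` (genes with the same non-NONE label in
#'   both), `n_overlap`.
#' @export
compare_genotype_patterns <- function(wt, mut) {
  genes <- intersect(names(wt), names(mut))
  labs <- sort(unique(c(wt, mut)))
  labs <- c(setdiff(labs, "NONE"), if ("NONE" %in% labs) "NONE")
  tally <- cbind(WT = table(factor(wt[genes], levels = labs)),
                 MUT = table(factor(mut[genes], levels = labs)))
  same <- genes[wt[genes] == mut[genes] & wt[genes] != "NONE"]
  list(tally = tally, overlap_genes = same, n_overlap = length(same))
}
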