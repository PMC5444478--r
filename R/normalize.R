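#' Expression filter: minimum count in every replicate of some cell
#'
#' A gene passes when there exists a genotype/stage cell (default scope) or a
#' genotype (scope `"genotype"`) in which every biological replicate has at
#' least `min_count` mapped reads.
#'
#' @param cm a [count_matrix].
#' @param min_count minimum read count per replicate (default 5).
#' @param scope `"cell"` (per genotype/stage cell) or `"genotype"` (all
#'   samples of a genotype).
#' @return character vector of passing gene ids.
#' @export
expression_filter <- function(cm, min_count = 5L, scope = c("cell", "genotype")) {
  scope <- match.arg(scope)
  grp <- if (scope == "cell") sample_cells(cm$samples) else
    factor(cm$samples$genotype)
  pass <- rep(FALSE, nrow(cm$counts))
  for (g in levels(grp)) {
    cols <- which(grp == g)
    if (!length(cols)) next
    pass <- pass | apply(cm$counts[, cols, drop = FALSE] >= min_count, 1L, all)
  }
  rownames(cm$counts)[pass]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample scaling: per-sample factors from
#' doubly trimmed (30% of M, 5% of A tails), inverse-variance-weighted mean
#' log count ratios against a reference sample, rescaled to geometric mean 1.
#' Genes with a zero count in either sample of a comparison are excluded.
#'
#' @param cm a [count_matrix].
#' @param ref_sample reference sample id, or `NULL` to pick the sample whose
#'   upper-quartile (library-size-scaled) count is closest to the mean.
#' @return data.frame with `sample_id`, `library_size`, `tmm_factor`,
#'   `effective_size` (= library_size * tmm_factor).
#' @export
tmm_factors <- function(cm, ref_sample = NULL) {
  counts <- cm$counts
  libsize <- colSums(counts)
  if (any(libsize == 0))
    stop("sample with all-zero counts: ", colnames(counts)[libsize == 0][1L])
  ref <- if (is.null(ref_sample)) NULL else match(ref_sample, colnames(counts))
  f <- edgeR::calcNormFactors(counts, lib.size = libsize, method = "TMM",
                              refColumn = ref,
                              logratioTrim = 0.30, sumTrim = 0.05,
                              doWeighting = TRUE)
  data.frame(sample_id = colnames(counts),
             library_size = unname(libsize),
             tmm_factor = unname(f),
             effective_size = unname(libsize * f),
             stringsAsFactors = FALSE)
}

#' FPKM expression values
#'
#' `fpkm_gi = count_gi / (length_g / 1e3) / (effective_size_i / 1e6)`, with
#' the TMM-effective library size by default.
#'
#' @param cm a [count_matrix].
#' @param annotation gene annotation data.frame with `gene_id`, `length_bp`.
#' @param norm output of [tmm_factors()].
#' @param use_effective use TMM-effective library sizes (default) or raw
#'   column sums.
#' @return numeric matrix of FPKM values; genes lacking a length are dropped
#'   with a warning.
#' @export
fpkm <- function(cm, annotation, norm, use_effective = TRUE) {
  len <- annotation$length_bp[match(rownames(cm$counts), annotation$gene_id)]
  if (anyNA(len)) {
    drop <- rownames(cm$counts)[is.na(len)]
    warning("dropping ", length(drop), " gene(s) without length annotation: ",
            paste(head(drop, 3L), collapse = ", "),
            if (length(drop) > 3L) ", ...")
  }
  keep <- !is.na(len)
  size <- if (use_effective) norm$effective_size else norm$library_size
  size <- size[match(colnames(cm$counts), norm$sample_id)]
  sweep(sweep(cm$counts[keep, , drop = FALSE], 1L, len[keep] / 1e3, "/"),
        2L, size / 1e6, "/")
}

#' Fit the length/GC capture offset
#'
#' Regresses per-gene mean `log((count + 0.5) / effective_size)` on natural
#' cubic splines (4 df each) of log gene length and GC content, additively.
#' The centered fitted values are the per-gene offsets `o_g` used by the
#' activity model.
#'
#' @param cm a [count_matrix] restricted (or not) to filtered genes.
#' @param annotation annotation with `length_bp` and `gc`.
#' @param norm output of [tmm_factors()].
#' @param genes optional gene subset to fit on (offsets are still predicted
#'   for every annotated gene in `cm`).
#' @return list of class `offset_model`: `offsets` (named, centered), `fit`
#'   (the lm), `df`, `resid_sd`.
#' @export
fit_length_gc_offset <- function(cm, annotation, norm, genes = NULL) {
  ids <- rownames(cm$counts)
  ann <- annotation[match(ids, annotation$gene_id), ]
  ok <- !is.na(ann$length_bp) & !is.na(ann$gc)
  fit_ids <- ids[ok]
  if (!is.null(genes)) fit_ids <- intersect(fit_ids, genes)
  if (length(fit_ids) < 50L)
    stop("need >= 50 annotated genes to fit a stable length/GC smooth")
  size <- norm$effective_size[match(colnames(cm$counts), norm$sample_id)]
  y_all <- rowMeans(log(sweep(cm$counts + 0.5, 2L, size, "/")))
  dat <- data.frame(y = y_all[fit_ids],
                    loglen = log(ann$length_bp[match(fit_ids, ids)]),
                    gc = ann$gc[match(fit_ids, ids)])
  # drop a spline term when its covariate is (nearly) constant
  terms <- c(
    if (diff(range(dat$loglen)) > 1e-6) "splines::ns(loglen, df = 4)",
    if (diff(range(dat$gc)) > 1e-6) "splines::ns(gc, df = 4)")
  form <- if (length(terms))
    stats::reformulate(terms, response = "y") else y ~ 1
  fit <- lm(form, data = dat)
  newdat <- data.frame(loglen = log(ann$length_bp[ok]), gc = ann$gc[ok])
  o <- predict(fit, newdata = newdat)
  o <- o - mean(o)
  structure(list(offsets = setNames(as.numeric(o), ids[ok]), fit = fit,
                 df = fit$rank - 1L, resid_sd = summary(fit)$sigma),
            class = "offset_model")
}

#' Null (zero) gene offsets
#' @param cm a [count_matrix].
#' @return offset_model with all offsets zero.
#' @export
zero_offsets <- function(cm) {
  structure(list(offsets = setNames(numeric(nrow(cm$counts)),
                                    rownames(cm$counts)),
                 fit = NULL, df = 0L, resid_sd = NA_real_),
            class = "offset_model")
}
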