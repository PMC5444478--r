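#' Log expression matrix for linear modelling
#'
#' `log2(FPKM + pseudocount)`; the pseudocount stabilizes zeros before the
#' log transform.
#'
#' @param fpkm_mat FPKM matrix.
#' @param pseudocount added before the log2 (default 0.5).
#' @return numeric matrix.
#' @export
log_expression <- function(fpkm_mat, pseudocount = 0.5) {
  log2(fpkm_mat + pseudocount)
}

#' Consensus intra-lane correlation
#'
#' Per-gene REML estimate of the intra-block correlation under a
#' random-intercept lane model, combined on the atanh scale into one
#' consensus value (non-finite per-gene estimates trimmed).
#'
#' @param logexpr genes x samples log-expression matrix.
#' @param design model matrix.
#' @param lanes per-sample lane labels.
#' @return consensus correlation in (-1, 1); 0 with a warning when there is
#'   a single lane.
#' @export
estimate_lane_correlation <- function(logexpr, design, lanes) {
  lanes <- as.factor(lanes)
  if (nlevels(lanes) < 2L) {
    warning("single sequencing lane: intra-lane correlation set to 0")
    return(0)
  }
  dc <- limma::duplicateCorrelation(logexpr, design, block = lanes)
  rho <- dc$consensus.correlation
  if (!is.finite(rho)) { warning("correlation estimate non-finite; using 0"); rho <- 0 }
  min(max(rho, -0.99), 0.99)
}

#' Per-gene generalized least squares fits for a set of contrasts
#'
#' Gene-wise linear models with the block-correlation structure implied by
#' the consensus intra-lane correlation, re-parameterized to the requested
#' contrasts.
#'
#' @param logexpr genes x samples log-expression matrix.
#' @param design model matrix (one column per genotype/stage cell for the
#'   standard design).
#' @param contrasts coefficients x contrasts matrix (e.g. WT minus MUT per
#'   stage).
#' @param rho consensus intra-lane correlation from
#'   [estimate_lane_correlation()].
#' @param lanes per-sample lane labels (required when `rho != 0`).
#' @return an `MArrayLM` fit with `coefficients`, `stdev.unscaled`, `sigma`,
#'   `df.residual`.
#' @export
fit_contrasts <- function(logexpr, design, contrasts, rho = 0, lanes = NULL) {
  if (qr(design)$rank < ncol(design)) {
    bad <- colnames(design)[qr(design)$pivot[-seq_len(qr(design)$rank)]]
    stop("rank-deficient design; confounded column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- if (rho != 0) {
    if (is.null(lanes)) stop("`lanes` required when rho != 0")
    limma::lmFit(logexpr, design, block = as.factor(lanes), correlation = rho)
  } else limma::lmFit(logexpr, design)
  limma::contrasts.fit(fit, contrasts)
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Fits a scaled inverse-chi-square distribution across the gene-wise
#' residual variances by matching moments of log s^2 (digamma/trigamma
#' equations solved numerically) and returns the shrunken posterior
#' variances `(d0 s0^2 + df s^2) / (d0 + df)`.
#'
#' @param s2 gene-wise residual variances.
#' @param df residual degrees of freedom (scalar or per gene).
#' @return list: `d0` (prior df, possibly `Inf`), `s0_sq` (prior variance),
#'   `var_post` (posterior variances).
#' @export
moderate_variances <- function(s2, df) {
  sq <- limma::squeezeVar(s2, df)
  list(d0 = sq$df.prior, s0_sq = sq$var.prior, var_post = sq$var.post)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: `q_(i) = min_(j>=i) m p_(j) / j`, capped at 1.
#'
#' @param p p-values in \[0,1\].
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Apply the DE decision rule and tabulate the stage Venn partition
#'
#' A gene/contrast is differentially expressed iff `q < fdr` and
#' `|log2fc| >= lfc` jointly.
#'
#' @param results long data.frame with `gene`, `contrast`, `log2fc`, `q`.
#' @param fdr FDR threshold (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @return `results` with `de_call` and `direction` added, plus attribute
#'   `venn`: counts of the 7 non-empty regions over the contrasts.
#' @export
call_de <- function(results, fdr = 0.05, lfc = 1) {
  results$de_call <- results$q < fdr & abs(results$log2fc) >= lfc
  results$direction <- ifelse(!results$de_call, NA_character_,
                              ifelse(results$log2fc > 0, "WT_UP", "MUT_UP"))
  attr(results, "venn") <- de_venn(results)
  results
}

#' Venn partition of DE calls across contrasts
#'
#' @param results output of [call_de()] (or any long table with `gene`,
#'   `contrast`, `de_call`).
#' @return named integer vector over membership signatures (e.g. `"25"`,
#'   `"25+30"`, `"25+30+35"`), counting each gene once in its exact region.
#' @export
de_venn <- function(results) {
  de <- results[results$de_call, , drop = FALSE]
  if (!nrow(de)) return(setNames(integer(), character()))
  sig <- tapply(as.character(de$contrast), de$gene, function(x)
    paste(sort(unique(x)), collapse = "+"))
  table(factor(sig))
}

#' Per-stage wild-type vs mutant differential expression
#'
#' The full DE stage: log2(FPKM + pseudocount) on filtered genes, a
#' cell-means design, consensus intra-lane correlation, gene-wise GLS fits
#' of the per-stage WT - MUT contrasts, one shared empirical-Bayes variance
#' moderation, per-contrast BH adjustment, and the joint FDR/fold-change
#' decision rule.
#'
#' @param fpkm_mat FPKM matrix (filtered genes).
#' @param samples sample metadata data.frame.
#' @param fdr,lfc decision thresholds.
#' @param pseudocount pseudocount for the log transform.
#' @return list of class `de_result`: `table` (long data.frame: gene,
#'   contrast (stage), log2fc, t, p, q, de_call, direction), `venn`, `rho`,
#'   `moderation` (`d0`, `s0_sq`).
#' @export
run_de <- function(fpkm_mat, samples, fdr = 0.05, lfc = 1, pseudocount = 0.5) {
  logexpr <- log_expression(fpkm_mat, pseudocount)
  cell <- sample_cells(samples)
  design <- model.matrix(~ 0 + cell)
  colnames(design) <- levels(cell)
  stages <- sort(unique(samples$stage))
  cmat <- vapply(stages, function(s) {
    v <- numeric(ncol(design))
    v[match(paste0("WT_", s), colnames(design))] <- 1
    v[match(paste0("MUT_", s), colnames(design))] <- -1
    v
  }, numeric(ncol(design)))
  colnames(cmat) <- paste0("stage_", stages)
  rownames(cmat) <- colnames(design)
  rho <- estimate_lane_correlation(logexpr, design, samples$lane)
  fit <- fit_contrasts(logexpr, design, cmat, rho, samples$lane)
  eb <- limma::eBayes(fit)
  tab <- do.call(rbind, lapply(seq_along(stages), function(j) {
    p <- eb$p.value[, j]
    data.frame(gene = rownames(logexpr),
               contrast = as.character(stages[j]),
               log2fc = eb$coefficients[, j],
               t = eb$t[, j],
               p = p,
               q = bh_adjust(p),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  tab <- call_de(tab, fdr = fdr, lfc = lfc)
  structure(list(table = tab, venn = attr(tab, "venn"), rho = rho,
                 moderation = list(d0 = eb$df.prior, s0_sq = eb$s2.prior)),
            class = "de_result")
}
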