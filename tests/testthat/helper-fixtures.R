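# Small in-code fixtures shared across test files.

toy_samples <- function(stages = c(25L, 30L), reps = 2L,
                        genotypes = c("WT", "MUT"), n_lanes = 2L) {
  grid <- expand.grid(replicate = seq_len(reps), stage = stages,
                      genotype = genotypes, stringsAsFactors = FALSE)
  data.frame(
    sample_id = with(grid, paste0(genotype, "_", stage, "_r", replicate)),
    genotype = grid$genotype, stage = grid$stage,
    replicate = grid$replicate,
    lane = paste0("L", ((grid$replicate - 1L) %% n_lanes) + 1L),
    stringsAsFactors = FALSE)
}

toy_count_matrix <- function(counts, samples = NULL) {
  if (is.null(samples)) samples <- toy_samples()[seq_len(ncol(counts)), ]
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  colnames(counts) <- samples$sample_id
  count_matrix(counts, samples)
}

# Step-by-step TMM oracle: doubly trimmed (rank-based), inverse-variance
# weighted mean of M-values against the reference with the upper-quartile
# auto-selection rule, factors rescaled to geometric mean 1.
tmm_oracle <- function(counts, ref = NULL) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2L, function(x) quantile(x, 0.75)) / lib
  if (is.null(ref)) ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    obs <- counts[, j] / lib[j]
    rf <- counts[, ref] / lib[ref]
    keep0 <- obs > 0 & rf > 0
    logR <- log2(obs[keep0] / rf[keep0])
    absE <- (log2(obs[keep0]) + log2(rf[keep0])) / 2
    v <- (lib[j] - counts[keep0, j]) / lib[j] / counts[keep0, j] +
      (lib[ref] - counts[keep0, ref]) / lib[ref] / counts[keep0, ref]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- 2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
    if (!is.finite(f)) f <- 1
    f
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1L))
  f / exp(mean(log(f)))
}

# Exhaustive BH step-up oracle: q_(i) = min_{j >= i} m p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * p[o][i:m] / (i:m))), numeric(1L))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Brute-force sliding-window motif scan (0-based offsets, sense strand).
scan_oracle <- function(seq, motif) {
  L <- nchar(seq); k <- nchar(motif)
  if (L < k) return(integer())
  starts <- which(vapply(seq_len(L - k + 1L), function(i)
    substr(seq, i, i + k - 1L) == motif, logical(1L)))
  as.integer(starts - 1L)
}

# Yates chi-square hand formula + chi-square(1) tail oracle.
yates_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
  list(statistic = stat, p_value = pchisq(stat, df = 1L, lower.tail = FALSE))
}
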