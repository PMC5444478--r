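test_that("lane correlation: null near zero, planted ICC recovered, cap works", {
  set.seed(41)
  n <- 2000L; ns <- 8L
  lanes <- rep(paste0("L", 1:4), each = 2L)
  design <- matrix(1, ns, 1L)

  # i.i.d. noise: consensus correlation ~ 0
  y0 <- matrix(rnorm(n * ns), n, ns)
  rho0 <- estimate_lane_correlation(y0, design, lanes)
  expect_lt(abs(rho0), 0.05)

  # lane variance equal to residual variance: ICC = 0.5
  u <- matrix(rnorm(n * 4L), n, 4L)[, as.integer(factor(lanes))]
  y1 <- u + matrix(rnorm(n * ns), n, ns)
  rho1 <- estimate_lane_correlation(y1, design, lanes)
  expect_equal(rho1, 0.5, tolerance = 0.1)

  # duplicated lanes: estimate pushed to the cap
  y2 <- matrix(rnorm(n * 4L), n, 4L)[, as.integer(factor(lanes))]
  rho2 <- estimate_lane_correlation(y2 + 1e-6 * matrix(rnorm(n * ns), n, ns),
                                    design, lanes)
  expect_gt(rho2, 0.95)
  expect_lte(rho2, 0.99)

  expect_warning(r1 <- estimate_lane_correlation(y0, design, rep("L1", ns)),
                 "single")
  expect_identical(r1, 0)
})

test_that("contrast fits reduce to group-mean differences when rho = 0", {
  sam <- toy_samples(stages = 25L, reps = 4L)
  set.seed(42)
  y <- matrix(rnorm(5L * 8L, 8, 1), 5L, 8L,
              dimnames = list(paste0("g", 1:5), sam$sample_id))
  cell <- sample_cells(sam)
  design <- model.matrix(~ 0 + cell); colnames(design) <- levels(cell)
  cmat <- matrix(c(1, -1), 2L, 1L,
                 dimnames = list(levels(cell), "WT_minus_MUT"))
  fit <- fit_contrasts(y, design, cmat, rho = 0)
  wt <- sam$genotype == "WT"
  expect_equal(unname(fit$coefficients[, 1L]),
               unname(rowMeans(y[, wt]) - rowMeans(y[, !wt])),
               tolerance = 1e-12)
  # stderr matches the pooled two-sample formula
  s2 <- apply(y, 1L, function(r)
    (sum((r[wt] - mean(r[wt]))^2) + sum((r[!wt] - mean(r[!wt]))^2)) / 6)
  expect_equal(unname(fit$sigma^2), unname(s2), tolerance = 1e-12)
  expect_equal(unname(fit$stdev.unscaled[, 1L]), rep(sqrt(1 / 4 + 1 / 4), 5L))

  # adding a constant to every sample leaves contrasts unchanged
  fit2 <- fit_contrasts(y + 3, design, cmat, rho = 0)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-12)

  bad <- cbind(design, WT_25_again = design[, "WT_25"])
  expect_error(fit_contrasts(y, bad, rbind(cmat, 0), rho = 0),
               "rank-deficient")
})

test_that("GLS with block correlation matches direct matrix algebra", {
  sam <- toy_samples(stages = c(25L, 30L), reps = 2L, n_lanes = 2L)
  set.seed(43)
  y <- matrix(rnorm(5L * nrow(sam), 5, 1), 5L, nrow(sam),
              dimnames = list(paste0("g", 1:5), sam$sample_id))
  cell <- sample_cells(sam)
  X <- model.matrix(~ 0 + cell); colnames(X) <- levels(cell)
  rho <- 0.35
  lanes <- sam$lane
  cmat <- matrix(0, ncol(X), 1L, dimnames = list(colnames(X), "c1"))
  cmat["WT_25", 1L] <- 1; cmat["MUT_25", 1L] <- -1

  fit <- fit_contrasts(y, X, cmat, rho = rho, lanes = lanes)

  B <- outer(lanes, lanes, "==") * rho; diag(B) <- 1
  Vi <- solve(B)
  XtViX_inv <- solve(t(X) %*% Vi %*% X)
  P <- XtViX_inv %*% t(X) %*% Vi
  for (g in 1:5) {
    bhat <- P %*% y[g, ]
    expect_equal(unname((t(cmat) %*% bhat)[1L, 1L]),
                 unname(fit$coefficients[g, 1L]), tolerance = 1e-10)
  }
  expect_equal(unname(fit$stdev.unscaled[1L, 1L]),
               sqrt((t(cmat) %*% XtViX_inv %*% cmat)[1L, 1L]),
               tolerance = 1e-10)
})

test_that("variance moderation matches its scaled inverse-chi-square model", {
  # equal variances: no spread to explain, prior df infinite
  eq <- moderate_variances(rep(2.5, 200L), df = 6L)
  expect_identical(eq$d0, Inf)
  expect_equal(eq$var_post, rep(2.5, 200L))

  # parameter recovery from the generating model
  set.seed(44)
  d0 <- 4; s0 <- 2; df <- 6L; n <- 5000L
  sigma2 <- d0 * s0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, df) / df
  mod <- moderate_variances(s2, df)
  expect_gt(mod$d0, 3); expect_lt(mod$d0, 5)
  expect_gt(mod$s0_sq, 1.8); expect_lt(mod$s0_sq, 2.2)
  # shrinkage formula holds element-wise
  expect_equal(mod$var_post,
               (mod$d0 * mod$s0_sq + df * s2) / (mod$d0 + df),
               tolerance = 1e-10)
})

test_that("BH adjustment equals the exhaustive step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5L)), rep(0.2, 5L))
  expect_equal(bh_adjust(0.07), 0.07)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")

  set.seed(45)
  for (i in 1:25) {
    p <- runif(sample(1:10, 1L))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("DE calls are the conjunction of FDR and fold-change gates", {
  tab <- data.frame(gene = c("g1", "g2", "g3", "g3", "g3"),
                    contrast = c("25", "25", "25", "30", "35"),
                    log2fc = c(0.9, -1.4, 2, 2, 2),
                    q = c(0.04, 0.04, 0.001, 0.001, 0.001))
  out <- call_de(tab)
  expect_false(out$de_call[1L])           # fold-change gate
  expect_true(out$de_call[2L])
  expect_identical(out$direction[2L], "MUT_UP")
  venn <- attr(out, "venn")
  expect_identical(unname(venn[["25+30+35"]]), 1L)  # g3 counted once
  expect_identical(unname(venn[["25"]]), 1L)
})

test_that("swapping genotype labels negates fold-changes, preserves p and q", {
  sim <- simulate_experiment(sim_config(n_genes = 300L, de_fraction = 0.2,
                                        seed = 46L))
  cm <- sim$counts
  filt <- expression_filter(cm)
  norm <- tmm_factors(cm)
  fk <- fpkm(cm, sim$annotation, norm)[filt, ]
  de1 <- run_de(fk, cm$samples)

  swapped <- cm$samples
  swapped$genotype <- ifelse(swapped$genotype == "WT", "MUT", "WT")
  de2 <- run_de(fk, swapped)
  expect_equal(de2$table$log2fc, -de1$table$log2fc, tolerance = 1e-10)
  expect_equal(de2$table$p, de1$table$p, tolerance = 1e-10)
  expect_equal(de2$table$q, de1$table$q, tolerance = 1e-10)
  expect_equal(abs(de2$table$t), abs(de1$table$t), tolerance = 1e-10)
})

test_that("observed FDR among calls is controlled on simulated data", {
  # genotype-specific activity off: the DE truth label is then the only
  # source of genotype differences
  sim <- simulate_experiment(sim_config(n_genes = 2000L, de_fraction = 0.1,
                                        specific_fraction = 0, seed = 47L))
  cm <- sim$counts
  filt <- expression_filter(cm)
  norm <- tmm_factors(cm)
  fk <- fpkm(cm, sim$annotation, norm)[filt, ]
  de <- run_de(fk, cm$samples)
  truth <- sim$truth$genes
  # per-call false discovery rate over gene x contrast decisions
  calls <- de$table[de$table$de_call, ]
  fdr_obs <- mean(!calls$gene %in% truth$gene_id[truth$de])
  expect_lte(fdr_obs, 0.08)
  # and reasonable power on |log2FC| >= 1 effects at 4 replicates
  called <- unique(calls$gene)
  de_filt <- intersect(truth$gene_id[truth$de], filt)
  expect_gt(mean(de_filt %in% called), 0.6)
})
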