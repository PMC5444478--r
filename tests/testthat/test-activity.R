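hyper6 <- function(cells, m = -10, v = 4, m_phi = log(0.1), v_phi = 1) {
  activity_hyperparams(m_cell = setNames(rep(m, length(cells)), cells),
                       v_cell = setNames(rep(v, length(cells)), cells),
                       m_phi = m_phi, v_phi = v_phi)
}

test_that("activity call applies the strict posterior-probability rule", {
  post <- data.frame(gene = "g1", cell = c("WT_25", "WT_30"),
                     post_mean = c(-10, -10 + 0.3), post_sd = c(1, 0.3))
  out <- call_activity(post, threshold = -10)
  # marginal centered exactly at T: P = 0.5, strictly-greater rule => inactive
  expect_equal(out$p_active[1L], 0.5)
  expect_identical(out$call[1L], "INACTIVE")
  # marginal N(T + sd, sd^2): P = Phi(1)
  expect_equal(out$p_active[2L], pnorm(1), tolerance = 1e-12)
  expect_identical(out$call[2L], "ACTIVE")
  expect_error(call_activity(transform(post, post_sd = 0), -10), "positive")
})

test_that("no-signal gene shrinks to a low prior and is called inactive", {
  cells <- c("WT_25", "MUT_25")
  cell <- factor(rep(cells, each = 4L), levels = cells)
  y <- rep(0L, 8L)
  fit <- fit_gene_posterior(y, cell, lane = NULL, offset = rep(log(1e6), 8L),
                            hyper = hyper6(cells, m = -16, v = 1))
  expect_true(all(abs(fit$post_mean - (-16)) < 1))
  out <- call_activity(data.frame(gene = "g", cell = cells,
                                  post_mean = fit$post_mean,
                                  post_sd = fit$post_sd),
                       threshold = -12)
  expect_true(all(out$p_active < 0.01))
  expect_true(all(out$call == "INACTIVE"))
})

test_that("vanishing dispersion and flat prior reach the Poisson MLE", {
  # single-cell design: posterior mode -> log(mean(y) / mean(exp(offset)))
  y <- c(12L, 18L, 9L, 15L)
  off <- log(c(0.9e6, 1.1e6, 1.0e6, 1.05e6))
  hy <- activity_hyperparams(m_cell = c(cell = -12), v_cell = c(cell = 1e6),
                             m_phi = log(1e-8), v_phi = 1e-8)
  fit <- fit_gene_posterior(y, factor(rep("cell", 4L)), NULL, off, hy)
  expect_equal(unname(fit$post_mean),
               log(sum(y) / sum(exp(off))), tolerance = 1e-3)
  # and matches a Poisson GLM fit
  glmfit <- glm(y ~ 1 + offset(off), family = poisson())
  expect_equal(unname(fit$post_mean), unname(coef(glmfit)), tolerance = 1e-3)
  expect_equal(unname(fit$post_sd),
               unname(sqrt(vcov(glmfit)[1L, 1L])), tolerance = 1e-2)
})

test_that("posterior means shrink between the gene MLE and the prior mean", {
  cells <- "WT_25"
  set.seed(31)
  for (i in 1:20) {
    mu_true <- exp(rnorm(1L, -9, 1) + log(1e6))
    y <- rnbinom(4L, mu = mu_true, size = 10)
    hy <- hyper6(cells, m = -9, v = 0.5, m_phi = log(0.1), v_phi = 0.25)
    fit <- fit_gene_posterior(y, factor(rep(cells, 4L)), NULL,
                              rep(log(1e6), 4L), hy)
    if (!fit$converged) next
    mle <- log((sum(y) + 1e-9) / (4 * 1e6))
    lo <- min(mle, -9) - 1e-6
    hi <- max(mle, -9) + 1e-6
    expect_gte(fit$post_mean[[1L]], lo)
    expect_lte(fit$post_mean[[1L]], hi)
  }
})

test_that("active sets are nested as the threshold increases", {
  sim <- simulate_experiment(sim_config(n_genes = 240L, seed = 32L))
  norm <- tmm_factors(sim$counts)
  act <- fit_activity(sim$counts, norm, eb_max_genes = 240L)
  T0 <- act$threshold
  prev <- NULL
  for (Tq in c(T0 - 2, T0 - 1, T0, T0 + 1, T0 + 2)) {
    called <- call_activity(act$posterior, Tq)
    cur <- paste(called$gene, called$cell)[called$call == "ACTIVE"]
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  # P_gts(T) is non-increasing in T for a fixed posterior
  p1 <- call_activity(act$posterior, T0)$p_active
  p2 <- call_activity(act$posterior, T0 + 0.5)$p_active
  expect_true(all(p2 <= p1))
})

test_that("hyperparameter estimation recovers cell means and spreads", {
  # genes with beta ~ N(2, 1) per cell, no lanes, offsets 0
  set.seed(33)
  n <- 600L; cells <- c("c1", "c2", "c3")
  cell <- factor(rep(cells, each = 4L), levels = cells)
  beta <- matrix(rnorm(n * 3L, 2, 1), n, 3L)
  phi <- rlnorm(n, log(0.1), 0.4)
  counts <- t(vapply(seq_len(n), function(g)
    rnbinom(12L, mu = exp(beta[g, as.integer(cell)]), size = 1 / phi[g]),
    numeric(12L)))
  offs <- matrix(0, n, 12L)
  # the moment-matching fixed point is approached slowly; hitting the
  # iteration cap warns by contract while the estimates are already stable
  eb <- suppressWarnings(estimate_hyperparams(counts, cell, lane = NULL, offs))
  expect_true(all(abs(unlist(eb$hyper$m_cell) - 2) < 0.1))
  expect_true(all(abs(sqrt(unlist(eb$hyper$v_cell)) - 1) < 0.15))
  expect_equal(eb$hyper$m_phi, log(0.1), tolerance = 0.25)

  # doubling all offsets shifts every m by -log 2, v unchanged
  eb2 <- suppressWarnings(
    estimate_hyperparams(counts, cell, lane = NULL, offs + log(2)))
  expect_equal(unlist(eb2$hyper$m_cell), unlist(eb$hyper$m_cell) - log(2),
               tolerance = 0.02)
  expect_equal(unlist(eb2$hyper$v_cell), unlist(eb$hyper$v_cell),
               tolerance = 0.05)
})

test_that("degenerate spread: identical genes drive v toward its floor", {
  n <- 250L
  counts <- matrix(20L, n, 8L)
  cell <- factor(rep(c("a", "b"), each = 4L))
  expect_warning(
    eb <- estimate_hyperparams(counts, cell, NULL, matrix(0, n, 8L),
                               max_iter = 8L),
    "did not converge")
  expect_true(all(unlist(eb$hyper$v_cell) < 0.01))
  expect_true(all(unlist(eb$hyper$v_cell) >= 1e-6))
})

test_that("activity summary equals a brute-force recount", {
  sim <- simulate_experiment(sim_config(n_genes = 240L, seed = 34L))
  norm <- tmm_factors(sim$counts)
  act <- fit_activity(sim$counts, norm, eb_max_genes = 240L)
  s <- summarize_activity(act$posterior)

  post <- act$posterior
  tab <- matrix(FALSE, 240L, 6L,
                dimnames = list(sort(unique(post$gene)), unique(post$cell)))
  for (r in seq_len(nrow(post)))
    tab[post$gene[r], post$cell[r]] <- post$call[r] == "ACTIVE"
  expect_identical(unname(s$per_cell), unname(colSums(tab)))
  expect_identical(s$n_any, sum(rowSums(tab) > 0))
  expect_identical(s$n_constitutive, sum(rowSums(tab) == 6L))
  wt_cols <- grepl("^WT_", colnames(tab))
  wt_any <- rowSums(tab[, wt_cols]) > 0
  mut_any <- rowSums(tab[, !wt_cols]) > 0
  expect_setequal(s$wt_exclusive, rownames(tab)[wt_any & !mut_any])
  expect_setequal(s$mut_exclusive, rownames(tab)[mut_any & !wt_any])
  # constitutive genes appear in every per-cell active set
  for (cl in colnames(tab))
    expect_true(all(s$constitutive %in% rownames(tab)[tab[, cl]]))
})
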