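#' Hyperparameters of the gene-activity model
#'
#' The per-gene negative-binomial mixed model has one fixed effect per
#' genotype/stage cell, Gaussian lane random effects whose precision carries
#' a vague Gamma prior, and a gene-constant log dispersion. Across genes the
#' cell fixed effects are exchangeable draws from independent normals
#' (unrestricted means, diagonal covariance) and the log dispersion from a
#' normal; these cross-gene distributions are the empirical-Bayes priors
#' whose parameters this object holds.
#'
#' @param m_cell,v_cell named numeric vectors (one entry per cell): prior
#'   mean and variance of the cell fixed effects.
#' @param m_phi,v_phi prior mean and variance of log dispersion.
#' @param lane_prior `c(shape, rate)` of the Gamma prior on the lane-effect
#'   precision; fixed vague by default, never updated.
#' @return list of class `activity_hyper`.
#' @export
activity_hyperparams <- function(m_cell, v_cell, m_phi = log(0.1), v_phi = 1,
                                 lane_prior = c(shape = 0.5, rate = 0.005)) {
  if (any(v_cell <= 0) || v_phi <= 0) stop("prior variances must be positive")
  if (any(lane_prior <= 0)) stop("gamma prior parameters must be positive")
  structure(list(m_cell = m_cell, v_cell = pmax(v_cell, 1e-6),
                 m_phi = m_phi, v_phi = max(v_phi, 1e-6),
                 lane_prior = lane_prior),
            class = "activity_hyper")
}

## Laplace approximation to one gene's posterior.
## Parameters: beta (one per cell), u (one per lane, if >= 2 lanes),
## lambda = log(phi), omega = log(lane precision).
fit_gene_laplace <- function(y, cell, lane, offset, hyper, start = NULL,
                             restarts = 2L) {
  cell <- as.factor(cell)
  k <- nlevels(cell)
  ci <- as.integer(cell)
  use_lanes <- !is.null(lane) && nlevels(as.factor(lane)) >= 2L
  if (use_lanes) {
    lane <- as.factor(lane)
    L <- nlevels(lane)
    li <- as.integer(lane)
  } else L <- 0L
  m <- hyper$m_cell; v <- hyper$v_cell
  a <- hyper$lane_prior[[1L]]; b <- hyper$lane_prior[[2L]]
  npar <- k + L + 1L + (L > 0L)
  i_beta <- seq_len(k)
  i_u <- if (L) k + seq_len(L) else integer()
  i_lam <- k + L + 1L
  i_om <- if (L) npar else integer()

  fn <- function(p) {
    beta <- p[i_beta]; lam <- p[i_lam]
    eta <- beta[ci] + offset
    if (L) eta <- eta + p[i_u][li]
    mu <- exp(pmin(eta, 50))
    r <- exp(-lam)
    nll <- -sum(dnbinom(y, size = r, mu = mu, log = TRUE))
    nll <- nll + sum((beta - m)^2 / (2 * v)) +
      (lam - hyper$m_phi)^2 / (2 * hyper$v_phi)
    if (L) {
      u <- p[i_u]; om <- p[i_om]; tau <- exp(om)
      nll <- nll - (0.5 * L * om - 0.5 * tau * sum(u^2)) - (a * om - b * tau)
    }
    if (!is.finite(nll)) nll <- 1e10
    nll
  }
  gr <- function(p) {
    beta <- p[i_beta]; lam <- p[i_lam]
    eta <- beta[ci] + offset
    if (L) eta <- eta + p[i_u][li]
    eta <- pmin(eta, 50)
    mu <- exp(eta)
    r <- exp(-lam)
    s <- y - mu * (y + r) / (mu + r)
    g <- numeric(length(p))
    g[i_beta] <- -rowsum(s, ci, reorder = TRUE)[, 1L] + (beta - m) / v
    dldr <- sum(digamma(y + r) - digamma(r) + log(r) + 1 -
                  log(r + mu) - (y + r) / (r + mu))
    g[i_lam] <- r * dldr + (lam - hyper$m_phi) / hyper$v_phi
    if (L) {
      u <- p[i_u]; tau <- exp(p[i_om])
      g[i_u] <- -rowsum(s, li, reorder = TRUE)[, 1L] + tau * u
      g[i_om] <- -(0.5 * L - 0.5 * tau * sum(u^2) + a - b * tau)
    }
    g
  }

  crude_start <- function() {
    tot <- rowsum(y + 0.5 / max(tabulate(ci)), ci, reorder = TRUE)[, 1L]
    den <- rowsum(exp(pmin(offset, 50)), ci, reorder = TRUE)[, 1L]
    p0 <- numeric(npar)
    p0[i_beta] <- pmin(pmax(log(tot / den), m - 6), m + 6)
    p0[i_lam] <- hyper$m_phi
    if (L) p0[i_om] <- log(a / b)
    p0
  }
  lower <- rep(-40, npar); upper <- rep(40, npar)
  lower[i_lam] <- log(1e-8); upper[i_lam] <- log(1e3)
  if (L) { lower[i_om] <- -20; upper[i_om] <- 20
           lower[i_u] <- -10; upper[i_u] <- 10 }

  p0 <- if (is.null(start)) crude_start() else pmin(pmax(start, lower), upper)
  res <- NULL
  for (try in 0:restarts) {
    cand <- tryCatch(
      optim(p0, fn, gr, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300L)),
      error = function(e) NULL)
    if (!is.null(cand) && cand$convergence == 0L) { res <- cand; break }
    if (!is.null(cand) && is.null(res)) res <- cand
    p0 <- crude_start() + rnorm(npar, 0, 0.25)
    p0 <- pmin(pmax(p0, lower), upper)
  }
  prior_fallback <- function() {
    list(post_mean = m, post_sd = sqrt(v),
         phi_mean = hyper$m_phi, phi_sd = sqrt(hyper$v_phi),
         par = crude_start(), converged = FALSE)
  }
  if (is.null(res)) return(prior_fallback())
  H <- tryCatch(optimHess(res$par, fn, gr), error = function(e) NULL)
  Sigma <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(Sigma) || any(!is.finite(diag(Sigma))) ||
      any(diag(Sigma)[c(i_beta, i_lam)] <= 0))
    return(prior_fallback())
  sdv <- sqrt(pmax(diag(Sigma), 1e-12))
  list(post_mean = setNames(res$par[i_beta], levels(cell)),
       post_sd = setNames(pmax(sdv[i_beta], 1e-6), levels(cell)),
       phi_mean = res$par[i_lam], phi_sd = max(sdv[i_lam], 1e-6),
       par = res$par, converged = res$convergence == 0L)
}

#' Posterior of one gene's activity model
#'
#' Laplace approximation to the joint posterior of the cell fixed effects,
#' lane effects, log dispersion and log lane precision: the mode of
#' log-prior + NB log-likelihood is found by bounded quasi-Newton
#' optimization and the Gaussian approximation is taken from the negative
#' inverse Hessian. Non-convergence after restarts falls back to the prior
#' (flagged).
#'
#' @param y integer counts, one per sample.
#' @param cell factor of genotype/stage cell per sample.
#' @param lane factor of sequencing lane per sample (or `NULL`; with fewer
#'   than 2 lanes the lane effect is dropped).
#' @param offset per-sample offset: log effective library size plus the
#'   gene's length/GC offset.
#' @param hyper an [activity_hyperparams()] object.
#' @return list: `post_mean`, `post_sd` (per cell), `phi_mean`, `phi_sd`
#'   (log-dispersion posterior), `converged`.
#' @export
fit_gene_posterior <- function(y, cell, lane, offset, hyper) {
  stopifnot(length(y) == length(offset), all(is.finite(offset)))
  fit_gene_laplace(y, cell, lane, offset, hyper)
}

#' Empirical-Bayes estimation of the activity-model hyperparameters
#'
#' Iterates (1) per-gene Laplace fits under the current hyperparameters,
#' (2) moment-matching updates: the prior mean/variance of each cell effect
#' is set to the mean of posterior means and the variance of posterior means
#' plus the average posterior variance; the log-dispersion prior is updated
#' analogously. The lane-precision prior stays fixed and vague.
#'
#' @param counts genes x samples integer matrix.
#' @param cell,lane per-sample factors.
#' @param offsets genes x samples matrix of offsets.
#' @param init optional starting [activity_hyperparams()]; otherwise crude
#'   moment estimates.
#' @param tol relative-change convergence tolerance (default 1e-3).
#' @param max_iter maximum iterations (default 25).
#' @return list: `hyper`, `fits` (per-gene list from the final iteration),
#'   `n_iter`, `converged`.
#' @export
estimate_hyperparams <- function(counts, cell, lane, offsets, init = NULL,
                                 tol = 1e-3, max_iter = 25L) {
  n <- nrow(counts)
  if (n < 200L) stop("need >= 200 genes for empirical-Bayes estimation")
  cell <- as.factor(cell)
  k <- nlevels(cell)
  if (is.null(init)) init <- crude_hyperparams(counts, cell, offsets)
  hyper <- init
  pars <- vector("list", n)
  fits <- NULL
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    fits <- lapply(seq_len(n), function(g)
      fit_gene_laplace(counts[g, ], cell, lane, offsets[g, ], hyper,
                       start = pars[[g]]))
    pars <- lapply(fits, `[[`, "par")
    pm <- t(vapply(fits, `[[`, numeric(k), "post_mean"))
    pv <- t(vapply(fits, `[[`, numeric(k), "post_sd"))^2
    lm_ <- vapply(fits, `[[`, numeric(1L), "phi_mean")
    lv <- vapply(fits, `[[`, numeric(1L), "phi_sd")^2
    new <- activity_hyperparams(
      m_cell = setNames(colMeans(pm), levels(cell)),
      v_cell = setNames(pmax(apply(pm, 2L, var) + colMeans(pv), 1e-6),
                        levels(cell)),
      m_phi = mean(lm_), v_phi = max(var(lm_) + mean(lv), 1e-6),
      lane_prior = hyper$lane_prior)
    old_v <- c(hyper$m_cell, hyper$v_cell, hyper$m_phi, hyper$v_phi)
    new_v <- c(new$m_cell, new$v_cell, new$m_phi, new$v_phi)
    delta <- max(abs(new_v - old_v) / (abs(old_v) + 0.1))
    hyper <- new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("empirical-Bayes iteration did not converge in ", max_iter,
            " iterations; returning last iterate")
  list(hyper = hyper, fits = fits, n_iter = n_iter, converged = converged)
}

crude_hyperparams <- function(counts, cell, offsets) {
  cell <- as.factor(cell)
  k <- nlevels(cell)
  bcrude <- matrix(NA_real_, nrow(counts), k)
  phicrude <- numeric(nrow(counts))
  eo <- exp(pmin(offsets, 50))
  for (j in seq_len(k)) {
    cols <- which(as.integer(cell) == j)
    bcrude[, j] <- log((rowSums(counts[, cols, drop = FALSE]) + 0.5) /
                         rowSums(eo[, cols, drop = FALSE]))
    mu <- rowMeans(counts[, cols, drop = FALSE])
    s2 <- apply(counts[, cols, drop = FALSE], 1L, var)
    est <- (s2 - mu) / pmax(mu, 1e-8)^2
    phicrude <- phicrude + pmax(est, 1e-3) / k
  }
  activity_hyperparams(
    m_cell = setNames(colMeans(bcrude), levels(cell)),
    v_cell = setNames(pmax(apply(bcrude, 2L, var), 1e-6), levels(cell)),
    m_phi = mean(log(phicrude)), v_phi = max(var(log(phicrude)), 0.25))
}

#' Default activity threshold
#'
#' The model never observes the activity boundary directly; the default ties
#' it to the read-count scale of the expression filter: `T` is chosen so
#' that a gene sitting exactly at the boundary is expected to yield
#' `min_reads` reads in the median-depth sample,
#' `T = log(min_reads) - median(log(effective_size))`.
#'
#' @param norm output of [tmm_factors()].
#' @param min_reads expected read count at the boundary (default 5).
#' @return numeric threshold on the fixed-effect (log relative abundance)
#'   scale.
#' @export
default_activity_threshold <- function(norm, min_reads = 5) {
  log(min_reads) - median(log(norm$effective_size))
}

#' Posterior activity calls
#'
#' `P_gts(T) = Pr(beta_gts > T | data)` under the Gaussian posterior
#' marginal; a gene is called active in a cell iff `P_gts(T) > 0.5`
#' (strictly), equivalently posterior mean > T.
#'
#' @param post data.frame with columns `gene`, `cell`, `post_mean`,
#'   `post_sd`.
#' @param threshold activity threshold `T`.
#' @return `post` with columns `p_active` and `call`
#'   (`"ACTIVE"`/`"INACTIVE"`) added/replaced.
#' @export
call_activity <- function(post, threshold) {
  if (any(post$post_sd <= 0)) stop("posterior sd must be positive")
  post$p_active <- pnorm((post$post_mean - threshold) / post$post_sd)
  post$call <- ifelse(post$p_active > 0.5, "ACTIVE", "INACTIVE")
  post
}

#' Fit the gene-activity model to an experiment
#'
#' End-to-end activity calling: builds per-sample offsets from TMM-effective
#' library sizes plus per-gene length/GC offsets, estimates hyperparameters
#' by empirical Bayes on up to `eb_max_genes` genes, fits every gene's
#' posterior, and applies the activity rule.
#'
#' @param cm a [count_matrix].
#' @param norm output of [tmm_factors()].
#' @param offset_model optional [fit_length_gc_offset()] result; genes
#'   without an offset get 0.
#' @param threshold activity threshold `T`; default
#'   [default_activity_threshold()].
#' @param eb_max_genes cap on genes used for hyperparameter estimation
#'   (deterministic evenly spaced subset).
#' @param eb_tol,eb_max_iter empirical-Bayes convergence controls.
#' @return list of class `activity_result`: `posterior` (long data.frame:
#'   gene, cell, post_mean, post_sd, p_active, call, converged), `phi`
#'   (per-gene log-dispersion posterior), `hyper`, `threshold`.
#' @export
fit_activity <- function(cm, norm, offset_model = NULL, threshold = NULL,
                         eb_max_genes = 2000L, eb_tol = 1e-3,
                         eb_max_iter = 25L) {
  counts <- cm$counts
  cell <- sample_cells(cm$samples)
  lane <- factor(cm$samples$lane)
  size <- norm$effective_size[match(colnames(counts), norm$sample_id)]
  o_g <- setNames(numeric(nrow(counts)), rownames(counts))
  if (!is.null(offset_model)) {
    hit <- intersect(names(offset_model$offsets), names(o_g))
    o_g[hit] <- offset_model$offsets[hit]
  }
  offsets <- outer(o_g, log(size), "+")
  if (is.null(threshold)) threshold <- default_activity_threshold(norm)

  n <- nrow(counts)
  eb_idx <- if (n > eb_max_genes)
    unique(round(seq(1L, n, length.out = eb_max_genes))) else seq_len(n)
  eb <- estimate_hyperparams(counts[eb_idx, , drop = FALSE], cell, lane,
                             offsets[eb_idx, , drop = FALSE],
                             tol = eb_tol, max_iter = eb_max_iter)
  hyper <- eb$hyper
  fits <- vector("list", n)
  fits[eb_idx] <- eb$fits
  todo <- setdiff(seq_len(n), eb_idx)
  for (g in todo)
    fits[[g]] <- fit_gene_laplace(counts[g, ], cell, lane, offsets[g, ], hyper)

  k <- nlevels(cell)
  post <- data.frame(
    gene = rep(rownames(counts), each = k),
    cell = rep(levels(cell), n),
    post_mean = as.numeric(vapply(fits, `[[`, numeric(k), "post_mean")),
    post_sd = as.numeric(vapply(fits, `[[`, numeric(k), "post_sd")),
    converged = rep(vapply(fits, `[[`, logical(1L), "converged"), each = k),
    stringsAsFactors = FALSE)
  post <- call_activity(post, threshold)
  phi <- data.frame(gene = rownames(counts),
                    log_phi_mean = vapply(fits, `[[`, numeric(1L), "phi_mean"),
                    log_phi_sd = vapply(fits, `[[`, numeric(1L), "phi_sd"),
                    stringsAsFactors = FALSE)
  structure(list(posterior = post, phi = phi, hyper = hyper,
                 threshold = threshold, eb_iterations = eb$n_iter),
            class = "activity_result")
}

#' Summaries of activity calls
#'
#' Per-cell totals, the active union, the constitutive intersection,
#' genotype-exclusive sets, and the cross-tabulation of per-genotype
#' stage-activity patterns.
#'
#' @param post long data.frame with `gene`, `cell`, `call` (e.g. the
#'   `posterior` element of [fit_activity()]).
#' @return list: `per_cell` (named counts), `n_any`, `n_constitutive`,
#'   `active_any`, `constitutive`, `wt_exclusive`, `mut_exclusive` (gene id
#'   vectors), `pattern_table` (WT stage pattern x MUT stage pattern).
#' @export
summarize_activity <- function(post) {
  act <- post$call == "ACTIVE"
  tab <- tapply(act, list(post$gene, post$cell), any)
  tab <- tab[, unique(post$cell), drop = FALSE]
  is_wt <- grepl("^WT_", colnames(tab))
  wt_any <- rowSums(tab[, is_wt, drop = FALSE]) > 0
  mut_any <- rowSums(tab[, !is_wt, drop = FALSE]) > 0
  genes <- rownames(tab)
  pat <- function(m) apply(m, 1L, function(r) paste(as.integer(r), collapse = ""))
  list(per_cell = colSums(tab),
       n_any = sum(wt_any | mut_any),
       n_constitutive = sum(rowSums(tab) == ncol(tab)),
       active_any = genes[wt_any | mut_any],
       constitutive = genes[rowSums(tab) == ncol(tab)],
       wt_exclusive = genes[wt_any & !mut_any],
       mut_exclusive = genes[mut_any & !wt_any],
       pattern_table = table(WT = pat(tab[, is_wt, drop = FALSE]),
                             MUT = pat(tab[, !is_wt, drop = FALSE])))
}
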