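test_that("expression filter implements the all-replicates-in-one-cell rule", {
  sam <- toy_samples(stages = c(25L, 30L, 35L), reps = 4L)
  n <- nrow(sam)
  m <- matrix(0L, 3L, n)
  wt30 <- which(sam$genotype == "WT" & sam$stage == 30L)
  m[1L, wt30] <- 5L                      # boundary: exactly 5 in all reps
  m[2L, ] <- 9L                          # one replicate below 5 in every cell
  cells <- paste(sam$genotype, sam$stage)
  m[2L, match(unique(cells), cells)] <- 4L
  m[3L, ] <- 4L
  cm <- toy_count_matrix(m, sam)
  expect_identical(expression_filter(cm, 5L), "g001")

  # raising min_count never grows the passing set
  prev <- expression_filter(cm, 1L)
  for (mc in 2:6) {
    cur <- expression_filter(cm, mc)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("expression filter equals a brute-force scan over all cells", {
  sim <- simulate_experiment(sim_config(n_genes = 200L, seed = 21L))
  cm <- sim$counts
  got <- expression_filter(cm, 5L)
  cells <- paste(cm$samples$genotype, cm$samples$stage)
  brute <- rownames(cm$counts)[vapply(seq_len(nrow(cm$counts)), function(g) {
    any(vapply(unique(cells), function(cl)
      all(cm$counts[g, cells == cl] >= 5L), logical(1L)))
  }, logical(1L))]
  expect_identical(got, brute)

  # genotype scope pools a genotype's stages
  bruteg <- rownames(cm$counts)[vapply(seq_len(nrow(cm$counts)), function(g)
    any(vapply(c("WT", "MUT"), function(gt)
      all(cm$counts[g, cm$samples$genotype == gt] >= 5L), logical(1L))),
    logical(1L))]
  expect_identical(expression_filter(cm, 5L, scope = "genotype"), bruteg)
})

test_that("TMM factors: identical and proportional columns give unit factors", {
  sam <- toy_samples()[1:2, ]
  a <- c(10L, 50L, 200L, 1000L, 30L, 77L)
  cm <- toy_count_matrix(cbind(a, a), sam)
  expect_equal(tmm_factors(cm)$tmm_factor, c(1, 1))

  cm2 <- toy_count_matrix(cbind(a, 2L * a), sam)
  expect_equal(tmm_factors(cm2)$tmm_factor, c(1, 1))

  cm0 <- toy_count_matrix(cbind(a, 0L * a), sam)
  expect_error(tmm_factors(cm0), "all-zero")
})

test_that("TMM factors match the doubly-trimmed weighted-mean oracle", {
  set.seed(42)
  counts <- matrix(rnbinom(60L, mu = 200, size = 5) + 1L, 20L, 3L)
  sam <- toy_samples(stages = c(25L, 30L), reps = 2L)[1:3, ]
  cm <- toy_count_matrix(counts, sam)
  expect_equal(tmm_factors(cm)$tmm_factor, tmm_oracle(counts),
               tolerance = 1e-10)

  # permuting gene order never changes factors
  perm <- sample(nrow(counts))
  cmp <- toy_count_matrix(counts[perm, ], sam)
  expect_equal(tmm_factors(cmp)$tmm_factor, tmm_factors(cm)$tmm_factor)

  # duplicated columns get identical factors
  cmd <- toy_count_matrix(counts[, c(1L, 1L, 2L)], sam)
  f <- tmm_factors(cmd)$tmm_factor
  expect_equal(f[1L], f[2L])
})

test_that("FPKM matches the element-wise formula and is linear", {
  sam <- toy_samples()[1:2, ]
  cm <- toy_count_matrix(matrix(c(10L, 0L, 20L, 40L), 2L), sam)
  ann <- data.frame(gene_id = rownames(cm$counts),
                    length_bp = c(1000L, 500L))
  norm <- data.frame(sample_id = sam$sample_id,
                     library_size = c(1e6, 1e6),
                     tmm_factor = c(1, 1), effective_size = c(1e6, 2e6))
  fk <- fpkm(cm, ann, norm)
  expect_equal(fk["g001", 1L], 10)          # unit denominators
  expect_equal(fk["g002", 1L], 0)
  expect_equal(fk["g001", 2L], 20 / 1 / 2)  # effective size 2e6

  # random fixture against the hand formula; halving length doubles FPKM
  set.seed(7)
  counts <- matrix(rnbinom(50L, mu = 100, size = 2), 25L, 2L)
  cm2 <- toy_count_matrix(counts, sam)
  ann2 <- data.frame(gene_id = rownames(cm2$counts),
                     length_bp = sample(500:3000, 25L))
  norm2 <- tmm_factors(cm2)
  fk2 <- fpkm(cm2, ann2, norm2)
  hand <- counts / (ann2$length_bp / 1e3)
  hand <- sweep(hand, 2L, norm2$effective_size / 1e6, "/")
  expect_equal(unname(fk2), unname(hand), tolerance = 1e-12)
  ann_half <- transform(ann2, length_bp = as.integer(length_bp / 2L))
  expect_equal(unname(fpkm(cm2, ann_half, norm2)),
               unname(2 * fk2 * ann2$length_bp /
                        (2 * as.integer(ann2$length_bp / 2L))),
               tolerance = 1e-12)
})

test_that("length/GC offset recovers a known log-length capture effect", {
  cfg <- sim_config(n_genes = 2000L,
                    capture_coefs = c(log_len = 1.0, gc1 = 0, gc2 = 0),
                    inactive_fraction = 0, specific_fraction = 0,
                    de_fraction = 0, lane_sd = 0, seed = 22L)
  sim <- simulate_experiment(cfg)
  norm <- tmm_factors(sim$counts)
  om <- fit_length_gc_offset(sim$counts, sim$annotation, norm)
  loglen <- log(sim$annotation$length_bp)
  slope <- coef(lm(om$offsets[sim$annotation$gene_id] ~ loglen))[["loglen"]]
  expect_equal(slope, 1.0, tolerance = 0.1)
})

test_that("offsets are scale-invariant and vanish for constant covariates", {
  cfg <- sim_config(n_genes = 500L,
                    length_dist = c(meanlog = log(1500), sdlog = 0),
                    capture_coefs = c(log_len = 0, gc1 = 0, gc2 = 0),
                    seed = 23L)
  sim <- simulate_experiment(cfg)
  sim$annotation$gc <- 0.5  # exactly constant covariates
  norm <- tmm_factors(sim$counts)
  om <- fit_length_gc_offset(sim$counts, sim$annotation, norm)
  expect_true(all(abs(om$offsets) < 1e-8))

  # multiplying all counts by 4 leaves centered offsets unchanged
  # (well-expressed genes: the log pseudocount is negligible)
  cfg2 <- sim_config(n_genes = 600L, inactive_fraction = 0,
                     specific_fraction = 0,
                     baseline_logmean = c(mean = log(3e-4), sd = 1),
                     seed = 24L)
  sim2 <- simulate_experiment(cfg2)
  norm2 <- tmm_factors(sim2$counts)
  om_a <- fit_length_gc_offset(sim2$counts, sim2$annotation, norm2)
  cm4 <- count_matrix(sim2$counts$counts * 4L, sim2$counts$samples)
  # same effective sizes: scaling is absorbed by the centered intercept
  om_b <- fit_length_gc_offset(cm4, sim2$annotation, norm2)
  expect_equal(om_a$offsets, om_b$offsets, tolerance = 0.02)

  small <- count_matrix(sim2$counts$counts[1:40, ], sim2$counts$samples)
  expect_error(fit_length_gc_offset(small, sim2$annotation, norm2), ">= 50")
})
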