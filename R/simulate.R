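#' Simulation configuration
#'
#' Defines the generative model for synthetic embryo RNA-Seq experiments:
#' negative-binomial counts for two genotypes at three developmental stages
#' with four biological replicates per cell, Gaussian sequencing-lane effects
#' on the log scale, length/GC-dependent capture, a configurable fraction of
#' transcriptionally inactive genes, differentially expressed genes with
#' |log2FC| >= 1 by construction, planted dynamic expression patterns,
#' synteny labels enriched among DE genes, and promoters with planted
#' GCGGCG motifs.
#'
#' The count model is `y_gi ~ NB(mu, phi)` with
#' `log mu = beta_g,cell(i) + u_lane(i) + log(libsize_i) + f(length_g, gc_g)`
#' and `Var = mu + phi mu^2`. Fixed effects `beta` are log relative
#' abundances; `f` is a centered smooth `a*log(length) + quadratic(gc)`.
#'
#' @param n_genes number of genes.
#' @param stages integer vector of developmental stages (days after
#'   pollination).
#' @param genotypes genotype labels; first is the reference (wild type).
#' @param reps_per_cell biological replicates per genotype/stage cell.
#' @param n_lanes number of sequencing lanes; replicate r of every cell is
#'   assigned to lane `((r-1) %% n_lanes) + 1`.
#' @param lane_sd standard deviation of Gaussian lane effects (log scale).
#' @param baseline_logmean `c(mean, sd)` of the normal distribution of active
#'   genes' log relative abundance.
#' @param inactive_fraction fraction of genes inactive in every cell.
#' @param inactive_level fixed effect assigned to inactive gene/cells (log
#'   relative abundance, far below any activity threshold).
#' @param specific_fraction fraction of genes active in only one genotype
#'   (applied once per genotype).
#' @param de_fraction fraction of (doubly active) genes differentially
#'   expressed between genotypes.
#' @param de_log2fc_min,de_log2fc_rate |log2FC| of DE genes is drawn as
#'   `de_log2fc_min + Exponential(de_log2fc_rate)`, sign Bernoulli(1/2).
#' @param pattern_genes optional named integer vector of per-pattern gene
#'   quotas (names like `"UP.SAME"`); assigned to active genes in both
#'   genotypes.
#' @param pattern_log2fc absolute per-transition effect (log2 units) of
#'   planted patterns.
#' @param dispersion `c(meanlog, sdlog)` of the log-normal NB dispersion.
#' @param length_dist `c(meanlog, sdlog)` of log-normal gene lengths (bp).
#' @param gc_dist `c(shape1, shape2)` of the Beta distribution of GC content.
#' @param capture_coefs `c(log_len, gc1, gc2)`: coefficients of the capture
#'   function `log_len*log(length) + gc1*(gc-0.5) + gc2*(gc-0.5)^2`,
#'   centered over genes.
#' @param libsize `c(meanlog, sdlog)` of log-normal library sizes.
#' @param synteny_nonsyn_base baseline probability that a gene is
#'   non-syntenic.
#' @param synteny_de_enrichment odds multiplier for non-syntenic origin among
#'   DE genes.
#' @param motif_fraction fraction of DE-gene promoters that receive a planted
#'   GCGGCG motif.
#' @param promoter_len promoter length (bp upstream of ATG).
#' @param seed integer seed; the whole experiment is reproducible given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       stages = c(25L, 30L, 35L),
                       genotypes = c("WT", "MUT"),
                       reps_per_cell = 4L,
                       n_lanes = 4L,
                       lane_sd = 0.05,
                       baseline_logmean = c(mean = log(1e-4), sd = 1.5),
                       inactive_fraction = 0.2,
                       inactive_level = log(5e-7),
                       specific_fraction = 0.025,
                       de_fraction = 0.1,
                       de_log2fc_min = 1,
                       de_log2fc_rate = 1,
                       pattern_genes = NULL,
                       pattern_log2fc = 2,
                       dispersion = c(meanlog = log(0.1), sdlog = 0.5),
                       length_dist = c(meanlog = log(1500), sdlog = 0.4),
                       gc_dist = c(shape1 = 20, shape2 = 20),
                       capture_coefs = c(log_len = 0.2, gc1 = 0.5, gc2 = -2),
                       libsize = c(meanlog = log(1e6), sdlog = 0.1),
                       synteny_nonsyn_base = 0.39,
                       synteny_de_enrichment = 2.7,
                       motif_fraction = 0.37,
                       promoter_len = 1000L,
                       seed = 1L) {
  if (!is.null(pattern_genes)) pattern_genes <- unlist(pattern_genes)
  cfg <- as.list(environment())
  cfg$pattern_genes <- pattern_genes
  for (f in c("inactive_fraction", "specific_fraction", "de_fraction",
              "motif_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("`", f, "` must lie in [0,1]")
  if (de_log2fc_min < 1)
    stop("DE effects must satisfy |log2FC| >= 1: de_log2fc_min >= 1")
  if (!is.null(pattern_genes)) {
    cat_t <- enumerate_patterns(length(stages))
    bad <- setdiff(names(pattern_genes), cat_t)
    if (length(bad)) stop("unknown pattern label(s): ", paste(bad, collapse = ", "))
    if (sum(pattern_genes) > n_genes)
      stop("pattern quotas exceed n_genes")
  }
  structure(cfg, class = "sim_config")
}

capture_fn <- function(length_bp, gc, coefs) {
  f <- coefs[["log_len"]] * log(length_bp) +
    coefs[["gc1"]] * (gc - 0.5) + coefs[["gc2"]] * (gc - 0.5)^2
  f - mean(f)
}

#' Simulate a full synthetic experiment with ground truth
#'
#' Draws gene annotations, fixed effects, lane effects, library sizes and
#' NB counts from the generative model of [sim_config()], plus motif-free
#' promoter sequences with GCGGCG motifs planted in a fraction of DE genes.
#'
#' @param config a [sim_config()].
#' @return A list with elements `counts` ([count_matrix]), `annotation`
#'   (data.frame), `promoters` (named character vector), and `truth`
#'   (list: `genes` data.frame of per-gene labels, `beta` genes x cells
#'   matrix of true fixed effects, `lane_effects`, `libsizes`, `capture`,
#'   `config`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  n <- cfg$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  stages <- sort(cfg$stages)
  cells <- paste(rep(cfg$genotypes, each = length(stages)),
                 rep(stages, length(cfg$genotypes)), sep = "_")

  ## annotation
  len <- pmax(200L, as.integer(round(rlnorm(n, cfg$length_dist[["meanlog"]],
                                            cfg$length_dist[["sdlog"]]))))
  gc <- rbeta(n, cfg$gc_dist[["shape1"]], cfg$gc_dist[["shape2"]])
  f_g <- capture_fn(len, gc, cfg$capture_coefs)

  ## gene status labels
  status <- rep("active", n)
  n_inact <- round(cfg$inactive_fraction * n)
  n_spec <- round(cfg$specific_fraction * n)
  pool <- sample(n)
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  idx_inact <- if (n_inact) take(n_inact) else integer()
  idx_wt_only <- if (n_spec) take(n_spec) else integer()
  idx_mut_only <- if (n_spec) take(n_spec) else integer()
  status[idx_inact] <- "inactive"
  status[idx_wt_only] <- "wt_only"
  status[idx_mut_only] <- "mut_only"

  ## DE among genes active in both genotypes
  both <- which(status == "active")
  n_de <- round(cfg$de_fraction * length(both))
  idx_de <- if (n_de) sample(both, n_de) else integer()
  lfc <- numeric(n)
  if (n_de)
    lfc[idx_de] <- (cfg$de_log2fc_min + stats::rexp(n_de, cfg$de_log2fc_rate)) *
      sample(c(-1, 1), n_de, replace = TRUE)

  ## dynamic patterns among doubly-active genes (DE genes allowed: a constant
  ## genotype shift does not alter transitions)
  pattern <- rep(NA_character_, n)
  if (!is.null(cfg$pattern_genes)) {
    avail <- setdiff(both, integer())
    avail <- sample(avail)
    k0 <- 0L
    for (p in names(cfg$pattern_genes)) {
      q <- cfg$pattern_genes[[p]]
      if (k0 + q > length(avail)) stop("pattern quotas exceed available active genes")
      pattern[avail[k0 + seq_len(q)]] <- p
      k0 <- k0 + q
    }
  }

  ## fixed effects per gene x cell
  base <- rnorm(n, cfg$baseline_logmean[["mean"]], cfg$baseline_logmean[["sd"]])
  beta <- matrix(cfg$inactive_level, n, length(cells),
                 dimnames = list(genes, cells))
  ln2 <- log(2)
  for (gt in cfg$genotypes) {
    for (si in seq_along(stages)) {
      cell <- paste(gt, stages[si], sep = "_")
      act <- status == "active" |
        (status == "wt_only" & gt == cfg$genotypes[1L]) |
        (status == "mut_only" & gt == cfg$genotypes[2L])
      b <- base
      ## pattern stage offsets
      has_pat <- !is.na(pattern)
      if (any(has_pat)) {
        steps <- pattern_stage_offsets(pattern[has_pat], si, cfg$pattern_log2fc)
        b[has_pat] <- b[has_pat] + steps * ln2
      }
      ## DE genotype shift (WT minus MUT = lfc)
      sgn <- if (gt == cfg$genotypes[1L]) +0.5 else -0.5
      b <- b + sgn * lfc * ln2
      beta[act, cell] <- b[act]
    }
  }

  ## dispersion
  phi <- rlnorm(n, cfg$dispersion[["meanlog"]], cfg$dispersion[["sdlog"]])

  ## samples, lanes, library sizes
  samples <- expand.grid(replicate = seq_len(cfg$reps_per_cell),
                         stage = stages, genotype = cfg$genotypes,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("genotype", "stage", "replicate")]
  samples$sample_id <- with(samples, paste0(genotype, "_", stage, "_r", replicate))
  samples$lane <- paste0("L", ((samples$replicate - 1L) %% cfg$n_lanes) + 1L)
  samples <- samples[, c("sample_id", "genotype", "stage", "replicate", "lane")]
  u <- rnorm(cfg$n_lanes, 0, cfg$lane_sd)
  names(u) <- paste0("L", seq_len(cfg$n_lanes))
  libsz <- rlnorm(nrow(samples), cfg$libsize[["meanlog"]], cfg$libsize[["sdlog"]])

  ## counts
  cnt <- matrix(0L, n, nrow(samples), dimnames = list(genes, samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    cell <- paste(samples$genotype[i], samples$stage[i], sep = "_")
    mu <- exp(beta[, cell] + u[[samples$lane[i]]] + log(libsz[i]) + f_g)
    cnt[, i] <- rnbinom(n, mu = mu, size = 1 / phi)
  }

  ## synteny: odds multiplier for DE genes
  p0 <- cfg$synteny_nonsyn_base
  odds <- p0 / (1 - p0)
  p_de <- odds * cfg$synteny_de_enrichment /
    (1 + odds * cfg$synteny_de_enrichment)
  p_gene <- ifelse(seq_len(n) %in% idx_de, p_de, p0)
  synteny <- ifelse(runif(n) < p_gene, "NON_SYNTENIC", "SYNTENIC")

  ann <- data.frame(gene_id = genes, length_bp = len, gc = gc,
                    synteny = synteny, category = NA_character_,
                    tf_family = NA_character_, chrom = NA_character_,
                    strand = NA_character_, atg_pos = NA_integer_,
                    stringsAsFactors = FALSE)

  ## promoters: motif-free, then plant in a fraction of DE genes
  prom <- random_promoters(n, cfg$promoter_len, ids = genes)
  motif_n <- integer(n)
  if (n_de && cfg$motif_fraction > 0) {
    planted <- plant_motifs(prom[genes[idx_de]], cfg$motif_fraction,
                            seed = sample.int(.Machine$integer.max, 1L))
    prom[names(planted$promoters)] <- planted$promoters
    motif_n[match(names(planted$positions), genes)] <-
      lengths(planted$positions)
  }

  truth_genes <- data.frame(
    gene_id = genes,
    status = status,
    active_wt = status %in% c("active", "wt_only"),
    active_mut = status %in% c("active", "mut_only"),
    de = seq_len(n) %in% idx_de,
    log2fc = lfc,
    pattern = ifelse(is.na(pattern), "NONE", pattern),
    phi = phi,
    motif_planted = motif_n,
    synteny = synteny,
    stringsAsFactors = FALSE)

  list(counts = count_matrix(cnt, samples),
       annotation = validate_annotation(ann),
       promoters = prom,
       truth = list(genes = truth_genes, beta = beta, lane_effects = u,
                    libsizes = setNames(libsz, samples$sample_id),
                    capture = setNames(f_g, genes), config = cfg))
}

## cumulative log2 offset of a pattern label at stage index si (1-based)
pattern_stage_offsets <- function(pattern, si, step) {
  if (si == 1L) return(numeric(length(pattern)))
  vapply(strsplit(pattern, ".", fixed = TRUE), function(tr) {
    d <- c(UP = step, DOWN = -step, SAME = 0)[tr[seq_len(si - 1L)]]
    sum(d)
  }, numeric(1L))
}

#' Generate random motif-free promoter sequences
#'
#' Uniform ACGT sequences; any GCGGCG occurrence arising by chance is
#' resampled until the sequence is motif-free.
#'
#' @param n number of promoters.
#' @param len promoter length (bp).
#' @param ids names for the sequences.
#' @return named character vector.
#' @export
random_promoters <- function(n, len = 1000L, ids = sprintf("p%05d", seq_len(n))) {
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(bases, len, replace = TRUE), collapse = ""), character(1L))
  for (iter in seq_len(100L)) {
    hit <- gregexpr("(?=GCGGCG)", seqs, perl = TRUE)
    dirty <- vapply(hit, function(h) h[1L] > 0L, logical(1L))
    if (!any(dirty)) break
    for (i in which(dirty)) {
      s <- strsplit(seqs[i], "")[[1L]]
      for (pos in as.integer(hit[[i]]))
        s[pos:(pos + 5L)] <- sample(bases, 6L, replace = TRUE)
      seqs[i] <- paste(s, collapse = "")
    }
  }
  setNames(seqs, ids)
}

#' Plant GCGGCG motifs into a fraction of promoters
#'
#' Exactly `round(fraction * n)` promoters receive one motif at a uniformly
#' drawn, recorded position. Input promoters must be motif-free.
#'
#' @param promoters named character vector of motif-free sequences.
#' @param fraction fraction of promoters to receive a motif, in \[0,1\].
#' @param seed optional integer seed for the selection and positions.
#' @return list with `promoters` (modified sequences, all inputs),
#'   `positions` (named list: per planted promoter, 0-based motif offsets).
#' @export
plant_motifs <- function(promoters, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1) stop("`fraction` must lie in [0,1]")
  if (any(grepl("GCGGCG", promoters, fixed = TRUE)))
    stop("promoters must be motif-free before planting")
  doit <- function() {
    n <- length(promoters)
    k <- round(fraction * n)
    chosen <- if (k) sample(names(promoters), k) else character()
    pos <- list()
    for (id in chosen) {
      L <- nchar(promoters[[id]])
      at <- sample.int(L - 5L, 1L)  # 1-based start
      substr(promoters[[id]], at, at + 5L) <- "GCGGCG"
      pos[[id]] <- at - 1L          # report 0-based
    }
    list(promoters = promoters, positions = pos)
  }
  if (is.null(seed)) doit() else withr::with_seed(seed, doit())
}
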