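pipeline_defaults <- function() {
  list(
    seed = 1L,
    counts = NULL, counts_meta = NULL, annotation = NULL, promoters = NULL,
    genome = NULL,
    simulate = TRUE, sim = list(),
    min_count = 5L, filter_scope = "cell",
    activity_threshold = NULL, eb_max_genes = 2000L,
    fdr = 0.05, lfc = 1, alpha = 0.01, pseudocount = 0.5,
    promoter_len = 1000L, both_strands = FALSE,
    background = "active", linkage = "average")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take documented defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list of overrides applied last.
#' @return configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user[names(overrides)] <- overrides
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  if (!cfg$filter_scope %in% c("cell", "genotype"))
    stop("filter_scope must be 'cell' or 'genotype'")
  if (!cfg$background %in% c("active", "filtered"))
    stop("background must be 'active' or 'filtered'")
  for (f in c("fdr", "alpha"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) stop("`", f, "` must lie in (0,1)")
  if (cfg$min_count < 0 || cfg$lfc < 0 || cfg$promoter_len < 1)
    stop("thresholds outside documented ranges")
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- cbind(setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                        rownames_as), as.data.frame(x))
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) -> filter/normalize -> activity -> differential
#' expression -> dynamic patterns -> promoter motifs -> enrichment -> QC,
#' collecting headline numbers into a report. Deterministic given the
#' config seed.
#'
#' @param config a [read_pipeline_config()] object (or a plain list of the
#'   same keys).
#' @param out_dir output directory for result tables and `report.json`, or
#'   `NULL` to skip writing.
#' @return list with every stage's result and `report` (the headline
#'   summary list).
#' @export
run_pipeline <- function(config = read_pipeline_config(), out_dir = NULL) {
  cfg <- config
  truth <- NULL
  if (!is.null(cfg$counts)) {
    cm <- read_counts(cfg$counts, meta = cfg$counts_meta)
    ann <- if (!is.null(cfg$annotation)) read_annotation(cfg$annotation) else
      stop("an annotation table is required with external counts")
    promoters <- if (!is.null(cfg$promoters)) read_fasta(cfg$promoters) else
      if (!is.null(cfg$genome))
        extract_promoters(ann, read_fasta(cfg$genome), cfg$promoter_len) else
          NULL
  } else if (isTRUE(cfg$simulate)) {
    scfg <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
    sim <- simulate_experiment(scfg)
    cm <- sim$counts; ann <- sim$annotation
    promoters <- sim$promoters; truth <- sim$truth
  } else stop("no input: supply `counts` or set `simulate: true`")

  ## normalization
  filtered <- expression_filter(cm, cfg$min_count, cfg$filter_scope)
  norm <- tmm_factors(cm)
  offs <- tryCatch(fit_length_gc_offset(cm, ann, norm, genes = filtered),
                   error = function(e) { warning(conditionMessage(e)); NULL })
  fpkm_mat <- fpkm(cm, ann, norm)

  ## activity on all genes
  act <- fit_activity(cm, norm, offset_model = offs,
                      threshold = cfg$activity_threshold,
                      eb_max_genes = cfg$eb_max_genes)
  act_sum <- summarize_activity(act$posterior)

  ## differential expression on filtered genes
  fpkm_f <- fpkm_mat[intersect(rownames(fpkm_mat), filtered), , drop = FALSE]
  de <- run_de(fpkm_f, cm$samples, fdr = cfg$fdr, lfc = cfg$lfc,
               pseudocount = cfg$pseudocount)
  de_genes <- unique(de$table$gene[de$table$de_call])

  ## dynamic patterns per genotype
  pat_wt <- run_transition_patterns(fpkm_f, cm$samples, "WT",
                                    cfg$fdr, cfg$lfc, cfg$pseudocount)
  pat_mut <- run_transition_patterns(fpkm_f, cm$samples, "MUT",
                                     cfg$fdr, cfg$lfc, cfg$pseudocount)
  pat_cmp <- compare_genotype_patterns(pat_wt$patterns, pat_mut$patterns)

  ## promoter motifs
  motifs <- NULL; motif_summary <- NULL
  if (!is.null(promoters)) {
    motifs <- scan_promoters(promoters, both_strands = cfg$both_strands)
    sets <- list(all = intersect(names(promoters), rownames(cm$counts)),
                 de = intersect(de_genes, names(promoters)))
    sets <- Filter(length, sets)
    motif_summary <- motif_set_summary(motifs, sets)
  }

  ## enrichment
  background <- if (cfg$background == "active") act_sum$active_any else filtered
  syn_de <- synteny_enrichment(de_genes, ann, reference = background,
                               alpha = cfg$alpha)
  syn_wt <- synteny_enrichment(act_sum$wt_exclusive, ann,
                               reference = background, alpha = cfg$alpha)
  syn_mut <- synteny_enrichment(act_sum$mut_exclusive, ann,
                                reference = background, alpha = cfg$alpha)
  cat_enr <- if (!all(is.na(ann$category))) {
    cmap <- ann[!is.na(ann$category), c("gene_id", "category")]
    category_enrichment(intersect(de_genes, background), cmap, background,
                        alpha = cfg$alpha)
  } else NULL

  ## sample QC
  logexpr <- log_expression(fpkm_f, cfg$pseudocount)
  qc <- list(pca = pca_samples(logexpr),
             hclust = hcluster_samples(logexpr, cfg$linkage))

  report <- list(
    n_genes = nrow(cm$counts), n_samples = ncol(cm$counts),
    n_filtered = length(filtered),
    activity = list(threshold = act$threshold,
                    per_cell = as.list(act_sum$per_cell),
                    n_active_any = act_sum$n_any,
                    n_constitutive = act_sum$n_constitutive,
                    n_wt_exclusive = length(act_sum$wt_exclusive),
                    n_mut_exclusive = length(act_sum$mut_exclusive)),
    de = list(n_de = length(de_genes), venn = as.list(de$venn),
              rho = de$rho),
    patterns = list(n_wt = sum(pat_wt$patterns != "NONE"),
                    n_mut = sum(pat_mut$patterns != "NONE"),
                    n_same_pattern = pat_cmp$n_overlap),
    motifs = if (!is.null(motif_summary))
      split(motif_summary[c("n_with_motif", "n_total", "fraction")],
            motif_summary$set),
    enrichment = list(de_nonsyntenic_p = syn_de$p,
                      wt_exclusive_nonsyntenic_p = syn_wt$p,
                      mut_exclusive_nonsyntenic_p = syn_mut$p))

  res <- list(counts = cm, annotation = ann, truth = truth,
              filtered = filtered, norm = norm, offsets = offs,
              fpkm = fpkm_mat, activity = act, activity_summary = act_sum,
              de = de, patterns = list(WT = pat_wt, MUT = pat_mut,
                                       comparison = pat_cmp),
              motifs = motifs, motif_summary = motif_summary,
              enrichment = list(synteny_de = syn_de, synteny_wt = syn_wt,
                                synteny_mut = syn_mut, category = cat_enr),
              qc = qc, report = report, config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_counts(res$counts, p("counts.tsv"))
  write_annotation(res$annotation, p("annotation.tsv"))
  write_tsv(res$norm, p("factors.tsv"))
  write_tsv(round(res$fpkm, 4L), p("fpkm.tsv"), rownames_as = "gene_id")
  writeLines(res$filtered, p("filtered_genes.txt"))
  write_tsv(res$activity$posterior, p("activity.tsv"))
  write_tsv(res$de$table, p("de.tsv"))
  write_tsv(data.frame(gene_id = names(res$patterns$WT$patterns),
                       wt = res$patterns$WT$patterns,
                       mut = res$patterns$MUT$patterns[
                         names(res$patterns$WT$patterns)]),
            p("patterns.tsv"))
  if (!is.null(res$motifs)) write_tsv(res$motifs, p("motifs.tsv"))
  if (!is.null(res$motif_summary))
    write_tsv(res$motif_summary, p("motif_summary.tsv"))
  write_tsv(rbind(cbind(set = "de", res$enrichment$synteny_de),
                  cbind(set = "wt_exclusive", res$enrichment$synteny_wt),
                  cbind(set = "mut_exclusive", res$enrichment$synteny_mut)),
            p("enrichment_synteny.tsv"))
  if (!is.null(res$enrichment$category))
    write_tsv(res$enrichment$category, p("enrichment_category.tsv"))
  write_tsv(round(res$qc$pca$scores, 6L), p("pc_scores.tsv"),
            rownames_as = "sample_id")
  jsonlite::write_json(res$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(out_dir)
}
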