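#' Chi-square test with Yates' continuity correction on a 2x2 table
#'
#' Statistic `sum(max(|O - E| - 0.5, 0)^2 / E)` over the four cells, with
#' expected counts from the row/column margins, referred to the chi-square
#' distribution with 1 df. Tables with a zero expected cell are reported as
#' `NA` with a warning.
#'
#' @param table 2x2 matrix of non-negative counts (see
#'   [contingency_2x2()]).
#' @return list: `statistic`, `p_value`, `expected`.
#' @export
chisq_yates <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L))
  if (any(table < 0)) stop("contingency cells must be non-negative")
  if (sum(table) == 0) stop("contingency grand total must be > 0")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(E == 0)) {
    warning("zero expected cell; test not defined")
    return(list(statistic = NA_real_, p_value = NA_real_, expected = E))
  }
  ct <- suppressWarnings(chisq.test(table, correct = TRUE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, expected = E)
}

#' Functional-category over/under-representation
#'
#' Per category, the 2x2 table (in-category vs not) x (in the gene set vs
#' rest of the background) is tested by [chisq_yates()]; the expected count
#' is the set size times the category's share of the background. Genes
#' mapping to several categories count once per category.
#'
#' @param genes gene set (e.g. DE genes), a subset of `background`.
#' @param category_map data.frame with `gene_id`, `category` (a gene may
#'   appear in several rows).
#' @param background background gene ids (e.g. all expressed genes).
#' @param alpha significance level (default 0.01).
#' @return data.frame per category: `category`, `observed`, `expected`,
#'   `set_total`, `background_in_category`, `chi2`, `p`, `direction`
#'   (`OVER`/`UNDER`/`NONE`), `significant`.
#' @export
category_enrichment <- function(genes, category_map, background,
                                alpha = 0.01) {
  extra <- setdiff(genes, background)
  if (length(extra)) stop("gene set must be a subset of the background")
  cm <- category_map[category_map$gene_id %in% background, , drop = FALSE]
  skipped <- setdiff(unique(category_map$category), unique(cm$category))
  if (length(skipped))
    warning("category absent from background, skipped: ",
            paste(skipped, collapse = ", "))
  n_set <- length(genes)
  n_bg <- length(background)
  out <- do.call(rbind, lapply(sort(unique(cm$category)), function(cat) {
    in_cat <- unique(cm$gene_id[cm$category == cat])
    a <- sum(genes %in% in_cat)
    b <- length(in_cat) - a
    cc <- n_set - a
    d <- (n_bg - length(in_cat)) - cc
    ts <- chisq_yates(contingency_2x2(a, b, cc, d))
    expected <- n_set * length(in_cat) / n_bg
    sig <- !is.na(ts$p_value) && ts$p_value < alpha
    data.frame(category = cat, observed = a, expected = expected,
               set_total = n_set, background_in_category = length(in_cat),
               chi2 = ts$statistic, p = ts$p_value,
               direction = if (!sig) "NONE" else
                 if (a > expected) "OVER" else "UNDER",
               significant = sig,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Syntenic/non-syntenic enrichment of a gene set
#'
#' Tests whether the non-syntenic fraction of a gene set differs from a
#' reference universe via the Yates-corrected chi-square on the 2x2 table
#' (set vs reference) x (non-syntenic vs syntenic). Genes with unknown
#' synteny are excluded (count reported).
#'
#' @param genes gene set ids.
#' @param annotation annotation data.frame with `gene_id`, `synteny`; or
#'   `NULL` when `reference` gives explicit counts.
#' @param reference either a vector of reference gene ids (looked up in
#'   `annotation`) or a named numeric `c(non_syntenic = , syntenic = )` of
#'   printed reference counts.
#' @param alpha significance level (default 0.01).
#' @return data.frame row: `n_set`, `nonsyn_set`, `set_fraction`,
#'   `ref_fraction`, `chi2`, `p`, `direction`, `significant`,
#'   `n_unknown_excluded`.
#' @export
synteny_enrichment <- function(genes, annotation = NULL, reference,
                               alpha = 0.01) {
  count_split <- function(ids) {
    syn <- annotation$synteny[match(ids, annotation$gene_id)]
    c(non_syntenic = sum(syn == "NON_SYNTENIC", na.rm = TRUE),
      syntenic = sum(syn == "SYNTENIC", na.rm = TRUE),
      unknown = sum(is.na(syn) | syn == "UNKNOWN"))
  }
  if (!length(genes)) {
    warning("empty gene set")
    return(data.frame(n_set = 0L, nonsyn_set = NA_integer_,
                      set_fraction = NA_real_, ref_fraction = NA_real_,
                      chi2 = NA_real_, p = NA_real_, direction = NA_character_,
                      significant = NA, n_unknown_excluded = 0L))
  }
  gs <- count_split(genes)
  ref <- if (is.numeric(reference)) {
    c(reference[["non_syntenic"]], reference[["syntenic"]], 0)
  } else count_split(reference)
  tab <- contingency_2x2(gs[1L], gs[2L], ref[1L], ref[2L])
  ts <- chisq_yates(tab)
  set_frac <- gs[[1L]] / (gs[[1L]] + gs[[2L]])
  ref_frac <- ref[[1L]] / (ref[[1L]] + ref[[2L]])
  sig <- !is.na(ts$p_value) && ts$p_value < alpha
  data.frame(n_set = length(genes), nonsyn_set = unname(gs[1L]),
             set_fraction = set_frac, ref_fraction = ref_frac,
             chi2 = ts$statistic, p = ts$p_value,
             direction = if (!sig) "NONE" else
               if (set_frac > ref_frac) "OVER" else "UNDER",
             significant = sig,
             n_unknown_excluded = unname(gs[3L]) + unname(ref[3L]),
             stringsAsFactors = FALSE, row.names = NULL)
}
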