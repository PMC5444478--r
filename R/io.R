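#' Construct a validated count matrix with sample metadata
#'
#' The central container of the pipeline: a genes x samples matrix of
#' non-negative integer read counts together with the experimental design
#' (genotype, developmental stage, biological replicate, sequencing lane)
#' of every sample.
#'
#' @param counts integer matrix, genes in rows, samples in columns. Must have
#'   row names (gene ids) and column names (sample ids).
#' @param samples data.frame with columns `sample_id`, `genotype` (one of
#'   `"WT"`, `"MUT"`), `stage` (integer, days after pollination), `replicate`
#'   (positive integer) and `lane` (categorical label). Row order must match
#'   the column order of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ", rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyNA(counts)) stop("`counts` contains missing cells")
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1L, , drop = TRUE]
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]]))
  }
  storage.mode(counts) <- "integer"
  samples <- validate_sample_meta(samples)
  if (!identical(as.character(samples$sample_id), colnames(counts)))
    stop("sample metadata rows must match count columns (same ids, same order)")
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

validate_sample_meta <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "stage", "replicate", "lane")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample id: ",
         samples$sample_id[duplicated(samples$sample_id)][1L])
  samples$genotype <- as.character(samples$genotype)
  bad <- setdiff(unique(samples$genotype), c("WT", "MUT"))
  if (length(bad)) stop("unknown genotype label(s): ", paste(bad, collapse = ", "))
  samples$stage <- as.integer(samples$stage)
  samples$replicate <- as.integer(samples$replicate)
  if (any(samples$replicate < 1L)) stop("replicate numbers must be positive")
  samples$lane <- as.character(samples$lane)
  samples[, need]
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cells <- interaction(x$samples$genotype, x$samples$stage, drop = TRUE)
  cat("cells:", paste(levels(cells), collapse = " "), "\n")
  invisible(x)
}

#' Sample cell labels (genotype by stage)
#'
#' @param samples sample metadata data.frame.
#' @return factor of `genotype_stage` labels, one per sample.
#' @export
sample_cells <- function(samples) {
  factor(paste(samples$genotype, samples$stage, sep = "_"),
         levels = unique(paste(rep(c("WT", "MUT"), each = length(unique(samples$stage))),
                               rep(sort(unique(samples$stage)), 2L), sep = "_")))
}

#' Read a count matrix from TSV
#'
#' The file holds genes in rows and samples in columns. Sample metadata is
#' taken either from `#`-prefixed header lines (one per field, e.g.
#' `#genotype<TAB>WT<TAB>MUT ...`, fields `genotype`, `stage`, `replicate`,
#' `lane`) or from a separate metadata TSV with columns `sample_id`,
#' `genotype`, `stage`, `replicate`, `lane`. An explicit `meta` file takes
#' precedence over inline header lines.
#'
#' @param path counts TSV path.
#' @param meta optional metadata TSV path.
#' @return A [count_matrix].
#' @export
read_counts <- function(path, meta = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  inline <- list()
  if (length(hdr)) {
    for (h in lines[hdr]) {
      f <- strsplit(sub("^#", "", h), "\t", fixed = TRUE)[[1L]]
      inline[[f[1L]]] <- f[-1L]
    }
    lines <- lines[-hdr]
  }
  con <- textConnection(lines)
  on.exit(close(con))
  tab <- read.delim(con, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]))
  }
  rownames(mat) <- gene_ids
  if (!is.null(meta)) {
    samples <- read.delim(meta, stringsAsFactors = FALSE)
    samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  } else if (length(inline)) {
    samples <- data.frame(sample_id = colnames(mat), stringsAsFactors = FALSE)
    for (f in c("genotype", "stage", "replicate", "lane")) {
      if (is.null(inline[[f]]))
        stop("inline metadata missing '#", f, "' header line")
      if (length(inline[[f]]) != ncol(mat))
        stop("inline '#", f, "' line has ", length(inline[[f]]),
             " values for ", ncol(mat), " samples")
      samples[[f]] <- inline[[f]]
    }
  } else {
    stop("no sample metadata: supply `meta` or inline '#' header lines")
  }
  count_matrix(mat, samples)
}

#' Write a count matrix to TSV
#'
#' Emits inline `#`-prefixed metadata lines followed by the gene x sample
#' table, so that [read_counts()] round-trips the object.
#'
#' @param cm a [count_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in c("genotype", "stage", "replicate", "lane"))
    writeLines(paste(c(paste0("#", f), as.character(cm$samples[[f]])),
                     collapse = "\t"), con)
  writeLines(paste(c("gene_id", colnames(cm$counts)), collapse = "\t"), con)
  write.table(cm$counts, con, sep = "\t", quote = FALSE,
              col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Read a gene annotation table from TSV
#'
#' Required columns: `gene_id`, `length_bp`. Optional: `gc` (fraction in
#' \[0,1\]), `synteny` (`SYNTENIC`/`NON_SYNTENIC`/`UNKNOWN`), `category`,
#' `tf_family`, and promoter coordinates `chrom`, `strand` (`+`/`-`),
#' `atg_pos` (1-based position of the A of the start codon). Missing optional
#' columns are filled with `UNKNOWN`/`NA`, never fabricated.
#'
#' @param path annotation TSV path.
#' @return data.frame, one row per gene.
#' @export
read_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "length_bp"), names(ann))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene id in annotation: ",
         ann$gene_id[duplicated(ann$gene_id)][1L])
  ann$length_bp <- as.integer(ann$length_bp)
  if (any(!is.finite(ann$length_bp)) || any(ann$length_bp < 1L))
    stop("length_bp must be a positive integer for every gene")
  if (!is.null(ann$gc)) {
    if (any(is.finite(ann$gc) & (ann$gc < 0 | ann$gc > 1)))
      stop("gc outside [0,1] for gene ",
           ann$gene_id[which(ann$gc < 0 | ann$gc > 1)[1L]])
  } else ann$gc <- NA_real_
  if (!is.null(ann$synteny)) {
    ann$synteny <- toupper(as.character(ann$synteny))
    ann$synteny[is.na(ann$synteny) | ann$synteny == ""] <- "UNKNOWN"
    bad <- setdiff(unique(ann$synteny), c("SYNTENIC", "NON_SYNTENIC", "UNKNOWN"))
    if (length(bad)) stop("unknown synteny label(s): ", paste(bad, collapse = ", "))
  } else ann$synteny <- "UNKNOWN"
  for (f in c("category", "tf_family", "chrom", "strand"))
    if (is.null(ann[[f]])) ann[[f]] <- NA_character_
  if (is.null(ann$atg_pos)) ann$atg_pos <- NA_integer_
  ann$atg_pos <- as.integer(ann$atg_pos)
  if (any(!is.na(ann$atg_pos) & ann$atg_pos < 1L))
    stop("atg_pos must be >= 1 (1-based) when present")
  if (any(!is.na(ann$strand) & !ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' when present")
  ann
}

#' Write a gene annotation table to TSV
#' @param ann annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences over
#'   \{A, C, G, T, N\}.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  if (any(nchar(out) == 0L))
    stop("empty FASTA record: ", names(out)[nchar(out) == 0L][1L])
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop("non-ACGTN character in record: ", names(out)[bad][1L])
  out
}

#' Write sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' 2x2 contingency table constructor
#'
#' Rows are in-set / out-of-set, columns property-yes / property-no.
#'
#' @param a,b,c,d non-negative integer cell counts (row-major).
#' @return 2x2 integer matrix.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("contingency cells must be non-negative")
  if (sum(cells) == 0) stop("contingency grand total must be > 0")
  matrix(as.numeric(cells), nrow = 2L, byrow = TRUE,
         dimnames = list(c("in_set", "out_set"), c("yes", "no")))
}
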