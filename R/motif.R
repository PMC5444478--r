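#' Extract promoter sequences upstream of the ATG
#'
#' For a plus-strand gene the promoter is the `promoter_len` bases
#' immediately 5' of the ATG (1-based positions `atg_pos - L` to
#' `atg_pos - 1`); for a minus-strand gene, positions `atg_pos + 1` to
#' `atg_pos + L`, reverse-complemented. Promoters running past a contig
#' edge are clipped with a warning; genes with unknown strand are skipped
#' with a warning.
#'
#' @param annotation data.frame with `gene_id`, `chrom`, `strand`,
#'   `atg_pos` (1-based position of the A of the start codon).
#' @param genome named character vector of contig sequences (uppercase), as
#'   from [read_fasta()].
#' @param promoter_len promoter length in bp (default 1000).
#' @return named character vector of strand-corrected promoter sequences.
#' @export
extract_promoters <- function(annotation, genome, promoter_len = 1000L) {
  out <- character(0)
  for (i in seq_len(nrow(annotation))) {
    gid <- annotation$gene_id[i]
    chrom <- annotation$chrom[i]
    strand <- annotation$strand[i]
    atg <- annotation$atg_pos[i]
    if (is.na(strand) || !strand %in% c("+", "-")) {
      warning("gene ", gid, ": unknown strand, skipped")
      next
    }
    if (is.na(chrom) || !chrom %in% names(genome))
      stop("gene ", gid, ": contig '", chrom, "' not in genome")
    clen <- nchar(genome[[chrom]])
    if (is.na(atg) || atg < 1L || atg > clen)
      stop("gene ", gid, ": atg_pos outside contig bounds")
    if (strand == "+") {
      from <- atg - promoter_len
      if (from < 1L) {
        warning("gene ", gid, ": promoter clipped at contig start")
        from <- 1L
      }
      if (atg == 1L) { out[gid] <- ""; next }
      out[gid] <- substr(genome[[chrom]], from, atg - 1L)
    } else {
      to <- atg + promoter_len
      if (to > clen) {
        warning("gene ", gid, ": promoter clipped at contig end")
        to <- clen
      }
      if (atg == clen) { out[gid] <- ""; next }
      seq <- substr(genome[[chrom]], atg + 1L, to)
      out[gid] <- reverse_complement(seq)
    }
  }
  out
}

#' Reverse complement of a DNA string
#' @param seq uppercase ACGTN string.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a promoter for the LBD motif
#'
#' All (overlapping) exact occurrences of the motif by sliding window; `N`
#' never matches. With `both_strands = TRUE` the reverse complement of the
#' motif is also scanned on the given strand and hits are tagged with
#' strand `"-"`. The motif is non-palindromic, so the default sense-strand
#' scan and the two-strand scan genuinely differ.
#'
#' @param promoter uppercase promoter sequence.
#' @param motif motif string over ACGT (default `"GCGGCG"`).
#' @param both_strands also scan for the reverse complement.
#' @return list: `offsets` (0-based match starts), `strand` (per hit),
#'   `has_motif`.
#' @export
scan_lbd <- function(promoter, motif = "GCGGCG", both_strands = FALSE) {
  if (grepl("[^ACGT]", motif)) stop("motif must contain only A, C, G, T")
  if (nchar(promoter) < nchar(motif))
    return(list(offsets = integer(), strand = character(), has_motif = FALSE))
  hits <- function(pat) {
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(promoter),
                                  fixed = TRUE)
    Biostrings::start(m) - 1L
  }
  off <- hits(motif)
  str <- rep("+", length(off))
  if (both_strands) {
    off2 <- hits(reverse_complement(motif))
    ord <- order(c(off, off2))
    str <- c(str, rep("-", length(off2)))[ord]
    off <- c(off, off2)[ord]
  }
  list(offsets = as.integer(off), strand = str, has_motif = length(off) > 0L)
}

#' Scan many promoters for the LBD motif
#'
#' @param promoters named character vector of promoter sequences.
#' @inheritParams scan_lbd
#' @return data.frame: `gene_id`, `n_hits`, `has_motif`; attribute `hits`
#'   holds the per-gene offset lists.
#' @export
scan_promoters <- function(promoters, motif = "GCGGCG", both_strands = FALSE) {
  res <- lapply(promoters, scan_lbd, motif = motif,
                both_strands = both_strands)
  out <- data.frame(gene_id = names(promoters),
                    n_hits = vapply(res, function(r) length(r$offsets),
                                    integer(1L)),
                    has_motif = vapply(res, `[[`, logical(1L), "has_motif"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "hits") <- lapply(res, `[[`, "offsets")
  out
}

#' Motif prevalence within gene sets
#'
#' @param hits output of [scan_promoters()].
#' @param gene_sets named list of gene-id vectors (must be subsets of the
#'   scanned genes).
#' @return data.frame per set: `set`, `n_with_motif`, `n_total`, `fraction`
#'   and `percent` (rounded); empty sets yield `NA` with the counts.
#' @export
motif_set_summary <- function(hits, gene_sets) {
  has <- setNames(hits$has_motif, hits$gene_id)
  do.call(rbind, lapply(names(gene_sets), function(nm) {
    g <- gene_sets[[nm]]
    miss <- setdiff(g, names(has))
    if (length(miss)) stop("set '", nm, "' contains unscanned gene(s): ",
                           paste(head(miss, 3L), collapse = ", "))
    n <- length(g)
    k <- sum(has[g])
    data.frame(set = nm, n_with_motif = k, n_total = n,
               fraction = if (n) k / n else NA_real_,
               percent = if (n) round(100 * k / n) else NA_real_,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
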