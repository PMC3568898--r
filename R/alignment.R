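# Gapped three-way (plus optional outgroup) genome alignment keyed on the
# japonica (Osj) reference, one block per chromosome. Substitution-only
# regions occupy one column per reference base; insertions in a non-reference
# genome add columns where the other genomes carry "-".

#' Construct a three-way genome alignment
#'
#' @param blocks Named list (by chromosome) of named character vectors of
#'   equal-length gapped sequences; names must include `osj`, `og`, `osi`.
#' @return An object of class `triple_alignment`.
#' @export
triple_alignment <- function(blocks) {
  for (ch in names(blocks)) {
    b <- blocks[[ch]]
    stopifnot(all(c("osj", "og", "osi") %in% names(b)),
              length(unique(nchar(b))) == 1L)
  }
  structure(list(blocks = blocks), class = "triple_alignment")
}

#' @export
print.triple_alignment <- function(x, ...) {
  cat("triple_alignment:", length(x$blocks), "block(s);",
      paste(names(x$blocks), collapse = ", "), "\n")
  invisible(x)
}

aln_matrix <- function(aln, chrom) {
  b <- aln$blocks[[chrom]]
  if (is.null(b)) stop("no alignment block for chromosome ", chrom)
  do.call(rbind, lapply(b, function(s) strsplit(s, "")[[1]]))
}

# 0-based genome position of each alignment column for one taxon (NA at
# gaps), and the inverse map (column index, 1-based, per genome position).
aln_maps <- function(aln, chrom, taxon) {
  ch <- strsplit(aln$blocks[[chrom]][[taxon]], "")[[1]]
  ungapped <- ch != "-"
  pos_of_col <- ifelse(ungapped, cumsum(ungapped) - 1L, NA_integer_)
  col_of_pos <- which(ungapped)
  list(pos_of_col = pos_of_col, col_of_pos = col_of_pos)
}

# Alignment columns spanned by a 0-based half-open reference (osj) interval.
aln_cols_for_ref <- function(aln, chrom, start, end) {
  m <- aln_maps(aln, chrom, "osj")
  if (end > length(m$col_of_pos) || start < 0) {
    stop("interval outside the aligned reference")
  }
  if (end <= start) return(integer(0))
  seq.int(m$col_of_pos[start + 1L], m$col_of_pos[end])
}

# Lift a 0-based half-open interval from `taxon` coordinates to osj
# coordinates; NULL when the interval is unliftable (osj gapped there).
lift_to_osj <- function(aln, chrom, taxon, start, end) {
  m_t <- aln_maps(aln, chrom, taxon)
  m_r <- aln_maps(aln, chrom, "osj")
  if (end > length(m_t$col_of_pos)) return(NULL)
  cols <- seq.int(m_t$col_of_pos[start + 1L], m_t$col_of_pos[end])
  ref_pos <- m_r$pos_of_col[cols]
  ref_pos <- ref_pos[!is.na(ref_pos)]
  if (!length(ref_pos)) return(NULL)
  c(start = min(ref_pos), end = max(ref_pos) + 1L)
}

# Per-taxon ungapped sequences of an alignment.
aln_sequences <- function(aln, taxa = c("osj", "og", "osi")) {
  out <- lapply(taxa, function(tx) {
    vapply(aln$blocks, function(b) gsub("-", "", b[[tx]], fixed = TRUE),
           character(1))
  })
  names(out) <- taxa
  out
}

#' Write or read a three-way alignment as MAF
#'
#' One MAF block per chromosome; the japonica row is the reference. Only
#' the subset of MAF needed for these alignments is handled: `a` score
#' lines and `s` sequence lines.
#'
#' @param aln A [triple_alignment()].
#' @param path File path.
#' @return `write_maf`: `path`, invisibly. `read_maf`: a
#'   [triple_alignment()].
#' @export
write_maf <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (ch in names(aln$blocks)) {
    b <- aln$blocks[[ch]]
    writeLines("a score=0", con)
    for (tx in names(b)) {
      ungapped <- gsub("-", "", b[[tx]], fixed = TRUE)
      writeLines(sprintf("s %s.%s 0 %d + %d %s", tx, ch,
                         nchar(ungapped), nchar(ungapped), b[[tx]]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_maf
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  s_lines <- grep("^s ", lines, value = TRUE)
  parts <- strsplit(s_lines, "\\s+")
  src <- vapply(parts, `[[`, character(1), 2L)
  seqs <- vapply(parts, `[[`, character(1), 7L)
  taxon <- sub("\\..*$", "", src)
  chrom <- sub("^[^.]+\\.", "", src)
  blocks <- lapply(split(seq_along(src), chrom), function(i) {
    stats::setNames(seqs[i], taxon[i])
  })
  triple_alignment(blocks)
}

#' Aligned columns as a site table
#'
#' Flattens the alignment into the per-site data frame consumed by the
#' windowed-divergence module: one row per alignment column that has an
#' ungapped reference (osj) base.
#'
#' @param aln A [triple_alignment()].
#' @param annotation Optional [GenomicRanges::GRanges] with metadata
#'   column `class` used to label each site (`CDS-exon`, `other-exon`,
#'   `non-exonic`, ...); unlabelled sites get `"non-exonic"`.
#' @return Data frame with `chrom`, `ref_pos`, `base_osj`, `base_og`,
#'   `base_osi`, `annotation_class`.
#' @export
alignment_columns <- function(aln, annotation = NULL) {
  out <- lapply(names(aln$blocks), function(ch) {
    m <- aln_matrix(aln, ch)
    ref_ok <- m["osj", ] != "-"
    base_or_na <- function(x) ifelse(toupper(x) %in% BASES, toupper(x),
                                     NA_character_)
    data.frame(chrom = ch,
               ref_pos = cumsum(ref_ok)[ref_ok] - 1L,
               base_osj = base_or_na(m["osj", ref_ok]),
               base_og = base_or_na(m["og", ref_ok]),
               base_osi = base_or_na(m["osi", ref_ok]))
  })
  out <- do.call(rbind, out)
  out$annotation_class <- "non-exonic"
  if (!is.null(annotation)) {
    gr <- GenomicRanges::GRanges(out$chrom,
                                 IRanges::IRanges(out$ref_pos + 1L,
                                                  width = 1L))
    hit <- GenomicRanges::findOverlaps(gr, annotation,
                                       ignore.strand = TRUE)
    out$annotation_class[S4Vectors::queryHits(hit)] <-
      as.character(annotation$class[S4Vectors::subjectHits(hit)])
  }
  out
}
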