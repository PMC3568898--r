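# Perfect-microsatellite detection, cross-genome clustering, polymorphism
# classification and the SSR contingency tests.

#' SSR detection and clustering configuration
#'
#' @param min_units Named minimum numbers of repeat units per motif size:
#'   defaults 9 (di-), 6 (tri-), 5 (tetra-nucleotide).
#' @param flank_bp Width of the alignment flanks that must be gap-free
#'   around a clustered SSR (default 50).
#' @return A list of class `ssr_config`.
#' @export
ssr_config <- function(min_units = c(`2` = 9L, `3` = 6L, `4` = 5L),
                       flank_bp = 50L) {
  stopifnot(all(min_units >= 2), all(c("2", "3", "4") %in% names(min_units)))
  structure(list(min_units = min_units, flank_bp = as.integer(flank_bp)),
            class = "ssr_config")
}

is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (strrep(unit, u / d) == motif) return(FALSE)
  }
  TRUE
}

#' Detect perfect microsatellites in a sequence
#'
#' Finds all maximal perfect tandem tracts of primitive 2-4 nt motifs
#' meeting the per-unit minimum repeat counts. Tracts are trimmed to whole
#' units (left-anchored); tracts containing non-ACGT characters are
#' excluded. Overlapping candidates are resolved longest-tract-first, then
#' leftmost, then smallest unit, so reported tracts never overlap or nest.
#'
#' @param seq DNA string (case-insensitive).
#' @param cfg An [ssr_config()].
#' @param chrom Chromosome name recorded in the output.
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open),
#'   `motif`, `unit`, `n_units`, `tract`.
#' @examples
#' detect_ssrs(paste0(strrep("AC", 10), "GGG", strrep("TTA", 7)))
#' @export
detect_ssrs <- function(seq, cfg = ssr_config(), chrom = "chr") {
  s <- toupper(seq)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  valid <- ch %in% BASES
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      unit = integer(0), n_units = integer(0),
                      tract = character(0))
  cand <- list()
  for (u in 2:4) {
    if (n < 2L * u) next
    eq <- ch[seq_len(n - u)] == ch[seq.int(u + 1L, n)] &
      valid[seq_len(n - u)] & valid[seq.int(u + 1L, n)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      m <- r$lengths[j]
      n_units <- (m + u) %/% u
      if (n_units < cfg$min_units[[as.character(u)]]) next
      st <- starts[j]                       # 1-based tract start
      motif <- substr(s, st, st + u - 1L)
      if (!is_primitive_motif(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = chrom, start = st - 1L, end = st - 1L + n_units * u,
        motif = motif, unit = u, n_units = n_units)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start, cand$unit), ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  occ_start <- integer(0); occ_end <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < occ_end & cand$end[i] > occ_start)) {
      keep[i] <- TRUE
      occ_start <- c(occ_start, cand$start[i])
      occ_end <- c(occ_end, cand$end[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out$tract <- substring(s, out$start + 1L, out$end)
  rownames(out) <- NULL
  out
}

#' Canonical representation of an SSR motif
#'
#' The lexicographic minimum of the motif and its reverse complement.
#' Rotations are deliberately not merged, so e.g. CGC/GCG, CGG/CCG and
#' GGC/GCC remain three distinct classes.
#'
#' @param motif Primitive 2-4 nt motif (vectorized).
#' @return The canonical motif string(s).
#' @examples
#' canonical_motif("GCG")  # "CGC"
#' @export
canonical_motif <- function(motif) {
  vapply(toupper(motif), function(m) {
    if (!is_primitive_motif(m)) stop("motif is not primitive: ", m)
    min(m, revcomp(m))
  }, character(1), USE.NAMES = FALSE)
}

#' Cluster SSR loci across the three genomes
#'
#' Maps each detected locus to its span of alignment columns (so
#' insertion columns belonging to a tract are retained), merges
#' overlapping column spans into clusters, and keeps clusters represented
#' in all three genomes whose `flank_bp` reference flanks align without
#' gaps in any genome. Gaps inside the cluster region itself are allowed:
#' they are the length polymorphisms under study. The per-genome
#' `tract_*` entries are the ungapped aligned region sequences, which the
#' classifier compares. Loci not representable on the japonica reference
#' are dropped.
#'
#' @param loci Named list `osj`, `og`, `osi` of [detect_ssrs()] outputs
#'   (one data frame per genome, coordinates in each genome's own space).
#' @param aln A [triple_alignment()].
#' @param cfg An [ssr_config()].
#' @return Data frame of clusters: `chrom`, `start`, `end` (0-based
#'   half-open japonica coordinates of the region), per-genome `n_loci_*`
#'   and `tract_*` region sequences, and the japonica locus `motif_osj` /
#'   `unit_osj` (NA when japonica has several loci in the region).
#' @export
cluster_across_genomes <- function(loci, aln, cfg = ssr_config()) {
  taxa <- c("osj", "og", "osi")
  stopifnot(all(taxa %in% names(loci)))
  lifted <- list()
  for (tx in taxa) {
    df <- loci[[tx]]
    if (is.null(df) || nrow(df) == 0L) next
    for (i in seq_len(nrow(df))) {
      m <- aln_maps(aln, df$chrom[i], tx)
      if (df$end[i] > length(m$col_of_pos)) next
      lifted[[length(lifted) + 1L]] <- data.frame(
        genome = tx, chrom = df$chrom[i],
        col_start = m$col_of_pos[df$start[i] + 1L],
        col_end = m$col_of_pos[df$end[i]],
        motif = df$motif[i], unit = df$unit[i], n_units = df$n_units[i])
    }
  }
  if (!length(lifted)) return(NULL)
  lifted <- do.call(rbind, lifted)
  gr <- GenomicRanges::GRanges(lifted$chrom,
                               IRanges::IRanges(lifted$col_start,
                                                lifted$col_end))
  memb <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(gr))
  lifted$cluster <- S4Vectors::subjectHits(memb)
  out <- list()
  for (cl in unique(lifted$cluster)) {
    sub <- lifted[lifted$cluster == cl, , drop = FALSE]
    if (!all(taxa %in% sub$genome)) next
    chrom <- sub$chrom[1]
    cols <- seq.int(min(sub$col_start), max(sub$col_end))
    m <- aln_matrix(aln, chrom)[taxa, , drop = FALSE]
    ref_map <- aln_maps(aln, chrom, "osj")
    ref_pos <- ref_map$pos_of_col[cols]
    ref_pos <- ref_pos[!is.na(ref_pos)]
    if (!length(ref_pos)) next
    span <- c(min(ref_pos), max(ref_pos) + 1L)
    lo <- max(0L, span[1] - cfg$flank_bp)
    hi <- min(length(ref_map$col_of_pos), span[2] + cfg$flank_bp)
    flank_cols <- setdiff(aln_cols_for_ref(aln, chrom, lo, hi), cols)
    if (length(flank_cols) && any(m[, flank_cols] == "-")) next
    rec <- list(chrom = chrom, start = span[1], end = span[2])
    for (tx in taxa) {
      g <- sub[sub$genome == tx, , drop = FALSE]
      rec[[paste0("n_loci_", tx)]] <- nrow(g)
      rec[[paste0("tract_", tx)]] <-
        paste(m[tx, cols][m[tx, cols] != "-"], collapse = "")
    }
    one_osj <- sum(sub$genome == "osj") == 1L
    rec$motif_osj <- if (one_osj) sub$motif[sub$genome == "osj"] else
      NA_character_
    rec$unit_osj <- if (one_osj) sub$unit[sub$genome == "osj"] else
      NA_integer_
    out[[length(out) + 1L]] <- as.data.frame(rec)
  }
  if (!length(out)) return(NULL)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify a cross-genome SSR cluster
#'
#' Compares the aligned region sequences of the three genomes: identical
#' sequences in all genomes are `shared`; a region length differing in
#' exactly one genome (equal in the other two) is a lineage-specific
#' length polymorphism; equal lengths with exactly one deviating sequence
#' is a lineage-specific same-length (sequence) polymorphism; anything
#' else - including clusters without exactly one detected locus per
#' genome - is `other`.
#'
#' @param clusters Output of [cluster_across_genomes()].
#' @return The clusters with `polymorphism_class` (`shared`,
#'   `length_poly`, `seq_poly`, `other`) and `lineage` (`Osj`, `Osi`,
#'   `Og`, or `none`) columns added.
#' @export
classify_cluster <- function(clusters) {
  n <- nrow(clusters)
  cls <- character(n); lin <- rep("none", n)
  taxa <- c("osj", "osi", "og")
  label <- c(osj = "Osj", osi = "Osi", og = "Og")
  for (i in seq_len(n)) {
    if (any(clusters[i, paste0("n_loci_", taxa)] != 1L)) {
      cls[i] <- "other"; next
    }
    tr <- toupper(unlist(clusters[i, paste0("tract_", taxa)]))
    names(tr) <- taxa
    len <- nchar(tr)
    if (length(unique(tr)) == 1L) { cls[i] <- "shared"; next }
    len_tab <- table(len)
    if (length(len_tab) == 2L && min(len_tab) == 1L) {
      odd <- taxa[len == as.integer(names(len_tab)[len_tab == 1L])]
      cls[i] <- "length_poly"; lin[i] <- label[[odd]]
      next
    }
    if (length(unique(len)) == 1L) {
      seq_tab <- table(tr)
      if (length(seq_tab) == 2L && min(seq_tab) == 1L) {
        odd <- taxa[tr == names(seq_tab)[seq_tab == 1L]]
        cls[i] <- "seq_poly"; lin[i] <- label[[odd]]
        next
      }
    }
    cls[i] <- "other"
  }
  clusters$polymorphism_class <- cls
  clusters$lineage <- lin
  clusters
}

#' Assign each cluster to a genomic region class
#'
#' A cluster is `protein_coding` when its japonica region lies entirely
#' within annotated CDS, `non_transcribed` when entirely outside all
#' annotated transcripts, and `other` (UTR, intron, or boundary-spanning)
#' otherwise.
#'
#' @param clusters Output of [classify_cluster()].
#' @param cds,transcripts [GenomicRanges::GRanges] of CDS intervals and
#'   transcript extents (1-based).
#' @return The clusters with a `region_class` column added.
#' @export
assign_region <- function(clusters, cds, transcripts) {
  gr <- GenomicRanges::GRanges(clusters$chrom,
                               IRanges::IRanges(clusters$start + 1L,
                                                clusters$end))
  within_cds <- IRanges::overlapsAny(gr, cds, type = "within",
                                     ignore.strand = TRUE)
  touches_tx <- IRanges::overlapsAny(gr, transcripts, ignore.strand = TRUE)
  clusters$region_class <- ifelse(within_cds, "protein_coding",
                                  ifelse(!touches_tx, "non_transcribed",
                                         "other"))
  clusters
}

#' Contingency tests over classified SSR clusters
#'
#' Reproduces the SSR statistics: (i) polymorphic (non-shared) vs shared
#' counts between non-transcribed and protein-coding regions; (ii)
#' tri-nucleotide vs other unit sizes between the two regions; (iii) per
#' lineage, tri-nucleotide length polymorphisms vs same-length sequence
#' polymorphisms between the two regions (G-tests); and (iv) a Pearson
#' chi-square (df = 2) of tri-nucleotide length-polymorphism counts
#' across the three lineages between regions. Also reports total tract
#' length per genome.
#'
#' @param clusters Output of [assign_region()].
#' @param williams_correction Passed to [gtest_2x2()].
#' @return A list with elements `polymorphic_by_region`, `tri_by_region`,
#'   `length_vs_seq` (named per lineage; a character reason when a
#'   stratum is empty), `length_poly_chisq`, and `total_tract_bp`.
#' @export
ssr_gtests <- function(clusters, williams_correction = FALSE) {
  nt <- clusters$region_class == "non_transcribed"
  pc <- clusters$region_class == "protein_coding"
  poly <- clusters$polymorphism_class != "shared"
  tri <- !is.na(clusters$unit_osj) & clusters$unit_osj == 3L
  res <- list()
  res$polymorphic_by_region <- if (any(nt) && any(pc) && any(poly) &&
                                     any(!poly)) {
    gtest_2x2(contingency_2x2(sum(nt & poly), sum(nt & !poly),
                              sum(pc & poly), sum(pc & !poly)),
              williams_correction)
  } else "skipped: empty stratum"
  res$tri_by_region <- if (any(pc) && any(nt) && any(tri) && any(!tri)) {
    gtest_2x2(contingency_2x2(sum(pc & tri), sum(pc & !tri),
                              sum(nt & tri), sum(nt & !tri)),
              williams_correction)
  } else "skipped: empty stratum"
  res$length_vs_seq <- lapply(c(Osj = "Osj", Osi = "Osi", Og = "Og"),
                              function(L) {
    lp <- clusters$polymorphism_class == "length_poly" &
      clusters$lineage == L & tri
    sp <- clusters$polymorphism_class == "seq_poly" &
      clusters$lineage == L & tri
    tab <- c(sum(lp & nt), sum(sp & nt), sum(lp & pc), sum(sp & pc))
    if (tab[1] + tab[2] == 0 || tab[3] + tab[4] == 0 ||
        tab[1] + tab[3] == 0 || tab[2] + tab[4] == 0) {
      return("skipped: empty stratum")
    }
    gtest_2x2(contingency_2x2(tab[1], tab[2], tab[3], tab[4]),
              williams_correction)
  })
  lp_counts <- vapply(c("Osj", "Osi", "Og"), function(L) {
    c(sum(clusters$polymorphism_class == "length_poly" &
            clusters$lineage == L & tri & nt),
      sum(clusters$polymorphism_class == "length_poly" &
            clusters$lineage == L & tri & pc))
  }, numeric(2))
  res$length_poly_chisq <- if (all(colSums(lp_counts) > 0) &&
                                 all(rowSums(lp_counts) > 0)) {
    ct <- stats::chisq.test(lp_counts, correct = FALSE)
    new_test_result(unname(ct$statistic), unname(ct$parameter),
                    unname(ct$p.value),
                    method = "Pearson chi-square (lineage x region)")
  } else "skipped: empty stratum"
  res$total_tract_bp <- vapply(c(osj = "osj", osi = "osi", og = "og"),
                               function(tx) {
    sum(nchar(clusters[[paste0("tract_", tx)]]), na.rm = TRUE)
  }, numeric(1))
  res
}

#' Write SSR loci as BED
#'
#' One line per locus, name = canonical motif, score = number of units.
#'
#' @param loci A [detect_ssrs()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ssr_bed <- function(loci, path) {
  bed <- data.frame(loci$chrom, loci$start, loci$end,
                    canonical_motif(loci$motif), loci$n_units, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
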