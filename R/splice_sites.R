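# Donor/acceptor splice-site contexts across the three aligned genomes,
# lineage assignment of splice-site substitutions, flank cleanliness, and
# intron coding-potential testing.

SPLICE_TAXA <- c("osj", "osi", "og")

subseq_taxon <- function(chars, cols, strand) {
  s <- paste(chars[cols], collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Extract splice-site contexts from gene models and the alignment
#'
#' For every intron of every gene model (defined on the japonica genome),
#' extracts the donor (first two intron bases) and acceptor (last two)
#' motifs on the transcript strand together with 10-bp flanks on each
#' side, for all three genomes. A record is `gap_free` only when the site
#' and both flanks align without gaps in all three genomes; only gap-free
#' records are eligible for lineage assignment.
#'
#' @param genes List of gene models; each a list with `gene_id`, `chrom`,
#'   `strand`, `exons` (matrix of 0-based half-open `start`,`end` rows,
#'   genomic order) and optionally `cds` (same shape).
#' @param aln A [triple_alignment()].
#' @param flank_bp Flank width (default 10).
#' @return Data frame with one row per splice site: identifiers, per-taxon
#'   `motif_*`, `flank5_*`, `flank3_*`, `gap_free`, `canonical_*`
#'   (GT for donors / AG for acceptors), `between_coding`, `phase`,
#'   `intron_length` and `intron_seq` (japonica sequence, transcript
#'   strand). Introns shorter than 4 nt are skipped with a message.
#' @export
extract_splice_contexts <- function(genes, aln, flank_bp = 10L) {
  rows <- list()
  for (g in genes) {
    ex <- g$exons[order(g$exons[, 1]), , drop = FALSE]
    if (nrow(ex) < 2L) next
    chars <- lapply(SPLICE_TAXA, function(tx)
      strsplit(aln$blocks[[g$chrom]][[tx]], "")[[1]])
    names(chars) <- SPLICE_TAXA
    n_introns <- nrow(ex) - 1L
    cds <- if (!is.null(g$cds)) g$cds else ex
    # cumulative coding length up to each intron, for phase (plus strand
    # order; reversed below for minus strand)
    exon_lens <- ex[, 2] - ex[, 1]
    for (i in seq_len(n_introns)) {
      istart <- ex[i, 2]; iend <- ex[i + 1L, 1]
      ilen <- iend - istart
      if (ilen < 4L) {
        message("skipping intron < 4 nt in ", g$gene_id)
        next
      }
      tx_index <- if (g$strand == "+") i else n_introns - i + 1L
      # coding length upstream of this intron in transcript direction
      up_len <- if (g$strand == "+") sum(exon_lens[seq_len(i)])
                else sum(exon_lens[seq.int(i + 1L, nrow(ex))])
      phase <- up_len %% 3L
      between_coding <- all(c(
        any(cds[, 1] < ex[i, 2] & cds[, 2] >= ex[i, 2]),
        any(cds[, 1] <= ex[i + 1L, 1] & cds[, 2] > ex[i + 1L, 1])))
      # genomic intervals of the two sites and their flanks
      if (g$strand == "+") {
        site <- list(donor = c(istart, istart + 2L),
                     acceptor = c(iend - 2L, iend))
        fl5 <- list(donor = c(istart - flank_bp, istart),
                    acceptor = c(iend - 2L - flank_bp, iend - 2L))
        fl3 <- list(donor = c(istart + 2L, istart + 2L + flank_bp),
                    acceptor = c(iend, iend + flank_bp))
      } else {
        site <- list(donor = c(iend - 2L, iend),
                     acceptor = c(istart, istart + 2L))
        fl5 <- list(donor = c(iend, iend + flank_bp),
                    acceptor = c(istart + 2L, istart + 2L + flank_bp))
        fl3 <- list(donor = c(iend - 2L - flank_bp, iend - 2L),
                    acceptor = c(istart - flank_bp, istart))
      }
      iseq_cols <- aln_cols_for_ref(aln, g$chrom, istart, iend)
      iseq <- subseq_taxon(chars$osj, iseq_cols[chars$osj[iseq_cols] != "-"],
                           g$strand)
      for (kind in c("donor", "acceptor")) {
        span <- range(c(site[[kind]], fl5[[kind]], fl3[[kind]]))
        if (span[1] < 0) next
        cols_all <- tryCatch(
          aln_cols_for_ref(aln, g$chrom, span[1], span[2]),
          error = function(e) NULL)
        if (is.null(cols_all)) next
        gap_free <- !any(vapply(chars, function(x) any(x[cols_all] == "-"),
                                logical(1)))
        get_seq <- function(iv, tx) {
          cols <- aln_cols_for_ref(aln, g$chrom, iv[1], iv[2])
          toupper(subseq_taxon(chars[[tx]], cols, g$strand))
        }
        rec <- list(gene_id = g$gene_id, intron_index = tx_index,
                    kind = kind, chrom = g$chrom, strand = g$strand,
                    gap_free = gap_free, between_coding = between_coding,
                    phase = phase, intron_length = ilen,
                    intron_seq = toupper(iseq))
        for (tx in SPLICE_TAXA) {
          rec[[paste0("motif_", tx)]] <- get_seq(site[[kind]], tx)
          rec[[paste0("flank5_", tx)]] <- get_seq(fl5[[kind]], tx)
          rec[[paste0("flank3_", tx)]] <- get_seq(fl3[[kind]], tx)
          rec[[paste0("canonical_", tx)]] <-
            rec[[paste0("motif_", tx)]] == if (kind == "donor") "GT" else "AG"
        }
        rows[[length(rows) + 1L]] <- as.data.frame(rec)
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign splice-site substitutions to lineages
#'
#' For each gap-free record, compares the three motifs: when exactly one
#' taxon differs from the two (equal) others the substitution is assigned
#' to that taxon's lineage; all-equal motifs give `"none"`; three distinct
#' motifs give `"ambiguous"`. African rice (Og) assignments are flagged
#' `unpolarized` because without an outgroup the direction of the change
#' on the Og branch cannot be determined.
#'
#' @param records Output of [extract_splice_contexts()].
#' @return The records with `lineage` and `unpolarized` columns added;
#'   non-gap-free records get `NA` lineage.
#' @export
assign_splice_lineage <- function(records) {
  m <- cbind(osj = records$motif_osj, osi = records$motif_osi,
             og = records$motif_og)
  lin <- apply(m, 1, function(x) {
    if (x["osj"] == x["osi"] && x["osi"] == x["og"]) return("none")
    if (x["osi"] == x["og"]) return("Osj")
    if (x["osj"] == x["og"]) return("Osi")
    if (x["osj"] == x["osi"]) return("Og")
    "ambiguous"
  })
  lin[!records$gap_free] <- NA_character_
  records$lineage <- lin
  records$unpolarized <- !is.na(lin) & lin == "Og"
  records
}

#' Keep only records with substitution-free flanks
#'
#' Retains gap-free records whose 10-bp flanks on both sides are identical
#' across the three genomes, the stricter criterion used to control for
#' misalignment around splice sites.
#'
#' @param records Output of [assign_splice_lineage()].
#' @return The flank-clean subset.
#' @export
flank_clean_filter <- function(records) {
  clean <- records$gap_free &
    records$flank5_osj == records$flank5_osi &
    records$flank5_osi == records$flank5_og &
    records$flank3_osj == records$flank3_osi &
    records$flank3_osi == records$flank3_og
  records[clean, , drop = FALSE]
}

#' Coding potential of an intron
#'
#' Tests whether translating an intron would connect the reading frames of
#' its flanking exons: the intron length must be a multiple of 3 and the
#' codons read in the frame continuing the upstream exon must contain no
#' stop codon. The raw stop scan is reported separately so the
#' length-independent reading is also available.
#'
#' @param intron_seq Intron sequence on the transcript strand.
#' @param phase Codon offset (0, 1, 2) of the intron's first base: 0 means
#'   the upstream exon ends on a codon boundary.
#' @return A list with `intron_length`, `length_mod3`, `has_inframe_stop`
#'   and `coding_potential_retained`.
#' @examples
#' intron_coding_potential("GTTGGCAAG", phase = 0)
#' @export
intron_coding_potential <- function(intron_seq, phase = 0L) {
  stopifnot(phase %in% 0:2)
  intron_seq <- toupper(intron_seq)
  len <- nchar(intron_seq)
  start <- ((3L - phase) %% 3L) + 1L
  starts <- seq.int(start, len - 2L, by = 3L)
  starts <- starts[starts + 2L <= len]
  codons <- if (length(starts)) substring(intron_seq, starts, starts + 2L)
            else character(0)
  has_stop <- any(codons %in% stop_codons())
  list(intron_length = len, length_mod3 = len %% 3L,
       has_inframe_stop = has_stop,
       coding_potential_retained = (len %% 3L == 0L) && !has_stop)
}

#' Lineage summary of splice-site substitutions
#'
#' Tabulates, per lineage, the number of introns with site changes (with
#' the donor:acceptor split; an intron appears in both columns only when
#' both of its sites changed), the subset lying between protein-coding
#' exons, and the subset whose intron retains coding potential. The
#' parenthetical GT/AG counts use the japonica motifs of the intron.
#'
#' @param records Output of [assign_splice_lineage()] (all records, so
#'   canonical motifs of unchanged sites are available).
#' @param coding Optional data frame `gene_id`, `intron_index`,
#'   `coding_potential_retained` from [intron_coding_potential()] runs.
#' @return Data frame with one row per lineage (`Osj`, `Osi`, `Og`).
#' @export
summarize_splice_lineages <- function(records, coding = NULL) {
  intron_key <- function(df) paste(df$gene_id, df$intron_index)
  canonical_intron <- function(keys) {
    vapply(keys, function(k) {
      r <- records[intron_key(records) == k, ]
      don <- r$motif_osj[r$kind == "donor"]
      acc <- r$motif_osj[r$kind == "acceptor"]
      length(don) && length(acc) && don[1] == "GT" && acc[1] == "AG"
    }, logical(1))
  }
  out <- lapply(c("Osj", "Osi", "Og"), function(taxon) {
    rec <- records[!is.na(records$lineage) & records$lineage == taxon, ,
                   drop = FALSE]
    keys <- unique(intron_key(rec))
    n_donor <- length(unique(intron_key(rec[rec$kind == "donor", ])))
    n_acceptor <- length(unique(intron_key(rec[rec$kind == "acceptor", ])))
    bc_keys <- unique(intron_key(rec[rec$between_coding, , drop = FALSE]))
    canon_bc <- sum(canonical_intron(bc_keys))
    if (!is.null(coding)) {
      ckey <- paste(coding$gene_id, coding$intron_index)
      ret_keys <- bc_keys[bc_keys %in%
                            ckey[coding$coding_potential_retained]]
    } else ret_keys <- character(0)
    data.frame(lineage = taxon,
               n_introns = length(keys),
               n_donor = n_donor, n_acceptor = n_acceptor,
               n_between_coding = length(bc_keys),
               n_between_coding_gtag = canon_bc,
               n_coding_potential = length(ret_keys),
               n_coding_potential_gtag = sum(canonical_intron(ret_keys)))
  })
  do.call(rbind, out)
}
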