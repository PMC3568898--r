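# Shotgun-read QC, mapping-hit selection, consensus construction and contig
# summary statistics.
#
# Reads are held in a plain data.frame with columns:
#   id      read identifier
#   seq     bases; uppercase = non-repetitive, lowercase = repeat-masked
#   qual    phred scores encoded as Sanger ASCII (offset 33)
#   library "MF" (methylation filtration) or "SH" (subtractive hybridization)

#' Quality-control thresholds for shotgun reads
#'
#' Defaults follow the read-cleaning rules used for the African rice
#' shotgun set: 3'-trimming below phred 15, a 100-bp minimum length,
#' organelle-similarity rejection at >= 95% identity, E <= 1e-10 and >= 90%
#' coverage, a 30-bp minimum of non-repetitive (uppercase) sequence, and
#' mapping thresholds of >= 90% identity and E <= 1e-10.
#'
#' @param trim_phred_below,min_length,organelle_min_identity,
#'   organelle_max_evalue,organelle_min_coverage,min_nonrepeat_bp,
#'   map_min_identity,map_max_evalue See description.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(trim_phred_below = 15L, min_length = 100L,
                      organelle_min_identity = 95, organelle_max_evalue = 1e-10,
                      organelle_min_coverage = 90, min_nonrepeat_bp = 30L,
                      map_min_identity = 90, map_max_evalue = 1e-10) {
  structure(list(trim_phred_below = trim_phred_below, min_length = min_length,
                 organelle_min_identity = organelle_min_identity,
                 organelle_max_evalue = organelle_max_evalue,
                 organelle_min_coverage = organelle_min_coverage,
                 min_nonrepeat_bp = min_nonrepeat_bp,
                 map_min_identity = map_min_identity,
                 map_max_evalue = map_max_evalue),
            class = "qc_config")
}

#' Consensus-calling thresholds
#'
#' @param min_depth Minimum number of qualifying reads per site (default 2).
#' @param min_phred Minimum phred score for a read base to qualify
#'   (default 20).
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(min_depth = 2L, min_phred = 20L) {
  stopifnot(min_depth >= 1)
  structure(list(min_depth = as.integer(min_depth),
                 min_phred = as.integer(min_phred)),
            class = "consensus_config")
}

#' Convert phred integer scores to/from Sanger ASCII
#'
#' @param q Integer vector of phred scores in `[0, 93]`.
#' @return `phred_to_ascii`: a single character string;
#'   `ascii_to_phred`: an integer vector.
#' @export
phred_to_ascii <- function(q) {
  stopifnot(all(q >= 0), all(q <= 93))
  intToUtf8(q + 33L)
}

#' @rdname phred_to_ascii
#' @param s Sanger-encoded quality string.
#' @export
ascii_to_phred <- function(s) {
  utf8ToInt(s) - 33L
}

#' Trim low-quality 3' tails from reads
#'
#' Removes the maximal suffix of each read in which every phred score is
#' below `trim_phred_below`. Idempotent; may return zero-length reads.
#'
#' @param reads Read data.frame (see module header).
#' @param cfg A [qc_config()].
#' @return The reads with `seq` and `qual` trimmed in step.
#' @export
trim_3prime <- function(reads, cfg = qc_config()) {
  keep_len <- vapply(reads$qual, function(s) {
    q <- ascii_to_phred(s)
    low <- rev(q) < cfg$trim_phred_below
    n_trim <- match(FALSE, low, nomatch = length(q) + 1L) - 1L
    length(q) - n_trim
  }, integer(1), USE.NAMES = FALSE)
  reads$seq <- substr(reads$seq, 1L, keep_len)
  reads$qual <- substr(reads$qual, 1L, keep_len)
  reads
}

count_uppercase <- function(seq) {
  nchar(gsub("[^ACGTN]", "", seq))
}

#' Filter trimmed reads by length, organelle similarity and repeat content
#'
#' Applies, in order: minimum length; the organelle screen (a read is
#' rejected when identity, E-value and coverage all meet their thresholds);
#' and the minimum count of non-repetitive (uppercase) bases. Each rejected
#' read carries the first rule it failed.
#'
#' @param reads Read data.frame, already 3'-trimmed.
#' @param cfg A [qc_config()].
#' @param organelle_screen `NULL` to skip, or a function
#'   `f(reads) -> data.frame(identity, evalue, coverage)` with one row per
#'   read (NA identity = no similarity found). See [organelle_screen()].
#' @return A list with `kept` (read data.frame) and `rejected` (read
#'   data.frame with a `reason` column: `"length"`, `"organelle"`,
#'   `"non_repeat"`).
#' @export
filter_reads <- function(reads, cfg = qc_config(), organelle_screen = NULL) {
  reason <- rep(NA_character_, nrow(reads))
  reason[nchar(reads$seq) < cfg$min_length] <- "length"
  if (!is.null(organelle_screen)) {
    todo <- which(is.na(reason))
    if (length(todo)) {
      scr <- organelle_screen(reads[todo, , drop = FALSE])
      hit <- !is.na(scr$identity) &
        scr$identity >= cfg$organelle_min_identity &
        scr$evalue <= cfg$organelle_max_evalue &
        scr$coverage >= cfg$organelle_min_coverage
      reason[todo[hit]] <- "organelle"
    }
  }
  todo <- which(is.na(reason))
  low <- count_uppercase(reads$seq[todo]) < cfg$min_nonrepeat_bp
  reason[todo[low]] <- "non_repeat"
  rejected <- reads[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(kept = reads[is.na(reason), , drop = FALSE], rejected = rejected)
}

#' Select the best mapping position among candidate hits
#'
#' Candidates are first thresholded on mapping identity and E-value, then
#' ordered by identity (descending), E-value (ascending) and score
#' (descending). A residual full tie is broken deterministically by
#' `(chrom, start, strand)`.
#'
#' @param cands Data frame with columns `read_id`, `chrom`, `start`,
#'   `end`, `strand`, `identity`, `evalue`, `score`.
#' @param cfg A [qc_config()].
#' @return The selected one-row data frame, or `NULL` if no candidate
#'   passes the thresholds.
#' @export
select_best_hit <- function(cands, cfg = qc_config()) {
  if (is.null(cands) || nrow(cands) == 0L) return(NULL)
  ok <- cands$identity >= cfg$map_min_identity &
    cands$evalue <= cfg$map_max_evalue
  cands <- cands[ok, , drop = FALSE]
  if (nrow(cands) == 0L) return(NULL)
  ord <- order(-cands$identity, cands$evalue, -cands$score,
               cands$chrom, cands$start, cands$strand)
  cands[ord[1L], , drop = FALSE]
}

#' Toy seed-and-extend read aligner
#'
#' A deliberately simple gap-free aligner for synthetic reads: exact seed
#' words from the read are located in the reference (both strands), each
#' seed position is extended to a full-length gap-free comparison, and
#' per-candidate identity, a Karlin-Altschul-style toy E-value
#' (`ref_bp * 2^-score`, floored at 1e-300) and score (matches minus twice
#' the mismatches) are reported. Mapping in the original study was done
#' with a full local aligner; this backend exists to exercise the hit
#' selection and consensus rules on simulated data and is pluggable.
#'
#' @param reads Read data.frame.
#' @param reference Named character vector of reference sequences.
#' @param k Seed word length.
#' @param seed_offsets 0-based read offsets at which seed words are taken.
#' @return Data frame of candidate hits (see [select_best_hit()]) with one
#'   row per candidate placement; reads without any seed hit are absent.
#' @export
kmer_align <- function(reads, reference, k = 24L, seed_offsets = c(0L, 24L,
                                                                   48L)) {
  refs_up <- toupper(reference)
  hits <- list()
  for (i in seq_len(nrow(reads))) {
    seq_up <- toupper(reads$seq[i])
    n <- nchar(seq_up)
    if (n < k) next
    cand_pos <- list()
    for (off in seed_offsets[seed_offsets + k <= n]) {
      word <- substr(seq_up, off + 1L, off + k)
      if (grepl("N", word, fixed = TRUE)) next
      for (chrom in names(refs_up)) {
        for (strand in c("+", "-")) {
          target <- if (strand == "+") seq_up else revcomp(seq_up)
          woff <- if (strand == "+") off else n - off - k
          w <- substr(target, woff + 1L, woff + k)
          m <- gregexpr(w, refs_up[[chrom]], fixed = TRUE)[[1]]
          if (m[1] == -1L) next
          for (pos in as.integer(m)) {
            start <- pos - 1L - woff       # 0-based read start on reference
            if (start < 0L || start + n > nchar(refs_up[[chrom]])) next
            cand_pos[[length(cand_pos) + 1L]] <-
              list(chrom = chrom, start = start, strand = strand,
                   target = target)
          }
        }
      }
    }
    if (!length(cand_pos)) next
    seen <- character(0)
    for (cp in cand_pos) {
      key <- paste(cp$chrom, cp$start, cp$strand)
      if (key %in% seen) next
      seen <- c(seen, key)
      refseg <- substr(refs_up[[cp$chrom]], cp$start + 1L, cp$start + n)
      matches <- sum(strsplit(refseg, "")[[1]] ==
                       strsplit(cp$target, "")[[1]])
      mism <- n - matches
      score <- matches - 2L * mism
      hits[[length(hits) + 1L]] <- data.frame(
        read_id = reads$id[i], chrom = cp$chrom, start = cp$start,
        end = cp$start + n, strand = cp$strand,
        identity = 100 * matches / n,
        evalue = max(sum(nchar(reference)) * 2^(-score), 1e-300),
        score = score, n_mismatch = mism)
    }
  }
  if (!length(hits)) return(NULL)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Organelle-similarity screening backend
#'
#' Wraps [kmer_align()] over a set of organelle reference sequences into
#' the screening interface consumed by [filter_reads()].
#'
#' @param organelle_seqs Named character vector of organelle genome
#'   sequences.
#' @param k Seed length passed to the aligner.
#' @return A function `f(reads) -> data.frame(identity, evalue, coverage)`.
#' @export
organelle_screen <- function(organelle_seqs, k = 24L) {
  force(organelle_seqs); force(k)
  function(reads) {
    out <- data.frame(identity = rep(NA_real_, nrow(reads)),
                      evalue = NA_real_, coverage = NA_real_)
    hits <- kmer_align(reads, organelle_seqs, k = k)
    if (is.null(hits)) return(out)
    for (i in seq_len(nrow(reads))) {
      h <- hits[hits$read_id == reads$id[i], , drop = FALSE]
      if (nrow(h) == 0L) next
      best <- h[order(-h$identity, h$evalue), ][1L, ]
      out$identity[i] <- best$identity
      out$evalue[i] <- best$evalue
      # gap-free full-length extension: aligned span equals read length
      out$coverage[i] <- 100
    }
    out
  }
}

# Expand mapped reads into one row per covered reference base.
expand_mapped <- function(mapped) {
  n <- nchar(mapped$seq)
  idx <- rep.int(seq_len(nrow(mapped)), n)
  offset <- sequence(n) - 1L
  seq_fwd <- ifelse(mapped$strand == "-", revcomp(mapped$seq), mapped$seq)
  qual_fwd <- vapply(seq_len(nrow(mapped)), function(i) {
    if (mapped$strand[i] == "-")
      intToUtf8(rev(utf8ToInt(mapped$qual[i]))) else mapped$qual[i]
  }, character(1))
  data.frame(
    chrom = mapped$chrom[idx],
    pos = mapped$start[idx] + offset,
    base = toupper(substring(seq_fwd[idx], offset + 1L, offset + 1L)),
    phred = utf8ToInt(paste(qual_fwd, collapse = ""))[seq_along(idx)] - 33L,
    library = mapped$library[idx],
    read_id = mapped$read_id[idx])
}

#' Build a per-site consensus from mapped reads
#'
#' For each covered reference position: if all read bases agree the shared
#' base is called; otherwise the base with the highest phred score is
#' taken; a phred tie is broken in favour of methylation-filtration (MF)
#' reads; a remaining tie leaves the site flagged ambiguous. Contigs are
#' the maximal runs of covered positions.
#'
#' @param mapped Data frame of gap-free mapped reads: `read_id`, `chrom`,
#'   `start` (0-based), `strand`, `seq`, `qual`, `library`.
#' @param cfg A [consensus_config()] (carried through to
#'   [supported_sites()]).
#' @return A list with `sites` (chrom, pos, base, depth, max_phred,
#'   ambiguous), `evidence` (the per-base expansion) and `contigs`
#'   (chrom, start, end half-open intervals).
#' @export
build_consensus <- function(mapped, cfg = consensus_config()) {
  stopifnot(nrow(mapped) > 0)
  ev <- expand_mapped(mapped)
  lib_pref <- ifelse(ev$library == "MF", 0L, 1L)
  ord <- order(ev$chrom, ev$pos, -ev$phred, lib_pref, ev$base)
  ev_s <- ev[ord, ]
  lib_s <- lib_pref[ord]
  key <- paste(ev_s$chrom, ev_s$pos)
  first <- !duplicated(key)
  g <- cumsum(first)
  depth <- tabulate(g)
  # distinct bases per site
  ndistinct <- tabulate(g[!duplicated(cbind(g, ev_s$base))])
  top <- which(first)
  max_phred <- ev_s$phred[top]
  # rows tied with the top row on phred and library preference
  tied <- ev_s$phred == max_phred[g] & lib_s == lib_s[top][g]
  n_tied_bases <- tabulate(g[tied][!duplicated(cbind(g, ev_s$base)[tied, ,
                                                                   drop = FALSE])])
  ambiguous <- ndistinct > 1L & n_tied_bases > 1L
  sites <- data.frame(chrom = ev_s$chrom[top], pos = ev_s$pos[top],
                      base = ifelse(ambiguous, NA_character_,
                                    ev_s$base[top]),
                      depth = depth, max_phred = max_phred,
                      ambiguous = ambiguous)
  by_chrom <- split(sites$pos, sites$chrom)
  contigs <- do.call(rbind, Map(function(p, ch) {
    p <- sort(unique(p))
    brk <- c(TRUE, diff(p) > 1L)
    data.frame(chrom = ch, start = p[brk], end = p[c(brk[-1], TRUE)] + 1L)
  }, by_chrom, names(by_chrom)))
  rownames(contigs) <- NULL
  list(sites = sites, evidence = ev, contigs = contigs, cfg = cfg)
}

#' Sites qualified for substitution analysis
#'
#' From the retained per-site evidence, keeps sites covered by at least
#' `min_depth` reads with phred >= `min_phred` and calls the strict
#' majority base among those qualifying reads; sites with an exact tie are
#' excluded.
#'
#' @param consensus Output of [build_consensus()].
#' @param cfg A [consensus_config()].
#' @return Data frame with `chrom`, `pos`, `base`, `depth` (qualifying
#'   reads).
#' @export
supported_sites <- function(consensus, cfg = consensus_config()) {
  ev <- consensus$evidence
  ev <- ev[ev$phred >= cfg$min_phred, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      base = character(0), depth = integer(0)))
  }
  key <- factor(paste(ev$chrom, ev$pos))
  counts <- table(key, factor(ev$base, levels = c(BASES, "N")))
  depth <- rowSums(counts)
  top <- apply(counts, 1, max)
  top_is_unique <- rowSums(counts == top) == 1L
  ok <- depth >= cfg$min_depth & top > depth / 2 & top_is_unique
  call <- colnames(counts)[apply(counts, 1, which.max)]
  parts <- strsplit(rownames(counts), " ", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[[`, character(1), 1L),
                    pos = as.integer(vapply(parts, `[[`, character(1), 2L)),
                    base = call, depth = as.integer(depth))[ok, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Contig summary statistics
#'
#' @param contigs Data frame of reference intervals `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param annotation Optional [GenomicRanges::GRanges] with a metadata
#'   column `class`; bp of contig overlap is reported per class.
#' @param reference_bp Optional total reference size for a coverage
#'   fraction.
#' @return A list with `n`, `total_bp`, `n50`, `covered_bp`, optionally
#'   `coverage_fraction` and `composition` (named bp per annotation
#'   class, with `unannotated` as remainder).
#' @export
contig_stats <- function(contigs, annotation = NULL, reference_bp = NULL) {
  len <- contigs$end - contigs$start
  total <- sum(len)
  n50 <- {
    l <- sort(len, decreasing = TRUE)
    l[which(cumsum(l) >= total / 2)[1L]]
  }
  gr <- GenomicRanges::GRanges(contigs$chrom,
                               IRanges::IRanges(contigs$start + 1L,
                                                contigs$end))
  covered <- sum(IRanges::width(GenomicRanges::reduce(gr)))
  out <- list(n = nrow(contigs), total_bp = total, n50 = n50,
              covered_bp = covered)
  if (!is.null(reference_bp)) out$coverage_fraction <- covered / reference_bp
  if (!is.null(annotation)) {
    comp <- vapply(split(annotation, annotation$class), function(ann) {
      ov <- GenomicRanges::intersect(GenomicRanges::reduce(gr),
                                     GenomicRanges::reduce(ann),
                                     ignore.strand = TRUE)
      sum(IRanges::width(ov))
    }, numeric(1))
    comp <- c(comp, unannotated = covered - sum(comp))
    out$composition <- comp
  }
  out
}

#' Read or write FASTQ with library tags
#'
#' The library tag (`MF`/`SH`) is carried in the read id as a
#' space-separated suffix (`@id MF`). Lowercase (repeat-masked) bases are
#' preserved.
#'
#' @param reads Read data.frame.
#' @param path File path.
#' @return `write_fastq`: `path`, invisibly. `read_fastq`: a read
#'   data.frame.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$id, " ", reads$library)
  lines[seq(2, length(lines), 4)] <- reads$seq
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- reads$qual
  writeLines(lines, path)
  invisible(path)
}

#' Read or write (soft-masked) FASTA
#'
#' Case is preserved, so lowercase repeat-masking survives the round trip.
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @return `write_fasta`: `path`, invisibly. `read_fasta`: a named
#'   character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 4L == 0L)
  hdr <- sub("^@", "", lines[seq(1, length(lines), 4)])
  parts <- strsplit(hdr, " ", fixed = TRUE)
  data.frame(id = vapply(parts, `[[`, character(1), 1L),
             seq = lines[seq(2, length(lines), 4)],
             qual = lines[seq(4, length(lines), 4)],
             library = vapply(parts, function(p)
               if (length(p) > 1L) p[2L] else NA_character_, character(1)))
}
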