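# Ground-truth simulator: an ancestral genome with gene models evolves on
# the species topology ((Og, (Osj, Osi)), outgroup) under a Kimura-type
# substitution process with codon-aware selection, optionally with planted
# splice-site mutations and microsatellite events, and phred-scored shotgun
# reads from two library types.

#' Simulation configuration
#'
#' Defaults reflect the rice study conditions: per-lineage substitution
#' rates giving an Og-Osj distance of about 5e-3, transition/transversion
#' rate ratio `kappa = 3.44` (implying a transition/transversion count
#' ratio of 1.72 on neutral sites), and nonsynonymous acceptance
#' probabilities (dN/dS) of 0.30 on the Og branch and 0.25 on the Osj and
#' Osi branches.
#'
#' @param seed Integer seed; fixed seed gives identical output.
#' @param genome_length Approximate genome length in bp (intergenic gaps
#'   are scaled to reach it).
#' @param gene_count Number of gene models.
#' @param exons_per_gene Integer vector sampled from for the exon count
#'   (minimum 2, so every gene has a first intron).
#' @param exon_codons Range of codons per exon.
#' @param intron_bp Range of intron lengths.
#' @param minus_strand_fraction Fraction of genes on the minus strand.
#' @param rates Named per-branch substitution (proposal) probabilities per
#'   site: `og`, `internal`, `osj`, `osi`, `outgroup`.
#' @param kappa Transition/transversion rate ratio of the mutation
#'   process.
#' @param omega Named per-branch acceptance probabilities for
#'   nonsynonymous changes.
#' @param repeat_fraction Fraction of the genome soft-masked as repeat.
#' @param ssr_loci Named counts of microsatellite tracts planted in the
#'   ancestor: `non_transcribed` and `protein_coding`.
#' @param ssr_units Number of repeat units per planted tract, expressed as
#'   extra units above the detection minimum (range).
#' @param planted_splice Data frame `gene`, `intron`, `kind`
#'   (`donor`/`acceptor`), `taxon` (`osj`/`osi`/`og`), `new_motif`
#'   (2 nt, transcript strand); or NULL.
#' @param planted_ssr Data frame `locus` (id from the planted table, e.g.
#'   `"ssr3"`), `taxon`, `type` (`"length"` or `"point"`), `delta_units`
#'   (non-zero integer, for length events); or NULL.
#' @param read_length,fragment_bp,coverage Shotgun read simulation:
#'   read length, mean fragment size (sequenced from both ends), and mean
#'   per-base coverage.
#' @param contaminant_fraction Fraction of read pairs drawn from an
#'   organelle-like contaminant sequence.
#' @param phred_max,phred_min Quality profile endpoints (phred declines
#'   along the read).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 120000L, gene_count = 20L,
                       exons_per_gene = 2:4, exon_codons = c(30L, 80L),
                       intron_bp = c(80L, 160L),
                       minus_strand_fraction = 0.25,
                       rates = c(og = 2.5e-3, internal = 1.2e-3,
                                 osj = 1.5e-3, osi = 1.5e-3,
                                 outgroup = 0.10),
                       kappa = 3.44,
                       omega = c(og = 0.30, internal = 0.25, osj = 0.25,
                                 osi = 0.25, outgroup = 0.20),
                       repeat_fraction = 0.15,
                       ssr_loci = c(non_transcribed = 10L,
                                    protein_coding = 6L),
                       ssr_units = c(3L, 6L),
                       planted_splice = NULL, planted_ssr = NULL,
                       read_length = 500L, fragment_bp = 2000L,
                       coverage = 3, contaminant_fraction = 0.05,
                       phred_max = 40L, phred_min = 8L) {
  stopifnot(all(rates >= 0), all(omega > 0), kappa > 0, min(exons_per_gene) >= 2)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# ---------------------------------------------------------------------------
# genome layout

sample_sense_codons <- function(n, no_start = FALSE) {
  pool <- sense_codons()
  sample(pool, n, replace = TRUE)
}

# Build the ancestral genome and its gene models. All coordinates 0-based.
build_ancestor <- function(cfg) {
  genes <- list()
  ssr <- list()
  seq_parts <- character(0)
  cursor <- 0L
  gene_bp <- function(ne, codons, introns) sum(codons) * 3L + sum(introns)
  # rough plan to hit genome_length
  plan <- lapply(seq_len(cfg$gene_count), function(i) {
    ne <- sample(cfg$exons_per_gene, 1L)
    codons <- sample(seq(cfg$exon_codons[1], cfg$exon_codons[2]), ne,
                     replace = TRUE)
    introns <- sample(seq(cfg$intron_bp[1], cfg$intron_bp[2]), ne - 1L,
                      replace = TRUE)
    list(ne = ne, codons = codons, introns = introns)
  })
  total_gene_bp <- sum(vapply(plan, function(p)
    gene_bp(p$ne, p$codons, p$introns), numeric(1)))
  gap <- max(300L, (cfg$genome_length - total_gene_bp) %/%
               (cfg$gene_count + 1L))
  rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")
  for (i in seq_len(cfg$gene_count)) {
    g <- plan[[i]]
    this_gap <- gap + sample(-50:50, 1L)
    seq_parts <- c(seq_parts, rand_dna(this_gap))
    cursor <- cursor + this_gap
    strand <- if (stats::runif(1) < cfg$minus_strand_fraction) "-" else "+"
    # CDS codons in transcript order: ATG + sense codons (no stop)
    codons <- c("ATG", sample_sense_codons(sum(g$codons) - 1L))
    cds_seq <- paste(codons, collapse = "")
    # split into exons (transcript order), genomic order depends on strand
    exon_tx <- character(g$ne)
    off <- 0L
    for (e in seq_len(g$ne)) {
      exon_tx[e] <- substr(cds_seq, off * 3L + 1L, (off + g$codons[e]) * 3L)
      off <- off + g$codons[e]
    }
    introns_tx <- vapply(g$introns, function(il) {
      paste0("GT", rand_dna(il - 4L), "AG")
    }, character(1))
    tx_seq <- exon_tx[1]
    for (e in seq_len(g$ne - 1L)) {
      tx_seq <- paste0(tx_seq, introns_tx[e], exon_tx[e + 1L])
    }
    genomic <- if (strand == "+") tx_seq else revcomp(tx_seq)
    gstart <- cursor
    # exon intervals in genomic order
    lens_tx <- rbind(nchar(exon_tx),
                     c(nchar(introns_tx), 0L))[seq_len(2L * g$ne - 1L)]
    offs <- cumsum(c(0L, lens_tx[-length(lens_tx)]))
    tx_iv <- cbind(offs[seq(1L, length(offs), 2L)],
                   offs[seq(1L, length(offs), 2L)] +
                     nchar(exon_tx))
    if (strand == "-") {
      n_tot <- nchar(tx_seq)
      tx_iv <- cbind(n_tot - tx_iv[, 2], n_tot - tx_iv[, 1])
      tx_iv <- tx_iv[rev(seq_len(nrow(tx_iv))), , drop = FALSE]
    }
    exons <- tx_iv + gstart
    genes[[i]] <- list(gene_id = paste0("g", i), chrom = "chr1",
                       strand = strand, start = gstart,
                       end = gstart + nchar(tx_seq),
                       exons = exons, cds = exons,
                       n_codons = sum(g$codons))
    seq_parts <- c(seq_parts, genomic)
    cursor <- cursor + nchar(tx_seq)
  }
  tail_gap <- max(300L, cfg$genome_length - cursor)
  seq_parts <- c(seq_parts, rand_dna(tail_gap))
  anc <- strsplit(paste(seq_parts, collapse = ""), "")[[1]]
  list(seq = anc, genes = genes)
}

ssr_motif_pool <- list(`2` = c("AC", "AT", "AG", "CT", "GA", "TG"),
                       `3` = c("CGC", "CCG", "GCC", "CAG", "GAA", "AAG",
                               "ACT"),
                       `4` = c("AAGG", "ACAG", "AATC", "AGAT"))

# Plant microsatellite tracts into the ancestor; returns the truth table.
plant_ssrs <- function(anc, genes, cfg) {
  min_units <- c(`2` = 9L, `3` = 6L, `4` = 5L)
  n <- length(anc$seq)
  gene_iv <- do.call(rbind, lapply(anc$genes, function(g)
    c(g$start, g$end)))
  in_gene <- logical(n)
  for (i in seq_len(nrow(gene_iv))) {
    in_gene[seq.int(gene_iv[i, 1] + 1L, gene_iv[i, 2])] <- TRUE
  }
  taken_start <- integer(0); taken_end <- integer(0)
  rows <- list(); id <- 0L
  place_tract <- function(start0, tract, unit, n_units, region, gene_id) {
    u <- unit
    chars <- strsplit(tract, "")[[1]]
    anc$seq[seq.int(start0 + 1L, start0 + length(chars))] <<- chars
    # break periodicity at both boundaries
    if (start0 >= 1L) {
      bad <- c(anc$seq[start0 + u], anc$seq[start0])
      anc$seq[start0] <<- sample(setdiff(BASES, bad), 1L)
    }
    endp <- start0 + length(chars)
    if (endp < n) {
      bad <- c(anc$seq[endp + 1L - u], anc$seq[endp + 1L])
      anc$seq[endp + 1L] <<- sample(setdiff(BASES, bad), 1L)
    }
    id <<- id + 1L
    rows[[id]] <<- data.frame(locus = paste0("ssr", id), region = region,
                              gene_id = gene_id, chrom = "chr1",
                              start = start0, end = start0 + n_units * u,
                              unit = u, n_units = n_units,
                              motif = substr(tract, 1L, u))
    taken_start <<- c(taken_start, start0 - 80L)
    taken_end <<- c(taken_end, start0 + n_units * u + 80L)
  }
  # non-transcribed tracts
  tries <- 0L
  planted <- 0L
  while (planted < cfg$ssr_loci[["non_transcribed"]] && tries < 5000L) {
    tries <- tries + 1L
    u <- sample(c(2L, 3L, 4L), 1L)
    k <- min_units[[as.character(u)]] +
      sample(seq(cfg$ssr_units[1], cfg$ssr_units[2]), 1L)
    pool <- ssr_motif_pool[[as.character(u)]]
    motif <- sample(pool, 1L)
    len <- u * k
    start0 <- sample.int(n - len - 200L, 1L) + 100L
    span <- seq.int(start0 + 1L - 80L, start0 + len + 80L)
    span <- span[span >= 1L & span <= n]
    if (any(in_gene[span])) next
    if (any(start0 < taken_end & (start0 + len) > taken_start)) next
    place_tract(start0, strrep(motif, k), u, k, "non_transcribed", NA)
    planted <- planted + 1L
  }
  # protein-coding tracts: tri-nucleotide, codon-aligned inside one exon
  codon_motifs <- c("GCT", "GCA", "CAG", "GAA", "ACC", "TCA")
  cand_genes <- sample(seq_along(anc$genes))
  planted <- 0L
  for (gi in cand_genes) {
    if (planted >= cfg$ssr_loci[["protein_coding"]]) break
    g <- anc$genes[[gi]]
    ex <- g$exons
    widths <- ex[, 2] - ex[, 1]
    e <- which.max(widths)
    k <- 6L + sample(seq(cfg$ssr_units[1], cfg$ssr_units[2]), 1L)
    if (widths[e] < (k + 4L) * 3L) next
    # codon-aligned offset inside the exon: frame shift = coding length of
    # the transcript-preceding exons
    widths_tx <- if (g$strand == "+") widths else rev(widths)
    e_tx <- if (g$strand == "+") e else nrow(ex) - e + 1L
    frame_shift <- if (e_tx > 1L) sum(widths_tx[seq_len(e_tx - 1L)]) %% 3L
                   else 0L
    off <- 6L + (3L - frame_shift) %% 3L
    len <- k * 3L
    start0 <- if (g$strand == "+") ex[e, 1] + off
              else ex[e, 2] - off - len
    if (start0 + len + 6L > ex[e, 2] || start0 - 6L < ex[e, 1]) next
    if (any(start0 < taken_end & (start0 + len) > taken_start)) next
    motif_tx <- sample(codon_motifs, 1L)
    tract_tx <- strrep(motif_tx, k)
    tract_genomic <- if (g$strand == "+") tract_tx else revcomp(tract_tx)
    motif_genomic <- substr(tract_genomic, 1L, 3L)
    chars <- strsplit(tract_genomic, "")[[1]]
    anc$seq[seq.int(start0 + 1L, start0 + len)] <- chars
    # periodicity break at boundaries, preserving sense codons: the
    # neighbouring codons are resampled until they break the repeat
    if (anc$seq[start0] == anc$seq[start0 + 3L]) {
      rep_pos <- start0
      repl <- setdiff(BASES, c(anc$seq[start0 + 3L], "T"))
      anc$seq[rep_pos] <- sample(repl, 1L)
    }
    if (start0 + len + 1L <= n &&
        anc$seq[start0 + len + 1L] == anc$seq[start0 + len + 1L - 3L]) {
      repl <- setdiff(BASES, c(anc$seq[start0 + len + 1L - 3L], "T"))
      anc$seq[start0 + len + 1L] <- sample(repl, 1L)
    }
    id <- id + 1L
    rows[[id]] <- data.frame(locus = paste0("ssr", id),
                             region = "protein_coding", gene_id = g$gene_id,
                             chrom = "chr1", start = start0,
                             end = start0 + len, unit = 3L, n_units = k,
                             motif = motif_genomic)
    taken_start <- c(taken_start, start0 - 80L)
    taken_end <- c(taken_end, start0 + len + 80L)
    planted <- planted + 1L
  }
  list(seq = anc$seq, genes = anc$genes,
       ssr_table = if (id > 0L) do.call(rbind, rows) else NULL)
}

# ---------------------------------------------------------------------------
# codon bookkeeping and branch evolution

# For each genome position inside CDS, the global codon id and the position
# of that base within the codon (transcript strand).
codon_index <- function(genes, n) {
  codon_id <- integer(n)         # 0 = non-coding
  codon_slot <- integer(n)
  codon_pos <- list()            # genomic positions (1-based) per codon, tx order
  strand_of_codon <- character(0)
  next_id <- 0L
  for (g in genes) {
    ex <- g$exons[order(g$exons[, 1]), , drop = FALSE]
    pos <- unlist(lapply(seq_len(nrow(ex)), function(e)
      seq.int(ex[e, 1] + 1L, ex[e, 2])))
    if (g$strand == "-") pos <- rev(pos)
    stopifnot(length(pos) %% 3L == 0L)
    ids <- next_id + rep(seq_len(length(pos) / 3L), each = 3L)
    slots <- rep(1:3, length(pos) / 3L)
    codon_id[pos] <- ids
    codon_slot[pos] <- slots
    for (k in unique(ids)) {
      codon_pos[[k]] <- pos[ids == k]
    }
    strand_of_codon <- c(strand_of_codon,
                         rep(g$strand, length(pos) / 3L))
    next_id <- next_id + length(pos) / 3L
  }
  list(codon_id = codon_id, codon_slot = codon_slot, codon_pos = codon_pos,
       strand = strand_of_codon)
}

complement1 <- c(A = "T", C = "G", G = "C", T = "A")

empty_ledger <- function() {
  data.frame(branch = character(0), pos = integer(0), from = character(0),
             to = character(0), coding = logical(0), syn = logical(0))
}

ts_of <- c(A = "G", G = "A", C = "T", T = "C")

# Kimura-biased replacement bases for a vector of current bases.
draw_mutant_bases <- function(b, kappa) {
  n <- length(b)
  p_ts <- kappa / (kappa + 2)
  is_ts <- stats::runif(n) < p_ts
  out <- ts_of[b]
  tv <- which(!is_ts)
  if (length(tv)) {
    # two transversion targets per base: the two bases of the other class
    tv_targets <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
    pick <- 1L + (stats::runif(length(tv)) < 0.5)
    out[tv] <- mapply(function(base, k) tv_targets[[base]][k],
                      b[tv], pick)
  }
  unname(out)
}

# Evolve a character vector one branch. Returns the mutated sequence and
# the event ledger.
evolve_branch <- function(seq_chars, rate, kappa, omega, cidx,
                          protect = logical(length(seq_chars)),
                          branch = "") {
  n <- length(seq_chars)
  if (rate <= 0) return(list(seq = seq_chars, events = empty_ledger()))
  prop <- which(stats::runif(n) < rate & !protect &
                  seq_chars %in% BASES)
  if (!length(prop)) return(list(seq = seq_chars, events = empty_ledger()))
  k <- length(prop)
  ev_pos <- integer(k); ev_from <- ev_to <- character(k)
  ev_coding <- ev_syn <- logical(k)
  n_ev <- 0L
  gc <- genetic_code()
  nb_all <- draw_mutant_bases(seq_chars[prop], kappa)
  for (j in seq_len(k)) {
    p <- prop[j]
    b <- seq_chars[p]
    nb <- nb_all[j]
    cid <- cidx$codon_id[p]
    if (cid == 0L) {
      seq_chars[p] <- nb
      n_ev <- n_ev + 1L
      ev_pos[n_ev] <- p - 1L; ev_from[n_ev] <- b; ev_to[n_ev] <- nb
      ev_coding[n_ev] <- FALSE; ev_syn[n_ev] <- NA
      next
    }
    pos3 <- cidx$codon_pos[[cid]]
    strand <- cidx$strand[cid]
    bases <- seq_chars[pos3]
    if (strand == "-") bases <- complement1[bases]
    cod <- paste(bases, collapse = "")
    slot <- cidx$codon_slot[p]
    new_base_tx <- if (strand == "-") complement1[[nb]] else nb
    new_cod <- codon_set(cod, slot, new_base_tx)
    if (is.na(gc[new_cod]) || gc[[new_cod]] == "*") next
    syn <- gc[[new_cod]] == gc[[cod]]
    if (!syn && stats::runif(1) > omega) next
    seq_chars[p] <- nb
    n_ev <- n_ev + 1L
    ev_pos[n_ev] <- p - 1L; ev_from[n_ev] <- b; ev_to[n_ev] <- nb
    ev_coding[n_ev] <- TRUE; ev_syn[n_ev] <- syn
  }
  idx <- seq_len(n_ev)
  list(seq = seq_chars,
       events = data.frame(branch = rep(branch, n_ev), pos = ev_pos[idx],
                           from = ev_from[idx], to = ev_to[idx],
                           coding = ev_coding[idx], syn = ev_syn[idx]))
}

# Vectorized codon-level branch evolution for coding-only panels: each
# nucleotide site proposes a mutation with probability `rate`; proposals
# creating stops are rejected and nonsynonymous ones accepted with
# probability `omega`. Codons receiving several proposals in one branch
# are handled sequentially.
evolve_codons <- function(codons, rate, kappa, omega, branch = "") {
  L <- length(codons)
  if (rate <= 0) return(list(codons = codons, events = empty_ledger()))
  n_sites <- 3L * L
  sites <- which(stats::runif(n_sites) < rate)
  if (!length(sites)) return(list(codons = codons, events = empty_ledger()))
  gc <- genetic_code()
  cid <- (sites - 1L) %/% 3L + 1L
  slot <- (sites - 1L) %% 3L + 1L
  dup_cids <- unique(cid[duplicated(cid)])
  single <- !(cid %in% dup_cids)
  ev <- list()
  apply_single <- function(cid_s, slot_s) {
    cods <- codons[cid_s]
    from <- substr(cods, slot_s, slot_s)
    nb <- draw_mutant_bases(from, kappa)
    new_cods <- paste0(substr(cods, 1L, slot_s - 1L), nb,
                       substring(cods, slot_s + 1L))
    aa_old <- gc[cods]; aa_new <- gc[new_cods]
    ok <- aa_new != "*"
    syn <- aa_new == aa_old
    accept <- ok & (syn | stats::runif(length(cods)) <= omega)
    codons[cid_s[accept]] <<- new_cods[accept]
    if (any(accept)) {
      ev[[length(ev) + 1L]] <<- data.frame(
        branch = branch, pos = sites_pos(cid_s[accept], slot_s[accept]),
        from = from[accept], to = nb[accept], coding = TRUE,
        syn = syn[accept])
    }
  }
  sites_pos <- function(cid_s, slot_s) (cid_s - 1L) * 3L + slot_s - 1L
  if (any(single)) apply_single(cid[single], slot[single])
  for (dc in dup_cids) {
    for (j in which(cid == dc)) apply_single(cid[j], slot[j])
  }
  events <- if (length(ev)) do.call(rbind, ev) else empty_ledger()
  list(codons = codons, events = events)
}

# ---------------------------------------------------------------------------
# planted events

apply_planted_splice <- function(seqs, genes, planted, aln_protect) {
  truth <- list()
  if (is.null(planted) || nrow(planted) == 0L) {
    return(list(seqs = seqs, truth = NULL))
  }
  gmap <- stats::setNames(genes, vapply(genes, `[[`, character(1),
                                        "gene_id"))
  for (i in seq_len(nrow(planted))) {
    g <- gmap[[planted$gene[i]]]
    stopifnot(!is.null(g))
    ex <- g$exons[order(g$exons[, 1]), , drop = FALSE]
    n_introns <- nrow(ex) - 1L
    idx_tx <- planted$intron[i]
    idx_gen <- if (g$strand == "+") idx_tx else n_introns - idx_tx + 1L
    istart <- ex[idx_gen, 2]; iend <- ex[idx_gen + 1L, 1]
    kind <- planted$kind[i]
    # genomic interval of the 2-nt site
    iv <- if ((kind == "donor") == (g$strand == "+")) {
      c(istart, istart + 2L)
    } else {
      c(iend - 2L, iend)
    }
    motif <- toupper(planted$new_motif[i])
    genomic <- if (g$strand == "+") motif else revcomp(motif)
    tx <- planted$taxon[i]
    old <- paste(seqs[[tx]][seq.int(iv[1] + 1L, iv[2])], collapse = "")
    seqs[[tx]][seq.int(iv[1] + 1L, iv[2])] <-
      strsplit(genomic, "")[[1]]
    truth[[i]] <- data.frame(gene = g$gene_id, intron = idx_tx,
                             kind = kind, taxon = tx, new_motif = motif,
                             genomic_start = iv[1],
                             lineage = c(osj = "Osj", osi = "Osi",
                                         og = "Og")[[tx]])
  }
  list(seqs = seqs, truth = do.call(rbind, truth))
}

apply_planted_ssr <- function(seqs, ssr_table, planted) {
  # returns per-taxon deletion masks and insertion lists plus truth
  n <- length(seqs$osj)
  del <- list(osj = logical(n), osi = logical(n), og = logical(n))
  ins <- list()   # each: list(after (0-based anc pos), taxon, seq)
  truth <- list()
  if (is.null(planted) || nrow(planted) == 0L) {
    return(list(seqs = seqs, del = del, ins = ins, truth = NULL))
  }
  for (i in seq_len(nrow(planted))) {
    loc <- ssr_table[ssr_table$locus == planted$locus[i], ]
    stopifnot(nrow(loc) == 1L)
    tx <- planted$taxon[i]
    u <- loc$unit
    if (planted$type[i] == "length") {
      d <- planted$delta_units[i]
      stopifnot(d != 0L)
      if (d < 0L) {
        k <- -d
        stopifnot(loc$n_units - k >= 1L)
        rm_pos <- seq.int(loc$end - k * u + 1L, loc$end)
        del[[tx]][rm_pos] <- TRUE
      } else {
        motif_here <- paste(seqs[[tx]][seq.int(loc$start + 1L,
                                               loc$start + u)],
                            collapse = "")
        ins[[length(ins) + 1L]] <- list(after = loc$end, taxon = tx,
                                        seq = strrep(motif_here, d))
      }
      expect_class <- "length_poly"
    } else {
      # point change inside the second unit; the remaining run keeps the
      # locus detectable in this genome
      p <- loc$start + u + 1L           # 0-based position in unit 2
      old <- seqs[[tx]][p + 1L]
      repl <- setdiff(BASES, c(old, seqs[[tx]][p + 1L - u]))
      seqs[[tx]][p + 1L] <- repl[1L]
      expect_class <- "seq_poly"
    }
    truth[[i]] <- data.frame(locus = loc$locus, taxon = tx,
                             type = planted$type[i],
                             delta_units = if (planted$type[i] == "length")
                               planted$delta_units[i] else 0L,
                             region = loc$region,
                             expected_class = expect_class,
                             expected_lineage = c(osj = "Osj", osi = "Osi",
                                                  og = "Og")[[tx]])
  }
  list(seqs = seqs, del = del, ins = ins, truth = do.call(rbind, truth))
}

# ---------------------------------------------------------------------------

#' Simulate three rice genomes and an outgroup with ground truth
#'
#' Draws an ancestral genome with gene models (GT..AG introns), evolves it
#' on the topology ((Og, (Osj, Osi)), outgroup) under per-branch rates,
#' transition bias `kappa`, and codon-aware selection accepting
#' nonsynonymous changes with probability `omega`, applies any planted
#' splice-site and microsatellite events, and emits the exact alignment
#' (no aligner involved) together with a complete event ledger.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genomes` (named ungapped soft-masked strings:
#'   `osj`, `og`, `osi`, `outgroup`), `alignment` (a
#'   [triple_alignment()] whose blocks also carry the outgroup row),
#'   `genes` (gene models in japonica coordinates), `annotation` (list of
#'   `cds`, `transcripts`, `exons` GRanges and a `class`-labelled
#'   combined GRanges), `ledger` (substitution events in ancestor
#'   coordinates), `ssr_table`, `ssr_truth`, `splice_truth`,
#'   `repeat_intervals`, and `config`.
#' @export
simulate_genomes <- function(cfg = sim_config()) {
  withr_seed(cfg$seed, {
    anc0 <- build_ancestor(cfg)
    anc <- plant_ssrs(anc0, anc0$genes, cfg)
    n <- length(anc$seq)
    cidx <- codon_index(anc$genes, n)
    # positions protected from random substitution: planted SSR tracts
    # (with a small margin) and planted splice motifs with flanks
    protect <- logical(n)
    if (!is.null(anc$ssr_table)) {
      for (i in seq_len(nrow(anc$ssr_table))) {
        s <- max(0L, anc$ssr_table$start[i] - 4L)
        e <- min(n, anc$ssr_table$end[i] + 4L)
        protect[seq.int(s + 1L, e)] <- TRUE
      }
    }
    if (!is.null(cfg$planted_splice)) {
      gmap <- stats::setNames(anc$genes,
                              vapply(anc$genes, `[[`, character(1),
                                     "gene_id"))
      for (i in seq_len(nrow(cfg$planted_splice))) {
        g <- gmap[[cfg$planted_splice$gene[i]]]
        ex <- g$exons[order(g$exons[, 1]), , drop = FALSE]
        ni <- nrow(ex) - 1L
        idx <- cfg$planted_splice$intron[i]
        idx_gen <- if (g$strand == "+") idx else ni - idx + 1L
        lo <- max(0L, ex[idx_gen, 2] - 14L)
        hi <- min(n, ex[idx_gen + 1L, 1] + 14L)
        protect[seq.int(lo + 1L, hi)] <- TRUE
      }
    }
    # evolve along the topology
    led <- list()
    ev <- evolve_branch(anc$seq, cfg$rates[["og"]], cfg$kappa,
                        cfg$omega[["og"]], cidx, protect, "og")
    og <- ev$seq; led$og <- ev$events
    ev <- evolve_branch(anc$seq, cfg$rates[["internal"]], cfg$kappa,
                        cfg$omega[["internal"]], cidx, protect, "internal")
    m <- ev$seq; led$internal <- ev$events
    ev <- evolve_branch(m, cfg$rates[["osj"]], cfg$kappa,
                        cfg$omega[["osj"]], cidx, protect, "osj")
    osj <- ev$seq; led$osj <- ev$events
    ev <- evolve_branch(m, cfg$rates[["osi"]], cfg$kappa,
                        cfg$omega[["osi"]], cidx, protect, "osi")
    osi <- ev$seq; led$osi <- ev$events
    ev <- evolve_branch(anc$seq, cfg$rates[["outgroup"]], cfg$kappa,
                        cfg$omega[["outgroup"]], cidx, protect, "outgroup")
    outg <- ev$seq; led$outgroup <- ev$events
    seqs <- list(osj = osj, og = og, osi = osi, outgroup = outg)
    # planted events
    sp <- apply_planted_splice(seqs, anc$genes, cfg$planted_splice)
    seqs <- sp$seqs
    pe <- apply_planted_ssr(seqs, anc$ssr_table, cfg$planted_ssr)
    seqs <- pe$seqs
    # repeat soft-masking: intergenic intervals up to repeat_fraction
    rep_iv <- list()
    in_gene <- logical(n)
    for (g in anc$genes) in_gene[seq.int(g$start + 1L, g$end)] <- TRUE
    target <- cfg$repeat_fraction * n
    masked <- 0; tries <- 0L
    mask <- logical(n)
    while (masked < target && tries < 2000L) {
      tries <- tries + 1L
      w <- sample(100:400, 1L)
      s <- sample.int(n - w, 1L)
      idx <- seq.int(s, s + w - 1L)
      if (any(in_gene[idx]) || any(mask[idx]) || any(protect[idx])) next
      mask[idx] <- TRUE
      masked <- masked + w
      rep_iv[[length(rep_iv) + 1L]] <- c(start = s - 1L, end = s + w - 1L)
    }
    # assemble gapped alignment columns
    taxa <- c("osj", "og", "osi", "outgroup")
    for (tx in c("osj", "og", "osi")) {
      seqs[[tx]][pe$del[[tx]]] <- "-"
    }
    col_chars <- lapply(taxa, function(tx) seqs[[tx]])
    names(col_chars) <- taxa
    col_mask <- mask
    if (length(pe$ins)) {
      # insertion segments after given ancestor positions
      ins_after <- vapply(pe$ins, function(x) x$after, numeric(1))
      ord <- order(ins_after)
      # build by splicing from the end backwards
      for (k in rev(ord)) {
        e <- pe$ins[[k]]
        seg_len <- nchar(e$seq)
        seg <- lapply(taxa, function(tx) {
          if (tx == e$taxon) strsplit(e$seq, "")[[1]] else
            rep("-", seg_len)
        })
        names(seg) <- taxa
        at <- e$after
        for (tx in taxa) {
          col_chars[[tx]] <- append(col_chars[[tx]], seg[[tx]], after = at)
        }
        col_mask <- append(col_mask, rep(FALSE, seg_len), after = at)
      }
    }
    blocks <- list(chr1 = vapply(col_chars, function(x)
      paste(x, collapse = ""), character(1)))
    aln <- triple_alignment(blocks)
    # soft-masked ungapped genome strings
    genome_of <- function(tx) {
      ch <- col_chars[[tx]]
      keep <- ch != "-"
      ch <- ch[keep]
      mk <- col_mask[keep]
      ch[mk] <- tolower(ch[mk])
      paste(ch, collapse = "")
    }
    genomes <- lapply(stats::setNames(taxa, taxa), genome_of)
    # gene models in japonica coordinates via the alignment maps
    maps <- aln_maps(aln, "chr1", "osj")
    # ancestor position -> alignment column, accounting for insertions
    anc_col <- seq_len(n)
    if (length(pe$ins)) {
      shift <- integer(n)
      for (e in pe$ins) {
        if (e$after < n) {
          shift[seq.int(e$after + 1L, n)] <-
            shift[seq.int(e$after + 1L, n)] + nchar(e$seq)
        }
      }
      anc_col <- seq_len(n) + shift
    }
    anc_to_osj <- function(p0) {
      # 0-based ancestor pos -> 0-based osj pos (NA if deleted in osj)
      maps$pos_of_col[anc_col[p0 + 1L]]
    }
    genes_osj <- lapply(anc$genes, function(g) {
      ex <- g$exons
      ex_osj <- cbind(vapply(ex[, 1], anc_to_osj, numeric(1)),
                      vapply(ex[, 2] - 1L, anc_to_osj, numeric(1)) + 1L)
      g$exons_anc <- g$exons
      g$cds_anc <- g$cds
      g$exons <- ex_osj
      g$cds <- ex_osj
      g$start_anc <- g$start; g$end_anc <- g$end
      g$start <- anc_to_osj(g$start)
      g$end <- anc_to_osj(g$end - 1L) + 1L
      g
    })
    ledger <- do.call(rbind, led)
    rownames(ledger) <- NULL
    cds_gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
      start = unlist(lapply(genes_osj, function(g) g$cds[, 1] + 1L)),
      end = unlist(lapply(genes_osj, function(g) g$cds[, 2]))))
    tx_gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
      start = vapply(genes_osj, function(g) g$start + 1L, numeric(1)),
      end = vapply(genes_osj, function(g) g$end, numeric(1))))
    ann_cls <- cds_gr
    ann_cls$class <- "CDS-exon"
    list(genomes = genomes, alignment = aln, genes = genes_osj,
         annotation = list(cds = cds_gr, transcripts = tx_gr,
                           classes = ann_cls),
         ledger = ledger, ssr_table = anc$ssr_table, ssr_truth = pe$truth,
         splice_truth = sp$truth,
         repeat_intervals = if (length(rep_iv)) do.call(rbind, rep_iv)
                            else NULL,
         config = cfg)
  })
}

#' Simulate a coding-only gene panel on the species topology
#'
#' A lighter-weight generator for dN/dS parameter-recovery studies:
#' `n_genes` genes of `n_codons` sense codons evolve on the same topology
#' and under the same codon-aware engine as [simulate_genomes()], without
#' the genomic scaffolding.
#'
#' @param n_genes,n_codons Panel size.
#' @param rates,kappa,omega As in [sim_config()].
#' @param seed Integer seed.
#' @param trim_termini_aa Codons masked at each alignment end (0: keep
#'   everything, appropriate when counting planted events).
#' @return A list with `alignments` (list of `codon_alignment` objects for
#'   taxa osj/og/outgroup), `osi` (per-gene codon vectors), and `truth`
#'   (realized substitution events per branch).
#' @export
simulate_codon_panel <- function(n_genes = 100L, n_codons = 100L,
                                 rates = c(og = 2.5e-3, internal = 1.2e-3,
                                           osj = 1.5e-3, osi = 1.5e-3,
                                           outgroup = 0.10),
                                 kappa = 3.44,
                                 omega = c(og = 0.30, internal = 0.25,
                                           osj = 0.25, osi = 0.25,
                                           outgroup = 0.20),
                                 seed = 1L, trim_termini_aa = 0L) {
  withr_seed(seed, {
    total <- n_genes * n_codons
    anc_cod <- sample_sense_codons(total)
    led <- list()
    ev <- evolve_codons(anc_cod, rates[["og"]], kappa, omega[["og"]], "og")
    og <- ev$codons; led$og <- ev$events
    ev <- evolve_codons(anc_cod, rates[["internal"]], kappa,
                        omega[["internal"]], "internal")
    m <- ev$codons; led$internal <- ev$events
    ev <- evolve_codons(m, rates[["osj"]], kappa, omega[["osj"]], "osj")
    osj <- ev$codons; led$osj <- ev$events
    ev <- evolve_codons(m, rates[["osi"]], kappa, omega[["osi"]], "osi")
    osi <- ev$codons; led$osi <- ev$events
    ev <- evolve_codons(anc_cod, rates[["outgroup"]], kappa,
                        omega[["outgroup"]], "outgroup")
    outg <- ev$codons; led$outgroup <- ev$events
    cods <- list(osj = osj, og = og, osi = osi, outgroup = outg)
    idx_of_gene <- function(i) seq.int((i - 1L) * n_codons + 1L,
                                       i * n_codons)
    alns <- lapply(seq_len(n_genes), function(i) {
      build_codon_alignment(paste0("g", i),
                            cods$osj[idx_of_gene(i)],
                            cods$og[idx_of_gene(i)],
                            cods$outgroup[idx_of_gene(i)],
                            coverage = 1,
                            filter = alignment_filter(
                              min_aa = 1L, min_coverage = 0.001,
                              trim_termini_aa = trim_termini_aa))
    })
    truth <- do.call(rbind, led)
    rownames(truth) <- NULL
    list(alignments = alns[!vapply(alns, is.null, logical(1))],
         osi = lapply(seq_len(n_genes), function(i)
           cods$osi[idx_of_gene(i)]),
         truth = truth)
  })
}

#' Export simulated gene models as GFF3
#'
#' Writes gene/mRNA/exon/CDS features (japonica coordinates) through
#' rtracklayer.
#'
#' @param sim Output of [simulate_genomes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
sim_genes_gff3 <- function(sim, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 export")
  }
  feats <- list()
  for (g in sim$genes) {
    n_ex <- nrow(g$exons)
    widths <- g$cds[, 2] - g$cds[, 1]
    w_tx <- if (g$strand == "+") widths else rev(widths)
    # GFF3 phase: bases to skip at the start of each CDS part
    ph_tx <- (3L - cumsum(c(0L, w_tx[-length(w_tx)])) %% 3L) %% 3L
    phase <- if (g$strand == "+") ph_tx else rev(ph_tx)
    feats[[length(feats) + 1L]] <- data.frame(
      chrom = g$chrom,
      start = c(g$start + 1L, g$start + 1L, g$exons[, 1] + 1L,
                g$cds[, 1] + 1L),
      end = c(g$end, g$end, g$exons[, 2], g$cds[, 2]),
      strand = g$strand,
      type = c("gene", "mRNA", rep("exon", n_ex), rep("CDS", n_ex)),
      phase = c(NA, NA, rep(NA, n_ex), phase),
      ID = c(g$gene_id, paste0(g$gene_id, ".1"),
             paste0(g$gene_id, ".exon", seq_len(n_ex)),
             paste0(g$gene_id, ".cds", seq_len(n_ex))))
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand, type = df$type,
                               phase = as.integer(df$phase), ID = df$ID)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Simulate phred-scored shotgun reads from a genome
#'
#' Fragments of about `fragment_bp` are sequenced from both ends with a
#' declining quality profile; sequencing errors are injected at the
#' phred-implied rates; each read carries an `MF` (methylation
#' filtration) or `SH` (subtractive hybridization) library tag.
#' Contaminant read pairs are drawn from an organelle-like sequence
#' generated alongside.
#'
#' @param genome Soft-masked genome string (single chromosome).
#' @param cfg A [sim_config()].
#' @param chrom Chromosome name recorded in the truth table.
#' @param error_free Disable error injection (for exactness tests).
#' @return A list with `reads` (read data.frame: id, seq, qual, library),
#'   `truth` (per-read origin, 0-based genome start, strand), and
#'   `organelle` (named contaminant source sequence).
#' @export
simulate_reads <- function(genome, cfg = sim_config(), chrom = "chr1",
                           error_free = FALSE) {
  withr_seed(cfg$seed + 7L, {
    n <- nchar(genome)
    rl <- cfg$read_length
    n_pairs <- max(0L, round(cfg$coverage * n / (2L * rl)))
    organelle <- paste(sample(BASES, 30000L, replace = TRUE),
                       collapse = "")
    if (n_pairs == 0L) {
      return(list(reads = data.frame(id = character(0), seq = character(0),
                                     qual = character(0),
                                     library = character(0)),
                  truth = NULL,
                  organelle = c(organelle = organelle)))
    }
    profile_q <- pmax(cfg$phred_min,
                      round(cfg$phred_max - (cfg$phred_max - cfg$phred_min) *
                              (seq_len(rl) / rl)^1.5))
    reads <- list(); truth <- list()
    add_read <- function(id, src, start0, strand, origin, src_name) {
      raw <- substr(src, start0 + 1L, start0 + rl)
      if (nchar(raw) < rl) return(invisible(NULL))
      if (strand == "-") raw <- revcomp(raw)
      ch <- strsplit(raw, "")[[1]]
      q <- profile_q
      if (!error_free) {
        err <- stats::runif(rl) < 10^(-q / 10)
        for (j in which(err & toupper(ch) %in% BASES)) {
          low <- ch[j] %in% letters
          nb <- sample(setdiff(BASES, toupper(ch[j])), 1L)
          ch[j] <- if (low) tolower(nb) else nb
        }
      }
      lib <- sample(c("MF", "SH"), 1L)
      reads[[length(reads) + 1L]] <<- data.frame(
        id = id, seq = paste(ch, collapse = ""),
        qual = phred_to_ascii(q), library = lib)
      truth[[length(truth) + 1L]] <<- data.frame(
        id = id, origin = origin, source = src_name, start = start0,
        strand = strand)
    }
    for (i in seq_len(n_pairs)) {
      contaminant <- stats::runif(1) < cfg$contaminant_fraction
      src <- if (contaminant) organelle else genome
      src_name <- if (contaminant) "organelle" else chrom
      L <- nchar(src)
      frag <- min(L, max(2L * rl,
                         round(stats::rnorm(1, cfg$fragment_bp,
                                            cfg$fragment_bp / 10))))
      fs <- sample.int(max(1L, L - frag + 1L), 1L) - 1L
      add_read(sprintf("r%05d_f", i), src, fs, "+",
               if (contaminant) "contaminant" else "genuine", src_name)
      add_read(sprintf("r%05d_r", i), src, fs + frag - rl, "-",
               if (contaminant) "contaminant" else "genuine", src_name)
    }
    list(reads = do.call(rbind, reads), truth = do.call(rbind, truth),
         organelle = c(organelle = organelle))
  })
}
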