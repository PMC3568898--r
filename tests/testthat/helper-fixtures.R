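# Shared fixtures built in code.

# A read data.frame from base sequences and integer phred vectors.
make_reads <- function(seqs, phreds, library = "MF",
                       ids = paste0("r", seq_along(seqs))) {
  data.frame(id = ids, seq = seqs,
             qual = vapply(phreds, phred_to_ascii, character(1)),
             library = rep_len(library, length(seqs)))
}

# A single-block triple alignment from equal-length (gapped) strings.
make_alignment <- function(osj, og, osi, outgroup = NULL, chrom = "chr1") {
  b <- c(osj = osj, og = og, osi = osi)
  if (!is.null(outgroup)) b <- c(b, outgroup = outgroup)
  blocks <- list(b)
  names(blocks) <- chrom
  triple_alignment(blocks)
}

# A one-gene model (plus strand by default) over explicit exon intervals.
make_gene <- function(gene_id, exons, strand = "+", chrom = "chr1") {
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       start = min(exons[, 1]), end = max(exons[, 2]),
       exons = exons, cds = exons)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Independent brute-force SSR oracle: regex scan over every primitive
# 2-4 nt motif, followed by the same longest/leftmost/smallest-unit
# overlap resolution the detector documents.
regex_ssr_oracle <- function(s, min_units = c(`2` = 9L, `3` = 6L,
                                              `4` = 5L)) {
  s <- toupper(s)
  bases <- c("A", "C", "G", "T")
  motifs <- unlist(lapply(2:4, function(u) {
    m <- do.call(paste0, expand.grid(rep(list(bases), u)))
    m[vapply(m, oryzaevol:::is_primitive_motif, logical(1))]
  }))
  cand <- list()
  for (m in motifs) {
    u <- nchar(m)
    k <- min_units[[as.character(u)]]
    pat <- sprintf("(?:%s){%d,}", m, k)
    hits <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    lens <- attr(hits, "match.length")
    for (i in seq_along(hits)) {
      cand[[length(cand) + 1L]] <- data.frame(
        start = hits[i] - 1L, end = hits[i] - 1L + lens[i], motif = m,
        unit = u, n_units = lens[i] %/% u)
    }
  }
  if (!length(cand)) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), unit = integer(0),
                      n_units = integer(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start, cand$unit), ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  occ_s <- integer(0); occ_e <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < occ_e & cand$end[i] > occ_s)) {
      keep[i] <- TRUE
      occ_s <- c(occ_s, cand$start[i]); occ_e <- c(occ_e, cand$end[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# Independent pathway-enumeration oracle for codon substitution counting:
# recursive enumeration of substitution orders, dropping pathways that
# pass through a stop codon.
pathway_oracle <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  enumerate <- function(cur, target) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(pos)) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      if (code[[nxt]] == "*") next
      step <- if (code[[nxt]] == code[[cur]]) c(sd = 1, nd = 0) else
        c(sd = 0, nd = 1)
      for (rest in enumerate(nxt, target)) {
        out[[length(out) + 1L]] <- step + rest
      }
    }
    out
  }
  paths <- enumerate(c1, c2)
  if (!length(paths)) return(c(sd = 0, nd = 0, n_pathways = 0))
  m <- do.call(rbind, paths)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]), n_pathways = nrow(m))
}

# Independent unmodified Nei-Gojobori site counts (all single changes
# weighted 1/3; changes to stops excluded from both S and N, matching the
# package's counting convention).
ng86_sites_oracle <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  s_tot <- 0
  z_tot <- 0
  for (cod in codons) {
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cod, p, p))) {
        mut <- cod
        substr(mut, p, p) <- b
        if (code[[mut]] == "*") z_tot <- z_tot + 1 / 3
        else if (code[[mut]] == code[[cod]]) s_tot <- s_tot + 1 / 3
      }
    }
  }
  c(S = s_tot, N = 3 * length(codons) - s_tot - z_tot)
}
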