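# A compact hand-built locus: one gene, two exons, one intron with known
# donor/acceptor motifs, identical across genomes unless edited.
build_locus <- function(edit_taxon = NULL, edit_site = NULL,
                        edit_to = NULL, strand = "+",
                        flank_edit_taxon = NULL) {
  set.seed(101)
  exon1 <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  exon2 <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  intron <- paste0("GT", paste(sample(c("A", "C", "G", "T"), 26, TRUE),
                               collapse = ""), "AG")
  tx <- paste0(exon1, intron, exon2)
  genomic <- if (strand == "+") tx else
    oryzaevol::revcomp(tx)
  seqs <- list(osj = genomic, og = genomic, osi = genomic)
  if (!is.null(edit_taxon)) {
    # donor occupies tx positions 31-32, acceptor 59-60
    iv <- if (edit_site == "donor") c(31, 32) else c(59, 60)
    s <- tx
    substr(s, iv[1], iv[2]) <- edit_to
    seqs[[edit_taxon]] <- if (strand == "+") s else oryzaevol::revcomp(s)
  }
  if (!is.null(flank_edit_taxon)) {
    s <- tx
    substr(s, 35, 35) <- chartr("ACGT", "GTAC", substr(s, 35, 35))
    seqs[[flank_edit_taxon]] <- if (strand == "+") s else
      oryzaevol::revcomp(s)
  }
  exons <- if (strand == "+") rbind(c(0, 30), c(60, 90)) else
    rbind(c(0, 30), c(60, 90))
  gene <- make_gene("g1", exons, strand = strand)
  list(aln = make_alignment(seqs$osj, seqs$og, seqs$osi), gene = gene)
}

test_that("donor and acceptor motifs extract on the transcript strand", {
  L <- build_locus()
  rec <- extract_splice_contexts(list(L$gene), L$aln)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$motif_osj[rec$kind == "donor"], "GT")
  expect_equal(rec$motif_osj[rec$kind == "acceptor"], "AG")
  expect_true(all(rec$gap_free))
  expect_true(all(rec$canonical_osj))
  # minus strand: same motifs after reverse complement
  Lm <- build_locus(strand = "-")
  recm <- extract_splice_contexts(list(Lm$gene), Lm$aln)
  expect_equal(recm$motif_osj[recm$kind == "donor"], "GT")
  expect_equal(recm$motif_osj[recm$kind == "acceptor"], "AG")
})

test_that("extraction round-trips under strand reversal", {
  L <- build_locus(edit_taxon = "osi", edit_site = "donor", edit_to = "GC")
  Lm <- build_locus(edit_taxon = "osi", edit_site = "donor",
                    edit_to = "GC", strand = "-")
  cols <- c("kind", "motif_osj", "motif_osi", "motif_og", "flank5_osj",
            "flank3_osj")
  a <- extract_splice_contexts(list(L$gene), L$aln)[, cols]
  b <- extract_splice_contexts(list(Lm$gene), Lm$aln)[, cols]
  expect_equal(a[order(a$kind), ], b[order(b$kind), ],
               ignore_attr = TRUE)
})

test_that("alignment gaps near a site disqualify the record", {
  L <- build_locus()
  # open a gap in the African genome 3 nt downstream of the donor
  og <- L$aln$blocks$chr1[["og"]]
  substr(og, 36, 36) <- "-"
  aln <- make_alignment(L$aln$blocks$chr1[["osj"]], og,
                        L$aln$blocks$chr1[["osi"]])
  rec <- extract_splice_contexts(list(L$gene), aln)
  expect_false(rec$gap_free[rec$kind == "donor"])
  rec <- assign_splice_lineage(rec)
  expect_true(is.na(rec$lineage[rec$kind == "donor"]))
})

test_that("lineage assignment matches the observed motif patterns", {
  # donor GT in Osj only, GC in Osi and Og: Osj-lineage change
  L <- build_locus(edit_taxon = "osi", edit_site = "donor", edit_to = "GC")
  L2 <- build_locus(edit_taxon = "og", edit_site = "donor", edit_to = "GC")
  # both edits together mimic the japonica-specific GT: edit osi and og
  seqs_aln <- make_alignment(L$aln$blocks$chr1[["osj"]],
                             L2$aln$blocks$chr1[["og"]],
                             L$aln$blocks$chr1[["osi"]])
  rec <- assign_splice_lineage(
    extract_splice_contexts(list(L$gene), seqs_aln))
  don <- rec[rec$kind == "donor", ]
  expect_equal(don$motif_osj, "GT")
  expect_equal(don$motif_osi, "GC")
  expect_equal(don$motif_og, "GC")
  expect_equal(don$lineage, "Osj")
  expect_false(don$unpolarized)
  # acceptor TG in Og, AG in Osj and Osi: Og change, unpolarized
  L3 <- build_locus(edit_taxon = "og", edit_site = "acceptor",
                    edit_to = "TG")
  rec3 <- assign_splice_lineage(
    extract_splice_contexts(list(L3$gene), L3$aln))
  acc <- rec3[rec3$kind == "acceptor", ]
  expect_equal(acc$lineage, "Og")
  expect_true(acc$unpolarized)
  # identical motifs: none
  L4 <- build_locus()
  rec4 <- assign_splice_lineage(
    extract_splice_contexts(list(L4$gene), L4$aln))
  expect_true(all(rec4$lineage == "none"))
})

test_that("flank cleanliness removes records with flank substitutions", {
  L <- build_locus(flank_edit_taxon = "osi")
  rec <- assign_splice_lineage(extract_splice_contexts(list(L$gene),
                                                       L$aln))
  fc <- flank_clean_filter(rec)
  # the donor flank3 carries the Osi substitution: donor removed
  expect_false("donor" %in% fc$kind)
  expect_true("acceptor" %in% fc$kind)
})

test_that("intron coding potential requires frame connection and no stops", {
  r <- intron_coding_potential("GTATAGCCC", phase = 0)
  expect_true(r$has_inframe_stop)       # codons GTA TAG CCC
  expect_false(r$coding_potential_retained)
  r2 <- intron_coding_potential("GTTGGCAAG", phase = 0)
  expect_false(r2$has_inframe_stop)
  expect_true(r2$coding_potential_retained)
  # length not a multiple of 3 can never connect the frames
  r3 <- intron_coding_potential("GTTGGCAAGA", phase = 0)
  expect_false(r3$coding_potential_retained)
  expect_equal(r3$length_mod3, 1)
  # phase shifts the scanned frame: TAG no longer in frame
  r4 <- intron_coding_potential("GTATAGCCC", phase = 2)
  expect_false(r4$has_inframe_stop)
})

test_that("lineage summary counts introns once even with two changed sites", {
  L <- build_locus(edit_taxon = "osi", edit_site = "donor", edit_to = "GC")
  # also edit the acceptor of the same intron in the same taxon
  osi <- L$aln$blocks$chr1[["osi"]]
  substr(osi, 59, 60) <- "TG"
  aln <- make_alignment(L$aln$blocks$chr1[["osj"]],
                        L$aln$blocks$chr1[["og"]], osi)
  rec <- assign_splice_lineage(extract_splice_contexts(list(L$gene), aln))
  s <- summarize_splice_lineages(rec)
  osi_row <- s[s$lineage == "Osi", ]
  expect_equal(osi_row$n_introns, 1)
  expect_equal(osi_row$n_donor, 1)
  expect_equal(osi_row$n_acceptor, 1)
  expect_equal(s[s$lineage == "Og", "n_introns"], 0)
  # empty record set: all zeros
  L0 <- build_locus()
  rec0 <- assign_splice_lineage(
    extract_splice_contexts(list(L0$gene), L0$aln))
  s0 <- summarize_splice_lineages(rec0)
  expect_true(all(s0$n_introns == 0))
})

test_that("planted splice mutations are recovered exactly on clean genomes", {
  ps <- data.frame(gene = c("g1", "g3", "g5", "g7"), intron = 1L,
                   kind = c("donor", "acceptor", "donor", "acceptor"),
                   taxon = c("osj", "osi", "og", "osj"),
                   new_motif = c("GC", "TG", "GA", "AC"))
  cfg <- sim_config(seed = 5, planted_splice = ps,
                    rates = c(og = 0, internal = 0, osj = 0, osi = 0,
                              outgroup = 0))
  sim <- simulate_genomes(cfg)
  rec <- assign_splice_lineage(
    extract_splice_contexts(sim$genes, sim$alignment))
  hits <- rec[rec$lineage %in% c("Osj", "Osi", "Og"), ]
  expect_equal(nrow(hits), 4)
  key_got <- sort(paste(hits$gene_id, hits$kind, hits$lineage))
  key_want <- sort(paste(sim$splice_truth$gene, sim$splice_truth$kind,
                         sim$splice_truth$lineage))
  expect_equal(key_got, key_want)
  # all planted records survive the flank-cleanliness filter
  fc <- flank_clean_filter(rec)
  expect_equal(sum(fc$lineage %in% c("Osj", "Osi", "Og")), 4)
  # zero mutation rate and no planting: no positives at all
  cfg0 <- sim_config(seed = 6, rates = c(og = 0, internal = 0, osj = 0,
                                         osi = 0, outgroup = 0))
  sim0 <- simulate_genomes(cfg0)
  rec0 <- assign_splice_lineage(
    extract_splice_contexts(sim0$genes, sim0$alignment))
  expect_true(all(rec0$lineage == "none"))
})

test_that("coding potential agrees with translating the exon-intron-exon run", {
  # cross-check: a full translation of exon1 + intron + exon2 contains a
  # stop inside the intron segment exactly when the scan reports one
  set.seed(77)
  for (i in 1:10) {
    n_cod <- 4 + i %% 3
    intron <- paste(sample(c("A", "C", "G", "T"), n_cod * 3, TRUE),
                    collapse = "")
    exon1 <- paste(rand_codons <- sample(setdiff(
      names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA")), 6, TRUE),
      collapse = "")
    r <- intron_coding_potential(intron, phase = 0)
    full <- paste0(exon1, intron)
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(full))), "")[[1]]
    intron_aa <- aa[7:(6 + n_cod)]
    expect_equal(r$has_inframe_stop, any(intron_aa == "*"))
  }
})
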