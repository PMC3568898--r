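test_that("perfect tandem tracts are detected with exact coordinates", {
  hit <- detect_ssrs(strrep("AC", 10))
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$start, hit$end, hit$unit, hit$n_units),
               c(0, 20, 2, 10))
  expect_equal(hit$motif, "AC")
  # below the tri-nucleotide minimum of six units: nothing
  expect_equal(nrow(detect_ssrs(strrep("ATG", 5))), 0)
  expect_equal(nrow(detect_ssrs(strrep("ATG", 6))), 1)
  # embedded in random flanks with a periodicity break on each side
  set.seed(22)
  s <- paste0(random_dna(100), "C", strrep("AT", 9), "G", random_dna(100))
  hit2 <- detect_ssrs(s)
  expect_equal(nrow(hit2), 1)
  expect_equal(c(hit2$start, hit2$end), c(101, 119))
  # tracts containing N are excluded
  expect_equal(nrow(detect_ssrs(paste0(strrep("AC", 5), "N",
                                       strrep("AC", 4)))), 0)
})

test_that("non-primitive motifs are never reported", {
  # (AT)x12 must come out as a di-nucleotide tract, not ATAT
  hit <- detect_ssrs(strrep("AT", 12))
  expect_equal(hit$unit, 2)
  hit2 <- detect_ssrs(strrep("AAG", 8))
  expect_equal(hit2$unit, 3)
})

test_that("detector matches the regex oracle on random strings with planted tracts", {
  set.seed(33)
  n_str <- 120
  for (i in seq_len(n_str)) {
    s <- random_dna(1000)
    if (i %% 2 == 0) {
      m <- sample(c("AC", "AT", "CAG", "CCG", "AAGG"), 1)
      k <- c(`2` = 9L, `3` = 6L, `4` = 5L)[[as.character(nchar(m))]] +
        sample(0:4, 1)
      at <- sample(100:800, 1)
      s <- paste0(substr(s, 1, at), strrep(m, k),
                  substr(s, at + 1, 1000))
    }
    got <- detect_ssrs(s)
    want <- regex_ssr_oracle(s)
    expect_equal(got[, c("start", "end", "motif", "unit", "n_units")],
                 want[, c("start", "end", "motif", "unit", "n_units")],
                 ignore_attr = TRUE)
  }
})

test_that("canonical motifs pair with their reverse complements only", {
  expect_equal(canonical_motif("GCG"), "CGC")
  expect_equal(canonical_motif("CGG"), "CCG")
  expect_equal(canonical_motif("AT"), "AT")
  # rotations stay distinct: the three common rice tri-motif classes
  expect_length(unique(canonical_motif(c("CGC", "CGG", "GGC"))), 3)
  # idempotent and reverse-complement-invariant
  set.seed(12)
  motifs <- c("AC", "AG", "CAG", "GAA", "AAGG", "ACGT")
  expect_equal(canonical_motif(canonical_motif(motifs)),
               canonical_motif(motifs))
  expect_equal(canonical_motif(revcomp(motifs)), canonical_motif(motifs))
  expect_error(canonical_motif("ATAT"), "primitive")
})

test_that("clusters require all three genomes and gap-free flanks", {
  set.seed(44)
  flank <- random_dna(60)
  flank2 <- random_dna(60)
  tract <- strrep("CAG", 8)
  mk <- function(t) paste0(flank, t, flank2)
  aln <- make_alignment(mk(tract), mk(tract), mk(tract))
  loci <- lapply(list(osj = mk(tract), og = mk(tract), osi = mk(tract)),
                 detect_ssrs, chrom = "chr1")
  cl <- cluster_across_genomes(loci, aln)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_loci_osj, 1)
  # tract absent in one genome: no cluster survives
  loci2 <- loci
  loci2$og <- loci2$og[0, ]
  expect_null(cluster_across_genomes(loci2, aln))
  # an alignment gap 30 bp upstream of the tract drops the cluster
  gapped <- mk(tract)
  substr(gapped, 31, 31) <- "-"
  aln_gap <- make_alignment(mk(tract), gapped, mk(tract))
  og_seq <- gsub("-", "", gapped)
  loci3 <- list(osj = detect_ssrs(mk(tract), chrom = "chr1"),
                og = detect_ssrs(og_seq, chrom = "chr1"),
                osi = detect_ssrs(mk(tract), chrom = "chr1"))
  expect_null(cluster_across_genomes(loci3, aln_gap))
})

test_that("cluster classification follows the three-way comparison rules", {
  base <- data.frame(chrom = "chr1", start = 0L, end = 30L,
                     n_loci_osj = 1L, tract_osj = strrep("AT", 10),
                     n_loci_og = 1L, tract_og = strrep("AT", 10),
                     n_loci_osi = 1L, tract_osi = strrep("AT", 10),
                     motif_osj = "AT", unit_osj = 2L)
  shared <- classify_cluster(base)
  expect_equal(shared$polymorphism_class, "shared")
  expect_equal(shared$lineage, "none")
  lp <- base; lp$tract_og <- strrep("AT", 12)
  lp <- classify_cluster(lp)
  expect_equal(lp$polymorphism_class, "length_poly")
  expect_equal(lp$lineage, "Og")
  sp <- base
  sp$tract_osi <- paste0(strrep("AT", 4), "AA", strrep("AT", 5))
  sp <- classify_cluster(sp)
  expect_equal(sp$polymorphism_class, "seq_poly")
  expect_equal(sp$lineage, "Osi")
  # three different lengths: other
  oth <- base; oth$tract_og <- strrep("AT", 12)
  oth$tract_osi <- strrep("AT", 14)
  expect_equal(classify_cluster(oth)$polymorphism_class, "other")
  # two loci in one genome: other
  dup <- base; dup$n_loci_og <- 2L
  expect_equal(classify_cluster(dup)$polymorphism_class, "other")
})

test_that("classification is symmetric under genome relabelling", {
  base <- data.frame(chrom = "chr1", start = 0L, end = 30L,
                     n_loci_osj = 1L, tract_osj = strrep("AT", 10),
                     n_loci_og = 1L, tract_og = strrep("AT", 12),
                     n_loci_osi = 1L, tract_osi = strrep("AT", 10),
                     motif_osj = "AT", unit_osj = 2L)
  r1 <- classify_cluster(base)
  swapped <- base
  swapped$tract_og <- base$tract_osi
  swapped$tract_osi <- base$tract_og
  r2 <- classify_cluster(swapped)
  expect_equal(r1$polymorphism_class, r2$polymorphism_class)
  expect_equal(r1$lineage, "Og")
  expect_equal(r2$lineage, "Osi")
})

test_that("region assignment distinguishes CDS, non-transcribed and other", {
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 260))
  cl <- data.frame(chrom = "chr1",
                   start = c(120L, 300L, 190L),
                   end = c(150L, 330L, 220L))
  r <- assign_region(cl, cds, tx)
  expect_equal(r$region_class,
               c("protein_coding", "non_transcribed", "other"))
})

test_that("planted SSR events are recovered with class, lineage and region", {
  pssr <- data.frame(locus = c("ssr1", "ssr2", "ssr3", "ssr11", "ssr12"),
                     taxon = c("og", "osj", "osi", "og", "osi"),
                     type = c("length", "length", "point", "length",
                              "point"),
                     delta_units = c(2L, -1L, 0L, 1L, 0L))
  cfg <- sim_config(seed = 9, planted_ssr = pssr,
                    rates = c(og = 0, internal = 0, osj = 0, osi = 0,
                              outgroup = 0))
  sim <- simulate_genomes(cfg)
  loci <- lapply(sim$genomes[c("osj", "og", "osi")], detect_ssrs,
                 chrom = "chr1")
  cl <- classify_cluster(cluster_across_genomes(loci, sim$alignment))
  cl <- assign_region(cl, sim$annotation$cds, sim$annotation$transcripts)
  # conservation: every cluster gets exactly one class
  expect_equal(sum(table(cl$polymorphism_class)), nrow(cl))
  # each planted event appears as one cluster with the expected labels
  truth <- sim$ssr_truth
  for (i in seq_len(nrow(truth))) {
    loc <- sim$ssr_table[sim$ssr_table$locus == truth$locus[i], ]
    hit <- cl[cl$start < loc$end & cl$end > loc$start, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$polymorphism_class, truth$expected_class[i])
    expect_equal(hit$lineage, truth$expected_lineage[i])
    expect_equal(hit$region_class, truth$region[i])
  }
  # everything unplanted is shared
  expect_equal(sum(cl$polymorphism_class != "shared"), nrow(truth))
})

test_that("SSR contingency tests cover the documented contrasts", {
  pssr <- data.frame(locus = paste0("ssr", c(1:6, 11:14)),
                     taxon = rep(c("og", "osj", "osi"), length.out = 10),
                     type = rep(c("length", "point"), 5),
                     delta_units = rep(c(1L, 0L), 5))
  cfg <- sim_config(seed = 19, planted_ssr = pssr,
                    ssr_loci = c(non_transcribed = 10L,
                                 protein_coding = 6L),
                    rates = c(og = 0, internal = 0, osj = 0, osi = 0,
                              outgroup = 0))
  sim <- simulate_genomes(cfg)
  loci <- lapply(sim$genomes[c("osj", "og", "osi")], detect_ssrs,
                 chrom = "chr1")
  cl <- classify_cluster(cluster_across_genomes(loci, sim$alignment))
  cl <- assign_region(cl, sim$annotation$cds, sim$annotation$transcripts)
  res <- ssr_gtests(cl)
  expect_s3_class(res$polymorphic_by_region, "evol_test")
  expect_true(is.numeric(res$total_tract_bp))
  expect_length(res$length_vs_seq, 3)
  # all-shared input skips the polymorphism test
  cfg0 <- sim_config(seed = 20, rates = c(og = 0, internal = 0, osj = 0,
                                          osi = 0, outgroup = 0))
  sim0 <- simulate_genomes(cfg0)
  loci0 <- lapply(sim0$genomes[c("osj", "og", "osi")], detect_ssrs,
                  chrom = "chr1")
  cl0 <- classify_cluster(cluster_across_genomes(loci0, sim0$alignment))
  cl0 <- assign_region(cl0, sim0$annotation$cds,
                       sim0$annotation$transcripts)
  res0 <- ssr_gtests(cl0)
  expect_match(res0$polymorphic_by_region, "skipped")
})

test_that("BED export writes canonical motif names", {
  loci <- detect_ssrs(paste0(random_dna(30), "T", strrep("GCG", 7), "A",
                             random_dna(30)))
  f <- tempfile(fileext = ".bed")
  write_ssr_bed(loci, f)
  bed <- utils::read.delim(f, header = FALSE)
  expect_equal(bed$V4, "CGC")
})
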