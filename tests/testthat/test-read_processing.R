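test_that("3'-trimming removes the maximal low-quality suffix", {
  r <- make_reads("ACGTAC", list(c(30, 30, 14, 30, 14, 14)))
  t <- trim_3prime(r)
  expect_equal(nchar(t$seq), 4)
  expect_equal(t$seq, "ACGT")
  expect_equal(nchar(t$qual), 4)
  # all high quality: unchanged
  r2 <- make_reads("ACGT", list(c(15, 15, 20, 40)))
  expect_identical(trim_3prime(r2)$seq, "ACGT")
  # all low: empty read
  r3 <- make_reads("ACGT", list(c(10, 3, 14, 2)))
  expect_equal(nchar(trim_3prime(r3)$seq), 0)
})

test_that("3'-trimming is idempotent", {
  set.seed(11)
  seqs <- vapply(1:20, function(i) random_dna(50), character(1))
  phreds <- lapply(1:20, function(i) sample(0:45, 50, replace = TRUE))
  r <- make_reads(seqs, phreds)
  t1 <- trim_3prime(r)
  t2 <- trim_3prime(t1)
  expect_identical(t1$seq, t2$seq)
  expect_identical(t1$qual, t2$qual)
})

test_that("read filtering applies length, organelle and repeat rules in order", {
  reads <- make_reads(
    c(random_dna(99),                      # too short
      paste0(strrep("a", 125), random_dna(25)),  # 25 bp non-repeat
      random_dna(150)),                    # clean
    list(rep(30, 99), rep(30, 150), rep(30, 150)))
  res <- filter_reads(reads, qc_config())
  expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(reads))
  expect_equal(res$rejected$reason, c("length", "non_repeat"))
  expect_equal(res$kept$id, "r3")
})

test_that("organelle screen rejects exactly the planted contaminants", {
  cfg <- sim_config(seed = 21, genome_length = 20000L, gene_count = 3L,
                    coverage = 1.5, contaminant_fraction = 0.2)
  sim <- simulate_genomes(cfg)
  rs <- simulate_reads(sim$genomes$og, cfg, error_free = TRUE)
  res <- filter_reads(rs$reads, qc_config(),
                      organelle_screen(rs$organelle))
  planted <- sort(rs$truth$id[rs$truth$origin == "contaminant"])
  flagged <- sort(res$rejected$id[res$rejected$reason == "organelle"])
  expect_identical(flagged, planted)
})

test_that("best-hit selection follows identity, then E-value, then score", {
  one <- data.frame(read_id = "r", chrom = "c1", start = 10L, end = 100L,
                    strand = "+", identity = 99, evalue = 1e-40,
                    score = 80)
  expect_identical(select_best_hit(one)$start, 10L)
  two <- rbind(one, within(one, { start <- 50L; evalue <- 1e-50 }))
  # equal identity: lower E-value wins
  expect_equal(select_best_hit(two)$start, 50L)
  three <- rbind(one, within(one, { start <- 70L; identity <- 99.5 }))
  expect_equal(select_best_hit(three)$start, 70L)
  # full tie: deterministic lowest (chrom, start)
  tie <- rbind(within(one, start <- 30L), one)
  expect_equal(select_best_hit(tie)$start, 10L)
  # below thresholds: nothing
  low <- within(one, identity <- 80)
  expect_null(select_best_hit(low))
})

test_that("consensus picks agreement, then phred, then MF library", {
  mk <- function(bases, phreds, libs) {
    data.frame(read_id = paste0("r", seq_along(bases)), chrom = "c",
               start = 0L, strand = "+", seq = bases,
               qual = vapply(phreds, function(q) phred_to_ascii(q),
                             character(1)),
               library = libs)
  }
  # agreement
  cons <- build_consensus(mk(c("A", "A"), list(30, 20), c("SH", "SH")))
  expect_equal(cons$sites$base, "A")
  expect_equal(cons$sites$depth, 2)
  # highest phred
  cons <- build_consensus(mk(c("A", "G"), list(30, 20), c("SH", "SH")))
  expect_equal(cons$sites$base, "A")
  # phred tie broken toward methylation filtration
  cons <- build_consensus(mk(c("A", "G"), list(30, 30), c("SH", "MF")))
  expect_equal(cons$sites$base, "G")
  # full tie: ambiguous
  cons <- build_consensus(mk(c("A", "G"), list(30, 30), c("MF", "MF")))
  expect_true(cons$sites$ambiguous)
  expect_true(is.na(cons$sites$base))
})

test_that("consensus is invariant under read order", {
  set.seed(5)
  reads <- data.frame(read_id = paste0("r", 1:6), chrom = "c",
                      start = c(0L, 5L, 10L, 3L, 8L, 0L), strand = "+",
                      seq = vapply(1:6, function(i) random_dna(20),
                                   character(1)),
                      qual = vapply(1:6, function(i)
                        phred_to_ascii(sample(10:40, 20, TRUE)),
                        character(1)),
                      library = sample(c("MF", "SH"), 6, TRUE))
  c1 <- build_consensus(reads)
  c2 <- build_consensus(reads[sample(6), ])
  expect_identical(c1$sites, c2$sites)
  expect_identical(c1$contigs, c2$contigs)
})

test_that("supported sites require depth, quality and a strict majority", {
  mk <- function(bases, phreds) {
    data.frame(read_id = paste0("r", seq_along(bases)), chrom = "c",
               start = 0L, strand = "+", seq = bases,
               qual = vapply(phreds, phred_to_ascii, character(1)),
               library = "MF")
  }
  # depth 1: excluded
  s <- supported_sites(build_consensus(mk("A", list(40))))
  expect_equal(nrow(s), 0)
  # A,A,G all qualifying: majority A
  s <- supported_sites(build_consensus(mk(c("A", "A", "G"),
                                          list(30, 25, 40))))
  expect_equal(s$base, "A")
  expect_equal(s$depth, 3)
  # 2-way tie: excluded
  s <- supported_sites(build_consensus(mk(c("A", "G"), list(30, 30))))
  expect_equal(nrow(s), 0)
  # low-quality reads do not count toward depth
  s <- supported_sites(build_consensus(mk(c("A", "A"), list(19, 30))))
  expect_equal(nrow(s), 0)
})

test_that("supported sites are a subset of covered sites with enough depth", {
  cfg <- sim_config(seed = 31, genome_length = 15000L, gene_count = 2L,
                    coverage = 3, contaminant_fraction = 0)
  sim <- simulate_genomes(cfg)
  rs <- simulate_reads(sim$genomes$og, cfg)
  flt <- filter_reads(trim_3prime(rs$reads), qc_config())
  hits <- kmer_align(flt$kept, c(chr1 = sim$genomes$osj))
  best <- do.call(rbind, lapply(split(hits, hits$read_id),
                                select_best_hit))
  mapped <- merge(flt$kept, best[, c("read_id", "chrom", "start",
                                     "strand")],
                  by.x = "id", by.y = "read_id")
  mapped$read_id <- mapped$id
  cons <- build_consensus(mapped)
  supp <- supported_sites(cons)
  key_all <- paste(cons$sites$chrom, cons$sites$pos)
  expect_true(all(paste(supp$chrom, supp$pos) %in% key_all))
  expect_true(all(supp$depth >= 2))
})

test_that("contig statistics compute N50 and coverage", {
  expect_equal(contig_stats(data.frame(chrom = "c", start = 0L,
                                       end = 1L))$n50, 1)
  # brute-force check of the N50 definition on [10, 9, 2]
  cs <- contig_stats(data.frame(chrom = "c", start = c(0, 20, 40),
                                end = c(10, 29, 42)))
  lens <- sort(c(10, 9, 2), decreasing = TRUE)
  brute <- lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
  expect_equal(cs$n50, brute)
  expect_equal(cs$n50, 9)
  expect_equal(cs$total_bp, 21)
  # disjoint contigs covering 100 bp of a 1000-bp reference
  cs2 <- contig_stats(data.frame(chrom = "c", start = c(0, 500),
                                 end = c(60, 540)),
                      reference_bp = 1000)
  expect_equal(cs2$covered_bp, 100)
  expect_equal(cs2$coverage_fraction, 0.1)
})

test_that("FASTA round-trips preserve soft-masking", {
  seqs <- c(chr1 = "ACGTacgtNN", chr2 = "ttttACGT")
  f <- tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
})

test_that("FASTQ round-trips preserve soft-masking and library tags", {
  r <- make_reads(c("ACgtAC", "ggTTaa"), list(rep(30, 6), rep(12, 6)),
                  library = c("MF", "SH"))
  f <- tempfile(fileext = ".fastq")
  write_fastq(r, f)
  r2 <- read_fastq(f)
  expect_identical(r2$seq, r$seq)
  expect_identical(r2$qual, r$qual)
  expect_identical(r2$library, r$library)
})
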