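rand_codons <- function(n) sample(setdiff(names(Biostrings::GENETIC_CODE),
                                          c("TAA", "TAG", "TGA")), n,
                                  replace = TRUE)

test_that("codon alignment filters follow the length-or-coverage rule", {
  mk <- function(n_aa) paste(rand_codons(n_aa), collapse = "")
  set.seed(2)
  s <- mk(99)
  expect_null(build_codon_alignment("g", s, s, s, coverage = 0.60))
  a <- build_codon_alignment("g", s, s, s, coverage = 0.71)
  expect_s3_class(a, "codon_alignment")
  # boundary: exactly 100 aa passes regardless of coverage
  s100 <- mk(100)
  expect_s3_class(build_codon_alignment("g", s100, s100, s100,
                                        coverage = 0.1),
                  "codon_alignment")
  # internal stop in the African sequence: rejected
  og_stop <- paste0(substr(s100, 1, 150), "TAA", substr(s100, 154, 300))
  expect_null(build_codon_alignment("g", s100, og_stop, s100,
                                    coverage = 1))
  # gaps: rejected
  og_gap <- paste0(substr(s100, 1, 150), "-1-", substr(s100, 154, 300))
  expect_null(build_codon_alignment("g", s100, og_gap, s100, coverage = 1))
  # frame violation
  expect_error(build_codon_alignment("g", "ACGTA", "ACGTA", "ACGTA"),
               "multiple of 3")
  # terminus trimming masks 10 codons at each end
  a100 <- build_codon_alignment("g", s100, s100, s100, coverage = 1)
  expect_equal(sum(!a100$keep), 20)
  expect_false(any(a100$keep[c(1:10, 91:100)]))
})

test_that("parsimony lineage assignment follows the three-state patterns", {
  r <- assign_lineage_specific(c("A", "G", "A", "G"),
                               c("G", "G", "G", "G"),
                               c("G", "C", "C", "G"))
  expect_equal(as.vector(r), c("Og", "none", "ambiguous", "none"))
  # missing data is skipped and counted
  r2 <- assign_lineage_specific(c("A", NA), c("G", "A"), c("G", "A"))
  expect_equal(attr(r2, "n_skipped"), 1)
  # swapping the two ingroup taxa swaps the assigned counts
  set.seed(8)
  og <- sample(c("A", "C", "G", "T"), 200, TRUE)
  osj <- og; osj[sample(200, 30)] <- sample(c("A", "C", "G", "T"), 30, TRUE)
  out <- og; out[sample(200, 15)] <- sample(c("A", "C", "G", "T"), 15, TRUE)
  a <- assign_lineage_specific(og, osj, out)
  b <- assign_lineage_specific(osj, og, out)
  expect_equal(sum(a == "Og", na.rm = TRUE), sum(b == "Osj", na.rm = TRUE))
  expect_equal(sum(a == "Osj", na.rm = TRUE), sum(b == "Og", na.rm = TRUE))
})

test_that("property schemes partition the 20 amino acids", {
  for (nm in c("charge", "polarity", "volume", "hydropathy")) {
    sc <- property_scheme(nm)
    expect_setequal(names(sc$classes),
                    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  }
  # D and E share the negative-charge class
  sc <- property_scheme("charge")
  expect_equal(unname(sc$classes["D"]), unname(sc$classes["E"]))
})

test_that("property-change test builds the right table and degenerates to G=0", {
  subs <- data.frame(lineage = c("Og", "Og", "Osj", "Osj"),
                     from = c("D", "K", "D", "A"),
                     to = c("E", "D", "E", "V"))
  r <- property_change_test(subs, property_scheme("charge"))
  # D->E preserving, K->D changing, D->E preserving, A->V preserving
  expect_equal(as.vector(r$table), c(1, 2, 1, 0))
  one_class <- as_property_scheme("all", list(
    all = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  r0 <- property_change_test(subs, one_class)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("scheme files load from flat key-value format", {
  f <- tempfile()
  writeLines(c("# charge partition", "positive = KRH", "negative = DE",
               "neutral = ACFGILMNPQSTVWY"), f)
  sc <- read_property_scheme(f, "custom")
  expect_equal(unname(sc$classes["K"]), "positive")
  expect_error(read_property_scheme({
    writeLines(c("a = KR", "b = DE"), f); f
  }), "partition")
})

test_that("gamma-Poisson distance matches the closed form and its limit", {
  expect_equal(gamma_poisson_distance(0), 0)
  expect_equal(gamma_poisson_distance(0.1, a = 2.25), 0.107866,
               tolerance = 1e-5)
  expect_equal(gamma_poisson_distance(0.2, a = 1e6), -log(0.8),
               tolerance = 1e-4)
  p <- seq(0, 0.8, by = 0.05)
  expect_true(all(diff(gamma_poisson_distance(p)) > 0))
  expect_error(gamma_poisson_distance(1), "saturation")
})

test_that("site counts follow the weighted scheme and sum to 3L", {
  # ATG admits no synonymous change
  expect_equal(mng_site_counts("ATG", mng_params(R = 2))$S, 0)
  # TTT at R = 1: only position-3 transition T->C is synonymous
  expect_equal(mng_site_counts("TTT", mng_params(R = 1))$S, 1 / 3)
  # at R = 2 the transition weight rises to 2/4
  expect_equal(mng_site_counts("TTT", mng_params(R = 2))$S, 2 / 4)
  set.seed(3)
  for (R in c(0.5, 1, 3.44)) {
    cods <- rand_codons(50)
    sc <- mng_site_counts(cods, mng_params(R = R))
    # stop-change weights are excluded from both S and N
    expect_equal(sc$S + sc$N + sc$S_stop, 150)
    expect_gte(sc$S_stop, 0)
  }
  expect_error(mng_site_counts("TAA"), "non-sense")
})

test_that("R = 1 reproduces unmodified Nei-Gojobori site counts", {
  set.seed(4)
  cods <- rand_codons(200)
  sc <- mng_site_counts(cods, mng_params(R = 1))
  oracle <- ng86_sites_oracle(cods)
  expect_equal(sc$S, unname(oracle["S"]), tolerance = 1e-12)
})

test_that("pairwise difference counting averages over pathways", {
  r <- suppressWarnings(mng_pairwise("TTT", "TTC", mng_params(R = 1)))
  expect_equal(c(r$Sd, r$Nd), c(1, 0))
  # two-step pathways enumerated by the independent oracle
  r2 <- suppressWarnings(mng_pairwise("TTT", "TCC", mng_params(R = 1)))
  o2 <- pathway_oracle("TTT", "TCC")
  expect_equal(c(r2$Sd, r2$Nd), unname(o2[c("sd", "nd")]))
  expect_equal(c(r2$Sd, r2$Nd), c(1, 1))
  r0 <- mng_pairwise(c("ATG", "AAA"), c("ATG", "AAA"))
  expect_equal(c(r0$Sd, r0$Nd, r0$dS, r0$dN), c(0, 0, 0, 0))
})

test_that("pathway counts equal exhaustive enumeration on sampled codon pairs", {
  set.seed(6)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  pairs <- cbind(sample(sense, 120, TRUE), sample(sense, 120, TRUE))
  for (i in seq_len(nrow(pairs))) {
    got <- oryzaevol:::codon_pair_subs(pairs[i, 1], pairs[i, 2])
    want <- pathway_oracle(pairs[i, 1], pairs[i, 2])
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("three-taxon least squares solves branch lengths exactly", {
  b <- ls_branch_lengths(0.2, 0.3, 0.4)$b
  expect_equal(unname(b), c(0.05, 0.15, 0.25))
  # all pairwise distances equal 2x: all branches x
  b2 <- ls_branch_lengths(0.3, 0.3, 0.3)$b
  expect_equal(unname(b2), rep(0.15, 3))
  # additive planted distances recovered exactly
  set.seed(9)
  for (i in 1:20) {
    t <- runif(3, 0, 0.5)
    fit <- ls_branch_lengths(t[1] + t[2], t[1] + t[3], t[2] + t[3])
    expect_equal(unname(fit$b), t, tolerance = 1e-12)
    expect_false(fit$clamped)
  }
  # triangle violation clamps with a flag
  expect_warning(fit <- ls_branch_lengths(0.1, 0.5, 0.1), "clamped")
  expect_true(fit$clamped)
  expect_true(all(fit$b >= 0))
})

test_that("lineage dN/dS handles identical sequences and recovers a panel", {
  s <- rand_codons(120)
  alns <- list(build_codon_alignment("g1", s, s, s, 1,
                                     alignment_filter(1, 0.001, 0)),
               build_codon_alignment("g2", s, s, s, 1,
                                     alignment_filter(1, 0.001, 0)))
  r <- lineage_dnds(alns, n_replicates = 5, seed = 1)
  expect_true(all(is.na(r$omega)))      # zero branches: omega undefined
  expect_null(r$gtest)
  # small smoke panel: omega estimable and positive
  p <- simulate_codon_panel(n_genes = 150, n_codons = 100, seed = 14)
  res <- lineage_dnds(p$alignments, mng_params(R = 3.44),
                      n_replicates = 20, seed = 2)
  expect_true(all(res$omega > 0))
  expect_true(all(res$omega < 1))
  expect_true(all(is.finite(res$omega_sd)))
})

test_that("amino-acid branch lengths and the rate test come from parsimony", {
  p <- simulate_codon_panel(n_genes = 150, n_codons = 100, seed = 15)
  aa <- aa_branch_lengths(p$alignments, a = 2.25)
  expect_true(all(aa$b >= 0))
  expect_gt(aa$b["o"], aa$b["x"])       # outgroup branch is much longer
  expect_equal(sum(aa$lineage_counts),
               nrow(aa$substitutions))
  expect_s3_class(aa$tajima, "evol_test")
})

test_that("mutual best hits are symmetric", {
  sc <- data.frame(query = c("a", "a", "b", "b"),
                   subject = c("x", "y", "x", "y"),
                   score = c(10, 5, 4, 8))
  mb <- mutual_best_hits(sc)
  expect_equal(nrow(mb), 2)
  expect_setequal(paste(mb$query, mb$subject), c("a x", "b y"))
})
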