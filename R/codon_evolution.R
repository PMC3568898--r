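# Three-taxon codon alignments, parsimony lineage assignment,
# amino-acid-property change tests, and per-lineage dN/dS.

#' Filters for three-taxon codon alignments
#'
#' @param min_aa Minimum aligned amino-acid length (an alignment passes if
#'   it reaches this length OR exceeds `min_coverage`).
#' @param min_coverage Minimum coverage fraction of the reference protein
#'   (strictly greater than).
#' @param trim_termini_aa Number of amino acids at each terminus excluded
#'   from substitution counting (misalignment guard).
#' @return A list of class `alignment_filter`.
#' @export
alignment_filter <- function(min_aa = 100L, min_coverage = 0.70,
                             trim_termini_aa = 10L) {
  stopifnot(min_aa >= 1, min_coverage > 0, min_coverage <= 1,
            trim_termini_aa >= 0)
  structure(list(min_aa = as.integer(min_aa), min_coverage = min_coverage,
                 trim_termini_aa = as.integer(trim_termini_aa)),
            class = "alignment_filter")
}

#' Build (and filter) a three-taxon codon alignment
#'
#' Integrates codon sequences of the japonica reference (`osj`), African
#' rice (`og`) and the outgroup, keyed on the Osj reading frame. The
#' alignment is rejected if the Og or outgroup sequence contains a gap
#' character or a premature stop codon, or if it is shorter than `min_aa`
#' amino acids with coverage not exceeding `min_coverage`. The
#' `trim_termini_aa` codons at each end are flagged for exclusion from
#' substitution counting via the logical `keep` mask.
#'
#' @param gene_id Gene identifier.
#' @param osj,og,outgroup Aligned coding sequences (DNA strings of equal
#'   length, multiple of 3, or codon vectors). A terminal stop codon on all
#'   taxa is tolerated and dropped.
#' @param coverage Fraction of the reference protein covered.
#' @param filter An [alignment_filter()].
#' @return A list of class `codon_alignment` with elements `gene_id`,
#'   `codons` (3-row character matrix: osj, og, outgroup), `keep`,
#'   `coverage`; or `NULL` when the alignment is rejected by a filter.
#' @export
build_codon_alignment <- function(gene_id, osj, og, outgroup, coverage = 1,
                                  filter = alignment_filter()) {
  to_codons <- function(x) {
    if (length(x) == 1L) {
      if (nchar(x) %% 3L != 0L)
        stop("malformed annotation: CDS length not a multiple of 3 (",
             gene_id, ")")
      split_codons(toupper(x))
    } else toupper(x)
  }
  seqs <- lapply(list(osj = osj, og = og, outgroup = outgroup), to_codons)
  L <- unique(lengths(seqs))
  if (length(L) != 1L) stop("taxa differ in aligned length (", gene_id, ")")
  reject <- function(reason) NULL
  if (any(grepl("-", unlist(seqs), fixed = TRUE))) {
    return(reject("gap in Og or outgroup sequence"))
  }
  # Drop a shared terminal stop, then reject on any remaining stop.
  aa <- lapply(seqs, translate_codons)
  if (all(vapply(aa, function(x) x[L] == "*", logical(1)))) {
    seqs <- lapply(seqs, function(x) x[-L])
    aa <- lapply(aa, function(x) x[-L])
    L <- L - 1L
  }
  if (any(vapply(aa[c("og", "outgroup")], function(x) any(x == "*"),
                 logical(1)))) {
    return(reject("premature stop codon"))
  }
  if (!(L >= filter$min_aa || coverage > filter$min_coverage)) {
    return(reject("too short and coverage too low"))
  }
  keep <- rep(TRUE, L)
  t <- filter$trim_termini_aa
  if (t > 0 && L > 0) {
    keep[seq_len(min(t, L))] <- FALSE
    keep[seq.int(max(1L, L - t + 1L), L)] <- FALSE
  }
  structure(list(gene_id = gene_id,
                 codons = rbind(osj = seqs$osj, og = seqs$og,
                                outgroup = seqs$outgroup),
                 keep = keep, coverage = coverage),
            class = "codon_alignment")
}

#' Parsimony assignment of lineage-specific substitutions
#'
#' For site states of African rice (`og`), japonica (`osj`) and the
#' outgroup (residues, codons, or nucleotides): a site where Og alone
#' differs while Osj equals the outgroup is an Og-specific substitution,
#' and symmetrically for Osj. Sites where Og equals Osj (including changes
#' on the outgroup or internal branch) are unassigned (`"none"`); sites
#' where all three states differ are `"ambiguous"`.
#'
#' @param og,osj,outgroup Equal-length character vectors of states; `NA`
#'   marks missing data and the site is skipped.
#' @return Character vector with values `"Og"`, `"Osj"`, `"none"`,
#'   `"ambiguous"`, or `NA` for skipped sites; the number skipped is
#'   attached as attribute `n_skipped`.
#' @export
assign_lineage_specific <- function(og, osj, outgroup) {
  stopifnot(length(og) == length(osj), length(osj) == length(outgroup))
  out <- rep(NA_character_, length(og))
  miss <- is.na(og) | is.na(osj) | is.na(outgroup)
  i <- !miss
  out[i & og == osj] <- "none"
  out[i & og != osj & osj == outgroup] <- "Og"
  out[i & og != osj & og == outgroup] <- "Osj"
  out[i & og != osj & og != outgroup & osj != outgroup] <- "ambiguous"
  attr(out, "n_skipped") <- sum(miss)
  out
}

#' Amino-acid property classification schemes
#'
#' Four default partitions of the 20 amino acids into named property
#' classes: side-chain charge, polarity, volume, and hydropathy. These are
#' documented defaults; alternative published partitions can be supplied as
#' a named list mapping class names to residue vectors, or loaded from a
#' key-value file with [read_property_scheme()].
#'
#' @param name One of `"charge"`, `"polarity"`, `"volume"`,
#'   `"hydropathy"`.
#' @return A list of class `property_scheme` with `name` and `classes`
#'   (named character vector mapping residue -> class).
#' @export
property_scheme <- function(name = c("charge", "polarity", "volume",
                                     "hydropathy")) {
  name <- match.arg(name)
  defs <- list(
    charge = list(positive = c("K", "R", "H"), negative = c("D", "E"),
                  uncharged = c("A", "C", "F", "G", "I", "L", "M", "N", "P",
                                "Q", "S", "T", "V", "W", "Y")),
    polarity = list(polar = c("R", "N", "D", "C", "E", "Q", "H", "K", "S",
                              "T", "Y"),
                    nonpolar = c("A", "G", "I", "L", "M", "F", "P", "W",
                                 "V")),
    volume = list(small = c("G", "A", "S", "C", "T", "P", "D", "N"),
                  large = c("E", "Q", "H", "K", "R", "V", "I", "L", "M",
                            "F", "Y", "W")),
    hydropathy = list(hydrophobic = c("A", "C", "F", "I", "L", "M", "V"),
                      neutral = c("G", "H", "P", "S", "T", "W", "Y"),
                      hydrophilic = c("D", "E", "K", "N", "Q", "R"))
  )
  as_property_scheme(name, defs[[name]])
}

#' @rdname property_scheme
#' @param classes Named list mapping class names to residue vectors; must
#'   partition the 20 amino acids.
#' @export
as_property_scheme <- function(name, classes) {
  residues <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(residues) || length(residues) != 20L ||
      !setequal(residues, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
    stop("property classes must partition the 20 amino acids")
  }
  map <- rep(names(classes), lengths(classes))
  names(map) <- residues
  structure(list(name = name, classes = map), class = "property_scheme")
}

#' Read a property scheme from a flat key-value file
#'
#' Format: one line per class, `class_name = RESIDUES` (e.g.
#' `positive = KRH`). Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param name Scheme name (defaults to the file name).
#' @return A `property_scheme`.
#' @export
read_property_scheme <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  parts <- strsplit(lines, "\\s*=\\s*")
  classes <- lapply(parts, function(p) strsplit(toupper(p[2]), "")[[1]])
  names(classes) <- vapply(parts, `[[`, character(1), 1L)
  as_property_scheme(name, classes)
}

#' G-test of property-changing vs property-preserving substitutions
#'
#' Builds the 2x2 table lineage x {class-preserving, class-changing} from a
#' set of lineage-labelled ordered residue substitutions and applies
#' [gtest_2x2()].
#'
#' @param substitutions Data frame with columns `lineage` (two levels,
#'   e.g. `"Og"`/`"Osj"`), `from`, `to` (single residues).
#' @param scheme A [property_scheme()].
#' @param williams_correction Passed to [gtest_2x2()].
#' @return An `evol_test` with the table attached as element `table`.
#' @export
property_change_test <- function(substitutions, scheme,
                                 williams_correction = FALSE) {
  stopifnot(all(c("lineage", "from", "to") %in% names(substitutions)))
  lin <- unique(substitutions$lineage)
  if (length(lin) != 2L) stop("insufficient data: need exactly two lineages")
  cls <- scheme$classes
  changing <- cls[substitutions$from] != cls[substitutions$to]
  counts <- table(factor(substitutions$lineage, levels = lin),
                  factor(changing, levels = c(FALSE, TRUE)))
  res <- if (any(colSums(counts) == 0)) {
    # degenerate: every substitution preserves (or changes) class in both
    # lineages, so the proportions are trivially equal
    new_test_result(0, 1L, 1, method = "G-test", correction = FALSE)
  } else {
    gtest_2x2(contingency_2x2(counts[1, 1], counts[1, 2],
                              counts[2, 1], counts[2, 2]),
              williams_correction = williams_correction)
  }
  res$scheme <- scheme$name
  res$table <- counts
  res
}

# Per-gene sufficient statistics for lineage dN/dS: pathway-averaged
# difference counts and site counts for the three pairs.
gene_pair_stats <- function(aln, params) {
  m <- aln$codons[, aln$keep, drop = FALSE]
  pairs <- list(osj_og = c("osj", "og"),
                osj_out = c("osj", "outgroup"),
                og_out = c("og", "outgroup"))
  out <- list(gene_id = aln$gene_id)
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    sx <- mng_site_counts(m[p[1], ], params)
    sy <- mng_site_counts(m[p[2], ], params)
    diff <- which(m[p[1], ] != m[p[2], ])
    Sd <- 0; Nd <- 0
    for (i in diff) {
      r <- codon_pair_subs(m[p[1], i], m[p[2], i])
      if (r[["n_pathways"]] > 0) {
        Sd <- Sd + r[["sd"]]; Nd <- Nd + r[["nd"]]
      }
    }
    out[[paste0(nm, "_Sd")]] <- Sd
    out[[paste0(nm, "_Nd")]] <- Nd
    out[[paste0(nm, "_S")]] <- (sx$S + sy$S) / 2
    out[[paste0(nm, "_N")]] <- (sx$N + sy$N) / 2
  }
  cnt <- lineage_substitution_counts(aln)
  out$lin_Og_Sd <- cnt[["Og_Sd"]]; out$lin_Og_Nd <- cnt[["Og_Nd"]]
  out$lin_Osj_Sd <- cnt[["Osj_Sd"]]; out$lin_Osj_Nd <- cnt[["Osj_Nd"]]
  out
}

#' Lineage-specific synonymous/nonsynonymous substitution counts
#'
#' Assigns each codon column of a three-taxon alignment to a lineage by
#' parsimony and accumulates pathway-averaged synonymous and
#' nonsynonymous difference counts between the derived codon and the
#' shared (ancestral) state.
#'
#' @param aln A `codon_alignment`.
#' @return Named numeric vector `Og_Nd`, `Og_Sd`, `Osj_Nd`, `Osj_Sd`.
#' @export
lineage_substitution_counts <- function(aln) {
  m <- aln$codons[, aln$keep, drop = FALSE]
  lin <- assign_lineage_specific(m["og", ], m["osj", ], m["outgroup", ])
  cnt <- c(Og_Nd = 0, Og_Sd = 0, Osj_Nd = 0, Osj_Sd = 0)
  for (taxon in c("Og", "Osj")) {
    idx <- which(!is.na(lin) & lin == taxon)
    row <- if (taxon == "Og") "og" else "osj"
    for (i in idx) {
      anc <- m["outgroup", i]          # shared state of the other two
      r <- codon_pair_subs(anc, m[row, i])
      if (r[["n_pathways"]] > 0) {
        cnt[[paste0(taxon, "_Sd")]] <- cnt[[paste0(taxon, "_Sd")]] + r[["sd"]]
        cnt[[paste0(taxon, "_Nd")]] <- cnt[[paste0(taxon, "_Nd")]] + r[["nd"]]
      }
    }
  }
  cnt
}

# Concatenated (summed) stats -> per-lineage dN/dS via least squares.
omega_from_stats <- function(stats_df) {
  d <- list()
  for (nm in c("osj_og", "osj_out", "og_out")) {
    S <- sum(stats_df[[paste0(nm, "_S")]])
    N <- sum(stats_df[[paste0(nm, "_N")]])
    d[[paste0(nm, "_dS")]] <- jukes_cantor(sum(stats_df[[paste0(nm, "_Sd")]]) / S)
    d[[paste0(nm, "_dN")]] <- jukes_cantor(sum(stats_df[[paste0(nm, "_Nd")]]) / N)
  }
  # x = Og, y = Osj in the three-taxon solution; clamping is reported via
  # the flag rather than per-call warnings (bootstrap replicates would
  # otherwise flood the console)
  fS <- suppressWarnings(ls_branch_lengths(d$osj_og_dS, d$og_out_dS,
                                           d$osj_out_dS))
  fN <- suppressWarnings(ls_branch_lengths(d$osj_og_dN, d$og_out_dN,
                                           d$osj_out_dN))
  bS <- fS$b; bN <- fN$b
  omega <- c(Og = unname(if (bS["x"] > 0) bN["x"] / bS["x"] else NA_real_),
             Osj = unname(if (bS["y"] > 0) bN["y"] / bS["y"] else NA_real_))
  list(distances = d, bS = bS, bN = bN, omega = omega,
       clamped = fS$clamped || fN$clamped)
}

#' Per-lineage dN/dS with bootstrap standard deviations
#'
#' Concatenates pathway-averaged synonymous and nonsynonymous counts over
#' genes for the three taxon pairs, converts them to Jukes-Cantor-corrected
#' distances, solves the three-taxon least-squares branch lengths for dS
#' and dN separately, and reports per-lineage `omega = bN / bS` for the Og
#' and Osj branches with bootstrap standard deviations over genes. Also
#' counts parsimony lineage-specific synonymous and nonsynonymous
#' substitutions and applies a G-test to the 2x2 lineage x {N, S} table.
#'
#' @param alignments List of `codon_alignment` objects (>= 2).
#' @param params An [mng_params()].
#' @param n_replicates,seed Bootstrap configuration (genes are the
#'   resampling unit).
#' @return A list with `omega`, `omega_sd`, `bS`, `bN`, `distances`,
#'   `counts` (lineage-specific Sd/Nd per lineage), `gtest` (an
#'   `evol_test`), and `per_gene` (the per-gene statistics data frame).
#' @export
lineage_dnds <- function(alignments, params = mng_params(),
                         n_replicates = 1000L, seed = 1L) {
  if (length(alignments) < 2L) stop("need >= 2 alignments")
  per_gene <- do.call(rbind, lapply(alignments, function(a) {
    as.data.frame(gene_pair_stats(a, params))
  }))
  fit <- omega_from_stats(per_gene)
  if (isTRUE(fit$clamped)) {
    warning("negative least-squares branch length(s) clamped to zero")
  }
  counts <- c(Og_Nd = sum(per_gene$lin_Og_Nd), Og_Sd = sum(per_gene$lin_Og_Sd),
              Osj_Nd = sum(per_gene$lin_Osj_Nd),
              Osj_Sd = sum(per_gene$lin_Osj_Sd))
  gt <- if (all(round(counts) > 0)) {
    gtest_2x2(contingency_2x2(round(counts["Og_Nd"]), round(counts["Og_Sd"]),
                              round(counts["Osj_Nd"]),
                              round(counts["Osj_Sd"])))
  } else NULL
  sd_og <- bootstrap_sd(per_gene, function(d) omega_from_stats(d)$omega["Og"],
                        n_replicates = n_replicates, seed = seed)
  sd_osj <- bootstrap_sd(per_gene, function(d) omega_from_stats(d)$omega["Osj"],
                         n_replicates = n_replicates, seed = seed + 1L)
  list(omega = fit$omega,
       omega_sd = c(Og = as.numeric(sd_og), Osj = as.numeric(sd_osj)),
       bS = fit$bS, bN = fit$bN, distances = fit$distances,
       counts = counts, gtest = gt, per_gene = per_gene)
}

#' Amino-acid branch lengths from three-taxon alignments
#'
#' Computes pairwise amino-acid p-distances over the concatenated
#' (terminus-trimmed) alignment columns, corrects them with the
#' gamma-Poisson distance of shape `a`, and solves the three-taxon
#' least-squares branch lengths. Lineage-specific amino-acid substitutions
#' are counted by parsimony and compared with Tajima's relative-rate test.
#'
#' @param alignments List of `codon_alignment` objects.
#' @param a Gamma shape parameter (default 2.25).
#' @return A list with `b` (branch lengths: `x` = Og, `y` = Osj, `o` =
#'   outgroup), `p` (pairwise p-distances), `n_sites`, `lineage_counts`
#'   (named Og/Osj amino-acid substitution counts), `n_variable_sites`,
#'   `tajima` (an `evol_test`), and `substitutions` (data frame of
#'   lineage-labelled residue changes for property tests).
#' @export
aa_branch_lengths <- function(alignments, a = 2.25) {
  cols <- lapply(alignments, function(al) {
    m <- al$codons[, al$keep, drop = FALSE]
    apply(m, 1, translate_codons)      # L x 3 matrix
  })
  aa <- do.call(rbind, cols)
  n <- nrow(aa)
  p_xy <- mean(aa[, "og"] != aa[, "osj"])
  p_xo <- mean(aa[, "og"] != aa[, "outgroup"])
  p_yo <- mean(aa[, "osj"] != aa[, "outgroup"])
  d <- vapply(c(p_xy, p_xo, p_yo), gamma_poisson_distance, numeric(1), a = a)
  b <- ls_branch_lengths(d[1], d[2], d[3])$b
  lin <- assign_lineage_specific(aa[, "og"], aa[, "osj"], aa[, "outgroup"])
  n_og <- sum(lin == "Og", na.rm = TRUE)
  n_osj <- sum(lin == "Osj", na.rm = TRUE)
  variable <- sum(lin %in% c("Og", "Osj", "ambiguous") |
                    (lin == "none" & aa[, "og"] != aa[, "outgroup"]),
                  na.rm = TRUE)
  subs <- rbind(
    data.frame(lineage = rep("Og", n_og),
               from = aa[which(lin == "Og"), "outgroup"],
               to = aa[which(lin == "Og"), "og"]),
    data.frame(lineage = rep("Osj", n_osj),
               from = aa[which(lin == "Osj"), "outgroup"],
               to = aa[which(lin == "Osj"), "osj"])
  )
  list(b = b, p = c(og_osj = p_xy, og_out = p_xo, osj_out = p_yo),
       n_sites = n,
       lineage_counts = c(Og = n_og, Osj = n_osj),
       n_variable_sites = variable,
       tajima = if (n_og + n_osj > 0) tajima_rrt(n_og, n_osj) else NULL,
       substitutions = subs)
}

#' Toy mutual-best-hit ortholog assignment
#'
#' Given a similarity score table between two gene sets, returns the pairs
#' that are each other's best hit. Intended for synthetic data; real
#' ortholog tables are accepted as input elsewhere.
#'
#' @param scores Data frame with columns `query`, `subject`, `score`.
#' @return Data frame with columns `query`, `subject` of mutual best hits.
#' @export
mutual_best_hits <- function(scores) {
  stopifnot(all(c("query", "subject", "score") %in% names(scores)))
  best_q <- scores[order(scores$query, -scores$score), ]
  best_q <- best_q[!duplicated(best_q$query), ]
  best_s <- scores[order(scores$subject, -scores$score), ]
  best_s <- best_s[!duplicated(best_s$subject), ]
  key_q <- paste(best_q$query, best_q$subject)
  key_s <- paste(best_s$query, best_s$subject)
  hit <- best_q[key_q %in% key_s, c("query", "subject")]
  rownames(hit) <- NULL
  hit
}
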