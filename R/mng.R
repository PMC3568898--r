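# Modified Nei-Gojobori synonymous / nonsynonymous counting with pathway
# averaging, Jukes-Cantor correction, and the gamma-Poisson amino-acid
# distance.

#' Parameters for the modified Nei-Gojobori method
#'
#' The modified method weights each potential transition by `R/(R+2)` and
#' each potential transversion by `1/(R+2)` when counting synonymous and
#' nonsynonymous sites, where `R` is the transition/transversion *rate*
#' ratio (the relative rate of the single transitional change at a site
#' against either one of its two transversional changes). `R = 1` recovers
#' the unmodified Nei-Gojobori site counts. Because every site has one
#' transitional and two transversional neighbours, an observed
#' transition/transversion *count* ratio of 1.72 - the genome-wide value
#' between the African and Asian rice genomes - corresponds to
#' `R = 2 * 1.72 = 3.44`, the default.
#'
#' @param R Positive transition/transversion rate-ratio weight.
#' @return A list of class `mng_params`.
#' @export
mng_params <- function(R = 3.44) {
  stopifnot(is.numeric(R), length(R) == 1L, R > 0)
  structure(list(R = R), class = "mng_params")
}

# Per-codon site fractions for a given R, over the three positions: each
# position contributes weight R/(R+2) for its transition neighbour and
# 1/(R+2) for each transversion neighbour. `syn` sums weights of
# synonymous changes, `stop` those of changes creating a stop codon;
# the nonsynonymous fraction is the remainder. Stop-creating changes are
# excluded from both S and N: the mutational opportunity they represent
# cannot be realized in protein-coding sequence, and counting it as
# nonsynonymous deflates dN (and hence dN/dS) by the stop share, about 5%
# at R = 3.44.
mng_syn_fraction_table <- function(R) {
  key <- paste0("synfrac_", format(R, digits = 15))
  if (!is.null(codon_table_env[[key]])) return(codon_table_env[[key]])
  gc <- genetic_code()
  codons <- names(gc)
  w_ts <- R / (R + 2)
  w_tv <- 1 / (R + 2)
  s <- z <- numeric(length(codons))
  names(s) <- names(z) <- codons
  for (cod in codons) {
    if (gc[[cod]] == "*") { s[[cod]] <- NA_real_; z[[cod]] <- NA_real_; next }
    tot <- 0; tot_stop <- 0
    for (pos in 1:3) {
      from <- substr(cod, pos, pos)
      for (to in setdiff(BASES, from)) {
        mut <- codon_set(cod, pos, to)
        w <- if (classify_substitution(from, to) == "transition") w_ts
             else w_tv
        if (gc[[mut]] == "*") tot_stop <- tot_stop + w
        else if (gc[[mut]] == gc[[cod]]) tot <- tot + w
      }
    }
    s[[cod]] <- tot
    z[[cod]] <- tot_stop
  }
  codon_table_env[[key]] <- list(syn = s, stop = z)
  codon_table_env[[key]]
}

#' Synonymous and nonsynonymous site counts of a codon sequence
#'
#' Potential sites are weighted by transition/transversion class (see
#' [mng_params()]). Changes that would create a stop codon are excluded
#' from both the synonymous and the nonsynonymous site counts, so
#' `S + N = 3L - S_stop` where `S_stop` is the (small) stop-change weight
#' reported alongside.
#'
#' @param codons Character vector of sense codons (or a DNA string whose
#'   length is a multiple of 3).
#' @param params An [mng_params()] object.
#' @return A list with elements `S` (synonymous sites), `N`
#'   (nonsynonymous sites), `S_stop` (excluded stop-change weight) and
#'   `per_codon` (synonymous site fraction per codon).
#' @examples
#' mng_site_counts(c("TTT", "ATG"), mng_params(R = 1))
#' @export
mng_site_counts <- function(codons, params = mng_params()) {
  if (length(codons) == 1L && nchar(codons) > 3L) codons <- split_codons(codons)
  codons <- toupper(codons)
  tab <- mng_syn_fraction_table(params$R)
  s <- tab$syn[codons]
  z <- tab$stop[codons]
  if (anyNA(s)) stop("non-sense codon in sequence: ",
                     paste(unique(codons[is.na(s)]), collapse = ", "))
  S <- sum(s)
  Z <- sum(z)
  list(S = S, N = 3 * length(codons) - S - Z, S_stop = Z,
       per_codon = unname(s))
}

# Pathway-averaged (Sd, Nd) between two codons differing at k positions.
# All k! substitution orders are enumerated; a pathway is discarded if any
# step passes through a stop codon. Returns c(sd, nd, n_pathways); if every
# pathway is blocked n_pathways = 0 and sd = nd = 0.
codon_pair_subs <- function(c1, c2) {
  key <- paste0("pair_", c1, "_", c2)
  if (!is.null(codon_table_env[[key]])) return(codon_table_env[[key]])
  gc <- genetic_code()
  pos <- codon_diff_positions(c1, c2)
  k <- length(pos)
  res <- if (k == 0L) {
    c(sd = 0, nd = 0, n_pathways = 1)
  } else {
    perms <- permutations_of(pos)
    sd_tot <- 0; nd_tot <- 0; n_ok <- 0L
    for (ord in perms) {
      cur <- c1
      sd <- 0L; nd <- 0L; ok <- TRUE
      for (p in ord) {
        nxt <- codon_set(cur, p, substr(c2, p, p))
        if (gc[[nxt]] == "*") { ok <- FALSE; break }
        if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1L else nd <- nd + 1L
        cur <- nxt
      }
      if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_ok <- n_ok + 1L }
    }
    if (n_ok == 0L) c(sd = 0, nd = 0, n_pathways = 0)
    else c(sd = sd_tot / n_ok, nd = nd_tot / n_ok, n_pathways = n_ok)
  }
  codon_table_env[[key]] <- res
  res
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Jukes-Cantor correction of a proportion of differing sites
#'
#' @param p Proportion in `[0, 3/4)`.
#' @return `-(3/4) * log(1 - (4/3) * p)`.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0)) stop("proportion must be non-negative")
  if (any(p >= 0.75)) stop("correction saturates: proportion >= 3/4")
  -0.75 * log(1 - (4 / 3) * p)
}

#' Pairwise synonymous and nonsynonymous distances (modified Nei-Gojobori)
#'
#' Counts synonymous and nonsynonymous differences between two in-frame
#' codon sequences by averaging over all substitution pathways (excluding
#' pathways through stop codons), divides by the average site counts of the
#' two sequences, and applies the Jukes-Cantor correction.
#'
#' @param seq_x,seq_y Equal-length character vectors of sense codons (or
#'   DNA strings).
#' @param params An [mng_params()] object.
#' @return A list with `Sd`, `Nd` (pathway-averaged difference counts),
#'   `S`, `N` (averaged site counts), `pS`, `pN`, `dS`, `dN`, and
#'   `n_skipped` (codon pairs with all pathways blocked by stop codons).
#' @examples
#' mng_pairwise("TTTATG", "TTCATG", mng_params(R = 1))
#' @export
mng_pairwise <- function(seq_x, seq_y, params = mng_params()) {
  if (length(seq_x) == 1L && nchar(seq_x) > 3L) seq_x <- split_codons(seq_x)
  if (length(seq_y) == 1L && nchar(seq_y) > 3L) seq_y <- split_codons(seq_y)
  seq_x <- toupper(seq_x); seq_y <- toupper(seq_y)
  if (length(seq_x) != length(seq_y)) stop("sequences differ in codon length")
  sx <- mng_site_counts(seq_x, params)
  sy <- mng_site_counts(seq_y, params)
  S <- (sx$S + sy$S) / 2
  N <- (sx$N + sy$N) / 2
  diff <- which(seq_x != seq_y)
  Sd <- 0; Nd <- 0; n_skipped <- 0L
  for (i in diff) {
    r <- codon_pair_subs(seq_x[i], seq_y[i])
    if (r[["n_pathways"]] == 0) { n_skipped <- n_skipped + 1L; next }
    Sd <- Sd + r[["sd"]]; Nd <- Nd + r[["nd"]]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  saturated <- pS >= 0.75 || pN >= 0.75
  if (saturated) warning("Jukes-Cantor correction saturates; dS/dN set NA")
  list(Sd = Sd, Nd = Nd, S = S, N = N, pS = pS, pN = pN,
       dS = if (pS < 0.75) jukes_cantor(pS) else NA_real_,
       dN = if (pN < 0.75) jukes_cantor(pN) else NA_real_,
       saturated = saturated, n_skipped = n_skipped)
}

#' Gamma-corrected Poisson amino-acid distance
#'
#' Converts a proportion `p` of differing amino-acid sites into a distance
#' under a Poisson process with gamma-distributed rate variation of shape
#' `a`: `d = a * ((1 - p)^(-1/a) - 1)`. As `a` grows the ordinary Poisson
#' correction `-ln(1 - p)` is recovered. The default shape `a = 2.25`
#' matches the value used for the rice amino-acid branch lengths.
#'
#' @param p Proportion of differing sites, in `[0, 1)`.
#' @param a Positive gamma shape parameter.
#' @return The corrected distance (non-negative).
#' @examples
#' gamma_poisson_distance(0.1, a = 2.25)
#' @export
gamma_poisson_distance <- function(p, a = 2.25) {
  stopifnot(is.numeric(a), a > 0)
  if (any(p < 0)) stop("proportion must be non-negative")
  if (any(p >= 1)) stop("saturation: proportion must be < 1")
  a * ((1 - p)^(-1 / a) - 1)
}

#' Three-taxon least-squares branch lengths
#'
#' For three taxa the least-squares solution on an unrooted star tree is
#' exact: `b_x = (d_xy + d_xo - d_yo) / 2` and symmetrically for the other
#' branches. Negative solutions (non-additive distances) are clamped to
#' zero and flagged.
#'
#' @param d_xy,d_xo,d_yo Pairwise distances between taxa x, y and
#'   outgroup o.
#' @return A list with `b` (named vector of branch lengths `x`, `y`, `o`)
#'   and `clamped` (logical, any branch clamped to zero).
#' @examples
#' ls_branch_lengths(0.2, 0.3, 0.4)
#' @export
ls_branch_lengths <- function(d_xy, d_xo, d_yo) {
  stopifnot(d_xy >= 0, d_xo >= 0, d_yo >= 0)
  b <- c(x = (d_xy + d_xo - d_yo) / 2,
         y = (d_xy + d_yo - d_xo) / 2,
         o = (d_xo + d_yo - d_xy) / 2)
  clamped <- any(b < 0)
  if (clamped) {
    warning("negative branch length(s) clamped to zero")
    b[b < 0] <- 0
  }
  list(b = b, clamped = clamped)
}
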