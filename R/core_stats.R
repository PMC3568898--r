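#' Build and validate a 2x2 contingency table
#'
#' Counts are arranged with rows as groups (e.g. mapped vs unmapped
#' sequences, or non-transcribed vs protein-coding regions) and columns as
#' outcomes (e.g. with vs without a domain, length-polymorphic vs
#' sequence-polymorphic).
#'
#' @param a,b,c,d Non-negative counts: first row `(a, b)`, second row
#'   `(c, d)`.
#' @return An object of class `contingency_2x2`, a 2x2 integer-valued matrix.
#' @examples
#' contingency_2x2(50, 3691, 33, 498)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (length(x) != 4L || anyNA(x) || !is.numeric(x)) {
    stop("contingency_2x2 requires four numeric counts")
  }
  if (any(x < 0)) stop("contingency table entries must be non-negative")
  if (any(abs(x - round(x)) > 1e-8)) {
    stop("contingency table entries must be integer counts")
  }
  m <- matrix(round(x), nrow = 2L, byrow = TRUE,
              dimnames = list(group = c("g1", "g2"),
                              outcome = c("o1", "o2")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("invalid table: every row and column margin must be > 0")
  }
  class(m) <- c("contingency_2x2", class(m))
  m
}

as_contingency_2x2 <- function(x) {
  if (inherits(x, "contingency_2x2")) return(x)
  if (is.matrix(x) && all(dim(x) == c(2L, 2L))) {
    return(contingency_2x2(x[1, 1], x[1, 2], x[2, 1], x[2, 2]))
  }
  if (is.numeric(x) && length(x) == 4L) {
    return(contingency_2x2(x[1], x[2], x[3], x[4]))
  }
  stop("cannot interpret input as a 2x2 contingency table")
}

new_test_result <- function(statistic, df, p_value, method, ...) {
  stopifnot(statistic >= -1e-12, df >= 1, p_value >= 0, p_value <= 1)
  structure(
    list(statistic = max(statistic, 0), df = as.integer(df),
         p_value = p_value, method = method, ...),
    class = "evol_test"
  )
}

#' @export
print.evol_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic, digits = 6),
      ", df = ", x$df,
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Upper tail of the chi-square distribution
#'
#' Thin wrapper around [stats::pchisq()] used by the G-test and the Tajima
#' relative-rate test. For `df = 1` this equals `erfc(sqrt(x/2))`.
#'
#' @param x Non-negative quantile.
#' @param df Positive integer degrees of freedom.
#' @return The survival probability `P(X >= x)` in `[0, 1]`.
#' @export
chi2_upper_tail <- function(x, df = 1L) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("chi-square quantile must be finite and non-negative")
  }
  if (any(df < 1)) stop("df must be a positive integer")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Log-likelihood-ratio G-test of independence for a 2x2 table
#'
#' Computes `G = 2 * sum(O * ln(O/E))` with expecteds from the row and
#' column margins and the convention `0 * ln(0/E) = 0`, and refers G to the
#' chi-square distribution with one degree of freedom. This is the test used
#' for domain-enrichment tables, lineage substitution counts, and
#' microsatellite polymorphism contrasts. The Williams correction (dividing
#' G by `q = 1 + ((N/r1 + N/r2 - 1) * (N/c1 + N/c2 - 1)) / (6N)`) is
#' available but off by default.
#'
#' @param table A `contingency_2x2`, a 2x2 matrix, or a length-4 vector
#'   `(a, b, c, d)` read row-wise.
#' @param williams_correction Apply the Williams continuity adjustment?
#' @return An `evol_test` with elements `statistic`, `df`, `p_value`,
#'   and `correction`.
#' @examples
#' gtest_2x2(contingency_2x2(50, 3691, 33, 498))
#' @export
gtest_2x2 <- function(table, williams_correction = FALSE) {
  m <- as_contingency_2x2(table)
  O <- unclass(m)
  N <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / N
  terms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms)
  if (williams_correction) {
    r <- rowSums(O); cc <- colSums(O)
    q <- 1 + ((N / r[1] + N / r[2] - 1) * (N / cc[1] + N / cc[2] - 1)) / (6 * N)
    G <- G / q
  }
  new_test_result(G, 1L, chi2_upper_tail(max(G, 0), 1L),
                  method = if (williams_correction)
                    "G-test (Williams-corrected)" else "G-test",
                  correction = williams_correction)
}

#' Tajima's relative-rate test
#'
#' Given the counts of sites where only taxon 1 (`m1`) or only taxon 2
#' (`m2`) differs from the other taxon and the outgroup, tests equality of
#' evolutionary rates on the two lineages with
#' `chi2 = (m1 - m2)^2 / (m1 + m2)` on one degree of freedom.
#'
#' @param m1,m2 Lineage-specific difference counts.
#' @return An `evol_test`.
#' @examples
#' tajima_rrt(286, 315)
#' @export
tajima_rrt <- function(m1, m2) {
  stopifnot(is.numeric(m1), is.numeric(m2), m1 >= 0, m2 >= 0)
  if (m1 + m2 == 0) {
    stop("undefined test: no lineage-specific differences (m1 + m2 = 0)")
  }
  x <- (m1 - m2)^2 / (m1 + m2)
  new_test_result(x, 1L, chi2_upper_tail(x, 1L),
                  method = "Tajima relative-rate test",
                  m1 = m1, m2 = m2)
}

#' Bootstrap standard deviation of a per-gene statistic
#'
#' Resamples genes (the resampling unit) with replacement and returns the
#' standard deviation of the statistic across replicates. Used for the
#' standard deviation of the nonsynonymous/synonymous distance ratio with
#' 1000 iterations by default.
#'
#' @param units A list (or data.frame) of per-gene records; each bootstrap
#'   replicate is `statistic(units[idx])` for a resampled index vector.
#' @param statistic Function taking a subset of `units` (same type as
#'   `units`) and returning a single number.
#' @param n_replicates Number of bootstrap iterations (default 1000).
#' @param seed Integer seed making the resampling deterministic.
#' @return The bootstrap standard deviation (non-negative scalar). Replicates
#'   where the statistic is not finite (e.g. a ratio with zero denominator)
#'   are dropped; the number retained is attached as attribute `n_used`.
#' @export
bootstrap_sd <- function(units, statistic, n_replicates = 1000L, seed = 1L) {
  n <- if (is.data.frame(units)) nrow(units) else length(units)
  if (n < 2L) stop("insufficient data: need >= 2 resampling units")
  stopifnot(n_replicates >= 1L)
  take <- if (is.data.frame(units)) {
    function(idx) units[idx, , drop = FALSE]
  } else {
    function(idx) units[idx]
  }
  vals <- withr_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      statistic(take(sample.int(n, n, replace = TRUE)))
    }, numeric(1))
  })
  ok <- is.finite(vals)
  out <- if (sum(ok) >= 2L) stats::sd(vals[ok]) else NA_real_
  attr(out, "n_used") <- sum(ok)
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read and test a set of 2x2 enrichment tables
#'
#' Reads a TSV with columns `row_label`, `with`, `without` describing, for
#' each label, the first data row of a 2x2 table, with the final line
#' (label `"background"` or the complement row) supplying the second row;
#' alternatively accepts a data.frame with columns `label, a, b, c, d`.
#' Applies [gtest_2x2()] to each row.
#'
#' @param tables A data.frame with columns `label, a, b, c, d`.
#' @param williams_correction Passed to [gtest_2x2()].
#' @return The input data.frame with columns `G`, `df`, `p_value` appended.
#' @export
enrichment_gtests <- function(tables, williams_correction = FALSE) {
  stopifnot(all(c("label", "a", "b", "c", "d") %in% names(tables)))
  res <- lapply(seq_len(nrow(tables)), function(i) {
    gtest_2x2(c(tables$a[i], tables$b[i], tables$c[i], tables$d[i]),
              williams_correction = williams_correction)
  })
  tables$G <- vapply(res, `[[`, numeric(1), "statistic")
  tables$df <- vapply(res, `[[`, integer(1), "df")
  tables$p_value <- vapply(res, `[[`, numeric(1), "p_value")
  tables
}

#' Write a test result as a JSON report
#'
#' @param result An `evol_test`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_test_json <- function(result, path) {
  stopifnot(inherits(result, "evol_test"))
  out <- list(statistic = result$statistic, df = result$df,
              p_value = result$p_value, method = result$method)
  if (!is.null(result$correction)) out$correction <- result$correction
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
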