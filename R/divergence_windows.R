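# Windowed substitution counts and transition/transversion ratios over the
# three-way genome alignment.

#' Window configuration for substitution profiles
#'
#' @param window_bp Window width in bp (default 10 kb).
#' @param step_bp Step between window starts in bp (default 10 kb, i.e.
#'   non-overlapping tiling).
#' @param annotation_filter Annotation classes of sites to count;
#'   `"non-exonic"` (the default) restricts to sites outside annotated
#'   exons, `NULL` uses all sites.
#' @return A list of class `window_config`.
#' @export
window_config <- function(window_bp = 10000L, step_bp = 10000L,
                          annotation_filter = "non-exonic") {
  stopifnot(window_bp > 0, step_bp > 0)
  structure(list(window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 annotation_filter = annotation_filter),
            class = "window_config")
}

filter_columns <- function(columns, annotation_filter) {
  if (is.null(annotation_filter)) return(columns)
  columns[columns$annotation_class %in% annotation_filter, , drop = FALSE]
}

pair_bases <- function(columns, pair) {
  cols <- paste0("base_", tolower(pair))
  missing <- setdiff(cols, names(columns))
  if (length(missing)) stop("unknown genome pair: ", paste(pair, collapse = "/"))
  list(x = columns[[cols[1]]], y = columns[[cols[2]]])
}

#' Per-window substitution counts along a chromosome
#'
#' Counts differing comparable sites (both bases present) between a genome
#' pair in fixed-width windows. Windows are anchored at position 0 and
#' cover `[w * step, w * step + window_bp)` half-open; the final partial
#' window is reported with its true extent. Windows containing no
#' comparable site are flagged (`no_data = TRUE`) to distinguish absence
#' of data from zero substitutions.
#'
#' @param columns Data frame of aligned columns with `chrom`, `ref_pos`
#'   (0-based), `base_osj`, `base_og`, `base_osi` (NA = missing) and
#'   `annotation_class`.
#' @param cfg A [window_config()].
#' @param pair Character vector of two genome names, e.g.
#'   `c("osj", "og")`.
#' @return Data frame with `chrom`, `start`, `end`, `substitutions`,
#'   `comparable_sites`, `no_data`.
#' @export
window_counts <- function(columns, cfg = window_config(),
                          pair = c("osj", "og")) {
  columns <- filter_columns(columns, cfg$annotation_filter)
  out <- lapply(split(columns, columns$chrom), function(cc) {
    b <- pair_bases(cc, pair)
    comparable <- !is.na(b$x) & !is.na(b$y)
    chrom_end <- max(cc$ref_pos) + 1L
    n_win <- max(1L, ceiling(max(chrom_end - cfg$window_bp, 0) /
                               cfg$step_bp) + 1L)
    starts <- (seq_len(n_win) - 1L) * cfg$step_bp
    ends <- pmin(starts + cfg$window_bp, chrom_end)
    sub <- comp <- integer(n_win)
    # a site can fall in several windows when step < window
    for (w in seq_len(n_win)) {
      in_w <- cc$ref_pos >= starts[w] & cc$ref_pos < starts[w] + cfg$window_bp
      comp[w] <- sum(comparable & in_w)
      sub[w] <- sum(comparable & in_w & b$x != b$y)
    }
    data.frame(chrom = cc$chrom[1], start = starts, end = ends,
               substitutions = sub, comparable_sites = comp,
               no_data = comp == 0L)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Transition/transversion ratio over aligned columns
#'
#' @param columns Data frame of aligned columns (see [window_counts()]).
#' @param pair Genome pair.
#' @param annotation_filter Optional restriction by annotation class
#'   (default: all sites).
#' @param by Either `"genome"` (one ratio) or `"chromosome"`.
#' @return For `by = "genome"` a single ratio (NA with a warning if there
#'   are no transversions); otherwise a data frame per chromosome with
#'   `transitions`, `transversions` and `tstv`.
#' @export
tstv_ratio <- function(columns, pair = c("osj", "og"),
                       annotation_filter = NULL, by = c("genome",
                                                        "chromosome")) {
  by <- match.arg(by)
  columns <- filter_columns(columns, annotation_filter)
  count_one <- function(cc) {
    b <- pair_bases(cc, pair)
    cls <- classify_substitution(b$x, b$y)
    c(ts = sum(cls == "transition", na.rm = TRUE),
      tv = sum(cls == "transversion", na.rm = TRUE))
  }
  if (by == "genome") {
    n <- count_one(columns)
    if (n[["tv"]] == 0) {
      warning("undefined ratio: no transversions in scope")
      return(NA_real_)
    }
    return(unname(n[["ts"]] / n[["tv"]]))
  }
  res <- t(vapply(split(columns, columns$chrom), count_one, numeric(2)))
  data.frame(chrom = rownames(res), transitions = res[, "ts"],
             transversions = res[, "tv"],
             tstv = ifelse(res[, "tv"] > 0, res[, "ts"] / res[, "tv"],
                           NA_real_),
             row.names = NULL)
}

#' Write windowed counts as a bedgraph-like TSV
#'
#' @param windows Output of [window_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_tsv <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
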