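# Exploration-exploitation descriptives: kernel-density summaries of
# dwelling time / entropy distributions and dwell-count-GTE correlation
# matrices per agent condition.

#' Kernel-density summary: mode, centroid, FWHM
#'
#' Gaussian-kernel density on a 512-point grid spanning the data plus three
#' bandwidths on each side. The mode is the grid argmax, the centroid is the
#' sample mean, and the FWHM is the distance between the outermost crossings
#' of half-maximal density (linearly interpolated). Both mode and FWHM
#' depend on the bandwidth, so the bandwidth used is always part of the
#' result.
#'
#' @param values Numeric sample (>= 10 values).
#' @param bandwidth `"silverman"` (Silverman's rule of thumb, the default)
#'   or a positive number.
#' @return Object of class `kde_summary`: list with `mode`, `centroid`,
#'   `fwhm`, `bandwidth`, `n`.
#' @export
kde_summary <- function(values, bandwidth = "silverman") {
  values <- values[!is.na(values)]
  if (length(values) < 10) stop("need at least 10 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate density: constant sample", call. = FALSE)
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(values)
        else as.numeric(bandwidth)
  if (!is.finite(bw) || bw <= 0) stop("invalid bandwidth", call. = FALSE)
  den <- stats::density(values, bw = bw, n = 512,
                        from = min(values) - 3 * bw,
                        to = max(values) + 3 * bw)
  imax <- which.max(den$y)
  half <- den$y[imax] / 2
  above <- den$y >= half
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  interp <- function(i, rising) {
    # linear interpolation of the half-max crossing next to grid index i
    if (rising) {
      if (i == 1) return(den$x[1])
      x0 <- den$x[i - 1]; x1 <- den$x[i]
      y0 <- den$y[i - 1]; y1 <- den$y[i]
    } else {
      if (i == length(den$x)) return(den$x[i])
      x0 <- den$x[i]; x1 <- den$x[i + 1]
      y0 <- den$y[i]; y1 <- den$y[i + 1]
    }
    x0 + (half - y0) / (y1 - y0) * (x1 - x0)
  }
  fwhm <- interp(i2, rising = FALSE) - interp(i1, rising = TRUE)
  structure(list(mode = den$x[imax], centroid = mean(values), fwhm = fwhm,
                 bandwidth = bw, n = length(values)),
            class = "kde_summary")
}

#' @export
print.kde_summary <- function(x, ...) {
  cat(sprintf("KDE summary (n = %d, bw = %.4g): mode %.4g, centroid %.4g, FWHM %.4g\n",
              x$n, x$bandwidth, x$mode, x$centroid, x$fwhm))
  invisible(x)
}

#' Pearson correlation matrix of dwell, fixation count, and GTE
#'
#' Pairwise Pearson correlations over listwise-complete rows; zero-variance
#' columns yield `NA` entries (flagged via a warning).
#'
#' @param table Data frame with columns `dwell`, `count`, `gte` (one row per
#'   agent or object).
#' @return 3 x 3 symmetric correlation matrix.
#' @export
correlation_matrix <- function(table) {
  cols <- c("dwell", "count", "gte")
  stopifnot(all(cols %in% names(table)))
  X <- table[stats::complete.cases(table[, cols]), cols, drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 complete rows", call. = FALSE)
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    warning("zero-variance column(s): ",
            paste(cols[sds == 0], collapse = ", "),
            "; correlations set to NA")
  M <- suppressWarnings(stats::cor(X))
  M[!is.finite(M)] <- NA_real_
  diag(M) <- 1
  M
}

#' Per-condition exploration-exploitation descriptives
#'
#' For each agent condition, computes KDE summaries of per-agent total dwell
#' and GTE and the dwell-count-GTE correlation matrix.
#'
#' @param agents Data frame with one row per agent: `agent_type`, `dwell`,
#'   `count`, `gte`.
#' @param bandwidth Passed to [kde_summary()].
#' @return Named list per condition with elements `dwell_kde`, `gte_kde`,
#'   `corr`, `n`.
#' @export
describe_conditions <- function(agents, bandwidth = "silverman") {
  stopifnot(all(c("agent_type", "dwell", "count", "gte") %in% names(agents)))
  out <- lapply(split(agents, agents$agent_type), function(g) {
    list(dwell_kde = if (nrow(g) >= 10) kde_summary(g$dwell, bandwidth),
         gte_kde = if (nrow(g) >= 10 && !all(is.na(g$gte)))
           kde_summary(g$gte[!is.na(g$gte)], bandwidth),
         corr = if (nrow(g) >= 3) correlation_matrix(g),
         n = nrow(g))
  })
  out
}
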