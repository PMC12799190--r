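#' Forward transition counts over visual categories
#'
#' Tabulates first-order forward transitions of a fixation category sequence:
#' each fixation is linked exclusively to the subsequent fixation, so a
#' sequence of length `n` contributes `n - 1` transitions. Category-level
#' self-transitions (consecutive fixations in the same category, e.g. two
#' different buildings) are counted by default; set `drop_self = TRUE` to
#' exclude them for sensitivity analyses.
#'
#' @param seq Character vector of category labels, one per fixation, in
#'   temporal order. All labels must belong to `categories`.
#' @param categories Character vector defining the category set (and matrix
#'   order). Defaults to the canonical eight-category taxonomy.
#' @param drop_self Drop transitions whose origin and destination category
#'   coincide. Default `FALSE`.
#' @return An object of class `transition_counts`: a list with `counts`
#'   (k x k integer matrix, rows = current category, columns = next),
#'   `N_row` (per-row totals), `S1_row` (per-row singleton counts, i.e.
#'   transition types observed exactly once), and `k`.
#' @export
build_transition_matrix <- function(seq, categories = gaze_categories(),
                                    drop_self = FALSE) {
  if (length(seq) < 2)
    stop("need at least 2 fixations to form a transition", call. = FALSE)
  seq <- as.character(seq)
  unknown <- setdiff(unique(seq), categories)
  if (length(unknown))
    stop("unknown category label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  k <- length(categories)
  from <- factor(seq[-length(seq)], levels = categories)
  to <- factor(seq[-1L], levels = categories)
  if (drop_self) {
    keep <- as.integer(from) != as.integer(to)
    from <- from[keep]; to <- to[keep]
  }
  counts <- table(from, to)
  counts <- matrix(as.integer(counts), nrow = k, ncol = k,
                   dimnames = list(categories, categories))
  structure(
    list(counts = counts,
         N_row = rowSums(counts),
         S1_row = apply(counts, 1L, function(r) sum(r == 1L)),
         k = k),
    class = "transition_counts")
}

#' Row-normalize transition counts into conditional probabilities
#'
#' Rows with at least one observed transition are divided by their total;
#' rows for categories never fixated (or never followed) stay all-zero and
#' are flagged.
#'
#' @param tc A `transition_counts` object.
#' @return A k x k matrix of conditional probabilities with attribute
#'   `zero_rows` (logical vector marking unobserved rows).
#' @export
row_normalize <- function(tc) {
  stopifnot(inherits(tc, "transition_counts"))
  P <- tc$counts
  zero <- tc$N_row == 0
  nz <- which(!zero)
  P[nz, ] <- P[nz, , drop = FALSE] / tc$N_row[nz]
  storage.mode(P) <- "double"
  attr(P, "zero_rows") <- zero
  P
}

#' Chao-Shen coverage-corrected Shannon entropy of one count vector
#'
#' Bias-corrected entropy estimator for sparse multinomial counts. The
#' estimated sample coverage `C = 1 - S1/N` (singletons over total) rescales
#' the maximum-likelihood probabilities, and each term is divided by its
#' Horvitz-Thompson inclusion probability `la(x) = 1 - (1 - p_adj(x))^N`,
#' compensating for transition types never observed. When every observation
#' is a singleton (`S1 = N`) the coverage would vanish, so `S1` is replaced
#' by `N - 1`, the standard implementation fix.
#'
#' @param row_counts Non-negative integer vector of counts for one origin
#'   category (one row of the transition count matrix).
#' @return List with `H` (entropy in bits, >= 0) and `C` (estimated sample
#'   coverage in (0, 1]).
#' @examples
#' chao_shen_entropy(c(2, 1, 1))  # approx 2.544 bits
#' @export
chao_shen_entropy <- function(row_counts) {
  row_counts <- as.numeric(row_counts)
  if (any(row_counts < 0) || any(row_counts != floor(row_counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  N <- sum(row_counts)
  if (N < 1)
    stop("all-zero count row: entropy undefined; skip unobserved rows",
         call. = FALSE)
  S1 <- sum(row_counts == 1)
  if (S1 == N) S1 <- N - 1
  C <- 1 - S1 / N
  obs <- row_counts > 0
  p_ml <- row_counts[obs] / N
  p_adj <- C * p_ml
  la <- 1 - (1 - p_adj)^N
  # point mass with full coverage: p_adj = 1 contributes 0 (0 * log 0)
  term <- ifelse(p_adj > 0 & p_adj < 1,
                 -p_adj * log2(p_adj) / la,
                 0)
  list(H = sum(term), C = C)
}

#' Stationary distribution of a row-normalized transition matrix
#'
#' Principal left eigenvector of the transition matrix restricted to observed
#' categories (rows with data), normalized to sum to one. If the restricted
#' chain is reducible (eigenvalue 1 with multiplicity > 1), the eigenvector is
#' complex, or the solution fails `pi P = pi` at tolerance 1e-10, the
#' empirical marginal `row_totals / sum(row_totals)` is returned instead and
#' the result is flagged via its `method` attribute.
#'
#' @param P Row-stochastic matrix (zero rows allowed for unobserved
#'   categories, as produced by [row_normalize()]).
#' @param row_totals Per-row transition totals, used for the empirical
#'   fallback and to identify observed rows.
#' @return Numeric vector `pi` (length k, sums to 1, zero on unobserved
#'   categories) with attribute `method` equal to `"eigen"` or
#'   `"empirical"`.
#' @export
stationary_distribution <- function(P, row_totals) {
  k <- nrow(P)
  stopifnot(length(row_totals) == k)
  obs <- which(row_totals > 0)
  if (!length(obs)) stop("no observed transitions", call. = FALSE)
  empirical <- function() {
    pi <- row_totals / sum(row_totals)
    attr(pi, "method") <- "empirical"
    pi
  }
  Psub <- P[obs, obs, drop = FALSE]
  # restriction can lose probability mass (transitions into unobserved rows);
  # renormalize rows, falling back if a row dies entirely
  rs <- rowSums(Psub)
  if (any(rs <= 0)) return(empirical())
  Psub <- Psub / rs
  ev <- eigen(t(Psub))
  near1 <- abs(ev$values - 1) < 1e-8
  if (sum(near1) != 1L) return(empirical())   # reducible or periodic
  v <- ev$vectors[, which(near1)]
  if (max(abs(Im(v))) > 1e-8) return(empirical())
  v <- Re(v)
  if (any(v > 1e-12) && any(v < -1e-12)) return(empirical())
  v <- abs(v) / sum(abs(v))
  if (max(abs(drop(v %*% Psub) - v)) > 1e-10) return(empirical())
  pi <- numeric(k)
  pi[obs] <- v
  names(pi) <- rownames(P)
  attr(pi, "method") <- "eigen"
  pi
}

#' Stationary-weighted global entropy
#'
#' Weighted average of per-category corrected entropies, the weights being the
#' stationary probability of fixating each category.
#'
#' @param H_row Per-category entropies (bits); unobserved categories
#'   contribute 0 with weight 0.
#' @param pi Stationary distribution (sums to 1).
#' @return Global entropy in bits.
#' @export
global_entropy <- function(H_row, pi) {
  if (length(H_row) != length(pi))
    stop("H_row and pi must have equal length", call. = FALSE)
  sum(pi * H_row)
}

#' Normalize an entropy by its theoretical maximum
#'
#' Divides by `log2(k)`, the entropy of the uniform distribution over the
#' `k`-category design, yielding a value in `[0, 1]`. Values that exceed the
#' bounds by numerical noise are clipped (with a warning).
#'
#' @param H Entropy in bits (>= 0).
#' @param k Number of categories in the design (default 8).
#' @return Normalized entropy in `[0, 1]`.
#' @export
normalize_entropy <- function(H, k = 8) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  h <- H / log2(k)
  if (any(h < 0 | h > 1)) {
    warning("normalized entropy clipped to [0, 1]")
    h <- pmin(pmax(h, 0), 1)
  }
  h
}

#' Gaze transition entropy of a fixation category sequence
#'
#' Full pipeline: forward transition counts, row normalization, per-row
#' Chao-Shen corrected entropy, stationary weighting, and normalization by
#' the theoretical maximum `log2(k)`. Higher values indicate less predictable
#' scanning.
#'
#' @inheritParams build_transition_matrix
#' @param stationary Either `"eigen"` (principal left eigenvector, default)
#'   or `"empirical"` (marginal transition frequency per origin category).
#' @return Object of class `entropy_result`: list with `counts`
#'   (`transition_counts`), `P` (row-normalized matrix), `H_row` (bits, 0 for
#'   unobserved rows), `C_row` (coverage, `NA` for unobserved rows), `pi`,
#'   `H_global` (bits), `H_norm` (in `[0, 1]`), `k`, and
#'   `stationary_method`.
#' @examples
#' set.seed(1)
#' s <- sample(gaze_categories(), 500, replace = TRUE)
#' gte(s)$H_norm
#' @export
gte <- function(seq, categories = gaze_categories(), drop_self = FALSE,
                stationary = c("eigen", "empirical")) {
  stationary <- match.arg(stationary)
  tc <- build_transition_matrix(seq, categories = categories,
                                drop_self = drop_self)
  P <- row_normalize(tc)
  k <- tc$k
  H_row <- numeric(k)
  C_row <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    if (tc$N_row[i] > 0) {
      cs <- chao_shen_entropy(tc$counts[i, ])
      H_row[i] <- cs$H
      C_row[i] <- cs$C
    }
  }
  if (stationary == "eigen") {
    pi <- stationary_distribution(P, tc$N_row)
  } else {
    pi <- tc$N_row / sum(tc$N_row)
    attr(pi, "method") <- "empirical"
  }
  H_global <- global_entropy(H_row, pi)
  # Chao-Shen rows can exceed log2(k) slightly under sparse sampling; the
  # normalized score is defined as clipped to [0, 1]
  H_norm <- suppressWarnings(normalize_entropy(H_global, k))
  structure(
    list(counts = tc, P = P, H_row = H_row, C_row = C_row,
         pi = as.numeric(pi), H_global = H_global, H_norm = H_norm, k = k,
         stationary_method = attr(pi, "method")),
    class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat("Gaze transition entropy\n")
  cat(sprintf("  categories observed : %d of %d\n",
              sum(x$counts$N_row > 0), x$k))
  cat(sprintf("  H_global            : %.4f bits\n", x$H_global))
  cat(sprintf("  H_norm              : %.4f\n", x$H_norm))
  cat(sprintf("  stationary weights  : %s\n", x$stationary_method))
  invisible(x)
}

#' Per-session gaze transition entropy table
#'
#' Convenience wrapper computing one [gte()] result per participant-session
#' group of a fixation log.
#'
#' @param fixations Data frame with columns `participant`, `session`,
#'   `category` (temporal order within group assumed, or enforced via
#'   `start` when present).
#' @inheritParams gte
#' @return Data frame with one row per (participant, session):
#'   `H_global`, `H_norm`, `n_fixations`, `stationary_method`.
#' @export
gte_by_session <- function(fixations, categories = gaze_categories(),
                           drop_self = FALSE,
                           stationary = c("eigen", "empirical")) {
  stationary <- match.arg(stationary)
  stopifnot(all(c("participant", "session", "category") %in% names(fixations)))
  if ("start" %in% names(fixations))
    fixations <- fixations[order(fixations$participant, fixations$session,
                                 fixations$start), ]
  groups <- split(fixations,
                  list(fixations$participant, fixations$session),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    if (nrow(g) < 2) return(NULL)
    r <- gte(g$category, categories = categories, drop_self = drop_self,
             stationary = stationary)
    data.frame(participant = g$participant[1], session = g$session[1],
               H_global = r$H_global, H_norm = r$H_norm,
               n_fixations = nrow(g),
               stationary_method = r$stationary_method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
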