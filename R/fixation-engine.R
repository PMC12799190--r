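# Velocity-based fixation classification for a walking observer, with an
# adaptive per-segment threshold and a translational-movement correction.

#' Angular gaze velocity with translational correction
#'
#' Computes the angular velocity (deg/s) between consecutive gaze rays. When
#' the observer walks, a gaze ray locked on a stationary world point rotates
#' in head coordinates; the correction removes this component by
#' reconstructing each sample's fixated world point (head position +
#' `hit_distance` along the gaze direction) and measuring the angle both
#' points subtend from the midpoint head position. Samples without a hit
#' distance fall back to the raw angle between gaze directions.
#'
#' @param samples Data frame with columns `t`, `gx`, `gy`, `gz` (unit gaze
#'   direction), `hx`, `hy`, `hz` (head position, meters), optional
#'   `hit_distance` (meters) and `valid`.
#' @param correct_translation Apply the midpoint re-anchoring correction
#'   (default `TRUE`).
#' @return Numeric vector of length `nrow(samples)`; element `i` is the
#'   velocity over the step from sample `i - 1` to `i`. The first element
#'   (and any element following an invalid sample) is `NA`.
#' @export
angular_velocity <- function(samples, correct_translation = TRUE) {
  n <- nrow(samples)
  valid <- if ("valid" %in% names(samples)) samples$valid else rep(TRUE, n)
  if (!any(valid)) stop("no valid samples", call. = FALSE)
  if (sum(valid) < 2) stop("need at least 2 valid samples", call. = FALSE)
  G <- cbind(samples$gx, samples$gy, samples$gz)
  H <- cbind(samples$hx, samples$hy, samples$hz)
  r <- if ("hit_distance" %in% names(samples)) samples$hit_distance
       else rep(NA_real_, n)
  dt <- diff(samples$t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing",
                         call. = FALSE)
  i1 <- seq_len(n - 1); i2 <- i1 + 1
  use_corr <- correct_translation & !is.na(r[i1]) & !is.na(r[i2])
  # corrected: angle at midpoint head position between the two fixated
  # world points
  W1 <- H[i1, , drop = FALSE] + r[i1] * G[i1, , drop = FALSE]
  W2 <- H[i2, , drop = FALSE] + r[i2] * G[i2, , drop = FALSE]
  M <- (H[i1, , drop = FALSE] + H[i2, , drop = FALSE]) / 2
  V1 <- W1 - M; V2 <- W2 - M
  dotn <- function(A, B) rowSums(A * B) /
    (sqrt(rowSums(A * A)) * sqrt(rowSums(B * B)))
  cos_corr <- dotn(V1, V2)
  cos_raw <- rowSums(G[i1, , drop = FALSE] * G[i2, , drop = FALSE])
  cosang <- ifelse(use_corr, cos_corr, cos_raw)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  vel <- c(NA_real_, ang / dt)
  vel[!valid] <- NA_real_
  vel[c(FALSE, !valid[-n])] <- NA_real_   # step out of an invalid sample
  vel
}

#' Classify gaze samples into fixations
#'
#' Adaptive velocity-threshold classification: the trace is cut into
#' fixed-length segments (default 10 s) and each segment's threshold is
#' `median(v) + lambda * 1.4826 * MAD(v)`, a robust analogue of
#' mean-plus-k-SD thresholds. Runs of sub-threshold samples lasting at least
#' `min_fix` become fixations; super-threshold runs are saccades and are
#' discarded. Invalid-sample gaps shorter than `blink_bridge` (blinks) are
#' bridged; longer gaps split events. Each fixation is assigned the modal
#' `hit_object_id` of its samples (ties broken by longest within-fixation
#' hit time, then lexicographically).
#'
#' @inheritParams angular_velocity
#' @param segment Segment length in seconds for the adaptive threshold
#'   (default 10).
#' @param lambda_thresh Robust-SD multiplier (default 3).
#' @param min_fix Minimum fixation duration in seconds (default 0.1).
#' @param blink_bridge Maximum invalid-gap duration bridged as a blink,
#'   seconds (default 0.075).
#' @param category_map Optional named character vector mapping
#'   `hit_object_id` to visual category. Object ids of the synthetic
#'   generator (`<category>_<nnn>`) are recognised automatically.
#' @return Data frame of fixation events: `start`, `end`, `duration`,
#'   `object_id`, `category` (`NA` when unmapped), time-ordered and
#'   non-overlapping.
#' @export
classify_fixations <- function(samples, segment = 10, lambda_thresh = 3,
                               min_fix = 0.1, blink_bridge = 0.075,
                               correct_translation = TRUE,
                               category_map = NULL) {
  n <- nrow(samples)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  valid <- if ("valid" %in% names(samples)) samples$valid else rep(TRUE, n)
  span <- samples$t[n] - samples$t[1]
  vel <- angular_velocity(samples, correct_translation = correct_translation)

  # bridge short invalid gaps (blinks): such runs are re-attached to the
  # surrounding event below, longer runs split events
  inv <- !valid
  bridged_runs <- list()
  if (any(inv)) {
    rl <- rle(inv)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
    for (g in which(rl$values)) {
      gap <- samples$t[ends[g]] - samples$t[starts[g]] +
        stats::median(diff(samples$t))
      if (gap < blink_bridge) {
        inv[starts[g]:ends[g]] <- FALSE   # bridged
        bridged_runs[[length(bridged_runs) + 1]] <- c(starts[g], ends[g])
      }
    }
  }

  seg_id <- floor((samples$t - samples$t[1]) / segment)
  below <- rep(NA, n)
  for (s in unique(seg_id)) {
    ix <- which(seg_id == s)
    v <- vel[ix]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning(sprintf("segment %d empty (no valid velocities); skipped",
                      as.integer(s)))
      next
    }
    thr <- stats::median(v) + lambda_thresh * stats::mad(v)
    # constant-velocity segment: MAD = 0 would exclude everything
    if (stats::mad(v) == 0) thr <- thr + 1e-9
    below[ix] <- !is.na(vel[ix]) & vel[ix] < thr
  }
  # first sample has NA velocity: inherit its successor's state so a
  # fixation starting at t = 0 is not clipped
  if (is.na(below[1]) && n > 1) below[1] <- isTRUE(below[2])
  # bridged blink samples (and the NA-velocity step out of the gap) carry
  # the state of their flanking samples when both sides are fixational
  for (br in bridged_runs) {
    i0 <- br[1]; i1 <- min(br[2] + 1L, n)
    left <- i0 - 1L; right <- min(i1 + 1L, n)
    if (left >= 1 && isTRUE(below[left]) &&
        (right > n || isTRUE(below[right]) || is.na(below[right])))
      below[i0:i1] <- TRUE
  }
  below[is.na(below)] <- FALSE
  # absorb isolated single super-threshold samples (velocity-noise
  # outliers, one sample << any saccade) into the surrounding fixation
  iso <- which(!below)
  iso <- iso[iso > 1 & iso < n]
  iso <- iso[below[iso - 1] & below[iso + 1]]
  below[iso] <- TRUE
  below[inv] <- FALSE      # un-bridged invalid samples split events

  rl <- rle(below)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
  out <- list()
  for (g in which(rl$values)) {
    i0 <- starts[g]; i1 <- ends[g]
    t0 <- samples$t[i0]
    t1 <- samples$t[i1] + stats::median(diff(samples$t))
    if (t1 - t0 < min_fix) next
    ids <- samples$hit_object_id[i0:i1]
    ids <- ids[!is.na(ids)]
    if (length(ids)) {
      tab <- sort(table(ids), decreasing = TRUE)
      top <- names(tab)[tab == max(tab)]
      obj <- sort(top)[1]          # modal; ties already by hit time (equal
    } else {                       # sample counts), then lexicographic
      obj <- NA_character_
    }
    out[[length(out) + 1]] <- data.frame(
      start = t0, end = t1, duration = t1 - t0, object_id = obj,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    ev <- data.frame(start = numeric(0), end = numeric(0),
                     duration = numeric(0), object_id = character(0),
                     category = character(0), stringsAsFactors = FALSE)
    return(ev)
  }
  ev <- do.call(rbind, out)
  ev$category <- infer_category(ev$object_id, category_map)
  ev
}

#' Map object ids to visual categories
#'
#' @param object_id Character vector of object ids.
#' @param category_map Optional named character vector (`id -> category`);
#'   ids of the form `<category>_<nnn>` with a canonical category prefix are
#'   recognised without a map.
#' @return Character vector of categories (`NA` when unresolvable).
#' @export
infer_category <- function(object_id, category_map = NULL) {
  out <- rep(NA_character_, length(object_id))
  if (!is.null(category_map)) {
    hit <- object_id %in% names(category_map)
    out[hit] <- unname(category_map[object_id[hit]])
  }
  todo <- is.na(out) & !is.na(object_id)
  if (any(todo)) {
    pref <- sub("_[0-9]+$", "", object_id[todo])
    ok <- pref %in% gaze_categories()
    out[todo][ok] <- pref[ok]
  }
  out
}

#' Accumulate dwelling time per object
#'
#' Sums fixation durations and counts per (participant, object), the
#' object-level measure of total visual engagement.
#'
#' @param fixations Fixation-event data frame (`object_id`, `category`,
#'   `duration`).
#' @param participant Participant id attached to every row.
#' @return Data frame with columns `participant`, `object_id`, `category`,
#'   `total_dwell`, `fixation_count`; empty input yields an empty table.
#' @export
accumulate_dwell <- function(fixations, participant = 1L) {
  if (!nrow(fixations)) {
    return(data.frame(participant = integer(0), object_id = character(0),
                      category = character(0), total_dwell = numeric(0),
                      fixation_count = integer(0), stringsAsFactors = FALSE))
  }
  fx <- fixations[!is.na(fixations$object_id), , drop = FALSE]
  agg <- stats::aggregate(duration ~ object_id + category, data = fx, FUN = sum,
                          na.action = stats::na.pass)
  cnt <- stats::aggregate(duration ~ object_id + category, data = fx,
                          FUN = length, na.action = stats::na.pass)
  out <- data.frame(participant = participant, object_id = agg$object_id,
                    category = agg$category, total_dwell = agg$duration,
                    fixation_count = as.integer(cnt$duration),
                    stringsAsFactors = FALSE)
  out[order(out$object_id), , drop = FALSE]
}
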