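# Agent-locked 30-s pre/post windows and per-window transition entropy.

#' Extract agent encounters with non-overlapping pre/post windows
#'
#' Scans agent fixations in temporal order and retains a fixation as an
#' encounter onset iff (a) no already-retained encounter on the same agent
#' lies within the preceding `window` seconds (a per-agent refractory
#' period; set `scope = "global"` to enforce it across all agents), and
#' (b) both the pre window `[onset - window, onset)` and the post window
#' `[onset, onset + window)` fit inside the session span — edge-truncated
#' windows are dropped, not shortened. The onset fixation itself belongs to
#' the post window.
#'
#' @param fixations Time-ordered fixation data frame (`start`, `end`,
#'   `object_id`, `category`), agent fixations marked by the agent
#'   categories.
#' @param session_span Numeric length-2 interval `c(t0, t1)` of the session.
#' @param window Window length in seconds (default 30).
#' @param scope `"agent"` (refractory period per agent collider, default)
#'   or `"global"` (across all agents).
#' @return Data frame of encounters: `agent_id`, `agent_type`, `onset`,
#'   `pre_start`, `pre_end`, `post_start`, `post_end`, `encounter_index`
#'   (1-based, in onset order). Empty if no agent fixation qualifies.
#' @export
extract_encounters <- function(fixations, session_span, window = 30,
                               scope = c("agent", "global")) {
  scope <- match.arg(scope)
  stopifnot(length(session_span) == 2, session_span[2] > session_span[1])
  ag <- fixations[!is.na(fixations$category) &
                    fixations$category %in% agent_categories(), ,
                  drop = FALSE]
  empty <- data.frame(agent_id = character(0), agent_type = character(0),
                      onset = numeric(0), pre_start = numeric(0),
                      pre_end = numeric(0), post_start = numeric(0),
                      post_end = numeric(0), encounter_index = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(ag)) return(empty)
  ag <- ag[order(ag$start), , drop = FALSE]
  last_onset <- new.env(parent = emptyenv())
  last_any <- -Inf
  keep <- logical(nrow(ag))
  for (i in seq_len(nrow(ag))) {
    t0 <- ag$start[i]
    if (t0 - window < session_span[1] || t0 + window > session_span[2]) next
    ref <- if (scope == "global") last_any
           else if (!is.null(last_onset[[ag$object_id[i]]]))
             last_onset[[ag$object_id[i]]] else -Inf
    if (t0 - ref < window) next
    keep[i] <- TRUE
    last_onset[[ag$object_id[i]]] <- t0
    last_any <- t0
  }
  ag <- ag[keep, , drop = FALSE]
  if (!nrow(ag)) return(empty)
  data.frame(agent_id = ag$object_id,
             agent_type = .category_to_condition(ag$category),
             onset = ag$start,
             pre_start = ag$start - window, pre_end = ag$start,
             post_start = ag$start, post_end = ag$start + window,
             encounter_index = seq_len(nrow(ag)),
             stringsAsFactors = FALSE)
}

#' Gaze transition entropy within a time window
#'
#' Restricts the fixation log to events whose midpoint lies in the half-open
#' interval `[interval[1], interval[2])` and computes [gte()] on the
#' restricted category sequence. Windows holding fewer than 3 fixations
#' yield `NA` (flagged), since no meaningful transition matrix exists.
#'
#' @param fixations Fixation data frame with `start`, `end`, `category`.
#' @param interval Numeric length-2 window.
#' @inheritParams gte
#' @return A list with `H_norm` (numeric or `NA`), `n_fixations`, and
#'   `flag` (`"ok"` or `"too_few_fixations"`).
#' @export
window_gte <- function(fixations, interval, categories = gaze_categories(),
                       drop_self = FALSE,
                       stationary = c("eigen", "empirical")) {
  stationary <- match.arg(stationary)
  stopifnot(length(interval) == 2, interval[2] > interval[1])
  mid <- (fixations$start + fixations$end) / 2
  sel <- fixations[mid >= interval[1] & mid < interval[2], , drop = FALSE]
  sel <- sel[!is.na(sel$category), , drop = FALSE]
  if (nrow(sel) < 3) {
    return(list(H_norm = NA_real_, n_fixations = nrow(sel),
                flag = "too_few_fixations"))
  }
  sel <- sel[order(sel$start), , drop = FALSE]
  r <- gte(sel$category, categories = categories, drop_self = drop_self,
           stationary = stationary)
  list(H_norm = r$H_norm, n_fixations = nrow(sel), flag = "ok")
}

#' Per-encounter pre/post window entropies
#'
#' Joins [extract_encounters()] output with [window_gte()] values for the
#' pre and post windows of every retained encounter.
#'
#' @param fixations Fixation log (one session).
#' @param encounters Output of [extract_encounters()].
#' @inheritParams window_gte
#' @return `encounters` with added columns `gte_pre`, `gte_post`,
#'   `n_fix_pre`, `n_fix_post` (`NA` where a window held < 3 fixations).
#' @export
encounter_gte <- function(fixations, encounters,
                          categories = gaze_categories(),
                          drop_self = FALSE,
                          stationary = c("eigen", "empirical")) {
  stationary <- match.arg(stationary)
  n <- nrow(encounters)
  gp <- gq <- rep(NA_real_, n)
  np <- nq <- integer(n)
  for (i in seq_len(n)) {
    pre <- window_gte(fixations,
                      c(encounters$pre_start[i], encounters$pre_end[i]),
                      categories, drop_self, stationary)
    post <- window_gte(fixations,
                       c(encounters$post_start[i], encounters$post_end[i]),
                       categories, drop_self, stationary)
    gp[i] <- pre$H_norm; gq[i] <- post$H_norm
    np[i] <- pre$n_fixations; nq[i] <- post$n_fixations
  }
  encounters$gte_pre <- gp
  encounters$gte_post <- gq
  encounters$n_fix_pre <- np
  encounters$n_fix_post <- nq
  encounters
}
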