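# Synthetic-data generator: emulates the statistical structure the analysis
# assumes (category-labelled fixation sequences from condition-specific Markov
# chains, Gamma dwell durations, agent encounters that flatten the
# post-encounter transition structure, and pointing errors from a Gamma-log
# model with GTE and dwell covariates), so the whole pipeline is testable
# without any recorded eye-tracking data.

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-stream sub-seed from a base seed (kept < 2^31)
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (i in ix) {
    s <- (s * 69069 + as.double(abs(i)) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

.check_stochastic <- function(P, tol = 1e-9) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("transition matrix must be square", call. = FALSE)
  if (any(P < 0))
    stop("transition matrix entries must be non-negative", call. = FALSE)
  if (any(abs(rowSums(P) - 1) > tol))
    stop("every transition matrix row must sum to 1", call. = FALSE)
  invisible(TRUE)
}

#' Default condition-specific transition matrix
#'
#' A structured row-stochastic matrix over the eight visual categories with
#' the gross features of free exploration in the virtual city: most
#' transitions land on background and ordinary buildings, each category is
#' somewhat sticky (repeated fixations within a category), and agent-origin
#' rows are flatter than building rows. Conditions differ only in how much
#' the agent-origin rows are mixed toward the uniform distribution, so that
#' incongruent-agent rows carry the highest conditional entropy, mirroring
#' the ordering of the study conditions.
#'
#' @param condition One of `"acontextual"`, `"congruent"`, `"incongruent"`.
#' @return 8 x 8 row-stochastic matrix with category dimnames.
#' @export
default_transition_matrix <- function(condition = c("acontextual",
                                                    "congruent",
                                                    "incongruent")) {
  condition <- match.arg(condition)
  cats <- gaze_categories()
  k <- length(cats)
  # long-run visit profile of the virtual city: background and buildings
  # dominate, task houses and landmarks are rare; only the agent types
  # present in the condition's experiment carry mass
  m <- c(background = 0.33, building = 0.33, task_residential = 0.08,
         task_public = 0.08, landmark = 0.04, agent_acontextual = 0,
         agent_congruent = 0, agent_incongruent = 0)
  present <- switch(condition,
                    acontextual = "agent_acontextual",
                    congruent = c("agent_acontextual", "agent_congruent"),
                    incongruent = c("agent_acontextual",
                                    "agent_incongruent"))
  # agents are rare targets: ~2% of fixations, so successive encounters
  # stay well separated relative to the 30-s windows
  m[present] <- 0.02 / length(present)
  m <- m / sum(m)
  # each row is a self-sticky mixture alpha * e_c + (1 - alpha) * m; the
  # stickiness alpha is solved so the row's normalized entropy hits the
  # level characteristic of its category (agents flattest, incongruent
  # agents flattest of all)
  target <- c(background = 0.40, building = 0.43, task_residential = 0.48,
              task_public = 0.48, landmark = 0.54, agent_acontextual = 0.63,
              agent_congruent = 0.63, agent_incongruent = 0.67)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  P <- matrix(rep(m, each = k), nrow = k, dimnames = list(cats, cats))
  for (i in seq_len(k)) {
    if (m[i] == 0) next        # unreachable category: row never used
    a <- stats::uniroot(function(a) {
      p <- (1 - a) * m; p[i] <- p[i] + a
      ent(p) / log2(k) - target[i]
    }, c(1e-4, 1 - 1e-4))$root
    P[i, ] <- (1 - a) * m
    P[i, i] <- P[i, i] + a
  }
  P
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults reproduce the
#' study conditions: 53 participants, five 30-minute exploration sessions
#' sampled at 90 Hz, the eight-category taxonomy, condition-specific
#' transition matrices, Gamma dwell durations, and generating coefficients
#' for the five regression models on their link scales.
#'
#' @param n_participants Number of participants (default 53).
#' @param n_sessions Exploration sessions per participant (default 5).
#' @param session_length Session length in seconds (> 60; default 1800).
#' @param sample_rate Gaze sampling rate in Hz (default 90).
#' @param categories Category taxonomy (default [gaze_categories()]).
#' @param transition_matrix_by_condition Named list of row-stochastic 8 x 8
#'   matrices, one per agent condition.
#' @param dwell_shape,dwell_rate Gamma parameters of fixation durations
#'   (seconds); defaults shape 1.49, rate 3.7 (mean approx 0.4 s).
#' @param saccade_peak_velocity Guaranteed saccadic peak velocity, deg/s.
#' @param fixation_velocity_noise Upper bound on within-fixation angular
#'   noise velocity, deg/s.
#' @param encounter_flattening Mixing weight `lambda` in `[0, 1]` applied to
#'   post-encounter transition rows (toward uniform) for 30 s after an agent
#'   fixation.
#' @param true_coefficients Named list of generating coefficient vectors for
#'   models `dwell`, `prepost`, `postgte`, `perf`, `mediator`.
#' @param seed Base integer seed recorded in the config and fanned out to
#'   every generator call.
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_participants = 53,
                       n_sessions = 5,
                       session_length = 1800,
                       sample_rate = 90,
                       categories = gaze_categories(),
                       transition_matrix_by_condition = NULL,
                       dwell_shape = 1.49,
                       dwell_rate = 3.7,
                       saccade_peak_velocity = 300,
                       fixation_velocity_noise = 10,
                       encounter_flattening = 0.6,
                       true_coefficients = default_true_coefficients(),
                       seed = 20260101) {
  if (is.null(transition_matrix_by_condition)) {
    transition_matrix_by_condition <- sapply(
      agent_types(), default_transition_matrix, simplify = FALSE)
  }
  for (nm in names(transition_matrix_by_condition))
    .check_stochastic(transition_matrix_by_condition[[nm]])
  if (encounter_flattening < 0 || encounter_flattening > 1)
    stop("encounter_flattening must lie in [0, 1]", call. = FALSE)
  if (dwell_shape <= 0 || dwell_rate <= 0)
    stop("dwell parameters must be positive", call. = FALSE)
  if (session_length <= 60)
    stop("session_length must exceed 60 s (one full pre+post window)",
         call. = FALSE)
  structure(
    list(n_participants = n_participants, n_sessions = n_sessions,
         session_length = session_length, sample_rate = sample_rate,
         categories = categories,
         transition_matrix_by_condition = transition_matrix_by_condition,
         dwell_shape = dwell_shape, dwell_rate = dwell_rate,
         saccade_peak_velocity = saccade_peak_velocity,
         fixation_velocity_noise = fixation_velocity_noise,
         encounter_flattening = encounter_flattening,
         true_coefficients = true_coefficients,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Default generating coefficients for the five regression models
#'
#' Link-scale coefficient vectors used by the generator, chosen to reproduce
#' the magnitudes of the study's fitted models: e.g. an agent-by-incongruent
#' dwell interaction of 0.41, a pre-to-post entropy shift of 0.38 logits
#' around an intercept of 0.55, a post-encounter grand-mean logit of 0.94,
#' and a GTE slope of -0.31 on log pointing error.
#'
#' @return Named list of named numeric vectors (`dwell`, `prepost`,
#'   `postgte`, `perf`, `mediator`).
#' @export
default_true_coefficients <- function() {
  list(
    dwell = c(beta0 = 2.10, betaO = -1.30, betaC = 0.08, betaI = 0.012,
              betaOC = 0.06, betaOI = 0.41, kappa = 1.49,
              sigma_u = 0.20, sigma_v = 0.19),
    prepost = c(beta0 = 0.55, betaP = 0.38, phi = 30,
                sigma_u = 0.19, sigma_v = 0.19),
    postgte = c(beta0 = 0.94, gamma1 = 0.043, gamma2 = -0.073, phi = 30,
                sigma_u = 0.19, sigma_v = 0.19),
    perf = c(beta0 = 4.09, betaC = 0.01, betaI = -0.12, betaPub = -0.09,
             betaGTE = -0.31, betaDWA = -0.03, betaDWB = -0.04,
             kappa = 1.5, sigma_u = 0.33, sigma_v = 0.19),
    mediator = c(beta0 = 0.94, betaC = 0.065, betaI = 0.065, betaPub = 0.05,
                 phi = 30, sigma_u = 0.19, sigma_v = 0.19))
}

.need_coefs <- function(theta, needed, model) {
  missing <- setdiff(needed, names(theta))
  if (length(missing))
    stop(sprintf("missing %s coefficient(s): %s", model,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Simulate a fixation category sequence from a Markov chain
#'
#' @param P Row-stochastic transition matrix with category dimnames (or
#'   `categories` supplied).
#' @param n Sequence length (>= 2).
#' @param start_category Label of the first fixation (must match a row of
#'   `P`).
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @param categories Optional labels when `P` has no dimnames.
#' @return Character vector of length `n`.
#' @export
simulate_fixation_sequence <- function(P, n, start_category = NULL,
                                       seed = NULL, categories = NULL) {
  .check_stochastic(P)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  labs <- if (!is.null(categories)) categories else rownames(P)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(P)))
  if (is.null(start_category)) start_category <- labs[1]
  s0 <- match(start_category, labs)
  if (is.na(s0)) stop("start_category not among matrix categories",
                      call. = FALSE)
  with_seed(seed, {
    k <- nrow(P)
    out <- integer(n)
    out[1] <- s0
    # inverse-CDF sampling row by row
    cum <- t(apply(P, 1, cumsum))
    u <- stats::runif(n - 1)
    for (i in 2:n) {
      out[i] <- findInterval(u[i - 1], cum[out[i - 1], ]) + 1L
      if (out[i] > k) out[i] <- k
    }
    labs[out]
  })
}

#' Flatten post-encounter transition structure toward uniform
#'
#' Mixes every row of a transition matrix with the uniform distribution:
#' `post = (1 - lambda) * pre + lambda * U`. For any non-uniform `pre` and
#' `lambda > 0` this raises the normalized transition entropy, encoding the
#' broadened scanning observed after agent encounters as a generative
#' mechanism.
#'
#' @param pre_P Row-stochastic matrix.
#' @param lambda Mixing weight in `[0, 1]`.
#' @return Row-stochastic matrix of the same shape.
#' @export
simulate_encounter_shift <- function(pre_P, lambda) {
  .check_stochastic(pre_P)
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]", call. = FALSE)
  k <- ncol(pre_P)
  (1 - lambda) * pre_P + lambda * matrix(1 / k, nrow(pre_P), k,
                                         dimnames = dimnames(pre_P))
}

# unit vector from spherical offset of `ang` degrees away from `d`
.rotate_towards <- function(d, target, frac) {
  v <- (1 - frac) * d + frac * target
  v / sqrt(sum(v^2))
}

.random_unit <- function(min_angle_from = NULL, min_angle = 0) {
  repeat {
    v <- stats::rnorm(3)
    v[3] <- abs(v[3]) * 0.2          # roughly horizontal gaze
    v <- v / sqrt(sum(v^2))
    if (is.null(min_angle_from)) return(v)
    ang <- acos(pmin(1, sum(v * min_angle_from))) * 180 / pi
    if (ang >= min_angle) return(v)
  }
}

#' Simulate one gaze-recording session
#'
#' Generates a fixation-level ground truth (categories from the
#' condition-specific Markov chain, truncated-Gamma durations, agent
#' encounters that flatten the transition rows toward the uniform
#' distribution over non-agent categories for the following 30 s) and
#' renders it into a 90 Hz gaze-sample table: during fixations the gaze ray
#' tracks a fixed world point while the head translates (so uncorrected
#' angular velocity is inflated by walking), and fixations are separated by
#' saccades with symmetric triangular velocity profiles of 30-80 ms.
#'
#' @param config A [sim_config()].
#' @param participant,session Integer ids.
#' @param condition Agent condition governing the session's transition
#'   matrix.
#' @param blink_every Mean seconds between simulated blinks (invalid-sample
#'   gaps of 60 ms, short enough to be bridged by the classifier); `Inf`
#'   disables blinks.
#' @return List with `samples` (data frame: `t`, `gx`, `gy`, `gz`, `hx`,
#'   `hy`, `hz`, `hit_object_id`, `hit_distance`, `valid`) and `truth`
#'   (class `ground_truth`: `fixation_log`, `encounter_onsets`,
#'   `generating_coefficients`, `condition`).
#' @export
simulate_gaze_session <- function(config, participant = 1, session = 1,
                                  condition = "acontextual",
                                  blink_every = 15) {
  stopifnot(inherits(config, "sim_config"))
  P0 <- config$transition_matrix_by_condition[[condition]]
  if (is.null(P0)) stop("no transition matrix for condition ", condition,
                        call. = FALSE)
  seed <- derive_seed(config$seed, participant, session,
                      match(condition, agent_types()))
  with_seed(seed, {
    cats <- config$categories
    k <- length(cats)
    # post-encounter broadening: rows mixed toward the uniform distribution
    # over NON-agent categories, so scanning widens across the environment
    # without inflating the rate of further agent fixations (which would
    # cascade encounters and contaminate later pre windows)
    nonag <- !(cats %in% agent_categories())
    Q <- rep(0, k); Q[nonag] <- 1 / sum(nonag)
    lam <- config$encounter_flattening
    Ppost <- (1 - lam) * P0 + lam * matrix(Q, k, k, byrow = TRUE,
                                           dimnames = dimnames(P0))
    min_dur <- 0.15
    mean_dur <- min_dur + config$dwell_shape / config$dwell_rate
    n_guess <- ceiling(config$session_length / (mean_dur + 0.055)) + 10
    if (config$session_length < mean_dur + 0.2)
      stop("session_length too short for a single fixation", call. = FALSE)

    # --- ground-truth fixation log ---------------------------------------
    start <- numeric(n_guess); end <- numeric(n_guess)
    cat_ix <- integer(n_guess); obj <- character(n_guess)
    onsets <- numeric(0)
    flatten_until <- -Inf
    t <- 0; i <- 0
    prev <- sample.int(k, 1)
    n_objects <- c(background = 500, building = 236, task_residential = 26,
                   task_public = 26, landmark = 4, agent_acontextual = 28,
                   agent_congruent = 28, agent_incongruent = 28)
    while (TRUE) {
      dur <- min_dur + stats::rgamma(1, config$dwell_shape, config$dwell_rate)
      gap <- stats::runif(1, 0.03, 0.08)
      if (t + dur > config$session_length) break
      Pcur <- if (t < flatten_until) Ppost else P0
      nxt <- findInterval(stats::runif(1), cumsum(Pcur[prev, ])) + 1L
      if (nxt > k) nxt <- k
      i <- i + 1
      start[i] <- t; end[i] <- t + dur; cat_ix[i] <- nxt
      nobj <- n_objects[[cats[nxt]]]
      if (is.null(nobj)) nobj <- 50
      obj[i] <- sprintf("%s_%03d", cats[nxt], sample.int(nobj, 1))
      if (cats[nxt] %in% agent_categories()) {
        onsets <- c(onsets, t)
        flatten_until <- t + 30
      }
      t <- t + dur + gap
      prev <- nxt
    }
    if (i == 0) stop("session_length too short for a single fixation",
                     call. = FALSE)
    fixlog <- data.frame(start = start[1:i], end = end[1:i],
                         object_id = obj[1:i], category = cats[cat_ix[1:i]],
                         stringsAsFactors = FALSE)

    # --- render to 90 Hz samples ------------------------------------------
    dt <- 1 / config$sample_rate
    ts <- seq(0, config$session_length - dt, by = dt)
    ns <- length(ts)
    walk_v <- 1.0   # m/s
    head <- cbind(hx = walk_v * ts, hy = 0.2 * sin(0.1 * ts), hz = 1.7)
    G <- matrix(NA_real_, ns, 3)
    hit <- rep(NA_character_, ns)
    dist <- rep(NA_real_, ns)
    noise_sd <- config$fixation_velocity_noise * dt / (4 * 57.29578)
    d_prev <- .random_unit()
    for (f in seq_len(nrow(fixlog))) {
      idx <- which(ts >= fixlog$start[f] & ts < fixlog$end[f])
      if (!length(idx)) next
      d0 <- .random_unit(min_angle_from = d_prev, min_angle = 20)
      r <- stats::runif(1, 3, 30)
      tm <- mean(ts[idx])
      hp_mid <- c(walk_v * tm, 0.2 * sin(0.1 * tm), 1.7)
      W <- hp_mid + r * d0
      for (s_i in idx) {
        v <- W - head[s_i, ]
        v <- v / sqrt(sum(v^2))
        v <- v + stats::rnorm(3, 0, noise_sd)
        G[s_i, ] <- v / sqrt(sum(v^2))
      }
      hit[idx] <- fixlog$object_id[f]
      dist[idx] <- sqrt(sum((W - hp_mid)^2))
      # saccade samples between this fixation and the next: slerp-like path
      if (f < nrow(fixlog)) {
        gap_idx <- which(ts >= fixlog$end[f] & ts < fixlog$start[f + 1])
        if (length(gap_idx)) {
          frac <- seq_along(gap_idx) / (length(gap_idx) + 1)
          # triangular velocity profile: quadratic position ramp
          pos <- ifelse(frac < 0.5, 2 * frac^2, 1 - 2 * (1 - frac)^2)
          tgt <- .random_unit(min_angle_from = d0, min_angle = 25)
          for (j in seq_along(gap_idx))
            G[gap_idx[j], ] <- .rotate_towards(d0, tgt, pos[j])
        }
      }
      d_prev <- d0
    }
    # any unassigned samples (leading/trailing): hold previous direction
    na_rows <- which(is.na(G[, 1]))
    for (s_i in na_rows)
      G[s_i, ] <- if (s_i > 1 && !is.na(G[s_i - 1, 1])) G[s_i - 1, ]
                  else c(1, 0, 0)
    valid <- rep(TRUE, ns)
    if (is.finite(blink_every)) {
      n_blinks <- stats::rpois(1, config$session_length / blink_every)
      if (n_blinks > 0) {
        b0 <- stats::runif(n_blinks, 0, config$session_length - 0.1)
        for (b in b0) valid[ts >= b & ts < b + 0.06] <- FALSE
      }
    }
    samples <- data.frame(t = ts, gx = G[, 1], gy = G[, 2], gz = G[, 3],
                          hx = head[, 1], hy = head[, 2], hz = head[, 3],
                          hit_object_id = hit, hit_distance = dist,
                          valid = valid, stringsAsFactors = FALSE)
    truth <- structure(
      list(fixation_log = fixlog, encounter_onsets = onsets,
           generating_coefficients = config$true_coefficients,
           condition = condition, participant = participant,
           session = session, seed = seed),
      class = "ground_truth")
    list(samples = samples, truth = truth)
  })
}

# draw balanced factors and random intercepts shared by the model generators
.re_draws <- function(n_groups, sd) stats::rnorm(n_groups, 0, sd)

#' Simulate pointing-task trials from the performance model
#'
#' Generates trial-wise absolute pointing errors from the hierarchical
#' Gamma-log performance model: treatment-coded agent type, public/residential
#' building type, post-encounter GTE and z-scored dwell covariates enter a
#' log-linear predictor with participant and starting-location random
#' intercepts; errors are Gamma with mean `exp(linear predictor)` and shape
#' `kappa`.
#'
#' @param config A [sim_config()]; `config$true_coefficients$perf` must name
#'   `beta0, betaC, betaI, betaPub, betaGTE, betaDWA, betaDWB, kappa,
#'   sigma_u, sigma_v`.
#' @param n_trials Number of trials.
#' @param n_locations Number of pointing starting locations (default 28).
#' @param gte_post Optional vector (length `n_trials` or 1) of mediator
#'   values in `(0, 1)`; by default drawn from the mediator model.
#' @param seed Optional seed override (default derived from `config$seed`).
#' @return Data frame with columns `participant`, `start_location`,
#'   `agent_type`, `building_type`, `gte_post`, `dw_agent_z`,
#'   `dw_building_z`, `error`; attribute `ranef` holds the generating
#'   random-intercept draws.
#' @export
simulate_pointing_trials <- function(config, n_trials, n_locations = 28,
                                     gte_post = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  th <- config$true_coefficients$perf
  .need_coefs(th, c("beta0", "betaC", "betaI", "betaPub", "betaGTE",
                    "betaDWA", "betaDWB", "kappa", "sigma_u", "sigma_v"),
              "perf")
  if (is.null(seed)) seed <- derive_seed(config$seed, 104729)
  with_seed(seed, {
    if (n_trials == 0) {
      return(data.frame(participant = integer(0), start_location = integer(0),
                        agent_type = character(0), building_type = character(0),
                        gte_post = numeric(0), dw_agent_z = numeric(0),
                        dw_building_z = numeric(0), error = numeric(0)))
    }
    np <- config$n_participants
    part <- sample.int(np, n_trials, replace = TRUE)
    loc <- sample.int(n_locations, n_trials, replace = TRUE)
    atype <- sample(agent_types(), n_trials, replace = TRUE)
    btype <- sample(c("residential", "public"), n_trials, replace = TRUE)
    u <- .re_draws(np, th[["sigma_u"]])
    v <- .re_draws(n_locations, th[["sigma_v"]])
    if (is.null(gte_post)) {
      thm <- config$true_coefficients$mediator
      mu_m <- stats::plogis(thm[["beta0"]] +
                              thm[["betaC"]] * (atype == "congruent") +
                              thm[["betaI"]] * (atype == "incongruent") +
                              thm[["betaPub"]] * (btype == "public"))
      gte_post <- stats::rbeta(n_trials, mu_m * thm[["phi"]],
                               (1 - mu_m) * thm[["phi"]])
    } else {
      gte_post <- rep_len(gte_post, n_trials)
    }
    dwa <- stats::rnorm(n_trials)
    dwb <- stats::rnorm(n_trials)
    lp <- th[["beta0"]] +
      th[["betaC"]] * (atype == "congruent") +
      th[["betaI"]] * (atype == "incongruent") +
      th[["betaPub"]] * (btype == "public") +
      th[["betaGTE"]] * gte_post +
      th[["betaDWA"]] * dwa + th[["betaDWB"]] * dwb +
      u[part] + v[loc]
    mu <- exp(lp)
    err <- stats::rgamma(n_trials, shape = th[["kappa"]],
                         rate = th[["kappa"]] / mu)
    out <- data.frame(participant = part, start_location = loc,
                      agent_type = atype, building_type = btype,
                      gte_post = gte_post, dw_agent_z = dwa,
                      dw_building_z = dwb, error = err,
                      stringsAsFactors = FALSE)
    attr(out, "ranef") <- list(participant = u, start_location = v)
    out
  })
}

#' Simulate a linked mediator + outcome dataset
#'
#' Draws per-encounter post-encounter GTE from the Beta-logit mediator model
#' and trial-wise pointing errors from the Gamma-log outcome model using the
#' realized mediator values, sharing participant and starting-location keys,
#' so that downstream counterfactual mediation can be validated against the
#' generating coefficients.
#'
#' @inheritParams simulate_pointing_trials
#' @param n Number of rows (encounters = trials).
#' @return List with `mediator` and `trials` data frames (shared
#'   `participant` / `start_location` keys; `trials` carries the realized
#'   `gte_post` and the Gamma error).
#' @export
simulate_mediation_dataset <- function(config, n, n_locations = 28,
                                       seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  thm <- config$true_coefficients$mediator
  thy <- config$true_coefficients$perf
  .need_coefs(thm, c("beta0", "betaC", "betaI", "betaPub", "phi",
                     "sigma_u", "sigma_v"), "mediator")
  .need_coefs(thy, c("beta0", "betaC", "betaI", "betaPub", "betaGTE",
                     "betaDWA", "betaDWB", "kappa", "sigma_u", "sigma_v"),
              "perf")
  if (thm[["phi"]] <= 0) stop("phi must be positive", call. = FALSE)
  if (is.null(seed)) seed <- derive_seed(config$seed, 224737)
  with_seed(seed, {
    np <- config$n_participants
    part <- sample.int(np, n, replace = TRUE)
    loc <- sample.int(n_locations, n, replace = TRUE)
    atype <- sample(agent_types(), n, replace = TRUE)
    btype <- sample(c("residential", "public"), n, replace = TRUE)
    uM <- .re_draws(np, thm[["sigma_u"]])
    vM <- .re_draws(n_locations, thm[["sigma_v"]])
    mu_m <- stats::plogis(thm[["beta0"]] +
                            thm[["betaC"]] * (atype == "congruent") +
                            thm[["betaI"]] * (atype == "incongruent") +
                            thm[["betaPub"]] * (btype == "public") +
                            uM[part] + vM[loc])
    m <- stats::rbeta(n, mu_m * thm[["phi"]], (1 - mu_m) * thm[["phi"]])
    mediator <- data.frame(participant = part, start_location = loc,
                           agent_type = atype, building_type = btype,
                           gte_post = m, stringsAsFactors = FALSE)
    trials <- simulate_pointing_trials(
      config, n_trials = n, n_locations = n_locations, gte_post = m,
      seed = derive_seed(seed, 2))
    # align the designs: outcome rows must share keys and contrasts with the
    # mediator rows
    trials$participant <- part
    trials$start_location <- loc
    trials$agent_type <- atype
    trials$building_type <- btype
    uY <- .re_draws(np, thy[["sigma_u"]])
    vY <- .re_draws(n_locations, thy[["sigma_v"]])
    lp <- thy[["beta0"]] +
      thy[["betaC"]] * (atype == "congruent") +
      thy[["betaI"]] * (atype == "incongruent") +
      thy[["betaPub"]] * (btype == "public") +
      thy[["betaGTE"]] * m +
      thy[["betaDWA"]] * trials$dw_agent_z +
      thy[["betaDWB"]] * trials$dw_building_z +
      uY[part] + vY[loc]
    trials$error <- stats::rgamma(n, shape = thy[["kappa"]],
                                  rate = thy[["kappa"]] / exp(lp))
    attr(trials, "ranef") <- list(participant = uY, start_location = vY)
    attr(mediator, "ranef") <- list(participant = uM, start_location = vM)
    list(mediator = mediator, trials = trials)
  })
}

#' Simulate analysis records directly from one model's generative equation
#'
#' Produces observation-level data for any of the five regression models at
#' its generating coefficients, for parameter-recovery and coverage testing.
#'
#' @param config A [sim_config()].
#' @param model One of `"dwell"`, `"prepost"`, `"postgte"`, `"perf"`,
#'   `"mediator"`.
#' @param n Number of rows.
#' @param n_participants,n_sessions,n_locations Grouping sizes (defaults
#'   from `config`).
#' @param seed Optional seed override.
#' @return Data frame shaped for [fit_model()] (Beta responses on the raw
#'   `[0, 1]` scale via `H`; apply [sv_transform()] before fitting).
#' @export
simulate_model_data <- function(config, model, n,
                                n_participants = config$n_participants,
                                n_sessions = config$n_sessions,
                                n_locations = 28, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  model <- match.arg(model, c("dwell", "prepost", "postgte", "perf",
                              "mediator"))
  if (model == "perf")
    return(simulate_pointing_trials(config, n, n_locations, seed = seed))
  if (model == "mediator")
    return(simulate_mediation_dataset(config, n, n_locations,
                                      seed = seed)$mediator)
  th <- config$true_coefficients[[model]]
  if (is.null(seed)) seed <- derive_seed(config$seed, match(model, c(
    "dwell", "prepost", "postgte")) + 7)
  with_seed(seed, {
    part <- sample.int(n_participants, n, replace = TRUE)
    sess <- sample.int(n_sessions, n, replace = TRUE)
    u <- .re_draws(n_participants, th[["sigma_u"]])
    v <- matrix(stats::rnorm(n_participants * n_sessions, 0, th[["sigma_v"]]),
                n_participants, n_sessions)
    re <- u[part] + v[cbind(part, sess)]
    if (model == "dwell") {
      .need_coefs(th, c("beta0", "betaO", "betaC", "betaI", "betaOC",
                        "betaOI", "kappa"), "dwell")
      okind <- sample(c("building", "agent"), n, replace = TRUE)
      atype <- sample(agent_types(), n, replace = TRUE)
      O <- as.numeric(okind == "agent")
      TC <- as.numeric(atype == "congruent")
      TI <- as.numeric(atype == "incongruent")
      lp <- th[["beta0"]] + th[["betaO"]] * O + th[["betaC"]] * TC +
        th[["betaI"]] * TI + th[["betaOC"]] * O * TC +
        th[["betaOI"]] * O * TI + re
      dwell <- stats::rgamma(n, th[["kappa"]], th[["kappa"]] / exp(lp))
      out <- data.frame(participant = part, session = sess,
                        object_kind = okind, agent_type = atype,
                        dwell = dwell, stringsAsFactors = FALSE)
    } else if (model == "prepost") {
      .need_coefs(th, c("beta0", "betaP", "phi"), "prepost")
      prepost <- sample(0:1, n, replace = TRUE)
      kk <- sample.int(20, n, replace = TRUE)
      mu <- stats::plogis(th[["beta0"]] + th[["betaP"]] * prepost + re)
      H <- stats::rbeta(n, mu * th[["phi"]], (1 - mu) * th[["phi"]])
      out <- data.frame(participant = part, session = sess,
                        prepost = prepost, encounter_index = kk, H = H)
    } else {   # postgte
      .need_coefs(th, c("beta0", "gamma1", "gamma2", "phi"), "postgte")
      atype <- sample(agent_types(), n, replace = TRUE)
      Z <- code_contrasts(agent_types(), "sum")
      z <- Z[match(atype, agent_types()), , drop = FALSE]
      mu <- stats::plogis(th[["beta0"]] + th[["gamma1"]] * z[, 1] +
                            th[["gamma2"]] * z[, 2] + re)
      H <- stats::rbeta(n, mu * th[["phi"]], (1 - mu) * th[["phi"]])
      out <- data.frame(participant = part, session = sess,
                        agent_type = atype, H = H, stringsAsFactors = FALSE)
    }
    attr(out, "ranef") <- list(participant = u, session = v)
    out
  })
}

#' Write a simulation config to JSON
#'
#' Serializes every scalar field plus the transition matrices and generating
#' coefficients, seed included, so a run can be reproduced from its sidecar.
#'
#' @param config A [sim_config()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
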