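# Counterfactual mediation of agent context on pointing error through
# post-encounter gaze transition entropy, by Bayesian parametric
# g-computation: per replication, one mediator-model draw and one
# outcome-model draw are paired at random, the plug-in mediator mean under
# each agent level and context is pushed through the outcome model with
# random intercepts at zero and dwell covariates at their standardized
# means, and context-marginal potential outcomes are averaged with the
# empirical residential/public weights.

.agent_dummies <- function(level) {
  c(C = as.numeric(level == "congruent"),
    I = as.numeric(level == "incongruent"))
}

#' Plug-in mediator mean under an agent level and context
#'
#' Inverse-logit of the mediator model's linear predictor with random
#' intercepts at zero (average participant and starting location). The Beta
#' precision affects dispersion only, so no stochastic Beta draw is needed
#' for a point prediction.
#'
#' @param draw Named numeric vector of mediator-model coefficients
#'   (`beta0`, `betaC`, `betaI`, `betaPub`).
#' @param a_k Agent level generating the mediator (`"acontextual"`,
#'   `"congruent"`, `"incongruent"`).
#' @param context `"residential"` or `"public"`.
#' @return Mediator mean in `(0, 1)`.
#' @export
mediator_mean <- function(draw, a_k, context = c("residential", "public")) {
  context <- match.arg(context)
  need <- c("beta0", "betaC", "betaI", "betaPub")
  missing <- setdiff(need, names(draw))
  if (length(missing))
    stop("missing mediator coefficient(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dd <- .agent_dummies(a_k)
  stats::plogis(draw[["beta0"]] + draw[["betaC"]] * dd["C"] +
                  draw[["betaI"]] * dd["I"] +
                  draw[["betaPub"]] * (context == "public"))[[1]]
}

#' Expected pointing error under an agent level, mediator value and context
#'
#' Gamma-log outcome mean with dwell covariates pinned at 0 on the z-scale
#' and random intercepts at zero: `exp(beta0 + betaC C_j + betaI I_j +
#' betaPub P_c + betaGTE m)`.
#'
#' @param drawY Named numeric vector of outcome-model coefficients
#'   (`beta0`, `betaC`, `betaI`, `betaPub`, `betaGTE`).
#' @param a_j Agent level at which the outcome model is evaluated.
#' @param m Mediator value in `(0, 1)`.
#' @param context `"residential"` or `"public"`.
#' @return Expected absolute pointing error (> 0).
#' @export
outcome_mean <- function(drawY, a_j, m, context = c("residential", "public")) {
  context <- match.arg(context)
  if (any(m <= 0 | m >= 1))
    stop("mediator value must lie strictly inside (0, 1)", call. = FALSE)
  need <- c("beta0", "betaC", "betaI", "betaPub", "betaGTE")
  missing <- setdiff(need, names(drawY))
  if (length(missing))
    stop("missing outcome coefficient(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dd <- .agent_dummies(a_j)
  exp(drawY[["beta0"]] + drawY[["betaC"]] * dd[["C"]] +
        drawY[["betaI"]] * dd[["I"]] +
        drawY[["betaPub"]] * (context == "public") +
        drawY[["betaGTE"]] * m)
}

#' Mediation input bundle
#'
#' @param mediator_posterior,outcome_posterior Fitted `gaze_posterior`
#'   objects (or plain draw matrices with registry column names) for the
#'   mediator and performance models.
#' @param w_res,w_pub Empirical context weights (non-negative, sum to 1).
#' @param a1 Treatment agent level (baseline is always acontextual).
#' @param R Number of g-computation replications.
#' @param seed Integer seed for the draw pairing.
#' @return Object of class `mediation_input`.
#' @export
mediation_input <- function(mediator_posterior, outcome_posterior,
                            w_res = 0.5, w_pub = 1 - w_res,
                            a1 = c("congruent", "incongruent"),
                            R = 4000, seed = 1) {
  a1 <- match.arg(a1)
  if (w_res < 0 || w_pub < 0 || abs(w_res + w_pub - 1) > 1e-9)
    stop("context weights must be non-negative and sum to 1", call. = FALSE)
  getdraws <- function(x) if (inherits(x, "gaze_posterior")) x$draws else x
  structure(
    list(mediator = getdraws(mediator_posterior),
         outcome = getdraws(outcome_posterior),
         w_res = w_res, w_pub = w_pub, a1 = a1, R = R,
         seed = as.integer(seed)),
    class = "mediation_input")
}

#' Potential outcomes per g-computation replication
#'
#' For each replication, pairs one mediator-model draw with one
#' outcome-model draw (independent uniform sampling with replacement,
#' seeded) and forms the three context-marginal counterfactuals: `Y00`
#' (mediator and outcome at baseline), `Y10` (outcome at treatment, mediator
#' held at baseline), `Y11` (both at treatment). The same context enters the
#' mediator and outcome pieces, then contexts are averaged with the
#' empirical weights.
#'
#' @param input A [mediation_input()].
#' @return Data frame with `R` rows: `Y00`, `Y10`, `Y11` (all > 0).
#' @export
potential_outcomes <- function(input) {
  stopifnot(inherits(input, "mediation_input"))
  with_seed(input$seed, {
    Rn <- input$R
    im <- sample.int(nrow(input$mediator), Rn, replace = TRUE)
    io <- sample.int(nrow(input$outcome), Rn, replace = TRUE)
    M <- input$mediator[im, , drop = FALSE]
    O <- input$outcome[io, , drop = FALSE]
    lvl <- c("acontextual", input$a1)
    ctxs <- c("residential", "public")
    w <- c(residential = input$w_res, public = input$w_pub)
    # vectorized over draws: mediator mean per (k, c), outcome per (j, k, c)
    mu_m <- function(k, ctx)
      stats::plogis(M[, "beta0"] +
                      M[, "betaC"] * (lvl[k + 1] == "congruent") +
                      M[, "betaI"] * (lvl[k + 1] == "incongruent") +
                      M[, "betaPub"] * (ctx == "public"))
    mu_y <- function(j, k, ctx)
      exp(O[, "beta0"] +
            O[, "betaC"] * (lvl[j + 1] == "congruent") +
            O[, "betaI"] * (lvl[j + 1] == "incongruent") +
            O[, "betaPub"] * (ctx == "public") +
            O[, "betaGTE"] * mu_m(k, ctx))
    Yjk <- function(j, k)
      w["residential"] * mu_y(j, k, "residential") +
      w["public"] * mu_y(j, k, "public")
    data.frame(Y00 = Yjk(0, 0), Y10 = Yjk(1, 0), Y11 = Yjk(1, 1))
  })
}

#' Natural direct, indirect, and total effects from potential outcomes
#'
#' Per draw: `NDE = Y10 - Y00`, `NIE = Y11 - Y10`, `TE = Y11 - Y00`, and the
#' risk-ratio counterparts `RR_NDE = Y10/Y00`, `RR_NIE = Y11/Y10`,
#' `RR_TE = Y11/Y00`. The additive (`TE = NDE + NIE`) and multiplicative
#' (`RR_TE = RR_NDE * RR_NIE`) decompositions hold exactly per draw by
#' construction.
#'
#' @param po Data frame of potential outcomes (`Y00`, `Y10`, `Y11`).
#' @return Object of class `mediation_effects`: list with `draws` (per-draw
#'   effects) and `summary` (posterior mean and 95% credible interval per
#'   effect).
#' @export
mediation_effects <- function(po) {
  stopifnot(nrow(po) >= 1, all(c("Y00", "Y10", "Y11") %in% names(po)))
  d <- data.frame(
    NDE = po$Y10 - po$Y00, NIE = po$Y11 - po$Y10, TE = po$Y11 - po$Y00,
    RR_NDE = po$Y10 / po$Y00, RR_NIE = po$Y11 / po$Y10,
    RR_TE = po$Y11 / po$Y00)
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  s <- do.call(rbind, lapply(names(d), function(nm) {
    q <- qs(d[[nm]])
    data.frame(effect = nm, mean = mean(d[[nm]]), lower = q[1], upper = q[2],
               stringsAsFactors = FALSE)
  }))
  structure(list(draws = d, summary = s), class = "mediation_effects")
}

#' @export
print.mediation_effects <- function(x, ...) {
  cat("Counterfactual mediation effects (posterior mean [95% CrI])\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Run the full counterfactual mediation analysis
#'
#' Composes [potential_outcomes()] and [mediation_effects()] for one or both
#' treatment contrasts against the acontextual baseline.
#'
#' @inheritParams mediation_input
#' @param contrast `"congruent"`, `"incongruent"`, or `"both"`.
#' @return Named list of `mediation_effects`, one per contrast, with
#'   attribute `seed`.
#' @export
run_mediation <- function(mediator_posterior, outcome_posterior,
                          w_res = 0.5, w_pub = 1 - w_res,
                          contrast = c("both", "congruent", "incongruent"),
                          R = 4000, seed = 1) {
  contrast <- match.arg(contrast)
  levels <- if (contrast == "both") c("congruent", "incongruent")
            else contrast
  out <- lapply(levels, function(a1) {
    inp <- mediation_input(mediator_posterior, outcome_posterior,
                           w_res = w_res, w_pub = w_pub, a1 = a1, R = R,
                           seed = derive_seed(seed, match(a1, agent_types())))
    mediation_effects(potential_outcomes(inp))
  })
  names(out) <- levels
  attr(out, "seed") <- seed
  out
}

#' Closed-form mediation effects at known coefficients
#'
#' Evaluates the g-computation identities at fixed (e.g. generating)
#' mediator and outcome coefficients, giving the exact truth that a
#' simulation-based analysis should recover.
#'
#' @param theta_m Named mediator coefficients (`beta0`, `betaC`, `betaI`,
#'   `betaPub`).
#' @param theta_y Named outcome coefficients (`beta0`, `betaC`, `betaI`,
#'   `betaPub`, `betaGTE`).
#' @inheritParams mediation_input
#' @return Named numeric vector: `NDE`, `NIE`, `TE`, `RR_NDE`, `RR_NIE`,
#'   `RR_TE`.
#' @export
mediation_truth <- function(theta_m, theta_y, a1, w_res = 0.5,
                            w_pub = 1 - w_res) {
  lvl <- c("acontextual", a1)
  Y <- function(j, k) {
    sum(vapply(c("residential", "public"), function(ctx) {
      m <- mediator_mean(theta_m, lvl[k + 1], ctx)
      wgt <- if (ctx == "residential") w_res else w_pub
      wgt * outcome_mean(theta_y, lvl[j + 1], m, ctx)
    }, numeric(1)))
  }
  y00 <- Y(0, 0); y10 <- Y(1, 0); y11 <- Y(1, 1)
  c(NDE = y10 - y00, NIE = y11 - y10, TE = y11 - y00,
    RR_NDE = y10 / y00, RR_NIE = y11 / y10, RR_TE = y11 / y00)
}
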