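# Declarative specification and MCMC fitting of the five Bayesian
# hierarchical regressions: dwelling time (Gamma-log), pre/post entropy
# (Beta-logit with a spline over encounter index), post-encounter entropy
# (Beta-logit, sum contrasts), pointing performance (Gamma-log) and the
# mediator model for post-encounter GTE (Beta-logit). Sampling via JAGS.

#' Smithson-Verkuilen transform
#'
#' Squeezes responses on the closed unit interval into the open interval
#' required by a Beta likelihood: `H* = (H * (n - 1) + 0.5) / n`, where `n`
#' is the analysis-sample size.
#'
#' @param H Numeric vector in `[0, 1]`.
#' @param n Analysis-sample size (>= 1).
#' @return Numeric vector strictly inside `(0, 1)`.
#' @export
sv_transform <- function(H, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (any(H < 0 | H > 1, na.rm = TRUE))
    stop("H must lie in [0, 1]", call. = FALSE)
  (H * (n - 1) + 0.5) / n
}

#' Contrast coding for a categorical factor
#'
#' `"treatment"`: reference level (first) coded all-zero, each other level an
#' indicator column. `"sum"` (sum-to-zero / effect coding): with three levels
#' in order, rows are `(1, 0)`, `(0, 1)`, `(-1, -1)`, so the intercept is the
#' grand mean and coefficients are level deviations.
#'
#' @param levels Ordered character vector of 2 or 3 levels.
#' @param scheme `"treatment"` or `"sum"`.
#' @return Numeric matrix with one row per level, `length(levels) - 1`
#'   columns, rownames = levels.
#' @export
code_contrasts <- function(levels, scheme = c("treatment", "sum")) {
  if (length(scheme) != 1 || !scheme %in% c("treatment", "sum"))
    stop("unknown contrast scheme: ", paste(scheme, collapse = ","),
         call. = FALSE)
  L <- length(levels)
  if (L < 2 || L > 3) stop("2 or 3 levels supported", call. = FALSE)
  if (scheme == "treatment") {
    M <- diag(L)[, -1, drop = FALSE]
  } else {
    M <- stats::contr.sum(L)
  }
  dimnames(M) <- list(levels, paste0("Z", seq_len(L - 1)))
  M
}

#' Centered cubic regression-spline basis
#'
#' Builds a cubic regression-spline basis of the requested dimension over
#' the observed range of the encounter index and centers every column, so
#' the smooth carries no intercept. Coefficients on these columns receive a
#' hierarchical shrinkage (smooth-SD) prior in [fit_model()].
#'
#' @param k_values Numeric vector of encounter indices.
#' @param dim Basis dimension (default 5).
#' @return Matrix with `length(k_values)` rows and `dim` columns (column
#'   means zero); attribute `smooth` stores the mgcv smooth object for
#'   prediction.
#' @export
spline_basis <- function(k_values, dim = 5) {
  if (!length(k_values)) stop("k_values must be non-empty", call. = FALSE)
  n_unique <- length(unique(k_values))
  if (n_unique < 2)
    stop("degenerate spline basis: fewer than 2 distinct index values",
         call. = FALSE)
  if (n_unique < dim) {
    warning(sprintf("only %d distinct index values; spline dimension reduced from %d",
                    n_unique, dim))
    dim <- n_unique
  }
  sm <- mgcv::smoothCon(mgcv::s(k, k = dim, bs = "cr"),
                        data = data.frame(k = as.numeric(k_values)),
                        absorb.cons = FALSE)[[1]]
  X <- sm$X
  X <- sweep(X, 2, colMeans(X))
  colnames(X) <- paste0("s", seq_len(ncol(X)))
  attr(X, "smooth") <- sm
  X
}

#' MCMC sampler profile
#'
#' `"full"`: four chains of 6,000 iterations including 3,000 warmup, the
#' production setting. `"test"`: two chains of 1,000 iterations including
#' 500 warmup, for desk-scale runs.
#'
#' @param profile `"test"` or `"full"`; individual fields may be
#'   overridden.
#' @param chains,iter,warmup Optional overrides.
#' @return List with `chains`, `iter`, `warmup`, `profile`.
#' @export
mcmc_profile <- function(profile = c("test", "full"), chains = NULL,
                         iter = NULL, warmup = NULL) {
  profile <- match.arg(profile)
  p <- if (profile == "full") list(chains = 4, iter = 6000, warmup = 3000)
       else list(chains = 2, iter = 1000, warmup = 500)
  if (!is.null(chains)) p$chains <- chains
  if (!is.null(iter)) p$iter <- iter
  if (!is.null(warmup)) p$warmup <- warmup
  p$profile <- profile
  p
}

# coefficient registries, one per model
.registry <- list(
  dwell = c("beta0", "betaO", "betaC", "betaI", "betaOC", "betaOI",
            "kappa", "sigma_u", "sigma_v"),
  prepost = c("beta0", "betaP", paste0("s", 1:5), "phi",
              "sigma_u", "sigma_v", "sigma_s"),
  postgte = c("beta0", "gamma1", "gamma2", "phi", "sigma_u", "sigma_v"),
  perf = c("beta0", "betaC", "betaI", "betaPub", "betaGTE", "betaDWA",
           "betaDWB", "kappa", "sigma_u", "sigma_v"),
  mediator = c("beta0", "betaC", "betaI", "betaPub", "phi",
               "sigma_u", "sigma_v"))

#' Declarative specification of one hierarchical regression
#'
#' Returns the likelihood, link, contrast scheme, random-effect structure,
#' priors, and coefficient registry of one of the five models:
#' \describe{
#'   \item{dwell}{Gamma-log model of per-object dwelling time on object kind
#'     (building/agent), agent condition (treatment dummies) and their
#'     interaction; nested intercepts participant + session-in-participant.}
#'   \item{prepost}{Beta-logit model of windowed entropy on a pre/post
#'     indicator plus a dimension-5 smoothing spline over encounter index;
#'     nested intercepts.}
#'   \item{postgte}{Beta-logit model of post-encounter entropy on agent
#'     condition under sum-to-zero contrasts; nested intercepts.}
#'   \item{perf}{Gamma-log model of absolute pointing error on agent
#'     condition, building type, post-encounter GTE and z-scored dwell
#'     covariates; crossed intercepts participant + starting location.}
#'   \item{mediator}{Beta-logit model of post-encounter GTE on agent
#'     condition and building type; crossed intercepts.}
#' }
#'
#' @param name One of `"dwell"`, `"prepost"`, `"postgte"`, `"perf"`,
#'   `"mediator"`.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name = c("dwell", "prepost", "postgte", "perf",
                                "mediator")) {
  name <- match.arg(name)
  base <- list(name = name, registry = .registry[[name]])
  spec <- switch(name,
    dwell = c(base, list(
      likelihood = "gamma_log", response = "dwell", contrasts = "treatment",
      ranef = "nested", spline = FALSE,
      fixed = c("beta0", "betaO", "betaC", "betaI", "betaOC", "betaOI"))),
    prepost = c(base, list(
      likelihood = "beta_logit", response = "H_star",
      contrasts = "treatment", ranef = "nested", spline = TRUE,
      fixed = c("beta0", "betaP"))),
    postgte = c(base, list(
      likelihood = "beta_logit", response = "H_star", contrasts = "sum",
      ranef = "nested", spline = FALSE,
      fixed = c("beta0", "gamma1", "gamma2"))),
    perf = c(base, list(
      likelihood = "gamma_log", response = "error", contrasts = "treatment",
      ranef = "crossed", spline = FALSE,
      fixed = c("beta0", "betaC", "betaI", "betaPub", "betaGTE",
                "betaDWA", "betaDWB"))),
    mediator = c(base, list(
      likelihood = "beta_logit", response = "M_star", contrasts = "treatment",
      ranef = "crossed", spline = FALSE,
      fixed = c("beta0", "betaC", "betaI", "betaPub"))))
  structure(spec, class = "model_spec")
}

# build the fixed-effect design matrix (and spline matrix) for a spec
.design <- function(spec, data) {
  n <- nrow(data)
  at <- function() factor(data$agent_type, levels = agent_types())
  X <- switch(spec$name,
    dwell = {
      O <- as.numeric(data$object_kind == "agent")
      Z <- code_contrasts(agent_types(), "treatment")
      z <- Z[as.integer(at()), , drop = FALSE]
      cbind(beta0 = 1, betaO = O, betaC = z[, 1], betaI = z[, 2],
            betaOC = O * z[, 1], betaOI = O * z[, 2])
    },
    prepost = cbind(beta0 = 1, betaP = as.numeric(data$prepost)),
    postgte = {
      Z <- code_contrasts(agent_types(), "sum")
      z <- Z[as.integer(at()), , drop = FALSE]
      cbind(beta0 = 1, gamma1 = z[, 1], gamma2 = z[, 2])
    },
    perf = {
      Z <- code_contrasts(agent_types(), "treatment")
      z <- Z[as.integer(at()), , drop = FALSE]
      cbind(beta0 = 1, betaC = z[, 1], betaI = z[, 2],
            betaPub = as.numeric(data$building_type == "public"),
            betaGTE = data$gte_post,
            betaDWA = data$dw_agent_z, betaDWB = data$dw_building_z)
    },
    mediator = {
      Z <- code_contrasts(agent_types(), "treatment")
      z <- Z[as.integer(at()), , drop = FALSE]
      cbind(beta0 = 1, betaC = z[, 1], betaI = z[, 2],
            betaPub = as.numeric(data$building_type == "public"))
    })
  S <- NULL
  if (isTRUE(spec$spline)) S <- spline_basis(data$encounter_index, dim = 5)
  g1 <- as.integer(factor(data$participant))
  if (spec$ranef == "nested") {
    f2 <- factor(paste(data$participant, data$session, sep = ":"))
    g2 <- as.integer(f2)
    # parent participant of each session-in-participant level
    par2 <- g1[match(levels(f2), as.character(f2))]
  } else {
    g2 <- as.integer(factor(data$start_location))
    par2 <- NULL
  }
  list(X = X, S = S, g1 = g1, g2 = g2, par2 = par2, n = n)
}

# JAGS model code for a family / spline / random-effect combination
.jags_code <- function(likelihood, spline, nested) {
  lik <- if (likelihood == "gamma_log") "
    log(mu[i]) <- eta[i]
    y[i] ~ dgamma(kappa, kappa / mu[i])" else "
    logit(mu[i]) <- eta[i]
    y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)"
  eta_s <- if (spline) " + inprod(S[i, ], bs[])" else ""
  priors <- if (likelihood == "gamma_log") "
  b[1] ~ dt(0, pow(2.5, -2), 1)
  for (j in 2:p) { b[j] ~ dnorm(0, 1) }
  sigma_u ~ dt(0, pow(2.5, -2), 1) T(0,)
  sigma_v ~ dt(0, pow(2.5, -2), 1) T(0,)
  kappa ~ dgamma(0.01, 0.01)" else "
  b[1] ~ dt(0, pow(2.5, -2), 3)
  for (j in 2:p) { b[j] ~ dnorm(0, 1) }
  sigma_u ~ dt(0, pow(2.5, -2), 3) T(0,)
  sigma_v ~ dt(0, pow(2.5, -2), 3) T(0,)
  phi ~ dgamma(0.01, 0.01)"
  spl <- if (spline) "
  for (j in 1:ps) { zs[j] ~ dnorm(0, 1); bs[j] <- sigma_s * zs[j] }
  sigma_s ~ dt(0, pow(0.8, -2), 3) T(0,)" else ""
  # intercepts are hierarchically centered (participant level on the
  # population intercept; for nested designs the session level on its
  # participant), which mixes far better than zero-mean deviations when
  # groups are data-rich; crossed second levels and the spline stay
  # non-centered, avoiding the funnel when their SDs are small
  re <- if (nested) "
  for (i in 1:n) {
    eta[i] <- inprod(X[i, ], bs_l[])%s + vv[g2[i]]%s
  }
  for (j in 1:n2) { vv[j] ~ dnorm(uu[par2[j]], pow(sigma_v, -2)) }
  for (j in 1:n1) { uu[j] ~ dnorm(b[1], pow(sigma_u, -2)) }" else "
  for (i in 1:n) {
    eta[i] <- inprod(X[i, ], bs_l[])%s + uu[g1[i]] + sigma_v * zv[g2[i]]%s
  }
  for (j in 1:n1) { uu[j] ~ dnorm(b[1], pow(sigma_u, -2)) }
  for (j in 1:n2) { zv[j] ~ dnorm(0, 1) }"
  re <- sprintf(re, eta_s, lik)
  sprintf("model {%s
  for (j in 1:p) { bs_l[j] <- b[j] * (1 - equals(j, 1)) }%s%s
}", re, priors, spl)
}

#' Fit a hierarchical model specification by MCMC
#'
#' Assembles the design implied by a [model_spec()], validates the response
#' (strictly positive for Gamma likelihoods, strictly inside `(0, 1)` for
#' Beta likelihoods — apply [sv_transform()] upstream), and samples the
#' posterior with JAGS under the weakly-informative priors of the spec:
#' Normal(0, 1) slopes; Cauchy(0, 2.5) intercept and group SDs for Gamma
#' models; Student-t(3, 0, 2.5) intercept and group SDs plus
#' Student-t(3, 0, 0.8) smooth SDs for Beta models. Convergence is assessed
#' by split-chain R-hat; a fit with any reported R-hat >= 1.01 is flagged
#' (with a warning), never silently returned as converged.
#'
#' @param spec A [model_spec()].
#' @param data Data frame carrying the columns the spec requires (see
#'   [model_spec()]); Beta responses must already be SV-transformed
#'   (`H_star` / `M_star`).
#' @param mcmc An [mcmc_profile()].
#' @param seed Integer seed; fanned out to per-chain RNG states.
#' @param quiet Suppress JAGS progress output (default `TRUE`).
#' @return Object of class `gaze_posterior`: `draws` (matrix, one column per
#'   registry coefficient, link scale), `rhat`, `ess`, `converged`,
#'   `spec`, `mcmc`, `seed`, `n_obs`.
#' @export
fit_model <- function(spec, data, mcmc = mcmc_profile("test"), seed = 1,
                      quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  y <- data[[spec$response]]
  if (is.null(y)) {
    # mediator fits accept a raw gte_post column transformed by the caller
    stop("data lacks required response column '", spec$response, "'",
         call. = FALSE)
  }
  if (spec$likelihood == "gamma_log" && any(y <= 0))
    stop("Gamma response must be strictly positive", call. = FALSE)
  if (spec$likelihood == "beta_logit" && any(y <= 0 | y >= 1))
    stop("Beta response must lie strictly inside (0, 1); apply ",
         "sv_transform() first", call. = FALSE)
  d <- .design(spec, data)
  # center non-intercept columns for sampling (removes the intercept/slope
  # ridge); the intercept is reconstructed on the original scale afterwards
  mx <- c(0, colMeans(d$X[, -1, drop = FALSE]))
  Xc <- d$X
  if (ncol(Xc) > 1)
    Xc[, -1] <- sweep(Xc[, -1, drop = FALSE], 2, mx[-1])
  nested <- spec$ranef == "nested"
  jd <- list(y = y, X = Xc, n = d$n, p = ncol(d$X), g1 = d$g1, g2 = d$g2,
             n1 = max(d$g1), n2 = max(d$g2))
  if (nested) jd$par2 <- d$par2
  if (!nested) jd$g1 <- d$g1 else jd$g1 <- NULL
  if (isTRUE(spec$spline)) { jd$S <- d$S; jd$ps <- ncol(d$S) }
  code <- .jags_code(spec$likelihood, isTRUE(spec$spline), nested)
  # GLM-based starting values keep short chains well inside the typical set
  eta0 <- if (spec$likelihood == "gamma_log") log(y) else stats::qlogis(y)
  b0 <- tryCatch(stats::lm.fit(Xc, eta0)$coefficients,
                 error = function(e) rep(0, ncol(d$X)))
  b0[!is.finite(b0)] <- 0
  inits <- with_seed(derive_seed(seed, 999), lapply(seq_len(mcmc$chains), function(ch) {
    jit <- function(x, s) x + stats::rnorm(length(x), 0, s)
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = derive_seed(seed, ch),
                b = jit(unname(b0), 0.05),
                uu = rep(unname(b0[1]), jd$n1),
                sigma_u = 0.2, sigma_v = 0.2)
    if (nested) ini$vv <- rep(unname(b0[1]), jd$n2)
    else ini$zv <- rep(0, jd$n2)
    if (spec$likelihood == "gamma_log") ini$kappa <- 2 else ini$phi <- 20
    if (isTRUE(spec$spline)) { ini$zs <- rep(0, jd$ps); ini$sigma_s <- 0.3 }
    ini
  }))
  monitors <- c("b", "sigma_u", "sigma_v",
                if (spec$likelihood == "gamma_log") "kappa" else "phi",
                if (isTRUE(spec$spline)) c("bs", "sigma_s"))
  n_adapt <- max(100L, floor(mcmc$warmup / 2))
  n_burn <- mcmc$warmup - n_adapt
  run <- function() {
    jm <- rjags::jags.model(textConnection(code), data = jd,
                            n.chains = mcmc$chains, n.adapt = n_adapt,
                            inits = inits, quiet = TRUE)
    if (n_burn > 0) stats::update(jm, n_burn, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = mcmc$iter - mcmc$warmup,
                        progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()
  # undo the column centering: b[1]_orig = b[1]_c - sum_j b[j] * mean_j
  if (any(mx != 0)) {
    samp <- coda::as.mcmc.list(lapply(samp, function(ch) {
      M <- as.matrix(ch)
      bcols <- sprintf("b[%d]", seq_len(ncol(d$X)))
      M[, "b[1]"] <- M[, "b[1]"] - M[, bcols, drop = FALSE] %*% mx
      coda::mcmc(M, start = stats::start(ch), thin = coda::thin(ch))
    }))
  }
  # rename JAGS parameters to registry names
  nm <- colnames(samp[[1]])
  new <- nm
  new[nm == "kappa"] <- "kappa"; new[nm == "phi"] <- "phi"
  fx <- spec$fixed
  for (j in seq_along(fx)) new[nm == sprintf("b[%d]", j)] <- fx[j]
  if (isTRUE(spec$spline))
    for (j in seq_len(jd$ps)) new[nm == sprintf("bs[%d]", j)] <- sprintf("s%d", j)
  rh <- tryCatch(
    coda::gelman.diag(samp, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1],
    error = function(e) stats::setNames(rep(NA_real_, length(nm)), nm))
  ess <- coda::effectiveSize(samp)
  draws <- do.call(rbind, lapply(samp, as.matrix))
  colnames(draws) <- new
  names(rh) <- new; names(ess) <- new
  keep <- intersect(spec$registry, new)
  converged <- all(rh[keep] < 1.01, na.rm = TRUE)
  if (!converged)
    warning(sprintf("model '%s' flagged non-converged: max R-hat = %.3f",
                    spec$name, max(rh[keep], na.rm = TRUE)))
  structure(
    list(draws = draws[, keep, drop = FALSE], rhat = rh[keep],
         ess = ess[keep], converged = converged, spec = spec, mcmc = mcmc,
         seed = seed, n_obs = d$n),
    class = "gaze_posterior")
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing a given probability mass of the draws.
#'
#' @param x Numeric vector of posterior draws.
#' @param prob Probability mass (default 0.89).
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.89) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  m <- max(1L, floor(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  w <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(w)
  c(x[i], x[i + m])
}

#' Summarize a fitted posterior
#'
#' @param post A `gaze_posterior`.
#' @param prob Interval probability: 0.89 (highest-density, the default
#'   reporting convention) or 0.95 are both supported.
#' @return Data frame: `coefficient`, `mean`, `lower`, `upper`, `rhat`,
#'   `ess`.
#' @export
summarize_posterior <- function(post, prob = 0.89) {
  stopifnot(inherits(post, "gaze_posterior"))
  draws <- post$draws
  out <- data.frame(
    coefficient = colnames(draws),
    mean = colMeans(draws),
    lower = apply(draws, 2, function(x) hdi(x, prob)[1]),
    upper = apply(draws, 2, function(x) hdi(x, prob)[2]),
    rhat = as.numeric(post$rhat[colnames(draws)]),
    ess = as.numeric(post$ess[colnames(draws)]),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prob") <- prob
  out
}

#' @export
print.gaze_posterior <- function(x, ...) {
  cat(sprintf("Hierarchical model '%s' (%s), %d obs, %d draws%s\n",
              x$spec$name, x$spec$likelihood, x$n_obs, nrow(x$draws),
              if (x$converged) "" else "  [NON-CONVERGED]"))
  print(summarize_posterior(x), digits = 3)
  invisible(x)
}

#' Back-transform a link-scale effect
#'
#' @param beta Finite link-scale coefficient.
#' @param link `"log"` or `"logit"` (the model's link; used for input
#'   checking only).
#' @param mode `"percent_change"` (`100 * (exp(beta) - 1)`), `"odds_ratio"`
#'   (`exp(beta)`), or `"inv_logit"` (`1 / (1 + exp(-beta))`).
#' @return Transformed value.
#' @export
effect_transform <- function(beta, link = c("log", "logit"),
                             mode = c("percent_change", "odds_ratio",
                                      "inv_logit")) {
  link <- match.arg(link)
  mode <- match.arg(mode)
  stopifnot(is.finite(beta))
  switch(mode,
         percent_change = 100 * (exp(beta) - 1),
         odds_ratio = exp(beta),
         inv_logit = stats::plogis(beta))
}

#' z-score a covariate, retaining the scaling
#'
#' @param x Numeric vector.
#' @return Scaled vector with attributes `center` and `scale`, so that
#'   counterfactual predictions can pin the covariate at its mean (0 on the
#'   z-scale).
#' @export
zscore <- function(x) {
  m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) s <- 1
  out <- (x - m) / s
  attr(out, "center") <- m; attr(out, "scale") <- s
  out
}
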