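test_that("Smithson-Verkuilen transform squeezes to the open interval", {
  expect_equal(sv_transform(0, 100), 0.005)
  expect_equal(sv_transform(1, 100), 0.995)
  expect_equal(sv_transform(0.5, 17), 0.5)
  expect_equal(sv_transform(0.5, 100000), 0.5)
  expect_error(sv_transform(1.2, 10), "\\[0, 1\\]")
  expect_error(sv_transform(0.5, 0), "n must be")
  h <- runif(50)
  expect_true(all(sv_transform(h, 50) > 0 & sv_transform(h, 50) < 1))
})

test_that("contrast coding produces the stated design rows", {
  Z <- code_contrasts(agent_types(), "sum")
  expect_equal(unname(Z["acontextual", ]), c(1, 0))
  expect_equal(unname(Z["congruent", ]), c(0, 1))
  expect_equal(unname(Z["incongruent", ]), c(-1, -1))
  expect_equal(unname(colSums(Z)), c(0, 0))

  Tm <- code_contrasts(agent_types(), "treatment")
  expect_equal(unname(Tm["acontextual", ]), c(0, 0))
  expect_equal(unname(Tm["congruent", ]), c(1, 0))
  expect_equal(unname(Tm["incongruent", ]), c(0, 1))

  T2 <- code_contrasts(c("pre", "post"), "treatment")
  expect_equal(unname(T2[, 1]), c(0, 1))
  expect_error(code_contrasts(agent_types(), "helmert"), "unknown")
})

test_that("sum coding reproduces the level-mean identities", {
  # eta_A = b0 + g1, eta_C = b0 + g2, eta_I = b0 - g1 - g2 exactly
  b0 <- 0.94; g1 <- 0.009; g2 <- -0.015
  Z <- code_contrasts(agent_types(), "sum")
  eta <- b0 + Z %*% c(g1, g2)
  expect_equal(unname(eta[, 1]),
               c(b0 + g1, b0 + g2, b0 - g1 - g2))
})

test_that("spline basis is centered with the requested dimension", {
  B <- spline_basis(1:100, dim = 5)
  expect_equal(dim(B), c(100L, 5L))
  expect_equal(unname(colMeans(B)), rep(0, 5), tolerance = 1e-9)
  expect_error(spline_basis(rep(3, 10)), "degenerate")
  expect_error(spline_basis(numeric(0)), "non-empty")
})

test_that("effect transforms match link arithmetic", {
  expect_equal(effect_transform(0.08, "log", "percent_change"), 8.33,
               tolerance = 1e-2)
  expect_equal(effect_transform(0, "log", "percent_change"), 0)
  expect_equal(effect_transform(0, "logit", "odds_ratio"), 1)
  expect_equal(effect_transform(0, "logit", "inv_logit"), 0.5)
  expect_equal(effect_transform(0.94, "logit", "inv_logit"), 0.719,
               tolerance = 1e-3)
  expect_equal(effect_transform(-0.31, "log", "odds_ratio"), exp(-0.31))
})

test_that("HDI matches normal-quantile oracle and degenerate cases", {
  set.seed(99)
  x <- rnorm(200000)
  h <- hdi(x, 0.89)
  expect_equal(h[1], -1.598, tolerance = 0.02)
  expect_equal(h[2], 1.598, tolerance = 0.02)
  expect_equal(hdi(rep(2.5, 100), 0.95), c(2.5, 2.5))
  h95 <- hdi(x, 0.95)
  expect_equal(h95[2] - h95[1], 2 * 1.96, tolerance = 0.03)
})

test_that("fit_model validates responses and missing columns", {
  cfg <- test_config()
  d <- simulate_model_data(cfg, "postgte", 50, seed = 1)
  expect_error(fit_model(model_spec("postgte"), d), "H_star")
  d$H_star <- d$H                        # raw, may touch the bounds
  d$H_star[1] <- 1
  expect_error(fit_model(model_spec("postgte"), d), "sv_transform")
  d2 <- simulate_model_data(cfg, "dwell", 50, seed = 1)
  d2$dwell[1] <- -1
  expect_error(fit_model(model_spec("dwell"), d2), "positive")
})

test_that("coefficient registries name every symbol exactly once", {
  all_names <- unlist(lapply(c("dwell", "prepost", "postgte", "perf",
                               "mediator"), function(m) {
    sp <- model_spec(m)
    paste(m, sp$registry)
  }))
  expect_equal(anyDuplicated(all_names), 0L)
  expect_true(all(c("dwell betaOI", "prepost betaP", "postgte gamma2",
                    "perf betaGTE", "mediator betaC") %in% all_names))
})

test_that("posterior recovery agrees with an independent frequentist fit", {
  skip_if_not_installed("glmmTMB")
  cfg <- sim_config(n_participants = 15, seed = 7)
  d <- simulate_model_data(cfg, "postgte", 500, seed = 44)
  d$H_star <- sv_transform(d$H, nrow(d))
  post <- quiet_fit(model_spec("postgte"), d, seed = 9)
  s <- summarize_posterior(post)

  ref <- glmmTMB::glmmTMB(
    H_star ~ agent_type + (1 | participant) + (1 | participant:session),
    data = transform(d, agent_type = factor(agent_type,
                                            levels = agent_types())),
    family = glmmTMB::beta_family(),
    contrasts = list(agent_type = "contr.sum"))
  fe <- glmmTMB::fixef(ref)$cond
  expect_equal(s$mean[s$coefficient == "beta0"], unname(fe[1]),
               tolerance = 0.05)
  expect_equal(s$mean[s$coefficient == "gamma1"], unname(fe[2]),
               tolerance = 0.05)
  expect_equal(s$mean[s$coefficient == "gamma2"], unname(fe[3]),
               tolerance = 0.05)
})

test_that("prior-predictive draws are admissible for every likelihood", {
  set.seed(1234)
  for (m in c("dwell", "perf")) {
    b <- rnorm(5)
    mu <- exp(rnorm(200, mean(b), 1))
    kap <- abs(rcauchy(1, 0, 2.5)) + 0.1
    y <- rgamma(200, kap, kap / mu)
    expect_true(all(y >= 0))
  }
  mu <- plogis(rnorm(200, 0, 1))
  phi <- rgamma(1, 2, 0.1) + 1
  h <- rbeta(200, mu * phi, (1 - mu) * phi)
  expect_true(all(h > 0 & h < 1))
})

test_that("spline smooth recovers a monotone trend over encounter index", {
  cfg <- sim_config(n_participants = 15, seed = 3)
  th <- cfg$true_coefficients$prepost
  n <- 700
  set.seed(88)
  part <- sample.int(15, n, TRUE)
  sess <- sample.int(2, n, TRUE)
  kk <- sample.int(20, n, TRUE)
  trend <- 0.04 * (kk - mean(kk))    # linear-in-index signal
  u <- rnorm(15, 0, 0.19)
  mu <- plogis(0.55 + trend + u[part])
  H <- rbeta(n, mu * 30, (1 - mu) * 30)
  d <- data.frame(participant = part, session = sess, prepost = 0,
                  encounter_index = kk, H = H)
  d$H_star <- sv_transform(d$H, n)
  post <- quiet_fit(model_spec("prepost"), d, seed = 10)
  B <- spline_basis(sort(unique(kk)), 5)
  sm <- colMeans(post$draws[, paste0("s", 1:5)])
  fitted_trend <- as.numeric(B %*% sm)
  truth <- 0.04 * (sort(unique(kk)) - mean(kk))
  expect_gte(cor(fitted_trend, truth), 0.9)
})

test_that("null effects are recovered as null", {
  cfg <- test_config()
  th <- cfg$true_coefficients
  th$postgte[c("gamma1", "gamma2")] <- 0
  cfg0 <- sim_config(n_participants = 12, true_coefficients = th, seed = 91)
  d <- simulate_model_data(cfg0, "postgte", 400, seed = 92)
  d$H_star <- sv_transform(d$H, nrow(d))
  post <- quiet_fit(model_spec("postgte"), d, seed = 12)
  for (g in c("gamma1", "gamma2")) {
    q <- quantile(post$draws[, g], c(0.025, 0.975))
    expect_lt(q[1], 0)
    expect_gt(q[2], 0)
  }
})

test_that("a longer run passes the convergence gate", {
  cfg <- test_config()
  d <- simulate_model_data(cfg, "mediator", 300, seed = 50)
  d$M_star <- sv_transform(d$gte_post, nrow(d))
  post <- quiet_fit(model_spec("mediator"), d,
                    mcmc_profile("test", iter = 3000, warmup = 1000),
                    seed = 2)
  expect_lt(max(post$rhat, na.rm = TRUE), 1.05)
  s <- summarize_posterior(post, prob = 0.95)
  expect_true(all(c("mean", "lower", "upper", "rhat") %in% names(s)))
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
})

test_that("zscore stores its centering so covariates can be pinned", {
  x <- rnorm(50, 10, 3)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(attr(z, "center"), mean(x))
  expect_equal(as.numeric(z * attr(z, "scale") + attr(z, "center")), x)
})
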