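test_that("config validation rejects malformed inputs", {
  expect_s3_class(test_config(), "sim_config")
  bad <- default_transition_matrix("congruent")
  bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(sim_config(transition_matrix_by_condition =
                            list(acontextual = bad)), "sum to 1")
  expect_error(sim_config(encounter_flattening = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(dwell_shape = -1), "positive")
  expect_error(sim_config(session_length = 50), "60")
})

test_that("markov sequences follow their transition matrix", {
  # absorbing identity-like chain stays in its start state
  I8 <- diag(8)
  dimnames(I8) <- list(gaze_categories(), gaze_categories())
  s <- simulate_fixation_sequence(I8, 100, "background", seed = 1)
  expect_equal(s, rep("background", 100))

  # uniform chain: all 64 conditional frequencies near 1/8
  U <- matrix(1 / 8, 8, 8, dimnames = list(gaze_categories(),
                                           gaze_categories()))
  s2 <- simulate_fixation_sequence(U, 50000, "background", seed = 2)
  tc <- build_transition_matrix(s2)
  # joint frequency of each of the 64 transitions near 1/64
  expect_lt(max(abs(tc$counts / sum(tc$counts) - 1 / 64)), 0.005)
  # conditional probabilities near 1/8 (3.5 binomial SDs at ~6250 per row)
  Phat <- row_normalize(tc)
  expect_lt(max(abs(Phat - 1 / 8)), 3.5 * sqrt((1 / 8) * (7 / 8) / 6000))

  # two-state chain: empirical state frequencies near pi = (5/6, 1/6)
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE,
              dimnames = list(c("x", "y"), c("x", "y")))
  s3 <- simulate_fixation_sequence(P, 100000, "x", seed = 3)
  expect_equal(unname(table(s3)["x"] / 100000), 5 / 6, tolerance = 0.012)

  expect_error(simulate_fixation_sequence(matrix(1, 2, 2), 10, "a"),
               "sum to 1")
  expect_error(simulate_fixation_sequence(P, 1, "x"), "n must be")
})

test_that("uniform-chain entropy reaches the theoretical maximum", {
  U <- matrix(1 / 8, 8, 8, dimnames = list(gaze_categories(),
                                           gaze_categories()))
  s <- simulate_fixation_sequence(U, 50000, "background", seed = 11)
  r <- gte(s)
  expect_gte(r$H_norm, 0.98)
  expect_equal(as.numeric(r$pi), rep(1 / 8, 8), tolerance = 0.02)
})

test_that("encounter shift mixes toward uniform and raises entropy", {
  P <- default_transition_matrix("acontextual")
  expect_equal(simulate_encounter_shift(P, 0), P)
  P1 <- simulate_encounter_shift(P, 1)
  expect_equal(unname(P1), matrix(1 / 8, 8, 8), tolerance = 1e-12)

  # point-mass rows at lambda = 0.5: 0.5 + 0.5/8 on target, 0.0625 elsewhere
  Ppm <- diag(8)
  dimnames(Ppm) <- list(gaze_categories(), gaze_categories())
  Ph <- simulate_encounter_shift(Ppm, 0.5)
  expect_equal(unname(diag(Ph)), rep(0.5625, 8))
  expect_equal(unname(Ph[1, 2]), 0.0625)

  expect_error(simulate_encounter_shift(P, -0.1), "lambda")

  # monotonicity of normalized GTE in lambda
  h <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(lam) {
    s <- simulate_fixation_sequence(simulate_encounter_shift(P, lam),
                                    10000, "background", seed = 77)
    gte(s)$H_norm
  }, numeric(1))
  expect_true(all(diff(h) > -0.005))
  expect_gt(h[5], h[1])
})

test_that("gaze sessions are deterministic and internally consistent", {
  cfg <- test_config()
  s1 <- simulate_gaze_session(cfg, 2, 1, condition = "congruent")
  s2 <- simulate_gaze_session(cfg, 2, 1, condition = "congruent")
  expect_identical(s1, s2)

  fx <- s1$truth$fixation_log
  # disjoint, ordered fixation intervals
  expect_true(all(diff(fx$start) > 0))
  expect_true(all(fx$end[-nrow(fx)] <= fx$start[-1] + 1e-12))
  expect_true(all(fx$end > fx$start))
  # samples respect the ground-truth log
  expect_true(nrow(fx) >= 1)
  mid <- floor(nrow(fx) / 2)
  samp <- s1$samples
  in_fix <- samp$t >= fx$start[mid] & samp$t < fx$end[mid]
  expect_true(all(samp$hit_object_id[in_fix] == fx$object_id[mid]))
})

test_that("classifier recovers simulated fixations (round trip)", {
  cfg <- test_config()
  ss <- simulate_gaze_session(cfg, 1, 1, condition = "incongruent")
  fx <- classify_fixations(ss$samples)
  gtr <- ss$truth$fixation_log
  jacc <- vapply(seq_len(nrow(gtr)), function(i) {
    ov <- pmin(gtr$end[i], fx$end) - pmax(gtr$start[i], fx$start)
    un <- pmax(gtr$end[i], fx$end) - pmin(gtr$start[i], fx$start)
    max(ov / un)
  }, numeric(1))
  expect_gte(mean(jacc >= 0.5), 0.9)
  # recovered categories match on matched events
  hit <- vapply(seq_len(nrow(gtr)), function(i) {
    j <- which.max(pmin(gtr$end[i], fx$end) - pmax(gtr$start[i], fx$start))
    fx$category[j] == gtr$category[i]
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("session transition structure round-trips through the pipeline", {
  # lambda = 0 so the generating matrix is used throughout the session
  cfg <- sim_config(n_participants = 2, n_sessions = 1,
                    session_length = 1200, encounter_flattening = 0,
                    seed = 99)
  P <- cfg$transition_matrix_by_condition$congruent
  seqs <- character(0)
  for (p in 1:2) {
    ss <- simulate_gaze_session(cfg, p, 1, condition = "congruent")
    fx <- classify_fixations(ss$samples)
    seqs <- c(seqs, fx$category[!is.na(fx$category)])
  }
  tc <- build_transition_matrix(seqs)
  Phat <- row_normalize(tc)
  heavy <- tc$N_row > 200
  expect_gt(sum(heavy), 1)
  expect_lt(max(abs(Phat[heavy, ] - P[heavy, ])), 0.05)
})

test_that("pointing trials follow the Gamma-log performance model", {
  cfg <- test_config()
  # all covariates at reference, random-effect SDs zero: mean = exp(beta0)
  th <- cfg$true_coefficients
  th$perf[c("sigma_u", "sigma_v")] <- 0
  th$perf[c("betaC", "betaI", "betaPub", "betaGTE", "betaDWA",
            "betaDWB")] <- 0
  cfg0 <- sim_config(n_participants = 12, true_coefficients = th, seed = 5)
  tr <- simulate_pointing_trials(cfg0, 4000, seed = 17)
  mu <- exp(th$perf[["beta0"]])
  se <- stats::sd(tr$error) / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$error) - mu), 2.5 * se + 0.02 * mu)
  expect_true(all(tr$error > 0))

  # link-scale arithmetic: two-point mediator shifts the mean by
  # exp(betaGTE * (0.8 - 0.2))
  th2 <- th
  th2$perf["betaGTE"] <- -0.31
  cfg2 <- sim_config(n_participants = 12, true_coefficients = th2, seed = 6)
  m <- rep(c(0.2, 0.8), 4000)
  tr2 <- simulate_pointing_trials(cfg2, 8000, gte_post = m, seed = 18)
  ratio <- mean(tr2$error[tr2$gte_post == 0.8]) /
    mean(tr2$error[tr2$gte_post == 0.2])
  expect_equal(ratio, exp(-0.31 * 0.6), tolerance = 0.05)

  # empty call and missing-coefficient error
  expect_equal(nrow(simulate_pointing_trials(cfg, 0)), 0)
  th3 <- cfg$true_coefficients
  th3$perf <- th3$perf[setdiff(names(th3$perf), "betaGTE")]
  cfg3 <- sim_config(true_coefficients = th3)
  expect_error(simulate_pointing_trials(cfg3, 10), "betaGTE")
})

test_that("mediation dataset links mediator and outcome generatively", {
  cfg <- test_config()
  md <- simulate_mediation_dataset(cfg, 500, seed = 21)
  expect_equal(nrow(md$mediator), nrow(md$trials))
  expect_identical(md$mediator$participant, md$trials$participant)
  expect_identical(md$mediator$gte_post, md$trials$gte_post)
  expect_true(all(md$mediator$gte_post > 0 & md$mediator$gte_post < 1))

  # null mediator effects: group means of the mediator indistinguishable
  th <- cfg$true_coefficients
  th$mediator[c("betaC", "betaI")] <- 0
  cfgn <- sim_config(n_participants = 12, true_coefficients = th, seed = 31)
  mdn <- simulate_mediation_dataset(cfgn, 6000, seed = 22)
  g <- split(mdn$mediator$gte_post, mdn$mediator$agent_type)
  dif <- mean(g$congruent) - mean(g$acontextual)
  se <- sqrt(stats::var(g$congruent) / length(g$congruent) +
               stats::var(g$acontextual) / length(g$acontextual))
  expect_lt(abs(dif), 3 * se)

  # high-precision null model centers the mediator at 1/2
  th2 <- cfg$true_coefficients
  th2$mediator[] <- c(0, 0, 0, 0, 1000, 0, 0)
  cfg2 <- sim_config(n_participants = 12, true_coefficients = th2, seed = 8)
  md2 <- simulate_mediation_dataset(cfg2, 4000, seed = 23)
  expect_lt(abs(mean(md2$mediator$gte_post) - 0.5), 0.01)

  th3 <- cfg$true_coefficients
  th3$mediator["phi"] <- -1
  cfg3 <- sim_config(true_coefficients = th3)
  expect_error(simulate_mediation_dataset(cfg3, 10), "phi")
})

test_that("generator random intercepts center near zero", {
  cfg <- test_config()
  d <- simulate_model_data(cfg, "dwell", 500, n_participants = 40, seed = 3)
  re <- attr(d, "ranef")
  expect_lt(abs(mean(re$participant)),
            3 * stats::sd(re$participant) / sqrt(length(re$participant)))
})
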