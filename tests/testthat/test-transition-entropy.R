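test_that("forward transition counts enumerate consecutive pairs", {
  cats <- c("a", "b")
  tc <- build_transition_matrix(c("b", "a", "b", "a"), categories = cats)
  expect_equal(tc$counts["b", "a"], 2L)
  expect_equal(tc$counts["a", "b"], 1L)
  expect_equal(sum(tc$counts), 3L)

  tc2 <- build_transition_matrix(c("a", "a", "a"), categories = cats)
  expect_equal(tc2$counts["a", "a"], 2L)
  expect_equal(sum(tc2$counts), 2L)

  # self-transition flag removes the diagonal
  tc3 <- build_transition_matrix(c("a", "a", "b", "a"), categories = cats,
                                 drop_self = TRUE)
  expect_equal(tc3$counts["a", "a"], 0L)
  expect_equal(sum(tc3$counts), 2L)

  expect_error(build_transition_matrix("a", categories = cats), "at least 2")
  expect_error(build_transition_matrix(c("a", "zzz"), categories = cats),
               "zzz")
})

test_that("singleton counts and row totals match their definitions", {
  tc <- build_transition_matrix(c("a", "b", "c", "a", "b", "a"),
                                categories = c("a", "b", "c"))
  # transitions: a->b (x2), b->c, b->a, c->a
  expect_equal(unname(tc$N_row), c(2L, 2L, 1L))
  expect_equal(unname(tc$S1_row), c(0L, 2L, 1L))
  expect_true(all(tc$S1_row <= tc$N_row))
})

test_that("row normalization divides observed rows and flags empty ones", {
  tc <- build_transition_matrix(c("a", "b", "a", "a", "b"),
                                categories = c("a", "b", "c"))
  P <- row_normalize(tc)
  nz <- tc$N_row > 0
  expect_equal(unname(rowSums(P)[nz]), rep(1, sum(nz)), tolerance = 1e-12)
  expect_equal(unname(rowSums(P)[!nz]), rep(0, sum(!nz)))
  expect_equal(attr(P, "zero_rows"), c(a = FALSE, b = FALSE, c = TRUE))
})

test_that("Chao-Shen entropy matches hand-computed values", {
  # (2,1,1): N=4, S1=2, C=0.5, p_adj=(.25,.125,.125),
  # la = (1-.75^4, 1-.875^4, 1-.875^4); H = .5/.68359375 + 2*.375/.41381836
  r <- chao_shen_entropy(c(2, 1, 1))
  expect_equal(r$C, 0.5)
  expect_equal(r$H, 0.5 / 0.68359375 + 2 * 0.375 / 0.41381836,
               tolerance = 1e-7)
  expect_equal(r$H, 2.544, tolerance = 1e-3)

  # point mass: no singletons, full coverage, zero entropy
  r0 <- chao_shen_entropy(c(10, 0, 0))
  expect_equal(r0$H, 0)
  expect_equal(r0$C, 1)

  # all-singleton degenerate row uses the S1 = N - 1 substitution
  r1 <- chao_shen_entropy(c(1, 1, 1))
  expect_gt(r1$C, 0)
  expect_true(is.finite(r1$H))

  expect_error(chao_shen_entropy(c(0, 0)), "all-zero")
  expect_error(chao_shen_entropy(c(1.5, 1)), "integer")
})

test_that("corrected entropy approaches the plug-in limit without singletons", {
  # large balanced counts: coverage 1, inclusion ~ 1, so the corrected
  # estimator must agree with plug-in entropy
  counts <- c(12500, 12500, 12500, 12500)
  expect_equal(chao_shen_entropy(counts)$H, plugin_entropy(counts),
               tolerance = 1e-6)
  counts2 <- c(30000, 15000, 5000)
  expect_equal(chao_shen_entropy(counts2)$H, plugin_entropy(counts2),
               tolerance = 1e-6)
})

test_that("stationary distribution solves pi P = pi with empirical fallback", {
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE)
  pi <- stationary_distribution(P, c(10, 10))
  expect_equal(as.numeric(pi), c(5 / 6, 1 / 6), tolerance = 1e-10)
  expect_equal(attr(pi, "method"), "eigen")

  U <- matrix(1 / 8, 8, 8)
  piu <- stationary_distribution(U, rep(1, 8))
  expect_equal(as.numeric(piu), rep(1 / 8, 8), tolerance = 1e-10)

  # two-block reducible chain: eigenvalue 1 is degenerate -> empirical
  B <- rbind(c(0.5, 0.5, 0, 0), c(0.5, 0.5, 0, 0),
             c(0, 0, 0.5, 0.5), c(0, 0, 0.5, 0.5))
  pib <- stationary_distribution(B, c(1, 1, 1, 1))
  expect_equal(attr(pib, "method"), "empirical")
  expect_equal(as.numeric(pib), rep(0.25, 4))
})

test_that("global and normalized entropy behave as weighted average and ratio", {
  expect_equal(global_entropy(rep(3, 8), rep(1 / 8, 8)), 3)
  expect_equal(global_entropy(c(2, 0), c(0.5, 0.5)), 1)
  expect_equal(global_entropy(c(1.3, 2.2), c(1, 0)), 1.3)
  expect_error(global_entropy(c(1, 2), c(1)), "equal length")

  expect_equal(normalize_entropy(3, 8), 1)
  expect_equal(normalize_entropy(0, 8), 0)
  expect_equal(normalize_entropy(1.5, 8), 0.5)
  expect_error(normalize_entropy(1, 1), "k must be")
  expect_warning(h <- normalize_entropy(3.2, 8), "clipped")
  expect_equal(h, 1)
})

test_that("gte composes the pipeline with bounded normalized output", {
  # deterministic alternating cycle: every row is a point mass
  cyc <- rep(c("building", "background"), 500)
  expect_equal(gte(cyc)$H_norm, 0)

  # near-uniform chain approaches the maximum
  set.seed(7)
  u <- sample(gaze_categories(), 50000, replace = TRUE)
  expect_gte(gte(u)$H_norm, 0.98)

  # any sequence stays in [0, 1]
  set.seed(8)
  for (i in 1:20) {
    s <- sample(gaze_categories()[1:sample(2:8, 1)], sample(5:200, 1),
                replace = TRUE)
    if (length(unique(s)) < 2) s <- c(s, gaze_categories()[1:2])
    h <- gte(s)$H_norm
    expect_gte(h, 0)
    expect_lte(h, 1)
  }
})

test_that("transition frequencies of a simulated chain recover the matrix", {
  P <- default_transition_matrix("incongruent")
  sq <- simulate_fixation_sequence(P, 10000, "background", seed = 31)
  tc <- build_transition_matrix(sq)
  Phat <- row_normalize(tc)
  obs <- tc$N_row > 100
  expect_lt(max(abs(Phat[obs, ] - P[obs, ])), 0.03)
})

test_that("relabeling categories leaves global entropy unchanged", {
  set.seed(12)
  s <- simulate_fixation_sequence(default_transition_matrix("congruent"),
                                  4000, "building", seed = 13)
  perm <- sample(gaze_categories())
  relabeled <- perm[match(s, gaze_categories())]
  r1 <- gte(s)
  r2 <- gte(relabeled, categories = gaze_categories())
  expect_equal(r1$H_global, r2$H_global, tolerance = 1e-10)
  expect_equal(r1$H_norm, r2$H_norm, tolerance = 1e-10)
})

test_that("shuffling a structured sequence increases entropy", {
  for (seed in 1:3) {
    # strongly diagonal chain: concentrated rows, roughly uniform marginals
    k <- 4
    P <- matrix(0.05 / 3, k, k); diag(P) <- 0.95
    dimnames(P) <- list(letters[1:k], letters[1:k])
    s <- simulate_fixation_sequence(P, 3000, "a", seed = seed)
    h_struct <- gte(s, categories = letters[1:k])$H_norm
    set.seed(seed + 100)
    h_shuf <- gte(sample(s), categories = letters[1:k])$H_norm
    expect_gt(h_shuf, h_struct)
  }
})

test_that("per-session entropy table aggregates by participant and session", {
  set.seed(5)
  fx <- data.frame(
    participant = rep(1:2, each = 40), session = rep(c(1, 2, 1, 2), each = 20),
    category = sample(gaze_categories(), 80, replace = TRUE),
    start = rep(seq(0, 19), 4))
  tab <- gte_by_session(fx)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$H_norm >= 0 & tab$H_norm <= 1))
  expect_equal(tab$n_fixations, rep(20L, 4))
})
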