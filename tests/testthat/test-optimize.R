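test_that("the composite objective matches closed forms and a voxel oracle", {
  d <- c(8, 8, 8)
  masks <- list(tgt = array(TRUE, d))
  spec <- data.frame(structure = "tgt", type = "min", level = 60, weight = 5,
                     robust = TRUE)
  # dose exactly at the level: zero penalty
  expect_equal(composite_objective(array(60, d), masks, spec), 0)
  # uniform dose 5% below the level L: penalty = w * (0.05 L)^2
  expect_equal(composite_objective(array(0.95 * 60, d), masks, spec),
               5 * (0.05 * 60)^2)
  # random dose/mask against an independent per-voxel summation oracle
  set.seed(8)
  dose <- array(runif(prod(d), 40, 80), d)
  m <- array(runif(prod(d)) < 0.4, d)
  spec2 <- rbind(spec,
                 data.frame(structure = "oar", type = "max", level = 50,
                            weight = 2, robust = TRUE),
                 data.frame(structure = "oar", type = "mean", level = 0,
                            weight = 1, robust = FALSE))
  masks2 <- list(tgt = m, oar = !m)
  oracle <- 0
  n_t <- sum(m); n_o <- sum(!m)
  for (v in seq_along(dose)) {
    if (m[v]) oracle <- oracle + 5 * max(60 - dose[v], 0)^2 / n_t
    else oracle <- oracle + 2 * max(dose[v] - 50, 0)^2 / n_o + 1 * dose[v] / n_o
  }
  expect_equal(composite_objective(dose, masks2, spec2), oracle,
               tolerance = 1e-12)
  expect_error(composite_objective(dose, masks2[1], spec2), "missing structure")
})

test_that("a one-spot problem recovers the closed-form least-squares weight", {
  # one spot, influence a_i, uniform-dose term at level L:
  # f(w) = mean((a_i w - L)^2), minimized at w* = L sum(a) / sum(a^2)
  set.seed(4)
  a <- runif(30, 0.5, 1.5)
  A <- Matrix::Matrix(matrix(a, ncol = 1), sparse = TRUE)
  terms <- data.frame(structure = "tgt", type = "uniform", level = 66,
                      weight = 10, robust = TRUE)
  ctx <- make_opt_context(A, list(tgt = 1:30), terms)
  res <- optimize_weights(list(ctx), list(), nspots = 1, w0 = 1,
                          maxit = 200, taus = 0.01, factr = 10)
  wstar <- 66 * sum(a) / sum(a^2)
  expect_equal(res$weights, wstar, tolerance = 1e-6)
  expect_true(all(diff(res$trace) <= 1e-9))
})

test_that("duplicated scenarios do not change the minimax solution", {
  set.seed(5)
  A1 <- matrix(runif(40, 0.2, 1), 20, 2)
  A2 <- A1 * 0.9
  ctx1 <- toy_context(A1); ctx2 <- toy_context(A2)
  r_dedup <- optimize_weights(list(ctx1, ctx2), list(), nspots = 2,
                              w0 = c(30, 30), maxit = 300, taus = 0.02,
                              factr = 100)
  r_dup <- optimize_weights(list(ctx1, ctx2, ctx2, ctx1), list(), nspots = 2,
                            w0 = c(30, 30), maxit = 300, taus = 0.02,
                            factr = 100)
  expect_equal(r_dup$weights, r_dedup$weights, tolerance = 1e-3)
})

test_that("a 2-spot 3-scenario minimax matches exhaustive grid search", {
  set.seed(6)
  mats <- lapply(1:3, function(i) matrix(runif(30, 0.2, 1.2), 15, 2))
  ctxs <- lapply(mats, toy_context)
  res <- optimize_weights(ctxs, list(), nspots = 2, w0 = c(40, 40),
                          maxit = 400, taus = c(0.1, 0.01), factr = 100)
  worst <- function(w) max(vapply(mats, toy_objective_oracle, numeric(1),
                                  w = w))
  # exhaustive search over the 2D weight grid
  grid <- seq(0, 150, by = 0.5)
  best <- Inf
  for (w1 in grid) {
    vals <- vapply(grid, function(w2) worst(c(w1, w2)), numeric(1))
    best <- min(best, min(vals))
  }
  expect_lt(worst(res$weights), best * 1.01)
  expect_true(all(res$weights >= 0))
  expect_true(all(diff(res$trace) <= 1e-9))
})

test_that("larger setup uncertainty cannot improve the nominal optimum", {
  # monotone robustness cost on a synthetic fixture: the nominal objective
  # achieved under the 3 mm scenario set is at least that under 1 mm
  set.seed(9)
  base <- matrix(runif(60, 0.3, 1.2), 30, 2)
  shifted <- function(eps) base + eps * matrix(rnorm(60), 30, 2)
  set.seed(10); ctx1 <- lapply(1:4, function(i) toy_context(shifted(0.05)))
  set.seed(10); ctx3 <- lapply(1:4, function(i) toy_context(shifted(0.15)))
  nom <- toy_context(base)
  r1 <- optimize_weights(ctx1, list(nom), nspots = 2, w0 = c(40, 40),
                         maxit = 300, taus = 0.02, factr = 100)
  r3 <- optimize_weights(ctx3, list(nom), nspots = 2, w0 = c(40, 40),
                         maxit = 300, taus = 0.02, factr = 100)
  f_nom <- function(w) toy_objective_oracle(base, w)
  expect_gte(f_nom(r3$weights) + 1e-6, f_nom(r1$weights))
})
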