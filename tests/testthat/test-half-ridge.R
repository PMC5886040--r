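test_that("ridge weights match the closed form", {
  pc <- paired_comparisons(X = cbind(c(1, -1)), y = c(1, -1))
  expect_equal(unname(ridge_weights(pc, 0)), 1)
  expect_equal(unname(ridge_weights(pc, 1)), 2 / 3)  # 2/(2+1)
  expect_lt(abs(ridge_weights(pc, 1e9)), 1e-6)
  expect_error(ridge_weights(pc, -1), "nonnegative")
  # duplicated cue columns make theta = 0 singular
  dup <- paired_comparisons(X = cbind(c(1, -1, 1), c(1, -1, 1)),
                            y = c(1, -1, 1))
  expect_error(ridge_weights(dup, 0), "theta > 0")
})

test_that("untruncated posterior mean norm shrinks monotonically in theta", {
  pc <- random_pc(4, 30, seed = 15)
  norms <- vapply(10^seq(-3, 3, by = 0.5),
                  function(th) sqrt(sum(ridge_weights(pc, th)^2)), 0)
  expect_true(all(diff(norms) < 1e-12))
})

test_that("with no discriminating data the posterior equals the half-normal prior", {
  pc0 <- paired_comparisons(X = matrix(0, 30, 2), y = rep(c(1, -1), 15))
  for (eta in c(0.5, 2)) {
    cfg <- half_ridge_config(eta = eta, directions = c(1, -1), seed = 42)
    post <- half_ridge_posterior(pc0, cfg)
    expected <- c(1, -1) * eta * sqrt(2 / pi)
    expect_lt(max(abs(post$mean - expected) / (3 * post$diagnostics$mcse + 1e-12)), 1)
  }
})

test_that("posterior samples and mean respect the orthant", {
  pc <- random_pc(3, 25, seed = 31, directions = c(1, -1, 1))
  cfg <- half_ridge_config(eta = 0.7, directions = c(1, -1, 1), seed = 2)
  post <- half_ridge_posterior(pc, cfg)
  ok <- sweep(post$samples, 2L, c(1, -1, 1), `*`)
  expect_true(all(ok >= 0))
  expect_true(all(post$mean * c(1, -1, 1) >= 0))
})

test_that("weak prior recovers OLS when it is interior to the orthant", {
  # strong consistent signal so the OLS solution is well inside the orthant
  spec <- environment_spec(m = 3, n_objects = 15, weight_scale = 1.5,
                           cue_correlation = 0, noise_sd = 0.3, seed = 220)
  pc <- generate_pairs(spec)
  ols <- ridge_weights(pc, 0)
  expect_true(all(ols * spec$directions > 0))
  cfg <- half_ridge_config(eta = 1e3, directions = spec$directions, seed = 62)
  post <- half_ridge_posterior(pc, cfg)
  expect_lt(max(abs(post$mean - ols) / (5 * post$diagnostics$mcse + 1e-8)), 1)
  # and the constrained least-squares solution is OLS itself here
  expect_equal(signed_ls_weights(pc), ols, tolerance = 1e-8)
})

test_that("Gibbs mean agrees with a rejection-sampling oracle", {
  for (s in 1:3) {
    pc <- random_pc(3, 20, seed = 90 + s, directions = c(1, 1, -1))
    cfg <- half_ridge_config(eta = 1, directions = c(1, 1, -1), seed = s)
    post <- half_ridge_posterior(pc, cfg)
    oracle <- rejection_posterior_mean(pc, eta = 1, sigma = 1,
                                       directions = c(1, 1, -1), seed = s)
    comb <- sqrt(post$diagnostics$mcse^2 + oracle$se^2)
    expect_lt(max(abs(post$mean - oracle$mean) / (4 * comb)), 1)
  }
})

test_that("rescaled strong-prior limit has half-normal mean with cue signs", {
  est <- rescaled_limit_mean(c(1), n_draws = 1e6, seed = 5)
  expect_lt(abs(est - sqrt(2 / pi)), 0.003)
  est2 <- rescaled_limit_mean(c(-1, -1), n_draws = 1e5, seed = 6)
  expect_true(all(est2 < 0))
  expect_lt(abs(abs(est2[1]) - abs(est2[2])),
            4 * sqrt(sum(attr(est2, "se")^2)))
  a <- rescaled_limit_mean(c(1), n_draws = 1e5, seed = 7)
  b <- rescaled_limit_mean(c(1), n_draws = 1e5, seed = 8)
  expect_lt(abs(a - b),
            4 * sqrt(attr(a, "se")^2 + attr(b, "se")^2))
  expect_error(rescaled_limit_mean(c(1), n_draws = 100), "1e4")
})

test_that("decisions follow the sign of the posterior-mean evidence", {
  # crafted degenerate posterior: constant draws, so MC error is zero
  fake <- structure(list(
    mean = c(0.5, 0.5),
    samples = matrix(rep(c(0.5, 0.5), each = 100), 100, 2),
    directions = c(1, 1)), class = "half_ridge_posterior")
  expect_equal(half_ridge_predict(c(1, -1), fake), 0L)  # exact balance
  expect_equal(half_ridge_predict(c(1, 0), fake), 1L)
  # equal positive weights reproduce directed tallying on every input
  xs <- all_comparisons(3)
  fake3 <- structure(list(
    mean = rep(0.4, 3),
    samples = matrix(0.4, 50, 3),
    directions = rep(1, 3)), class = "half_ridge_posterior")
  expect_equal(half_ridge_predict(xs, fake3), tally_directed(xs, rep(1, 3)))
})

test_that("choices are invariant to positive rescaling of the posterior", {
  pc <- random_pc(3, 20, seed = 55)
  cfg <- half_ridge_config(eta = 0.5, directions = rep(1, 3), seed = 9)
  post <- half_ridge_posterior(pc, cfg)
  scaled <- post
  scaled$mean <- post$mean * 37.5
  scaled$samples <- post$samples * 37.5
  xs <- all_comparisons(3)
  expect_equal(half_ridge_predict(xs, scaled), half_ridge_predict(xs, post))
})

test_that("strong prior reproduces directed tallying exhaustively", {
  xs <- all_comparisons(4)
  for (s in 1:3) {
    pc <- random_pc(4, 30, seed = 200 + s)
    cfg <- half_ridge_config(eta = 1e-3, directions = pc$directions,
                             seed = s)
    post <- half_ridge_posterior(pc, cfg)
    expect_equal(half_ridge_predict(xs, post),
                 tally_directed(xs, pc$directions))
  }
})

test_that("posterior sampling is reproducible and antisymmetric in x", {
  pc <- random_pc(3, 18, seed = 70)
  cfg <- half_ridge_config(eta = 1, directions = rep(1, 3), seed = 77)
  p1 <- half_ridge_posterior(pc, cfg)
  p2 <- half_ridge_posterior(pc, cfg)
  expect_identical(p1$samples, p2$samples)
  xs <- all_comparisons(3)
  expect_equal(half_ridge_predict(-xs, p1), -half_ridge_predict(xs, p1))
})

test_that("configuration and input validation", {
  expect_error(half_ridge_config(eta = 0), "eta")
  expect_error(half_ridge_config(eta = 1, sigma = 0), "sigma")
  expect_error(half_ridge_config(eta = 1, n_keep = 0), "n_keep")
  pc <- random_pc(2, 10, seed = 3)
  pc$directions <- NULL
  expect_error(half_ridge_posterior(pc, half_ridge_config(eta = 1)),
               "directions")
  bad <- random_pc(2, 10, seed = 3)
  bad$X[1, 1] <- NA
  expect_error(half_ridge_posterior(bad, half_ridge_config(
    eta = 1, directions = c(1, 1))), "non-finite")
})
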