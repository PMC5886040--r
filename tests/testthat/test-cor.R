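test_that("lambda = 0 reduces every weight column to the OLS solution", {
  pc <- random_pc(4, 40, seed = 101)
  w <- cor_weights(pc, 0)
  ols <- ridge_weights(pc, 0)
  for (j in 1:4) expect_equal(unname(w$W[, j]), unname(ols), tolerance = 1e-8)
  # both rules then return the sign of the OLS prediction
  xs <- all_comparisons(4)
  pred <- drop(xs %*% ols)
  want <- as.integer(sign(pred) * (abs(pred) > 1e-12))
  expect_equal(cor_predict(xs, w, "ttb"), want)
  expect_equal(cor_predict(xs, w, "tally"), want)
})

test_that("strong penalty kills cross-weights and leaves validity slopes", {
  pc <- random_pc(4, 35, seed = 102)
  w <- cor_weights(pc, 1e8)
  dg <- diag(w$W)
  off <- w$W - diag(dg)
  expect_lt(max(abs(off)), 1e-4 * max(abs(dg)))
  v <- cue_validity(pc)$validities
  expect_equal(unname(dg), 2 * v - 1, tolerance = 1e-4)
  # the simple-regression slope identity is exact in integer arithmetic
  for (j in 1:4) {
    xj <- pc$X[, j]
    expect_identical(as.integer(sum(xj * pc$y)),
                     as.integer((2 * sum(xj * pc$y == 1) - sum(xj != 0))))
  }
})

test_that("orthogonal cues make the direct weights penalty-free slopes", {
  # one discriminating cue per comparison => X'X diagonal: there is no cue
  # covariance to suppress, so regularization never touches the diagonal
  X <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1), c(1, 0, 0), c(0, 1, 0))
  y <- c(1, -1, 1, 1, -1, 1, 1, 1)
  pc <- paired_comparisons(X, y)
  slopes <- drop(crossprod(X, y)) / colSums(X^2)
  for (lam in c(0, 1e-6, 50, 1e8)) {
    W <- cor_weights(pc, lam)$W
    expect_equal(unname(diag(W)), unname(slopes), tolerance = 1e-10)
  }
  # cross-weights start at the (orthogonal) OLS solution and vanish
  expect_equal(unname(cor_weights(pc, 0)$W[2, 1]), unname(slopes[2]),
               tolerance = 1e-10)
  expect_lt(max(abs(cor_weights(pc, 1e8)$W - diag(slopes))), 1e-7)
})

test_that("multiplexed outputs are x times the weight matrix", {
  pc <- random_pc(3, 20, seed = 103)
  w <- cor_weights(pc, 1)
  ident <- w
  ident$W <- diag(3)
  expect_equal(cor_outputs(c(1, 0, -1), ident), c(1, 0, -1),
               ignore_attr = TRUE)
  expect_equal(cor_outputs(c(0, 0, 0), w), rep(0, 3), ignore_attr = TRUE)
  w0 <- cor_weights(pc, 0)
  out <- cor_outputs(c(1, -1, 0), w0)
  expect_equal(max(out) - min(out), 0, tolerance = 1e-10)
})

test_that("decision rules follow the stated valence logic", {
  expect_equal(ttb_rule(c(0.2, -0.5, 0.1)), -1L)
  expect_equal(ttb_rule(c(0, 0, 0)), 0L)
  expect_equal(ttb_rule(c(0.5, -0.5)), 1L)       # tie -> lowest index
  expect_equal(tally_rule(c(0.2, -0.5, 0.1)), 1L)
  expect_equal(tally_rule(c(0.2, -0.5)), 0L)
  expect_equal(tally_rule(c(-0.2, -0.5, -0.1)), -1L)
  expect_error(ttb_rule(numeric(0)), "empty")
  expect_error(tally_rule(numeric(0)), "empty")
})

test_that("rules and predictions are antisymmetric", {
  set.seed(14)
  for (r in 1:20) {
    yhat <- round(rnorm(4), 2)
    expect_equal(ttb_rule(-yhat), -ttb_rule(yhat))
    expect_equal(tally_rule(-yhat), -tally_rule(yhat))
  }
  pc <- random_pc(4, 30, seed = 104)
  xs <- all_comparisons(4)
  for (lam in c(0.01, 10, 1e8)) {
    w <- cor_weights(pc, lam)
    expect_equal(cor_predict(-xs, w, "ttb"), -cor_predict(xs, w, "ttb"))
    expect_equal(cor_predict(-xs, w, "tally"), -cor_predict(xs, w, "tally"))
  }
})

test_that("cross-weight mass decreases continuously to zero in lambda", {
  pc <- random_pc(4, 30, seed = 105)
  grid <- 10^seq(-4, 8, by = 0.5)
  offnorm <- vapply(grid, function(l) {
    W <- cor_weights(pc, l)$W
    sqrt(sum((W - diag(diag(W)))^2))
  }, 0)
  expect_true(all(diff(offnorm) < 1e-10))
  expect_lt(offnorm[length(offnorm)], 1e-6)
  # continuity: small lambda steps move W only slightly
  W_a <- cor_weights(pc, 1)$W
  W_b <- cor_weights(pc, 1.001)$W
  expect_lt(max(abs(W_a - W_b)), 1e-3)
})

test_that("COR at strong penalty reproduces both heuristics exhaustively", {
  xs <- all_comparisons(4)
  for (s in 1:5) {
    pc <- random_pc(4, 30, seed = 300 + s)
    prof <- cue_validity(pc)
    w <- cor_weights(pc, 1e8)
    expect_equal(cor_predict(xs, w, "ttb"), take_the_best(xs, prof))
    expect_equal(cor_predict(xs, w, "tally"), tally_undirected(xs, prof))
  }
})

test_that("never-discriminating cues are ignored by both rules", {
  X <- rbind(c(1, 0, 1), c(-1, 0, 1), c(1, 0, -1), c(-1, 0, -1), c(1, 0, 0))
  pc <- paired_comparisons(X, c(1, -1, 1, -1, 1))
  w <- cor_weights(pc, 1e8)
  expect_equal(unname(diag(w$W)[2]), 0)  # no data, no direct weight
  yhat <- cor_outputs(c(1, 1, 1), w)
  # the dead copy's output is residual cross-talk of order n/lambda,
  # far below the decision rules' null tolerance
  expect_lt(abs(yhat[2]), 1e-6)
  expect_equal(cor_predict(xs <- all_comparisons(3), w, "ttb"),
               take_the_best(xs, cue_validity(pc)))
})

test_that("lambda = 0 with collinear cues is a diagnosed error", {
  dup <- paired_comparisons(X = cbind(c(1, -1, 1), c(1, -1, 1)),
                            y = c(1, -1, 1))
  expect_error(cor_weights(dup, 0), "lambda > 0")
  expect_error(cor_weights(dup, -1), "nonnegative")
})
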