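#' Covariance Orthogonalizing Regularization (COR) weights
#'
#' COR multiplexes the outcome once per cue, turning the task into a
#' multivariate regression with an m x m weight matrix `W`: column j holds
#' the weights feeding the j-th copy of the outcome. Only the cross-weights
#' (off-diagonal entries) are penalized: column j solves
#' `min_w ||y - Xw||^2 + lambda * sum_{k != j} w_k^2`, i.e.
#' `w = (X'X + lambda M_j)^{-1} X'y` with `M_j` the identity with its
#' (j,j) entry zeroed. This is the mean of the Gaussian posterior with a
#' flat prior on the direct weight and independent N(0, 1/lambda) priors on
#' the cross-weights (error variance fixed at 1, so `lambda = 1/eta^2`).
#'
#' At `lambda = 0` every column equals the ordinary least-squares solution;
#' as `lambda -> Inf` the cross-weights vanish and diagonal entry j tends to
#' the simple-regression slope `sum_i x_ij y_i / sum_i x_ij^2 = 2 v_j - 1`,
#' a linear transform of cue validity. Thus the strength of the prior
#' interpolates between full sensitivity to cue covariance and none.
#'
#' A cue that never discriminates in training leaves its direct weight
#' without likelihood or penalty; its column is taken as the minimum-norm
#' solution (direct weight 0, remaining weights solving the reduced
#' penalized problem), so that copy's output is always 0 and both decision
#' rules ignore it.
#'
#' @param pc a [paired_comparisons()] training set.
#' @param lambda cross-weight penalty (prior precision), >= 0.
#' @return Object of class `cor_weights`: list with `W` (m x m matrix,
#'   direct weights on the diagonal), `lambda`, `cue_names`.
#' @export
cor_weights <- function(pc, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("lambda must be a single nonnegative number", call. = FALSE)
  }
  X <- pc$X
  y <- pc$y
  m <- ncol(X)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  dead <- diag(XtX) == 0
  if (lambda == 0 && rcond(XtX) < 1e-12) {
    stop("X'X is numerically singular at lambda = 0; use lambda > 0",
         call. = FALSE)
  }
  W <- matrix(0, m, m, dimnames = list(pc$cue_names, pc$cue_names))
  for (j in seq_len(m)) {
    if (dead[j]) {
      live <- which(!dead)
      if (length(live)) {
        A <- XtX[live, live, drop = FALSE] + diag(lambda, length(live))
        W[live, j] <- drop(solve(A, Xty[live]))
      }
    } else {
      A <- XtX + diag(lambda, m)
      A[j, j] <- XtX[j, j]
      W[, j] <- drop(solve(A, Xty))
    }
  }
  structure(list(W = W, lambda = lambda, cue_names = pc$cue_names),
            class = "cor_weights")
}

#' @export
print.cor_weights <- function(x, ...) {
  cat(sprintf("cor_weights: m=%d, lambda=%g\n", ncol(x$W), x$lambda))
  print(signif(x$W, 4))
  invisible(x)
}

#' Multiplexed outputs of the COR model
#'
#' One output per copy of the criterion: `yhat = x W`.
#'
#' @param x one comparison (length-m vector) or a matrix of comparisons.
#' @param w a [cor_weights()] object.
#' @return Numeric vector of m outputs (or an n x m matrix for matrix
#'   input).
#' @export
cor_outputs <- function(x, w) {
  stopifnot(inherits(w, "cor_weights"))
  x <- as_comparison_matrix(x, ncol(w$W))
  out <- x %*% w$W
  if (nrow(out) == 1L) drop(out) else out
}

# Outputs that are null in the strong-penalty limit are made exactly null
# before a rule sees them. Two guards: a relative one (below null_tol of
# the row maximum; catches residual cross-talk next to real outputs) and
# an absolute floor (null_abs; catches rows where *every* output is
# penalty residue of order n/lambda, e.g. when the only discriminating
# cue is uninformative). Decision-relevant outputs are bounded below by
# the smallest validity slope, 1/n_train, far above the floor.
null_outputs <- function(yhat, null_tol, null_abs) {
  yhat <- rbind(yhat)
  thr <- pmax(null_abs, null_tol * apply(abs(yhat), 1L, max))
  yhat * (abs(yhat) > thr)
}

#' TTB decision rule on a COR output vector
#'
#' Selects the output with maximum absolute value (ties broken by lowest
#' index) and takes its valence: +1 left, -1 right, 0 guess. With strong
#' regularization each output reduces to `x_j * (2 v_j - 1)`, so this rule
#' reproduces take-the-best's lexicographic search.
#'
#' @param yhat numeric output vector from [cor_outputs()] (or a matrix, one
#'   vector per row).
#' @param null_tol outputs smaller than `null_tol * max(abs(yhat))` are
#'   treated as null. Default 1e-3.
#' @param null_abs absolute output floor; outputs below it are null.
#'   Default 1e-4: above the penalty residue (order n/lambda) at the
#'   strong-penalty stand-in lambda = 1e8, below the smallest genuine
#'   validity slope 1/n_train at any realistic training size.
#' @param tie_tol outputs within `tie_tol * max(1, max(abs(yhat)))` of the
#'   maximum absolute output count as tied, and ties go to the lowest
#'   index. The window sits above the cross-weight residue left at large
#'   finite penalties and below the smallest gap between genuinely
#'   distinct validity slopes (rationals with denominators up to n, hence
#'   gaps of at least 1/n^2). Default 2e-5.
#' @return Integer choice(s) in \{-1, 0, +1\}.
#' @export
ttb_rule <- function(yhat, null_tol = 1e-3, null_abs = 1e-4,
                     tie_tol = 2e-5) {
  if (length(yhat) == 0L) stop("empty output vector", call. = FALSE)
  z <- null_outputs(yhat, null_tol, null_abs)
  az <- abs(z)
  amax <- apply(az, 1L, max)
  tied <- (amax - az) <= tie_tol * pmax(amax, 1)
  jstar <- max.col(tied, ties.method = "first")
  as.integer(sign(z[cbind(seq_len(nrow(z)), jstar)]))
}

#' Tallying decision rule on a COR output vector
#'
#' Chooses the option favored by the majority of outputs:
#' `z = sum_j sign(yhat_j)`, choice `sign(z)` with 0 meaning guess. With
#' strong regularization the output signs are the direction-corrected cue
#' codes, so this rule reproduces undirected tallying.
#'
#' @inheritParams ttb_rule
#' @return Integer choice(s) in \{-1, 0, +1\}.
#' @export
tally_rule <- function(yhat, null_tol = 1e-3, null_abs = 1e-4) {
  if (length(yhat) == 0L) stop("empty output vector", call. = FALSE)
  z <- null_outputs(yhat, null_tol, null_abs)
  as.integer(sign(rowSums(sign(z))))
}

#' Decisions from the COR model
#'
#' Composition of [cor_outputs()] with one of the two decision rules.
#'
#' @param x one comparison or a matrix of comparisons.
#' @param w a [cor_weights()] object.
#' @param rule `"ttb"` or `"tally"`.
#' @param null_tol,null_abs passed to the rule.
#' @return Integer choice(s) in \{-1, 0, +1\}.
#' @export
cor_predict <- function(x, w, rule = c("ttb", "tally"), null_tol = 1e-3,
                        null_abs = 1e-4) {
  rule <- match.arg(rule)
  x <- as_comparison_matrix(x, ncol(w$W))
  yhat <- x %*% w$W
  if (rule == "ttb") ttb_rule(yhat, null_tol, null_abs)
  else tally_rule(yhat, null_tol, null_abs)
}
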