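#' Ridge regression weights for paired comparisons
#'
#' Minimizes `||y - Xw||^2 + theta * ||w||^2`, i.e. returns
#' `(X'X + theta I)^{-1} X'y`. With `theta = 0` this is ordinary least
#' squares; `theta` corresponds to `sigma^2 / eta^2` in the Bayesian reading
#' (error variance over prior variance).
#'
#' @param pc a [paired_comparisons()] object (or any list with `X`, `y`).
#' @param theta nonnegative penalty.
#' @return Named numeric weight vector of length m.
#' @export
ridge_weights <- function(pc, theta = 0) {
  if (theta < 0) stop("theta must be nonnegative", call. = FALSE)
  X <- pc$X
  y <- pc$y
  A <- crossprod(X) + diag(theta, ncol(X))
  if (rcond(A) < 1e-12) {
    stop("X'X (+ theta I) is numerically singular; use a penalty theta > 0",
         call. = FALSE)
  }
  w <- drop(solve(A, crossprod(X, y)))
  names(w) <- colnames(X)
  w
}

#' Configuration of the half-ridge model
#'
#' The half-ridge model places a zero-mean Gaussian prior with standard
#' deviation `eta` on every cue weight, truncated to the orthant O fixed by
#' the cues' known directionalities (`directions_j * w_j >= 0`). The
#' likelihood is Gaussian with error standard deviation `sigma`. The prior
#' strength `1/eta^2` indexes a continuum: as `eta -> 0` decisions converge
#' to directed tallying; as `eta -> Inf` to sign-constrained regression.
#'
#' @param eta prior standard deviation (> 0).
#' @param sigma likelihood error standard deviation (> 0). Default 1, so
#'   `eta` alone indexes the continuum.
#' @param directions optional length-m sign vector defining the orthant; may
#'   instead be carried by the data ([paired_comparisons()]).
#' @param n_keep posterior draws retained after burn-in.
#' @param burn_in discarded initial sweeps.
#' @param thin keep every `thin`-th draw.
#' @param seed integer seed for the sampler; `NULL` uses the current RNG
#'   state.
#' @return Object of class `half_ridge_config`.
#' @export
half_ridge_config <- function(eta, sigma = 1, directions = NULL,
                              n_keep = 4000, burn_in = 1000, thin = 1,
                              seed = NULL) {
  if (!is.numeric(eta) || eta <= 0) stop("eta must be > 0", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0",
                                             call. = FALSE)
  n_keep <- as.integer(n_keep)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (n_keep < 1L || burn_in < 0L || thin < 1L) {
    stop("need n_keep >= 1, burn_in >= 0, thin >= 1", call. = FALSE)
  }
  structure(list(eta = eta, sigma = sigma, directions = directions,
                 n_keep = n_keep, burn_in = burn_in, thin = thin,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "half_ridge_config")
}

#' Posterior of the half-ridge model
#'
#' The untruncated posterior of the weights is Gaussian with covariance
#' `V = (X'X/sigma^2 + I/eta^2)^{-1}` and mean `V X'y / sigma^2`; the
#' half-ridge posterior is this Gaussian restricted to the orthant O. It is
#' sampled by component-wise Gibbs updates whose full conditionals are exact
#' univariate truncated normals. The posterior mean (average of retained
#' draws) summarizes the posterior for decision making.
#'
#' Convergence is monitored by the split-chain potential scale reduction
#' factor (each coordinate's kept chain split in half); values above 1.1
#' trigger a warning and are recorded in `diagnostics`.
#'
#' @param pc a [paired_comparisons()] training set; all-zero cue columns are
#'   retained (the prior dominates those coordinates).
#' @param config a [half_ridge_config()]. Directions must be supplied either
#'   here or on `pc`.
#' @return Object of class `half_ridge_posterior`: list with `samples`
#'   (n_keep x m matrix), `mean`, `untruncated_mean`, `untruncated_cov`,
#'   `directions`, `config`, and `diagnostics` (`rhat`, `mcse` per
#'   coordinate).
#' @export
half_ridge_posterior <- function(pc, config) {
  stopifnot(inherits(config, "half_ridge_config"))
  X <- pc$X
  y <- pc$y
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in the training comparisons", call. = FALSE)
  }
  m <- ncol(X)
  directions <- config$directions
  if (is.null(directions)) directions <- pc$directions
  if (is.null(directions)) {
    stop(paste("the half-ridge model needs known cue directions",
               "(in the config or on the data)"), call. = FALSE)
  }
  directions <- check_directions(directions, m)
  P <- crossprod(X) / config$sigma^2 + diag(1 / config$eta^2, m)
  b <- drop(crossprod(X, y)) / config$sigma^2
  V <- chol2inv(chol(P))
  mu_unc <- drop(V %*% b)
  init <- directions * pmax(directions * mu_unc, 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  samples <- gibbs_orthant_gaussian(P, b, directions, init,
                                    config$n_keep, config$burn_in,
                                    config$thin)
  colnames(samples) <- colnames(X)
  post_mean <- colMeans(samples)
  rhat <- apply(samples, 2L, split_rhat)
  mcse <- apply(samples, 2L, batch_means_mcse)
  if (any(rhat > 1.1, na.rm = TRUE)) {
    warning(sprintf(
      "sampler may not have converged: max split-chain Rhat = %.3f",
      max(rhat, na.rm = TRUE)), call. = FALSE)
  }
  structure(list(samples = samples, mean = post_mean,
                 untruncated_mean = mu_unc, untruncated_cov = V,
                 directions = directions, config = config,
                 diagnostics = list(rhat = rhat, mcse = mcse)),
            class = "half_ridge_posterior")
}

#' @export
print.half_ridge_posterior <- function(x, ...) {
  cat(sprintf(
    "half_ridge_posterior: m=%d, eta=%g, sigma=%g, %d draws kept\n",
    length(x$mean), x$config$eta, x$config$sigma, nrow(x$samples)))
  cat("posterior mean:", paste(signif(x$mean, 4), collapse = " "), "\n")
  cat(sprintf("max split-chain Rhat: %.3f\n",
              max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

# split-chain potential scale reduction on a single chain
split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  w <- mean(apply(halves, 2L, stats::var))
  bvar <- n * stats::var(colMeans(halves))
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + bvar / n) / w)
}

# Monte-Carlo standard error of the mean by batch means
batch_means_mcse <- function(x) {
  n <- length(x)
  nb <- max(2L, floor(sqrt(n)))
  bs <- n %/% nb
  if (bs < 1L) return(stats::sd(x) / sqrt(n))
  bm <- colMeans(matrix(x[seq_len(nb * bs)], nrow = bs))
  stats::sd(bm) / sqrt(nb)
}

#' Monte-Carlo witness of the strong-prior limit
#'
#' In the limit `eta -> 0` the rescaled posterior `w/eta` converges in
#' distribution to a standard Gaussian restricted to the orthant O,
#' independently of the training data; each coordinate's limiting mean is
#' `directions_j * sqrt(2/pi)` (the mean of a half-normal). This function
#' estimates that limit by direct Monte Carlo: the mean of direction-signed
#' absolute standard normal draws.
#'
#' @param directions length-m sign vector.
#' @param n_draws Monte-Carlo draws per coordinate (>= 1e4).
#' @param seed optional integer seed.
#' @return Numeric length-m estimate of `E[w/eta]`, with the per-coordinate
#'   Monte-Carlo standard error attached as `attr(, "se")`.
#' @export
rescaled_limit_mean <- function(directions, n_draws = 1e6, seed = NULL) {
  directions <- check_directions(directions, length(directions))
  n_draws <- as.integer(n_draws)
  if (n_draws < 1e4) stop("use at least 1e4 draws", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  est <- numeric(length(directions))
  se <- numeric(length(directions))
  for (j in seq_along(directions)) {
    z <- abs(stats::rnorm(n_draws))
    est[j] <- directions[j] * mean(z)
    se[j] <- stats::sd(z) / sqrt(n_draws)
  }
  attr(est, "se") <- se
  est
}

#' Decisions from a half-ridge posterior
#'
#' The choice for a comparison `x` is the sign of `x . mean(w)`. Because the
#' posterior mean is a Monte-Carlo estimate, evidence whose magnitude is
#' indistinguishable from zero at the sampler's resolution (within
#' `mc_mult` batch-means standard errors of `x . w`, plus a 1e-12 absolute
#' floor for exact ties) yields a guess (0). Guessing exactly where directed
#' tallying guesses is what the strong-prior limit requires.
#'
#' @param x one comparison (length-m vector) or a matrix of comparisons.
#' @param posterior a [half_ridge_posterior()].
#' @param mc_mult multiple of the Monte-Carlo standard error of `x . w`
#'   below which the evidence counts as null. Default 5.
#' @return Integer choice(s) in \{-1, 0, +1\}.
#' @export
half_ridge_predict <- function(x, posterior, mc_mult = 5) {
  stopifnot(inherits(posterior, "half_ridge_posterior"))
  x <- as_comparison_matrix(x, length(posterior$mean))
  dots <- drop(x %*% posterior$mean)
  # MC uncertainty of each dot product, from the posterior draws
  draw_dots <- posterior$samples %*% t(x)
  n <- nrow(draw_dots)
  nb <- max(2L, floor(sqrt(n)))
  bs <- n %/% nb
  idx <- seq_len(nb * bs)
  batch <- rep(seq_len(nb), each = bs)
  bm <- rowsum(draw_dots[idx, , drop = FALSE], batch) / bs
  mcse <- sqrt(pmax(colMeans(bm^2) - colMeans(bm)^2, 0) * nb / (nb - 1)) /
    sqrt(nb)
  tol <- 1e-12 + mc_mult * mcse
  out <- integer(length(dots))
  decided <- abs(dots) > tol
  out[decided] <- as.integer(sign(dots[decided]))
  out
}

#' Sign-constrained least squares
#'
#' Solves `min_w ||y - Xw||^2` subject to `directions_j * w_j >= 0`, by the
#' Lawson-Hanson active-set algorithm applied to the direction-flipped
#' design. This is the weak-prior (`eta -> Inf`) limit of the half-ridge
#' posterior mode; when the unconstrained least-squares solution already
#' lies in the orthant it coincides with ordinary least squares.
#'
#' @param pc a [paired_comparisons()] object.
#' @param directions length-m sign vector (defaults to `pc$directions`).
#' @return Named numeric weight vector satisfying the sign constraints.
#' @export
signed_ls_weights <- function(pc, directions = NULL) {
  if (is.null(directions)) directions <- pc$directions
  directions <- check_directions(directions, ncol(pc$X))
  A <- sweep(pc$X, 2L, directions, `*`)
  u <- nnls_lawson_hanson(A, pc$y)
  w <- directions * u
  names(w) <- colnames(pc$X)
  w
}

# nonnegative least squares, Lawson & Hanson active-set
nnls_lawson_hanson <- function(A, b, tol = 1e-10, max_iter = 500L) {
  m <- ncol(A)
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  x <- numeric(m)
  passive <- rep(FALSE, m)
  scale <- max(1, max(abs(Atb)))
  for (iter in seq_len(max_iter)) {
    grad <- Atb - drop(AtA %*% x)
    cand <- which(!passive & grad > tol * scale)
    if (length(cand) == 0L) break
    passive[cand[which.max(grad[cand])]] <- TRUE
    repeat {
      s <- numeric(m)
      p <- which(passive)
      s[p] <- drop(solve(AtA[p, p, drop = FALSE], Atb[p]))
      if (all(s[p] > tol * scale)) {
        x <- s
        break
      }
      neg <- p[s[p] <= tol * scale]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      x[x < tol * scale & passive] <- 0
      passive <- passive & x > 0
    }
  }
  x
}
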