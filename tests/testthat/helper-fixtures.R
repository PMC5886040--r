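# shared fixtures and independent oracles

# all 3^m comparison vectors over {-1, 0, +1}
all_comparisons <- function(m) {
  as.matrix(expand.grid(rep(list(c(-1, 0, 1)), m)))
}

# small deterministic training set, m = 2
toy_pc <- function() {
  paired_comparisons(
    X = rbind(c(1, 1), c(1, -1), c(0, -1), c(-1, 1), c(1, 0)),
    y = c(1, -1, 1, -1, 1),
    directions = c(1, 1))
}

# a reproducible random training set with known directions
random_pc <- function(m, n, seed, directions = rep(1, m), p_zero = 0.3) {
  set.seed(seed)
  repeat {
    X <- matrix(sample(c(-1, 0, 1), n * m, replace = TRUE,
                       prob = c((1 - p_zero) / 2, p_zero, (1 - p_zero) / 2)),
                n, m)
    w <- directions * abs(rnorm(m))
    y <- sign(X %*% w + rnorm(n, 0, 0.8))
    keep <- y != 0
    if (sum(keep) >= max(4L, n - 5L) && all(colSums(X[keep, , drop = FALSE] != 0) > 0)) {
      return(paired_comparisons(X[keep, , drop = FALSE], y[keep],
                                directions = directions))
    }
  }
}

# independent oracle for the half-ridge posterior mean: rejection sampling
# from the untruncated Gaussian posterior, keeping draws in the orthant
rejection_posterior_mean <- function(pc, eta, sigma, directions,
                                     n_accept = 4000, seed = 1) {
  set.seed(seed)
  X <- pc$X
  m <- ncol(X)
  P <- crossprod(X) / sigma^2 + diag(1 / eta^2, m)
  V <- chol2inv(chol(P))
  mu <- drop(V %*% crossprod(X, pc$y)) / sigma^2
  L <- t(chol(V))
  kept <- matrix(NA_real_, n_accept, m)
  got <- 0L
  while (got < n_accept) {
    draws <- mu + L %*% matrix(rnorm(m * 5000), m)
    ok <- colSums(draws * directions >= 0) == m
    take <- which(ok)
    if (length(take)) {
      take <- take[seq_len(min(length(take), n_accept - got))]
      kept[got + seq_along(take), ] <- t(draws[, take, drop = FALSE])
      got <- got + length(take)
    }
  }
  list(mean = colMeans(kept),
       se = apply(kept, 2L, sd) / sqrt(n_accept))
}

# write a small objects CSV and return its path
write_objects_csv <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  utils::write.table(df, path, sep = if (ext == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE)
  path
}
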