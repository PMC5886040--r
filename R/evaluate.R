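#' Decision model descriptors for the evaluation harness
#'
#' Lightweight descriptors naming a decision procedure and its settings; the
#' harness ([sweep_prior()], [compare_models()]) fits each on training
#' comparisons and predicts held-out ones.
#'
#' * `model_ttb()` — take-the-best with validities learned from training.
#' * `model_tally(directed)` — tallying; directed tallying uses the known
#'   cue directions and no training, undirected learns directions from
#'   validities.
#' * `model_ols(theta)` — linear regression comparator: [ridge_weights()]
#'   with a tiny stabilizing penalty, decisions by the sign of the
#'   prediction, cue coding learned from the data (no known directions).
#' * `model_half_ridge(eta, ...)` — the half-ridge posterior-mean decision
#'   model (needs known directions).
#' * `model_cor(lambda, rule)` — the COR model with the chosen decision
#'   rule.
#'
#' @param directed use known cue directions (`TRUE`) or learn them.
#' @param theta stabilizing ridge penalty for the regression comparator.
#' @param eta,sigma,n_keep,burn_in,thin half-ridge settings, see
#'   [half_ridge_config()].
#' @param lambda,rule,null_tol COR settings, see [cor_weights()] and
#'   [cor_predict()].
#' @return An object of class `decision_model`.
#' @name decision_models
NULL

#' @rdname decision_models
#' @export
model_ttb <- function() {
  structure(list(type = "ttb", label = "ttb"), class = "decision_model")
}

#' @rdname decision_models
#' @export
model_tally <- function(directed = FALSE) {
  structure(list(type = if (directed) "tally_directed" else "tally",
                 label = if (directed) "tally_directed" else "tally"),
            class = "decision_model")
}

#' @rdname decision_models
#' @export
model_ols <- function(theta = 1e-8) {
  structure(list(type = "ols", theta = theta, label = "ols"),
            class = "decision_model")
}

#' @rdname decision_models
#' @export
model_half_ridge <- function(eta, sigma = 1, n_keep = 2000, burn_in = 500,
                             thin = 1) {
  structure(list(type = "half_ridge", eta = eta, sigma = sigma,
                 n_keep = n_keep, burn_in = burn_in, thin = thin,
                 label = sprintf("half_ridge(eta=%g)", eta)),
            class = "decision_model")
}

#' @rdname decision_models
#' @export
model_cor <- function(lambda, rule = c("ttb", "tally"), null_tol = 1e-3) {
  rule <- match.arg(rule)
  structure(list(type = "cor", lambda = lambda, rule = rule,
                 null_tol = null_tol,
                 label = sprintf("cor(lambda=%g,%s)", lambda, rule)),
            class = "decision_model")
}

as_decision_model <- function(x) {
  if (inherits(x, "decision_model")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(switch(x,
                  ttb = model_ttb(),
                  tally = model_tally(FALSE),
                  tally_directed = model_tally(TRUE),
                  ols = model_ols(),
                  stop(sprintf("unknown model '%s'", x), call. = FALSE)))
  }
  stop("models must be decision_model objects or shorthand strings",
       call. = FALSE)
}

# fit a decision model on train and return choices for the rows of test_X
fit_and_choose <- function(model, train, test_X, directions = NULL) {
  switch(model$type,
         ttb = take_the_best(test_X, cue_validity(train)),
         tally = tally_undirected(test_X, cue_validity(train)),
         tally_directed = {
           if (is.null(directions)) directions <- train$directions
           if (is.null(directions)) {
             stop("directed tallying needs known cue directions",
                  call. = FALSE)
           }
           tally_directed(test_X, directions)
         },
         ols = {
           w <- ridge_weights(train, model$theta)
           p <- drop(test_X %*% w)
           as.integer(sign(p) * (abs(p) > 1e-12))
         },
         half_ridge = {
           cfg <- half_ridge_config(eta = model$eta, sigma = model$sigma,
                                    directions = directions,
                                    n_keep = model$n_keep,
                                    burn_in = model$burn_in,
                                    thin = model$thin)
           half_ridge_predict(test_X, half_ridge_posterior(train, cfg))
         },
         cor = cor_predict(test_X, cor_weights(train, model$lambda),
                           rule = model$rule, null_tol = model$null_tol),
         stop(sprintf("unknown model type '%s'", model$type), call. = FALSE))
}

#' Split paired comparisons into training and test sets
#'
#' Uniform random pair-level split without replacement.
#'
#' @param pc a [paired_comparisons()] object.
#' @param train_size number of training comparisons, `1 <= train_size < n`.
#' @param seed optional integer seed.
#' @return List with elements `train` and `test`, both
#'   [paired_comparisons()].
#' @export
split_pairs <- function(pc, train_size, seed = NULL) {
  n <- n_pairs(pc)
  train_size <- as.integer(train_size)
  if (is.na(train_size) || train_size < 1L || train_size >= n) {
    stop(sprintf(
      "train_size must be in [1, %d) so that the test set is nonempty", n),
      call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, train_size)
  list(train = pc[idx], test = pc[-idx])
}

#' Generalization accuracy with guesses scored one half
#'
#' Per-item score: 1 if the choice matches the outcome, 0.5 for a guess
#' (choice 0), else 0. Scoring a guess as 0.5 is the expectation of a fair
#' coin flip and removes needless Monte-Carlo noise.
#'
#' @param choices integer choices in \{-1, 0, +1\}.
#' @param y outcomes in \{-1, +1\}.
#' @return Mean score in \[0, 1\].
#' @export
accuracy <- function(choices, y) {
  if (length(choices) != length(y)) {
    stop("choices and y must have equal length", call. = FALSE)
  }
  if (length(y) == 0L) return(NaN)
  mean(ifelse(choices == 0L, 0.5, as.numeric(choices == y)))
}

# Draw one training/test replication. `x` is either a fixed
# paired_comparisons set (only the split is random) or an environment_spec
# (a fresh environment is generated each replication). Draws in which any
# cue never discriminates in training, or with too few comparisons, are
# resampled and counted.
draw_replication <- function(x, train_size, max_resample = 100L) {
  resampled <- 0L
  repeat {
    if (inherits(x, "environment_spec")) {
      spec <- x
      spec$seed <- NULL  # driven by the harness RNG stream
      pc <- generate_pairs(spec)
    } else {
      pc <- x
    }
    ok <- n_pairs(pc) > train_size
    if (ok) {
      sp <- split_pairs(pc, train_size)
      ok <- all(colSums(sp$train$X != 0) > 0)
    }
    if (ok) {
      return(list(train = sp$train, test = sp$test, resampled = resampled))
    }
    resampled <- resampled + 1L
    if (resampled > max_resample) {
      stop("too many degenerate training draws; check the environment spec",
           call. = FALSE)
    }
  }
}

#' Prior-strength sweep (generalization curve)
#'
#' For each replication, draws a fresh training/test split (and a fresh
#' environment when `x` is an [environment_spec()]), fits the model at every
#' point of the prior-strength grid, and scores test accuracy. The grid is
#' `eta` for the half-ridge model (strong prior on the left) and `lambda`
#' for COR (strong prior on the right).
#'
#' @param x a [paired_comparisons()] set or an [environment_spec()].
#' @param model `"half_ridge"` or `"cor"`.
#' @param grid strictly increasing vector of prior strengths (`eta` or
#'   `lambda` values). Default: 25 log-spaced points over `1e-3..1e3` for
#'   the half-ridge model, `1e-6..1e8` for COR (numerical stand-ins for the
#'   two limits).
#' @param train_size training comparisons per replication.
#' @param n_reps number of replications (>= 2).
#' @param seed integer seed governing the whole sweep.
#' @param rule COR decision rule.
#' @param sigma,n_keep,burn_in half-ridge sampler settings per fit.
#' @param max_resample cap on degenerate-draw resampling per replication.
#' @return A data frame of class `sweep_curve` with columns `strength`,
#'   `mean_accuracy`, `sem` (sd across replications / sqrt(n_reps)).
#'   Attributes: `replications` (n_reps x grid accuracy matrix), `model`,
#'   `train_size`, `n_reps`, `degenerate_resamples`.
#' @export
sweep_prior <- function(x, model = c("half_ridge", "cor"), grid = NULL,
                        train_size, n_reps = 20, seed = NULL,
                        rule = c("ttb", "tally"), sigma = 1, n_keep = 2000,
                        burn_in = 500, max_resample = 100L) {
  model <- match.arg(model)
  rule <- match.arg(rule)
  if (is.null(grid)) {
    grid <- if (model == "half_ridge") log_grid(1e-3, 1e3, 25L)
            else log_grid(1e-6, 1e8, 25L)
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing",
                                 call. = FALSE)
  n_reps <- as.integer(n_reps)
  if (n_reps < 2L) stop("n_reps must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(NA_real_, n_reps, length(grid))
  degen <- 0L
  for (r in seq_len(n_reps)) {
    repl <- draw_replication(x, train_size, max_resample)
    degen <- degen + repl$resampled
    directions <- repl$train$directions
    for (g in seq_along(grid)) {
      mod <- if (model == "half_ridge") {
        model_half_ridge(eta = grid[g], sigma = sigma, n_keep = n_keep,
                         burn_in = burn_in)
      } else {
        model_cor(lambda = grid[g], rule = rule)
      }
      ch <- fit_and_choose(mod, repl$train, repl$test$X, directions)
      acc[r, g] <- accuracy(ch, repl$test$y)
    }
  }
  out <- data.frame(strength = grid,
                    mean_accuracy = colMeans(acc),
                    sem = apply(acc, 2L, stats::sd) / sqrt(n_reps))
  structure(out, replications = acc,
            model = if (model == "cor") paste0("cor+", rule) else model,
            train_size = train_size, n_reps = n_reps,
            degenerate_resamples = degen,
            class = c("sweep_curve", "data.frame"))
}

log_grid <- function(from, to, length_out) {
  exp(seq(log(from), log(to), length.out = length_out))
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf(
    "sweep_curve: %s, train_size=%d, %d replications%s\n",
    attr(x, "model"), attr(x, "train_size"), attr(x, "n_reps"),
    if (attr(x, "degenerate_resamples") > 0)
      sprintf(" (%d degenerate draws resampled)",
              attr(x, "degenerate_resamples")) else ""))
  best <- which.max(x$mean_accuracy)
  cat(sprintf("best: strength=%.4g, accuracy=%.4f +/- %.4f\n",
              x$strength[best], x$mean_accuracy[best], x$sem[best]))
  NextMethod()
}

#' Compare decision models across training sizes
#'
#' Paired-seed evaluation: at each training size, every replication's
#' environment and split are shared by all models, so model differences are
#' within-replication and their SEMs can be computed on paired differences.
#'
#' @param x a [paired_comparisons()] set or an [environment_spec()].
#' @param models named list of `decision_model` objects (see
#'   [decision_models]) or shorthand strings among `"ttb"`, `"tally"`,
#'   `"tally_directed"`, `"ols"`.
#' @param train_sizes vector of training-set sizes.
#' @param n_reps replications per training size.
#' @param seed integer seed.
#' @param max_resample cap on degenerate-draw resampling.
#' @return A data frame of class `comparison_result` with columns `model`,
#'   `train_size`, `mean_accuracy`, `sem`. Attribute `replications` is an
#'   array `[n_reps, model, train_size]` of per-replication accuracies.
#' @export
compare_models <- function(x, models, train_sizes, n_reps = 50,
                           seed = NULL, max_resample = 100L) {
  models <- lapply(models, as_decision_model)
  if (length(models) < 2L) stop("need at least two models", call. = FALSE)
  labels <- names(models)
  if (is.null(labels) || any(labels == "")) {
    labels <- vapply(models, `[[`, "", "label")
    names(models) <- labels
  }
  n_reps <- as.integer(n_reps)
  if (!is.null(seed)) set.seed(seed)
  acc <- array(NA_real_, dim = c(n_reps, length(models), length(train_sizes)),
               dimnames = list(NULL, labels, as.character(train_sizes)))
  for (s in seq_along(train_sizes)) {
    for (r in seq_len(n_reps)) {
      repl <- draw_replication(x, train_sizes[s], max_resample)
      for (k in seq_along(models)) {
        ch <- fit_and_choose(models[[k]], repl$train, repl$test$X,
                             repl$train$directions)
        acc[r, k, s] <- accuracy(ch, repl$test$y)
      }
    }
  }
  out <- expand.grid(model = labels, train_size = train_sizes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_accuracy <- as.vector(apply(acc, c(2L, 3L), mean))
  out$sem <- as.vector(apply(acc, c(2L, 3L), stats::sd)) / sqrt(n_reps)
  structure(out, replications = acc, n_reps = n_reps,
            class = c("comparison_result", "data.frame"))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("comparison_result: %d replications per training size\n",
              attr(x, "n_reps")))
  NextMethod()
}

#' Paired accuracy difference between two models in a comparison
#'
#' Mean and SEM of the per-replication accuracy difference
#' `model_a - model_b` at one training size, using the paired replications
#' stored by [compare_models()].
#'
#' @param result a `comparison_result`.
#' @param model_a,model_b model labels as in `result$model`.
#' @param train_size one of the evaluated training sizes.
#' @return List with `delta` (mean difference), `sem` (SEM of the paired
#'   differences), `n_reps`.
#' @export
paired_difference <- function(result, model_a, model_b, train_size) {
  acc <- attr(result, "replications")
  s <- as.character(train_size)
  d <- acc[, model_a, s] - acc[, model_b, s]
  list(delta = mean(d), sem = stats::sd(d) / sqrt(length(d)),
       n_reps = length(d))
}
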