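#' Specification of a synthetic binary-cue decision environment
#'
#' Describes a generative model for paired-comparison environments with
#' controllable cue predictiveness, cue-cue correlation, and criterion noise.
#' True cue weights are drawn from a half-Gaussian (the same family the
#' half-ridge model assumes): `w*_j = directions_j * |N(0, weight_scale^2)|`.
#' Binary cues arise by thresholding equicorrelated latent Gaussians at zero
#' (one common factor gives every cue pair latent correlation
#' `cue_correlation`), and the criterion of each object is
#' `cues . w* + N(0, noise_sd^2)`.
#'
#' @param m number of cues (>= 1).
#' @param n_objects number of objects (>= 2).
#' @param weight_scale standard deviation tau of true-weight magnitudes
#'   (>= 0). Larger values make cue predictiveness more dispersed.
#' @param cue_correlation pairwise latent correlation rho of the cue values,
#'   in \[0, 1). The induced correlation between the thresholded binary cues
#'   is `2/pi * asin(rho)`.
#' @param noise_sd standard deviation sigma_e of Gaussian noise added to the
#'   latent criterion (>= 0).
#' @param directions length-m sign vector of true cue directionalities;
#'   default all +1.
#' @param seed integer seed making generation reproducible; `NULL` leaves the
#'   RNG state alone.
#' @return An object of class `environment_spec`.
#' @export
#' @examples
#' spec <- environment_spec(m = 3, n_objects = 10, seed = 7)
#' env <- generate_environment(spec)
#' attr(env, "true_weights")
environment_spec <- function(m, n_objects, weight_scale = 1,
                             cue_correlation = 0, noise_sd = 0,
                             directions = rep(1, m), seed = NULL) {
  m <- as.integer(m)
  n_objects <- as.integer(n_objects)
  if (is.na(m) || m < 1L) stop("m must be >= 1", call. = FALSE)
  if (is.na(n_objects) || n_objects < 2L) {
    stop("n_objects must be >= 2", call. = FALSE)
  }
  if (weight_scale < 0) stop("weight_scale must be >= 0", call. = FALSE)
  if (cue_correlation < 0 || cue_correlation >= 1) {
    stop("cue_correlation must be in [0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  directions <- check_directions(directions, m)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(m = m, n_objects = n_objects, weight_scale = weight_scale,
                 cue_correlation = cue_correlation, noise_sd = noise_sd,
                 directions = directions, seed = seed),
            class = "environment_spec")
}

#' @export
print.environment_spec <- function(x, ...) {
  cat(sprintf(
    "environment_spec: m=%d cues, %d objects, tau=%g, rho=%g, sigma_e=%g\n",
    x$m, x$n_objects, x$weight_scale, x$cue_correlation, x$noise_sd))
  invisible(x)
}

#' Generate a synthetic object table from an environment specification
#'
#' @param spec an [environment_spec()].
#' @return An [object_table()] with binary \{0, 1\} cues. The realized true
#'   weight vector is attached as `attr(, "true_weights")` (for
#'   parameter-recovery tests) and the spec as `attr(, "spec")`.
#' @export
generate_environment <- function(spec) {
  stopifnot(inherits(spec, "environment_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  m <- spec$m
  n <- spec$n_objects
  w_true <- spec$directions * abs(stats::rnorm(m, 0, spec$weight_scale))
  rho <- spec$cue_correlation
  common <- stats::rnorm(n)
  latent <- sqrt(rho) * common +
    sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
  cues <- (latent > 0) * 1
  colnames(cues) <- paste0("cue", seq_len(m))
  criterion <- drop(cues %*% w_true) + stats::rnorm(n, 0, spec$noise_sd)
  out <- object_table(criterion = criterion, cues = cues)
  attr(out, "true_weights") <- w_true
  attr(out, "spec") <- spec
  out
}

#' Generate a subsampled paired-comparison set from an environment
#'
#' Composes [generate_environment()] and [make_pairs()], then subsamples
#' `n_pairs` comparisons uniformly without replacement. Known cue directions
#' from the spec are carried into the result.
#'
#' @param spec an [environment_spec()].
#' @param n_pairs number of comparisons to keep; must not exceed the number
#'   available after tied-criterion pairs are dropped. `NULL` keeps all.
#' @param seed seed for the subsampling step (the environment itself is
#'   governed by `spec$seed`).
#' @return A [paired_comparisons()] object with the environment's
#'   `true_weights` attached as an attribute.
#' @export
generate_pairs <- function(spec, n_pairs = NULL, seed = NULL) {
  env <- generate_environment(spec)
  pc <- make_pairs(env, directions = spec$directions)
  if (!is.null(n_pairs)) {
    n_pairs <- as.integer(n_pairs)
    if (n_pairs > n_pairs(pc)) {
      stop(sprintf("requested %d pairs but only %d are available",
                   n_pairs, n_pairs(pc)), call. = FALSE)
    }
    if (!is.null(seed)) set.seed(seed)
    pc <- pc[sort(sample.int(n_pairs(pc), n_pairs))]
  }
  attr(pc, "true_weights") <- attr(env, "true_weights")
  pc
}

#' Read / write an environment specification as YAML or JSON
#'
#' The file holds the fields of [environment_spec()] under their argument
#' names. Format is chosen by extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path file path.
#' @param spec an [environment_spec()] (for writing).
#' @return `read_environment_spec` returns an [environment_spec()];
#'   `write_environment_spec` returns `path` invisibly.
#' @export
read_environment_spec <- function(path) {
  fields <- read_config(path)
  do.call(environment_spec, fields[intersect(names(fields),
    names(formals(environment_spec)))])
}

#' @rdname read_environment_spec
#' @export
write_environment_spec <- function(spec, path) {
  stopifnot(inherits(spec, "environment_spec"))
  fields <- unclass(spec)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    require_pkg("yaml")
    yaml::write_yaml(fields, path)
  } else {
    require_pkg("jsonlite")
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    require_pkg("yaml")
    yaml::read_yaml(path)
  } else {
    require_pkg("jsonlite")
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

require_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop(sprintf("package '%s' is required for this feature", pkg),
         call. = FALSE)
  }
}
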