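#' Cue validities, learned directions and the take-the-best cue order
#'
#' The validity of a cue is the proportion of correct inferences it makes on
#' its own, among the training comparisons where it discriminates:
#' `v_j = #\{i : x_ij * y_i = +1\} / #\{i : x_ij != 0\}`. A cue that never
#' discriminates gets `v_j = 0.5` ("uninformative") by convention. Learned
#' directions are `+1` when `v_j >= 0.5`, else `-1`; the equivalent validity
#' of the direction-recoded cue is `max(v_j, 1 - v_j)`.
#'
#' `rank_order` ranks cues for take-the-best by descending direction-corrected
#' validity `max(v_j, 1 - v_j)` (the validity each cue attains once recoded to
#' point in its learned direction), ties broken by ascending cue index. Note
#' `2 * max(v, 1 - v) - 1 = |2v - 1|`, so this order matches the magnitude of
#' the simple-regression slope each cue earns in the strong-prior limit of the
#' COR model.
#'
#' @param pc a [paired_comparisons()] training set with at least one
#'   comparison.
#' @return An object of class `cue_profile`: list with `validities`,
#'   `directions` (learned), `discrimination_counts`, `rank_order`.
#' @export
#' @examples
#' pc <- paired_comparisons(X = rbind(c(1, 1), c(1, -1), c(0, -1)),
#'                          y = c(1, -1, 1))
#' cue_validity(pc)
cue_validity <- function(pc) {
  X <- pc$X
  y <- pc$y
  if (length(y) == 0L) stop("empty paired-comparison set", call. = FALSE)
  disc <- colSums(X != 0)
  correct <- colSums((X * y) == 1)
  v <- ifelse(disc > 0, correct / disc, 0.5)
  directions <- ifelse(v >= 0.5, 1, -1)
  corrected <- pmax(v, 1 - v)
  rank_order <- order(-corrected, seq_along(v))
  structure(list(validities = as.numeric(v),
                 directions = as.numeric(directions),
                 discrimination_counts = as.integer(disc),
                 rank_order = as.integer(rank_order),
                 cue_names = pc$cue_names),
            class = "cue_profile")
}

#' @export
print.cue_profile <- function(x, ...) {
  cat("cue_profile:\n")
  print(data.frame(cue = x$cue_names, validity = round(x$validities, 3),
                   direction = x$directions,
                   discriminations = x$discrimination_counts))
  cat("take-the-best order:", paste(x$rank_order, collapse = " > "), "\n")
  invisible(x)
}

# coerce a single comparison (vector) or several (matrix rows) to a matrix
as_comparison_matrix <- function(x, m) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != m) {
    stop(sprintf("comparison has %d cues, expected %d", ncol(x), m),
         call. = FALSE)
  }
  x
}

#' Directed tallying
#'
#' Counts cues for each alternative using known cue directionalities: the
#' evidence is `z = sum_j directions_j * x_j` and the choice is `sign(z)`
#' (+1 left, -1 right, 0 guess). No training data is used.
#'
#' @param x one comparison (length-m vector in \{-1,0,+1\}) or a matrix with
#'   one comparison per row.
#' @param directions length-m sign vector of known cue directionalities.
#' @return Integer choice(s) in \{-1, 0, +1\}, one per comparison.
#' @export
tally_directed <- function(x, directions) {
  directions <- check_directions(directions, length(directions))
  x <- as_comparison_matrix(x, length(directions))
  z <- drop(x %*% directions)
  as.integer(sign(z))
}

#' Undirected tallying
#'
#' As [tally_directed()], but with directions learned from training data via
#' cue validities; cues whose validity is exactly 0.5 (uninformative) are
#' excluded from the tally.
#'
#' @param x one comparison or a matrix of comparisons.
#' @param profile a [cue_validity()] profile from the training comparisons.
#' @return Integer choice(s) in \{-1, 0, +1\}.
#' @export
tally_undirected <- function(x, profile) {
  stopifnot(inherits(profile, "cue_profile"))
  d <- profile$directions
  d[profile$validities == 0.5] <- 0
  x <- as_comparison_matrix(x, length(d))
  as.integer(sign(drop(x %*% d)))
}

#' Take-the-best
#'
#' Walks the cues from most to least valid (direction-corrected validity,
#' ties by ascending cue index) and decides by the first cue that
#' discriminates: `sign(direction_j * x_j)`. Cues with validity exactly 0.5
#' never decide. If no cue discriminates the choice is a guess (0).
#'
#' @param x one comparison or a matrix of comparisons.
#' @param profile a [cue_validity()] profile from the training comparisons.
#' @return Integer choice(s) in \{-1, 0, +1\}.
#' @export
take_the_best <- function(x, profile) {
  stopifnot(inherits(profile, "cue_profile"))
  m <- length(profile$validities)
  x <- as_comparison_matrix(x, m)
  ord <- profile$rank_order
  usable <- profile$validities[ord] != 0.5
  signed <- sweep(x[, ord, drop = FALSE], 2L, profile$directions[ord], `*`)
  live <- sweep(signed != 0, 2L, usable, `&`)
  out <- integer(nrow(x))
  has <- rowSums(live) > 0
  if (any(has)) {
    first <- max.col(live, ties.method = "first")
    picked <- signed[cbind(seq_len(nrow(x)), first)]
    out[has] <- as.integer(sign(picked[has]))
  }
  out
}
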