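#' Table of objects with a criterion and cue values
#'
#' The basic input for a binary-comparison task: a set of objects (e.g. soccer
#' teams, cities, houses), each with a numeric criterion (the quantity
#' compared, e.g. match outcome strength or price) and one or more numeric or
#' binary cue values.
#'
#' @param criterion numeric vector, one value per object.
#' @param cues numeric matrix or data frame with one row per object and one
#'   column per cue; column names are used as cue names.
#' @param id optional character vector of object labels; defaults to
#'   `obj1, obj2, ...`.
#'
#' @return An object of class `object_table`: a list with elements `id`,
#'   `criterion` and `cues` (numeric matrix with column names).
#' @seealso [make_pairs()], [read_objects()]
#' @export
#' @examples
#' ot <- object_table(criterion = c(10, 5, 7),
#'                    cues = cbind(size = c(1, 0, 1), age = c(0, 0, 1)))
#' make_pairs(ot)
object_table <- function(criterion, cues, id = NULL) {
  cues <- as.matrix(cues)
  storage.mode(cues) <- "double"
  if (is.null(colnames(cues))) {
    colnames(cues) <- paste0("cue", seq_len(ncol(cues)))
  }
  n <- nrow(cues)
  if (n < 2L) {
    stop("an object table needs at least 2 objects", call. = FALSE)
  }
  if (ncol(cues) < 1L) {
    stop("an object table needs at least 1 cue", call. = FALSE)
  }
  criterion <- as.numeric(criterion)
  if (length(criterion) != n) {
    stop("criterion length must match the number of objects", call. = FALSE)
  }
  if (anyNA(criterion) || any(!is.finite(criterion))) {
    stop("criterion must be numeric and non-missing for every object",
         call. = FALSE)
  }
  if (anyNA(cues)) {
    bad <- which(is.na(cues), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing cue value at object %d, cue '%s'",
                 bad[1L], colnames(cues)[bad[2L]]), call. = FALSE)
  }
  if (is.null(id)) id <- paste0("obj", seq_len(n))
  structure(list(id = as.character(id), criterion = criterion, cues = cues),
            class = "object_table")
}

#' @export
print.object_table <- function(x, ...) {
  cat(sprintf("object_table: %d objects, %d cues (%s)\n",
              length(x$id), ncol(x$cues),
              paste(colnames(x$cues), collapse = ", ")))
  invisible(x)
}

#' Read an object table from a delimited text file
#'
#' Reads a CSV (or TSV, chosen by file extension) with a header row, one row
#' per object. The named criterion column supplies the criterion; an optional
#' `id` column supplies object labels; every remaining column must be numeric
#' and becomes a cue.
#'
#' @param path path to a delimited text file.
#' @param criterion_column name of the criterion column.
#' @param id_column name of the label column, if present. Default `"id"`.
#' @return An [object_table()].
#' @export
read_objects <- function(path, criterion_column, id_column = "id") {
  sep <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!criterion_column %in% names(df)) {
    stop(sprintf("criterion column '%s' not found in '%s'",
                 criterion_column, path), call. = FALSE)
  }
  id <- NULL
  if (id_column %in% names(df)) {
    id <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
  }
  criterion <- df[[criterion_column]]
  if (!is.numeric(criterion)) {
    stop(sprintf("criterion column '%s' is not numeric", criterion_column),
         call. = FALSE)
  }
  df[[criterion_column]] <- NULL
  if (ncol(df) < 1L) stop("no cue columns found", call. = FALSE)
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))))[1L]
      stop(sprintf("non-numeric cue value in column '%s', row %d", nm, bad),
           call. = FALSE)
    }
  }
  object_table(criterion = criterion, cues = as.matrix(df), id = id)
}

#' Construct a paired-comparison set
#'
#' Low-level constructor for the `paired_comparisons` container: an n x m
#' cue-difference matrix `X` with entries in \{-1, 0, +1\} (a cue is coded +1
#' when it favors the left object of the pair, -1 when it favors the right,
#' 0 when it does not discriminate) and outcomes `y` in \{-1, +1\} (which
#' object had the greater criterion).
#'
#' @param X integer matrix with entries in \{-1, 0, +1\}.
#' @param y integer vector with entries in \{-1, +1\}.
#' @param cue_names optional cue labels (defaults to colnames of `X`).
#' @param directions optional length-m vector in \{-1, +1\}: cue
#'   directionalities known a priori (used by directed tallying and the
#'   half-ridge model).
#' @param pair_ids optional n x 2 character matrix of (left, right) object
#'   labels.
#' @return An object of class `paired_comparisons`.
#' @export
paired_comparisons <- function(X, y, cue_names = NULL, directions = NULL,
                               pair_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(X %in% c(-1, 0, 1))) {
    stop("X entries must be in {-1, 0, +1}", call. = FALSE)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) {
    stop("y entries must be in {-1, +1}", call. = FALSE)
  }
  if (length(y) != nrow(X)) {
    stop("length(y) must equal nrow(X)", call. = FALSE)
  }
  if (is.null(cue_names)) {
    cue_names <- colnames(X)
    if (is.null(cue_names)) cue_names <- paste0("cue", seq_len(ncol(X)))
  }
  colnames(X) <- cue_names
  if (!is.null(directions)) {
    directions <- check_directions(directions, ncol(X))
  }
  if (!is.null(pair_ids)) {
    pair_ids <- as.matrix(pair_ids)
    stopifnot(nrow(pair_ids) == nrow(X), ncol(pair_ids) == 2L)
  }
  structure(list(X = X, y = y, cue_names = cue_names,
                 directions = directions, pair_ids = pair_ids),
            class = "paired_comparisons")
}

check_directions <- function(directions, m) {
  directions <- as.numeric(directions)
  if (length(directions) != m || !all(directions %in% c(-1, 1))) {
    stop("directions must be a length-m vector with entries in {-1, +1}",
         call. = FALSE)
  }
  directions
}

#' @export
print.paired_comparisons <- function(x, ...) {
  cat(sprintf("paired_comparisons: %d comparisons, %d cues%s\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$directions)) "" else " (known directions)"))
  invisible(x)
}

#' @export
`[.paired_comparisons` <- function(x, i, ...) {
  paired_comparisons(x$X[i, , drop = FALSE], x$y[i],
                     cue_names = x$cue_names, directions = x$directions,
                     pair_ids = if (!is.null(x$pair_ids))
                       x$pair_ids[i, , drop = FALSE])
}

#' Number of comparisons / cues in a paired-comparison set
#' @param pc a [paired_comparisons()] object.
#' @return integer count.
#' @export
n_pairs <- function(pc) nrow(pc$X)

#' @rdname n_pairs
#' @export
n_cues <- function(pc) ncol(pc$X)

#' Build paired comparisons from an object table
#'
#' Forms one comparison for every unordered pair of objects with unequal
#' criterion. For the pair (A, B) with A the earlier row ("left"), cue j is
#' coded `sign(cue_j(A) - cue_j(B))` and the outcome `sign(crit(A) - crit(B))`.
#' Pairs with tied criterion are dropped, since the outcome space \{-1, +1\}
#' has no code for a tie.
#'
#' @param objects an [object_table()].
#' @param dichotomize if `TRUE`, continuous cues are median-split into
#'   \{0, 1\} (value above the cue's median becomes 1) before pairing;
#'   already-binary cues are left untouched. Default `FALSE`: signed
#'   differences of the raw cue values are used directly.
#' @param directions optional known cue directionalities, carried through to
#'   the result.
#' @return A [paired_comparisons()] object.
#' @export
make_pairs <- function(objects, dichotomize = FALSE, directions = NULL) {
  stopifnot(inherits(objects, "object_table"))
  cues <- objects$cues
  if (dichotomize) cues <- apply(cues, 2L, median_split)
  k <- length(objects$criterion)
  idx <- utils::combn(k, 2L)
  a <- idx[1L, ]
  b <- idx[2L, ]
  keep <- objects$criterion[a] != objects$criterion[b]
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0L) {
    X <- matrix(0, 0L, ncol(cues), dimnames = list(NULL, colnames(cues)))
    return(paired_comparisons(X, numeric(0), directions = directions,
                              pair_ids = matrix(character(0), 0L, 2L)))
  }
  X <- sign(cues[a, , drop = FALSE] - cues[b, , drop = FALSE])
  y <- sign(objects$criterion[a] - objects$criterion[b])
  paired_comparisons(X, y, cue_names = colnames(cues),
                     directions = directions,
                     pair_ids = cbind(objects$id[a], objects$id[b]))
}

# median split to {0,1}; a no-op on cues that are already binary
median_split <- function(x) {
  if (all(x %in% c(0, 1))) return(x)
  as.numeric(x > stats::median(x))
}

#' Validate a paired-comparison encoding
#'
#' Checks the \{-1, 0, +1\} / \{-1, +1\} encoding invariants and reports the
#' per-cue discrimination counts (number of nonzero entries per cue column).
#'
#' @param pc a [paired_comparisons()] object, or a list with elements `X` and
#'   `y` (e.g. read from a file) that has not yet been validated.
#' @return A list of class `pairs_report` with elements `ok` (logical),
#'   `problems` (character vector describing offending entries),
#'   `discrimination_counts` (named integer vector), `n`, `m`.
#' @export
validate_pairs <- function(pc) {
  X <- as.matrix(pc$X)
  y <- as.numeric(pc$y)
  problems <- character(0)
  bad_x <- which(!(X %in% c(-1, 0, 1)))
  if (length(bad_x)) {
    rc <- arrayInd(bad_x, dim(X))
    problems <- c(problems, sprintf(
      "X[%d,%d] = %s not in {-1,0,+1}", rc[, 1L], rc[, 2L], format(X[bad_x])))
  }
  bad_y <- which(!(y %in% c(-1, 1)))
  if (length(bad_y)) {
    problems <- c(problems, sprintf("y[%d] = %s not in {-1,+1}",
                                    bad_y, format(y[bad_y])))
  }
  if (length(y) != nrow(X)) {
    problems <- c(problems, "length(y) != nrow(X)")
  }
  counts <- colSums(X != 0)
  names(counts) <- if (!is.null(colnames(X))) colnames(X) else
    paste0("cue", seq_len(ncol(X)))
  structure(list(ok = length(problems) == 0L, problems = problems,
                 discrimination_counts = counts,
                 n = nrow(X), m = ncol(X)),
            class = "pairs_report")
}

#' @export
print.pairs_report <- function(x, ...) {
  cat(sprintf("paired-comparison check: %s (%d comparisons, %d cues)\n",
              if (x$ok) "PASS" else "FAIL", x$n, x$m))
  cat("discrimination counts:",
      paste(sprintf("%s=%d", names(x$discrimination_counts),
                    x$discrimination_counts), collapse = ", "), "\n")
  if (!x$ok) cat("problems:\n", paste(" -", x$problems, collapse = "\n"), "\n")
  invisible(x)
}

#' Write / read paired comparisons as CSV
#'
#' The file has columns `left`, `right` (object labels, if known),
#' `x_<cue>` for each cue, and `y`.
#'
#' @param pc a [paired_comparisons()] object.
#' @param path output (input) CSV path.
#' @return `write_pairs` returns `path` invisibly; `read_pairs` returns a
#'   [paired_comparisons()] object.
#' @export
write_pairs <- function(pc, path) {
  df <- as.data.frame(pc$X)
  names(df) <- paste0("x_", pc$cue_names)
  df$y <- pc$y
  if (!is.null(pc$pair_ids)) {
    df <- cbind(left = pc$pair_ids[, 1L], right = pc$pair_ids[, 2L], df)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  xcols <- grep("^x_", names(df), value = TRUE)
  if (length(xcols) == 0L || !"y" %in% names(df)) {
    stop("pairs file needs x_<cue> columns and a y column", call. = FALSE)
  }
  pair_ids <- if (all(c("left", "right") %in% names(df)))
    cbind(df$left, df$right)
  paired_comparisons(as.matrix(df[xcols]), df$y,
                     cue_names = sub("^x_", "", xcols), pair_ids = pair_ids)
}
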