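#' Cohort health tensor
#'
#' The central data container: an \eqn{N \times M \times K} array of sensor
#' readings for \eqn{N} students over \eqn{M} health criteria (heart rate,
#' blood pressure, ...) at \eqn{K} time points, plus an observation mask.
#' Entry \eqn{a_{i,j,k}} is student \eqn{i}'s reading on criterion \eqn{j} at
#' time \eqn{k}; the length-\eqn{K} slice \eqn{A_{i,j}} is one time-aware
#' health curve. Units are criterion-specific and treated as opaque.
#'
#' @param values numeric array of dimension \code{c(N, M, K)}, or a matrix
#'   (interpreted as \code{K = 1}). All observed entries must be finite.
#' @param student_ids,criterion_ids character vectors of unique identifiers;
#'   default to \code{s1..sN} / \code{c1..cM} or the array dimnames.
#' @param mask optional logical array of the same dimension, \code{TRUE} where
#'   the entry was observed. \code{NULL} means fully observed.
#' @return an object of class \code{"health_tensor"}: a list with elements
#'   \code{values}, \code{mask}, \code{student_ids}, \code{criterion_ids} and
#'   dimensions \code{N}, \code{M}, \code{K}.
#' @examples
#' t <- health_tensor(array(rnorm(2 * 3 * 4), c(2, 3, 4)))
#' dim(t$values)
#' @export
health_tensor <- function(values, student_ids = NULL, criterion_ids = NULL,
                          mask = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    abort_validation("values must be an N x M x K array")
  d <- dim(values)
  if (any(d < 1L)) abort_validation("N, M and K must all be >= 1")
  dn <- dimnames(values)
  if (is.null(student_ids)) student_ids <- if (!is.null(dn[[1]])) dn[[1]] else paste0("s", seq_len(d[1]))
  if (is.null(criterion_ids)) criterion_ids <- if (!is.null(dn[[2]])) dn[[2]] else paste0("c", seq_len(d[2]))
  student_ids <- as.character(student_ids)
  criterion_ids <- as.character(criterion_ids)
  if (length(student_ids) != d[1] || anyDuplicated(student_ids))
    abort_validation("student_ids must be ", d[1], " unique identifiers")
  if (length(criterion_ids) != d[2] || anyDuplicated(criterion_ids))
    abort_validation("criterion_ids must be ", d[2], " unique identifiers")
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), d))
      abort_validation("mask must be a logical array with the same dimensions as values")
    if (anyNA(mask)) abort_validation("mask must not contain NA")
    if (all(mask)) mask <- NULL
  }
  obs <- if (is.null(mask)) values else values[mask]
  if (anyNA(obs) || any(!is.finite(obs)))
    abort_validation("all observed values must be finite")
  storage.mode(values) <- "double"
  dimnames(values) <- list(student_ids, criterion_ids, NULL)
  if (!is.null(mask)) dimnames(mask) <- dimnames(values)
  structure(list(values = values, mask = mask,
                 student_ids = student_ids, criterion_ids = criterion_ids,
                 N = d[1], M = d[2], K = d[3]),
            class = "health_tensor")
}

#' @export
print.health_tensor <- function(x, ...) {
  cat(sprintf("Health tensor: %d students x %d criteria x %d time points\n",
              x$N, x$M, x$K))
  n_obs <- if (is.null(x$mask)) length(x$values) else sum(x$mask)
  cat(sprintf("  observed entries: %d of %d (%.1f%%)\n",
              n_obs, length(x$values), 100 * n_obs / length(x$values)))
  invisible(x)
}

#' @export
dim.health_tensor <- function(x) dim(x$values)

# Values with unobserved entries zeroed; this is the array entering the
# inner products (a zero contribution leaves the projection sign driven by
# the observed data).
tensor_values0 <- function(tensor) {
  v <- tensor$values
  if (!is.null(tensor$mask)) v[!tensor$mask] <- 0
  v
}

#' Run configuration for index construction and detection
#'
#' Bundles the hashing and detection parameters: \code{p} independent hash
#' tables, \code{q} index repetitions per table, similarity threshold
#' \code{T} (two students are similar when their match count is at least
#' \code{T}; necessarily \code{T <= q}), the root random seed, and whether an
#' independent hyperplane is drawn per criterion.
#'
#' @param p number of hash tables (>= 1).
#' @param q index repetitions per table (>= 1).
#' @param T similarity threshold, integer in \code{1..q}.
#' @param seed non-negative integer root seed.
#' @param per_criterion_planes if \code{TRUE}, draw an independent random
#'   hyperplane for every (table, repetition, criterion) slot instead of
#'   sharing one plane across criteria within a (table, repetition).
#' @return an object of class \code{"run_config"}.
#' @examples
#' run_config(p = 4, q = 6, T = 2, seed = 1)
#' @export
run_config <- function(p = 4L, q = 6L, T = 2L, seed = 0L,
                       per_criterion_planes = FALSE) {
  if (!is_count(p)) abort_validation("p must be a positive integer")
  if (!is_count(q)) abort_validation("q must be a positive integer")
  if (!is_count(T)) abort_validation("T must be a positive integer")
  if (T > q) abort_validation("T must satisfy T <= q (got T=", T, ", q=", q, ")")
  if (!is_count(seed, min = 0L)) abort_validation("seed must be a non-negative integer")
  if (!isTRUE(per_criterion_planes) && !isFALSE(per_criterion_planes))
    abort_validation("per_criterion_planes must be TRUE or FALSE")
  structure(list(p = as.integer(p), q = as.integer(q), T = as.integer(T),
                 seed = as.double(seed),
                 per_criterion_planes = per_criterion_planes),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: p=%d tables, q=%d repetitions, T=%d, seed=%s%s\n",
              x$p, x$q, x$T, format(x$seed, scientific = FALSE),
              if (x$per_criterion_planes) ", per-criterion planes" else ""))
  invisible(x)
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with keys \code{p}, \code{q}, \code{T}, \code{seed}
#'   and optionally \code{per_criterion_planes}.
#' @return a \code{\link{run_config}} object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io("file not found: ", path)
  cfg <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) abort_parse("malformed JSON in ", path, ": ",
                                                  conditionMessage(e)))
  for (key in c("p", "q", "T", "seed"))
    if (is.null(cfg[[key]]))
      abort_schema("run config is missing required key '", key, "'")
  run_config(p = cfg$p, q = cfg$q, T = cfg$T, seed = cfg$seed,
             per_criterion_planes = isTRUE(cfg$per_criterion_planes))
}

#' Read a cohort health tensor
#'
#' Two interchange formats are supported. \emph{Long CSV} has the header
#' \code{student_id,criterion_id,time_index,value} with 0-based
#' \code{time_index}; a (student, criterion, time) triple absent from the
#' file is treated as unobserved (\code{mask = FALSE}) by default.
#' \emph{Dense JSON} is a bundle
#' \code{{"students":[...],"criteria":[...],"K":n,"values":[[[...]]]}} with
#' \code{values[i][j][k]} and an optional parallel \code{mask}.
#'
#' @param path file to read.
#' @param format \code{"long-csv"} or \code{"dense-json"}.
#' @param missing for long CSV: \code{"mask"} records absent triples as
#'   unobserved; \code{"error"} raises a schema error when any
#'   (student, criterion) series is incomplete.
#' @return a \code{\link{health_tensor}}.
#' @export
read_tensor <- function(path, format = c("long-csv", "dense-json"),
                        missing = c("mask", "error")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (!file.exists(path)) abort_io("file not found: ", path)
  if (format == "long-csv") read_tensor_long_csv(path, missing)
  else read_tensor_dense_json(path)
}

read_tensor_long_csv <- function(path, missing) {
  df <- tryCatch(
    utils::read.csv(path, colClasses = c("character", "character", "integer",
                                         "numeric")),
    error = function(e) abort_parse("cannot parse ", path, ": ",
                                    conditionMessage(e)))
  need <- c("student_id", "criterion_id", "time_index", "value")
  if (!identical(names(df), need))
    abort_parse("long CSV must have header ", paste(need, collapse = ","))
  if (nrow(df) == 0L) abort_parse("empty tensor file: ", path)
  bad <- which(is.na(df$time_index) | is.na(df$value) | !is.finite(df$value) |
                 df$time_index < 0L)
  if (length(bad))
    abort_parse("malformed row at line ", bad[1] + 1L, " of ", path)
  students <- unique(df$student_id)
  criteria <- unique(df$criterion_id)
  K <- max(df$time_index) + 1L
  i <- match(df$student_id, students)
  j <- match(df$criterion_id, criteria)
  k <- df$time_index + 1L
  idx <- cbind(i, j, k)
  if (anyDuplicated(idx))
    abort_schema("duplicate (student, criterion, time) triple in ", path)
  values <- array(0, c(length(students), length(criteria), K))
  mask <- array(FALSE, dim(values))
  values[idx] <- df$value
  mask[idx] <- TRUE
  if (missing == "error" && !all(mask))
    abort_schema("inconsistent K across entries in ", path,
                 ": not every (student, criterion) series has ", K, " values")
  health_tensor(values, students, criteria,
                mask = if (all(mask)) NULL else mask)
}

read_tensor_dense_json <- function(path) {
  b <- tryCatch(jsonlite::fromJSON(path),
                error = function(e) abort_parse("malformed JSON in ", path, ": ",
                                                conditionMessage(e)))
  for (key in c("students", "criteria", "K", "values"))
    if (is.null(b[[key]])) abort_schema("dense JSON bundle is missing '", key, "'")
  v <- b$values
  if (!is.array(v) || length(dim(v)) != 3L)
    abort_schema("values must be a regular [N][M][K] nested array")
  if (dim(v)[3] != b$K)
    abort_schema("declared K=", b$K, " but values have K=", dim(v)[3])
  mask <- NULL
  if (!is.null(b$mask)) {
    if (!identical(dim(b$mask), dim(v)))
      abort_schema("mask dimensions differ from values")
    mask <- array(as.logical(b$mask), dim(v))
    v[!mask] <- 0
  }
  health_tensor(v, b$students, b$criteria, mask = mask)
}

#' Write a cohort health tensor
#'
#' Serializes with full decimal precision so that
#' \code{read_tensor(write_tensor(t))} reproduces \code{t} bit-exactly.
#' Masked (unobserved) triples are omitted from long CSV and re-read as
#' unobserved. Files are written atomically.
#'
#' @param tensor a \code{\link{health_tensor}}.
#' @param path output file.
#' @param format \code{"long-csv"} or \code{"dense-json"}.
#' @return \code{path}, invisibly.
#' @export
write_tensor <- function(tensor, path, format = c("long-csv", "dense-json")) {
  format <- match.arg(format)
  if (!inherits(tensor, "health_tensor"))
    abort_validation("tensor must be a health_tensor")
  if (format == "long-csv") {
    obs <- if (is.null(tensor$mask)) array(TRUE, dim(tensor$values)) else tensor$mask
    idx <- which(obs, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
    df <- data.frame(student_id = tensor$student_ids[idx[, 1]],
                     criterion_id = tensor$criterion_ids[idx[, 2]],
                     time_index = idx[, 3] - 1L,
                     value = format_full(tensor$values[idx]))
    atomic_write(path, function(tmp)
      utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE))
  } else {
    bundle <- list(students = I(tensor$student_ids),
                   criteria = I(tensor$criterion_ids),
                   K = tensor$K,
                   values = tensor_values0(tensor))
    if (!is.null(tensor$mask)) bundle$mask <- tensor$mask
    atomic_write(path, function(tmp)
      jsonlite::write_json(bundle, tmp, digits = I(17), auto_unbox = TRUE))
  }
}
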