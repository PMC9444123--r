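# Random-hyperplane hashing: each health curve A_{i,j} (length K) is reduced
# to the sign bit of its inner product with a random plane B whose entries are
# uniform on [-1, 1]; the M bits of one student are packed MSB-first into one
# M-bit "health index". Repeating q times per table over p tables gives the
# index table that replaces raw readings downstream.

#' Derived seed for one projection slot
#'
#' Every (table, repetition[, criterion]) slot draws its hyperplane from its
#' own substream seed, mixed from the root seed with a small
#' linear-congruential scheme, so construction order never matters and an
#' index built at \code{(p, q)} restricted to smaller \code{(p', q')} is
#' bit-identical to a direct build. This function is the reproducibility
#' contract: \code{sample_projection(K, plane_seed(seed, t, z))} is the plane
#' of slot \code{(t, z)}.
#'
#' @param seed non-negative root seed.
#' @param table,repetition 1-based slot coordinates.
#' @param criterion 1-based criterion when planes are per-criterion, else 0.
#' @return integer-valued seed below \code{2^31}.
#' @export
plane_seed <- function(seed, table, repetition, criterion = 0L) {
  h <- as.double(seed) %% 2147483647
  for (v in c(table, repetition, criterion))
    h <- (h * 69069 + as.double(v) + 1) %% 2147483647
  h
}

#' Sample a random projection hyperplane
#'
#' Draws a K-dimensional vector with components independently uniform on
#' \eqn{[-1, 1]}; the sign of the inner product of a health curve with such a
#' vector is one hash bit.
#'
#' @param K curve length (positive integer).
#' @param seed integer seed; the same seed always yields the same plane.
#' @return numeric vector of length \code{K} with entries in \eqn{[-1, 1]}.
#' @examples
#' sample_projection(4, seed = 7)
#' @export
sample_projection <- function(K, seed) {
  if (!is_count(K)) abort_validation("K must be a positive integer")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% 2147483647)
  stats::runif(K, -1, 1)
}

#' Project a health curve onto a hyperplane
#'
#' The inner product \eqn{\Omega = \sum_k a_k b_k}. Unobserved components
#' should be zeroed by the caller; a zero component contributes nothing.
#'
#' @param series numeric vector (one health curve \eqn{A_{i,j}}).
#' @param plane numeric vector of the same length.
#' @return the scalar inner product.
#' @examples
#' project(c(1, 2), c(0.5, -0.5))  # -0.5
#' @export
project <- function(series, plane) {
  if (length(series) != length(plane))
    abort_validation("series and plane must have equal length (",
                     length(series), " vs ", length(plane), ")")
  sum(series * plane)
}

#' Binarize a projection
#'
#' Maps \eqn{\Omega > 0} to bit 1 and \eqn{\Omega \le 0} to bit 0. The tie
#' \eqn{\Omega = 0} has measure zero for continuous data; mapping it to 0
#' keeps the hash total and deterministic.
#'
#' @param omega finite numeric scalar or vector.
#' @return integer bit(s) in \{0, 1\}.
#' @export
binarize <- function(omega) {
  if (anyNA(omega) || any(!is.finite(omega)))
    abort_validation("omega must be finite")
  as.integer(omega > 0)
}

#' Convert a bit signature to its decimal health index
#'
#' Interprets the M bits \eqn{(\Psi_{i,1}, ..., \Psi_{i,M})} as a base-2
#' number with the first bit (criterion \eqn{c_1}) most significant; e.g.
#' signature \code{c(1, 1, 1)} gives index 7. For \code{M <= 53} bits the
#' exact value fits a double and is returned as numeric; for longer
#' signatures the exact value is returned as a lowercase hexadecimal string
#' (the index is only ever compared for equality, so no arithmetic is lost).
#'
#' @param bits vector of 0/1 values, most significant first.
#' @param as \code{"auto"} (numeric when exact, else hex), \code{"numeric"},
#'   or \code{"hex"}.
#' @return numeric scalar or hex string.
#' @examples
#' signature_to_index(c(1, 1, 1))      # 7
#' signature_to_index(c(1, 0, 1))      # 5
#' signature_to_index(rep(1, 8), as = "hex")  # "ff"
#' @export
signature_to_index <- function(bits, as = c("auto", "numeric", "hex")) {
  as <- match.arg(as)
  if (length(bits) == 0L) abort_validation("signature must have at least one bit")
  if (anyNA(bits) || !all(bits %in% c(0, 1)))
    abort_validation("signature elements must all be 0 or 1")
  if (as == "hex" || (as == "auto" && length(bits) > 53L))
    return(bits_to_hex(matrix(as.integer(bits), nrow = 1L))[1L])
  if (length(bits) > 53L)
    abort_validation("signature longer than 53 bits does not fit a double; ",
                     "use as = \"hex\"")
  sum(bits * 2^((length(bits) - 1L):0))
}

# Pack each row of a 0/1 integer matrix (n x M, MSB first) into a lowercase
# hex string of ceiling(M / 4) digits, zero-padded at the most significant end.
bits_to_hex <- function(bits) {
  n <- nrow(bits)
  M <- ncol(bits)
  pad <- (4L - M %% 4L) %% 4L
  if (pad) bits <- cbind(matrix(0L, n, pad), bits)
  ndig <- ncol(bits) %/% 4L
  # weight the 4 bits of each hex digit, then sum within digit groups
  w <- rep(c(8L, 4L, 2L, 1L), ndig)
  weighted <- bits * rep(w, each = n)
  digits <- weighted[, seq(1L, ncol(bits), by = 4L), drop = FALSE] +
    weighted[, seq(2L, ncol(bits), by = 4L), drop = FALSE] +
    weighted[, seq(3L, ncol(bits), by = 4L), drop = FALSE] +
    weighted[, seq(4L, ncol(bits), by = 4L), drop = FALSE]
  hex_chars <- strsplit("0123456789abcdef", "")[[1L]]
  chars <- matrix(hex_chars[digits + 1L], nrow = n)
  apply(chars, 1L, paste, collapse = "")
}

#' Build the privacy-preserving index table of a cohort
#'
#' For every hash table \eqn{t \in 1..p} and repetition \eqn{z \in 1..q},
#' draws the random hyperplane(s) for that slot, projects every health curve,
#' binarizes the signs and packs each student's M bits (criterion order,
#' MSB first) into one M-bit health index \eqn{\pi_{i,z}^{(t)}}. The result
#' contains only these indexes plus identifiers and configuration — no raw
#' reading appears in it, which is the privacy argument for transmitting it
#' in place of the tensor.
#'
#' @param tensor a \code{\link{health_tensor}}.
#' @param config a \code{\link{run_config}}.
#' @return an object of class \code{"anodet_index"}: list with \code{p},
#'   \code{q}, \code{M}, \code{seed}, \code{per_criterion_planes},
#'   \code{student_ids} and \code{tables}, where \code{tables[[t]]} is an
#'   \code{N x q} character matrix of hex-encoded indexes.
#' @examples
#' t <- health_tensor(array(rnorm(4 * 3 * 8), c(4, 3, 8)))
#' idx <- build_index(t, run_config(p = 2, q = 3, T = 2, seed = 1))
#' idx$tables[[1]]
#' @export
build_index <- function(tensor, config) {
  if (!inherits(tensor, "health_tensor"))
    abort_validation("tensor must be a health_tensor")
  if (!inherits(config, "run_config"))
    abort_validation("config must be a run_config")
  v <- tensor_values0(tensor)
  N <- tensor$N; M <- tensor$M; K <- tensor$K
  flat <- matrix(v, nrow = N * M, ncol = K)  # (i, j) pairs down rows, k across
  tables <- vector("list", config$p)
  for (t in seq_len(config$p)) {
    tab <- matrix(NA_character_, N, config$q,
                  dimnames = list(tensor$student_ids, NULL))
    for (z in seq_len(config$q)) {
      if (config$per_criterion_planes) {
        omega <- matrix(0, N, M)
        for (j in seq_len(M)) {
          B <- sample_projection(K, plane_seed(config$seed, t, z, j))
          omega[, j] <- matrix(v[, j, ], nrow = N) %*% B
        }
      } else {
        B <- sample_projection(K, plane_seed(config$seed, t, z))
        omega <- matrix(flat %*% B, N, M)
      }
      tab[, z] <- bits_to_hex(matrix(as.integer(omega > 0), N, M))
    }
    tables[[t]] <- tab
  }
  structure(list(p = config$p, q = config$q, M = M, seed = config$seed,
                 per_criterion_planes = config$per_criterion_planes,
                 student_ids = tensor$student_ids, tables = tables),
            class = "anodet_index")
}

#' @export
print.anodet_index <- function(x, ...) {
  cat(sprintf(
    "Health index table: %d students, %d tables x %d repetitions, M=%d bits, seed=%s\n",
    length(x$student_ids), x$p, x$q, x$M,
    format(x$seed, scientific = FALSE)))
  invisible(x)
}

#' Restrict an index table to its first tables and repetitions
#'
#' Because every (table, repetition) slot has its own derived random
#' substream, the restriction of an index built at \code{(p, q)} to
#' \code{(p' <= p, q' <= q)} is bit-identical to an index built directly at
#' \code{(p', q')} with the same seed. Parameter sweeps exploit this.
#'
#' @param index an \code{anodet_index}.
#' @param p,q the restricted table and repetition counts.
#' @return an \code{anodet_index}.
#' @export
subset_index <- function(index, p = index$p, q = index$q) {
  if (!is_count(p) || p > index$p) abort_validation("p must be in 1..", index$p)
  if (!is_count(q) || q > index$q) abort_validation("q must be in 1..", index$q)
  index$tables <- lapply(index$tables[seq_len(p)],
                         function(tab) tab[, seq_len(q), drop = FALSE])
  index$p <- as.integer(p)
  index$q <- as.integer(q)
  index
}

#' Write / read an index table as JSON
#'
#' Format: \code{{"p":..,"q":..,"M":..,"seed":..,"tables":[{"table":t,
#' "pi":{"<student_id>":["<hex>", ...q entries]}}]}}.
#'
#' @param index an \code{anodet_index}.
#' @param path JSON file location.
#' @return \code{write_index}: \code{path} invisibly; \code{read_index}: the
#'   \code{anodet_index}.
#' @export
write_index <- function(index, path) {
  if (!inherits(index, "anodet_index"))
    abort_validation("index must be an anodet_index")
  tables <- lapply(seq_len(index$p), function(t) {
    pi_list <- lapply(seq_along(index$student_ids),
                      function(i) I(index$tables[[t]][i, ]))
    names(pi_list) <- index$student_ids
    list(table = t, pi = pi_list)
  })
  obj <- list(p = index$p, q = index$q, M = index$M, seed = index$seed,
              per_criterion_planes = index$per_criterion_planes,
              tables = tables)
  atomic_write(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA))
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  if (!file.exists(path)) abort_io("file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) abort_parse("malformed JSON in ", path,
                                                  ": ", conditionMessage(e)))
  for (key in c("p", "q", "M", "seed", "tables"))
    if (is.null(obj[[key]])) abort_schema("index file is missing '", key, "'")
  if (length(obj$tables) != obj$p)
    abort_schema("index file declares p=", obj$p, " but has ",
                 length(obj$tables), " tables")
  ids <- names(obj$tables[[1]]$pi)
  tables <- lapply(obj$tables, function(tb) {
    if (!identical(names(tb$pi), ids))
      abort_schema("student ids differ across tables")
    m <- do.call(rbind, lapply(tb$pi, function(v) {
      v <- unlist(v)
      if (length(v) != obj$q)
        abort_schema("a student has ", length(v), " indexes, expected q=", obj$q)
      as.character(v)
    }))
    rownames(m) <- ids
    m
  })
  structure(list(p = as.integer(obj$p), q = as.integer(obj$q),
                 M = as.integer(obj$M), seed = as.double(obj$seed),
                 per_criterion_planes = isTRUE(obj$per_criterion_planes),
                 student_ids = ids, tables = tables),
            class = "anodet_index")
}
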