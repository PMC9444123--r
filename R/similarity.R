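# Match-count similarity and the threshold graph. Two students' similarity is
# the number of repetitions z (out of q) in which their health indexes are
# equal in at least one of the p hash tables; students with similarity >= T
# are connected, connected components are the health groups, and degree-zero
# students are the anomalies.

#' Match-count similarity between two students
#'
#' \eqn{Sim(s_i, s_j) = \sum_{z=1}^{q} [\exists t: \pi_{i,z}^{(t)} =
#' \pi_{j,z}^{(t)}]}: a repetition counts as a match when the two indexes
#' agree in \emph{any} of the \code{p} tables (additional tables loosen the
#' match condition). The result is an integer in \code{0..q}.
#'
#' @param index_i,index_j the two students' indexes: a \code{p x q} matrix
#'   (tables down rows, repetitions across), or a length-\code{q} vector when
#'   \code{p = 1}. Values may be numeric or hex strings, as long as both
#'   students use the same encoding.
#' @param p number of hash tables (checked against the inputs).
#' @return integer match count in \code{0..q}.
#' @examples
#' pair_similarity(c(1, 2, 3, 4, 5), c(1, 2, 3, 6, 7), p = 1)  # 3
#' @export
pair_similarity <- function(index_i, index_j, p = 1L) {
  index_i <- as_index_matrix(index_i, p)
  index_j <- as_index_matrix(index_j, p)
  if (!identical(dim(index_i), dim(index_j)))
    abort_validation("the two students have mismatched (p, q) index shapes")
  sum(apply(index_i == index_j, 2L, any))
}

as_index_matrix <- function(x, p) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (nrow(x) != p)
    abort_validation("index has ", nrow(x), " tables, expected p = ", p)
  matrix(as.character(x), nrow = nrow(x))
}

#' All-pairs similarity of an index table
#'
#' Computes the symmetric \code{N x N} integer matrix of match counts. The
#' diagonal is \code{q} by convention (a student matches itself in every
#' repetition); it never feeds the anomaly decision.
#'
#' @param index an \code{anodet_index} from \code{\link{build_index}}.
#' @return an object of class \code{"anodet_simgraph"} with the similarity
#'   matrix filled and no adjacency yet; pass it to
#'   \code{\link{threshold_graph}}.
#' @export
similarity_matrix <- function(index) {
  if (!inherits(index, "anodet_index"))
    abort_validation("index must be an anodet_index")
  N <- length(index$student_ids)
  sim <- matrix(0L, N, N, dimnames = list(index$student_ids, index$student_ids))
  for (z in seq_len(index$q)) {
    matched <- matrix(FALSE, N, N)
    for (t in seq_len(index$p)) {
      pi_tz <- index$tables[[t]][, z]
      code <- match(pi_tz, pi_tz)  # equal strings share the first-occurrence code
      matched <- matched | outer(code, code, "==")
    }
    sim <- sim + matched
  }
  diag(sim) <- index$q
  structure(list(n_students = N, student_ids = index$student_ids,
                 sim = sim, q = index$q, p = index$p, seed = index$seed,
                 T = NA_integer_, adjacency = NULL),
            class = "anodet_simgraph")
}

#' @export
print.anodet_simgraph <- function(x, ...) {
  cat(sprintf("Similarity graph: %d students, Sim in 0..%d (p=%d tables)\n",
              x$n_students, x$q, x$p))
  if (!is.null(x$adjacency))
    cat(sprintf("  threshold T=%d: %d edges\n", x$T, sum(x$adjacency) / 2))
  else cat("  no threshold applied yet\n")
  invisible(x)
}

#' Apply the similarity threshold
#'
#' Marks students \eqn{i \ne j} as similar exactly when
#' \eqn{Sim(s_i, s_j) \ge T}.
#'
#' @param graph an \code{anodet_simgraph}.
#' @param T integer threshold, \code{1 <= T <= q}.
#' @return the graph with its adjacency filled.
#' @export
threshold_graph <- function(graph, T) {
  if (!inherits(graph, "anodet_simgraph"))
    abort_validation("graph must be an anodet_simgraph")
  if (!is_count(T) || T > graph$q)
    abort_validation("T must be an integer in 1..q (q = ", graph$q, ")")
  adj <- graph$sim >= T
  diag(adj) <- FALSE
  graph$T <- as.integer(T)
  graph$adjacency <- adj
  graph
}

#' Group students by similarity
#'
#' Partitions the cohort into the connected components of the threshold
#' graph — the transitive closure of the pairwise "similar" relation. Groups
#' are ordered by their smallest member index, members by index, so output is
#' reproducible.
#'
#' @param graph an \code{anodet_simgraph} with adjacency (see
#'   \code{\link{threshold_graph}}).
#' @return list of character vectors of student ids, one per group.
#' @export
cluster_students <- function(graph) {
  if (!inherits(graph, "anodet_simgraph") || is.null(graph$adjacency))
    abort_validation("graph must carry an adjacency; call threshold_graph() first")
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(seq_along(comp), comp)
  groups <- groups[order(vapply(groups, min, 0L))]
  unname(lapply(groups, function(ix) graph$student_ids[sort(ix)]))
}

#' Detect anomalous students
#'
#' A student is anomalous exactly when it has no similar peer at threshold
#' \code{T}, i.e. is a degree-zero vertex of the threshold graph. The report
#' also carries the group partition and per-student neighbor counts.
#'
#' @param graph an \code{anodet_simgraph} with adjacency.
#' @return an object of class \code{"anodet_report"}: list with
#'   \code{groups}, \code{anomalies}, \code{neighbor_counts}, and the echoed
#'   \code{T}, \code{p}, \code{q}, \code{seed}.
#' @export
detect_anomalies <- function(graph) {
  if (!inherits(graph, "anodet_simgraph") || is.null(graph$adjacency))
    abort_validation("graph must carry an adjacency; call threshold_graph() first")
  degree <- rowSums(graph$adjacency)
  names(degree) <- graph$student_ids
  structure(list(groups = cluster_students(graph),
                 anomalies = graph$student_ids[degree == 0L],
                 neighbor_counts = degree,
                 T = graph$T, p = graph$p, q = graph$q, seed = graph$seed),
            class = "anodet_report")
}

#' @export
print.anodet_report <- function(x, ...) {
  n <- length(x$neighbor_counts)
  cat(sprintf("Anomaly report (p=%d, q=%d, T=%d): %d students, %d groups, %d anomalies\n",
              x$p, x$q, x$T, n, length(x$groups), length(x$anomalies)))
  if (length(x$anomalies))
    cat("  anomalies:", paste(x$anomalies, collapse = ", "), "\n")
  invisible(x)
}

#' Write an anomaly report as JSON
#'
#' @param report an \code{anodet_report}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "anodet_report"))
    abort_validation("report must be an anodet_report")
  obj <- list(config = list(p = report$p, q = report$q, T = report$T,
                            seed = report$seed),
              groups = lapply(report$groups, I),  # keep singleton groups as arrays
              anomalies = I(report$anomalies),
              neighbor_counts = as.list(report$neighbor_counts))
  atomic_write(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA))
}
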