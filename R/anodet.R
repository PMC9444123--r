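#' Fit a privacy-preserving anomaly detector to a cohort
#'
#' The full pipeline in one call: builds the \code{p x q} random-hyperplane
#' health-index table from the cohort tensor, computes the match-count
#' similarity between every pair of students, applies threshold \code{T},
#' groups students by connected components and flags every student without a
#' similar peer as anomalous. Only the index table — never a raw reading —
#' would need to leave the device in a deployed setting.
#'
#' @param tensor a \code{\link{health_tensor}} (or a \code{labeled_cohort},
#'   whose tensor is used and whose ground truth is kept for scoring).
#' @param p number of hash tables.
#' @param q index repetitions per table.
#' @param T similarity threshold (\code{1 <= T <= q}).
#' @param seed root random seed for the projection planes.
#' @param per_criterion_planes draw an independent plane per criterion (see
#'   \code{\link{run_config}}).
#' @param center subtract each curve's own mean before hashing. Off by
#'   default (raw values are hashed); useful when absolute offsets dominate
#'   curve shape.
#' @return an object of class \code{"anodet"}: list with the \code{config},
#'   the \code{index} (\code{anodet_index}), the thresholded \code{graph}
#'   (\code{anodet_simgraph}), the \code{report} (\code{anodet_report}) and,
#'   when ground truth was supplied, \code{truth_anomalies}. Supports
#'   \code{print}, \code{summary}, \code{plot} and \code{predict}.
#' @examples
#' cohort <- generate_cohort(generator_config(N = 40, M = 8, K = 32, seed = 2))
#' fit <- ano_det(cohort, p = 4, q = 4, T = 2, seed = 2)
#' fit
#' fit$report$anomalies
#' @export
ano_det <- function(tensor, p = 4L, q = 6L, T = 2L, seed = 0L,
                    per_criterion_planes = FALSE, center = FALSE) {
  truth <- NULL
  if (inherits(tensor, "labeled_cohort")) {
    truth <- tensor$truth_anomalies
    tensor <- tensor$tensor
  }
  if (!inherits(tensor, "health_tensor"))
    abort_validation("tensor must be a health_tensor or labeled_cohort")
  if (center) {
    v <- tensor$values
    mu <- apply(tensor_values0(tensor), c(1, 2), mean)
    v <- sweep(v, c(1, 2), mu)
    tensor <- health_tensor(v, tensor$student_ids, tensor$criterion_ids,
                            mask = tensor$mask)
  }
  config <- run_config(p = p, q = q, T = T, seed = seed,
                       per_criterion_planes = per_criterion_planes)
  index <- build_index(tensor, config)
  graph <- threshold_graph(similarity_matrix(index), config$T)
  report <- detect_anomalies(graph)
  structure(list(config = config, tensor = tensor, index = index,
                 graph = graph, report = report, truth_anomalies = truth),
            class = "anodet")
}

#' @export
print.anodet <- function(x, ...) {
  cat("Privacy-preserving cohort anomaly detection\n")
  cat(sprintf("  cohort: %d students x %d criteria x %d time points\n",
              x$tensor$N, x$tensor$M, x$tensor$K))
  cat(sprintf("  index: p=%d tables, q=%d repetitions, M=%d-bit indexes, seed=%s\n",
              x$config$p, x$config$q, x$index$M,
              format(x$config$seed, scientific = FALSE)))
  cat(sprintf("  threshold T=%d: %d groups, %d anomalies\n",
              x$config$T, length(x$report$groups),
              length(x$report$anomalies)))
  if (length(x$report$anomalies))
    cat("  anomalies:", paste(x$report$anomalies, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.anodet <- function(object, ...) {
  sim <- object$graph$sim
  off <- sim[upper.tri(sim)]
  s <- list(config = object$config,
            n_students = object$tensor$N,
            sim_table = table(factor(off, levels = 0:object$config$q)),
            neighbor_counts = object$report$neighbor_counts,
            group_sizes = lengths(object$report$groups),
            anomalies = object$report$anomalies)
  if (!is.null(object$truth_anomalies)) {
    found <- object$report$anomalies
    truth <- object$truth_anomalies
    tp <- length(intersect(found, truth))
    s$recall <- if (length(truth)) tp / length(truth) else NA_real_
    s$precision <- if (length(found)) tp / length(found) else NA_real_
    s$truth_anomalies <- truth
  }
  class(s) <- "summary.anodet"
  s
}

#' @export
print.summary.anodet <- function(x, ...) {
  print(x$config)
  cat(sprintf("Students: %d; groups: %d (sizes %s); anomalies: %d\n",
              x$n_students, length(x$group_sizes),
              paste(x$group_sizes, collapse = ", "),
              length(x$anomalies)))
  cat("Pairwise match-count distribution (Sim = 0..q):\n")
  print(x$sim_table)
  cat(sprintf("Neighbor counts: min %d, median %.1f, max %d\n",
              min(x$neighbor_counts), stats::median(x$neighbor_counts),
              max(x$neighbor_counts)))
  if (!is.null(x$recall))
    cat(sprintf("Against planted truth: recall %.2f, precision %.2f\n",
                x$recall, x$precision))
  invisible(x)
}

#' Plot the similarity graph of a fitted detector
#'
#' Draws the threshold graph with students colored by detected group;
#' anomalous (degree-zero) students are shown as red squares.
#'
#' @param x an \code{anodet} fit.
#' @param ... passed to \code{\link[igraph]{plot.igraph}}.
#' @export
plot.anodet <- function(x, ...) {
  g <- igraph::graph_from_adjacency_matrix(x$graph$adjacency,
                                           mode = "undirected")
  groups <- x$report$groups
  member <- rep(NA_integer_, x$tensor$N)
  names(member) <- x$tensor$student_ids
  for (i in seq_along(groups)) member[groups[[i]]] <- i
  is_anom <- x$tensor$student_ids %in% x$report$anomalies
  pal <- grDevices::hcl.colors(max(member), palette = "Dark 3")
  igraph::plot.igraph(
    g,
    vertex.color = ifelse(is_anom, "red", pal[member]),
    vertex.shape = ifelse(is_anom, "square", "circle"),
    vertex.size = 7, vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Predict held-out readings from a fitted detector
#'
#' Neighbor-mean prediction of hidden (student, criterion, time) entries
#' using the fit's threshold graph; see
#' \code{\link{predict_heldout_anodet}} for the protocol.
#'
#' @param object an \code{anodet} fit whose tensor has masked entries.
#' @param heldout data frame with columns \code{student_id},
#'   \code{criterion_id}, \code{time_index}.
#' @param ... unused.
#' @return numeric vector of predictions aligned with \code{heldout} rows.
#' @export
predict.anodet <- function(object, heldout, ...) {
  predict_by_weights(object$tensor, object$graph$adjacency * 1, heldout)
}
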