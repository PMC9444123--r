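# Evaluation harness: hide entries, predict them back, and score with
# MAE/RMSE. The index-based predictor uses unweighted means over threshold-T
# neighbors; the plaintext baseline is classical user-based collaborative
# filtering (Pearson weights over co-observed entries, top-k positive
# neighbors). Timing is reported but never asserted against absolute values.

# Flatten an N x M x K tensor to N x (M*K) with NA at unobserved cells, plus
# the matching column index for (criterion, time) pairs.
flatten_observed <- function(tensor) {
  v <- tensor$values
  if (!is.null(tensor$mask)) v[!tensor$mask] <- NA_real_
  matrix(v, nrow = tensor$N)  # column = (j, k) in k-major order per R arrays
}

heldout_columns <- function(tensor, heldout) {
  i <- match(heldout$student_id, tensor$student_ids)
  j <- match(heldout$criterion_id, tensor$criterion_ids)
  k <- heldout$time_index + 1L
  if (anyNA(i) || anyNA(j) || any(k < 1L) || any(k > tensor$K))
    abort_validation("held-out triple refers to an unknown student, criterion or time")
  # column index of (j, k) in the N x (M*K) flattening: R arrays are
  # column-major, so cell (i, j, k) flattens to column j + (k-1)*M... careful:
  # matrix(v, nrow=N) keeps dimension order (j fastest after i), i.e.
  # column = j + (k - 1) * M.
  list(row = i, col = j + (k - 1L) * tensor$M)
}

# Common prediction core: given a 0/1 neighbor weight matrix W (N x N, zero
# diagonal), predict each held-out cell as the weighted mean of the
# neighbors' observed values there, falling back to the cohort mean of that
# (criterion, time) column, then to the global observed mean.
predict_by_weights <- function(tensor, W, heldout) {
  V <- flatten_observed(tensor)
  loc <- heldout_columns(tensor, heldout)
  if (any(!is.na(V[cbind(loc$row, loc$col)])))
    abort_validation("a held-out triple is still observed in the masked tensor")
  obs <- !is.na(V)
  V0 <- V
  V0[!obs] <- 0
  num <- W %*% V0
  den <- W %*% obs
  pred_nbr <- num[cbind(loc$row, loc$col)]
  cnt <- den[cbind(loc$row, loc$col)]
  col_mean <- colSums(V0) / pmax(colSums(obs), 1)
  col_has <- colSums(obs) > 0
  global_mean <- if (any(obs)) mean(V[obs]) else 0
  pred <- ifelse(cnt > 0, pred_nbr / ifelse(cnt > 0, cnt, 1),
                 ifelse(col_has[loc$col], col_mean[loc$col], global_mean))
  as.numeric(pred)
}

#' Predict held-out entries from index-based neighbors
#'
#' For each held-out (student, criterion, time) triple, predicts the
#' unweighted mean of the values observed there by the student's
#' threshold-\code{T} neighbors (match count \eqn{\ge T}). If no neighbor
#' observes the cell, falls back to the cohort mean of that
#' (criterion, time) slot; if nothing is observed there at all, to the
#' global observed mean.
#'
#' @param tensor the masked \code{\link{health_tensor}} the index was built
#'   from.
#' @param index the \code{anodet_index} built from \code{tensor}.
#' @param T similarity threshold.
#' @param heldout data frame with columns \code{student_id},
#'   \code{criterion_id}, \code{time_index} (0-based) and \code{true_value}.
#' @return numeric vector of predictions aligned with \code{heldout} rows.
#' @export
predict_heldout_anodet <- function(tensor, index, T, heldout) {
  graph <- threshold_graph(similarity_matrix(index), T)
  W <- graph$adjacency * 1
  predict_by_weights(tensor, W, heldout)
}

#' Predict held-out entries with user-based collaborative filtering
#'
#' The plaintext baseline: neighbor weights are Pearson correlations between
#' students' co-observed flattened (criterion, time) entries; each student
#' keeps its \code{k_neighbors} most correlated positively-correlated peers,
#' and predictions are correlation-weighted means with the same fallbacks as
#' \code{\link{predict_heldout_anodet}}.
#'
#' @param tensor the masked \code{\link{health_tensor}}.
#' @param k_neighbors number of neighbors retained per student.
#' @param heldout held-out data frame (see
#'   \code{\link{predict_heldout_anodet}}).
#' @return numeric vector of predictions aligned with \code{heldout} rows.
#' @export
predict_heldout_ucf <- function(tensor, k_neighbors = 10L, heldout) {
  V <- flatten_observed(tensor)
  suppressWarnings(C <- stats::cor(t(V), use = "pairwise.complete.obs"))
  C[is.na(C)] <- 0
  diag(C) <- 0
  C[C <= 0] <- 0
  W <- matrix(0, nrow(C), ncol(C))
  for (i in seq_len(nrow(C))) {
    pos <- which(C[i, ] > 0)
    if (length(pos) > k_neighbors)
      pos <- pos[order(C[i, pos], decreasing = TRUE)[seq_len(k_neighbors)]]
    W[i, pos] <- C[i, pos]
  }
  predict_by_weights(tensor, W, heldout)
}

#' Prediction error measures
#'
#' Mean absolute error and root-mean-square error of paired predictions and
#' truths. For any prediction set, \code{rmse >= mae} (power-mean
#' inequality).
#'
#' @param predictions,truths equal-length non-empty numeric vectors.
#' @return a non-negative scalar.
#' @examples
#' mae(c(1, 3), c(1, 1))   # 1
#' rmse(c(1, 3), c(1, 1))  # sqrt(2)
#' @export
mae <- function(predictions, truths) {
  check_paired(predictions, truths)
  mean(abs(predictions - truths))
}

#' @rdname mae
#' @export
rmse <- function(predictions, truths) {
  check_paired(predictions, truths)
  sqrt(mean((predictions - truths)^2))
}

check_paired <- function(predictions, truths) {
  if (length(predictions) == 0L || length(predictions) != length(truths))
    abort_validation("predictions and truths must be equal-length, non-empty")
  if (anyNA(predictions) || anyNA(truths))
    abort_validation("predictions and truths must not contain NA")
}

#' Sweep a (p, q, T) grid over synthetic cohorts
#'
#' For each seed: generates a cohort, hides a fraction of entries, builds one
#' index at the largest (p, q) in the grid, and for every grid point scores
#' held-out prediction for the index-based method and the UCF baseline
#' (optionally also a single-table exact-match LSH comparator with
#' \code{p = 1, T = q}). Restricting the large index to smaller (p, q) is
#' bit-identical to building it directly (per-slot random substreams), so the
#' sweep is exact, not approximate.
#'
#' @param grid data frame with integer columns \code{p}, \code{q}, \code{T}
#'   (every row must satisfy \code{T <= q}).
#' @param gen_config a \code{\link{generator_config}}; its seed is replaced
#'   by each sweep seed in turn.
#' @param mask_fraction fraction of entries hidden for scoring.
#' @param seeds integer vector of cohort seeds.
#' @param k_neighbors UCF neighbor count.
#' @param include_brute also report the \code{brute-lsh} comparator.
#' @return data frame with columns \code{method}, \code{p}, \code{q},
#'   \code{T}, \code{seed}, \code{mae}, \code{rmse}, \code{n_heldout},
#'   \code{index_seconds}, \code{predict_seconds}, \code{n_anomalies},
#'   \code{mean_neighbors}.
#' @export
run_profile <- function(grid, gen_config, mask_fraction = 0.1, seeds = 1L,
                        k_neighbors = 10L, include_brute = FALSE) {
  if (!is.data.frame(grid) || !all(c("p", "q", "T") %in% names(grid)) ||
      nrow(grid) == 0L)
    abort_validation("grid must be a non-empty data frame with columns p, q, T")
  if (any(grid$T > grid$q))
    abort_validation("every grid row must satisfy T <= q")
  if (!inherits(gen_config, "generator_config"))
    abort_validation("gen_config must be a generator_config")
  p_max <- max(grid$p)
  q_max <- max(grid$q, if (include_brute) grid$q else integer(0))
  rows <- list()
  for (seed in seeds) {
    gc <- gen_config
    gc$seed <- as.double(seed)
    cohort <- generate_cohort(gc)
    masked <- mask_entries(cohort, mask_fraction, seed = seed)
    truths <- masked$heldout$true_value
    n_h <- nrow(masked$heldout)

    t0 <- proc.time()[["elapsed"]]
    big_index <- build_index(masked$tensor,
                             run_config(p = p_max, q = q_max, T = 1L,
                                        seed = seed))
    index_seconds_full <- proc.time()[["elapsed"]] - t0

    # per-slot match matrices, OR-accumulated over tables: cum[[t]][[z]] is
    # "indexes equal in some table <= t at repetition z"
    N <- length(big_index$student_ids)
    cum <- vector("list", p_max)
    prev <- replicate(q_max, matrix(FALSE, N, N), simplify = FALSE)
    for (t in seq_len(p_max)) {
      for (z in seq_len(q_max)) {
        pi_tz <- big_index$tables[[t]][, z]
        code <- match(pi_tz, pi_tz)
        prev[[z]] <- prev[[z]] | outer(code, code, "==")
      }
      cum[[t]] <- prev
    }
    sim_of <- function(p, q) {
      s <- Reduce(`+`, lapply(cum[[p]][seq_len(q)], function(m) m * 1L))
      diag(s) <- q
      s
    }

    t0 <- proc.time()[["elapsed"]]
    ucf_pred <- predict_heldout_ucf(masked$tensor, k_neighbors, masked$heldout)
    ucf_seconds <- proc.time()[["elapsed"]] - t0
    ucf_mae <- mae(ucf_pred, truths)
    ucf_rmse <- rmse(ucf_pred, truths)

    for (r in seq_len(nrow(grid))) {
      p <- grid$p[r]; q <- grid$q[r]; Tr <- grid$T[r]
      sim <- sim_of(p, q)
      adj <- sim >= Tr
      diag(adj) <- FALSE
      t0 <- proc.time()[["elapsed"]]
      pred <- predict_by_weights(masked$tensor, adj * 1, masked$heldout)
      predict_seconds <- proc.time()[["elapsed"]] - t0
      # index cost attributed proportionally to the slots this grid point uses
      idx_secs <- index_seconds_full * (p * q) / (p_max * q_max)
      rows[[length(rows) + 1L]] <- data.frame(
        method = "ano-det", p = p, q = q, T = Tr, seed = seed,
        mae = mae(pred, truths), rmse = rmse(pred, truths), n_heldout = n_h,
        index_seconds = idx_secs, predict_seconds = predict_seconds,
        n_anomalies = sum(rowSums(adj) == 0),
        mean_neighbors = mean(rowSums(adj)))
      rows[[length(rows) + 1L]] <- data.frame(
        method = "ucf", p = p, q = q, T = Tr, seed = seed,
        mae = ucf_mae, rmse = ucf_rmse, n_heldout = n_h,
        index_seconds = 0, predict_seconds = ucf_seconds,
        n_anomalies = NA_real_, mean_neighbors = NA_real_)
      if (include_brute) {
        sim1 <- sim_of(1L, q)
        adj1 <- sim1 >= q
        diag(adj1) <- FALSE
        t0 <- proc.time()[["elapsed"]]
        pred1 <- predict_by_weights(masked$tensor, adj1 * 1, masked$heldout)
        brute_seconds <- proc.time()[["elapsed"]] - t0
        rows[[length(rows) + 1L]] <- data.frame(
          method = "brute-lsh", p = 1L, q = q, T = q, seed = seed,
          mae = mae(pred1, truths), rmse = rmse(pred1, truths),
          n_heldout = n_h,
          index_seconds = index_seconds_full * q / (p_max * q_max),
          predict_seconds = brute_seconds,
          n_anomalies = sum(rowSums(adj1) == 0),
          mean_neighbors = mean(rowSums(adj1)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
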