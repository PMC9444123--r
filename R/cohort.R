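# Synthetic wearable-like cohorts with latent health groups and planted
# anomalies. Every downstream module is testable against the ground-truth
# labels this generator carries; it makes no claim of physiological realism
# beyond smooth group-shared curves, additive noise, and anomalous students
# displaced away from every group.

#' Generator configuration
#'
#' Describes a synthetic cohort: \code{N} students in \code{n_groups} latent
#' health groups, \code{M} criteria observed at \code{K} time points. Each
#' (group, criterion) pair has a smooth baseline curve (a low-order mixture
#' of sinusoids on a standardized, centered scale); normal students follow
#' their group's curves plus Gaussian noise, while a planted fraction of
#' anomalous students have every curve displaced by \code{separation} times
#' the inter-group baseline spread in a random direction per criterion.
#'
#' @param N,M,K cohort dimensions (students, criteria, time points).
#' @param n_groups number of latent healthy-profile groups.
#' @param anomaly_fraction fraction of students planted as anomalies, in
#'   \code{[0, 1)}; the planted count is \code{round(N * anomaly_fraction)}.
#' @param noise_sd standard deviation of the additive per-reading noise, on
#'   the standardized criterion scale.
#' @param separation displacement of anomalous curves, as a multiple of the
#'   per-criterion inter-group baseline spread (> 0).
#' @param seed integer seed; generation is a pure function of this config.
#' @return an object of class \code{"generator_config"}.
#' @export
generator_config <- function(N = 100L, M = 20L, K = 64L, n_groups = 4L,
                             anomaly_fraction = 0.05, noise_sd = 0.5,
                             separation = 4, seed = 0L) {
  if (!is_count(N) || !is_count(M) || !is_count(K))
    abort_validation("N, M and K must be positive integers")
  if (!is_count(n_groups)) abort_validation("n_groups must be >= 1")
  if (!is.numeric(anomaly_fraction) || anomaly_fraction < 0 ||
      anomaly_fraction >= 1 || round(N * anomaly_fraction) >= N)
    abort_validation("anomaly_fraction must lie in [0, 1) with round(N * fraction) < N")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    abort_validation("noise_sd must be >= 0")
  if (!is.numeric(separation) || separation <= 0)
    abort_validation("separation must be > 0")
  if (!is_count(seed, min = 0L)) abort_validation("seed must be a non-negative integer")
  structure(list(N = as.integer(N), M = as.integer(M), K = as.integer(K),
                 n_groups = as.integer(n_groups),
                 anomaly_fraction = anomaly_fraction, noise_sd = noise_sd,
                 separation = separation, seed = as.double(seed)),
            class = "generator_config")
}

#' Read a generator configuration from JSON
#'
#' Missing keys fall back to the \code{\link{generator_config}} defaults.
#'
#' @param path JSON file.
#' @return a \code{generator_config}.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) abort_io("file not found: ", path)
  cfg <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) abort_parse("malformed JSON in ", path,
                                                  ": ", conditionMessage(e)))
  defaults <- formals(generator_config)
  args <- lapply(names(defaults), function(k) if (!is.null(cfg[[k]])) cfg[[k]] else eval(defaults[[k]]))
  names(args) <- names(defaults)
  do.call(generator_config, args)
}

# One smooth baseline curve of length K: centered offset plus up to three
# sinusoids with small integer frequencies. Standardized scale by design:
# hashing is driven by curve shape differences, not by absolute offsets.
baseline_curve <- function(K) {
  curve <- rep(stats::rnorm(1), K)
  k <- seq_len(K) - 1L
  for (h in 1:3) {
    amp <- stats::runif(1, 0.3, 1.2)
    freq <- sample(1:4, 1)
    phase <- stats::runif(1, 0, 2 * pi)
    curve <- curve + amp * sin(2 * pi * freq * k / K + phase)
  }
  curve
}

#' Generate a labelled synthetic cohort
#'
#' @param config a \code{\link{generator_config}}.
#' @return an object of class \code{"labeled_cohort"}: list with
#'   \code{tensor} (a \code{\link{health_tensor}}), \code{group_of} (named
#'   character vector, latent group \code{"g1"...} or \code{"anomaly"}),
#'   \code{truth_anomalies} (character vector of planted anomaly ids) and the
#'   echoed \code{config}.
#' @examples
#' cohort <- generate_cohort(generator_config(N = 20, M = 4, K = 16, seed = 1))
#' cohort$truth_anomalies
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    abort_validation("config must be a generator_config")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed %% 2147483647)
  N <- config$N; M <- config$M; K <- config$K; G <- config$n_groups

  # group baselines: G x M list of K-curves
  baselines <- array(0, c(G, M, K))
  for (g in seq_len(G)) for (j in seq_len(M))
    baselines[g, j, ] <- baseline_curve(K)

  # per-criterion inter-group spread: RMS per-timepoint distance between
  # group baseline curves (single group: sd of the curve itself)
  spread <- vapply(seq_len(M), function(j) {
    if (G == 1L) return(max(stats::sd(baselines[1, j, ]), 1e-8))
    d <- 0; np <- 0
    for (g1 in seq_len(G - 1)) for (g2 in (g1 + 1):G) {
      d <- d + mean((baselines[g1, j, ] - baselines[g2, j, ])^2)
      np <- np + 1
    }
    sqrt(d / np)
  }, 0)

  n_anom <- round(N * config$anomaly_fraction)
  anom_idx <- if (n_anom > 0) sort(sample.int(N, n_anom)) else integer(0)
  group_idx <- sample(rep_len(seq_len(G), N))  # balanced assignment, shuffled

  values <- array(0, c(N, M, K))
  student_ids <- paste0("s", seq_len(N))
  group_of <- character(N)
  names(group_of) <- student_ids
  for (i in seq_len(N)) {
    g <- group_idx[i]
    base <- baselines[g, , , drop = TRUE]
    base <- matrix(base, M, K)
    if (i %in% anom_idx) {
      # displace every curve by separation * spread_j in a random direction
      for (j in seq_len(M)) {
        dir <- stats::rnorm(K)
        dir <- dir / sqrt(mean(dir^2))  # per-timepoint RMS 1
        base[j, ] <- base[j, ] + config$separation * spread[j] * dir
      }
      group_of[i] <- "anomaly"
    } else {
      group_of[i] <- paste0("g", g)
    }
    noise <- if (config$noise_sd > 0)
      matrix(stats::rnorm(M * K, 0, config$noise_sd), M, K) else 0
    values[i, , ] <- base + noise
  }
  structure(list(tensor = health_tensor(values, student_ids),
                 group_of = group_of,
                 truth_anomalies = student_ids[anom_idx],
                 config = config),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf("Labelled cohort: %d students (%d groups, %d planted anomalies), %d criteria, K=%d\n",
              x$config$N, x$config$n_groups, length(x$truth_anomalies),
              x$config$M, x$config$K))
  invisible(x)
}

#' Hide a random fraction of tensor entries
#'
#' Hides exactly \code{floor(N * M * K * fraction)} uniformly chosen observed
#' (student, criterion, time) triples, returning the masked tensor and the
#' held-out list with true values — the protocol behind the MAE/RMSE
#' evaluation.
#'
#' @param cohort a \code{labeled_cohort} or a \code{health_tensor}.
#' @param fraction fraction of entries to hide, in (0, 1).
#' @param seed integer seed; masking is deterministic given it.
#' @return list with \code{tensor} (masked) and \code{heldout}, a data frame
#'   with columns \code{student_id}, \code{criterion_id}, \code{time_index}
#'   (0-based) and \code{true_value}.
#' @export
mask_entries <- function(cohort, fraction, seed = 0L) {
  tensor <- if (inherits(cohort, "labeled_cohort")) cohort$tensor else cohort
  if (!inherits(tensor, "health_tensor"))
    abort_validation("cohort must be a labeled_cohort or health_tensor")
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 ||
      fraction >= 1)
    abort_validation("fraction must lie strictly between 0 and 1")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% 2147483647)
  total <- length(tensor$values)
  n_hide <- floor(total * fraction)
  observed <- if (is.null(tensor$mask)) seq_len(total) else which(tensor$mask)
  if (n_hide > length(observed))
    abort_validation("fraction hides more entries than are observed")
  hide <- sort(sample(observed, n_hide))
  mask <- if (is.null(tensor$mask)) array(TRUE, dim(tensor$values)) else tensor$mask
  mask[hide] <- FALSE
  ai <- arrayInd(hide, dim(tensor$values))
  heldout <- data.frame(student_id = tensor$student_ids[ai[, 1]],
                        criterion_id = tensor$criterion_ids[ai[, 2]],
                        time_index = ai[, 3] - 1L,
                        true_value = tensor$values[hide])
  masked_values <- tensor$values
  masked_values[!mask] <- 0
  list(tensor = health_tensor(masked_values, tensor$student_ids,
                              tensor$criterion_ids, mask = mask),
       heldout = heldout)
}

#' Write cohort labels as JSON
#'
#' Format: \code{{"groups":{"s1":"g1",...},"anomalies":["s7",...]}}.
#'
#' @param cohort a \code{labeled_cohort}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(cohort, path) {
  if (!inherits(cohort, "labeled_cohort"))
    abort_validation("cohort must be a labeled_cohort")
  obj <- list(groups = as.list(cohort$group_of),
              anomalies = I(cohort$truth_anomalies))
  atomic_write(path, function(tmp)
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE))
}
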