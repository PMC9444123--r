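# Shared fixtures and independent brute-force oracles. The oracles share only
# the seeded plane sampler (the method's input) with the implementation; all
# projection, binarization, packing and matching is redone with plain loops.

random_tensor <- function(N, M, K, seed, mask_fraction = 0) {
  set.seed(seed)
  v <- array(stats::rnorm(N * M * K), c(N, M, K))
  mask <- NULL
  if (mask_fraction > 0) {
    mask <- array(stats::runif(N * M * K) >= mask_fraction, c(N, M, K))
    if (all(mask)) mask <- NULL
  }
  health_tensor(v, mask = mask)
}

# bit signatures by explicit loops: bits[[t]][[z]] is an N x M 0/1 matrix
brute_signatures <- function(tensor, p, q, seed, per_criterion = FALSE) {
  v <- tensor$values
  if (!is.null(tensor$mask)) v[!tensor$mask] <- 0
  N <- dim(v)[1]; M <- dim(v)[2]; K <- dim(v)[3]
  lapply(seq_len(p), function(t) lapply(seq_len(q), function(z) {
    bits <- matrix(0L, N, M)
    if (!per_criterion) B <- sample_projection(K, plane_seed(seed, t, z))
    for (j in seq_len(M)) {
      if (per_criterion) B <- sample_projection(K, plane_seed(seed, t, z, j))
      for (i in seq_len(N)) {
        omega <- 0
        for (k in seq_len(K)) omega <- omega + v[i, j, k] * B[k]
        bits[i, j] <- if (omega > 0) 1L else 0L
      }
    }
    bits
  }))
}

# all-pairs match-count similarity straight from the bit signatures
brute_sim_matrix <- function(tensor, p, q, seed, per_criterion = FALSE) {
  sig <- brute_signatures(tensor, p, q, seed, per_criterion)
  N <- dim(tensor$values)[1]
  sim <- matrix(0L, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) { sim[i, j] <- q; next }
    s <- 0L
    for (z in seq_len(q)) {
      matched <- FALSE
      for (t in seq_len(p))
        if (all(sig[[t]][[z]][i, ] == sig[[t]][[z]][j, ])) { matched <- TRUE; break }
      if (matched) s <- s + 1L
    }
    sim[i, j] <- s
  }
  sim
}

# connected components by breadth-first traversal (independent of igraph)
brute_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# direct loop implementation of the neighbor-mean prediction protocol
brute_neighbor_mean <- function(tensor, adj, heldout, weights = NULL) {
  v <- tensor$values
  obs <- if (is.null(tensor$mask)) array(TRUE, dim(v)) else tensor$mask
  all_obs <- v[obs]
  global_mean <- mean(all_obs)
  sapply(seq_len(nrow(heldout)), function(r) {
    i <- match(heldout$student_id[r], tensor$student_ids)
    j <- match(heldout$criterion_id[r], tensor$criterion_ids)
    k <- heldout$time_index[r] + 1L
    nbrs <- which(adj[i, ] & obs[, j, k])
    if (length(nbrs)) {
      w <- if (is.null(weights)) rep(1, length(nbrs)) else weights[i, nbrs]
      return(sum(w * v[cbind(nbrs, j, k)]) / sum(w))
    }
    col_obs <- which(obs[, j, k])
    if (length(col_obs)) return(mean(v[cbind(col_obs, j, k)]))
    global_mean
  })
}

# a hand-buildable similarity graph for clustering tests
simgraph_from_sim <- function(sim, q, ids = paste0("s", seq_len(nrow(sim)))) {
  dimnames(sim) <- list(ids, ids)
  structure(list(n_students = nrow(sim), student_ids = ids, sim = sim,
                 q = q, p = 1L, seed = 0, T = NA_integer_, adjacency = NULL),
            class = "anodet_simgraph")
}
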