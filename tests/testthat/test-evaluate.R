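test_that("error measures match their closed forms", {
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(1, -1), c(0, 0)), 1)
  expect_equal(rmse(c(1, -1), c(0, 0)), 1)
  expect_equal(mae(c(0, 2), c(0, 0)), 1)
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2))
  expect_error(mae(numeric(0), numeric(0)), class = "anodet_validation_error")
  expect_error(rmse(1:3, 1:2), class = "anodet_validation_error")
  set.seed(1)
  for (i in 1:20) {
    p <- rnorm(50); t <- rnorm(50)
    expect_gte(rmse(p, t), mae(p, t))
  }
})

# two hand-built students: s1 and s2 identical so they are mutual neighbors
hand_pair_tensor <- function() {
  v <- array(0, c(3, 1, 4))
  v[1, 1, ] <- c(80, 81, 82, 83)
  v[2, 1, ] <- c(80, 81, 82, 83)
  v[3, 1, ] <- c(-5, -6, -7, -8)   # opposite sign, never a neighbor
  mask <- array(TRUE, c(3, 1, 4))
  mask[1, 1, 2] <- FALSE           # s1's value at k=1 is hidden
  health_tensor(v, mask = mask)
}

test_that("neighbor-mean prediction uses neighbors then declared fallbacks", {
  t <- hand_pair_tensor()
  idx <- build_index(t, run_config(p = 2, q = 3, T = 2, seed = 1))
  heldout <- data.frame(student_id = "s1", criterion_id = "c1",
                        time_index = 1L, true_value = 81)
  pred <- predict_heldout_anodet(t, idx, 2, heldout)
  expect_equal(pred, 81)  # the single neighbor observes 81
  # an isolated student falls back to the cohort (criterion, time) mean
  mask2 <- array(TRUE, c(3, 1, 4)); mask2[3, 1, 3] <- FALSE
  t2 <- health_tensor(t$values, mask = mask2)
  idx2 <- build_index(t2, run_config(p = 2, q = 3, T = 2, seed = 1))
  heldout2 <- data.frame(student_id = "s3", criterion_id = "c1",
                         time_index = 2L, true_value = -7)
  expect_equal(predict_heldout_anodet(t2, idx2, 2, heldout2), mean(c(82, 82)))
  # asking for a triple that is still observed is refused
  expect_error(predict_heldout_anodet(t2, idx2, 2,
                                      data.frame(student_id = "s1",
                                                 criterion_id = "c1",
                                                 time_index = 0L,
                                                 true_value = 80)),
               class = "anodet_validation_error")
})

test_that("index-based predictions equal a loop oracle on a random cohort", {
  co <- generate_cohort(generator_config(N = 10, M = 4, K = 12,
                                         anomaly_fraction = 0.1, seed = 12))
  m <- mask_entries(co, 0.1, seed = 12)
  idx <- build_index(m$tensor, run_config(p = 3, q = 4, T = 2, seed = 12))
  pred <- predict_heldout_anodet(m$tensor, idx, 2, m$heldout)
  g <- threshold_graph(similarity_matrix(idx), 2)
  oracle <- brute_neighbor_mean(m$tensor, g$adjacency, m$heldout)
  expect_equal(pred, oracle, tolerance = 1e-12)
})

test_that("the UCF baseline behaves classically and matches its oracle", {
  # two perfectly correlated students: prediction equals the peer's value
  v <- array(0, c(2, 1, 6))
  v[1, 1, ] <- 1:6
  v[2, 1, ] <- 1:6
  mask <- array(TRUE, dim(v)); mask[1, 1, 3] <- FALSE
  t <- health_tensor(v, mask = mask)
  heldout <- data.frame(student_id = "s1", criterion_id = "c1",
                        time_index = 2L, true_value = 3)
  expect_equal(predict_heldout_ucf(t, 10, heldout), 3)
  # an all-constant cohort predicts that constant (via the fallback path,
  # since constant rows have no defined correlation)
  vc <- array(5, c(3, 1, 4))
  maskc <- array(TRUE, dim(vc)); maskc[2, 1, 2] <- FALSE
  tc <- health_tensor(vc, mask = maskc)
  ho <- data.frame(student_id = "s2", criterion_id = "c1",
                   time_index = 1L, true_value = 5)
  expect_equal(predict_heldout_ucf(tc, 10, ho), 5)
  # random cohort against an independent weighted-mean implementation
  co <- generate_cohort(generator_config(N = 12, M = 3, K = 10,
                                         anomaly_fraction = 0, seed = 19))
  m <- mask_entries(co, 0.15, seed = 19)
  pred <- predict_heldout_ucf(m$tensor, 5, m$heldout)
  V <- m$tensor$values
  V[!m$tensor$mask] <- NA
  V <- matrix(V, nrow = 12)
  suppressWarnings(C <- cor(t(V), use = "pairwise.complete.obs"))
  C[is.na(C)] <- 0; diag(C) <- 0
  W <- matrix(0, 12, 12)
  for (i in 1:12) {
    pos <- which(C[i, ] > 0)
    if (length(pos) > 5) pos <- pos[order(C[i, pos], decreasing = TRUE)[1:5]]
    W[i, pos] <- C[i, pos]
  }
  oracle <- brute_neighbor_mean(m$tensor, W > 0, m$heldout, weights = W)
  expect_equal(pred, oracle, tolerance = 1e-12)
})

test_that("a profile sweep emits one report per method and grid point", {
  gen <- generator_config(N = 20, M = 4, K = 16, anomaly_fraction = 0.1)
  grid <- data.frame(p = 2L, q = 3L, T = 2L)
  rep1 <- run_profile(grid, gen, mask_fraction = 0.1, seeds = 3L)
  expect_equal(nrow(rep1), 2)
  expect_setequal(rep1$method, c("ano-det", "ucf"))
  expect_true(all(rep1$rmse >= rep1$mae))
  rep2 <- run_profile(grid, gen, mask_fraction = 0.1, seeds = 3L)
  expect_equal(rep1$mae, rep2$mae)  # fully seeded
  rep3 <- run_profile(grid, gen, mask_fraction = 0.1, seeds = 3L,
                      include_brute = TRUE)
  expect_equal(nrow(rep3), 3)
  expect_error(run_profile(data.frame(p = 1, q = 2, T = 3), gen),
               class = "anodet_validation_error")
})

test_that("sweeping via one large index equals independent per-point runs", {
  gen <- generator_config(N = 15, M = 3, K = 12, anomaly_fraction = 0.1)
  grid <- data.frame(p = c(1L, 3L), q = c(2L, 4L), T = c(1L, 2L))
  rep <- run_profile(grid, gen, mask_fraction = 0.1, seeds = 5L)
  ad <- rep[rep$method == "ano-det", ]
  for (r in 1:2) {
    co <- generate_cohort(generator_config(N = 15, M = 3, K = 12,
                                           anomaly_fraction = 0.1, seed = 5))
    m <- mask_entries(co, 0.1, seed = 5)
    idx <- build_index(m$tensor, run_config(grid$p[r], grid$q[r], 1L, seed = 5))
    pred <- predict_heldout_anodet(m$tensor, idx, grid$T[r], m$heldout)
    expect_equal(ad$mae[ad$p == grid$p[r] & ad$q == grid$q[r]],
                 mae(pred, m$heldout$true_value))
  }
})

test_that("match counts never decrease as repetitions are appended", {
  t <- random_tensor(12, 4, 8, seed = 77)
  sims <- lapply(2:5, function(q) similarity_matrix(
    build_index(t, run_config(2, q, 1, seed = 77)))$sim)
  for (i in 2:length(sims)) expect_true(all(sims[[i]] >= sims[[i - 1]]))
})
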