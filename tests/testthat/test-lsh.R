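test_that("sampled planes are deterministic and uniform on [-1, 1]", {
  expect_identical(sample_projection(3, seed = 11), sample_projection(3, seed = 11))
  expect_error(sample_projection(0, seed = 1), class = "anodet_validation_error")
  draws <- unlist(lapply(1:100, function(s) sample_projection(100, seed = s)))
  expect_true(all(draws >= -1 & draws <= 1))
  expect_lt(abs(mean(draws)), 0.05)
  expect_lt(min(draws), -0.99)
  expect_gt(max(draws), 0.99)
})

test_that("projection is the inner product", {
  expect_equal(project(c(1, 2), c(0.5, -0.5)), -0.5)
  expect_equal(project(rep(0, 7), sample_projection(7, 1)), 0)
  expect_error(project(1:3, 1:2), class = "anodet_validation_error")
  set.seed(5)
  a <- rnorm(64); b <- rnorm(64)
  acc <- 0
  for (k in 1:64) acc <- acc + a[k] * b[k]  # independent summation
  expect_equal(project(a, b), acc, tolerance = 1e-9)
})

test_that("binarization follows the sign rule with ties to zero", {
  expect_identical(binarize(2.5), 1L)
  expect_identical(binarize(-0.1), 0L)
  expect_identical(binarize(0), 0L)
  expect_identical(binarize(c(-1, 0, 3)), c(0L, 0L, 1L))
  expect_error(binarize(Inf), class = "anodet_validation_error")
  expect_error(binarize(NA_real_), class = "anodet_validation_error")
})

test_that("signatures pack MSB-first into decimal indexes", {
  expect_equal(signature_to_index(c(1, 1, 1)), 7)
  expect_equal(signature_to_index(c(0, 0, 0)), 0)
  expect_equal(signature_to_index(c(1, 0, 1)), 5)
  expect_error(signature_to_index(integer(0)), class = "anodet_validation_error")
  expect_error(signature_to_index(c(1, 2)), class = "anodet_validation_error")
  # hex form agrees with the numeric form on random short signatures
  set.seed(3)
  for (rep in 1:20) {
    bits <- sample(0:1, sample(1:24, 1), replace = TRUE)
    expect_equal(strtoi(signature_to_index(bits, as = "hex"), 16L),
                 signature_to_index(bits))
  }
  # signatures beyond double precision stay exact as hex
  long <- rep(c(1, 0), 100)
  h <- signature_to_index(long)
  expect_type(h, "character")
  expect_equal(nchar(h), 50)
})

test_that("index construction is deterministic and a pure function of curves", {
  t <- random_tensor(5, 3, 8, seed = 21)
  cfg <- run_config(p = 2, q = 3, T = 1, seed = 21)
  expect_identical(build_index(t, cfg), build_index(t, cfg))
  # two identical students hash identically in every slot
  v <- t$values
  v[2, , ] <- v[1, , ]
  t2 <- health_tensor(v)
  idx <- build_index(t2, cfg)
  for (tab in idx$tables) expect_identical(tab[1, ], tab[2, ])
})

test_that("hashes are invariant to positive scaling of each curve", {
  t <- random_tensor(6, 4, 10, seed = 8)
  cfg <- run_config(p = 2, q = 3, T = 1, seed = 8)
  set.seed(99)
  lambda <- array(rep(runif(6 * 4, 0.1, 10), times = 10), c(6, 4, 10))
  t_scaled <- health_tensor(t$values * lambda)
  expect_identical(build_index(t, cfg)$tables, build_index(t_scaled, cfg)$tables)
})

test_that("index values match a hand computation on a tiny cohort", {
  # 2 students x 3 criteria x 2 time points; plane fixed by its slot seed
  v <- array(0, c(2, 3, 2))
  v[1, 1, ] <- c(1, 0); v[1, 2, ] <- c(0, 1); v[1, 3, ] <- c(-1, -1)
  v[2, 1, ] <- c(-1, 0); v[2, 2, ] <- c(2, 2); v[2, 3, ] <- c(1, 0)
  t <- health_tensor(v)
  cfg <- run_config(p = 1, q = 1, T = 1, seed = 5)
  B <- sample_projection(2, plane_seed(5, 1, 1))
  hex_digit <- c("0", "1", "2", "3", "4", "5", "6", "7",
                 "8", "9", "a", "b", "c", "d", "e", "f")
  expected <- sapply(1:2, function(i) {
    bits <- sapply(1:3, function(j) as.integer(sum(v[i, j, ] * B) > 0))
    hex_digit[4 * bits[1] + 2 * bits[2] + bits[3] + 1]  # M=3 -> one hex digit
  })
  idx <- build_index(t, cfg)
  expect_identical(unname(idx$tables[[1]][, 1]), expected)
})

test_that("signatures agree with the loop oracle, with shared and per-criterion planes", {
  for (per_crit in c(FALSE, TRUE)) {
    t <- random_tensor(4, 5, 6, seed = 31, mask_fraction = 0.15)
    cfg <- run_config(p = 2, q = 2, T = 1, seed = 31,
                      per_criterion_planes = per_crit)
    idx <- build_index(t, cfg)
    sig <- brute_signatures(t, 2, 2, 31, per_criterion = per_crit)
    for (tt in 1:2) for (z in 1:2) {
      expected <- sapply(1:4, function(i)
        signature_to_index(sig[[tt]][[z]][i, ], as = "hex"))
      expect_identical(unname(idx$tables[[tt]][, z]), expected)
    }
  }
})

test_that("index tables round-trip through their JSON interchange format", {
  t <- random_tensor(4, 9, 5, seed = 13)
  idx <- build_index(t, run_config(p = 3, q = 2, T = 1, seed = 13))
  f <- withr::local_tempfile(fileext = ".json")
  write_index(idx, f)
  idx2 <- read_index(f)
  expect_identical(idx2$tables, idx$tables)
  expect_identical(idx2$p, idx$p)
  expect_identical(idx2$q, idx$q)
  expect_identical(idx2$M, idx$M)
})

test_that("restricting a large index equals building the small one directly", {
  t <- random_tensor(6, 4, 8, seed = 17)
  big <- build_index(t, run_config(p = 4, q = 5, T = 1, seed = 17))
  small <- build_index(t, run_config(p = 2, q = 3, T = 1, seed = 17))
  expect_identical(subset_index(big, 2, 3)$tables, small$tables)
  expect_error(subset_index(big, 5, 1), class = "anodet_validation_error")
})

test_that("the index file carries no raw sensor readings", {
  t <- random_tensor(5, 6, 7, seed = 23)
  idx <- build_index(t, run_config(p = 2, q = 2, T = 1, seed = 23))
  f <- withr::local_tempfile(fileext = ".json")
  write_index(idx, f)
  payload <- paste(readLines(f), collapse = "")
  # every index is a bounded-width hex string, and no decimal rendering of a
  # raw value appears anywhere in the file
  expect_true(all(grepl("^[0-9a-f]+$", unlist(idx$tables))))
  expect_true(all(nchar(unlist(idx$tables)) == ceiling(6 / 4)))
  for (val in format(t$values, digits = 10))
    expect_false(grepl(val, payload, fixed = TRUE))
})
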