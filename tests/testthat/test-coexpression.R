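## Brute-force oracles for the network primitives.

brute_adjacency <- function(expr, beta) {
  n <- nrow(expr)
  a <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    a[i, j] <- abs(cor(expr[i, ], expr[j, ]))^beta
  a
}

brute_tom_dissimilarity <- function(a) {
  n <- nrow(a)
  d <- matrix(0, n, n)
  k <- rowSums(a) - 1
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    denom <- min(k[i], k[j]) + 1 - a[i, j]
    d[i, j] <- if (denom <= 0) 1 else 1 - (l + a[i, j]) / denom
  }
  d
}

random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

test_that("connectivity selection keeps the most connected genes", {
  sim <- simulate_modular_expression(5, c(5), 30, 0.6, seed = 21)
  expect_identical(select_top_connected(sim$expr, nrow(sim$expr)), sim$expr)

  ## duplicated gene pair beats an independent noise gene
  set.seed(22)
  base <- rnorm(50)
  expr <- rbind(g1 = base, g2 = base + rnorm(50, sd = 1e-6), g3 = rnorm(50))
  colnames(expr) <- paste0("s", 1:50)
  kept <- select_top_connected(expr, 2)
  expect_identical(rownames(kept), c("g1", "g2"))

  ## matches a brute-force connectivity ranking
  sim2 <- simulate_modular_expression(10, c(6, 4), 40, 0.5, seed = 23)
  cc <- abs(cor(t(sim2$expr)))
  conn <- rowSums(cc) - 1
  expected <- sort(order(-round(conn, 4), seq_along(conn))[1:8])
  expect_identical(rownames(select_top_connected(sim2$expr, 8)),
                   rownames(sim2$expr)[expected])
})

test_that("adjacency matches closed forms and the brute-force double loop", {
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  colnames(x) <- paste0("s", 1:4)
  expect_equal(adjacency_matrix(x, 1)["g1", "g2"], 1)

  ## cor -0.5 at beta 2 -> 0.25
  y <- rbind(a = c(1, 0, 0, 1, 0.5), b = c(0.5, 1, 0, 0, 0))
  colnames(y) <- paste0("s", 1:5)
  r <- cor(y["a", ], y["b", ])
  expect_equal(adjacency_matrix(y, 2)["a", "b"], r^2, tolerance = 1e-12)

  sim <- simulate_modular_expression(2, c(4), 20, 0.5, seed = 31)
  expect_equal(adjacency_matrix(sim$expr, 3),
               brute_adjacency(sim$expr, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("TOM dissimilarity matches the brute-force triple loop", {
  ones <- matrix(1, 3, 3)
  expect_equal(tom_dissimilarity(ones), matrix(0, 3, 3))

  none <- diag(3)
  d <- tom_dissimilarity(none)
  expect_equal(d[lower.tri(d)], rep(1, 3))

  withr::with_seed(32, {
    for (rep in 1:5) {
      a <- random_adjacency(8)
      expect_equal(tom_dissimilarity(a), brute_tom_dissimilarity(a),
                   tolerance = 1e-12)
    }
  })
})

test_that("TOM output is symmetric and within [0, 1]", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      d <- tom_dissimilarity(random_adjacency(12))
      expect_equal(d, t(d), tolerance = 1e-12)
      expect_true(all(d >= 0 & d <= 1))
      expect_equal(diag(d), rep(0, 12))
    }
  })
})

test_that("soft threshold scan behaves and flags degenerate input", {
  sim <- simulate_modular_expression(100, rep(50, 5), 100, 0.7, seed = 1)
  fit <- pick_soft_threshold(sim$expr)
  ## mean connectivity strictly decreases with the power
  expect_true(all(diff(fit$fit_table$mean_connectivity) < 0))
  ## the planted structure supports a scale-free fit at the chosen power
  chosen <- fit$fit_table[fit$fit_table$power == fit$power, ]
  expect_gte(chosen$signed_r2, 0.8)
  ## chosen power is the smallest candidate reaching the target
  reaching <- fit$fit_table$power[fit$fit_table$signed_r2 >= 0.8]
  expect_equal(fit$power, min(reaching))

  flat <- matrix(rep(c(1, 2, 3, 2, 4), each = 4), nrow = 4, byrow = FALSE,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  expect_error(suppressWarnings(pick_soft_threshold(flat)), "degenerate")
})

test_that("consensus TOM reduces to the full-data TOM and averages resamples", {
  sim <- simulate_modular_expression(5, c(5, 5), 20, 0.6, seed = 41)
  full <- tom_dissimilarity(adjacency_matrix(sim$expr, 4))
  net0 <- consensus_tom(sim$expr, 4, n_resamples = 7, leave_out_fraction = 0,
                        seed = 1)
  expect_equal(unname(net0$consensus_dissimilarity), unname(full),
               tolerance = 1e-15)

  ## mean-of-resamples oracle: replay the identical subsample draws
  net3 <- consensus_tom(sim$expr, 4, n_resamples = 3,
                        leave_out_fraction = 0.1, seed = 55)
  n_keep <- ceiling(0.9 * ncol(sim$expr))
  toms <- withr::with_seed(55, {
    lapply(1:3, function(b) {
      keep <- sample.int(ncol(sim$expr), n_keep)
      tom_dissimilarity(adjacency_matrix(sim$expr[, keep], 4))
    })
  })
  expect_equal(net3$consensus_dissimilarity,
               (toms[[1]] + toms[[2]] + toms[[3]]) / 3, tolerance = 1e-15)
  ## consensus entries bounded by the per-resample extremes
  lo <- pmin(toms[[1]], toms[[2]], toms[[3]])
  hi <- pmax(toms[[1]], toms[[2]], toms[[3]])
  expect_true(all(net3$consensus_dissimilarity >= lo - 1e-12))
  expect_true(all(net3$consensus_dissimilarity <= hi + 1e-12))
})

test_that("consensus is seed-reproducible and stabilizes with more resamples", {
  sim <- simulate_modular_expression(10, c(10), 30, 0.6, seed = 42)
  a <- consensus_tom(sim$expr, 4, 10, 0.1, seed = 9)
  b <- consensus_tom(sim$expr, 4, 10, 0.1, seed = 9)
  expect_identical(a, b)

  ## different seeds: deviation shrinks as resamples grow
  dev_at <- function(n_res) {
    x <- consensus_tom(sim$expr, 4, n_res, 0.1, seed = 1)
    y <- consensus_tom(sim$expr, 4, n_res, 0.1, seed = 2)
    max(abs(x$consensus_dissimilarity - y$consensus_dissimilarity))
  }
  expect_lt(dev_at(100), dev_at(10))
})
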