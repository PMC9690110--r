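test_that("distance_matrix computes pairwise distances with valid structure", {
  X <- rbind(c(0, 0), c(3, 4))
  expect_equal(distance_matrix(X)[1, 2], 5)

  X2 <- rbind(c(1, 2), c(1, 2), c(4, 6))
  D2 <- distance_matrix(X2)
  expect_equal(D2[1, 2], 0)

  D3 <- distance_matrix(matrix(c(0, 1, 3), ncol = 1))
  expect_equal(D3[upper.tri(D3)], c(1, 3, 2))

  expect_true(isSymmetric(D3))
  expect_equal(diag(D3), c("1" = 0, "2" = 0, "3" = 0))

  expect_error(distance_matrix(matrix(c(0, NA), 2, 1)), "non-finite")
  expect_error(distance_matrix(matrix(1, 1, 3)), "at least 2")
})

test_that("manhattan and correlation metrics are available", {
  X <- rbind(c(0, 0), c(3, 4))
  expect_equal(distance_matrix(X, "manhattan")[1, 2], 7)
  Xc <- rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1))
  Dc <- distance_matrix(Xc, "correlation")
  expect_equal(Dc[1, 2], 0)       # perfectly correlated rows
  expect_equal(Dc[1, 3], 2)       # perfectly anti-correlated rows
})

test_that("tau is the reciprocal of the median upper-triangle distance", {
  D <- matrix(5, 3, 3); diag(D) <- 0
  expect_equal(estimate_tau(D)$tau, 0.2)

  D3 <- distance_matrix(matrix(c(0, 1, 3), ncol = 1))
  expect_equal(estimate_tau(D3)$median_distance, 2)
  expect_equal(estimate_tau(D3)$tau, 0.5)

  # even count: median is the mean of the two central order statistics
  D4 <- matrix(0, 4, 4)
  D4[upper.tri(D4)] <- c(1, 2, 4, 3, 5, 6)
  D4 <- D4 + t(D4)
  expect_equal(estimate_tau(D4)$median_distance, 3.5)
  expect_equal(estimate_tau(D4)$tau, 1 / 3.5)

  Dz <- matrix(0, 3, 3)
  expect_error(estimate_tau(Dz), "undefined")
})

test_that("similarity kernel hits its limiting values", {
  D <- distance_matrix(matrix(c(0, 1, 3), ncol = 1))
  sc <- estimate_tau(D)
  L <- similarity_matrix(D)
  expect_equal(diag(L), c("1" = 1, "2" = 1, "3" = 1))      # d = 0
  # the pair exactly at the median distance (subjects 2 and 3) gets exp(-1)
  expect_equal(sc$median_distance, 2)
  expect_equal(L[2, 3], exp(-1))
  # direct evaluation with fixed tau
  D2 <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(similarity_matrix(D2, tau = 0.5)[1, 2], exp(-1))
})

test_that("similarity is scale-equivariant and order-preserving", {
  set.seed(31)
  X <- matrix(rnorm(40), 10, 4)
  D <- distance_matrix(X)
  for (s in c(0.01, 3, 1000)) {
    Ls <- similarity_matrix(D * s)        # tau re-estimated internally
    expect_equal(Ls, similarity_matrix(D), tolerance = 1e-12)
  }
  L <- similarity_matrix(D)
  for (r in c(1, 5, 10)) {
    expect_equal(order(L[r, -r], decreasing = TRUE), order(D[r, -r]))
  }
  expect_true(all(L > 0 & L <= 1))
  expect_true(all((L == 1) == (D == 0)))
})

test_that("user-supplied distance matrices are validated and symmetrized", {
  D <- matrix(c(0, 1, 1 + 1e-10, 0), 2, 2)
  expect_equal(validate_distance_matrix(D)[1, 2],
               validate_distance_matrix(D)[2, 1])
  Dbad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(validate_distance_matrix(Dbad), "symmetric")
  Dneg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(validate_distance_matrix(Dneg), "nonnegative")
})
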