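test_that("EPA conditionals reduce exactly to the CRP under zero discount", {
  # position 2, one seated subject, alpha = 1: join/new both 1/2
  Lc <- matrix(0.7, 4, 4); diag(Lc) <- 1
  w <- epa_conditional(Lc, perm = 1:4, i_pos = 2, partial_labels = 1L,
                       alpha = 1, delta = 0)
  expect_equal(w, c(0.5, 0.5))

  # attraction ratio is 1 for a single table regardless of similarities
  L <- diag(3)
  L[3, 1] <- L[1, 3] <- 0.8
  L[3, 2] <- L[2, 3] <- 0.2
  L[1, 2] <- L[2, 1] <- 0.5
  w3 <- epa_conditional(L, perm = 1:3, i_pos = 3, partial_labels = c(1L, 1L),
                        alpha = 1, delta = 0)
  expect_equal(w3, c(2 / 3, 1 / 3))

  # exhaustive small partials, constant similarity: equals size-based seating
  for (n in 3:6) {
    for (i_pos in 2:n) {
      parts <- enumerate_partitions(i_pos - 1)
      for (pl in parts) {
        w <- epa_conditional(matrix(0.7, n, n),
                             perm = seq_len(n), i_pos = i_pos,
                             partial_labels = pl, alpha = 1.3, delta = 0)
        sizes <- tabulate(pl)
        crp <- c(sizes, 1.3) / (1.3 + i_pos - 1)
        expect_equal(w, crp, tolerance = 1e-12)
      }
    }
  }
})

test_that("probabilities sum to one across the valid parameter range", {
  set.seed(12)
  for (i in 1:30) {
    n <- sample(3:7, 1)
    L <- similarity_matrix(distance_matrix(matrix(rnorm(n * 2), n, 2)))
    i_pos <- sample(2:n, 1)
    pl <- enumerate_partitions(i_pos - 1)
    pl <- pl[[sample(length(pl), 1)]]
    delta <- runif(1, 0, 0.9)
    alpha <- runif(1, -delta + 0.05, 3)
    w <- epa_conditional(L, sample.int(n), i_pos, pl, alpha, delta)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= -1e-15))
  }
})

test_that("West's posterior draws have the stated gamma law", {
  set.seed(4)
  draws <- replicate(1e5, sample_alpha_west(3, 10))
  m <- 3 / (1 + -digamma(1) + log(10))
  expect_equal(mean(draws), m, tolerance = 3 * sqrt(3) /
                 ((1 - digamma(1) + log(10)) * sqrt(1e5)) / m)
  expect_true(all(draws > 0))

  # one cluster with a = b = 1: exponential with the West rate
  set.seed(6)
  d1 <- replicate(1e4, sample_alpha_west(1, 10))
  ks <- suppressWarnings(ks.test(d1, "pexp", 1 - digamma(1) + log(10)))
  expect_gt(ks$p.value, 0.01)

  set.seed(2); a1 <- sample_alpha_west(5, 20)
  set.seed(2); a2 <- sample_alpha_west(5, 20)
  expect_identical(a1, a2)
  expect_error(sample_alpha_west(0, 10), "positive")
})

test_that("the CRP chain matches sequential CRP sampling exactly", {
  # prior-only, fixed alpha: every iteration is an independent CRP seating
  n <- 4
  D <- matrix(1, n, n); diag(D) <- 0
  fit <- run_epa(distances = D, prior = "crp", use_likelihood = FALSE,
                 fixed_alpha = 1, burn_in = 0, samples = 4000, seed = 31)
  canon <- function(lab) paste(as.integer(match(lab, unique(lab))), collapse = "")
  freq <- table(apply(fit$draws, 1, canon))
  parts <- enumerate_partitions(n)
  probs <- vapply(parts, crp_partition_prob, numeric(1), alpha = 1)
  names(probs) <- vapply(parts, paste, character(1), collapse = "")
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  obs <- as.numeric(freq[names(probs)])
  obs[is.na(obs)] <- 0
  chi <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(chi$p.value, 0.001)
})

test_that("EPA runs are reproducible and alpha stays positive", {
  set.seed(123)
  X <- rbind(matrix(rnorm(16), 8, 2), matrix(rnorm(16) + 10, 8, 2))
  f1 <- run_epa(X, burn_in = 10, samples = 20, seed = 5)
  f2 <- run_epa(X, burn_in = 10, samples = 20, seed = 5)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$log_info$alpha > 0))
  for (t in seq_len(nrow(f1$draws))) {
    lab <- f1$draws[t, ]
    expect_setequal(unique(lab), seq_len(max(lab)))
  }
})

test_that("crp equals epa with zero discount and constant similarity", {
  n <- 6
  D <- matrix(2.5, n, n); diag(D) <- 0  # off-diagonal-constant distances
  f_crp <- run_epa(distances = D, prior = "crp", use_likelihood = FALSE,
                   burn_in = 5, samples = 25, seed = 77)
  f_epa <- run_epa(distances = D, prior = "epa", delta = 0,
                   use_likelihood = FALSE, burn_in = 5, samples = 25, seed = 77)
  expect_identical(f_crp$draws, f_epa$draws)
})
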