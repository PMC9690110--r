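test_that("proximity matrices encode co-membership", {
  expect_equal(proximity_matrix(c(1, 1, 2)),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_equal(proximity_matrix(rep(1, 4)), matrix(1, 4, 4))
  expect_equal(proximity_matrix(1:4), diag(4))
})

test_that("the posterior similarity matrix is the entrywise draw mean", {
  d1 <- c(1, 1, 2, 2); d2 <- c(1, 1, 1, 2); d3 <- c(1, 2, 2, 2)
  B <- posterior_similarity(rbind(d1, d2, d3))
  manual <- (proximity_matrix(d1) + proximity_matrix(d2) + proximity_matrix(d3)) / 3
  expect_equal(B, manual)
  expect_equal(diag(B), rep(1, 4))
  expect_true(all(B >= 0 & B <= 1))

  expect_equal(posterior_similarity(rbind(d1)), proximity_matrix(d1))
  # one disagreeing pair across two draws averages to 1/2
  B2 <- posterior_similarity(rbind(c(1, 1, 2), c(1, 2, 2)))
  expect_equal(B2[1, 2], 0.5)
  expect_error(posterior_similarity(matrix(integer(0), 0, 3)), "at least one")
})

test_that("pear equals the draw-averaged expected adjusted Rand", {
  set.seed(90)
  for (rep in 1:50) {
    n <- 8; T <- 20
    draws <- t(replicate(T, {
      lab <- sample.int(sample(2:4, 1), n, replace = TRUE)
      as.integer(match(lab, unique(lab)))
    }))
    Bbar <- posterior_similarity(draws)
    cand <- draws[sample.int(T, 1), ]
    # oracle: ratio of draw-averaged ARI numerator and denominator pieces
    pieces <- vapply(seq_len(T), function(t) ari_pieces(cand, draws[t, ]),
                     numeric(2))
    oracle <- if (mean(pieces["den", ]) == 0) 0 else
      mean(pieces["num", ]) / mean(pieces["den", ])
    expect_equal(pear(cand, Bbar), oracle, tolerance = 1e-10)
  }
})

test_that("pear is 1 against copies of itself and 0 in the degenerate case", {
  c0 <- c(1, 1, 2, 3, 3, 3)
  Bbar <- posterior_similarity(rbind(c0, c0, c0))
  expect_equal(pear(c0, Bbar), 1)
  # all-singleton candidate against an identity similarity matrix: 0/0 -> 0
  expect_equal(pear(1:5, diag(5)), 0)
})

test_that("pear is invariant to label names and draw order", {
  set.seed(14)
  draws <- t(replicate(10, sample.int(3, 6, replace = TRUE)))
  Bbar <- posterior_similarity(draws)
  cand <- c(1, 2, 1, 3, 3, 2)
  relab <- c(3, 1, 3, 2, 2, 1)  # same partition, permuted names
  expect_equal(pear(cand, Bbar), pear(relab, Bbar))
  Bshuf <- posterior_similarity(draws[sample.int(10), ])
  expect_equal(Bbar, Bshuf)
})

test_that("consensus selection maximizes pear over the recorded draws", {
  good <- c(1, 1, 1, 2, 2, 2)
  noisy <- c(1, 2, 1, 2, 1, 2)
  draws <- rbind(good, good, good, noisy)
  sel <- select_consensus(draws)
  expect_equal(sel$assignment, good)
  expect_equal(sel$argmax_index, 1L)  # earliest of the tied maximizers
  expect_true(any(apply(draws, 1, function(r) all(r == sel$assignment))))

  same <- rbind(good, good)
  sel2 <- select_consensus(same)
  expect_equal(sel2$pear_value, 1)
})
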