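test_that("transition matrices are stochastic, reversible and semigroup", {
  m <- jtt_model()
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(m$Q))), 1e-12)
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  P0 <- transition_matrix(m, 0)
  expect_equal(unname(P0), diag(20))
  for (t in c(0.1, 0.5, 2)) {
    P <- transition_matrix(m, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  }
  P <- transition_matrix(m, 0.5)
  # detailed balance pi_i P_ij = pi_j P_ji
  expect_lt(max(abs(m$pi * P - t(m$pi * P))), 1e-10)
  # semigroup P(t1 + t2) = P(t1) P(t2)
  expect_lt(max(abs(transition_matrix(m, 0.37) -
                      transition_matrix(m, 0.2) %*%
                      transition_matrix(m, 0.17))), 1e-10)
  expect_error(transition_matrix(m, -0.1), "non-negative")
})

test_that("discrete gamma category rates average to one", {
  for (a in c(0.3, 1, 5)) {
    r <- fibevo:::discrete_gamma_rates(a, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
  m <- jtt_model(alpha = 0.5)
  expect_equal(m$n_categories, 4L)
  expect_equal(sum(m$cat_weights), 1)
})

test_that("model construction validates its parameters", {
  expect_error(jtt_model(p_inv = 1), "p_inv")
  expect_error(jtt_model(alpha = -1), "alpha")
})
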