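test_that("forward model matches the processing tree", {
  # certain detection forces the definitely-yes category
  cp <- cell_probabilities(theta_pd(1, 0.3, 0.9, 0.2, 0.7))
  expect_equal(cp$prob[cp$condition == "present"], c(0, 0, 0, 1))

  # no detection, always guess yes, never high confidence -> probably-yes
  cp <- cell_probabilities(theta_pd(0, 0.3, 1, 0.2, 0))
  expect_equal(cp$prob[cp$condition == "present"], c(0, 0, 1, 0))

  # worked example at the printed MLE: expected counts land on the observed
  # counts in the two identified present-side cells
  th <- fit_mle(radiology)$theta
  cp <- cell_probabilities(th)
  present <- cp$prob[cp$condition == "present"]
  expect_equal(round(present, 4), c(0.0267, 0.0909, 0.2353, 0.6471))
  expect_equal(51 * present[3:4], c(12, 33), tolerance = 1e-10)
})

test_that("cell probabilities are simplex points for any theta", {
  set.seed(41)
  for (i in 1:50) {
    th <- as_theta_pd(runif(5))
    cp <- cell_probabilities(th)
    expect_true(all(cp$prob >= 0 & cp$prob <= 1))
    expect_equal(sum(cp$prob[cp$condition == "present"]), 1, tolerance = 1e-12)
    expect_equal(sum(cp$prob[cp$condition == "absent"]), 1, tolerance = 1e-12)
    expect_equal(cp$prob, unlist(oracle_cell_probs(th), use.names = FALSE))
  }
})

test_that("hit/false-alarm rates agree with the ROC operating points", {
  set.seed(42)
  for (i in 1:25) {
    th <- random_theta()
    cp <- cell_probabilities(th)
    pts <- operating_points(th)
    present <- cp$prob[cp$condition == "present"]
    absent <- cp$prob[cp$condition == "absent"]
    # high-confidence-yes rates are the P2 coordinates
    expect_equal(present[4], pts$y[pts$point == "P2"], tolerance = 1e-12)
    expect_equal(absent[4], pts$x[pts$point == "P2"], tolerance = 1e-12)
    # any-yes rates are the P3 coordinates
    expect_equal(sum(present[3:4]), pts$y[pts$point == "P3"], tolerance = 1e-12)
    expect_equal(sum(absent[3:4]), pts$x[pts$point == "P3"], tolerance = 1e-12)
  }
})

test_that("definite responses respond monotonically to the mixing rates", {
  set.seed(43)
  eps <- 1e-6
  for (i in 1:25) {
    th <- theta_vec(random_theta())
    up_d <- th; up_d[1] <- th[1] + eps
    up_nt <- th; up_nt[2] <- th[2] + eps
    p4 <- function(t) {
      cp <- cell_probabilities(as_theta_pd(t))
      cp$prob[cp$condition == "present"][4]
    }
    q1 <- function(t) {
      cp <- cell_probabilities(as_theta_pd(t))
      cp$prob[cp$condition == "absent"][1]
    }
    expect_gte(p4(up_d), p4(th))
    expect_gte(q1(up_nt), q1(th))
  }
})

test_that("log-likelihood follows the log-safe multinomial contract", {
  empty <- counts_from(c(0, 0, 0, 0), c(0, 0, 0, 0))
  expect_identical(log_likelihood(empty, theta_pd(0.3, 0.4, 0.5, 0.6, 0.7)), 0)

  # impossible datum: certain detection but a definitely-no response
  impossible <- counts_from(c(1, 0, 0, 0), c(0, 0, 0, 1))
  expect_identical(
    log_likelihood(impossible, theta_pd(1, 0, 0.5, 0.5, 0.5)), -Inf
  )

  # the MLE beats an arbitrary interior point on the worked example
  ll_mle <- log_likelihood(radiology, fit_mle(radiology)$theta)
  ll_mid <- log_likelihood(radiology, theta_pd(0.5, 0.5, 0.5, 0.5, 0.5))
  expect_gt(ll_mle, ll_mid)
  expect_equal(
    ll_mle,
    oracle_loglik(
      fit_mle(radiology)$theta, c(3, 3, 12, 33), c(33, 9, 14, 2)
    )
  )
})

test_that("simulation is reproducible and follows the cell probabilities", {
  th <- theta_pd(1, 0.4, 0.6, 0.3, 0.2)
  sim <- sample_counts(th, n_present = 20, n_absent = 0, seed = 9)
  v <- sim$count[sim$condition == "present"]
  expect_equal(v, c(0, 0, 0, 20))

  th <- random_theta()
  a <- sample_counts(th, 100, 100, seed = 123)
  b <- sample_counts(th, 100, 100, seed = 123)
  expect_identical(a$count, b$count)

  # law of large numbers: proportions within 3 binomial SEs at n = 1e5
  n <- 1e5
  th <- theta_pd(0.4, 0.5, 0.6, 0.45, 0.3)
  sim <- sample_counts(th, n, n, seed = 7)
  cp <- cell_probabilities(th)
  for (cond in c("present", "absent")) {
    phat <- sim$count[sim$condition == cond] / n
    p <- cp$prob[cp$condition == cond]
    expect_true(all(abs(phat - p) <= 3 * sqrt(p * (1 - p) / n) + 1e-12))
  }
})
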