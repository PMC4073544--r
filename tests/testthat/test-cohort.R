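test_that("cohort generation follows the design and the seed", {
  design <- shrinkage_design(seed = 14)
  cohort <- generate_cohort(design)
  expect_equal(nrow(cohort), 90)
  expect_equal(sort(unique(cohort$group)), 1:9)
  expect_equal(as.vector(table(cohort$group)), rep(10, 9))
  # the design grid fixes theta_d and theta_nt per cell
  expect_true(all(cohort$theta_d %in% c(0.2, 0.5, 0.8)))
  expect_true(all(cohort$theta_nt %in% c(0.2, 0.5, 0.8)))
  expect_equal(
    unique(cohort[, c("theta_d", "theta_nt", "group")])$group, 1:9
  )
  # every observer contributes 20 trials per condition
  totals <- vapply(cohort$counts, function(ct) {
    c(sum(ct$count[ct$condition == "present"]),
      sum(ct$count[ct$condition == "absent"]))
  }, numeric(2))
  expect_true(all(totals == 20))

  expect_identical(
    generate_cohort(design)$counts[[37]]$count,
    cohort$counts[[37]]$count
  )
})

test_that("beta-distributed truths have the nominal moments", {
  design <- cohort_design(
    n_g = 4000, n_r = 1,
    truth_spec = list(
      theta_d = 0.5, theta_nt = 0.5,
      theta_g = list(beta = c(28, 14)),
      theta_g_prime = list(beta = c(28, 14)),
      theta_h = list(beta = c(2, 4))
    ),
    seed = 15
  )
  cohort <- generate_cohort(design)
  expect_equal(mean(cohort$theta_g), 28 / 42, tolerance = 0.01)
  expect_equal(mean(cohort$theta_h), 2 / 6, tolerance = 0.01)
  expect_equal(sd(cohort$theta_h),
    sqrt(2 * 4 / (6^2 * 7)),
    tolerance = 0.01
  )
})

test_that("degenerate truth specs give identical observers", {
  design <- cohort_design(
    n_g = 6, n_r = 30,
    truth_spec = list(
      theta_d = 0.6, theta_nt = 0.5, theta_g = 0.7,
      theta_g_prime = 0.4, theta_h = 0.25
    ),
    seed = 16
  )
  cohort <- generate_cohort(design)
  expect_equal(nrow(unique(cohort[, c(
    "theta_d", "theta_nt", "theta_g", "theta_g_prime", "theta_h"
  )])), 1)
})

test_that("pooling counts respects proportion invariance", {
  counts <- radiology
  one <- list(counts)
  two <- list(counts, counts)
  # a single observer pools to itself
  expect_equal(
    theta_vec(pooled_fit(one, method = "mle")$theta),
    theta_vec(fit_mle(counts)$theta)
  )
  # duplicating an observer leaves the proportions, hence the MLE, unchanged
  expect_equal(
    theta_vec(pooled_fit(two, method = "mle")$theta),
    theta_vec(fit_mle(counts)$theta),
    tolerance = 1e-12
  )
})

test_that("pooled estimates converge on homogeneous cohorts", {
  truth <- c(0.6, 0.5, 0.7, 0.4, 0.25)
  design <- cohort_design(
    n_g = 60, n_r = 200,
    truth_spec = as.list(stats::setNames(truth, names(theta_pd(
      0.6, 0.5, 0.7, 0.4, 0.25
    )))),
    seed = 17
  )
  fit <- pooled_fit(generate_cohort(design), method = "mle")
  expect_lt(max(abs(theta_vec(fit$theta) - truth)), 0.02)
})

test_that("the fixed-shift adjustment has the stated algebra", {
  individual <- tibble::tibble(
    observer = 1:2,
    theta_d = c(0.4, 0.6), theta_nt = c(0.5, 0.5), theta_g = c(0.6, 0.8),
    theta_g_prime = c(0.3, 0.5), theta_h = c(0.2, 0.4)
  )
  pooled <- theta_pd(0.55, 0.5, 0.7, 0.4, 0.3)
  adj <- adjusted_estimates(individual, pooled)

  # the worked arithmetic: individual (0.4, 0.6), pooled 0.55 -> (0.45, 0.65)
  expect_equal(adj$adjusted$theta_d, c(0.45, 0.65))
  # mean of adjusted equals pooled, exactly, for every parameter
  for (p in names(pooled)) {
    expect_equal(mean(adj$adjusted[[p]]), pooled[[p]], tolerance = 1e-12)
  }
  # perfect correlation: a common constant separates the two sets
  expect_equal(
    unique(round(adj$adjusted$theta_d - adj$individual$theta_d, 12)),
    unname(round(adj$shift["theta_d"], 12))
  )

  # pooled equal to the group mean leaves estimates untouched
  same <- adjusted_estimates(individual, as_theta_pd(colMeans(
    individual[, names(pooled)]
  )))
  expect_equal(same$adjusted$theta_d, individual$theta_d)

  # clipping keeps values in range but may break the identity
  individual$theta_d <- c(0.02, 0.98)
  clipped <- adjusted_estimates(individual, theta_pd(0.9, 0.5, 0.7, 0.4, 0.3),
    clip = TRUE
  )
  expect_true(all(clipped$adjusted$theta_d <= 1))

  expect_error(
    adjusted_estimates(individual[0, ], pooled), "non-empty"
  )
})
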