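test_that("operating points follow the key-point equations", {
  # no detection, all guesses "no": the model points collapse to the corners
  pts <- operating_points(theta_pd(0, 0, 0, 1, 0))
  expect_equal(pts$x[pts$point == "P3"], 0)
  expect_equal(pts$y[pts$point == "P3"], 0)
  expect_equal(unlist(pts[pts$point == "P5", c("x", "y")]),
    c(x = 1, y = 1),
    tolerance = 1e-12
  )

  # perfect observer: both extreme points sit in the ROC corner
  pts <- operating_points(theta_pd(1, 1, 0.5, 0.5, 0.5))
  expect_equal(unlist(pts[pts$point == "P1", c("x", "y")]), c(x = 0, y = 1))
  expect_equal(unlist(pts[pts$point == "P5", c("x", "y")]), c(x = 0, y = 1))

  # worked example: the any-yes point equals the observed raw rates
  pts <- operating_points(fit_mle(radiology)$theta)
  expect_equal(pts$x[pts$point == "P3"], 16 / 58, tolerance = 1e-10)
  expect_equal(pts$y[pts$point == "P3"], 45 / 51, tolerance = 1e-10)

  # coordinates never leave the unit square and never decrease
  set.seed(21)
  for (i in 1:25) {
    pts <- operating_points(random_theta())
    expect_true(all(pts$x >= 0 & pts$x <= 1 & pts$y >= 0 & pts$y <= 1))
    expect_true(all(diff(pts$x) >= -1e-12))
    expect_true(all(diff(pts$y) >= -1e-12))
  }
})

test_that("the risk-variable paths pass through the operating points", {
  set.seed(22)
  for (i in 1:25) {
    th <- random_theta()
    h <- th[["theta_h"]]
    pts <- operating_points(th)
    v0 <- roc_path(th, "v", 0)
    v1 <- roc_path(th, "v", 1)
    w1 <- roc_path(th, "w", 1)
    expect_equal(c(v0$x, v0$y), unlist(pts[pts$point == "P1", c("x", "y")],
      use.names = FALSE
    ), tolerance = 1e-12)
    expect_equal(c(v1$x, v1$y), unlist(pts[pts$point == "P3", c("x", "y")],
      use.names = FALSE
    ), tolerance = 1e-12)
    expect_equal(c(w1$x, w1$y), unlist(pts[pts$point == "P5", c("x", "y")],
      use.names = FALSE
    ), tolerance = 1e-12)
    # v = theta_h lands on P2, w = 1 - theta_h on P4
    v2 <- roc_path(th, "v", h)
    w4 <- roc_path(th, "w", 1 - h)
    expect_equal(c(v2$x, v2$y), unlist(pts[pts$point == "P2", c("x", "y")],
      use.names = FALSE
    ), tolerance = 1e-12)
    expect_equal(c(w4$x, w4$y), unlist(pts[pts$point == "P4", c("x", "y")],
      use.names = FALSE
    ), tolerance = 1e-12)
  }
  expect_error(roc_path(random_theta(), "q", 0.5))
})

test_that("limb slopes match the point geometry and the closed-form ratio", {
  slope <- function(p1, p2) (p2$y - p1$y) / (p2$x - p1$x)
  set.seed(23)
  for (i in 1:25) {
    th <- random_theta()
    s <- roc_slopes(th)
    pts <- split(operating_points(th), ~point)
    # collinearity: P1-P2-P3 share one slope, P3-P4-P5 the other
    expect_equal(slope(pts$P1, pts$P2), s$s13, tolerance = 1e-9)
    expect_equal(slope(pts$P2, pts$P3), s$s13, tolerance = 1e-9)
    expect_equal(slope(pts$P3, pts$P4), s$s35, tolerance = 1e-9)
    expect_equal(slope(pts$P4, pts$P5), s$s35, tolerance = 1e-9)
    # two independent routes to the slope ratio agree
    expect_equal(s$r, s$s35 / s$s13, tolerance = 1e-9)
    # r <= 1 exactly on the informed-guessing side
    expect_equal(
      s$r <= 1,
      th[["theta_g"]] >= 1 - th[["theta_g_prime"]]
    )
  }

  # pure response bias: a single line of slope (1-theta_d)/(1-theta_nt)
  th <- theta_pd(0.3, 0.5, 0.6, 0.4, 0.25)
  s <- roc_slopes(th)
  expect_equal(s$r, 1, tolerance = 1e-12)
  expect_equal(s$s13, (1 - 0.3) / (1 - 0.5), tolerance = 1e-12)
  expect_equal(roc_slopes(theta_pd(0.2, 0.7, 0.5, 0.5, 0.9))$r, 1)

  # worked example, frozen from two independent evaluations
  s <- roc_slopes(fit_mle(radiology)$theta)
  expect_equal(s$s13, 1.103806, tolerance = 1e-5)
  expect_equal(s$s35, 0.585859, tolerance = 1e-5)
  expect_equal(s$r, 0.530762, tolerance = 1e-5)

  expect_true(roc_slopes(theta_pd(0.5, 1, 0.5, 0.5, 0.5))$degenerate)
})

test_that("area measures match the printed example and the polygon oracle", {
  # PPM estimates from the worked example
  m <- area_metrics(theta_pd(0.552, 0.496, 0.734, 0.405, 0.25))
  expect_equal(round(m$D_c, 3), 0.774)
  expect_equal(round(m$D_g, 3), 0.031)
  expect_equal(round(m$D, 3), 0.806)
  expect_equal(m$D, m$D_c + m$D_g)
  expect_equal(m$A_c, m$D_c / 2)

  # chance performance and a perfect detector
  expect_equal(area_metrics(theta_pd(0, 0, 0.6, 0.4, 0.3))$D, 0)
  perfect <- area_metrics(theta_pd(1, 0.2, 0.5, 0.5, 0.5))
  expect_equal(perfect$D_c, 1)
  expect_equal(perfect$D_g, 0)
  expect_equal(perfect$D, 1)

  # shoelace oracle: D is twice the polygon area over the diagonal
  set.seed(24)
  checked <- 0
  for (i in 1:50) {
    th <- random_theta()
    if (th[["theta_g"]] < 1 - th[["theta_g_prime"]]) next
    m <- area_metrics(th)
    expect_equal(m$D, shoelace_D(operating_points(th)), tolerance = 1e-10)
    checked <- checked + 1
  }
  expect_gt(checked, 10)

  # anti-informed guessing yields a signed negative D_g, with a warning
  expect_warning(m <- area_metrics(theta_pd(0.2, 0.2, 0.2, 0.2, 0.5)), "negative")
  expect_lt(m$D_g, 0)
  expect_false(m$informed)
  expect_equal(m$D, m$D_c + m$D_g)
})

test_that("threshold-model special cases reduce to single lines", {
  # single high threshold: theta_nt = 0, pure response bias
  th <- theta_pd(0.4, 0, 0.7, 0.3, 0.2)
  s <- roc_slopes(th)
  expect_equal(s$r, 1, tolerance = 1e-12)
  pts <- operating_points(th)
  expect_equal(unlist(pts[pts$point == "P1", c("x", "y")]), c(x = 0, y = 0.4))
  expect_equal(unlist(pts[pts$point == "P5", c("x", "y")]), c(x = 1, y = 1))
  # one-limb line through (0, theta_d): y = theta_d + (1 - theta_d) x
  mid <- roc_path(th, "v", 0.37)
  expect_equal(mid$y, 0.4 + (1 - 0.4) * mid$x / (1 - 0), tolerance = 1e-12)

  # double high threshold: theta_nt = theta_d, pure response bias
  th <- theta_pd(0.4, 0.4, 0.7, 0.3, 0.2)
  pts <- operating_points(th)
  expect_equal(roc_slopes(th)$r, 1, tolerance = 1e-12)
  mid <- roc_path(th, "w", 0.61)
  expect_equal(mid$y, 0.4 + (1 - 0.4) / (1 - 0.4) * mid$x, tolerance = 1e-12)
})
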