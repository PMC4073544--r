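# Shared fixtures and independent oracles for the test suite.

radiology <- pdetect::radiology_scans()

random_theta <- function(margin = 0.05) {
  pdetect::as_theta_pd(stats::runif(5, margin, 1 - margin))
}

theta_vec <- function(theta) as.numeric(unclass(theta))

# forward model written independently of the package internals (scalar,
# straight off the processing tree)
oracle_cell_probs <- function(theta) {
  d <- theta[[1]]; nt <- theta[[2]]; g <- theta[[3]]
  gp <- theta[[4]]; h <- theta[[5]]
  list(
    present = c(
      (1 - d) * (1 - g) * h,
      (1 - d) * (1 - g) * (1 - h),
      (1 - d) * g * (1 - h),
      d + (1 - d) * g * h
    ),
    absent = c(
      nt + (1 - nt) * gp * h,
      (1 - nt) * gp * (1 - h),
      (1 - nt) * (1 - gp) * (1 - h),
      (1 - nt) * (1 - gp) * h
    )
  )
}

oracle_loglik <- function(theta, x, y) {
  cp <- oracle_cell_probs(theta)
  term <- function(counts, p) {
    act <- counts > 0
    if (!any(act)) return(0)
    if (any(p[act] == 0)) return(-Inf)
    sum(counts[act] * log(p[act]))
  }
  term(x, cp$present) + term(y, cp$absent)
}

# vectorised log-likelihood over a matrix of theta rows (for grid search)
oracle_loglik_mat <- function(TH, x, y) {
  d <- TH[, 1]; nt <- TH[, 2]; g <- TH[, 3]; gp <- TH[, 4]; h <- TH[, 5]
  P <- cbind(
    (1 - d) * (1 - g) * h, (1 - d) * (1 - g) * (1 - h),
    (1 - d) * g * (1 - h), d + (1 - d) * g * h
  )
  Q <- cbind(
    nt + (1 - nt) * gp * h, (1 - nt) * gp * (1 - h),
    (1 - nt) * (1 - gp) * (1 - h), (1 - nt) * (1 - gp) * h
  )
  as.vector(log(pmax(P, 1e-300)) %*% x + log(pmax(Q, 1e-300)) %*% y)
}

# brute-force MLE oracle: coarse 5-D grid, then a dense 0.01-step grid in a
# +-0.05 window around the coarse optimum
grid_mle_oracle <- function(x, y) {
  coarse <- seq(0.05, 0.95, by = 0.1)
  TH <- as.matrix(expand.grid(coarse, coarse, coarse, coarse, coarse))
  ll <- oracle_loglik_mat(TH, x, y)
  centre <- TH[which.max(ll), ]
  axes <- lapply(centre, function(c0) {
    pmin(pmax(seq(c0 - 0.05, c0 + 0.05, by = 0.01), 1e-6), 1 - 1e-6)
  })
  TH2 <- as.matrix(expand.grid(axes))
  ll2 <- oracle_loglik_mat(TH2, x, y)
  list(theta = TH2[which.max(ll2), ], loglik = max(ll2))
}

# independent numerical optimiser oracle (multi-start BFGS + simplex polish)
optim_mle_oracle <- function(x, y) {
  nll <- function(t) -oracle_loglik_mat(matrix(pmin(pmax(t, 1e-9), 1 - 1e-9),
    nrow = 1
  ), x, y)
  best <- NULL
  for (s in list(
    rep(0.5, 5), c(0.3, 0.3, 0.6, 0.6, 0.3),
    c(0.7, 0.7, 0.4, 0.4, 0.2), c(0.2, 0.8, 0.5, 0.5, 0.5),
    c(0.9, 0.1, 0.5, 0.5, 0.1)
  )) {
    o <- stats::optim(s, nll,
      method = "L-BFGS-B",
      lower = 1e-9, upper = 1 - 1e-9, control = list(maxit = 1000)
    )
    if (is.null(best) || o$value < best$value) best <- o
  }
  best <- stats::optim(best$par, nll,
    method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-14)
  )
  list(theta = pmin(pmax(best$par, 0), 1), loglik = -best$value)
}

# twice the signed area between the ROC polygon P0..P6 and the diagonal,
# by the shoelace formula on the closed polygon (points, then back down the
# diagonal)
shoelace_D <- function(points) {
  xs <- c(points$x, 0)
  ys <- c(points$y, 0)
  n <- length(xs)
  2 * 0.5 * abs(sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys))
}

counts_from <- function(present, absent) {
  pdetect::detection_counts(present = present, absent = absent)
}
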