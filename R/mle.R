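#' Maximum-likelihood fit of the PD model
#'
#' The PD likelihood admits a closed-form interior maximum. With present
#' counts \eqn{x_1..x_4}, absent counts \eqn{y_1..y_4} and condition totals
#' \eqn{N_x, N_y}, the profile MLE of the shared high-confidence guessing
#' rate pools the two binomial splits that identify it:
#' \deqn{\hat\theta_h = (x_1 + y_4) / (x_1 + x_2 + y_3 + y_4),}
#' after which the remaining parameters follow by inverting the tree:
#' \eqn{1-\hat\theta_d = (x_1+x_2)/N_x + x_3/(N_x(1-\hat\theta_h))} and
#' \eqn{\hat\theta_g = x_3/(N_x(1-\hat\theta_h)(1-\hat\theta_d))}, with the
#' mirror-image formulas on the absent side. When any closed-form value
#' falls outside \eqn{[0,1]} (common at small samples) the fit falls back to
#' constrained numerical maximisation over the unit hypercube and the
#' affected parameters are flagged.
#'
#' @param counts A `pd_counts` table (see [detection_counts()]).
#' @return An object of class `c("pd_mle", "pd_fit")` with elements
#'   `theta` (the `theta_pd` estimate), `g_squared`, `pearson_x2`, `df`,
#'   `loglik`, `boundary_flags` and `method = "mle"`. Use [tidy()] /
#'   [glance()] for tibble summaries.
#' @examples
#' fit <- fit_mle(radiology_scans())
#' tidy(fit)
#' @export
fit_mle <- function(counts) {
  v <- counts_vectors(counts)
  x <- v$present; y <- v$absent
  n_x <- sum(x); n_y <- sum(y)
  if (n_x == 0 && n_y == 0) {
    stop("cannot fit the PD model to an empty table", call. = FALSE)
  }
  if (n_x == 0 || n_y == 0) {
    return(fit_mle_one_condition(counts, x, y))
  }

  est <- closed_form_mle(x, y)
  flags <- !is.finite(est) | est < 0 | est > 1
  if (any(flags)) {
    est <- numerical_mle(x, y)
  }
  theta <- as_theta_pd(pmin(pmax(est, 0), 1))
  gof <- goodness_of_fit(counts, theta)
  structure(
    list(
      theta = theta, method = "mle",
      g_squared = gof$g_squared, pearson_x2 = gof$pearson_x2, df = gof$df,
      loglik = log_likelihood(counts, theta),
      boundary_flags = stats::setNames(flags, .theta_names),
      counts = counts
    ),
    class = c("pd_mle", "pd_fit")
  )
}

closed_form_mle <- function(x, y) {
  n_x <- sum(x); n_y <- sum(y)
  h <- (x[1] + y[4]) / (x[1] + x[2] + y[3] + y[4])
  one_minus_d <- (x[1] + x[2]) / n_x + x[3] / (n_x * (1 - h))
  g <- (x[3] / (n_x * (1 - h))) / one_minus_d
  one_minus_nt <- (y[3] + y[4]) / n_y + y[2] / (n_y * (1 - h))
  gp <- (y[2] / (n_y * (1 - h))) / one_minus_nt
  c(1 - one_minus_d, 1 - one_minus_nt, g, gp, h)
}

# multi-start box-constrained optimisation; used when the closed form exits
# the unit hypercube or hits a zero denominator
numerical_mle <- function(x, y) {
  starts <- list(
    rep(0.5, 5),
    c(0.25, 0.25, 0.5, 0.5, 0.25),
    c(0.75, 0.75, 0.5, 0.5, 0.25),
    c(0.5, 0.5, 0.75, 0.25, 0.5),
    c(0.1, 0.9, 0.6, 0.6, 0.3)
  )
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, negloglik_raw,
      x = x, y = y, method = "L-BFGS-B",
      lower = 1e-9, upper = 1 - 1e-9, control = list(maxit = 500)
    )
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  best$par
}

# one condition has no observations: only that condition's sub-tree is
# identified. theta_h then comes from the remaining binomial split alone.
fit_mle_one_condition <- function(counts, x, y) {
  est <- rep(NA_real_, 5)
  flags <- rep(TRUE, 5)
  if (sum(x) > 0) {
    h <- x[1] / (x[1] + x[2])
    if (!is.finite(h)) h <- NA_real_
    one_minus_d <- if (is.finite(h) && h < 1) {
      (x[1] + x[2]) / sum(x) + x[3] / (sum(x) * (1 - h))
    } else {
      NA_real_
    }
    est[5] <- h
    est[1] <- 1 - one_minus_d
    est[3] <- if (is.finite(one_minus_d) && one_minus_d > 0) {
      (x[3] / (sum(x) * (1 - h))) / one_minus_d
    } else {
      NA_real_
    }
    flags[c(1, 3, 5)] <- !is.finite(est[c(1, 3, 5)])
  } else {
    h <- y[4] / (y[3] + y[4])
    one_minus_nt <- if (is.finite(h) && h < 1) {
      (y[3] + y[4]) / sum(y) + y[2] / (sum(y) * (1 - h))
    } else {
      NA_real_
    }
    est[5] <- h
    est[2] <- 1 - one_minus_nt
    est[4] <- if (is.finite(one_minus_nt) && one_minus_nt > 0) {
      (y[2] / (sum(y) * (1 - h))) / one_minus_nt
    } else {
      NA_real_
    }
    flags[c(2, 4, 5)] <- !is.finite(est[c(2, 4, 5)])
  }
  est_clamped <- pmin(pmax(est, 0), 1)
  theta <- structure(stats::setNames(est_clamped, .theta_names),
    class = "theta_pd"
  )
  structure(
    list(
      theta = theta, method = "mle",
      g_squared = NA_real_, pearson_x2 = NA_real_, df = NA_integer_,
      loglik = NA_real_,
      boundary_flags = stats::setNames(flags, .theta_names),
      counts = counts
    ),
    class = c("pd_mle", "pd_fit")
  )
}

#' Goodness of fit of a PD parameter vector to a count table
#'
#' Likelihood-ratio statistic \eqn{G^2 = 2\sum O \ln(O/E)} and Pearson
#' \eqn{X^2 = \sum (O-E)^2/E} over all eight cells, with expected counts
#' from the forward model times the condition totals. Observed zeros
#' contribute nothing to \eqn{G^2}; an expected zero facing a positive
#' observed count yields `Inf`. For the full five-parameter model fitted to
#' six free proportions, `df = 1`.
#'
#' @param counts A `pd_counts` table.
#' @param theta A `theta_pd` vector (or coercible).
#' @return A one-row tibble with `g_squared`, `pearson_x2`, `df`.
#' @export
goodness_of_fit <- function(counts, theta) {
  v <- counts_vectors(counts)
  theta <- as_theta_pd(theta)
  cp <- cell_prob_matrix(matrix(theta, nrow = 1))
  obs <- c(v$present, v$absent)
  exp_ <- c(cp$present[1, ] * sum(v$present), cp$absent[1, ] * sum(v$absent))
  active <- obs > 0
  g2 <- if (any(exp_[active] == 0)) {
    Inf
  } else {
    2 * sum(obs[active] * log(obs[active] / exp_[active]))
  }
  x2 <- if (any(exp_ == 0 & obs > 0)) {
    Inf
  } else {
    sum(((obs - exp_)^2 / exp_)[exp_ > 0])
  }
  tibble::tibble(g_squared = g2, pearson_x2 = x2, df = 1L)
}
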