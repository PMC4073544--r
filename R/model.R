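# Vectorised forward model: theta matrix (n x 5) -> list of n x 4 cell
# probability matrices. Everything downstream (likelihood, PPM, simulation)
# funnels through here.
cell_prob_matrix <- function(th) {
  d <- th[, 1]; nt <- th[, 2]; g <- th[, 3]; gp <- th[, 4]; h <- th[, 5]
  present <- cbind(
    (1 - d) * (1 - g) * h,
    (1 - d) * (1 - g) * (1 - h),
    (1 - d) * g * (1 - h),
    d + (1 - d) * g * h
  )
  absent <- cbind(
    nt + (1 - nt) * gp * h,
    (1 - nt) * gp * (1 - h),
    (1 - nt) * (1 - gp) * (1 - h),
    (1 - nt) * (1 - gp) * h
  )
  list(present = present, absent = absent)
}

#' Category probabilities implied by PD parameters
#'
#' Maps a PD parameter vector forward through the processing tree to the
#' multinomial probabilities of the four confidence categories in each
#' condition. On target-present trials a certain detection (probability
#' `theta_d`) always yields "definitely yes"; otherwise the observer guesses
#' "yes" with probability `theta_g` and uses the high-confidence rating with
#' probability `theta_h`. Target-absent trials mirror this with `theta_nt`
#' and `theta_g_prime`.
#'
#' @param theta A `theta_pd` vector (or coercible).
#' @return A tibble of class `pd_cell_probs` with columns `condition`,
#'   `category`, `prob`; each condition's probabilities sum to one.
#' @examples
#' cell_probabilities(theta_pd(0.578, 0.523, 0.721, 0.421, 0.227))
#' @export
cell_probabilities <- function(theta) {
  theta <- as_theta_pd(theta)
  cp <- cell_prob_matrix(matrix(theta, nrow = 1))
  out <- tibble::tibble(
    condition = rep(c("present", "absent"), each = 4L),
    category = rep(1:4, 2L),
    prob = c(cp$present[1, ], cp$absent[1, ])
  )
  class(out) <- c("pd_cell_probs", class(out))
  out
}

# internal: pd_cell_probs (or data frame) -> list(present=, absent=)
cell_prob_vectors <- function(phi) {
  if (is.list(phi) && !is.data.frame(phi) &&
    all(c("present", "absent") %in% names(phi))) {
    p <- phi$present; q <- phi$absent
  } else {
    if (!all(c("condition", "category", "prob") %in% names(phi))) {
      stop("cell probabilities need columns condition, category, prob",
        call. = FALSE
      )
    }
    pr <- phi[phi$condition == "present", ]
    ab <- phi[phi$condition == "absent", ]
    p <- pr$prob[order(pr$category)]
    q <- ab$prob[order(ab$category)]
  }
  tol <- 1e-12
  for (v in list(p, q)) {
    if (length(v) != 4L || any(v < -tol) || any(v > 1 + tol)) {
      stop("each condition needs 4 probabilities in [0, 1]", call. = FALSE)
    }
    if (abs(sum(v) - 1) > 1e-8) {
      stop("cell probabilities must sum to 1 per condition", call. = FALSE)
    }
  }
  list(present = pmin(pmax(p, 0), 1), absent = pmin(pmax(q, 0), 1))
}

# log-safe multinomial log-likelihood; 0*log(0) = 0, positive count on a
# zero-probability cell gives -Inf
loglik_cells <- function(counts_vec, prob_vec) {
  active <- counts_vec > 0
  if (!any(active)) return(0)
  if (any(prob_vec[active] == 0)) return(-Inf)
  sum(counts_vec[active] * log(prob_vec[active]))
}

#' Multinomial log-likelihood of a PD parameter vector
#'
#' @param counts A `pd_counts` table (see [detection_counts()]).
#' @param theta A `theta_pd` vector (or coercible).
#' @return The joint log-likelihood over both conditions; `-Inf` when a
#'   zero-probability category holds a positive count.
#' @export
log_likelihood <- function(counts, theta) {
  v <- counts_vectors(counts)
  theta <- as_theta_pd(theta)
  cp <- cell_prob_matrix(matrix(theta, nrow = 1))
  loglik_cells(v$present, cp$present[1, ]) +
    loglik_cells(v$absent, cp$absent[1, ])
}

# fast path used by optimisers: theta as plain numeric, counts as vectors
negloglik_raw <- function(theta, x, y) {
  cp <- cell_prob_matrix(matrix(theta, nrow = 1))
  -(sum(x * log(pmax(cp$present[1, ], 1e-300))) +
    sum(y * log(pmax(cp$absent[1, ], 1e-300))))
}

#' Simulate a count table from PD parameters
#'
#' Draws one multinomial sample per condition from the category
#' probabilities implied by `theta`.
#'
#' @param theta A `theta_pd` vector (or coercible).
#' @param n_present,n_absent Number of trials per condition.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A `pd_counts` tibble.
#' @examples
#' sample_counts(theta_pd(0.6, 0.5, 0.7, 0.4, 0.25), 50, 50, seed = 1)
#' @export
sample_counts <- function(theta, n_present, n_absent, seed = NULL) {
  theta <- as_theta_pd(theta)
  stopifnot(n_present >= 0, n_absent >= 0)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, sample_counts(theta, n_present, n_absent)))
  }
  cp <- cell_prob_matrix(matrix(theta, nrow = 1))
  detection_counts(
    present = as.vector(stats::rmultinom(1, n_present, cp$present[1, ])),
    absent = as.vector(stats::rmultinom(1, n_absent, cp$absent[1, ]))
  )
}
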