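# Dirichlet sampler: n draws from Dirichlet(alpha), returned as n x k matrix
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  m <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sw <- rowSums(m)
  # all-zero rows are astronomically unlikely but keep the map total
  sw[sw == 0] <- 1
  m / sw
}

# Vectorised inverse map from cell proportions to PD parameters.
# P, Q: n x 4 matrices of present/absent proportions. theta_h is identified
# twice (the guess-no split in the present tree, the guess-yes split in the
# absent tree); the count-weighted pooled ratio below coincides with the
# exact profile MLE when applied to observed proportions.
ppm_map_matrix <- function(P, Q, n_present, n_absent) {
  num <- n_present * P[, 1] + n_absent * Q[, 4]
  den <- n_present * (P[, 1] + P[, 2]) + n_absent * (Q[, 3] + Q[, 4])
  h <- num / den
  one_minus_d <- P[, 1] + P[, 2] + P[, 3] / (1 - h)
  g <- (P[, 3] / (1 - h)) / one_minus_d
  one_minus_nt <- Q[, 3] + Q[, 4] + Q[, 2] / (1 - h)
  gp <- (Q[, 2] / (1 - h)) / one_minus_nt
  theta <- cbind(
    theta_d = 1 - one_minus_d, theta_nt = 1 - one_minus_nt,
    theta_g = g, theta_g_prime = gp, theta_h = h
  )
  coherent <- is.finite(h) & h >= 0 & h < 1 &
    is.finite(one_minus_d) & one_minus_d <= 1 & one_minus_d >= 0 &
    is.finite(one_minus_nt) & one_minus_nt <= 1 & one_minus_nt >= 0 &
    is.finite(g) & g >= 0 & g <= 1 &
    is.finite(gp) & gp >= 0 & gp <= 1
  list(theta = theta, coherent = coherent)
}

#' Invert cell proportions to PD parameters
#'
#' The inverse of [cell_probabilities()], as used by the population
#' parameter mapping (PPM) sampler: given a joint draw of category
#' proportions for both conditions, solve the tree equations for the five
#' parameters. Because `theta_h` is constrained by two independent binomial
#' splits, it is recovered by the count-weighted pooled ratio
#' \eqn{h = (N_x\phi_1 + N_y\phi'_4) / (N_x(\phi_1+\phi_2) +
#' N_y(\phi'_3+\phi'_4))}. A proportion vector whose mapped parameters do
#' not all lie in \eqn{[0,1]} is *incoherent*: it cannot have been produced
#' by any PD parameter vector under this mapping.
#'
#' @param phi Cell probabilities: a `pd_cell_probs` tibble or a list with
#'   `present` and `absent` probability 4-vectors.
#' @param n_present,n_absent Condition sample sizes (weights for the pooled
#'   `theta_h` ratio).
#' @return A list with `theta` (a `theta_pd`, or `NULL` when incoherent)
#'   and logical `coherent`.
#' @examples
#' th <- theta_pd(0.5, 0.5, 0.7, 0.4, 0.25)
#' map_phi_to_theta(cell_probabilities(th), 50, 50)$theta
#' @export
map_phi_to_theta <- function(phi, n_present, n_absent) {
  v <- cell_prob_vectors(phi)
  m <- ppm_map_matrix(
    matrix(v$present, nrow = 1), matrix(v$absent, nrow = 1),
    n_present, n_absent
  )
  if (!m$coherent[1]) {
    return(list(theta = NULL, coherent = FALSE))
  }
  list(theta = as_theta_pd(pmin(pmax(m$theta[1, ], 0), 1)), coherent = TRUE)
}

#' Exact Bayesian fit by population parameter mapping (PPM)
#'
#' Samples category proportions for each condition from its Dirichlet
#' posterior, maps every joint draw to PD parameters with
#' [map_phi_to_theta()], and retains the coherent draws. The retained
#' fraction estimates the model's *coherence probability* - the posterior
#' probability that the observed proportions are reachable by the PD tree
#' at all. Unlike Markov chain sampling, the draws are exact, independent
#' and need no burn-in.
#'
#' The default prior adds `prior = 1/2` (Jeffreys-style) to each cell
#' count; `prior = 1` gives the uniform Dirichlet prior.
#'
#' @param counts A `pd_counts` table.
#' @param n_samples Number of posterior draws to attempt.
#' @param prior Dirichlet prior concentration added to every cell.
#' @param level Credible-interval level.
#' @param seed Optional integer seed for reproducible draws.
#' @return An object of class `c("pd_ppm", "pd_posterior")`: retained
#'   `draws` (matrix with one column per parameter), posterior-mean
#'   `theta`, central credible `intervals`, `coherence` (retained /
#'   requested), `n_requested`, `n_retained`, `method`, `seed`.
#' @examples
#' fit <- fit_ppm(radiology_scans(), n_samples = 5000, seed = 1)
#' glance(fit)
#' @export
fit_ppm <- function(counts, n_samples = 20000, prior = 0.5, level = 0.95,
                    seed = NULL) {
  stopifnot(n_samples >= 1, prior >= 0, level > 0, level < 1)
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      fit_ppm(counts, n_samples, prior, level, seed = NULL)
    ) |> set_posterior_seed(seed))
  }
  v <- counts_vectors(counts)
  P <- rdirichlet_mat(n_samples, v$present + prior)
  Q <- rdirichlet_mat(n_samples, v$absent + prior)
  n_x <- sum(v$present)
  n_y <- sum(v$absent)
  if (n_x + n_y == 0) {
    n_x <- n_y <- 1 # empty table: weight the two theta_h splits equally
  }
  m <- ppm_map_matrix(P, Q, n_x, n_y)
  draws <- m$theta[m$coherent, , drop = FALSE]
  if (nrow(draws) == 0L) {
    stop(
      "no coherent PPM draws (coherence probability ~ 0 of ", n_samples,
      " samples); the PD model cannot reach the observed proportions",
      call. = FALSE
    )
  }
  draws <- pmin(pmax(draws, 0), 1)
  new_pd_posterior(
    draws = draws, method = "ppm", level = level,
    coherence = nrow(draws) / n_samples,
    n_requested = as.integer(n_samples), counts = counts, seed = seed
  )
}

set_posterior_seed <- function(fit, seed) {
  fit$seed <- seed
  fit
}

new_pd_posterior <- function(draws, method, level, coherence, n_requested,
                             counts, seed = NULL) {
  colnames(draws) <- .theta_names
  q <- apply(draws, 2, stats::quantile,
    probs = c((1 - level) / 2, 1 - (1 - level) / 2)
  )
  intervals <- tibble::tibble(
    parameter = .theta_names,
    lower = q[1, ], upper = q[2, ], level = level
  )
  structure(
    list(
      draws = draws,
      theta = as_theta_pd(colMeans(draws)),
      intervals = intervals,
      coherence = coherence,
      n_requested = n_requested,
      n_retained = nrow(draws),
      method = method,
      counts = counts,
      seed = seed
    ),
    class = c(paste0("pd_", method), "pd_posterior")
  )
}
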