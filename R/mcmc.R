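#' Bayesian fit by Markov chain Monte Carlo
#'
#' Samples the PD posterior under independent uniform priors on all five
#' parameters using single-site random-walk Metropolis on the logit scale:
#' each parameter in turn receives a Gaussian perturbation of its logit
#' (the uniform prior contributes the logistic Jacobian to the target
#' density). The posterior is five-dimensional and unimodal with a cheap
#' multinomial likelihood, so this simple sampler mixes well.
#'
#' @param counts A `pd_counts` table.
#' @param n_iter Total iterations (sweeps over the five parameters).
#' @param n_burn Burn-in iterations discarded from the front.
#' @param proposal_sd Standard deviation of the logit-scale random walk.
#' @param level Credible-interval level.
#' @param seed Optional integer seed.
#' @return An object of class `c("pd_mcmc", "pd_posterior")`; see
#'   [fit_ppm()] for the fields. `coherence` is 1 by construction.
#' @examples
#' fit <- fit_mcmc(radiology_scans(), n_iter = 2000, n_burn = 500, seed = 1)
#' tidy(fit)
#' @export
fit_mcmc <- function(counts, n_iter = 20000, n_burn = 5000,
                     proposal_sd = 0.5, level = 0.95, seed = NULL) {
  stopifnot(n_iter > n_burn, n_burn >= 0, proposal_sd > 0)
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      fit_mcmc(counts, n_iter, n_burn, proposal_sd, level, seed = NULL)
    ) |> set_posterior_seed(seed))
  }
  v <- counts_vectors(counts)
  x <- v$present; y <- v$absent

  logpost <- function(z) {
    th <- stats::plogis(z)
    cp <- cell_prob_matrix(matrix(th, nrow = 1))
    ll <- loglik_cells(x, cp$present[1, ]) + loglik_cells(y, cp$absent[1, ])
    ll + sum(log(th) + log1p(-th)) # logistic Jacobian (uniform prior on theta)
  }

  z <- rep(0, 5) # theta = 0.5 everywhere
  cur <- logpost(z)
  if (!is.finite(cur)) {
    for (k in 1:100) {
      z_try <- stats::qlogis(stats::runif(5, 0.05, 0.95))
      cur_try <- logpost(z_try)
      if (is.finite(cur_try)) {
        z <- z_try; cur <- cur_try
        break
      }
    }
    if (!is.finite(cur)) {
      stop("could not find a starting point with finite posterior density",
        call. = FALSE
      )
    }
  }

  draws <- matrix(NA_real_, n_iter, 5)
  noise <- matrix(stats::rnorm(n_iter * 5, sd = proposal_sd), n_iter, 5)
  logu <- matrix(log(stats::runif(n_iter * 5)), n_iter, 5)
  for (i in seq_len(n_iter)) {
    for (j in 1:5) {
      z_prop <- z
      z_prop[j] <- z[j] + noise[i, j]
      lp <- logpost(z_prop)
      if (logu[i, j] < lp - cur) {
        z <- z_prop
        cur <- lp
      }
    }
    draws[i, ] <- stats::plogis(z)
  }
  kept <- draws[(n_burn + 1):n_iter, , drop = FALSE]
  new_pd_posterior(
    draws = kept, method = "mcmc", level = level,
    coherence = 1, n_requested = nrow(kept), counts = counts, seed = seed
  )
}
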