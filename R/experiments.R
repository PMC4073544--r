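# Fast point estimators on raw count vectors, used inside the Monte Carlo
# experiments where constructing tibbles per replicate would dominate.

mle_point <- function(x, y) {
  est <- closed_form_mle(x, y)
  if (all(is.finite(est)) && all(est >= 0) && all(est <= 1)) {
    return(est)
  }
  numerical_mle(x, y)
}

ppm_point <- function(x, y, n_samples = 2000, prior = 0.5) {
  n_x <- sum(x); n_y <- sum(y)
  for (attempt in 1:3) {
    P <- rdirichlet_mat(n_samples, x + prior)
    Q <- rdirichlet_mat(n_samples, y + prior)
    m <- ppm_map_matrix(P, Q, n_x, n_y)
    if (any(m$coherent)) {
      return(pmin(pmax(colMeans(m$theta[m$coherent, , drop = FALSE]), 0), 1))
    }
    n_samples <- n_samples * 4L
  }
  # essentially incoherent data: fall back to the clamped map of the mean draw
  pmin(pmax(colMeans(m$theta), 0), 1)
}

estimate_point <- function(x, y, method, n_samples, prior) {
  switch(method,
    mle = mle_point(x, y),
    ppm = ppm_point(x, y, n_samples, prior),
    stop("unknown estimation method '", method, "'", call. = FALSE)
  )
}

#' Monte Carlo accuracy of PPM and MLE point estimates
#'
#' For each replicate a true parameter vector is drawn i.i.d. uniform on
#' \eqn{[0,1]} per parameter, `n` trials are simulated per condition, and
#' the absolute estimation error is recorded for every parameter under
#' each estimator (PPM posterior mean and MLE). Reports the mean (MAE) and
#' standard deviation (SDE) of the absolute errors.
#'
#' @param n_list Trials per condition; one Monte Carlo table row each.
#' @param reps Replicates per sample size.
#' @param methods Estimators to benchmark (`"ppm"`, `"mle"`).
#' @param n_samples PPM posterior draws per replicate.
#' @param prior PPM Dirichlet prior concentration.
#' @param seed Optional integer seed.
#' @return A tibble of class `pd_benchmark`: `n`, `method`, `parameter`,
#'   `mae`, `sde`, `reps`.
#' @examples
#' run_estimator_accuracy(n_list = 10, reps = 50, seed = 1)
#' @export
run_estimator_accuracy <- function(n_list = c(10, 20, 50, 100), reps = 2000,
                                   methods = c("ppm", "mle"),
                                   n_samples = 2000, prior = 0.5,
                                   seed = NULL) {
  stopifnot(reps >= 1, all(n_list >= 1))
  methods <- match.arg(methods, c("ppm", "mle"), several.ok = TRUE)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, run_estimator_accuracy(
      n_list, reps, methods, n_samples, prior,
      seed = NULL
    )))
  }
  rows <- list()
  for (n in n_list) {
    errs <- lapply(methods, function(m) matrix(NA_real_, reps, 5))
    names(errs) <- methods
    for (r in seq_len(reps)) {
      truth <- stats::runif(5)
      cp <- cell_prob_matrix(matrix(truth, nrow = 1))
      x <- as.vector(stats::rmultinom(1, n, cp$present[1, ]))
      y <- as.vector(stats::rmultinom(1, n, cp$absent[1, ]))
      for (m in methods) {
        errs[[m]][r, ] <- abs(estimate_point(x, y, m, n_samples, prior) - truth)
      }
    }
    for (m in methods) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n = n, method = m, parameter = .theta_names,
        mae = colMeans(errs[[m]]),
        sde = apply(errs[[m]], 2, stats::sd),
        reps = reps
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pd_benchmark", class(out))
  out
}

#' Pooling versus averaging for group-level estimates
#'
#' For every (`n_g`, `n_r`) design cell and replicate: a heterogeneous
#' cohort is generated (each observer's parameter drawn from a Beta with a
#' replicate-level mean, itself uniform, and fixed concentration), the
#' group mean of each parameter is estimated two ways - by averaging
#' per-observer fits and by fitting once to the summed counts - and the
#' absolute errors against the true cohort mean are recorded. The *pooling
#' advantage* is the averaging error minus the pooling error (positive
#' means pooling is more accurate).
#'
#' @param n_g_list,n_r_list Observers per group and trials per condition.
#' @param reps Replicates per design cell.
#' @param method Point estimator for both routes (`"ppm"` or `"mle"`).
#' @param concentration Beta concentration of the between-observer spread
#'   (larger = more homogeneous cohorts).
#' @param n_samples,prior PPM settings.
#' @param seed Optional integer seed.
#' @return A tibble of class `pd_benchmark`: one row per design cell and
#'   parameter with `averaging_error`, `pooling_error`, `advantage`.
#' @export
run_pooling_vs_averaging <- function(n_g_list = c(20, 40, 80),
                                     n_r_list = c(20, 50, 100, 400),
                                     reps = 100, method = c("ppm", "mle"),
                                     concentration = 32,
                                     n_samples = 1000, prior = 0.5,
                                     seed = NULL) {
  method <- match.arg(method)
  stopifnot(reps >= 1, concentration > 0)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, run_pooling_vs_averaging(
      n_g_list, n_r_list, reps, method, concentration, n_samples, prior,
      seed = NULL
    )))
  }
  rows <- list()
  for (n_g in n_g_list) {
    for (n_r in n_r_list) {
      avg_err <- pool_err <- matrix(NA_real_, reps, 5)
      for (r in seq_len(reps)) {
        mu <- stats::runif(5)
        truths <- vapply(mu, function(m) {
          stats::rbeta(n_g, m * concentration, (1 - m) * concentration)
        }, numeric(n_g))
        truths <- matrix(truths, nrow = n_g)
        true_mean <- colMeans(truths)
        est <- matrix(NA_real_, n_g, 5)
        xs <- ys <- matrix(0, n_g, 4)
        for (i in seq_len(n_g)) {
          cp <- cell_prob_matrix(truths[i, , drop = FALSE])
          xs[i, ] <- as.vector(stats::rmultinom(1, n_r, cp$present[1, ]))
          ys[i, ] <- as.vector(stats::rmultinom(1, n_r, cp$absent[1, ]))
          est[i, ] <- estimate_point(xs[i, ], ys[i, ], method, n_samples, prior)
        }
        pooled <- estimate_point(
          colSums(xs), colSums(ys), method, n_samples, prior
        )
        avg_err[r, ] <- abs(colMeans(est) - true_mean)
        pool_err[r, ] <- abs(pooled - true_mean)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_g = n_g, n_r = n_r, parameter = .theta_names,
        averaging_error = colMeans(avg_err),
        pooling_error = colMeans(pool_err),
        advantage = colMeans(avg_err) - colMeans(pool_err),
        reps = reps
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pd_benchmark", class(out))
  out
}

#' The 90-observer shrinkage experiment
#'
#' Replicates the individual-difference benchmark: generate the
#' [shrinkage_design()] cohort, estimate every observer separately,
#' compute the pooled fit and the [adjusted_estimates()], and score both
#' sets of individual estimates by the root-mean-square distance between
#' the estimated and true (`theta_d`, `theta_nt`) points:
#' \eqn{\mathrm{rms} = \sqrt{\tfrac1{n_g}\sum_i
#' [(\hat\theta_{di}-\theta_{di})^2 + (\hat\theta_{nti}-\theta_{nti})^2]}.}
#'
#' `group = "cohort"` pools across all observers (one common shift);
#' `group = "cell"` pools within each 3 x 3 design cell, so the shift
#' corrects cell-specific estimation bias.
#'
#' @param reps Number of cohort replications.
#' @param estimator Individual-observer estimator (`"ppm"` or `"mle"`).
#' @param group Pooling scope for the adjustment.
#' @param design The cohort design (defaults to [shrinkage_design()]).
#' @param n_samples,prior PPM settings.
#' @param seed Optional integer seed.
#' @return A tibble of class `pd_shrinkage` with one row per replication:
#'   `rep`, `rms_individual`, `rms_adjusted`, `reduction` (fractional rms
#'   reduction achieved by the adjustment).
#' @examples
#' run_shrinkage_experiment(reps = 2, seed = 1)
#' @export
run_shrinkage_experiment <- function(reps = 10, estimator = c("ppm", "mle"),
                                     group = c("cohort", "cell"),
                                     design = shrinkage_design(),
                                     n_samples = 2000, prior = 0.5,
                                     seed = NULL) {
  estimator <- match.arg(estimator)
  group <- match.arg(group)
  stopifnot(reps >= 1)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, run_shrinkage_experiment(
      reps, estimator, group, design, n_samples, prior,
      seed = NULL
    )))
  }
  rms <- function(est, truth) {
    sqrt(mean((est[, 1] - truth[, 1])^2 + (est[, 2] - truth[, 2])^2))
  }
  out <- lapply(seq_len(reps), function(r) {
    cohort <- generate_cohort(design)
    truth <- as.matrix(cohort[, .theta_names])
    vs <- lapply(cohort$counts, counts_vectors)
    est <- t(vapply(vs, function(v) {
      estimate_point(v$present, v$absent, estimator, n_samples, prior)
    }, numeric(5)))
    colnames(est) <- .theta_names
    adj <- est
    groups <- if (group == "cell") cohort$group else rep(1L, nrow(cohort))
    for (gr in unique(groups)) {
      idx <- which(groups == gr)
      pooled <- estimate_point(
        Reduce(`+`, lapply(vs[idx], `[[`, "present")),
        Reduce(`+`, lapply(vs[idx], `[[`, "absent")),
        estimator, n_samples, prior
      )
      adj[idx, ] <- sweep(
        est[idx, , drop = FALSE], 2,
        pooled - colMeans(est[idx, , drop = FALSE]), `+`
      )
    }
    ri <- rms(est, truth)
    ra <- rms(adj, truth)
    tibble::tibble(
      rep = r, rms_individual = ri, rms_adjusted = ra,
      reduction = 1 - ra / ri
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("pd_shrinkage", class(out))
  out
}
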