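#' Design of a simulated observer cohort
#'
#' Describes how a group of simulated observers is generated: how many
#' observers, how many trials per condition each contributes, and the
#' distribution of each PD parameter across observers.
#'
#' Each element of `truth_spec` (named after the five parameters) may be:
#' the string `"uniform"` (i.i.d. uniform on \eqn{[0,1]}); a numeric vector
#' recycled across observers (a single value makes the cohort homogeneous
#' in that parameter; a length-`n_g` vector fixes a grid); a list
#' `list(beta = c(a, b))` for i.i.d. Beta(a, b) draws; or a function
#' `f(n)` returning `n` draws.
#'
#' @param n_g Number of observers.
#' @param n_r Trials per condition per observer.
#' @param truth_spec Named list over the five parameters; see Details.
#' @param groups Optional integer vector of length `n_g` labelling
#'   subgroups of the cohort (used by per-group pooling).
#' @param seed Optional integer seed used by [generate_cohort()].
#' @return A list of class `pd_cohort_design`.
#' @seealso [shrinkage_design()] for the 90-observer benchmark design.
#' @export
cohort_design <- function(n_g, n_r,
                          truth_spec = stats::setNames(
                            as.list(rep("uniform", 5)), .theta_names
                          ),
                          groups = NULL, seed = NULL) {
  stopifnot(n_g >= 1, n_r >= 1)
  if (!all(.theta_names %in% names(truth_spec))) {
    stop("truth_spec must name all five PD parameters", call. = FALSE)
  }
  if (!is.null(groups)) stopifnot(length(groups) == n_g)
  structure(
    list(
      n_g = as.integer(n_g), n_r = as.integer(n_r),
      truth_spec = truth_spec[.theta_names],
      groups = groups, seed = seed
    ),
    class = "pd_cohort_design"
  )
}

draw_truth_values <- function(spec, n) {
  if (is.character(spec) && identical(spec, "uniform")) {
    return(stats::runif(n))
  }
  if (is.function(spec)) {
    return(spec(n))
  }
  if (is.list(spec) && !is.null(spec$beta)) {
    stopifnot(all(spec$beta > 0))
    return(stats::rbeta(n, spec$beta[1], spec$beta[2]))
  }
  rep_len(as.numeric(spec), n)
}

#' The 90-observer shrinkage benchmark design
#'
#' Ten observers for each of the 3 x 3 combinations of
#' `theta_d`, `theta_nt` in \{0.2, 0.5, 0.8\}; for every observer
#' `theta_h` ~ Beta(2, 4) and `theta_g`, `theta_g_prime` ~ Beta(28, 14);
#' 20 trials per condition. The design-cell label is stored in `groups`.
#'
#' @param n_per_cell Observers per design cell.
#' @param n_r Trials per condition per observer.
#' @param levels Grid values for `theta_d` and `theta_nt`.
#' @param seed Optional integer seed.
#' @return A `pd_cohort_design`.
#' @export
shrinkage_design <- function(n_per_cell = 10, n_r = 20,
                             levels = c(0.2, 0.5, 0.8), seed = NULL) {
  cells <- expand.grid(theta_d = levels, theta_nt = levels)
  groups <- rep(seq_len(nrow(cells)), times = n_per_cell)
  cohort_design(
    n_g = length(groups), n_r = n_r,
    truth_spec = list(
      theta_d = cells$theta_d[groups],
      theta_nt = cells$theta_nt[groups],
      theta_g = list(beta = c(28, 14)),
      theta_g_prime = list(beta = c(28, 14)),
      theta_h = list(beta = c(2, 4))
    ),
    groups = groups, seed = seed
  )
}

#' Generate a cohort of simulated observers
#'
#' Draws each observer's true PD parameters from the design's
#' `truth_spec`, then simulates that observer's count table with
#' [sample_counts()].
#'
#' @param design A `pd_cohort_design`.
#' @return A tibble with one row per observer: `observer`, `group`, the
#'   five true parameter columns, and a `counts` list-column of
#'   `pd_counts` tables.
#' @examples
#' cohort <- generate_cohort(cohort_design(5, 50, seed = 1))
#' pooled_fit(cohort)
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "pd_cohort_design"))
  if (!is.null(design$seed)) {
    design2 <- design
    design2$seed <- NULL
    return(withr::with_seed(design$seed, generate_cohort(design2)))
  }
  n <- design$n_g
  truths <- vapply(
    design$truth_spec, draw_truth_values,
    numeric(n), n = n
  )
  truths <- matrix(truths, nrow = n, dimnames = list(NULL, .theta_names))
  counts <- lapply(seq_len(n), function(i) {
    sample_counts(as_theta_pd(truths[i, ]), design$n_r, design$n_r)
  })
  out <- tibble::as_tibble(as.data.frame(truths))
  out <- tibble::add_column(out,
    observer = seq_len(n),
    group = if (is.null(design$groups)) rep(1L, n) else design$groups,
    .before = 1
  )
  out$counts <- counts
  out
}

# sum the count tables of a cohort tibble (or list of pd_counts)
sum_cohort_counts <- function(cohort) {
  tables <- if (is.data.frame(cohort)) cohort$counts else cohort
  vs <- lapply(tables, counts_vectors)
  detection_counts(
    present = Reduce(`+`, lapply(vs, `[[`, "present")),
    absent = Reduce(`+`, lapply(vs, `[[`, "absent"))
  )
}

#' Fit the PD model to a cohort's pooled counts
#'
#' Sums the response counts over all observers cell by cell and fits the
#' model once to the pooled table.
#'
#' @param cohort A cohort tibble from [generate_cohort()] (or a list of
#'   `pd_counts` tables).
#' @param method `"mle"` or `"ppm"`.
#' @param ... Passed on to [fit_mle()] or [fit_ppm()].
#' @return The fit object ([fit_mle()] or [fit_ppm()]).
#' @export
pooled_fit <- function(cohort, method = c("mle", "ppm"), ...) {
  method <- match.arg(method)
  pooled <- sum_cohort_counts(cohort)
  switch(method,
    mle = fit_mle(pooled),
    ppm = fit_ppm(pooled, ...)
  )
}

#' Group-adjusted ("shrinkage") individual estimates
#'
#' Shifts every observer's estimate by the common constant
#' `pooled - mean(individual)` per parameter, so that the mean of the
#' adjusted estimates equals the pooled-data estimate exactly. The
#' adjustment is affine, so individual differences are preserved
#' (adjusted and raw estimates correlate perfectly); it trades a small
#' common shift for the greater accuracy of the pooled fit, in the spirit
#' of James-Stein shrinkage.
#'
#' @param individual A data frame with one row per observer containing the
#'   five parameter columns (e.g. individual fits stacked with [tidy()]).
#' @param pooled The pooled estimate: a `theta_pd`, a fit object, or
#'   anything [as_theta_pd()] accepts.
#' @param clip If `TRUE`, clip adjusted values into \eqn{[0,1]} (breaks
#'   the exact mean identity; off by default).
#' @return An object of class `pd_cohort_estimates`: a list with
#'   `individual`, `adjusted` (tibbles), `pooled`, `group_mean`, `shift`.
#' @export
adjusted_estimates <- function(individual, pooled, clip = FALSE) {
  if (!is.data.frame(individual) || nrow(individual) == 0L) {
    stop("individual estimates must be a non-empty data frame", call. = FALSE)
  }
  if (!all(.theta_names %in% names(individual))) {
    stop("individual estimates need the five theta_* columns", call. = FALSE)
  }
  if (inherits(pooled, "pd_fit") || inherits(pooled, "pd_posterior")) {
    pooled <- pooled$theta
  }
  pooled <- as_theta_pd(pooled)
  est <- as.matrix(individual[, .theta_names])
  group_mean <- colMeans(est)
  shift <- unclass(pooled) - group_mean
  adj <- sweep(est, 2, shift, `+`)
  if (clip) adj <- pmin(pmax(adj, 0), 1)
  adjusted <- individual
  adjusted[, .theta_names] <- adj
  structure(
    list(
      individual = tibble::as_tibble(individual),
      adjusted = tibble::as_tibble(adjusted),
      pooled = pooled,
      group_mean = group_mean,
      shift = shift
    ),
    class = "pd_cohort_estimates"
  )
}
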