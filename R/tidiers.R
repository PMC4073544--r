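#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PD maximum-likelihood fit
#'
#' @param x A `pd_mle` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `boundary`.
#' @export
tidy.pd_mle <- function(x, ...) {
  tibble::tibble(
    term = .theta_names,
    estimate = as.numeric(x$theta),
    boundary = unname(x$boundary_flags)
  )
}

#' @export
glance.pd_mle <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    g_squared = x$g_squared,
    pearson_x2 = x$pearson_x2,
    df = x$df,
    logLik = x$loglik
  )
}

#' Tidy a PD posterior fit
#'
#' @param x A `pd_posterior` object from [fit_ppm()] or [fit_mcmc()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (posterior mean), `conf.low`,
#'   `conf.high` (central credible interval).
#' @export
tidy.pd_posterior <- function(x, ...) {
  tibble::tibble(
    term = .theta_names,
    estimate = as.numeric(x$theta),
    conf.low = x$intervals$lower,
    conf.high = x$intervals$upper
  )
}

#' @export
glance.pd_posterior <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    coherence = x$coherence,
    n_requested = x$n_requested,
    n_retained = x$n_retained
  )
}

#' @export
tidy.pd_sdt <- function(x, ...) {
  tibble::tibble(
    term = c("d_prime", "sigma_ratio", paste0("c", 1:3)),
    estimate = c(x$d_prime, x$sigma_ratio, x$criteria)
  )
}

#' @export
glance.pd_sdt <- function(x, ...) {
  tibble::tibble(
    method = "sdt",
    g_squared = x$g_squared,
    pearson_x2 = x$pearson_x2,
    df = x$df,
    logLik = x$loglik,
    identifiable = x$identifiable
  )
}
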