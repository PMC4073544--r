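#' Posterior probability that a parameter exceeds a threshold
#'
#' Fraction of retained posterior draws with `parameter > threshold`, e.g.
#' the mixture question "is certain detection really present?" phrased as
#' `P(theta_d > 0.39)`.
#'
#' @param result A `pd_posterior` fit from [fit_ppm()] or [fit_mcmc()].
#' @param parameter One of `"theta_d"`, `"theta_nt"`, `"theta_g"`,
#'   `"theta_g_prime"`, `"theta_h"`.
#' @param threshold Threshold value.
#' @return A probability in \eqn{[0, 1]}.
#' @examples
#' fit <- fit_mcmc(radiology_scans(), n_iter = 2000, n_burn = 500, seed = 1)
#' posterior_probability(fit, "theta_d", 0.39)
#' @export
posterior_probability <- function(result, parameter, threshold) {
  stopifnot(inherits(result, "pd_posterior"))
  if (!parameter %in% .theta_names) {
    stop(
      "unknown parameter '", parameter, "'; expected one of: ",
      paste(.theta_names, collapse = ", "),
      call. = FALSE
    )
  }
  mean(result$draws[, parameter] > threshold)
}

#' @export
print.pd_posterior <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<PD %s posterior> %d retained draws", toupper(x$method), x$n_retained
  ))
  if (x$method == "ppm") {
    cat(sprintf(" (coherence %.3f)", x$coherence))
  }
  cat("\nPosterior means:\n")
  print(round(unclass(x$theta), digits))
  invisible(x)
}

#' @export
print.pd_mle <- function(x, digits = 3, ...) {
  cat("<PD maximum-likelihood fit>\n")
  print(round(unclass(x$theta), digits))
  cat(sprintf(
    "G^2(%d) = %.3f, Pearson X^2 = %.3f\n", x$df, x$g_squared, x$pearson_x2
  ))
  if (any(x$boundary_flags, na.rm = TRUE)) {
    cat(
      "numerical fallback used for:",
      paste(names(which(x$boundary_flags)), collapse = ", "), "\n"
    )
  }
  invisible(x)
}
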