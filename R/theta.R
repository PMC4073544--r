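#' Parameter vector of the perceptual-detection (PD) model
#'
#' The PD model is a multinomial processing tree for two-condition
#' (target-present / target-absent) detection experiments with four ordered
#' confidence categories. It has five probability parameters:
#'
#' \describe{
#'   \item{`theta_d`}{probability of certain target detection on a
#'     target-present trial (the target-present mixing rate).}
#'   \item{`theta_nt`}{probability of confidently identifying a non-target on
#'     a target-absent trial (the target-absent mixing rate).}
#'   \item{`theta_g`}{probability of guessing "yes" on a target-present trial
#'     when the target was not detected.}
#'   \item{`theta_g_prime`}{probability of guessing "no" on a target-absent
#'     trial when the non-target was not identified.}
#'   \item{`theta_h`}{probability of (over-confidently) using the
#'     high-confidence rating when guessing; shared across conditions.}
#' }
#'
#' @param theta_d,theta_nt,theta_g,theta_g_prime,theta_h Probabilities in
#'   \eqn{[0, 1]}.
#' @return A named numeric vector of class `theta_pd`.
#' @examples
#' theta_pd(0.578, 0.523, 0.721, 0.421, 0.227)
#' @export
theta_pd <- function(theta_d, theta_nt, theta_g, theta_g_prime, theta_h) {
  as_theta_pd(c(
    theta_d = theta_d, theta_nt = theta_nt, theta_g = theta_g,
    theta_g_prime = theta_g_prime, theta_h = theta_h
  ))
}

.theta_names <- c("theta_d", "theta_nt", "theta_g", "theta_g_prime", "theta_h")

#' Coerce to a `theta_pd` parameter vector
#'
#' Accepts a numeric vector of length five (in the order
#' `theta_d`, `theta_nt`, `theta_g`, `theta_g_prime`, `theta_h`, or fully
#' named in any order), a list, or a one-row data frame with those columns.
#'
#' @param x Object to coerce.
#' @return A `theta_pd` vector.
#' @export
as_theta_pd <- function(x) {
  if (inherits(x, "theta_pd")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single row of parameter values", call. = FALSE)
    x <- unlist(x[, intersect(names(x), .theta_names)])
  }
  x <- unlist(x)
  if (length(x) != 5L) stop("a PD parameter vector has exactly 5 elements", call. = FALSE)
  if (!is.null(names(x)) && all(.theta_names %in% names(x))) {
    x <- x[.theta_names]
  } else {
    names(x) <- .theta_names
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("PD parameters must be probabilities in [0, 1]", call. = FALSE)
  }
  structure(as.numeric(stats::setNames(x, .theta_names)),
    names = .theta_names, class = "theta_pd"
  )
}

#' @export
print.theta_pd <- function(x, digits = 3, ...) {
  cat("<theta_pd>\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Compare guessing to pure response bias
#'
#' Returns \eqn{\gamma = \theta_g - (1 - \theta_g')}. Under pure response
#' bias the "yes"-guess rate is the same in both conditions, so
#' \eqn{\gamma = 0}; \eqn{\gamma > 0} indicates informed (partial-information)
#' guessing: the observer guesses "yes" more often when a target really is
#' present.
#'
#' @param theta A `theta_pd` vector (or anything `as_theta_pd()` accepts).
#' @return A single signed number in \eqn{[-1, 1]}.
#' @examples
#' guessing_assessment(theta_pd(0.552, 0.496, 0.734, 0.405, 0.25))
#' @export
guessing_assessment <- function(theta) {
  theta <- as_theta_pd(theta)
  unname(theta["theta_g"] - (1 - theta["theta_g_prime"]))
}
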