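#' ROC operating points of the PD model
#'
#' The PD model's receiver operating characteristic is a two-limb polygon,
#' not a smooth curve. Sweeping the response criterion from strictest to
#' most lax gives seven key points in (false-alarm, hit) space: the corners
#' \eqn{P_0 = (0,0)} and \eqn{P_6 = (1,1)}, the extreme model points
#' \eqn{P_1 = (0, \theta_d)} and \eqn{P_5 = (1-\theta_{nt}, 1)}, and the
#' three observable operating points \eqn{P_2} (high-confidence "yes"),
#' \eqn{P_3} (any "yes") and \eqn{P_4} (anything but a high-confidence
#' "no").
#'
#' @param theta A `theta_pd` vector (or coercible).
#' @return A tibble of class `pd_roc` with columns `point`, `x`
#'   (false-alarm rate) and `y` (hit rate), ordered P0..P6.
#' @examples
#' operating_points(theta_pd(0.578, 0.523, 0.721, 0.421, 0.227))
#' @export
operating_points <- function(theta) {
  th <- as_theta_pd(theta)
  d <- th[["theta_d"]]; nt <- th[["theta_nt"]]
  g <- th[["theta_g"]]; gp <- th[["theta_g_prime"]]; h <- th[["theta_h"]]
  out <- tibble::tibble(
    point = paste0("P", 0:6),
    x = c(
      0, 0,
      (1 - nt) * (1 - gp) * h,
      (1 - nt) * (1 - gp),
      (1 - nt) * (1 - gp * h),
      1 - nt, 1
    ),
    y = c(
      0, d,
      d + (1 - d) * g * h,
      d + (1 - d) * g,
      d + (1 - d) * (1 - (1 - g) * h),
      1, 1
    )
  )
  class(out) <- c("pd_roc", class(out))
  attr(out, "theta") <- th
  out
}

#' Points on the two linear limbs of the PD ROC
#'
#' The lower limb (`"v"`) runs from \eqn{P_1} to \eqn{P_3} as a
#' hypothetical risk variable \eqn{v} goes 0 to 1; the upper limb (`"w"`)
#' runs from \eqn{P_3} to \eqn{P_5}. Setting \eqn{v = \theta_h} lands on
#' \eqn{P_2} and \eqn{w = 1 - \theta_h} on \eqn{P_4}.
#'
#' @param theta A `theta_pd` vector (or coercible).
#' @param limb `"v"` (lower limb) or `"w"` (upper limb).
#' @param t Risk-variable values in \eqn{[0, 1]} (vectorised).
#' @return A tibble with columns `limb`, `t`, `x`, `y`.
#' @export
roc_path <- function(theta, limb = c("v", "w"), t) {
  limb <- match.arg(limb)
  stopifnot(all(t >= 0 & t <= 1))
  th <- as_theta_pd(theta)
  d <- th[["theta_d"]]; nt <- th[["theta_nt"]]
  g <- th[["theta_g"]]; gp <- th[["theta_g_prime"]]
  if (limb == "v") {
    x <- (1 - nt) * (1 - gp) * t
    y <- d + (1 - d) * g * t
  } else {
    x <- (1 - nt) * (1 - gp + gp * t)
    y <- d + (1 - d) * g + (1 - d) * (1 - g) * t
  }
  tibble::tibble(limb = limb, t = t, x = x, y = y)
}

#' Limb slopes of the PD ROC and their ratio
#'
#' The lower limb \eqn{P_1\!-\!P_3} has slope
#' \eqn{s_{13} = (1-\theta_d)\theta_g / [(1-\theta_{nt})(1-\theta_g')]},
#' the upper limb \eqn{P_3\!-\!P_5} has slope
#' \eqn{s_{35} = (1-\theta_d)(1-\theta_g) / [(1-\theta_{nt})\theta_g']},
#' and their ratio reduces to
#' \eqn{r = (1-\theta_g)(1-\theta_g') / (\theta_g \theta_g')}, which is
#' \eqn{\le 1} exactly when guessing is informed
#' (\eqn{\theta_g \ge 1 - \theta_g'}). A limb with zero horizontal extent
#' has an undefined (`NaN`/`Inf`) slope and is flagged.
#'
#' @param theta A `theta_pd` vector (or coercible).
#' @return A one-row tibble with `s13`, `s35`, `r` and logical
#'   `degenerate`.
#' @export
roc_slopes <- function(theta) {
  th <- as_theta_pd(theta)
  d <- th[["theta_d"]]; nt <- th[["theta_nt"]]
  g <- th[["theta_g"]]; gp <- th[["theta_g_prime"]]
  s13 <- (1 - d) * g / ((1 - nt) * (1 - gp))
  s35 <- (1 - d) * (1 - g) / ((1 - nt) * gp)
  r <- (1 - g) * (1 - gp) / (g * gp)
  degenerate <- !is.finite(s13) || !is.finite(s35)
  tibble::tibble(s13 = s13, s35 = s35, r = r, degenerate = degenerate)
}

#' Area-based detection measures of the PD model
#'
#' Twice the area between the PD ROC and the chance diagonal, split into a
#' certain-detection part and an effective-guessing part:
#' \deqn{D_c = \theta_d + \theta_{nt} - \theta_d\theta_{nt},}
#' \deqn{D_g = (1-\theta_{nt})(1-\theta_d)[\theta_g - (1-\theta_g')],}
#' \deqn{D = D_c + D_g.}
#' `D_c` ranges over \eqn{[0,1]} and ignores guessing entirely; `D_g`
#' rescales the \eqn{P_1 P_3 P_5} triangle and is negative when guessing is
#' worse than pure response bias (a warning is raised but the signed value
#' is kept, preserving the identity `D = D_c + D_g`). `A_c` and `A_g` are
#' the underlying areas (half the `D` values).
#'
#' @param theta A `theta_pd` vector (or coercible).
#' @return A one-row tibble with `D_c`, `D_g`, `D`, `A_c`, `A_g` and
#'   logical `informed` (`D_g >= 0`).
#' @examples
#' area_metrics(theta_pd(0.552, 0.496, 0.734, 0.405, 0.25))
#' @export
area_metrics <- function(theta) {
  th <- as_theta_pd(theta)
  d <- th[["theta_d"]]; nt <- th[["theta_nt"]]
  g <- th[["theta_g"]]; gp <- th[["theta_g_prime"]]
  d_c <- d + nt - d * nt
  d_g <- (1 - nt) * (1 - d) * (g - (1 - gp))
  if (d_g < 0) {
    warning("D_g is negative: guessing is worse than pure response bias",
      call. = FALSE
    )
  }
  tibble::tibble(
    D_c = d_c, D_g = d_g, D = d_c + d_g,
    A_c = d_c / 2, A_g = d_g / 2, informed = d_g >= 0
  )
}
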