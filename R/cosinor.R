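#' Fit a single-component cosinor model
#'
#' Linear least-squares fit of \eqn{y = M + \beta_1 \cos(\omega t) + \beta_2
#' \sin(\omega t)} with \eqn{\omega = 2\pi/\tau} at a fixed period \eqn{\tau}.
#' Mesor \eqn{M}, amplitude \eqn{A = \sqrt{\beta_1^2 + \beta_2^2}} and
#' acrophase \eqn{\phi} (time of the fitted maximum, hours mod \eqn{\tau})
#' are derived from the coefficients. A constant series yields \eqn{A = 0}
#' with acrophase reported as 0 and flagged undefined.
#'
#' @param data Data frame with columns `time_h` and `value`.
#' @param period Fixed period \eqn{\tau}, hours (default 24).
#' @return An object of class `cosinor_fit` with fields `mesor`, `amplitude`,
#'   `acrophase_h`, `period`, `coefficients`, `vcov`, `sigma2`, `n`,
#'   `phase_defined`.
#' @examples
#' d <- tibble::tibble(time_h = 0:23,
#'                     value = 5 + 2 * cos(2 * pi * (0:23 - 18) / 24))
#' fit <- cosinor_fit(d)
#' c(fit$mesor, fit$amplitude, fit$acrophase_h)
#' @export
cosinor_fit <- function(data, period = 24) {
  s <- as_series(data)
  tmods <- unique(round(wrap_hours(s$time_h, period), 9))
  if (nrow(s) < 4 || length(tmods) < 3) {
    abort("need >= 4 observations at >= 3 distinct mod-period times.")
  }
  w <- 2 * pi / period
  X <- cbind(`(Intercept)` = 1, cosw = cos(w * s$time_h),
             sinw = sin(w * s$time_h))
  qx <- qr(X)
  if (qx$rank < 3) abort("collinear cosinor design.")
  fit <- lm(s$value ~ X - 1)
  b <- unname(coef(fit))
  A <- sqrt(b[2]^2 + b[3]^2)
  defined <- A > sqrt(.Machine$double.eps)
  phi <- if (defined) wrap_hours(atan2(b[3], b[2]) / w, period) else 0
  structure(
    list(mesor = b[1], amplitude = A, acrophase_h = phi, period = period,
         coefficients = setNames(b, c("mesor", "cos", "sin")),
         vcov = unname(suppressWarnings(vcov(fit))),
         sigma2 = suppressWarnings(summary(fit))$sigma^2,
         n = nrow(s), phase_defined = defined),
    class = "cosinor_fit"
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf("Cosinor fit (period %g h): mesor %.4g, amplitude %.4g, acrophase %.3g h%s\n",
              x$period, x$mesor, x$amplitude, x$acrophase_h,
              if (x$phase_defined) "" else " (phase undefined)"))
  invisible(x)
}

# Delta-method SEs for amplitude and acrophase from (b1, b2) covariance.
cosinor_derived_se <- function(b1, b2, V, period) {
  A <- sqrt(b1^2 + b2^2)
  gA <- c(b1, b2) / A
  se_A <- sqrt(drop(t(gA) %*% V %*% gA))
  gphi <- c(-b2, b1) / A^2 * period / (2 * pi)
  se_phi <- sqrt(drop(t(gphi) %*% V %*% gphi))
  list(se_A = se_A, se_phi = se_phi)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a cosinor fit
#'
#' @param x A `cosinor_fit`.
#' @param ... Unused.
#' @return A tibble with one row per quantity (mesor, amplitude,
#'   acrophase_h), with delta-method standard errors for the derived terms.
#' @method tidy cosinor_fit
#' @export
tidy.cosinor_fit <- function(x, ...) {
  se_m <- sqrt(x$vcov[1, 1])
  d <- cosinor_derived_se(x$coefficients[2], x$coefficients[3],
                          x$vcov[2:3, 2:3], x$period)
  tibble(
    term = c("mesor", "amplitude", "acrophase_h"),
    estimate = c(x$mesor, x$amplitude, x$acrophase_h),
    std.error = c(se_m, d$se_A, if (x$phase_defined) d$se_phi else NA_real_)
  )
}

#' @rdname tidy.cosinor_fit
#' @method glance cosinor_fit
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble(period = x$period, sigma = sqrt(x$sigma2), nobs = x$n,
         phase_defined = x$phase_defined)
}

#' Compare cosinor rhythms between two groups
#'
#' Joint linear cosinor model with a group indicator interacting with the
#' cosine and sine terms; Wald tests (delta method for the amplitude and
#' acrophase transforms) for the between-group differences in mesor,
#' amplitude and acrophase at a fixed shared period. The phase difference is
#' wrapped to \eqn{(-\tau/2, \tau/2]}.
#'
#' @param data Data frame with columns `time_h`, `value`, `group` (two levels).
#' @param period Shared period, hours (default 24).
#' @return An object of class `cosinor_comparison` with per-group fits and
#'   fields `delta_mesor`, `delta_amplitude`, `delta_phase_h`, `p_mesor`,
#'   `p_amplitude`, `p_phase`, `phase_defined`.
#' @examples
#' t <- rep(0:23, 2)
#' d <- tibble::tibble(time_h = c(t, t),
#'                     value = c(cos(2 * pi * (t - 6) / 24),
#'                               cos(2 * pi * (t - 18) / 24)) + rnorm(96, 0, .1),
#'                     group = rep(c("A", "B"), each = 48))
#' cc <- cosinor_group_comparison(d)
#' cc$delta_phase_h
#' @export
cosinor_group_comparison <- function(data, period = 24) {
  stopifnot(all(c("time_h", "value", "group") %in% names(data)))
  g <- factor(data$group)
  if (nlevels(g) != 2) abort("`group` must have exactly two levels.")
  w <- 2 * pi / period
  cw <- cos(w * data$time_h); sw <- sin(w * data$time_h)
  g2 <- as.numeric(g == levels(g)[2])
  fit <- lm(data$value ~ g2 * cw + g2 * sw)
  b <- coef(fit); V <- suppressWarnings(vcov(fit))
  # order: (Int), g2, cw, sw, g2:cw, g2:sw
  b1 <- c(b["cw"], b["sw"])
  b2 <- b1 + c(b["g2:cw"], b["g2:sw"])
  A1 <- sqrt(sum(b1^2)); A2 <- sqrt(sum(b2^2))
  eps <- sqrt(.Machine$double.eps)
  defined <- A1 > eps && A2 > eps
  phi1 <- wrap_hours(atan2(b1[2], b1[1]) / w, period)
  phi2 <- wrap_hours(atan2(b2[2], b2[1]) / w, period)
  dphi <- wrap_signed(phi2 - phi1, period)

  # delta-method variance of (A2 - A1) and (phi2 - phi1) over all 6 coefs
  gradA <- rep(0, 6); gradP <- rep(0, 6)
  names(gradA) <- names(b)
  if (defined) {
    gA1 <- b1 / A1; gA2 <- b2 / A2
    gradA[c("cw", "sw")] <- gA2 - gA1
    gradA[c("g2:cw", "g2:sw")] <- gA2
    gP1 <- c(-b1[2], b1[1]) / A1^2 * period / (2 * pi)
    gP2 <- c(-b2[2], b2[1]) / A2^2 * period / (2 * pi)
    gradP[c(3, 4)] <- gP2 - gP1
    gradP[c(5, 6)] <- gP2
  }
  se_dA <- sqrt(drop(t(gradA) %*% V %*% gradA))
  se_dP <- sqrt(drop(t(gradP) %*% V %*% gradP))
  dA <- A2 - A1
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(groups = levels(g),
         mesor = c(b[1], b[1] + b["g2"]),
         amplitude = c(A1, A2), acrophase_h = c(phi1, phi2),
         delta_mesor = unname(b["g2"]),
         delta_amplitude = dA, delta_phase_h = dphi,
         se_amplitude = se_dA, se_phase = se_dP,
         p_mesor = sm["g2", 4],
         p_amplitude = if (se_dA > 0) 2 * pnorm(-abs(dA / se_dA)) else NA_real_,
         p_phase = if (defined && se_dP > 0) 2 * pnorm(-abs(dphi / se_dP)) else NA_real_,
         phase_defined = defined, period = period, n = nrow(data)),
    class = "cosinor_comparison"
  )
}

#' @export
print.cosinor_comparison <- function(x, ...) {
  cat(sprintf("Cosinor comparison (%s vs %s, period %g h)\n", x$groups[1],
              x$groups[2], x$period))
  cat(sprintf("  delta mesor     %8.4g  p = %.3g\n", x$delta_mesor, x$p_mesor))
  cat(sprintf("  delta amplitude %8.4g  p = %.3g\n", x$delta_amplitude,
              x$p_amplitude))
  cat(sprintf("  delta phase (h) %8.4g  p = %.3g%s\n", x$delta_phase_h,
              x$p_phase, if (x$phase_defined) "" else " (undefined)"))
  invisible(x)
}

#' Tidy a cosinor group comparison
#'
#' @param x A `cosinor_comparison`.
#' @param ... Unused.
#' @return A tibble with one row per contrast (mesor, amplitude, phase).
#' @method tidy cosinor_comparison
#' @export
tidy.cosinor_comparison <- function(x, ...) {
  tibble(
    term = c("delta_mesor", "delta_amplitude", "delta_phase_h"),
    estimate = c(x$delta_mesor, x$delta_amplitude, x$delta_phase_h),
    std.error = c(NA_real_, x$se_amplitude, x$se_phase),
    p.value = c(x$p_mesor, x$p_amplitude, x$p_phase)
  )
}

#' @rdname tidy.cosinor_comparison
#' @method glance cosinor_comparison
#' @export
glance.cosinor_comparison <- function(x, ...) {
  tibble(period = x$period, nobs = x$n, phase_defined = x$phase_defined)
}
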