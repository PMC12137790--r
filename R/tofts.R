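# Extended Tofts forward models, instantaneous and time-averaged.
#
# With the analytic AIF, every quantity below has a closed form built from
# .convCB (aif.R).  Writing Ktrans = kep * ve, the running integral of the
# leakage term is Ktrans * int_0^t conv(Cp, exp(-kep .)) = ve * (I1 - K),
# where I1 = int_0^t Cp and K = conv(Cp, exp(-kep .)).  This removes all
# divisions by kep, so the kep -> 0 boundary of the fit box is exact.

.check_pk1 <- function(u) {
  stopifnot(is(u, "PKParameters"))
  if (length(u) != 1L)
    stop("a single parameter set is required here; subset with u[i]",
         call. = FALSE)
}

# tissue curve at t [min]
.ct_min <- function(t, u, theta) {
  u@vp * .cp_min(t, theta) +
    u@kep * u@ve * .cpconv_min(t, u@kep, theta)
}

# running integral of the tissue curve, I2(t) = int_0^t C [min]
.ctint_min <- function(t, u, theta) {
  i1 <- .cpint_min(t, theta)
  u@vp * i1 + u@ve * (i1 - .cpconv_min(t, u@kep, theta))
}

#' Extended Tofts tissue concentration
#'
#' The instantaneous (conventional) extended Tofts model:
#' \deqn{C(t) = v_p C_p(t) + K^{trans} \int_0^t C_p(\tau)
#'   e^{-k_{ep}(t-\tau)} d\tau,}
#' with `Ktrans = kep * ve`. The convolution of the analytical AIF with the
#' exponential kernel is evaluated in closed form. Returns 0 for `t <= 0`.
#'
#' @param t time(s) since contrast arrival \[s\].
#' @param u a [PKParameters-class] object of length 1.
#' @param theta an [AIFParameters-class] object.
#' @return Tissue concentration(s) \[mmol/L\].
#' @examples
#' u <- PKParameters(vp = 0.025, ve = 0.3, kep = 1)
#' toftsConcentration(c(30, 60, 120), u)
#' @seealso [averagedToftsConcentration()]
#' @export
toftsConcentration <- function(t, u, theta = AIFParameters()) {
  .check_time(t)
  .check_pk1(u)
  stopifnot(is(theta, "AIFParameters"))
  .ct_min(t * .MIN, u, theta)
}

#' Time-averaged extended Tofts tissue concentration
#'
#' The extended Tofts model convolved with a unit-area rectangle of width
#' `dt` — the forward model for acquisitions that oversample the k-space
#' center, where each frame measures the mean concentration over its window:
#' \deqn{C'(t) = \frac{1}{\Delta t}\int_{t-\Delta t/2}^{t+\Delta t/2}
#'   C(\tau)\, d\tau.}
#'
#' `method = "analytic"` (the production route) exploits the identity that
#' rect-averaging the tissue curve equals evaluating the model with the
#' rect-averaged AIF, and computes the window mean exactly from the
#' closed-form running integral of `C`. `method = "quadrature"` integrates
#' [toftsConcentration()] numerically over the window (adaptive quadrature,
#' relative tolerance 1e-10) and serves as an independent check of the
#' analytic route.
#'
#' @param t window-center time(s) \[s\].
#' @param u a [PKParameters-class] object of length 1.
#' @param theta an [AIFParameters-class] object.
#' @param dt frame duration \[s\], `> 0`.
#' @param method `"analytic"` or `"quadrature"`.
#' @return Time-averaged tissue concentration(s) \[mmol/L\].
#' @examples
#' u <- PKParameters(vp = 0.05, ve = 0.3, kep = 2)
#' averagedToftsConcentration(37.5, u, dt = 15)
#' @seealso [averagedToftsViaConvolvedAif()]
#' @export
averagedToftsConcentration <- function(t, u, theta = AIFParameters(), dt,
                                       method = c("analytic", "quadrature")) {
  .check_time(t)
  .check_pk1(u)
  stopifnot(is(theta, "AIFParameters"))
  method <- match.arg(method)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single duration > 0 (seconds)", call. = FALSE)
  if (method == "analytic") {
    tm <- t * .MIN
    dm <- dt * .MIN
    hi <- pmax(tm + dm / 2, 0)
    lo <- pmax(tm - dm / 2, 0)
    (.ctint_min(hi, u, theta) - .ctint_min(lo, u, theta)) / dm
  } else {
    vapply(t, function(tc) {
      stats::integrate(function(tau) toftsConcentration(tau, u, theta),
                       lower = tc - dt / 2, upper = tc + dt / 2,
                       rel.tol = 1e-10, abs.tol = 1e-13,
                       subdivisions = 400L)$value / dt
    }, numeric(1))
  }
}

#' Time-averaged extended Tofts via the convolved AIF
#'
#' Evaluates the conventional extended Tofts expression with the
#' time-averaged AIF `Cp'` in place of `Cp`:
#' \deqn{C'(t) = v_p C_p'(t) + K^{trans}\int C_p'(\tau)
#'   e^{-k_{ep}(t-\tau)} d\tau,}
#' the equivalent formulation of the rect-convolved model (convolution is
#' associative, so averaging the tissue curve and averaging the AIF commute).
#' The leakage integral runs over the full support of `Cp'`, which begins at
#' `-dt/2`. All terms are closed-form.
#'
#' This route is algebraically identical to
#' `averagedToftsConcentration(method = "analytic")`; it is exposed
#' separately so the equivalence can be exercised against the quadrature
#' route.
#'
#' @inheritParams averagedToftsConcentration
#' @return Time-averaged tissue concentration(s) \[mmol/L\].
#' @export
averagedToftsViaConvolvedAif <- function(t, u, theta = AIFParameters(), dt) {
  .check_time(t)
  .check_pk1(u)
  stopifnot(is(theta, "AIFParameters"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single duration > 0 (seconds)", call. = FALSE)
  tm <- t * .MIN
  dm <- dt * .MIN
  hi <- pmax(tm + dm / 2, 0)
  lo <- pmax(tm - dm / 2, 0)
  # vp * Cp'(t)
  cp_avg <- (.cpint_min(hi, theta) - .cpint_min(lo, theta)) / dm
  # Ktrans * conv(Cp', exp(-kep .)) = ve * window-mean of (I1 - K)
  ik_hi <- .cpint_min(hi, theta) - .cpconv_min(hi, u@kep, theta)
  ik_lo <- .cpint_min(lo, theta) - .cpconv_min(lo, u@kep, theta)
  u@vp * cp_avg + u@ve * (ik_hi - ik_lo) / dm
}
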