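# Analytical AIF: raised-cosine bolus + exponential washout (Orton model).
# All internal time arithmetic is in minutes (PK rates are per minute); the
# exported interface takes seconds. .MIN converts once -- see the methods
# vignette for the unit convention.
.MIN <- 1 / 60

.check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric time(s) in seconds", call. = FALSE)
}

# conv((1 - cos(mb*tau)) * 1[0 < tau <= tB], exp(-alpha*tau))(t), t in min.
# alpha = 0 gives the running integral of the truncated raised cosine.
# Piecewise: inside the bolus (t <= tB = 2*pi/mb) the closed form below;
# beyond tB the bolus has ended, so the value decays as exp(-alpha*(t - tB)).
.convCB <- function(t, alpha, mb) {
  tB <- 2 * pi / mb
  out <- numeric(length(t))
  hfun <- function(tt) {
    if (alpha > 1e-8) {
      (-expm1(-alpha * tt)) / alpha -
        (alpha * cos(mb * tt) + mb * sin(mb * tt) - alpha * exp(-alpha * tt)) /
          (alpha^2 + mb^2)
    } else {
      # alpha -> 0 limit; for alpha <= 1e-8 the omitted terms are O(alpha*t^2)
      tt - sin(mb * tt) / mb
    }
  }
  in_bolus <- t > 0 & t <= tB
  after <- t > tB
  if (any(in_bolus)) out[in_bolus] <- hfun(t[in_bolus])
  if (any(after)) {
    hB <- hfun(tB)
    out[after] <- if (alpha > 1e-8) hB * exp(-alpha * (t[after] - tB)) else hB
  }
  out
}

# [conv(CB, exp(-me*.)) - conv(CB, exp(-a*.))] / (a - me), the washout term
# convolved with exp(-a*.).  Near a == me the quotient is replaced by a
# symmetric finite difference of .convCB in alpha (error O(delta^2)).
.convCB_ratio <- function(t, a, me, mb) {
  if (abs(a - me) > 1e-6) {
    (.convCB(t, me, mb) - .convCB(t, a, mb)) / (a - me)
  } else {
    delta <- 1e-4
    (.convCB(t, me - delta, mb) - .convCB(t, me + delta, mb)) / (2 * delta)
  }
}

# Plasma AIF at t [min]
.cp_min <- function(t, theta) {
  s <- 1 / (1 - theta@hematocrit)
  tB <- 2 * pi / theta@mb
  bolus <- ifelse(t > 0 & t <= tB, 1 - cos(theta@mb * t), 0)
  s * theta@ab * (bolus + theta@ae * .convCB(t, theta@me, theta@mb))
}

# Running integral of the plasma AIF, I1(t) = int_0^t Cp [min]
.cpint_min <- function(t, theta) {
  s <- 1 / (1 - theta@hematocrit)
  s * theta@ab * (.convCB(t, 0, theta@mb) +
    (theta@ae / theta@me) * (.convCB(t, 0, theta@mb) -
                             .convCB(t, theta@me, theta@mb)))
}

# conv(Cp, exp(-kep*.))(t) [min] -- the extended Tofts leakage kernel
.cpconv_min <- function(t, kep, theta) {
  s <- 1 / (1 - theta@hematocrit)
  s * theta@ab * (.convCB(t, kep, theta@mb) +
    theta@ae * .convCB_ratio(t, kep, theta@me, theta@mb))
}

#' Plasma concentration of the population AIF
#'
#' Evaluates the analytical arterial input function: a raised-cosine
#' first-pass bolus of duration `2*pi/mb` minutes followed by an exponential
#' washout (the washout is the bolus convolved with `exp(-me*t)`). The
#' whole-blood curve defined by the shape parameters is divided by
#' `1 - hematocrit` to yield plasma concentration. Contrast arrival is at
#' `t = 0`; the function returns 0 for `t <= 0`.
#'
#' @param t time(s) since contrast arrival \[s\]; may be a vector.
#' @param theta an [AIFParameters-class] object.
#' @return Plasma concentration(s) \[mmol/L\].
#' @examples
#' aifConcentration(c(0, 10, 60, 300), AIFParameters())
#' @seealso [averagedAifConcentration()], [bloodToPlasma()]
#' @export
aifConcentration <- function(t, theta = AIFParameters()) {
  .check_time(t)
  stopifnot(is(theta, "AIFParameters"))
  .cp_min(t * .MIN, theta)
}

#' Time-averaged plasma concentration of the population AIF
#'
#' The AIF convolved with a unit-area rectangle of width `dt`: the mean of
#' [aifConcentration()] over the centered window `[t - dt/2, t + dt/2]`.
#' Computed exactly from the closed-form running integral of the AIF, so no
#' quadrature is involved.
#'
#' @param t window-center time(s) \[s\].
#' @param theta an [AIFParameters-class] object.
#' @param dt frame duration \[s\], `> 0`.
#' @return Time-averaged plasma concentration(s) \[mmol/L\].
#' @examples
#' averagedAifConcentration(30, AIFParameters(), dt = 15)
#' @export
averagedAifConcentration <- function(t, theta = AIFParameters(), dt) {
  .check_time(t)
  stopifnot(is(theta, "AIFParameters"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single duration > 0 (seconds)", call. = FALSE)
  tm <- t * .MIN
  dm <- dt * .MIN
  hi <- pmax(tm + dm / 2, 0)
  lo <- pmax(tm - dm / 2, 0)
  (.cpint_min(hi, theta) - .cpint_min(lo, theta)) / dm
}

#' Whole-blood to plasma concentration
#'
#' `Cp = Cb / (1 - hematocrit)`: contrast agent resides in plasma only, so a
#' whole-blood concentration measured in an artery is scaled by the plasma
#' fraction.
#'
#' @param cb whole-blood concentration(s) \[mmol/L\].
#' @param hematocrit hematocrit fraction in `[0, 1)` (default 0.42, the
#'   healthy-adult average).
#' @return Plasma concentration(s) \[mmol/L\].
#' @examples
#' bloodToPlasma(0.58, 0.42)  # 1.0
#' @export
bloodToPlasma <- function(cb, hematocrit = 0.42) {
  if (!is.numeric(hematocrit) || length(hematocrit) != 1L ||
      !is.finite(hematocrit) || hematocrit < 0 || hematocrit >= 1)
    stop("'hematocrit' must be a single value in [0, 1)", call. = FALSE)
  cb / (1 - hematocrit)
}
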