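# Spoiled gradient-echo signal model, conversion, signal-domain averaging,
# and the Gaussian noise rule used by the simulations.

# 1/T1 [1/ms]: r1 is in L/mmol/s, T1 in ms, hence the factor 1000
.r1_ms <- function(C, p) 1 / p@T10 + p@r1 * C / 1000

#' Spoiled gradient-echo signal
#'
#' Steady-state SPGR signal for a given contrast-agent concentration:
#' \deqn{S = S_0 \sin\alpha \frac{1 - E}{1 - E\cos\alpha}, \quad
#'   E = e^{-TR/T_1(C)}, \quad 1/T_1(C) = 1/T_{10} + r_1 C.}
#' Strictly increasing in `C`, which makes the conversion invertible.
#'
#' @param C concentration(s) \[mmol/L\], `>= 0`.
#' @param p an [SPGRParameters-class] object.
#' @param allowNegative permit `C < 0` (noisy concentration samples); the
#'   formula remains valid as long as `1/T1(C) > 0`.
#' @return Signal value(s) \[a.u.\].
#' @examples
#' spgrSignal(c(0, 0.5, 1), SPGRParameters())
#' @seealso [signalToConcentration()]
#' @export
spgrSignal <- function(C, p = SPGRParameters(), allowNegative = FALSE) {
  stopifnot(is(p, "SPGRParameters"))
  if (!is.numeric(C) || any(!is.finite(C)))
    stop("'C' must be finite numeric concentration(s)", call. = FALSE)
  if (!allowNegative && any(C < 0))
    stop("'C' must be >= 0 (set allowNegative = TRUE for noisy samples)",
         call. = FALSE)
  r1eff <- .r1_ms(C, p)
  if (any(r1eff <= 0))
    stop("concentration too negative: effective relaxation rate <= 0",
         call. = FALSE)
  a <- p@flip * pi / 180
  E <- exp(-p@TR * r1eff)
  p@S0 * sin(a) * (1 - E) / (1 - E * cos(a))
}

#' Concentration from spoiled gradient-echo signal
#'
#' Exact algebraic inversion of [spgrSignal()]: solve for `E`, then `T1`,
#' then `C`. Signals at or below the zero-concentration baseline map to
#' `C <= 0`; such negative concentrations (noise on low-enhancement frames)
#' are returned as-is when `allowNegative = TRUE`, otherwise rejected.
#' Signals outside the attainable range `[0, S0*sin(a)*(1-cos(a))^{-1}...)`
#' (i.e. `y = S / (S0 sin a) >= 1`) are flagged with `NaN`.
#'
#' @param S signal value(s) \[a.u.\].
#' @param p an [SPGRParameters-class] object.
#' @param allowNegative return negative concentrations for sub-baseline
#'   signals instead of rejecting them (default `TRUE`: the fitters tolerate
#'   negative samples, and clipping would bias low-signal frames).
#' @return Concentration(s) \[mmol/L\]; `NaN` where `S` is unattainable.
#' @examples
#' p <- SPGRParameters()
#' signalToConcentration(spgrSignal(0.5, p), p)  # 0.5
#' @export
signalToConcentration <- function(S, p = SPGRParameters(),
                                  allowNegative = TRUE) {
  stopifnot(is(p, "SPGRParameters"))
  if (!is.numeric(S) || any(!is.finite(S)))
    stop("'S' must be finite numeric signal(s)", call. = FALSE)
  a <- p@flip * pi / 180
  y <- S / (p@S0 * sin(a))
  E <- (1 - y) / (1 - y * cos(a))
  C <- rep(NaN, length(S))
  ok <- is.finite(E) & E > 0 & E < 1 & y >= 0 & y < 1
  C[ok] <- (-log(E[ok]) / p@TR - 1 / p@T10) * 1000 / p@r1
  if (!allowNegative && any(is.finite(C) & C < 0))
    stop("signal below baseline maps to negative concentration; ",
         "set allowNegative = TRUE to permit this", call. = FALSE)
  C
}

#' Time-averaged spoiled gradient-echo signal
#'
#' Signal-domain counterpart of the rect-convolved model: the SPGR signal of
#' the extended Tofts curve averaged over the centered frame window,
#' \deqn{S'(t) = \frac{1}{\Delta t} \mathrm{rect}(t/\Delta t) * S(t).}
#' Because the signal equation is nonlinear in concentration there is no
#' closed form; the window mean is computed by midpoint sampling of the
#' analytic `S(C(t))` at a step no coarser than `step` seconds.
#'
#' @param t window-center time(s) \[s\].
#' @param u a [PKParameters-class] object of length 1.
#' @param theta an [AIFParameters-class] object.
#' @param p an [SPGRParameters-class] object.
#' @param dt frame duration \[s\], `> 0`.
#' @param step sampling step for the numerical window mean \[s\]
#'   (default 0.1).
#' @return Time-averaged signal(s) \[a.u.\].
#' @export
averagedSignal <- function(t, u, theta = AIFParameters(),
                           p = SPGRParameters(), dt, step = 0.1) {
  .check_time(t)
  .check_pk1(u)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single duration > 0 (seconds)", call. = FALSE)
  stopifnot(step > 0)
  k <- max(1L, as.integer(ceiling(dt / step)))
  offs <- (seq_len(k) - 0.5) / k * dt - dt / 2
  vapply(t, function(tc) {
    C <- toftsConcentration(tc + offs, u, theta)
    mean(spgrSignal(C, p))
  }, numeric(1))
}

#' Per-curve noise standard deviation
#'
#' The simulation noise rule: `sigma = referenceMean / snr`, where
#' `referenceMean` is the mean of the time-averaged samples of the
#' ground-truth curve. The same sigma is used for the discrete and the
#' time-averaged sampling of that curve.
#'
#' @param referenceMean mean of the time-averaged curve samples.
#' @param snr target SNR, `> 0` (`Inf` gives sigma 0).
#' @return Noise standard deviation.
#' @examples
#' noiseSigma(2, 20)  # 0.1
#' @export
noiseSigma <- function(referenceMean, snr) {
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("'snr' must be a single value > 0", call. = FALSE)
  if (is.infinite(snr)) return(0)
  referenceMean / snr
}

#' Add i.i.d. Gaussian noise to a sampled curve
#'
#' Draws zero-mean Gaussian noise with standard deviation
#' `referenceMean / snr` and adds it to the samples. With `snr = Inf` the
#' curve is returned unchanged. Reproducible under [set.seed()] (or pass
#' `seed`).
#'
#' @param values sampled curve values (non-empty numeric).
#' @param referenceMean mean of the corresponding time-averaged curve, used
#'   to set sigma; see [noiseSigma()].
#' @param snr target SNR.
#' @param seed optional integer seed set before drawing.
#' @return A list with elements `values` (noisy samples) and `sigma`.
#' @export
addGaussianNoise <- function(values, referenceMean, snr, seed = NULL) {
  if (!is.numeric(values) || length(values) == 0L)
    stop("'values' must be a non-empty numeric vector", call. = FALSE)
  sigma <- noiseSigma(referenceMean, snr)
  if (!is.null(seed)) set.seed(seed)
  noisy <- if (sigma == 0) values else
    values + stats::rnorm(length(values), sd = sigma)
  list(values = noisy, sigma = sigma)
}
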