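#' @import methods
NULL

#' Analytical arterial input function parameters
#'
#' Parameters of the analytical population arterial input function (AIF): a
#' raised-cosine first-pass bolus followed by an exponential washout (the
#' Orton model). The four shape parameters are the bolus amplitude `ab`
#' \[mmol/L\] and angular rate `mb` \[1/min\], and the washout amplitude `ae`
#' \[dimensionless\] and decay rate `me` \[1/min\]. Amplitudes describe
#' whole-blood concentration; [aifConcentration()] divides by `1 - hematocrit`
#' to return plasma concentration.
#'
#' The defaults are the Orton (2008) population values for the raised-cosine
#' model (`ab` 2.84, `mb` 22.8, `ae` 1.36, `me` 0.171) with a healthy-adult
#' hematocrit of 0.42.
#'
#' @slot ab bolus amplitude \[mmol/L\], `>= 0`.
#' @slot mb bolus angular rate \[1/min\], `> 0`; the bolus lasts `2*pi/mb` min.
#' @slot ae washout amplitude (relative to `ab`), `>= 0`.
#' @slot me washout decay rate \[1/min\], `> 0`.
#' @slot hematocrit blood hematocrit fraction in `[0, 1)`.
#' @seealso [aifConcentration()], [averagedAifConcentration()], [bloodToPlasma()]
#' @export
setClass("AIFParameters",
  representation(ab = "numeric", mb = "numeric", ae = "numeric",
                 me = "numeric", hematocrit = "numeric"),
  prototype(ab = 2.84, mb = 22.8, ae = 1.36, me = 0.171, hematocrit = 0.42))

setValidity("AIFParameters", function(object) {
  msg <- character()
  for (s in c("ab", "mb", "ae", "me", "hematocrit")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg) == 0L) {
    if (object@ab < 0 || object@ae < 0)
      msg <- c(msg, "amplitudes 'ab' and 'ae' must be >= 0")
    if (object@mb <= 0 || object@me <= 0)
      msg <- c(msg, "rates 'mb' and 'me' must be > 0")
    if (object@hematocrit < 0 || object@hematocrit >= 1)
      msg <- c(msg, "'hematocrit' must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct AIF parameters
#'
#' @param ab,mb,ae,me AIF shape parameters; see [AIFParameters-class].
#' @param hematocrit hematocrit fraction in `[0, 1)`.
#' @return An [AIFParameters-class] object.
#' @examples
#' theta <- AIFParameters()          # population AIF
#' aifConcentration(60, theta)       # plasma concentration at t = 60 s
#' @export
AIFParameters <- function(ab = 2.84, mb = 22.8, ae = 1.36, me = 0.171,
                          hematocrit = 0.42) {
  new("AIFParameters", ab = ab, mb = mb, ae = ae, me = me,
      hematocrit = hematocrit)
}

#' Extended Tofts tissue parameters
#'
#' Vector-like container for extended Tofts pharmacokinetic parameters. The
#' internal parameterization is `(vp, ve, kep)`; the transfer constant
#' `Ktrans = kep * ve` \[1/min\] is derived through [ktrans()], so the
#' identity holds exactly by construction. `vp + ve <= 1` is deliberately not
#' enforced: the simulation priors sample the two fractions independently.
#'
#' @slot vp plasma volume fraction(s) in `[0, 1]`.
#' @slot ve extracellular-extravascular volume fraction(s) in `[0, 1]`.
#' @slot kep reflux rate(s) \[1/min\] in `[0, 3]`.
#' @seealso [sampleParameters()], [toftsConcentration()]
#' @export
setClass("PKParameters",
  representation(vp = "numeric", ve = "numeric", kep = "numeric"))

setValidity("PKParameters", function(object) {
  n <- length(object@vp)
  msg <- character()
  if (length(object@ve) != n || length(object@kep) != n)
    msg <- c(msg, "'vp', 've' and 'kep' must have equal length")
  if (any(!is.finite(object@vp)) || any(!is.finite(object@ve)) ||
      any(!is.finite(object@kep)))
    msg <- c(msg, "all parameters must be finite")
  else {
    if (any(object@vp < 0 | object@vp > 1))
      msg <- c(msg, "'vp' must lie in [0, 1]")
    if (any(object@ve < 0 | object@ve > 1))
      msg <- c(msg, "'ve' must lie in [0, 1]")
    if (any(object@kep < 0 | object@kep > 3))
      msg <- c(msg, "'kep' must lie in [0, 3]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct tissue parameters
#'
#' @param vp,ve,kep numeric vectors of equal length; see [PKParameters-class].
#' @return A [PKParameters-class] object.
#' @examples
#' u <- PKParameters(vp = 0.025, ve = 0.3, kep = 1)
#' ktrans(u)   # 0.3 min^-1
#' @export
PKParameters <- function(vp, ve, kep) {
  new("PKParameters", vp = as.numeric(vp), ve = as.numeric(ve),
      kep = as.numeric(kep))
}

#' Spoiled gradient-echo acquisition parameters
#'
#' Parameters of the steady-state spoiled gradient-echo (SPGR) signal
#' equation used to map contrast-agent concentration to signal. Defaults
#' follow a 3 T abdominal protocol: TR 3.8 ms, flip angle 25 degrees,
#' baseline pancreas T1 of 725 ms, and gadoterate relaxivity r1 of
#' 3.5 L mmol^-1 s^-1.
#'
#' @slot TR repetition time \[ms\], `> 0`.
#' @slot flip flip angle \[degrees\], in `(0, 90)`.
#' @slot T10 pre-contrast T1 \[ms\], `> 0`.
#' @slot r1 longitudinal relaxivity \[L mmol^-1 s^-1\], `> 0`.
#' @slot S0 equilibrium signal scale \[a.u.\], `> 0`.
#' @seealso [spgrSignal()], [signalToConcentration()]
#' @export
setClass("SPGRParameters",
  representation(TR = "numeric", flip = "numeric", T10 = "numeric",
                 r1 = "numeric", S0 = "numeric"),
  prototype(TR = 3.8, flip = 25, T10 = 725, r1 = 3.5, S0 = 1000))

setValidity("SPGRParameters", function(object) {
  msg <- character()
  for (s in c("TR", "flip", "T10", "r1", "S0")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg) == 0L) {
    if (object@TR <= 0) msg <- c(msg, "'TR' must be > 0")
    if (object@flip <= 0 || object@flip >= 90)
      msg <- c(msg, "'flip' must lie in (0, 90) degrees")
    if (object@T10 <= 0) msg <- c(msg, "'T10' must be > 0")
    if (object@r1 <= 0) msg <- c(msg, "'r1' must be > 0")
    if (object@S0 <= 0) msg <- c(msg, "'S0' must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct SPGR parameters
#'
#' @param TR,flip,T10,r1,S0 see [SPGRParameters-class].
#' @return An [SPGRParameters-class] object.
#' @export
SPGRParameters <- function(TR = 3.8, flip = 25, T10 = 725, r1 = 3.5,
                           S0 = 1000) {
  new("SPGRParameters", TR = TR, flip = flip, T10 = T10, r1 = r1, S0 = S0)
}

#' Gaussian noise model for simulated curves
#'
#' The per-curve noise standard deviation is `mean(C') / SNR`, where the mean
#' is taken over the frames of that curve's time-averaged sampling; the same
#' sigma is applied to the discrete and the time-averaged samples of the
#' curve. `SNR = Inf` means noiseless.
#'
#' @slot snr target signal-to-noise ratio, `> 0` (default 20).
#' @seealso [addGaussianNoise()], [generateDataset()]
#' @export
setClass("NoiseModel", representation(snr = "numeric"), prototype(snr = 20))

setValidity("NoiseModel", function(object) {
  if (length(object@snr) != 1L || is.na(object@snr) || object@snr <= 0)
    "'snr' must be a single value > 0 (Inf for noiseless)" else TRUE
})

#' Construct a noise model
#' @param snr target SNR (`Inf` for noiseless).
#' @return A [NoiseModel-class] object.
#' @export
NoiseModel <- function(snr = 20) new("NoiseModel", snr = snr)

#' Frame timing of a dynamic acquisition
#'
#' Describes the temporal sampling of a dynamic series: frame duration `dt`,
#' total duration, sampling mode, and how the frame grid is aligned with the
#' contrast arrival at `t = 0`. The number of frames is
#' `floor(duration / dt)` (durations not divisible by `dt` are truncated to
#' full frames). In `"discrete"` mode each frame is the instantaneous value
#' at the frame center (Cartesian snapshot); in `"time_averaged"` mode each
#' frame is the mean over its window (k-space-center-oversampling
#' trajectories).
#'
#' The `alignment` governs where the bolus arrival falls inside the first
#' frame window. With `"centered"` the arrival coincides with a window
#' start, so frame centers are `dt/2, 3*dt/2, ...`; with `"start"` the
#' arrival sits mid-window, so frame centers are `0, dt, 2*dt, ...`; with
#' `"random"` (the default for simulations) the arrival phase is drawn
#' uniformly over one frame per curve, reflecting that injection is not
#' synchronized to the scanner's frame clock. The choice matters: with a
#' deterministic grid, whether a discrete sample happens to land on the AIF
#' bolus peak decides how much vascular information Cartesian sampling
#' retains at long frame durations.
#'
#' @slot dt frame duration \[s\], `> 0`.
#' @slot duration total acquisition duration \[s\], `>= dt`.
#' @slot mode `"discrete"` or `"time_averaged"`.
#' @slot alignment `"random"`, `"centered"` or `"start"`.
#' @seealso [frameTimes()], [generateDataset()]
#' @export
setClass("AcquisitionScheme",
  representation(dt = "numeric", duration = "numeric", mode = "character",
                 alignment = "character"),
  prototype(dt = 4, duration = 300, mode = "time_averaged",
            alignment = "random"))

setValidity("AcquisitionScheme", function(object) {
  msg <- character()
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "'dt' must be a single value > 0")
  if (length(object@duration) != 1L || !is.finite(object@duration))
    msg <- c(msg, "'duration' must be a single finite number")
  else if (length(msg) == 0L && object@duration < object@dt)
    msg <- c(msg, "'duration' must be >= 'dt'")
  if (!object@mode %in% c("discrete", "time_averaged"))
    msg <- c(msg, "'mode' must be 'discrete' or 'time_averaged'")
  if (!object@alignment %in% c("random", "centered", "start"))
    msg <- c(msg, "'alignment' must be 'random', 'centered' or 'start'")
  if (length(msg)) msg else TRUE
})

#' Construct an acquisition scheme
#' @param dt frame duration \[s\].
#' @param duration total duration \[s\].
#' @param mode `"discrete"` or `"time_averaged"`.
#' @param alignment frame-grid alignment with contrast arrival; see
#'   [AcquisitionScheme-class].
#' @return An [AcquisitionScheme-class] object.
#' @examples
#' nFrames(AcquisitionScheme(dt = 8, duration = 300))  # 37
#' @export
AcquisitionScheme <- function(dt = 4, duration = 300,
                              mode = c("time_averaged", "discrete"),
                              alignment = c("random", "centered", "start")) {
  new("AcquisitionScheme", dt = dt, duration = duration,
      mode = match.arg(mode), alignment = match.arg(alignment))
}

#' Prior distributions for the Monte Carlo tissue parameters
#'
#' The study priors: `ve ~ U[0, 1]`, `kep ~ U[0, 3]` \[1/min\], and `vp`
#' either exponential with rate 40 truncated (by rejection) to
#' `[0, 0.37]` — mean approximately 0.025 — or uniform on `[0, 1]`.
#'
#' @slot vpPrior `"exponential"` or `"uniform"`.
#' @slot vpRate rate of the exponential vp prior, `> 0`.
#' @slot vpMax truncation bound of the exponential vp prior.
#' @slot veRange,kepRange length-2 supports of the uniform priors.
#' @seealso [sampleParameters()]
#' @export
setClass("ParameterPrior",
  representation(vpPrior = "character", vpRate = "numeric", vpMax = "numeric",
                 veRange = "numeric", kepRange = "numeric"),
  prototype(vpPrior = "exponential", vpRate = 40, vpMax = 0.37,
            veRange = c(0, 1), kepRange = c(0, 3)))

setValidity("ParameterPrior", function(object) {
  msg <- character()
  if (!object@vpPrior %in% c("exponential", "uniform"))
    msg <- c(msg, "'vpPrior' must be 'exponential' or 'uniform'")
  if (object@vpRate <= 0) msg <- c(msg, "'vpRate' must be > 0")
  if (object@vpMax <= 0 || object@vpMax > 1)
    msg <- c(msg, "'vpMax' must lie in (0, 1]")
  ok_range <- function(r, lo, hi) length(r) == 2L && r[1] < r[2] &&
    r[1] >= lo && r[2] <= hi
  if (!ok_range(object@veRange, 0, 1))
    msg <- c(msg, "'veRange' must be an increasing pair within [0, 1]")
  if (!ok_range(object@kepRange, 0, 3))
    msg <- c(msg, "'kepRange' must be an increasing pair within [0, 3]")
  if (length(msg)) msg else TRUE
})

#' Construct a parameter prior
#' @param vpPrior `"exponential"` (study default) or `"uniform"`.
#' @param vpRate,vpMax exponential-prior rate and truncation bound.
#' @param veRange,kepRange uniform supports for `ve` and `kep`.
#' @return A [ParameterPrior-class] object.
#' @export
ParameterPrior <- function(vpPrior = c("exponential", "uniform"), vpRate = 40,
                           vpMax = 0.37, veRange = c(0, 1),
                           kepRange = c(0, 3)) {
  new("ParameterPrior", vpPrior = match.arg(vpPrior), vpRate = vpRate,
      vpMax = vpMax, veRange = veRange, kepRange = kepRange)
}

#' A sampled concentration or signal curve
#'
#' Frame timestamps (seconds, frame centers) with sampled values
#' (concentration \[mmol/L\] or signal \[a.u.\]) and, when known, the noise
#' standard deviation.
#'
#' @slot times frame-center timestamps \[s\], strictly increasing.
#' @slot values sampled values, same length as `times`.
#' @slot sigma noise standard deviation (`NA` if unknown).
#' @seealso [readCurveTable()], [fitCurve()]
#' @export
setClass("SampledCurve",
  representation(times = "numeric", values = "numeric", sigma = "numeric"),
  prototype(sigma = NA_real_))

setValidity("SampledCurve", function(object) {
  msg <- character()
  if (length(object@times) == 0L)
    msg <- c(msg, "curve must contain at least one sample")
  if (length(object@values) != length(object@times))
    msg <- c(msg, "'times' and 'values' must have equal length")
  if (any(!is.finite(object@times)) || is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "'times' must be finite and strictly increasing")
  if (length(object@sigma) != 1L)
    msg <- c(msg, "'sigma' must be a single value (NA if unknown)")
  if (length(msg)) msg else TRUE
})

#' Construct a sampled curve
#' @param times frame-center timestamps \[s\].
#' @param values sampled values.
#' @param sigma noise SD, `NA` if unknown.
#' @return A [SampledCurve-class] object.
#' @export
SampledCurve <- function(times, values, sigma = NA_real_) {
  new("SampledCurve", times = as.numeric(times), values = as.numeric(values),
      sigma = as.numeric(sigma))
}

#' Result of a single curve fit
#'
#' @slot estimate fitted [PKParameters-class] (length 1).
#' @slot rss residual sum of squares.
#' @slot converged optimizer convergence flag.
#' @slot niter number of objective evaluations used.
#' @slot variant model variant: `"conventional"`, `"time_averaged"` or
#'   `"signal_domain"`.
#' @slot dt frame duration \[s\] used by the averaged variants (`NA` for the
#'   conventional variant).
#' @seealso [fitCurve()]
#' @export
setClass("FitResult",
  representation(estimate = "PKParameters", rss = "numeric",
                 converged = "logical", niter = "numeric",
                 variant = "character", dt = "numeric"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (length(object@estimate@vp) != 1L)
    msg <- c(msg, "'estimate' must hold exactly one parameter set")
  if (length(object@rss) != 1L || is.na(object@rss) || object@rss < 0)
    msg <- c(msg, "'rss' must be a single value >= 0")
  if (!object@variant %in% c("conventional", "time_averaged", "signal_domain"))
    msg <- c(msg, "unknown model variant")
  if (length(msg)) msg else TRUE
})

#' Result of a Monte Carlo experiment
#'
#' Per-curve ground truth, estimates, and errors (`estimate - truth`) for
#' `Ktrans`, `vp` and `ve`, for one experimental condition at one frame
#' duration.
#'
#' @slot experiment experiment id (`"reference"`, `"exp1"`, `"exp2"`,
#'   `"s4_exp1"`, `"s4_exp2"`, `"s5_signal"`).
#' @slot dt frame duration \[s\].
#' @slot truth,estimates [PKParameters-class] of equal length.
#' @slot errors data.frame with columns `Ktrans`, `vp`, `ve`.
#' @slot converged per-curve convergence flags.
#' @seealso [runExperiment()], [summarizeErrors()]
#' @export
setClass("ExperimentResult",
  representation(experiment = "character", dt = "numeric",
                 truth = "PKParameters", estimates = "PKParameters",
                 errors = "data.frame", converged = "logical"))

setValidity("ExperimentResult", function(object) {
  msg <- character()
  n <- length(object@truth@vp)
  if (length(object@estimates@vp) != n)
    msg <- c(msg, "'truth' and 'estimates' must have equal length")
  if (nrow(object@errors) != n ||
      !all(c("Ktrans", "vp", "ve") %in% names(object@errors)))
    msg <- c(msg, "'errors' must have one row per curve and columns Ktrans, vp, ve")
  if (length(object@converged) != n)
    msg <- c(msg, "'converged' must have one flag per curve")
  if (length(msg)) msg else TRUE
})
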