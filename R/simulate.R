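# Monte Carlo generator and experiment harness.
#
# Study conditions: 5-min curves, frame durations 4/8/10/15 s, frame centers
# at dt/2, 3dt/2, ..., SNR 20 in the concentration domain, priors
# ve ~ U[0,1], kep ~ U[0,3] /min, vp ~ Exp(40) truncated to [0, 0.37]
# (mean ~0.025).  Noise draws are independent between the discrete and the
# time-averaged sampling of a curve; only sigma is shared.

#' Draw tissue parameters from the study priors
#'
#' Samples `n` parameter sets: `ve` and `kep` uniform on their supports and
#' `vp` either truncated-exponential (rejection sampling: redraw until
#' inside `[0, vpMax]`) or uniform. Reproducible under `seed`.
#'
#' @param n number of parameter sets, `>= 1`.
#' @param prior a [ParameterPrior-class] object.
#' @param seed optional integer seed.
#' @return A [PKParameters-class] object of length `n`.
#' @examples
#' u <- sampleParameters(1000, seed = 1)
#' mean(vp(u))   # ~0.025
#' @export
sampleParameters <- function(n, prior = ParameterPrior(), seed = NULL) {
  stopifnot(is(prior, "ParameterPrior"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  ve <- stats::runif(n, prior@veRange[1], prior@veRange[2])
  kp <- stats::runif(n, prior@kepRange[1], prior@kepRange[2])
  if (prior@vpPrior == "exponential") {
    vpv <- stats::rexp(n, rate = prior@vpRate)
    bad <- which(vpv > prior@vpMax)
    while (length(bad)) {
      vpv[bad] <- stats::rexp(length(bad), rate = prior@vpRate)
      bad <- bad[vpv[bad] > prior@vpMax]
    }
  } else {
    vpv <- stats::runif(n, 0, 1)
  }
  PKParameters(vpv, ve, kp)
}

# arrival phases for one dataset: per-curve U[0, dt) for "random",
# degenerate otherwise (drawn first so the noise stream follows)
.draw_phases <- function(scheme, n) {
  switch(scheme@alignment,
         random = stats::runif(n, 0, scheme@dt),
         centered = rep(0, n),
         start = rep(scheme@dt / 2, n))
}

#' Generate paired discrete and time-averaged sampled curves
#'
#' For each ground-truth parameter set, samples the extended Tofts curve at
#' the frame centers of `scheme` in both acquisition modes: discrete
#' snapshots `C(t_i)` (Cartesian) and frame means `C'(t_i)`
#' (k-space-center oversampling). Both are computed in closed form. One
#' noise sigma per curve is derived from the mean of its noiseless
#' time-averaged samples (`sigma = mean(C') / snr`) and applied to both
#' sample sets with independent Gaussian draws.
#'
#' With `alignment = "random"` (the default) each curve receives its own
#' arrival phase, drawn uniformly over one frame; the per-curve frame grids
#' are returned in `times` and are known to the fitters (scanner frame
#' times and injection time are both known in practice).
#'
#' @param params a [PKParameters-class] object (the ground truths).
#' @param scheme an [AcquisitionScheme-class] object (its `dt`/`duration`/
#'   `alignment` define the frame grids; both modes are always generated).
#' @param theta an [AIFParameters-class] object.
#' @param noise a [NoiseModel-class] object (`snr = Inf` for noiseless).
#' @param seed optional integer seed for the phase and noise draws.
#' @return A list with elements `times` (`n x nFrames` matrix of frame
#'   centers \[s\]), `discrete` and `averaged` (`n x nFrames` matrices of
#'   noisy samples), `sigma` (per-curve noise SD), `phases` (per-curve
#'   arrival phase \[s\]), `truth` (the input `params`), and `scheme`.
#' @export
generateDataset <- function(params, scheme = AcquisitionScheme(),
                            theta = AIFParameters(), noise = NoiseModel(),
                            seed = NULL) {
  stopifnot(is(params, "PKParameters"), is(scheme, "AcquisitionScheme"),
            is(theta, "AIFParameters"), is(noise, "NoiseModel"))
  n <- length(params)
  m <- nFrames(scheme)
  dm <- scheme@dt * .MIN
  if (!is.null(seed)) set.seed(seed)
  phases <- .draw_phases(scheme, n)

  times <- disc <- avg <- matrix(0, n, m)
  sig <- numeric(n)
  for (i in seq_len(n)) {
    centers <- frameTimes(scheme, phase = phases[i])
    times[i, ] <- centers
    tm <- centers * .MIN
    hi <- pmax(tm + dm / 2, 0)
    lo <- pmax(tm - dm / 2, 0)
    vp_ <- params@vp[i]; ve_ <- params@ve[i]; kep_ <- params@kep[i]
    disc_i <- vp_ * .cp_min(tm, theta) +
      ve_ * kep_ * .cpconv_min(tm, kep_, theta)
    i1hi <- .cpint_min(hi, theta); i1lo <- .cpint_min(lo, theta)
    khi <- .cpconv_min(hi, kep_, theta)
    klo <- .cpconv_min(lo, kep_, theta)
    avg_i <- (vp_ * (i1hi - i1lo) + ve_ * ((i1hi - khi) - (i1lo - klo))) / dm
    s <- noiseSigma(mean(avg_i), noise@snr)
    sig[i] <- s
    if (s > 0) {
      disc[i, ] <- disc_i + stats::rnorm(m, sd = s)
      avg[i, ] <- avg_i + stats::rnorm(m, sd = s)
    } else {
      disc[i, ] <- disc_i
      avg[i, ] <- avg_i
    }
  }
  list(times = times, discrete = disc, averaged = avg, sigma = sig,
       phases = phases, truth = params, scheme = scheme)
}

.EXPERIMENT_IDS <- c("reference", "exp1", "exp2", "s4_exp1", "s4_exp2",
                     "s5_signal", "s5_concentration")

#' Run one Monte Carlo experiment
#'
#' Generates the simulated dataset for the given frame duration and fits the
#' model variant of the requested experiment:
#' * `"reference"` — conventional model fitted to discrete (Cartesian)
#'   samples;
#' * `"exp1"` — conventional model fitted to time-averaged samples
#'   (averaging ignored);
#' * `"exp2"` — time-averaged (corrected) model fitted to time-averaged
#'   samples;
#' * `"s4_exp1"`, `"s4_exp2"` — as `exp1`/`exp2` but with the time-averaged
#'   AIF `Cp'` as input function (patient-specific AIF measured with the
#'   averaging acquisition);
#' * `"s5_signal"` — the same noisy time-averaged concentration samples as
#'   `exp2`, transformed to SPGR signal and fitted with the numerically
#'   time-averaged signal model (averaging applied in the signal domain);
#' * `"s5_concentration"` — the corrected concentration-domain fit on the
#'   identical data (the comparator for `s5_signal`; equals `exp2`).
#'
#' The same `seed` yields identical ground-truth draws and noise
#' realizations across experiment ids that share a data path, so
#' `reference`/`exp1`/`exp2` at a given `dt` form a paired design
#' (`exp1` and `exp2` fit the identical noisy curves), as do
#' `s5_signal`/`s5_concentration`.
#'
#' @param experiment experiment id, see above.
#' @param dt frame duration \[s\].
#' @param n number of simulated curves.
#' @param prior a [ParameterPrior-class] object.
#' @param theta an [AIFParameters-class] object.
#' @param noise a [NoiseModel-class] object.
#' @param spgr an [SPGRParameters-class] object (signal-domain experiments).
#' @param seed integer seed; drives the parameter, phase and noise draws.
#' @param duration total acquisition duration \[s\] (default 300).
#' @param alignment frame-grid alignment; see [AcquisitionScheme-class].
#' @return An [ExperimentResult-class] object with per-curve ground truth,
#'   estimates, and errors (`estimate - truth`) for `Ktrans`, `vp`, `ve`.
#' @examples
#' r <- runExperiment("exp2", dt = 15, n = 5, seed = 1)
#' summarizeErrors(r)
#' @export
runExperiment <- function(experiment, dt, n = 2000,
                          prior = ParameterPrior(),
                          theta = AIFParameters(), noise = NoiseModel(),
                          spgr = SPGRParameters(), seed = 1,
                          duration = 300,
                          alignment = c("random", "centered", "start")) {
  if (!is.character(experiment) || length(experiment) != 1L ||
      !experiment %in% .EXPERIMENT_IDS)
    stop("unknown experiment id; use one of: ",
         paste(.EXPERIMENT_IDS, collapse = ", "), call. = FALSE)
  params <- sampleParameters(n, prior, seed = seed)
  scheme <- AcquisitionScheme(dt = dt, duration = duration,
                              alignment = match.arg(alignment))

  ds <- generateDataset(params, scheme, theta, noise, seed = seed + 1L)
  fit <- switch(experiment,
    reference = .fitBatch(ds$times, ds$discrete, "conventional", theta),
    exp1 = .fitBatch(ds$times, ds$averaged, "conventional", theta),
    exp2 = ,
    s5_concentration = .fitBatch(ds$times, ds$averaged, "time_averaged",
                                 theta, dt),
    s4_exp1 = .fitBatch(ds$times, ds$averaged, "conventional", theta, dt,
                        aifAveraged = TRUE),
    s4_exp2 = .fitBatch(ds$times, ds$averaged, "time_averaged", theta, dt,
                        aifAveraged = TRUE),
    s5_signal = .fitBatch(ds$times,
                          matrix(spgrSignal(as.vector(ds$averaged), spgr,
                                            allowNegative = TRUE),
                                 nrow = n),
                          "signal_domain", theta, dt, spgr = spgr))
  est <- PKParameters(fit$vp, fit$ve, fit$kep)
  err <- data.frame(Ktrans = ktrans(est) - ktrans(params),
                    vp = fit$vp - params@vp,
                    ve = fit$ve - params@ve)
  new("ExperimentResult", experiment = experiment, dt = dt, truth = params,
      estimates = est, errors = err, converged = fit$converged)
}
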