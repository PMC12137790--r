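#' Accessors for tissue parameters
#'
#' `vp()`, `ve()` and `kep()` extract the stored parameter vectors;
#' `ktrans()` returns the derived transfer constant `kep * ve` \[1/min\].
#'
#' @param x a [PKParameters-class] object.
#' @return A numeric vector.
#' @name pk-accessors
#' @aliases vp ve kep ktrans
#' @examples
#' u <- PKParameters(vp = c(0.02, 0.1), ve = c(0.3, 0.5), kep = c(1, 2))
#' ktrans(u)
NULL

#' @rdname pk-accessors
#' @export
setGeneric("vp", function(x) standardGeneric("vp"))
#' @rdname pk-accessors
#' @export
setGeneric("ve", function(x) standardGeneric("ve"))
#' @rdname pk-accessors
#' @export
setGeneric("kep", function(x) standardGeneric("kep"))
#' @rdname pk-accessors
#' @export
setGeneric("ktrans", function(x) standardGeneric("ktrans"))

#' @rdname pk-accessors
setMethod("vp", "PKParameters", function(x) x@vp)
#' @rdname pk-accessors
setMethod("ve", "PKParameters", function(x) x@ve)
#' @rdname pk-accessors
setMethod("kep", "PKParameters", function(x) x@kep)
#' @rdname pk-accessors
setMethod("ktrans", "PKParameters", function(x) x@kep * x@ve)

#' @describeIn PKParameters number of parameter sets stored.
#' @param x a `PKParameters` object.
#' @export
setMethod("length", "PKParameters", function(x) length(x@vp))

#' @describeIn PKParameters subset parameter sets.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PKParameters", function(x, i, j, ..., drop = TRUE) {
  PKParameters(x@vp[i], x@ve[i], x@kep[i])
})

#' @describeIn PKParameters coerce to a data.frame with columns `vp`, `ve`,
#'   `kep`, `Ktrans`.
#' @param row.names,optional passed on for compatibility, unused.
#' @export
setMethod("as.data.frame", "PKParameters",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(vp = x@vp, ve = x@ve, kep = x@kep, Ktrans = x@kep * x@ve)
  })

#' Hematocrit accessor
#' @param x an [AIFParameters-class] object.
#' @return The hematocrit fraction.
#' @export
setGeneric("hematocrit", function(x) standardGeneric("hematocrit"))

#' @describeIn hematocrit method for AIF parameters.
setMethod("hematocrit", "AIFParameters", function(x) x@hematocrit)

#' AIF shape parameters as a named vector
#' @param x an [AIFParameters-class] object.
#' @return Named numeric vector `c(ab, mb, ae, me)`.
#' @export
setGeneric("aifTheta", function(x) standardGeneric("aifTheta"))

#' @describeIn aifTheta method for AIF parameters.
setMethod("aifTheta", "AIFParameters", function(x) {
  c(ab = x@ab, mb = x@mb, ae = x@ae, me = x@me)
})

#' Number of frames in an acquisition scheme
#' @param x an [AcquisitionScheme-class] object.
#' @return Integer frame count, `floor(duration / dt)`.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @describeIn nFrames method for acquisition schemes.
setMethod("nFrames", "AcquisitionScheme", function(x) {
  as.integer(floor(x@duration / x@dt + 1e-9))
})

#' Frame-center timestamps of an acquisition scheme
#'
#' For a given arrival phase `a` (seconds between the first frame-window
#' start and contrast arrival), frame centers are
#' `(j + 1/2) * dt - a` for `j = 0, ..., nFrames - 1`. `a = 0` is the
#' `"centered"` alignment, `a = dt/2` the `"start"` alignment. For a scheme
#' with `alignment = "random"` the phase is per-curve and drawn in
#' [generateDataset()]; `frameTimes()` then returns the `phase = 0` grid
#' unless a phase is supplied.
#'
#' @param x an [AcquisitionScheme-class] object.
#' @param phase arrival phase `a` \[s\] in `[0, dt)`; default per alignment.
#' @return Numeric vector of frame centers \[s\].
#' @export
setGeneric("frameTimes", function(x, phase = NULL) standardGeneric("frameTimes"))

#' @rdname frameTimes
setMethod("frameTimes", "AcquisitionScheme", function(x, phase = NULL) {
  if (is.null(phase))
    phase <- switch(x@alignment, start = x@dt / 2, 0)
  (seq_len(nFrames(x)) - 0.5) * x@dt - phase
})

#' Curve accessors
#' @param x a [SampledCurve-class] object.
#' @return Numeric vector (`curveTimes`, `curveValues`) or scalar
#'   (`curveSigma`).
#' @name curve-accessors
NULL

#' @rdname curve-accessors
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))
#' @rdname curve-accessors
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))
#' @rdname curve-accessors
#' @export
setGeneric("curveSigma", function(x) standardGeneric("curveSigma"))

#' @rdname curve-accessors
setMethod("curveTimes", "SampledCurve", function(x) x@times)
#' @rdname curve-accessors
setMethod("curveValues", "SampledCurve", function(x) x@values)
#' @rdname curve-accessors
setMethod("curveSigma", "SampledCurve", function(x) x@sigma)

#' Fit-result accessors
#' @param x a [FitResult-class] or [ExperimentResult-class] object.
#' @return `estimates()` returns a [PKParameters-class]; `rss()` a number;
#'   `converged()` logical; `errors()` a data.frame.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))
#' @rdname fit-accessors
#' @export
setGeneric("rss", function(x) standardGeneric("rss"))
#' @rdname fit-accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname fit-accessors
#' @export
setGeneric("errors", function(x) standardGeneric("errors"))
#' @rdname fit-accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' @rdname fit-accessors
setMethod("estimates", "FitResult", function(x) x@estimate)
#' @rdname fit-accessors
setMethod("rss", "FitResult", function(x) x@rss)
#' @rdname fit-accessors
setMethod("converged", "FitResult", function(x) x@converged)
#' @rdname fit-accessors
setMethod("estimates", "ExperimentResult", function(x) x@estimates)
#' @rdname fit-accessors
setMethod("converged", "ExperimentResult", function(x) x@converged)
#' @rdname fit-accessors
setMethod("errors", "ExperimentResult", function(x) x@errors)
#' @rdname fit-accessors
setMethod("truth", "ExperimentResult", function(x) x@truth)

setMethod("show", "AIFParameters", function(object) {
  cat("AIFParameters (raised-cosine bolus + exponential washout)\n")
  cat(sprintf("  ab = %.4g mmol/L, mb = %.4g /min, ae = %.4g, me = %.4g /min\n",
              object@ab, object@mb, object@ae, object@me))
  cat(sprintf("  hematocrit = %.2f\n", object@hematocrit))
})

setMethod("show", "PKParameters", function(object) {
  n <- length(object)
  cat(sprintf("PKParameters with %d parameter set%s\n", n,
              if (n == 1L) "" else "s"))
  if (n > 0L) {
    k <- min(n, 5L)
    print(utils::head(as.data.frame(object), k))
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
  }
})

setMethod("show", "SPGRParameters", function(object) {
  cat("SPGRParameters\n")
  cat(sprintf("  TR = %.3g ms, flip = %.3g deg, T10 = %.4g ms\n",
              object@TR, object@flip, object@T10))
  cat(sprintf("  r1 = %.3g L/mmol/s, S0 = %.4g a.u.\n", object@r1, object@S0))
})

setMethod("show", "AcquisitionScheme", function(object) {
  cat(sprintf("AcquisitionScheme: %s, dt = %.4g s, duration = %.4g s (%d frames), %s alignment\n",
              object@mode, object@dt, object@duration, nFrames(object),
              object@alignment))
})

setMethod("show", "SampledCurve", function(object) {
  cat(sprintf("SampledCurve with %d frames spanning [%.4g, %.4g] s",
              length(object@times), min(object@times), max(object@times)))
  if (!is.na(object@sigma)) cat(sprintf(", sigma = %.4g", object@sigma))
  cat("\n")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s%s)\n", object@variant,
              if (!is.na(object@dt)) sprintf(", dt = %g s", object@dt) else ""))
  est <- as.data.frame(object@estimate)
  cat(sprintf("  vp = %.5g, ve = %.5g, kep = %.5g /min, Ktrans = %.5g /min\n",
              est$vp, est$ve, est$kep, est$Ktrans))
  cat(sprintf("  RSS = %.5g, converged = %s, evaluations = %d\n",
              object@rss, object@converged, as.integer(object@niter)))
})

setMethod("show", "ExperimentResult", function(object) {
  cat(sprintf("ExperimentResult '%s' at dt = %g s, n = %d curves\n",
              object@experiment, object@dt, length(object@truth)))
  cat(sprintf("  converged: %d/%d\n", sum(object@converged),
              length(object@converged)))
  s <- summarizeErrors(object)
  print(s, row.names = FALSE)
})
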