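# Accuracy/precision metrics, significance testing and bookkeeping.
#
# Accuracy = mean error (estimate - truth); precision = SD of the errors.
# Accuracy differences: paired Wilcoxon signed-rank on absolute errors (so
# that "more accurate" has a direction); precision differences: Levene's
# test on the two paired error samples (median-centered Brown-Forsythe by
# default, matching common practice; mean centering available).

#' Summarize estimation errors
#'
#' Mean error (accuracy) and standard deviation of the errors (precision)
#' per pharmacokinetic parameter.
#'
#' @param object an [ExperimentResult-class], or a data.frame/matrix of
#'   errors with columns `Ktrans`, `vp`, `ve`.
#' @param truth optional [PKParameters-class]; when supplied together with a
#'   [PKParameters-class] `object`, errors are computed as
#'   `object - truth` first.
#' @return A data.frame with columns `parameter`, `mean_error`, `sd_error`,
#'   `n`.
#' @examples
#' est <- PKParameters(c(0.03, 0.02), c(0.31, 0.29), c(1.1, 0.9))
#' tru <- PKParameters(c(0.025, 0.025), c(0.3, 0.3), c(1, 1))
#' summarizeErrors(est, tru)
#' @export
summarizeErrors <- function(object, truth = NULL) {
  if (is(object, "ExperimentResult")) {
    err <- errors(object)
  } else if (is(object, "PKParameters")) {
    if (is.null(truth) || !is(truth, "PKParameters"))
      stop("'truth' (PKParameters) is required with estimates", call. = FALSE)
    if (length(object) != length(truth))
      stop("'object' and 'truth' must have equal length", call. = FALSE)
    err <- data.frame(Ktrans = ktrans(object) - ktrans(truth),
                      vp = vp(object) - vp(truth),
                      ve = ve(object) - ve(truth))
  } else {
    err <- as.data.frame(object)
    if (!all(c("Ktrans", "vp", "ve") %in% names(err)))
      stop("error table must have columns Ktrans, vp, ve", call. = FALSE)
  }
  if (nrow(err) == 0L) stop("no errors to summarize", call. = FALSE)
  data.frame(
    parameter = c("Ktrans", "vp", "ve"),
    mean_error = vapply(err[c("Ktrans", "vp", "ve")], mean, numeric(1)),
    sd_error = vapply(err[c("Ktrans", "vp", "ve")], stats::sd, numeric(1)),
    n = nrow(err),
    row.names = NULL)
}

#' Compare two paired error samples
#'
#' Tests one parameter's errors from two experimental conditions run on the
#' same ground truths. Accuracy is compared with a paired Wilcoxon
#' signed-rank test (on absolute errors by default, so that a significant
#' result has a direction: the condition with the smaller mean absolute
#' error is "more accurate"); precision with Levene's test on the two error
#' samples (smaller error SD is "more precise").
#'
#' @param errorsA,errorsB paired error vectors of equal length.
#' @param alpha significance level (default 0.05).
#' @param accuracyOn `"absolute"` (default) or `"signed"`: whether the
#'   Wilcoxon test is run on `|error|` or on the signed errors.
#' @param leveneCenter `"median"` (Brown-Forsythe, default) or `"mean"`.
#' @return A one-row data.frame: `p_accuracy`, `p_precision`,
#'   `sig_accuracy`, `sig_precision`, `better_accuracy`,
#'   `better_precision` (each `"A"` or `"B"`).
#' @examples
#' set.seed(1)
#' a <- rnorm(200, sd = 0.01); b <- rnorm(200, sd = 0.03)
#' compareConditions(a, b)
#' @export
compareConditions <- function(errorsA, errorsB, alpha = 0.05,
                              accuracyOn = c("absolute", "signed"),
                              leveneCenter = c("median", "mean")) {
  accuracyOn <- match.arg(accuracyOn)
  leveneCenter <- match.arg(leveneCenter)
  if (length(errorsA) != length(errorsB))
    stop("paired comparison requires equal-length error vectors",
         call. = FALSE)
  if (length(errorsA) < 2L)
    stop("at least 2 paired errors are required", call. = FALSE)

  xa <- if (accuracyOn == "absolute") abs(errorsA) else errorsA
  xb <- if (accuracyOn == "absolute") abs(errorsB) else errorsB
  d <- xa - xb
  p_acc <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(xa, xb, paired = TRUE)$p.value)

  if (stats::sd(errorsA) == 0 && stats::sd(errorsB) == 0) {
    p_prec <- 1
  } else {
    grp <- factor(rep(c("A", "B"), each = length(errorsA)))
    lev <- car::leveneTest(c(errorsA, errorsB), grp, center = leveneCenter)
    p_prec <- lev[["Pr(>F)"]][1]
  }

  data.frame(
    p_accuracy = p_acc,
    p_precision = p_prec,
    sig_accuracy = p_acc < alpha,
    sig_precision = p_prec < alpha,
    better_accuracy = if (mean(abs(errorsA)) <= mean(abs(errorsB))) "A" else "B",
    better_precision = if (stats::sd(errorsA) <= stats::sd(errorsB)) "A" else "B",
    stringsAsFactors = FALSE)
}

#' Compare two experiments over the full parameter grid
#'
#' Runs [compareConditions()] for each of `Ktrans`, `vp`, `ve` on the paired
#' error tables of two [ExperimentResult-class] objects from the same
#' ground truths.
#'
#' @param resultA,resultB [ExperimentResult-class] objects at the same `dt`
#'   with equal curve counts.
#' @param ... passed to [compareConditions()].
#' @return A data.frame with one row per parameter, including columns
#'   `parameter` and `dt`.
#' @export
compareExperiments <- function(resultA, resultB, ...) {
  stopifnot(is(resultA, "ExperimentResult"), is(resultB, "ExperimentResult"))
  if (resultA@dt != resultB@dt)
    stop("experiments were run at different frame durations", call. = FALSE)
  do.call(rbind, lapply(c("Ktrans", "vp", "ve"), function(p) {
    row <- compareConditions(errors(resultA)[[p]], errors(resultB)[[p]], ...)
    cbind(data.frame(parameter = p, dt = resultA@dt,
                     stringsAsFactors = FALSE), row)
  }))
}

#' Count significant comparisons on a parameter-by-frame-duration grid
#'
#' Bookkeeping for the "k of N comparisons" statements: counts rows of a
#' comparison table that are significant *and* favor the stated condition.
#' The table must cover the complete grid (every parameter at every frame
#' duration, once).
#'
#' @param outcomes a data.frame as produced by rbinding
#'   [compareExperiments()] rows across frame durations; must contain
#'   columns `parameter`, `dt`, and the chosen significance/direction
#'   columns.
#' @param measure `"accuracy"` or `"precision"`.
#' @param favoring `"A"` or `"B"`: which condition must be the better one
#'   for a significant row to count.
#' @param parameters,dts the expected grid (defaults: all three parameters,
#'   the frame durations present in `outcomes`).
#' @return A list with `count` and `total`.
#' @export
countSignificant <- function(outcomes, measure = c("accuracy", "precision"),
                             favoring = "A",
                             parameters = c("Ktrans", "vp", "ve"),
                             dts = sort(unique(outcomes$dt))) {
  measure <- match.arg(measure)
  stopifnot(favoring %in% c("A", "B"))
  grid <- expand.grid(parameter = parameters, dt = dts,
                      stringsAsFactors = FALSE)
  key <- paste(outcomes$parameter, outcomes$dt)
  want <- paste(grid$parameter, grid$dt)
  if (!all(want %in% key) || anyDuplicated(key[key %in% want]))
    stop("'outcomes' must cover the parameter x dt grid exactly once",
         call. = FALSE)
  rows <- outcomes[key %in% want, ]
  sig <- rows[[paste0("sig_", measure)]]
  dir <- rows[[paste0("better_", measure)]]
  list(count = sum(sig & dir == favoring), total = nrow(grid))
}

#' Mean absolute difference against the fastest acquisition
#'
#' The in-vivo-style consistency metric: the mean over voxels (or ROI
#' entries) of `|estimate(dt) - estimate(reference dt)|`. Lower values mean
#' the parameter estimate is more consistent across reconstruction frame
#' durations.
#'
#' @param estimate parameter estimates (numeric vector/array) at some frame
#'   duration.
#' @param reference estimates of the same voxels at the reference frame
#'   duration (4 s in the study design); same length and `NA` pattern.
#' @return The mean absolute difference (scalar).
#' @examples
#' meanAbsoluteDifference(c(0.12, 0.14), c(0.10, 0.10))  # 0.03
#' @export
meanAbsoluteDifference <- function(estimate, reference) {
  estimate <- as.vector(estimate)
  reference <- as.vector(reference)
  if (length(estimate) != length(reference))
    stop("maps must share the same spatial support", call. = FALSE)
  if (!identical(is.na(estimate), is.na(reference)))
    stop("maps must share the same NA (mask) pattern", call. = FALSE)
  mean(abs(estimate - reference), na.rm = TRUE)
}
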