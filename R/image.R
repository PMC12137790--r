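# Voxelwise parameter-map fitting for 4D dynamic series.

#' Fit parameter maps to a 4D dynamic series
#'
#' Converts each voxel's dynamic signal to concentration with the SPGR model
#' (unless the input already is concentration) and fits the requested
#' extended Tofts variant with [fitCurve()] machinery. Voxels outside the
#' mask are skipped and reported as `NA`.
#'
#' @param volume a 4D numeric array (x, y, z, frames) of dynamic values, or
#'   a 4D image read with [readDynamicSeries()].
#' @param times frame-center timestamps \[s\], length `dim(volume)[4]`.
#' @param variant model variant, see [fitCurve()].
#' @param theta an [AIFParameters-class] object.
#' @param dt frame duration \[s\]; required for the averaged variants.
#' @param spgr an [SPGRParameters-class] object (used for the
#'   signal-to-concentration conversion and the signal-domain variant).
#' @param mask optional 3D logical/numeric array selecting voxels to fit.
#' @param input `"signal"` (convert each voxel curve to concentration
#'   first) or `"concentration"` (fit as-is).
#' @param ... further arguments to the fitter (init, bounds, ...).
#' @return A list of 3D arrays `vp`, `ve`, `kep`, `Ktrans` (and
#'   `converged`), each shaped like the spatial grid.
#' @export
fitImage <- function(volume, times, variant = c("conventional",
                     "time_averaged", "signal_domain"),
                     theta = AIFParameters(), dt = NULL,
                     spgr = SPGRParameters(), mask = NULL,
                     input = c("signal", "concentration"), ...) {
  variant <- match.arg(variant)
  input <- match.arg(input)
  volume <- unclass(volume)
  d <- dim(volume)
  if (is.null(d) || length(d) != 4L)
    stop("'volume' must be a 4D array (x, y, z, frames)", call. = FALSE)
  if (is.null(times) || length(times) != d[4])
    stop("frame timing metadata is required: 'times' must have one entry ",
         "per frame", call. = FALSE)
  spat <- d[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, spat)
  } else {
    mask <- array(as.logical(mask), spat)
    mask[is.na(mask)] <- FALSE
  }
  nvox <- prod(spat)
  Y <- matrix(aperm(volume, c(4, 1, 2, 3)), nrow = d[4])  # frames x voxels

  out <- list(vp = array(NA_real_, spat), ve = array(NA_real_, spat),
              kep = array(NA_real_, spat), Ktrans = array(NA_real_, spat),
              converged = array(NA, spat))
  idx <- which(as.vector(mask))
  if (length(idx) == 0L) return(out)

  fit_variant <- if (variant == "signal_domain") "signal_domain" else variant
  convert <- input == "signal" && variant != "signal_domain"
  modelArgs <- list(variant = fit_variant, theta = theta, dt = dt,
                    spgr = spgr, ...)
  for (v in idx) {
    y <- Y[, v]
    if (convert) y <- signalToConcentration(y, spgr)
    fit <- do.call(fitCurve, c(list(times = times, values = y), modelArgs))
    e <- estimates(fit)
    out$vp[v] <- vp(e); out$ve[v] <- ve(e); out$kep[v] <- kep(e)
    out$Ktrans[v] <- ktrans(e); out$converged[v] <- converged(fit)
  }
  out
}

#' Read a 4D dynamic series with its frame timing sidecar
#'
#' Reads a NIfTI-1 volume and a JSON sidecar holding the frame timing
#' (`frame_times_s`, an array of frame-center timestamps in seconds, and
#' optionally `frame_duration_s`).
#'
#' @param niftiPath path to the 4D NIfTI file.
#' @param timingPath path to the JSON timing sidecar; defaults to the NIfTI
#'   path with a `.json` extension.
#' @return A list with `volume` (the `RNifti` image), `times`, and `dt`
#'   (`NULL` when absent from the sidecar).
#' @export
readDynamicSeries <- function(niftiPath,
                              timingPath = sub("\\.nii(\\.gz)?$", ".json",
                                               niftiPath)) {
  img <- RNifti::readNifti(niftiPath)
  if (!file.exists(timingPath))
    stop("frame timing sidecar not found: ", timingPath, call. = FALSE)
  meta <- jsonlite::read_json(timingPath, simplifyVector = TRUE)
  if (is.null(meta$frame_times_s))
    stop("timing sidecar must contain 'frame_times_s'", call. = FALSE)
  list(volume = img, times = as.numeric(meta$frame_times_s),
       dt = if (is.null(meta$frame_duration_s)) NULL
            else as.numeric(meta$frame_duration_s))
}

#' Write parameter maps as NIfTI volumes
#'
#' Writes each 3D map from [fitImage()] as `<prefix>_<name>.nii.gz`,
#' inheriting the spatial header from a template image when given.
#'
#' @param maps list of 3D arrays (e.g. the output of [fitImage()]).
#' @param prefix output path prefix.
#' @param template optional `RNifti` image supplying the affine/header.
#' @return Invisibly, the vector of files written.
#' @export
writeParameterMaps <- function(maps, prefix, template = NULL) {
  nm <- intersect(names(maps), c("vp", "ve", "kep", "Ktrans"))
  paths <- character(0)
  for (p in nm) {
    arr <- maps[[p]]
    img <- if (is.null(template)) RNifti::asNifti(arr)
           else RNifti::asNifti(arr, reference = template)
    path <- paste0(prefix, "_", p, ".nii.gz")
    RNifti::writeNifti(img, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
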