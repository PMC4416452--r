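#' Preprocessing configuration
#'
#' Bundles the spectral pre-treatment parameters: the detector splice
#' positions of a three-sensor field spectroradiometer (VNIR ends at 1000 nm,
#' SWIR1 spans 1001-1800 nm, SWIR2 starts at 1801 nm), the Savitzky-Golay
#' half-window and polynomial order (default: four points per side, i.e. a
#' nine-point filter, second-order polynomial), and the wavelength range kept
#' for modeling (default 400-1800 nm inclusive; the noisy 1801-2500 nm SWIR2
#' region is omitted).
#'
#' @param vnir_end last VNIR wavelength (nm).
#' @param swir2_start first SWIR2 wavelength (nm).
#' @param sg_half_window Savitzky-Golay points per side.
#' @param sg_poly_order Savitzky-Golay polynomial order.
#' @param model_range length-2 numeric, inclusive nm range kept for modeling.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(vnir_end = 1000, swir2_start = 1801,
                              sg_half_window = 4L, sg_poly_order = 2L,
                              model_range = c(400, 1800)) {
  if (sg_poly_order >= 2L * sg_half_window + 1L)
    stop("sg_poly_order must be < filter width (2*half_window + 1)")
  if (length(model_range) != 2L || model_range[1L] >= model_range[2L])
    stop("model_range must be an increasing nm pair")
  structure(list(vnir_end = vnir_end, swir2_start = swir2_start,
                 sg_half_window = as.integer(sg_half_window),
                 sg_poly_order = as.integer(sg_poly_order),
                 model_range = as.numeric(model_range)),
            class = "preprocess_config")
}

#' Correct detector splice jumps
#'
#' Removes the radiometric discontinuities at the two sensor change-overs by
#' a multiplicative correction with the SWIR1 sensor as the reference: the
#' VNIR segment (wavelengths <= `vnir_end`) is multiplied by
#' `f_V = r(vnir_end + 1) / r(vnir_end)` and the SWIR2 segment (wavelengths
#' >= `swir2_start`) by `f_S = r(swir2_start - 1) / r(swir2_start)`, per
#' spectrum. SWIR1 is left bit-identical; the corrected spectrum is
#' continuous at both splices under this convention. A second application is
#' a no-op (factors become 1).
#'
#' @param set a [spectra_set] in `raw` state whose grid spans both splices.
#' @param config a [preprocess_config].
#' @return The corrected `spectra_set` (state `jump_corrected`) with the
#'   per-sample factors in `attr(, "jump_factors")`.
#' @export
correct_sensor_jumps <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "spectra_set"))
  if (!set$state %in% c("raw", "jump_corrected"))
    stop("jump correction expects a raw spectrum, got state '", set$state, "'")
  wl <- set$wavelengths
  pos <- match(c(config$vnir_end, config$vnir_end + 1,
                 config$swir2_start - 1, config$swir2_start), wl)
  if (anyNA(pos))
    stop("grid does not span both splice points (",
         config$vnir_end, "/", config$vnir_end + 1, " and ",
         config$swir2_start - 1, "/", config$swir2_start, " nm)")
  m <- set$matrix
  if (any(m[, pos[1L]] == 0) || any(m[, pos[4L]] == 0))
    stop("zero reflectance at a splice reference band: correction undefined")
  f_v <- m[, pos[2L]] / m[, pos[1L]]
  f_s <- m[, pos[3L]] / m[, pos[4L]]
  if (any(c(f_v, f_s) < 0.5 | c(f_v, f_s) > 2))
    warning("splice correction factor outside [0.5, 2]: suspect spectrum")
  vnir <- wl <= config$vnir_end
  swir2 <- wl >= config$swir2_start
  m[, vnir] <- m[, vnir] * f_v
  m[, swir2] <- m[, swir2] * f_s
  out <- spectra_set(m, wl, set$sample_ids, state = "jump_corrected")
  attr(out, "jump_factors") <- cbind(f_vnir = f_v, f_swir2 = f_s)
  out
}

#' Standard normal variate transformation
#'
#' Centers each spectrum on zero and scales it to unit sample standard
#' deviation (divisor n - 1), removing multiplicative scatter effects.
#' Applied over the full measured axis, before any range omission.
#'
#' @param set a [spectra_set], not yet derivative state.
#' @return A `spectra_set` in state `snv`; every row has mean 0 and sample
#'   SD 1 to machine precision.
#' @export
snv_transform <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  if (set$state %in% c("snv", "first_derivative"))
    stop("SNV expects a reflectance spectrum, got state '", set$state, "'")
  mu <- rowMeans(set$matrix)
  sdev <- apply(set$matrix, 1L, stats::sd)
  if (any(sdev == 0))
    stop("constant spectrum (SD = 0): SNV undefined for sample ",
         paste(set$sample_ids[sdev == 0], collapse = ", "))
  m <- (set$matrix - mu) / sdev
  spectra_set(m, set$wavelengths, set$sample_ids, state = "snv")
}

#' Savitzky-Golay first derivative
#'
#' At each interior grid point the first derivative is estimated as the
#' slope of the local least-squares polynomial (order `sg_poly_order`)
#' fitted over the `2 * sg_half_window + 1` point window, divided by the
#' grid step so values are per nm. The `sg_half_window` points at each edge
#' have no full window and are dropped from the output axis rather than
#' filled by polynomial extrapolation.
#'
#' @param set a [spectra_set] on a uniform grid (pipeline order: state
#'   `snv`, but any non-derivative state is accepted).
#' @param config a [preprocess_config].
#' @return A `spectra_set` in state `first_derivative` with a shortened axis.
#' @export
savgol_first_derivative <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "spectra_set"))
  if (set$state == "first_derivative")
    stop("spectrum is already in first-derivative state")
  h <- config$sg_half_window
  width <- 2L * h + 1L
  p <- length(set$wavelengths)
  if (p < width)
    stop("spectrum shorter than the Savitzky-Golay filter width")
  step <- diff(set$wavelengths)[1L]
  # central-row convolution weights of the SG derivative filter
  w <- signal::sgolay(p = config$sg_poly_order, n = width, m = 1)[h + 1L, ]
  interior <- (h + 1L):(p - h)
  out <- matrix(0, nrow(set$matrix), length(interior))
  for (j in seq_along(interior)) {
    idx <- (interior[j] - h):(interior[j] + h)
    out[, j] <- set$matrix[, idx, drop = FALSE] %*% w
  }
  out <- out / step
  spectra_set(out, set$wavelengths[interior], set$sample_ids,
              state = "first_derivative")
}

#' Restrict a spectra_set to the modeling wavelength range
#'
#' Keeps columns inside the inclusive `model_range` (default 400-1800 nm;
#' on the full 350-2500 nm export grid that is 1401 columns before
#' derivative edge loss).
#'
#' @param set a [spectra_set].
#' @param config a [preprocess_config].
#' @return The restricted `spectra_set` (state unchanged).
#' @export
subset_model_range <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "spectra_set"))
  keep <- set$wavelengths >= config$model_range[1L] &
    set$wavelengths <= config$model_range[2L]
  if (!any(keep))
    stop("model_range [", config$model_range[1L], ", ",
         config$model_range[2L], "] does not intersect the measured grid")
  spectra_set(set$matrix[, keep, drop = FALSE], set$wavelengths[keep],
              set$sample_ids, state = set$state)
}

#' Full spectral preprocessing pipeline
#'
#' Applies, in fixed order: splice-jump correction, SNV transformation over
#' the full measured axis, Savitzky-Golay first derivative, and restriction
#' to the modeling range. The state machine forbids re-derivation, so
#' applying the pipeline twice errors.
#'
#' @param set a [spectra_set] in `raw` state.
#' @param config a [preprocess_config].
#' @return A derivative-state `spectra_set` ready for PLS, with the state
#'   transitions recorded in `attr(, "processing_log")`.
#' @export
preprocess_pipeline <- function(set, config = preprocess_config()) {
  log <- character()
  step <- function(x, what) {
    log <<- c(log, sprintf("%s -> %s", what, x$state))
    x
  }
  set <- step(correct_sensor_jumps(set, config), "jump correction")
  set <- step(snv_transform(set), "SNV")
  set <- step(savgol_first_derivative(set, config), "Savitzky-Golay d1")
  set <- step(subset_model_range(set, config),
              sprintf("restrict to [%g, %g] nm", config$model_range[1L],
                      config$model_range[2L]))
  attr(set, "processing_log") <- log
  set
}
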