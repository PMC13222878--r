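#' Fit a grey-value calibration curve from enzyme standards
#'
#' Ordinary least squares of observed grey value on known activity,
#' \code{grey = slope * activity + intercept}. The inverted line converts
#' membrane images to activity in nmol cm-2 h-1.
#'
#' @param standards data.frame (or matrix) with columns \code{activity}
#'   and \code{grey}; at least two distinct activities are required.
#' @return a \linkS4class{CalibrationCurve}.
#' @export
fitCalibration <- function(standards) {
  standards <- as.data.frame(standards)
  if (!all(c("activity", "grey") %in% colnames(standards)))
    stop("standards need columns 'activity' and 'grey'")
  if (nrow(standards) < 2) stop("at least 2 standards are required")
  if (length(unique(standards$activity)) < 2)
    stop("all standard activities identical: calibration not invertible")
  fit <- stats::lm(grey ~ activity, data = standards)
  cf <- stats::coef(fit)
  ss_tot <- sum((standards$grey - mean(standards$grey))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  methods::new("CalibrationCurve", slope = unname(cf["activity"]),
               intercept = unname(cf["(Intercept)"]),
               rSquared = r2, standards = standards)
}

#' Convert a zymogram to a per-pixel enzyme activity map
#'
#' Inverts the calibration line: \code{activity = (grey - intercept) /
#' slope}. Negative back-calculated activities are clamped to zero and the
#' clamp count recorded.
#'
#' @param z a \linkS4class{Zymogram}.
#' @param calib a \linkS4class{CalibrationCurve}.
#' @return an \linkS4class{ActivityMap}.
#' @export
greyToActivity <- function(z, calib) {
  if (calib@slope == 0) stop("calibration slope is zero")
  act <- (z@image - calib@intercept) / calib@slope
  n_neg <- sum(act < 0)
  if (n_neg > 0) {
    message(n_neg, " pixel(s) with negative activity clamped to 0")
    act[act < 0] <- 0
  }
  methods::new("ActivityMap", activity = act, nClamped = as.integer(n_neg))
}

.check_roi <- function(img, roi) {
  if (!is.logical(roi) || !identical(dim(roi), dim(img)))
    stop("roi must be a logical mask with the image's shape")
  if (!any(roi)) stop("roi is empty")
}

#' Hotspot grey-value threshold (mean + 2 SD) over a region of interest
#'
#' Returns \code{mean(grey[roi]) + 2 * sd(grey[roi])} with the sample
#' standard deviation (n - 1 denominator).
#'
#' @param z a \linkS4class{Zymogram}.
#' @param roi logical mask of the analysed region.
#' @return threshold in grey units.
#' @export
hotspotThreshold <- function(z, roi = NULL) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(z@image), ncol(z@image))
  .check_roi(z@image, roi)
  v <- z@image[roi]
  m <- mean(v)
  s <- if (length(v) > 1) stats::sd(v) else 0
  m + 2 * s
}

#' Detect enzymatic hotspots by the mean + 2 SD rule
#'
#' A pixel is a hotspot when its grey value strictly exceeds the ROI
#' threshold. Percent hotspot area is \code{100 * Nh / (Nh + Nb)} where
#' Nh and Nb partition the ROI into hotspot and background pixels.
#' \code{eq1AsPrinted = TRUE} instead divides by \code{Nh - Nb}, the
#' literal published form of the area formula, for audit only: that
#' denominator can be negative or zero.
#'
#' @param z a \linkS4class{Zymogram}.
#' @param roi logical mask of the analysed region (whole image if NULL).
#' @param eq1AsPrinted use the literal (sign-flawed) printed denominator.
#' @return a \linkS4class{HotspotResult}.
#' @export
detectHotspots <- function(z, roi = NULL, eq1AsPrinted = FALSE) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(z@image), ncol(z@image))
  thr <- hotspotThreshold(z, roi)
  mask <- (z@image > thr) & roi
  nh <- sum(mask)
  nb <- sum(roi) - nh
  denom <- if (eq1AsPrinted) nh - nb else nh + nb
  pct <- if (denom == 0) NaN else 100 * nh / denom
  methods::new("HotspotResult", threshold = thr, mask = mask,
               percentArea = pct, nHotspot = as.integer(nh),
               nBackground = as.integer(nb))
}

#' Segment rhizoplane, rhizosphere and background compartments
#'
#' The rhizoplane is the root footprint itself; the rhizosphere is a band
#' of \code{bandWidthPx} pixels around it (8-connectivity / chessboard
#' dilation minus the root), clipped to the ROI; everything else in the
#' ROI is background (bulk soil).
#'
#' @param rootMask logical root-footprint mask.
#' @param bandWidthPx rhizosphere band width in pixels (>= 1).
#' @param roi logical region of interest (whole image if NULL).
#' @return a \linkS4class{CompartmentMasks}.
#' @export
segmentCompartments <- function(rootMask, bandWidthPx, roi = NULL) {
  if (!any(rootMask)) stop("rootMask is empty")
  if (bandWidthPx < 1) stop("bandWidthPx must be >= 1")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(rootMask), ncol(rootMask))
  if (any(rootMask & !roi)) stop("rootMask must lie within roi")
  brush <- EBImage::makeBrush(2L * as.integer(bandWidthPx) + 1L,
                              shape = "box")
  dil <- EBImage::dilate(EBImage::Image(rootMask * 1), brush) > 0
  dil <- matrix(as.logical(dil), nrow(rootMask), ncol(rootMask))
  rhizoplane <- rootMask & roi
  rhizosphere <- dil & !rootMask & roi
  background <- roi & !dil
  methods::new("CompartmentMasks", rhizoplane = rhizoplane,
               rhizosphere = rhizosphere, background = background)
}

#' Per-compartment activity statistics and hotspot percentages
#'
#' Mean and SD of activity per compartment, plus percent hotspot area.
#' Hotspot detection can use a compartment-local mean + 2 SD threshold
#' (default) or one global threshold computed over the union of the three
#' compartments. Empty compartments yield NA statistics, never 0.
#'
#' @param a an \linkS4class{ActivityMap}.
#' @param masks a \linkS4class{CompartmentMasks}.
#' @param thresholdMode "local" (per-compartment threshold) or "global".
#' @return data.frame with one row per compartment: n_px, mean, sd,
#'   percent_hotspot.
#' @export
compartmentStats <- function(a, masks, thresholdMode = c("local", "global")) {
  thresholdMode <- match.arg(thresholdMode)
  act <- a@activity
  z <- methods::new("Zymogram", image = act, pixelSize = 1,
                    exposure = list())
  roi_all <- masks@rhizoplane | masks@rhizosphere | masks@background
  global_thr <- if (thresholdMode == "global") hotspotThreshold(z, roi_all)
  comp <- list(rhizoplane = masks@rhizoplane,
               rhizosphere = masks@rhizosphere,
               background = masks@background)
  rows <- lapply(names(comp), function(nm) {
    m <- comp[[nm]]
    n <- sum(m)
    if (n == 0)
      return(data.frame(compartment = nm, n_px = 0L, mean = NA_real_,
                        sd = NA_real_, percent_hotspot = NA_real_))
    v <- act[m]
    pct <- if (thresholdMode == "local")
      detectHotspots(z, m)@percentArea
    else 100 * sum(act[m] > global_thr) / n
    data.frame(compartment = nm, n_px = n, mean = mean(v),
               sd = if (n > 1) stats::sd(v) else NA_real_,
               percent_hotspot = pct)
  })
  do.call(rbind, rows)
}
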