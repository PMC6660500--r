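#' Planar scintigraphic count image
#'
#' Container for a 2-D anterior thoracic count image. Measured (Poisson)
#' images hold integer counts; noiseless phantom images may hold real-valued
#' expectation counts.
#'
#' @param counts Non-negative numeric matrix of counts.
#' @param pixel_size_mm Pixel size in mm (isotropic).
#' @param timepoint `"early"` (~15 min post injection) or `"late"` (~4 h).
#' @param duration_min Acquisition duration in minutes.
#' @return An object of class `planar_image`.
#' @export
planar_image <- function(counts, pixel_size_mm = 4.42,
                         timepoint = c("early", "late"),
                         duration_min = 10) {
  timepoint <- match.arg(timepoint)
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("count matrix must be non-empty")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (pixel_size_mm <= 0) stop("pixel size must be positive")
  structure(list(counts = counts, pixel_size_mm = pixel_size_mm,
                 timepoint = timepoint, duration_min = duration_min),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("planar_image: %d x %d, %s, %.2f mm px, %g min, total %.4g counts\n",
              nrow(x$counts), ncol(x$counts), x$timepoint, x$pixel_size_mm,
              x$duration_min, sum(x$counts)))
  invisible(x)
}

#' Mean counts per pixel inside an ROI
#'
#' Arithmetic mean of the counts over the pixels whose centers fall inside the
#' ROI (see [roi_pixels()] for the rasterization rule).
#'
#' @param image A [planar_image()].
#' @param roi An ROI from [roi_polygon()] or [roi_square()].
#' @return Mean counts per pixel (scalar).
#' @export
mean_counts <- function(image, roi) {
  stopifnot(inherits(image, "planar_image"))
  px <- roi_pixels(roi, dim(image$counts))
  mean(image$counts[px])
}

#' Heart-to-mediastinum ratio
#'
#' Mean counts per pixel in the myocardial ROI divided by the mean counts per
#' pixel in the mediastinal reference ROI. The ratio is the standard global
#' index of cardiac sympathetic innervation on planar mIBG images and is
#' invariant to global count scaling.
#'
#' @param image A [planar_image()].
#' @param heart_roi Polygonal myocardial ROI.
#' @param med_roi 7 x 7 mediastinal square ROI.
#' @return The dimensionless H/M ratio.
#' @export
hm_ratio <- function(image, heart_roi, med_roi) {
  h <- mean_counts(image, heart_roi)
  m <- mean_counts(image, med_roi)
  if (m <= 0) stop("mediastinal mean counts are zero; H/M undefined")
  h / m
}

#' Background- and decay-corrected myocardial washout
#'
#' Percentage loss of background-corrected cardiac tracer between the early
#' and late planar images:
#' \deqn{WO = 100 \times \frac{(H_e - M_e) - (H_l - M_l) \times f}{H_e - M_e}}
#' where `f` corrects the late counts for physical isotope decay over the
#' early-to-late interval. The conventional factor for 123-I over 3 h 45 min
#' is 1.21 (the default); [decay_factor()] recomputes it from the half-life.
#'
#' @param He,Me Early heart and mediastinal mean counts per pixel.
#' @param Hl,Ml Late heart and mediastinal mean counts per pixel.
#' @param decay_factor Decay-correction multiplier applied to the late
#'   background-corrected counts.
#' @return Washout in percent. 0 means no net tracer loss beyond physical
#'   decay; 100 means complete washout (`Hl == Ml`).
#' @export
washout <- function(He, Me, Hl, Ml, decay_factor = 1.21) {
  if (any(c(He, Me, Hl, Ml) < 0)) stop("counts must be non-negative")
  if (He <= Me) {
    stop("washout undefined: early heart counts must exceed mediastinal counts")
  }
  if (decay_factor <= 0) stop("decay factor must be positive")
  100 * ((He - Me) - (Hl - Ml) * decay_factor) / (He - Me)
}

#' Physical decay-correction factor
#'
#' Multiplier that restores counts lost to physical isotope decay over an
#' acquisition interval: `2^(interval / half_life)`. For 123-I
#' (half-life 13.22 h) over the conventional 3 h 45 min early-to-late
#' interval this evaluates to 1.217, consistent with the conventional
#' two-decimal constant 1.21 used in [washout()].
#'
#' @param interval_hours Time between the early and late acquisitions, hours.
#' @param half_life_hours Isotope half-life in hours; default 13.22 (123-I).
#' @return The decay-correction multiplier (>= 1 for positive intervals).
#' @export
decay_factor <- function(interval_hours, half_life_hours = 13.22) {
  if (interval_hours < 0) stop("interval must be non-negative")
  if (half_life_hours <= 0) stop("half-life must be positive")
  2^(interval_hours / half_life_hours)
}

#' Automatic mediastinal ROI placement
#'
#' Finds the 7 x 7 pixel square with minimal mean counts inside the upper
#' midline band of the image, emulating manual placement of the mediastinal
#' reference region on the upper half of the mediastinum. The search is
#' restricted to the middle third of the columns and the upper half of the
#' rows, with a 1-pixel margin from the image border. Ties resolve to the
#' topmost, then leftmost candidate.
#'
#' @param image A [planar_image()].
#' @param size Square side in pixels (default 7).
#' @return A [roi_square()].
#' @export
auto_mediastinal_roi <- function(image, size = 7L) {
  stopifnot(inherits(image, "planar_image"))
  cts <- image$counts
  nr <- nrow(cts); nc <- ncol(cts)
  # candidate anchors: square fully inside [1-px margin], anchor rows in the
  # upper half, anchor cols in the middle third
  row_max <- min(floor(nr / 2), nr - size - 1L)
  col_lo <- max(1L, floor(nc / 3))
  col_hi <- min(nc - size - 1L, ceiling(2 * nc / 3) - size)
  if (row_max < 1L || col_hi < col_lo) {
    stop("image too small for automatic mediastinal ROI placement")
  }
  # summed-area table for O(1) window sums
  sat <- apply(apply(cts, 2, cumsum), 1, cumsum)  # sat[c, r] after transpose
  sat <- t(sat)
  win_sum <- function(r0, c0) {  # 1-based top-left, size x size
    r1 <- r0 + size - 1L; c1 <- c0 + size - 1L
    s <- sat[r1, c1]
    if (r0 > 1L) s <- s - sat[r0 - 1L, c1]
    if (c0 > 1L) s <- s - sat[r1, c0 - 1L]
    if (r0 > 1L && c0 > 1L) s <- s + sat[r0 - 1L, c0 - 1L]
    s
  }
  best <- NULL; best_sum <- Inf
  for (r0 in seq(2L, row_max + 1L)) {       # 1-based; >= 2 keeps the margin
    for (c0 in seq(col_lo + 1L, col_hi + 1L)) {
      s <- win_sum(r0, c0)
      if (s < best_sum - 1e-9) {            # strict improvement => top/left tie-break
        best_sum <- s
        best <- c(r0, c0)
      }
    }
  }
  if (is.null(best)) stop("no valid mediastinal ROI candidate; supply one manually")
  roi_square(row0 = best[1] - 1L, col0 = best[2] - 1L, size = size)
}

#' Full planar quantification
#'
#' Computes the four mean counts, both H/M ratios, and washout from an
#' early/late image pair and their ROI sets.
#'
#' @param early,late [planar_image()] objects at the two time points.
#' @param roi_early ROI set: a list with elements `heart` (polygon) and
#'   `mediastinum` (7 x 7 square).
#' @param roi_late ROI set for the late image; defaults to `roi_early`
#'   (propagated ROIs).
#' @param decay_factor Decay correction passed to [washout()].
#' @return A `planar_metrics` list: `He`, `Me`, `Hl`, `Ml`, `early_hm`,
#'   `late_hm`, `wo_percent`.
#' @examples
#' ph <- make_planar_pair(planar_truth(He = 162, Me = 100, Hl = 130, Ml = 90))
#' planar_metrics(ph$early, ph$late, ph$roi)
#' @export
planar_metrics <- function(early, late, roi_early, roi_late = roi_early,
                           decay_factor = 1.21) {
  stopifnot(early$timepoint == "early", late$timepoint == "late")
  He <- mean_counts(early, roi_early$heart)
  Me <- mean_counts(early, roi_early$mediastinum)
  Hl <- mean_counts(late, roi_late$heart)
  Ml <- mean_counts(late, roi_late$mediastinum)
  if (Me <= 0 || Ml <= 0) stop("mediastinal mean counts are zero; H/M undefined")
  out <- list(He = He, Me = Me, Hl = Hl, Ml = Ml,
              early_hm = He / Me, late_hm = Hl / Ml,
              wo_percent = washout(He, Me, Hl, Ml, decay_factor))
  class(out) <- "planar_metrics"
  out
}

#' @export
print.planar_metrics <- function(x, ...) {
  cat(sprintf("planar metrics: early H/M %.3f, late H/M %.3f, washout %.1f%%\n",
              x$early_hm, x$late_hm, x$wo_percent))
  cat(sprintf("  means/px: He %.2f  Me %.2f  Hl %.2f  Ml %.2f\n",
              x$He, x$Me, x$Hl, x$Ml))
  invisible(x)
}
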