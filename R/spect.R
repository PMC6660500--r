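#' Short-axis SPECT count volume
#'
#' A reconstructed, already reoriented short-axis volume: a 3-D count array
#' indexed `[slice, row, col]` with the slices running from apex to base,
#' plus the left-ventricular axis metadata needed to place the 17-segment
#' model (per-slice center, radial wall band, apex/base slice range and the
#' number of apical-cap slices).
#'
#' @param counts Non-negative 3-D numeric array `[slice, row, col]`.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param lv_axis List with `center` (length-2, 0-based `c(row, col)`, or an
#'   `n_slice x 2` matrix of per-slice centers), `r_inner`, `r_outer` (wall
#'   band radii in voxels), `apex_slice` < `base_slice` (0-based inclusive),
#'   and `apex_cap_slices` (number of tip slices forming segment 17).
#' @return An object of class `short_axis_volume`.
#' @export
short_axis_volume <- function(counts, voxel_size_mm = 6.8, lv_axis) {
  if (length(dim(counts)) != 3L) stop("counts must be a 3-D array")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  g <- lv_axis
  ns <- dim(counts)[1]
  if (is.null(dim(g$center))) g$center <- matrix(g$center, ns, 2, byrow = TRUE)
  if (g$apex_slice >= g$base_slice) stop("apex slice index must be < base slice index")
  if (g$apex_slice < 0L || g$base_slice > ns - 1L) {
    stop("apex/base slice indices outside volume")
  }
  if (any(g$center[, 1] < 0) || any(g$center[, 1] > dim(counts)[2] - 1) ||
      any(g$center[, 2] < 0) || any(g$center[, 2] > dim(counts)[3] - 1)) {
    stop("slice centers outside slice bounds")
  }
  if (g$r_inner < 0 || g$r_outer <= g$r_inner) stop("need 0 <= r_inner < r_outer")
  if (is.null(g$apex_cap_slices)) g$apex_cap_slices <- 1L
  structure(list(counts = counts, voxel_size_mm = voxel_size_mm, lv_axis = g),
            class = "short_axis_volume")
}

# Ring allocation shared by the generator and the quantifier: the myocardial
# slices apex..base are split into the apical cap (segment 17), then apical /
# mid / basal thirds (extra slices go to basal, then mid).
ring_of_slice <- function(slice, geom) {
  span <- geom$base_slice - geom$apex_slice + 1L
  cap <- min(geom$apex_cap_slices, span - 3L)
  if (cap < 1L) cap <- 1L
  rest <- span - cap
  n_ap <- rest %/% 3L
  n_mid <- rest %/% 3L + as.integer(rest %% 3L == 2L)
  k <- slice - geom$apex_slice  # 0-based offset from apex
  out <- rep(NA_character_, length(slice))
  out[k >= 0 & k < cap] <- "apex"
  out[k >= cap & k < cap + n_ap] <- "apical"
  out[k >= cap + n_ap & k < cap + n_ap + n_mid] <- "mid"
  out[k >= cap + n_ap + n_mid & k < span] <- "basal"
  out
}

# AHA angular convention used throughout: theta measured from the image
# "right" direction (+col), increasing counter-clockwise with anterior at the
# top (decreasing row). 6-sector rings anchor at the anterior-septal junction
# (120 deg): anterior [60,120), anteroseptal [120,180), inferoseptal
# [180,240), inferior [240,300), inferolateral [300,360), anterolateral
# [0,60). Apical 4-sector ring: anterior [45,135), septal [135,225),
# inferior [225,315), lateral elsewhere.
sector6 <- function(theta) {
  idx <- integer(length(theta))
  idx[theta >= 60 & theta < 120] <- 1L   # anterior
  idx[theta >= 120 & theta < 180] <- 2L  # anteroseptal
  idx[theta >= 180 & theta < 240] <- 3L  # inferoseptal
  idx[theta >= 240 & theta < 300] <- 4L  # inferior
  idx[theta >= 300 & theta < 360] <- 5L  # inferolateral
  idx[theta >= 0 & theta < 60] <- 6L     # anterolateral
  idx
}

sector4 <- function(theta) {
  idx <- rep(4L, length(theta))          # lateral
  idx[theta >= 45 & theta < 135] <- 1L   # anterior
  idx[theta >= 135 & theta < 225] <- 2L  # septal
  idx[theta >= 225 & theta < 315] <- 3L  # inferior
  idx
}

# Per-voxel segment labels (1..17; NA outside the wall) for one slice.
slice_segment_labels <- function(slice, geom, dim_rc) {
  ring <- ring_of_slice(slice, geom)
  if (is.na(ring)) return(matrix(NA_integer_, dim_rc[1], dim_rc[2]))
  ctr <- geom$center[slice + 1L, ]
  rows <- matrix(0:(dim_rc[1] - 1L), dim_rc[1], dim_rc[2])
  cols <- matrix(0:(dim_rc[2] - 1L), dim_rc[1], dim_rc[2], byrow = TRUE)
  dy <- ctr[1] - rows     # +y is "up" (toward smaller row index)
  dx <- cols - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  lab <- matrix(NA_integer_, dim_rc[1], dim_rc[2])
  if (ring == "apex") {
    lab[r <= geom$r_outer] <- 17L
  } else {
    wall <- r >= geom$r_inner & r <= geom$r_outer
    seg <- switch(ring,
                  basal = sector6(theta),
                  mid = sector6(theta) + 6L,
                  apical = sector4(theta) + 12L)
    lab[wall] <- seg[wall]
  }
  lab
}

# Full 3-D label array from the axis metadata alone.
segment_label_array <- function(dim3, geom) {
  lab <- array(NA_integer_, dim3)
  for (s in geom$apex_slice:geom$base_slice) {
    lab[s + 1L, , ] <- slice_segment_labels(s, geom, dim3[2:3])
  }
  lab
}

#' Per-segment uptake from a short-axis volume
#'
#' Averages the counts over each AHA segment's wall voxels (annulus band
#' around the per-slice center, angular sectors as in the standard layout;
#' the apical cap is a filled disk forming segment 17) and expresses each
#' segment as a percentage of the maximum segmental uptake.
#'
#' @param volume A [short_axis_volume()].
#' @param background Count level subtracted before normalization (default 0;
#'   synthetic volumes are generated background-free by default).
#' @return Numeric vector of 17 uptake percentages, max = 100.
#' @export
segment_uptake <- function(volume, background = 0) {
  stopifnot(inherits(volume, "short_axis_volume"))
  lab <- segment_label_array(dim(volume$counts), volume$lv_axis)
  vals <- volume$counts - background
  vals[vals < 0] <- 0
  up <- vapply(1:17, function(s) {
    v <- vals[which(lab == s)]
    if (length(v) == 0L) stop("segment ", s, " has no wall voxels; check geometry")
    mean(v)
  }, numeric(1))
  mx <- max(up)
  if (mx <= 0) stop("all-zero myocardial counts; uptake undefined")
  pmin(100, 100 * up / mx)  # guard the 100% ceiling against rounding noise
}

#' Five-point segmental defect score
#'
#' Scores a segmental uptake percentage on the conventional 5-point scale.
#' After rounding to the nearest integer percent: uptake of at least 70% is
#' normal (0); 60-69% mildly reduced (1); 50-59% moderately reduced (2);
#' 40-49% severely reduced (3); 39% or less absent (4).
#'
#' @param uptake_pct Uptake percentage(s) in `[0, 100]`; vectorized.
#' @param strict_gt70 If `TRUE`, only uptake strictly greater than 70% scores
#'   0 and exactly 70% falls into the mild-reduction bin. Default `FALSE`
#'   (contiguous bins: >= 70 is normal).
#' @return Integer score(s) in 0..4.
#' @export
score_segment <- function(uptake_pct, strict_gt70 = FALSE) {
  if (anyNA(uptake_pct) || any(uptake_pct < 0 | uptake_pct > 100)) {
    stop("uptake must lie in [0, 100]")
  }
  r <- round(uptake_pct)
  normal <- if (strict_gt70) r > 70 else r >= 70
  sc <- integer(length(r))
  sc[!normal & r >= 60] <- 1L
  sc[r < 60 & r >= 50] <- 2L
  sc[r < 50 & r >= 40] <- 3L
  sc[r < 40] <- 4L
  sc
}

#' Scored 17-segment profile
#'
#' @param uptake_pct 17 segmental uptake percentages (max normalized to 100).
#' @param timepoint `"early"` or `"late"`.
#' @param strict_gt70 Scoring boundary policy, see [score_segment()].
#' @return A `segment_profile`: uptake, integer scores, timepoint.
#' @export
segment_profile <- function(uptake_pct, timepoint = c("early", "late"),
                            strict_gt70 = FALSE) {
  timepoint <- match.arg(timepoint)
  if (length(uptake_pct) != 17L) stop("a segment profile has exactly 17 segments")
  structure(list(uptake_pct = as.numeric(uptake_pct),
                 scores = score_segment(uptake_pct, strict_gt70),
                 timepoint = timepoint),
            class = "segment_profile")
}

#' Summed defect scores
#'
#' Early summed score (ESS), late summed score (LSS) and their difference
#' DSS = ESS - LSS, each the integer sum of the 17 segmental scores at the
#' respective time point. A negative DSS indicates more extensive defects on
#' the late images.
#'
#' @param early,late [segment_profile()] objects at the two time points.
#' @return List with integers `ess`, `lss`, `dss`.
#' @export
summed_scores <- function(early, late) {
  stopifnot(inherits(early, "segment_profile"), inherits(late, "segment_profile"))
  if (early$timepoint != "early" || late$timepoint != "late") {
    stop("profiles must be an early/late pair")
  }
  if (length(early$scores) != 17L || length(late$scores) != 17L ||
      anyNA(early$scores) || anyNA(late$scores)) {
    stop("profiles must carry 17 non-missing scores")
  }
  ess <- as.integer(sum(early$scores))
  lss <- as.integer(sum(late$scores))
  list(ess = ess, lss = lss, dss = ess - lss)
}

#' Simulated multi-reader segmental scoring
#'
#' Emulates independent visual readers: each reader observes the segmental
#' uptake percentages with additive Gaussian perturbation (their calibration
#' bias and imprecision) before applying the 5-point score. Feeds the ICC
#' inter-observer analysis.
#'
#' @param x A [short_axis_volume()] or a 17-vector of true uptake percentages.
#' @param reader_configs List (length >= 2) of per-reader lists with elements
#'   `sd` (perturbation SD in uptake points) and optional `bias`.
#' @param timepoint Passed to [segment_profile()].
#' @param seed Optional integer seed for reproducibility.
#' @return List of per-reader [segment_profile()] objects.
#' @export
multi_reader_scores <- function(x, reader_configs, timepoint = "early",
                                seed = NULL) {
  if (length(reader_configs) < 2L) stop("need at least 2 reader configurations")
  uptake <- if (inherits(x, "short_axis_volume")) segment_uptake(x) else as.numeric(x)
  if (length(uptake) != 17L) stop("expected 17 segmental uptake values")
  if (!is.null(seed)) set.seed(seed)
  lapply(reader_configs, function(cf) {
    bias <- if (is.null(cf$bias)) 0 else cf$bias
    pert <- uptake + bias + stats::rnorm(17L, 0, cf$sd)
    pert <- pmin(100, pmax(0, pert))
    segment_profile(pert, timepoint = timepoint)
  })
}
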