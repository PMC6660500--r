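#' Ground truth for a planar phantom pair
#'
#' Holds the true mean counts per pixel of the heart (H) and mediastinal (M)
#' regions on the early (e) and late (l) images, and the washout percentage
#' they imply. The washout field is always derived from the four means via
#' [washout()], so the truth is closed under the washout equation.
#'
#' @param He,Me Early heart/mediastinal mean counts per pixel (`He > Me >= 0`).
#' @param Hl,Ml Late heart/mediastinal mean counts per pixel (non-negative).
#' @param decay_factor Decay correction used to derive the true washout.
#' @return A `planar_truth` list: `He`, `Me`, `Hl`, `Ml`, `WO`.
#' @export
planar_truth <- function(He, Me, Hl, Ml, decay_factor = 1.21) {
  if (anyNA(c(He, Me, Hl, Ml))) stop("truth means must be non-missing")
  if (!(He > Me && Me >= 0)) stop("invalid truth: need He > Me >= 0")
  if (Hl < 0 || Ml < 0) stop("invalid truth: late means must be non-negative")
  structure(list(He = He, Me = Me, Hl = Hl, Ml = Ml,
                 WO = washout(He, Me, Hl, Ml, decay_factor),
                 decay_factor = decay_factor),
            class = "planar_truth")
}

# Phantom layout shared by both time points: a low-count vertical mediastinal
# band in the middle third of the image, lungs elsewhere, and a circular
# "heart" in the lower half straddling the band. Returns region masks and the
# heart polygon.
planar_layout <- function(shape) {
  nr <- shape[1]; nc <- shape[2]
  band_cols <- seq.int(floor(nc * 3 / 8), ceiling(nc * 5 / 8)) # 0-based cols
  heart_c <- c(x = (nc - 1) * 0.52, y = (nr - 1) * 0.62)
  heart_r <- 0.17 * min(nr, nc)
  ang <- seq(0, 2 * pi, length.out = 33L)[-33L]
  poly <- roi_polygon(cbind(x = heart_c["x"] + heart_r * cos(ang),
                            y = heart_c["y"] + heart_r * sin(ang)))
  list(band_cols = band_cols, heart_poly = poly,
       med_anchor = c(row0 = max(1L, round(nr * 0.10)),
                      col0 = round((nc - 1) / 2 - 3)))
}

#' Synthetic planar early/late image pair
#'
#' Builds an anterior-view phantom pair with a circular myocardial region at
#' the true heart mean counts, a vertical mediastinal band at the true
#' mediastinal mean, and lung background slightly above the mediastinal
#' level. With `noise = "on"` each pixel is an independent Poisson draw with
#' the phantom mean as its expectation; with `noise = "off"` the images are
#' exact expectation images, so the downstream quantification reproduces the
#' truth to machine precision.
#'
#' @param truth A [planar_truth()].
#' @param image_shape `c(nrow, ncol)`, at least 32 x 32; default 128 x 128.
#' @param noise `"off"` (expectation image) or `"on"` (Poisson counts).
#' @param seed Optional integer seed (used when `noise = "on"`).
#' @param lung_factor Lung background as a multiple of the mediastinal mean.
#' @return List with `early` and `late` [planar_image()]s and `roi`, the
#'   generating ROI set (`heart` polygon, `mediastinum` 7 x 7 square).
#' @export
make_planar_pair <- function(truth, image_shape = c(128L, 128L),
                             noise = c("off", "on"), seed = NULL,
                             lung_factor = 1.3) {
  noise <- match.arg(noise)
  stopifnot(inherits(truth, "planar_truth"))
  if (any(image_shape < 32L)) stop("image shape must be at least 32 x 32")
  lay <- planar_layout(image_shape)
  paint <- function(H, M) {
    img <- matrix(M * lung_factor, image_shape[1], image_shape[2])
    img[, lay$band_cols + 1L] <- M
    px <- roi_pixels(lay$heart_poly, image_shape)
    img[px] <- H
    img
  }
  if (!is.null(seed)) set.seed(seed)
  mk <- function(H, M, tp) {
    img <- paint(H, M)
    if (noise == "on") img <- matrix(stats::rpois(length(img), img), nrow(img))
    planar_image(img, timepoint = tp)
  }
  list(early = mk(truth$He, truth$Me, "early"),
       late = mk(truth$Hl, truth$Ml, "late"),
       roi = list(heart = lay$heart_poly,
                  mediastinum = roi_square(lay$med_anchor["row0"],
                                           lay$med_anchor["col0"])))
}

#' Ground truth for a SPECT short-axis phantom
#'
#' @param segment_uptake 17 values in `[0, 100]` (% of maximum); the maximum
#'   must be 100 when any myocardium is present.
#' @param dim Volume dimensions `c(slices, rows, cols)`.
#' @param center 0-based `c(row, col)` wall center (all slices).
#' @param r_inner,r_outer Wall band radii in voxels.
#' @param apex_slice,base_slice 0-based inclusive myocardial slice range.
#' @param apex_cap_slices Tip slices forming segment 17.
#' @param peak_counts Voxel mean at 100% uptake.
#' @param background_level Count level outside the wall.
#' @return A `volume_truth` list.
#' @export
volume_truth <- function(segment_uptake,
                         dim = c(20L, 64L, 64L),
                         center = c(31.5, 31.5),
                         r_inner = 12, r_outer = 18,
                         apex_slice = 2L, base_slice = 17L,
                         apex_cap_slices = 2L,
                         peak_counts = 200, background_level = 0) {
  if (length(segment_uptake) != 17L) stop("need exactly 17 segment uptake values")
  if (any(segment_uptake < 0 | segment_uptake > 100)) {
    stop("segment uptake must lie in [0, 100]")
  }
  if (max(segment_uptake) != 100) stop("maximum segment uptake must equal 100")
  if (center[1] - r_outer < 0 || center[1] + r_outer > dim[2] - 1 ||
      center[2] - r_outer < 0 || center[2] + r_outer > dim[3] - 1 ||
      base_slice > dim[1] - 1L || apex_slice < 0L) {
    stop("wall geometry exceeds volume bounds")
  }
  structure(list(segment_uptake = as.numeric(segment_uptake), dim = dim,
                 center = center, r_inner = r_inner, r_outer = r_outer,
                 apex_slice = as.integer(apex_slice),
                 base_slice = as.integer(base_slice),
                 apex_cap_slices = as.integer(apex_cap_slices),
                 peak_counts = peak_counts,
                 background_level = background_level),
            class = "volume_truth")
}

#' Synthetic short-axis SPECT volume
#'
#' Paints an annular left-ventricular wall whose angular and apical sectors
#' follow the AHA 17-segment layout; each segment's voxel mean is
#' proportional to its true uptake percentage. With `noise = "on"` voxel
#' counts are Poisson draws around those means.
#'
#' @param truth A [volume_truth()].
#' @param noise `"off"` or `"on"`.
#' @param seed Optional integer seed (used when `noise = "on"`).
#' @return A [short_axis_volume()]; the generating voxel-to-segment label
#'   array is attached as attribute `"segment_map"` for test oracles.
#' @export
make_spect_volume <- function(truth, noise = c("off", "on"), seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(truth, "volume_truth"))
  geom <- list(center = truth$center, r_inner = truth$r_inner,
               r_outer = truth$r_outer, apex_slice = truth$apex_slice,
               base_slice = truth$base_slice,
               apex_cap_slices = truth$apex_cap_slices)
  geom$center <- matrix(geom$center, truth$dim[1], 2, byrow = TRUE)
  lab <- segment_label_array(truth$dim, geom)
  arr <- array(truth$background_level, truth$dim)
  wall <- !is.na(lab)
  arr[wall] <- truth$background_level +
    truth$peak_counts * truth$segment_uptake[lab[wall]] / 100
  if (noise == "on") {
    if (!is.null(seed)) set.seed(seed)
    arr <- array(stats::rpois(length(arr), arr), truth$dim)
  }
  vol <- short_axis_volume(arr, lv_axis = geom)
  attr(vol, "segment_map") <- lab
  vol
}
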