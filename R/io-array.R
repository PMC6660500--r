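#' Write/read a planar image as a plain array container
#'
#' The plain container is a tab-separated count matrix (`<prefix>.tsv`) with
#' a JSON sidecar (`<prefix>.json`) carrying pixel size, time point and
#' acquisition duration — a text-only round-trip format for tests and
#' scripted pipelines.
#'
#' @param image A [planar_image()].
#' @param prefix Path prefix (without extension).
#' @return `write_planar_array` returns the prefix invisibly;
#'   `read_planar_array` returns a [planar_image()].
#' @export
write_planar_array <- function(image, prefix) {
  stopifnot(inherits(image, "planar_image"))
  utils::write.table(image$counts, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(pixel_size_mm = image$pixel_size_mm,
                            timepoint = image$timepoint,
                            duration_min = image$duration_min,
                            shape = dim(image$counts)),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_planar_array
#' @export
read_planar_array <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  counts <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(counts) <- NULL
  if (!all(dim(counts) == meta$shape)) stop("sidecar shape does not match matrix")
  planar_image(counts, pixel_size_mm = meta$pixel_size_mm,
               timepoint = meta$timepoint, duration_min = meta$duration_min)
}

#' Write/read a short-axis volume as a plain array container
#'
#' Slices are stacked vertically in one tab-separated matrix; the JSON
#' sidecar carries the dimensions, voxel size and left-ventricular axis
#' metadata.
#'
#' @param volume A [short_axis_volume()].
#' @param prefix Path prefix (without extension).
#' @export
write_volume_array <- function(volume, prefix) {
  stopifnot(inherits(volume, "short_axis_volume"))
  d <- dim(volume$counts)
  flat <- do.call(rbind, lapply(seq_len(d[1]), function(s) volume$counts[s, , ]))
  utils::write.table(flat, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  g <- volume$lv_axis
  jsonlite::write_json(list(dim = d, voxel_size_mm = volume$voxel_size_mm,
                            lv_axis = list(center = g$center,
                                           r_inner = g$r_inner,
                                           r_outer = g$r_outer,
                                           apex_slice = g$apex_slice,
                                           base_slice = g$base_slice,
                                           apex_cap_slices = g$apex_cap_slices)),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_volume_array
#' @export
read_volume_array <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  d <- meta$dim
  arr <- array(0, d)
  for (s in seq_len(d[1])) arr[s, , ] <- flat[(s - 1) * d[2] + seq_len(d[2]), ]
  g <- meta$lv_axis
  if (!is.null(dim(g$center)) && ncol(g$center) == 2) g$center <- as.matrix(g$center)
  short_axis_volume(arr, voxel_size_mm = meta$voxel_size_mm, lv_axis = g)
}

#' Write/read ROI sets as JSON
#'
#' Vertex lists in 0-based, row-major pixel coordinates.
#'
#' @param roi_set List with `heart` ([roi_polygon()]) and `mediastinum`
#'   ([roi_square()]).
#' @param path JSON file path.
#' @export
write_roi_set <- function(roi_set, path) {
  jsonlite::write_json(
    list(heart = list(vertices = unname(as.data.frame(roi_set$heart$vertices))),
         mediastinum = list(row0 = roi_set$mediastinum$row0,
                            col0 = roi_set$mediastinum$col0,
                            size = roi_set$mediastinum$size)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- as.matrix(j$heart$vertices)
  colnames(v) <- c("x", "y")
  list(heart = roi_polygon(v),
       mediastinum = roi_square(j$mediastinum$row0, j$mediastinum$col0,
                                j$mediastinum$size))
}

#' Write/read a cohort table as CSV
#'
#' Comma-separated, UTF-8, header row, missing values as empty fields,
#' months as decimal floats. See the package vignette for the column
#' dictionary.
#'
#' @param cohort Cohort data frame (from [make_cohort()] or compatible).
#' @param path CSV file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if ("event_type" %in% names(df)) {
    df$event_type <- factor(df$event_type, levels = event_type_levels())
  }
  df
}
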