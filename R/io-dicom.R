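# Minimal DICOM support: explicit-VR little-endian secondary-capture objects
# carrying a single-frame planar count image or a multi-frame short-axis
# volume. Only the tags the pipeline needs are written/understood; unknown
# elements are skipped on read.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_SC_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.7"

# ---- low-level encoding -----------------------------------------------------

dcm_uint <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                       endian = "little")

# even-length padding required by the standard
dcm_pad <- function(r, pad = as.raw(0L)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

dcm_element <- function(group, element, vr, value_raw) {
  value_raw <- dcm_pad(value_raw,
                       if (vr %in% c("UI")) as.raw(0L) else charToRaw(" ")[1])
  head <- c(dcm_uint(group, 2), dcm_uint(element, 2), charToRaw(vr))
  hdr <- if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(head, raw(2), dcm_uint(length(value_raw), 4))
  } else {
    c(head, dcm_uint(length(value_raw), 2))
  }
  c(hdr, value_raw)
}

dcm_str <- function(group, element, vr, s) {
  dcm_element(group, element, vr, charToRaw(s))
}

dcm_us <- function(group, element, v) {
  dcm_element(group, element, "US", dcm_uint(v, 2))
}

# ---- writing ----------------------------------------------------------------

dcm_pixel_raw <- function(mat_list) {
  vals <- unlist(lapply(mat_list, function(m) as.vector(t(m))))  # row-major
  if (any(vals < 0) || any(vals > 65535)) {
    stop("pixel values outside the 16-bit unsigned range")
  }
  writeBin(as.integer(round(vals)), raw(), size = 2, endian = "little")
}

dcm_write <- function(path, modality, rows, cols, pixel_raw,
                      pixel_spacing_mm = NULL, n_frames = NULL,
                      series_description = NULL) {
  # deterministic instance UID derived from the content (reproducible bundles)
  sig <- sum(as.numeric(pixel_raw[seq(1, length(pixel_raw), by = 7)])) +
    1e3 * rows + cols
  sop_uid <- sprintf("2.25.%.0f%d%d", sig %% 1e12, rows, cols)
  meta <- c(dcm_str(0x0002, 0x0002, "UI", DICOM_SC_SOP_CLASS),
            dcm_str(0x0002, 0x0003, "UI", sop_uid),
            dcm_str(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT_LE))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_uint(length(meta), 4)), meta)
  ds <- c(dcm_str(0x0008, 0x0016, "UI", DICOM_SC_SOP_CLASS),
          dcm_str(0x0008, 0x0018, "UI", sop_uid),
          dcm_str(0x0008, 0x0060, "CS", modality))
  if (!is.null(series_description)) {
    ds <- c(ds, dcm_str(0x0008, 0x103E, "LO", series_description))
  }
  if (!is.null(n_frames)) {
    ds <- c(ds, dcm_str(0x0028, 0x0008, "IS", as.character(n_frames)))
  }
  ds <- c(ds,
          dcm_us(0x0028, 0x0002, 1L),
          dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
          dcm_us(0x0028, 0x0010, rows),
          dcm_us(0x0028, 0x0011, cols))
  if (!is.null(pixel_spacing_mm)) {
    ds <- c(ds, dcm_str(0x0028, 0x0030, "DS",
                        sprintf("%g\\%g", pixel_spacing_mm, pixel_spacing_mm)))
  }
  ds <- c(ds,
          dcm_us(0x0028, 0x0100, 16L), dcm_us(0x0028, 0x0101, 16L),
          dcm_us(0x0028, 0x0102, 15L), dcm_us(0x0028, 0x0103, 0L),
          dcm_element(0x7FE0, 0x0010, "OW", pixel_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

#' Write a planar image as a DICOM secondary-capture file
#'
#' Explicit-VR little-endian, 16-bit unsigned pixels; the time point is
#' stored in the series description. Poisson count images round-trip
#' exactly; expectation images are rounded to integers on write.
#'
#' @param image A [planar_image()].
#' @param path Output file path.
#' @export
write_planar_dicom <- function(image, path) {
  stopifnot(inherits(image, "planar_image"))
  dcm_write(path, modality = "NM",
            rows = nrow(image$counts), cols = ncol(image$counts),
            pixel_raw = dcm_pixel_raw(list(image$counts)),
            pixel_spacing_mm = image$pixel_size_mm,
            series_description = paste0("mibg-planar-", image$timepoint))
}

#' Write a short-axis volume as a multi-frame DICOM file
#'
#' The left-ventricular axis metadata is not representable in plain
#' secondary capture and travels in a JSON sidecar (`<path>.json`).
#'
#' @param volume A [short_axis_volume()].
#' @param path Output file path.
#' @export
write_volume_dicom <- function(volume, path) {
  stopifnot(inherits(volume, "short_axis_volume"))
  d <- dim(volume$counts)
  frames <- lapply(seq_len(d[1]), function(s) volume$counts[s, , ])
  dcm_write(path, modality = "NM", rows = d[2], cols = d[3],
            pixel_raw = dcm_pixel_raw(frames),
            pixel_spacing_mm = volume$voxel_size_mm, n_frames = d[1],
            series_description = "mibg-spect-short-axis")
  g <- volume$lv_axis
  jsonlite::write_json(list(lv_axis = list(center = g$center,
                                           r_inner = g$r_inner,
                                           r_outer = g$r_outer,
                                           apex_slice = g$apex_slice,
                                           base_slice = g$base_slice,
                                           apex_cap_slices = g$apex_cap_slices)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- reading ----------------------------------------------------------------

dcm_parse <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 140) stop("not a DICOM file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, raw(), 128)
  if (!identical(rawToChar(readBin(con, raw(), 4)), "DICM")) {
    stop("not a DICOM file (missing DICM magic): ", path)
  }
  elements <- list()
  repeat {
    hdr <- readBin(con, raw(), 8)
    if (length(hdr) == 0L) break
    if (length(hdr) < 8L) stop("truncated DICOM element header")
    group <- readBin(hdr[1:2], "integer", size = 2, endian = "little",
                     signed = FALSE)
    element <- readBin(hdr[3:4], "integer", size = 2, endian = "little",
                       signed = FALSE)
    vr <- rawToChar(hdr[5:6])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UN", "UT")) {
      lenraw <- readBin(con, raw(), 4)
      if (length(lenraw) < 4L) stop("truncated DICOM element header")
      len <- readBin(lenraw, "integer", size = 4, endian = "little")
    } else {
      len <- readBin(hdr[7:8], "integer", size = 2, endian = "little",
                     signed = FALSE)
    }
    if (len < 0L) stop("unsupported undefined-length DICOM element")
    value <- readBin(con, raw(), len)
    if (length(value) < len) stop("truncated DICOM file: element value cut short")
    key <- sprintf("%04X,%04X", group, element)
    elements[[key]] <- list(vr = vr, value = value)
  }
  elements
}

dcm_get_str <- function(el, key) {
  if (is.null(el[[key]])) return(NULL)
  trimws(rawToChar(el[[key]]$value))
}

dcm_get_us <- function(el, key) {
  if (is.null(el[[key]])) return(NULL)
  readBin(el[[key]]$value, "integer", size = 2, endian = "little",
          signed = FALSE)
}

dcm_read_pixels <- function(el, rows, cols, n_frames) {
  px <- el[["7FE0,0010"]]
  if (is.null(px)) stop("DICOM file has no pixel data")
  vals <- readBin(px$value, "integer", n = length(px$value) / 2, size = 2,
                  endian = "little", signed = FALSE)
  if (length(vals) < rows * cols * n_frames) {
    stop("pixel data shorter than Rows x Columns x Frames")
  }
  lapply(seq_len(n_frames), function(f) {
    off <- (f - 1) * rows * cols
    matrix(vals[off + seq_len(rows * cols)], rows, cols, byrow = TRUE)
  })
}

dcm_pixel_spacing <- function(el) {
  ps <- dcm_get_str(el, "0028,0030")
  if (is.null(ps)) {
    warning("no PixelSpacing in DICOM file; defaulting to 1 mm")
    return(1)
  }
  as.numeric(strsplit(ps, "\\\\")[[1]][1])
}

#' Read a planar image from a DICOM file
#'
#' Accepts explicit-VR little-endian single-frame files (nuclear-medicine or
#' secondary capture). The time point is taken from the series description
#' when it carries an `early`/`late` marker, otherwise from the `timepoint`
#' argument. Missing pixel spacing falls back to 1 mm with a warning;
#' truncated or non-DICOM input raises a format error.
#'
#' @param path DICOM file path.
#' @param timepoint Fallback time point when the file metadata has none.
#' @return A [planar_image()].
#' @export
read_planar_dicom <- function(path, timepoint = "early") {
  el <- dcm_parse(path)
  rows <- dcm_get_us(el, "0028,0010")
  cols <- dcm_get_us(el, "0028,0011")
  if (is.null(rows) || is.null(cols)) stop("DICOM file lacks Rows/Columns")
  desc <- dcm_get_str(el, "0008,103E")
  if (!is.null(desc)) {
    if (grepl("early", desc)) timepoint <- "early"
    if (grepl("late", desc)) timepoint <- "late"
  }
  counts <- dcm_read_pixels(el, rows, cols, 1L)[[1]]
  planar_image(counts, pixel_size_mm = dcm_pixel_spacing(el),
               timepoint = timepoint)
}

#' Read a short-axis volume from a multi-frame DICOM file
#'
#' Requires the JSON axis sidecar written by [write_volume_dicom()] (or an
#' `lv_axis` list supplied directly).
#'
#' @param path DICOM file path.
#' @param lv_axis Optional axis metadata overriding the sidecar.
#' @return A [short_axis_volume()].
#' @export
read_volume_dicom <- function(path, lv_axis = NULL) {
  el <- dcm_parse(path)
  rows <- dcm_get_us(el, "0028,0010")
  cols <- dcm_get_us(el, "0028,0011")
  nf <- as.integer(dcm_get_str(el, "0028,0008"))
  if (is.null(rows) || is.null(cols) || is.na(nf)) {
    stop("DICOM volume lacks Rows/Columns/NumberOfFrames")
  }
  frames <- dcm_read_pixels(el, rows, cols, nf)
  arr <- array(0, c(nf, rows, cols))
  for (f in seq_len(nf)) arr[f, , ] <- frames[[f]]
  if (is.null(lv_axis)) {
    side <- paste0(path, ".json")
    if (!file.exists(side)) stop("no lv_axis given and no sidecar at ", side)
    g <- jsonlite::read_json(side, simplifyVector = TRUE)$lv_axis
    if (!is.null(dim(g$center))) g$center <- as.matrix(g$center)
    lv_axis <- g
  }
  short_axis_volume(arr, voxel_size_mm = dcm_pixel_spacing(el),
                    lv_axis = lv_axis)
}
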