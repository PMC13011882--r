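## Minimal DICOM secondary-capture export (explicit VR little endian) and a
## matching reader for verification.  Only the standard attributes a viewer
## needs for a magnitude image series are written: geometry (pixel spacing,
## position, orientation, slice location), identity (study/series/SOP UIDs)
## and 16-bit unsigned pixel data with a rescale slope back to the
## reconstructed intensities.

.uid_root <- "2.25."

.gen_uid <- function() {
  paste0(.uid_root,
         paste0(sample(0:9, 30, replace = TRUE), collapse = ""))
}

.raw_uint <- function(x, width) {
  writeBin(as.integer(x), raw(), size = width, endian = "little")
}

# one explicit-VR data element
.dcm_elem <- function(group, elem, vr, value) {
  if (is.character(value)) {
    v <- charToRaw(value)
    if (length(v) %% 2L == 1L)
      v <- c(v, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  } else v <- value
  head <- c(.raw_uint(group, 2), .raw_uint(elem, 2), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .raw_uint(length(v), 4), v)
  } else {
    c(head, .raw_uint(length(v), 2), v)
  }
}

#' Export an image volume as a DICOM series
#'
#' Writes one secondary-capture DICOM file per slice (explicit VR little
#' endian) with correct pixel spacing, slice positions and freshly generated
#' study/series/instance UIDs.  Pixel values are scaled to the full unsigned
#' 16-bit range; the rescale slope restores the original intensity scale.
#'
#' @param img an [image_volume()].
#' @param out_dir output directory (created if missing).
#' @param series_description free-text series label.
#' @param patient patient/phantom name.
#' @return character vector of written file paths, invisibly.
#' @export
export_dicom <- function(img, out_dir, series_description = "halbachmri recon",
                         patient = "PHANTOM") {
  stopifnot(inherits(img, "image_volume"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2L) != 0L)
    stop("output directory not writable: ", out_dir)
  d <- dim(img$data)
  vmax <- max(img$data)
  slope <- if (vmax > 0) vmax / 65535 else 1
  pix <- round(img$data / slope)
  study_uid <- .gen_uid()
  series_uid <- .gen_uid()
  sop_class <- "1.2.840.10008.5.1.4.1.1.7"   # secondary capture
  ts_uid <- "1.2.840.10008.1.2.1"            # explicit VR little endian
  today <- format(Sys.Date(), "%Y%m%d")
  paths <- character(d[3])
  for (s in seq_len(d[3])) {
    sop_uid <- .gen_uid()
    # pixel matrix: rows along phase (y), columns along readout (x)
    slc <- t(pix[, , s])
    z_mm <- (s - (d[3] + 1) / 2) * img$voxel_size[3] * 1e3
    x0_mm <- -(d[1] - 1) / 2 * img$voxel_size[1] * 1e3
    y0_mm <- -(d[2] - 1) / 2 * img$voxel_size[2] * 1e3
    ds <- function(...) paste(sprintf("%.8g", c(...)), collapse = "\\")
    body <- c(
      .dcm_elem(0x0008, 0x0008, "CS", "DERIVED\\SECONDARY"),
      .dcm_elem(0x0008, 0x0016, "UI", sop_class),
      .dcm_elem(0x0008, 0x0018, "UI", sop_uid),
      .dcm_elem(0x0008, 0x0020, "DA", today),
      .dcm_elem(0x0008, 0x0060, "CS", "OT"),
      .dcm_elem(0x0008, 0x103E, "LO", series_description),
      .dcm_elem(0x0010, 0x0010, "PN", patient),
      .dcm_elem(0x0010, 0x0020, "LO", patient),
      .dcm_elem(0x0018, 0x0050, "DS", ds(img$voxel_size[3] * 1e3)),
      .dcm_elem(0x0020, 0x000D, "UI", study_uid),
      .dcm_elem(0x0020, 0x000E, "UI", series_uid),
      .dcm_elem(0x0020, 0x0011, "IS", "1"),
      .dcm_elem(0x0020, 0x0013, "IS", as.character(s)),
      .dcm_elem(0x0020, 0x0032, "DS", ds(x0_mm, y0_mm, z_mm)),
      .dcm_elem(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      .dcm_elem(0x0020, 0x1041, "DS", ds(z_mm)),
      .dcm_elem(0x0028, 0x0002, "US", .raw_uint(1, 2)),
      .dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcm_elem(0x0028, 0x0010, "US", .raw_uint(d[2], 2)),  # rows = phase
      .dcm_elem(0x0028, 0x0011, "US", .raw_uint(d[1], 2)),  # cols = readout
      .dcm_elem(0x0028, 0x0030, "DS",
                ds(img$voxel_size[2] * 1e3, img$voxel_size[1] * 1e3)),
      .dcm_elem(0x0028, 0x0100, "US", .raw_uint(16, 2)),
      .dcm_elem(0x0028, 0x0101, "US", .raw_uint(16, 2)),
      .dcm_elem(0x0028, 0x0102, "US", .raw_uint(15, 2)),
      .dcm_elem(0x0028, 0x0103, "US", .raw_uint(0, 2)),
      .dcm_elem(0x0028, 0x1052, "DS", "0"),
      .dcm_elem(0x0028, 0x1053, "DS", ds(slope)),
      .dcm_elem(0x7FE0, 0x0010, "OW",
                writeBin(as.integer(t(slc)), raw(), size = 2,
                         endian = "little")))
    meta_body <- c(
      .dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      .dcm_elem(0x0002, 0x0002, "UI", sop_class),
      .dcm_elem(0x0002, 0x0003, "UI", sop_uid),
      .dcm_elem(0x0002, 0x0010, "UI", ts_uid),
      .dcm_elem(0x0002, 0x0012, "UI", paste0(.uid_root, "846424")))
    meta <- c(.dcm_elem(0x0002, 0x0000, "UL",
                        .raw_uint(length(meta_body), 4)), meta_body)
    path <- file.path(out_dir, sprintf("slice_%03d.dcm", s))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
    paths[s] <- path
  }
  invisible(paths)
}

#' Read one DICOM slice written by [export_dicom()]
#'
#' Minimal explicit-VR little-endian parser returning the attributes needed
#' to verify a round trip: pixel matrix, geometry and UIDs.
#'
#' @param path DICOM file path.
#' @return list with `rows`, `cols`, `pixel` (integer matrix, rows x cols),
#'   `pixel_spacing_mm`, `slice_location_mm`, `instance_number`,
#'   `rescale_slope`, `sop_instance_uid`, `series_uid`, and `tags` (raw
#'   values of every element, named "gggg,eeee").
#' @export
read_dicom_slice <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (rawToChar(bytes[129:132]) != "DICM") stop("not a DICOM file: ", path)
  pos <- 133L
  tags <- list()
  n <- length(bytes)
  u16 <- function(i) readBin(bytes[i:(i + 1L)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(bytes[i:(i + 3L)], "integer", size = 4,
                             endian = "little")
  while (pos + 7L <= n) {
    grp <- u16(pos); el <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L); pos <- pos + 12L
    } else {
      len <- u16(pos + 6L); pos <- pos + 8L
    }
    val <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
    tags[[sprintf("%04x,%04x", grp, el)]] <- list(vr = vr, value = val)
    pos <- pos + len
  }
  str_of <- function(tag) {
    t <- tags[[tag]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$value))
  }
  us_of <- function(tag) readBin(tags[[tag]]$value, "integer", size = 2,
                                 endian = "little", signed = FALSE)
  rows <- us_of("0028,0010"); cols <- us_of("0028,0011")
  px <- readBin(tags[["7fe0,0010"]]$value, "integer",
                n = rows * cols, size = 2, endian = "little", signed = FALSE)
  list(rows = rows, cols = cols,
       pixel = matrix(px, rows, cols, byrow = TRUE),
       pixel_spacing_mm = as.numeric(strsplit(str_of("0028,0030"),
                                              "\\", fixed = TRUE)[[1]]),
       slice_location_mm = as.numeric(str_of("0020,1041")),
       instance_number = as.integer(str_of("0020,0013")),
       rescale_slope = as.numeric(str_of("0028,1053")),
       sop_instance_uid = str_of("0008,0018"),
       series_uid = str_of("0020,000e"),
       tags = tags)
}
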