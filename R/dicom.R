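# Minimal single-frame MR DICOM support: Explicit VR Little Endian only,
# standard tags only. Enough to write a phantom series and read it (or any
# series restricted to the same dialect) back; not a general DICOM toolkit.

UID_ROOT <- "1.2.826.0.1.3680043.10.474"
UID_TRANSFER_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_SOP_MR <- "1.2.840.10008.5.1.4.1.1.4"

# deterministic numeric hash of a string for UID building
uid_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 999999937
  as.character(h)
}

dcm_pad <- function(val, pad = as.raw(0x20)) {
  if (length(val) %% 2 == 1) c(val, pad) else val
}

dcm_element <- function(group, elem, vr, value) {
  long_form <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  hdr <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
           writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
           charToRaw(vr))
  if (long_form) {
    c(hdr, as.raw(c(0, 0)),
      writeBin(length(value), raw(), size = 4, endian = "little"), value)
  } else {
    c(hdr, writeBin(length(value), raw(), size = 2, endian = "little"), value)
  }
}

dcm_str <- function(group, elem, vr, s, pad = as.raw(0x20)) {
  dcm_element(group, elem, vr, dcm_pad(charToRaw(s), pad))
}

dcm_us <- function(group, elem, x) {
  dcm_element(group, elem, "US",
              writeBin(as.integer(x), raw(), size = 2, endian = "little"))
}

dcm_ds <- function(group, elem, x) {
  dcm_str(group, elem, "DS", paste(sprintf("%.10g", x), collapse = "\\"))
}

#' Write a volume as a DICOM series
#'
#' Emits one single-frame MR DICOM file per axial slice (Explicit VR Little
#' Endian, 16-bit unsigned pixels), with consistent patient/series
#' identifiers, identity row/column orientation and ImagePositionPatient
#' stepping along z in the chosen direction. With `z_direction = -1` the
#' files are written superior-first (descending z), the situation the series
#' reader must detect and undo. Intensities are truncated to integers in
#' \[0, 65535\]; phantom volumes are integer-valued by construction, so the
#' round trip through [load_series()] is lossless.
#'
#' @param exam a [volume_record()], or a list with a `volume` element (as
#'   returned by [generate_phantom()] / [realize_exam()]).
#' @param out_dir directory to create the slice files in.
#' @param z_direction +1 (inferior-first file order) or -1 (superior-first).
#' @return `out_dir`, invisibly usable as the series directory.
#' @export
write_dicom_series <- function(exam, out_dir, z_direction = 1L) {
  v <- if (inherits(exam, "volume_record")) exam else exam$volume
  stopifnot(inherits(v, "volume_record"))
  if (!z_direction %in% c(-1L, 1L)) abort("`z_direction` must be +1 or -1.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("Cannot create directory '%s'.", out_dir))
  d <- dim(v$intensities)
  sp <- v$spacing
  exam_id <- v$meta$exam_id %||% "exam"
  study_uid <- paste(UID_ROOT, "1", uid_hash(exam_id), sep = ".")
  series_uid <- paste(UID_ROOT, "2", uid_hash(exam_id), sep = ".")
  age <- v$meta$age
  age_str <- if (is.null(age) || is.na(age)) "000Y" else sprintf("%03dY", as.integer(age))
  lat <- v$meta$cancer_laterality %||% "none"

  pix <- v$intensities
  pix[] <- pmin(pmax(trunc(pix), 0), 65535)

  for (i in seq_len(d[3])) {
    k <- if (z_direction == 1L) i else d[3] - i + 1L
    z <- (k - 1) * sp[3]
    sop_uid <- paste(series_uid, i, sep = ".")
    meta <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_str(0x0002, 0x0002, "UI", UID_SOP_MR, as.raw(0)),
      dcm_str(0x0002, 0x0003, "UI", sop_uid, as.raw(0)),
      dcm_str(0x0002, 0x0010, "UI", UID_TRANSFER_EXPLICIT_LE, as.raw(0)),
      dcm_str(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".0.1"), as.raw(0))
    )
    group_len <- dcm_element(0x0002, 0x0000, "UL",
                             writeBin(length(meta), raw(), size = 4,
                                      endian = "little"))
    slice <- as.integer(pix[, , k])
    body <- c(
      dcm_str(0x0008, 0x0016, "UI", UID_SOP_MR, as.raw(0)),
      dcm_str(0x0008, 0x0018, "UI", sop_uid, as.raw(0)),
      dcm_str(0x0008, 0x0060, "CS", "MR"),
      dcm_str(0x0010, 0x0010, "PN", "Phantom^Synthetic"),
      dcm_str(0x0010, 0x0020, "LO", exam_id),
      dcm_str(0x0010, 0x1010, "AS", age_str),
      dcm_str(0x0010, 0x4000, "LT", paste0("laterality=", lat)),
      dcm_ds(0x0018, 0x0050, sp[3]),
      dcm_str(0x0020, 0x000D, "UI", study_uid, as.raw(0)),
      dcm_str(0x0020, 0x000E, "UI", series_uid, as.raw(0)),
      dcm_str(0x0020, 0x0013, "IS", as.character(i)),
      dcm_ds(0x0020, 0x0032, c(0, 0, z)),
      dcm_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
      dcm_us(0x0028, 0x0002, 1L),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, d[2]),   # Rows    = y extent
      dcm_us(0x0028, 0x0011, d[1]),   # Columns = x extent
      dcm_ds(0x0028, 0x0030, c(sp[2], sp[1])),  # row spacing \ col spacing
      dcm_us(0x0028, 0x0100, 16L),
      dcm_us(0x0028, 0x0101, 16L),
      dcm_us(0x0028, 0x0102, 15L),
      dcm_us(0x0028, 0x0103, 0L),
      dcm_element(0x7FE0, 0x0010, "OW",
                  writeBin(slice, raw(), size = 2, endian = "little"))
    )
    con <- file(file.path(out_dir, sprintf("slice-%04d.dcm", i)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), group_len, meta, body), con)
    close(con)
  }
  invisible(out_dir)
}

# Parse one Explicit-VR-LE single-frame file into a named list of raw values
# keyed "GGGG,EEEE".
parse_dicom_file <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    abort(sprintf("'%s' is not a DICOM part-10 file.", path))
  }
  pos <- 133L
  out <- list()
  n <- length(bytes)
  u16 <- function(p) readBin(bytes[p:(p + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(p) readBin(bytes[p:(p + 3)], "integer", size = 4,
                             endian = "little")
  while (pos + 7 <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      abort(sprintf("Implicit-VR or unsupported encoding in '%s' (tag %04X,%04X).",
                    path, group, elem))
    }
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      val_start <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      val_start <- pos + 8L
    }
    if (len < 0 || val_start + len - 1 > n) {
      abort(sprintf("Truncated DICOM element in '%s'.", path))
    }
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr,
                       raw = if (len > 0) bytes[val_start:(val_start + len - 1)] else raw(0))
    pos <- val_start + len
  }
  ts <- dcm_string(out, "0002,0010")
  if (!identical(ts, UID_TRANSFER_EXPLICIT_LE)) {
    abort(sprintf("Unsupported transfer syntax '%s' in '%s'.", ts %||% "?", path))
  }
  out
}

dcm_string <- function(el, key) {
  e <- el[[key]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$raw[e$raw != as.raw(0)]))
}

dcm_numbers <- function(el, key) {
  s <- dcm_string(el, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_uint16 <- function(el, key) {
  e <- el[[key]]
  if (is.null(e)) return(NULL)
  readBin(e$raw, "integer", size = 2, endian = "little", signed = FALSE)
}

#' Load a DICOM series as an oriented 3D volume
#'
#' Reads every single-frame file of one series, sorts the slices by their
#' ImagePositionPatient projected onto the slice normal (not by instance
#' number), and assembles the left-posterior-superior oriented volume.
#' Series written superior-first (descending z positions) are detected and
#' re-ordered, so both z directions load to the same volume. Voxel spacing
#' comes from PixelSpacing and the median inter-slice position delta.
#'
#' @param series_dir directory containing the slice files of one series.
#' @return A [volume_record()]; attribute `z_direction` records the file
#'   order found on disk (+1 ascending, -1 descending).
#' @export
load_series <- function(series_dir) {
  files <- sort(list.files(series_dir, full.names = TRUE,
                           pattern = "\\.dcm$", ignore.case = TRUE))
  if (length(files) == 0) {
    files <- sort(list.files(series_dir, full.names = TRUE))
  }
  if (length(files) < 2) abort("Need at least 2 slice files to assemble a volume.")
  parsed <- lapply(files, parse_dicom_file)

  series_uids <- vapply(parsed, function(el) dcm_string(el, "0020,000E") %||% "",
                        character(1))
  if (length(unique(series_uids)) != 1) {
    abort(sprintf("Directory mixes %d series (distinct SeriesInstanceUID); refusing to merge.",
                  length(unique(series_uids))))
  }
  ipp <- lapply(seq_along(parsed), function(i) {
    p <- dcm_numbers(parsed[[i]], "0020,0032")
    if (is.null(p) || length(p) != 3) {
      abort(sprintf("Missing/invalid ImagePositionPatient in '%s'.", files[i]))
    }
    p
  })
  iop <- dcm_numbers(parsed[[1]], "0020,0037")
  if (is.null(iop) || length(iop) != 6) {
    abort(sprintf("Missing ImageOrientationPatient in '%s'.", files[1]))
  }
  rowv <- iop[1:3]; colv <- iop[4:6]
  normal <- c(rowv[2] * colv[3] - rowv[3] * colv[2],
              rowv[3] * colv[1] - rowv[1] * colv[3],
              rowv[1] * colv[2] - rowv[2] * colv[1])
  proj <- vapply(ipp, function(p) sum(p * normal), numeric(1))
  ord <- order(proj)
  z_direction <- if (identical(ord, seq_along(ord))) 1L else -1L

  rows <- vapply(parsed, function(el) dcm_uint16(el, "0028,0010"), integer(1))
  cols <- vapply(parsed, function(el) dcm_uint16(el, "0028,0011"), integer(1))
  if (length(unique(rows)) != 1 || length(unique(cols)) != 1) {
    abort("Slices disagree on Rows/Columns; not a single volume.")
  }
  X <- cols[1]; Y <- rows[1]; Z <- length(parsed)
  vol <- array(0, c(X, Y, Z))
  for (k in seq_len(Z)) {
    el <- parsed[[ord[k]]]
    pix <- el[["7FE0,0010"]]
    if (is.null(pix)) abort(sprintf("Missing PixelData in '%s'.", files[ord[k]]))
    v <- readBin(pix$raw, "integer", n = X * Y, size = 2,
                 endian = "little", signed = FALSE)
    vol[, , k] <- array(v, c(X, Y))
  }
  ps <- dcm_numbers(parsed[[1]], "0028,0030")  # row spacing \ col spacing
  dz <- median(diff(sort(proj)))
  spacing <- c(ps[2], ps[1], dz)
  orientation <- if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) < 1e-6) "LPS" else "other"

  age_s <- dcm_string(parsed[[1]], "0010,1010")
  age <- if (!is.null(age_s) && grepl("^[0-9]+Y$", age_s)) {
    as.numeric(sub("Y$", "", age_s))
  } else NA_real_
  comments <- dcm_string(parsed[[1]], "0010,4000") %||% ""
  lat <- if (grepl("laterality=", comments)) {
    sub(".*laterality=([a-z]+).*", "\\1", comments)
  } else "none"

  out <- volume_record(vol, spacing = spacing, orientation = orientation,
                       meta = list(exam_id = dcm_string(parsed[[1]], "0010,0020") %||% "exam",
                                   age = age, cancer_laterality = lat))
  attr(out, "z_direction") <- z_direction
  out
}
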