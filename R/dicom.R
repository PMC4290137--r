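# Minimal DICOM series reader: single-frame, uncompressed, little-endian
# slices (explicit or implicit VR). Enough to assemble an angiography volume
# from a directory of exported slices; compressed transfer syntaxes and
# undefined-length sequences are rejected with a clear error.

dicom_uint <- function(raw, size, offset) {
  b <- as.integer(raw[(offset + 1):(offset + size)])
  sum(b * 256^(seq_len(size) - 1))
}

# DICOM string values may be NUL- or space-padded
dicom_str <- function(body) trimws(rawToChar(body[body != as.raw(0)]))

# parse one DICOM file, returning the tags we need
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)

  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  pos <- 132L          # after preamble + DICM
  explicit <- TRUE     # file meta group is always explicit VR little endian
  transfer <- NULL
  switched <- FALSE

  while (pos + 8 <= length(raw)) {
    group <- dicom_uint(raw, 2, pos)
    elem <- dicom_uint(raw, 2, pos + 2)
    if (group != 0x0002 && !switched && !is.null(transfer)) {
      explicit <- transfer != "1.2.840.10008.1.2"
      switched <- TRUE
    }
    if (explicit || group == 0x0002) {
      vr <- rawToChar(raw[(pos + 5):(pos + 6)])
      if (vr %in% long_vrs) {
        len <- dicom_uint(raw, 4, pos + 8)
        hdr <- 12L
      } else {
        len <- dicom_uint(raw, 2, pos + 6)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- dicom_uint(raw, 4, pos + 4)
      hdr <- 8L
    }
    if (len >= 0xFFFFFFFF)
      stop("undefined-length DICOM sequences are not supported: ", path,
           call. = FALSE)
    body <- if (len > 0) raw[(pos + hdr + 1):(pos + hdr + len)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)

    if (key == "0002,0010") transfer <- dicom_str(body)
    if (key %in% c("0008,0018", "0020,000E", "0020,000D"))
      tags[[key]] <- dicom_str(body)
    if (key %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103"))
      tags[[key]] <- dicom_uint(body, 2, 0)
    if (key %in% c("0028,0030", "0018,0050", "0018,0088", "0020,0032",
                   "0020,0037", "0028,1052", "0028,1053", "0020,0013"))
      tags[[key]] <- dicom_str(body)
    if (key == "7FE0,0010") tags[["pixel_data"]] <- body
    pos <- pos + hdr + len
  }
  if (!is.null(transfer) &&
      !transfer %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop("unsupported DICOM transfer syntax ", transfer, " in ", path,
         call. = FALSE)
  tags
}

parse_ds <- function(s) if (is.null(s)) NULL else
  as.numeric(strsplit(trimws(s), "\\\\")[[1]])

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!file.info(files)$isdir]
  if (length(files) == 0) stop("empty DICOM directory: ", dir, call. = FALSE)
  slices <- lapply(files, parse_dicom_file)

  uids <- unique(vapply(slices, function(s) s[["0020,000E"]] %||% "",
                        character(1)))
  if (length(uids) > 1)
    stop("DICOM directory contains more than one series (",
         paste(uids, collapse = ", "), "); split it by SeriesInstanceUID",
         call. = FALSE)

  first <- slices[[1]]
  ncol_px <- first[["0028,0011"]]
  nrow_px <- first[["0028,0010"]]
  bits <- first[["0028,0100"]] %||% 16
  signed <- (first[["0028,0103"]] %||% 0) == 1

  # slice ordering: position projected on the slice normal, else InstanceNumber
  iop <- parse_ds(first[["0020,0037"]])
  ipps <- lapply(slices, function(s) parse_ds(s[["0020,0032"]]))
  if (!is.null(iop) && !any(vapply(ipps, is.null, logical(1)))) {
    normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
                iop[3] * iop[4] - iop[1] * iop[6],
                iop[1] * iop[5] - iop[2] * iop[4])
    proj <- vapply(ipps, function(p) sum(p * normal), numeric(1))
    ord <- order(proj)
    zsp <- if (length(proj) > 1) median(abs(diff(sort(proj)))) else NA_real_
  } else {
    inst <- vapply(slices, function(s)
      as.numeric(trimws(s[["0020,0013"]] %||% "0")), numeric(1))
    ord <- order(inst)
    zsp <- NA_real_
  }
  slices <- slices[ord]

  decode <- function(s) {
    px <- s[["pixel_data"]]
    n <- nrow_px * ncol_px
    vals <- if (bits == 8) {
      as.double(readBin(px, "integer", n = n, size = 1, signed = FALSE))
    } else {
      as.double(readBin(px, "integer", n = n, size = 2, signed = signed,
                        endian = "little"))
    }
    slope <- parse_ds(s[["0028,1053"]]) %||% 1
    inter <- parse_ds(s[["0028,1052"]]) %||% 0
    # PixelData is row-major: column index fastest -> maps to our x axis
    matrix(vals * slope + inter, nrow = ncol_px, ncol = nrow_px)
  }
  data <- array(0, c(ncol_px, nrow_px, length(slices)))
  for (i in seq_along(slices)) data[, , i] <- decode(slices[[i]])

  psp <- parse_ds(first[["0028,0030"]]) %||% c(1, 1)
  if (is.na(zsp) || !length(zsp))
    zsp <- parse_ds(first[["0018,0088"]]) %||%
      parse_ds(first[["0018,0050"]]) %||% 1
  origin <- parse_ds(slices[[1]][["0020,0032"]]) %||% c(0, 0, 0)
  # PixelSpacing is (row, col) = (y, x)
  image_volume(data, spacing = c(psp[2], psp[1], zsp), origin = origin)
}
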