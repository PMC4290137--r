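# Minimal DICOM part-10 writer for fixtures: explicit VR little endian,
# single-frame 16-bit slices. Only used to exercise the reader.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_pad <- function(s, pad = charToRaw(" ")) {
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, pad)
  b
}
dcm_nul <- as.raw(0)

dcm_elem <- function(group, elem, vr, body) {
  head <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_u32(length(body)), body)
  } else {
    c(head, dcm_u16(length(body)), body)
  }
}

# pixels: integer matrix (ncol_px x nrow_px), column index = x (fastest)
write_test_dicom_slice <- function(path, pixels, series_uid, instance,
                                   ipp = c(0, 0, instance * 2),
                                   pixel_spacing = c(0.5, 0.5)) {
  ncol_px <- nrow(pixels)
  nrow_px <- ncol(pixels)
  ts <- dcm_pad("1.2.840.10008.1.2.1", dcm_nul)
  meta <- c(dcm_elem(0x0002, 0x0002, "UI", dcm_pad("1.2.840.10008.5.1.4.1.1.4", dcm_nul)),
            dcm_elem(0x0002, 0x0003, "UI", dcm_pad(paste0(series_uid, ".", instance), dcm_nul)),
            dcm_elem(0x0002, 0x0010, "UI", ts))
  meta <- c(dcm_elem(0x0002, 0x0000, "UL", dcm_u32(length(meta))), meta)
  # PixelData in row-major order: column fastest, i.e. t(pixels) by rows
  px <- writeBin(as.integer(as.vector(pixels)), raw(), size = 2,
                 endian = "little")
  body <- c(
    dcm_elem(0x0008, 0x0018, "UI", dcm_pad(paste0(series_uid, ".", instance), dcm_nul)),
    dcm_elem(0x0020, 0x000D, "UI", dcm_pad(paste0(series_uid, ".study"), dcm_nul)),
    dcm_elem(0x0020, 0x000E, "UI", dcm_pad(series_uid, dcm_nul)),
    dcm_elem(0x0020, 0x0013, "IS", dcm_pad(as.character(instance))),
    dcm_elem(0x0020, 0x0032, "DS", dcm_pad(paste(ipp, collapse = "\\"))),
    dcm_elem(0x0020, 0x0037, "DS", dcm_pad("1\\0\\0\\0\\1\\0")),
    dcm_elem(0x0028, 0x0010, "US", dcm_u16(nrow_px)),
    dcm_elem(0x0028, 0x0011, "US", dcm_u16(ncol_px)),
    dcm_elem(0x0028, 0x0030, "DS",
             dcm_pad(paste(pixel_spacing, collapse = "\\"))),
    dcm_elem(0x0028, 0x0100, "US", dcm_u16(16)),
    dcm_elem(0x0028, 0x0103, "US", dcm_u16(0)),
    dcm_elem(0x7FE0, 0x0010, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
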