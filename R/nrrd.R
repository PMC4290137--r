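# Minimal NRRD reader/writer for 3D scalar volumes.
#
# Supports: dimension 3; types double, float, uint8/uchar, int16/short,
# uint16/ushort, int32/int; encodings raw and gzip; little-endian data;
# attached headers only. Spacing from either "spacings" or diagonal
# "space directions"; origin from "space origin".

read_nrrd <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  nl <- which(raw == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L) { hdr_end <- p; break }
    # tolerate CRLF
    if (p == prev + 2L && raw[p - 1L] == as.raw(13L)) { hdr_end <- p; break }
    prev <- p
  }
  if (is.na(hdr_end)) stop("not a valid NRRD file (no header terminator): ", path,
                           call. = FALSE)
  hdr <- strsplit(rawToChar(raw[seq_len(hdr_end)]), "\r?\n")[[1]]
  if (!grepl("^NRRD", hdr[1])) stop("not a NRRD file: ", path, call. = FALSE)

  fields <- list()
  for (line in hdr[-1]) {
    if (!nzchar(line) || grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) == 3) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }

  need <- function(f) {
    if (is.null(fields[[f]])) stop("NRRD header missing field: ", f, call. = FALSE)
    fields[[f]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("only 3-dimensional NRRD volumes are supported", call. = FALSE)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- tolower(need("type"))
  enc <- tolower(need("encoding"))
  endian <- tolower(fields[["endian"]] %||% "little")
  if (endian != "little") stop("only little-endian NRRD supported", call. = FALSE)

  payload <- raw[(hdr_end + 1L):length(raw)]
  if (enc %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") {
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  }

  n <- prod(sizes)
  vals <- switch(type,
    "double" = readBin(payload, "double", n = n, size = 8, endian = "little"),
    "float" = readBin(payload, "double", n = n, size = 4, endian = "little"),
    "uchar" = , "uint8" = , "unsigned char" =
      as.double(readBin(payload, "integer", n = n, size = 1, signed = FALSE)),
    "short" = , "int16" = , "signed short" =
      as.double(readBin(payload, "integer", n = n, size = 2, signed = TRUE,
                        endian = "little")),
    "ushort" = , "uint16" = , "unsigned short" =
      as.double(readBin(payload, "integer", n = n, size = 2, signed = FALSE,
                        endian = "little")),
    "int" = , "int32" = , "signed int" =
      as.double(readBin(payload, "integer", n = n, size = 4, endian = "little")),
    stop("unsupported NRRD type: ", type, call. = FALSE)
  )
  if (length(vals) < n) stop("truncated NRRD data: ", path, call. = FALSE)

  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(vecs) == 3) {
      m <- vapply(vecs, function(v)
        as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
      spacing <- sqrt(colSums(m^2))
    }
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]),
                                  ",")[[1]])
  image_volume(array(vals, sizes), spacing = spacing, origin = origin)
}

write_nrrd <- function(volume, path, type = c("double", "uint8"),
                       encoding = c("raw", "gzip")) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  data <- volume$data
  hdr <- c(
    "NRRD0004",
    "# produced by lhvessel",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dim(data), collapse = " ")),
    paste0("space directions: ",
           sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   volume$spacing[1], volume$spacing[2], volume$spacing[3])),
    "kinds: domain domain domain",
    "endian: little",
    paste0("encoding: ", encoding),
    paste0("space origin: ", sprintf("(%.17g,%.17g,%.17g)",
                                     volume$origin[1], volume$origin[2],
                                     volume$origin[3])),
    ""
  )
  payload <- if (type == "double") {
    writeBin(as.double(data), raw(), size = 8, endian = "little")
  } else {
    if (any(data < 0 | data > 255)) stop("uint8 NRRD needs values in [0,255]",
                                         call. = FALSE)
    as.raw(as.integer(data))
  }
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(payload, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
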