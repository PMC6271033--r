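#' @include accessors.R
NULL

# ENVI data type codes -> (R read type, size, signed)
.ENVI_TYPES <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `3`  = list(what = "integer", size = 4L, signed = TRUE),
  `4`  = list(what = "numeric", size = 4L, signed = TRUE),
  `5`  = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (length(txt) == 0 || !grepl("^ENVI", txt[1]))
    stop("not an ENVI header (missing 'ENVI' magic line): ", header_path)
  body <- paste(txt[-1], collapse = "\n")
  # join { ... } blocks, then split into "key = value" entries
  fields <- list()
  lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!grepl("=", ln, fixed = TRUE)) { i <- i + 1L; next }
    key <- tolower(trimws(sub("=.*", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{")) {
      while (!grepl("\\}", val) && i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
      val <- gsub("[{}]", "", val)
    }
    fields[[key]] <- trimws(val)
    i <- i + 1L
  }
  fields
}

.require_keys <- function(fields, keys) {
  miss <- setdiff(keys, names(fields))
  if (length(miss))
    stop("ENVI header missing required key(s): ", paste(miss, collapse = ", "))
}

#' Read an ENVI hypercube
#'
#' Reads an ENVI header/data file pair into a [Hypercube-class]. All three
#' interleaves (BSQ, BIL, BIP) and data types byte, int16, int32, uint16,
#' float32 and float64 are supported; the in-memory result is always in
#' (line, sample, band) order.
#'
#' @param header_path path to the text header (`.hdr`). The data file is
#'   taken from the header's basename (header `x.hdr` -> data `x` or
#'   `x.dat`, whichever exists).
#' @param signalKind signal kind to tag the cube with (the ENVI format does
#'   not record it); default `"raw_counts"`.
#' @return A [Hypercube-class].
#' @seealso [writeENVI()]
#' @export
readENVI <- function(header_path, signalKind = "raw_counts") {
  f <- .parse_envi_header(header_path)
  .require_keys(f, c("samples", "lines", "bands", "interleave", "data type"))
  ns <- as.integer(f$samples); nl <- as.integer(f$lines); nb <- as.integer(f$bands)
  if (any(is.na(c(ns, nl, nb))) || ns < 1 || nl < 1 || nb < 1)
    stop("ENVI header: samples/lines/bands must be positive integers")
  interleave <- tolower(f$interleave)
  if (!interleave %in% c("bsq", "bil", "bip"))
    stop("ENVI header: unsupported interleave '", interleave, "'")
  dt <- .ENVI_TYPES[[f$`data type`]]
  if (is.null(dt)) stop("ENVI header: unsupported data type ", f$`data type`)
  endian <- if (identical(f$`byte order`, "1")) "big" else "little"
  offset <- as.integer(f$`header offset` %||% "0")

  if (is.null(f[["wavelength", exact = TRUE]])) stop("ENVI header: no 'wavelength' list present")
  wl <- as.numeric(strsplit(f[["wavelength", exact = TRUE]], ",")[[1]])
  if (length(wl) != nb)
    stop(sprintf("ENVI header: %d wavelengths listed but bands = %d", length(wl), nb))

  base <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  data_path <- if (file.exists(base)) base else paste0(base, ".dat")
  if (!file.exists(data_path)) stop("ENVI data file not found for header: ", header_path)

  n <- as.numeric(ns) * nl * nb
  expect_bytes <- offset + n * dt$size
  if (file.size(data_path) < expect_bytes)
    stop(sprintf("ENVI data file truncated: %d bytes, expected >= %d",
                 file.size(data_path), expect_bytes))

  con <- file(data_path, "rb")
  on.exit(close(con))
  if (offset > 0) readBin(con, "raw", offset)
  v <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
               signed = dt$signed || dt$size > 2L)
  v <- as.numeric(v)

  cube <- switch(interleave,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3, 2, 1)))
  meta <- list(source = data_path)
  if (!is.null(f$description)) meta$description <- f$description
  Hypercube(cube, wl, signalKind = signalKind, metadata = meta)
}

#' Write an ENVI hypercube
#'
#' Writes a [Hypercube-class] as a standard ENVI header/data pair readable
#' by [readENVI()] and third-party ENVI readers. Wavelengths are emitted
#' with 8 significant digits.
#'
#' @param cube a valid [Hypercube-class].
#' @param header_path output header path (`.hdr`); the data file gets the
#'   same path without the extension.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param data_type ENVI data type code: 4 (float32, default), 5 (float64)
#'   or 12 (uint16).
#' @return Invisibly, the data file path.
#' @export
writeENVI <- function(cube, header_path, interleave = c("bsq", "bil", "bip"),
                      data_type = 4L) {
  stopifnot(is(cube, "Hypercube"))
  validObject(cube)
  interleave <- match.arg(interleave)
  dt <- .ENVI_TYPES[[as.character(data_type)]]
  if (is.null(dt) || !data_type %in% c(4L, 5L, 12L))
    stop("supported output data types: 4 (float32), 5 (float64), 12 (uint16)")
  d <- dim(cube@data)
  nl <- d[1]; ns <- d[2]; nb <- d[3]

  hdr <- c(
    "ENVI",
    sprintf("description = {%s}", cube@metadata$description %||% "hsichem export"),
    sprintf("samples = %d", ns),
    sprintf("lines = %d", nl),
    sprintf("bands = %d", nb),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(formatC(cube@wavelengths, digits = 8, format = "g"),
                  collapse = ", ")))
  writeLines(hdr, header_path)

  v <- switch(interleave,
    bsq = as.vector(aperm(cube@data, c(2, 1, 3))),
    bil = as.vector(aperm(cube@data, c(2, 3, 1))),
    bip = as.vector(aperm(cube@data, c(3, 2, 1))))

  data_path <- sub("\\.hdr$", "", header_path, ignore.case = TRUE)
  con <- file(data_path, "wb")
  on.exit(close(con))
  if (data_type == 12L) {
    iv <- as.integer(round(v))
    if (any(iv < 0 | iv > 65535)) stop("values outside uint16 range")
    iv[iv > 32767L] <- iv[iv > 32767L] - 65536L  # two's-complement for writeBin
    writeBin(iv, con, size = 2L, endian = "little")
  } else {
    writeBin(v, con, size = dt$size, endian = "little")
  }
  invisible(data_path)
}

#' Export a pixel mask as an ENVI image plus provenance CSV
#'
#' Writes the kept/removed mask as a single-band 0/1 ENVI image and the
#' per-pixel removal provenance as a CSV (columns y, x, provenance; 0-based
#' coordinates).
#'
#' @param mask a [PixelMask-class].
#' @param header_path output ENVI header path.
#' @param csv_path output CSV path (default: header path with `.csv`).
#' @return Invisibly, the CSV path.
#' @export
writeMaskENVI <- function(mask, header_path,
                          csv_path = sub("\\.hdr$", ".csv", header_path)) {
  keep <- keepMatrix(mask)
  cube <- Hypercube(array(as.numeric(keep), c(dim(keep), 1L)),
                    wavelengths = 0, signalKind = "raw_counts",
                    metadata = list(description = "pixel mask (1 = kept)"))
  writeENVI(cube, header_path, interleave = "bsq", data_type = 4L)
  idx <- which(!keep, arr.ind = TRUE)
  df <- data.frame(y = idx[, 1] - 1L, x = idx[, 2] - 1L,
                   provenance = maskProvenance(mask)[!keep])
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(csv_path)
}
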