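# Image reading/writing.  PNG and JPEG go through the `png` and `jpeg`
# packages; TIFF uses a package-internal minimal codec (uncompressed
# baseline, 8-bit grayscale or RGB, little- or big-endian, strip-based)
# because no TIFF package is available in the supported environment.
# Plain PGM/PPM (P2/P5/P3/P6) are supported as text-friendly formats.

read_tiff_minimal <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 4)
  le <- identical(as.integer(hdr[1:2]), c(0x49L, 0x49L))
  if (!le && !identical(as.integer(hdr[1:2]), c(0x4DL, 0x4DL)))
    stop("not a TIFF file: ", path)
  endian <- if (le) "little" else "big"
  magic <- as.integer(hdr[3]) + 256L * as.integer(hdr[4])
  if (le && magic != 42L) stop("bad TIFF magic in ", path)
  rd <- function(what, n, size) readBin(con, what, n = n, size = size,
                                        endian = endian,
                                        signed = (size >= 4))
  ifd_off <- rd("integer", 1, 4)
  seek(con, ifd_off)
  n_tag <- rd("integer", 1, 2)
  tags <- list()
  for (i in seq_len(n_tag)) {
    tag <- rd("integer", 1, 2)
    typ <- rd("integer", 1, 2)
    cnt <- rd("integer", 1, 4)
    val_raw <- readBin(con, "raw", 4)
    tags[[as.character(tag)]] <- list(type = typ, count = cnt,
                                      raw = val_raw)
  }
  parse_vals <- function(entry) {
    typ <- entry$type; cnt <- entry$count
    size <- c(1, 1, 2, 4)[typ]  # BYTE, ASCII, SHORT, LONG
    if (is.na(size)) stop("unsupported TIFF tag type ", typ)
    decode <- function(raw) {
      con2 <- rawConnection(raw)
      on.exit(close(con2))
      readBin(con2, "integer", n = cnt, size = size, endian = endian,
              signed = (size >= 4))
    }
    if (cnt * size <= 4) {
      decode(entry$raw)
    } else {
      con3 <- rawConnection(entry$raw)
      off <- readBin(con3, "integer", 1, 4, endian = endian)
      close(con3)
      seek(con, off)
      readBin(con, "integer", n = cnt, size = size, endian = endian,
              signed = (size >= 4))
    }
  }
  need <- function(tag, default = NULL) {
    e <- tags[[as.character(tag)]]
    if (is.null(e)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag)
      return(default)
    }
    parse_vals(e)
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 8L)
  comp <- need(259, 1L)
  spp <- need(277, 1L)
  if (comp != 1) stop("only uncompressed TIFF is supported (compression ",
                      comp, ")")
  if (any(bits != 8)) stop("only 8-bit TIFF is supported")
  offsets <- need(273)
  counts <- need(279)
  rows_per_strip <- need(278, h)
  data <- raw(0)
  for (i in seq_along(offsets)) {
    seek(con, offsets[i])
    data <- c(data, readBin(con, "raw", counts[i]))
  }
  v <- as.integer(data)
  if (spp == 1) {
    matrix(v[seq_len(w * h)], nrow = h, ncol = w, byrow = TRUE)
  } else {
    px <- v[seq_len(w * h * spp)]
    arr <- array(0, dim = c(h, w, spp))
    for (s in seq_len(spp))
      arr[, , s] <- matrix(px[seq(s, length(px), by = spp)],
                           nrow = h, ncol = w, byrow = TRUE)
    arr
  }
}

write_tiff_minimal <- function(img, path) {
  img <- round(clip_intensity(img))
  h <- nrow(img); w <- ncol(img)
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  writeBin(charToRaw("II"), con); wr2(42); wr4(8)
  n_tag <- 8L
  data_off <- 8L + 2L + n_tag * 12L + 4L
  wr2(n_tag)
  tag <- function(id, typ, cnt, val) { wr2(id); wr2(typ); wr4(cnt); wr4(val) }
  tag(256, 4, 1, w)            # ImageWidth
  tag(257, 4, 1, h)            # ImageLength
  tag(258, 3, 1, 8)            # BitsPerSample
  tag(259, 3, 1, 1)            # Compression = none
  tag(262, 3, 1, 1)            # Photometric = BlackIsZero
  tag(273, 4, 1, data_off)     # StripOffsets
  tag(278, 4, 1, h)            # RowsPerStrip
  tag(279, 4, 1, w * h)        # StripByteCounts
  wr4(0)                       # next IFD
  writeBin(as.raw(as.vector(t(img))), con)
  invisible(path)
}

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- local({
    buf <- character(0)
    function() {
      repeat {
        if (length(buf) > 0) {
          t <- buf[1]; buf <<- buf[-1]; return(t)
        }
        line <- readLines(con, n = 1, warn = FALSE)
        if (length(line) == 0) stop("unexpected end of PNM header")
        line <- sub("#.*", "", line)
        buf <<- strsplit(trimws(line), "[[:space:]]+")[[1]]
        buf <<- buf[nzchar(buf)]
      }
    }
  })
  magic <- tok()
  if (!magic %in% c("P2", "P5", "P3", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path)
  w <- as.integer(tok()); h <- as.integer(tok())
  maxv <- as.integer(tok())
  spp <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * spp
  v <- if (magic %in% c("P2", "P3")) {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
    as.integer(vals)
  } else {
    as.integer(readBin(con, "raw", n))
  }
  v <- v * (255 / maxv)
  if (spp == 1) {
    matrix(v, nrow = h, ncol = w, byrow = TRUE)
  } else {
    arr <- array(0, dim = c(h, w, 3))
    for (s in 1:3)
      arr[, , s] <- matrix(v[seq(s, n, by = 3)], nrow = h, ncol = w,
                           byrow = TRUE)
    arr
  }
}

write_pgm <- function(img, path, ascii = TRUE) {
  img <- round(clip_intensity(img))
  h <- nrow(img); w <- ncol(img)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    apply(img, 1, function(row) writeLines(paste(row, collapse = " "), con))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(w, h), "255"), con)
    writeBin(as.raw(as.vector(t(img))), con)
  }
  invisible(path)
}

#' Read a microscopy image as a grayscale matrix
#'
#' Supports TIFF (uncompressed baseline 8-bit), PNG, JPEG and PGM/PPM.
#' RGB inputs are collapsed to Rec.601 luminance; intensities are rescaled
#' to `[0, 255]`.  With `resize_factor < 1` the image is downscaled with
#' Gaussian anti-aliasing before being returned; the factor and original
#' size are attached as attributes `resize_factor` and `orig_dim`.
#'
#' @param path image file path.
#' @param resize_factor working-scale factor in `(0, 1]`.
#' @return grayscale matrix on `[0, 255]`.
#' @export
read_image <- function(path, resize_factor = 1) {
  if (!file.exists(path)) stop("image file not found: ", path)
  stopifnot(resize_factor > 0, resize_factor <= 1)
  ext <- tolower(tools::file_ext(path))
  raw_img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    tif = ,
    tiff = read_tiff_minimal(path),
    pgm = ,
    ppm = ,
    pnm = read_pnm(path),
    stop("unsupported image format '.", ext,
         "' (TIFF/PNG/JPEG/PGM supported)"))
  g <- as_gray(raw_img)
  orig <- dim(g)
  if (resize_factor < 1) g <- resize_gray(g, resize_factor)
  attr(g, "resize_factor") <- resize_factor
  attr(g, "orig_dim") <- orig
  g
}

#' Write a grayscale image
#'
#' Format chosen by extension: PNG, TIFF (uncompressed 8-bit), or
#' PGM (plain text).
#'
#' @param img grayscale matrix on `[0, 255]`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(clip_intensity(img) / 255, path),
    tif = ,
    tiff = write_tiff_minimal(img, path),
    pgm = write_pgm(img, path),
    stop("unsupported output format '.", ext, "'"))
  invisible(path)
}
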