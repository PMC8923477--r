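# Image readers/writers. PNG via the png package, TIFF via the tiff
# package; PGM (both ASCII P2 and binary P5, 8- or 16-bit) is parsed here
# directly, the format being a header plus raw samples. All readers return a
# numeric matrix scaled to [0, 255]; RGB inputs are collapsed by Rec. 601
# luminance.

.luminance <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  if (dim(arr)[3] >= 3L)
    return(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
  arr[, , 1]
}

.read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens: magic, width, height, maxval; '#' starts a comment
  tokens <- character(0)
  buf <- character(0)
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop_io("truncated PGM header in ", path)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!magic %in% c("P2", "P5") || is.na(w) || is.na(h) || is.na(maxval) ||
      maxval < 1)
    stop_io("not a valid PGM file: ", path)
  n <- h * w
  vals <- if (magic == "P5") {
    if (maxval < 256) as.numeric(readBin(con, "integer", n, size = 1L,
                                         signed = FALSE))
    else as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                            endian = "big"))
  } else {
    scan(con, what = numeric(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop_io("truncated PGM pixel data in ", path)
  # PGM stores row-major (top row first)
  matrix(vals, h, w, byrow = TRUE) / maxval * 255
}

.write_pgm <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con,
            eos = NULL)
  writeBin(as.integer(t(img)), con, size = 1L)
}

#' Read a grayscale image as a numeric matrix on [0, 255]
#'
#' Supports PNG, TIFF and PGM (by file extension). Color images are
#' converted by luminance; 8- and 16-bit integer data are rescaled so the
#' nominal maximum maps to 255.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, or `.pgm` file.
#' @return Numeric matrix (rows = image rows).
#' @export
read_gray <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_io("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = .luminance(png::readPNG(path)) * 255,
    tif = ,
    tiff = .luminance(tiff::readTIFF(path)) * 255,
    pgm = .read_pgm(path),
    stop_io("unsupported image format \".", ext, "\": ", path))
  if (!is.matrix(img)) img <- matrix(img, 1L)
  img
}

.quantize <- function(img) {
  round(pmin(pmax(img, 0), 255))
}

#' Write an intensity field as an 8-bit grayscale image
#'
#' Values are clipped to `[0, 255]`, rounded, and written as 8-bit PNG,
#' TIFF or PGM according to the file extension.
#'
#' @param img Numeric matrix.
#' @param path Output path ending in `.png`, `.tif`/`.tiff`, or `.pgm`.
#' @return Invisibly, the path.
#' @export
write_gray <- function(img, path) {
  assert_image(img, "img")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("output directory does not exist: ", dir)
  q <- .quantize(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(q / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(q / 255, path, bits.per.sample = 8L),
    pgm = .write_pgm(q, path),
    stop_io("unsupported output format \".", ext, "\": ", path))
  invisible(path)
}

#' @rdname write_gray
#' @param mask Binary matrix; written with 0 mapped to 0 and 1 to 255.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop_invalid("mask must be binary (values exactly 0 or 1)")
  write_gray(mask * 255, path)
}

# Float TIFF writer for the relaxed indicator field (no quantization).
.write_field_tiff <- function(x, path) {
  tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

# Read a mask image: grayscale thresholded at 128, 0 = damaged.
.read_mask <- function(path) {
  (read_gray(path) >= 128) + 0
}
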