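# Image file input/output. PNG and TIFF go through the png and tiff
# packages (which return intensities on their [0, 1] convention); PGM/PPM
# (both plain "P2"/"P3" and raw "P5"/"P6") are parsed here and returned at
# their stored integer scale. With the default sd-relative tolerance the
# entropy is invariant to either affine convention.

.luma <- c(0.299, 0.587, 0.114)

# Collapse an h x w x channels array to a single-channel matrix.
.to_gray <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3L]
    if (nc == 1L) return(a[, , 1L])
    if (nc == 2L) return(a[, , 1L])                     # gray + alpha
    r <- a[, , 1L]; g <- a[, , 2L]; b <- a[, , 3L]      # drop any alpha
    return(.luma[1L] * r + .luma[2L] * g + .luma[3L] * b)
  }
  stop("unsupported image array layout", call. = FALSE)
}

# Tokenized PNM header/content reader. Plain formats are whitespace
# separated decimals; raw formats put binary samples after a single
# whitespace byte following the maxval token.
.read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop(sprintf("not a supported PGM/PPM file (magic '%s'): %s", magic, path),
         call. = FALSE)
  plain <- magic %in% c("P2", "P3")
  nchan <- if (magic %in% c("P3", "P6")) 3L else 1L
  # read header tokens (width, height, maxval), skipping '#' comments
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "")
      stop(sprintf("truncated PNM header: %s", path), call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1L]; h <- tokens[2L]; maxval <- tokens[3L]
  n <- w * h * nchan
  if (plain) {
    vals <- scan(con, what = integer(), n = n, comment.char = "#",
                 quiet = TRUE)
  } else {
    if (maxval < 256L) {
      vals <- as.integer(readBin(con, "raw", n))
    } else {
      vals <- readBin(con, "integer", n, size = 2L, signed = FALSE,
                      endian = "big")
    }
  }
  if (length(vals) != n)
    stop(sprintf("truncated PNM data: %s", path), call. = FALSE)
  if (nchan == 1L) {
    matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
  } else {
    px <- matrix(as.numeric(vals), nrow = 3L)   # samples interleaved RGB
    gray <- colSums(px * .luma)
    matrix(gray, nrow = h, ncol = w, byrow = TRUE)
  }
}

#' Read a raster image as a grayscale intensity matrix
#'
#' Supported formats (by extension): PNG, TIFF (`.tif`/`.tiff`), PGM and
#' PPM (plain or raw). RGB input is converted with the luma weights
#' 0.299, 0.587, 0.114; alpha channels are dropped. Intensities are kept
#' at the reader's native scale — `[0, 1]` for PNG/TIFF, the stored
#' integer range for PGM/PPM — with no per-image normalization.
#'
#' @param path path to the image file.
#' @return a numeric matrix (rows = image rows).
#' @seealso [write_pgm()]
#' @export
read_image <- function(path) {
  if (length(path) != 1L || !is.character(path))
    stop("path must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  u <- switch(ext,
              png = .to_gray(png::readPNG(path)),
              tif = , tiff = .to_gray(tiff::readTIFF(path)),
              pgm = , ppm = , pnm = .read_pnm(path),
              stop(sprintf("unsupported image format '.%s': %s", ext, path),
                   call. = FALSE))
  if (length(u) == 0L || !all(is.finite(u)))
    stop(sprintf("empty or invalid image: %s", path), call. = FALSE)
  u
}

#' Write a grayscale matrix as a plain (ASCII) PGM file
#'
#' Values are rounded to integers in `0..maxval`; with `rescale = TRUE`
#' the matrix is first mapped linearly from its own range onto
#' `0..maxval` (an affine change, which the sd-relative tolerance makes
#' entropy-neutral).
#'
#' @param image numeric matrix.
#' @param path output path.
#' @param maxval maximum gray value, default 255.
#' @param rescale linearly map the image range onto `0..maxval`? Default
#'   `FALSE`.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, maxval = 255L, rescale = FALSE) {
  .check_image(image)
  if (rescale) {
    rng <- range(image)
    image <- if (diff(rng) > 0) (image - rng[1L]) / diff(rng) * maxval
             else image * 0
  }
  vals <- round(image)
  if (any(vals < 0 | vals > maxval))
    stop(sprintf("values outside 0..%d; use rescale = TRUE", maxval),
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  write(t(vals), file = con, ncolumns = min(ncol(image), 16L))
  invisible(path)
}
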