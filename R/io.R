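# Raster I/O: PNG and JPEG through existing readers, PGM (P2/P5) natively.
# All images come out as numeric matrices on a 0-255 float scale; colour
# inputs are reduced to luminance with the ITU-R BT.601 weights.

BT601 <- c(0.299, 0.587, 0.114)

#' Load a raster image as a luminance matrix
#'
#' Reads PNG, PGM (plain P2 or binary P5) or JPEG and returns a numeric
#' matrix on a 0-255 scale. Colour images are converted to luminance with the
#' BT.601 weights 0.299 R + 0.587 G + 0.114 B; an alpha channel is ignored.
#' JPEG decoding uses the EBImage package.
#'
#' @param path Path to a readable `.png`, `.pgm`, `.jpg`/`.jpeg` file.
#' @return Numeric matrix (rows = image rows top to bottom).
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop_gradsim("`path` must be a single file path.", "gradsim_io_error")
  }
  if (!file.exists(path)) {
    stop_gradsim(sprintf("Cannot read image: file '%s' does not exist.", path),
                 "gradsim_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path) * 255,
    pgm = read_pgm(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop_gradsim("JPEG input requires the EBImage package.", "gradsim_io_error")
      }
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img) * 255
      # EBImage stores images x-by-y(-by-channel); transpose to row-major
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
    },
    stop_gradsim(sprintf("Unsupported image format '%s' for '%s'.", ext, path),
                 "gradsim_io_error")
  )
  to_luminance(arr)
}

to_luminance <- function(arr) {
  if (is.matrix(arr)) return(arr + 0)
  nc <- dim(arr)[3]
  if (nc >= 3L) {
    BT601[1] * arr[, , 1] + BT601[2] * arr[, , 2] + BT601[3] * arr[, , 3]
  } else {
    arr[, , 1]
  }
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) {
    stop_gradsim(sprintf("'%s' is not a P2/P5 PGM file (magic '%s').", path, magic),
                 "gradsim_io_error")
  }
  # header tokens (width, height, maxval), skipping whitespace and # comments
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") {
      stop_gradsim(sprintf("Truncated PGM header in '%s'.", path), "gradsim_io_error")
    }
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r", "")) break
      }
    } else if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0L) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  if (magic == "P5") {
    if (maxval > 255) {
      stop_gradsim("16-bit P5 PGM is not supported.", "gradsim_io_error")
    }
    vals <- as.integer(readBin(con, "raw", w * h))
  } else {
    txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
  }
  if (length(vals) < w * h) {
    stop_gradsim(sprintf("PGM '%s' has %d pixels, expected %d.", path,
                         length(vals), w * h), "gradsim_io_error")
  }
  matrix(vals[seq_len(w * h)] * (255 / maxval), nrow = h, ncol = w, byrow = TRUE)
}

#' Write a luminance matrix as an image file
#'
#' `write_image_png()` writes 8-bit grayscale PNG; `write_image_pgm()` writes
#' plain-text (P2) PGM. Values are clipped to 0-255 and rounded.
#'
#' @param img Numeric matrix on a 0-255 scale.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  check_gray_image(img, min_dim = 1L)
  png::writePNG(clip255(img) / 255, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
write_image_pgm <- function(img, path) {
  check_gray_image(img, min_dim = 1L)
  v <- round(clip255(img))
  lines <- c("P2", sprintf("%d %d", ncol(img), nrow(img)), "255",
             apply(v, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
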