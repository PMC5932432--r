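# Grayscale image input/output. PNG via the png package, TIFF via the tiff
# package (suggested), plain/raw PGM parsed directly. Images are represented
# internally as numeric matrices in [0, 1], row = image row.

#' Read a grayscale image
#'
#' Supports PNG, TIFF (if the \pkg{tiff} package is installed) and PGM
#' (both ASCII `P2` and binary `P5`). Color inputs are averaged to one
#' channel; intensities are returned as doubles in `[0, 1]`.
#'
#' @param path image file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the tiff package")
      }
      tiff::readTIFF(path)
    },
    pgm = read_pgm(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  img <- as.matrix(img)
  storage.mode(img) <- "double"
  img
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # header tokens: width, height, maxval; '#' comments allowed
  tokens <- character(0)
  buf <- ""
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0L || ch == "") stop("truncated PGM header")
    if (ch == "#") {               # skip to end of line
      repeat {
        ch <- readChar(con, 1L)
        if (length(ch) == 0L || ch %in% c("\n", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) { tokens <- c(tokens, buf); buf <- "" }
    } else buf <- paste0(buf, ch)
  }
  w <- as.integer(tokens[1L]); h <- as.integer(tokens[2L])
  maxval <- as.integer(tokens[3L])
  n <- w * h
  vals <- if (magic == "P5") {
    if (maxval < 256L) as.integer(readBin(con, "raw", n))
    else {
      raw2 <- readBin(con, "raw", 2L * n)
      256L * as.integer(raw2[seq(1L, 2L * n, 2L)]) +
        as.integer(raw2[seq(2L, 2L * n, 2L)])
    }
  } else {
    rest <- readChar(con, file.size(path), useBytes = TRUE)
    as.integer(strsplit(trimws(rest), "[[:space:]]+")[[1L]])[seq_len(n)]
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a grayscale image
#'
#' PNG (8-bit) via \pkg{png}, TIFF (32-bit float) via \pkg{tiff}, or ASCII
#' PGM. Values are clamped to `[0, 1]` first.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("writing TIFF requires the tiff package")
      }
      tiff::writeTIFF(img, path, bits.per.sample = 32L)
    },
    pgm = write_pgm(img, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

write_pgm <- function(img, path) {
  v <- round(t(img) * 255)             # row-major order
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  writeLines(paste(as.integer(v), collapse = " "), con)
}

#' Write a binary mask as an 8-bit PNG with values \{0, 255\}
#'
#' @param mask logical (or 0/1) matrix.
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- as_binary(mask, "mask")
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path `.png` path.
#' @return logical matrix (pixels above half intensity are `TRUE`).
#' @export
read_mask <- function(path) {
  read_image(path) > 0.5
}
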