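#' Read a microscope image as an intensity array
#'
#' Reads an 8-bit grayscale or 24-bit RGB image and returns intensities on the
#' 0--255 scale: a numeric `H x W` matrix for grayscale input, or an
#' `H x W x 3` array for RGB input (an alpha channel, if present, is dropped).
#' Supported formats are PNG, JPEG and netpbm PGM/PPM (plain `P2`/`P3` or raw
#' `P5`/`P6`). Rows run top to bottom, columns left to right.
#'
#' @param path path to a `.png`, `.jpg`/`.jpeg`, `.pgm` or `.ppm` file.
#' @return numeric matrix (gray) or 3-slice array (RGB) of intensities in
#'   `[0, 255]`.
#' @seealso [to_grayscale()], [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    stop("TIFF input is not supported in this build; convert to PNG first")
  img <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    pgm  = ,
    ppm  = return(read_pnm(path)),
    stop("unsupported image format: .", ext)
  )
  img <- img * 255
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE] else img <- img[, , 1]
  }
  img
}

#' Write a grayscale or binary image
#'
#' Writes a `H x W` intensity matrix (0--255 scale) as PNG or plain-text PGM
#' (`P2`). Binary masks (values in \{0, 1\}) are scaled to \{0, 255\} so the
#' item is visible; pass `scale = FALSE` to write values verbatim.
#'
#' @param img numeric matrix of intensities in `[0, 255]` (or a 0/1 mask).
#' @param path output path ending in `.png` or `.pgm`.
#' @param scale rescale 0/1 masks to 0/255 (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, scale = TRUE) {
  stopifnot(is.matrix(img))
  if (scale && all(img %in% c(0, 1))) img <- img * 255
  img <- pmin(pmax(round(img), 0), 255)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    # one image row per line, space-separated
    writeLines(apply(img, 1L, paste, collapse = " "), con)
  } else {
    stop("unsupported output format: .", ext)
  }
  invisible(path)
}

# netpbm reader: P2/P5 (gray) and P3/P6 (RGB), maxval <= 255.
# The whole file is read as raw once; the header (magic, width, height, maxval)
# is tokenized byte-wise so comments and arbitrary whitespace are handled, then
# pixel data is taken from the remaining bytes (raw) or text (plain).
read_pnm <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  is_space <- function(b) b %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  next_token <- function() {
    tok <- raw(0)
    while (pos <= length(bytes)) {
      b <- bytes[pos]
      if (b == as.raw(0x23)) { # '#' comment to end of line
        while (pos <= length(bytes) && bytes[pos] != as.raw(0x0a)) pos <<- pos + 1L
        next
      }
      if (is_space(b)) {
        pos <<- pos + 1L
        if (length(tok)) return(rawToChar(tok))
        next
      }
      tok <- c(tok, b)
      pos <<- pos + 1L
    }
    if (length(tok)) rawToChar(tok) else stop("unexpected end of netpbm header")
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported netpbm type: ", magic)
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(w) || is.na(h) || w < 1 || h < 1) stop("corrupt netpbm header")
  if (is.na(maxval) || maxval < 1 || maxval > 255)
    stop("only 8-bit netpbm images are supported")
  nchan <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nchan
  vals <- if (magic %in% c("P5", "P6")) {
    # next_token consumed the single whitespace byte after maxval already
    if (length(bytes) - pos + 1L < n) stop("truncated netpbm data")
    as.integer(bytes[pos:(pos + n - 1L)])
  } else {
    txt <- rawToChar(bytes[pos:length(bytes)])
    v <- suppressWarnings(as.numeric(scan(text = txt, what = character(),
                                          quiet = TRUE, comment.char = "#")))
    if (length(v) < n || anyNA(v[seq_len(n)])) stop("truncated netpbm data")
    v[seq_len(n)]
  }
  vals <- vals * (255 / maxval)
  if (nchan == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    arr <- array(0, dim = c(h, w, 3))
    for (k in 1:3) arr[, , k] <- matrix(vals[seq(k, n, by = 3L)],
                                        nrow = h, ncol = w, byrow = TRUE)
    arr
  }
}
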