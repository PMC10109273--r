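# Plain-text image I/O.
#
# The imaging stage consumes in-memory matrices; on disk, images travel as
# ASCII PGM (P2) or CSV matrices. PGM is the simplest standard grayscale
# interchange format and, unlike PNG/TIFF, needs no binary decoder.

#' Read / write ASCII PGM (P2) images
#'
#' Plain (ASCII) portable graymap: header `P2`, width, height, maxval, then
#' row-major integer samples. Intensities are mapped linearly to \[0, 1\].
#' Comments (`#`) are honoured on read.
#'
#' @param path PGM file path.
#' @return `read_pgm()` returns a numeric matrix (rows x cols) in \[0, 1\].
#' @export
read_pgm <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  tok <- unlist(strsplit(paste(raw, collapse = " "), "[ \t]+"))
  tok <- tok[nzchar(tok)]
  if (length(tok) < 4L || tok[1] != "P2")
    stop_invalid("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h)
    stop_invalid("PGM sample count mismatch in ", path)
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @param pixels numeric matrix in \[0, 1\].
#' @param maxval integer grayscale range on disk, default 255.
#' @export
write_pgm <- function(pixels, path, maxval = 255) {
  stopifnot(is.matrix(pixels))
  q <- round(pmin(pmax(pixels, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(pixels), nrow(pixels)), as.character(maxval)),
             con)
  apply(q, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Read a grayscale image file for channel measurement
#'
#' Dispatches on extension: `.pgm` (ASCII P2) or `.csv` (numeric matrix,
#' no header).
#'
#' @param path image file path.
#' @param pixel_scale_um_per_px um per pixel.
#' @param ... passed to [channel_image()].
#' @return a [channel_image()].
#' @export
read_channel_image <- function(path, pixel_scale_um_per_px, ...) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    pgm = read_pgm(path),
    csv = as.matrix(read.csv(path, header = FALSE)),
    stop_invalid("unsupported image format `.", ext,
                 "`; use ASCII PGM or CSV"))
  dimnames(px) <- NULL
  channel_image(px, pixel_scale_um_per_px, ...)
}
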