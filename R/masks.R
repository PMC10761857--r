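#' Binary pore mask
#'
#' Construct a pore mask from a binary matrix. The grid follows image
#' convention: rows are y (top-left origin), columns are x, and the imposed
#' flow direction runs from the first column (inlet edge) to the last column
#' (outlet edge). Pore pixels are 1, solid pixels 0.
#'
#' @param grid Integer or logical matrix; non-zero / `TRUE` marks pore space.
#' @param pixel_size Pixel edge length in micrometres (default 0.65, the
#'   10X-magnification scale of the reference imaging setup).
#' @return An object of class `pore_mask`: a list with `grid` (integer matrix
#'   of 0/1) and `pixel_size` (micrometres per pixel).
#' @examples
#' m <- pore_mask(matrix(1L, 32, 64), pixel_size = 1)
#' porosity(m)
#' @export
pore_mask <- function(grid, pixel_size = 0.65) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (micrometres/pixel)")
  g <- matrix(as.integer(grid != 0), nrow(grid), ncol(grid))
  structure(list(grid = g, pixel_size = as.numeric(pixel_size)),
            class = "pore_mask")
}

#' @export
print.pore_mask <- function(x, ...) {
  cat(sprintf("<pore_mask> %d x %d px @ %.3g um/px, porosity %.3f\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size, porosity(x)))
  invisible(x)
}

#' Porosity of a pore mask
#'
#' @param mask A [pore_mask()].
#' @return Pore-pixel fraction of the grid.
#' @export
porosity <- function(mask) {
  stopifnot(inherits(mask, "pore_mask"))
  mean(mask$grid == 1L)
}

as_pore_mask <- function(x, pixel_size = NULL) {
  if (inherits(x, "pore_mask")) {
    if (!is.null(pixel_size)) x$pixel_size <- pixel_size
    return(x)
  }
  pore_mask(x, pixel_size = if (is.null(pixel_size)) 0.65 else pixel_size)
}

validate_mask <- function(mask, require_both_phases = TRUE) {
  stopifnot(inherits(mask, "pore_mask"))
  if (require_both_phases) {
    if (all(mask$grid == 1L)) stop("degenerate mask: all pore")
    if (all(mask$grid == 0L)) stop("degenerate mask: all solid")
  }
  invisible(mask)
}

#' Does the pore phase percolate from inlet to outlet?
#'
#' Uses 4-connectivity for the pore phase and the left/right image edges as
#' inlet/outlet.
#' @param mask A [pore_mask()].
#' @return `TRUE` if at least one pore component touches both edges.
#' @export
percolates <- function(mask) {
  stopifnot(inherits(mask, "pore_mask"))
  lab <- cpp_label(mask$grid, 4L)
  left <- unique(lab[, 1L]); right <- unique(lab[, ncol(lab)])
  any(setdiff(left, 0L) %in% setdiff(right, 0L))
}

#' Read / write pore masks
#'
#' On disk, masks are 8-bit PNG or single-page TIFF images with pore = 255
#' and solid = 0; in memory the mapping is pore = 1, solid = 0.
#'
#' @param path File path ending in `.png` or `.tif`/`.tiff`.
#' @param pixel_size Micrometres per pixel to attach on read.
#' @param mask A [pore_mask()] to write.
#' @return `read_pore_mask()` returns a [pore_mask()]; `write_pore_mask()`
#'   returns `path` invisibly.
#' @export
read_pore_mask <- function(path, pixel_size = 0.65) {
  img <- read_image_file(path)
  pore_mask(matrix(as.integer(img > 0.5), nrow(img), ncol(img)),
            pixel_size = pixel_size)
}

#' @rdname read_pore_mask
#' @export
write_pore_mask <- function(mask, path) {
  stopifnot(inherits(mask, "pore_mask"))
  write_image_file(mask$grid, path)  # 1 -> white, 0 -> black
  invisible(path)
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required")
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
    img <- tiff::readTIFF(path)
  } else stop("unsupported image extension: ", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

write_image_file <- function(grid, path, max_value = max(grid, 1)) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(grid / max_value, 0), 1)
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required")
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}
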