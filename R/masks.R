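# Semantic masks, instance maps and their on-disk encodings.

CLASS_BG <- 0L
CLASS_MYELIN <- 1L
CLASS_AXON <- 2L
# AxonDeepSeg-style 8-bit PNG encoding
PNG_LEVELS <- c(background = 0L, myelin = 127L, axon = 255L)

#' Three-class semantic mask
#'
#' An integer matrix over `{0 = background, 1 = myelin, 2 = axon}` with the
#' pixel pitch attached. On disk, masks use the 8-bit PNG encoding
#' background = 0, myelin = 127, axon = 255.
#'
#' @param labels Integer matrix with values in `{0, 1, 2}`.
#' @param pixel_size Pixel pitch, um per pixel.
#' @return An object of class `semantic_mask`.
#' @export
semantic_mask <- function(labels, pixel_size) {
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  if (!all(labels %in% 0:2)) stopf("semantic mask values must be 0, 1 or 2")
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  storage.mode(labels) <- "integer"
  structure(labels, pixel_size = pixel_size, class = "semantic_mask")
}

#' @export
print.semantic_mask <- function(x, ...) {
  tab <- table(factor(x, levels = 0:2,
                      labels = c("background", "myelin", "axon")))
  cat(sprintf("semantic_mask %d x %d px (%.3f um/px)\n",
              nrow(x), ncol(x), attr(x, "pixel_size")))
  print(tab)
  invisible(x)
}

#' Per-fiber instance map
#'
#' Pairs an integer label matrix (0 = background, k = fiber k) with a role
#' matrix flagging each labeled pixel as myelin (1) or axon (2).
#'
#' @param labels Non-negative integer matrix of instance labels.
#' @param roles Integer matrix, same shape, with 0/1/2 =
#'   background/myelin/axon.
#' @param pixel_size Pixel pitch, um per pixel.
#' @param discarded_myelin Count of myelin components discarded because they
#'   touched no axon (set by [separate_instances()]).
#' @return An object of class `instance_map`.
#' @export
instance_map <- function(labels, roles, pixel_size, discarded_myelin = 0L) {
  if (!is.matrix(labels) || !is.matrix(roles) ||
      !all(dim(labels) == dim(roles)))
    stopf("labels and roles must be matrices of identical shape")
  if (any(labels < 0)) stopf("instance labels must be >= 0")
  if (any((labels > 0) != (roles > 0)))
    stopf("labels and roles must mark the same pixels")
  storage.mode(labels) <- "integer"
  storage.mode(roles) <- "integer"
  structure(list(labels = labels, roles = roles, pixel_size = pixel_size,
                 discarded_myelin = as.integer(discarded_myelin)),
            class = "instance_map")
}

#' @export
print.instance_map <- function(x, ...) {
  cat(sprintf("instance_map %d x %d px, %d instances (%.3f um/px)\n",
              nrow(x$labels), ncol(x$labels),
              length(setdiff(unique(as.vector(x$labels)), 0L)),
              x$pixel_size))
  invisible(x)
}

#' Collapse an instance map back to a semantic mask
#'
#' @param imap An [instance_map()].
#' @return A [semantic_mask()] built from the role matrix.
#' @export
collapse_instances <- function(imap) {
  stopifnot(inherits(imap, "instance_map"))
  semantic_mask(imap$roles, imap$pixel_size)
}

## ---- file I/O ------------------------------------------------------------

#' Read and write 8-bit grayscale images as PNG
#'
#' Images are integer matrices with values in `[0, 255]`.
#'
#' @param image Integer matrix, 0-255.
#' @param path File path.
#' @return `read_image_png` returns an integer matrix; `write_image_png`
#'   returns `path` invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Read and write semantic masks in the 0/127/255 PNG encoding
#'
#' @param mask A [semantic_mask()].
#' @param path File path.
#' @param pixel_size Pixel pitch to attach on read, um per pixel.
#' @return `read_mask_png` returns a [semantic_mask()]; `write_mask_png`
#'   returns `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "semantic_mask"))
  enc <- PNG_LEVELS[unclass(mask) + 1L]
  png::writePNG(matrix(enc, nrow(mask), ncol(mask)) / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, pixel_size) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  v <- as.integer(round(x * 255))
  lab <- match(v, PNG_LEVELS) - 1L
  if (anyNA(lab))
    stopf("mask PNG contains values other than 0/127/255")
  semantic_mask(matrix(lab, nrow(x), ncol(x)), pixel_size)
}

#' Write and read instance label matrices
#'
#' Labels with a maximum below 256 are stored as 8-bit grayscale PNG (value =
#' label); larger label ranges fall back to a plain tab-separated text matrix.
#'
#' @param labels Integer label matrix (e.g. `imap$labels`).
#' @param path Output path; extension chooses the format (`.png` or `.tsv`).
#' @return `read_instance_labels` returns an integer matrix.
#' @export
write_instance_labels <- function(labels, path) {
  if (grepl("\\.png$", path)) {
    if (max(labels) > 255)
      stopf("more than 255 instances; use a .tsv path")
    png::writePNG(labels / 255, path)
  } else {
    utils::write.table(labels, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_instance_labels
#' @export
read_instance_labels <- function(path) {
  if (grepl("\\.png$", path)) {
    read_image_png(path)
  } else {
    as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  }
}

#' Write and read fiber ground-truth tables as CSV
#'
#' Column layout: `fiber_id, center_row, center_col, inner_diameter_um,
#' myelin_thickness_um, g_ratio, axis_ratio, orientation_rad`.
#'
#' @param truths Fiber truth data frame.
#' @param path File path.
#' @return `read_truth_csv` returns the data frame.
#' @export
write_truth_csv <- function(truths, path) {
  utils::write.csv(truths, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path)
}
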