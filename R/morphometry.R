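# Per-fiber morphometrics from instance maps.

#' Area-equivalent diameter of a pixel region
#'
#' Diameter of the circle whose area equals the region's pixel area:
#' `d = 2 * sqrt(n * pixel_size^2 / pi)`.
#'
#' @param pixel_count Number of pixels in the region (>= 1).
#' @param pixel_size Pixel pitch, um per pixel.
#' @return Diameter in um.
#' @examples
#' equivalent_diameter(28, 0.166)  # ~0.991 um
#' @export
equivalent_diameter <- function(pixel_count, pixel_size) {
  if (any(pixel_count < 1)) stopf("pixel_count must be >= 1 (empty region)")
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  2 * sqrt(pixel_count * pixel_size^2 / pi)
}

# Eccentricity of the best-fit ellipse from normalized second central
# moments of a pixel-coordinate set: e = sqrt(1 - lambda_min/lambda_max).
moment_eccentricity <- function(rows, cols) {
  n <- length(rows)
  if (n < 2) return(0)
  mr <- mean(rows); mc <- mean(cols)
  crr <- mean((rows - mr)^2)
  ccc <- mean((cols - mc)^2)
  crc <- mean((rows - mr) * (cols - mc))
  tr <- crr + ccc
  det <- crr * ccc - crc^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

#' Measure one fiber from its axon and myelin pixel sets
#'
#' Inner diameter uses the axon pixels only; outer diameter uses axon plus
#' myelin pixels; both are area-equivalent circle diameters. Then
#' `g = inner / outer` and `myelin_thickness = (outer - inner) / 2`.
#' Eccentricity comes from the best-fit ellipse (normalized second central
#' moments) of either the axon pixel set (default) or the whole fiber.
#' A fiber with no myelin pixels yields `g = 1` (flagged for removal by the
#' quality-control screen, which requires g < 1).
#'
#' @param axon_idx,myelin_idx Column-major pixel indices of the two classes.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param pixel_size Pixel pitch, um per pixel.
#' @param fiber_id Integer id copied into the record.
#' @param eccentricity_on `"axon"` (default) or `"fiber"`: pixel set used for
#'   the best-fit ellipse.
#' @return One-row data frame (a fiber record) with columns `fiber_id,
#'   axon_area_um2, axon_diameter_um, outer_diameter_um,
#'   myelin_thickness_um, g_ratio, eccentricity, centroid_row, centroid_col,
#'   touches_border`.
#' @export
measure_fiber <- function(axon_idx, myelin_idx, dim, pixel_size,
                          fiber_id = 1L, eccentricity_on = c("axon", "fiber")) {
  eccentricity_on <- match.arg(eccentricity_on)
  if (length(axon_idx) < 1) stopf("instance must have at least one axon pixel")
  h <- dim[1]; w <- dim[2]
  inner <- equivalent_diameter(length(axon_idx), pixel_size)
  outer <- equivalent_diameter(length(axon_idx) + length(myelin_idx),
                               pixel_size)
  ecc_idx <- if (eccentricity_on == "axon") axon_idx
             else c(axon_idx, myelin_idx)
  er <- (ecc_idx - 1L) %% h + 1L
  ec <- (ecc_idx - 1L) %/% h + 1L
  all_idx <- c(axon_idx, myelin_idx)
  ar <- (all_idx - 1L) %% h + 1L
  ac <- (all_idx - 1L) %/% h + 1L
  axr <- (axon_idx - 1L) %% h + 1L
  axc <- (axon_idx - 1L) %/% h + 1L
  data.frame(
    fiber_id = as.integer(fiber_id),
    axon_area_um2 = length(axon_idx) * pixel_size^2,
    axon_diameter_um = inner,
    outer_diameter_um = outer,
    myelin_thickness_um = (outer - inner) / 2,
    g_ratio = inner / outer,
    eccentricity = moment_eccentricity(er, ec),
    centroid_row = mean(axr),
    centroid_col = mean(axc),
    touches_border = any(ar == 1L | ar == h | ac == 1L | ac == w)
  )
}

#' Measure every fiber in an instance map
#'
#' Applies [measure_fiber()] to each instance. All physical outputs are in
#' um / um^2; pixel counts never appear in the records.
#'
#' @param imap An [instance_map()].
#' @param eccentricity_on Passed to [measure_fiber()].
#' @return Data frame of fiber records, one row per instance, ordered by
#'   instance label.
#' @export
measure_instances <- function(imap, eccentricity_on = c("axon", "fiber")) {
  stopifnot(inherits(imap, "instance_map"))
  eccentricity_on <- match.arg(eccentricity_on)
  ids <- setdiff(sort(unique(as.vector(imap$labels))), 0L)
  d <- dim(imap$labels)
  recs <- lapply(ids, function(id) {
    idx <- which(imap$labels == id)
    role <- imap$roles[idx]
    measure_fiber(idx[role == CLASS_AXON], idx[role == CLASS_MYELIN],
                  d, imap$pixel_size, fiber_id = id,
                  eccentricity_on = eccentricity_on)
  })
  if (length(recs) == 0)
    return(measure_fiber(1L, integer(0), c(1L, 1L), 1)[0, ])
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Myelinated fiber density
#'
#' Fiber count divided by the imaged area, in fibers per mm^2.
#'
#' @param n_fibers Fiber count.
#' @param image_shape Integer pair `c(rows, cols)` in pixels, or total pixel
#'   count.
#' @param pixel_size Pixel pitch, um per pixel.
#' @return Density in fibers/mm^2.
#' @examples
#' fiber_density(5, c(500, 1000), 0.166)  # ~362.9
#' @export
fiber_density <- function(n_fibers, image_shape, pixel_size) {
  npx <- prod(image_shape)
  if (npx <= 0 || pixel_size <= 0) stopf("image area must be positive")
  n_fibers / (npx * pixel_size^2 * 1e-6)
}
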