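# Synthetic CARS-like fiber image generator with exact ground truth.

#' Lognormal parameters matching a target mean and SD
#'
#' Closed-form moment matching: returns `(meanlog, sdlog)` such that a
#' lognormal with those parameters has arithmetic mean `mean` and standard
#' deviation `sd`.
#'
#' @param mean,sd Target arithmetic mean (> 0) and SD (>= 0).
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @examples
#' lognormal_moment_match(1.0, 0.5)  # meanlog -0.1116, sdlog 0.4724
#' @export
lognormal_moment_match <- function(mean, sd) {
  if (mean <= 0) stopf("mean must be > 0")
  if (sd < 0) stopf("sd must be >= 0")
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# k-th raw moment of a lognormal truncated below at `floor`.
truncated_lognormal_moment <- function(meanlog, sdlog, floor, k) {
  if (floor <= 0) return(exp(k * meanlog + k^2 * sdlog^2 / 2))
  surv <- pnorm((meanlog - log(floor)) / sdlog)
  exp(k * meanlog + k^2 * sdlog^2 / 2) *
    pnorm((meanlog + k * sdlog^2 - log(floor)) / sdlog) / surv
}

#' Lognormal parameters whose floor-truncated moments match a target
#'
#' Solves for `(meanlog, sdlog)` such that the lognormal *truncated below at*
#' `floor` has the requested mean and SD. With `floor <= 0` this reduces to
#' [lognormal_moment_match()]. Errors when the truncation is unsatisfiable
#' (floor at or above the requested mean, or the solver cannot reach the
#' target moments).
#'
#' @param mean,sd Target post-truncation mean and SD.
#' @param floor Lower truncation bound, same units as `mean`.
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @export
truncated_lognormal_match <- function(mean, sd, floor = 0) {
  init <- lognormal_moment_match(mean, sd)
  if (floor <= 0 || sd == 0) {
    if (floor >= mean) stopf("truncation floor %.3g >= requested mean %.3g",
                             floor, mean)
    return(init)
  }
  if (floor >= mean)
    stopf("unsatisfiable truncation: floor %.3g >= requested mean %.3g",
          floor, mean)
  obj <- function(p) {
    mu <- p[1]; sg <- exp(p[2])
    m1 <- truncated_lognormal_moment(mu, sg, floor, 1)
    v <- truncated_lognormal_moment(mu, sg, floor, 2) - m1^2
    (m1 - mean)^2 + (sqrt(max(v, 0)) - sd)^2
  }
  o <- stats::optim(c(init[[1]], log(init[[2]])), obj,
                    control = list(reltol = 1e-15, maxit = 5000))
  if (o$value > 1e-8)
    stopf("unsatisfiable truncation: cannot match mean %.3g, sd %.3g with floor %.3g",
          mean, sd, floor)
  c(meanlog = o$par[1], sdlog = exp(o$par[2]))
}

empty_truths <- function() {
  data.frame(fiber_id = integer(), center_row = numeric(),
             center_col = numeric(), inner_diameter_um = numeric(),
             myelin_thickness_um = numeric(), g_ratio = numeric(),
             axis_ratio = numeric(), orientation_rad = numeric())
}

#' Draw a ground-truth fiber population
#'
#' Draws `round(target_density * area_mm2)` fibers. Inner diameters come from
#' a lognormal whose floor-truncated moments match `(mean_diameter,
#' sd_diameter)` (inverse-CDF sampling, so the count is exact and the draw is
#' deterministic given the seed). Myelin thickness follows the linear model
#' in [population_params()], clipped so every true g-ratio lies inside
#' `params$g_clip`; `g_ratio = d / (d + 2 m)` holds to machine precision.
#' Axis ratios and orientations are uniform. Centers are `NA` until
#' [place_fibers()] assigns them.
#'
#' @param params A [population_params()] object.
#' @param area_mm2 Imaged area in mm^2 (> 0).
#' @param seed Optional integer seed overriding `params$seed`.
#' @return A data frame of fiber truths (one row per fiber) with columns
#'   `fiber_id, center_row, center_col, inner_diameter_um,
#'   myelin_thickness_um, g_ratio, axis_ratio, orientation_rad`.
#' @export
sample_population <- function(params, area_mm2, seed = params$seed) {
  stopifnot(inherits(params, "population_params"))
  if (area_mm2 <= 0) stopf("area_mm2 must be > 0")
  n <- round(params$target_density * area_mm2)
  if (n == 0) return(empty_truths())

  if (params$sd_diameter == 0) {
    ln <- NULL  # degenerate: all diameters equal the mean
  } else {
    ln <- truncated_lognormal_match(params$mean_diameter, params$sd_diameter,
                                    params$min_diameter)
  }
  with_seed(seed, {
    if (is.null(ln)) {
      if (params$min_diameter > params$mean_diameter)
        stopf("unsatisfiable truncation: floor above degenerate diameter")
      d <- rep(params$mean_diameter, n)
    } else {
      f0 <- if (params$min_diameter > 0)
        plnorm(params$min_diameter, ln[["meanlog"]], ln[["sdlog"]]) else 0
      d <- qlnorm(stats::runif(n, f0, 1), ln[["meanlog"]], ln[["sdlog"]])
    }
    m <- params$thickness_intercept + params$thickness_slope * d +
      stats::rnorm(n, 0, params$thickness_noise_sd)
    # clip so g = d/(d+2m) stays inside the open g_clip band
    g_lo <- params$g_clip[1]; g_hi <- params$g_clip[2]
    m_min <- d * (1 - g_hi) / (2 * g_hi)
    m_max <- d * (1 - g_lo) / (2 * g_lo)
    m <- pmin(pmax(m, m_min), m_max)
    q <- stats::runif(n, params$axis_ratio_range[1], params$axis_ratio_range[2])
    theta <- stats::runif(n, 0, pi)
    data.frame(
      fiber_id = seq_len(n), center_row = NA_real_, center_col = NA_real_,
      inner_diameter_um = d, myelin_thickness_um = m,
      g_ratio = d / (d + 2 * m), axis_ratio = q, orientation_rad = theta
    )
  })
}

# Outer bounding-circle radius in px (semi-major axis of the outer ellipse).
outer_radius_px <- function(truths, pixel_size) {
  outer_r <- (truths$inner_diameter_um + 2 * truths$myelin_thickness_um) / 2
  outer_r * sqrt(truths$axis_ratio) / pixel_size
}

#' Place fibers in an image without overlap
#'
#' Assigns centers by rejection sampling so that the circles circumscribing
#' the outer ellipses, plus a 1-px guard margin, are pairwise disjoint and
#' every fiber lies fully inside the image. Larger fibers are placed first;
#' the returned table preserves the input order. Fibers that cannot be
#' placed within `max_tries` attempts are dropped, with the count in
#' attribute `"n_dropped"`.
#'
#' @param truths Fiber table from [sample_population()].
#' @param render A [render_params()] object (image geometry).
#' @param seed Optional integer seed.
#' @param max_tries Placement attempts per fiber before dropping it.
#' @return `truths` with `center_row` / `center_col` filled (dropped fibers
#'   removed), attribute `n_dropped`.
#' @export
place_fibers <- function(truths, render, seed = NULL, max_tries = 1000L) {
  stopifnot(inherits(render, "render_params"))
  if (nrow(truths) == 0) {
    attr(truths, "n_dropped") <- 0L
    return(truths)
  }
  h <- render$image_height; w <- render$image_width
  rad <- outer_radius_px(truths, render$pixel_size)
  if (any(2 * rad + 2 > min(h, w)))
    stopf("fiber outer envelope larger than the image")
  ord <- order(rad, decreasing = TRUE)
  placed_r <- placed_c <- placed_rad <- numeric(0)
  row_out <- col_out <- rep(NA_real_, nrow(truths))
  dropped <- logical(nrow(truths))
  with_seed(seed, {
    for (i in ord) {
      ri <- rad[i]
      lo_r <- ri + 1; hi_r <- h - ri - 1
      lo_c <- ri + 1; hi_c <- w - ri - 1
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        cr <- stats::runif(1, lo_r, hi_r)
        cc <- stats::runif(1, lo_c, hi_c)
        if (length(placed_r) == 0 ||
            all((placed_r - cr)^2 + (placed_c - cc)^2 >
                (placed_rad + ri + 1)^2)) {
          ok <- TRUE
          break
        }
      }
      if (ok) {
        placed_r <- c(placed_r, cr); placed_c <- c(placed_c, cc)
        placed_rad <- c(placed_rad, ri)
        row_out[i] <- cr; col_out[i] <- cc
      } else {
        dropped[i] <- TRUE
      }
    }
  })
  if (all(dropped))
    stopf("requested density geometrically impossible: no fiber could be placed")
  out <- truths[!dropped, , drop = FALSE]
  out$center_row <- row_out[!dropped]
  out$center_col <- col_out[!dropped]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(dropped)
  out
}

# Rasterize one fiber into label/role matrices (modified in place by caller).
# A pixel belongs to a region iff its center lies inside the analytic ellipse.
# Inner ellipse: area pi*(d/2)^2; outer ellipse: concentric, same axis ratio
# and orientation, area pi*((d+2m)/2)^2 -- so area-equivalent diameters equal
# d and d+2m by construction.
rasterize_fiber <- function(truth, pixel_size, h, w) {
  r_in <- truth$inner_diameter_um / 2 / pixel_size
  r_out <- (truth$inner_diameter_um + 2 * truth$myelin_thickness_um) / 2 /
    pixel_size
  sq <- sqrt(truth$axis_ratio)
  a_in <- r_in * sq; b_in <- r_in / sq
  a_out <- r_out * sq; b_out <- r_out / sq
  rows <- max(1, floor(truth$center_row - a_out - 1)):
    min(h, ceiling(truth$center_row + a_out + 1))
  cols <- max(1, floor(truth$center_col - a_out - 1)):
    min(w, ceiling(truth$center_col + a_out + 1))
  dr <- rows - truth$center_row
  dc <- cols - truth$center_col
  ct <- cos(truth$orientation_rad); st <- sin(truth$orientation_rad)
  # rotated coordinates on the bounding-box grid
  u <- outer(dr, dc, function(x, y) x * ct + y * st)
  v <- outer(dr, dc, function(x, y) -x * st + y * ct)
  inside_out <- (u / a_out)^2 + (v / b_out)^2 <= 1
  inside_in <- (u / a_in)^2 + (v / b_in)^2 <= 1
  list(rows = rows, cols = cols, outer = inside_out, inner = inside_in)
}

#' Render a placed fiber population into an image plus ground truth
#'
#' Rasterizes myelin annuli and axon lumens from the analytic geometry
#' (pixel-center-in-ellipse rule), then builds the 8-bit image: class
#' intensities, optional bright two-photon artifact disks (image only --
#' never the truth masks), Gaussian PSF blur, additive Gaussian noise,
#' clipping to `[0, 255]` and rounding. Semantic and instance truth masks
#' are rasterized from the unblurred geometry.
#'
#' @param truths Placed fiber table from [place_fibers()].
#' @param render A [render_params()] object.
#' @param seed Optional integer seed (noise and artifacts).
#' @return An object of class `synthetic_sample`: list with `image` (integer
#'   matrix, 0-255), `semantic_truth` ([semantic_mask]), `instance_truth`
#'   ([instance_map]), `truths`, `render`.
#' @export
render_sample <- function(truths, render, seed = NULL) {
  stopifnot(inherits(render, "render_params"))
  h <- render$image_height; w <- render$image_width
  labels <- matrix(0L, h, w)
  roles <- matrix(0L, h, w)
  if (nrow(truths) > 0) {
    if (anyNA(truths$center_row))
      stopf("truths must be placed (run place_fibers first)")
    for (i in seq_len(nrow(truths))) {
      ras <- rasterize_fiber(truths[i, ], render$pixel_size, h, w)
      sub_lab <- labels[ras$rows, ras$cols, drop = FALSE]
      sub_rol <- roles[ras$rows, ras$cols, drop = FALSE]
      sub_lab[ras$outer] <- truths$fiber_id[i]
      sub_rol[ras$outer] <- 1L              # myelin
      sub_rol[ras$inner] <- 2L              # axon lumen
      labels[ras$rows, ras$cols] <- sub_lab
      roles[ras$rows, ras$cols] <- sub_rol
    }
  }
  img <- matrix(render$background_intensity, h, w)
  img[roles == 1L] <- render$myelin_intensity
  img[roles == 2L] <- render$axon_intensity
  with_seed(seed, {
    if (render$artifact_rate > 0) {
      n_art <- stats::rpois(1, render$artifact_rate)
      if (n_art > 0) {
        ar <- render$artifact_radius
        for (k in seq_len(n_art)) {
          cr <- stats::runif(1, 1, h); cc <- stats::runif(1, 1, w)
          rows <- max(1, floor(cr - ar)):min(h, ceiling(cr + ar))
          cols <- max(1, floor(cc - ar)):min(w, ceiling(cc + ar))
          disk <- outer((rows - cr)^2, (cols - cc)^2, "+") <= ar^2
          sub <- img[rows, cols, drop = FALSE]
          sub[disk] <- pmax(sub[disk], render$artifact_intensity)
          img[rows, cols] <- sub
        }
      }
    }
    if (render$psf_sigma > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = render$psf_sigma))
    if (render$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, render$noise_sd)
    NULL
  })
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), h, w)
  structure(list(
    image = img,
    semantic_truth = semantic_mask(roles, render$pixel_size),
    instance_truth = instance_map(labels, roles, render$pixel_size),
    truths = truths,
    render = render
  ), class = "synthetic_sample")
}

#' Generate one synthetic sample end to end
#'
#' Convenience wrapper: [sample_population()] for the image's area, then
#' [place_fibers()], then [render_sample()]. The three stages consume seeds
#' `seed`, `seed + 1`, `seed + 2` so the whole sample is reproducible from a
#' single integer.
#'
#' @param population A [population_params()] object.
#' @param render A [render_params()] object.
#' @param seed Integer seed, or `NULL` for the current RNG state.
#' @return A `synthetic_sample` (see [render_sample()]).
#' @export
generate_sample <- function(population, render, seed = NULL) {
  area_mm2 <- render$image_height * render$image_width *
    render$pixel_size^2 * 1e-6
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL)
           else as.list((as.numeric(seed) + 0:2) %% (2^31 - 5))
  truths <- sample_population(population, area_mm2, seed = seeds[[1]])
  placed <- place_fibers(truths, render, seed = seeds[[2]])
  out <- render_sample(placed, render, seed = seeds[[3]])
  attr(out, "n_dropped") <- attr(placed, "n_dropped")
  out
}
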