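# Synthetic fiber-image generator: distributions, placement, rasterization.

test_that("lognormal moment matching reproduces the closed form", {
  mm <- lognormal_moment_match(1.0, 0.5)
  expect_equal(unname(mm["meanlog"]), -0.1116, tolerance = 1e-3)
  expect_equal(unname(mm["sdlog"]), 0.4724, tolerance = 1e-3)
  # Monte-Carlo sanity at large n
  set.seed(9)
  x <- rlnorm(1e5, mm["meanlog"], mm["sdlog"])
  expect_equal(mean(x), 1.0, tolerance = 0.01)
  expect_equal(sd(x), 0.5, tolerance = 0.02)
})

test_that("untruncated draws recover requested moments within 3 SE", {
  p <- population_params(mean_diameter = 0.93, sd_diameter = 0.54,
                         min_diameter = 0, target_density = 844.36,
                         seed = 123)
  n <- 2e4
  tr <- sample_population(p, n / 844.36)
  expect_equal(nrow(tr), n)
  se <- 0.54 / sqrt(n)
  expect_lt(abs(mean(tr$inner_diameter_um) - 0.93), 3 * se)
  # SE of the sample SD under this heavy-tailed lognormal (kurtosis ~7.3):
  # sd * sqrt((kappa - 1) / (4 n)) ~ 0.0048
  expect_lt(abs(sd(tr$inner_diameter_um) - 0.54), 3 * 0.0048)
})

test_that("floor-truncated draws match the requested post-truncation moments", {
  p <- uf_reference_preset()$population
  p$seed <- 5L
  tr <- sample_population(p, 6)  # ~5000 fibers
  d <- tr$inner_diameter_um
  expect_true(all(d >= 0.37))
  expect_lt(abs(mean(d) - 0.93), 3 * 0.54 / sqrt(length(d)))
  expect_lt(abs(sd(d) - 0.54), 3 * 0.54 / sqrt(2 * length(d)))
})

test_that("degenerate spread gives identical fibers", {
  p <- population_params(sd_diameter = 0, thickness_noise_sd = 0,
                         min_diameter = 0, seed = 1)
  tr <- sample_population(p, 0.05)
  expect_gt(nrow(tr), 1)
  expect_equal(length(unique(tr$inner_diameter_um)), 1L)
  expect_equal(length(unique(tr$g_ratio)), 1L)
})

test_that("truth tables satisfy the g-ratio identity to 1e-9", {
  p <- uf_reference_preset()$population
  p$seed <- 7L
  tr <- sample_population(p, 0.5)
  d <- tr$inner_diameter_um; m <- tr$myelin_thickness_um
  expect_lt(max(abs(tr$g_ratio - d / (d + 2 * m))), 1e-9)
  expect_true(all(tr$g_ratio > 0.05 - 1e-12 & tr$g_ratio < 0.95 + 1e-12))
})

test_that("tiny area requests zero fibers without error", {
  p <- uf_reference_preset()$population
  tr <- sample_population(p, 1e-7, seed = 1)
  expect_equal(nrow(tr), 0)
})

test_that("unsatisfiable truncation is an error", {
  p <- population_params(mean_diameter = 0.5, sd_diameter = 0.1,
                         min_diameter = 2.0)
  expect_error(sample_population(p, 1, seed = 1), "truncation")
})

test_that("placement keeps outer envelopes disjoint inside the image", {
  p <- uf_reference_preset()
  tr <- sample_population(p$population, 0.014, seed = 21)
  placed <- place_fibers(tr, p$render, seed = 22)
  expect_equal(attr(placed, "n_dropped"), 0L)
  r_px <- (placed$inner_diameter_um + 2 * placed$myelin_thickness_um) / 2 *
    sqrt(placed$axis_ratio) / p$render$pixel_size
  n <- nrow(placed)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    gap <- sqrt((placed$center_row[i] - placed$center_row[j])^2 +
                (placed$center_col[i] - placed$center_col[j])^2) -
      (r_px[i] + r_px[j])
    expect_gt(gap, 0)
  }
  expect_true(all(placed$center_row > r_px & placed$center_row <
                    p$render$image_height - r_px))
})

test_that("impossible densities error or report drops", {
  # many large fibers on a tiny canvas: far beyond any packing bound
  tr <- do.call(rbind, lapply(1:40, function(i) {
    t <- single_fiber_truth(d = 3, m = 0.5)
    t$fiber_id <- i
    t$center_row <- t$center_col <- NA_real_
    t
  }))
  render <- small_render()
  res <- tryCatch(place_fibers(tr, render, seed = 3, max_tries = 50),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "impossible|placed")
  } else {
    expect_gt(attr(res, "n_dropped"), 0)
  }
})

test_that("placement and full samples are seed-deterministic", {
  p <- uf_reference_preset()
  s1 <- generate_sample(p$population, p$render, seed = 31)
  s2 <- generate_sample(p$population, p$render, seed = 31)
  expect_identical(s1$image, s2$image)
  expect_identical(unclass(s1$semantic_truth), unclass(s2$semantic_truth))
  expect_identical(s1$instance_truth$labels, s2$instance_truth$labels)
  expect_identical(s1$truths, s2$truths)
  s3 <- generate_sample(p$population, p$render, seed = 32)
  expect_false(identical(s1$image, s3$image))
})

test_that("rasterized axon area matches the analytic disk", {
  # d = 1.0 um at 0.166 um/px: pi * (0.5/0.166)^2 ~ 28.5 px
  tr <- single_fiber_truth(d = 1.0, m = 0.25, row = 25, col = 25)
  s <- render_fibers(tr)
  n_axon <- sum(unclass(s$semantic_truth) == 2)
  expect_lt(abs(n_axon - pi * (0.5 / 0.166)^2), 2.5)
})

test_that("empty truth list renders background plus noise only", {
  render <- render_params(image_height = 40, image_width = 40,
                          artifact_rate = 0)
  s <- render_sample(empty <- single_fiber_truth()[0, ], render, seed = 4)
  expect_true(all(unclass(s$semantic_truth) == 0))
  expect_true(all(s$instance_truth$labels == 0))
  expect_lt(abs(mean(s$image) - render$background_intensity), 3)
})

test_that("noiseless render has exactly three intensity levels", {
  tr <- single_fiber_truth()
  s <- render_fibers(tr)
  expect_setequal(unique(as.vector(s$image)), c(20L, 60L, 200L))
})

test_that("artifacts corrupt the image but never the truth masks", {
  render <- small_render(artifact_rate = 8)
  tr <- single_fiber_truth()
  s_clean <- render_sample(tr, small_render(), seed = 6)
  s_art <- render_sample(tr, render, seed = 6)
  expect_identical(unclass(s_art$semantic_truth),
                   unclass(s_clean$semantic_truth))
  expect_gt(sum(s_art$image == 250), 0)
})

test_that("semantic truth equals the class collapse of instance truth", {
  p <- uf_reference_preset()
  s <- generate_sample(p$population, p$render, seed = 41)
  collapsed <- collapse_instances(s$instance_truth)
  expect_identical(unclass(collapsed), unclass(s$semantic_truth))
})

test_that("the reference preset is frozen and matches its targets", {
  p1 <- uf_reference_preset()
  p2 <- uf_reference_preset()
  expect_identical(p1, p2)
  expect_equal(p1$population$mean_diameter, 0.93)
  expect_equal(p1$population$sd_diameter, 0.54)
  expect_equal(p1$population$target_density, 844.36)
  expect_equal(p1$render$pixel_size, 0.166)
  expect_equal(dim(matrix(0, p1$render$image_height, p1$render$image_width)),
               c(500L, 1000L))
  # thickness implied at the mean fiber lies in the published 0.48 +/- 0.14
  m_mean <- p1$population$thickness_intercept +
    p1$population$thickness_slope * 0.93
  expect_lt(abs(m_mean - 0.48), 0.14)
  # population mean g close to 0.47 (large draw)
  pop <- p1$population; pop$seed <- 99L
  tr <- sample_population(pop, 12)  # ~10000 fibers
  expect_lt(abs(mean(tr$g_ratio) - 0.47), 0.02)
  expect_lt(abs(mean(tr$myelin_thickness_um) - 0.48), 0.02)
})
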