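# End-to-end reproducible runs: generate -> instances -> morphometry -> qc
# -> stats, with file outputs and a machine-readable manifest.

#' Build a pipeline run configuration
#'
#' A run is fully reproducible from its configuration: preset (or explicit
#' parameter objects), number of images, base seed, quality-control policy
#' and bin scheme.
#'
#' @param out_dir Output directory for the run.
#' @param preset `"uf-reference"` or `"oblique-stress"`; ignored when
#'   `population`/`render` are given explicitly.
#' @param population,render Optional [population_params()] /
#'   [render_params()] overriding the preset.
#' @param n_images Number of images to generate.
#' @param seed Integer base seed; image i uses seeds derived from
#'   `seed + 3 i`.
#' @param segmentation One of `"truth"` (instances from the ground-truth
#'   semantic masks) or `"baseline"` (run [baseline_segment()] on the
#'   rendered images).
#' @param qc A [qc_policy()].
#' @param bins A [bin_scheme()].
#' @param eccentricity_on Passed to [measure_instances()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       preset = "uf-reference",
                       population = NULL, render = NULL,
                       n_images = 20L, seed = 1L,
                       segmentation = c("truth", "baseline"),
                       qc = qc_policy(), bins = bin_scheme(),
                       eccentricity_on = "axon") {
  segmentation <- match.arg(segmentation)
  if (is.null(population) || is.null(render)) {
    p <- switch(preset,
                "uf-reference" = uf_reference_preset(),
                "oblique-stress" = oblique_stress_preset(),
                stopf("unknown preset '%s'", preset))
    if (is.null(population)) population <- p$population
    if (is.null(render)) render <- p$render
  }
  if (n_images < 0) stopf("n_images must be >= 0")
  structure(list(out_dir = out_dir, preset = preset,
                 population = population, render = render,
                 n_images = as.integer(n_images), seed = as.integer(seed),
                 segmentation = segmentation, qc = qc, bins = bins,
                 eccentricity_on = eccentricity_on),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()]; `population`,
#' `render` and `qc` may be nested maps of the corresponding constructor
#' arguments.
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  args <- list(
    out_dir = if (!is.null(out_dir)) out_dir else y$out_dir,
    preset = if (!is.null(y$preset)) y$preset else "uf-reference",
    n_images = if (!is.null(y$n_images)) y$n_images else 20L,
    seed = if (!is.null(y$seed)) y$seed else 1L
  )
  if (!is.null(y$segmentation)) args$segmentation <- y$segmentation
  if (!is.null(y$population))
    args$population <- do.call(population_params, y$population)
  if (!is.null(y$render)) args$render <- do.call(render_params, y$render)
  if (!is.null(y$qc)) args$qc <- do.call(qc_policy, y$qc)
  if (!is.null(y$bins)) args$bins <- bin_scheme(y$bins$edges)
  do.call(run_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full morphometry pipeline
#'
#' For each image: generate the synthetic sample (image, truth masks, truth
#' table, all written to the run directory), obtain a semantic mask
#' (ground-truth or baseline segmentation), separate instances, and measure
#' fibers. Measured records are pooled, screened by the quality-control
#' policy, and summarized. All outputs are files, so externally produced
#' masks can be substituted at any stage; a JSON manifest records seeds,
#' versions and per-stage counts. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `records`, `kept`, `removed`, `summary`
#'   (a [summarize_population()] result), and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  for (d in file.path(out, c("images", "masks", "instances", "truths")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  render <- config$render
  area_img <- render$image_height * render$image_width *
    render$pixel_size^2 * 1e-6
  all_records <- list()
  n_generated <- n_segmented <- n_dropped <- 0L

  for (i in seq_len(config$n_images)) {
    tag <- sprintf("img%03d", i)
    seed_i <- (config$seed + 3 * (i - 1)) %% (2^31 - 5)
    sample <- stage("generate",
                    generate_sample(config$population, render, seed = seed_i))
    n_generated <- n_generated + nrow(sample$truths)
    n_dropped <- n_dropped + attr(sample, "n_dropped")
    write_image_png(sample$image, file.path(out, "images",
                                            paste0(tag, ".png")))
    write_mask_png(sample$semantic_truth,
                   file.path(out, "masks", paste0(tag, "_truth.png")))
    write_truth_csv(sample$truths,
                    file.path(out, "truths", paste0(tag, ".csv")))

    mask <- if (config$segmentation == "truth") sample$semantic_truth
            else stage("segment",
                       baseline_segment(sample$image, render$pixel_size))
    imap <- stage("instances", separate_instances(mask))
    lab_path <- file.path(out, "instances",
                          paste0(tag, if (max(imap$labels) > 255) ".tsv"
                                 else ".png"))
    write_instance_labels(imap$labels, lab_path)
    recs <- stage("morphometry",
                  measure_instances(imap,
                                    eccentricity_on = config$eccentricity_on))
    if (nrow(recs) > 0) recs <- cbind(image = tag, recs)
    n_segmented <- n_segmented + nrow(recs)
    all_records[[i]] <- recs
    say("%s: %d fibers generated, %d measured", tag,
        nrow(sample$truths), nrow(recs))
  }

  records <- if (length(all_records) > 0) do.call(rbind, all_records)
             else cbind(image = character(0), measure_instances(
               instance_map(matrix(0L, 1, 1), matrix(0L, 1, 1), 1)))
  screened <- stage("qc", qc_screen(records, config$qc))
  total_area <- config$n_images * area_img
  summary <- stage("stats", summarize_population(
    screened$kept, area_mm2 = if (total_area > 0) total_area else NA_real_,
    scheme = config$bins))

  utils::write.csv(records, file.path(out, "records.csv"), row.names = FALSE)
  utils::write.csv(screened$kept, file.path(out, "kept.csv"),
                   row.names = FALSE)
  utils::write.csv(screened$removed, file.path(out, "removed.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$per_bin, file.path(out, "per_bin.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$overall, file.path(out, "overall.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "axonmorph",
    version = as.character(utils::packageVersion("axonmorph")),
    preset = config$preset,
    seed = config$seed,
    n_images = config$n_images,
    segmentation = config$segmentation,
    counts = list(generated = n_generated, placement_dropped = n_dropped,
                  measured = n_segmented, kept = nrow(screened$kept),
                  removed = nrow(screened$removed)),
    density_mm2 = summary$density_mm2
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("run complete: %d kept / %d measured fibers",
      nrow(screened$kept), n_segmented)
  invisible(list(records = records, kept = screened$kept,
                 removed = screened$removed, summary = summary,
                 manifest = manifest))
}
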