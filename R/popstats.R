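# Diameter binning and population-level aggregation.

#' Diameter bin scheme
#'
#' Half-open bins `[lo, hi)` over axon diameter, with a final open-ended bin
#' `[last_edge, Inf)`. The default edges start at the quality-control floor
#' 0.335 um, step to 0.5 um, then rise in 0.25 um increments to 1.75 um,
#' with everything above 1.75 um pooled ("1.75+").
#'
#' @param edges Strictly increasing finite bin edges, um; the final bin is
#'   `[max(edges), Inf)`.
#' @return An object of class `bin_scheme` with `edges` and display `labels`.
#' @export
bin_scheme <- function(edges = c(0.335, 0.5, 0.75, 1.0, 1.25, 1.5, 1.75)) {
  if (length(edges) < 2 || any(diff(edges) <= 0) || any(!is.finite(edges)))
    stopf("edges must be strictly increasing and finite")
  k <- length(edges)
  labels <- c(sprintf("[%.3g, %.3g)", edges[-k], edges[-1]),
              sprintf("%.3g+", edges[k]))
  structure(list(edges = as.numeric(edges), labels = labels),
            class = "bin_scheme")
}

#' Assign records to diameter bins
#'
#' Half-open assignment `[lo, hi)`; diameters at or above the last edge go
#' to the open-ended final bin. A diameter below the first edge is an error
#' (the quality-control screen should have removed it).
#'
#' @param records Fiber record data frame.
#' @param scheme A [bin_scheme()].
#' @return `records` with an added factor column `diameter_bin` (levels =
#'   `scheme$labels`, including empty bins).
#' @export
bin_records <- function(records, scheme = bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"))
  d <- records$axon_diameter_um
  if (any(d < scheme$edges[1]))
    stopf("diameter below first bin edge (%.3g um); screen records first",
          scheme$edges[1])
  idx <- findInterval(d, c(scheme$edges, Inf), rightmost.closed = FALSE)
  records$diameter_bin <- factor(scheme$labels[idx], levels = scheme$labels)
  records
}

mean_sd <- function(x) {
  c(mean = if (length(x) >= 1) mean(x) else NA_real_,
    sd = if (length(x) >= 2) stats::sd(x) else NA_real_)
}

#' Summarize a screened fiber population
#'
#' Overall mean and sample SD (n-1 denominator) for axon diameter, myelin
#' thickness and g-ratio; per-bin counts and mean/SD triples; myelinated
#' fiber density (total count / total imaged area); pairwise Pearson
#' correlations with two-sided p-values; and ordinary-least-squares R^2 for
#' thickness ~ diameter and g ~ diameter. With fewer than two records, SDs,
#' correlations and R^2 are reported as `NA`.
#'
#' @param records Screened fiber record data frame.
#' @param area_mm2 Total imaged area in mm^2 (for the density), or `NA` to
#'   skip density.
#' @param scheme A [bin_scheme()].
#' @return An object of class `population_summary`: list with `n`, `overall`
#'   (data frame metric x mean/sd), `per_bin`, `density_mm2`,
#'   `correlations` (pairwise r and p), `r2_thickness_diameter`,
#'   `r2_g_diameter`, `scheme`.
#' @export
summarize_population <- function(records, area_mm2 = NA_real_,
                                 scheme = bin_scheme()) {
  metrics <- c(diameter = "axon_diameter_um",
               thickness = "myelin_thickness_um",
               g_ratio = "g_ratio")
  n <- nrow(records)
  overall <- do.call(rbind, lapply(metrics, function(col) {
    ms <- mean_sd(records[[col]])
    data.frame(mean = ms[["mean"]], sd = ms[["sd"]])
  }))
  overall <- cbind(metric = names(metrics), overall)
  rownames(overall) <- NULL

  binned <- bin_records(records, scheme)
  per_bin <- do.call(rbind, lapply(levels(binned$diameter_bin), function(b) {
    sub <- binned[binned$diameter_bin == b, , drop = FALSE]
    row <- data.frame(bin = b, n = nrow(sub))
    for (m in names(metrics)) {
      ms <- mean_sd(sub[[metrics[[m]]]])
      row[[paste0(m, "_mean")]] <- ms[["mean"]]
      row[[paste0(m, "_sd")]] <- ms[["sd"]]
    }
    row
  }))

  pairs <- utils::combn(names(metrics), 2)
  correlations <- do.call(rbind, apply(pairs, 2, function(p) {
    x <- records[[metrics[[p[1]]]]]; y <- records[[metrics[[p[2]]]]]
    if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      data.frame(var1 = p[1], var2 = p[2], r = NA_real_, p_value = NA_real_)
    } else {
      ct <- stats::cor.test(x, y, method = "pearson")
      data.frame(var1 = p[1], var2 = p[2], r = unname(ct$estimate),
                 p_value = ct$p.value)
    }
  }))

  # simple-OLS R^2 equals the squared Pearson correlation
  r2 <- function(yc, xc) {
    x <- records[[xc]]; y <- records[[yc]]
    if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }
  structure(list(
    n = n,
    overall = overall,
    per_bin = per_bin,
    density_mm2 = if (is.na(area_mm2)) NA_real_
                  else n / area_mm2,
    correlations = correlations,
    r2_thickness_diameter = r2("myelin_thickness_um", "axon_diameter_um"),
    r2_g_diameter = r2("g_ratio", "axon_diameter_um"),
    scheme = scheme
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("population_summary: n = %d fibers\n", x$n))
  if (!is.na(x$density_mm2))
    cat(sprintf("  density: %.2f fibers/mm^2\n", x$density_mm2))
  ov <- x$overall
  for (i in seq_len(nrow(ov)))
    cat(sprintf("  %-10s mean %.4g, sd %.4g\n",
                ov$metric[i], ov$mean[i], ov$sd[i]))
  cat(sprintf("  R2 thickness~diameter: %.3f, R2 g~diameter: %.3f\n",
              x$r2_thickness_diameter, x$r2_g_diameter))
  invisible(x)
}

#' Side-by-side per-bin comparison of two populations
#'
#' Descriptive per-bin means and SDs for two summaries sharing a bin scheme
#' (no hypothesis test). Empty bins stay `NA`, not zero.
#'
#' @param summary_a,summary_b [summarize_population()] results with
#'   identical bin schemes.
#' @param labels Length-2 character, column-name suffixes for the groups.
#' @return Data frame, one row per bin, with each group's count and
#'   mean/SD columns.
#' @export
compare_regions <- function(summary_a, summary_b, labels = c("a", "b")) {
  stopifnot(inherits(summary_a, "population_summary"),
            inherits(summary_b, "population_summary"))
  if (!isTRUE(all.equal(summary_a$scheme$edges, summary_b$scheme$edges)))
    stopf("bin schemes differ between the two summaries")
  a <- summary_a$per_bin; b <- summary_b$per_bin
  names(a)[-1] <- paste0(names(a)[-1], "_", labels[1])
  names(b)[-1] <- paste0(names(b)[-1], "_", labels[2])
  merge(a, b, by = "bin", sort = FALSE)
}
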