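# Multicriteria post-hoc screening of fiber records.

#' Quality-control policy
#'
#' Thresholds for the post-hoc screen that removes implausibly segmented
#' fibers. A record is kept iff `g_min < g < g_max` (implausible g-ratios
#' indicate mis-segmented boundaries; exactly 1 would mean zero myelin),
#' `diameter >= min_diameter` (below ~2 px the area-equivalent diameter is
#' dominated by partial-volume error; the boundary value itself is kept),
#' and `eccentricity <= max_eccentricity` (the circular-equivalence model
#' breaks down for highly elongated profiles; the boundary value is kept).
#'
#' @param g_min,g_max Exclusive bounds on g-ratio.
#' @param min_diameter Minimum axon diameter, um (inclusive; default 0.335).
#' @param max_eccentricity Maximum eccentricity (inclusive; default 0.9).
#' @return An object of class `qc_policy`.
#' @export
qc_policy <- function(g_min = 0, g_max = 1, min_diameter = 0.335,
                      max_eccentricity = 0.9) {
  if (!(g_min >= 0 && g_min < g_max && g_max <= 1))
    stopf("need 0 <= g_min < g_max <= 1")
  if (min_diameter < 0) stopf("min_diameter must be >= 0")
  if (!(max_eccentricity > 0 && max_eccentricity <= 1))
    stopf("max_eccentricity must be in (0, 1]")
  structure(list(g_min = g_min, g_max = g_max, min_diameter = min_diameter,
                 max_eccentricity = max_eccentricity), class = "qc_policy")
}

#' Screen fiber records against a quality-control policy
#'
#' Partitions records into kept and removed, preserving input order. Each
#' removed record is tagged with *every* rule it violates in a `reasons`
#' column (semicolon-separated): `"g_ratio"`, `"diameter"`, `"eccentricity"`;
#' records with any non-finite metric are removed with reason `"invalid"`.
#'
#' @param records Fiber record data frame (see [measure_instances()]).
#' @param policy A [qc_policy()].
#' @return List with elements `kept` (data frame) and `removed` (data frame
#'   with the extra `reasons` column); `nrow(kept) + nrow(removed) ==
#'   nrow(records)`.
#' @export
qc_screen <- function(records, policy = qc_policy()) {
  stopifnot(inherits(policy, "qc_policy"))
  n <- nrow(records)
  if (n == 0) {
    removed <- records
    removed$reasons <- character(0)
    return(list(kept = records, removed = removed))
  }
  g <- records$g_ratio
  d <- records$axon_diameter_um
  e <- records$eccentricity
  invalid <- !is.finite(g) | !is.finite(d) | !is.finite(e)
  bad_g <- !invalid & !(g > policy$g_min & g < policy$g_max)
  bad_d <- !invalid & d < policy$min_diameter
  bad_e <- !invalid & e > policy$max_eccentricity
  reasons <- character(n)
  for (i in seq_len(n)) {
    r <- c(if (invalid[i]) "invalid",
           if (bad_g[i]) "g_ratio",
           if (bad_d[i]) "diameter",
           if (bad_e[i]) "eccentricity")
    reasons[i] <- paste(r, collapse = ";")
  }
  drop <- invalid | bad_g | bad_d | bad_e
  removed <- records[drop, , drop = FALSE]
  removed$reasons <- reasons[drop]
  rownames(removed) <- NULL
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}
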