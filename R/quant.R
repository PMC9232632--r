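#' Vehicle-normalize gated counts
#'
#' Converts per-well gated counts into vehicle-normalized readouts: each
#' treated well's bulk, LSC and lymphocyte counts are divided by the
#' aggregate (arithmetic mean by default) of the same-sample vehicle (DMSO)
#' well counts, following the screen's normalization to negative controls.
#' Within-bulk state proportions (\code{prop_lsc}, \code{prop_diff}) are
#' computed from the raw counts and are not vehicle-normalized. Replicate
#' wells are kept separate; aggregation happens downstream in
#' [summarizeReplicates()].
#'
#' A sample without any vehicle well is a hard error. A vehicle mean of zero
#' for one readout flags that readout unusable (ratio \code{NA}) while the
#' others proceed.
#'
#' @param counts data.frame of per-well counts from [gatePlate()].
#' @param layout plate layout data.frame with columns \code{well, sample,
#'   treatment, role, replicate}.
#' @param stat vehicle aggregation statistic, \code{"mean"} (default) or
#'   \code{"median"}.
#' @return data.frame with one row per well: layout columns plus
#'   \code{bulk_ratio, lsc_ratio, lymph_ratio, prop_lsc, prop_diff} and the
#'   vehicle means used (\code{veh_bulk, veh_lsc, veh_lymph}).
#' @export
normalizePlate <- function(counts, layout, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  agg <- if (stat == "mean") mean else median
  d <- merge(layout, counts, by = "well", sort = FALSE)
  if (nrow(d) != nrow(layout))
    stop("counts and layout do not cover the same wells")
  out <- NULL
  for (s in unique(d$sample)) {
    ds <- d[d$sample == s, , drop = FALSE]
    veh <- ds[ds$role == "vehicle", , drop = FALSE]
    if (nrow(veh) == 0L)
      stop("no vehicle wells for sample '", s, "'")
    vb <- agg(veh$bulk); vl <- agg(veh$lsc); vy <- agg(veh$lymph)
    ratio <- function(x, v) if (v > 0) x / v else rep(NA_real_, length(x))
    ds$bulk_ratio <- ratio(ds$bulk, vb)
    ds$lsc_ratio <- ratio(ds$lsc, vl)
    ds$lymph_ratio <- ratio(ds$lymph, vy)
    ds$prop_lsc <- ifelse(ds$bulk > 0, ds$lsc / ds$bulk, NA_real_)
    ds$prop_diff <- ifelse(ds$bulk > 0, ds$diff / ds$bulk, NA_real_)
    ds$veh_bulk <- vb; ds$veh_lsc <- vl; ds$veh_lymph <- vy
    out <- rbind(out, ds)
  }
  rownames(out) <- NULL
  out
}

#' Summarize replicate wells per condition
#'
#' Mean and standard deviation per (sample, treatment, readout) across
#' replicate wells, emulating the reporting of technical triplicates as
#' mean +/- SD. Conditions with a single well get SD 0 and are flagged.
#'
#' @param readouts data.frame from [normalizePlate()].
#' @param readoutCols character, readout columns to summarize.
#' @return data.frame with columns \code{sample, treatment, readout, mean,
#'   sd, n, single_well}.
#' @export
summarizeReplicates <- function(readouts,
                                readoutCols = c("bulk_ratio", "lsc_ratio",
                                                "lymph_ratio", "prop_lsc",
                                                "prop_diff")) {
  key <- interaction(readouts$sample, readouts$treatment, drop = TRUE,
                     sep = "\r")
  out <- list()
  for (k in levels(key)) {
    rk <- readouts[key == k, , drop = FALSE]
    for (col in readoutCols) {
      x <- rk[[col]]
      x <- x[!is.na(x)]
      n <- length(x)
      out[[length(out) + 1L]] <- data.frame(
        sample = rk$sample[1L], treatment = rk$treatment[1L],
        readout = col,
        mean = if (n) mean(x) else NA_real_,
        sd = if (n > 1L) sd(x) else 0,
        n = n,
        single_well = n <= 1L)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
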