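#' Untruncated trapezoidal area over the dose-response curve
#'
#' Drug activity is scored as the actual (trapezoidal) area over the curve
#' of vehicle-normalized cell counts, without fitting a dose-response model
#' and without truncation: neither the normalized values nor the resulting
#' area are clipped, so outgrowth above vehicle (v > 1) legitimately yields
#' a negative AOC. Higher AOC means greater drug activity.
#'
#' Concentrations are mapped to \code{log10} scale and, by default, affinely
#' rescaled to the unit interval, so AOC is comparable across drugs with
#' different dose ranges and lies in [0, 1] whenever all normalized values
#' do. With \code{rescale = FALSE} the raw log10-concentration width is used
#' instead. For a constant profile \code{v == k} the AOC is \code{1 - k}
#' (under rescaling).
#'
#' @param concentration strictly increasing, strictly positive dose vector
#'   (length >= 2).
#' @param value vehicle-normalized values at those doses (finite).
#' @param rescale logical; rescale log10 concentration to [0, 1]
#'   (default TRUE).
#' @return numeric AOC, with attributes \code{method}
#'   (\code{"trapezoid-untruncated"}), \code{truncated} (FALSE) and
#'   \code{range} (the dose range).
#' @examples
#' computeAOC(c(1, 10, 100), c(1, 0.5, 0))   # 0.5
#' computeAOC(c(1, 10), c(1.2, 1.2))         # -0.2 (outgrowth)
#' @export
computeAOC <- function(concentration, value, rescale = TRUE) {
  n <- length(concentration)
  if (n < 2L) stop("at least 2 doses required")
  if (length(value) != n) stop("concentration and value lengths differ")
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (any(diff(concentration) <= 0))
    stop("concentrations must be strictly increasing")
  if (any(!is.finite(value))) stop("values must be finite")
  x <- log10(concentration)
  if (rescale) x <- (x - x[1L]) / (x[n] - x[1L])
  y <- 1 - value
  aoc <- sum(diff(x) * (y[-n] + y[-1L]) / 2)
  structure(aoc, method = "trapezoid-untruncated", truncated = FALSE,
            range = range(concentration))
}

#' AOC per group of a tidy dose-response table
#'
#' Convenience wrapper: averages replicate values per dose (mean), then
#' applies [computeAOC()] within each group.
#'
#' @param data data.frame with at least the concentration and value columns.
#' @param concCol,valueCol column names of dose and normalized value.
#' @param by character vector of grouping columns (e.g. sample, drug,
#'   readout).
#' @param rescale passed to [computeAOC()].
#' @return data.frame: grouping columns plus \code{aoc}, \code{n_doses},
#'   \code{method}.
#' @export
aocByGroup <- function(data, concCol = "conc", valueCol = "value",
                       by = "drug", rescale = TRUE) {
  key <- interaction(data[by], drop = TRUE, sep = "\r")
  out <- lapply(levels(key), function(k) {
    dk <- data[key == k, , drop = FALSE]
    m <- tapply(dk[[valueCol]], dk[[concCol]], mean)
    conc <- as.numeric(names(m))
    o <- order(conc)
    a <- computeAOC(conc[o], as.numeric(m)[o], rescale = rescale)
    cbind(dk[1L, by, drop = FALSE],
          data.frame(aoc = as.numeric(a), n_doses = length(conc),
                     method = attr(a, "method")))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fixed-dose activity triple per treatment
#'
#' For screens run at a single fixed concentration per drug, computes per
#' (sample, treatment) the three readouts of the multiparametric assay as
#' raw signed quantities: bulk activity \code{1 - bulk_ratio} (mean over
#' replicates), and the changes of the within-bulk LSC and DIFF proportions
#' relative to the same-sample vehicle wells. No scaling or sign
#' re-orientation is applied here; that is the pattern module's job
#' ([scaleReadouts()]).
#'
#' @param readouts data.frame from [normalizePlate()].
#' @return data.frame with columns \code{sample, treatment, bulk_activity,
#'   lsc_prop_delta, diff_prop_delta, bulk_ratio, prop_lsc, prop_diff,
#'   veh_prop_lsc, veh_prop_diff}.
#' @export
fixedDoseActivity <- function(readouts) {
  out <- list()
  for (s in unique(readouts$sample)) {
    ds <- readouts[readouts$sample == s, , drop = FALSE]
    veh <- ds[ds$role == "vehicle", , drop = FALSE]
    if (nrow(veh) == 0L) stop("no vehicle wells for sample '", s, "'")
    vpl <- mean(veh$prop_lsc, na.rm = TRUE)
    vpd <- mean(veh$prop_diff, na.rm = TRUE)
    trt <- ds[ds$role != "vehicle", , drop = FALSE]
    for (tr in unique(trt$treatment)) {
      dt <- trt[trt$treatment == tr, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        sample = s, treatment = tr,
        bulk_activity = 1 - mean(dt$bulk_ratio, na.rm = TRUE),
        lsc_prop_delta = mean(dt$prop_lsc, na.rm = TRUE) - vpl,
        diff_prop_delta = mean(dt$prop_diff, na.rm = TRUE) - vpd,
        bulk_ratio = mean(dt$bulk_ratio, na.rm = TRUE),
        prop_lsc = mean(dt$prop_lsc, na.rm = TRUE),
        prop_diff = mean(dt$prop_diff, na.rm = TRUE),
        veh_prop_lsc = vpl, veh_prop_diff = vpd)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fixed-ratio serial dilution series
#'
#' Builds the concentration pairs of a two-drug backbone delivered at a
#' fixed concentration ratio across a serial dilution, e.g. the 5-point,
#' 10-fold daunorubicin-cytarabine series at a fixed 1:20 ratio: pairs
#' \code{(base/fold^k, ratio * base/fold^k)} for \code{k = 0 ...
#' nPoints - 1}, in descending concentration.
#'
#' @param base top concentration of the first drug, > 0.
#' @param ratio second-to-first drug concentration ratio, > 0 (default 20).
#' @param nPoints number of dilution points, >= 2 (default 5).
#' @param fold dilution factor between consecutive points, > 1 (default 10).
#' @return data.frame with columns \code{conc1}, \code{conc2} (descending);
#'   every row preserves \code{conc2 / conc1 == ratio} exactly.
#' @examples
#' fixedRatioSeries(1, ratio = 20, nPoints = 5, fold = 10)
#' @export
fixedRatioSeries <- function(base, ratio = 20, nPoints = 5L, fold = 10) {
  if (base <= 0 || ratio <= 0 || nPoints < 2L || fold <= 1)
    stop("invalid series parameters")
  c1 <- base / fold^(seq_len(nPoints) - 1L)
  data.frame(conc1 = c1, conc2 = ratio * c1)
}

#' Interpolated inhibitory concentration from a dose-response profile
#'
#' Finds the concentration at which the vehicle-normalized value crosses
#' \code{1 - level/100} (e.g. IC40 at v = 0.6), by linear interpolation of
#' v against log10 concentration between the first bracketing dose pair.
#'
#' @param concentration strictly increasing positive dose vector.
#' @param value vehicle-normalized values at those doses.
#' @param level inhibition percentage in (0, 100).
#' @return the interpolated concentration, in the input units.
#' @export
interpolateIC <- function(concentration, value, level) {
  if (level <= 0 || level >= 100) stop("level must be in (0, 100)")
  if (any(diff(concentration) <= 0) || any(concentration <= 0))
    stop("concentrations must be strictly increasing and positive")
  target <- 1 - level / 100
  n <- length(value)
  for (i in seq_len(n - 1L)) {
    v1 <- value[i]; v2 <- value[i + 1L]
    if ((v1 - target) * (v2 - target) <= 0 && v1 != v2) {
      lx <- log10(concentration[i]) +
        (v1 - target) / (v1 - v2) *
        (log10(concentration[i + 1L]) - log10(concentration[i]))
      return(10^lx)
    }
    if (v1 == target) return(concentration[i])
  }
  if (value[n] == target) return(concentration[n])
  stop("IC", level, " not bracketed by the supplied dose-response profile")
}

#' Select a clinically bounded screening concentration
#'
#' Implements the concentration-selection rules of the screen. In
#' \code{"screen_max"} mode the maximal testing concentration is the lower
#' of the drug's peak plasma concentration (Cmax, from pharmacokinetics) and
#' the IC40 for healthy CD34+ hematopoietic stem/progenitor cells. In
#' \code{"screen_low"} mode (fixed low-dose third agents) it is the lower of
#' 20% of Cmax and the healthy-CD34 IC10.
#'
#' @param cd34Conc,cd34Value healthy-CD34 dose-response profile (strictly
#'   increasing positive concentrations, vehicle-normalized values).
#' @param cmax peak plasma concentration, > 0, in the same units.
#' @param mode \code{"screen_max"} or \code{"screen_low"}.
#' @return list with \code{concentration}, the interpolated \code{ic}, the
#'   PK bound \code{pkBound}, and \code{limiting} (\code{"PK"} or
#'   \code{"CD34"}).
#' @examples
#' selectScreenConcentration(c(10, 100, 1000, 10000),
#'                           c(1.0, 0.8, 0.4, 0.2), cmax = 1000)
#' @export
selectScreenConcentration <- function(cd34Conc, cd34Value, cmax,
                                      mode = c("screen_max", "screen_low")) {
  mode <- match.arg(mode)
  if (cmax <= 0) stop("Cmax must be positive")
  if (mode == "screen_max") {
    ic <- interpolateIC(cd34Conc, cd34Value, 40)
    pk <- cmax
  } else {
    ic <- interpolateIC(cd34Conc, cd34Value, 10)
    pk <- 0.2 * cmax
  }
  list(concentration = min(pk, ic), ic = ic, pkBound = pk,
       limiting = if (pk <= ic) "PK" else "CD34")
}
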