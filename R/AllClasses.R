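#' Panel map: marker-to-channel assignment and per-channel intensity model
#'
#' A \code{PanelMap} records how the six biological marker roles of the
#' screening panel (viability stain, GFP for stromal cells, CD45, GPR56,
#' pooled differentiation markers CD11b/CD14/CD15, pooled lymphocyte markers
#' CD3/CD19) map onto cytometer channels, together with the two-component
#' log-intensity model used by the synthetic generator: for every channel a
#' negative and a positive log10-intensity mean with their dispersions.
#' Intensities are modelled post-compensation on the log scale; no spillover
#' is represented.
#'
#' @slot channels named character, marker role -> channel name; all six
#'   roles mapped to distinct channels.
#' @slot negMean,posMean named numeric, per-marker negative/positive
#'   component means on the log10 scale; \code{posMean > negMean} everywhere.
#' @slot negSD,posSD named numeric, per-marker component standard deviations
#'   (strictly positive).
#'
#' @seealso [defaultPanel()], [simulateWell()], [estimateThresholds()]
#' @export
setClass("PanelMap",
  representation(
    channels = "character",
    negMean = "numeric",
    posMean = "numeric",
    negSD = "numeric",
    posSD = "numeric"
  )
)

setValidity("PanelMap", function(object) {
  msg <- character()
  for (s in c("channels", "negMean", "posMean", "negSD", "posSD")) {
    v <- slot(object, s)
    if (!identical(sort(names(v)), sort(.MARKERS)))
      msg <- c(msg, sprintf("slot '%s' must be named by the six markers: %s",
                            s, paste(.MARKERS, collapse = ", ")))
  }
  if (length(msg)) return(msg)
  if (anyDuplicated(object@channels))
    msg <- c(msg, "all six markers must map to distinct channels")
  if (!all(object@posMean[.MARKERS] > object@negMean[.MARKERS]))
    msg <- c(msg, "positive mean must exceed negative mean on every channel")
  if (!all(object@negSD > 0) || !all(object@posSD > 0))
    msg <- c(msg, "component standard deviations must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Construct a default flow panel
#'
#' Builds a [PanelMap-class] with conventional channel names and a symmetric
#' two-component log-normal intensity model shared across channels.
#'
#' \code{separation} is the distance, in component standard deviations,
#' between each component mean and the midpoint gate boundary; the two means
#' are therefore \code{2 * separation * sd} apart. A separation of 4 places
#' each population 4 SD away from the boundary, so single-channel
#' misclassification is of order \code{pnorm(-4)}.
#'
#' @param separation numeric, mean-to-boundary distance in SD units
#'   (default 4).
#' @param sd numeric, component standard deviation on the log10 scale
#'   (default 0.25).
#' @param negMean numeric, negative component mean (default 1).
#' @param channels optional named character vector to override the default
#'   marker -> channel names.
#' @return A validated [PanelMap-class] object.
#' @examples
#' pm <- defaultPanel()
#' channels(pm)
#' @export
defaultPanel <- function(separation = 4, sd = 0.25, negMean = 1,
                         channels = NULL) {
  stopifnot(separation > 0, sd > 0)
  chan <- c(viability = "Via-A", GFP = "GFP-A", CD45 = "PerCP-A",
            GPR56 = "PE-A", Diff = "APC-A", Lymph = "BV421-A")
  if (!is.null(channels)) chan[names(channels)] <- channels
  one <- setNames(rep(negMean, 6), .MARKERS)
  new("PanelMap",
      channels = chan,
      negMean = one,
      posMean = one + 2 * separation * sd,
      negSD = setNames(rep(sd, 6), .MARKERS),
      posSD = setNames(rep(sd, 6), .MARKERS))
}

#' @describeIn PanelMap-class marker -> channel mapping
#' @param object a \code{PanelMap}
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))

#' @rdname PanelMap-class
#' @export
setMethod("channels", "PanelMap", function(object) object@channels)

setMethod("show", "PanelMap", function(object) {
  cat("PanelMap with", length(object@channels), "marker roles\n")
  for (m in .MARKERS)
    cat(sprintf("  %-9s -> %-8s  neg %.2f (sd %.2f)  pos %.2f (sd %.2f)\n",
                m, object@channels[m], object@negMean[m], object@negSD[m],
                object@posMean[m], object@posSD[m]))
})

#' Ground truth for the synthetic plate generator
#'
#' Encodes the known composition and drug-effect models from which synthetic
#' wells are simulated, and against which recovery is tested. Wells are
#' seeded with a mixture of GFP+ stromal cells, CD3/CD19+ lymphocytes, and a
#' leukemic bulk partitioned into GPR56+/Diff- (LSC), GPR56-/Diff+ (DIFF)
#' and GPR56-/Diff- basal states; the remainder of the seeding fraction is
#' dead at baseline. Each drug carries per-population survival models (Hill
#' form: maximal kill fraction E, half-effect concentration EC50, slope h)
#' and optionally a differentiation-induction model moving basal and LSC
#' cells into the Diff+ state before survival is applied.
#'
#' @slot fractions named numeric over \code{stroma, lymph, LSC, DIFF, basal};
#'   each in [0,1], sum <= 1, remainder dead at baseline.
#' @slot drugs named list of drug models built with [drugModel()].
#' @slot seeding positive integer, cells seeded per well (default emulates
#'   50,000 mononuclear cells per well).
#' @slot cv numeric >= 0, coefficient of variation of the multiplicative
#'   log-normal per-well seeding factor emulating technical replicate noise.
#' @slot acquiredFraction numeric in (0,1], fraction of well contents
#'   acquired as events by the cytometer (exposed as a parameter because
#'   acquired event depth is instrument/run dependent).
#'
#' @seealso [GroundTruth()], [drugModel()], [expectedCounts()],
#'   [simulateWell()]
#' @export
setClass("GroundTruth",
  representation(
    fractions = "numeric",
    drugs = "list",
    seeding = "integer",
    cv = "numeric",
    acquiredFraction = "numeric"
  )
)

.checkHill <- function(x, what, drug) {
  msg <- character()
  need <- c("E", "ec50", "h")
  if (!all(need %in% names(x)))
    return(sprintf("drug '%s': %s needs named components E, ec50, h",
                   drug, what))
  if (x[["E"]] < 0 || x[["E"]] > 1)
    msg <- c(msg, sprintf("drug '%s': %s E must lie in [0,1]", drug, what))
  if (x[["ec50"]] <= 0)
    msg <- c(msg, sprintf("drug '%s': %s EC50 must be > 0", drug, what))
  if (x[["h"]] <= 0)
    msg <- c(msg, sprintf("drug '%s': %s slope h must be > 0", drug, what))
  msg
}

setValidity("GroundTruth", function(object) {
  msg <- character()
  f <- object@fractions
  pops <- setdiff(.POPULATIONS, "dp")
  if (!identical(sort(names(f)), sort(pops)))
    msg <- c(msg, sprintf("fractions must be named: %s",
                          paste(pops, collapse = ", ")))
  else {
    if (any(f < 0) || any(f > 1)) msg <- c(msg, "fractions must lie in [0,1]")
    if (sum(f) > 1 + 1e-12)
      msg <- c(msg, "fractions must sum to at most 1 (remainder is dead)")
  }
  if (length(object@seeding) != 1L || is.na(object@seeding) ||
      object@seeding < 1L)
    msg <- c(msg, "seeding must be a positive integer")
  if (object@cv < 0) msg <- c(msg, "cv must be >= 0")
  if (object@acquiredFraction <= 0 || object@acquiredFraction > 1)
    msg <- c(msg, "acquiredFraction must lie in (0, 1]")
  if (length(object@drugs) && is.null(names(object@drugs)))
    msg <- c(msg, "drugs must be a named list")
  for (d in names(object@drugs)) {
    m <- object@drugs[[d]]
    for (p in names(m$kill)) {
      if (!p %in% .POPULATIONS)
        msg <- c(msg, sprintf("drug '%s': unknown kill target '%s'", d, p))
      msg <- c(msg, .checkHill(m$kill[[p]], paste0("kill[", p, "]"), d))
    }
    if (!is.null(m$diff)) msg <- c(msg, .checkHill(m$diff, "diff", d))
    if (m$retention < 0 || m$retention > 1)
      msg <- c(msg, sprintf("drug '%s': retention must lie in [0,1]", d))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GroundTruth-class constructor.
#' @param fractions,drugs,seeding,cv,acquiredFraction see slots above.
#' @export
GroundTruth <- function(fractions = c(stroma = 0.05, lymph = 0.10,
                                      LSC = 0.08, DIFF = 0.12, basal = 0.55),
                        drugs = list(), seeding = 50000L, cv = 0.10,
                        acquiredFraction = 0.10) {
  new("GroundTruth", fractions = fractions, drugs = drugs,
      seeding = as.integer(seeding), cv = cv,
      acquiredFraction = acquiredFraction)
}

#' Build a drug-effect model for the synthetic generator
#'
#' @param kill named list over target populations (\code{stroma, lymph, LSC,
#'   DIFF, basal, dp}); each element a named numeric \code{c(E=, ec50=, h=)}
#'   giving the Hill survival model \code{1 - E * c^h / (c^h + ec50^h)}.
#'   Populations without an entry are unaffected.
#' @param diff optional named numeric \code{c(E=, ec50=, h=)}: maximal
#'   transition fraction (E), EC50 and slope of the
#'   differentiation-induction model that moves basal and LSC cells into the
#'   Diff+ state before survival is applied.
#' @param retention probability that a transitioning LSC retains GPR56 and
#'   becomes double positive rather than DIFF (default 0: LSCs are strictly
#'   GPR56+/Diff-).
#' @return list understood by the \code{drugs} slot of
#'   [GroundTruth-class].
#' @examples
#' cytotoxic <- drugModel(kill = list(
#'   LSC = c(E = 0.5, ec50 = 100, h = 1.5),
#'   DIFF = c(E = 0.9, ec50 = 100, h = 1.5),
#'   basal = c(E = 0.9, ec50 = 100, h = 1.5)))
#' @export
drugModel <- function(kill = list(), diff = NULL, retention = 0) {
  list(kill = kill, diff = diff, retention = retention)
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", object@seeding, "cells/well, replicate CV",
      object@cv, "\n")
  f <- object@fractions
  cat("  fractions:",
      paste(sprintf("%s %.2f", names(f), f), collapse = ", "),
      sprintf("(dead %.2f)\n", 1 - sum(f)))
  cat("  drugs:", if (length(object@drugs))
    paste(names(object@drugs), collapse = ", ") else "(none)", "\n")
})

#' Gate thresholds with provenance
#'
#' Scalar log10-intensity cutoffs for the six panel markers, as estimated
#' from vehicle wells by [estimateThresholds()] or supplied manually.
#' The \code{provenance} flag records, per marker, whether the cutoff was
#' \code{"estimated"} (mixture fit) or \code{"configured"} (override).
#'
#' @slot cutoffs named numeric, per-marker cutoff on the log10 scale.
#' @slot channels named character, marker -> channel mapping carried over
#'   from the panel so gating can address event-table columns.
#' @slot provenance named character in \code{{"estimated", "configured"}}.
#' @seealso [estimateThresholds()], [gateWell()]
#' @export
setClass("GateThresholds",
  representation(
    cutoffs = "numeric",
    channels = "character",
    provenance = "character"
  )
)

setValidity("GateThresholds", function(object) {
  msg <- character()
  for (s in c("cutoffs", "channels", "provenance"))
    if (!identical(sort(names(slot(object, s))), sort(.MARKERS)))
      msg <- c(msg, sprintf("slot '%s' must be named by the six markers", s))
  if (length(msg)) return(msg)
  if (!all(is.finite(object@cutoffs)))
    msg <- c(msg, "all cutoffs must be finite")
  if (!all(object@provenance %in% c("estimated", "configured")))
    msg <- c(msg, "provenance must be 'estimated' or 'configured'")
  if (length(msg)) msg else TRUE
})

#' @describeIn GateThresholds-class per-marker cutoffs
#' @param object a \code{GateThresholds}
#' @export
setGeneric("cutoffs", function(object) standardGeneric("cutoffs"))

#' @rdname GateThresholds-class
#' @export
setMethod("cutoffs", "GateThresholds", function(object) object@cutoffs)

setMethod("show", "GateThresholds", function(object) {
  cat("GateThresholds\n")
  for (m in .MARKERS)
    cat(sprintf("  %-9s (%s): %.4f  [%s]\n", m, object@channels[m],
                object@cutoffs[m], object@provenance[m]))
})
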