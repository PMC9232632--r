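# one-dimensional two-component Gaussian EM with fixed, deterministic
# initialization (means at the 25th/75th percentiles, equal weights,
# common sd = sd(x)/2)
.fit2gauss <- function(x, maxit = 500L, tol = 1e-10) {
  mu <- unname(quantile(x, c(0.25, 0.75), names = FALSE))
  s <- rep(max(sd(x) / 2, 1e-6), 2)
  w <- c(0.5, 0.5)
  ll <- -Inf
  for (it in seq_len(maxit)) {
    d1 <- w[1] * dnorm(x, mu[1], s[1])
    d2 <- w[2] * dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    g <- d1 / tot
    n1 <- sum(g); n2 <- length(x) - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    s <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                sum((1 - g) * (x - mu[2])^2) / n2))
    s <- pmax(s, 1e-6)
    w <- c(n1, n2) / length(x)
    llNew <- sum(log(tot))
    if (is.finite(ll) && abs(llNew - ll) < tol * (abs(ll) + 1)) break
    ll <- llNew
  }
  o <- order(mu)
  list(mu = mu[o], sd = s[o], w = w[o])
}

# equal-posterior point between the two component means; falls back to the
# midpoint of the component medians (= means for Gaussians) when no root of
# the posterior-equality quadratic is bracketed by the means
.equalPosteriorCut <- function(fit) {
  mu <- fit$mu; s <- fit$sd; w <- fit$w
  # log(w1 phi1(x)) = log(w2 phi2(x))  =>  a x^2 + b x + c = 0
  a <- 1 / s[2]^2 - 1 / s[1]^2
  b <- 2 * (mu[1] / s[1]^2 - mu[2] / s[2]^2)
  cc <- mu[2]^2 / s[2]^2 - mu[1]^2 / s[1]^2 +
    2 * (log(w[1] / s[1]) - log(w[2] / s[2]))
  fallback <- mean(mu)
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric() else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric()
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > mu[1] & roots < mu[2]]
  if (length(inside)) inside[1] else fallback
}

#' Estimate gate thresholds from vehicle wells
#'
#' Replaces manual gating with a deterministic automated procedure: for each
#' panel channel, the pooled log10 intensities of the vehicle (DMSO) wells
#' are fit with a two-component one-dimensional Gaussian mixture by EM
#' (fixed initialization: component means at the 25th and 75th percentiles,
#' equal weights), and the cutoff is placed at the point of equal posterior
#' probability between the two components. If no equal-posterior point lies
#' between the component means, the midpoint of the component medians is
#' used. Manual per-marker overrides always win and are flagged
#' \code{"configured"}.
#'
#' The viability channel is fit on all pooled events; the remaining channels
#' are fit on viable events only (below the viability cutoff), mirroring the
#' gating hierarchy.
#'
#' @param vehicleEvents a single event table or a list of event tables from
#'   vehicle wells (as produced by [simulateWell()] or read from CSV).
#' @param panel a [PanelMap-class].
#' @param overrides optional named numeric of per-marker cutoffs (names in
#'   \code{viability, GFP, CD45, GPR56, Diff, Lymph}).
#' @return a [GateThresholds-class].
#' @seealso [gateWell()]
#' @export
estimateThresholds <- function(vehicleEvents, panel, overrides = NULL) {
  if (is.data.frame(vehicleEvents)) vehicleEvents <- list(vehicleEvents)
  if (length(vehicleEvents) < 1L) stop("at least one vehicle well required")
  chan <- panel@channels
  missing <- setdiff(unname(chan), colnames(vehicleEvents[[1L]]))
  if (length(missing))
    stop("missing channel(s) in event table: ", paste(missing, collapse = ", "))
  pooled <- do.call(rbind, lapply(vehicleEvents, function(e)
    e[, unname(chan), drop = FALSE]))
  if (nrow(pooled) < 100L)
    stop("too few pooled events (", nrow(pooled), " < 100)")
  if (!is.null(overrides) &&
      length(setdiff(names(overrides), .MARKERS)))
    stop("override names must be marker roles: ",
         paste(.MARKERS, collapse = ", "))

  cut <- setNames(rep(NA_real_, 6), .MARKERS)
  prov <- setNames(rep("estimated", 6), .MARKERS)

  fitOne <- function(x, marker) {
    if (length(x) < 2L || sd(x) < 1e-8)
      stop("degenerate (near zero-variance) channel for marker '", marker,
           "': supply an override")
    fit <- .fit2gauss(x)
    # a single-component channel splits into two heavily overlapping
    # halves; require clear separation (means >= 2*(sd1+sd2) apart)
    if (fit$mu[2] - fit$mu[1] < 2 * sum(fit$sd) || min(fit$w) < 1e-4)
      stop("could not resolve two components for marker '", marker,
           "': supply an override")
    .equalPosteriorCut(fit)
  }

  # viability first, on all events
  if (!is.null(overrides) && "viability" %in% names(overrides)) {
    cut["viability"] <- overrides[["viability"]]
    prov["viability"] <- "configured"
  } else {
    cut["viability"] <- fitOne(pooled[[chan[["viability"]]]], "viability")
  }
  viable <- pooled[pooled[[chan[["viability"]]]] <= cut[["viability"]], ,
                   drop = FALSE]
  if (nrow(viable) < 100L)
    stop("too few pooled viable events (", nrow(viable), " < 100)")

  for (m in setdiff(.MARKERS, "viability")) {
    if (!is.null(overrides) && m %in% names(overrides)) {
      cut[m] <- overrides[[m]]
      prov[m] <- "configured"
    } else {
      cut[m] <- fitOne(viable[[chan[[m]]]], m)
    }
  }
  new("GateThresholds", cutoffs = cut, channels = chan, provenance = prov)
}

#' Assign each event to its terminal gate
#'
#' Per-event version of [gateWell()]: applies the same hierarchy and
#' returns, for every event, the label of the terminal gate it lands in.
#'
#' @inheritParams gateWell
#' @return character vector, one of \code{"dead", "msc", "cd45neg",
#'   "lymph", "lsc", "diff", "basal", "dp"} per event.
#' @export
assignEvents <- function(events, thresholds, useCD45 = FALSE) {
  chan <- thresholds@channels
  cut <- thresholds@cutoffs
  missing <- setdiff(unname(chan), colnames(events))
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  n <- nrow(events)
  if (n == 0L) return(character())
  lab <- rep(NA_character_, n)
  dead <- events[[chan[["viability"]]]] > cut[["viability"]]
  lab[dead] <- "dead"
  gfpPos <- !dead & events[[chan[["GFP"]]]] > cut[["GFP"]]
  lab[gfpPos] <- "msc"
  keep <- !dead & !gfpPos
  if (useCD45) {
    neg45 <- keep & events[[chan[["CD45"]]]] <= cut[["CD45"]]
    lab[neg45] <- "cd45neg"
    keep <- keep & !neg45
  }
  ly <- keep & events[[chan[["Lymph"]]]] > cut[["Lymph"]]
  lab[ly] <- "lymph"
  bulk <- keep & !ly
  g <- events[[chan[["GPR56"]]]] > cut[["GPR56"]]
  d <- events[[chan[["Diff"]]]] > cut[["Diff"]]
  lab[bulk & g & !d] <- "lsc"
  lab[bulk & !g & d] <- "diff"
  lab[bulk & !g & !d] <- "basal"
  lab[bulk & g & d] <- "dp"
  lab
}

#' Gate one well into the hierarchical populations
#'
#' Applies the fixed gating hierarchy to an event table: events above the
#' viability-stain cutoff are dead (the stain labels dead cells); among
#' viable events, GFP+ events are excluded as stromal cells (MSCs); the
#' remaining events are split into CD3/CD19+ lymphocytes versus the leukemic
#' bulk; bulk events are assigned by the GPR56 x Diff quadrants to LSC
#' (GPR56+/Diff-), DIFF (GPR56-/Diff+), basal (GPR56-/Diff-) or double
#' positive (GPR56+/Diff+, counted inside bulk but excluded from both LSC
#' and DIFF). Every viable GFP- event lands in exactly one terminal
#' population. CD45 is carried in the panel but not a decision node by
#' default; \code{useCD45 = TRUE} inserts a CD45+ gate before the lymphocyte
#' split, with CD45- events counted separately.
#'
#' @param events event table (data.frame, one row per event, panel channels
#'   as columns; extra columns such as \code{.truth} are ignored).
#' @param thresholds a [GateThresholds-class].
#' @param useCD45 logical; gate on CD45+ before the lymphocyte split.
#' @param well optional well id; defaults to the table's \code{"well"}
#'   attribute.
#' @return one-row data.frame with integer columns \code{total, viable, msc,
#'   cd45neg, lymph, bulk, lsc, diff, basal, dp}; an empty table yields all
#'   zeros.
#' @export
gateWell <- function(events, thresholds, useCD45 = FALSE, well = NULL) {
  chan <- thresholds@channels
  cut <- thresholds@cutoffs
  if (is.null(well)) {
    well <- attr(events, "well")
    if (is.null(well)) well <- NA_character_
  }
  zero <- data.frame(well = well, total = 0L, viable = 0L, msc = 0L,
                     cd45neg = 0L, lymph = 0L, bulk = 0L, lsc = 0L,
                     diff = 0L, basal = 0L, dp = 0L)
  if (nrow(events) == 0L) return(zero)
  lab <- assignEvents(events, thresholds, useCD45 = useCD45)
  k <- function(x) sum(lab == x)
  data.frame(
    well = well,
    total = nrow(events),
    viable = sum(lab != "dead"),
    msc = k("msc"),
    cd45neg = k("cd45neg"),
    lymph = k("lymph"),
    bulk = k("lsc") + k("diff") + k("basal") + k("dp"),
    lsc = k("lsc"),
    diff = k("diff"),
    basal = k("basal"),
    dp = k("dp")
  )
}

#' Gate every well of a plate
#'
#' @param events named list of event tables (names are well ids).
#' @param thresholds a [GateThresholds-class].
#' @param useCD45 see [gateWell()].
#' @return data.frame of per-well counts, one row per well.
#' @export
gatePlate <- function(events, thresholds, useCD45 = FALSE) {
  out <- do.call(rbind, lapply(names(events), function(w)
    gateWell(events[[w]], thresholds, useCD45 = useCD45, well = w)))
  rownames(out) <- NULL
  out
}

#' Write gate thresholds to a JSON audit file
#'
#' @param thresholds a [GateThresholds-class].
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writeThresholds <- function(thresholds, path) {
  jsonlite::write_json(
    list(cutoffs = as.list(thresholds@cutoffs),
         channels = as.list(thresholds@channels),
         provenance = as.list(thresholds@provenance)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeThresholds
#' @export
readThresholds <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GateThresholds", cutoffs = unlist(j$cutoffs),
      channels = unlist(j$channels), provenance = unlist(j$provenance))
}
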