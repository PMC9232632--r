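#' Hill-form effect fraction
#'
#' Fraction of maximal effect reached at concentration \code{conc} for a
#' Hill model with half-effect concentration \code{ec50} and slope \code{h}:
#' \code{conc^h / (conc^h + ec50^h)}. Returns 0 at concentration 0.
#'
#' @param conc non-negative concentration(s).
#' @param ec50 half-effect concentration, > 0.
#' @param h Hill slope, > 0.
#' @return numeric in [0, 1).
#' @export
hillFraction <- function(conc, ec50, h) {
  stopifnot(all(conc >= 0), ec50 > 0, h > 0)
  ifelse(conc == 0, 0, 1 / (1 + (ec50 / conc)^h))
}

#' Encode / decode well treatments
#'
#' Treatments are carried in plate layouts as compact strings:
#' \code{"drugA@conc;drugB@conc"}; the empty string denotes a vehicle
#' (DMSO-only) well. Concentrations are in the drug's native units as used
#' by the ground-truth EC50s.
#'
#' @param drug character vector of drug identifiers.
#' @param conc numeric vector of non-negative concentrations (recycled
#'   against \code{drug}).
#' @return \code{formatTreatment}: a single string.
#' @examples
#' formatTreatment(c("DNR", "AraC"), c(0.1, 2))
#' parseTreatment("DNR@0.1;AraC@2")
#' @export
formatTreatment <- function(drug, conc) {
  if (length(drug) == 0L) return("")
  stopifnot(all(conc >= 0))
  paste(sprintf("%s@%.10g", drug, conc), collapse = ";")
}

#' @rdname formatTreatment
#' @param treatment a treatment string.
#' @return \code{parseTreatment}: data.frame with columns \code{drug},
#'   \code{conc} (zero rows for vehicle).
#' @export
parseTreatment <- function(treatment) {
  if (is.na(treatment) || !nzchar(treatment))
    return(data.frame(drug = character(), conc = numeric()))
  parts <- strsplit(strsplit(treatment, ";", fixed = TRUE)[[1L]],
                    "@", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed treatment string: ", treatment)
  out <- data.frame(drug = vapply(parts, `[`, "", 1L),
                    conc = as.numeric(vapply(parts, `[`, "", 2L)))
  if (any(is.na(out$conc)) || any(out$conc < 0))
    stop("negative or non-numeric concentration in treatment: ", treatment)
  out
}

# combined transition fraction and per-population survival under a treatment
.treatmentEffects <- function(gt, treatment) {
  trt <- if (is.data.frame(treatment)) treatment else parseTreatment(treatment)
  unknown <- setdiff(trt$drug, names(gt@drugs))
  if (length(unknown))
    stop("unknown drug id(s): ", paste(unknown, collapse = ", "))
  survive <- setNames(rep(1, length(.POPULATIONS)), .POPULATIONS)
  stayUntransitioned <- 1
  retention <- 0
  for (i in seq_len(nrow(trt))) {
    m <- gt@drugs[[trt$drug[i]]]
    cc <- trt$conc[i]
    for (p in names(m$kill)) {
      k <- m$kill[[p]]
      survive[p] <- survive[p] *
        (1 - k[["E"]] * hillFraction(cc, k[["ec50"]], k[["h"]]))
    }
    if (!is.null(m$diff)) {
      t_d <- m$diff[["E"]] * hillFraction(cc, m$diff[["ec50"]], m$diff[["h"]])
      stayUntransitioned <- stayUntransitioned * (1 - t_d)
      retention <- max(retention, m$retention)
    }
  }
  list(survive = survive, transition = 1 - stayUntransitioned,
       retention = retention)
}

#' Expected viable counts under a treatment
#'
#' Closed-form expectation of the per-population viable cell counts in a
#' well seeded from a [GroundTruth-class] under a given treatment, before
#' acquisition subsampling and replicate noise. Differentiation transitions
#' (basal and LSC cells moving into the Diff+ state) are applied before the
#' survival models, matching the generator; transitioned cells adopt the
#' survival model of their destination state.
#'
#' @param groundTruth a [GroundTruth-class].
#' @param treatment treatment string (see [formatTreatment()]) or a
#'   data.frame with columns \code{drug}, \code{conc}.
#' @return named numeric of expected counts over \code{stroma, lymph, LSC,
#'   DIFF, basal, dp, dead}; sums to the seeding count.
#' @examples
#' gt <- GroundTruth(drugs = list(
#'   X = drugModel(kill = list(basal = c(E = 1, ec50 = 10, h = 2)))))
#' expectedCounts(gt, "X@1000")
#' @export
expectedCounts <- function(groundTruth, treatment = "") {
  gt <- groundTruth
  eff <- .treatmentEffects(gt, treatment)
  f <- gt@fractions
  t <- eff$transition
  r <- eff$retention
  s <- eff$survive
  n0 <- as.numeric(gt@seeding)
  viable <- c(
    stroma = f[["stroma"]] * s[["stroma"]],
    lymph  = f[["lymph"]] * s[["lymph"]],
    LSC    = f[["LSC"]] * (1 - t) * s[["LSC"]],
    DIFF   = (f[["DIFF"]] + f[["basal"]] * t + f[["LSC"]] * t * (1 - r)) *
             s[["DIFF"]],
    basal  = f[["basal"]] * (1 - t) * s[["basal"]],
    dp     = f[["LSC"]] * t * r * s[["dp"]]
  ) * n0
  c(viable, dead = n0 - sum(viable))
}

# which populations are positive on which marker; dead events are positive
# only for the viability stain (stain labels dead cells)
.POSITIVITY <- local({
  m <- matrix(FALSE, nrow = 7, ncol = 6,
              dimnames = list(c(.POPULATIONS, "dead"), .MARKERS))
  m["stroma", "GFP"] <- TRUE
  m[c("lymph", "LSC", "DIFF", "basal", "dp"), "CD45"] <- TRUE
  m["lymph", "Lymph"] <- TRUE
  m[c("LSC", "dp"), "GPR56"] <- TRUE
  m[c("DIFF", "dp"), "Diff"] <- TRUE
  m["dead", "viability"] <- TRUE
  m
})

#' Simulate one well of event-level flow data
#'
#' Draws a synthetic event table for a single well: the seeded cell mixture
#' is partitioned by the baseline fractions, differentiation transitions are
#' applied (basal/LSC cells moving into the Diff+ state, LSCs retaining
#' GPR56 with the model's retention probability), per-population Hill
#' survival is applied per drug, a per-well multiplicative log-normal
#' seeding factor emulates technical replicate noise, and the acquired
#' fraction of events is drawn. Each acquired event receives log10
#' intensities on all six panel channels from the two-component model of the
#' [PanelMap-class]; dead events (baseline dead plus drug-killed) carry a
#' high viability-stain signal and negative signal elsewhere.
#'
#' The expected viable count of population p equals
#' \code{seeding * fraction_p * prod_drugs(1 - E * c^h / (c^h + EC50^h))}
#' (after transitions); see [expectedCounts()].
#'
#' @param groundTruth a [GroundTruth-class].
#' @param layoutEntry one-row data.frame (or list) with at least \code{well}
#'   and \code{treatment}.
#' @param panel a [PanelMap-class].
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return data.frame with one row per acquired event, one column per panel
#'   channel, plus a \code{.truth} column with the generating population
#'   label (ignored by gating; present for recovery testing). The well id is
#'   attached as attribute \code{"well"}.
#' @export
simulateWell <- function(groundTruth, layoutEntry, panel, seed) {
  gt <- groundTruth
  set.seed(as.integer(seed) %% .Machine$integer.max)
  eff <- .treatmentEffects(gt, layoutEntry$treatment)

  # replicate noise: multiplicative log-normal factor on seeding, mean 1
  n0 <- gt@seeding
  if (gt@cv > 0) {
    sdlog <- sqrt(log(1 + gt@cv^2))
    n0 <- max(1L, round(n0 * rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)))
  }

  f <- gt@fractions
  probs <- c(f[["stroma"]], f[["lymph"]], f[["LSC"]], f[["DIFF"]],
             f[["basal"]], 1 - sum(f))
  n <- drop(rmultinom(1, n0, probs))
  names(n) <- c("stroma", "lymph", "LSC", "DIFF", "basal", "dead")

  # differentiation transitions before survival
  t <- eff$transition
  r <- eff$retention
  fromBasal <- rbinom(1, n[["basal"]], t)
  fromLSC <- rbinom(1, n[["LSC"]], t)
  toDP <- rbinom(1, fromLSC, r)
  counts <- c(
    stroma = n[["stroma"]], lymph = n[["lymph"]],
    LSC = n[["LSC"]] - fromLSC,
    DIFF = n[["DIFF"]] + fromBasal + (fromLSC - toDP),
    basal = n[["basal"]] - fromBasal,
    dp = toDP
  )

  # survival thinning; killed cells join the dead pool
  surv <- vapply(.POPULATIONS, function(p)
    rbinom(1, counts[[p]], eff$survive[[p]]), integer(1))
  dead <- n0 - sum(surv)

  # acquisition subsampling
  acq <- vapply(c(surv, dead = dead), function(k)
    rbinom(1, k, gt@acquiredFraction), integer(1))

  labels <- rep(names(acq), acq)
  nev <- length(labels)
  ev <- matrix(NA_real_, nrow = nev, ncol = length(.MARKERS),
               dimnames = list(NULL, unname(panel@channels[.MARKERS])))
  for (m in .MARKERS) {
    pos <- .POSITIVITY[labels, m]
    mu <- ifelse(pos, panel@posMean[[m]], panel@negMean[[m]])
    sdv <- ifelse(pos, panel@posSD[[m]], panel@negSD[[m]])
    ev[, panel@channels[[m]]] <- rnorm(nev, mu, sdv)
  }
  out <- as.data.frame(ev)
  out$.truth <- labels
  attr(out, "well") <- if (!is.null(layoutEntry$well)) layoutEntry$well else NA
  out
}

#' Assemble a plate-simulation configuration
#'
#' @param groundTruth a [GroundTruth-class].
#' @param panel a [PanelMap-class] (default [defaultPanel()]).
#' @param samples character vector of sample identifiers.
#' @param treatments character vector of treatment strings (see
#'   [formatTreatment()]); applied to every sample.
#' @param nVehicle vehicle (DMSO) wells per sample, >= 1.
#' @param nReplicates replicate wells per treated condition.
#' @return a \code{plateConfig} list consumed by [simulatePlate()].
#' @export
plateConfig <- function(groundTruth, panel = defaultPanel(), samples = "S1",
                        treatments = character(), nVehicle = 3L,
                        nReplicates = 1L) {
  stopifnot(is(groundTruth, "GroundTruth"), is(panel, "PanelMap"),
            nVehicle >= 1L, nReplicates >= 1L)
  structure(list(groundTruth = groundTruth, panel = panel, samples = samples,
                 treatments = treatments, nVehicle = as.integer(nVehicle),
                 nReplicates = as.integer(nReplicates)),
            class = "plateConfig")
}

#' Simulate a whole plate with ground-truth sidecar
#'
#' Builds the plate layout implied by the configuration (per sample: vehicle
#' wells then each treatment times its replicates), splits the master seed
#' into one sub-seed per well, and simulates every well with
#' [simulateWell()]. Deterministic given \code{seed}: the master seed drives
#' a single stream from which per-well seeds are drawn, so the same seed
#' reproduces the identical plate.
#'
#' @param config a [plateConfig()] list.
#' @param seed integer master seed.
#' @return list with elements \code{events} (named list of event tables, one
#'   per well), \code{layout} (data.frame: \code{well, sample, treatment,
#'   role, replicate}), \code{groundTruth}, \code{panel}.
#' @export
simulatePlate <- function(config, seed) {
  if (!inherits(config, "plateConfig"))
    stop("malformed config: expected an object from plateConfig()")
  rows <- list()
  for (s in config$samples) {
    for (v in seq_len(config$nVehicle))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, treatment = "", role = "vehicle", replicate = v)
    for (trt in config$treatments)
      for (rp in seq_len(config$nReplicates))
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, treatment = trt, role = "treated", replicate = rp)
  }
  layout <- do.call(rbind, rows)
  layout <- cbind(well = sprintf("W%03d", seq_len(nrow(layout))), layout)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  wellSeeds <- sample.int(.Machine$integer.max - 1L, nrow(layout))
  events <- lapply(seq_len(nrow(layout)), function(i)
    simulateWell(config$groundTruth, layout[i, ], config$panel, wellSeeds[i]))
  names(events) <- layout$well
  list(events = events, layout = layout,
       groundTruth = config$groundTruth, panel = config$panel)
}

#' Read a plate-simulation configuration from YAML
#'
#' The YAML mirrors [plateConfig()]: top-level keys \code{samples},
#' \code{treatments}, \code{nVehicle}, \code{nReplicates}, a
#' \code{groundTruth} block (\code{fractions}, \code{seeding}, \code{cv},
#' \code{acquiredFraction}, and a \code{drugs} map whose entries hold
#' \code{kill} maps of per-population \code{[E, ec50, h]} triples plus
#' optional \code{diff} and \code{retention}), and an optional \code{panel}
#' block (\code{separation}, \code{sd}, \code{negMean}).
#'
#' @param path path to a YAML file.
#' @return a [plateConfig()] list.
#' @export
readPlateConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$groundTruth))
    stop("malformed config: missing groundTruth block")
  g <- y$groundTruth
  drugs <- lapply(g$drugs, function(d) {
    kill <- lapply(d$kill, function(k)
      c(E = k[[1]], ec50 = k[[2]], h = k[[3]]))
    diff <- if (!is.null(d$diff))
      c(E = d$diff[[1]], ec50 = d$diff[[2]], h = d$diff[[3]])
    drugModel(kill = kill, diff = diff,
              retention = if (is.null(d$retention)) 0 else d$retention)
  })
  gt <- GroundTruth(
    fractions = unlist(g$fractions),
    drugs = drugs,
    seeding = if (is.null(g$seeding)) 50000L else g$seeding,
    cv = if (is.null(g$cv)) 0.10 else g$cv,
    acquiredFraction = if (is.null(g$acquiredFraction)) 0.10
                       else g$acquiredFraction)
  p <- y$panel
  panel <- defaultPanel(
    separation = if (is.null(p$separation)) 4 else p$separation,
    sd = if (is.null(p$sd)) 0.25 else p$sd,
    negMean = if (is.null(p$negMean)) 1 else p$negMean)
  plateConfig(gt, panel,
              samples = if (is.null(y$samples)) "S1" else unlist(y$samples),
              treatments = if (is.null(y$treatments)) character()
                           else unlist(y$treatments),
              nVehicle = if (is.null(y$nVehicle)) 3L else y$nVehicle,
              nReplicates = if (is.null(y$nReplicates)) 1L else y$nReplicates)
}

#' Write a simulated plate to disk
#'
#' Emits one CSV event table per well (one row per event, one column per
#' channel, plus the \code{.truth} label column), the layout CSV, and a
#' ground-truth JSON sidecar for recovery tests.
#'
#' @param sim result of [simulatePlate()].
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
writePlate <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (w in names(sim$events))
    write.csv(sim$events[[w]], file.path(dir, paste0(w, ".csv")),
              row.names = FALSE)
  write.csv(sim$layout, file.path(dir, "layout.csv"), row.names = FALSE)
  gt <- sim$groundTruth
  jsonlite::write_json(
    list(fractions = as.list(gt@fractions),
         seeding = gt@seeding, cv = gt@cv,
         acquiredFraction = gt@acquiredFraction,
         drugs = lapply(gt@drugs, function(d)
           list(kill = lapply(d$kill, as.list),
                diff = if (is.null(d$diff)) NULL else as.list(d$diff),
                retention = d$retention))),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Canonical three-archetype screening scenario
#'
#' Builds a [GroundTruth-class] carrying one drug panel per response
#' archetype, the ground-truth labels, and the fixed-dose treatment strings,
#' for recovery testing of the pattern pipeline: cytotoxic drugs kill all
#' leukemic states about equally (bulk shrinks, proportions barely move),
#' stemness-specific drugs kill only the LSC state (LSC proportion falls),
#' and differentiating drugs move basal/LSC cells into the Diff+ state
#' (DIFF proportion rises, bulk roughly conserved). Hill parameters vary
#' slightly between drugs within an archetype so rows are not duplicated.
#'
#' @param nPerArchetype drugs per archetype (default 5).
#' @param conc fixed screening concentration applied to every drug
#'   (default 200, well above every EC50 so effects are near maximal).
#' @param acquiredFraction passed to [GroundTruth()] (default 0.04, keeping
#'   simulated wells light).
#' @return list with \code{groundTruth}, \code{treatments} (character),
#'   \code{truth} (named character: drug -> archetype label).
#' @export
archetypeGroundTruth <- function(nPerArchetype = 5L, conc = 200,
                                 acquiredFraction = 0.04) {
  drugs <- list()
  truth <- character()
  for (i in seq_len(nPerArchetype)) {
    ec <- 20 + 5 * i
    eC <- 0.72 + 0.03 * i
    d <- sprintf("ct%02d", i)
    drugs[[d]] <- drugModel(kill = list(
      LSC = c(E = eC, ec50 = ec, h = 2),
      DIFF = c(E = eC, ec50 = ec, h = 2),
      basal = c(E = eC, ec50 = ec, h = 2),
      dp = c(E = eC, ec50 = ec, h = 2)))
    truth[d] <- "cytotoxic"

    eS <- 0.78 + 0.02 * i
    d <- sprintf("st%02d", i)
    drugs[[d]] <- drugModel(kill = list(
      LSC = c(E = eS, ec50 = ec, h = 2),
      dp = c(E = eS, ec50 = ec, h = 2)))
    truth[d] <- "stemness_specific"

    eD <- 0.52 + 0.03 * i
    d <- sprintf("df%02d", i)
    drugs[[d]] <- drugModel(diff = c(E = eD, ec50 = ec, h = 2))
    truth[d] <- "differentiating"
  }
  gt <- GroundTruth(drugs = drugs, acquiredFraction = acquiredFraction)
  list(groundTruth = gt,
       treatments = vapply(names(drugs), function(d)
         formatTreatment(d, conc), ""),
       truth = truth)
}

#' Run the fixed-dose pattern pipeline on one simulated plate
#'
#' Convenience driver tying the modules together for recovery studies:
#' simulates a plate for the given archetype scenario, estimates gate
#' thresholds on its vehicle wells, gates, normalizes, computes fixed-dose
#' activity triples, scales and clusters.
#'
#' @param scenario result of [archetypeGroundTruth()].
#' @param seed integer seed for the plate simulation.
#' @param k number of pattern clusters (default 3).
#' @param nVehicle vehicle wells (default 3).
#' @return the [clusterPatterns()] data.frame with a \code{truth} column
#'   added (drug ids are the treatment drug names).
#' @export
runPatternRecovery <- function(scenario, seed, k = 3L, nVehicle = 3L) {
  cfg <- plateConfig(scenario$groundTruth, defaultPanel(),
                     treatments = unname(scenario$treatments),
                     nVehicle = nVehicle)
  sim <- simulatePlate(cfg, seed)
  veh <- sim$layout$well[sim$layout$role == "vehicle"]
  th <- estimateThresholds(sim$events[veh], sim$panel)
  counts <- gatePlate(sim$events, th)
  norm <- normalizePlate(counts, sim$layout)
  act <- fixedDoseActivity(norm)
  act$drug <- vapply(act$treatment, function(t) parseTreatment(t)$drug[1], "")
  m <- as.matrix(act[, c("bulk_ratio", "prop_lsc", "prop_diff")])
  colnames(m) <- c("bulk", "lsc", "diff")
  rownames(m) <- act$drug
  res <- clusterPatterns(scaleReadouts(m), k = k)
  res$truth <- scenario$truth[res$drug]
  res
}
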