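# noiseless ground truth for expectation checks
gtClean <- function(drugs = list())
  GroundTruth(drugs = drugs, seeding = 50000L, cv = 0,
              acquiredFraction = 1)

test_that("ground-truth validity rejects ill-formed parameters", {
  expect_error(GroundTruth(fractions = c(stroma = 0.5, lymph = 0.4,
                                         LSC = 0.3, DIFF = 0.2,
                                         basal = 0.2)),
               "sum to at most 1")
  expect_error(GroundTruth(seeding = 0), "positive integer")
  expect_error(GroundTruth(drugs = list(
    X = drugModel(kill = list(basal = c(E = 1.5, ec50 = 1, h = 1))))),
    "E must lie")
  expect_error(GroundTruth(drugs = list(
    X = drugModel(kill = list(basal = c(E = 0.5, ec50 = -1, h = 1))))),
    "EC50")
})

test_that("no-drug wells reproduce baseline fractions within binomial error", {
  gt <- gtClean()
  ev <- simulateWell(gt, list(well = "W1", treatment = ""), defaultPanel(),
                     seed = 11)
  expect_equal(nrow(ev), 50000L)  # total events conserved at full acquisition
  exp <- expectedCounts(gt, "")
  obs <- table(factor(ev$.truth, levels = names(exp)))
  for (p in names(exp)) {
    n <- 50000
    pr <- exp[[p]] / n
    tol <- 3 * sqrt(n * pr * (1 - pr))
    expect_lt(abs(obs[[p]] - exp[[p]]), tol + 1)
  }
})

test_that("a saturating basal+LSC kill leaves a DIFF-only viable bulk", {
  gt <- gtClean(drugs = list(X = drugModel(kill = list(
    basal = c(E = 1, ec50 = 10, h = 8),
    LSC = c(E = 1, ec50 = 10, h = 8)))))
  exp <- expectedCounts(gt, "X@1000")  # c = 100 x EC50
  expect_equal(unname(exp[["basal"]]), 0, tolerance = 1e-6)
  expect_equal(unname(exp[["LSC"]]), 0, tolerance = 1e-6)
  ev <- simulateWell(gt, list(well = "W1", treatment = "X@1000"),
                     defaultPanel(), seed = 5)
  obs <- table(factor(ev$.truth, levels = names(exp)))
  expect_lte(obs[["basal"]], 3 * sqrt(50000 * 1e-4))  # within 3 SD of zero
  expect_lte(obs[["LSC"]], 3 * sqrt(50000 * 1e-4))
  bulk <- sum(obs[c("LSC", "DIFF", "basal", "dp")])
  expect_equal(unname(bulk), unname(obs[["DIFF"]]))
})

test_that("expected lymphocytes at the seeding scale match the closed form", {
  gt <- gtClean()
  expect_equal(unname(expectedCounts(gt, "")[["lymph"]]), 5000)
  ev <- simulateWell(gt, list(well = "W1", treatment = ""), defaultPanel(),
                     seed = 3)
  n <- sum(ev$.truth == "lymph")
  expect_lt(abs(n - 5000), 3 * sqrt(50000 * 0.1 * 0.9))
})

test_that("empirical means over 50 replicate wells match analytic expectations", {
  gt <- GroundTruth(drugs = list(X = drugModel(
    kill = list(basal = c(E = 0.8, ec50 = 50, h = 1.5),
                LSC = c(E = 0.4, ec50 = 50, h = 1.5)),
    diff = c(E = 0.3, ec50 = 50, h = 1.5))),
    seeding = 20000L, cv = 0.1, acquiredFraction = 0.2)
  pm <- defaultPanel()
  for (trt in c("X@20", "X@200")) {
    exp <- expectedCounts(gt, trt) * gt@acquiredFraction
    counts <- sapply(1:50, function(i) {
      ev <- simulateWell(gt, list(well = "W", treatment = trt), pm,
                         seed = 1000 + i)
      table(factor(ev$.truth, levels = names(exp)))
    })
    for (p in names(exp)) {
      se <- sd(counts[p, ]) / sqrt(50)
      expect_lt(abs(mean(counts[p, ]) - exp[[p]]), 3 * se + 1e-9,
                label = paste("population", p, "at", trt))
    }
  }
})

test_that("expected viable bulk is non-increasing in dose for a cytotoxin", {
  gt <- gtClean(drugs = list(X = drugModel(kill = list(
    basal = c(E = 0.9, ec50 = 30, h = 2),
    DIFF = c(E = 0.9, ec50 = 30, h = 2),
    LSC = c(E = 0.9, ec50 = 30, h = 2)))))
  doses <- c(0, 1, 3, 10, 30, 100, 300, 1000)
  bulk <- vapply(doses, function(cc) {
    e <- expectedCounts(gt, formatTreatment("X", cc))
    sum(e[c("LSC", "DIFF", "basal", "dp")])
  }, numeric(1))
  expect_true(all(diff(bulk) <= 1e-9))
})

test_that("differentiation transitions run before survival and can retain GPR56", {
  gt <- gtClean(drugs = list(D = drugModel(
    kill = list(DIFF = c(E = 1, ec50 = 10, h = 8)),
    diff = c(E = 1, ec50 = 10, h = 8), retention = 1)))
  exp <- expectedCounts(gt, "D@1000")
  # all basal transitioned into DIFF then killed; all LSC became dp (kept)
  expect_equal(unname(exp[["basal"]]), 0, tolerance = 1e-6)
  expect_equal(unname(exp[["DIFF"]]), 0, tolerance = 1e-6)
  expect_equal(unname(exp[["LSC"]]), 0, tolerance = 1e-6)
  expect_equal(unname(exp[["dp"]]), 4000, tolerance = 1e-3)
})

test_that("plates are reproducible by seed and vary across seeds", {
  sc <- archetypeGroundTruth(nPerArchetype = 1L)
  cfg <- plateConfig(sc$groundTruth, defaultPanel(),
                     treatments = unname(sc$treatments)[1], nVehicle = 1L)
  a <- simulatePlate(cfg, 42)
  b <- simulatePlate(cfg, 42)
  c <- simulatePlate(cfg, 43)
  expect_identical(a$events, b$events)
  expect_false(identical(a$events, c$events))
  expect_identical(a$layout, b$layout)
})

test_that("vehicle-only plates are statistically exchangeable", {
  cfg <- plateConfig(GroundTruth(acquiredFraction = 0.05), defaultPanel(),
                     nVehicle = 6L)
  sim <- simulatePlate(cfg, 9)
  expect_true(all(sim$layout$role == "vehicle"))
  sizes <- vapply(sim$events, nrow, integer(1))
  # all wells drawn from the same model: totals within a few SD of the mean
  expect_lt(max(abs(sizes - mean(sizes))) / sd(sizes), 4)
})

test_that("fixed-ratio backbone treatments carry concentration pairs (c, 20c)", {
  ser <- fixedRatioSeries(1, ratio = 20, nPoints = 5, fold = 10)
  trts <- apply(ser, 1, function(r)
    formatTreatment(c("DNR", "AraC"), c(r[["conc1"]], r[["conc2"]])))
  parsed <- lapply(trts, parseTreatment)
  for (i in seq_along(parsed)) {
    expect_equal(parsed[[i]]$conc[2] / parsed[[i]]$conc[1], 20)
    expect_equal(parsed[[i]]$conc[1], 10^(-(i - 1)))
  }
})

test_that("generator input errors are caught", {
  gt <- gtClean()
  expect_error(simulateWell(gt, list(well = "W", treatment = "nope@1"),
                            defaultPanel(), 1), "unknown drug")
  expect_error(parseTreatment("X@-3"), "negative")
  expect_error(parseTreatment("X@1@2"), "malformed")
  expect_error(simulatePlate(list(), 1), "malformed config")
})

test_that("plate round-trips through CSV/JSON sidecar files", {
  sc <- archetypeGroundTruth(nPerArchetype = 1L)
  cfg <- plateConfig(sc$groundTruth, defaultPanel(),
                     treatments = unname(sc$treatments)[1], nVehicle = 1L)
  sim <- simulatePlate(cfg, 4)
  dir <- tempfile("plate")
  writePlate(sim, dir)
  lay <- readLayout(file.path(dir, "layout.csv"))
  expect_equal(lay$well, sim$layout$well)
  expect_equal(lay$treatment, sim$layout$treatment)
  ev <- readEvents(file.path(dir, paste0(lay$well[1], ".csv")))
  expect_equal(nrow(ev), nrow(sim$events[[lay$well[1]]]))
  expect_equal(attr(ev, "well"), lay$well[1])
  gtJson <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                simplifyVector = TRUE)
  expect_equal(gtJson$seeding, 50000L)
  unlink(dir, recursive = TRUE)
})

test_that("YAML plate configs build the same scenario as plateConfig()", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "samples: [S1]",
    "treatments: ['X@100']",
    "nVehicle: 2",
    "nReplicates: 1",
    "groundTruth:",
    "  fractions: {stroma: 0.05, lymph: 0.10, LSC: 0.08, DIFF: 0.12, basal: 0.55}",
    "  seeding: 10000",
    "  cv: 0.1",
    "  acquiredFraction: 0.5",
    "  drugs:",
    "    X:",
    "      kill:",
    "        basal: [0.9, 50, 2]",
    "panel: {separation: 4, sd: 0.25}"), path)
  cfg <- readPlateConfig(path)
  expect_s4_class(cfg$groundTruth, "GroundTruth")
  expect_equal(cfg$groundTruth@seeding, 10000L)
  expect_equal(cfg$groundTruth@drugs$X$kill$basal[["ec50"]], 50)
  sim <- simulatePlate(cfg, 2)
  expect_equal(nrow(sim$layout), 3L)
  unlink(path)
})
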