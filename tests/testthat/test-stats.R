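test_that("chemosensitivity calls use the strict lymphocyte-reference rule", {
  expect_equal(sensitivityCall(0.5, 0.3)$call, "sensitive")
  expect_equal(sensitivityCall(0.3, 0.3)$call, "resistant")  # tie rule
  expect_equal(sensitivityCall(-0.1, 0.0)$call, "resistant") # negative AOC
  # scale consistency: shifting both AOCs never changes the call
  set.seed(3)
  a <- runif(50, -0.5, 1); b <- runif(50, -0.5, 1); k <- runif(50, -2, 2)
  expect_equal(sensitivityCall(a, b)$call, sensitivityCall(a + k, b + k)$call)
  expect_error(sensitivityCall(c(1, 2), 1), "same length")
})

test_that("benefit deltas and the population-level test behave as specified", {
  aoc <- data.frame(patient = rep(c("P1", "P2", "P3"), each = 3),
                    regimen = rep(c("backbone", "ven", "rux"), 3),
                    aoc = c(0.4, 0.6, 0.45,
                            0.3, 0.5, 0.35,
                            0.5, 0.7, 0.55))
  d <- benefitDeltas(aoc)
  expect_equal(d$delta[d$agent == "ven"], rep(0.2, 3))
  cb <- combinationBenefit(aoc)
  # zero-variance deltas -> degenerate flag, mean reported, no p/q
  expect_true(all(cb$degenerate))
  expect_equal(cb$mean_delta[cb$agent == "ven"], 0.2)
  expect_true(all(is.na(cb$p)))
  expect_error(combinationBenefit(
    data.frame(patient = "P1", regimen = "ven", aoc = 0.5)), "backbone")
})

test_that("agents with fewer than 3 patients are reported without p or q", {
  aoc <- data.frame(
    patient = c("P1", "P2", "P3", "P1", "P2", "P3", "P1", "P2"),
    regimen = c("backbone", "backbone", "backbone",
                "ven", "ven", "ven", "rux", "rux"),
    aoc = c(0.4, 0.3, 0.5, 0.62, 0.51, 0.73, 0.45, 0.33))
  cb <- combinationBenefit(aoc)
  expect_true(is.na(cb$p[cb$agent == "rux"]))
  expect_equal(cb$n[cb$agent == "rux"], 2L)
  ven <- cb[cb$agent == "ven", ]
  expect_false(is.na(ven$p))
  expect_gte(ven$q, ven$p)
  # cross-check against the base t test
  tt <- t.test(c(0.22, 0.21, 0.23), mu = 0)
  expect_equal(ven$p, tt$p.value, tolerance = 1e-12)
})

test_that("per-patient nomination follows argmax with documented tie rules", {
  d <- data.frame(patient = "P1", agent = c("ven", "rux"),
                  delta = c(0.3, 0.1))
  expect_equal(nominateOptimal(d)$nominated, "ven")
  dn <- data.frame(patient = "P1", agent = c("a", "b"),
                   delta = c(-0.1, -0.2))
  expect_equal(nominateOptimal(dn)$nominated, "no benefit")
  dt <- data.frame(patient = "P1", agent = c("b", "a"),
                   delta = c(0.2, 0.2))
  out <- nominateOptimal(dt)
  expect_equal(out$nominated, "a")  # lexicographically smallest
  expect_true(out$tie)
  expect_error(nominateOptimal(dt[0, ]), "empty")
})

test_that("Mann-Whitney matches enumeration and the base implementation", {
  mw <- mannWhitney(1:3, 4:6)
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p, 0.1)          # 2/C(6,3)
  expect_equal(mw$method, "exact-enumeration")
  expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3))$p, 1)  # identical groups
  set.seed(11)
  for (i in 1:10) {                 # exact branch vs wilcox.test
    a <- sample(1:1000, sample(3:7, 1))
    b <- sample(setdiff(1:1000, a), sample(3:7, 1))
    ref <- suppressWarnings(wilcox.test(a, b, exact = TRUE))
    expect_equal(mannWhitney(a, b)$p, ref$p.value, tolerance = 1e-12)
  }
  for (i in 1:10) {                 # tie/approx branch vs wilcox.test
    a <- sample(1:5, 15, replace = TRUE)
    b <- sample(2:6, 20, replace = TRUE)
    mw <- mannWhitney(a, b)
    expect_equal(mw$method, "normal-tie-corrected")
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(mw$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(mannWhitney(numeric(), 1:3), "non-empty")
})

test_that("Mann-Whitney holds its size on a simulated null", {
  set.seed(19)
  reps <- 2000
  hits <- 0
  for (i in seq_len(reps)) {
    a <- rnorm(20); b <- rnorm(20)
    if (mannWhitney(a, b)$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.03)
  expect_lt(hits / reps, 0.07)
})

test_that("Fisher exact matches the printed remission table and enumeration", {
  # 9/9 CR among patients with chemosensitive blasts vs 20/29 among
  # chemoresistant
  p <- fisherExact2x2(matrix(c(9, 0, 20, 9), 2, byrow = TRUE))$p
  expect_equal(round(p, 2), 0.08)
  expect_equal(fisherExact2x2(matrix(c(1, 1, 1, 1), 2))$p, 1)
  expect_equal(fisherExact2x2(matrix(c(5, 0, 0, 5), 2))$p, 2 / 252,
               tolerance = 1e-12)
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisherExact2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  expect_error(fisherExact2x2(matrix(c(0, 0, 1, 1), 2)), "margins")
  set.seed(23)
  for (i in 1:30) {                 # vs base fisher.test and vs brute force
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisherExact2x2(tab)$p
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(p, bruteFisher(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
  }
})

test_that("BH q-values match hand computation, the direct definition and p.adjust", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFDR(c(0.005, 0.04, 0.05)), c(0.015, 0.05, 0.05))
  expect_equal(bhFDR(0.2), 0.2)     # single p
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bhFDR(p)
    expect_equal(q, directBH(p))
    expect_equal(q, p.adjust(p, "BH"))
    expect_true(all(q >= p))
    perm <- sample(length(p))
    expect_equal(bhFDR(p[perm]), q[perm])  # order-preserving
  }
})

test_that("an injected benefit is recovered with the smallest q", {
  agents <- sprintf("agent%02d", 1:10)
  scr <- simulateBenefitScreen(nPatients = 20, agents = agents,
                               effects = c(agent03 = 0.3),
                               noiseSD = 0.1, seed = 77)
  cb <- combinationBenefit(scr)
  expect_equal(cb$agent[which.min(cb$q)], "agent03")
  expect_lt(cb$q[cb$agent == "agent03"], 0.05)
  nom <- nominateOptimal(attr(cb, "deltas"))
  expect_gt(mean(nom$nominated == "agent03"), 0.5)
})

test_that("the chemogenomic scan flags the sensitizing mutation first", {
  set.seed(55)
  patients <- sprintf("P%02d", 1:24)
  mut <- cbind(FLT3 = rep(c(1, 0), each = 12),
               NPM1 = sample(0:1, 24, replace = TRUE),
               TP53 = 0)                      # constant -> skipped
  rownames(mut) <- patients
  act <- do.call(rbind, lapply(c("ven", "rux"), function(a)
    do.call(rbind, lapply(c("bulk", "lsc"), function(rd)
      data.frame(patient = patients, agent = a, readout = rd,
                 value = rnorm(24, 0.2, 0.05) +
                   ifelse(a == "ven" & mut[, "FLT3"] == 1, 0.25, 0))))))
  res <- chemogenomicScan(act, mut)
  top <- res[order(res$q), ][1:2, ]
  expect_true(all(top$agent == "ven" & top$gene == "FLT3"))
  expect_true(all(top$q < 0.05))
  skipped <- attr(res, "skipped")
  expect_true(all(skipped$gene == "TP53"))
  expect_false("TP53" %in% res$gene)
})

test_that("permuted-genotype nulls rarely reach significance in the scan", {
  set.seed(101)
  patients <- sprintf("P%02d", 1:20)
  act <- do.call(rbind, lapply(c("a1", "a2"), function(a)
    data.frame(patient = patients, agent = a, readout = "lsc",
               value = rnorm(20, 0.2, 0.1))))
  rate <- vapply(1:100, function(i) {
    mut <- cbind(G1 = sample(rep(0:1, 10)), G2 = sample(rep(0:1, 10)),
                 G3 = sample(rep(0:1, 10)))
    rownames(mut) <- patients
    res <- chemogenomicScan(act, mut)
    mean(res$q < 0.05)
  }, numeric(1))
  expect_lte(mean(rate), 0.05)
})

test_that("benefit screens are reproducible by seed", {
  a <- simulateBenefitScreen(agents = c("x", "y"), seed = 5)
  b <- simulateBenefitScreen(agents = c("x", "y"), seed = 5)
  d <- simulateBenefitScreen(agents = c("x", "y"), seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, d))
})
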