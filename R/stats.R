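#' Lymphocyte-referenced chemosensitivity call
#'
#' Classifies a patient's leukemic population as chemosensitive or
#' chemoresistant using the patient's own lymphocytes as an internal
#' reference: the call is \code{"sensitive"} if and only if the drug
#' activity (AOC) on the population strictly exceeds the activity on the
#' lymphocytes; equality is \code{"resistant"}. Both AOCs must come from
#' the same dose series. Negative AOCs (outgrowth) are legal inputs.
#'
#' @param aocPop AOC on the leukemic population (bulk or LSC); vectorized.
#' @param aocLymph AOC on the matched lymphocytes (same length).
#' @param patient optional patient id(s).
#' @param population population label, e.g. \code{"bulk"} or \code{"LSC"}.
#' @return data.frame with columns \code{patient, population, aoc_pop,
#'   aoc_lymph, call}.
#' @examples
#' sensitivityCall(0.5, 0.3)    # sensitive
#' sensitivityCall(0.3, 0.3)    # resistant (tie rule)
#' @export
sensitivityCall <- function(aocPop, aocLymph, patient = NA,
                            population = "bulk") {
  if (length(aocPop) != length(aocLymph))
    stop("aocPop and aocLymph must have the same length")
  if (any(!is.finite(aocPop)) || any(!is.finite(aocLymph)))
    stop("AOCs must be finite")
  data.frame(patient = patient, population = population,
             aoc_pop = aocPop, aoc_lymph = aocLymph,
             call = ifelse(aocPop > aocLymph, "sensitive", "resistant"))
}

#' Per-patient triplet-minus-backbone activity deltas
#'
#' @param aoc data.frame with columns \code{patient, regimen, aoc}; one
#'   backbone row per patient plus triplet rows (regimen = third-agent id).
#' @param backbone regimen id of the backbone (default \code{"backbone"}).
#' @return data.frame with columns \code{patient, agent, delta}.
#' @export
benefitDeltas <- function(aoc, backbone = "backbone") {
  bb <- aoc[aoc$regimen == backbone, , drop = FALSE]
  if (nrow(bb) == 0L) stop("no backbone AOCs found (regimen '", backbone, "')")
  if (anyDuplicated(bb$patient))
    stop("multiple backbone AOCs for one patient")
  bbMap <- setNames(bb$aoc, bb$patient)
  tr <- aoc[aoc$regimen != backbone, , drop = FALSE]
  miss <- setdiff(unique(tr$patient), names(bbMap))
  if (length(miss))
    stop("patients without a backbone AOC: ", paste(miss, collapse = ", "))
  out <- data.frame(patient = tr$patient, agent = tr$regimen,
                    delta = tr$aoc - bbMap[as.character(tr$patient)])
  rownames(out) <- NULL
  out
}

#' Population-level combination benefit with FDR control
#'
#' For each third agent added to the backbone, tests whether the per-patient
#' activity deltas (triplet AOC minus backbone AOC, both on the same dose
#' series) differ from zero: a one-sample two-sided t test per agent
#' (mathematically identical to a paired two-sample test of triplet vs
#' backbone), Benjamini-Hochberg corrected across agents. Agents with fewer
#' than 3 paired patients are reported without p/q; zero-variance deltas are
#' flagged degenerate (mean reported, p/q NA).
#'
#' @param aoc per-patient AOC table, see [benefitDeltas()].
#' @param backbone backbone regimen id.
#' @return data.frame with one row per agent: \code{agent, n, mean_delta,
#'   statistic, p, q, degenerate}; per-patient deltas attached as attribute
#'   \code{"deltas"}.
#' @export
combinationBenefit <- function(aoc, backbone = "backbone") {
  deltas <- benefitDeltas(aoc, backbone = backbone)
  agents <- sort(unique(deltas$agent))
  rows <- lapply(agents, function(a) {
    d <- deltas$delta[deltas$agent == a]
    d <- d[is.finite(d)]
    n <- length(d)
    if (n < 3L)
      return(data.frame(agent = a, n = n, mean_delta = mean(d),
                        statistic = NA_real_, p = NA_real_,
                        degenerate = FALSE))
    if (sd(d) <= 1e-10 * max(abs(d), 1))
      return(data.frame(agent = a, n = n, mean_delta = mean(d),
                        statistic = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    tt <- t.test(d, mu = 0, alternative = "two.sided")
    data.frame(agent = a, n = n, mean_delta = mean(d),
               statistic = unname(tt$statistic), p = tt$p.value,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  if (any(tested)) out$q[tested] <- bhFDR(out$p[tested])
  out <- out[, c("agent", "n", "mean_delta", "statistic", "p", "q",
                 "degenerate")]
  rownames(out) <- NULL
  attr(out, "deltas") <- deltas
  out
}

#' Nominate the optimal combination per patient
#'
#' Per patient, the nominated third agent is the one with the largest
#' positive activity delta on the LSC readout; if no agent has a positive
#' delta the patient is called \code{"no benefit"}. Exact ties go to the
#' lexicographically smallest agent id and are flagged.
#'
#' @param deltas data.frame with columns \code{patient, agent, delta} (see
#'   [benefitDeltas()]).
#' @return data.frame with columns \code{patient, nominated, delta, tie}.
#' @export
nominateOptimal <- function(deltas) {
  if (nrow(deltas) == 0L) stop("empty delta table")
  out <- lapply(unique(deltas$patient), function(p) {
    d <- deltas[deltas$patient == p & is.finite(deltas$delta), , drop = FALSE]
    if (nrow(d) == 0L) stop("no usable deltas for patient ", p)
    if (all(d$delta <= 0))
      return(data.frame(patient = p, nominated = "no benefit",
                        delta = max(d$delta), tie = FALSE))
    best <- max(d$delta)
    winners <- sort(d$agent[d$delta == best])
    data.frame(patient = p, nominated = winners[1L], delta = best,
               tie = length(winners) > 1L)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' When \code{min(n) <= 8} and there are no ties, the exact two-sided
#' p-value is computed by full enumeration of all group assignments of the
#' pooled ranks (\code{p = 2 * min(P(U <= u), P(U >= u))}, capped at 1);
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. The method used is recorded.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return data.frame (one row): \code{test, statistic, p, n_a, n_b,
#'   method}; the statistic is the Mann-Whitney U of group \code{a}.
#' @examples
#' mannWhitney(1:3, 4:6)   # U = 0, exact p = 0.1
#' @export
mannWhitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && min(n1, n2) <= 8L) {
    idx <- combn(N, n1)
    rsums <- colSums(matrix(r[idx], nrow = n1))
    us <- rsums - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    method <- "exact-enumeration"
  } else {
    mu <- n1 * n2 / 2
    tie <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal-tie-corrected"
  }
  data.frame(test = "mann-whitney", statistic = u, p = p,
             n_a = n1, n_b = n2, method = method)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the standard probability-mass criterion: with
#' all margins fixed, the p-value is the sum of hypergeometric probabilities
#' of every table whose probability does not exceed that of the observed
#' table (comparison with relative tolerance 1e-7).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return data.frame (one row): \code{test, statistic} (the observed
#'   top-left cell), \code{p, n}.
#' @examples
#' # complete remission by blast chemosensitivity
#' fisherExact2x2(matrix(c(9, 0, 20, 9), 2, byrow = TRUE))
#' @export
fisherExact2x2 <- function(table) {
  x <- as.matrix(table)
  if (!all(dim(x) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(x < 0) || any(abs(x - round(x)) > 1e-9))
    stop("cells must be non-negative integers")
  x <- round(x)
  r1 <- sum(x[1L, ]); c1 <- sum(x[, 1L]); N <- sum(x)
  if (any(c(rowSums(x), colSums(x)) == 0)) stop("all margins must be positive")
  support <- max(0L, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  pObs <- probs[support == x[1L, 1L]]
  p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  # lean one-row frame: this kernel is called inside large enumeration loops
  structure(list(test = "fisher-exact", statistic = x[1L, 1L], p = p, n = N),
            class = "data.frame", row.names = 1L)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement:
#' \code{q(i) = min over j >= i of m * p(j) / j} on the sorted p-values,
#' mapped back to input order and capped at 1. Elementwise \code{q >= p},
#' and permuting the input permutes the output identically.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same length and order.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03))    # all 0.03
#' @export
bhFDR <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(1, rev(cummin(rev(q))))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Chemogenomic association scan
#'
#' Systematic screen for mutation-drug sensitivity relations: for every
#' (agent, readout, gene) with at least \code{minGroup} patients per
#' genotype group, the activity values of mutated versus wildtype patients
#' are compared by [mannWhitney()], and Benjamini-Hochberg correction is
#' applied across all performed tests. Under-powered pairs (including
#' constant genotype columns) are skipped and listed.
#'
#' @param activity data.frame with columns \code{patient, agent, readout,
#'   value} (e.g. benefit deltas or AOCs).
#' @param mutations data.frame or matrix, patients (rownames) x genes, 0/1.
#' @param minGroup minimum patients per genotype group (default 3).
#' @return data.frame with columns \code{agent, readout, gene, n_mut, n_wt,
#'   statistic, p, q, method}; skipped pairs attached as attribute
#'   \code{"skipped"} (columns \code{agent, readout, gene, reason}).
#' @export
chemogenomicScan <- function(activity, mutations, minGroup = 3L) {
  mut <- as.matrix(mutations)
  if (is.null(rownames(mut))) stop("mutation table needs patient rownames")
  res <- list(); skipped <- list()
  combos <- unique(activity[, c("agent", "readout")])
  for (i in seq_len(nrow(combos))) {
    a <- combos$agent[i]; rd <- combos$readout[i]
    da <- activity[activity$agent == a & activity$readout == rd, ,
                   drop = FALSE]
    da <- da[da$patient %in% rownames(mut) & is.finite(da$value), ,
             drop = FALSE]
    for (g in colnames(mut)) {
      geno <- mut[as.character(da$patient), g]
      vm <- da$value[geno == 1]; vw <- da$value[geno == 0]
      if (length(vm) < minGroup || length(vw) < minGroup) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          agent = a, readout = rd, gene = g,
          reason = "fewer than minGroup patients per genotype")
        next
      }
      mw <- mannWhitney(vm, vw)
      res[[length(res) + 1L]] <- data.frame(
        agent = a, readout = rd, gene = g,
        n_mut = length(vm), n_wt = length(vw),
        statistic = mw$statistic, p = mw$p, method = mw$method)
    }
  }
  res <- if (length(res)) do.call(rbind, res) else
    data.frame(agent = character(), readout = character(),
               gene = character(), n_mut = integer(), n_wt = integer(),
               statistic = numeric(), p = numeric(), method = character())
  res$q <- if (nrow(res)) bhFDR(res$p) else numeric()
  res <- res[, c("agent", "readout", "gene", "n_mut", "n_wt", "statistic",
                 "p", "q", "method")]
  rownames(res) <- NULL
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(agent = character(), readout = character(),
               gene = character(), reason = character())
  res
}

#' Simulate a combination screen at the AOC level
#'
#' Generates the per-patient AOC table of a backbone-plus-third-agent
#' screen directly on the activity scale: each patient draws a backbone AOC
#' from a normal distribution, and each triplet AOC equals the patient's
#' backbone AOC plus the agent's systematic benefit plus independent
#' technical noise. Used for power and calibration checks of
#' [combinationBenefit()] and [nominateOptimal()].
#'
#' @param nPatients number of patients (default 20).
#' @param agents character vector of third-agent ids.
#' @param effects named numeric of systematic AOC benefits per agent
#'   (missing agents get 0).
#' @param noiseSD SD of the per-(patient, agent) technical noise
#'   (default 0.1).
#' @param backboneMean,backboneSD distribution of backbone AOCs
#'   (defaults 0.4, 0.15).
#' @param seed integer seed.
#' @return data.frame with columns \code{patient, regimen, aoc}, regimens
#'   \code{"backbone"} plus each agent.
#' @export
simulateBenefitScreen <- function(nPatients = 20L, agents,
                                  effects = numeric(), noiseSD = 0.1,
                                  backboneMean = 0.4, backboneSD = 0.15,
                                  seed = 1L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  patients <- sprintf("P%02d", seq_len(nPatients))
  bb <- rnorm(nPatients, backboneMean, backboneSD)
  eff <- setNames(rep(0, length(agents)), agents)
  eff[names(effects)[names(effects) %in% agents]] <-
    effects[names(effects) %in% agents]
  rows <- data.frame(patient = patients, regimen = "backbone", aoc = bb)
  for (a in agents)
    rows <- rbind(rows, data.frame(
      patient = patients, regimen = a,
      aoc = bb + eff[[a]] + rnorm(nPatients, 0, noiseSD)))
  rownames(rows) <- NULL
  rows
}
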