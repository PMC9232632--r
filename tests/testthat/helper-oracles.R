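# independent oracles and small fixture builders shared across tests

# brute-force Riemann refinement of the piecewise-linear dose-response
# interpolant; independent of computeAOC's trapezoid
riemannAOC <- function(conc, v, nGrid = 1e5, rescale = TRUE) {
  x <- log10(conc)
  if (rescale) x <- (x - min(x)) / (max(x) - min(x))
  nSeg <- length(x) - 1L
  sub <- ceiling(nGrid / nSeg)
  total <- 0
  for (i in seq_len(nSeg)) {
    dx <- (x[i + 1L] - x[i]) / sub
    mids <- x[i] + (seq_len(sub) - 0.5) * dx
    vi <- approx(x, v, xout = mids)$y
    total <- total + sum(1 - vi) * dx
  }
  total
}

# two-sided Fisher p by direct enumeration over all tables with the
# observed margins, using the closed-form table probability
# r1! r2! c1! c2! / (N! a! b! c! d!)
bruteFisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; N <- a + b + c + d
  lconst <- lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
    lfactorial(c2) - lfactorial(N)
  ks <- max(0, r1 - c2):min(r1, c1)
  probs <- vapply(ks, function(k)
    exp(lconst - lfactorial(k) - lfactorial(r1 - k) -
          lfactorial(c1 - k) - lfactorial(r2 - c1 + k)), numeric(1))
  pObs <- probs[ks == a]
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# direct BH definition: q(i) = min over j >= i of m * p(j) / j
directBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# event table with intensities placed explicitly; channels follow
# defaultPanel(), values on the log10 scale
handEvents <- function(via, gfp, cd45, gpr56, diff, lymph) {
  pm <- defaultPanel()
  ev <- data.frame(via, gfp, cd45, gpr56, diff, lymph)
  colnames(ev) <- unname(channels(pm)[c("viability", "GFP", "CD45",
                                        "GPR56", "Diff", "Lymph")])
  ev
}

# thresholds fixed at a common cutoff for all markers
flatThresholds <- function(cut = 2) {
  pm <- defaultPanel()
  methods::new("GateThresholds",
               cutoffs = setNames(rep(cut, 6), names(channels(pm))),
               channels = channels(pm),
               provenance = setNames(rep("configured", 6),
                                     names(channels(pm))))
}

# map generator truth labels onto gate labels
truthToGate <- c(stroma = "msc", lymph = "lymph", LSC = "lsc",
                 DIFF = "diff", basal = "basal", dp = "dp", dead = "dead")
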