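#' Scale fixed-dose readouts with the assay's sign conventions
#'
#' Standardizes the drugs x 3 readout matrix so that a higher value always
#' means higher drug activity: the residual-bulk and LSC-proportion columns
#' are sign-flipped (fewer bulk cells and a lower LSC proportion are
#' activity), the DIFF-proportion column is kept, and every column is
#' centred and scaled to unit sample variance. Constant columns map to
#' all-zeros and are flagged.
#'
#' @param x numeric matrix or data.frame, one row per drug (rownames are
#'   drug ids), columns \code{bulk} (residual bulk, e.g. bulk_ratio),
#'   \code{lsc} (LSC proportion or its delta) and \code{diff} (DIFF
#'   proportion or its delta). At least 2 drugs.
#' @param flip columns to sign-flip before scaling
#'   (default \code{c("bulk", "lsc")}).
#' @return numeric matrix with columns \code{bulk, lsc, diff}, attribute
#'   \code{"constant"} naming any constant columns.
#' @export
scaleReadouts <- function(x, flip = c("bulk", "lsc")) {
  x <- as.matrix(x)
  need <- c("bulk", "lsc", "diff")
  if (!all(need %in% colnames(x)))
    stop("readout matrix must have columns: ", paste(need, collapse = ", "))
  x <- x[, need, drop = FALSE]
  if (nrow(x) < 2L) stop("at least 2 drugs required")
  for (cn in intersect(flip, need)) x[, cn] <- -x[, cn]
  constant <- character()
  for (cn in need) {
    s <- sd(x[, cn])
    if (!is.finite(s) || s == 0) {
      x[, cn] <- 0
      constant <- c(constant, cn)
    } else {
      x[, cn] <- (x[, cn] - mean(x[, cn])) / s
    }
  }
  if (length(constant))
    warning("constant readout column(s) mapped to zeros: ",
            paste(constant, collapse = ", "))
  structure(x, constant = constant)
}

.ARCHETYPES <- c(bulk = "cytotoxic", lsc = "stemness_specific",
                 diff = "differentiating")

# assign archetype labels to cluster centroids: clusters are visited in
# decreasing order of their best coordinate, taking their best still-free
# label; ties and collisions thus go to the cluster with the larger centroid
# coordinate, the other falling back to its next-best coordinate
.labelCentroids <- function(centroids) {
  k <- nrow(centroids)
  labels <- rep(NA_character_, k)
  free <- names(.ARCHETYPES)
  remaining <- seq_len(k)
  while (length(remaining)) {
    if (!length(free)) {
      # more clusters than archetype labels: fall back to plain argmax
      for (i in remaining) {
        j <- which.max(centroids[i, c("bulk", "lsc", "diff")])
        labels[i] <- .ARCHETYPES[[names(.ARCHETYPES)[j]]]
      }
      break
    }
    best <- vapply(remaining, function(i)
      max(centroids[i, free]), numeric(1))
    i <- remaining[which.max(best)]
    sub <- centroids[i, free]
    # fixed priority bulk > lsc > diff on exact ties (free kept in that order)
    coord <- free[which.max(sub)]
    labels[i] <- .ARCHETYPES[[coord]]
    free <- setdiff(free, coord)
    remaining <- setdiff(remaining, i)
  }
  labels
}

#' Cluster drugs into response patterns
#'
#' Unsupervised classification of drugs into the three archetypal activity
#' patterns of the multiparametric screen: cytotoxic (predominant activity
#' on the leukemic bulk), stemness-specific (predominant reduction of the
#' LSC proportion) and differentiating (predominant increase of the DIFF
#' proportion). Drugs are clustered on the scaled readout matrix by
#' agglomerative hierarchical clustering (Euclidean distance, Ward linkage)
#' cut at \code{k} clusters; each cluster is labelled by the argmax
#' coordinate of its centroid, with exact ties broken in the fixed priority
#' bulk > lsc > diff, and label collisions resolved in favour of the
#' cluster with the larger centroid coordinate (the other takes its
#' next-best coordinate). Rows are processed in canonical sorted-drug-id
#' order so results are invariant to input row order.
#'
#' @param scaled matrix from [scaleReadouts()] (rownames are drug ids).
#' @param k number of clusters (default 3); must not exceed the number of
#'   drugs.
#' @param method linkage for [stats::hclust()] (default \code{"ward.D2"}).
#' @return data.frame with columns \code{drug, cluster, label, bulk, lsc,
#'   diff}, rows in sorted drug-id order; cluster centroids are attached as
#'   attribute \code{"centroids"}.
#' @export
clusterPatterns <- function(scaled, k = 3L, method = "ward.D2") {
  scaled <- as.matrix(scaled)
  if (is.null(rownames(scaled)))
    rownames(scaled) <- sprintf("drug%03d", seq_len(nrow(scaled)))
  if (k > nrow(scaled))
    stop("k (", k, ") exceeds the number of drugs (", nrow(scaled), ")")
  scaled <- scaled[order(rownames(scaled)), , drop = FALSE]
  cl <- if (k == nrow(scaled)) seq_len(nrow(scaled)) else
    cutree(hclust(dist(scaled), method = method), k = k)
  centroids <- do.call(rbind, lapply(seq_len(k), function(i)
    colMeans(scaled[cl == i, , drop = FALSE])))
  labels <- .labelCentroids(centroids)
  out <- data.frame(drug = rownames(scaled), cluster = as.integer(cl),
                    label = labels[cl],
                    bulk = scaled[, "bulk"], lsc = scaled[, "lsc"],
                    diff = scaled[, "diff"])
  rownames(out) <- NULL
  attr(out, "centroids") <- centroids
  out
}

#' Rule-based pattern call for a single drug
#'
#' Fallback classifier for cases where clustering is undefined (a single
#' drug): the archetype is the argmax of the scaled readout triple, with an
#' \code{"inactive"} call when every |scaled value| is below the threshold.
#'
#' @param scaledTriple named numeric \code{c(bulk=, lsc=, diff=)} on the
#'   [scaleReadouts()] scale.
#' @param threshold inactivity threshold on |scaled| (default 0.5).
#' @return one of \code{"cytotoxic", "stemness_specific", "differentiating",
#'   "inactive"}.
#' @export
classifyPattern <- function(scaledTriple, threshold = 0.5) {
  need <- c("bulk", "lsc", "diff")
  if (!all(need %in% names(scaledTriple)))
    stop("scaledTriple must be named bulk, lsc, diff")
  v <- scaledTriple[need]
  if (all(abs(v) < threshold)) return("inactive")
  .ARCHETYPES[[need[which.max(v)]]]
}
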