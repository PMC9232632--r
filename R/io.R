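#' Read event and layout tables
#'
#' Plain-tabular I/O for the pipeline: event tables are CSVs with one row
#' per acquired event and one column per channel (extra columns are carried
#' along and ignored by gating); layouts are CSVs keyed by well id with
#' columns \code{well, sample, treatment, role, replicate}.
#'
#' @param path CSV path.
#' @param well optional well id to attach to the event table (defaults to
#'   the file name without extension).
#' @return \code{readEvents}: data.frame of events with attribute
#'   \code{"well"}.
#' @export
readEvents <- function(path, well = NULL) {
  ev <- read.csv(path, check.names = FALSE)
  attr(ev, "well") <- if (is.null(well))
    sub("\\.[^.]*$", "", basename(path)) else well
  ev
}

#' @rdname readEvents
#' @return \code{readLayout}: layout data.frame.
#' @export
readLayout <- function(path) {
  lay <- read.csv(path, check.names = FALSE)
  need <- c("well", "sample", "treatment", "role", "replicate")
  miss <- setdiff(need, colnames(lay))
  if (length(miss))
    stop("layout is missing column(s): ", paste(miss, collapse = ", "))
  lay$treatment[is.na(lay$treatment)] <- ""
  lay
}
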