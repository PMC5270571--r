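#' Fresh-media reference statistics per NMR peak
#'
#' Computes, from the fresh-media replicate columns of a peak-integral
#' experiment, the per-peak mean and sample standard deviation (n−1
#' denominator) against which all spent and double-spent conditions are
#' z-scored.
#'
#' @param pe a [PeakExperiment()] whose \code{condition} column includes at
#'   least two \code{"fresh"} replicates, or a numeric matrix of fresh
#'   replicate rows (replicates x peaks).
#' @return data.frame \code{peak_id, mean, sd}.  A peak with zero standard
#'   deviation across fresh replicates is an error (its z-scores would be
#'   undefined), reported by peak id.
#' @examples
#' m <- rbind(c(1, 0), c(1, 2), c(3, 0), c(3, 2))
#' colnames(m) <- c("p1", "p2")
#' referenceStats(m)
#' @export
referenceStats <- function(pe) {
  if (is(pe, "PeakExperiment")) {
    keep <- SummarizedExperiment::colData(pe)$condition == "fresh"
    if (sum(keep) < 2L) stop("need at least 2 fresh-media replicates")
    m <- t(SummarizedExperiment::assay(pe, "integrals")[, keep, drop = FALSE])
  } else {
    m <- as.matrix(pe)
    if (nrow(m) < 2L) stop("need at least 2 fresh-media replicates")
  }
  mu <- colMeans(m)
  sdev <- apply(m, 2L, stats::sd)
  zero <- colnames(m)[sdev == 0]
  if (length(zero))
    stop("zero standard deviation across fresh replicates for peak(s): ",
         paste(head(zero, 10L), collapse = ", "))
  data.frame(peak_id = colnames(m), mean = unname(mu), sd = unname(sdev),
             stringsAsFactors = FALSE)
}

.call_from_z <- function(z, threshold = 2) {
  ifelse(z > threshold, "High", ifelse(z < -threshold, "Low", "Medium"))
}

#' z-score a condition's peak integrals against the fresh-media reference
#'
#' For every peak, \code{z = (x − mean_fresh) / sd_fresh}.  Abundance calls
#' follow the ±2 SD rule with strict inequalities: \code{High} when
#' \code{z > threshold}, \code{Low} when \code{z < −threshold}, otherwise
#' \code{Medium} (so \code{z = ±2} exactly is Medium).
#'
#' @param values named numeric vector of peak integrals for one condition
#'   (names are peak ids; typically the mean across the condition's
#'   replicates).
#' @param ref reference from [referenceStats()]; must cover every peak in
#'   \code{values}.
#' @param threshold call threshold in fresh-media SD units (default 2).
#' @return data.frame \code{peak_id, z, call}.
#' @examples
#' ref <- data.frame(peak_id = "p1", mean = 1, sd = 0.5)
#' zscoreProfile(c(p1 = 2.6), ref)
#' @export
zscoreProfile <- function(values, ref, threshold = 2) {
  stopifnot(threshold > 0)
  missing <- setdiff(ref$peak_id, names(values))
  if (length(missing))
    stop("condition row missing peak(s): ",
         paste(head(missing, 10L), collapse = ", "))
  x <- values[ref$peak_id]
  z <- (as.numeric(x) - ref$mean) / ref$sd
  data.frame(peak_id = ref$peak_id, z = z,
             call = .call_from_z(z, threshold),
             stringsAsFactors = FALSE)
}

#' Clip z-scores for display
#'
#' Heat-map display clips extreme z-scores to ±bound (default ±6); this is
#' display-only and never feeds any abundance call or classification.
#'
#' @param z numeric vector of z-scores.
#' @param bound positive clipping bound (default 6).
#' @return \code{pmin(pmax(z, -bound), bound)}.
#' @examples
#' clipForDisplay(c(-7, 1.5, 8))
#' @export
clipForDisplay <- function(z, bound = 6) {
  stopifnot(bound > 0)
  pmin(pmax(z, -bound), bound)
}

#' Consumed and produced peak sets of an abundance profile
#'
#' Splits a condition's profile into the set of peaks it consumed
#' (\code{z < −threshold}) and produced (\code{z > threshold}), with strict
#' inequalities.
#'
#' @param profile data.frame from [zscoreProfile()] (columns \code{peak_id},
#'   \code{z}).
#' @param threshold SD threshold (default 2).
#' @return List with character vectors \code{consumed} and \code{produced}.
#' @examples
#' consumedProducedSets(data.frame(peak_id = c("glc", "ppa"),
#'                                 z = c(-5, 4)))
#' @export
consumedProducedSets <- function(profile, threshold = 2) {
  list(consumed = profile$peak_id[profile$z < -threshold],
       produced = profile$peak_id[profile$z > threshold])
}

#' Abundance profiles for every non-fresh condition of a peak experiment
#'
#' Averages each condition's replicate integrals (averaging before
#' z-scoring), then z-scores every condition against the fresh-media
#' reference and makes High/Medium/Low calls.  Double-spent conditions are
#' scored against the fresh reference exactly like single-spent ones;
#' spent-to-double-spent transitions are comparisons of the resulting calls
#' (see [buildComparisonRecords()]).
#'
#' @param pe a [PeakExperiment()].
#' @param threshold call threshold in SD units (default 2).
#' @return Long data.frame \code{condition_id, peak_id, z, call} covering
#'   every condition except \code{fresh}.  Attributes record the threshold
#'   and the n−1 SD convention.
#' @export
abundanceProfiles <- function(pe, threshold = 2) {
  stopifnot(is(pe, "PeakExperiment"))
  ref <- referenceStats(pe)
  cd <- SummarizedExperiment::colData(pe)
  m <- SummarizedExperiment::assay(pe, "integrals")
  conds <- setdiff(unique(cd$condition), "fresh")
  res <- do.call(rbind, lapply(conds, function(cn) {
    cols <- which(cd$condition == cn)
    vals <- rowMeans(m[, cols, drop = FALSE])
    prof <- zscoreProfile(vals, ref, threshold)
    cbind(condition_id = cn, prof)
  }))
  attr(res, "threshold") <- threshold
  attr(res, "sd_convention") <- "sample SD, n-1 denominator"
  res
}
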