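#' Normalize a raw optical-density series to endpoint calibrations
#'
#' Growth is tracked continuously at OD870 by miniaturized in-chamber plate
#' readers, but inoculation density and final density are measured at OD600
#' on a bench-top reader.  The raw series is rescaled by the affine map that
#' anchors its first reading to \code{od600_start} and its last reading to
#' \code{od600_end}; the time grid is unchanged.
#'
#' @param od numeric vector of raw OD870 readings (time-ordered).
#' @param od600_start OD600 at inoculation (0.001 in the screen's protocol).
#' @param od600_end OD600 measured at the final time point.
#' @return Numeric vector of normalized OD600-scale readings.
#' @examples
#' normalizeToEndpoints(c(0.1, 0.3, 0.5), 0, 1)
#' @export
normalizeToEndpoints <- function(od, od600_start, od600_end) {
  stopifnot(length(od) >= 2L, od600_start >= 0, od600_end >= 0)
  span <- od[length(od)] - od[1L]
  if (span == 0) {
    if (od600_start == od600_end) return(rep(od600_start, length(od)))
    stop("flat raw series with distinct endpoint calibrations: ",
         "affine transform undefined")
  }
  od600_start + (od - od[1L]) * (od600_end - od600_start) / span
}

#' Average the four LED-channel curves of one well
#'
#' Each well is read by four independent LED pairs; their normalized curves
#' are averaged pointwise into a single growth curve per well.
#'
#' @param curves data.frame with columns \code{channel_id}, \code{time_h},
#'   \code{od} holding the (normalized) curves of one well.
#' @return data.frame with columns \code{time_h}, \code{od} (the pointwise
#'   mean across channels).
#' @examples
#' d <- data.frame(channel_id = rep(1:2, each = 2),
#'                 time_h = rep(c(0, 1), 2), od = c(0, 1, 0, 3))
#' averageChannels(d)
#' @export
averageChannels <- function(curves) {
  stopifnot(all(c("channel_id", "time_h", "od") %in% names(curves)))
  split_curves <- split(curves[c("time_h", "od")], curves$channel_id)
  grids <- lapply(split_curves, `[[`, "time_h")
  ref <- grids[[1L]]
  same <- vapply(grids, function(g)
    length(g) == length(ref) && all(g == ref), logical(1))
  if (!all(same))
    stop("channels of one well must share an identical time grid")
  od_mat <- vapply(split_curves, `[[`, numeric(length(ref)), "od")
  data.frame(time_h = ref,
             od = rowMeans(matrix(od_mat, nrow = length(ref))))
}

#' Area under a growth curve by trapezoidal integration
#'
#' @param time_h strictly increasing time grid (hours).
#' @param od optical-density readings on that grid.
#' @return Area in OD·h over the stored grid (no extrapolation).
#' @examples
#' curveAuc(c(0, 1), c(0, 1))  # 0.5
#' @export
curveAuc <- function(time_h, od) {
  if (length(time_h) < 2L) stop("AUC requires at least 2 time points")
  if (any(diff(time_h) <= 0)) stop("time grid must be strictly increasing")
  if (length(od) != length(time_h)) stop("time and od lengths differ")
  pracma::trapz(time_h, od)
}

#' Call growth from AUC relative to fresh-media AUC
#'
#' Growth in a spent-media condition is quantified as the area under the
#' normalized curve expressed as a percentage of the same species' AUC in
#' fresh media; the species is called as having grown when that percentage
#' reaches the threshold (default 10\%, inclusive).
#'
#' @param auc_condition AUC in the condition of interest (OD·h).
#' @param auc_fresh AUC of the same species in fresh media; must be > 0.
#' @param threshold_percent growth threshold in percent (default 10).
#' @return List with \code{auc}, \code{relative_auc} (percent) and
#'   \code{grew}.
#' @examples
#' callGrowth(4.5, 10)  # 45%, grew
#' @export
callGrowth <- function(auc_condition, auc_fresh, threshold_percent = 10) {
  if (!is.numeric(auc_fresh) || auc_fresh <= 0)
    stop("fresh-media AUC must be positive")
  rel <- 100 * auc_condition / auc_fresh
  list(auc = auc_condition, relative_auc = rel,
       grew = rel >= threshold_percent)
}

#' Growth summaries for a full screen
#'
#' Runs the complete growth stage: per well, normalize each channel's raw
#' OD870 series to the well's endpoint OD600 calibrations, average the four
#' channels, and integrate; then average AUC across replicate wells of each
#' (species, medium) condition and express it relative to the species'
#' fresh-media AUC.
#'
#' @param curves long data.frame \code{well_id, channel_id, time_h, od870}.
#' @param calibration data.frame \code{well_id, od600_start, od600_end}.
#' @param conditions data.frame \code{well_id, species, medium} where
#'   \code{medium} is \code{"fresh"} or \code{"spent<donor>"}.
#' @param threshold_percent growth-call threshold (default 10).
#' @return data.frame with one row per (species, medium):
#'   \code{species, medium, n_wells, auc, auc_sd, relative_auc, grew}.
#'   The applied threshold is recorded in the \code{"threshold_percent"}
#'   attribute.
#' @export
summariseGrowth <- function(curves, calibration, conditions,
                            threshold_percent = 10) {
  stopifnot(all(c("well_id", "channel_id", "time_h", "od870") %in%
                  names(curves)),
            all(c("well_id", "od600_start", "od600_end") %in%
                  names(calibration)),
            all(c("well_id", "species", "medium") %in% names(conditions)))
  cal <- calibration[match(unique(curves$well_id), calibration$well_id), ]
  if (anyNA(cal$well_id))
    stop("calibration missing for some wells")
  per_well <- lapply(split(curves, curves$well_id), function(w) {
    wc <- calibration[calibration$well_id == w$well_id[1L], ]
    norm <- do.call(rbind, lapply(split(w, w$channel_id), function(ch) {
      ch <- ch[order(ch$time_h), ]
      data.frame(channel_id = ch$channel_id, time_h = ch$time_h,
                 od = normalizeToEndpoints(ch$od870, wc$od600_start,
                                           wc$od600_end))
    }))
    avg <- averageChannels(norm)
    data.frame(well_id = w$well_id[1L],
               auc = curveAuc(avg$time_h, avg$od))
  })
  well_auc <- do.call(rbind, per_well)
  well_auc <- merge(well_auc, conditions, by = "well_id")
  agg <- stats::aggregate(auc ~ species + medium, data = well_auc,
                          FUN = function(a) c(mean = mean(a), sd = sd(a),
                                              n = length(a)))
  res <- data.frame(species = agg$species, medium = agg$medium,
                    n_wells = as.integer(agg$auc[, "n"]),
                    auc = agg$auc[, "mean"], auc_sd = agg$auc[, "sd"])
  fresh <- res[res$medium == "fresh", ]
  no_fresh <- setdiff(res$species, fresh$species)
  if (length(no_fresh))
    stop("no fresh-media wells for species: ",
         paste(no_fresh, collapse = ", "))
  fresh_auc <- stats::setNames(fresh$auc, fresh$species)
  if (any(fresh_auc <= 0))
    stop("fresh-media AUC must be positive for every species")
  res$relative_auc <- 100 * res$auc / fresh_auc[res$species]
  res$grew <- res$relative_auc >= threshold_percent
  attr(res, "threshold_percent") <- threshold_percent
  res[order(res$species, res$medium), ]
}
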