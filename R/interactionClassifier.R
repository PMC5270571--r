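.CALL_LEVELS <- c("Low", "Medium", "High")
.GROUP_LEVELS <- c("NoChange", "Lower", "Higher")

#' Classify a spent-to-double-spent call transition
#'
#' Maps a pair of abundance calls (the metabolite's call in the donor's
#' spent medium and in the double-spent medium derived from it) to one of
#' the nine ordered transitions, grouped as NoChange (High, Medium, Low),
#' Lower in double spent (High to Low, High to Medium, Medium to Low) and
#' Higher in double spent (Low to High, Low to Medium, Medium to High).
#' Crossed with the grower's growth flag this yields the 18 scenarios of
#' the screen.
#'
#' @param spent_call,double_call character vectors of calls in
#'   \code{c("Low", "Medium", "High")}; recycled to a common length.
#' @return data.frame \code{transition, group} (both character;
#'   \code{transition} is e.g. \code{"High"} for no change or
#'   \code{"High to Medium"}).
#' @examples
#' classifyTransition("High", "Medium")
#' @export
classifyTransition <- function(spent_call, double_call) {
  n <- max(length(spent_call), length(double_call))
  spent_call <- rep_len(as.character(spent_call), n)
  double_call <- rep_len(as.character(double_call), n)
  ok <- spent_call %in% .CALL_LEVELS & double_call %in% .CALL_LEVELS
  if (!all(ok))
    stop("calls must be one of ", paste(.CALL_LEVELS, collapse = ", "))
  i1 <- match(spent_call, .CALL_LEVELS)
  i2 <- match(double_call, .CALL_LEVELS)
  group <- ifelse(i1 == i2, "NoChange", ifelse(i2 < i1, "Lower", "Higher"))
  transition <- ifelse(i1 == i2, spent_call,
                       paste(spent_call, "to", double_call))
  data.frame(transition = transition, group = group,
             stringsAsFactors = FALSE)
}

#' Build comparison records from abundance profiles and growth calls
#'
#' Assembles the atoms of the interaction analysis: one record per
#' (donor, grower, peak) triple, carrying the peak's call in the donor's
#' spent medium (\code{spent<donor>}), its call in the double-spent medium
#' (\code{ds<grower>_in_spent<donor>}), and whether the grower grew in that
#' spent medium (from the growth stage — growth is never inferred from
#' metabolite data).  Self pairs (donor = grower) are never formed: the
#' screen's double-spent conditions exclude them by construction.
#'
#' @param profiles long data.frame from [abundanceProfiles()].
#' @param growth data.frame from [summariseGrowth()] (columns
#'   \code{species, medium, grew}).
#' @return data.frame \code{donor, grower, peak_id, spent_call,
#'   double_call, spent_z, double_z, grew}.
#' @export
buildComparisonRecords <- function(profiles, growth) {
  ds <- unique(profiles$condition_id[grepl("^ds", profiles$condition_id)])
  m <- regmatches(ds, regexec("^ds(.+)_in_spent(.+)$", ds))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed double-spent condition id(s): ",
         paste(head(ds[bad], 5L), collapse = ", "))
  recs <- do.call(rbind, lapply(m, function(mm) {
    grower <- mm[2L]; donor <- mm[3L]
    if (grower == donor)
      stop("self pair in double-spent conditions: ", mm[1L])
    dsp <- profiles[profiles$condition_id == mm[1L], ]
    spp <- profiles[profiles$condition_id == paste0("spent", donor), ]
    if (!nrow(spp))
      stop("missing single-spent profile for donor ", donor)
    gi <- which(growth$species == grower &
                  growth$medium == paste0("spent", donor))
    if (length(gi) != 1L)
      stop("missing or ambiguous growth call for ", grower,
           " in spent", donor)
    idx <- match(dsp$peak_id, spp$peak_id)
    if (anyNA(idx))
      stop("peak mismatch between spent and double-spent profiles of ",
           donor)
    data.frame(donor = donor, grower = grower, peak_id = dsp$peak_id,
               spent_call = spp$call[idx], double_call = dsp$call,
               spent_z = spp$z[idx], double_z = dsp$z,
               grew = growth$grew[gi], stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  recs
}

#' Tabulate comparison records into the 18-scenario interaction table
#'
#' Counts records per (growth status x transition) cell with group
#' subtotals, growth-status totals and the grand total — the shape of the
#' screen's classification table.  Marginal identities (each subtotal the
#' sum of its three cells, each growth-status total the sum of its nine
#' cells, grand total the sum of both) are asserted on every call.
#'
#' @param records data.frame with columns \code{donor, grower, peak_id,
#'   spent_call, double_call, grew}; each (donor, grower, peak) triple may
#'   appear at most once.
#' @return data.frame of 18 rows \code{growth, group, transition, count}
#'   with attributes \code{group_subtotals} (6), \code{growth_totals} (2)
#'   and \code{grand_total}.
#' @examples
#' r <- data.frame(donor = "a", grower = "b", peak_id = "p",
#'                 spent_call = "High", double_call = "Medium", grew = TRUE)
#' tabulateTransitions(r)
#' @export
tabulateTransitions <- function(records) {
  if (nrow(records)) {
    key <- paste(records$donor, records$grower, records$peak_id)
    if (anyDuplicated(key))
      stop("duplicate (donor, grower, peak) triple(s): ",
           paste(head(unique(key[duplicated(key)]), 5L), collapse = "; "))
  }
  cls <- if (nrow(records))
    classifyTransition(records$spent_call, records$double_call) else
    data.frame(transition = character(0), group = character(0))
  grid <- expand.grid(
    double_call = .CALL_LEVELS, spent_call = .CALL_LEVELS,
    growth = c("growth", "no_growth"), stringsAsFactors = FALSE)
  lab <- classifyTransition(grid$spent_call, grid$double_call)
  grid$group <- lab$group
  grid$transition <- lab$transition
  ord <- order(match(grid$growth, c("growth", "no_growth")),
               match(grid$group, .GROUP_LEVELS),
               match(grid$spent_call, rev(.CALL_LEVELS)),
               match(grid$double_call, rev(.CALL_LEVELS)))
  grid <- grid[ord, c("growth", "group", "transition")]
  obs_growth <- ifelse(records$grew, "growth", "no_growth")
  obs_key <- if (nrow(records))
    paste(obs_growth, cls$transition) else character(0)
  grid$count <- as.integer(
    vapply(paste(grid$growth, grid$transition),
           function(k) sum(obs_key == k), numeric(1)))
  rownames(grid) <- NULL
  sub <- stats::aggregate(count ~ growth + group, data = grid, FUN = sum)
  tot <- stats::aggregate(count ~ growth, data = grid, FUN = sum)
  grand <- sum(grid$count)
  stopifnot(sum(sub$count) == grand, sum(tot$count) == grand,
            grand == nrow(records))
  attr(grid, "group_subtotals") <- sub
  attr(grid, "growth_totals") <- stats::setNames(tot$count, tot$growth)
  attr(grid, "grand_total") <- grand
  class(grid) <- c("InteractionTable", "data.frame")
  grid
}

#' Summary ratios of an interaction table
#'
#' Derives the headline proportions of the screen from a tabulated
#' interaction table: the fraction of comparisons unchanged between spent
#' and double-spent media, the fraction of unchanged comparisons occurring
#' under no growth, the fraction of no-growth comparisons that nevertheless
#' changed, and the fraction of changed comparisons that were increases.
#'
#' @param tab an \code{InteractionTable} from [tabulateTransitions()].
#' @return Named list of counts and percentages:
#'   \code{n_total, n_unchanged, n_changed, n_no_growth,
#'   n_unchanged_no_growth, n_changed_no_growth, n_increase,
#'   pct_unchanged, pct_unchanged_no_growth, pct_changed_no_growth,
#'   pct_increase_among_changed}.
#' @export
interactionSummary <- function(tab) {
  stopifnot(inherits(tab, "InteractionTable"))
  n_total <- attr(tab, "grand_total")
  unchanged <- sum(tab$count[tab$group == "NoChange"])
  changed <- n_total - unchanged
  no_growth <- sum(tab$count[tab$growth == "no_growth"])
  unchanged_ng <- sum(tab$count[tab$group == "NoChange" &
                                  tab$growth == "no_growth"])
  changed_ng <- no_growth - unchanged_ng
  increase <- sum(tab$count[tab$group == "Higher"])
  list(n_total = n_total, n_unchanged = unchanged, n_changed = changed,
       n_no_growth = no_growth, n_unchanged_no_growth = unchanged_ng,
       n_changed_no_growth = changed_ng, n_increase = increase,
       pct_unchanged = 100 * unchanged / n_total,
       pct_unchanged_no_growth = 100 * unchanged_ng / unchanged,
       pct_changed_no_growth = 100 * changed_ng / no_growth,
       pct_increase_among_changed = 100 * increase / changed)
}

#' Detect potential cross-feeding records
#'
#' A record constitutes evidence for cross-feeding when the grower grew in
#' the donor's spent medium while a metabolite the donor had produced
#' (call High in spent) decreased in the double-spent medium (call Medium
#' or Low): the second species grew and simultaneously consumed a
#' metabolite produced by the first.
#'
#' @param records data.frame from [buildComparisonRecords()].
#' @return Subset of \code{records} with an added column
#'   \code{call = "cross_feeding"}.
#' @export
detectCrossFeeding <- function(records) {
  hit <- records$grew & records$spent_call == "High" &
    records$double_call %in% c("Medium", "Low")
  out <- records[hit, , drop = FALSE]
  if (nrow(out)) out$call <- "cross_feeding" else out$call <- character(0)
  rownames(out) <- NULL
  out
}

#' Detect emergent metabolism
#'
#' A grower exhibits emergent metabolism when, growing in another species'
#' spent medium, it shows a production or consumption behavior absent from
#' its own fresh-media behavior: emergent production when the double-spent
#' transition is Higher but the grower's own single-spent call for that
#' peak is not High; emergent consumption when the transition is Lower but
#' that call is not Low.  Both calls require growth.
#'
#' @param records data.frame from [buildComparisonRecords()].
#' @param fresh_calls data.frame \code{species, peak_id, call} giving each
#'   grower's behavior in fresh media, i.e. the abundance calls of its own
#'   single-spent condition; every grower appearing in \code{records} must
#'   be covered.
#' @return Subset of \code{records} with an added \code{call} column in
#'   \code{c("emergent_production", "emergent_consumption")}.
#' @export
detectEmergent <- function(records, fresh_calls) {
  stopifnot(all(c("species", "peak_id", "call") %in% names(fresh_calls)))
  missing <- setdiff(unique(records$grower), unique(fresh_calls$species))
  if (length(missing))
    stop("no fresh-media (single-spent) profile for grower(s): ",
         paste(missing, collapse = ", "))
  cls <- classifyTransition(records$spent_call, records$double_call)
  own <- fresh_calls$call[match(paste(records$grower, records$peak_id),
                                paste(fresh_calls$species,
                                      fresh_calls$peak_id))]
  if (anyNA(own))
    stop("fresh-media calls missing for some (grower, peak) pairs")
  prod <- records$grew & cls$group == "Higher" & own != "High"
  cons <- records$grew & cls$group == "Lower" & own != "Low"
  tag <- function(idx, label) {
    sub <- records[idx, , drop = FALSE]
    sub$call <- rep(label, nrow(sub))
    sub
  }
  out <- rbind(tag(prod, "emergent_production"),
               tag(cons, "emergent_consumption"))
  rownames(out) <- NULL
  out
}

#' Shared-consumption competition markers per species pair
#'
#' Peaks called Low in both species' single-spent profiles mark metabolites
#' the pair would be expected to compete for in co-culture (e.g. glucose
#' for the \emph{Clostridium}/\emph{Parabacteroides} pair of the motivating
#' screen).
#'
#' @param fresh_calls data.frame \code{species, peak_id, call} (each
#'   species' behavior in fresh media); at least 2 species.
#' @return data.frame \code{species_a, species_b, peak_id} with one row per
#'   shared-Low peak per unordered pair.
#' @export
competitionMarkers <- function(fresh_calls) {
  sp <- sort(unique(fresh_calls$species))
  if (length(sp) < 2L) stop("need at least 2 species")
  low <- lapply(stats::setNames(sp, sp), function(s)
    fresh_calls$peak_id[fresh_calls$species == s &
                          fresh_calls$call == "Low"])
  pairs <- utils::combn(sp, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    shared <- intersect(low[[pairs[1L, j]]], low[[pairs[2L, j]]])
    if (!length(shared)) return(NULL)
    data.frame(species_a = pairs[1L, j], species_b = pairs[2L, j],
               peak_id = shared, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(species_a = character(0), species_b = character(0),
                      peak_id = character(0))
  out
}

#' Reconstruct a record set realizing published scenario counts
#'
#' Expands a table of per-scenario counts (growth status, spent call,
#' double call, count) into an explicit set of comparison records with
#' synthetic donor/grower/peak identifiers, so that published summary
#' tables can be pushed through [tabulateTransitions()],
#' [interactionSummary()] and [detectCrossFeeding()] like any record set.
#' Records under growth and under no growth are attached to distinct
#' (donor, grower) pairs, and peak ids are unique within each pair.
#'
#' @param counts data.frame with columns \code{growth}
#'   (\code{"growth"}/\code{"no_growth"}), \code{spent_call},
#'   \code{double_call}, \code{count}.
#' @return data.frame of comparison records (see
#'   [buildComparisonRecords()]; z columns omitted).
#' @export
recordsFromScenarioCounts <- function(counts) {
  stopifnot(all(c("growth", "spent_call", "double_call", "count") %in%
                  names(counts)),
            all(counts$growth %in% c("growth", "no_growth")),
            all(counts$count >= 0))
  out <- do.call(rbind, lapply(c("growth", "no_growth"), function(g) {
    sub <- counts[counts$growth == g & counts$count > 0, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    n <- sum(sub$count)
    data.frame(donor = paste0("donor_", g), grower = paste0("grower_", g),
               peak_id = sprintf("peak_%05d", seq_len(n)),
               spent_call = rep(sub$spent_call, sub$count),
               double_call = rep(sub$double_call, sub$count),
               grew = g == "growth", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
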