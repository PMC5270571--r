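#' Define a synthetic screen scenario
#'
#' Bundles every parameter of the synthetic-data generator, whose defaults
#' mirror the dimensions of the motivating screen: 15 metagenomic samples,
#' phylum pools of 989 Firmicutes and 176 Bacteroidetes, 8 consortium
#' species of which 7 grow in the defined medium, 85 NMR peaks, 70 h growth
#' curves started at OD600 0.001 read on 4 channels, a ±2 SD call threshold
#' and planted effects of at least 4 fresh-media SD.  The NOG universe
#' defaults to 5000 orthologs with a sample-frequency distribution placing
#' about 2.7\% of observed NOGs in the core (present in all samples).
#'
#' @param seed integer seed; every generated artifact is a deterministic
#'   function of the scenario including this seed.
#' @param n_nogs size of the NOG universe.
#' @param n_categories number of single-letter functional categories.
#' @param multi_fraction fraction of NOGs annotated in more than one
#'   category (given the sentinel category \code{"multi"}).
#' @param pool_sizes named vector of phylum pool sizes for the random
#'   consortium null model.
#' @param n_metagenome_samples number of metagenomic samples.
#' @param core_fraction expected fraction of observed NOGs at maximal
#'   frequency (the core).
#' @param species_size_frac expected fraction of the NOG universe in a
#'   non-designated species' annotation set.
#' @param designated_size_frac same for the designated large-genome
#'   species.
#' @param pool_size_frac same for random-pool species.
#' @param unique_core_fraction fraction of the core set made exclusive to
#'   the designated species (its planted unique contribution).
#' @param n_peaks number of NMR peaks.
#' @param fresh_replicates fresh-media replicate rows in the peak table.
#' @param condition_replicates replicate rows per non-fresh condition.
#' @param noise_sd additive Gaussian noise SD on peak integrals
#'   (fresh-media SD unit for planted effects).
#' @param n_produced_per_donor,n_consumed_per_donor planted
#'   production/consumption events per donor in single-spent media.
#' @param n_crossfeeding,n_emergent_production,n_emergent_consumption
#'   planted interaction events across the screen.
#' @param effect_range magnitude range (in fresh SD units) for planted
#'   effects; the minimum must exceed the call threshold of 2.
#' @param p_grow probability that a grower grows in another species'
#'   spent medium (self-spent is always no-growth); default 12/42, the
#'   growth rate observed in the motivating screen.
#' @param od_start inoculation OD600.
#' @param od_final_fresh carrying-capacity OD600 in fresh media.
#' @param growth_rate,t_mid logistic rate (per h) and midpoint (h).
#' @param duration_h,od_interval_h span and sampling interval of the
#'   curves.
#' @param n_wells replicate wells per condition; \code{n_channels} LED
#'   channels per well.
#' @param n_channels channels per well.
#' @param od_noise_sd Gaussian noise SD on raw OD870 readings.
#' @return A list of class \code{"SyntheticScenario"}.
#' @export
syntheticScenario <- function(seed = 1L,
                              n_nogs = 5000L,
                              n_categories = 20L,
                              multi_fraction = 0.008,
                              pool_sizes = c(Firmicutes = 989L,
                                             Bacteroidetes = 176L),
                              n_metagenome_samples = 15L,
                              core_fraction = 0.027,
                              species_size_frac = 0.10,
                              designated_size_frac = 0.25,
                              pool_size_frac = 0.08,
                              unique_core_fraction = 0.29,
                              n_peaks = 85L,
                              fresh_replicates = 5L,
                              condition_replicates = 3L,
                              noise_sd = 0.05,
                              n_produced_per_donor = 8L,
                              n_consumed_per_donor = 8L,
                              n_crossfeeding = 3L,
                              n_emergent_production = 4L,
                              n_emergent_consumption = 4L,
                              effect_range = c(4, 8),
                              p_grow = 12 / 42,
                              od_start = 0.001,
                              od_final_fresh = 1.0,
                              growth_rate = 0.3,
                              t_mid = 15,
                              duration_h = 70,
                              od_interval_h = 1,
                              n_wells = 4L,
                              n_channels = 4L,
                              od_noise_sd = 0.01) {
  species <- sprintf("sp%d", seq_len(8L))
  phyla <- stats::setNames(c(rep("Firmicutes", 6L), "Deferribacteres",
                             "Bacteroidetes"), species)
  sc <- list(seed = as.integer(seed), n_nogs = as.integer(n_nogs),
             n_categories = as.integer(n_categories),
             multi_fraction = multi_fraction, pool_sizes = pool_sizes,
             n_metagenome_samples = as.integer(n_metagenome_samples),
             core_fraction = core_fraction,
             species_size_frac = species_size_frac,
             designated_size_frac = designated_size_frac,
             pool_size_frac = pool_size_frac,
             unique_core_fraction = unique_core_fraction,
             species = species, species_phyla = phyla,
             designated_species = "sp8",
             growers = setdiff(species, "sp7"),
             n_peaks = as.integer(n_peaks),
             fresh_replicates = as.integer(fresh_replicates),
             condition_replicates = as.integer(condition_replicates),
             noise_sd = noise_sd,
             n_produced_per_donor = as.integer(n_produced_per_donor),
             n_consumed_per_donor = as.integer(n_consumed_per_donor),
             n_crossfeeding = as.integer(n_crossfeeding),
             n_emergent_production = as.integer(n_emergent_production),
             n_emergent_consumption = as.integer(n_emergent_consumption),
             effect_range = effect_range, p_grow = p_grow,
             od_start = od_start, od_final_fresh = od_final_fresh,
             growth_rate = growth_rate, t_mid = t_mid,
             duration_h = duration_h, od_interval_h = od_interval_h,
             n_wells = as.integer(n_wells),
             n_channels = as.integer(n_channels),
             od_noise_sd = od_noise_sd)
  stopifnot(sc$n_nogs >= 10L, sc$n_metagenome_samples >= 1L,
            sc$n_peaks >= 10L, sc$fresh_replicates >= 2L,
            sc$condition_replicates >= 1L, sc$noise_sd > 0,
            effect_range[1] > 2, effect_range[2] >= effect_range[1],
            unique_core_fraction >= 0, unique_core_fraction <= 1,
            p_grow >= 0, p_grow <= 1)
  class(sc) <- "SyntheticScenario"
  sc
}

#' Ground-truth growth pattern of a scenario
#'
#' Deterministic (seeded) assignment of which grower grows in which medium:
#' fresh media always supports growth, a species never grows in its own
#' spent medium, and every other spent medium supports growth with
#' probability \code{p_grow}.  Growing spent conditions receive a relative
#' carrying capacity in (0.15, 0.95) of the fresh capacity.
#'
#' @param scenario a [syntheticScenario()].
#' @return data.frame \code{species, medium, grew, rel_capacity}.
#' @export
scenarioGrowthTruth <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  set.seed(scenario$seed + 104L)
  g <- scenario$growers
  grid <- expand.grid(species = g,
                      medium = c("fresh", paste0("spent", g)),
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$species, grid$medium), ]
  self <- grid$medium == paste0("spent", grid$species)
  fresh <- grid$medium == "fresh"
  grew <- rep(FALSE, nrow(grid))
  grew[fresh] <- TRUE
  other <- !fresh & !self
  grew[other] <- stats::runif(sum(other)) < scenario$p_grow
  rel <- rep(0, nrow(grid))
  rel[fresh] <- 1
  rel[grew & !fresh] <- stats::runif(sum(grew & !fresh), 0.15, 0.95)
  grid$grew <- grew
  grid$rel_capacity <- rel
  rownames(grid) <- NULL
  grid
}

.peak_names <- function(n_peaks) {
  named <- c("glucose", "lactose", "alanine", "glycine", "histidine",
             "isoleucine", "leucine", "lysine", "methionine",
             "phenylalanine", "threonine", "tryptophan", "tyrosine",
             "valine", "lactate", "acetate", "propionate", "butyrate",
             "formate", "succinate", "fumarate", "pyruvate", "ethanol",
             "betaine", "nicotinamide", "adenosine", "uridine", "uracil",
             "aspartate", "glutamate", "3-hydroxybutyrate", "choline",
             "trehalose", "glycerol", "citrate", "serine")
  if (n_peaks <= length(named)) return(named[seq_len(n_peaks)])
  c(named, paste("Unknown", seq_len(n_peaks - length(named))))
}

#' Generate a synthetic NOG world
#'
#' Builds a NOG catalog, per-sample metagenome annotation sets whose
#' frequencies follow the scenario's frequency distribution, annotation
#' sets for the 8 consortium species (with the designated large-genome
#' species holding a planted exclusive fraction of the core set), and
#' random phylum pools for the consortium null model.  Species and pool
#' members preferentially carry high-frequency NOGs, so coverage rises
#' with sample frequency as in real surveys.
#'
#' @param scenario a [syntheticScenario()].
#' @return List with \code{catalog} ([NogCatalog()]), \code{species}
#'   ([NogSetList()] with phyla), \code{metagenome}
#'   ([MetagenomeCollection()]), \code{pools} (named list phylum ->
#'   member ids), \code{pool_sets} ([NogSetList()]), and \code{truth}
#'   (core ids, the designated species' planted unique-core ids, NOG
#'   frequencies).
#' @export
generateNogWorld <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  set.seed(scenario$seed + 101L)
  n <- scenario$n_nogs
  ns <- scenario$n_metagenome_samples
  ids <- sprintf("NOG%05d", seq_len(n))
  cats <- LETTERS[seq_len(scenario$n_categories)]
  category <- sample(cats, n, replace = TRUE)
  category[stats::runif(n) < scenario$multi_fraction] <- "multi"
  catalog <- NogCatalog(ids, category)

  # sample-frequency distribution: geometric decay over 1..(ns-1) plus a
  # planted core mass at frequency ns
  if (ns > 1L) {
    w <- exp(-0.35 * (0:(ns - 2L)))
    w <- w / sum(w) * (1 - scenario$core_fraction)
    w <- c(w, scenario$core_fraction)
  } else w <- 1
  freq <- sample.int(ns, n, replace = TRUE, prob = w)
  placement <- lapply(freq, function(k) sample.int(ns, k))
  sample_of <- unlist(placement)
  nog_of <- rep(ids, freq)
  samples <- split(nog_of, factor(sample_of, levels = seq_len(ns)))
  names(samples) <- sprintf("sample%02d", seq_len(ns))
  metagenome <- MetagenomeCollection(samples)
  core <- ids[freq == ns]

  # frequency-weighted inclusion probability, normalized to a target size
  wt <- 0.25 + 0.75 * freq / ns
  wt <- wt / mean(wt)
  draw_set <- function(frac) ids[stats::runif(n) < pmin(1, frac * wt)]

  sp_sets <- lapply(scenario$species, function(s)
    draw_set(if (s == scenario$designated_species)
      scenario$designated_size_frac else scenario$species_size_frac))
  names(sp_sets) <- scenario$species

  n_uc <- round(scenario$unique_core_fraction * length(core))
  if (n_uc > length(core))
    stop("infeasible unique_core_fraction")
  uc <- if (n_uc > 0) sample(core, n_uc) else character(0)
  des <- scenario$designated_species
  sp_sets <- lapply(stats::setNames(names(sp_sets), names(sp_sets)),
                    function(s) {
                      if (s == des) union(sp_sets[[s]], uc)
                      else setdiff(sp_sets[[s]], uc)
                    })
  species <- NogSetList(sp_sets, phylum = scenario$species_phyla)

  pools <- lapply(stats::setNames(names(scenario$pool_sizes),
                                  names(scenario$pool_sizes)),
                  function(ph) sprintf("%s%04d", substr(ph, 1L, 1L),
                                       seq_len(scenario$pool_sizes[[ph]])))
  pool_members <- unlist(pools, use.names = FALSE)
  pool_phyla <- rep(names(pools), lengths(pools))
  pool_sets <- lapply(pool_members, function(m) {
    s <- draw_set(scenario$pool_size_frac)
    s[!s %in% uc]  # planted unique-core NOGs stay exclusive
  })
  names(pool_sets) <- pool_members
  pool_sets <- NogSetList(pool_sets, phylum = pool_phyla)

  list(catalog = catalog, species = species, metagenome = metagenome,
       pools = pools, pool_sets = pool_sets,
       truth = list(core = core, designated_unique_core = uc,
                    frequency = stats::setNames(freq, ids)))
}

.logistic_od <- function(t, od_start, capacity, rate, t_mid) {
  if (capacity <= od_start) return(rep(od_start, length(t)))
  low <- od_start
  low + (capacity - low) / (1 + exp(-rate * (t - t_mid)))
}

#' Generate synthetic growth-curve data
#'
#' Produces raw multi-channel OD870 series, endpoint OD600 calibrations and
#' a condition map for every (grower, medium) condition of the screen.
#' Growing conditions follow a logistic curve scaled by the condition's
#' relative carrying capacity; non-growing conditions stay at the
#' inoculation density.  Raw OD870 readings are an affine instrument
#' distortion of the true OD600 plus independent Gaussian channel noise.
#'
#' @param scenario a [syntheticScenario()].
#' @return List with \code{curves} (long data.frame \code{well_id,
#'   channel_id, time_h, od870}), \code{calibration} (\code{well_id,
#'   od600_start, od600_end}), \code{conditions} (\code{well_id, species,
#'   medium}) and \code{truth} (the [scenarioGrowthTruth()] table).
#' @export
generateGrowth <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  truth <- scenarioGrowthTruth(scenario)
  set.seed(scenario$seed + 102L)
  t_grid <- seq(0, scenario$duration_h, by = scenario$od_interval_h)
  well_rows <- list(); cal_rows <- list(); cond_rows <- list()
  wid <- 0L
  for (i in seq_len(nrow(truth))) {
    capacity <- scenario$od_start +
      truth$rel_capacity[i] * (scenario$od_final_fresh - scenario$od_start)
    od600 <- if (truth$grew[i])
      .logistic_od(t_grid, scenario$od_start, capacity,
                   scenario$growth_rate, scenario$t_mid)
    else rep(scenario$od_start, length(t_grid))
    for (w in seq_len(scenario$n_wells)) {
      wid <- wid + 1L
      well <- sprintf("w%04d", wid)
      raw <- lapply(seq_len(scenario$n_channels), function(ch)
        data.frame(well_id = well, channel_id = ch, time_h = t_grid,
                   od870 = 0.05 + 2 * od600 +
                     stats::rnorm(length(t_grid), 0,
                                  scenario$od_noise_sd)))
      well_rows[[length(well_rows) + 1L]] <- do.call(rbind, raw)
      cal_rows[[length(cal_rows) + 1L]] <-
        data.frame(well_id = well, od600_start = scenario$od_start,
                   od600_end = od600[length(od600)])
      cond_rows[[length(cond_rows) + 1L]] <-
        data.frame(well_id = well, species = truth$species[i],
                   medium = truth$medium[i])
    }
  }
  list(curves = do.call(rbind, well_rows),
       calibration = do.call(rbind, cal_rows),
       conditions = do.call(rbind, cond_rows),
       truth = truth)
}

#' Planted metabolic events of a scenario
#'
#' Seeded generation of the ground-truth event list: per-donor production
#' and consumption effects in single-spent media (drawn from disjoint
#' production- and consumption-eligible peak pools, so unplanted
#' cross-feeding signatures cannot arise by construction), planted
#' cross-feeding triples (donor-produced peak taken up by a grower that
#' grows in that spent medium), and planted emergent production and
#' consumption events (behaviors a grower shows only in a specific double-
#' spent condition).  Effect sizes are in fresh-media SD units with
#' magnitude in \code{effect_range}.
#'
#' @param scenario a [syntheticScenario()].
#' @param growth_truth the [scenarioGrowthTruth()] table.
#' @return data.frame \code{donor, grower, peak_id, type, effect} where
#'   \code{grower} is \code{NA} for single-spent production/consumption
#'   events and \code{type} is one of \code{production, consumption,
#'   cross_feeding, emergent_production, emergent_consumption}.
#' @export
scenarioPlantedEvents <- function(scenario, growth_truth) {
  set.seed(scenario$seed + 103L)
  peaks <- .peak_names(scenario$n_peaks)
  g <- scenario$growers
  eff <- function(k, sign) sign * stats::runif(k, scenario$effect_range[1],
                                               scenario$effect_range[2])
  n_prod_pool <- ceiling(scenario$n_peaks * 0.45)
  prod_pool <- sample(peaks, n_prod_pool)
  cons_pool <- setdiff(peaks, prod_pool)
  stopifnot(scenario$n_produced_per_donor <= length(prod_pool),
            scenario$n_consumed_per_donor <= length(cons_pool))
  ev <- list()
  for (d in g) {
    pp <- sample(prod_pool, scenario$n_produced_per_donor)
    cc <- sample(cons_pool, scenario$n_consumed_per_donor)
    ev[[length(ev) + 1L]] <- data.frame(
      donor = d, grower = NA_character_, peak_id = c(pp, cc),
      type = rep(c("production", "consumption"),
                 c(length(pp), length(cc))),
      effect = c(eff(length(pp), 1), eff(length(cc), -1)))
  }
  ev <- do.call(rbind, ev)

  grow_pairs <- growth_truth[growth_truth$grew &
                               growth_truth$medium != "fresh", ]
  grow_pairs$donor <- sub("^spent", "", grow_pairs$medium)
  extra <- list()
  if (nrow(grow_pairs)) {
    # cross-feeding: grower consumes a donor-produced peak
    n_cf <- min(scenario$n_crossfeeding, nrow(grow_pairs))
    cf_rows <- grow_pairs[sample.int(nrow(grow_pairs), n_cf), ]
    for (i in seq_len(nrow(cf_rows))) {
      d <- cf_rows$donor[i]; gr <- cf_rows$species[i]
      dp <- ev[ev$donor == d & ev$type == "production", ]
      # the grower must not itself act on the planted peak, so the
      # decrease in double-spent media is attributable to its uptake
      cand <- setdiff(dp$peak_id, ev$peak_id[ev$donor == gr])
      if (!length(cand)) next
      pk <- if (length(cand) == 1L) cand else sample(cand, 1L)
      uptake <- -(dp$effect[dp$peak_id == pk] + stats::runif(1, 0, 4))
      extra[[length(extra) + 1L]] <- data.frame(
        donor = d, grower = gr, peak_id = pk, type = "cross_feeding",
        effect = uptake)
    }
    # emergent events on peaks untouched by the donor or the grower
    pick_emergent <- function(n_ev, type, sign) {
      planted <- do.call(rbind, extra)
      rows <- grow_pairs[sample.int(nrow(grow_pairs), min(n_ev,
                                    nrow(grow_pairs)), replace = FALSE), ]
      do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
        d <- rows$donor[i]; gr <- rows$species[i]
        used <- ev$peak_id[ev$donor %in% c(d, gr)]
        if (!is.null(planted))
          used <- c(used, planted$peak_id[planted$donor == d &
                                            planted$grower == gr])
        free <- setdiff(peaks, used)
        if (!length(free)) return(NULL)
        data.frame(donor = d, grower = gr,
                   peak_id = sample(free, 1L), type = type,
                   effect = eff(1L, sign))
      }))
    }
    extra[[length(extra) + 1L]] <-
      pick_emergent(scenario$n_emergent_production,
                    "emergent_production", 1)
    extra[[length(extra) + 1L]] <-
      pick_emergent(scenario$n_emergent_consumption,
                    "emergent_consumption", -1)
  }
  out <- rbind(ev, do.call(rbind, extra))
  key <- paste(out$donor, out$grower, out$peak_id, sep = "\r")
  if (anyDuplicated(key))
    stop("contradictory planted events on the same (condition, peak)")
  rownames(out) <- NULL
  out
}

#' Generate a synthetic peak-integral table
#'
#' Builds the full peak table of the screen: fresh-media replicates around
#' a lognormal baseline with additive Gaussian noise (truncated at 0),
#' single-spent conditions shifted by each donor's planted
#' production/consumption effects, and double-spent conditions composed
#' from the donor's spent profile plus — when the grower grew — the
#' grower's own fresh-media behavior, planted cross-feeding uptakes and
#' planted emergent events.  Conditions where the grower did not grow
#' reproduce the spent profile unchanged (plus noise).
#'
#' @param scenario a [syntheticScenario()].
#' @return List with \code{peaks} (a [PeakExperiment()]) and \code{truth}
#'   (planted \code{events}, the \code{growth} table and the peak
#'   \code{baseline}).
#' @export
generatePeaks <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  growth_truth <- scenarioGrowthTruth(scenario)
  events <- scenarioPlantedEvents(scenario, growth_truth)
  set.seed(scenario$seed + 105L)
  peaks <- .peak_names(scenario$n_peaks)
  baseline <- stats::rlnorm(scenario$n_peaks, 0, 0.3)
  names(baseline) <- peaks
  sdu <- scenario$noise_sd
  g <- scenario$growers

  shift_of <- function(donor, grower = NULL) {
    # z-shift (in SD units) applied on top of baseline for a condition
    s <- stats::setNames(rep(0, scenario$n_peaks), peaks)
    de <- events[events$donor == donor & is.na(events$grower), ]
    s[de$peak_id] <- s[de$peak_id] + de$effect
    if (!is.null(grower)) {
      ge <- events[events$donor == grower & is.na(events$grower), ]
      s[ge$peak_id] <- s[ge$peak_id] + ge$effect
      ie <- events[!is.na(events$grower) & events$donor == donor &
                     events$grower == grower, ]
      s[ie$peak_id] <- s[ie$peak_id] + ie$effect
    }
    s
  }

  grew_in <- function(grower, donor) {
    i <- growth_truth$species == grower &
      growth_truth$medium == paste0("spent", donor)
    growth_truth$grew[i]
  }

  cond_means <- list(fresh = baseline)
  for (d in g)
    cond_means[[paste0("spent", d)]] <- baseline + sdu * shift_of(d)
  for (gr in g) for (d in setdiff(g, gr)) {
    cn <- paste0("ds", gr, "_in_spent", d)
    cond_means[[cn]] <- if (grew_in(gr, d))
      baseline + sdu * shift_of(d, gr) else baseline + sdu * shift_of(d)
  }

  reps <- function(cn) if (cn == "fresh") scenario$fresh_replicates else
    scenario$condition_replicates
  cols <- list(); cond <- character(0); repl <- integer(0)
  for (cn in names(cond_means)) for (r in seq_len(reps(cn))) {
    v <- cond_means[[cn]] + stats::rnorm(scenario$n_peaks, 0, sdu)
    cols[[length(cols) + 1L]] <- pmax(v, 0)
    cond <- c(cond, cn); repl <- c(repl, r)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- peaks
  pe <- PeakExperiment(m, condition = cond, replicate = repl)
  list(peaks = pe,
       truth = list(events = events, growth = growth_truth,
                    baseline = baseline))
}

#' Write every synthetic input of a scenario to disk
#'
#' Runs all three generators and serializes their outputs in the plain-text
#' formats the analysis stages consume, plus a \code{truth.json} ground
#' truth: \code{catalog.tsv}, \code{species_annotations.tsv},
#' \code{metagenome_annotations.tsv}, \code{pool_annotations.tsv},
#' \code{pool_phyla.tsv}, \code{growth_curves.csv},
#' \code{calibration.csv}, \code{conditions.csv}, \code{peaks.csv}.
#'
#' @param scenario a [syntheticScenario()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with the in-memory \code{world},
#'   \code{growth}, \code{peaks} objects and the written \code{paths}.
#' @export
simulateAll <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "SyntheticScenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  world <- generateNogWorld(scenario)
  growth <- generateGrowth(scenario)
  pk <- generatePeaks(scenario)
  p <- function(f) file.path(out_dir, f)

  writeNogCatalog(world$catalog, p("catalog.tsv"))
  writeAnnotationPairs(world$species, p("species_annotations.tsv"))
  mg <- NogSetList(world$metagenome@samples)
  writeAnnotationPairs(mg, p("metagenome_annotations.tsv"))
  writeAnnotationPairs(world$pool_sets, p("pool_annotations.tsv"))
  utils::write.table(
    data.frame(species_id = entityIds(world$pool_sets),
               phylum = unname(entityPhyla(world$pool_sets))),
    p("pool_phyla.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(growth$curves, p("growth_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(growth$calibration, p("calibration.csv"),
                   row.names = FALSE)
  utils::write.csv(growth$conditions, p("conditions.csv"),
                   row.names = FALSE)
  writePeakTable(pk$peaks, p("peaks.csv"))
  truth <- list(core = world$truth$core,
                designated_unique_core = world$truth$designated_unique_core,
                growth = growth$truth, events = pk$truth$events,
                seed = scenario$seed)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  paths <- stats::setNames(
    file.path(out_dir, c("catalog.tsv", "species_annotations.tsv",
                         "metagenome_annotations.tsv",
                         "pool_annotations.tsv", "pool_phyla.tsv",
                         "growth_curves.csv", "calibration.csv",
                         "conditions.csv", "peaks.csv", "truth.json")),
    c("catalog", "species_annotations", "metagenome_annotations",
      "pool_annotations", "pool_phyla", "growth_curves", "calibration",
      "conditions", "peaks", "truth"))
  invisible(list(world = world, growth = growth, peaks = pk,
                 paths = paths))
}
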