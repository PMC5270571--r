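#' Default pipeline configuration
#'
#' Assembles the full configuration of [runPipeline()]: input paths (as
#' written by [simulateAll()]), analysis thresholds (E-value 1e-10, z-score
#' call threshold 2, display clip 6, growth threshold 10\% relative AUC),
#' the consortium null-model design (sizes 8/16/32 in a 6:2
#' Firmicutes:Bacteroidetes ratio) and seeds.  Every tunable surfaces here
#' and is recorded in the run manifest; nothing is hard-coded downstream.
#'
#' @param input_dir directory holding the input files (see
#'   [simulateAll()]).
#' @param out_dir output directory for result tables and the manifest.
#' @param seed integer seed for the consortium draws.
#' @param sizes consortium sizes to draw.
#' @param n_draws random consortia per size.
#' @param ratio phylum ratio of the null model.
#' @param z_threshold abundance-call threshold in fresh SD units.
#' @param clip_bound display clipping bound for z-scores.
#' @param growth_threshold growth-call threshold (percent relative AUC).
#' @param e_value_threshold best-hit E-value cutoff (used when annotation
#'   sets are built from hit tables).
#' @param n_tests Bonferroni test count for the NOG-metabolite
#'   correlations; \code{NULL} means the number of pairs actually tested.
#' @return A named list, the \code{config} argument of [runPipeline()].
#' @export
pipelineConfig <- function(input_dir, out_dir = NULL, seed = 1L,
                           sizes = c(8L, 16L, 32L), n_draws = 200L,
                           ratio = c(Firmicutes = 6, Bacteroidetes = 2),
                           z_threshold = 2, clip_bound = 6,
                           growth_threshold = 10,
                           e_value_threshold = 1e-10, n_tests = NULL) {
  stopifnot(z_threshold > 0, clip_bound > 0, growth_threshold >= 0,
            e_value_threshold > 0, n_draws >= 1)
  files <- c(catalog = "catalog.tsv",
             species_annotations = "species_annotations.tsv",
             metagenome_annotations = "metagenome_annotations.tsv",
             pool_annotations = "pool_annotations.tsv",
             pool_phyla = "pool_phyla.tsv",
             growth_curves = "growth_curves.csv",
             calibration = "calibration.csv",
             conditions = "conditions.csv",
             peaks = "peaks.csv")
  list(inputs = as.list(stats::setNames(file.path(input_dir, files),
                                        names(files))),
       out_dir = out_dir, seed = as.integer(seed),
       sizes = as.integer(sizes), n_draws = as.integer(n_draws),
       ratio = ratio, z_threshold = z_threshold, clip_bound = clip_bound,
       growth_threshold = growth_threshold,
       e_value_threshold = e_value_threshold, n_tests = n_tests)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipelineConfig()] (at least
#'   \code{input_dir}; other fields optional).
#' @return A config list (see [pipelineConfig()]).
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$input_dir))
  args <- y[intersect(names(y), names(formals(pipelineConfig)))]
  args$input_dir <- y$input_dir
  if (!is.null(y$ratio)) args$ratio <- unlist(y$ratio)
  do.call(pipelineConfig, args)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the five analysis stages in dependency order on one set of
#' input files: (1) NOG coverage of the metagenome collection by the focal
#' consortium and by stratified random consortia with percentile bands,
#' core-set identification and unique contributions; (2) growth-curve
#' normalization, channel averaging, AUC and growth calls; (3) peak
#' z-score profiles against fresh media; (4) the 18-scenario interaction
#' classification with cross-feeding, emergent-metabolism and competition
#' calls; (5) genetic vs metabolic Jaccard distances and NOG-metabolite
#' Spearman correlations.  Multi-category NOGs are discarded at analysis
#' entry.  Identical config (including seed) yields identical results.
#'
#' @param config list from [pipelineConfig()] / [readPipelineConfig()], or
#'   a path to a YAML config file.
#' @return Invisibly, a list with components \code{coverage},
#'   \code{growth}, \code{profiles}, \code{interactions},
#'   \code{distances} and \code{manifest}.  If \code{config$out_dir} is
#'   set, result tables and \code{manifest.json} are also written there.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  inp <- config$inputs
  for (f in unlist(inp))
    if (!file.exists(f)) stop("input file missing: ", f)

  ## stage 1: coverage ------------------------------------------------
  catalog <- readNogCatalog(inp$catalog)
  species <- readAnnotationPairs(inp$species_annotations)
  metagenome_sets <- readAnnotationPairs(inp$metagenome_annotations)
  pool_phyla_df <- utils::read.delim(inp$pool_phyla,
                                     stringsAsFactors = FALSE)
  pool_phyla <- stats::setNames(pool_phyla_df$phylum,
                                pool_phyla_df$species_id)
  pool_sets <- readAnnotationPairs(inp$pool_annotations,
                                   phyla = pool_phyla)

  keep_single <- function(s) discardMulticategory(s, catalog)
  sp_sets <- lapply(nogSets(species), keep_single)
  mg_sets <- lapply(nogSets(metagenome_sets), keep_single)
  pl_sets <- lapply(nogSets(pool_sets), keep_single)
  collection <- MetagenomeCollection(mg_sets)
  n_samp <- nSamples(collection)

  freq <- sampleFrequency(collection)
  core <- coreNogs(freq, n_samp)
  focal_cov <- coverageByFrequency(sp_sets, collection)
  uniq <- uniqueContributions(sp_sets, core, catalog)

  pools <- split(names(pool_phyla), pool_phyla)
  null_model <- lapply(stats::setNames(config$sizes, config$sizes),
                       function(size) {
    strata <- scaleStrata(size, config$ratio)
    draws <- drawConsortia(pools, strata, config$n_draws,
                           seed = config$seed + size)
    covs <- lapply(draws, function(ids)
      coverageByFrequency(pl_sets[ids], collection))
    list(bands = percentileBands(covs),
         core_coverage = vapply(covs, function(cv)
           cv$percent[cv$bin == n_samp], numeric(1)))
  })

  coverage <- list(frequency = freq, core = core, focal = focal_cov,
                   unique_contributions = uniq, null_model = null_model)

  ## stage 2: growth --------------------------------------------------
  growth <- summariseGrowth(
    utils::read.csv(inp$growth_curves, stringsAsFactors = FALSE),
    utils::read.csv(inp$calibration, stringsAsFactors = FALSE),
    utils::read.csv(inp$conditions, stringsAsFactors = FALSE),
    threshold_percent = config$growth_threshold)

  ## stage 3: profiles ------------------------------------------------
  pe <- readPeakTable(inp$peaks)
  profiles <- abundanceProfiles(pe, threshold = config$z_threshold)

  ## stage 4: interaction classification -------------------------------
  records <- buildComparisonRecords(profiles, growth)
  tab <- tabulateTransitions(records)
  fresh_calls <- data.frame(
    species = sub("^spent", "",
                  profiles$condition_id[grepl("^spent",
                                              profiles$condition_id)]),
    peak_id = profiles$peak_id[grepl("^spent", profiles$condition_id)],
    call = profiles$call[grepl("^spent", profiles$condition_id)],
    stringsAsFactors = FALSE)
  interactions <- list(
    records = records, table = tab, summary = interactionSummary(tab),
    cross_feeding = detectCrossFeeding(records),
    emergent = detectEmergent(records, fresh_calls),
    competition = competitionMarkers(fresh_calls))

  ## stage 5: distances -----------------------------------------------
  growers <- unique(fresh_calls$species)
  met_sets <- lapply(stats::setNames(growers, growers), function(s)
    metabolicProfileSet(
      profiles[profiles$condition_id == paste0("spent", s), ],
      threshold = config$z_threshold))
  gen_sets <- sp_sets[growers]
  dists <- pairwiseDistances(gen_sets, met_sets)

  all_nogs <- sort(unique(unlist(gen_sets, use.names = FALSE)))
  presence <- vapply(gen_sets, function(s) all_nogs %in% s,
                     logical(length(all_nogs)))
  presence <- t(presence) * 1  # species x NOGs
  colnames(presence) <- all_nogs
  peak_ids <- unique(profiles$peak_id)
  zmat <- vapply(growers, function(s) {
    pr <- profiles[profiles$condition_id == paste0("spent", s), ]
    pr$z[match(peak_ids, pr$peak_id)]
  }, numeric(length(peak_ids)))
  zmat <- t(zmat)
  colnames(zmat) <- peak_ids
  corr <- nogMetaboliteCorrelation(presence, zmat,
                                   n_tests = config$n_tests)
  activity <- vapply(peak_ids, function(p) sum(vapply(met_sets,
    function(ms) any(startsWith(ms, paste0(p, "|"))), logical(1))),
    integer(1))
  names(activity) <- peak_ids
  corr_informative <- filterInformative(corr, presence, activity)
  distances <- list(pairs = dists, correlations = corr,
                    informative = corr_informative)

  manifest <- list(
    package_version = as.character(utils::packageVersion("asfscreen")),
    seed = config$seed, sizes = config$sizes, n_draws = config$n_draws,
    ratio = as.list(config$ratio), z_threshold = config$z_threshold,
    clip_bound = config$clip_bound,
    growth_threshold = config$growth_threshold,
    e_value_threshold = config$e_value_threshold,
    n_tests = attr(corr, "n_tests"),
    n_metagenome_samples = n_samp,
    sd_convention = "sample SD, n-1 denominator",
    call_convention = "High: z > t; Low: z < -t; strict inequalities",
    growth_boundary = "grew at exactly the threshold (inclusive)",
    percentile_convention = attr(null_model[[1L]]$bands,
                                 "percentile_convention"),
    emergent_rule = paste("behavior in double-spent vs grower's",
                          "fresh-media behavior; growth required"))

  result <- list(coverage = coverage, growth = growth,
                 profiles = profiles, interactions = interactions,
                 distances = distances, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    o <- function(f) file.path(config$out_dir, f)
    utils::write.csv(focal_cov, o("coverage_focal.csv"),
                     row.names = FALSE)
    for (size in names(null_model))
      utils::write.csv(null_model[[size]]$bands,
                       o(sprintf("coverage_bands_size%s.csv", size)),
                       row.names = FALSE)
    utils::write.csv(growth, o("growth_summary.csv"), row.names = FALSE)
    utils::write.csv(profiles, o("profiles.csv"), row.names = FALSE)
    writeInteractionTable(tab, o("interaction_table.csv"))
    calls <- rbind(interactions$cross_feeding, interactions$emergent)
    utils::write.csv(calls[, c("donor", "grower", "peak_id", "call")],
                     o("interaction_calls.csv"), row.names = FALSE)
    utils::write.csv(dists, o("distances.csv"), row.names = FALSE)
    utils::write.csv(corr_informative, o("correlations_informative.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, o("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
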