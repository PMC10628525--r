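#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the published
#' defaults: 10 mm peritumoral thickness, gray levels
#' `{8, 16, 32, 64, 256}`, a 2:1 stratified split, univariate selection
#' at dual-cohort AUC 0.70, multivariate flagging at 0.75.
#'
#' @param simulate `NULL`, or a list of [cohort_config()] arguments; when
#'   set the cohort is generated rather than read.
#' @param manifest path to a cohort `manifest.csv` (ignored when
#'   `simulate` is set).
#' @param thickness_mm peritumoral thickness (mm). Default 10.
#' @param gray_levels gray-level counts. Default `c(8, 16, 32, 64, 256)`.
#' @param split_ratio train:test ratio. Default `c(2, 1)`.
#' @param univariate_threshold dual-cohort screening AUC. Default 0.70.
#' @param multivariate_threshold model flag AUC. Default 0.75.
#' @param model_suite `"default"` (the 20 published models) or a
#'   character vector of model names.
#' @param seed master seed for the split, CV folds and simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, manifest = NULL,
                            thickness_mm = 10,
                            gray_levels = c(8, 16, 32, 64, 256),
                            split_ratio = c(2, 1),
                            univariate_threshold = 0.70,
                            multivariate_threshold = 0.75,
                            model_suite = "default", seed = 1L) {
  stopifnot(univariate_threshold > 0.5, univariate_threshold < 1,
            multivariate_threshold > 0.5, multivariate_threshold < 1,
            all(gray_levels >= 2))
  if (is.null(simulate) && is.null(manifest))
    stop("provide either a `simulate` block or a cohort `manifest`")
  structure(list(simulate = simulate, manifest = manifest,
                 thickness_mm = thickness_mm,
                 gray_levels = as.integer(gray_levels),
                 split_ratio = split_ratio,
                 univariate_threshold = univariate_threshold,
                 multivariate_threshold = multivariate_threshold,
                 model_suite = model_suite, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate/ingest -> peritumoral ring generation -> 310-feature
#' extraction (both regions x 3 time points) -> delta assembly ->
#' stratified split -> univariate screen -> multivariate model suite ->
#' interreader reliability (when second-reader masks are present). All
#' stage tables are written as CSV under `out_dir` together with a
#' machine-readable run manifest (`run_manifest.json`) and a log.
#'
#' @param config a [pipeline_config()] or path to a JSON file of its
#'   fields.
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the in-memory stage results
#'   (`features`, `split`, `screen`, `suite`, `reliability`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    cfg <- do.call(pipeline_config, cfg)
  } else cfg <- config
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) cat(paste0(format(Sys.time(), "%H:%M:%S "),
                                       ..., "\n"),
                                file = logf, append = TRUE)

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    ccfg <- do.call(cohort_config, sim_args)
    cohort <- generate_cohort(ccfg)
    log_line("simulate: ", length(cohort), " subjects")
  } else {
    cohort <- read_cohort(cfg$manifest)
    log_line("ingest: ", length(cohort), " subjects from ", cfg$manifest)
  }

  table <- cohort_feature_table(cohort, cfg$thickness_mm, cfg$gray_levels)
  utils::write.csv(table, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  log_line("features: ", nrow(table), " subjects x ",
           length(.feature_cols(table)), " columns")

  split <- stratified_split(table$response, seed = cfg$seed,
                            ratio = cfg$split_ratio)
  jsonlite::write_json(split, file.path(out_dir, "split.json"),
                       auto_unbox = TRUE)
  log_line("split: ", length(split$train), " train / ",
           length(split$test), " test")

  screen <- screen_features(table, split,
                            threshold = cfg$univariate_threshold)
  utils::write.csv(screen, file.path(out_dir, "screen.csv"),
                   row.names = FALSE)
  log_line("screen: ", sum(screen$selected), " features selected at AUC >= ",
           cfg$univariate_threshold)

  specs <- if (identical(cfg$model_suite, "default")) default_model_suite()
  else lapply(cfg$model_suite, parse_model_name)
  suite <- run_model_suite(specs, table, split, seed = cfg$seed,
                           threshold = cfg$multivariate_threshold)
  utils::write.csv(suite, file.path(out_dir, "model_suite.csv"),
                   row.names = FALSE)
  log_line("models: ", sum(suite$flagged), "/", nrow(suite),
           " flagged at dual AUC >= ", cfg$multivariate_threshold)

  reliability <- NULL
  if (!is.null(cohort[[1]]$reader2_masks)) {
    reliability <- interreader_analysis(cohort, cfg$thickness_mm,
                                        cfg$gray_levels)
    utils::write.csv(
      data.frame(feature = names(reliability$pearson),
                 pearson_r = unname(reliability$pearson),
                 p_signed_rank = unname(reliability$signed_rank_p),
                 variance_ratio = if (is.null(reliability$variance_ratio))
                   NA_real_ else unname(reliability$variance_ratio),
                 stringsAsFactors = FALSE),
      file.path(out_dir, "reliability.csv"), row.names = FALSE)
    utils::write.csv(reliability$summary,
                     file.path(out_dir, "reliability_summary.csv"),
                     row.names = FALSE)
    log_line("reliability: ", length(reliability$pearson), " features")
  }

  manifest <- list(
    config = unclass(cfg), seed = cfg$seed,
    n_subjects = nrow(table),
    conventions = attr(extract_features(
      array(stats::rnorm(8^3), dim = c(8, 8, 8)),
      array(1L, dim = c(8, 8, 8)), gray_levels = c(8L)), "conventions"),
    package_version = as.character(utils::packageVersion("deltaradiomics")))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(features = table, split = split, screen = screen,
                 suite = suite, reliability = reliability,
                 out_dir = out_dir))
}
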