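#' Pipeline configuration
#'
#' Validates paths and settings for an end-to-end run: isotope prep ->
#' mixing-model fit -> conventional analysis -> method comparison.
#'
#' @param consumers,sources,tef,remains input CSV paths (see the
#'   `read_*` functions for the expected columns).  `remains` may be
#'   `NULL` to skip the conventional and comparison stages.
#' @param outdir output directory (created if needed).
#' @param n_chains,n_iter,n_burnin,rhat_threshold mixing-model settings,
#'   see [mixing_model_spec()].
#' @param kappa_weighting,icc_type,n_draws comparison settings, see
#'   [compare_methods()].
#' @param exclude_others renormalize conventional proportions over the
#'   five modelled categories before comparing (default TRUE).
#' @param variance source-aggregation variance form, see
#'   [aggregate_sources()].
#' @param write_draws also write the full posterior draws in long CSV
#'   format (large; default FALSE).
#' @param seed master seed for fit and comparison.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(consumers, sources, tef, remains = NULL,
                            outdir = ".", n_chains = 4L, n_iter = 10000L,
                            n_burnin = 1000L, rhat_threshold = 1.1,
                            kappa_weighting = "linear", icc_type = "oneway",
                            n_draws = 1000L, exclude_others = TRUE,
                            variance = "mixture", write_draws = FALSE,
                            seed = 1L) {
  paths <- c(consumers = consumers, sources = sources, tef = tef)
  if (!is.null(remains)) paths <- c(paths, remains = remains)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_input("input file(s) not found: ", paste(missing, collapse = ", "))
  kappa_weighting <- match.arg(kappa_weighting, c("linear", "quadratic"))
  icc_type <- match.arg(icc_type, c("oneway", "agreement"))
  variance <- match.arg(variance, c("mixture", "stratified_mean"))
  structure(list(consumers = consumers, sources = sources, tef = tef,
                 remains = remains, outdir = outdir,
                 n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 rhat_threshold = rhat_threshold,
                 kappa_weighting = kappa_weighting, icc_type = icc_type,
                 n_draws = as.integer(n_draws),
                 exclude_others = isTRUE(exclude_others),
                 variance = variance, write_draws = isTRUE(write_draws),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_out <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full dual-method pipeline
#'
#' Executes prep -> fit -> conventional -> compare, writing every stage's
#' output CSV plus a JSON run manifest (settings, seed, R-hat summary,
#' package version) under `config$outdir`.  Inputs are never modified;
#' rerunning with the same config and seed reproduces the summary files
#' byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return named list of written file paths, invisibly; the manifest
#'   records convergence flags.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- list()

  # prep
  samples <- read_consumers(config$consumers)
  consumers <- average_siblings(samples)
  sources <- read_sources(config$sources, variance = config$variance)
  tef <- read_tef(config$tef)
  written$consumers <- write_out(consumers, config$outdir, "consumer_observations.csv")

  # fit
  spec <- mixing_model_spec(sources, tef, consumers,
                            n_chains = config$n_chains, n_iter = config$n_iter,
                            n_burnin = config$n_burnin, seed = config$seed,
                            rhat_threshold = config$rhat_threshold)
  post <- sample_posterior(spec)
  fit_sum <- summarize_posterior(post)
  written$fit_summary <- write_out(fit_sum, config$outdir, "fit_summary.csv")
  written$population_sia <- write_out(population_diet_summary(fit_sum),
                                      config$outdir, "population_sia.csv")
  if (config$write_draws)
    written$draws <- write_out(draws_long(post), config$outdir, "draws_long.csv")

  manifest <- list(
    package = "vulturediet",
    version = as.character(utils::packageVersion("vulturediet")),
    seed = config$seed,
    settings = config[c("n_chains", "n_iter", "n_burnin", "rhat_threshold",
                        "kappa_weighting", "icc_type", "n_draws",
                        "exclude_others", "variance")],
    rhat_max = max(fit_sum$rhat, na.rm = TRUE),
    all_converged = all(fit_sum$converged))

  # conventional + compare
  if (!is.null(config$remains)) {
    remains <- read_remains(config$remains)
    category <- classify_remains(remains)
    known <- setdiff(unique(category), c("others", "undetermined"))
    mismatch <- setdiff(known, sources$name)
    if (length(mismatch))
      stop_input("remains classify to categories absent from the source table: ",
                 paste(mismatch, collapse = ", "))
    counts <- count_items(remains, category = category)
    written$counts <- write_out(counts, config$outdir, "conventional_counts.csv")
    props6 <- diet_proportions(counts, exclude_others = FALSE)
    written$proportions_six <- write_out(props6, config$outdir,
                                         "conventional_proportions_six.csv")
    props5 <- diet_proportions(counts, exclude_others = TRUE)
    written$proportions <- write_out(props5, config$outdir,
                                     "conventional_proportions.csv")
    written$population_conventional <-
      write_out(population_conventional_summary(
        if (config$exclude_others) props5 else props6),
        config$outdir, "population_conventional.csv")
    # the comparison is always five-category: the mixing model has no
    # 'others' source, so its proportions are only commensurable with
    # the renormalized conventional proportions
    report <- compare_methods(post, fit_sum, props5,
                              kappa_weighting = config$kappa_weighting,
                              icc_type = config$icc_type,
                              n_draws = config$n_draws, seed = config$seed)
    written$agreement <- write_out(report$by_category, config$outdir,
                                   "agreement_by_category.csv")
    written$p_below_0 <- write_out(report$per_nest, config$outdir,
                                   "p_below_0_per_nest.csv")
    manifest$n_paired <- nrow(report$paired)
  }

  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  written$manifest <- manifest_path
  invisible(written)
}

# Long-format posterior draws (consumer, chain, iter, source, value)
draws_long <- function(post) {
  out <- vector("list", length(post$draws))
  for (i in seq_along(post$draws)) {
    arr <- post$draws[[i]]
    d <- dim(arr)
    out[[i]] <- data.frame(
      territory_id = post$consumers$territory_id[i],
      year = post$consumers$year[i],
      chain = rep(seq_len(d[1]), times = d[2] * d[3]),
      iter = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      source = rep(post$source_names, each = d[1] * d[2]),
      value = as.vector(arr), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a simulated study to CSV files
#'
#' Writes consumers, remains, sources, TEF and ground-truth tables for a
#' [simulate_study()] result, in the formats the `read_*` functions
#' expect.
#'
#' @param study result of [simulate_study()].
#' @param outdir output directory.
#' @return named list of file paths, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    consumers = write_out(study$consumers, outdir, "consumers.csv"),
    sources = write_out(as.data.frame(study$sources), outdir, "sources.csv"),
    tef = write_out(data.frame(isotope = c("13C", "15N"),
                               mu = c(study$tef$mu13C, study$tef$mu15N),
                               sd = c(study$tef$sd13C, study$tef$sd15N)),
                    outdir, "tef.csv"),
    truth = write_out(as.data.frame(study$truth), outdir, "ground_truth.csv"))
  if (!is.null(study$remains))
    paths$remains <- write_out(study$remains, outdir, "remains.csv")
  invisible(paths)
}
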