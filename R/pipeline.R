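#' Configuration of an end-to-end synthetic run
#'
#' Collects every tunable of the pipeline: the envelope summarization
#' mode (`"WTS"` full-resolution envelope, `"AWE"` epoch-averaged
#' envelope), band definitions, epoching, region set, penalty-selection
#' and stability-selection controls, and named seeds for each stochastic
#' stage.
#'
#' @param mode `"WTS"` or `"AWE"`.
#' @param spec a [synthetic_spec()] describing the generated cohort.
#' @param epoch_seconds epoch duration (default 2.16 s).
#' @param drop_first_epochs initial epochs discarded (default 5).
#' @param grid penalty grid (`NULL` for the default).
#' @param n_perm permutations per penalty-selection call.
#' @param n_reps randomized-Lasso repetitions (0 skips the stability
#'   stage).
#' @param stability_band band used as predictor in the stability stage,
#'   or `"all"` to concatenate every band.
#' @param seeds named list of integer seeds: `generator`, `permutation`,
#'   `weights`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("WTS", "AWE"), spec = synthetic_spec(),
                       epoch_seconds = 2.16, drop_first_epochs = 5,
                       grid = NULL, n_perm = 25, n_reps = 0,
                       stability_band = "all",
                       seeds = list(generator = 1L, permutation = 2L,
                                    weights = 3L)) {
  mode <- match.arg(mode)
  if (epoch_seconds <= 0) abort("`epoch_seconds` must be positive.")
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!identical(stability_band, "all") &&
      !stability_band %in% names(spec$bands)) {
    abort(sprintf("Unknown band '%s'; available: %s.", stability_band,
                  paste(names(spec$bands), collapse = ", ")))
  }
  structure(list(mode = mode, spec = spec, epoch_seconds = epoch_seconds,
                 drop_first_epochs = drop_first_epochs, grid = grid,
                 n_perm = n_perm, n_reps = n_reps,
                 stability_band = stability_band, seeds = seeds),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Generates a coupled cohort, extracts band-limited-power envelope
#' series (bandpass, Hilbert envelope, WTS or AWE summarization with
#' initial-epoch exclusion), estimates shrinkage covariances and
#' normalized precisions for both modalities, assembles edge datasets,
#' evaluates leave-one-out bidirectional prediction per band, and (when
#' `n_reps > 0`) runs randomized-Lasso stability selection. All artifacts
#' are written under `out_dir` with a manifest; the run is deterministic
#' given the configuration seeds.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with `edge_datasets` (per band plus
#'   `slow`), `connectomes`, `evaluation` (per-band `distance_report`s),
#'   `stability` (or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- config$spec
  spec$seed <- as.integer(config$seeds$generator)
  sim <- make_coupled_timeseries(spec)
  band_names <- names(spec$bands)

  conns <- list(slow = list())
  for (b in band_names) conns[[b]] <- list()
  for (s in seq_along(sim$subjects)) {
    sub <- sim$subjects[[s]]
    conns$slow[[s]] <- normalized_precision(shrinkage_covariance(sub$slow))
    for (b in band_names) {
      bp <- bandpass(sub$bands[[b]], spec$bands[[b]], band_name = b,
                     pad_seconds = config$epoch_seconds)
      env <- hilbert_envelope(bp)
      series <- if (config$mode == "AWE") {
        awe_series(env, config$epoch_seconds, config$drop_first_epochs)
      } else {
        wts_series(env, config$epoch_seconds, config$drop_first_epochs)
      }
      conns[[b]][[s]] <- normalized_precision(shrinkage_covariance(series))
    }
  }

  eds <- lapply(setNames(nm = c("slow", band_names)), function(b) {
    edge_dataset_from_connectomes(conns[[b]], band = b,
                                  modality = if (b == "slow") "slow" else "banded")
  })

  evaluation <- lapply(setNames(nm = band_names), function(b) {
    loo_predict(eds[[b]], eds$slow, grid = config$grid,
                n_perm = config$n_perm,
                seed = as.integer(config$seeds$permutation))
  })

  stability <- NULL
  if (config$n_reps > 0) {
    Xs <- if (identical(config$stability_band, "all")) {
      concat_bands(eds[band_names])
    } else {
      eds[[config$stability_band]]
    }
    sel <- select_penalties(Xs, eds$slow, grid = config$grid,
                            n_perm = config$n_perm,
                            seed = as.integer(config$seeds$permutation))
    stability <- randomized_scca(Xs, eds$slow, sel$c1, sel$c2,
                                 n_reps = config$n_reps,
                                 seed = as.integer(config$seeds$weights))
  }

  for (b in c("slow", band_names)) {
    write_edge_dataset(eds[[b]], file.path(out_dir, sprintf("edges_%s.tsv", b)))
  }
  for (b in band_names) {
    utils::write.table(evaluation[[b]], file.path(out_dir, sprintf("loo_%s.tsv", b)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    mode = config$mode, n_subjects = spec$n_subjects,
    n_regions = spec$n_regions, n_samples = spec$n_samples,
    sampling_rate = spec$sampling_rate,
    bands = lapply(spec$bands, as.numeric),
    coupling = spec$coupling, subject_dev = spec$subject_dev,
    epoch_seconds = config$epoch_seconds,
    drop_first_epochs = config$drop_first_epochs,
    seeds = config$seeds, n_perm = config$n_perm, n_reps = config$n_reps,
    files = list.files(out_dir))
  write_manifest(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(edge_datasets = eds, connectomes = conns,
                 evaluation = evaluation, stability = stability,
                 manifest = manifest))
}
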