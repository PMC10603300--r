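#' Write / read an EEG session as a plain-text archive
#'
#' The exact-precision interchange format: `signals.csv` (one column per
#' channel, microvolts), `events.csv` (trial table) and `meta.json`
#' (sampling rate, channel order). Unlike 16-bit integer exchange formats
#' this round-trips doubles exactly, which the pipeline's reproducibility
#' guarantees rely on.
#'
#' @param session an `eeg_session`.
#' @param dir archive directory (created if needed).
#' @return `write_eeg_archive()`: the directory, invisibly.
#' @export
write_eeg_archive <- function(session, dir) {
  stopifnot(inherits(session, "eeg_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(session$signals),
                     file.path(dir, "signals.csv"))
  data.table::fwrite(session$events, file.path(dir, "events.csv"))
  jsonlite::write_json(list(sfreq = session$sfreq, channels = session$channels),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_eeg_archive
#' @param expected_sfreq if given, reject archives recorded at any other
#'   sampling rate.
#' @param required_channels if given, reject archives missing any of these
#'   labels.
#' @return `read_eeg_archive()`: the `eeg_session`.
#' @export
read_eeg_archive <- function(dir, expected_sfreq = NULL,
                             required_channels = NULL) {
  for (f in c("signals.csv", "events.csv", "meta.json")) {
    if (!file.exists(file.path(dir, f))) {
      stop("EEG archive is missing ", file.path(dir, f), call. = FALSE)
    }
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (!is.null(expected_sfreq) && meta$sfreq != expected_sfreq) {
    stop("archive sampled at ", meta$sfreq, " Hz; expected ", expected_sfreq,
         " Hz (resample explicitly if intended)", call. = FALSE)
  }
  signals <- as.matrix(data.table::fread(file.path(dir, "signals.csv")))
  missing <- setdiff(required_channels, colnames(signals))
  if (length(missing) > 0L) {
    stop("archive lacks required channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  events <- as.data.frame(data.table::fread(file.path(dir, "events.csv")))
  structure(list(signals = signals[, meta$channels, drop = FALSE],
                 sfreq = meta$sfreq, channels = meta$channels,
                 events = events),
            class = "eeg_session")
}

#' Write a full simulated session to disk
#'
#' Emits the EEG archive plus `trajectories.csv` (long pen-sample table),
#' `ground_truth.csv` and `trials.csv`.
#'
#' @param session a `drawing_session` from [generate_session()].
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_session_archive <- function(session, dir) {
  stopifnot(inherits(session, "drawing_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_eeg_archive(session$eeg, file.path(dir, "eeg"))
  data.table::fwrite(trajectories_to_table(session$trajectories, session$trials),
                     file.path(dir, "trajectories.csv"))
  data.table::fwrite(session$truth, file.path(dir, "ground_truth.csv"))
  data.table::fwrite(session$trials, file.path(dir, "trials.csv"))
  invisible(dir)
}

#' Pipeline configuration
#'
#' Collects the stage parameters of a full run. `read_pipeline_config()`
#' loads the same structure from a YAML file; unknown keys are rejected.
#'
#' @param session a [session_config()] for the simulated session.
#' @param band_preset `"methods"` or `"results-variant"`, see
#'   [default_bands()].
#' @param n_iter split iterations for the network stage.
#' @param min_appearances required test appearances per trial (coverage),
#'   see [iterate_splits()].
#' @param train a [train_config()].
#' @param alpha significance threshold for the correlation reports.
#' @param n_perm permutations for the null bound of the comparison stage.
#' @param seed master seed for the analysis stages (the session keeps its
#'   own seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(session = session_config(),
                            band_preset = "methods",
                            n_iter = 50, min_appearances = 5L,
                            train = train_config(),
                            alpha = 0.01, n_perm = 2000, seed = 1L) {
  stopifnot(inherits(session, "session_config"),
            inherits(train, "train_config"))
  structure(list(session = session, band_preset = band_preset,
                 n_iter = n_iter, min_appearances = min_appearances,
                 train = train, alpha = alpha,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with (optional) top-level keys `session`, `train`,
#'   `band_preset`, `n_iter`, `alpha`, `n_perm`, `seed`; nested keys are
#'   passed to [session_config()] / [train_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("session", "train", "band_preset", "n_iter",
             "min_appearances", "alpha", "n_perm", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ses_args <- raw$session %||% list()
  if (!is.null(ses_args$coupling_strength)) {
    ses_args$coupling_strength <- unlist(ses_args$coupling_strength)
  }
  args <- list(
    session = do.call(session_config, ses_args),
    train = do.call(train_config, raw$train %||% list())
  )
  for (k in c("band_preset", "n_iter", "min_appearances", "alpha",
              "n_perm", "seed")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline on a simulated session
#'
#' simulate -> behaviour -> spectral -> coherence -> network -> evaluation.
#' All stage outputs are written as CSV under `out_dir` together with a
#' `manifest.json` recording package version, seeds and configuration, so a
#' rerun from the manifest reproduces every number exactly.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @param write_session also write the raw simulated session archive
#'   (large; off by default).
#' @return List with `behaviour`, `condition_summary`, `spectral`
#'   (ERD + features), `coherence`, `ann`, `reports`, `comparison`,
#'   `null_bound`, invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir,
                         write_session = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bands <- default_bands(cfg$band_preset)

  session <- generate_session(cfg$session)
  if (write_session) write_session_archive(session, file.path(out_dir, "session"))

  behaviour <- session$behaviour
  data.table::fwrite(behaviour, file.path(out_dir, "behaviour.csv"))
  condition_summary <- summarise_conditions(behaviour)
  data.table::fwrite(condition_summary, file.path(out_dir, "condition_summary.csv"))

  sp <- spectral_features(session$eeg, bands = bands)
  data.table::fwrite(sp$erd, file.path(out_dir, "erd.csv"))

  coh <- coherence_table(session$eeg, bands = bands)
  data.table::fwrite(coh$coherence, file.path(out_dir, "coherence.csv"))

  ci_tab <- data.frame(trial_id = behaviour$trial_id, ci = behaviour$ci)
  ann <- iterate_splits(sp$features, ci_tab$ci[match(colnames(sp$features),
                                                     as.character(ci_tab$trial_id))],
                        n_iter = cfg$n_iter, cfg = cfg$train, seed = cfg$seed,
                        min_appearances = cfg$min_appearances)
  data.table::fwrite(ann$predictions, file.path(out_dir, "ann_predictions.csv"))
  data.table::fwrite(ann$iterations, file.path(out_dir, "ann_iterations.csv"))

  reports <- list(
    erd = correlate_erd(sp$erd, ci_tab, alpha = cfg$alpha),
    coherence = correlate_coherence(coh$coherence, ci_tab, alpha = cfg$alpha),
    ann = evaluate_ann(ann$predictions, ci_tab, alpha = cfg$alpha)
  )
  data.table::fwrite(do.call(rbind, reports), file.path(out_dir, "correlations.csv"))
  comparison <- compare_approaches(reports)
  data.table::fwrite(comparison, file.path(out_dir, "comparison.csv"))

  uni_feats <- cbind(as.matrix(sp$erd[, setdiff(colnames(sp$erd),
                                                c("trial_id", "condition"))]),
                     as.matrix(coh$coherence[, setdiff(colnames(coh$coherence),
                                                       c("trial_id", "condition"))]))
  null_bound <- perm_null_max_abs_r(uni_feats, ci_tab$ci, n_perm = cfg$n_perm,
                                    seed = substream_seed(cfg$seed, "perm"))

  manifest <- list(
    package = "coupledraw",
    version = as.character(utils::packageVersion("coupledraw")),
    r_version = R.version.string,
    seed = cfg$seed,
    session_seed = cfg$session$seed,
    encoding_mode = cfg$session$encoding_mode,
    band_preset = cfg$band_preset,
    n_iter = cfg$n_iter,
    ann_mean_r = ann$mean_r,
    null_bound = null_bound
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(behaviour = behaviour, condition_summary = condition_summary,
                 spectral = sp, coherence = coh, ann = ann,
                 reports = reports, comparison = comparison,
                 null_bound = null_bound))
}
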