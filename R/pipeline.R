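#' Run the full analysis pipeline
#'
#' End-to-end orchestration on a synthetic (or previously written) cohort:
#' generate or read the cohort, fit the candidate state models and compare
#' them, reduce and average the winning model's group effects, compute the
#' decade-loss, variance-explained and brain-behaviour summaries, optionally
#' run leave-one-out group prediction, and write all artifacts plus a JSON
#' run manifest (config snapshot, seed, stage timings, file inventory with
#' checksums) to `out_dir`.
#'
#' @param config A [cohort_config()] (ignored when `subjects_path` and
#'   `visits_path` are supplied).
#' @param out_dir Output directory (created if needed).
#' @param subjects_path,visits_path Optional existing cohort tables to read
#'   instead of generating.
#' @param forms Candidate state models to compare.
#' @param skip_loo Skip the leave-one-out stage.
#' @param settings,peb_opts Passed to the fitting stages.
#' @return The run manifest (invisibly), also written as `manifest.json`.
#' @export
run_pipeline <- function(config = cohort_config(),
                         out_dir = "hdprog_run",
                         subjects_path = NULL, visits_path = NULL,
                         forms = c("constant_rate", "quadratic_rate",
                                   "dynamic", "dynamic_sigmoid"),
                         skip_loo = FALSE,
                         settings = vl_settings(),
                         peb_opts = peb_settings()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hdprog")),
    seed = config$seed,
    config = unclass(config[c("n_hd", "n_control", "time_window",
                              "noise_sd", "dynamics_form", "seed")]),
    stages = list(), outputs = list()
  )
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      .write_manifest(manifest, out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }
  out <- function(name) file.path(out_dir, name)
  wtsv <- function(df, name) {
    utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    manifest$outputs[[name]] <<- unname(tools::md5sum(out(name)))
  }

  cohort <- stage("cohort", {
    if (!is.null(subjects_path)) read_cohort(subjects_path, visits_path)
    else generate_cohort(config)
  })
  write_cohort(cohort, out("subjects.tsv"), out("visits.tsv"))
  for (f in c("subjects.tsv", "visits.tsv"))
    manifest$outputs[[f]] <- unname(tools::md5sum(out(f)))

  cmp <- stage("model_selection",
               select_state_model(cohort, settings = settings,
                                  forms = forms, keep_fits = TRUE))
  wtsv(data.frame(model = cmp$model_ids, F = cmp$free_energies,
                  prob = cmp$posterior_probs), "model_comparison.tsv")
  best <- cmp$model_ids[which.max(cmp$free_energies)]
  hier <- cmp$fits[[best]]

  bma <- stage("bma", bma_average(hier$peb))
  long <- expand.grid(parameter = rownames(bma$estimates),
                      covariate = colnames(bma$estimates),
                      stringsAsFactors = FALSE)
  long$estimate <- as.vector(bma$estimates)
  long$sd <- as.vector(bma$sd)
  long$Pp <- as.vector(bma$Pp)
  long$surviving <- as.vector(bma$surviving)
  wtsv(long, "bma.tsv")

  stage("summaries", {
    wtsv(decade_loss_summary(cohort), "decade_loss.tsv")
    if (best %in% c("dynamic")) {
      wtsv(variance_explained_over_time(cohort, fits = hier$fits),
           "r2_over_time.tsv")
      if (!is.null(cohort$visits$tms)) {
        bm <- behavior_fit_metrics(cohort, fits = hier$fits)
        wtsv(data.frame(channel = names(bm$r2), r2 = bm$r2,
                        r2_subject = bm$r2_subject,
                        decade_change = bm$decade_change),
             "behavior_metrics.tsv")
      }
    }
    NULL
  })

  if (!skip_loo) {
    loo <- stage("loo", loo_predict(cohort, "group",
                                    fits = hier$fits_pass1,
                                    peb_opts = peb_opts))
    wtsv(loo$table, "loo_group.tsv")
    manifest$loo <- list(accuracy = loo$accuracy, r = loo$r)
  }
  manifest$selected_model <- best
  manifest$free_energies <- stats::setNames(as.list(cmp$free_energies),
                                            cmp$model_ids)
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 2)
  .write_manifest(manifest, out_dir)
  invisible(manifest)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Read or write a cohort configuration as JSON
#'
#' The configuration file is a flat JSON object whose keys are the arguments
#' of [cohort_config()]; scalar fields are plain values, per-state maps are
#' named objects (state name to value), `true_decay` is an object with `hd`
#' and `control` maps, and `connectivity` is an array of two-element
#' `[source, target]` state-index pairs. Unknown keys are rejected. The seed
#' is always explicit in the file.
#'
#' @param path File path.
#' @param config A [cohort_config()] (for writing).
#' @return `read_cohort_config()` returns a validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$seed)) stop("config file must state an explicit seed")
  fill <- function(x) {
    # named per-state maps may be partial: missing states default to 0
    if (!is.null(names(x)) && all(names(x) %in% hd_state_names())) {
      full <- stats::setNames(numeric(28), hd_state_names())
      full[names(x)] <- unlist(x)
      full
    } else x
  }
  # JSON objects arrive as named lists; the config wants named vectors
  for (fld in c("visit_count_law", "control_visit_count_law", "cag_law",
                "behavior_targets", "behavior_baseline"))
    if (is.list(raw[[fld]])) raw[[fld]] <- unlist(raw[[fld]])
  for (fld in c("group_offset", "cag_slope"))
    if (!is.null(raw[[fld]])) raw[[fld]] <- fill(unlist(raw[[fld]]))
  if (!is.null(raw$true_decay))
    raw$true_decay <- lapply(raw$true_decay, function(v) fill(unlist(v)))
  if (!is.null(raw$connectivity))
    raw$connectivity <- matrix(unlist(raw$connectivity), ncol = 2,
                               byrow = TRUE)
  do.call(cohort_config, raw)
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  out <- unclass(config)
  out$behavior_weights <- NULL    # derived, not a config input
  out$region_labels <- NULL       # fixed by the package atlas
  out <- out[!vapply(out, is.null, logical(1))]
  # named vectors must serialize as JSON objects, not arrays
  named_flds <- c("visit_count_law", "control_visit_count_law", "cag_law",
                  "group_offset", "cag_slope", "behavior_targets",
                  "behavior_baseline")
  for (f in intersect(named_flds, names(out))) out[[f]] <- as.list(out[[f]])
  out$true_decay <- lapply(out$true_decay, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
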