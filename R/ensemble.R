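#' Run an ensemble of independent trajectories
#'
#' Simulates \code{n_runs} cells with seeds \code{base_seed + 0, 1,
#' ..., n_runs - 1}, so that any run can be regenerated in isolation
#' and ensembles are reproducible end to end.  A manifest capturing
#' everything needed to regenerate the ensemble bit-identically
#' (model hash, parameter snapshot, seeds, grid) is returned
#' alongside the trajectories.
#'
#' @param model A validated \code{ad_model}.
#' @param n_runs Number of runs (>= 1).
#' @param base_seed Integer; run i uses seed \code{base_seed + i - 1}.
#' @param grid_step Recording step in days.
#' @param experiment Label recorded in the manifest.
#' @return List with \code{trajectories} (list of
#'   \code{ad_trajectory}) and \code{manifest}.
#' @examples
#' ens <- run_ensemble(build_default_network(), n_runs = 2, base_seed = 1)
#' length(ens$trajectories)
#' @export
run_ensemble <- function(model, n_runs, base_seed, grid_step = 0.05,
                         experiment = model$name) {
  stopifnot(is.numeric(n_runs), n_runs >= 1, is.numeric(base_seed))
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  trajectories <- lapply(seeds, function(s) {
    tryCatch(simulate_trajectory(model, s, grid_step),
             error = function(e) stop("run with seed ", s, " failed: ",
                                      conditionMessage(e), call. = FALSE))
  })
  manifest <- list(
    experiment = experiment,
    model_name = model$name,
    model_hash = rlang::hash(model[c("species", "reactions",
                                     "parameters", "events", "horizon")]),
    parameters = as.list(parameter_values(model)),
    n_runs = as.integer(n_runs),
    base_seed = as.integer(base_seed),
    seeds = seeds,
    grid_step = grid_step,
    horizon = model$horizon,
    software_version = as.character(utils::packageVersion("adcycle")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  list(trajectories = trajectories, manifest = manifest)
}

# median over first-passage times with censoring: censored runs count
# as +Inf; an infinite median is reported as NA (censored)
censored_median <- function(x) {
  x[is.na(x)] <- Inf
  m <- median(x)
  if (is.finite(m)) m else NA_real_
}

#' Summarise an ensemble of trajectories
#'
#' Per-observable, per-time-point mean and standard deviation over
#' runs (sample sd, n-1 denominator; reported as 0 for a single run),
#' plus the end-of-run aggregate fractions and the median
#' first-passage times to plaque and tangle (NA when the median run
#' is censored).
#'
#' @param trajectories Non-empty list of \code{ad_trajectory} sharing
#'   one grid.
#' @param plan_name Label carried into the summary.
#' @return An object of class \code{ad_ensemble_summary}: list with
#'   \code{plan_name}, \code{grid}, \code{mean_series} and
#'   \code{sd_series} (observable x time matrices),
#'   \code{fraction_with_plaque_by_end},
#'   \code{fraction_with_tangle_by_end}, \code{median_first_plaque},
#'   \code{median_first_tangle}, \code{n_runs}.
#' @export
summarize_ensemble <- function(trajectories,
                               plan_name = trajectories[[1]]$model_name) {
  if (!length(trajectories)) stop("empty trajectory list", call. = FALSE)
  grid <- trajectories[[1]]$grid
  for (tr in trajectories) {
    if (!identical(tr$grid, grid))
      stop("trajectories do not share a common grid", call. = FALSE)
  }
  obs <- names(trajectories[[1]]$series)
  n <- length(trajectories)
  mean_series <- matrix(0, length(obs), length(grid),
                        dimnames = list(obs, NULL))
  sd_series <- mean_series
  for (o in obs) {
    mat <- vapply(trajectories, function(tr) tr$series[[o]],
                  numeric(length(grid)))
    mean_series[o, ] <- rowMeans(mat)
    sd_series[o, ] <- if (n > 1) apply(mat, 1, stats::sd) else 0
  }
  fp <- function(nm) vapply(trajectories, function(tr)
    if (nm %in% names(tr$first_passage)) tr$first_passage[[nm]]
    else NA_real_, 0)
  plaque_t <- fp("first_plaque")
  tangle_t <- fp("first_tangle")
  structure(list(
    plan_name = plan_name,
    grid = grid,
    mean_series = mean_series,
    sd_series = sd_series,
    fraction_with_plaque_by_end = mean(!is.na(plaque_t)),
    fraction_with_tangle_by_end = mean(!is.na(tangle_t)),
    median_first_plaque = censored_median(plaque_t),
    median_first_tangle = censored_median(tangle_t),
    n_runs = n
  ), class = "ad_ensemble_summary")
}

#' @export
print.ad_ensemble_summary <- function(x, ...) {
  cat("<ad_ensemble_summary> ", x$plan_name, " (n=", x$n_runs, ")\n",
      sep = "")
  end <- ncol(x$mean_series)
  key <- intersect(c("abeta_plaque", "tau_tangles", "total_p53"),
                   rownames(x$mean_series))
  if (length(key)) {
    cat("  end-of-run means:",
        paste(sprintf("%s=%.2f", key, x$mean_series[key, end]),
              collapse = " "), "\n")
  }
  cat(sprintf("  fraction with plaque=%.2f tangle=%.2f | median first plaque=%s tangle=%s\n",
              x$fraction_with_plaque_by_end,
              x$fraction_with_tangle_by_end,
              ifelse(is.na(x$median_first_plaque), "censored",
                     sprintf("%.2f d", x$median_first_plaque)),
              ifelse(is.na(x$median_first_tangle), "censored",
                     sprintf("%.2f d", x$median_first_tangle))))
  invisible(x)
}
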