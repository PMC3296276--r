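#' Apoptosis-threshold model
#'
#' Cell death is treated post hoc: a per-run p53 apoptosis threshold
#' is drawn from a normal distribution (default mean 600, variance
#' 50, i.e. sd about 7.1) and a run is considered dead from the
#' first recorded time its total p53 pool exceeds its threshold.
#' The variance is a variance (not an sd); both are configurable.
#'
#' @param mean Threshold mean (copy number; default 600).
#' @param variance Threshold variance (copy number squared; default 50).
#' @param floor Minimum admissible threshold after sampling (default 1).
#' @return An object of class \code{ad_threshold_model}.
#' @export
threshold_model <- function(mean = 600, variance = 50, floor = 1) {
  stopifnot(is.numeric(mean), length(mean) == 1L,
            is.numeric(variance), length(variance) == 1L,
            is.numeric(floor), length(floor) == 1L)
  if (!is.finite(mean) || mean <= 0) {
    stop("threshold mean must be positive", call. = FALSE)
  }
  if (is.na(variance) || variance < 0) {
    stop("threshold variance must be >= 0", call. = FALSE)
  }
  structure(list(mean = as.numeric(mean), variance = as.numeric(variance),
                 floor = as.numeric(floor)),
            class = "ad_threshold_model")
}

#' Sample apoptosis thresholds
#'
#' Draws from Normal(mean, sd = sqrt(variance)), clipped below at the
#' floor.  Reproducible under \code{set.seed}.
#'
#' @param model An [threshold_model()].
#' @param n Number of draws.
#' @return Numeric vector of thresholds, all \code{>= model$floor}.
#' @examples
#' set.seed(1); sample_threshold(threshold_model(), 3)
#' @export
sample_threshold <- function(model, n = 1) {
  stopifnot(inherits(model, "ad_threshold_model"))
  pmax(rnorm(n, model$mean, sqrt(model$variance)), model$floor)
}

#' First-passage time of total p53 across a threshold
#'
#' The earliest recording-grid time at which the run's total p53 pool
#' strictly exceeds the threshold ("exceeded" = strict inequality),
#' or NA if it never does within the horizon (censored).
#'
#' @param trajectory An \code{ad_trajectory} whose series include
#'   \code{total_p53}.
#' @param threshold Numeric threshold (copy number).
#' @return Grid time in days, or \code{NA_real_} when censored.
#' @examples
#' tr <- simulate_trajectory(build_default_network(), seed = 1)
#' first_passage_time(tr, 600)
#' @export
first_passage_time <- function(trajectory, threshold) {
  if (!"total_p53" %in% names(trajectory$series)) {
    stop("trajectory lacks the total_p53 observable", call. = FALSE)
  }
  i <- which(trajectory$series$total_p53 > threshold)
  if (length(i)) trajectory$grid[i[1]] else NA_real_
}

#' Threshold-based viability analysis over intervention conditions
#'
#' Post hoc and pure: never re-simulates.  For each condition, one
#' apoptosis threshold is drawn per run (from a stream seeded
#' independently of the trajectory seeds), the first-passage time of
#' total p53 across it found, and the percent-viable curve over the
#' shared grid computed as
#' \code{100 * (1 - deaths_by(t) / n_runs)}.
#'
#' @param condition_trajectories Named list: condition label -> list
#'   of \code{ad_trajectory} (all sharing one grid), e.g. built from
#'   [run_clearance_sweep()] output via \code{lapply(sweep,
#'   `[[`, "trajectories")}.
#' @param thresholds An [threshold_model()].
#' @param seed Integer seed for the threshold draws.
#' @return Named list of \code{ad_viability} objects: each has
#'   \code{condition}, \code{per_run} (data.frame with run seed,
#'   threshold, death_time, censored) and \code{viable_curve}
#'   (data.frame with time, percent_viable).
#' @export
viability_analysis <- function(condition_trajectories,
                               thresholds = threshold_model(),
                               seed = 1) {
  stopifnot(is.list(condition_trajectories),
            inherits(thresholds, "ad_threshold_model"))
  if (!length(condition_trajectories)) {
    stop("no conditions supplied", call. = FALSE)
  }
  grid <- NULL
  for (trs in condition_trajectories) {
    if (!length(trs)) stop("empty trajectory list", call. = FALSE)
    for (tr in trs) {
      if (is.null(grid)) grid <- tr$grid
      if (!identical(tr$grid, grid))
        stop("all conditions must share one recording grid",
             call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  out <- lapply(names(condition_trajectories), function(cond) {
    trs <- condition_trajectories[[cond]]
    n <- length(trs)
    thr <- sample_threshold(thresholds, n)
    death <- vapply(seq_len(n), function(i)
      first_passage_time(trs[[i]], thr[i]), 0)
    per_run <- data.frame(
      seed = vapply(trs, `[[`, 0L, "seed"),
      threshold = thr,
      death_time = death,
      censored = is.na(death))
    pct <- vapply(grid, function(t)
      100 * (1 - sum(!is.na(death) & death <= t) / n), 0)
    structure(list(condition = cond, per_run = per_run,
                   viable_curve = data.frame(time = grid,
                                             percent_viable = pct)),
              class = "ad_viability")
  })
  setNames(out, names(condition_trajectories))
}

#' @export
print.ad_viability <- function(x, ...) {
  n <- nrow(x$per_run)
  deaths <- sum(x$per_run$censored == FALSE)
  cat("<ad_viability> ", x$condition, ": ", deaths, "/", n,
      " deaths; end viability ",
      sprintf("%.1f%%", x$viable_curve$percent_viable[nrow(x$viable_curve)]),
      "\n", sep = "")
  invisible(x)
}
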