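#' Tidy long-format table of an ensemble's trajectories
#'
#' @param trajectories List of \code{ad_trajectory}.
#' @return data.frame with columns time, observable, count, run_id,
#'   seed.
#' @export
trajectories_table <- function(trajectories) {
  do.call(rbind, lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    obs <- names(tr$series)
    data.frame(
      time = rep(tr$grid, times = length(obs)),
      observable = rep(obs, each = length(tr$grid)),
      count = unlist(tr$series, use.names = FALSE),
      run_id = i,
      seed = tr$seed)
  }))
}

#' Tidy long-format table of an ensemble summary
#'
#' @param summary An \code{ad_ensemble_summary}.
#' @return data.frame with columns time, observable, mean, sd.
#' @export
summary_table <- function(summary) {
  obs <- rownames(summary$mean_series)
  data.frame(
    time = rep(summary$grid, times = length(obs)),
    observable = rep(obs, each = length(summary$grid)),
    mean = as.vector(t(summary$mean_series)),
    sd = as.vector(t(summary$sd_series)))
}

#' Write an experiment's artifacts to a directory
#'
#' Writes \code{summary.csv} (time x observable x mean x sd),
#' \code{trajectories.csv} (per-run long table),
#' \code{first_passage.csv}, and \code{manifest.json} (model hash,
#' parameter snapshot, seeds, software version).  All files are
#' deterministic: the same inputs produce byte-identical output.
#'
#' @param summary An \code{ad_ensemble_summary}.
#' @param trajectories List of \code{ad_trajectory} (defaults to the
#'   ones attached to the summary).
#' @param manifest Manifest list (defaults to the one attached).
#' @param out_dir Output directory; created if missing.  An existing
#'   non-empty directory is refused unless \code{overwrite = TRUE}.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(summary, trajectories = summary$trajectories,
                          manifest = summary$manifest, out_dir,
                          overwrite = FALSE) {
  stopifnot(inherits(summary, "ad_ensemble_summary"))
  if (dir.exists(out_dir) && length(dir(out_dir, all.files = FALSE)) &&
      !overwrite) {
    stop("output directory '", out_dir,
         "' is not empty (use overwrite = TRUE)", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("summary.csv", "trajectories.csv",
                                "first_passage.csv", "manifest.json"))
  write.csv(summary_table(summary), paths[1], row.names = FALSE)
  if (!is.null(trajectories)) {
    write.csv(trajectories_table(trajectories), paths[2],
              row.names = FALSE)
    get_fp <- function(tr, nm) {
      if (nm %in% names(tr$first_passage)) tr$first_passage[[nm]]
      else NA_real_
    }
    fp <- do.call(rbind, lapply(trajectories, function(tr)
      data.frame(seed = tr$seed,
                 first_plaque = get_fp(tr, "first_plaque"),
                 first_tangle = get_fp(tr, "first_tangle"))))
    write.csv(fp, paths[3], row.names = FALSE)
  }
  if (!is.null(manifest)) {
    # drop the wall-clock timestamp from the byte-determinism contract
    manifest$created <- NULL
    jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(paths)
}

#' Read a summary table back as mean/sd matrices
#'
#' Inverse of the \code{summary.csv} written by [write_outputs()];
#' integer series round-trip exactly.
#'
#' @param path Path to a \code{summary.csv}.
#' @return List with \code{grid}, \code{mean_series},
#'   \code{sd_series} in the same layout as an
#'   \code{ad_ensemble_summary}.
#' @export
read_summary_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  obs <- unique(df$observable)
  grid <- unique(df$time)
  mk <- function(col) {
    m <- matrix(NA_real_, length(obs), length(grid),
                dimnames = list(obs, NULL))
    for (o in obs) m[o, ] <- df[[col]][df$observable == o]
    m
  }
  list(grid = grid, mean_series = mk("mean"), sd_series = mk("sd"))
}

#' Write viability results
#'
#' Per-condition death-time table and a combined percent-viable curve
#' table (time, percent_viable, condition).
#'
#' @param viability Named list of \code{ad_viability} (from
#'   [viability_analysis()]).
#' @param out_dir Output directory; created if missing.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, the paths written.
#' @export
write_viability <- function(viability, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    stop("output directory '", out_dir,
         "' is not empty (use overwrite = TRUE)", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  deaths <- do.call(rbind, lapply(viability, function(v)
    cbind(condition = v$condition, v$per_run)))
  curves <- do.call(rbind, lapply(viability, function(v)
    cbind(v$viable_curve, condition = v$condition)))
  paths <- file.path(out_dir, c("death_times.csv", "viable_curves.csv"))
  write.csv(deaths, paths[1], row.names = FALSE)
  write.csv(curves, paths[2], row.names = FALSE)
  invisible(paths)
}

#' Serialise a model to a human-editable YAML document
#'
#' Round-trips losslessly through [read_model_yaml()].
#'
#' @param model A validated \code{ad_model}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_model_yaml <- function(model, path) {
  doc <- list(
    name = model$name,
    horizon = model$horizon,
    species = lapply(model$species, function(s)
      list(id = s$id, display_name = s$display_name,
           initial_count = s$initial_count,
           tags = as.list(s$tags))),
    parameters = lapply(model$parameters, function(p)
      list(id = p$id, value = p$value, description = p$description)),
    reactions = lapply(model$reactions, function(r)
      list(id = r$id,
           reactants = as.list(r$reactants),
           products = as.list(r$products),
           modifiers = as.list(r$modifiers),
           rate_parameter = r$rate_parameter,
           kinetics = r$kinetics)),
    events = lapply(model$events, function(e)
      list(fire_time = e$fire_time, parameter_id = e$parameter_id,
           action = e$action, operand = e$operand)))
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Read a model from its YAML serialisation
#'
#' @param path Path written by [write_model_yaml()] (or hand-edited
#'   in the same layout).
#' @return A validated \code{ad_model}.
#' @export
read_model_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  as_stoich <- function(x) {
    if (!length(x)) return(integer())
    setNames(as.integer(unlist(x)), names(x))
  }
  species <- lapply(doc$species, function(s)
    ad_species(s$id, s$display_name, s$initial_count,
               as.character(unlist(s$tags))))
  parameters <- lapply(doc$parameters, function(p)
    ad_parameter(p$id, p$value, p$description %||% ""))
  reactions <- lapply(doc$reactions, function(r)
    ad_reaction(r$id, as_stoich(r$reactants), as_stoich(r$products),
                as.character(unlist(r$modifiers)), r$rate_parameter,
                r$kinetics))
  events <- lapply(doc$events, function(e)
    timed_event(e$fire_time, e$parameter_id, e$action, e$operand))
  model_definition(doc$name, species, reactions, parameters, events,
                   doc$horizon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a trajectories table back into trajectory objects
#'
#' Inverse of the \code{trajectories.csv} written by
#' [write_outputs()].  The result carries the observable series, grid
#' and seed of each run (sufficient for [viability_analysis()] and
#' [summarize_ensemble()]); per-run first-passage times, if present in
#' \code{first_passage.csv} alongside, are attached too.
#'
#' @param path Path to a \code{trajectories.csv}.
#' @return List of \code{ad_trajectory} objects.
#' @export
read_trajectories_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  fp_path <- file.path(dirname(path), "first_passage.csv")
  fp_df <- if (file.exists(fp_path)) read.csv(fp_path) else NULL
  lapply(split(df, df$run_id), function(d) {
    obs <- unique(d$observable)
    grid <- unique(d$time)
    series <- lapply(obs, function(o) d$count[d$observable == o])
    names(series) <- obs
    seed <- d$seed[1]
    fp <- c(first_plaque = NA_real_, first_tangle = NA_real_)
    if (!is.null(fp_df) && seed %in% fp_df$seed) {
      row <- fp_df[match(seed, fp_df$seed), ]
      fp <- c(first_plaque = row$first_plaque, first_tangle = row$first_tangle)
    }
    structure(list(model_name = NA_character_, seed = seed, grid = grid,
                   counts = NULL, series = series, first_passage = fp),
              class = "ad_trajectory")
  })
}
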