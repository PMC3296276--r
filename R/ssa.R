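# compile an ad_model into the index-based form the C++ engine takes
compile_model <- function(model) {
  sp <- species_ids(model)
  ns <- length(sp)
  nr <- length(model$reactions)
  par_ids <- vapply(model$parameters, `[[`, "", "id")
  reactant_stoich <- matrix(0L, nr, ns, dimnames = list(NULL, sp))
  product_stoich <- matrix(0L, nr, ns, dimnames = list(NULL, sp))
  modifier_stoich <- matrix(0L, nr, ns, dimnames = list(NULL, sp))
  rate_idx <- integer(nr)
  for (r in seq_len(nr)) {
    rx <- model$reactions[[r]]
    if (length(rx$reactants))
      reactant_stoich[r, names(rx$reactants)] <- rx$reactants
    if (length(rx$products))
      product_stoich[r, names(rx$products)] <- rx$products
    for (m in rx$modifiers)
      modifier_stoich[r, m] <- modifier_stoich[r, m] + 1L
    rate_idx[r] <- match(rx$rate_parameter, par_ids) - 1L
  }
  ev <- model$events
  list(reactant_stoich = reactant_stoich,
       product_stoich = product_stoich,
       modifier_stoich = modifier_stoich,
       rate_idx = rate_idx,
       params = unname(parameter_values(model)),
       par_ids = par_ids,
       init = unname(as.numeric(initial_counts(model))),
       event_time = vapply(ev, `[[`, 0, "fire_time"),
       event_par = vapply(ev, function(e)
         match(e$parameter_id, par_ids) - 1L, 0L),
       event_action = vapply(ev, function(e)
         if (e$action == "set_value") 0L else 1L, 0L),
       event_operand = vapply(ev, `[[`, 0, "operand"))
}

# species whose first crossing of count >= 1 is recorded per run
fp_targets <- function(model) {
  c(first_plaque = "abeta_plaque", first_tangle = "tau_tangles")[
    c("abeta_plaque", "tau_tangles") %in% species_ids(model)]
}

#' Instantaneous state of a simulation
#'
#' Captures time, copy numbers, current parameter values and the
#' not-yet-fired timed events of a model; the unit moved forward by
#' [ssa_advance()].
#'
#' @param model A validated \code{ad_model}.
#' @return An object of class \code{ad_sim_state}.
#' @export
sim_state <- function(model) {
  structure(list(time = 0,
                 counts = as.numeric(initial_counts(model)),
                 param_values = parameter_values(model),
                 pending_events = model$events),
            class = "ad_sim_state",
            species = species_ids(model))
}

#' Mass-action propensity of a reaction
#'
#' The instantaneous firing rate given current copy numbers: the rate
#' constant times the number of distinct reactant tuples (for a
#' species at copy number n with stoichiometry m, the falling
#' factorial n(n-1)...(n-m+1)/m!; e.g. n(n-1)/2 for dimerisation),
#' times each modifier's copy number for modifier mass-action
#' kinetics.  Zero whenever any reactant count is below its
#' stoichiometry.
#'
#' @param reaction An [ad_reaction()].
#' @param state An [sim_state()] (or any list with named
#'   \code{counts}-compatible vector and \code{param_values}).
#' @return Non-negative numeric rate (per day).
#' @examples
#' m <- build_default_network()
#' propensity(m$reactions[[1]], sim_state(m))
#' @export
propensity <- function(reaction, state) {
  counts <- state$counts
  sp <- attr(state, "species")
  if (!is.null(sp)) names(counts) <- sp
  a <- as.numeric(state$param_values[[reaction$rate_parameter]])
  for (i in seq_along(reaction$reactants)) {
    s <- names(reaction$reactants)[i]
    m <- reaction$reactants[[i]]
    n <- counts[[s]]
    if (n < m) return(0)
    for (j in seq_len(m) - 1L) a <- a * (n - j)
    a <- a / factorial(m)
  }
  for (s in reaction$modifiers) a <- a * counts[[s]]
  max(a, 0)
}

#' Advance a simulation state by one transition
#'
#' One step of the Gillespie direct method with timed-event
#' interrupts: a waiting time tau ~ Exponential(total propensity) is
#' drawn and a candidate reaction selected proportionally to its
#' propensity; if the candidate firing time falls at or beyond the
#' next pending event, no reaction fires -- time jumps to the event,
#' the parameter change is applied and the drawn waiting time is
#' discarded (justified by memorylessness).  With zero total
#' propensity and no pending events the state advances to the
#' horizon.  This pure-R stepper is the reference semantics for the
#' compiled engine used by [simulate_trajectory()]; both consume the
#' same RNG stream and produce identical trajectories.
#'
#' @param state An [sim_state()].
#' @param model The \code{ad_model} being simulated.
#' @return List with elements \code{state} (the new
#'   \code{ad_sim_state}) and \code{fired} (a reaction id, an event
#'   label \code{"event:<parameter>@<time>"}, or \code{NA} when the
#'   state advanced to the horizon with nothing left to happen).
#' @export
ssa_advance <- function(state, model) {
  stopifnot(inherits(state, "ad_sim_state"))
  counts <- state$counts
  sp <- attr(state, "species")
  a <- vapply(model$reactions, propensity, 0, state = state)
  a0 <- sum(a)
  ev <- state$pending_events
  tev <- if (length(ev)) ev[[1]]$fire_time else Inf

  fire_event <- function(state) {
    e <- state$pending_events[[1]]
    state$time <- e$fire_time
    state$param_values[[e$parameter_id]] <-
      if (e$action == "set_value") e$operand
      else state$param_values[[e$parameter_id]] * e$operand
    state$pending_events <- state$pending_events[-1]
    list(state = state,
         fired = paste0("event:", e$parameter_id, "@", e$fire_time))
  }

  if (tev <= state$time) return(fire_event(state))
  if (a0 <= 0) {
    if (tev <= model$horizon) return(fire_event(state))
    state$time <- model$horizon
    return(list(state = state, fired = NA_character_))
  }
  u1 <- runif(1)
  tau <- -log(u1) / a0
  tcand <- state$time + tau
  if (tcand >= tev && tev <= model$horizon) return(fire_event(state))
  if (tcand > model$horizon) {
    state$time <- model$horizon
    return(list(state = state, fired = NA_character_))
  }
  u2 <- runif(1)
  target <- u2 * a0
  cum <- 0
  j <- length(a)
  for (r in seq_along(a)) {
    cum <- cum + a[r]
    if (target < cum) { j <- r; break }
  }
  rx <- model$reactions[[j]]
  names(counts) <- sp
  for (i in seq_along(rx$reactants)) {
    counts[[names(rx$reactants)[i]]] <-
      counts[[names(rx$reactants)[i]]] - rx$reactants[[i]]
  }
  for (i in seq_along(rx$products)) {
    counts[[names(rx$products)[i]]] <-
      counts[[names(rx$products)[i]]] + rx$products[[i]]
  }
  state$time <- tcand
  state$counts <- unname(counts)
  list(state = state, fired = rx$id)
}

trajectory_from_counts <- function(model, seed, grid, counts, fp) {
  rownames(counts) <- species_ids(model)
  obs <- model_observables(model)
  series <- lapply(obs, function(members) {
    if (length(members) == 1L) counts[members, ]
    else colSums(counts[members, , drop = FALSE])
  })
  structure(list(model_name = model$name, seed = seed, grid = grid,
                 counts = counts, series = series,
                 first_passage = fp),
            class = "ad_trajectory")
}

#' Simulate one cell (exact SSA trajectory)
#'
#' Runs the Gillespie direct method from time 0 to the model horizon,
#' firing timed events at their scheduled times, and records every
#' species on a fixed grid by piecewise-constant sampling (the value
#' at grid time t is the state after the last reaction or event at or
#' before t).  First-passage times to the first plaque and first
#' tangle are recorded at exact transition times (NA if never
#' reached).  The same (model, seed, grid_step) always yields a
#' bit-identical trajectory.
#'
#' @param model A validated \code{ad_model}.
#' @param seed Integer seed for this trajectory's RNG stream.
#' @param grid_step Recording step in days (default 0.05, about 240
#'   points over the 12-day horizon).
#' @return An object of class \code{ad_trajectory}: a list with
#'   \code{model_name}, \code{seed}, \code{grid}, \code{counts}
#'   (species x time matrix), \code{series} (named list of observable
#'   vectors, including \code{total_p53}), and \code{first_passage}
#'   (named numeric with \code{first_plaque}, \code{first_tangle};
#'   NA = censored).
#' @examples
#' tr <- simulate_trajectory(build_default_network(), seed = 1)
#' tr$first_passage
#' @export
simulate_trajectory <- function(model, seed, grid_step = 0.05) {
  stopifnot(inherits(model, "ad_model"), is.numeric(seed),
            length(seed) == 1L, is.finite(seed),
            is.numeric(grid_step), grid_step > 0)
  diag <- validate_network(model)
  if (any(diag$severity == "error")) {
    stop("invalid model: ", paste(diag$message[diag$severity == "error"],
                                  collapse = "; "), call. = FALSE)
  }
  cm <- compile_model(model)
  grid <- seq(0, model$horizon, by = grid_step)
  fpt <- fp_targets(model)
  fp_idx <- match(fpt, species_ids(model)) - 1L
  set.seed(as.integer(seed))
  res <- .ssa_simulate_cpp(cm$reactant_stoich, cm$product_stoich,
                           cm$modifier_stoich, cm$rate_idx, cm$params,
                           cm$init, cm$event_time,
                           as.integer(cm$event_par),
                           as.integer(cm$event_action), cm$event_operand,
                           model$horizon, grid, as.integer(fp_idx))
  fp <- setNames(as.numeric(res$first_passage), names(fpt))
  tr <- trajectory_from_counts(model, as.integer(seed), grid,
                               res$counts, fp)
  attr(tr, "final_params") <- setNames(res$final_params, cm$par_ids)
  attr(tr, "n_steps") <- res$n_steps
  tr
}

# pure-R twin of simulate_trajectory built on ssa_advance; only
# practical for small models, used to cross-check the compiled engine
simulate_trajectory_r <- function(model, seed, grid_step = 0.05) {
  grid <- seq(0, model$horizon, by = grid_step)
  sp <- species_ids(model)
  counts <- matrix(NA_real_, length(sp), length(grid))
  fpt <- fp_targets(model)
  fp <- setNames(rep(NA_real_, length(fpt)), names(fpt))
  set.seed(as.integer(seed))
  state <- sim_state(model)
  for (nm in names(fpt)) {
    if (state$counts[match(fpt[[nm]], sp)] >= 1) fp[[nm]] <- 0
  }
  gi <- 1L
  repeat {
    prev <- state$counts
    step <- ssa_advance(state, model)
    tnew <- step$state$time
    while (gi <= length(grid) && grid[gi] < tnew) {
      counts[, gi] <- prev
      gi <- gi + 1L
    }
    state <- step$state
    for (nm in names(fpt)) {
      if (is.na(fp[[nm]]) && state$counts[match(fpt[[nm]], sp)] >= 1)
        fp[[nm]] <- state$time
    }
    if (is.na(step$fired) || state$time >= model$horizon) break
  }
  while (gi <= length(grid)) {
    counts[, gi] <- state$counts
    gi <- gi + 1L
  }
  tr <- trajectory_from_counts(model, as.integer(seed), grid, counts, fp)
  attr(tr, "final_params") <- state$param_values
  tr
}

#' @export
print.ad_trajectory <- function(x, ...) {
  cat("<ad_trajectory> model=", x$model_name, " seed=", x$seed,
      " grid=[0, ", max(x$grid), "] x ", length(x$grid), "\n", sep = "")
  fp <- x$first_passage
  if (length(fp)) {
    cat("  first passage:",
        paste(names(fp), ifelse(is.na(fp), "censored",
                                sprintf("%.3f d", fp)),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
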