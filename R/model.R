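#' @useDynLib adcycle, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif setNames
#' @importFrom utils read.csv write.csv
NULL

VALID_TAGS <- c("p53_pool_member", "abeta_soluble", "aggregate", "damage",
                "signalling")

#' Define a molecular species
#'
#' A species is a pool of identical molecules tracked as a non-negative
#' integer copy number.  Tags mark the role a species plays in derived
#' observables (e.g. every species carrying \code{"p53_pool_member"}
#' contributes to the \code{total_p53} observable).
#'
#' @param id Short unique identifier (used in reactions and observables).
#' @param display_name Human-readable name; defaults to \code{id}.
#' @param initial_count Non-negative integer copy number at time zero.
#' @param tags Character vector of role labels; see \code{VALID_TAGS} in
#'   the package source for the recognised set.
#' @return An object of class \code{ad_species}.
#' @examples
#' ad_species("ROS", "reactive oxygen species", initial_count = 5,
#'            tags = "signalling")
#' @export
ad_species <- function(id, display_name = id, initial_count = 0,
                       tags = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(initial_count) != 1L || is.na(initial_count) ||
      initial_count < 0 || initial_count != round(initial_count)) {
    stop("initial_count for species '", id,
         "' must be a non-negative integer", call. = FALSE)
  }
  bad <- setdiff(tags, VALID_TAGS)
  if (length(bad)) {
    stop("unknown species tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(id = id, display_name = display_name,
                 initial_count = as.integer(initial_count),
                 tags = as.character(tags)),
            class = "ad_species")
}

#' Define a mass-action reaction
#'
#' Reactants and products are given as named integer vectors mapping
#' species ids to positive stoichiometries.  Modifiers scale the
#' propensity by their copy number but are neither consumed nor
#' produced (used to encode catalytic/activity effects such as
#' GSK3b_p53-driven amyloid-beta production).
#'
#' @param id Short unique identifier.
#' @param reactants Named integer vector (species id -> stoichiometry);
#'   empty for zero-order production.
#' @param products Named integer vector; empty for pure degradation.
#' @param modifiers Character vector of species ids.
#' @param rate_parameter Id of the rate-constant parameter.
#' @param kinetics Either \code{"mass_action"} or
#'   \code{"modifier_mass_action"} (the latter required when modifiers
#'   are present).
#' @return An object of class \code{ad_reaction}.
#' @examples
#' ad_reaction("oligomerisation", c(abeta_monomer = 2),
#'             c(abeta_oligomer = 1), rate_parameter = "k_oligo")
#' @export
ad_reaction <- function(id, reactants = integer(), products = integer(),
                        modifiers = character(), rate_parameter,
                        kinetics = if (length(modifiers))
                          "modifier_mass_action" else "mass_action") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(rate_parameter), length(rate_parameter) == 1L)
  kinetics <- match.arg(kinetics, c("mass_action", "modifier_mass_action"))
  as_stoich <- function(x, what) {
    if (length(x) == 0L) return(setNames(integer(), character()))
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("reaction '", id, "': ", what, " must be a named vector",
           call. = FALSE)
    }
    if (any(is.na(x)) || any(x <= 0) || any(x != round(x))) {
      stop("reaction '", id, "': ", what,
           " stoichiometries must be positive integers", call. = FALSE)
    }
    storage.mode(x) <- "integer"
    x
  }
  if (length(modifiers) && kinetics != "modifier_mass_action") {
    stop("reaction '", id,
         "': modifiers require kinetics = 'modifier_mass_action'",
         call. = FALSE)
  }
  structure(list(id = id,
                 reactants = as_stoich(reactants, "reactant"),
                 products = as_stoich(products, "product"),
                 modifiers = as.character(modifiers),
                 rate_parameter = rate_parameter,
                 kinetics = kinetics),
            class = "ad_reaction")
}

#' Define a rate-constant parameter
#'
#' Rate constants are expressed per day (first order / zero order) or
#' per molecule per day (second order).  Zero is a legal value: it is
#' how the ROS-production and GSK3beta/p53-binding blockades are
#' encoded.
#'
#' @param id Short unique identifier.
#' @param value Non-negative numeric rate constant.
#' @param description Free text.
#' @return An object of class \code{ad_parameter}.
#' @export
ad_parameter <- function(id, value, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.numeric(value), length(value) == 1L)
  if (is.na(value) || value < 0) {
    stop("parameter '", id, "' must have a non-negative value",
         call. = FALSE)
  }
  structure(list(id = id, value = as.numeric(value),
                 description = description),
            class = "ad_parameter")
}

#' Define a timed event
#'
#' A timed event is a scheduled, instantaneous change to one model
#' parameter during simulation (SBML timed-event semantics).  Each
#' event fires exactly once, at \code{fire_time} days.
#'
#' @param fire_time Simulation time (days) at which the event fires.
#' @param parameter_id Id of the parameter to change.
#' @param action \code{"set_value"} or \code{"multiply"}.
#' @param operand New value (\code{set_value}) or factor
#'   (\code{multiply}).
#' @return An object of class \code{ad_event}.
#' @examples
#' timed_event(8, "k_ab_clear", "multiply", 100)
#' @export
timed_event <- function(fire_time, parameter_id,
                        action = c("multiply", "set_value"), operand) {
  action <- match.arg(action)
  stopifnot(is.numeric(fire_time), length(fire_time) == 1L,
            is.character(parameter_id), length(parameter_id) == 1L,
            is.numeric(operand), length(operand) == 1L)
  if (is.na(fire_time) || fire_time < 0) {
    stop("event fire_time must be >= 0", call. = FALSE)
  }
  structure(list(fire_time = as.numeric(fire_time),
                 parameter_id = parameter_id, action = action,
                 operand = as.numeric(operand)),
            class = "ad_event")
}

#' Assemble a model definition
#'
#' Bundles species, reactions, parameters and timed events into a
#' validated reaction network with a simulation horizon.  Events are
#' stored sorted by firing time.
#'
#' @param name Model name (recorded in trajectories and manifests).
#' @param species List of [ad_species()] objects.
#' @param reactions List of [ad_reaction()] objects.
#' @param parameters List of [ad_parameter()] objects.
#' @param events List of [timed_event()] objects.
#' @param horizon Simulation horizon in days (default 12).
#' @return An object of class \code{ad_model}.
#' @seealso [build_default_network()], [validate_network()]
#' @export
model_definition <- function(name, species, reactions, parameters,
                             events = list(), horizon = 12) {
  stopifnot(is.list(species), is.list(reactions), is.list(parameters),
            is.list(events), is.numeric(horizon), length(horizon) == 1L,
            horizon > 0)
  if (length(events)) {
    events <- events[order(vapply(events, `[[`, 0, "fire_time"))]
  }
  model <- structure(list(name = as.character(name), species = species,
                          reactions = reactions, parameters = parameters,
                          events = events, horizon = as.numeric(horizon)),
                     class = "ad_model")
  diag <- validate_network(model)
  err <- diag[diag$severity == "error", , drop = FALSE]
  if (nrow(err)) {
    stop("invalid model '", name, "':\n  ",
         paste(err$message, collapse = "\n  "), call. = FALSE)
  }
  model
}

#' @export
print.ad_model <- function(x, ...) {
  cat("<ad_model> ", x$name, "\n", sep = "")
  cat("  species:    ", length(x$species), "\n", sep = "")
  cat("  reactions:  ", length(x$reactions), "\n", sep = "")
  cat("  parameters: ", length(x$parameters), "\n", sep = "")
  cat("  events:     ", length(x$events), "\n", sep = "")
  cat("  horizon:    ", x$horizon, " days\n", sep = "")
  invisible(x)
}

#' Species ids of a model
#' @param model An \code{ad_model}.
#' @return Character vector of species ids, in definition order.
#' @export
species_ids <- function(model) {
  vapply(model$species, `[[`, "", "id")
}

#' Initial copy numbers of a model
#' @param model An \code{ad_model}.
#' @return Named integer vector (species id -> initial count).
#' @export
initial_counts <- function(model) {
  setNames(vapply(model$species, `[[`, 0L, "initial_count"),
           species_ids(model))
}

#' Current parameter values of a model
#' @param model An \code{ad_model}.
#' @return Named numeric vector (parameter id -> value).
#' @export
parameter_values <- function(model) {
  setNames(vapply(model$parameters, `[[`, 0, "value"),
           vapply(model$parameters, `[[`, "", "id"))
}

#' Validate a reaction network
#'
#' Checks every structural invariant: unique ids, integer non-negative
#' initial counts, positive integer stoichiometries, resolvable
#' cross-references from reactions and events to species and
#' parameters, non-negative parameter values, and ordered event times.
#' Returns diagnostics rather than raising, so callers can report all
#' problems at once.
#'
#' @param model An \code{ad_model} (or a bare list with the same
#'   fields; useful for inspecting a model under construction).
#' @return A data.frame with columns \code{severity}
#'   (\code{"error"}/\code{"warning"}) and \code{message}; zero rows
#'   for a valid network.
#' @examples
#' nrow(validate_network(build_default_network()))  # 0
#' @export
validate_network <- function(model) {
  msgs <- character(); sev <- character()
  note <- function(severity, msg) {
    sev <<- c(sev, severity); msgs <<- c(msgs, msg)
  }
  sp_ids <- vapply(model$species, `[[`, "", "id")
  if (anyDuplicated(sp_ids)) {
    note("error", paste0("duplicate species id(s): ",
         paste(unique(sp_ids[duplicated(sp_ids)]), collapse = ", ")))
  }
  for (sp in model$species) {
    if (sp$initial_count < 0 || sp$initial_count != round(sp$initial_count))
      note("error", paste0("species '", sp$id,
           "': initial_count must be a non-negative integer"))
  }
  par_ids <- vapply(model$parameters, `[[`, "", "id")
  if (anyDuplicated(par_ids)) {
    note("error", paste0("duplicate parameter id(s): ",
         paste(unique(par_ids[duplicated(par_ids)]), collapse = ", ")))
  }
  for (pp in model$parameters) {
    if (is.na(pp$value) || pp$value < 0)
      note("error", paste0("parameter '", pp$id,
           "': value must be non-negative"))
  }
  rx_ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rx_ids)) {
    note("error", paste0("duplicate reaction id(s): ",
         paste(unique(rx_ids[duplicated(rx_ids)]), collapse = ", ")))
  }
  for (rx in model$reactions) {
    refs <- c(names(rx$reactants), names(rx$products), rx$modifiers)
    missing_sp <- setdiff(refs, sp_ids)
    if (length(missing_sp))
      note("error", paste0("reaction '", rx$id,
           "' references unknown species: ",
           paste(missing_sp, collapse = ", ")))
    if (!rx$rate_parameter %in% par_ids)
      note("error", paste0("reaction '", rx$id,
           "' references unknown parameter '", rx$rate_parameter, "'"))
    if (any(rx$reactants <= 0) || any(rx$products <= 0))
      note("error", paste0("reaction '", rx$id,
           "': stoichiometries must be positive integers"))
    if (length(rx$modifiers) && rx$kinetics != "modifier_mass_action")
      note("error", paste0("reaction '", rx$id,
           "': modifiers present but kinetics is not modifier_mass_action"))
  }
  ev_par <- vapply(model$events, `[[`, "", "parameter_id")
  missing_ev <- setdiff(ev_par, par_ids)
  if (length(missing_ev))
    note("error", paste0("event references unknown parameter(s): ",
         paste(missing_ev, collapse = ", ")))
  tt <- vapply(model$events, `[[`, 0, "fire_time")
  if (length(tt) && is.unsorted(tt))
    note("error", "events are not sorted by fire_time")
  if (any(tt < 0)) note("error", "event fire_time must be >= 0")
  data.frame(severity = sev, message = msgs, stringsAsFactors = FALSE)
}

#' Observables defined for a model
#'
#' Every species id is an identity observable; in addition
#' \code{total_p53} is the sum of all species tagged
#' \code{p53_pool_member} (the "total pool including bound and
#' ubiquitinated species" of the figure captions).
#'
#' @param model An \code{ad_model}.
#' @return Named list mapping observable name to the species ids summed.
#' @export
model_observables <- function(model) {
  obs <- lapply(species_ids(model), function(s) s)
  names(obs) <- species_ids(model)
  pool <- species_ids(model)[vapply(model$species, function(s)
    "p53_pool_member" %in% s$tags, TRUE)]
  if (length(pool)) obs$total_p53 <- pool
  obs
}

#' Evaluate an observable on a state
#'
#' @param state Named count vector (species id -> copy number), e.g.
#'   [initial_counts()] or one column of a trajectory.
#' @param observable Observable name; see [model_observables()].
#' @param model The \code{ad_model} the state belongs to (supplies the
#'   observable registry).
#' @return Non-negative integer total.
#' @examples
#' m <- build_default_network()
#' observable_total(initial_counts(m), "total_p53", m)
#' @export
observable_total <- function(state, observable, model) {
  obs <- model_observables(model)
  if (!observable %in% names(obs)) {
    stop("unknown observable '", observable, "'; valid observables: ",
         paste(names(obs), collapse = ", "), call. = FALSE)
  }
  members <- obs[[observable]]
  missing_sp <- setdiff(members, names(state))
  if (length(missing_sp)) {
    stop("state lacks species: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  sum(state[members])
}
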