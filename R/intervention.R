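#' Describe an intervention on the AD network
#'
#' Four kinds are supported, mirroring the in-silico experiments:
#' \describe{
#'   \item{clearance_boost}{Multiply the soluble-Abeta clearance rate
#'     constant by \code{fold_change} (default 100, i.e. two orders of
#'     magnitude) at \code{start_day}.  Day 0 edits the parameter
#'     directly; later days install a timed event.}
#'   \item{ros_block}{Set Abeta-mediated ROS production
#'     (\code{k_abeta_ros}) to zero from time 0, combined with a
#'     day-8 clearance boost.}
#'   \item{binding_block}{Set GSK3beta/p53 binding
#'     (\code{k_gsk_p53_bind}) to zero from time 0, combined with a
#'     day-8 clearance boost.}
#'   \item{none}{Identity (the no-intervention control).}
#' }
#'
#' @param kind Intervention kind.
#' @param start_day Day of the clearance boost (clearance_boost only).
#' @param fold_change Fold increase of the clearance rate (default 100).
#' @return An object of class \code{ad_intervention}.
#' @examples
#' intervention_spec("clearance_boost", start_day = 4)
#' @export
intervention_spec <- function(kind = c("none", "clearance_boost",
                                       "ros_block", "binding_block"),
                              start_day = NULL, fold_change = 100) {
  kind <- match.arg(kind)
  if (kind == "clearance_boost") {
    if (is.null(start_day) || !is.numeric(start_day) ||
        length(start_day) != 1L || is.na(start_day)) {
      stop("clearance_boost requires a numeric start_day", call. = FALSE)
    }
    if (!is.numeric(fold_change) || length(fold_change) != 1L ||
        is.na(fold_change) || fold_change <= 0) {
      stop("fold_change must be a positive number", call. = FALSE)
    }
  } else {
    start_day <- NULL
  }
  structure(list(kind = kind,
                 start_day = if (!is.null(start_day)) as.numeric(start_day),
                 fold_change = as.numeric(fold_change)),
            class = "ad_intervention")
}

# day-8 clearance boost layered under both blockades (the protocol of
# the blockade experiments)
BLOCKADE_CLEARANCE_DAY <- 8

#' Apply an intervention to a model
#'
#' Pure: returns a new model, leaving the input untouched.  A day-0
#' clearance boost multiplies \code{k_ab_clear} directly; a later
#' start day appends a \code{multiply} timed event.  The two blockades
#' zero their target parameter at time 0 and additionally apply a
#' day-8 clearance boost, matching the blockade experiment protocol.
#'
#' @param model A validated \code{ad_model} containing the parameters
#'   \code{k_ab_clear}, \code{k_abeta_ros} and \code{k_gsk_p53_bind}.
#' @param spec An [intervention_spec()].
#' @param boost_oligomer_clearance If \code{TRUE}, the clearance boost
#'   also applies to the oligomer-clearance rate (\code{k_ab2_clear});
#'   by default only monomer (soluble-form) removal is boosted.
#' @return A new validated \code{ad_model}.
#' @examples
#' m8 <- apply_intervention(build_default_network(),
#'                          intervention_spec("clearance_boost", 8))
#' length(m8$events)  # 1
#' @export
apply_intervention <- function(model, spec,
                               boost_oligomer_clearance = FALSE) {
  stopifnot(inherits(model, "ad_model"), inherits(spec, "ad_intervention"))
  if (spec$kind == "none") return(model)
  par_ids <- vapply(model$parameters, `[[`, "", "id")
  set_par <- function(m, id, value) {
    i <- match(id, par_ids)
    if (is.na(i)) stop("model lacks parameter '", id, "'", call. = FALSE)
    m$parameters[[i]]$value <- value
    m
  }
  get_par <- function(m, id) m$parameters[[match(id, par_ids)]]$value
  clear_targets <- c("k_ab_clear",
                     if (boost_oligomer_clearance) "k_ab2_clear")
  add_boost <- function(m, day, fold) {
    if (day < 0 || day > m$horizon) {
      stop("clearance_boost start_day must lie in [0, ", m$horizon, "]",
           call. = FALSE)
    }
    if (day == 0) {
      for (id in clear_targets) m <- set_par(m, id, get_par(m, id) * fold)
    } else {
      ev <- lapply(clear_targets, function(id)
        timed_event(day, id, "multiply", fold))
      m$events <- c(m$events, ev)
    }
    m
  }
  out <- model
  out <- switch(spec$kind,
    clearance_boost = add_boost(out, spec$start_day, spec$fold_change),
    ros_block = add_boost(set_par(out, "k_abeta_ros", 0),
                          BLOCKADE_CLEARANCE_DAY, spec$fold_change),
    binding_block = add_boost(set_par(out, "k_gsk_p53_bind", 0),
                              BLOCKADE_CLEARANCE_DAY, spec$fold_change))
  out$name <- paste0(model$name, "+", spec$kind,
                     if (spec$kind == "clearance_boost")
                       paste0("_day", spec$start_day))
  # re-validate (sorts events, checks invariants)
  model_definition(out$name, out$species, out$reactions, out$parameters,
                   out$events, out$horizon)
}
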