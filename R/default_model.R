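#' Default rate constants of the AD cycle model
#'
#' All first-order constants are per day; second-order constants per
#' molecule per day; zero-order constants in molecules per day.  The
#' set is calibrated so that the default ensemble reproduces the
#' qualitative behaviours of the modelled system: stochastic DNA
#' damage ignites the Abeta/ROS/p53/GSK3beta positive-feedback cycle
#' in the majority of 12-day runs (plaques and tangles in most cells,
#' none in a small minority, tangles preceding plaques), while a
#' 100-fold boost of soluble-Abeta clearance at day 0 keeps every run
#' aggregate-free with low p53.  See the methods vignette for the
#' calibration rationale.
#'
#' @return Named list of parameter descriptions and values.
#' @keywords internal
default_parameter_table <- function() {
  list(
    # p53 turnover (synthesis; Mdm2 capture -> ubiquitination ->
    # proteasomal degradation)
    k_syn_p53     = c(300,   "p53 synthesis (molecules/day)"),
    k_syn_p53_ab  = c(0.8,  "extra p53 synthesis per Abeta monomer (transcriptional induction)"),
    k_syn_mdm2    = c(90,    "Mdm2 synthesis (molecules/day)"),
    k_deg_mdm2    = c(1,     "Mdm2 degradation"),
    k_bind_mdm2   = c(0.5,   "p53 + Mdm2 association (per molecule/day)"),
    k_rel_mdm2    = c(0.5,   "p53-Mdm2 dissociation"),
    k_ub_p53      = c(10,    "ubiquitination of Mdm2-bound p53 (releases Mdm2)"),
    k_deg_p53_ub  = c(10,    "26S proteasomal degradation of ubiquitinated p53"),
    # oxidative stress and DNA damage response
    k_ros_basal   = c(1.6,    "basal ROS production (molecules/day)"),
    k_ros_decay   = c(10,    "ROS removal (antioxidant capacity)"),
    k_abeta_ros   = c(4,    "ROS production per Abeta monomer (blockade target)"),
    k_damage      = c(7.2,   "DNA lesion formation per ROS molecule"),
    k_repair      = c(6,     "DNA repair"),
    k_phos_p53    = c(2.5,   "p53 phosphorylation per lesion per p53 (stabilising; blocks Mdm2 binding)"),
    k_dephos_p53  = c(1,     "p53 dephosphorylation"),
    # GSK3beta / p53 module
    k_gsk_p53_bind = c(3e-3, "GSK3beta + phospho-p53 association (blockade target)"),
    k_gsk_p53_rel  = c(6,    "GSK3beta-p53 complex dissociation"),
    # amyloid-beta production, clearance, aggregation
    k_ab_basal    = c(0.3,     "basal Abeta monomer production (molecules/day)"),
    k_ab_prod     = c(100,    "Abeta production per GSK3b_p53 complex"),
    k_ab_prod_p53 = c(3,     "Abeta production per phospho-p53"),
    k_ab_clear    = c(6,     "soluble Abeta monomer clearance (intervention target)"),
    k_oligo       = c(8e-6,  "monomer dimerisation into oligomer (combinatoric)"),
    k_ab2_clear   = c(0.1,   "oligomer clearance"),
    k_plaque      = c(1e-3,  "oligomer pairing into plaque (combinatoric)"),
    # tau phosphorylation and aggregation
    k_tau_phos    = c(8e-4, "tau phosphorylation per active-kinase pair per tau (cooperative)"),
    k_tau_dephos  = c(1.5,   "tau dephosphorylation"),
    k_tangle      = c(1e-3,  "phospho-tau pairing into tangle (combinatoric)")
  )
}

#' Build the default Alzheimer's-disease reaction network
#'
#' Constructs the stochastic mass-action network linking amyloid-beta
#' and tau pathology through a positive-feedback cycle: Abeta raises
#' ROS, ROS damages DNA, DNA damage stabilises (phosphorylates) p53,
#' phospho-p53 binds GSK3beta, and the active complex drives both
#' further Abeta production and tau phosphorylation, closing the
#' cycle.  Aggregation is a three-tier Abeta chain (monomer ->
#' oligomer -> plaque) and irreversible pairing of phospho-tau into
#' tangles.  The horizon is 12 days; at time zero there are no
#' aggregates and no DNA damage, and the p53/Mdm2 module starts at its
#' unstressed basal level.
#'
#' @param overrides Optional named list/vector of parameter values to
#'   replace defaults (e.g. \code{list(k_abeta_ros = 0)} for the
#'   ROS-production blockade).  Unknown names are an error.
#' @param horizon Simulation horizon in days.
#' @return A validated \code{ad_model}.
#' @examples
#' m <- build_default_network()
#' m_block <- build_default_network(list(k_abeta_ros = 0))
#' @export
build_default_network <- function(overrides = NULL, horizon = 12) {
  tab <- default_parameter_table()
  vals <- vapply(tab, function(x) as.numeric(x[[1]]), 0)
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    unknown <- setdiff(names(overrides), names(vals))
    if (length(unknown)) {
      stop("unknown parameter override(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    vals[names(overrides)] <- as.numeric(overrides)
  }
  parameters <- Map(function(id, v)
    ad_parameter(id, vals[[id]], as.character(tab[[id]][[2]])),
    names(vals), vals)

  species <- list(
    ad_species("p53", "free p53", 10, tags = "p53_pool_member"),
    ad_species("p53_P", "phosphorylated p53", 0, tags = "p53_pool_member"),
    ad_species("p53_Mdm2", "p53-Mdm2 complex", 29, tags = "p53_pool_member"),
    ad_species("p53_Ub", "ubiquitinated p53", 29, tags = "p53_pool_member"),
    ad_species("Mdm2", "free Mdm2", 60),
    ad_species("GSK3b", "free GSK3beta", 300),
    ad_species("GSK3b_p53", "GSK3beta-p53 complex", 0,
               tags = c("p53_pool_member", "signalling")),
    ad_species("ROS", "reactive oxygen species", 0, tags = "signalling"),
    ad_species("damDNA", "unrepaired DNA lesions", 0, tags = "damage"),
    ad_species("abeta_monomer", "soluble Abeta monomer", 0,
               tags = "abeta_soluble"),
    ad_species("abeta_oligomer", "soluble Abeta oligomer", 0,
               tags = "abeta_soluble"),
    ad_species("abeta_plaque", "Abeta plaque", 0, tags = "aggregate"),
    ad_species("tau", "unphosphorylated tau", 1000),
    ad_species("tau_P", "phosphorylated tau", 0),
    ad_species("tau_tangles", "tau tangle", 0, tags = "aggregate")
  )

  rx <- function(...) ad_reaction(...)
  reactions <- list(
    # (1) p53 synthesis and Mdm2-mediated turnover
    rx("p53_synthesis", products = c(p53 = 1), rate_parameter = "k_syn_p53"),
    rx("p53_synthesis_abeta", products = c(p53 = 1),
       modifiers = "abeta_monomer", rate_parameter = "k_syn_p53_ab"),
    rx("mdm2_synthesis", products = c(Mdm2 = 1), rate_parameter = "k_syn_mdm2"),
    rx("mdm2_degradation", reactants = c(Mdm2 = 1),
       rate_parameter = "k_deg_mdm2"),
    rx("p53_mdm2_binding", reactants = c(p53 = 1, Mdm2 = 1),
       products = c(p53_Mdm2 = 1), rate_parameter = "k_bind_mdm2"),
    rx("p53_mdm2_release", reactants = c(p53_Mdm2 = 1),
       products = c(p53 = 1, Mdm2 = 1), rate_parameter = "k_rel_mdm2"),
    rx("p53_ubiquitination", reactants = c(p53_Mdm2 = 1),
       products = c(p53_Ub = 1, Mdm2 = 1), rate_parameter = "k_ub_p53"),
    rx("p53_proteasomal_degradation", reactants = c(p53_Ub = 1),
       rate_parameter = "k_deg_p53_ub"),
    # (2) oxidative stress, DNA damage, p53 activation
    rx("ros_basal_production", products = c(ROS = 1),
       rate_parameter = "k_ros_basal"),
    rx("ros_removal", reactants = c(ROS = 1), rate_parameter = "k_ros_decay"),
    rx("dna_damage", products = c(damDNA = 1), modifiers = "ROS",
       rate_parameter = "k_damage"),
    rx("dna_repair", reactants = c(damDNA = 1), rate_parameter = "k_repair"),
    rx("p53_phosphorylation", reactants = c(p53 = 1),
       products = c(p53_P = 1), modifiers = "damDNA",
       rate_parameter = "k_phos_p53"),
    rx("p53_dephosphorylation", reactants = c(p53_P = 1),
       products = c(p53 = 1), rate_parameter = "k_dephos_p53"),
    # (3) GSK3beta/p53 binding (blockade target)
    rx("gsk3_p53_binding", reactants = c(p53_P = 1, GSK3b = 1),
       products = c(GSK3b_p53 = 1), rate_parameter = "k_gsk_p53_bind"),
    rx("gsk3_p53_release", reactants = c(GSK3b_p53 = 1),
       products = c(p53_P = 1, GSK3b = 1), rate_parameter = "k_gsk_p53_rel"),
    # (4) Abeta production, clearance, aggregation
    rx("abeta_basal_production", products = c(abeta_monomer = 1),
       rate_parameter = "k_ab_basal"),
    rx("abeta_production_gsk", products = c(abeta_monomer = 1),
       modifiers = "GSK3b_p53", rate_parameter = "k_ab_prod"),
    rx("abeta_production_p53", products = c(abeta_monomer = 1),
       modifiers = "p53_P", rate_parameter = "k_ab_prod_p53"),
    rx("abeta_clearance", reactants = c(abeta_monomer = 1),
       rate_parameter = "k_ab_clear"),
    rx("abeta_oligomerisation", reactants = c(abeta_monomer = 2),
       products = c(abeta_oligomer = 1), rate_parameter = "k_oligo"),
    rx("oligomer_clearance", reactants = c(abeta_oligomer = 1),
       rate_parameter = "k_ab2_clear"),
    rx("plaque_formation", reactants = c(abeta_oligomer = 2),
       products = c(abeta_plaque = 1), rate_parameter = "k_plaque"),
    rx("abeta_ros_production", products = c(ROS = 1),
       modifiers = "abeta_monomer", rate_parameter = "k_abeta_ros"),
    # (5) tau phosphorylation and tangle formation
    # cooperative (pair) catalysis: hyperphosphorylation of the
    # pathological tau epitopes needs priming plus completion by two
    # active kinase complexes; the complexes are catalytic (restored
    # as products), giving propensity k * C(C-1)/2 * tau
    rx("tau_phosphorylation", reactants = c(tau = 1, GSK3b_p53 = 2),
       products = c(tau_P = 1, GSK3b_p53 = 2),
       rate_parameter = "k_tau_phos"),
    rx("tau_dephosphorylation", reactants = c(tau_P = 1),
       products = c(tau = 1), rate_parameter = "k_tau_dephos"),
    rx("tangle_formation", reactants = c(tau_P = 2),
       products = c(tau_tangles = 1), rate_parameter = "k_tangle")
  )

  model_definition("ad_cycle_default", species, reactions, parameters,
                   events = list(), horizon = horizon)
}

#' Default network with a disease-like elevated rate
#'
#' The default aggregation constants are set high enough that an
#' increase in tau phosphorylation or in Abeta production makes
#' aggregates appear within a few days; this helper builds that
#' elevated condition by multiplying one driving rate constant.
#'
#' @param which Which drive to elevate: \code{"abeta_production"}
#'   (multiplies the constitutive production constant
#'   \code{k_ab_basal}, as a familial overproduction mutation in APP
#'   processing would) or \code{"tau_phosphorylation"} (multiplies
#'   \code{k_tau_phos}).
#' @param fold Fold elevation; the calibrated defaults are 30 for the
#'   constitutive Abeta-production drive and 10 for the
#'   tau-phosphorylation drive.
#' @param ... Passed to [build_default_network()].
#' @return A validated \code{ad_model}.
#' @export
elevated_network <- function(which = c("abeta_production",
                                       "tau_phosphorylation"),
                             fold = NULL, ...) {
  which <- match.arg(which)
  if (is.null(fold)) fold <- switch(which, abeta_production = 30,
                                    tau_phosphorylation = 10)
  stopifnot(is.numeric(fold), length(fold) == 1L, fold > 0)
  pars <- switch(which,
                 abeta_production = "k_ab_basal",
                 tau_phosphorylation = "k_tau_phos")
  tab <- default_parameter_table()
  ov <- lapply(tab[pars], function(x) as.numeric(x[[1]]) * fold)
  m <- build_default_network(overrides = ov, ...)
  m$name <- paste0("ad_cycle_elevated_", which)
  m
}
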