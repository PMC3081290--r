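# Open-system (flow-coupled) simulation.  The clotting region exchanges
# every mobile species with an infinite plasma reservoir ("blood"):
#   dc_j/dt = F_j(c) + alpha * D_j * (c_j,blood - c_j)
# where alpha (cm^-2) is the general coupling constant set by blood flow
# and geometry and D_j is a diffusion-convection constant, identical for
# all transported species (5e-7 cm^2/s).  Species bound to immobile
# tissue or to the thrombus (TF, every TF complex, fibrin "Ia") are not
# transported.  alpha = 0 reduces exactly to the closed model.

#' Flow-coupling configuration
#'
#' @param alpha general coupling constant (cm^-2), >= 0
#' @param D diffusion-convection constant (cm^2/s), identical for all
#'   transported species
#' @param c_blood named vector of reservoir concentrations (mol/l);
#'   \code{NULL} uses the model's current initial state (undiluted plasma,
#'   attached drugs included) with all trigger species at zero
#' @export
flow_config <- function(alpha, D = 5e-7, c_blood = NULL) {
  stopifnot(alpha >= 0, D > 0)
  structure(list(alpha = alpha, D = D, c_blood = c_blood),
            class = "coag_flow_config")
}

#' Couple a model to the blood reservoir
#'
#' @param model a \code{coag_model}
#' @param flow a \code{\link{flow_config}}
#' @return the open-system model; with \code{alpha = 0} its trajectories
#'   are identical to the closed model's
#' @export
open_system <- function(model, flow) {
  stopifnot(inherits(model, "coag_model"), inherits(flow, "coag_flow_config"))
  cb <- flow$c_blood
  if (is.null(cb)) cb <- initial_state(model)
  missing_ <- setdiff(model$species$name, names(cb))
  full <- setNames(rep(0, nrow(model$species)), model$species$name)
  full[names(cb)] <- cb
  model$flow <- list(alpha = flow$alpha, D = flow$D, c_blood = full)
  model
}

#' In-vivo trigger scenarios
#'
#' The four physiologically plausible trigger scenarios: strong/weak
#' tissue-factor (extrinsic) and strong/weak factor XIIa (intrinsic)
#' activation.  The strong extrinsic trigger is safety relevant; the
#' other three probe efficacy.
#'
#' @param name one of \code{"extrinsic_strong"}, \code{"extrinsic_weak"},
#'   \code{"intrinsic_strong"}, \code{"intrinsic_weak"}
#' @return list with elements \code{name}, \code{TF} and \code{XIIa}
#'   (mol/l; exactly one non-zero)
#' @export
trigger_scenario <- function(name = c("extrinsic_strong", "extrinsic_weak",
                                      "intrinsic_strong", "intrinsic_weak")) {
  name <- match.arg(name)
  tab <- list(extrinsic_strong = c(TF = 1e-11, XIIa = 0),
              extrinsic_weak = c(TF = 1e-14, XIIa = 0),
              intrinsic_strong = c(TF = 0, XIIa = 1e-11),
              intrinsic_weak = c(TF = 0, XIIa = 1e-14))
  v <- tab[[name]]
  structure(list(name = name, TF = v[["TF"]], XIIa = v[["XIIa"]]),
            class = "coag_scenario")
}

#' Two-threshold clot decision rule
#'
#' A coagulation event is a crossing of either of two independent
#' thresholds, one on thrombin (factor IIa) and one on the fibrinogen
#' cleavage product (Ia), within the horizon.
#'
#' @param iia_threshold thrombin threshold (mol/l)
#' @param ia_threshold fibrin threshold (mol/l)
#' @param horizon decision horizon (s)
#' @export
clot_decision <- function(iia_threshold = 2e-9, ia_threshold = 100e-9,
                          horizon = 3600) {
  stopifnot(iia_threshold > 0, ia_threshold > 0, horizon > 0)
  structure(list(iia_threshold = iia_threshold, ia_threshold = ia_threshold,
                 horizon = horizon), class = "coag_clot_decision")
}

# Event-detecting integration: stops at the first crossing of any
# threshold; returns the crossing time (or NA) without storing a dense
# trajectory.
.simulate_clot <- function(model, horizon, thresholds,
                           rtol = 1e-8, atol = 1e-14, maxsteps = 100000L) {
  y0 <- initial_state(model)
  xp <- .compile_network(model)
  alpha <- if (is.null(model$flow)) 0 else model$flow$alpha
  idx <- match(names(thresholds), names(y0))
  if (anyNA(idx)) stop("unknown threshold species")
  func <- function(t, y, p) list(cn_rhs(xp, y, alpha))
  jacf <- function(t, y, p) cn_jac(xp, y, alpha)
  rootf <- function(t, y, p) y[idx] - thresholds
  out <- deSolve::lsodar(unname(y0), c(0, horizon), func, parms = NULL,
                         jacfunc = jacf, jactype = "fullusr",
                         rootfunc = rootf, rtol = rtol, atol = atol,
                         maxsteps = maxsteps)
  istate <- attr(out, "istate")[1]
  if (is.null(istate) || istate < 0)
    stop("stiff integration failed in clot detection (istate = ",
         istate, ")")
  troot <- attr(out, "troot")
  iroot <- attr(out, "indroot")
  if (is.null(troot) || !length(troot) || is.na(troot[1]))
    return(list(time = NA_real_, species = NA_character_))
  list(time = troot[1],
       species = names(thresholds)[if (!is.null(iroot)) iroot[1] else 1L])
}

#' Run an in-vivo trigger scenario
#'
#' Undiluted plasma initials plus the scenario trigger, coupled to the
#' blood reservoir at strength \code{alpha}, with the two-threshold clot
#' decision.  "No clot" within the horizon is a valid outcome, not an
#' error.
#'
#' @param model the base \code{coag_model}
#' @param scenario a \code{\link{trigger_scenario}}
#' @param drug optional \code{\link{drug_state}}
#' @param warfarin optional \code{\link{warfarin_state}}
#' @param alpha flow coupling constant (cm^-2)
#' @param decision a \code{\link{clot_decision}}
#' @param D diffusion-convection constant (cm^2/s)
#' @param ... solver controls passed to the event-detecting integrator
#' @return list with \code{clot} (logical), \code{clotting_time} (s or
#'   NA), \code{crossed} (threshold species), \code{alpha},
#'   \code{scenario}
#' @export
run_scenario <- function(model, scenario, drug = NULL, warfarin = NULL,
                         alpha = 0, decision = clot_decision(), D = 5e-7,
                         ...) {
  stopifnot(inherits(scenario, "coag_scenario"))
  if (!is.null(drug)) model <- attach_drug(model, drug)
  ini <- initial_state(model)
  if (!is.null(warfarin)) ini <- apply_warfarin(ini, warfarin)
  blood <- ini                      # reservoir: plasma without the trigger
  ini["TF"] <- scenario$TF
  ini["XIIa"] <- scenario$XIIa
  model <- set_initials(model, ini)
  model <- open_system(model, flow_config(alpha, D = D, c_blood = blood))
  hit <- .simulate_clot(model, decision$horizon,
                        c(IIa = decision$iia_threshold,
                          Ia = decision$ia_threshold), ...)
  list(clot = !is.na(hit$time), clotting_time = hit$time,
       crossed = hit$species, alpha = alpha, scenario = scenario$name)
}

#' Critical washout threshold alpha_crit
#'
#' The lowest flow-coupling strength that suppresses the coagulation
#' event for a given trigger scenario, found by bisection on a bracket
#' whose low end clots and high end suppresses (auto-expanded if
#' needed).
#'
#' @inheritParams run_scenario
#' @param bracket initial \code{c(lo, hi)} for alpha (cm^-2)
#' @param rel_tol relative bracket width at termination
#' @param max_expand maximum upper-bracket value during auto-expansion
#' @return list with \code{alpha_crit} (the suppressing end of the final
#'   bracket), \code{bracket} (lo clots, hi suppresses),
#'   \code{iterations}, \code{scenario}, \code{drug},
#'   \code{clot_time_at_alpha0}
#' @export
alpha_crit <- function(model, scenario, drug = NULL, warfarin = NULL,
                       decision = clot_decision(), bracket = c(1e2, 1e6),
                       rel_tol = 1e-3, D = 5e-7, max_expand = 1e12, ...) {
  clots <- function(a)
    run_scenario(model, scenario, drug = drug, warfarin = warfarin,
                 alpha = a, decision = decision, D = D, ...)$clot
  at0 <- run_scenario(model, scenario, drug = drug, warfarin = warfarin,
                      alpha = 0, decision = decision, D = D, ...)
  if (!at0$clot)
    stop("no-clot-at-rest: scenario ", scenario$name,
         " does not clot even at alpha = 0")
  lo <- bracket[1]; hi <- bracket[2]
  stopifnot(lo > 0, hi > lo)
  while (clots(hi)) {
    lo <- hi
    hi <- hi * 10
    if (hi > max_expand)
      stop("bracket-expansion failure: clot persists up to alpha = ",
           max_expand)
  }
  while (!clots(lo)) {
    hi <- lo
    lo <- lo / 10
    if (lo < 1e-12) break  # clots only in the closed limit
  }
  it <- 0L
  while ((hi - lo) / lo > rel_tol) {
    mid <- sqrt(lo * hi)
    if (clots(mid)) lo <- mid else hi <- mid
    it <- it + 1L
    if (it > 200L) stop("alpha_crit bisection did not converge")
  }
  list(alpha_crit = hi, bracket = c(lo, hi), iterations = it,
       scenario = scenario$name,
       drug = if (!is.null(drug)) drug$name else
         if (!is.null(warfarin)) "warfarin" else "none",
       clot_time_at_alpha0 = at0$clotting_time)
}
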