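# Virtual clotting assays.  An assay dilutes plasma (all proteins, drugs
# and the albumin pool alike), preactivates 1% of factor V, sets the
# trigger and reagent species at their final in-assay concentrations, and
# simulates the closed system.  The clot criterion is the fibrin product
# ("Ia") reaching 100 nM for the first time; the INR is the PT ratio with
# an assumed ISI exponent of 1.

#' Assay configuration
#'
#' Defaults reproduce the package's virtual test definitions: PT is
#' triggered with 4 nM tissue factor, aPTT with 2.2 nM factor XIa plus
#' 50 nM factor XIIa (both at 1/3 plasma dilution, reagent phospholipid
#' 10 uM molecules), and the thrombin generation assay with 5e-12 M TF at
#' 2/3 dilution and 4 uM phospholipid.
#'
#' @param dilution dilution factor applied to all plasma concentrations
#' @param triggers named numeric vector of final in-assay trigger
#'   concentrations (mol/l), set after dilution
#' @param fv_fraction preactivated factor V fraction
#' @param phospholipid_molecules reagent phospholipid in mol/l of lipid
#'   molecules (converted to binding sites via 333 molecules/site);
#'   \code{NULL} keeps the diluted plasma value
#' @param clot_species species whose threshold crossing defines clotting
#' @param clot_threshold mol/l
#' @param horizon assay horizon in seconds
#' @export
assay_config <- function(dilution, triggers, fv_fraction = 0.01,
                         phospholipid_molecules = 10e-6,
                         clot_species = "Ia", clot_threshold = 100e-9,
                         horizon = 600) {
  stopifnot(dilution > 0, dilution <= 1, clot_threshold > 0, horizon > 0)
  structure(list(dilution = dilution, triggers = triggers,
                 fv_fraction = fv_fraction,
                 phospholipid_molecules = phospholipid_molecules,
                 clot_species = clot_species,
                 clot_threshold = clot_threshold, horizon = horizon),
            class = "coag_assay_config")
}

#' @rdname assay_config
#' @export
pt_config <- function() assay_config(1 / 3, c(TF = 4e-9))

#' @rdname assay_config
#' @export
aptt_config <- function() assay_config(1 / 3, c(XIa = 2.2e-9, XIIa = 50e-9))

#' @rdname assay_config
#' @export
tga_config <- function()
  assay_config(2 / 3, c(TF = 5e-12), phospholipid_molecules = 4e-6,
               horizon = 3600)

# Prepare the assay model: attach drug / warfarin at plasma level, dilute,
# preactivate FV, then set triggers and reagent phospholipid at final
# in-assay concentrations.
.prepare_assay <- function(model, config, drug = NULL, warfarin = NULL) {
  if (!is.null(drug)) model <- attach_drug(model, drug)
  ini <- initial_state(model)
  if (!is.null(warfarin)) ini <- apply_warfarin(ini, warfarin)
  ini <- dilute(ini, config$dilution)
  ini <- preactivate_factor_v(ini, config$fv_fraction)
  ini[names(config$triggers)] <- config$triggers
  if (!is.null(config$phospholipid_molecules))
    ini[["PhosphoLipid"]] <- lipid_sites(config$phospholipid_molecules)
  set_initials(model, ini)
}

.run_assay <- function(model, config, drug, warfarin, label,
                       rtol = 1e-8, atol = 1e-14, n_out = 1201L,
                       control_must_clot = TRUE) {
  prepared <- .prepare_assay(model, config, drug, warfarin)
  traj <- simulate_model(prepared, config$horizon, n_out = n_out,
                         rtol = rtol, atol = atol)
  ct <- first_crossing_time(traj, config$clot_species, config$clot_threshold)
  if (is.na(ct) && is.null(drug) && is.null(warfarin) && control_must_clot)
    stop("drug-free control failed to clot within ", config$horizon,
         " s in the ", label, " assay: model misconfiguration")
  structure(list(assay = label, clotting_time = ct,
                 drug = if (!is.null(drug)) drug$name else
                   if (!is.null(warfarin)) "warfarin" else "none",
                 concentration = if (!is.null(drug)) drug$concentration
                   else NA_real_,
                 trajectory = traj),
            class = "coag_assay_result")
}

#' @export
print.coag_assay_result <- function(x, ...) {
  cat(x$assay, "assay,", x$drug,
      if (!is.na(x$concentration)) paste0("(",
        signif(x$concentration * 1e9, 4), " nM)") else "",
      ": clotting time",
      if (is.na(x$clotting_time)) "no clot" else
        paste(signif(x$clotting_time, 5), "s"), "\n")
  if (!is.null(x$peak_thrombin))
    cat("  peak thrombin:", signif(x$peak_thrombin * 1e9, 5), "nM at",
        signif(x$peak_time, 5), "s\n")
  invisible(x)
}

#' Virtual prothrombin time (PT)
#'
#' Dilutes plasma to 1/3, preactivates 1\% of factor V, triggers with 4 nM
#' tissue factor and reports the time at which fibrin first reaches
#' 100 nM.
#'
#' @param model the base \code{coag_model}
#' @param drug optional \code{\link{drug_state}}
#' @param warfarin optional \code{\link{warfarin_state}}
#' @param config assay configuration, default \code{\link{pt_config}}
#' @param ... solver controls passed through (\code{rtol}, \code{atol},
#'   \code{n_out})
#' @return a \code{coag_assay_result} with the clotting time (s) and the
#'   trajectory
#' @export
run_pt <- function(model, drug = NULL, warfarin = NULL,
                   config = pt_config(), ...) {
  .run_assay(model, config, drug, warfarin, "PT", ...)
}

#' Virtual activated partial thromboplastin time (aPTT)
#'
#' As \code{\link{run_pt}} but triggered with 2.2 nM factor XIa plus
#' 50 nM factor XIIa; the clot criterion is the same single fibrin
#' threshold.
#'
#' @inheritParams run_pt
#' @export
run_aptt <- function(model, drug = NULL, warfarin = NULL,
                     config = aptt_config(), ...) {
  .run_assay(model, config, drug, warfarin, "aPTT", ...)
}

#' International normalized ratio
#'
#' PT with study drug divided by PT without study drug (ISI exponent 1).
#'
#' @param pt_drug,pt_control clotting times in seconds
#' @return dimensionless INR
#' @export
inr <- function(pt_drug, pt_control) {
  if (!is.finite(pt_drug) || !is.finite(pt_control) ||
      pt_drug <= 0 || pt_control <= 0)
    stop("INR requires finite positive PT values")
  pt_drug / pt_control
}

#' Virtual thrombin generation assay
#'
#' Dilutes plasma to 2/3, sets phospholipid binding sites from 4 uM lipid
#' molecules, triggers with 5e-12 M tissue factor, and reports the peak
#' free thrombin concentration and its time.
#'
#' @inheritParams run_pt
#' @export
thrombin_generation <- function(model, drug = NULL, warfarin = NULL,
                                config = tga_config(), ...) {
  res <- .run_assay(model, config, drug, warfarin, "TGA",
                    control_must_clot = FALSE, ...)
  iia <- res$trajectory$concentrations[, "IIa"]
  k <- which.max(iia)
  res$peak_thrombin <- iia[k]
  res$peak_time <- res$trajectory$times[k]
  res
}

#' Thrombin-peak concentration-effect curve
#'
#' Runs the thrombin generation assay over a grid of drug concentrations
#' and records the peak thrombin height, i.e. the concentration-effect
#' relationship whose steep initial slope and high-concentration plateau
#' shape the therapeutic window.
#'
#' @param model the base \code{coag_model}
#' @param drug drug name
#' @param concentrations grid of total plasma concentrations
#' @param unit concentration unit (see \code{\link{mass_to_molar}})
#' @param config assay configuration
#' @param ... solver controls
#' @return data frame with columns \code{concentration},
#'   \code{peak_thrombin} (mol/l), \code{peak_time} (s)
#' @export
tga_concentration_effect <- function(model, drug = "rivaroxaban",
                                     concentrations = seq(0, 500, by = 10),
                                     unit = "ug_l", config = tga_config(),
                                     ...) {
  res <- lapply(concentrations, function(c_) {
    d <- if (c_ > 0) drug_state(drug, c_, unit) else NULL
    r <- thrombin_generation(model, drug = d, config = config, ...)
    data.frame(concentration = c_, peak_thrombin = r$peak_thrombin,
               peak_time = r$peak_time)
  })
  do.call(rbind, res)
}

#' Plateau onset of a concentration-effect curve
#'
#' Fits a continuous two-segment (steep/flat) piecewise-linear model to
#' effect versus concentration by least squares over candidate
#' breakpoints; the breakpoint estimates where the curve levels off.
#'
#' @param concentration,effect numeric vectors
#' @return the breakpoint concentration
#' @export
plateau_onset <- function(concentration, effect) {
  stopifnot(length(concentration) == length(effect),
            length(concentration) >= 5)
  o <- order(concentration)
  x <- concentration[o]; y <- effect[o]
  cands <- x[3:(length(x) - 2)]
  sse <- vapply(cands, function(b) {
    x1 <- pmin(x, b); x2 <- pmax(x - b, 0)
    sum(resid(stats::lm(y ~ x1 + x2))^2)
  }, numeric(1))
  cands[which.min(sse)]
}

#' Clotting response to variation of a single factor
#'
#' Scales one factor's initial concentration over \code{levels} (relative
#' to normal) and reruns the assay; PT results are reported as INR against
#' the level-1 control.
#'
#' @param model the base \code{coag_model}
#' @param factor species name of the factor to vary
#' @param levels numeric vector of relative levels (> 0)
#' @param assay \code{"pt"} or \code{"aptt"}
#' @param ... solver controls
#' @return data frame with columns \code{level}, \code{clotting_time} and,
#'   for PT, \code{inr}
#' @export
factor_variation_curve <- function(model, factor, levels,
                                   assay = c("pt", "aptt"), ...) {
  assay <- match.arg(assay)
  if (!factor %in% model$species$name) stop("unknown factor: ", factor)
  stopifnot(all(levels > 0))
  runner <- if (assay == "pt") run_pt else run_aptt
  base <- initial_state(model)
  times <- vapply(levels, function(lv) {
    m <- set_initials(model, setNames(base[[factor]] * lv, factor))
    runner(m, ...)$clotting_time
  }, numeric(1))
  out <- data.frame(level = levels, clotting_time = times)
  if (assay == "pt") {
    ct0 <- runner(model, ...)$clotting_time
    out$inr <- times / ct0
  }
  out
}
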