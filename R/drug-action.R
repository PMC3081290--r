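# Anticoagulant mechanisms.  Each kinetic drug (rivaroxaban, DX-9065a,
# melagatran, enoxaparin) is a set of species and mass-action reactions
# grafted onto the network; warfarin is an initial-condition transform of
# the vitamin K-dependent factors only and never a kinetic species.
# Protein binding is a reversible complexation against the diluted albumin
# pool (species Albumin_Factor), so the unbound fraction responds to
# plasma dilution.

.drug_db <- function() {
  list(
    rivaroxaban = list(
      species = "Bay59_7939", mw = 435.88, fu = 0.05,
      params = c(kBay1 = 1.7e7, kBay3 = 1.7e7, kBay5 = 50, kBay6 = 1e5,
                 kBay_Ki_Xa = 4e-10, kBay_Ki_XaVa = 2e-9,
                 kBay_Ki_XaATIII = 1e-7,
                 kBay_fu = 0.05 / 0.95, kBay_fu_on = 100),
      prov = c(kBay1 = "source-model", kBay3 = "fitted-here",
               kBay5 = "fitted-here", kBay6 = "fitted-here",
               kBay_Ki_Xa = "source-model", kBay_Ki_XaVa = "source-model",
               kBay_Ki_XaATIII = "fitted-here", kBay_fu = "source-model",
               kBay_fu_on = "fitted-here")
    ),
    dx9065a = list(
      species = "DX9065a", mw = 571.66, fu = 0.9,
      params = c(kDx1 = 1e7, kDx2 = 0.41, kDx3 = 1e7, kDx4 = 1.0,
                 kDx5 = 50, kDx6 = 1e5, kDx7 = 1e-2,
                 kDx_fu = 0.9 / 0.1, kDx_fu_on = 100),
      prov = c(kDx1 = "source-model", kDx2 = "source-model",
               kDx3 = "fitted-here", kDx4 = "fitted-here",
               kDx5 = "fitted-here", kDx6 = "fitted-here",
               kDx7 = "fitted-here", kDx_fu = "source-model",
               kDx_fu_on = "fitted-here")
    ),
    melagatran = list(
      species = "Xim", mw = 429.47, fu = 0.85,
      params = c(kXim1 = 1e7, kXim2 = 0.02, kXim3 = 1e7, kXim4 = 0.02,
                 kXim5 = 1e7, kXim6 = 0.02,
                 kXim_fu = 0.85 / 0.15, kXim_fu_on = 100),
      prov = c(kXim1 = "source-model", kXim2 = "source-model",
               kXim3 = "fitted-here", kXim4 = "fitted-here",
               kXim5 = "fitted-here", kXim6 = "fitted-here",
               kXim_fu = "source-model", kXim_fu_on = "fitted-here")
    ),
    enoxaparin = list(
      species = "Hep", mw = 4500, anti_xa_units_per_mg = 100, fu = 0.8,
      params = c(kHep_fu = 0.8 / 0.2, kHep_fu_on = 100,
                 kHep_ATIII_on = 1e7, kHep_Ki_ATIII = 2e-8,
                 kHep_Xa_ATIIIa = 3e5, kHep_XaVa_ATIIIa = 1.5e5,
                 kHep_IIa_ATIIIa = 1e4, kHep_IXa_ATIIIa = 2e4,
                 kHep_XIa_ATIIIa = 5e3),
      prov = c(kHep_fu = "source-model", kHep_fu_on = "fitted-here",
               kHep_ATIII_on = "source-model", kHep_Ki_ATIII = "source-model",
               kHep_Xa_ATIIIa = "fitted-here",
               kHep_XaVa_ATIIIa = "fitted-here",
               kHep_IIa_ATIIIa = "fitted-here",
               kHep_IXa_ATIIIa = "fitted-here",
               kHep_XIa_ATIIIa = "fitted-here")
    )
  )
}

#' Construct an anticoagulant drug state
#'
#' @param name one of \code{"rivaroxaban"}, \code{"dx9065a"},
#'   \code{"melagatran"}, \code{"enoxaparin"} (ximelagatran is represented
#'   by its active metabolite melagatran)
#' @param concentration total plasma concentration, interpreted per
#'   \code{unit}
#' @param unit one of \code{"mol_l"}, \code{"ug_l"}, \code{"mg_l"},
#'   \code{"uM"}, \code{"anti_xa_u_ml"}
#' @return an object of class \code{coag_drug}
#' @export
drug_state <- function(name = c("rivaroxaban", "dx9065a", "melagatran",
                                "enoxaparin"),
                       concentration, unit = "mol_l") {
  name <- match.arg(name)
  db <- .drug_db()[[name]]
  stopifnot(concentration >= 0)
  conc <- mass_to_molar(name, concentration, unit)
  structure(list(name = name, concentration = conc, mw = db$mw,
                 fu = db$fu, species = db$species,
                 params = db$params, prov = db$prov),
            class = "coag_drug")
}

#' @export
print.coag_drug <- function(x, ...) {
  cat("drug:", x$name, "at", signif(x$concentration * 1e9, 4),
      "nM total (fu =", x$fu, ")\n")
  invisible(x)
}

#' Convert a drug concentration to mol/l
#'
#' Mass units use the drug's molecular weight (average 4500 g/mol for
#' enoxaparin); anti-Factor Xa units use 100 U per mg enoxaparin.
#'
#' @param drug drug name or a \code{coag_drug}
#' @param value concentration value
#' @param unit \code{"mol_l"}, \code{"ug_l"}, \code{"mg_l"}, \code{"uM"}
#'   or \code{"anti_xa_u_ml"}
#' @return mol/l
#' @export
mass_to_molar <- function(drug, value,
                          unit = c("mol_l", "ug_l", "mg_l", "uM",
                                   "anti_xa_u_ml")) {
  unit <- match.arg(unit)
  name <- if (inherits(drug, "coag_drug")) drug$name else drug
  db <- .drug_db()[[name]]
  if (is.null(db)) stop("unknown drug: ", name)
  switch(unit,
         mol_l = value,
         ug_l = value * 1e-6 / db$mw,
         mg_l = value * 1e-3 / db$mw,
         uM = value * 1e-6,
         anti_xa_u_ml = {
           if (is.null(db$anti_xa_units_per_mg))
             stop("anti-Xa units are only defined for enoxaparin")
           # U/ml -> mg/ml -> g/l -> mol/l
           value / db$anti_xa_units_per_mg / db$mw
         })
}

# Species added by each mechanism (all mobile, none lipid-bound as such;
# the lipid-bound target stays inside the complex name).
.drug_species <- function(drug) {
  d <- drug$species
  nm <- switch(drug$name,
    rivaroxaban = c(d, paste0(d, "_Bound"), paste0(d, "_Xa"),
                    paste0(d, "_Xa_lipid"), paste0(d, "_Xa_Va_lipid"),
                    paste0(d, "_Xa_ATIII")),
    dx9065a = c(d, paste0(d, "_Bound"), paste0(d, "_Xa"),
                paste0(d, "_Xa_lipid"), paste0(d, "_Xa_Va_lipid"),
                paste0(d, "_Xa_ATIII")),
    melagatran = c(d, paste0(d, "_Bound"), "IIa_Xim", "mIIa_Xim",
                   "IIa_Tm_Xim"),
    enoxaparin = c("Hep", "Hep_Bound", "ATIIIa"))
  nm
}

.drug_reactions <- function(drug) {
  switch(drug$name,
    rivaroxaban = list(
      reversible("RBay1", c(Bay59_7939 = 1, Xa = 1), c(Bay59_7939_Xa = 1),
                 "kBay1", c("kBay1", "kBay_Ki_Xa"), group = "drug"),
      reversible("RBay1s", c(Bay59_7939 = 1, Xa_lipid = 1),
                 c(Bay59_7939_Xa_lipid = 1),
                 "kBay1", c("kBay1", "kBay_Ki_Xa"), group = "drug"),
      reversible("RBay2", c(Bay59_7939 = 1, Xa_Va_lipid = 1),
                 c(Bay59_7939_Xa_Va_lipid = 1),
                 "kBay3", c("kBay3", "kBay_Ki_XaVa"), group = "drug"),
      reaction("RBay3", c(Bay59_7939_Bound = 1), c(Bay59_7939 = 1),
               rate_law(list(
                 list(sign = 1, constants = c("kBay_fu_on", "kBay_fu"),
                      species = "Bay59_7939_Bound"),
                 list(sign = -1, constants = "kBay_fu_on",
                      species = c("Albumin_Factor", "Bay59_7939")))),
               group = "drug"),
      irreversible("RBay4", c(Bay59_7939_Xa = 1, ATIII = 1),
                   c(Bay59_7939_Xa_ATIII = 1), "kBay5", group = "drug"),
      reversible("RBay5", c(Bay59_7939 = 1, Xa_ATIII = 1),
                 c(Bay59_7939_Xa_ATIII = 1),
                 "kBay6", c("kBay6", "kBay_Ki_XaATIII"), group = "drug")
    ),
    dx9065a = list(
      reversible("RDx1", c(DX9065a = 1, Xa = 1), c(DX9065a_Xa = 1),
                 "kDx1", "kDx2", group = "drug"),
      reversible("RDx1s", c(DX9065a = 1, Xa_lipid = 1),
                 c(DX9065a_Xa_lipid = 1), "kDx1", "kDx2", group = "drug"),
      reversible("RDx2", c(DX9065a = 1, Xa_Va_lipid = 1),
                 c(DX9065a_Xa_Va_lipid = 1), "kDx3", "kDx4", group = "drug"),
      irreversible("RDx3", c(DX9065a_Xa = 1, ATIII = 1),
                   c(DX9065a_Xa_ATIII = 1), "kDx5", group = "drug"),
      reaction("RDx4", c(DX9065a = 1), c(DX9065a_Bound = 1),
               rate_law(list(
                 list(sign = 1, constants = "kDx_fu_on",
                      species = c("Albumin_Factor", "DX9065a")),
                 list(sign = -1, constants = c("kDx_fu_on", "kDx_fu"),
                      species = "DX9065a_Bound"))),
               group = "drug"),
      reversible("RDx5", c(DX9065a = 1, Xa_ATIII = 1),
                 c(DX9065a_Xa_ATIII = 1), "kDx6", "kDx7", group = "drug")
    ),
    melagatran = list(
      reversible("RXi1", c(Xim = 1, IIa = 1), c(IIa_Xim = 1),
                 "kXim1", "kXim2", group = "drug"),
      reversible("RXi2", c(Xim = 1, mIIa = 1), c(mIIa_Xim = 1),
                 "kXim3", "kXim4", group = "drug"),
      reversible("RXi3", c(Xim = 1, IIa_Tm = 1), c(IIa_Tm_Xim = 1),
                 "kXim5", "kXim6", group = "drug"),
      reaction("RXi4", c(Xim = 1), c(Xim_Bound = 1),
               rate_law(list(
                 list(sign = 1, constants = "kXim_fu_on",
                      species = c("Albumin_Factor", "Xim")),
                 list(sign = -1, constants = c("kXim_fu_on", "kXim_fu"),
                      species = "Xim_Bound"))),
               group = "drug")
    ),
    enoxaparin = list(
      reaction("RHep1", c(Hep = 1), c(Hep_Bound = 1),
               rate_law(list(
                 list(sign = 1, constants = "kHep_fu_on",
                      species = c("Albumin_Factor", "Hep")),
                 list(sign = -1, constants = c("kHep_fu_on", "kHep_fu"),
                      species = "Hep_Bound"))),
               group = "drug"),
      reversible("RHep2", c(ATIII = 1, Hep = 1), c(ATIIIa = 1),
                 "kHep_ATIII_on", c("kHep_ATIII_on", "kHep_Ki_ATIII"),
                 group = "drug"),
      irreversible("RHep3", c(Xa = 1, ATIIIa = 1),
                   c(Xa_ATIII = 1, Hep = 1), "kHep_Xa_ATIIIa",
                   group = "drug"),
      irreversible("RHep4", c(Xa_lipid = 1, ATIIIa = 1),
                   c(Xa_ATIII = 1, PhosphoLipid = 1, Hep = 1),
                   "kHep_Xa_ATIIIa", group = "drug"),
      irreversible("RHep5", c(Xa_Va_lipid = 1, ATIIIa = 1),
                   c(Xa_ATIII = 1, Hep = 1, Va_lipid = 1),
                   "kHep_XaVa_ATIIIa", group = "drug"),
      irreversible("RHep6", c(IIa = 1, ATIIIa = 1),
                   c(IIa_ATIII = 1, Hep = 1), "kHep_IIa_ATIIIa",
                   group = "drug"),
      irreversible("RHep7", c(mIIa = 1, ATIIIa = 1),
                   c(mIIa_ATIII = 1, Hep = 1), "kHep_IIa_ATIIIa",
                   group = "drug"),
      irreversible("RHep8", c(ATIIIa = 1, IXa = 1),
                   c(IXa_ATIII = 1, Hep = 1), "kHep_IXa_ATIIIa",
                   group = "drug"),
      irreversible("RHep9", c(ATIIIa = 1, IXa_lipid = 1),
                   c(IXa_ATIII = 1, PhosphoLipid = 1, Hep = 1),
                   "kHep_IXa_ATIIIa", group = "drug"),
      irreversible("RHep10", c(XIa = 1, ATIIIa = 1),
                   c(XIa_ATIII = 1, Hep = 1), "kHep_XIa_ATIIIa",
                   group = "drug"),
      irreversible("RHep11", c(XIa_lipid = 1, ATIIIa = 1),
                   c(XIa_ATIII = 1, PhosphoLipid = 1, Hep = 1),
                   "kHep_XIa_ATIIIa", group = "drug")
    ))
}

#' Attach an anticoagulant mechanism to a model
#'
#' Adds the drug's species (free, protein-bound and target complexes) and
#' its mechanism reactions.  The total drug is partitioned between free
#' and albumin-bound forms at the binding equilibrium implied by the
#' current albumin pool.  In a later flow coupling the drug is present in
#' the blood reservoir at the same concentrations, since the reservoir
#' defaults to the model's initial state.
#'
#' @param model a \code{coag_model}
#' @param drug a \code{\link{drug_state}}
#' @return the extended \code{coag_model}
#' @export
attach_drug <- function(model, drug) {
  stopifnot(inherits(model, "coag_model"), inherits(drug, "coag_drug"))
  newsp <- .drug_species(drug)
  clash <- intersect(newsp, model$species$name)
  if (length(clash))
    stop("species name collision attaching ", drug$name, ": ",
         paste(clash, collapse = ", "))
  alb <- model$species$initial_concentration[
    model$species$name == "Albumin_Factor"]
  kfu <- drug$params[[grep("_fu$", names(drug$params), value = TRUE)[1]]]
  free <- drug$concentration * kfu / (kfu + alb)
  bound <- drug$concentration - free
  init <- setNames(rep(0, length(newsp)), newsp)
  init[newsp[1]] <- free
  init[paste0(drug$species, "_Bound")] <- bound
  spdf <- rbind(model$species,
                data.frame(name = newsp, initial_concentration = unname(init),
                           mobile = TRUE, lipid_bound = FALSE))
  pars <- c(model$parameters, drug$params)
  prov <- c(attr(model$parameters, "provenance"), drug$prov)
  attr(pars, "provenance") <- prov
  out <- network_model(spdf, c(model$reactions, .drug_reactions(drug)), pars)
  out$flow <- model$flow
  out$drug <- drug
  out
}

#' Warfarin state
#'
#' Warfarin is represented as a simultaneous reduction of the initial
#' concentrations of the vitamin K-dependent factors II, VII, IX and X and
#' of proteins C and S to the fraction \code{f} of their normal values.
#' The trace of circulating activated factor VII (species \code{VIIa}) is
#' reduced with its parent zymogen, since it is the same vitamin
#' K-dependent protein.
#'
#' @param f fraction of normal in (0, 1]
#' @export
warfarin_state <- function(f) {
  if (!(f > 0 && f <= 1)) stop("warfarin factor fraction must be in (0, 1]")
  structure(list(f = f,
                 affected = c("II", "VII", "VIIa", "IX", "X", "PC", "PS")),
            class = "coag_warfarin")
}

#' Apply a warfarin state to initial concentrations
#'
#' @param initials named numeric vector (mol/l)
#' @param w a \code{\link{warfarin_state}}
#' @export
apply_warfarin <- function(initials, w) {
  stopifnot(inherits(w, "coag_warfarin"))
  initials[w$affected] <- initials[w$affected] * w$f
  initials
}

#' Factor fraction reproducing a target INR
#'
#' Finds the common vitamin K-dependent factor fraction \code{f} whose
#' simulated INR (PT with the reduced factors divided by the drug-free PT)
#' matches \code{target_inr}, by monotone bracketing root-finding on
#' (0, 1].
#'
#' @param model the base \code{coag_model}
#' @param target_inr target INR, >= 1
#' @param rel_tol relative tolerance on the achieved INR
#' @param f_min lower end of the search bracket
#' @param ... passed to \code{\link{run_pt}}
#' @return the fraction \code{f}
#' @export
warfarin_fraction_for_inr <- function(model, target_inr, rel_tol = 1e-3,
                                      f_min = 0.02, ...) {
  if (target_inr < 1) stop("target INR must be >= 1, got ", target_inr)
  if (target_inr == 1) return(1)
  pt0 <- run_pt(model, ...)$clotting_time
  inr_of <- function(f)
    run_pt(model, warfarin = warfarin_state(f), ...)$clotting_time / pt0
  # a non-clotting assay (NA) means the INR exceeds any finite target
  g <- function(f) {
    v <- inr_of(f)
    if (is.na(v)) Inf else log(v / target_inr)
  }
  g_hi <- g(1)  # INR(1) = 1 -> negative
  g_lo <- g(f_min)
  if (g_lo < 0)
    stop("target INR ", target_inr, " not reachable within f >= ", f_min)
  lo <- f_min; hi <- 1
  glo <- g_lo; ghi <- g_hi
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (abs(gm) <= rel_tol) return(mid)
    if (gm > 0) { lo <- mid; glo <- gm } else { hi <- mid; ghi <- gm }
  }
  stop("warfarin INR root-finding did not converge for target ", target_inr)
}
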