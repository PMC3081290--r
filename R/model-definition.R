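# Canonical definition of the coagulation network.
#
# The kinetic scheme is a reconstruction assembled from the published
# literature models it is based on: the tissue-factor (extrinsic) core
# follows the Hockin-Mann scheme (32 reactions, rate constants k1..k42);
# the contact (intrinsic) chain follows Kogan-type kinetics (constants
# 'Kog*'); fibrinogen cleavage uses Stevens-type kinetics (RI); the
# protein C/S feedback and phospholipid adsorption follow the
# Bungay / Kuharsky-Fogelson treatment ('RBu*', 'Rad*').  Parameters are
# provenance-tagged: "source-model" = taken from the cited literature
# model, "fitted-here" = adjusted during assembly of this package so that
# the virtual assays behave physiologically, "external-constant" =
# standard reference value (e.g. a molecular weight).  Because the
# parameter set is a reconstruction rather than a verbatim transcript of
# any single published table, the shipped model file is labelled
# synthetic.

#' Phospholipid site accounting configuration
#'
#' The species \code{PhosphoLipid} represents protein-binding sites on
#' phospholipid vesicles; one site corresponds to 333 lipid molecules.
#'
#' @param molecules_per_site lipid molecules per protein-binding site
#' @param site_species name of the site species
#' @export
lipid_config <- function(molecules_per_site = 333,
                         site_species = "PhosphoLipid") {
  stopifnot(molecules_per_site > 0)
  structure(list(molecules_per_site = molecules_per_site,
                 site_species = site_species), class = "coag_lipid_config")
}

#' Convert phospholipid molecule concentration to binding sites
#'
#' @param lipid_molecules phospholipid concentration in mol/l of molecules
#' @param cfg a \code{\link{lipid_config}}
#' @return mol/l of protein-binding sites
#' @export
lipid_sites <- function(lipid_molecules, cfg = lipid_config()) {
  stopifnot(all(lipid_molecules >= 0))
  lipid_molecules / cfg$molecules_per_site
}

# Species table: name, initial concentration (mol/l, undiluted plasma),
# mobile (transported by flow), lipid_bound.  TF, every TF-containing
# complex and the fibrin product Ia are immobile (bound to tissue or to
# the thrombus).  Albumin_Factor is a dimensionless binding-pool species
# (1 = undiluted plasma) used by the drug protein-binding reactions; it is
# diluted and transported like any plasma protein.
.coag_species <- function() {
  sp <- function(name, init, mobile = TRUE, lipid = FALSE)
    data.frame(name = name, initial_concentration = init,
               mobile = mobile, lipid_bound = lipid)
  rbind(
    sp("TF", 0, mobile = FALSE),
    sp("VII", 1.0e-8),
    sp("TF_VII", 0, mobile = FALSE),
    sp("VIIa", 1.0e-10),
    sp("TF_VIIa", 0, mobile = FALSE),
    sp("Xa", 0),
    sp("IIa", 0),
    sp("X", 1.6e-7),
    sp("TF_VIIa_X", 0, mobile = FALSE),
    sp("TF_VIIa_Xa", 0, mobile = FALSE),
    sp("IX", 9.0e-8),
    sp("TF_VIIa_IX", 0, mobile = FALSE),
    sp("IXa", 0),
    sp("II", 1.4e-6),
    sp("VIII", 7.0e-12),
    sp("VIIIa", 0),
    sp("IXa_VIIIa", 0),
    sp("IXa_VIIIa_X", 0),
    sp("VIIIa1_L", 0),
    sp("VIIIa2", 0),
    sp("V", 2.0e-8),
    sp("Va", 0),
    sp("Xa_Va_lipid", 0, lipid = TRUE),
    sp("Xa_Va_II_lipid", 0, lipid = TRUE),
    sp("mIIa", 0),
    sp("TFPI", 2.5e-9),
    sp("Xa_TFPI", 0),
    sp("TF_VIIa_Xa_TFPI", 0, mobile = FALSE),
    sp("ATIII", 3.4e-6),
    sp("Xa_ATIII", 0),
    sp("mIIa_ATIII", 0),
    sp("IXa_ATIII", 0),
    sp("IIa_ATIII", 0),
    sp("TF_VIIa_ATIII", 0, mobile = FALSE),
    sp("PhosphoLipid", 1.5015e-8, lipid = TRUE),  # 5 uM molecules / 333
    sp("Xa_lipid", 0, lipid = TRUE),
    sp("IXa_lipid", 0, lipid = TRUE),
    sp("Va_lipid", 0, lipid = TRUE),
    sp("XIa_lipid", 0, lipid = TRUE),
    sp("XIIa", 0),
    sp("XI", 3.0e-8),
    sp("XIa", 0),
    sp("XIa_ATIII", 0),
    sp("XIIa_inh", 0),
    sp("I", 7.0e-6),
    sp("Ia", 0, mobile = FALSE),
    sp("Tm", 5.0e-10),
    sp("IIa_Tm", 0),
    sp("PC", 6.0e-8),
    sp("APC", 0),
    sp("PS", 6.0e-8),
    sp("APC_PS", 0),
    sp("Va_i", 0),
    sp("VIIIa_i", 0),
    sp("APC_i", 0),
    sp("vWF", 3.0e-8),
    sp("VIII_vWF", 7.0e-10),
    sp("Albumin_Factor", 1.0)
  )
}

.coag_parameters <- function() {
  p <- c(
    # extrinsic core (Hockin-Mann numbering)
    k1 = 3.1e-3, k2 = 3.2e6, k3 = 3.1e-3, k4 = 2.3e7, k5 = 4.4e5,
    k6 = 1.3e7, k7 = 2.3e4, k8 = 2.5e7, k9 = 1.05, k10 = 6,
    k11 = 2.2e7, k12 = 19, k13 = 1e7, k14 = 2.4, k15 = 1.8,
    k16 = 7.5e3, k17 = 2e7, k18 = 1e7, k19 = 5e-3, k20 = 1e8,
    k21 = 1e-3, k22 = 8.2, k23 = 2.2e4, k24 = 6e-3, k25 = 1e-3,
    k26 = 2e7, k27 = 0.2, k28 = 4e8, k29 = 1e8, k30 = 103,
    k31 = 63.5, k32 = 1.5e7, k33 = 3.6e-4, k34 = 9e5, k35 = 1.1e-4,
    k36 = 3.2e8, k37 = 5e7,
    k38 = 5.0e2,   # Xa + ATIII, reduced relative to the extrinsic source
    k39 = 7.1e3, k40 = 4.9e2, k41 = 7.1e3, k42 = 2.3e2,
    # contact pathway
    Kog1 = 3e4, Kog2 = 2e7, Kog3 = 5e4, Kog3d = 1e2, Kog4 = 1e4,
    Kog5 = 1e-3, Kog6 = 1e2,
    # fibrinogen cleavage
    kRI = 1.2e7, kRIm = 1.2e6,
    # protein C/S
    kBu1 = 1e8, kBu2 = 0.05, kBu3 = 5e5, kBu4 = 1e7, kBu5 = 0.5,
    kBu6 = 1e6, kBu7 = 1e7, kBu8 = 1e5, kBu9 = 1e6, kBu10 = 6e-4,
    # von Willebrand factor carrier
    kvwf_on = 1e7, kvwf_off = 3e-3, kvwf_act = 2e7,
    # phospholipid adsorption
    kad_on = 5e7, kad_off_Xa = 5, kad_off_IXa = 12.5, kad_off_Va = 0.15,
    kad_on_XIa = 1e6, kad_off_XIa = 1
  )
  prov <- setNames(rep("source-model", length(p)), names(p))
  prov[c("k38", "Kog3", "Kog3d", "Kog5", "kBu8", "kad_off_XIa")] <- "fitted-here"
  attr(p, "provenance") <- prov
  p
}

.coag_reactions <- function() {
  ext <- list(
    reversible("R1", c(TF = 1, VII = 1), c(TF_VII = 1), "k2", "k1",
               group = "extrinsic"),
    reversible("R2", c(TF = 1, VIIa = 1), c(TF_VIIa = 1), "k4", "k3",
               group = "extrinsic"),
    irreversible("R3", c(TF_VIIa = 1, VII = 1), c(TF_VIIa = 1, VIIa = 1),
                 "k5", group = "extrinsic"),
    irreversible("R4", c(Xa = 1, VII = 1), c(Xa = 1, VIIa = 1), "k6",
                 group = "extrinsic"),
    irreversible("R5", c(IIa = 1, VII = 1), c(IIa = 1, VIIa = 1), "k7",
                 group = "extrinsic"),
    reversible("R6", c(TF_VIIa = 1, X = 1), c(TF_VIIa_X = 1), "k8", "k9",
               group = "extrinsic"),
    irreversible("R7", c(TF_VIIa_X = 1), c(TF_VIIa_Xa = 1), "k10",
                 group = "extrinsic"),
    reversible("R8", c(TF_VIIa = 1, Xa = 1), c(TF_VIIa_Xa = 1), "k11", "k12",
               group = "extrinsic"),
    irreversible("R9", c(Xa = 1, II = 1), c(Xa = 1, IIa = 1), "k16",
                 group = "extrinsic"),
    reversible("R10", c(TF_VIIa = 1, IX = 1), c(TF_VIIa_IX = 1), "k13", "k14",
               group = "extrinsic"),
    irreversible("R11", c(TF_VIIa_IX = 1), c(TF_VIIa = 1, IXa = 1), "k15",
                 group = "extrinsic"),
    irreversible("R12", c(IIa = 1, VIII = 1), c(IIa = 1, VIIIa = 1), "k17",
                 group = "extrinsic"),
    reversible("R13", c(VIIIa = 1, IXa = 1), c(IXa_VIIIa = 1), "k18", "k19",
               group = "extrinsic"),
    reversible("R14", c(IXa_VIIIa = 1, X = 1), c(IXa_VIIIa_X = 1),
               "k20", "k21", group = "extrinsic"),
    irreversible("R15", c(IXa_VIIIa_X = 1), c(IXa_VIIIa = 1, Xa = 1), "k22",
                 group = "extrinsic"),
    irreversible("R16", c(VIIIa1_L = 1, VIIIa2 = 1), c(VIIIa = 1), "k23",
                 group = "extrinsic"),
    irreversible("R17", c(VIIIa = 1), c(VIIIa1_L = 1, VIIIa2 = 1), "k24",
                 group = "extrinsic"),
    irreversible("R18", c(IXa_VIIIa_X = 1),
                 c(VIIIa1_L = 1, VIIIa2 = 1, X = 1, IXa = 1), "k25",
                 group = "extrinsic"),
    irreversible("R19", c(IXa_VIIIa = 1),
                 c(VIIIa1_L = 1, VIIIa2 = 1, IXa = 1), "k25",
                 group = "extrinsic"),
    irreversible("R20", c(IIa = 1, V = 1), c(IIa = 1, Va = 1), "k26",
                 group = "extrinsic"),
    reversible("R21", c(Xa = 1, Va_lipid = 1), c(Xa_Va_lipid = 1),
               "k28", "k27", group = "extrinsic"),
    reversible("R22", c(Xa_Va_lipid = 1, II = 1), c(Xa_Va_II_lipid = 1),
               "k29", "k30", group = "extrinsic"),
    irreversible("R23", c(Xa_Va_II_lipid = 1), c(Xa_Va_lipid = 1, mIIa = 1),
                 "k31", group = "extrinsic"),
    irreversible("R24", c(mIIa = 1, Xa_Va_lipid = 1),
                 c(IIa = 1, Xa_Va_lipid = 1), "k32", group = "extrinsic"),
    reversible("R25", c(Xa = 1, TFPI = 1), c(Xa_TFPI = 1), "k34", "k33",
               group = "extrinsic"),
    reversible("R26", c(TF_VIIa_Xa = 1, TFPI = 1), c(TF_VIIa_Xa_TFPI = 1),
               "k36", "k35", group = "extrinsic"),
    irreversible("R27", c(TF_VIIa = 1, Xa_TFPI = 1), c(TF_VIIa_Xa_TFPI = 1),
                 "k37", group = "extrinsic"),
    irreversible("R28", c(Xa = 1, ATIII = 1), c(Xa_ATIII = 1), "k38",
                 group = "extrinsic"),
    irreversible("R29", c(mIIa = 1, ATIII = 1), c(mIIa_ATIII = 1), "k39",
                 group = "extrinsic"),
    irreversible("R30", c(IXa = 1, ATIII = 1), c(IXa_ATIII = 1), "k40",
                 group = "extrinsic"),
    irreversible("R31", c(IIa = 1, ATIII = 1), c(IIa_ATIII = 1), "k41",
                 group = "extrinsic"),
    irreversible("R32", c(TF_VIIa = 1, ATIII = 1), c(TF_VIIa_ATIII = 1),
                 "k42", group = "extrinsic")
  )
  intr <- list(
    irreversible("RKog1", c(XIIa = 1, XI = 1), c(XIIa = 1, XIa = 1), "Kog1",
                 group = "intrinsic"),
    irreversible("RKog2", c(XIa = 1, IX = 1), c(XIa = 1, IXa = 1), "Kog2",
                 group = "intrinsic"),
    irreversible("RKog2s", c(XIa_lipid = 1, IX = 1),
                 c(XIa_lipid = 1, IXa = 1), "Kog2", group = "intrinsic"),
    irreversible("RKog3", c(IXa_lipid = 1, X = 1), c(IXa_lipid = 1, Xa = 1),
                 "Kog3", group = "intrinsic"),
    irreversible("RKog3d", c(IXa = 1, X = 1), c(IXa = 1, Xa = 1), "Kog3d",
                 group = "intrinsic"),
    irreversible("RKog4", c(IIa = 1, XI = 1), c(IIa = 1, XIa = 1), "Kog4",
                 group = "intrinsic"),
    irreversible("RKog5", c(XIIa = 1), c(XIIa_inh = 1), "Kog5",
                 group = "intrinsic"),
    irreversible("RKog6", c(XIa = 1, ATIII = 1), c(XIa_ATIII = 1), "Kog6",
                 group = "intrinsic")
  )
  fib <- list(
    irreversible("RI", c(IIa = 1, I = 1), c(IIa = 1, Ia = 1), "kRI",
                 group = "fibrin"),
    irreversible("RIm", c(mIIa = 1, I = 1), c(mIIa = 1, Ia = 1), "kRIm",
                 group = "fibrin")
  )
  pcs <- list(
    reversible("RBu1", c(IIa = 1, Tm = 1), c(IIa_Tm = 1), "kBu1", "kBu2",
               group = "proteinCS"),
    irreversible("RBu2", c(IIa_Tm = 1, PC = 1), c(IIa_Tm = 1, APC = 1),
                 "kBu3", group = "proteinCS"),
    reversible("RBu3", c(APC = 1, PS = 1), c(APC_PS = 1), "kBu4", "kBu5",
               group = "proteinCS"),
    irreversible("RBu4", c(APC_PS = 1, Va = 1), c(APC_PS = 1, Va_i = 1),
                 "kBu6", group = "proteinCS"),
    irreversible("RBu4a", c(APC_PS = 1, Va_lipid = 1),
                 c(APC_PS = 1, Va_i = 1, PhosphoLipid = 1), "kBu7",
                 group = "proteinCS"),
    irreversible("RBu4b", c(APC_PS = 1, Xa_Va_lipid = 1),
                 c(APC_PS = 1, Xa_lipid = 1, Va_i = 1), "kBu8",
                 group = "proteinCS"),
    irreversible("RBu5", c(APC_PS = 1, VIIIa = 1),
                 c(APC_PS = 1, VIIIa_i = 1), "kBu9", group = "proteinCS"),
    irreversible("RBu6", c(APC = 1), c(APC_i = 1), "kBu10",
                 group = "proteinCS")
  )
  vwf <- list(
    reversible("Rvwf1", c(VIII = 1, vWF = 1), c(VIII_vWF = 1),
               "kvwf_on", "kvwf_off", group = "vwf"),
    irreversible("Rvwf2", c(IIa = 1, VIII_vWF = 1),
                 c(IIa = 1, VIIIa = 1, vWF = 1), "kvwf_act", group = "vwf")
  )
  ads <- list(
    reversible("Rad1", c(Xa = 1, PhosphoLipid = 1), c(Xa_lipid = 1),
               "kad_on", "kad_off_Xa", group = "adsorption"),
    reversible("Rad2", c(IXa = 1, PhosphoLipid = 1), c(IXa_lipid = 1),
               "kad_on", "kad_off_IXa", group = "adsorption"),
    reversible("Rad3", c(Va = 1, PhosphoLipid = 1), c(Va_lipid = 1),
               "kad_on", "kad_off_Va", group = "adsorption"),
    reversible("Rad4", c(XIa = 1, PhosphoLipid = 1), c(XIa_lipid = 1),
               "kad_on_XIa", "kad_off_XIa", group = "adsorption")
  )
  # solution/membrane duplicates: several components react either dissolved
  # or phospholipid-bound
  dup <- list(
    irreversible("R9d", c(Xa_lipid = 1, II = 1), c(Xa_lipid = 1, IIa = 1),
                 "k16", group = "duplicate"),
    irreversible("R21s", c(Xa_lipid = 1, Va_lipid = 1),
                 c(Xa_Va_lipid = 1, PhosphoLipid = 1), "k28",
                 group = "duplicate"),
    irreversible("R28d", c(Xa_lipid = 1, ATIII = 1),
                 c(Xa_ATIII = 1, PhosphoLipid = 1), "k38",
                 group = "duplicate")
  )
  c(ext, intr, fib, pcs, vwf, ads, dup)
}

#' Build the full coagulation network model
#'
#' Assembles the package's reconstructed coagulation cascade: the
#' 32-reaction tissue-factor (extrinsic) core, the contact (intrinsic)
#' pathway, fibrinogen cleavage, the protein C/S negative feedback,
#' the von Willebrand factor carrier, phospholipid adsorption with
#' 333-molecules-per-site accounting, and solution/membrane reaction
#' duplicates.  Initial concentrations are undiluted physiological plasma
#' values; trigger species (TF, XIIa, XIa) start at zero and are set by
#' the assay or scenario layer.
#'
#' @return a validated \code{\link{network_model}}
#' @export
build_coagulation_model <- function() {
  network_model(.coag_species(), .coag_reactions(), .coag_parameters())
}
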