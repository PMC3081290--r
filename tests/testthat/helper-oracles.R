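# Shared fixtures and independent oracles.

# one shared base model for all test files
coag_base <- build_coagulation_model()

# Brute-force derivative oracle: accumulates every reaction's contribution
# one by one through eval_rate, independently of the compiled evaluator.
brute_force_rhs <- function(model, state) {
  dy <- setNames(rep(0, nrow(model$species)), model$species$name)
  for (rx in model$reactions) {
    v <- eval_rate(rx$rate, state, model$parameters)
    for (s in names(rx$reactants))
      dy[s] <- dy[s] - rx$reactants[[s]] * v
    for (s in names(rx$products))
      dy[s] <- dy[s] + rx$products[[s]] * v
  }
  dy
}

# random physiological-ish state on a log scale
random_state <- function(model, rng_min = 1e-12, rng_max = 1e-5) {
  n <- nrow(model$species)
  setNames(10^stats::runif(n, log10(rng_min), log10(rng_max)),
           model$species$name)
}

# minimal two-species network A -> B with unit mass-action rate
tiny_decay_model <- function(k = 1, A0 = 1) {
  network_model(
    data.frame(name = c("A", "B"), initial_concentration = c(A0, 0),
               mobile = TRUE, lipid_bound = FALSE),
    list(irreversible("decay", c(A = 1), c(B = 1), "k")),
    c(k = k))
}

tiny_reversible_model <- function(kf = 1, kr = 1, A0 = 1) {
  network_model(
    data.frame(name = c("A", "B"), initial_concentration = c(A0, 0),
               mobile = TRUE, lipid_bound = FALSE),
    list(reversible("iso", c(A = 1), c(B = 1), "kf", "kr")),
    c(kf = kf, kr = kr))
}

# prothrombin moiety: II plus every II/IIa-carrying species of the base
# model (drug complexes are added by the drug tests where relevant)
prothrombin_weights <- function() {
  c(II = 1, IIa = 1, mIIa = 1, Xa_Va_II_lipid = 1,
    IIa_ATIII = 1, mIIa_ATIII = 1, IIa_Tm = 1)
}
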