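# Core representation of a mass-action reaction network and its stiff ODE
# simulation.  All concentrations are mol/l, all times seconds, all rate
# constants in units consistent with mol/l and s.

#' Construct a mass-action rate law
#'
#' A rate law is a signed sum of monomial terms.  Each term evaluates to
#' \code{sign * prod(constants) * prod(concentrations)}, so the reversible
#' pattern \code{kf*(prod(reactants) - Ki*prod(products))} is expressed as
#' two terms sharing constants.  This monomial form covers every kinetic
#' expression in the model; no general expression parser exists or is
#' needed.
#'
#' @param terms a list of terms, each a list with elements \code{sign}
#'   (+1 or -1), \code{constants} (character vector of parameter symbols,
#'   multiplied together) and \code{species} (character vector of species
#'   names, with multiplicity).
#' @return an object of class \code{coag_rate_law}
#' @export
rate_law <- function(terms) {
  stopifnot(length(terms) >= 1L)
  for (tm in terms) {
    if (!all(c("sign", "constants", "species") %in% names(tm)))
      stop("each rate-law term needs 'sign', 'constants' and 'species'")
    if (!tm$sign %in% c(-1, 1)) stop("term sign must be +1 or -1")
    if (length(tm$constants) < 1L) stop("each term needs >= 1 rate constant")
  }
  structure(list(terms = terms), class = "coag_rate_law")
}

#' @export
print.coag_rate_law <- function(x, ...) {
  s <- vapply(x$terms, function(tm) {
    paste0(if (tm$sign < 0) "- " else "+ ",
           paste(c(tm$constants, tm$species), collapse = "*"))
  }, character(1))
  cat(paste(s, collapse = " "), "\n")
  invisible(x)
}

#' Evaluate a rate law at a given state
#'
#' @param rate a \code{coag_rate_law}
#' @param state named numeric vector of concentrations (mol/l)
#' @param params named numeric vector of rate constants
#' @return reaction rate in mol/(l*s)
#' @export
eval_rate <- function(rate, state, params) {
  stopifnot(inherits(rate, "coag_rate_law"))
  total <- 0
  for (tm in rate$terms) {
    miss <- setdiff(tm$constants, names(params))
    if (length(miss))
      stop("unresolved rate constant(s): ", paste(miss, collapse = ", "))
    missp <- setdiff(tm$species, names(state))
    if (length(missp))
      stop("unresolved species: ", paste(missp, collapse = ", "))
    total <- total + tm$sign * prod(params[tm$constants]) *
      prod(state[tm$species])
  }
  unname(total)
}

#' Construct a reaction
#'
#' @param id unique reaction identifier
#' @param reactants named integer vector of stoichiometric coefficients
#'   (may be empty for pure production)
#' @param products named integer vector of stoichiometric coefficients
#' @param rate a \code{coag_rate_law}
#' @param group optional module tag (e.g. \code{"extrinsic"},
#'   \code{"intrinsic"}, \code{"adsorption"}, \code{"drug"})
#' @return an object of class \code{coag_reaction}
#' @export
reaction <- function(id, reactants, products, rate, group = "other") {
  stopifnot(is.character(id), length(id) == 1L, inherits(rate, "coag_rate_law"))
  reactants <- .as_stoich(reactants)
  products <- .as_stoich(products)
  if (any(c(reactants, products) < 1))
    stop("stoichiometric coefficients must be >= 1 in reaction ", id)
  structure(list(id = id, reactants = reactants, products = products,
                 rate = rate, group = group),
            class = "coag_reaction")
}

.as_stoich <- function(x) {
  if (is.null(x) || length(x) == 0L) return(setNames(integer(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("stoichiometry vectors must be named by species")
  storage.mode(x) <- "integer"
  x
}

#' Shorthand for an irreversible mass-action reaction
#'
#' The rate is \code{prod(constants) * prod(reactant concentrations)}.
#' Species listed in \code{modifiers} multiply the rate law without entering
#' the stoichiometry (catalysts already present on both sides need no
#' modifier).
#'
#' @inheritParams reaction
#' @param constants character vector of parameter symbols multiplied into
#'   the single forward term
#' @param modifiers character vector of extra species in the rate law
#' @export
irreversible <- function(id, reactants, products, constants,
                         group = "other", modifiers = character(0)) {
  reactants <- .as_stoich(reactants)
  sp <- c(rep(names(reactants), reactants), modifiers)
  reaction(id, reactants, products,
           rate_law(list(list(sign = 1, constants = constants, species = sp))),
           group = group)
}

#' Shorthand for a reversible mass-action reaction
#'
#' Forward term \code{prod(kf)*prod(reactants)}, backward term
#' \code{-prod(kr)*prod(products)}, held in one reaction so that the
#' stoichiometric column carries the net conversion.
#'
#' @inheritParams irreversible
#' @param kf,kr character vectors of parameter symbols for the forward and
#'   backward monomials
#' @export
reversible <- function(id, reactants, products, kf, kr, group = "other") {
  reactants <- .as_stoich(reactants)
  products <- .as_stoich(products)
  reaction(id, reactants, products, rate_law(list(
    list(sign = 1, constants = kf,
         species = rep(names(reactants), reactants)),
    list(sign = -1, constants = kr,
         species = rep(names(products), products))
  )), group = group)
}

#' Assemble a validated network model
#'
#' Checks name uniqueness, resolvability of every species and parameter
#' symbol referenced by the reactions, and builds the species-by-reaction
#' stoichiometric matrix (products minus reactants).
#'
#' @param species data frame with columns \code{name},
#'   \code{initial_concentration} (mol/l), \code{mobile}, \code{lipid_bound}
#' @param reactions list of \code{coag_reaction}
#' @param parameters named numeric vector of rate constants; an optional
#'   \code{provenance} attribute (named character) tags each value as
#'   \code{"supplement"}, \code{"source-model"}, \code{"fitted-here"} or
#'   \code{"external-constant"}
#' @return an object of class \code{coag_model}
#' @export
network_model <- function(species, reactions, parameters) {
  stopifnot(is.data.frame(species),
            all(c("name", "initial_concentration", "mobile", "lipid_bound")
                %in% names(species)))
  if (anyDuplicated(species$name))
    stop("duplicate species name(s): ",
         paste(unique(species$name[duplicated(species$name)]), collapse = ", "))
  if (any(species$initial_concentration < 0))
    stop("negative initial concentration")
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate reaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(names(parameters)) || anyDuplicated(names(parameters)))
    stop("parameters must be uniquely named")
  if (any(!is.finite(parameters)))
    stop("non-finite parameter value(s): ",
         paste(names(parameters)[!is.finite(parameters)], collapse = ", "))

  spn <- species$name
  for (rx in reactions) {
    refd <- unique(c(names(rx$reactants), names(rx$products),
                     unlist(lapply(rx$rate$terms, `[[`, "species"))))
    miss <- setdiff(refd, spn)
    if (length(miss))
      stop("reaction ", rx$id, " references undeclared species: ",
           paste(miss, collapse = ", "))
    syms <- unique(unlist(lapply(rx$rate$terms, `[[`, "constants")))
    missk <- setdiff(syms, names(parameters))
    if (length(missk))
      stop("reaction ", rx$id, " references undeclared parameter(s): ",
           paste(missk, collapse = ", "))
  }

  S <- matrix(0, nrow = length(spn), ncol = length(reactions),
              dimnames = list(spn, ids))
  for (j in seq_along(reactions)) {
    rx <- reactions[[j]]
    S[names(rx$reactants), j] <- S[names(rx$reactants), j] - rx$reactants
    S[names(rx$products), j] <- S[names(rx$products), j] + rx$products
  }

  structure(list(species = species, reactions = reactions,
                 parameters = parameters, stoichiometric_matrix = S,
                 flow = NULL),
            class = "coag_model")
}

#' @export
print.coag_model <- function(x, ...) {
  cat("coagulation network model:", nrow(x$species), "species,",
      length(x$reactions), "reactions,", length(x$parameters), "parameters\n")
  grp <- table(vapply(x$reactions, `[[`, character(1), "group"))
  cat("  reaction groups:",
      paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$flow))
    cat("  open system: alpha =", x$flow$alpha, "cm^-2\n")
  invisible(x)
}

#' Initial-condition vector of a model
#'
#' @param model a \code{coag_model}
#' @return named numeric vector (mol/l)
#' @export
initial_state <- function(model) {
  setNames(model$species$initial_concentration, model$species$name)
}

#' Replace initial concentrations
#'
#' @param model a \code{coag_model}
#' @param initials named numeric vector; species not mentioned keep their
#'   current initial concentration
#' @export
set_initials <- function(model, initials) {
  i <- match(names(initials), model$species$name)
  if (anyNA(i))
    stop("unknown species: ", paste(names(initials)[is.na(i)], collapse = ", "))
  model$species$initial_concentration[i] <- unname(initials)
  model
}

# Lower the model to the integer-indexed form consumed by the compiled
# evaluator.  Rate-constant products are folded into per-term coefficients.
.compile_network <- function(model) {
  spn <- model$species$name
  tcoef <- numeric(0); trxn <- integer(0)
  tsp_ptr <- 0L; tsp_idx <- integer(0)
  for (j in seq_along(model$reactions)) {
    for (tm in model$reactions[[j]]$rate$terms) {
      tcoef <- c(tcoef, tm$sign * prod(model$parameters[tm$constants]))
      trxn <- c(trxn, j - 1L)
      idx <- match(tm$species, spn) - 1L
      tsp_idx <- c(tsp_idx, idx)
      tsp_ptr <- c(tsp_ptr, tsp_ptr[length(tsp_ptr)] + length(idx))
    }
  }
  S <- model$stoichiometric_matrix
  nz <- which(S != 0, arr.ind = TRUE)
  fl <- model$flow
  if (is.null(fl)) {
    mobile <- rep(0L, length(spn))
    D <- rep(0, length(spn)); cblood <- rep(0, length(spn))
  } else {
    mobile <- as.integer(model$species$mobile)
    D <- rep(fl$D, length(spn))
    cblood <- fl$c_blood[spn]
    cblood[is.na(cblood)] <- 0
  }
  cn_compile(length(spn), length(model$reactions),
             tcoef, trxn, as.integer(tsp_ptr), tsp_idx,
             nz[, 1] - 1L, nz[, 2] - 1L, S[nz],
             mobile, D, unname(cblood))
}

#' Assemble the derivative evaluator of a model
#'
#' Returns a function \code{f(state)} computing \code{d state / d t =
#' S v(state)} (plus the flow exchange term for an open system), where
#' \code{S} is the stoichiometric matrix and \code{v} the mass-action rate
#' vector.
#'
#' @param model a \code{coag_model}
#' @return function mapping a named state vector to a named derivative
#'   vector (mol/(l*s))
#' @export
assemble_rhs <- function(model) {
  xp <- .compile_network(model)
  spn <- model$species$name
  alpha <- if (is.null(model$flow)) 0 else model$flow$alpha
  function(state) {
    y <- if (is.null(names(state))) state else state[spn]
    setNames(cn_rhs(xp, unname(y), alpha), spn)
  }
}

#' Simulate a model trajectory
#'
#' Stiff-capable adaptive integration (\code{deSolve::lsoda}) with an
#' analytic Jacobian assembled from the mass-action monomials.  Tiny
#' negative excursions (within \code{100 * atol} of zero) are clipped to 0;
#' anything more negative raises an error, since that indicates a model or
#' parameter defect rather than round-off.
#'
#' @param model a \code{coag_model}
#' @param horizon simulation end time (s)
#' @param times optional explicit output times; default is an evenly spaced
#'   grid of \code{n_out} points
#' @param n_out number of output points when \code{times} is NULL
#' @param rtol,atol relative / absolute solver tolerances
#' @param maxsteps maximum internal solver steps between output points
#' @return an object of class \code{coag_trajectory} with elements
#'   \code{times} (s) and \code{concentrations} (time-by-species matrix,
#'   mol/l); the first row equals the initial conditions
#' @export
simulate_model <- function(model, horizon, times = NULL, n_out = 1200L,
                           rtol = 1e-8, atol = 1e-14, maxsteps = 50000L) {
  stopifnot(horizon > 0)
  if (is.null(times)) times <- seq(0, horizon, length.out = n_out)
  y0 <- initial_state(model)
  xp <- .compile_network(model)
  alpha <- if (is.null(model$flow)) 0 else model$flow$alpha
  func <- function(t, y, p) list(cn_rhs(xp, y, alpha))
  jacf <- function(t, y, p) cn_jac(xp, y, alpha)
  out <- deSolve::lsoda(unname(y0), times, func, parms = NULL,
                        jacfunc = jacf, jactype = "fullusr",
                        rtol = rtol, atol = atol, maxsteps = maxsteps)
  istate <- attr(out, "istate")[1]
  if (is.null(istate) || istate < 0 || nrow(out) < length(times))
    stop("stiff integration failed (istate = ", istate,
         ", returned ", nrow(out), "/", length(times), " output rows)")
  conc <- out[, -1, drop = FALSE]
  colnames(conc) <- names(y0)
  conc <- .clip_negatives(conc, atol)
  structure(list(times = out[, 1], concentrations = conc, model = model,
                 rtol = rtol, atol = atol),
            class = "coag_trajectory")
}

.clip_negatives <- function(conc, atol) {
  floor_ <- 100 * atol
  worst <- min(conc)
  if (worst < -floor_)
    stop("concentration fell to ", signif(worst, 4),
         " mol/l, below the numerical floor of ", signif(-floor_, 4),
         "; check model parameters")
  conc[conc < 0] <- 0
  conc
}

#' @export
print.coag_trajectory <- function(x, ...) {
  cat("trajectory:", length(x$times), "time points over",
      max(x$times), "s,", ncol(x$concentrations), "species\n")
  invisible(x)
}

#' Earliest threshold crossing of a species
#'
#' Finds the first output interval in which the concentration reaches
#' \code{threshold}, then refines by linear interpolation and (by default)
#' a fine re-integration of the bracketing interval from the stored state
#' at its left edge.
#'
#' @param traj a \code{coag_trajectory}
#' @param species species name
#' @param threshold mol/l
#' @param refine re-integrate the bracketing interval on a 200-point grid
#'   before interpolating
#' @return crossing time in seconds, or \code{NA_real_} if the threshold is
#'   never reached within the horizon
#' @export
first_crossing_time <- function(traj, species, threshold, refine = TRUE) {
  stopifnot(inherits(traj, "coag_trajectory"))
  if (!species %in% colnames(traj$concentrations))
    stop("species not in trajectory: ", species)
  c_ <- traj$concentrations[, species]
  if (c_[1] >= threshold) return(traj$times[1])
  k <- which(c_ >= threshold)
  if (!length(k)) return(NA_real_)
  k <- k[1]
  t0 <- traj$times[k - 1]; t1 <- traj$times[k]
  if (refine && !is.null(traj$model)) {
    m <- set_initials(traj$model, traj$concentrations[k - 1, ])
    fine <- simulate_model(m, horizon = t1 - t0,
                           times = seq(0, t1 - t0, length.out = 200L),
                           rtol = traj$rtol, atol = traj$atol)
    cf <- fine$concentrations[, species]
    kk <- which(cf >= threshold)
    if (length(kk)) {
      kk <- kk[1]
      if (kk == 1L) return(t0)
      return(t0 + .lin_cross(fine$times[kk - 1], fine$times[kk],
                             cf[kk - 1], cf[kk], threshold))
    }
  }
  .lin_cross(t0, t1, c_[k - 1], c_[k], threshold)
}

.lin_cross <- function(t0, t1, c0, c1, thr) {
  if (c1 == c0) return(t1)
  t0 + (thr - c0) / (c1 - c0) * (t1 - t0)
}

#' Maximum drift of a conserved moiety along a trajectory
#'
#' \code{weights} must define a left null-vector of the closed model's
#' stoichiometric matrix (e.g. the prothrombin moiety: II + mIIa + IIa +
#' every II/IIa-carrying complex).  Transport breaks closure, so a
#' flow-coupled model is rejected.
#'
#' @param traj a \code{coag_trajectory}
#' @param weights named numeric vector of integer weights over (a subset
#'   of) the species
#' @return max over time of \code{|sum(weights * c) - value at t = 0|}
#'   in mol/l
#' @export
conserved_moiety_residual <- function(traj, weights) {
  stopifnot(inherits(traj, "coag_trajectory"))
  model <- traj$model
  if (!is.null(model$flow) && model$flow$alpha > 0)
    stop("moiety conservation is not defined for an open (flow-coupled) ",
         "system: transport breaks closure")
  S <- model$stoichiometric_matrix
  w <- setNames(rep(0, nrow(S)), rownames(S))
  miss <- setdiff(names(weights), rownames(S))
  if (length(miss)) stop("unknown species in weights: ",
                         paste(miss, collapse = ", "))
  w[names(weights)] <- weights
  resid <- as.numeric(w %*% S)
  scale_ <- max(abs(S %*% rep(1, ncol(S))), 1)
  if (max(abs(resid)) > 1e-9 * scale_)
    stop("weights are not a left null-vector of the stoichiometric matrix ",
         "(worst reaction: ",
         colnames(S)[which.max(abs(resid))], ")")
  tot <- as.numeric(traj$concentrations %*% w)
  max(abs(tot - tot[1]))
}

#' Write a trajectory as tidy CSV
#'
#' Long format with columns \code{time_s}, \code{species},
#' \code{concentration_mol_l}.
#'
#' @param traj a \code{coag_trajectory}
#' @param path output file
#' @param species optional subset of species to write
#' @export
write_trajectory_csv <- function(traj, path, species = NULL) {
  sp <- species %||% colnames(traj$concentrations)
  df <- do.call(rbind, lapply(sp, function(s) {
    data.frame(time_s = traj$times, species = s,
               concentration_mol_l = traj$concentrations[, s])
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
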