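# Model-definition file handling (JSON canonical form, TSV export) and the
# in-vitro preparation steps shared by the assays: plasma dilution and
# factor V preactivation.

.MODEL_FORMAT_VERSION <- 1L

#' Write a model-definition file
#'
#' Serializes species, reactions (stoichiometry plus rate-law terms) and
#' provenance-tagged parameters as a single JSON document.
#'
#' @param model a \code{coag_model}
#' @param path output path
#' @export
write_model_json <- function(model, path) {
  rx <- lapply(model$reactions, function(r) {
    list(id = r$id, group = r$group,
         reactants = as.list(r$reactants),
         products = as.list(r$products),
         rate = lapply(r$rate$terms, function(tm)
           list(sign = tm$sign,
                constants = as.list(tm$constants),
                species = as.list(tm$species))))
  })
  prov <- attr(model$parameters, "provenance")
  if (is.null(prov))
    prov <- setNames(rep("source-model", length(model$parameters)),
                     names(model$parameters))
  pars <- lapply(names(model$parameters), function(s)
    list(symbol = s, value = model$parameters[[s]],
         provenance = unname(prov[s])))
  doc <- list(format_version = .MODEL_FORMAT_VERSION,
              species = model$species,
              reactions = rx,
              parameters = pars)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model-definition file
#'
#' Parses and fully validates a JSON model definition; no partially built
#' model escapes validation.  Errors name the offending entry (undeclared
#' species or parameter symbols, duplicate ids, unsupported format
#' version).
#'
#' @param path path to a JSON model definition written by
#'   \code{\link{write_model_json}}
#' @return a validated \code{coag_model}
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- doc$format_version
  if (is.null(ver) || ver != .MODEL_FORMAT_VERSION)
    stop("unsupported model file format version: ",
         if (is.null(ver)) "<missing>" else ver)
  species <- do.call(rbind, lapply(doc$species, function(s)
    data.frame(name = s$name,
               initial_concentration = as.numeric(s$initial_concentration),
               mobile = isTRUE(s$mobile),
               lipid_bound = isTRUE(s$lipid_bound))))
  reactions <- lapply(doc$reactions, function(r) {
    terms <- lapply(r$rate, function(tm)
      list(sign = as.numeric(tm$sign),
           constants = as.character(unlist(tm$constants)),
           species = as.character(unlist(tm$species))))
    reaction(r$id,
             .json_stoich(r$reactants), .json_stoich(r$products),
             rate_law(terms), group = r$group %||% "other")
  })
  vals <- vapply(doc$parameters, function(p) as.numeric(p$value), numeric(1))
  syms <- vapply(doc$parameters, function(p) as.character(p$symbol),
                 character(1))
  prov <- vapply(doc$parameters, function(p)
    as.character(p$provenance %||% NA_character_), character(1))
  if (anyNA(prov))
    stop("parameter(s) without provenance tag: ",
         paste(syms[is.na(prov)], collapse = ", "))
  pars <- setNames(vals, syms)
  attr(pars, "provenance") <- setNames(prov, syms)
  network_model(species, reactions, pars)
}

.json_stoich <- function(x) {
  if (is.null(x) || length(x) == 0L) return(setNames(integer(0), character(0)))
  setNames(as.integer(unlist(x)), names(x))
}

#' Export a model as three TSV tables
#'
#' Writes \code{<stem>_species.tsv}, \code{<stem>_reactions.tsv} and
#' \code{<stem>_parameters.tsv}.  The reaction table carries the rate law
#' as a human-readable signed-monomial string.
#'
#' @param model a \code{coag_model}
#' @param stem path stem for the three files
#' @return the three paths, invisibly
#' @export
write_model_tsv <- function(model, stem) {
  p_sp <- paste0(stem, "_species.tsv")
  p_rx <- paste0(stem, "_reactions.tsv")
  p_pa <- paste0(stem, "_parameters.tsv")
  write.table(model$species, p_sp, sep = "\t", row.names = FALSE,
              quote = FALSE)
  fmt_side <- function(v) paste(ifelse(v > 1, paste0(v, " "), ""),
                                names(v), sep = "", collapse = " + ")
  rx <- do.call(rbind, lapply(model$reactions, function(r) {
    law <- paste(vapply(r$rate$terms, function(tm)
      paste0(if (tm$sign < 0) "-" else "+",
             paste(c(tm$constants, tm$species), collapse = "*")),
      character(1)), collapse = " ")
    data.frame(id = r$id, group = r$group,
               reactants = fmt_side(r$reactants),
               products = fmt_side(r$products), rate = law)
  }))
  write.table(rx, p_rx, sep = "\t", row.names = FALSE, quote = FALSE)
  prov <- attr(model$parameters, "provenance")
  pa <- data.frame(symbol = names(model$parameters),
                   value = unname(model$parameters),
                   provenance = unname(prov[names(model$parameters)]))
  write.table(pa, p_pa, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p_sp, p_rx, p_pa))
}

#' Path to the shipped model-definition file
#'
#' The packaged JSON model definition (a provenance-tagged reconstruction;
#' see the methods vignette).
#'
#' @export
coagulation_model_file <- function() {
  system.file("extdata", "coagulation_model_synthetic.json",
              package = "coagsim", mustWork = TRUE)
}

#' Dilute plasma concentrations
#'
#' Multiplies every concentration (plasma proteins, drugs and the albumin
#' binding pool alike) by \code{factor}.  Trigger and reagent species are
#' set afterwards at their final in-assay concentrations and are not
#' further diluted.
#'
#' @param initials named numeric vector of concentrations (mol/l)
#' @param factor dilution factor in (0, 1]
#' @return diluted named vector
#' @export
dilute <- function(initials, factor) {
  if (!(factor > 0 && factor <= 1))
    stop("dilution factor must be in (0, 1], got ", factor)
  initials * factor
}

#' Preactivate a fraction of factor V
#'
#' Moves \code{fraction} of the factor V pool from V to Va; the total
#' V moiety is unchanged.
#'
#' @param initials named numeric vector of concentrations (mol/l)
#' @param fraction fraction in [0, 1] (default 1\%)
#' @export
preactivate_factor_v <- function(initials, fraction = 0.01) {
  stopifnot(fraction >= 0, fraction <= 1)
  moved <- initials[["V"]] * fraction
  initials[["V"]] <- initials[["V"]] - moved
  initials[["Va"]] <- initials[["Va"]] + moved
  initials
}
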