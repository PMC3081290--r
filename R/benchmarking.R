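# Regimen benchmarking: clotting times and alpha_crit per regimen per
# trigger scenario, referenced against warfarin titrated to INR 1.5
# (efficacy reference) and INR 3.0 (safety reference).

#' Dosing regimen table
#'
#' Plasma levels per dosing regimen: rivaroxaban (ug/l), ximelagatran
#' (uM, modelled as melagatran), DX-9065a (constant-level IV infusion,
#' ug/l), enoxaparin (mg/l), and warfarin titration targets expressed as
#' INR.  For constant-level regimens cmax = cmean = ctrough; warfarin rows
#' carry the INR in \code{inr_target} and no plasma level.
#'
#' @return data frame with columns \code{drug}, \code{dose_label},
#'   \code{daily_dose_mg}, \code{unit}, \code{cmax}, \code{cmean},
#'   \code{ctrough}, \code{inr_target}
#' @export
regimen_table <- function() {
  rv <- function(lab, daily, cmax, cmean, ctrough)
    data.frame(drug = "rivaroxaban", dose_label = lab,
               daily_dose_mg = daily, unit = "ug_l",
               cmax = cmax, cmean = cmean, ctrough = ctrough,
               inr_target = NA_real_)
  riva <- rbind(
    rv("5 OD", 5, 60.98, 24.280, 4.27),
    rv("5 BD", 10, 75.97, 42.83, 16.36),
    rv("10 OD", 10, 121.97, 48.56, 8.54),
    rv("10 BD", 20, 151.9, 85.66, 32.73),
    rv("20 OD", 20, 195.15, 77.69, 13.66),
    rv("20 BD", 40, 243.10, 137.06, 52.37),
    rv("53 OD", 53, 387.86, 154.42, 27.15),
    rv("53 BD", 106, 483.17, 272.42, 104.08))
  warf <- data.frame(drug = "warfarin",
                     dose_label = paste("INR", c(1.5, 2.0, 2.5, 3.0, 3.5, 4.0)),
                     daily_dose_mg = NA_real_, unit = "inr",
                     cmax = NA_real_, cmean = NA_real_, ctrough = NA_real_,
                     inr_target = c(1.5, 2.0, 2.5, 3.0, 3.5, 4.0))
  xim <- data.frame(drug = "melagatran",
                    dose_label = c("24 BD", "60 BD"),
                    daily_dose_mg = c(48, 120), unit = "uM",
                    cmax = c(0.21, 0.52), cmean = c(0.12, 0.31),
                    ctrough = c(0.04, 0.12), inr_target = NA_real_)
  dx <- data.frame(drug = "dx9065a",
                   dose_label = c("IV 100", "IV 200"),
                   daily_dose_mg = NA_real_, unit = "ug_l",
                   cmax = c(100, 200), cmean = c(100, 200),
                   ctrough = c(100, 200), inr_target = NA_real_)
  en <- function(lab, cmax, cmean, ctrough)
    data.frame(drug = "enoxaparin", dose_label = lab,
               daily_dose_mg = NA_real_, unit = "mg_l",
               cmax = cmax, cmean = cmean, ctrough = ctrough,
               inr_target = NA_real_)
  enox <- rbind(
    en("20 OD", 1.79, 0.76, 0.19),
    en("40 OD", 3.69, 1.57, 0.40),
    en("30 BD", 2.74, 1.95, 0.95),
    en("105 OD (1.5 mg/kg)", 12.8, 5.47, 1.40),
    en("70 BD (1 mg/kg)", 10.79, 7.67, 3.74))
  out <- rbind(riva, warf, xim, dx, enox)
  .validate_regimens(out)
  out
}

.validate_regimens <- function(df) {
  need <- c("drug", "dose_label", "unit", "cmax", "cmean", "ctrough")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("regimen table lacks column(s): ", paste(miss, collapse = ", "))
  lvl <- !is.na(df$cmax) & !is.na(df$cmean) & !is.na(df$ctrough)
  bad <- lvl & !(df$ctrough <= df$cmean & df$cmean <= df$cmax)
  if (any(bad))
    stop("regimen level ordering violated (need ctrough <= cmean <= cmax): ",
         paste(df$dose_label[bad], collapse = ", "))
  invisible(df)
}

#' Load a regimen table from TSV
#'
#' Columns as in \code{\link{regimen_table}}; the level ordering
#' \code{ctrough <= cmean <= cmax} is verified for every row.
#'
#' @param path TSV file
#' @export
load_regimens <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  .validate_regimens(df)
  df
}

.regimen_drug <- function(row, level) {
  conc <- row[[level]]
  if (is.na(conc)) return(NULL)
  drug_state(row$drug, conc, unit = row$unit)
}

#' Benchmark regimens across trigger scenarios
#'
#' For every regimen and scenario, computes the chosen metric (clotting
#' time at alpha = 0, or alpha_crit) at the requested concentration
#' levels.  Warfarin INR rows are realized through
#' \code{\link{warfarin_fraction_for_inr}} (single value), and a drug-free
#' control row is always included.  Scenarios that do not clot within the
#' horizon yield NA clotting time (reported as suppressed) or an NA
#' alpha_crit.
#'
#' @param model the base \code{coag_model}
#' @param regimens regimen data frame (default \code{\link{regimen_table}})
#' @param scenarios character vector of scenario names
#' @param metric \code{"clot_time"} or \code{"alpha_crit"}
#' @param levels concentration levels to evaluate
#' @param decision a \code{\link{clot_decision}}
#' @param alpha_rel_tol bisection tolerance for the alpha_crit metric
#' @param verbose print progress lines
#' @return a \code{data.frame} of class \code{coag_benchmark} with one row
#'   per regimen x scenario and one value column per level
#' @export
benchmark <- function(model, regimens = regimen_table(),
                      scenarios = c("extrinsic_strong", "extrinsic_weak",
                                    "intrinsic_strong", "intrinsic_weak"),
                      metric = c("clot_time", "alpha_crit"),
                      levels = c("cmean", "ctrough", "cmax"),
                      decision = clot_decision(), alpha_rel_tol = 1e-2,
                      verbose = FALSE) {
  metric <- match.arg(metric)
  .validate_regimens(regimens)
  eval_one <- function(sc, drug, warfarin) {
    if (metric == "clot_time") {
      run_scenario(model, trigger_scenario(sc), drug = drug,
                   warfarin = warfarin, alpha = 0,
                   decision = decision)$clotting_time
    } else {
      tryCatch(
        alpha_crit(model, trigger_scenario(sc), drug = drug,
                   warfarin = warfarin, decision = decision,
                   rel_tol = alpha_rel_tol)$alpha_crit,
        error = function(e) {
          if (grepl("no-clot-at-rest", conditionMessage(e))) NA_real_
          else stop(e)
        })
    }
  }
  # warfarin INR targets -> factor fractions, computed once
  inr_targets <- unique(regimens$inr_target[!is.na(regimens$inr_target)])
  warf_f <- setNames(vapply(inr_targets, function(ti)
    warfarin_fraction_for_inr(model, ti), numeric(1)),
    as.character(inr_targets))
  rows <- list()
  add_row <- function(drugname, lab, sc, vals) {
    rows[[length(rows) + 1]] <<- data.frame(
      drug = drugname, dose_label = lab, scenario = sc, metric = metric,
      t(vals))
  }
  for (sc in scenarios) {
    v <- eval_one(sc, NULL, NULL)
    add_row("none", "control", sc, setNames(rep(v, length(levels)), levels))
  }
  for (i in seq_len(nrow(regimens))) {
    row <- regimens[i, ]
    if (!is.na(row$inr_target)) {
      w <- warfarin_state(warf_f[[as.character(row$inr_target)]])
      for (sc in scenarios) {
        v <- eval_one(sc, NULL, w)
        add_row(row$drug, row$dose_label, sc,
                setNames(rep(v, length(levels)), levels))
        if (verbose) message(row$dose_label, " ", sc, ": ", signif(v, 4))
      }
    } else {
      for (sc in scenarios) {
        vals <- vapply(levels, function(lv) {
          d <- .regimen_drug(row, lv)
          if (is.null(d)) return(NA_real_)
          eval_one(sc, d, NULL)
        }, numeric(1))
        add_row(row$drug, row$dose_label, sc, vals)
        if (verbose) message(row$dose_label, " ", sc, ": ",
                             paste(signif(vals, 4), collapse = "/"))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "warfarin_fractions") <- warf_f
  class(out) <- c("coag_benchmark", class(out))
  out
}

#' Warfarin reference therapies
#'
#' @param efficacy_inr warfarin INR used as the efficacy reference
#' @param safety_inr warfarin INR used as the safety reference
#' @export
reference_therapy <- function(efficacy_inr = 1.5, safety_inr = 3.0) {
  stopifnot(safety_inr > efficacy_inr)
  list(efficacy_inr = efficacy_inr, safety_inr = safety_inr)
}

#' Classify regimens as safe and/or efficacious
#'
#' Clot-time metric: a regimen is safe if its strong-extrinsic clotting
#' time does not exceed the warfarin INR-3 reference, and efficacious if
#' its clotting time reaches at least the warfarin INR-1.5 reference in
#' all three efficacy scenarios.  For the alpha_crit metric the safety
#' inequality is inverted (safe iff alpha_crit >= INR-3 reference under
#' the strong extrinsic trigger; efficacious iff alpha_crit <= INR-1.5
#' reference in all three efficacy scenarios).  A suppressed scenario
#' (no clot, NA clotting time) counts as maximal prolongation /
#' complete inhibition.
#'
#' @param table a \code{coag_benchmark} from \code{\link{benchmark}}
#' @param refs a \code{\link{reference_therapy}}
#' @param level comparison level column (default \code{"cmean"})
#' @param safety_scenario the safety-relevant scenario
#' @return data frame with one row per regimen and logical columns
#'   \code{safe}, \code{efficacious}
#' @export
classify <- function(table, refs = reference_therapy(), level = "cmean",
                     safety_scenario = "extrinsic_strong") {
  stopifnot(level %in% names(table))
  eff_scen <- setdiff(unique(table$scenario), safety_scenario)
  ref_row <- function(inr_val, sc) {
    lab <- paste("INR", format(inr_val))
    v <- table[[level]][table$drug == "warfarin" &
                        table$dose_label == lab & table$scenario == sc]
    if (!length(v))
      stop("missing warfarin reference row: ", lab, " / ", sc)
    v
  }
  metric <- table$metric[1]
  regs <- unique(table[, c("drug", "dose_label")])
  regs <- regs[regs$drug != "none", ]
  val <- function(d, lab, sc)
    table[[level]][table$drug == d & table$dose_label == lab &
                   table$scenario == sc]
  # NA = suppressed = infinitely prolonged clotting / washout at any flow
  cmp_ct <- function(x, ref, op) {
    x <- ifelse(is.na(x), Inf, x); ref <- ifelse(is.na(ref), Inf, ref)
    if (op == "le") x <= ref else x >= ref
  }
  cmp_ac <- function(x, ref, op) {
    x <- ifelse(is.na(x), -Inf, x); ref <- ifelse(is.na(ref), -Inf, ref)
    if (op == "ge") x >= ref else x <= ref
  }
  out <- do.call(rbind, lapply(seq_len(nrow(regs)), function(i) {
    d <- regs$drug[i]; lab <- regs$dose_label[i]
    if (metric == "clot_time") {
      safe <- cmp_ct(val(d, lab, safety_scenario),
                     ref_row(refs$safety_inr, safety_scenario), "le")
      eff <- all(vapply(eff_scen, function(sc)
        cmp_ct(val(d, lab, sc), ref_row(refs$efficacy_inr, sc), "ge"),
        logical(1)))
    } else {
      safe <- cmp_ac(val(d, lab, safety_scenario),
                     ref_row(refs$safety_inr, safety_scenario), "ge")
      eff <- all(vapply(eff_scen, function(sc)
        cmp_ac(val(d, lab, sc), ref_row(refs$efficacy_inr, sc), "le"),
        logical(1)))
    }
    data.frame(drug = d, dose_label = lab, safe = safe, efficacious = eff)
  }))
  out
}

#' Therapeutic window from regimen flags
#'
#' Aggregates per-regimen safe/efficacious flags over total daily dose
#' (x BD counts twice) and reports the window endpoints; non-monotone
#' flag patterns are reported, not masked.
#'
#' @param flags output of \code{\link{classify}}
#' @param regimens regimen table supplying \code{daily_dose_mg}
#' @param drug drug whose window is sought
#' @return list with \code{min_efficacious_daily_dose},
#'   \code{max_safe_daily_dose}, \code{empty} (no window), and
#'   \code{non_monotone} diagnostics
#' @export
therapeutic_window <- function(flags, regimens = regimen_table(),
                               drug = "rivaroxaban") {
  f <- merge(flags[flags$drug == drug, ],
             regimens[regimens$drug == drug,
                      c("dose_label", "daily_dose_mg")],
             by = "dose_label")
  f <- f[order(f$daily_dose_mg), ]
  if (!nrow(f)) stop("no flags for drug ", drug)
  eff_doses <- f$daily_dose_mg[f$efficacious]
  safe_doses <- f$daily_dose_mg[f$safe]
  empty <- !length(eff_doses) || !length(safe_doses) ||
    min(eff_doses) > max(safe_doses)
  # a dose can appear twice (e.g. 5 BD and 10 OD both 10 mg/day); flag
  # order reversals over increasing dose
  nm_eff <- any(diff(f$efficacious) < 0)   # efficacy should switch F -> T
  nm_safe <- any(diff(f$safe) > 0)         # safety should switch T -> F
  list(min_efficacious_daily_dose =
         if (length(eff_doses)) min(eff_doses) else NA_real_,
       max_safe_daily_dose =
         if (length(safe_doses)) max(safe_doses) else NA_real_,
       empty = empty,
       non_monotone = c(efficacy = nm_eff, safety = nm_safe),
       flags = f)
}

#' Clotting time versus trigger strength for rivaroxaban and warfarin
#'
#' Sweeps the tissue-factor trigger concentration and records the in-vivo
#' (closed-system) clotting time at rivaroxaban trough/peak levels and at
#' the warfarin INR window edges, yielding the band data behind the
#' TF-sensitivity comparison of the two mechanisms.
#'
#' @param model the base \code{coag_model}
#' @param riva_levels rivaroxaban levels in ug/l, named (e.g.
#'   \code{c(ctrough = 30, cmax = 251)})
#' @param warfarin_inrs warfarin INR band edges
#' @param tf_grid tissue-factor concentrations (mol/l)
#' @param decision a \code{\link{clot_decision}}
#' @return data frame with columns \code{TF}, \code{therapy},
#'   \code{level}, \code{clotting_time}
#' @export
warfarin_comparison_curve <- function(model,
                                      riva_levels = c(ctrough = 30,
                                                      cmax = 251),
                                      warfarin_inrs = c(1.5, 3.0),
                                      tf_grid = 10^seq(-14, -9,
                                                       length.out = 11),
                                      decision = clot_decision()) {
  warf_f <- vapply(warfarin_inrs, function(ti)
    warfarin_fraction_for_inr(model, ti), numeric(1))
  ct_at <- function(tf, drug = NULL, warfarin = NULL) {
    sc <- structure(list(name = "tf_sweep", TF = tf, XIIa = 0),
                    class = "coag_scenario")
    run_scenario(model, sc, drug = drug, warfarin = warfarin, alpha = 0,
                 decision = decision)$clotting_time
  }
  rows <- list()
  for (tf in tf_grid) {
    for (nm in names(riva_levels))
      rows[[length(rows) + 1]] <- data.frame(
        TF = tf, therapy = "rivaroxaban", level = nm,
        clotting_time = ct_at(tf, drug = drug_state(
          "rivaroxaban", riva_levels[[nm]], "ug_l")))
    for (j in seq_along(warfarin_inrs))
      rows[[length(rows) + 1]] <- data.frame(
        TF = tf, therapy = "warfarin",
        level = paste("INR", warfarin_inrs[j]),
        clotting_time = ct_at(tf, warfarin = warfarin_state(warf_f[j])))
  }
  do.call(rbind, rows)
}
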