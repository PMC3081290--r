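test_that("the regimen table is ordered and internally consistent", {
  reg <- regimen_table()
  lvl <- !is.na(reg$cmax)
  expect_true(all(reg$ctrough[lvl] <= reg$cmean[lvl]))
  expect_true(all(reg$cmean[lvl] <= reg$cmax[lvl]))
  # the 53 mg arms were set up at double the 20 mg exposure
  cm <- function(lab)
    reg$cmean[reg$drug == "rivaroxaban" & reg$dose_label == lab]
  expect_equal(cm("53 OD") / cm("20 OD"), 2, tolerance = 0.01)
  expect_equal(cm("53 BD") / cm("20 BD"), 2, tolerance = 0.01)
  # the shipped TSV mirrors the built-in table
  tsv <- load_regimens(system.file("extdata", "regimens.tsv",
                                   package = "coagsim"))
  expect_equal(tsv$cmean, reg$cmean)
  bad <- reg
  bad$ctrough[1] <- bad$cmax[1] * 2
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_regimens(path), "ordering")
})

reduced_regimens <- function() {
  reg <- regimen_table()
  reg[(reg$drug == "rivaroxaban" &
         reg$dose_label %in% c("5 OD", "20 OD", "53 BD")) |
        reg$dose_label %in% c("INR 1.5", "INR 3"), ]
}

test_that("anticoagulation prolongs scenario clotting times dose-dependently", {
  bt <- benchmark(coag_base, reduced_regimens(),
                  scenarios = c("extrinsic_strong", "intrinsic_strong"),
                  metric = "clot_time", levels = "cmean")
  ctrl <- bt$cmean[bt$drug == "none" & bt$scenario == "extrinsic_strong"]
  riva <- bt[bt$drug == "rivaroxaban" & bt$scenario == "extrinsic_strong", ]
  riva <- riva[match(c("5 OD", "20 OD", "53 BD"), riva$dose_label), ]
  expect_true(all(is.na(riva$cmean) | riva$cmean > ctrl))
  expect_true(all(diff(ifelse(is.na(riva$cmean), Inf, riva$cmean)) >= 0))
})

test_that("classification is reflexive at the warfarin references", {
  bt <- benchmark(coag_base, reduced_regimens(), metric = "clot_time",
                  levels = "cmean")
  fl <- classify(bt)
  expect_true(fl$safe[fl$dose_label == "INR 3"])
  expect_true(fl$efficacious[fl$dose_label == "INR 1.5"])
  # row order does not matter
  fl2 <- classify(bt[rev(seq_len(nrow(bt))), ])
  key <- function(x) x[order(paste(x$drug, x$dose_label)), ]
  expect_equal(key(fl2), key(fl), ignore_attr = TRUE)
})

test_that("the therapeutic window logic reads the flag pattern", {
  reg <- regimen_table()
  flags <- data.frame(
    drug = "rivaroxaban",
    dose_label = c("5 OD", "5 BD", "10 OD", "10 BD", "20 OD", "20 BD",
                   "53 OD", "53 BD"),
    safe = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    efficacious = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  w <- therapeutic_window(flags, reg)
  expect_false(w$empty)
  expect_equal(w$min_efficacious_daily_dose, 10)
  expect_equal(w$max_safe_daily_dose, 40)
  expect_true(all(c(w$min_efficacious_daily_dose, w$max_safe_daily_dose)
                  %in% reg$daily_dose_mg[reg$drug == "rivaroxaban"]))
  # all safe, none efficacious -> empty window signal
  flags$efficacious <- FALSE
  flags$safe <- TRUE
  expect_true(therapeutic_window(flags, reg)$empty)
})

test_that("the TF sweep reproduces the two mechanisms' trigger sensitivity", {
  grid <- c(1e-14, 1e-12, 1e-9)
  cc <- warfarin_comparison_curve(coag_base, tf_grid = grid)
  for (lv in unique(paste(cc$therapy, cc$level))) {
    sel <- paste(cc$therapy, cc$level) == lv
    ct <- ifelse(is.na(cc$clotting_time[sel]), Inf, cc$clotting_time[sel])
    expect_true(all(diff(ct[order(cc$TF[sel])]) <= 0), info = lv)
  }
  # at the strongest trigger the vitamin K reference prolongs at least as
  # much as peak-level direct factor Xa inhibition
  top <- cc[cc$TF == 1e-9, ]
  expect_gte(top$clotting_time[top$therapy == "warfarin" &
                                 top$level == "INR 3"],
             top$clotting_time[top$therapy == "rivaroxaban" &
                                 top$level == "cmax"])
  # at the weakest trigger the two therapy bands overlap
  low <- cc[cc$TF == 1e-14, ]
  rb <- range(ifelse(is.na(low$clotting_time[low$therapy == "rivaroxaban"]),
                     Inf, low$clotting_time[low$therapy == "rivaroxaban"]))
  wb <- range(ifelse(is.na(low$clotting_time[low$therapy == "warfarin"]),
                     Inf, low$clotting_time[low$therapy == "warfarin"]))
  expect_true(rb[1] <= wb[2] && wb[1] <= rb[2])
})
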