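test_that("fold ratios reproduce the potency and selectivity arithmetic", {
  rec <- potency_records("rock")
  # potency gain of 12 over 13 on ROCK1: 3.39 / 0.0075 = 452
  expect_equal(as.numeric(fold_ratio(rec, 13, 12, "ROCK1")), 452,
               tolerance = 1e-12)
  # ROCK2 selectivity of 21: 1.143 / 0.051 ~ 22.4
  expect_equal(as.numeric(fold_ratio(rec, 21, 21, c("ROCK1", "ROCK2"))),
               1.143 / 0.051, tolerance = 1e-12)
  # identical records give exactly 1
  expect_equal(as.numeric(fold_ratio(rec, 12, 12, "ROCK1")), 1)
})

test_that("reciprocal fold ratios multiply to exactly one", {
  rec <- potency_records("rock")
  for (pair in list(c("12", "13"), c("21", "22"), c("14", "18"))) {
    f <- as.numeric(fold_ratio(rec, pair[1], pair[2], "ROCK2"))
    g <- as.numeric(fold_ratio(rec, pair[2], pair[1], "ROCK2"))
    expect_equal(f * g, 1, tolerance = 1e-15)
  }
})

test_that("percent records and extrapolated IC50s are rejected by default", {
  rec <- potency_records("rock")
  expect_error(fold_ratio(rec, 1, 12, "ROCK2"), "no IC50")
  expect_error(fold_ratio(rec, 1, 12, "ROCK1"), "extrapolated")
  f <- fold_ratio(rec, 1, 12, "ROCK1", allow_extrapolated = TRUE)
  expect_true(attr(f, "extrapolated"))
  expect_equal(attr(f, "display"), signif(44 / 0.0075, 2))
})

test_that("Cheng-Prusoff conversion follows the competitive-binding formula", {
  # 51 nM IC50 at [ATP] = 1 uM, Km = 10 uM
  expect_equal(cheng_prusoff_ki(0.051), 0.051 / 1.1, tolerance = 1e-12)
  # limits: no ATP -> Ki = IC50; [ATP] = Km -> Ki = IC50/2
  expect_equal(cheng_prusoff_ki(2.5, atp_conc = 0), 2.5)
  expect_equal(cheng_prusoff_ki(2.5, atp_conc = 10, km_atp = 10), 1.25)
  expect_error(cheng_prusoff_ki(1, km_atp = 0), "positive")
})

test_that("Ki conversion is monotone and round-trips to 1e-12 relative", {
  ic <- c(0.001, 0.051, 1.143, 44)
  ki <- cheng_prusoff_ki(ic)
  expect_true(all(diff(ki) > 0))
  expect_true(all(ki < ic))                       # atp_conc > 0
  expect_true(all(diff(cheng_prusoff_ki(1, km_atp = c(1, 5, 10, 50))) > 0))
  back <- ki_to_ic50(ki)
  expect_equal(back, ic, tolerance = 1e-12)
})

test_that("panel summaries single out the printed off-targets", {
  pan <- potency_records("panel")
  s21 <- panel_summary(pan, 21, threshold_percent = 10)
  expect_equal(s21$max_kinase, "PKG1a")
  expect_equal(s21$max_percent, 32.9)
  expect_equal(nrow(s21$above_threshold), 1)
  expect_equal(s21$n_below, 5)
  s18 <- panel_summary(pan, 18, threshold_percent = 50)
  expect_setequal(s18$above_threshold$kinase, c("PKAcb", "PKG1a"))
  expect_setequal(s18$above_threshold$percent, c(94.0, 98.9))
  none <- panel_summary(pan, 18, threshold_percent = 200)
  expect_equal(nrow(none$above_threshold), 0)
  empty <- panel_summary(pan, "99")
  expect_equal(nrow(empty$above_threshold), 0)
})

test_that("matched pairs report homologation and bioisostere fold gains", {
  rec <- potency_records("rock")
  # the screening hits 2 and 3 are outside the congeneric series
  expect_warning(tab <- sar_table(rec), "unannotated")
  h <- tab[tab$pair_type == "homologation" & tab$kinase == "ROCK2" &
             tab$compound_a == "12" & tab$compound_b == "17", ]
  expect_equal(nrow(h), 1)
  expect_equal(h$fold, 0.0141 / 0.003, tolerance = 1e-12)
  b <- tab[tab$pair_type == "bioisostere" & tab$kinase == "ROCK2" &
             tab$compound_a == "22" & tab$compound_b == "21", ]
  expect_equal(nrow(b), 1)
  expect_equal(b$fold, 0.232 / 0.051, tolerance = 1e-12)
  # a lone compound yields no pairs
  solo <- rec[rec$compound_id == "12", ]
  expect_equal(nrow(sar_table(solo)), 0)
})

test_that("bundled assay tables match their checked-in checksums", {
  sums <- c(rock_ic50.csv = "ba13031bf7f74b9ed5d2823f4c38c5d7",
            kinase_panel.csv = "fac7dbb35c5d7a596f30d4921a2207b8",
            pampa.csv = "12ec391c0657052f90b3c63369ffe1a7")
  for (f in names(sums)) {
    path <- system.file("extdata", f, package = "nahdesign")
    expect_equal(unname(tools::md5sum(path)), unname(sums[[f]]), info = f)
  }
  # spot transcription checks against the quoted values
  rec <- potency_records("rock")
  get <- function(id, kin) rec$value[rec$compound_id == id &
                                       rec$kinase == kin & rec$measure == "IC50"]
  expect_equal(get("12", "ROCK1"), 0.0075)
  expect_equal(get("12", "ROCK2"), 0.0141)
  expect_equal(get("18", "ROCK2"), 0.001)
  expect_equal(get("21", "ROCK1"), 1.143)
  pan <- potency_records("panel")
  expect_equal(pan$value[pan$compound_id == "21" & pan$kinase == "PKG1a"], 32.9)
  expect_equal(pan$value[pan$compound_id == "18" & pan$kinase == "PKAcb"], 94.0)
})
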