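test_that("descriptive summary bins age by decade and counts outcomes", {
  scar <- report_set(list(
    aer("DS1", "Stevens–Johnson syndrome", list(suspect("ALLOPURINOL")),
        receive_date = "2019-05-01", reporter = "health_professional",
        country = "FR", sex = "female", age_years = 65,
        outcomes = c("death", "hospitalization"))))
  tabs <- descriptive_summary(scar)
  age <- tabs$age
  expect_equal(age$count[age$label == "61-70"], 1L)
  expect_equal(sum(age$count), 1L)
  expect_equal(tabs$outcome$count[tabs$outcome$label == "death"], 1L)
  expect_equal(tabs$outcome$percent[tabs$outcome$label == "death"], 100)
  expect_equal(tabs$year$count[tabs$year$label == "2019"], 1L)
  expect_equal(tabs$sex$count[tabs$sex$label == "female"], 1L)

  # boundary ages: 10 belongs to 0-10, 11 to 11-20, 91 to >90
  scar2 <- report_set(list(
    aer("B1", "Exfoliative rash", age_years = 10),
    aer("B2", "Exfoliative rash", age_years = 11),
    aer("B3", "Exfoliative rash", age_years = 91),
    aer("B4", "Exfoliative rash")))
  age2 <- descriptive_summary(scar2)$age
  expect_equal(age2$count[age2$label == "0-10"], 1L)
  expect_equal(age2$count[age2$label == "11-20"], 1L)
  expect_equal(age2$count[age2$label == ">90"], 1L)
  expect_equal(age2$count[age2$label == "unknown"], 1L)
})

test_that("empty report sets give empty tables with zero denominators", {
  tabs <- descriptive_summary(report_set())
  for (tab in tabs) {
    expect_equal(attr(tab, "denominator"), 0L)
    expect_true(all(tab$count == 0L))
    expect_true(all(tab$percent == 0))
  }
})

test_that("partition tables sum to the denominator on simulated data", {
  cfg <- default_simulation_config(n_reports = 5000, seed = 17)
  flt <- filter_scar_reports(deduplicate_reports(generate_reports(cfg)))
  tabs <- descriptive_summary(flt$scar_set)
  n <- n_reports(flt$scar_set)
  for (nm in names(tabs)) {
    tab <- tabs[[nm]]
    expect_equal(attr(tab, "denominator"), n, info = nm)
    if (isTRUE(attr(tab, "partition")))
      expect_equal(sum(tab$count), n, info = nm)
    expect_equal(tab$percent,
                 percent_of(tab$count, n,
                            if (nm == "outcome") 0 else 1), info = nm)
  }
  expect_lte(nrow(tabs$country), 10L)
})

test_that("reporting proportions use distinct-report class semantics", {
  # one report with two suspects of the same ATC class counts once
  scar <- report_set(list(
    aer("RP1", "Stevens–Johnson syndrome",
        list(suspect("IBUPROFEN"), suspect("NAPROXEN")))))
  amap <- atc_map(list(ibuprofen = "M01AE01", naproxen = "M01AE02"))
  cul <- build_culprit_list(scar, atcmap = amap)
  cls <- reporting_proportions(scar, cul, "atc2", 10, "SMQ")
  expect_equal(nrow(cls), 1L)
  expect_equal(cls$label, "M01")
  expect_equal(cls$count, 1L)
  expect_equal(cls$percent, 100.0)

  # empty scope gives an empty table
  none <- reporting_proportions(scar, cul, "drug", 10,
                                "Toxic epidermal necrolysis")
  expect_equal(nrow(none), 0L)
  expect_error(reporting_proportions(scar, cul, "drug", 0), "top_n")
})

test_that("drug proportions reproduce direct counts (62/1000 -> 6.2%)", {
  reports <- c(
    lapply(1:62, function(i)
      aer(sprintf("T%04d", i), "Stevens–Johnson syndrome",
          list(suspect("DRUGA")))),
    lapply(63:1000, function(i)
      aer(sprintf("T%04d", i), "Stevens–Johnson syndrome",
          list(suspect(sprintf("OTHER%d", i %% 40))))))
  scar <- report_set(reports)
  cul <- build_culprit_list(scar)
  top <- reporting_proportions(scar, cul, "drug", 10, "SMQ")
  expect_equal(attr(top, "denominator"), 1000L)
  druga <- top[top$label == "druga", ]
  expect_equal(druga$count, 62L)
  expect_equal(druga$percent, 6.2)
  # sorted by count descending, ties by name
  expect_true(all(diff(top$count) <= 0))
})

test_that("positive-signal distribution conserves the drug total", {
  cfg <- default_simulation_config(
    n_reports = 8000, seed = 29,
    effects = list(effect_spec("lamotrigine", "SMQ", 8)))
  dd <- deduplicate_reports(generate_reports(cfg))
  flt <- filter_scar_reports(dd)
  cul <- build_culprit_list(flt$scar_set)
  sm <- signal_matrix(dd, cul)
  psd <- positive_signal_distribution(sm)
  total_row <- psd[psd$label == "Total", ]
  expect_equal(total_row$count, nrow(cul))
  expect_equal(total_row$percent, 100.0)
  expect_equal(sum(psd$count[psd$label != "Total"]), nrow(cul))
  per_drug <- tapply(sm$positive, sm$drug, sum)
  expect_equal(attr(psd, "n_at_least_one"), sum(per_drug >= 1))

  # all drugs zero-positive: at-least-one scalar is 0
  null_hist <- data.frame(n_positive = 0L, n_drugs = 7L)
  psd0 <- positive_signal_distribution(null_hist)
  expect_equal(attr(psd0, "n_at_least_one"), 0L)
})
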