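four_report_set <- function() {
  report_set(list(
    aer("F1", "Stevens–Johnson syndrome", list(suspect("DRUGX"))),
    aer("F2", "Headache", list(suspect("DRUGX"))),
    aer("F3", "Stevens–Johnson syndrome", list(suspect("DRUGY"))),
    aer("F4", "Headache", list(suspect("DRUGY")))))
}

test_that("contingency tables count reports into exactly one cell", {
  rs <- four_report_set()
  t_smq <- build_contingency(rs, "drugx", "SMQ")
  expect_equal(unlist(t_smq[c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_equal(t_smq$a + t_smq$b + t_smq$c + t_smq$d, n_reports(rs))

  empty <- build_contingency(report_set(), "drugx", "SMQ")
  expect_equal(unlist(empty[c("a", "b", "c", "d")]),
               c(a = 0L, b = 0L, c = 0L, d = 0L))

  # a drug absent from every report gives a+b = 0, not an error
  absent <- build_contingency(rs, "ghost", "SMQ")
  expect_equal(absent$a + absent$b, 0L)

  expect_error(contingency_table(-1, 0, 0, 0), "non-negative")
})

test_that("ROR and CI match direct evaluation of the formulas", {
  res <- compute_ror(contingency_table(5, 5, 5, 5))
  expect_equal(res$ror, 1.0)
  expect_equal(res$ci_low, exp(-1.96 * sqrt(0.8)), tolerance = 1e-12)
  expect_equal(res$ci_high, exp(1.96 * sqrt(0.8)), tolerance = 1e-12)

  res2 <- compute_ror(contingency_table(10, 90, 100, 9900))
  expect_equal(res2$ror, 11.0)
  o <- oracle_ror(10, 90, 100, 9900)
  expect_equal(res2$ci_low, o$ci_low, tolerance = 1e-12)
  expect_equal(res2$ci_high, o$ci_high, tolerance = 1e-12)

  # any table with a*d = b*c has ROR exactly 1
  expect_equal(compute_ror(contingency_table(3, 6, 7, 14))$ror, 1.0)
})

test_that("zero cells are not evaluable by default; haldane mode corrects", {
  res <- compute_ror(contingency_table(0, 10, 5, 100))
  expect_false(res$evaluable)
  expect_true(is.na(res$ror))

  hal <- compute_ror(contingency_table(0, 10, 5, 100), zero_cell = "haldane")
  expect_true(hal$evaluable)
  expect_true(hal$corrected)
  expect_equal(hal$ror, (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-12)
  # tables without zeros are untouched and unflagged in haldane mode
  clean <- compute_ror(contingency_table(5, 5, 5, 5), zero_cell = "haldane")
  expect_false(clean$corrected)
  expect_equal(clean$ror, 1.0)
})

test_that("the positive-signal rule is strict on both criteria", {
  expect_true(classify_signal(list(evaluable = TRUE, ci_low = 1.01), a = 3))
  expect_false(classify_signal(list(evaluable = TRUE, ci_low = 5.0), a = 2))
  expect_false(classify_signal(list(evaluable = TRUE, ci_low = 1.0), a = 100))
  expect_false(classify_signal(list(evaluable = FALSE, ci_low = NA), a = 50))
})

test_that("log-scale CI symmetry and drug-swap inversion hold", {
  set.seed(7)
  for (i in 1:50) {
    cells <- sample(1:300, 4, replace = TRUE)
    res <- compute_ror(do.call(contingency_table, as.list(cells)))
    expect_equal(log(res$ci_high) - log(res$ror),
                 log(res$ror) - log(res$ci_low), tolerance = 1e-12)
    # swapping the drug/other-drug columns inverts the odds ratio
    swapped <- compute_ror(contingency_table(cells[2], cells[1],
                                             cells[4], cells[3]))
    expect_equal(swapped$ror, 1 / res$ror, tolerance = 1e-12)
    expect_equal(swapped$ci_low, 1 / res$ci_high, tolerance = 1e-12)
    expect_equal(swapped$ci_high, 1 / res$ci_low, tolerance = 1e-12)
  }
})

test_that("signal_matrix yields 19 ordered results per culprit drug", {
  rs <- four_report_set()
  flt <- filter_scar_reports(rs)
  cul <- build_culprit_list(flt$scar_set)
  sm <- signal_matrix(rs, cul)
  smq <- scar_smq()
  expect_equal(nrow(sm), 19L * nrow(cul))
  for (d in cul$canonical_name) {
    block <- sm[sm$drug == d, ]
    expect_equal(block$scope, c("SMQ", smq$narrow_pts$name))
  }
  # scopes the drug never co-occurs with are not evaluable, not positive
  ten <- sm[sm$drug == "drugx" & sm$scope == "Toxic epidermal necrolysis", ]
  expect_false(ten$evaluable)
  expect_false(ten$positive)
  # cell conservation across every row
  expect_true(all(sm$a + sm$b + sm$c + sm$d == n_reports(rs)))
  # a(PT) <= a(SMQ) within each drug
  for (d in cul$canonical_name) {
    block <- sm[sm$drug == d, ]
    expect_true(all(block$a[block$scope != "SMQ"] <=
                      block$a[block$scope == "SMQ"]))
  }
})

test_that("screening matches a brute-force rescan of the matrix", {
  cfg <- default_simulation_config(
    n_reports = 8000, seed = 5,
    effects = list(effect_spec("allopurinol", "Stevens–Johnson syndrome", 30)))
  dd <- deduplicate_reports(generate_reports(cfg))
  flt <- filter_scar_reports(dd)
  cul <- build_culprit_list(flt$scar_set)
  sm <- signal_matrix(dd, cul)
  scr <- screen_positive_drugs(sm)
  per_drug <- tapply(sm$positive, sm$drug, sum)
  expect_setequal(scr$drugs, names(per_drug)[per_drug >= 1])
  expect_equal(sum(scr$histogram$n_drugs), nrow(cul))
  expect_equal(sum(scr$histogram$n_drugs[scr$histogram$n_positive >= 1]),
               length(scr$drugs))
})

test_that("scar_only background restricts the denominator set", {
  cfg <- default_simulation_config(n_reports = 6000, seed = 21)
  dd <- deduplicate_reports(generate_reports(cfg))
  flt <- filter_scar_reports(dd)
  cul <- build_culprit_list(flt$scar_set)
  sm <- signal_matrix(dd, cul, background = "scar_only")
  n_scar <- n_reports(flt$scar_set)
  expect_true(all(sm$a + sm$b + sm$c + sm$d == n_scar))
  # at SMQ level every background report has the event: d cells are empty
  expect_true(all(sm$c[sm$scope == "SMQ"] + sm$a[sm$scope == "SMQ"] == n_scar))
})
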