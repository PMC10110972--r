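test_that("only primary-suspect mentions with names are extracted", {
  r <- aer("E1", "Rash",
           list(suspect("LAMOTRIGINE"),
                drug_mention("concomitant", "VALPROATE")))
  out <- extract_primary_suspect_names(r)
  expect_equal(out$names, "LAMOTRIGINE")
  expect_equal(unname(out$excluded["missing_name"]), 0L)

  none <- extract_primary_suspect_names(
    aer("E2", "Rash", list(drug_mention("concomitant", "VALPROATE"))))
  expect_length(none$names, 0L)

  nameless <- extract_primary_suspect_names(
    aer("E3", "Rash", list(drug_mention("primary_suspect", NA, "BRAND"))))
  expect_length(nameless$names, 0L)
  expect_equal(unname(nameless$excluded["missing_name"]), 1L)
})

test_that("name normalization canonicalizes, maps and excludes", {
  idmap <- ingredient_map()
  expect_equal(normalize_name("Lamotrigine  ", idmap)$canonical, "lamotrigine")
  imap <- ingredient_map(c("diclofenac sodium" = "diclofenac",
                           "unspecified nsaid" = AMBIGUOUS))
  hit <- normalize_name("Diclofenac Sodium", imap)
  expect_equal(hit$canonical, "diclofenac")
  expect_equal(hit$reason, "")
  amb <- normalize_name("UNSPECIFIED NSAID", imap)
  expect_true(is.na(amb$canonical))
  expect_equal(amb$reason, "ambiguous")
  miss <- normalize_name(NA, imap)
  expect_equal(miss$reason, "missing_name")
})

test_that("culprit list aggregates per report with set semantics", {
  scar <- report_set(list(
    aer("C1", "Stevens–Johnson syndrome", list(suspect("ALLOPURINOL"))),
    aer("C2", "Toxic epidermal necrolysis", list(suspect("ALLOPURINOL"))),
    # the same canonical ingredient twice in one report counts once
    aer("C3", "Exfoliative rash",
        list(suspect("ACETAMINOPHEN"), suspect("Acetaminophen ")))))
  cul <- build_culprit_list(scar)
  expect_equal(cul$canonical_name, c("allopurinol", "acetaminophen"))
  expect_equal(cul$n_reports, c(2L, 1L))
  expect_equal(sort(cul$report_ids[[1]]), c("C1", "C2"))
  expect_equal(unname(attr(cul, "exclusions")["duplicated"]), 1L)

  expect_equal(nrow(build_culprit_list(report_set())), 0L)
})

test_that("culprit list order is invariant to report permutation", {
  reports <- list(
    aer("P1", "Stevens–Johnson syndrome", list(suspect("DRUG B"))),
    aer("P2", "Stevens–Johnson syndrome", list(suspect("DRUG A"))),
    aer("P3", "Toxic skin eruption", list(suspect("DRUG B"))))
  a <- build_culprit_list(report_set(reports))
  b <- build_culprit_list(report_set(rev(reports)))
  expect_equal(a$canonical_name, b$canonical_name)
  expect_equal(a$n_reports, b$n_reports)
  # count-descending, then name-ascending
  expect_equal(a$canonical_name, c("drug b", "drug a"))
})

test_that("ATC codes attach from the map and unmapped drugs are logged", {
  scar <- report_set(list(
    aer("A1", "Stevens–Johnson syndrome",
        list(suspect("LAMOTRIGINE"), suspect("MYSTERON")))))
  amap <- atc_map(list(lamotrigine = "N03AX09"))
  cul <- build_culprit_list(scar, atcmap = amap)
  expect_equal(cul$atc_codes[[match("lamotrigine", cul$canonical_name)]],
               "N03AX09")
  expect_equal(attr(cul, "unmapped_atc"), "mysteron")
  expect_error(atc_map(list(x = "BAD")), "malformed ATC")
})

test_that("per-scope culprit counts enumerate drugs by matched PT", {
  smq <- scar_smq()
  scar <- report_set(list(
    aer("S1", "Stevens–Johnson syndrome", list(suspect("LAMOTRIGINE")))))
  cul <- build_culprit_list(scar)
  tab <- culprit_counts_per_scope(cul, scar, smq)
  expect_equal(tab$n_drugs[tab$scope == "Stevens–Johnson syndrome"], 1L)
  expect_equal(tab$percent[tab$scope == "Stevens–Johnson syndrome"], 100.0)
  expect_equal(tab$n_drugs[tab$scope == "Toxic epidermal necrolysis"], 0L)
  expect_equal(tab$percent[tab$scope == "Toxic epidermal necrolysis"], 0.0)
  smq_row <- tab[tab$scope == smq$name, ]
  expect_equal(smq_row$n_drugs, 1L)
  expect_equal(smq_row$percent, 100.0)

  empty <- culprit_counts_per_scope(build_culprit_list(report_set()),
                                    report_set(), smq)
  expect_true(all(empty$n_drugs == 0L))
  expect_true(all(empty$percent == 0.0))

  # per-PT counts never exceed the SMQ total; percents re-derive from counts
  cfg <- default_simulation_config(n_reports = 4000, seed = 9)
  flt <- filter_scar_reports(deduplicate_reports(generate_reports(cfg)))
  cul2 <- build_culprit_list(flt$scar_set)
  tab2 <- culprit_counts_per_scope(cul2, flt$scar_set, smq)
  total <- tab2$n_drugs[tab2$scope == smq$name]
  expect_equal(total, nrow(cul2))
  expect_true(all(tab2$n_drugs <= total))
  expect_equal(tab2$percent, percent_of(tab2$n_drugs, total, 1))
})
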