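single_drug_config <- function(n, pt_odds, seed = 1,
                               filler = c("Nausea" = 0.3)) {
  simulation_config(
    n_reports = n,
    catalog = list(drug_spec("solodrug", "N03AX09", 1)),
    baseline_pt_odds = pt_odds, filler_reactions = filler,
    missing_name_probability = 0, duplicate_probability = 0,
    concomitant_probability = 0, seed = seed)
}

test_that("zero reports gives an empty set; seeds are reproducible", {
  cfg <- single_drug_config(0, c("Stevens–Johnson syndrome" = 0.01))
  expect_equal(n_reports(generate_reports(cfg)), 0L)

  cfg2 <- default_simulation_config(n_reports = 2000, seed = 77)
  expect_identical(generate_reports(cfg2), generate_reports(cfg2))
  # a different seed changes the draw
  cfg3 <- default_simulation_config(n_reports = 2000, seed = 78)
  expect_false(identical(generate_reports(cfg2), generate_reports(cfg3)))
})

test_that("PT frequency matches the configured odds (binomial oracle)", {
  n <- 100000
  cfg <- single_drug_config(n, c("Stevens–Johnson syndrome" = 0.01),
                            seed = 123)
  rs <- generate_reports(cfg)
  p <- 0.01 / 1.01
  hits <- sum(normalize_pt(rs$reactions$pt) ==
                normalize_pt("Stevens–Johnson syndrome"))
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(hits / n - p), 3 * se)
})

test_that("an injected odds multiplier is recovered by direct 2x2 recount", {
  n <- 100000
  cfg <- simulation_config(
    n_reports = n,
    catalog = list(drug_spec("druga", "N03AX09", 0.5),
                   drug_spec("drugb", "J01CA04", 0.5)),
    baseline_pt_odds = c("Toxic epidermal necrolysis" = 0.01),
    filler_reactions = c("Nausea" = 0.3),
    effects = list(effect_spec("druga", "Toxic epidermal necrolysis", 5)),
    missing_name_probability = 0, duplicate_probability = 0,
    concomitant_probability = 0, seed = 99)
  rs <- generate_reports(cfg)
  has_ten <- tapply(normalize_pt(rs$reactions$pt) ==
                      normalize_pt("Toxic epidermal necrolysis"),
                    rs$reactions$rec, any)
  event <- rep(FALSE, n)
  event[as.integer(names(has_ten))] <- has_ten
  is_a <- rs$drugs$generic_name[rs$drugs$role == "primary_suspect"] == "DRUGA"
  a <- sum(is_a & event); b <- sum(is_a & !event)
  cc <- sum(!is_a & event); d <- sum(!is_a & !event)
  o <- oracle_ror(a, b, cc, d)
  expect_gt(o$ci_high, 5)
  expect_lt(o$ci_low, 5)
})

test_that("no report is left without a reaction and duplicates copy ids", {
  cfg <- default_simulation_config(n_reports = 3000, seed = 31,
                                   duplicate_probability = 0.05)
  rs <- generate_reports(cfg)
  expect_true(all(rs$reports$rec %in% rs$reactions$rec))
  expect_gt(n_reports(rs), 3000L)
  dups <- rs$reports[duplicated(rs$reports$report_id), ]
  expect_gt(nrow(dups), 0L)
  # a duplicate is an exact copy of its source, apart from the record key
  src <- rs$reports[match(dups$report_id[1], rs$reports$report_id), ]
  copy <- dups[1, ]
  expect_equal(copy[setdiff(names(copy), "rec")],
               src[setdiff(names(src), "rec")], ignore_attr = TRUE)
  # deduplication restores the base count
  expect_equal(n_reports(deduplicate_reports(rs)), 3000L)
})

test_that("missing-name blanking keeps the mention via the product name", {
  cfg <- default_simulation_config(n_reports = 4000, seed = 13,
                                   missing_name_probability = 0.2)
  rs <- generate_reports(cfg)
  sus <- rs$drugs[rs$drugs$role == "primary_suspect", ]
  frac <- mean(is.na(sus$generic_name))
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.25)
  expect_true(all(!is.na(sus$raw_product_name)))
})

test_that("ground truth covers catalog x scopes with induced SMQ rows", {
  base <- c("Stevens–Johnson syndrome" = 0.01,
            "Toxic epidermal necrolysis" = 0.005)
  cfg_null <- simulation_config(
    n_reports = 10, catalog = list(drug_spec("druga", "N03AX09", 1)),
    baseline_pt_odds = base, seed = 1)
  gt <- ground_truth(cfg_null)
  expect_equal(nrow(gt), 19L)
  expect_true(all(gt$odds_multiplier == 1))
  expect_true(all(!gt$induced))

  cfg_smq <- simulation_config(
    n_reports = 10, catalog = list(drug_spec("druga", "N03AX09", 1)),
    baseline_pt_odds = base,
    effects = list(effect_spec("druga", "SMQ", 5)), seed = 1)
  gt_smq <- ground_truth(cfg_smq)
  expect_true(all(gt_smq$odds_multiplier == 5))
  expect_false(any(gt_smq$induced))

  cfg_pt <- simulation_config(
    n_reports = 10, catalog = list(drug_spec("druga", "N03AX09", 1)),
    baseline_pt_odds = base,
    effects = list(effect_spec("druga", "Stevens–Johnson syndrome", 5)),
    seed = 1)
  gt_pt <- ground_truth(cfg_pt)
  smq_row <- gt_pt[gt_pt$scope == "SMQ", ]
  expect_true(smq_row$induced)
  # marginal odds ratio by direct enumeration over the two-PT model
  p0 <- 1 - (1 / 1.01) * (1 / 1.005)
  p1 <- 1 - (1 / 1.05) * (1 / 1.005)
  expect_equal(smq_row$odds_multiplier,
               (p1 / (1 - p1)) / (p0 / (1 - p0)), tolerance = 1e-12)
  expect_equal(
    gt_pt$odds_multiplier[gt_pt$scope == "Stevens–Johnson syndrome"], 5)
  expect_equal(
    gt_pt$odds_multiplier[gt_pt$scope == "Toxic epidermal necrolysis"], 1)
})

test_that("simulation configs round-trip through their JSON schema", {
  cfg <- default_simulation_config(
    n_reports = 500, seed = 33,
    effects = list(effect_spec("allopurinol", "SMQ", 4),
                   effect_spec("lamotrigine", "Stevens–Johnson syndrome", 7)))
  path <- withr::local_tempfile(fileext = ".json")
  write_simulation_config(cfg, path)
  back <- read_simulation_config(path)
  expect_equal(back, cfg)
  # the reloaded config drives an identical generation
  expect_identical(generate_reports(back), generate_reports(cfg))
  # a config file missing a required field fails with the field named
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_reports": 10}', bad)
  expect_error(read_simulation_config(bad), "catalog")
})

test_that("invalid configurations fail naming the offending field", {
  cat1 <- list(drug_spec("a", "N03AX09", 0.5), drug_spec("b", "J01CA04", 0.4))
  expect_error(simulation_config(10, cat1,
                                 c("Stevens–Johnson syndrome" = 0.01)),
               "use_probability")
  cat2 <- list(drug_spec("a", "N03AX09", 1))
  expect_error(simulation_config(10, cat2, c("Not A Real PT" = 0.01)),
               "baseline_pt_odds")
  expect_error(simulation_config(10, cat2,
                                 c("Stevens–Johnson syndrome" = 0.01),
                                 effects = list(effect_spec("ghost", "SMQ", 2))),
               "effects.drug")
  expect_error(simulation_config(10, cat2,
                                 c("Stevens–Johnson syndrome" = 0.01),
                                 missing_name_probability = 1.5),
               "missing_name_probability")
  expect_error(effect_spec("a", "SMQ", 0), "odds_multiplier")
})

test_that("expected case counts match empirical counts at large n", {
  cfg <- default_simulation_config(n_reports = 150000, seed = 55,
                                   duplicate_probability = 0,
                                   missing_name_probability = 0)
  ec <- expected_case_counts(cfg)
  rs <- generate_reports(cfg)
  flt <- filter_scar_reports(rs)
  cul <- build_culprit_list(flt$scar_set)
  sm <- signal_matrix(rs, cul)
  m <- merge(sm[, c("drug", "scope", "a")], ec, by = c("drug", "scope"))
  big <- m[m$expected_a >= 20, ]
  expect_gt(nrow(big), 5)
  # Poisson-scale agreement: |a - E[a]| within 4 sqrt(E[a])
  expect_true(all(abs(big$a - big$expected_a) <= 4 * sqrt(big$expected_a)))
})
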