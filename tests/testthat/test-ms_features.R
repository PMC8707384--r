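# Published calculated m/z for the 17 annotated features of the bundled
# example table; rows 2, 10, 13 were produced by software with a slightly
# different mass table and agree only to 2e-4 Th.
TABLE_CALC <- data.frame(
  formula = c("C28H38N4O6", "C26H29NO5", "C22H26O6", "C17H30N2O3", "C26H28O6",
              "C24H30O6", "C37H55NO6", "C32H54N4O7", "C35H63NO3", "C42H75N7O17",
              "C21H31NO2", "C27H37N7O7", "C31H42N2O7S", "C42H63O4P",
              "C34H60N4O10", "C22H38O2", "C32H26O10"),
  adduct = c("[M+H]+", "[M+2ACN+H]+", "[M+H]+", "[M+2ACN+H]+", "[M+H]+",
             "[M+H]+", "[M+2ACN+H]+", "[M+ACN+H]+", "[M+H]+", "[M+ACN+H]+",
             "[M+2ACN+H]+", "[M+2ACN+H]+", "[M+2ACN+H]+", "[M+H]+", "[M+H]+",
             "[M+ACN+H]+", "[M+ACN+H]+"),
  calc = c(527.2864, 518.2650, 387.1802, 393.2860, 437.1959, 415.2115,
           692.4633, 648.4331, 546.4881, 991.5557, 412.2959, 654.3358,
           669.3317, 663.4537, 685.4382, 376.3210, 612.1864),
  stringsAsFactors = FALSE)
EXACT_ROWS <- setdiff(1:17, c(2, 10, 13))

test_that("formula parsing and monoisotopic masses", {
  expect_equal(monoisotopic_mass("H"), 1.00782503)
  expect_equal(monoisotopic_mass("C34H60N4O10"), 684.430942, tolerance = 1e-5)
  expect_equal(monoisotopic_mass(""), 0)
  expect_equal(parse_formula("CH4")[["H"]], 4L)
  expect_error(monoisotopic_mass("C28H38N4O6X"), "unsupported element")
  expect_error(parse_formula("C28-H38"), "cannot parse")
})

test_that("adduct normalization maps variants to one canonical label", {
  expect_equal(normalize_adduct("[M+H]+"), normalize_adduct(" [m+h]+ "))
  expect_equal(normalize_adduct("[M+ACN+H] ^+^"), "[M+ACN+H]+")
  expect_error(normalize_adduct("[M+Na]+"), "supported")
})

test_that("adduct_mz reproduces the published calculated column", {
  got <- mapply(adduct_mz, TABLE_CALC$formula, TABLE_CALC$adduct)
  expect_equal(unname(got[EXACT_ROWS]), TABLE_CALC$calc[EXACT_ROWS],
               tolerance = 1e-9)  # exact at 4 d.p. after rounding
  expect_true(all(abs(got[-EXACT_ROWS] - TABLE_CALC$calc[-EXACT_ROWS]) <= 2e-4))
})

test_that("ppm error convention", {
  expect_equal(ppm_error(500, 500), 0)
  expect_equal(round(ppm_error(527.2838, 527.2864), 2), 4.93)
  expect_equal(round(ppm_error(685.4385, 685.4382), 2), 0.44)
  expect_error(ppm_error(500, 0), "positive")
})

test_that("mass fraction above threshold", {
  ft <- feature_table("E", c("a", "b", "c", "d"), rt_min = 1:4,
                      mz_observed = c(200, 300, 400, 500))
  expect_equal(mass_fraction_above(ft, 330), 50)
  expect_equal(mass_fraction_above(ft, 100), 100)
  # the bundled 17-feature table: min observed m/z 376.32 -> all above 330
  expect_equal(mass_fraction_above(example_feature_table(), 330), 100)
  # neutral mode subtracts the adduct shift: M = 376.32 - 42.03 = 334.29
  ft2 <- feature_table("E", "x", 1, 376.3202, "C22H38O2", "[M+ACN+H]+")
  expect_equal(mass_fraction_above(ft2, 335), 100)
  expect_equal(mass_fraction_above(ft2, 335, neutral = TRUE), 0)
  expect_error(mass_fraction_above(feature_table("E", character(0),
                                                 numeric(0), numeric(0))),
               "empty")
})

test_that("identical duplicated tables group fully; disjoint ranges do not", {
  t1 <- feature_table("A", c("f1", "f2"), c(5, 10), c(400.2001, 600.303))
  t2 <- feature_table("B", c("g1", "g2"), c(5, 10), c(400.2001, 600.303))
  g <- match_features(list(t1, t2), ppm_tol = 10, rt_tol = 0.2)
  ic <- intersection_counts(g)
  expect_equal(ic$count[ic$subset == "A&B"], 2L)

  t3 <- feature_table("B", c("g1", "g2"), c(5, 10), c(450.5, 700.7))
  g2 <- match_features(list(t1, t3))
  ic2 <- intersection_counts(g2)
  expect_false("A&B" %in% ic2$subset)
  expect_equal(sum(ic2$count), 4L)
})

test_that("planted 9-feature overlap is recovered exactly", {
  tabs <- make_feature_tables(c("A", "B", "C"), n_unique = 20,
                              shared = list(AB = c("A", "B")), n_shared = 9,
                              jitter_ppm = 5, seed = 11)
  g <- match_features(tabs, ppm_tol = 10, rt_tol = 0.2)
  ic <- intersection_counts(g)
  expect_equal(ic$count[ic$subset == "A&B"], 9L)
  expect_equal(ic$count[ic$subset == "A"], 20L)
  expect_equal(ic$count[ic$subset == "C"], 20L)
})

test_that("group partition is exhaustive/disjoint; counts sum to groups", {
  for (seed in 1:5) {
    tabs <- make_feature_tables(c("A", "B", "C"), n_unique = 15,
                                shared = list(AB = c("A", "B"),
                                              BC = c("B", "C")),
                                n_shared = 4, seed = seed)
    g <- match_features(tabs)
    expect_false(anyNA(g$group))
    expect_equal(nrow(g), sum(vapply(tabs, nrow, integer(1))))
    ic <- intersection_counts(g)
    expect_equal(sum(ic$count), length(unique(g$group)))
  }
})

test_that("annotation assigns levels 3/4 with isomer counts", {
  feat <- feature_table("E", "f1", 2.81, 527.2838)
  one <- annotate_features(feat, data.frame(name = "cmpdA",
                                            formula = "C28H38N4O6"))
  expect_equal(one$summary$identification_level, 3L)
  expect_equal(one$summary$isomer_coincidence, 1L)

  four <- annotate_features(feat, data.frame(
    name = paste0("iso", 1:4), formula = rep("C28H38N4O6", 4)))
  expect_equal(four$summary$identification_level, 4L)
  expect_equal(four$summary$isomer_coincidence, 4L)

  none <- annotate_features(feat, data.frame(name = character(0),
                                             formula = character(0)))
  expect_equal(nrow(none$candidates), 0L)

  # window: a compound 20 ppm away is not a candidate at 10 ppm
  far <- annotate_features(
    feature_table("E", "f1", 2.81, 527.2864 * (1 + 20e-6)),
    data.frame(name = "cmpdA", formula = "C28H38N4O6"), adducts = "[M+H]+")
  expect_equal(nrow(far$candidates), 0L)
})

test_that("zero-jitter synthetic tables annotate every planted compound", {
  tabs <- make_feature_tables(c("A", "B"), n_unique = 8, jitter_ppm = 0,
                              seed = 4)
  compounds <- data.frame(name = tabs$A$feature_id, formula = tabs$A$formula)
  ann <- annotate_features(tabs$A, compounds, ppm_tol = 5)
  expect_equal(nrow(ann$summary), nrow(tabs$A))
  expect_equal(sort(ann$summary$feature_id), sort(tabs$A$feature_id))
  got <- ann$summary$formula[match(tabs$A$feature_id, ann$summary$feature_id)]
  expect_equal(got, tabs$A$formula)
})
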