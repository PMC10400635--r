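# Independent atomic-mass summation oracle: a test-local IUPAC table,
# distinct from the package's internal constants path.
ORACLE_MASS <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                 O = 15.9949146196, S = 31.97207100, F = 18.99840322,
                 Cl = 34.96885268, Na = 22.9897692809)
oracle_mass <- function(counts) {
  sum(ORACLE_MASS[names(counts)] * counts)
}

test_that("formula parsing round-trips through canonical Hill order", {
  f <- parse_formula("C22H27FN4O2")
  expect_equal(unclass(f)[c("C", "H", "F", "N", "O")],
               c(C = 22L, H = 27L, F = 1L, N = 4L, O = 2L),
               ignore_attr = TRUE)
  expect_equal(format_formula(f), "C22H27FN4O2")
  expect_equal(format_formula(parse_formula("H2O")), "H2O")
  expect_equal(format_formula(parse_formula("O1H2")), "H2O")
  expect_error(parse_formula("C-1"), "parse|element")
  expect_error(parse_formula("Xy3"), "unknown element")
})

test_that("monoisotopic masses match an independent summation", {
  expect_equal(monoisotopic_mass("C22H27FN4O2"),
               oracle_mass(c(C = 22, H = 27, F = 1, N = 4, O = 2)),
               tolerance = 1e-4)
  expect_equal(monoisotopic_mass("C22H27FN4O2"), 398.2118,
               tolerance = 1e-4)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(parse_formula("")), 0)
  # protonated molecular ion of the parent drug
  mh <- ion_rules("positive")
  mh <- mh[mh$name == "[M+H]+", ]
  expect_equal(xenofate:::ion_mz(monoisotopic_mass("C22H27FN4O2"), mh),
               399.2191, tolerance = 1e-4)
})

test_that("every default rule's delta mass matches formula arithmetic", {
  expected <- c("oxidation" = 15.994915,
                "demethylation" = -14.015650,
                "de-ethylation" = -28.031300,
                "dehydrogenation" = -2.015650,
                "saturation" = 2.015650,
                "oxidative defluorination" = -1.995663,
                "glucuronidation" = 176.032088,
                "sulfation" = 79.956815,
                "methylation" = 14.015650,
                "glycine conjugation" = 57.021464)
  rules <- default_rules()
  names(rules) <- vapply(rules, `[[`, "", "name")
  expect_setequal(names(rules), names(expected))
  for (nm in names(expected)) {
    expect_equal(rules[[nm]]$delta_mass, expected[[nm]],
                 tolerance = 1e-4, label = nm)
    # delta equals mass(added) - mass(removed) via the oracle table
    oracle_delta <- oracle_mass(unclass(rules[[nm]]$added)) -
      oracle_mass(unclass(rules[[nm]]$removed))
    if (length(rules[[nm]]$added) == 0) {
      oracle_delta <- -oracle_mass(unclass(rules[[nm]]$removed))
    }
    expect_equal(rules[[nm]]$delta_mass, oracle_delta, tolerance = 1e-4,
                 label = nm)
  }
})

test_that("apply_rule does formula arithmetic and rejects negatives", {
  rules <- default_rules()
  names(rules) <- vapply(rules, `[[`, "", "name")
  sun <- parse_formula("C22H27FN4O2")
  ox <- apply_rule(sun, rules[["oxidation"]])
  expect_equal(format_formula(ox), "C22H27FN4O3")
  expect_equal(monoisotopic_mass(ox) - monoisotopic_mass(sun),
               15.994915, tolerance = 1e-6)
  deet <- apply_rule(sun, rules[["de-ethylation"]])
  expect_equal(format_formula(deet), "C20H23FN4O2")
  expect_equal(monoisotopic_mass(deet) - monoisotopic_mass(sun),
               -28.031300, tolerance = 1e-6)
  expect_null(apply_rule(parse_formula("H2O"), rules[["de-ethylation"]]))
})

test_that("mass conservation holds for every rule on the parent", {
  sun <- parse_formula("C22H27FN4O2")
  for (r in default_rules()) {
    g <- apply_rule(sun, r)
    if (is.null(g)) next
    expect_equal(monoisotopic_mass(g) - monoisotopic_mass(sun),
                 r$delta_mass, tolerance = 1e-6, label = r$name)
  }
})

test_that("enumeration matches exhaustive hand enumeration", {
  ox_only <- list(transformation_rule("oxidation", "I", added = "O"))
  out <- enumerate_products("C10H12N2O", ox_only, max_steps = 2)
  expect_equal(nrow(out), 2)
  expect_setequal(out$formula, c("C10H12N2O2", "C10H12N2O3"))

  # parent too small to de-ethylate twice; phase II capped at one step
  two <- list(transformation_rule("de-ethylation", "I", removed = "C2H4"),
              transformation_rule("glucuronidation", "II",
                                  added = "C6H8O6"))
  out2 <- enumerate_products("C3H6O", two, max_steps = 2,
                             max_phase2 = 1)
  expect_equal(nrow(out2), 3)  # no double glucuronide
  expect_setequal(out2$formula, c("CH2O", "C9H14O7", "C7H10O7"))
})

test_that("raising max_steps only adds products", {
  p2 <- enumerate_products("C22H27FN4O2", max_steps = 2)
  p3 <- enumerate_products("C22H27FN4O2", max_steps = 3)
  expect_true(all(p2$formula %in% p3$formula))
  expect_gt(nrow(p3), nrow(p2))
})

test_that("dedup keeps the shortest path with deterministic tie-breaks", {
  # oxidation + saturation vs saturation + oxidation: same formula
  rules <- list(transformation_rule("oxidation", "I", added = "O"),
                transformation_rule("saturation", "I", added = "H2"))
  out <- enumerate_products("C10H12N2O", rules, max_steps = 2)
  both <- out[out$formula == "C10H14N2O2", ]
  expect_equal(nrow(both), 1)
  expect_equal(both$path, "oxidation > saturation")  # lexicographic tie
})

test_that("product matching uses ppm tolerance and deduplicates isomers", {
  groups <- data.frame(group_id = "G1", neutral_mass = 414.2060)
  prods <- data.frame(
    formula = c("C22H27FN4O3", "C22H27FN4O3"),
    neutral_mass = rep(monoisotopic_mass("C22H27FN4O3"), 2),
    path = c("oxidation", "oxidation > noop"),
    n_steps = c(1L, 2L), n_phase1 = c(1L, 2L), n_phase2 = c(0L, 0L),
    stringsAsFactors = FALSE)
  hits <- match_products(groups, prods)
  expect_equal(nrow(hits), 1)  # isomers deduplicated by formula
  expect_equal(hits$ppm_error, -1.7, tolerance = 0.1)
  far <- match_products(
    data.frame(group_id = "G2",
               neutral_mass = 414.2067 * (1 + 25e-6)),
    prods)
  expect_equal(nrow(far), 0)
})
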