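# Limiting-dilution Poisson mathematics and species proportions.

test_that("lambda estimation inverts the Poisson zero class", {
  e <- estimate_lambda(24, 96)
  expect_equal(e$p_positive, 0.25)
  expect_equal(e$lambda, -log(0.75), tolerance = 1e-12)
  expect_equal(e$lambda, 0.2877, tolerance = 1e-4)
  expect_true(e$ci_lambda[["lower"]] < e$lambda &&
                e$lambda < e$ci_lambda[["upper"]])
  expect_equal(estimate_lambda(0, 96)$lambda, 0)
  expect_error(estimate_lambda(96, 96), "dilute")
  expect_error(estimate_lambda(-1, 96), "lie in")
})

test_that("wilson interval matches prop.test's score interval", {
  for (case in list(c(24, 96), c(3, 96), c(60, 96))) {
    w <- wilson_ci(case[1], case[2])
    p <- prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(unname(w), as.numeric(p), tolerance = 1e-9)
  }
})

test_that("lambda recovery from simulated plates is within 3 binomial SE", {
  for (lambda in c(0.25, 0.8)) {
    cfg <- synth_config(smpcr = list(lambda = lambda, n_plates = 50L,
                                     proportions = c(`5` = 1)))
    sm <- gen_smpcr_plates(cfg, seed = 40 + round(100 * lambda))
    n_pos <- sum(sm$wells$outcome != "negative")
    n <- nrow(sm$wells)
    est <- estimate_lambda(n_pos, n)
    p_true <- 1 - exp(-lambda)
    se_lambda <- sqrt(p_true * (1 - p_true) / n) / (1 - p_true)
    expect_lt(abs(est$lambda - lambda), 3 * se_lambda)
  }
})

test_that("dilution factor scales lambda to the target occupancy", {
  expect_equal(dilution_factor(1.15, 0.25), -log(0.75) / 1.15,
               tolerance = 1e-12)
  expect_equal(dilution_factor(1.15, 0.25), 0.2502, tolerance = 1e-3)
  expect_equal(dilution_factor(-log(0.75), 0.25), 1, tolerance = 1e-12)
  expect_error(dilution_factor(0), "> 0")
})

test_that("multiplicity probability has the closed form and is monotone", {
  # closed form at the 1-in-4 operating point: e^-lambda = 0.75 exactly,
  # (1 - 0.75 * (1 + lambda)) / 0.25
  lam <- -log(0.75)
  expect_equal(multiplicity_probability(lam),
               (1 - 0.75 * (1 + lam)) / 0.25, tolerance = 1e-12)
  expect_equal(multiplicity_probability(lam), 0.13695, tolerance = 1e-4)
  # analytic limit at lambda -> 0 is 0
  expect_lt(multiplicity_probability(1e-8), 1e-7)
  grid <- multiplicity_probability(seq(0.01, 3, by = 0.01))
  expect_true(all(diff(grid) > 0))
  expect_error(multiplicity_probability(0), "> 0")
})

test_that("species proportions are positive-well fractions with Wilson CIs", {
  s <- species_proportions(data.frame(size_kb = c(4, 5),
                                      positive_wells = c(23, 77)),
                           cell_id = "P7_f1")
  expect_equal(s$species$proportion, c(0.23, 0.77))
  expect_equal(s$n_species, 2L)
  expect_equal(sum(s$species$proportion), 1, tolerance = 1e-9)
  expect_equal(unname(unlist(
    s$species[1, c("ci_lower", "ci_upper")])),
    unname(wilson_ci(23, 100)), tolerance = 1e-12)

  one <- species_proportions(data.frame(size_kb = 5, positive_wells = 12))
  expect_equal(one$species$proportion, 1)
  eq <- species_proportions(data.frame(size_kb = c(4, 6),
                                       positive_wells = c(10, 10)))
  expect_equal(eq$species$proportion, c(0.5, 0.5))
  expect_error(species_proportions(data.frame(size_kb = 4,
                                              positive_wells = 0)),
               "no positive")
})

test_that("proportions are invariant under species relabelling", {
  a <- species_proportions(data.frame(size_kb = c(4, 7, 9),
                                      positive_wells = c(5, 10, 15)))
  b <- species_proportions(data.frame(size_kb = c(9, 4, 7),
                                      positive_wells = c(15, 5, 10)))
  expect_equal(a$species, b$species)
})

test_that("well tallies convert plate read-outs to species counts", {
  wells <- data.frame(well = 1:6,
                      outcome = c("negative", "5", "negative", "8.5",
                                  "5", "negative"))
  t <- tally_wells(wells)
  expect_equal(t$size_kb, c(5, 8.5))
  expect_equal(t$positive_wells, c(2L, 1L))
  expect_equal(attr(t, "n_wells"), 6L)
  expect_error(tally_wells(data.frame(well = 1, outcome = "smear")),
               "non-numeric")
})

test_that("largest-deletion prevalence reproduces the published fractions", {
  fx <- load_paper_fixtures()
  lp <- largest_prevalence(fx$smpcr)
  lp <- lp[match(c("P7", "P8", "P16"), lp$patient_id), ]
  expect_equal(lp$n_multi, c(10L, 12L, 8L))
  expect_equal(lp$n_largest_most_prevalent, c(4L, 5L, 3L))
  expect_equal(lp$pct, c(40.0, 41.7, 37.5))
  expect_equal(lp$n_ties, c(0L, 0L, 0L))
})

test_that("ties are excluded from the numerator and reported", {
  cells <- data.frame(
    patient_id = "P",
    cell_id = c(1, 1, 2, 2, 3, 3),
    size_kb = c(4, 6, 5, 7, 5, 5),
    proportion = c(0.5, 0.5, 0.3, 0.7, 0.4, 0.6))
  lp <- largest_prevalence(cells)
  # cell 1: tied proportions; cell 3: tied sizes; cell 2: strict yes
  expect_equal(lp$n_multi, 3L)
  expect_equal(lp$n_ties, 2L)
  expect_equal(lp$n_largest_most_prevalent, 1L)

  singles <- data.frame(patient_id = "Q", cell_id = 1:3,
                        size_kb = c(4, 5, 6), proportion = 1)
  expect_true(is.na(largest_prevalence(singles)$fraction))
})

test_that("multiplicity distribution matches the published cell groupings", {
  fx <- load_paper_fixtures()
  # long-range PCR table: products per cell
  per_cell <- as.integer(table(fx$deletions$cell_id))
  md <- multiplicity_distribution(per_cell)
  expect_equal(md$n_cells, c(14L, 5L, 2L))
  expect_equal(md$pct[1:2], c(66.7, 23.8))
  # smPCR table, patient P7: 16 single- and 10 double-species fibres
  p7 <- fx$smpcr[fx$smpcr$patient_id == "P7", ]
  md7 <- multiplicity_distribution(as.integer(table(p7$cell_id)))
  expect_equal(md7$n_cells, c(16L, 10L))
  one <- multiplicity_distribution(1L)
  expect_equal(one$n_cells, 1L)
})

test_that("table anomalies are flagged, never corrected", {
  fx <- load_paper_fixtures()
  an <- flag_smpcr_anomalies(fx$smpcr)
  expect_setequal(an$anomaly,
                  c("largest_flag", "proportion_sum", "duplicate_size"))
  expect_true(all(an$patient_id == "P8"))
  expect_equal(sort(unique(an$cell_id[an$anomaly != "largest_flag"])), 7)
  expect_equal(an$cell_id[an$anomaly == "largest_flag"], 21)
  # the flagged rows stay untouched in the data itself
  f7 <- fx$smpcr[fx$smpcr$patient_id == "P8" & fx$smpcr$cell_id == 7, ]
  expect_equal(sum(f7$proportion), 1.3553)
})

test_that("pooled-plate proportions converge to the generating truth", {
  cfg <- synth_config(smpcr = list(lambda = 0.05, n_plates = 10L,
                                   proportions = c(`4` = 0.3, `8` = 0.7)))
  sm <- gen_smpcr_plates(cfg, seed = 55)
  t <- tally_wells(sm$wells)
  s <- species_proportions(t)
  # at low lambda the size-bias is negligible; truth within the Wilson CI
  for (i in seq_len(nrow(s$species))) {
    truth <- cfg$smpcr$proportions[[as.character(s$species$size_kb[i])]]
    expect_gt(truth, s$species$ci_lower[i] - 1e-9)
    expect_lt(truth, s$species$ci_upper[i] + 1e-9)
  }
})
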