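# Immunofluorescence z-scoring and classification.

make_controls <- function(n = 50, slope_nd = 2, int_nd = 1,
                          slope_cx = 1.5, int_cx = 0.5, resid_sd = 0,
                          seed = 1) {
  set.seed(seed)
  p <- runif(n, 0.5, 1.5)
  data.frame(
    fibre_id = sprintf("C%03d", seq_len(n)),
    od_porin = p,
    od_ndufb8 = int_nd + slope_nd * p + rnorm(n, 0, resid_sd),
    od_coxi = int_cx + slope_cx * p + rnorm(n, 0, resid_sd)
  )
}

test_that("background correction subtracts the NPC mean with a zero floor", {
  expect_equal(background_correct(0.50, 0.10), 0.40)
  expect_equal(background_correct(0.50, 0.00), 0.50)
  expect_equal(background_correct(0.05, 0.10), 0.00)
  expect_error(background_correct(-0.1, 0), ">= 0")
})

test_that("control model recovers an exact linear relationship", {
  m <- fit_control_model(make_controls(resid_sd = 0))
  expect_equal(m$slope_ndufb8, 2, tolerance = 1e-10)
  expect_equal(m$intercept_ndufb8, 1, tolerance = 1e-10)
  expect_equal(m$resid_sd_ndufb8, 0, tolerance = 1e-10)
  expect_equal(m$slope_coxi, 1.5, tolerance = 1e-10)
})

test_that("control model recovers slope within 3 SE under noise", {
  n <- 200
  ctrl <- make_controls(n = n, resid_sd = 0.1, seed = 11)
  m <- fit_control_model(ctrl)
  # closed-form OLS standard error as the oracle
  x <- ctrl$od_porin
  se_slope <- 0.1 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(m$slope_ndufb8 - 2), 3 * se_slope)
  expect_equal(m$resid_sd_ndufb8, 0.1, tolerance = 0.25)
})

test_that("degenerate control sets are rejected", {
  expect_error(fit_control_model(make_controls(n = 2)), "at least 3")
  flat <- make_controls(n = 10)
  flat$od_porin <- 1
  expect_error(fit_control_model(flat), "variance")
})

test_that("z-scores are residuals in units of the control scatter", {
  ctrl <- make_controls(n = 100, resid_sd = 0.05, seed = 2)
  m <- fit_control_model(ctrl)
  on_line <- data.frame(
    fibre_id = "f1", od_porin = 1,
    od_ndufb8 = m$intercept_ndufb8 + m$slope_ndufb8 * 1,
    od_coxi = m$intercept_coxi + m$slope_coxi * 1)
  z <- zscores(on_line, m)
  expect_equal(z$z_ndufb8, 0, tolerance = 1e-12)
  expect_equal(z$z_coxi, 0, tolerance = 1e-12)

  at_mean <- on_line
  at_mean$od_porin <- m$porin_mean
  at_mean$od_ndufb8 <- m$intercept_ndufb8 + m$slope_ndufb8 * m$porin_mean
  at_mean$od_coxi <- m$intercept_coxi + m$slope_coxi * m$porin_mean
  expect_equal(zscores(at_mean, m)$z_porin, 0, tolerance = 1e-12)

  shifted <- on_line
  shifted$od_ndufb8 <- shifted$od_ndufb8 - 2 * m$resid_sd_ndufb8
  expect_equal(zscores(shifted, m)$z_ndufb8, -2, tolerance = 1e-12)
})

test_that("control set scores itself to near-zero mean z per channel", {
  ctrl <- make_controls(n = 150, resid_sd = 0.08, seed = 3)
  m <- fit_control_model(ctrl)
  z <- zscores(ctrl, m)
  for (col in c("z_porin", "z_ndufb8", "z_coxi")) {
    expect_lt(abs(mean(z[[col]])), 3 / sqrt(nrow(ctrl)))
  }
})

test_that("log-space model scores log-displaced fibres exactly", {
  set.seed(4)
  n <- 80
  p <- runif(n, 0.5, 1.5)
  ctrl <- data.frame(fibre_id = sprintf("C%03d", 1:n), od_porin = p,
                     od_ndufb8 = exp(0.3 + 0.9 * log(p)),
                     od_coxi = exp(0.1 + 1.1 * log(p)))
  # exact line in log space needs some scatter for a finite z; perturb one
  ctrl$od_ndufb8[1] <- ctrl$od_ndufb8[1] * 1.05
  m <- fit_control_model(ctrl, log_transform = TRUE)
  expect_true(m$log_transform)
  f <- data.frame(fibre_id = "f", od_porin = 1,
                  od_ndufb8 = exp(0.3 + 0.9 * log(1)), od_coxi = exp(0.1))
  z <- zscores(f, m)
  expect_lt(abs(z$z_ndufb8), 0.5)
  expect_error(zscores(data.frame(fibre_id = "g", od_porin = 0,
                                  od_ndufb8 = 1, od_coxi = 1), m),
               "positive")
})

test_that("classification applies the documented boundaries", {
  z <- data.frame(z_porin = c(0, 2.6, 0, -2.5, 3.5),
                  z_ndufb8 = c(-5, 0, -7, -3.5, 0),
                  z_coxi = c(0, 0, -7, -6.5, 0))
  cl <- classify_fibre(z)
  expect_equal(cl$mrc_class,
               c("CI-CIV+", "CI+CIV+", "CI-CIV-", "CI-CIV-", "CI+CIV+"))
  expect_equal(cl$is_rrf, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(cl$level_ndufb8[3], "deficient")
  expect_equal(cl$level_ndufb8[4], "intermediate_plus")
  expect_equal(cl$level_coxi[4], "deficient")
  expect_equal(cl$mass_class, c("normal", "high", "normal", "low",
                                "very_high"))
})

test_that("every fibre gets exactly one MRC and one mass class", {
  set.seed(5)
  z <- data.frame(z_porin = rnorm(500, 0, 3), z_ndufb8 = rnorm(500, -3, 3),
                  z_coxi = rnorm(500, -3, 3))
  cl <- classify_fibre(z)
  expect_false(any(is.na(cl$mrc_class)))
  expect_false(any(is.na(cl$mass_class)))
  expect_true(all(cl$mrc_class %in%
                    c("CI+CIV+", "CI-CIV+", "CI+CIV-", "CI-CIV-")))
  expect_true(all(cl$mass_class %in%
                    c("very_low", "low", "normal", "high", "very_high")))
})

test_that("cohort summaries reproduce known contingency percentages", {
  # RRF cohort with the published composition: 535 CI-CIV-, 67 CI+CIV-,
  # 2 CI-CIV+ and 32 normal out of 636 RRF fibres
  mrc <- c(rep("CI-CIV-", 535), rep("CI+CIV-", 67), rep("CI-CIV+", 2),
           rep("CI+CIV+", 32))
  cl <- data.frame(fibre_id = seq_along(mrc), mrc_class = mrc,
                   is_rrf = TRUE,
                   fibre_type = NA_character_)
  s <- summarize_cohort(cl)
  expect_equal(s$rrf_by_mrc$pct[s$rrf_by_mrc$category == "CI-CIV-"], 84.1)
  expect_equal(s$rrf_by_mrc$pct[s$rrf_by_mrc$category == "CI+CIV-"], 10.5)
  expect_equal(s$rrf_by_mrc$pct[s$rrf_by_mrc$category == "CI-CIV+"], 0.3)
  expect_equal(sum(s$rrf_by_mrc$pct), 100, tolerance = 0.2)

  # typed RRF: 30 type I, 7 IIa, 1 IIx/IIb of 38
  cl2 <- data.frame(fibre_id = 1:38, mrc_class = "CI-CIV-", is_rrf = TRUE,
                    fibre_type = c(rep("I", 30), rep("IIa", 7), "IIx/IIb"))
  s2 <- summarize_cohort(cl2)
  expect_equal(s2$rrf_by_type$pct, c(78.9, 18.4, 2.6))

  single <- summarize_cohort(data.frame(fibre_id = 1, mrc_class = "CI+CIV+",
                                        is_rrf = FALSE))
  expect_equal(single$mrc$pct[single$mrc$category == "CI+CIV+"], 100)
  expect_error(summarize_cohort(data.frame()), "no classified")
})

test_that("mrc_plot_data is a faithful projection", {
  z <- data.frame(fibre_id = c("a", "b", "c"), z_porin = 0:2,
                  z_ndufb8 = c(0, -4, -7), z_coxi = c(0, 0, -7))
  cl <- classify_fibre(z)
  pd <- mrc_plot_data(cl)
  expect_equal(nrow(pd), 3)
  expect_equal(pd$fibre_id, c("a", "b", "c"))
  expect_true(all(c("z_ndufb8", "z_coxi", "mass_class") %in% names(pd)))
  expect_equal(nrow(mrc_plot_data(cl[0, ])), 0)
})
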