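# Standard curves, Cq inversion and the D-loop deletion metrics.

ideal_slope <- -1 / log10(2)  # -3.3219..., 100% efficiency

test_that("ideal 10-fold series gives 100% efficiency and r^2 = 1", {
  copies <- 10^(2:7)
  cq <- ideal_slope * log10(copies) + 38
  curve <- fit_standard_curve(copies, cq)
  expect_equal(curve$slope, ideal_slope, tolerance = 1e-9)
  expect_equal(curve$efficiency, 1, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate standard series are rejected", {
  expect_error(fit_standard_curve(c(100, 100, 100), c(30, 30.1, 29.9)),
               "distinct dilution")
  expect_error(fit_standard_curve(c(-1, 10), c(30, 25)), "> 0")
  expect_error(fit_standard_curve(c(10, 100), c(25, 30)), "negative")
})

test_that("cq_to_copies inverts the curve algebraically", {
  curve <- fit_standard_curve(10^(2:7), ideal_slope * (2:7) + 38)
  expect_equal(cq_to_copies(curve$intercept, curve), 1, tolerance = 1e-9)
  expect_equal(cq_to_copies(curve$intercept + curve$slope, curve), 10,
               tolerance = 1e-9)
  for (true_copies in c(3, 470, 1e5)) {
    cq <- curve$slope * log10(true_copies) + curve$intercept
    expect_equal(cq_to_copies(cq, curve), true_copies,
                 tolerance = 1e-9 * true_copies)
  }
})

test_that("replicates aggregate by median with a range QC flag", {
  a <- aggregate_replicates(c(20.0, 20.1, 20.2))
  expect_equal(a$cq, 20.1)
  expect_false(a$qc_flag)
  b <- aggregate_replicates(c(20.0, 20.0, 21.0))
  expect_equal(b$cq, 20.0)
  expect_true(b$qc_flag)
  expect_equal(aggregate_replicates(20.0)$cq, 20.0)
  expect_error(aggregate_replicates(numeric(0)), "no replicate")
})

test_that("deletion metrics match direct arithmetic and are not clipped", {
  m <- deletion_metrics(100, 100, 100)
  expect_equal(unlist(m), c(del_nd4_nd1_pct = 0, nd1_dloop_pct = 0,
                            nd4_dloop_pct = 0))
  expect_equal(deletion_metrics(100, 28, 100)$del_nd4_nd1_pct, 72)
  expect_equal(deletion_metrics(120, 100, 100)$nd1_dloop_pct, -20)
  expect_error(deletion_metrics(0, 1, 1), "> 0")
})

test_that("metrics agree with the molecule-counting oracle", {
  set.seed(10)
  # 60% of molecules lack ND4, all have ND1, all carry triple-stranded
  # D-loop
  n <- 5000
  has_nd4 <- runif(n) >= 0.6
  o <- oracle_triplex_metrics(rep(TRUE, n), has_nd4, rep(TRUE, n))
  m <- deletion_metrics(n, sum(has_nd4), n * 1.5)
  expect_equal(m$del_nd4_nd1_pct, o[["del_nd4_nd1_pct"]], tolerance = 1e-12)
  expect_equal(m$nd1_dloop_pct, o[["nd1_dloop_pct"]], tolerance = 1e-12)
  expect_equal(m$nd4_dloop_pct, o[["nd4_dloop_pct"]], tolerance = 1e-12)
  # all-wild-type limits of the D-loop rule
  all_ds <- oracle_triplex_metrics(rep(TRUE, n), rep(TRUE, n), rep(FALSE, n))
  expect_equal(unname(all_ds["nd1_dloop_pct"]), 0)
  all_ts <- oracle_triplex_metrics(rep(TRUE, n), rep(TRUE, n), rep(TRUE, n))
  expect_equal(unname(all_ts["nd1_dloop_pct"]), 100 / 3, tolerance = 1e-9)
})

test_that("metrics are invariant under common rescaling of all copies", {
  m1 <- deletion_metrics(200, 90, 310)
  m10 <- deletion_metrics(2000, 900, 3100)
  expect_equal(m1, m10, tolerance = 1e-12)
})

test_that("classifier reproduces published example fibres and boundaries", {
  expect_equal(classify_triplex(75.1, 39.8), "both")
  expect_equal(classify_triplex(19.9, 93.8), "ND4_deleted")
  expect_equal(classify_triplex(33.0, 33.0), "none")   # strict >
  expect_equal(classify_triplex(33.0001, 20), "ND1_deleted")
  # partitions: every point gets exactly one of the four labels
  set.seed(11)
  grid <- expand.grid(nd1 = seq(-20, 100, by = 7.3),
                      nd4 = seq(-20, 100, by = 7.3))
  cls <- classify_triplex(grid$nd1, grid$nd4)
  expect_true(all(cls %in% c("none", "ND4_deleted", "ND1_deleted", "both")))
})

test_that("plate quantification round-trips noise-free synthetic fibres", {
  genotypes <- data.frame(fibre_id = c("f1", "f2", "f3"),
                          total_molecules = c(1e4, 2e4, 5e3),
                          h_nd1 = c(0, 0, 0.5), h_nd4 = c(0, 0.6, 0.5))
  cfg <- synth_config(triplex = list(cq_sd = 0))
  tp <- gen_triplex_plate(genotypes, cfg, seed = 21)
  out <- quantify_triplex(tp$plate, tp$standards)
  res <- out$results[match(genotypes$fibre_id, out$results$fibre_id), ]
  expect_equal(res$copies_nd4, tp$truth$copies_nd4, tolerance = 1e-6)
  expect_equal(res$del_nd4_nd1_pct, tp$truth$del_nd4_nd1_pct,
               tolerance = 1e-6)
  expect_equal(res$deletion_class, c("none", "ND4_deleted", "both"))
  expect_false(any(res$qc_flag))
})

test_that("deletion level is recovered unbiased at realistic Cq noise", {
  # standard-curve calibration error is shared by every fibre on a plate,
  # so unbiasedness is assessed over independent plates (8 x 25 fibres)
  # with the Monte-Carlo SE taken across plate means
  h <- 0.6
  cfg <- synth_config(triplex = list(cq_sd = 0.2))
  plate_means <- vapply(1:8, function(pl) {
    genotypes <- data.frame(fibre_id = sprintf("p%d_f%02d", pl, 1:25),
                            total_molecules = 1e4, h_nd1 = 0, h_nd4 = h)
    tp <- gen_triplex_plate(genotypes, cfg, seed = 220 + pl)
    mean(quantify_triplex(tp$plate, tp$standards)$results$del_nd4_nd1_pct)
  }, numeric(1))
  mc_se <- sd(plate_means) / sqrt(length(plate_means))
  expect_lt(abs(mean(plate_means) - 100 * h), 3 * mc_se + 0.5)
})

test_that("deleted-species summary reproduces published category mix", {
  # 166 ND4-deleted, 6 ND1-deleted, 22 both out of 194 deleted fibres,
  # pushed through the classifier from representative metric values
  metrics <- rbind(
    data.frame(nd1 = 10, nd4 = 90)[rep(1, 166), ],
    data.frame(nd1 = 80, nd4 = 20)[rep(1, 6), ],
    data.frame(nd1 = 75, nd4 = 60)[rep(1, 22), ],
    data.frame(nd1 = 5, nd4 = 10)[rep(1, 40), ])  # plus undeleted fibres
  cls <- classify_triplex(metrics$nd1, metrics$nd4)
  s <- summarize_deletion_classes(cls)
  expect_equal(s$deleted$pct[s$deleted$category == "ND4_deleted"], 85.6)
  expect_equal(s$deleted$pct[s$deleted$category == "ND1_deleted"], 3.1)
  expect_equal(s$deleted$pct[s$deleted$category == "both"], 11.3)
  expect_equal(s$deleted$n, c(166L, 6L, 22L))
})

test_that("copy-number group summaries report quartiles per MRC class", {
  set.seed(12)
  vals <- c(rnorm(50, 100, 5), rnorm(30, 200, 5))
  cls <- c(rep("CI+CIV+", 50), rep("CI-CIV-", 30))
  s <- copy_number_summary(vals, cls)
  expect_equal(nrow(s), 2)
  expect_equal(s$n, c(50L, 30L))
  expect_lt(s$median[s$mrc_class == "CI+CIV+"],
            s$median[s$mrc_class == "CI-CIV-"])
})
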