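# Seeded synthetic-data generators.
#
# Every generator is a pure function of (config, seed) and emits the same
# table dialects the analysis stages read, together with the planted
# ground truth, so each pipeline stage can be tested for parameter
# recovery without any external data. The generators are structural
# stand-ins: they emulate the statistical shape of the assays (mosaic
# deletion levels, log-linear qPCR with Gaussian Cq noise, Poisson plate
# occupancy, repeat-mediated breakpoints), not any real patient.

#' Default synthetic-data configuration
#'
#' One nested list holding the generating parameters of all four
#' generators. Defaults describe a mosaic patient biopsy: roughly half
#' the fibres carry no deletion and affected fibres have Beta-distributed
#' (clonally expanded, high-skewed) deletion levels; respiratory-chain
#' deficiency appears once the level passes a biochemical threshold; RRF
#' hyperproliferation kicks in at very high levels; qPCR follows an ideal
#' 100%-efficiency standard curve with 0.1-cycle Cq noise; smPCR plates
#' run at the 1-in-4 occupancy operating point.
#'
#' @param ... Named overrides of any top-level section (`ifq`, `triplex`,
#'   `smpcr`, `deletions`), each itself a list merged over the defaults.
#' @return Nested list of class `synth_config`.
#' @export
synth_config <- function(...) {
  defaults <- list(
    ifq = list(
      n_controls = 100L, n_patient_fibres = 300L,
      porin_mean = 1.0, porin_sd = 0.15,
      slope_ndufb8 = 0.8, intercept_ndufb8 = 0.2,
      slope_coxi = 0.9, intercept_coxi = 0.1,
      resid_sd = 0.05,          # control scatter about the line (OD units)
      patient_noise_od = 0.02,  # extra patient measurement noise (OD units)
      frac_unaffected = 0.5,
      h_beta = c(2.5, 1.2),     # deletion-level distribution of affected fibres
      h0_ci = 0.45, slope_ci = 12,   # z-shift = -slope*max(0, h - h0)
      h0_civ = 0.60, slope_civ = 14,
      rrf_h0 = 0.8, rrf_boost = 4,   # porin z boost above rrf_h0
      type_probs = c(I = 0.40, IIa = 0.35, `IIx/IIb` = 0.25),
      rrf_type1_prob = 0.8
    ),
    triplex = list(
      curve_slope = -1 / log10(2),        # -3.3219: 100% efficiency
      curve_intercept = 38,
      cq_sd = 0.1, n_replicates = 3L,
      standard_copies = 10^(2:7),
      ts_frac = 0.5                        # triple-stranded D-loop fraction
    ),
    smpcr = list(
      lambda = 0.25, n_wells = 96L, n_plates = 1L,
      proportions = c(`4` = 0.3, `8` = 0.7)  # names are deletion sizes, kb
    ),
    deletions = list(
      n_deletions = 20L, ref_length = 16569L,
      repeat_fraction = 0.4, repeat_length_range = c(5L, 13L),
      window = 20L, min_size = 2000L
    )
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown synth_config section(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(over)) {
    defaults[[nm]][names(over[[nm]])] <- over[[nm]]
  }
  structure(defaults, class = "synth_config")
}

#' Generate a synthetic immunofluorescence cohort
#'
#' Controls scatter about known NDUFB8-on-porin and COX-I-on-porin
#' regression lines; patient fibres are a mixture of unaffected fibres and
#' fibres with Beta-distributed deletion level `h`, whose planted z-shifts
#' follow a thresholded linear link `z = -slope * max(0, h - h0)` per
#' channel, with a porin (RRF) boost at very high `h`. Ground-truth z
#' displacements and classes are emitted alongside.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return List: `controls`, `fibres` (both fibre-OD tables; `fibres`
#'   additionally carries `true_h`, `true_z_*` and `true_*` class
#'   columns), `true_model` (the generating `control_model`), `thresholds`.
#' @export
gen_if_cohort <- function(config = synth_config(), seed) {
  if (missing(seed)) stop("gen_if_cohort requires an explicit seed")
  set.seed(seed)
  cf <- config$ifq
  th <- if_thresholds()

  controls <- data.frame(
    fibre_id = sprintf("C%04d", seq_len(cf$n_controls)),
    patient_id = "control", subject_class = "control",
    stringsAsFactors = FALSE
  )
  cp <- stats::rnorm(cf$n_controls, cf$porin_mean, cf$porin_sd)
  cp <- pmax(cp, 0.05)
  controls$od_porin <- cp
  controls$od_ndufb8 <- pmax(
    cf$intercept_ndufb8 + cf$slope_ndufb8 * cp +
      stats::rnorm(cf$n_controls, 0, cf$resid_sd), 0)
  controls$od_coxi <- pmax(
    cf$intercept_coxi + cf$slope_coxi * cp +
      stats::rnorm(cf$n_controls, 0, cf$resid_sd), 0)
  controls$fibre_type <- sample(names(cf$type_probs), cf$n_controls,
                                replace = TRUE, prob = cf$type_probs)

  n <- cf$n_patient_fibres
  affected <- stats::runif(n) >= cf$frac_unaffected
  h <- ifelse(affected,
              stats::rbeta(n, cf$h_beta[1L], cf$h_beta[2L]), 0)
  z_nd <- -cf$slope_ci * pmax(0, h - cf$h0_ci)
  z_cx <- -cf$slope_civ * pmax(0, h - cf$h0_civ)
  z_p <- stats::rnorm(n, 0, 1) +
    cf$rrf_boost * pmax(0, h - cf$rrf_h0) / (1 - cf$rrf_h0)

  od_porin <- pmax(cf$porin_mean + z_p * cf$porin_sd, 0.05)
  # recompute the realised porin z after flooring so truth stays exact
  z_p <- (od_porin - cf$porin_mean) / cf$porin_sd
  od_nd <- pmax(cf$intercept_ndufb8 + cf$slope_ndufb8 * od_porin +
                  z_nd * cf$resid_sd +
                  stats::rnorm(n, 0, cf$patient_noise_od), 0)
  od_cx <- pmax(cf$intercept_coxi + cf$slope_coxi * od_porin +
                  z_cx * cf$resid_sd +
                  stats::rnorm(n, 0, cf$patient_noise_od), 0)

  fibres <- data.frame(
    fibre_id = sprintf("F%04d", seq_len(n)),
    patient_id = "P1", subject_class = "patient",
    od_porin = od_porin, od_ndufb8 = od_nd, od_coxi = od_cx,
    true_h = h, true_z_porin = z_p, true_z_ndufb8 = z_nd,
    true_z_coxi = z_cx,
    stringsAsFactors = FALSE
  )
  truth <- classify_fibre(
    data.frame(z_porin = z_p, z_ndufb8 = z_nd, z_coxi = z_cx), th)
  fibres$true_mrc_class <- truth$mrc_class
  fibres$true_mass_class <- truth$mass_class
  fibres$true_is_rrf <- truth$is_rrf
  fibres$fibre_type <- ifelse(
    fibres$true_is_rrf & stats::runif(n) < cf$rrf_type1_prob, "I",
    sample(names(cf$type_probs), n, replace = TRUE, prob = cf$type_probs))

  true_model <- structure(list(
    slope_ndufb8 = cf$slope_ndufb8, intercept_ndufb8 = cf$intercept_ndufb8,
    resid_sd_ndufb8 = cf$resid_sd,
    slope_coxi = cf$slope_coxi, intercept_coxi = cf$intercept_coxi,
    resid_sd_coxi = cf$resid_sd,
    porin_mean = cf$porin_mean, porin_sd = cf$porin_sd,
    n_controls = cf$n_controls, log_transform = FALSE
  ), class = "control_model")

  list(controls = controls, fibres = fibres, true_model = true_model,
       thresholds = th)
}

#' True target copies for a set of genotypes
#'
#' Molecule-level bookkeeping shared by the generator and its tests: a
#' fibre with `total` molecules, of which fractions `h_nd1` / `h_nd4` lack
#' the respective target, and `ts_frac` of molecules carry a
#' triple-stranded D-loop (1.5 template copies instead of 1).
#'
#' @param total Total molecules.
#' @param h_nd1,h_nd4 Fractions of molecules lacking MT-ND1 / MT-ND4.
#' @param ts_frac Triple-stranded D-loop fraction.
#' @return Named list of `nd1`, `nd4`, `dloop` template copies.
#' @export
true_triplex_copies <- function(total, h_nd1, h_nd4, ts_frac = 1) {
  if (any(h_nd1 < 0 | h_nd1 >= 1) || any(h_nd4 < 0 | h_nd4 >= 1)) {
    stop("deletion fractions must lie in [0, 1)")
  }
  list(nd1 = total * (1 - h_nd1),
       nd4 = total * (1 - h_nd4),
       dloop = total * (1 + 0.5 * ts_frac))
}

#' Generate a synthetic triplex qPCR plate
#'
#' Builds a standard dilution series and per-fibre triplicate Cq values
#' from a log-linear curve with Gaussian Cq noise, for given true
#' genotypes.
#'
#' @param genotypes Data frame with columns `fibre_id`, `total_molecules`,
#'   `h_nd1`, `h_nd4` (per-target deletion fractions, in `[0, 1)`), and
#'   optionally `ts_frac`.
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return List: `plate` (long-form sample table), `standards`, `truth`
#'   (genotypes with the true copies and true metrics), `curve` (the
#'   generating `standard_curve` parameters as a list).
#' @export
gen_triplex_plate <- function(genotypes, config = synth_config(), seed) {
  if (missing(seed)) stop("gen_triplex_plate requires an explicit seed")
  set.seed(seed)
  cf <- config$triplex
  needed <- c("fibre_id", "total_molecules", "h_nd1", "h_nd4")
  missing_cols <- setdiff(needed, names(genotypes))
  if (length(missing_cols)) {
    stop("genotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ts <- if ("ts_frac" %in% names(genotypes)) genotypes$ts_frac else cf$ts_frac
  copies <- true_triplex_copies(genotypes$total_molecules,
                                genotypes$h_nd1, genotypes$h_nd4, ts)
  ideal_cq <- function(x) cf$curve_slope * log10(x) + cf$curve_intercept

  standards <- do.call(rbind, lapply(c("ND1", "ND4", "DLOOP"), function(tg) {
    data.frame(target = tg, copies = cf$standard_copies,
               cq = ideal_cq(cf$standard_copies) +
                 stats::rnorm(length(cf$standard_copies), 0, cf$cq_sd))
  }))

  n <- nrow(genotypes)
  plate <- do.call(rbind, lapply(seq_len(n), function(i) {
    per_target <- function(tg, cp) {
      data.frame(sample_id = genotypes$fibre_id[i], target = tg,
                 replicate = seq_len(cf$n_replicates),
                 cq = ideal_cq(cp) +
                   stats::rnorm(cf$n_replicates, 0, cf$cq_sd))
    }
    rbind(per_target("ND1", copies$nd1[i]),
          per_target("ND4", copies$nd4[i]),
          per_target("DLOOP", copies$dloop[i]))
  }))

  truth <- genotypes
  truth$copies_nd1 <- copies$nd1
  truth$copies_nd4 <- copies$nd4
  truth$copies_dloop <- copies$dloop
  truth <- cbind(truth,
                 deletion_metrics(copies$nd1, copies$nd4, copies$dloop))
  list(plate = plate, standards = standards, truth = truth,
       curve = list(slope = cf$curve_slope,
                    intercept = cf$curve_intercept))
}

#' Generate synthetic smPCR plates
#'
#' Molecules land in wells as Poisson(lambda) and carry species identities
#' drawn from the true proportions; a positive well is labelled by the
#' species of largest deletion (i.e. the smallest genome present),
#' modelling the PCR preference for short templates.
#'
#' @param config A [synth_config()]; `config$smpcr$proportions` is a named
#'   vector (names = deletion size in kb) summing to 1.
#' @param seed Integer seed.
#' @param cell_id Cell label stamped on the output.
#' @return List: `wells` (long per-well table: `cell_id`, `plate`, `well`,
#'   `outcome`), `truth` (lambda and proportions).
#' @export
gen_smpcr_plates <- function(config = synth_config(), seed,
                             cell_id = "cell1") {
  if (missing(seed)) stop("gen_smpcr_plates requires an explicit seed")
  set.seed(seed)
  cf <- config$smpcr
  props <- cf$proportions
  if (abs(sum(props) - 1) > 1e-9) stop("proportions must sum to 1")
  if (cf$lambda < 0) stop("lambda must be >= 0")
  sizes <- as.numeric(names(props))
  if (anyNA(sizes)) stop("proportion names must be deletion sizes in kb")

  rows <- lapply(seq_len(cf$n_plates), function(pl) {
    n_mol <- stats::rpois(cf$n_wells, cf$lambda)
    outcome <- vapply(n_mol, function(k) {
      if (k == 0L) return("negative")
      idx <- sample.int(length(sizes), k, replace = TRUE, prob = props)
      format(max(sizes[idx]))  # largest deletion = smallest genome wins
    }, character(1))
    data.frame(cell_id = cell_id, plate = pl,
               well = seq_len(cf$n_wells), outcome = outcome,
               stringsAsFactors = FALSE)
  })
  list(wells = do.call(rbind, rows),
       truth = list(lambda = cf$lambda, proportions = props))
}

#' Generate a synthetic circular reference and deletion set
#'
#' Draws a uniform-random circular reference and a set of deletions; a
#' configured fraction is repeat-mediated: a random k-mer is written into
#' the reference at both junctions (ending at bp5 and starting at bp3)
#' before breakpoints are emitted, and the bases immediately outside the
#' planted copies are forced to differ so the junction repeat has exactly
#' the planted length.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return List: `reference` (character string), `deletions` (cell_id,
#'   product_id, bp5, bp3), `flanks` (extracted with the configured
#'   window), `truth` (`repeat_mediated`, `planted_repeat_length`).
#' @export
gen_deletion_set <- function(config = synth_config(), seed) {
  if (missing(seed)) stop("gen_deletion_set requires an explicit seed")
  set.seed(seed)
  cf <- config$deletions
  L <- cf$ref_length
  window <- cf$window
  kmax <- max(cf$repeat_length_range)
  if (kmax > window) stop("planted repeat longer than the flank window")
  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  n <- cf$n_deletions
  margin <- window + 2L
  if (L < cf$min_size + 4L * margin) {
    stop("ref_length too small for min_size and window")
  }
  # Junction windows (flank +/- one guard base) are kept disjoint across
  # deletions so planting one repeat can never corrupt another junction.
  used <- matrix(numeric(0), ncol = 2L)
  overlaps_used <- function(lo, hi) {
    nrow(used) > 0L && any(lo <= used[, 2L] & hi >= used[, 1L])
  }
  bp5 <- integer(n)
  bp3 <- integer(n)
  for (i in seq_len(n)) {
    for (try in seq_len(200L)) {
      b5 <- sample(seq.int(margin, L - cf$min_size - margin), 1L)
      b3 <- b5 + cf$min_size +
        sample.int(L - margin - cf$min_size - b5 + 1L, 1L) - 1L
      w5 <- c(b5 - margin, b5 + 1L)
      w3 <- c(b3 - 1L, b3 + margin)
      if (!overlaps_used(w5[1L], w5[2L]) && !overlaps_used(w3[1L], w3[2L]) &&
          w5[2L] < w3[1L]) {
        bp5[i] <- b5
        bp3[i] <- b3
        used <- rbind(used, w5, w3)
        break
      }
      if (try == 200L) stop("could not place disjoint deletion junctions; ",
                            "reduce n_deletions or enlarge ref_length")
    }
  }
  mediated <- stats::runif(n) < cf$repeat_fraction
  planted <- integer(n)
  other <- function(base) sample(setdiff(c("A", "C", "G", "T"), base), 1L)
  for (i in which(mediated)) {
    k <- sample(seq.int(cf$repeat_length_range[1L],
                        cf$repeat_length_range[2L]), 1L)
    kmer <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    ref[seq.int(bp5[i] - k + 1L, bp5[i])] <- kmer
    ref[seq.int(bp3[i], bp3[i] + k - 1L)] <- kmer
    # stop chance extension of the repeat on either side
    ref[bp5[i] - k] <- other(ref[bp3[i] - 1L])
    ref[bp3[i] + k] <- other(ref[bp5[i] + 1L])
    planted[i] <- k
  }
  reference <- paste(ref, collapse = "")
  deletions <- data.frame(
    cell_id = sprintf("syn%02d", seq_len(n)),
    product_id = sprintf("syn%02dX", seq_len(n)),
    bp5 = bp5, bp3 = bp3, stringsAsFactors = FALSE)
  flanks <- do.call(rbind, lapply(seq_len(n), function(i) {
    fl <- flanks_from_reference(reference, bp5[i], bp3[i], window)
    data.frame(product_id = deletions$product_id[i],
               five_prime_flank = fl$five_prime_flank,
               three_prime_flank = fl$three_prime_flank,
               stringsAsFactors = FALSE)
  }))
  list(reference = reference, deletions = deletions, flanks = flanks,
       truth = data.frame(product_id = deletions$product_id,
                          repeat_mediated = mediated,
                          planted_repeat_length = planted))
}
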