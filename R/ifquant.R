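# Quadruple-immunofluorescence densitometry: background correction, control
# regression, z-scores and respiratory-chain / mass / RRF classification.
#
# Each muscle fibre carries background-corrected optical densities (OD) for
# porin (mitochondrial mass), NDUFB8 (complex I) and COX-I (complex IV).
# NDUFB8 and COX-I are regressed on porin over control fibres; patient
# fibres are scored by their studentised residual from that control line
# (z_ndufb8, z_coxi), and porin itself by a plain control z-score (z_porin).

#' Background-correct an optical density
#'
#' Subtracts the mean signal of the matching channel in the no-primary
#' control (NPC) section and clips at zero: a fibre cannot carry negative
#' signal after correction.
#'
#' @param raw_od Raw optical density (>= 0). Vectorised.
#' @param npc_mean Per-channel mean OD of the no-primary-control section.
#' @return `max(raw_od - npc_mean, 0)`.
#' @export
background_correct <- function(raw_od, npc_mean) {
  if (any(npc_mean < 0)) stop("npc_mean must be >= 0")
  if (any(raw_od < 0)) stop("raw OD must be >= 0")
  pmax(raw_od - npc_mean, 0)
}

#' Threshold configuration for fibre classification
#'
#' Defaults: per-channel expression levels are called from the control
#' z-score with boundaries at -3 (normal / intermediate(+)), -4.5
#' (intermediate(+) / intermediate(-)) and -6 (intermediate(-) /
#' deficient); a channel counts as deficient ("-") in the three-group
#' respiratory-chain call when z < -3; ragged-red fibres (RRF) are porin
#' z > 2.5 (strict); mitochondrial-mass bands are cut at porin z = -3, -2,
#' +2, +3 (very_low / low / normal / high / very_high).
#'
#' @param z_normal,z_int_minus,z_deficient Per-channel level boundaries.
#' @param z_mrc Deficiency cut for the respiratory-chain class.
#' @param z_rrf RRF porin z-score cut (strict `>`).
#' @param mass_breaks Four increasing porin z-score cuts for the five mass
#'   bands.
#' @return A list of thresholds, class `if_thresholds`.
#' @export
if_thresholds <- function(z_normal = -3, z_int_minus = -4.5, z_deficient = -6,
                          z_mrc = -3, z_rrf = 2.5,
                          mass_breaks = c(-3, -2, 2, 3)) {
  if (!(z_deficient < z_int_minus && z_int_minus < z_normal)) {
    stop("level boundaries must satisfy z_deficient < z_int_minus < z_normal")
  }
  if (is.unsorted(mass_breaks, strictly = TRUE) || length(mass_breaks) != 4L) {
    stop("mass_breaks must be 4 strictly increasing values")
  }
  structure(list(z_normal = z_normal, z_int_minus = z_int_minus,
                 z_deficient = z_deficient, z_mrc = z_mrc, z_rrf = z_rrf,
                 mass_breaks = mass_breaks),
            class = "if_thresholds")
}

.check_fibre_od <- function(fibres, require_type = FALSE) {
  needed <- c("fibre_id", "od_porin", "od_ndufb8", "od_coxi")
  missing <- setdiff(needed, names(fibres))
  if (length(missing)) {
    stop("fibre table lacks column(s): ", paste(missing, collapse = ", "))
  }
  od <- as.matrix(fibres[, c("od_porin", "od_ndufb8", "od_coxi")])
  if (any(!is.finite(od)) || any(od < 0)) {
    stop("ODs must be finite and >= 0 after background correction")
  }
  invisible(fibres)
}

#' Fit the control model for z-scoring
#'
#' Ordinary least-squares regression of each probe channel (NDUFB8, COX-I)
#' on porin over control fibres, with the residual SD per channel, plus the
#' porin mean and SD over controls. Optionally the regression is done on
#' log-transformed ODs (`log_transform = TRUE`), in which case z-scores are
#' computed on the same scale.
#'
#' @param controls Data frame of control fibres with columns `fibre_id`,
#'   `od_porin`, `od_ndufb8`, `od_coxi`.
#' @param log_transform Regress and score on `log(OD)` instead of OD.
#' @return A list of class `control_model`.
#' @export
fit_control_model <- function(controls, log_transform = FALSE) {
  .check_fibre_od(controls)
  n <- nrow(controls)
  if (n < 3L) stop("need at least 3 control fibres, got ", n)
  x <- controls$od_porin
  if (log_transform) {
    if (any(controls$od_porin <= 0 | controls$od_ndufb8 <= 0 |
            controls$od_coxi <= 0)) {
      stop("log_transform requires strictly positive ODs")
    }
    x <- log(x)
  }
  if (stats::sd(x) == 0) stop("control porin OD has zero variance")

  fit_channel <- function(y) {
    if (log_transform) y <- log(y)
    fit <- stats::lm(y ~ x)
    co <- stats::coef(fit)
    list(intercept = unname(co[1L]), slope = unname(co[2L]),
         resid_sd = stats::sd(stats::resid(fit)))
  }
  nd <- fit_channel(controls$od_ndufb8)
  cx <- fit_channel(controls$od_coxi)
  structure(list(
    slope_ndufb8 = nd$slope, intercept_ndufb8 = nd$intercept,
    resid_sd_ndufb8 = nd$resid_sd,
    slope_coxi = cx$slope, intercept_coxi = cx$intercept,
    resid_sd_coxi = cx$resid_sd,
    porin_mean = mean(x), porin_sd = stats::sd(x),
    n_controls = n, log_transform = log_transform
  ), class = "control_model")
}

#' @export
print.control_model <- function(x, ...) {
  cat(sprintf(
    "control_model (%d controls%s)\n  NDUFB8 ~ porin: slope %.4g, intercept %.4g, resid SD %.4g\n  COX-I  ~ porin: slope %.4g, intercept %.4g, resid SD %.4g\n  porin: mean %.4g, SD %.4g\n",
    x$n_controls, if (x$log_transform) ", log OD" else "",
    x$slope_ndufb8, x$intercept_ndufb8, x$resid_sd_ndufb8,
    x$slope_coxi, x$intercept_coxi, x$resid_sd_coxi,
    x$porin_mean, x$porin_sd))
  invisible(x)
}

#' Control-referenced z-scores for fibres
#'
#' For NDUFB8 and COX-I the z-score is the fibre's residual from the control
#' regression line divided by the control residual SD; for porin it is the
#' plain control z-score. With a log-space control model the same formulas
#' are applied to log(OD).
#'
#' @param fibres Data frame with `fibre_id`, `od_porin`, `od_ndufb8`,
#'   `od_coxi` (other columns carried through).
#' @param model A `control_model` from [fit_control_model()].
#' @return `fibres` with added columns `z_porin`, `z_ndufb8`, `z_coxi`.
#' @export
zscores <- function(fibres, model) {
  stopifnot(inherits(model, "control_model"))
  .check_fibre_od(fibres)
  p <- fibres$od_porin
  nd <- fibres$od_ndufb8
  cx <- fibres$od_coxi
  if (model$log_transform) {
    if (any(p <= 0 | nd <= 0 | cx <= 0)) {
      stop("log-space model requires strictly positive ODs")
    }
    p <- log(p); nd <- log(nd); cx <- log(cx)
  }
  resid_nd <- nd - (model$intercept_ndufb8 + model$slope_ndufb8 * p)
  resid_cx <- cx - (model$intercept_coxi + model$slope_coxi * p)
  z_channel <- function(resid, sd, channel) {
    if (sd == 0) {
      if (any(abs(resid) > 1e-12)) {
        stop("control residual SD is 0 for ", channel,
             " but a fibre has a nonzero residual; z-score undefined")
      }
      return(rep(0, length(resid)))
    }
    resid / sd
  }
  fibres$z_porin <- (p - model$porin_mean) / model$porin_sd
  fibres$z_ndufb8 <- z_channel(resid_nd, model$resid_sd_ndufb8, "NDUFB8")
  fibres$z_coxi <- z_channel(resid_cx, model$resid_sd_coxi, "COX-I")
  fibres
}

.level_from_z <- function(z, th) {
  ifelse(z >= th$z_normal, "normal",
    ifelse(z >= th$z_int_minus, "intermediate_plus",
      ifelse(z >= th$z_deficient, "intermediate_minus", "deficient")))
}

#' Classify fibres from their z-scores
#'
#' Adds per-channel expression levels, the respiratory-chain (MRC) class
#' (CI+CIV+, CI-CIV+, CI+CIV-, CI-CIV-, where a channel is "-" when its
#' z-score falls below the deficiency cut), the five-band mitochondrial
#' mass class from the porin z-score, and the RRF flag (porin z strictly
#' above the RRF cut). Every fibre receives exactly one MRC class and one
#' mass class.
#'
#' @param fibres Data frame carrying `z_porin`, `z_ndufb8`, `z_coxi`
#'   (e.g. from [zscores()]).
#' @param thresholds An [if_thresholds()] configuration.
#' @return `fibres` with added columns `level_ndufb8`, `level_coxi`,
#'   `mrc_class`, `mass_class`, `is_rrf`.
#' @export
classify_fibre <- function(fibres, thresholds = if_thresholds()) {
  stopifnot(inherits(thresholds, "if_thresholds"))
  needed <- c("z_porin", "z_ndufb8", "z_coxi")
  missing <- setdiff(needed, names(fibres))
  if (length(missing)) {
    stop("fibre table lacks z-score column(s): ",
         paste(missing, collapse = ", "))
  }
  z <- as.matrix(fibres[, needed])
  if (any(!is.finite(z))) stop("z-scores must be finite")
  th <- thresholds
  fibres$level_ndufb8 <- .level_from_z(fibres$z_ndufb8, th)
  fibres$level_coxi <- .level_from_z(fibres$z_coxi, th)
  ci_def <- fibres$z_ndufb8 < th$z_mrc
  civ_def <- fibres$z_coxi < th$z_mrc
  fibres$mrc_class <- ifelse(ci_def & civ_def, "CI-CIV-",
                        ifelse(ci_def, "CI-CIV+",
                          ifelse(civ_def, "CI+CIV-", "CI+CIV+")))
  mb <- th$mass_breaks
  fibres$mass_class <- cut(fibres$z_porin,
                           breaks = c(-Inf, mb, Inf),
                           labels = c("very_low", "low", "normal",
                                      "high", "very_high"),
                           right = TRUE)
  fibres$mass_class <- as.character(fibres$mass_class)
  fibres$is_rrf <- fibres$z_porin > th$z_rrf
  fibres
}

#' Classify an immunofluorescence cohort end-to-end
#'
#' Fits the control model on control fibres, z-scores and classifies the
#' patient fibres (and, for QC, the controls themselves).
#'
#' @param fibres Patient fibre OD table.
#' @param controls Control fibre OD table.
#' @param thresholds An [if_thresholds()].
#' @param log_transform Passed to [fit_control_model()].
#' @return A list with `model` (the `control_model`), `fibres` and
#'   `controls` (both z-scored and classified).
#' @export
classify_if_cohort <- function(fibres, controls,
                               thresholds = if_thresholds(),
                               log_transform = FALSE) {
  model <- fit_control_model(controls, log_transform = log_transform)
  list(model = model,
       fibres = classify_fibre(zscores(fibres, model), thresholds),
       controls = classify_fibre(zscores(controls, model), thresholds))
}

#' Percentage of counts, to one decimal place
#'
#' @param counts Vector of category counts.
#' @return Percentages of the total, rounded to 1 dp.
#' @export
percent_1dp <- function(counts) {
  if (sum(counts) == 0) stop("cannot take percentages of an empty tally")
  round(100 * counts / sum(counts), 1)
}

.count_table <- function(values, levels) {
  counts <- table(factor(values, levels = levels))
  data.frame(category = levels,
             n = as.integer(counts),
             pct = percent_1dp(as.integer(counts)),
             stringsAsFactors = FALSE)
}

MRC_CLASSES <- c("CI+CIV+", "CI-CIV+", "CI+CIV-", "CI-CIV-")
FIBRE_TYPES <- c("I", "IIa", "IIx/IIb", "unknown")

#' Cohort contingency summaries
#'
#' Counts and percentages (1 dp; empty categories reported as 0) for:
#' the MRC class distribution over all fibres; the MRC class distribution
#' among RRF fibres (the "what deficiency do RRF show" summary); and the
#' fibre-type distribution among RRF fibres with a known type.
#'
#' @param classified Data frame from [classify_fibre()]; a `fibre_type`
#'   column is optional.
#' @return A list of data frames: `mrc`, `rrf_by_mrc`, `rrf_by_type`
#'   (NULL when no typed RRF fibres), plus `n_fibres` and `n_rrf`.
#' @export
summarize_cohort <- function(classified) {
  if (nrow(classified) == 0L) stop("no classified fibres to summarise")
  needed <- c("mrc_class", "is_rrf")
  missing <- setdiff(needed, names(classified))
  if (length(missing)) {
    stop("classified table lacks column(s): ", paste(missing, collapse = ", "))
  }
  rrf <- classified[classified$is_rrf, , drop = FALSE]
  rrf_by_type <- NULL
  if ("fibre_type" %in% names(classified) && nrow(rrf) > 0L) {
    typed <- rrf[!is.na(rrf$fibre_type) & rrf$fibre_type != "unknown", ,
                 drop = FALSE]
    if (nrow(typed) > 0L) {
      rrf_by_type <- .count_table(typed$fibre_type,
                                  setdiff(FIBRE_TYPES, "unknown"))
    }
  }
  list(
    mrc = .count_table(classified$mrc_class, MRC_CLASSES),
    rrf_by_mrc = if (nrow(rrf) > 0L) .count_table(rrf$mrc_class, MRC_CLASSES)
                 else NULL,
    rrf_by_type = rrf_by_type,
    n_fibres = nrow(classified),
    n_rrf = nrow(rrf)
  )
}

#' Per-fibre data behind an MRC profile plot
#'
#' Projection of a classified cohort to the columns a two-dimensional
#' NDUFB8-vs-COX-I expression profile plot needs, with each fibre coloured
#' by its mitochondrial mass band.
#'
#' @param classified Data frame from [classify_fibre()].
#' @return Data frame with `fibre_id`, `z_ndufb8`, `z_coxi`, `mass_class`
#'   (plus `patient_id` when present).
#' @export
mrc_plot_data <- function(classified) {
  cols <- intersect(c("fibre_id", "patient_id", "z_ndufb8", "z_coxi",
                      "mass_class"),
                    names(classified))
  classified[, cols, drop = FALSE]
}

#' Plot an MRC expression profile
#'
#' Scatter of COX-I versus NDUFB8 z-scores coloured by mitochondrial mass
#' band, with dashed lines at the classification boundaries. Requires
#' ggplot2.
#'
#' @param classified Data frame from [classify_fibre()].
#' @param thresholds The [if_thresholds()] used for the boundary guides.
#' @return A ggplot object.
#' @export
plot_mrc_profile <- function(classified, thresholds = if_thresholds()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_mrc_profile requires the ggplot2 package")
  }
  d <- mrc_plot_data(classified)
  d$mass_class <- factor(d$mass_class,
                         levels = c("very_low", "low", "normal",
                                    "high", "very_high"))
  pal <- c(very_low = "#2166ac", low = "#92c5de", normal = "#fddbc7",
           high = "#ef8a62", very_high = "#b2182b")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z_ndufb8, y = .data$z_coxi,
                                  colour = .data$mass_class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = thresholds$z_mrc, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thresholds$z_mrc, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = pal, drop = FALSE,
                                 name = "mito mass") +
    ggplot2::labs(x = "NDUFB8 z-score (complex I)",
                  y = "COX-I z-score (complex IV)")
}

#' Read a fibre OD table (CSV)
#'
#' Expected columns: `fibre_id`, `od_porin`, `od_ndufb8`, `od_coxi`;
#' optional `patient_id`, `subject_class`, `fibre_type` and raw/NPC columns.
#' If `npc_porin`, `npc_ndufb8`, `npc_coxi` columns are present the OD
#' columns are treated as raw and are background-corrected on load.
#'
#' @param path CSV path.
#' @return Validated fibre data frame.
#' @export
read_fibre_od <- function(path) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  npc_cols <- c("npc_porin", "npc_ndufb8", "npc_coxi")
  if (all(npc_cols %in% names(f))) {
    f$od_porin <- background_correct(f$od_porin, f$npc_porin)
    f$od_ndufb8 <- background_correct(f$od_ndufb8, f$npc_ndufb8)
    f$od_coxi <- background_correct(f$od_coxi, f$npc_coxi)
  }
  .check_fibre_od(f)
  f
}
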