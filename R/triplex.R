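# Triplex real-time PCR quantification of mtDNA deletion level.
#
# Three TaqMan targets are measured per fibre: MT-ND1, MT-ND4 and the
# D-loop. Copies come from inverting a plasmid standard curve
# Cq = m*log10(copies) + b. Deletion metrics:
#   del_nd4_nd1_pct = (1 - ND4/ND1) * 100    (deletion level proper)
#   nd1_dloop_pct   = (1 - ND1/Dloop) * 100
#   nd4_dloop_pct   = (1 - ND4/Dloop) * 100
# The control region can carry a third (7S) DNA strand, so D-loop copies
# run up to 1.5x the molecule count: apparent "deletion" of a coding
# target relative to the D-loop of up to 33% is normal, and only values
# strictly above 33% indicate a true deletion species.

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Cq on log10(copies) over a plasmid dilution series,
#' with amplification efficiency `E = 10^(-1/slope) - 1` and r-squared.
#'
#' @param copies Known template copy numbers (> 0).
#' @param cq Measured Cq values, same length.
#' @return A list of class `standard_curve` with `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `n_points`.
#' @export
fit_standard_curve <- function(copies, cq) {
  if (length(copies) != length(cq)) stop("copies and cq must match in length")
  if (any(!is.finite(copies)) || any(copies <= 0)) {
    stop("standard copies must be finite and > 0")
  }
  if (any(!is.finite(cq))) stop("Cq values must be finite")
  lx <- log10(copies)
  if (length(unique(lx)) < 2L) {
    stop("need at least 2 distinct dilution levels to fit a standard curve")
  }
  fit <- stats::lm(cq ~ lx)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope >= 0) {
    stop("standard curve slope must be negative (Cq decreases with copies)")
  }
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope, intercept = intercept,
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = r2, n_points = length(cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: Cq = %.4f*log10(copies) + %.4f  (E = %.1f%%, R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, 100 * x$efficiency, x$r_squared, x$n_points))
  invisible(x)
}

#' Convert Cq to template copies via a standard curve
#'
#' Inverts `Cq = slope*log10(copies) + intercept`:
#' `copies = 10^((cq - intercept)/slope)`. Vectorised.
#'
#' @param cq Cq value(s).
#' @param curve A `standard_curve`.
#' @return Estimated template copies.
#' @export
cq_to_copies <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Aggregate replicate Cq values
#'
#' Median of 1-3 replicate Cq values, with a QC flag raised when the
#' replicate range exceeds `max_range` cycles.
#'
#' @param cqs Numeric vector of 1-3 finite Cq values.
#' @param max_range QC range threshold in cycles (default 0.5).
#' @return List with `cq` (median) and `qc_flag` (logical).
#' @export
aggregate_replicates <- function(cqs, max_range = 0.5) {
  cqs <- cqs[!is.na(cqs)]
  if (length(cqs) == 0L) stop("no replicate Cq values to aggregate")
  if (any(!is.finite(cqs))) stop("Cq replicates must be finite")
  list(cq = stats::median(cqs),
       qc_flag = (max(cqs) - min(cqs)) > max_range)
}

#' Deletion metrics from absolute target copies
#'
#' Computes the three percentage metrics from MT-ND1, MT-ND4 and D-loop
#' copies. Values are reported as-is (small negative values can arise from
#' measurement noise and are not clipped). Vectorised.
#'
#' @param copies_nd1,copies_nd4,copies_dloop Absolute copies (> 0).
#' @return Data frame with `del_nd4_nd1_pct`, `nd1_dloop_pct`,
#'   `nd4_dloop_pct`.
#' @export
deletion_metrics <- function(copies_nd1, copies_nd4, copies_dloop) {
  n <- length(copies_nd1)
  if (length(copies_nd4) != n || length(copies_dloop) != n) {
    stop("copy vectors must have equal length")
  }
  all_copies <- c(copies_nd1, copies_nd4, copies_dloop)
  if (any(!is.finite(all_copies)) || any(all_copies <= 0)) {
    stop("copies must be finite and > 0")
  }
  data.frame(
    del_nd4_nd1_pct = (1 - copies_nd4 / copies_nd1) * 100,
    nd1_dloop_pct = (1 - copies_nd1 / copies_dloop) * 100,
    nd4_dloop_pct = (1 - copies_nd4 / copies_dloop) * 100
  )
}

#' Deletion class from D-loop-relative metrics
#'
#' A coding target counts as deleted when its D-loop-relative percentage is
#' strictly above the threshold (default 33%, the all-triple-stranded
#' D-loop limit); the class partitions the (nd1_dloop, nd4_dloop) plane
#' into none / ND4_deleted / ND1_deleted / both. Vectorised.
#'
#' @param nd1_dloop_pct,nd4_dloop_pct D-loop-relative percentages.
#' @param threshold Percentage threshold (strict `>`; default 33).
#' @return Character vector of classes.
#' @export
classify_triplex <- function(nd1_dloop_pct, nd4_dloop_pct, threshold = 33) {
  if (length(nd1_dloop_pct) != length(nd4_dloop_pct)) {
    stop("metric vectors must have equal length")
  }
  nd1_del <- nd1_dloop_pct > threshold
  nd4_del <- nd4_dloop_pct > threshold
  ifelse(nd1_del & nd4_del, "both",
    ifelse(nd4_del, "ND4_deleted",
      ifelse(nd1_del, "ND1_deleted", "none")))
}

#' Quantify a triplex qPCR plate
#'
#' Fits one standard curve per target from the standard series, aggregates
#' sample replicates (median, range QC), inverts Cq to copies and derives
#' the deletion metrics and class per fibre.
#'
#' @param plate Long-form sample table with columns `sample_id`, `target`
#'   (one of `ND1`, `ND4`, `DLOOP`), `cq`, and optionally `replicate`.
#' @param standards Standard series with columns `target`, `copies`, `cq`.
#' @param threshold Classification threshold passed to [classify_triplex()].
#' @param max_range Replicate-range QC threshold in cycles.
#' @return A list with `curves` (per-target `standard_curve`s) and
#'   `results`, a data frame per fibre: `fibre_id`, `copies_nd1`,
#'   `copies_nd4`, `copies_dloop`, the three metrics, `deletion_class`,
#'   `qc_flag`.
#' @export
quantify_triplex <- function(plate, standards, threshold = 33,
                             max_range = 0.5) {
  targets <- c("ND1", "ND4", "DLOOP")
  for (tab in list(plate, standards)) {
    if (!"target" %in% names(tab)) stop("tables need a 'target' column")
  }
  bad <- setdiff(unique(c(plate$target, standards$target)), targets)
  if (length(bad)) {
    stop("unknown target(s): ", paste(bad, collapse = ", "),
         " (expected ND1, ND4, DLOOP)")
  }
  missing_std <- setdiff(targets, unique(standards$target))
  if (length(missing_std)) {
    stop("standard series missing target(s): ",
         paste(missing_std, collapse = ", "))
  }
  curves <- lapply(stats::setNames(targets, targets), function(tg) {
    s <- standards[standards$target == tg, ]
    fit_standard_curve(s$copies, s$cq)
  })

  ids <- unique(plate$sample_id)
  rows <- lapply(ids, function(id) {
    sub <- plate[plate$sample_id == id, ]
    copies <- numeric(3)
    names(copies) <- targets
    qc <- FALSE
    for (tg in targets) {
      cqs <- sub$cq[sub$target == tg]
      if (length(cqs) == 0L) {
        stop("sample ", id, " has no Cq for target ", tg)
      }
      agg <- aggregate_replicates(cqs, max_range = max_range)
      qc <- qc || agg$qc_flag
      copies[tg] <- cq_to_copies(agg$cq, curves[[tg]])
    }
    m <- deletion_metrics(copies[["ND1"]], copies[["ND4"]], copies[["DLOOP"]])
    data.frame(fibre_id = id,
               copies_nd1 = copies[["ND1"]],
               copies_nd4 = copies[["ND4"]],
               copies_dloop = copies[["DLOOP"]],
               m,
               deletion_class = classify_triplex(m$nd1_dloop_pct,
                                                 m$nd4_dloop_pct,
                                                 threshold),
               qc_flag = qc,
               stringsAsFactors = FALSE)
  })
  list(curves = curves, results = do.call(rbind, rows))
}

TRIPLEX_CLASSES <- c("none", "ND4_deleted", "ND1_deleted", "both")

#' Summarise deletion classes over deleted fibres
#'
#' Counts and percentages (1 dp) of `ND4_deleted` / `ND1_deleted` / `both`
#' among fibres carrying a deletion (class != "none"), plus the overall
#' class tally.
#'
#' @param deletion_class Character vector of per-fibre classes.
#' @return List with `all` (tally over every fibre) and `deleted`
#'   (percentages among deleted fibres only; NULL when none).
#' @export
summarize_deletion_classes <- function(deletion_class) {
  if (length(deletion_class) == 0L) stop("no fibres to summarise")
  bad <- setdiff(unique(deletion_class), TRIPLEX_CLASSES)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  all_tab <- .count_table(deletion_class, TRIPLEX_CLASSES)
  deleted <- deletion_class[deletion_class != "none"]
  deleted_tab <- if (length(deleted)) {
    .count_table(deleted, setdiff(TRIPLEX_CLASSES, "none"))
  } else NULL
  list(all = all_tab, deleted = deleted_tab)
}

#' Copy-number summaries by respiratory-chain class
#'
#' Median and quartiles of a per-fibre quantity (e.g. D-loop copies, ND4
#' copies, porin OD) within each MRC class; the routine between-group
#' rank test is left to a standard `wilcox.test` call by the user.
#'
#' @param values Numeric per-fibre quantity.
#' @param mrc_class Per-fibre MRC class labels.
#' @return Data frame with class, n, q25, median, q75.
#' @export
copy_number_summary <- function(values, mrc_class) {
  if (length(values) != length(mrc_class)) {
    stop("values and mrc_class must have equal length")
  }
  cls <- intersect(MRC_CLASSES, unique(mrc_class))
  do.call(rbind, lapply(cls, function(cl) {
    v <- values[mrc_class == cl]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(mrc_class = cl, n = length(v),
               q25 = q[1], median = q[2], q75 = q[3])
  }))
}
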