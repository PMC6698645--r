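# Limiting-dilution single-molecule PCR (smPCR) mathematics.
#
# Template DNA is diluted until fewer than a quarter of wells on a 96-well
# plate amplify, so that a positive well derives (with high probability)
# from a single molecule. Molecules land in wells as Poisson(lambda); the
# fraction of positive wells p = 1 - exp(-lambda) inverts to
# lambda = -log(1 - p). Species proportions are the raw positive-well
# fractions per amplicon size.

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n < 1L || x < 0L || x > n) stop("need 0 <= x <= n, n >= 1")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Estimate mean molecules per well from plate occupancy
#'
#' Inverts the Poisson zero class: with `p` the fraction of positive wells,
#' `lambda = -log(1 - p)`. The confidence interval transforms a Wilson
#' interval on `p` through the same map.
#'
#' @param n_positive Number of positive wells (0 <= n_positive < n_wells;
#'   a fully positive plate leaves lambda unbounded and is an error
#'   instructing further dilution).
#' @param n_wells Number of wells on the plate (e.g. 96).
#' @param conf Confidence level for the interval.
#' @return List of class `occupancy_estimate`: `p_positive`, `lambda`,
#'   `ci_lambda`, `n_positive`, `n_wells`.
#' @export
estimate_lambda <- function(n_positive, n_wells, conf = 0.95) {
  if (n_wells < 1L) stop("n_wells must be >= 1")
  if (n_positive < 0L || n_positive > n_wells) {
    stop("n_positive must lie in [0, n_wells]")
  }
  if (n_positive == n_wells) {
    stop("every well is positive: lambda is unbounded; ",
         "dilute the template further and re-plate")
  }
  p <- n_positive / n_wells
  ci_p <- wilson_ci(n_positive, n_wells, conf)
  structure(list(
    p_positive = p,
    lambda = -log(1 - p),
    ci_lambda = c(lower = -log(1 - ci_p[["lower"]]),
                  upper = -log(1 - min(ci_p[["upper"]], 1 - 1e-12))),
    n_positive = n_positive, n_wells = n_wells
  ), class = "occupancy_estimate")
}

#' @export
print.occupancy_estimate <- function(x, ...) {
  cat(sprintf(
    "occupancy: %d/%d positive (p = %.3f), lambda = %.4f [%.4f, %.4f]\n",
    x$n_positive, x$n_wells, x$p_positive, x$lambda,
    x$ci_lambda[["lower"]], x$ci_lambda[["upper"]]))
  invisible(x)
}

#' Dilution factor to reach a target occupancy
#'
#' Multiplicative dilution of the template needed to move from the current
#' mean molecules per well to the lambda implied by a target positive
#' fraction (default 0.25, the "no more than 1 in 4 wells" operating
#' point): `factor = -log(1 - target_p) / current_lambda`.
#'
#' @param current_lambda Current mean molecules per well (> 0).
#' @param target_p Target fraction of positive wells (0 < target_p < 1).
#' @return The dilution factor (< 1 means dilute).
#' @export
dilution_factor <- function(current_lambda, target_p = 0.25) {
  if (current_lambda <= 0) stop("current_lambda must be > 0")
  if (target_p <= 0 || target_p >= 1) stop("target_p must lie in (0, 1)")
  -log(1 - target_p) / current_lambda
}

#' Probability a positive well holds more than one molecule
#'
#' Under Poisson(lambda) occupancy,
#' `P(>= 2 | >= 1) = (1 - e^-lambda (1 + lambda)) / (1 - e^-lambda)`.
#' This quantifies how "single-molecule" the plate really is. Vectorised.
#'
#' @param lambda Mean molecules per well (> 0).
#' @return Multiplicity probability in (0, 1).
#' @export
multiplicity_probability <- function(lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  (1 - exp(-lambda) * (1 + lambda)) / (1 - exp(-lambda))
}

#' Species proportions from positive-well counts
#'
#' Proportions are raw positive-well fractions per species (no Poisson
#' co-occupancy correction, matching the plate read-out), with Wilson
#' intervals; species are sorted by amplicon size.
#'
#' @param species_counts Data frame with columns `size_kb` and
#'   `positive_wells` (one row per species; species with zero positives are
#'   dropped from the summary).
#' @param cell_id Optional cell label carried into the summary.
#' @param conf Confidence level for the Wilson intervals.
#' @return List of class `cell_smpcr_summary`: `cell_id`, `species` (data
#'   frame with `size_kb`, `positive_wells`, `proportion`, `ci_lower`,
#'   `ci_upper`), `n_species`, `n_positive`.
#' @export
species_proportions <- function(species_counts, cell_id = NA_character_,
                                conf = 0.95) {
  needed <- c("size_kb", "positive_wells")
  missing <- setdiff(needed, names(species_counts))
  if (length(missing)) {
    stop("species table lacks column(s): ", paste(missing, collapse = ", "))
  }
  sc <- species_counts[species_counts$positive_wells > 0, , drop = FALSE]
  total <- sum(sc$positive_wells)
  if (total == 0L) stop("no positive wells: cannot estimate proportions")
  sc <- sc[order(sc$size_kb), , drop = FALSE]
  ci <- t(vapply(sc$positive_wells,
                 function(x) wilson_ci(x, total, conf),
                 numeric(2)))
  species <- data.frame(size_kb = sc$size_kb,
                        positive_wells = sc$positive_wells,
                        proportion = sc$positive_wells / total,
                        ci_lower = ci[, 1L], ci_upper = ci[, 2L])
  structure(list(cell_id = cell_id, species = species,
                 n_species = nrow(species), n_positive = total),
            class = "cell_smpcr_summary")
}

#' Per-well plate outcomes to species counts
#'
#' @param wells Data frame with columns `well` and `outcome` (`"negative"`
#'   or a species size label such as `"5"` / `"8.5"`, in kb).
#' @return Data frame with `size_kb`, `positive_wells`, plus attribute
#'   `n_wells`.
#' @export
tally_wells <- function(wells) {
  needed <- c("well", "outcome")
  missing <- setdiff(needed, names(wells))
  if (length(missing)) {
    stop("well table lacks column(s): ", paste(missing, collapse = ", "))
  }
  pos <- wells$outcome[wells$outcome != "negative"]
  sizes <- suppressWarnings(as.numeric(pos))
  if (anyNA(sizes)) {
    stop("non-numeric species label(s): ",
         paste(unique(pos[is.na(sizes)]), collapse = ", "))
  }
  tab <- table(sizes)
  out <- data.frame(size_kb = as.numeric(names(tab)),
                    positive_wells = as.integer(tab))
  attr(out, "n_wells") <- nrow(wells)
  out
}

# --- "largest deletion most prevalent" -------------------------------------
# The largest deletion yields the SMALLEST molecule; Table-3-style input
# lists per species the amplicon size (kb) and its proportion. A cell with
# >= 2 species counts toward the numerator when the species of largest
# deletion size has the strictly highest proportion; ties (in top
# proportion, or duplicated maximal size) are excluded from the numerator
# and reported separately.

#' Per-patient prevalence of the largest deletion species
#'
#' @param cells Long-form data frame with columns `patient_id`, `cell_id`,
#'   `size_kb` (deletion size; larger deletion = smaller molecule),
#'   `proportion` (one row per species per cell).
#' @return Data frame per patient: `patient_id`, `n_multi` (cells with >= 2
#'   species), `n_largest_most_prevalent`, `n_ties`, `fraction`, `pct`
#'   (1 dp); patients with no multi-species cells get `NA` fraction.
#' @export
largest_prevalence <- function(cells) {
  needed <- c("patient_id", "cell_id", "size_kb", "proportion")
  missing <- setdiff(needed, names(cells))
  if (length(missing)) {
    stop("cell species table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- lapply(split(cells, cells$patient_id), function(pc) {
    per_cell <- split(pc, pc$cell_id)
    multi <- Filter(function(s) nrow(s) >= 2L, per_cell)
    n_multi <- length(multi)
    n_yes <- 0L
    n_tie <- 0L
    for (s in multi) {
      top_prop <- max(s$proportion)
      top_size <- max(s$size_kb)
      prop_tie <- sum(s$proportion == top_prop) > 1L
      size_tie <- sum(s$size_kb == top_size) > 1L
      if (prop_tie || size_tie) {
        # Ambiguous ordering: counted separately, never in the numerator.
        n_tie <- n_tie + 1L
        next
      }
      if (s$proportion[which.max(s$size_kb)] == top_prop) n_yes <- n_yes + 1L
    }
    data.frame(patient_id = pc$patient_id[1L],
               n_multi = n_multi,
               n_largest_most_prevalent = n_yes,
               n_ties = n_tie,
               fraction = if (n_multi > 0L) n_yes / n_multi else NA_real_,
               pct = if (n_multi > 0L) round(100 * n_yes / n_multi, 1)
                     else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distribution of deletion-species multiplicity over cells
#'
#' Counts and percentages (1 dp) of cells harbouring 1, 2, 3, ... deletion
#' species.
#'
#' @param n_species Integer vector: species count per cell (>= 1).
#' @return Data frame with `n_species`, `n_cells`, `pct`.
#' @export
multiplicity_distribution <- function(n_species) {
  if (length(n_species) == 0L) stop("no cells to summarise")
  if (any(n_species < 1L)) stop("each cell must carry at least one species")
  levels <- seq_len(max(n_species))
  counts <- vapply(levels, function(k) sum(n_species == k), integer(1))
  data.frame(n_species = levels, n_cells = counts,
             pct = percent_1dp(counts))
}

#' Flag internal inconsistencies in a cell-species table
#'
#' Surfaces (never silently corrects) rows whose proportions do not sum to
#' 1 within `tol`, cells listing the same deletion size twice, and -- when a
#' printed "is the largest deletion most prevalent" flag column is supplied
#' -- cells where that flag disagrees with the ordering recomputed from the
#' size/proportion data.
#'
#' @param cells Long-form table as for [largest_prevalence()]; optionally a
#'   `printed_largest_flag` column (`"Yes"` / `"No"` / `NA`).
#' @param tol Tolerance on the per-cell proportion sum (default 0.01).
#' @return Data frame of anomalies: `patient_id`, `cell_id`, `anomaly`,
#'   `detail`; zero rows when the table is clean.
#' @export
flag_smpcr_anomalies <- function(cells, tol = 0.01) {
  rows <- list()
  for (pc in split(cells, paste(cells$patient_id, cells$cell_id, sep = "\r"))) {
    pid <- pc$patient_id[1L]
    cid <- pc$cell_id[1L]
    s <- sum(pc$proportion)
    if (abs(s - 1) > tol) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, cell_id = cid, anomaly = "proportion_sum",
        detail = sprintf("proportions sum to %.4g", s))
    }
    if (anyDuplicated(pc$size_kb)) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, cell_id = cid, anomaly = "duplicate_size",
        detail = sprintf("size %.4g kb listed more than once",
                         pc$size_kb[duplicated(pc$size_kb)][1L]))
    }
    if ("printed_largest_flag" %in% names(pc) && nrow(pc) >= 2L) {
      printed <- pc$printed_largest_flag[1L]
      if (!is.na(printed) && nzchar(printed)) {
        top_prop <- max(pc$proportion)
        strict <- sum(pc$proportion == top_prop) == 1L &&
          sum(pc$size_kb == max(pc$size_kb)) == 1L &&
          pc$proportion[which.max(pc$size_kb)] == top_prop
        computed <- if (strict) "Yes" else "No"
        if (computed != printed) {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = pid, cell_id = cid, anomaly = "largest_flag",
            detail = sprintf("printed '%s' but size/proportion data give '%s'",
                             printed, computed))
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(patient_id = character(0), cell_id = character(0),
                      anomaly = character(0), detail = character(0)))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Read a long-form smPCR species table (CSV)
#'
#' Expected columns: `patient_id`, `cell_id`, `size_kb` and either
#' `proportion` or `positive_wells` (+ optional `n_wells`).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_smpcr_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "cell_id", "size_kb")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop("smPCR table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!("proportion" %in% names(d)) && !("positive_wells" %in% names(d))) {
    stop("smPCR table needs a 'proportion' or 'positive_wells' column")
  }
  d
}
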