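# Moran-process simulator of intracellular clonal expansion of mtDNA
# species.
#
# Each cell holds a fixed total of N mtDNA molecules split over species
# (wild-type and/or deletion species of known genome length). One Moran
# event removes one molecule chosen uniformly and copies one molecule
# chosen with probability proportional to count_i * w_i, where
# w_i = (L_wt / L_i)^alpha. alpha = 0 is exact neutrality (random genetic
# drift through relaxed replication); alpha = 1 makes the replication rate
# inversely proportional to genome length (the naive replication-time
# argument behind "survival of the smallest"). Time is measured in Moran
# events; no calendar-time calibration is attempted.

WT_GENOME_KB <- 16.6

#' Define an mtDNA species for simulation
#'
#' @param label Species label.
#' @param length_kb Genome length in kb (0 < length_kb <= 16.6; the
#'   wild-type molecule is 16.6 kb).
#' @param copies Initial copy number (>= 0).
#' @param wildtype Whether this species is the wild-type genome (excluded
#'   by default from the "smallest most prevalent" comparison set, since
#'   the smPCR assay sees only deleted molecules).
#' @return A list of class `species_spec`.
#' @export
species_spec <- function(label, length_kb, copies, wildtype = FALSE) {
  if (length_kb <= 0 || length_kb > WT_GENOME_KB) {
    stop("length_kb must lie in (0, ", WT_GENOME_KB, "]")
  }
  if (copies < 0) stop("initial copies must be >= 0")
  structure(list(label = label, length_kb = length_kb,
                 copies = as.integer(copies), wildtype = wildtype),
            class = "species_spec")
}

#' Simulation configuration
#'
#' @param species List of [species_spec()] objects; initial copies must sum
#'   to `n_copies`.
#' @param alpha Replicative-advantage exponent (>= 0; 0 = neutral drift).
#' @param n_steps Moran events per cell.
#' @param n_cells Number of independent cells.
#' @param seed Integer seed; every run must name one explicitly.
#' @param n_copies Total copy number N per cell (conserved).
#' @param record_times Step indices at which to record states (defaults to
#'   the final step).
#' @param formation_rate Per-replication probability that the copy is
#'   instead a de novo deletion species (default 0; exploratory only).
#' @param include_wildtype Include the wild-type in the prevalence
#'   comparison set (default FALSE).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(species, alpha = 0, n_steps = 1000L, n_cells = 100L,
                       seed, n_copies = NULL, record_times = NULL,
                       formation_rate = 0, include_wildtype = FALSE) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  if (!length(species)) stop("at least one species is required")
  lapply(species, function(s) stopifnot(inherits(s, "species_spec")))
  labels <- vapply(species, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("species labels must be unique")
  copies <- vapply(species, `[[`, integer(1), "copies")
  total <- sum(copies)
  if (is.null(n_copies)) n_copies <- total
  if (total != n_copies) {
    stop("initial copies (", total, ") must sum to n_copies (", n_copies, ")")
  }
  if (n_copies <= 1L) stop("total copy number must exceed 1")
  if (alpha < 0) stop("alpha must be >= 0")
  if (formation_rate < 0 || formation_rate > 1) {
    stop("formation_rate must lie in [0, 1]")
  }
  if (is.null(record_times)) record_times <- n_steps
  record_times <- sort(unique(as.integer(record_times)))
  if (any(record_times < 0L) || any(record_times > n_steps)) {
    stop("record_times must lie in [0, n_steps]")
  }
  structure(list(species = species, alpha = alpha,
                 n_steps = as.integer(n_steps),
                 n_cells = as.integer(n_cells),
                 seed = as.integer(seed),
                 n_copies = as.integer(n_copies),
                 record_times = record_times,
                 formation_rate = formation_rate,
                 include_wildtype = include_wildtype),
            class = "sim_config")
}

#' Replication weights under the length-advantage model
#'
#' `w_i = (L_wt / L_i)^alpha`: 1 for every species at alpha = 0; larger for
#' shorter genomes at alpha > 0.
#'
#' @param lengths_kb Genome lengths in kb.
#' @param alpha Advantage exponent.
#' @param wt_length_kb Reference (wild-type) genome length.
#' @return Numeric weights.
#' @export
replication_weights <- function(lengths_kb, alpha,
                                wt_length_kb = WT_GENOME_KB) {
  if (any(lengths_kb <= 0)) stop("genome lengths must be > 0")
  (wt_length_kb / lengths_kb)^alpha
}

#' One Moran event
#'
#' Removes one molecule chosen uniformly and adds a copy of one molecule
#' chosen with probability proportional to `counts * weights`, both drawn
#' from the pre-event state; total copy number is conserved.
#'
#' @param counts Integer per-species copy counts (sum > 1).
#' @param weights Per-species replication weights (see
#'   [replication_weights()]).
#' @return Updated counts.
#' @export
moran_step <- function(counts, weights = rep(1, length(counts))) {
  n <- sum(counts)
  if (n <= 1L) stop("total copy number must exceed 1")
  if (length(weights) != length(counts)) {
    stop("weights must match counts in length")
  }
  s <- length(counts)
  death <- sample.int(s, 1L, prob = counts)
  birth <- sample.int(s, 1L, prob = counts * weights)
  counts[death] <- counts[death] - 1L
  counts[birth] <- counts[birth] + 1L
  counts
}

#' Simulate one cell's trajectory
#'
#' Runs `n_steps` Moran events from the configured initial state and
#' returns the per-species copy counts at each requested record time.
#' Deterministic given the config seed. With `formation_rate > 0` each
#' replication may instead create a de novo deletion species (a fresh
#' label with genome length drawn uniformly from 2 kb to the wild-type
#' length); the state then grows extra columns.
#'
#' @param config A [sim_config()].
#' @param cell_index Offsets the seed so cohort cells are independent yet
#'   reproducible.
#' @return Matrix of counts (record times x species), with the record step
#'   index in `rownames` and species labels in `colnames`.
#' @export
simulate_cell <- function(config, cell_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed + 7919L * (as.integer(cell_index) - 1L)) %% .Machine$integer.max)
  labels <- vapply(config$species, `[[`, character(1), "label")
  lengths <- vapply(config$species, `[[`, numeric(1), "length_kb")
  counts <- vapply(config$species, `[[`, integer(1), "copies")
  weights <- replication_weights(lengths, config$alpha)
  rec <- matrix(NA_integer_, nrow = length(config$record_times),
                ncol = length(counts),
                dimnames = list(config$record_times, labels))
  ri <- 1L
  record_if_due <- function(step) {
    while (ri <= length(config$record_times) &&
           config$record_times[ri] == step) {
      if (ncol(rec) < length(counts)) {  # de novo species appeared
        extra <- length(counts) - ncol(rec)
        rec <<- cbind(rec, matrix(NA_integer_, nrow(rec), extra))
        colnames(rec) <<- names(counts)
      }
      rec[ri, ] <<- counts
      ri <<- ri + 1L
    }
  }
  names(counts) <- labels
  record_if_due(0L)
  if (config$n_steps > 0L) {
    for (step in seq_len(config$n_steps)) {
      if (config$formation_rate > 0 &&
          stats::runif(1) < config$formation_rate) {
        # replication copies into a brand-new deletion species instead
        death <- sample.int(length(counts), 1L, prob = counts)
        new_len <- stats::runif(1, 2, WT_GENOME_KB)
        counts[death] <- counts[death] - 1L
        counts <- c(counts, 1L)
        new_lab <- sprintf("denovo_%d", length(counts))
        names(counts)[length(counts)] <- new_lab
        lengths <- c(lengths, new_len)
        weights <- replication_weights(lengths, config$alpha)
      } else {
        counts <- moran_step(counts, weights)
      }
      record_if_due(step)
    }
  }
  attr(rec, "lengths_kb") <- lengths
  rec
}

# Vectorised multi-cell Moran engine: one matrix op per event across all
# cells. Only used when no de novo formation is configured.
.simulate_cells_vectorised <- function(config) {
  set.seed(config$seed)
  labels <- vapply(config$species, `[[`, character(1), "label")
  lengths <- vapply(config$species, `[[`, numeric(1), "length_kb")
  init <- vapply(config$species, `[[`, integer(1), "copies")
  w <- replication_weights(lengths, config$alpha)
  n_cells <- config$n_cells
  S <- length(init)
  N <- config$n_copies
  C <- matrix(rep(init, each = n_cells), nrow = n_cells,
              dimnames = list(NULL, labels))
  snapshots <- vector("list", length(config$record_times))
  names(snapshots) <- as.character(config$record_times)
  take <- function(step) {
    hit <- which(config$record_times == step)
    for (h in hit) snapshots[[h]] <<- C
  }
  pick_species <- function(P) {
    # P: n_cells x S matrix of nonnegative masses; returns one index per
    # cell sampled proportionally per row.
    tot <- rowSums(P)
    u <- stats::runif(n_cells) * tot
    idx <- rep(1L, n_cells)
    cum <- P[, 1L]
    if (S > 1L) {
      for (j in seq_len(S - 1L)) {
        idx <- idx + (u > cum)
        if (j < S - 1L) cum <- cum + P[, j + 1L]
      }
    }
    idx
  }
  take(0L)
  if (config$n_steps > 0L) {
    for (step in seq_len(config$n_steps)) {
      death <- pick_species(C)
      birth <- pick_species(C * rep(w, each = n_cells))
      ij_d <- cbind(seq_len(n_cells), death)
      ij_b <- cbind(seq_len(n_cells), birth)
      C[ij_d] <- C[ij_d] - 1L
      C[ij_b] <- C[ij_b] + 1L
      take(step)
    }
  }
  stopifnot(all(rowSums(C) == N))
  list(snapshots = snapshots, lengths_kb = lengths,
       wildtype = vapply(config$species, `[[`, logical(1), "wildtype"))
}

#' Fraction of cells in which the smallest genome is most prevalent
#'
#' Given a per-cell species-count matrix, restricts to the comparison set
#' (deleted species only, unless `include_wildtype`), keeps cells carrying
#' at least two species of that set, drops cells whose ordering is
#' ambiguous (tied top counts or tied minimal genome length) and returns
#' the fraction of the remaining cells in which the species with the
#' smallest genome has the strictly highest count.
#'
#' @param counts Cells x species count matrix.
#' @param lengths_kb Genome length per species (columns of `counts`).
#' @param wildtype Logical per species.
#' @param include_wildtype Keep wild-type in the comparison set.
#' @return List: `fraction`, `n_numerator`, `n_denominator`, `n_ties`,
#'   `n_multi` (cells with >= 2 comparison species before tie exclusion).
#' @export
smallest_prevalent_fraction <- function(counts, lengths_kb,
                                        wildtype = rep(FALSE, ncol(counts)),
                                        include_wildtype = FALSE) {
  keep <- if (include_wildtype) rep(TRUE, ncol(counts)) else !wildtype
  if (sum(keep) < 2L) {
    return(list(fraction = NA_real_, n_numerator = 0L, n_denominator = 0L,
                n_ties = 0L, n_multi = 0L))
  }
  Ck <- counts[, keep, drop = FALSE]
  Lk <- lengths_kb[keep]
  present <- Ck > 0L
  multi <- rowSums(present) >= 2L
  n_multi <- sum(multi)
  n_yes <- 0L
  n_tie <- 0L
  for (i in which(multi)) {
    cnt <- Ck[i, ]
    lens <- Lk
    lens[cnt == 0L] <- NA_real_
    top <- max(cnt)
    min_len <- min(lens, na.rm = TRUE)
    if (sum(cnt == top) > 1L || sum(lens == min_len, na.rm = TRUE) > 1L) {
      n_tie <- n_tie + 1L
      next
    }
    if (cnt[which.min(lens)] == top) n_yes <- n_yes + 1L
  }
  denom <- n_multi - n_tie
  list(fraction = if (denom > 0L) n_yes / denom else NA_real_,
       n_numerator = n_yes, n_denominator = denom,
       n_ties = n_tie, n_multi = n_multi)
}

#' Simulate a cohort of cells
#'
#' Runs the Moran process independently in `n_cells` cells and aggregates:
#' per-species heteroplasmy quantiles at each record time, fixation/loss
#' counts at the final state, and the smPCR-comparable statistic (the
#' fraction of multi-species cells in which the smallest genome is most
#' prevalent; see [smallest_prevalent_fraction()]).
#'
#' @param config A [sim_config()] (with `formation_rate = 0`; de novo
#'   formation is available through [simulate_cell()] only).
#' @return List of class `sim_summary`: `final_counts` (cells x species),
#'   `heteroplasmy_quantiles` (per record time), `smallest_prevalent`,
#'   `fixed`, `lost` (per-species cell counts at the final record),
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cells < 1L) stop("n_cells must be >= 1")
  if (config$formation_rate > 0) {
    stop("simulate_cohort requires formation_rate = 0; ",
         "use simulate_cell for de novo formation runs")
  }
  eng <- .simulate_cells_vectorised(config)
  N <- config$n_copies
  het_q <- lapply(eng$snapshots, function(C) {
    apply(C / N, 2L, stats::quantile,
          probs = c(0.05, 0.25, 0.5, 0.75, 0.95))
  })
  final <- eng$snapshots[[length(eng$snapshots)]]
  sp <- smallest_prevalent_fraction(final, eng$lengths_kb, eng$wildtype,
                                    config$include_wildtype)
  structure(list(
    final_counts = final,
    heteroplasmy_quantiles = het_q,
    smallest_prevalent = sp,
    fixed = colSums(final == N),
    lost = colSums(final == 0L),
    config = config
  ), class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "sim_summary: %d cells, N = %d, alpha = %.3g, %d Moran events\n",
    cfg$n_cells, cfg$n_copies, cfg$alpha, cfg$n_steps))
  sp <- x$smallest_prevalent
  if (is.na(sp$fraction)) {
    cat("  smallest-most-prevalent: undefined (no comparable cells)\n")
  } else {
    cat(sprintf(
      "  smallest-most-prevalent: %d/%d = %.3f (%d tied cells excluded)\n",
      sp$n_numerator, sp$n_denominator, sp$fraction, sp$n_ties))
  }
  cat("  fixed:", paste(sprintf("%s=%d", names(x$fixed), x$fixed),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Exact binomial comparison of an observed prevalence count
#'
#' Two-sided exact binomial probability of the observed numerator given
#' the simulated smallest-most-prevalent fraction, by the minimum-
#' likelihood method (the sum of P(X = x) over all x no more probable than
#' the observed count); no normal approximation.
#'
#' @param simulated_fraction Success probability under the simulated model
#'   (in `[0, 1]`).
#' @param observed_numerator Observed count of cells with the smallest
#'   genome most prevalent.
#' @param observed_denominator Observed number of comparable cells (>= 1).
#' @return List with `p_value`, `expected`, `observed_fraction`.
#' @export
compare_to_observed <- function(simulated_fraction, observed_numerator,
                                observed_denominator) {
  if (observed_denominator < 1L) stop("denominator must be >= 1")
  if (observed_numerator < 0L || observed_numerator > observed_denominator) {
    stop("numerator must lie in [0, denominator]")
  }
  if (simulated_fraction < 0 || simulated_fraction > 1) {
    stop("simulated_fraction must lie in [0, 1]")
  }
  d <- stats::dbinom(0:observed_denominator, observed_denominator,
                     simulated_fraction)
  p_obs <- d[observed_numerator + 1L]
  # allow for floating-point ties at the observed likelihood
  p <- sum(d[d <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p),
       expected = simulated_fraction * observed_denominator,
       observed_fraction = observed_numerator / observed_denominator)
}
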