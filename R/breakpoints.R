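# Junction-repeat detection at mtDNA deletion breakpoints.
#
# A deletion junction carries a (perfect) direct repeat when the retained
# sequence ENDING at the 5' breakpoint and the retained sequence STARTING
# at the 3' breakpoint share a common affix: the last k bases of the 5'
# flank equal the first k bases of the 3' flank. Repeats shorter than 3 bp
# are classed as "no repeat".

#' Validate and normalise a flank sequence
#'
#' Uppercases and checks the alphabet; any character outside A/C/G/T is
#' rejected with an error naming the offending position(s).
#'
#' @param seq A single flank sequence.
#' @param label Label used in error messages.
#' @return The uppercased sequence.
#' @export
clean_flank <- function(seq, label = "flank") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(label, " must be a nonempty sequence")
  }
  up <- toupper(seq)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop(label, " contains non-ACGT character(s) '",
         paste(chars[bad], collapse = "', '"), "' at position(s) ",
         paste(bad, collapse = ", "))
  }
  up
}

#' Classify a junction repeat by its length
#'
#' Repeats of 2 bp or shorter are classed as "no repeat"; longer ones as
#' "{k}bp perfect repeat".
#'
#' @param length_bp Repeat length(s), >= 0. Vectorised.
#' @param min_length Minimum length counted as a repeat (default 3).
#' @return Character vector of class labels.
#' @export
classify_repeat <- function(length_bp, min_length = 3L) {
  if (any(length_bp < 0)) stop("repeat length must be >= 0")
  ifelse(length_bp >= min_length,
         paste0(length_bp, "bp perfect repeat"),
         "no repeat")
}

#' Longest perfect direct repeat at a deletion junction
#'
#' Finds the largest k such that the last k bases of the 5' retained flank
#' equal the first k bases of the 3' retained flank, and classifies it
#' under the >= 3 bp rule.
#'
#' @param five_prime_flank Retained sequence ending at the 5' breakpoint.
#' @param three_prime_flank Retained sequence starting at the 3' breakpoint.
#' @param min_length Minimum length counted as a repeat (default 3).
#' @return List of class `repeat_call`: `length_bp`, `sequence` (empty
#'   string when length 0), `klass`.
#' @export
longest_junction_repeat <- function(five_prime_flank, three_prime_flank,
                                    min_length = 3L) {
  f5 <- clean_flank(five_prime_flank, "five_prime_flank")
  f3 <- clean_flank(three_prime_flank, "three_prime_flank")
  n5 <- nchar(f5)
  n3 <- nchar(f3)
  kmax <- min(n5, n3)
  len <- 0L
  for (k in seq.int(kmax, 1L)) {
    if (substr(f5, n5 - k + 1L, n5) == substr(f3, 1L, k)) {
      len <- k
      break
    }
  }
  structure(list(length_bp = len,
                 sequence = if (len > 0L) substr(f3, 1L, len) else "",
                 klass = classify_repeat(len, min_length)),
            class = "repeat_call")
}

#' @export
print.repeat_call <- function(x, ...) {
  if (x$length_bp > 0L) {
    cat(sprintf("%s (%s)\n", x$klass, x$sequence))
  } else {
    cat("no repeat\n")
  }
  invisible(x)
}

#' Junction repeats for a table of flank pairs
#'
#' @param flanks Data frame with columns `product_id`, `five_prime_flank`,
#'   `three_prime_flank`.
#' @param min_length Minimum length counted as a repeat (default 3).
#' @return The input with added `repeat_length`, `repeat_sequence`,
#'   `repeat_class`.
#' @export
junction_repeat_table <- function(flanks, min_length = 3L) {
  needed <- c("product_id", "five_prime_flank", "three_prime_flank")
  missing <- setdiff(needed, names(flanks))
  if (length(missing)) {
    stop("flank table lacks column(s): ", paste(missing, collapse = ", "))
  }
  calls <- lapply(seq_len(nrow(flanks)), function(i) {
    longest_junction_repeat(flanks$five_prime_flank[i],
                            flanks$three_prime_flank[i],
                            min_length)
  })
  flanks$repeat_length <- vapply(calls, `[[`, integer(1), "length_bp")
  flanks$repeat_sequence <- vapply(calls, `[[`, character(1), "sequence")
  flanks$repeat_class <- vapply(calls, `[[`, character(1), "klass")
  flanks
}

#' Count repeat-bearing junctions at a length threshold
#'
#' Reports, for thresholds of interest (by default >= 2 bp and >= 3 bp),
#' how many junctions carry a common affix at least that long, with
#' percentages to 1 dp.
#'
#' @param repeat_lengths Integer vector of junction repeat lengths.
#' @param thresholds Length thresholds to tally at.
#' @return Data frame with `threshold_bp`, `n_repeat`, `n_total`, `pct`.
#' @export
repeat_count_summary <- function(repeat_lengths, thresholds = c(2L, 3L)) {
  n <- length(repeat_lengths)
  if (n == 0L) stop("no repeat lengths to summarise")
  do.call(rbind, lapply(thresholds, function(th) {
    k <- sum(repeat_lengths >= th)
    data.frame(threshold_bp = th, n_repeat = k, n_total = n,
               pct = round(100 * k / n, 1))
  }))
}

#' Read a single circular reference sequence from FASTA
#'
#' @param path FASTA file with exactly one record.
#' @return The sequence as a single uppercase character string.
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop("reference FASTA must contain exactly one record, found ",
         length(set))
  }
  toupper(as.character(set[[1L]]))
}

# Circular 1-based indexing into a sequence string.
.circular_substring <- function(seq, positions, len) {
  idx <- ((positions - 1L) %% len) + 1L
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  paste(chars[idx], collapse = "")
}

#' Extract breakpoint flanks from a circular reference
#'
#' The 5' flank is the `window` retained bases ending at `bp5`
#' (`bp5-window+1 ... bp5`) and the 3' flank the `window` retained bases
#' starting at `bp3` (`bp3 ... bp3+window-1`), both wrapping circularly.
#'
#' @param reference Circular reference sequence (character string, ACGT).
#' @param bp5,bp3 Breakpoints (1-based, on the reference).
#' @param window Flank length in bp (>= 1, <= reference length).
#' @return List with `five_prime_flank` and `three_prime_flank`.
#' @export
flanks_from_reference <- function(reference, bp5, bp3, window = 20L) {
  len <- nchar(reference)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window > len) stop("window exceeds reference length (", len, ")")
  if (bp5 < 1L || bp5 > len || bp3 < 1L || bp3 > len) {
    stop("breakpoints out of range [1, ", len, "]")
  }
  list(
    five_prime_flank = .circular_substring(reference,
                                           seq.int(bp5 - window + 1L, bp5),
                                           len),
    three_prime_flank = .circular_substring(reference,
                                            seq.int(bp3, bp3 + window - 1L),
                                            len)
  )
}

#' Concordance between triplex and breakpoint-derived deletion classes
#'
#' @param triplex_class Class from the triplex assay (see
#'   [classify_triplex()]); `NA` when not measured.
#' @param expected_class Class expected from the sequenced breakpoints (see
#'   [expected_triplex_class()]); `NA` when not sequenced. Vectorised.
#' @return Character vector: `"agree"`, `"disagree"`, or `"incomparable"`
#'   when either class is missing.
#' @export
concordance <- function(triplex_class, expected_class) {
  if (length(triplex_class) != length(expected_class)) {
    stop("class vectors must have equal length")
  }
  ifelse(is.na(triplex_class) | is.na(expected_class), "incomparable",
         ifelse(triplex_class == expected_class, "agree", "disagree"))
}

#' Read a flank-pair table (CSV)
#'
#' Expected columns: `product_id`, `five_prime_flank`, `three_prime_flank`;
#' sequences are validated and uppercased.
#'
#' @param path CSV path.
#' @return Validated flank data frame.
#' @export
read_flank_table <- function(path) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("product_id", "five_prime_flank", "three_prime_flank")
  missing <- setdiff(needed, names(f))
  if (length(missing)) {
    stop("flank table lacks column(s): ", paste(missing, collapse = ", "))
  }
  f$five_prime_flank <- vapply(seq_len(nrow(f)), function(i) {
    clean_flank(f$five_prime_flank[i],
                paste0("five_prime_flank[", f$product_id[i], "]"))
  }, character(1))
  f$three_prime_flank <- vapply(seq_len(nrow(f)), function(i) {
    clean_flank(f$three_prime_flank[i],
                paste0("three_prime_flank[", f$product_id[i], "]"))
  }, character(1))
  f
}
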