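# Independent brute-force oracles used across the suite. These deliberately
# take the dumbest correct route (per-position tallies, character-wise
# scans, molecule enumeration) so they share no code path with the
# implementation they check.

# Per-position oracle for deletion annotation: walk every genome position,
# mark whether it is removed, and tally coverage per feature.
oracle_annotate <- function(bp5, bp3, map) {
  L <- map$genome_length
  removed_pos <- rep(FALSE, L)
  if (bp3 - bp5 >= 2) removed_pos[(bp5 + 1):(bp3 - 1)] <- TRUE
  fully <- character(0)
  partially <- character(0)
  for (i in seq_len(nrow(map$features))) {
    s <- map$features$start[i]
    e <- map$features$end[i]
    span <- if (s <= e) s:e else c(s:L, 1:e)
    hit <- sum(removed_pos[span])
    if (hit == 0) next
    if (hit == length(span)) fully <- c(fully, map$features$name[i])
    else partially <- c(partially, map$features$name[i])
  }
  list(fully = fully, partially = partially)
}

# Character-wise junction-repeat oracle: scan k downward comparing base by
# base.
oracle_longest_repeat <- function(f5, f3) {
  a <- strsplit(f5, "")[[1]]
  b <- strsplit(f3, "")[[1]]
  for (k in seq.int(min(length(a), length(b)), 1)) {
    if (all(a[seq.int(length(a) - k + 1, length(a))] == b[seq_len(k)])) {
      return(k)
    }
  }
  0L
}

# Molecule-counting oracle for the triplex metrics: enumerate molecules
# with per-molecule target presence and D-loop strandedness and count
# template copies directly.
oracle_triplex_metrics <- function(has_nd1, has_nd4, triple_stranded) {
  nd1 <- sum(has_nd1)
  nd4 <- sum(has_nd4)
  dloop <- sum(ifelse(triple_stranded, 1.5, 1))
  c(del_nd4_nd1_pct = (1 - nd4 / nd1) * 100,
    nd1_dloop_pct = (1 - nd1 / dloop) * 100,
    nd4_dloop_pct = (1 - nd4 / dloop) * 100)
}

# Exact one-step Moran transition probabilities for two species with
# counts (k, N - k) and replication weights (w1, w2): returns
# P(k -> k+1), P(k -> k-1), P(stay).
oracle_moran_kernel <- function(k, N, w1 = 1, w2 = 1) {
  tot <- k * w1 + (N - k) * w2
  up <- ((N - k) / N) * (k * w1 / tot)
  down <- (k / N) * ((N - k) * w2 / tot)
  c(up = up, down = down, stay = 1 - up - down)
}

# Random ACGT string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
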