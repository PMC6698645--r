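# Circular mitochondrial genome coordinates and deletion annotation.
#
# All positions are 1-based inclusive in rCRS (NC_012920.1) numbering.
# A deletion with breakpoints (bp5, bp3) retains base bp5 (last retained
# base on the 5' side) and base bp3 (first retained base on the 3' side);
# the removed bases are the OPEN interval bp5+1 ... bp3-1, so that
# size = bp3 - bp5 - 1.

RCRS_LENGTH <- 16569L

FEATURE_KINDS <- c("protein_gene", "tRNA", "rRNA", "origin", "control_region")

REQUIRED_FEATURES <- c("MT-ND1", "MT-ND4", "MT-CO1", "MT-CO2", "MT-CO3",
                       "O_L", "control_region")

#' Built-in rCRS feature map
#'
#' Feature coordinates of the revised Cambridge Reference Sequence
#' (NC_012920.1, 16,569 bp, circular): the 13 protein-coding genes, the two
#' rRNAs, the light-strand replication origin O_L and the control region
#' (D-loop), which wraps the origin of numbering (16024..576).
#'
#' @return A `genome_map` object (see [load_genome_map()]).
#' @export
default_genome_map <- function() {
  features <- data.frame(
    name = c("MT-RNR1", "MT-RNR2", "MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2",
             "MT-ATP8", "MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4",
             "MT-ND5", "MT-ND6", "MT-CYB", "O_L", "control_region"),
    start = c(648L, 1671L, 3307L, 4470L, 5904L, 7586L,
              8366L, 8527L, 9207L, 10059L, 10470L, 10760L,
              12337L, 14149L, 14747L, 5721L, 16024L),
    end = c(1601L, 3229L, 4262L, 5511L, 7445L, 8269L,
            8572L, 9207L, 9990L, 10404L, 10766L, 12137L,
            14148L, 14673L, 15887L, 5798L, 576L),
    kind = c("rRNA", "rRNA", "protein_gene", "protein_gene", "protein_gene",
             "protein_gene", "protein_gene", "protein_gene", "protein_gene",
             "protein_gene", "protein_gene", "protein_gene", "protein_gene",
             "protein_gene", "protein_gene", "origin", "control_region"),
    stringsAsFactors = FALSE
  )
  new_genome_map(RCRS_LENGTH, features)
}

new_genome_map <- function(genome_length, features) {
  map <- structure(
    list(genome_length = as.integer(genome_length), features = features),
    class = "genome_map"
  )
  validate_genome_map(map)
  map
}

#' Validate a genome feature map
#'
#' Checks coordinate ranges, feature-name uniqueness, allowed feature kinds,
#' the presence of the features downstream analyses rely on (MT-ND1, MT-ND4,
#' the three MT-CO genes, O_L, control_region) and that only the control
#' region is allowed to wrap the origin of numbering.
#'
#' @param map A `genome_map` object.
#' @return The map, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_genome_map <- function(map) {
  stopifnot(inherits(map, "genome_map"))
  f <- map$features
  L <- map$genome_length
  if (L < 1L) stop("genome_length must be positive")
  needed_cols <- c("name", "start", "end", "kind")
  if (!all(needed_cols %in% names(f))) {
    stop("feature table must have columns: ", paste(needed_cols, collapse = ", "))
  }
  if (anyDuplicated(f$name)) {
    stop("duplicate feature names: ",
         paste(unique(f$name[duplicated(f$name)]), collapse = ", "))
  }
  bad_kind <- setdiff(unique(f$kind), FEATURE_KINDS)
  if (length(bad_kind)) {
    stop("unknown feature kind(s): ", paste(bad_kind, collapse = ", "))
  }
  out_of_range <- f$start < 1L | f$start > L | f$end < 1L | f$end > L
  if (any(out_of_range)) {
    stop("feature coordinates out of range [1, ", L, "]: ",
         paste(f$name[out_of_range], collapse = ", "))
  }
  wraps <- f$start > f$end
  if (any(wraps & f$kind != "control_region")) {
    stop("only control_region features may wrap the origin (start > end): ",
         paste(f$name[wraps & f$kind != "control_region"], collapse = ", "))
  }
  missing <- setdiff(REQUIRED_FEATURES, f$name)
  if (length(missing)) {
    stop("required feature(s) missing from map: ",
         paste(missing, collapse = ", "))
  }
  invisible(map)
}

#' Load a genome feature map
#'
#' Reads a 4-column tab-separated feature table (`name`, `start`, `end`,
#' `kind`) with 1-based inclusive coordinates, or returns the built-in rCRS
#' map when `path` is `NULL`. Note this dialect is 1-based inclusive, i.e.
#' deliberately NOT BED; use [read_features_bed()] / [write_features_bed()]
#' for strict 0-based half-open BED interchange.
#'
#' @param path Path to a feature table, or `NULL` for the built-in rCRS map.
#' @param genome_length Genome length in bp (default rCRS, 16,569).
#' @return A validated `genome_map`.
#' @export
load_genome_map <- function(path = NULL, genome_length = RCRS_LENGTH) {
  if (is.null(path)) return(default_genome_map())
  f <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  new_genome_map(genome_length, f)
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", x$genome_length, "bp,", nrow(x$features), "features\n")
  print(x$features, row.names = FALSE)
  invisible(x)
}

#' Write a feature map as a 1-based inclusive feature table
#'
#' @param map A `genome_map`.
#' @param path Output path.
#' @export
write_feature_table <- function(map, path) {
  validate_genome_map(map)
  utils::write.table(map$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write strict BED feature maps
#'
#' Strict BED is 0-based half-open; these helpers convert to and from the
#' package's 1-based inclusive internal representation. Wrapped features
#' (control region) cannot be represented as a single BED interval and are
#' rejected by the writer.
#'
#' @param path BED file path (columns: chrom, chromStart, chromEnd, name,
#'   score, strand; `kind` is carried in the score column slot as text in
#'   column 7 if present, else defaults to `protein_gene`).
#' @param genome_length Genome length in bp.
#' @return `read_features_bed` returns a `genome_map`.
#' @export
read_features_bed <- function(path, genome_length = RCRS_LENGTH) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 4L) stop("BED feature file needs at least 4 columns")
  kind <- if (ncol(b) >= 7L) b[[7L]] else rep("protein_gene", nrow(b))
  f <- data.frame(name = b[[4L]],
                  start = as.integer(b[[2L]]) + 1L,
                  end = as.integer(b[[3L]]),
                  kind = kind,
                  stringsAsFactors = FALSE)
  new_genome_map(genome_length, f)
}

#' @rdname read_features_bed
#' @param map A `genome_map` to write.
#' @export
write_features_bed <- function(map, path) {
  validate_genome_map(map)
  f <- map$features
  if (any(f$start > f$end)) {
    stop("wrapped features cannot be written as strict BED: ",
         paste(f$name[f$start > f$end], collapse = ", "))
  }
  b <- data.frame(chrom = "chrM", start = f$start - 1L, end = f$end,
                  name = f$name, score = 0L, strand = ".", kind = f$kind)
  utils::write.table(b, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Deletion size from breakpoints
#'
#' Size of the deletion whose last retained 5' base is `bp5` and first
#' retained 3' base is `bp3`, i.e. `bp3 - bp5 - 1` removed bases
#' (the open interval between the retained breakpoint bases). Vectorised.
#'
#' @param bp5 Position (1-based) of the last retained base on the 5' side.
#' @param bp3 Position (1-based) of the first retained base on the 3' side.
#' @return Integer deletion size(s) in bp.
#' @export
deletion_size <- function(bp5, bp3) {
  bp5 <- as.integer(bp5)
  bp3 <- as.integer(bp3)
  if (length(bp5) != length(bp3)) stop("bp5 and bp3 must have equal length")
  if (anyNA(bp5) || anyNA(bp3)) stop("breakpoints must be non-missing")
  if (any(bp5 >= bp3 - 1L)) {
    bad <- which(bp5 >= bp3 - 1L)
    stop("empty or invalid deletion (need bp5 < bp3 - 1) at index ",
         paste(bad, collapse = ", "))
  }
  bp3 - bp5 - 1L
}

#' Validate a table of deletion events
#'
#' @param deletions Data frame with columns `cell_id`, `product_id`, `bp5`,
#'   `bp3`.
#' @param genome_length Genome length for range checks.
#' @return The validated data frame with integer breakpoint columns.
#' @export
validate_deletions <- function(deletions, genome_length = RCRS_LENGTH) {
  needed <- c("cell_id", "product_id", "bp5", "bp3")
  missing <- setdiff(needed, names(deletions))
  if (length(missing)) {
    stop("deletion table lacks column(s): ", paste(missing, collapse = ", "))
  }
  deletions$bp5 <- suppressWarnings(as.integer(deletions$bp5))
  deletions$bp3 <- suppressWarnings(as.integer(deletions$bp3))
  if (anyNA(deletions$bp5) || anyNA(deletions$bp3)) {
    bad <- which(is.na(deletions$bp5) | is.na(deletions$bp3))
    stop("non-numeric or missing breakpoint(s) in row(s) ",
         paste(bad, collapse = ", "))
  }
  if (any(deletions$bp5 < 1L | deletions$bp3 > genome_length)) {
    stop("breakpoints out of range [1, ", genome_length, "]")
  }
  if (any(deletions$bp5 >= deletions$bp3)) {
    bad <- deletions$product_id[deletions$bp5 >= deletions$bp3]
    stop("bp5 must be < bp3 (wrapping deletions are not supported): ",
         paste(bad, collapse = ", "))
  }
  deletions
}

#' Read a deletion table (CSV)
#'
#' Expected columns: `cell_id`, `product_id`, `bp5`, `bp3`; extra columns are
#' carried through.
#'
#' @param path CSV path.
#' @param genome_length Genome length for validation.
#' @return Validated data frame of deletion events.
#' @export
read_deletion_table <- function(path, genome_length = RCRS_LENGTH) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_deletions(d, genome_length)
}

# Overlap of a (possibly wrapped) feature with the removed open interval
# (bp5, bp3). Returns the number of feature bases removed and the feature
# length. The removed interval never wraps (bp5 < bp3 enforced upstream).
.feature_removed_bases <- function(start, end, bp5, bp3, genome_length) {
  lo <- bp5 + 1L
  hi <- bp3 - 1L
  segs <- if (start <= end) {
    list(c(start, end))
  } else {
    list(c(start, genome_length), c(1L, end))
  }
  removed <- 0L
  total <- 0L
  for (s in segs) {
    total <- total + (s[2L] - s[1L] + 1L)
    ov_lo <- max(s[1L], lo)
    ov_hi <- min(s[2L], hi)
    if (ov_lo <= ov_hi) removed <- removed + (ov_hi - ov_lo + 1L)
  }
  c(removed = removed, total = total)
}

#' Annotate a deletion against a genome feature map
#'
#' Determines which features fall fully or partially inside the removed open
#' interval `(bp5, bp3)`, and derives the flags used downstream: removal of
#' the light-strand origin O_L, overlap with the minor arc (the arc between
#' the control region 3' end and the O_L start), and removal (full or
#' partial) of MT-ND1, MT-ND4 and any MT-CO gene.
#'
#' @param bp5,bp3 Breakpoints (last retained 5' base, first retained 3'
#'   base), 1-based rCRS numbering, `bp5 < bp3`.
#' @param map A `genome_map` (default: built-in rCRS map).
#' @return A list of class `deletion_annotation` with elements `size_bp`,
#'   `removed_interval`, `genes_fully_removed`, `genes_partially_removed`,
#'   `ol_removed`, `minor_arc_overlap`, `nd1_removed`, `nd4_removed`,
#'   `any_cox_removed`.
#' @export
annotate_deletion <- function(bp5, bp3, map = default_genome_map()) {
  validate_genome_map(map)
  bp5 <- as.integer(bp5)
  bp3 <- as.integer(bp3)
  if (length(bp5) != 1L || length(bp3) != 1L) {
    stop("annotate_deletion annotates one deletion at a time")
  }
  if (bp5 < 1L || bp3 > map$genome_length) stop("breakpoints out of range")
  if (bp5 >= bp3) stop("bp5 must be < bp3 (wrapping deletions not supported)")

  f <- map$features
  fully <- character(0)
  partially <- character(0)
  for (i in seq_len(nrow(f))) {
    rb <- .feature_removed_bases(f$start[i], f$end[i], bp5, bp3,
                                 map$genome_length)
    if (rb[["removed"]] == 0L) next
    if (rb[["removed"]] == rb[["total"]]) {
      fully <- c(fully, f$name[i])
    } else {
      partially <- c(partially, f$name[i])
    }
  }

  # Minor arc: between the control-region 3' end and the O_L start.
  cr <- f[f$name == "control_region", ]
  ol <- f[f$name == "O_L", ]
  minor_lo <- cr$end + 1L
  minor_hi <- ol$start - 1L
  minor_overlap <- (bp3 - 1L >= minor_lo) && (bp5 + 1L <= minor_hi)

  removed_any <- union(fully, partially)
  structure(list(
    size_bp = if (bp3 - bp5 >= 2L) bp3 - bp5 - 1L else 0L,
    removed_interval = c(bp5 = bp5, bp3 = bp3),
    genes_fully_removed = fully,
    genes_partially_removed = partially,
    ol_removed = "O_L" %in% fully,
    minor_arc_overlap = minor_overlap,
    nd1_removed = "MT-ND1" %in% removed_any,
    nd4_removed = "MT-ND4" %in% removed_any,
    any_cox_removed = any(c("MT-CO1", "MT-CO2", "MT-CO3") %in% removed_any)
  ), class = "deletion_annotation")
}

#' @export
print.deletion_annotation <- function(x, ...) {
  cat(sprintf("deletion (%d, %d): %d bp removed\n",
              x$removed_interval[["bp5"]], x$removed_interval[["bp3"]],
              x$size_bp))
  cat("  fully removed:    ",
      if (length(x$genes_fully_removed)) paste(x$genes_fully_removed, collapse = ", ") else "-", "\n")
  cat("  partially removed:",
      if (length(x$genes_partially_removed)) paste(x$genes_partially_removed, collapse = ", ") else "-", "\n")
  cat(sprintf("  O_L removed: %s; minor-arc overlap: %s\n",
              x$ol_removed, x$minor_arc_overlap))
  invisible(x)
}

#' Triplex deletion class expected from breakpoint annotation
#'
#' Classifies a deletion by whether it removes (fully or partially) the
#' MT-ND1 and/or MT-ND4 qPCR targets; this is the class the triplex assay is
#' expected to report for the same molecule. Partial removal counts as
#' removed because the assay's probe sites lie inside the genes and probe
#' coordinates are not modelled.
#'
#' @param annotation A `deletion_annotation` from [annotate_deletion()].
#' @return One of `"none"`, `"ND4_deleted"`, `"ND1_deleted"`, `"both"`.
#' @export
expected_triplex_class <- function(annotation) {
  stopifnot(inherits(annotation, "deletion_annotation"))
  if (annotation$nd1_removed && annotation$nd4_removed) return("both")
  if (annotation$nd4_removed) return("ND4_deleted")
  if (annotation$nd1_removed) return("ND1_deleted")
  "none"
}

#' Annotate a table of deletions
#'
#' Applies [annotate_deletion()] and [expected_triplex_class()] to every row
#' of a deletion table.
#'
#' @param deletions Data frame with `cell_id`, `product_id`, `bp5`, `bp3`.
#' @param map A `genome_map`.
#' @return The input with added columns `size_bp`, `ol_removed`,
#'   `minor_arc_overlap`, `nd1_removed`, `nd4_removed`, `any_cox_removed`,
#'   `expected_class`.
#' @export
annotate_deletion_table <- function(deletions, map = default_genome_map()) {
  deletions <- validate_deletions(deletions, map$genome_length)
  ann <- lapply(seq_len(nrow(deletions)), function(i) {
    annotate_deletion(deletions$bp5[i], deletions$bp3[i], map)
  })
  deletions$size_bp <- vapply(ann, `[[`, integer(1), "size_bp")
  deletions$ol_removed <- vapply(ann, `[[`, logical(1), "ol_removed")
  deletions$minor_arc_overlap <- vapply(ann, `[[`, logical(1), "minor_arc_overlap")
  deletions$nd1_removed <- vapply(ann, `[[`, logical(1), "nd1_removed")
  deletions$nd4_removed <- vapply(ann, `[[`, logical(1), "nd4_removed")
  deletions$any_cox_removed <- vapply(ann, `[[`, logical(1), "any_cox_removed")
  deletions$expected_class <- vapply(ann, expected_triplex_class, character(1))
  deletions
}
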