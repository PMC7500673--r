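#' Parse OTU lineages into a trimmed taxonomic structure
#'
#' Takes one lineage string per OTU (ranks separated by `delim`, optionally
#' carrying Greengenes-style prefixes such as `k__`, `p__`) and trims the rank
#' range so that level 1 is the deepest rank at which all OTUs still share a
#' taxon and level `I` is the shallowest rank at which every OTU is a distinct
#' taxon. Taxon labels are parent-qualified internally, so identical rank
#' names under different parents (e.g. two "Incertae Sedis" families) remain
#' distinct taxa.
#'
#' @param lineages character vector of delimiter-separated lineage strings,
#'   one per OTU. All lineages must have the same rank depth; an empty rank
#'   terminates its lineage.
#' @param otu_ids OTU identifiers; defaults to `names(lineages)` or
#'   `OTU1..OTUN`.
#' @param delim rank delimiter, default `";"`.
#' @param rank_names optional names for the input ranks (recycled into the
#'   retained level names); defaults to `rank1..rankD`.
#' @return An object of class `taxonomic_structure` with fields `otu_ids`,
#'   `levels` (retained level names, level 1 first), and `assignment`, an
#'   N x I character matrix of parent-qualified taxon labels.
#' @examples
#' lin <- c("c1;o1;f1;g1", "c1;o1;f1;g2", "c1;o1;f2;g3",
#'          "c1;o2;f3;g4", "c1;o2;f3;g5", "c1;o2;f3;g6")
#' ts <- parse_lineages(lin)
#' ts$levels
#' @export
parse_lineages <- function(lineages, otu_ids = NULL, delim = ";",
                           rank_names = NULL) {
  if (is.null(otu_ids)) otu_ids <- names(lineages)
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_along(lineages))
  if (anyDuplicated(otu_ids)) stop("duplicate OTU ids")
  n <- length(lineages)
  if (n < 2L) stop("need at least two OTUs")
  parts <- strsplit(as.character(lineages), delim, fixed = TRUE)
  parts <- lapply(parts, function(p) {
    p <- sub("^\\s*[a-zA-Z]__", "", trimws(p))
    # an empty rank terminates the lineage
    empty <- which(p == "")
    if (length(empty)) p <- p[seq_len(min(empty) - 1L)]
    p
  })
  depths <- lengths(parts)
  if (length(unique(depths)) != 1L)
    stop("unequal lineage depths after trimming empty ranks: ",
         paste(sort(unique(depths)), collapse = ", "))
  d <- depths[[1L]]
  if (d < 1L) stop("empty lineages")
  raw <- do.call(rbind, parts)
  # parent-qualified labels: cumulative paths down the ranks
  qual <- raw
  for (i in seq_len(d)[-1L]) qual[, i] <- paste(qual[, i - 1L], raw[, i], sep = "|")
  if (is.null(rank_names)) rank_names <- paste0("rank", seq_len(d))
  n_taxa <- apply(qual, 2L, function(col) length(unique(col)))
  # level 1: deepest rank at which all OTUs coincide
  shared <- which(n_taxa == 1L)
  # level I: shallowest rank at which all OTUs are distinct
  distinct <- which(n_taxa == n)
  if (!length(distinct))
    stop("OTUs are not all distinct at the deepest rank; lineages must ",
         "separate every OTU")
  if (!length(shared))
    stop("no rank at which all OTUs share a taxon; the structure needs a ",
         "common root (e.g. analyse one order or class at a time)")
  lo <- max(shared)
  hi <- min(distinct)
  keep <- lo:hi
  assignment <- qual[, keep, drop = FALSE]
  dimnames(assignment) <- list(otu_ids, rank_names[keep])
  ts <- structure(list(otu_ids = otu_ids,
                       levels = rank_names[keep],
                       assignment = assignment),
                  class = "taxonomic_structure")
  validate_taxonomic_structure(ts)
  ts
}

validate_taxonomic_structure <- function(ts) {
  a <- ts$assignment
  n <- nrow(a); i_max <- ncol(a)
  if (length(unique(a[, i_max])) != n)
    stop("not all OTUs distinct at the deepest retained level")
  if (i_max >= 2L) {
    for (i in seq_len(i_max - 1L)) {
      parent_of <- tapply(a[, i], a[, i + 1L], function(x) length(unique(x)))
      if (any(parent_of != 1L))
        stop("non-nested assignment: a taxon at level ", i + 1L,
             " appears under more than one parent")
    }
  }
  invisible(ts)
}

#' @export
print.taxonomic_structure <- function(x, ...) {
  cat("Taxonomic structure:", length(x$otu_ids), "OTUs,",
      length(x$levels), "levels (", paste(x$levels, collapse = " > "), ")\n")
  invisible(x)
}

#' Numeric representation of a taxonomic structure
#'
#' Computes, for each retained level `i`, the number of taxa `M_i` and the
#' vector `n_i` of OTU counts per taxon. Counts are accumulated bottom-up: at
#' the deepest level every taxon holds a single OTU, and each higher taxon's
#' count is the sum over its children. OTUs are re-sorted to be
#' taxonomy-contiguous (grouped by level-1 taxon, then level 2, ...); the
#' permutation back to the input order is recorded in `perm`.
#'
#' @param ts a `taxonomic_structure` from [parse_lineages()].
#' @return An object of class `numeric_representation` with fields `M`
#'   (per-level taxon counts), `n` (list of per-level count vectors),
#'   `otu_ids` (taxonomy-contiguous order), `taxa` (list of per-level taxon
#'   labels in listed order), `children` (per level, index of each taxon's
#'   parent at the level above) and `perm` such that
#'   `otu_ids == ts$otu_ids[perm]`.
#' @export
numeric_representation <- function(ts) {
  stopifnot(inherits(ts, "taxonomic_structure"))
  a <- ts$assignment
  i_max <- ncol(a)
  # taxonomy-contiguous ordering: group by level-1 taxon, then level 2, ...,
  # keeping taxa in first-appearance (input) order at every level
  codes <- lapply(seq_len(i_max), function(i) match(a[, i], unique(a[, i])))
  perm <- do.call(order, codes)
  a <- a[perm, , drop = FALSE]
  taxa <- lapply(seq_len(i_max), function(i) unique(a[, i]))
  M <- lengths(taxa)
  n <- vector("list", i_max)
  n[[i_max]] <- rep(1L, M[i_max])
  if (i_max >= 2L) {
    for (i in (i_max - 1L):1L) {
      # children counts at level i+1 grouped by their parent at level i
      parent <- a[match(taxa[[i + 1L]], a[, i + 1L]), i]
      n[[i]] <- as.integer(tapply(n[[i + 1L]], factor(parent, levels = taxa[[i]]),
                                  sum))
    }
  }
  structure(list(M = as.integer(M), n = n,
                 otu_ids = rownames(a), taxa = taxa,
                 levels = ts$levels, perm = perm),
            class = "numeric_representation")
}

#' @export
print.numeric_representation <- function(x, ...) {
  for (i in seq_along(x$n))
    cat(sprintf("n_%d = (%s)\n", i, paste(x$n[[i]], collapse = ", ")))
  invisible(x)
}

#' Build the taxonomic structure matrix
#'
#' Constructs the symbolic N x N matrix that assigns one correlation class to
#' every OTU pair, from a numeric representation `(n_1, ..., n_I)`. For each
#' level `i < I` a block-diagonal matrix is formed whose blocks (one per taxon,
#' sized by that taxon's OTU count) carry the interim value
#' `sum(M_0..M_{i-1}) + m_i`; levels are overlaid from level 1 down so the
#' deepest (first-common-taxon) value wins; finally the distinct interim values
#' are re-ranked ascending and relabeled with uppercase Roman numerals
#' (smallest value -> class `I`). Two pairs share a class exactly when their
#' first common taxon is the same; single-OTU taxa contribute no off-diagonal
#' entries and their interim values are silently skipped.
#'
#' @param nr a `numeric_representation` (or a `taxonomic_structure`, which is
#'   converted first).
#' @return A `structure_matrix` (see [structure_matrix()]) of kind
#'   `"taxonomic"` whose row/column names are the taxonomy-contiguous OTU ids.
#' @examples
#' lin <- c("c1;o1;f1;g1", "c1;o1;f1;g2", "c1;o1;f2;g3",
#'          "c1;o2;f3;g4", "c1;o2;f3;g5", "c1;o2;f3;g6")
#' build_structure_matrix(numeric_representation(parse_lineages(lin)))
#' @export
build_structure_matrix <- function(nr) {
  if (inherits(nr, "taxonomic_structure")) nr <- numeric_representation(nr)
  stopifnot(inherits(nr, "numeric_representation"))
  N <- sum(nr$n[[1L]])
  if (N < 2L) stop("need at least two OTUs")
  i_max <- length(nr$n)
  interim <- matrix(0L, N, N)
  offset <- 0L
  for (i in seq_len(i_max - 1L)) {
    counts <- nr$n[[i]]
    start <- cumsum(c(0L, counts[-length(counts)]))
    for (m in seq_along(counts)) {
      idx <- start[m] + seq_len(counts[m])
      val <- offset + m
      blk <- matrix(val, counts[m], counts[m])
      diag(blk) <- 0L
      # overlaying level i replaces the block diagonal of the interim matrix
      interim[idx, idx] <- blk
    }
    offset <- offset + nr$M[i]
  }
  off_vals <- sort(unique(interim[upper.tri(interim)]))
  labels <- matrix("D", N, N)
  if (length(off_vals)) {
    alphabet <- toupper(as.character(utils::as.roman(seq_along(off_vals))))
    cls <- alphabet[match(interim, off_vals)]
    labels[] <- ifelse(row(interim) == col(interim), "D", cls)
  } else {
    alphabet <- character()
  }
  dimnames(labels) <- list(nr$otu_ids, nr$otu_ids)
  structure_matrix(labels, alphabet = alphabet, kind = "taxonomic")
}
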