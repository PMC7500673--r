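#' Symbolic correlation-structure matrices
#'
#' A `structure_matrix` is a square symmetric grid of correlation-class
#' labels: the diagonal is always `"D"`, off-diagonal entries come from an
#' ordered alphabet of class labels. Taxonomic structures use uppercase Roman
#' numerals (`I`, `II`, ...); repeated-measure structures use lowercase
#' (`i`, `ii`, ...). Entries sharing a label are estimated by one correlation
#' coefficient.
#'
#' @param labels square character matrix, symmetric with `"D"` diagonal.
#' @param alphabet ordered character vector of the off-diagonal class labels;
#'   defaults to the distinct off-diagonal labels in Roman-numeral order.
#' @param kind `"taxonomic"` or `"repeat"`.
#' @return An object of class `structure_matrix` with fields `labels`,
#'   `alphabet`, `kind` and `dim`.
#' @export
structure_matrix <- function(labels, alphabet = NULL,
                             kind = c("taxonomic", "repeat")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(labels), nrow(labels) == ncol(labels),
            is.character(labels))
  if (any(diag(labels) != "D")) stop("diagonal entries must be 'D'")
  if (!isTRUE(all(labels == t(labels)))) stop("labels must be symmetric")
  off <- unique(labels[row(labels) != col(labels)])
  if (is.null(alphabet)) alphabet <- off[order(match_roman(off))]
  if (!all(off %in% alphabet))
    stop("off-diagonal labels outside the declared alphabet: ",
         paste(setdiff(off, alphabet), collapse = ", "))
  structure(list(labels = labels, alphabet = alphabet, kind = kind,
                 dim = nrow(labels)),
            class = "structure_matrix")
}

# rank of (upper or lower case) Roman numeral labels
match_roman <- function(x) {
  suppressWarnings(as.integer(utils::as.roman(toupper(x))))
}

roman_labels <- function(k, lower = FALSE) {
  if (k == 0L) return(character())
  out <- toupper(as.character(utils::as.roman(seq_len(k))))
  if (lower) tolower(out) else out
}

#' @export
print.structure_matrix <- function(x, ...) {
  cat(sprintf("%s structure matrix (%d x %d), classes: %s\n",
              x$kind, x$dim, x$dim,
              if (length(x$alphabet)) paste(x$alphabet, collapse = ", ")
              else "none"))
  print(x$labels, quote = FALSE)
  invisible(x)
}

#' @export
as.matrix.structure_matrix <- function(x, ...) x$labels

#' @export
dim.structure_matrix <- function(x) c(x$dim, x$dim)
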