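#' Within-OTU repeated-measure structures
#'
#' Builders for the symbolic correlation structure of repeated measures of a
#' single OTU: longitudinal time points (`time_structure`), repeated samples
#' such as twins within a pedigree (`sample_structure`), and their combination
#' into one grid over all (time, sample) cells (`combine_structures`). Classes
#' are lowercase Roman numerals.
#'
#' @param l number of time points.
#' @param kind correlation pattern over time: `"exchangeable"` (one class for
#'   all pairs), `"toeplitz"` (one class per absolute lag) or
#'   `"unstructured"` (one class per unordered pair).
#' @return A `structure_matrix` of kind `"repeat"`.
#' @examples
#' time_structure(3, "toeplitz")
#' combine_structures(time_structure(2), sample_structure(2))
#' @export
time_structure <- function(l, kind = c("exchangeable", "toeplitz",
                                       "unstructured")) {
  kind <- match.arg(kind)
  stopifnot(l >= 1)
  l <- as.integer(l)
  idx <- switch(kind,
    exchangeable = matrix(1L, l, l),
    toeplitz = abs(row(diag(l)) - col(diag(l))),
    unstructured = {
      m <- matrix(0L, l, l)
      k <- 0L
      for (a in seq_len(l)) for (b in seq_len(l)) if (a < b) {
        k <- k + 1L; m[a, b] <- m[b, a] <- k
      }
      m
    })
  n_cls <- if (l >= 2L) max(idx) else 0L
  alphabet <- roman_labels(n_cls, lower = TRUE)
  labels <- matrix("D", l, l)
  off <- row(idx) != col(idx)
  labels[off] <- alphabet[idx[off]]
  dimnames(labels) <- list(paste0("T", seq_len(l)), paste0("T", seq_len(l)))
  structure_matrix(labels, alphabet = alphabet, kind = "repeat")
}

#' @rdname time_structure
#' @param s number of repeated samples (e.g. 2 for a twin pair); the sample
#'   structure is always exchangeable.
#' @export
sample_structure <- function(s) {
  stopifnot(s >= 1)
  s <- as.integer(s)
  labels <- matrix(if (s >= 2L) "i" else "D", s, s)
  diag(labels) <- "D"
  dimnames(labels) <- list(paste0("S", seq_len(s)), paste0("S", seq_len(s)))
  structure_matrix(labels, alphabet = if (s >= 2L) "i" else character(),
                   kind = "repeat")
}

#' @rdname time_structure
#' @param omega_t time structure (`structure_matrix`).
#' @param omega_s sample structure (`structure_matrix`).
#' @details `combine_structures` lays the `L = l*s` cells out sample-major
#'   (samples outer, time points inner): cell order `(T1,S1), (T2,S1), ...,
#'   (T1,S2), ...`. The class of a pair of cells is determined by the pair
#'   (time class or `D`, sample class or `D`); each distinct combination gets
#'   one fresh lowercase class, numbered by first appearance in row-major
#'   order. Degenerate inputs (`l = 1` or `s = 1`) reduce to the other
#'   structure.
#' @export
combine_structures <- function(omega_t, omega_s) {
  stopifnot(inherits(omega_t, "structure_matrix"),
            inherits(omega_s, "structure_matrix"))
  l <- omega_t$dim; s <- omega_s$dim
  L <- l * s
  tl <- omega_t$labels; sl <- omega_s$labels
  cells_t <- rep(seq_len(l), times = s)
  cells_s <- rep(seq_len(s), each = l)
  key <- matrix("", L, L)
  for (a in seq_len(L)) for (b in seq_len(L))
    key[a, b] <- paste(tl[cells_t[a], cells_t[b]],
                       sl[cells_s[a], cells_s[b]], sep = "/")
  labels <- matrix("D", L, L)
  # distinct non-diagonal combinations in row-major first-appearance order
  seen <- character()
  for (a in seq_len(L)) for (b in seq_len(L)) {
    if (a == b) next
    k <- key[a, b]
    if (!k %in% seen) seen <- c(seen, k)
  }
  alphabet <- roman_labels(length(seen), lower = TRUE)
  for (a in seq_len(L)) for (b in seq_len(L)) if (a != b)
    labels[a, b] <- alphabet[match(key[a, b], seen)]
  nm <- sprintf("(T%d,S%d)", cells_t, cells_s)
  dimnames(labels) <- list(nm, nm)
  structure_matrix(labels, alphabet = alphabet, kind = "repeat")
}
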