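#' Integrate taxonomic and repeated-measure structures
#'
#' Builds the J x J symbolic working-correlation structure `R` (J = N OTUs
#' times L repeat cells) whose entry for cells `(a,u)`, `(b,v)` is the label
#' pair (taxonomic class of OTUs `a,b` or `D` when `a == b`, repeat class of
#' cells `u,v` or `D` when `u == v`). Cells are ordered OTU-major: all repeat
#' cells of OTU 1, then OTU 2, and so on.
#'
#' @param gamma taxonomic `structure_matrix` (N x N, uppercase classes).
#' @param omega repeat `structure_matrix` (L x L, lowercase classes); pass
#'   `NULL` (or a 1 x 1 structure) when there is a single observation per OTU.
#' @return An object of class `integrative_structure` with fields `n_otu`,
#'   `L`, `dim` (= J), `labels` (J x J character matrix of `"tax,rep"` label
#'   pairs, `"D,D"` on the diagonal) and `classes` (the distinct off-diagonal
#'   label pairs, first-appearance row-major order).
#' @examples
#' g <- structure_matrix(matrix(c("D", "I", "I", "D"), 2), kind = "taxonomic")
#' build_integrative_structure(g, time_structure(2))
#' @export
build_integrative_structure <- function(gamma, omega = NULL) {
  stopifnot(inherits(gamma, "structure_matrix"))
  if (is.null(omega))
    omega <- structure_matrix(matrix("D", 1, 1), kind = "repeat")
  stopifnot(inherits(omega, "structure_matrix"))
  N <- gamma$dim; L <- omega$dim; J <- N * L
  otu_of <- rep(seq_len(N), each = L)
  cell_of <- rep(seq_len(L), times = N)
  tax <- gamma$labels[cbind(rep(otu_of, times = J), rep(otu_of, each = J))]
  rpt <- omega$labels[cbind(rep(cell_of, times = J), rep(cell_of, each = J))]
  labels <- matrix(paste(tax, rpt, sep = ","), J, J)
  otu_nm <- rownames(gamma$labels)
  if (is.null(otu_nm)) otu_nm <- paste0("OTU", seq_len(N))
  cell_nm <- rownames(omega$labels)
  if (is.null(cell_nm)) cell_nm <- paste0("L", seq_len(L))
  nm <- paste(otu_nm[otu_of], cell_nm[cell_of], sep = ":")
  dimnames(labels) <- list(nm, nm)
  new_integrative_structure(labels, N, L)
}

new_integrative_structure <- function(labels, n_otu, L) {
  J <- nrow(labels)
  # distinct off-diagonal label pairs in row-major first-appearance order
  classes <- unique(as.vector(t(labels))[as.vector(t(row(labels) != col(labels)))])
  structure(list(n_otu = n_otu, L = L, dim = J,
                 labels = labels, classes = classes),
            class = "integrative_structure")
}

#' @export
print.integrative_structure <- function(x, ...) {
  cat(sprintf("Integrative correlation structure: J = %d (N = %d OTUs x L = %d cells)\n",
              x$dim, x$n_otu, x$L))
  cat("Classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Realize a symbolic structure as a numeric correlation matrix
#'
#' Substitutes a coefficient for every class label of an integrative
#' structure. Classes absent from `rho` default to 0. If the realized matrix
#' is not positive definite it is repaired by clipping eigenvalues at a small
#' floor and renormalizing to unit diagonal; the repair is flagged in the
#' `"repaired"` attribute.
#'
#' @param R an `integrative_structure`.
#' @param rho named numeric vector of coefficients, names matching the
#'   structure's class labels (e.g. `c("D,i" = 0.3, "I,D" = 0.3)`); all
#'   magnitudes must be `< 1`.
#' @param repair repair an indefinite matrix (default `TRUE`).
#' @return Numeric J x J correlation matrix with attribute `repaired`.
#' @export
realize_correlation <- function(R, rho = numeric(), repair = TRUE) {
  stopifnot(inherits(R, "integrative_structure"))
  if (length(rho) && any(abs(rho) >= 1))
    stop("correlation coefficients must have magnitude < 1")
  vals <- stats::setNames(rep(0, length(R$classes)), R$classes)
  known <- intersect(names(rho), R$classes)
  vals[known] <- rho[known]
  m <- matrix(0, R$dim, R$dim, dimnames = dimnames(R$labels))
  idx <- match(R$labels, R$classes)
  m[] <- ifelse(is.na(idx), 1, vals[idx])  # NA = diagonal "D,D"
  repaired <- FALSE
  if (repair) {
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-6) {
      m <- pd_repair(m)
      repaired <- TRUE
    }
  }
  attr(m, "repaired") <- repaired
  m
}

# eigenvalue clipping followed by renormalization to unit diagonal
pd_repair <- function(m, floor = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

#' Subset an integrative structure to observed cells
#'
#' Removes the rows and columns of the structure corresponding to missing
#' OTU x repeat cells of a cluster, preserving class labels — this is the
#' per-cluster working structure used when cluster sizes are unequal.
#'
#' @param R an `integrative_structure`.
#' @param observed logical mask of length J (`TRUE` = observed) or integer
#'   indices of observed cells.
#' @return An `integrative_structure` over the observed cells only; `classes`
#'   keeps the parent ordering (restricted to classes still present).
#' @export
subset_structure <- function(R, observed) {
  stopifnot(inherits(R, "integrative_structure"))
  if (is.logical(observed)) {
    stopifnot(length(observed) == R$dim)
    idx <- which(observed)
  } else idx <- as.integer(observed)
  if (!length(idx)) stop("at least one cell must be observed")
  labels <- R$labels[idx, idx, drop = FALSE]
  present <- unique(labels[row(labels) != col(labels)])
  structure(list(n_otu = R$n_otu, L = R$L, dim = length(idx),
                 labels = labels,
                 classes = R$classes[R$classes %in% present]),
            class = "integrative_structure")
}
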