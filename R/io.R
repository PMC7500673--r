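#' Read an OTU abundance table
#'
#' Reads a TSV abundance table (first column = row identifiers). Count tables
#' (all integers, some row total above 1) are auto-detected and converted to
#' relative abundances by the per-sample totals, with a notice.
#'
#' @param path TSV file path.
#' @param orientation `"samples_rows"` (default) or `"otus_rows"`.
#' @param convert convert counts to relative abundances (default `TRUE`).
#' @return Numeric samples x OTUs matrix of relative abundances.
#' @export
read_otu_table <- function(path, orientation = c("samples_rows", "otus_rows"),
                           convert = TRUE) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df) || ncol(df) < 2L) stop("empty or malformed OTU table: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate ids in OTU table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in OTU table")
  rownames(m) <- ids
  if (orientation == "otus_rows") m <- t(m)
  if (any(m < 0)) stop("negative abundances")
  if (convert) {
    tot <- rowSums(m)
    is_counts <- all(m == round(m)) && any(tot > 1 + 1e-8)
    if (is_counts) {
      message("count table detected; converting to relative abundances")
      keep <- tot > 0
      m[keep, ] <- m[keep, , drop = FALSE] / tot[keep]
    }
  }
  m
}

#' Read an OTU taxonomy table
#'
#' Accepts either a two-column TSV `otu_id`, `lineage` (semicolon-delimited
#' lineage strings, optional rank prefixes) or a wide TSV `otu_id`,
#' `<rank1>`, `<rank2>`, ... One row per OTU.
#'
#' @param path TSV file path.
#' @return A `taxonomic_structure` (see [parse_lineages()]).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df) || ncol(df) < 2L) stop("empty or malformed taxonomy: ", path)
  ids <- as.character(df[[1L]])
  if (ncol(df) == 2L && any(grepl(";", df[[2L]], fixed = TRUE))) {
    parse_lineages(df[[2L]], otu_ids = ids)
  } else if (ncol(df) == 2L) {
    parse_lineages(df[[2L]], otu_ids = ids)
  } else {
    lin <- apply(df[, -1L, drop = FALSE], 1L, paste, collapse = ";")
    parse_lineages(lin, otu_ids = ids, rank_names = colnames(df)[-1L])
  }
}

#' Read long-format sample metadata
#'
#' TSV with one row per sequenced sample; must contain a sample-id column
#' plus the columns naming the cluster (subject/pedigree), the
#' within-cluster repeated sample and the time point.
#'
#' @param path TSV file path.
#' @return A data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty metadata: ", path)
  df
}

#' Assemble a cluster x cell dataset from table, metadata and taxonomy
#'
#' Maps every (sample, OTU) abundance onto the J-cell grid (J = N OTUs x L
#' repeat cells, OTU-major; within an OTU, repeated samples outer and time
#' points inner) and builds the matching symbolic structures. Clusters with
#' missing individuals or visits yield partial grids (`NA` cells). Assembly
#' is independent of input row order.
#'
#' @param otu samples x OTUs abundance matrix (e.g. from [read_otu_table()]).
#' @param meta metadata data.frame with one row per sample.
#' @param taxonomy a `taxonomic_structure` covering every OTU in `otu`.
#' @param sample_id_col,cluster_col,sample_col,time_col metadata column names.
#' @param predictor_cols metadata columns to expand into K x J covariate
#'   grids (constant across the cells of one sample).
#' @param time_structure_kind correlation pattern over time points.
#' @return List: `y` (K x J grid), `x` (named list of covariate grids),
#'   `gamma`, `omega`, `structure`, `clusters` (cluster ids in row order),
#'   `otu_ids` (taxonomy-contiguous order), `cells` (cell labels).
#' @export
assemble_dataset <- function(otu, meta, taxonomy,
                             sample_id_col = "sample_id",
                             cluster_col = "cluster",
                             sample_col = "sample",
                             time_col = "time",
                             predictor_cols = character(),
                             time_structure_kind = "exchangeable") {
  stopifnot(inherits(taxonomy, "taxonomic_structure"))
  need <- c(sample_id_col, cluster_col, sample_col, time_col, predictor_cols)
  miss <- setdiff(need, colnames(meta))
  if (length(miss)) stop("metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  absent <- setdiff(colnames(otu), taxonomy$otu_ids)
  if (length(absent)) stop("OTUs absent from taxonomy: ",
                           paste(absent, collapse = ", "))
  unres <- setdiff(rownames(otu), as.character(meta[[sample_id_col]]))
  if (length(unres)) stop("samples not resolvable in metadata: ",
                          paste(unres, collapse = ", "))
  nr <- numeric_representation(taxonomy)
  gamma <- build_structure_matrix(nr)
  otu_ids <- nr$otu_ids
  otu <- otu[, otu_ids, drop = FALSE]
  times <- sort(unique(meta[[time_col]]))
  samples <- sort(unique(meta[[sample_col]]))
  l <- length(times); s <- length(samples)
  omega <- if (l > 1L && s > 1L)
    combine_structures(time_structure(l, time_structure_kind),
                       sample_structure(s))
  else if (s > 1L) sample_structure(s)
  else time_structure(l, time_structure_kind)
  structure_ <- build_integrative_structure(gamma, omega)
  L <- omega$dim
  clusters <- sort(unique(meta[[cluster_col]]))
  K <- length(clusters)
  N <- length(otu_ids)
  J <- N * L
  y <- matrix(NA_real_, K, J,
              dimnames = list(as.character(clusters),
                              rownames(structure_$labels)))
  x <- stats::setNames(
    lapply(predictor_cols, function(.) matrix(NA_real_, K, J)),
    predictor_cols)
  # encode character/factor covariates once over the whole column (first
  # level = 0); numeric covariates pass through
  cov_values <- stats::setNames(lapply(predictor_cols, function(pc) {
    v <- meta[[pc]]
    if (is.character(v) || is.factor(v)) as.numeric(factor(v)) - 1
    else as.numeric(v)
  }), predictor_cols)
  mrows <- match(rownames(otu), as.character(meta[[sample_id_col]]))
  for (si in seq_len(nrow(otu))) {
    mr <- mrows[si]
    k <- match(meta[[cluster_col]][mr], clusters)
    s_i <- match(meta[[sample_col]][mr], samples)
    t_i <- match(meta[[time_col]][mr], times)
    cell <- (s_i - 1L) * l + t_i  # samples outer, time points inner
    cols <- (seq_len(N) - 1L) * L + cell
    dup <- !is.na(y[k, cols[1L]])
    if (dup) stop("duplicate observation for cluster ", clusters[k],
                  ", sample ", samples[s_i], ", time ", times[t_i])
    y[k, cols] <- as.numeric(otu[si, ])
    for (pc in predictor_cols)
      x[[pc]][k, cols] <- cov_values[[pc]][mr]
  }
  list(y = y, x = x, gamma = gamma, omega = omega, structure = structure_,
       clusters = clusters, otu_ids = otu_ids,
       cells = colnames(y))
}

#' Write / read a symbolic structure matrix as TSV
#'
#' The TSV holds the class-label grid with row and column names; reading it
#' back reproduces the structure.
#'
#' @param x a `structure_matrix` or `integrative_structure`.
#' @param path output TSV path.
#' @export
write_structure_tsv <- function(x, path) {
  labels <- if (inherits(x, "integrative_structure")) x$labels else x$labels
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_structure_tsv
#' @param kind structure kind for the reconstructed object.
#' @export
read_structure_tsv <- function(path, kind = c("taxonomic", "repeat")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  structure_matrix(as.matrix(df), kind = kind)
}

#' Describe a structure as JSON
#'
#' JSON description of a symbolic structure: dimension, alphabet and the
#' class of every (row, column) pair.
#'
#' @param x a `structure_matrix` or `integrative_structure`.
#' @param path optional file to write to; if `NULL` the JSON string is
#'   returned.
#' @export
structure_json <- function(x, path = NULL) {
  labels <- x$labels
  alphabet <- if (inherits(x, "integrative_structure")) x$classes else x$alphabet
  ut <- which(upper.tri(labels), arr.ind = TRUE)
  desc <- list(dim = nrow(labels),
               alphabet = as.list(alphabet),
               pairs = lapply(seq_len(nrow(ut)), function(i) {
                 list(a = rownames(labels)[ut[i, 1L]],
                      b = colnames(labels)[ut[i, 2L]],
                      class = labels[ut[i, 1L], ut[i, 2L]])
               }))
  if (is.null(path))
    jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA)
  else {
    jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

# serialize an mtlc_fit to a report list mirroring the per-part tables
mtlc_report <- function(fit) {
  part <- function(g, w) {
    if (is.null(g)) return(NULL)
    list(coefficients = as.list(g$beta),
         robust_se = as.list(stats::setNames(sqrt(diag(g$vbeta)),
                                             names(g$beta))),
         phi = g$phi,
         rho = as.list(g$rho),
         converged = g$converged,
         n_iter = g$n_iter,
         wald = if (!is.null(w)) list(statistic = w$statistic, df = w$df,
                                      p_value = w$p_value))
  }
  list(prevalence = part(fit$fit0, fit$wald0),
       positive = part(fit$fitp, fit$waldp),
       combined = fit$combined,
       degenerate = as.list(fit$degenerate),
       transform = fit$transform)
}
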