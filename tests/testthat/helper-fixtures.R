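# Shared fixtures: the two worked taxonomies, a random nested-tree
# generator and brute-force oracles used by the property tests.

# six hypothetical OTUs: one class, two orders, three families, six genera
fig1_lineages <- c("c1;o1;f1;g1", "c1;o1;f1;g2", "c1;o1;f2;g3",
                   "c1;o2;f3;g4", "c1;o2;f3;g5", "c1;o2;f3;g6")

fig1_gamma <- matrix(c(
  "D",   "III", "II",  "I",  "I",  "I",
  "III", "D",   "II",  "I",  "I",  "I",
  "II",  "II",  "D",   "I",  "I",  "I",
  "I",   "I",   "I",   "D",  "IV", "IV",
  "I",   "I",   "I",   "IV", "D",  "IV",
  "I",   "I",   "I",   "IV", "IV", "D"), 6, 6, byrow = TRUE,
  dimnames = list(paste0("OTU", 1:6), paste0("OTU", 1:6)))

# nine genus-level OTUs in one order: families of 4, 1 and 4 genera
fig3_lineages <- c(paste0("Clostridiales;Lachnospiraceae;g", 1:4),
                   "Clostridiales;Incertae Sedis XIII;g5",
                   paste0("Clostridiales;Ruminococcaceae;g", 6:9))

fig3_gamma <- local({
  m <- matrix("I", 9, 9)
  m[1:4, 1:4] <- "II"
  m[6:9, 6:9] <- "III"
  diag(m) <- "D"
  dimnames(m) <- list(paste0("OTU", 1:9), paste0("OTU", 1:9))
  m
})

two_otu_gamma <- function() {
  structure_matrix(matrix(c("D", "I", "I", "D"), 2, 2,
                          dimnames = list(c("OTU1", "OTU2"),
                                          c("OTU1", "OTU2"))),
                   kind = "taxonomic")
}

# random nested lineages: a root rank, random splits below, distinct leaves
rand_nested_lineages <- function(n, depth) {
  labs <- matrix("", n, depth)
  labs[, 1] <- "root"
  if (depth >= 2) for (i in 2:depth) {
    for (g in unique(labs[, i - 1])) {
      rows <- which(labs[, i - 1] == g)
      k <- sample.int(min(3L, length(rows)), 1L)
      labs[rows, i] <- paste0(g, ".", sample.int(k, length(rows),
                                                 replace = TRUE))
    }
  }
  labs[, depth] <- paste0(labs[, depth], ".leaf", seq_len(n))
  apply(labs, 1, paste, collapse = ";")
}

# oracle: for every OTU pair, the identity of its first common taxon
# (deepest level at which the two assignments coincide)
oracle_first_common <- function(assignment) {
  n <- nrow(assignment)
  out <- matrix(NA_character_, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    eq <- which(assignment[a, ] == assignment[b, ])
    lev <- max(eq)
    out[a, b] <- out[b, a] <- paste0("L", lev, ":", assignment[a, lev])
  }
  out
}

# do two symmetric label matrices induce the same partition of OTU pairs?
same_pair_partition <- function(m1, m2) {
  ut <- upper.tri(m1)
  map <- tapply(m2[ut], m1[ut], function(v) length(unique(v)))
  rev_map <- tapply(m1[ut], m2[ut], function(v) length(unique(v)))
  all(map == 1L) && all(rev_map == 1L)
}

# quick dataset for small GEE fits
small_gaussian_data <- function(K = 60, J = 4, beta = c(1, 0.5), seed = 99) {
  set.seed(seed)
  x <- matrix(rbinom(K * J, 1, 0.5), K, J)
  y <- matrix(rnorm(K * J, beta[1] + beta[2] * x), K, J)
  list(y = y, x = x)
}

default_structure <- function() {
  build_integrative_structure(two_otu_gamma(), time_structure(2))
}

zero_pins <- function(st) stats::setNames(rep(0, length(st$classes)),
                                          st$classes)
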