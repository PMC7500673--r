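test_that("the six-OTU worked example parses, trims and counts correctly", {
  ts <- parse_lineages(fig1_lineages)
  expect_length(ts$levels, 4L)       # class, order, family, genus retained
  expect_equal(unname(lengths(lapply(seq_len(4), function(i)
    unique(ts$assignment[, i])))), c(1L, 2L, 3L, 6L))
  nr <- numeric_representation(ts)
  expect_equal(nr$M, c(1L, 2L, 3L, 6L))
  expect_equal(nr$n[[1L]], 6L)
  expect_equal(nr$n[[2L]], c(3L, 3L))
  expect_equal(nr$n[[3L]], c(2L, 1L, 3L))
  expect_equal(nr$n[[4L]], rep(1L, 6L))
})

test_that("lineage parsing trims shallow and deep uninformative ranks", {
  # ranks above the first split and below the last merge are dropped
  lin <- c("k1;p1;c1;o1;f1;g1", "k1;p1;c1;o1;f1;g2")
  ts <- parse_lineages(lin)
  expect_length(ts$levels, 2L)  # family (shared) and genus (distinct)
  nr <- numeric_representation(ts)
  expect_equal(nr$n, list(2L, c(1L, 1L)))

  # Greengenes prefixes are stripped, empty ranks terminate a lineage
  gg <- c("k__Bacteria;p__Firmicutes;g__A;", "k__Bacteria;p__Firmicutes;g__B;")
  ts2 <- parse_lineages(gg)
  expect_equal(unname(ts2$assignment[, ncol(ts2$assignment)]),
               c("Bacteria|Firmicutes|A", "Bacteria|Firmicutes|B"))
})

test_that("parse_lineages rejects malformed input", {
  expect_error(parse_lineages(c("a;b", "a;b;c")), "depth")
  expect_error(parse_lineages(c("a;b", "a;c"), otu_ids = c("x", "x")),
               "duplicate")
  expect_error(parse_lineages("a;b"), "at least two")
  expect_error(parse_lineages(c("a;x1", "b;x2")), "common root")
})

test_that("level trimming matches a brute-force rank scan on random trees", {
  set.seed(401)
  for (case in 1:20) {
    n <- sample(3:12, 1L)
    depth <- sample(3:5, 1L)
    lin <- rand_nested_lineages(n, depth)
    raw <- do.call(rbind, strsplit(lin, ";", fixed = TRUE))
    n_taxa <- apply(raw, 2, function(col) length(unique(col)))
    lo <- max(which(n_taxa == 1L))
    hi <- min(which(n_taxa == n))
    ts <- parse_lineages(lin)
    expect_length(ts$levels, hi - lo + 1L)
    expect_equal(length(unique(ts$assignment[, 1L])), 1L)
    expect_equal(length(unique(ts$assignment[, ncol(ts$assignment)])), n)
  }
})

test_that("the worked structure matrices are reproduced exactly", {
  g1 <- build_structure_matrix(numeric_representation(parse_lineages(fig1_lineages)))
  expect_identical(g1$labels, fig1_gamma)
  expect_identical(g1$alphabet, c("I", "II", "III", "IV"))

  nr3 <- numeric_representation(parse_lineages(fig3_lineages))
  expect_equal(nr3$n[[1L]], 9L)
  expect_equal(nr3$n[[2L]], c(4L, 1L, 4L))
  g3 <- build_structure_matrix(nr3)
  expect_identical(g3$labels, fig3_gamma)
  expect_identical(g3$alphabet, c("I", "II", "III"))
})

test_that("a two-OTU tree yields the single-class structure", {
  g <- build_structure_matrix(parse_lineages(c("f;a", "f;b")))
  expect_identical(unname(g$labels),
                   matrix(c("D", "I", "I", "D"), 2, 2))
})

test_that("structure classes equal first-common-taxon groups on random trees", {
  set.seed(402)
  for (case in 1:20) {
    n <- sample(4:20, 1L)
    lin <- rand_nested_lineages(n, sample(3:5, 1L))
    ts <- parse_lineages(lin)
    nr <- numeric_representation(ts)
    g <- build_structure_matrix(nr)
    # oracle on the same (taxonomy-contiguous) OTU order
    assignment <- ts$assignment[nr$perm, , drop = FALSE]
    fc <- oracle_first_common(assignment)
    expect_true(same_pair_partition(g$labels, fc))
    # class count = number of distinct first common taxa over all pairs
    expect_length(g$alphabet, length(unique(fc[upper.tri(fc)])))
  }
})

test_that("structure matrix is invariant to taxon relabeling", {
  set.seed(403)
  lin <- rand_nested_lineages(8, 4)
  g_ref <- build_structure_matrix(parse_lineages(lin))
  # consistently rename every taxon label at every rank
  raw <- do.call(rbind, strsplit(lin, ";", fixed = TRUE))
  for (j in seq_len(ncol(raw))) {
    u <- unique(raw[, j])
    raw[, j] <- paste0("tax", j, "_", match(raw[, j], u))
  }
  lin2 <- apply(raw, 1, paste, collapse = ";")
  g_new <- build_structure_matrix(parse_lineages(lin2))
  expect_identical(unname(g_ref$labels), unname(g_new$labels))
})
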