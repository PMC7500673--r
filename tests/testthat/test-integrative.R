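test_that("the 2-OTU x 2-time integrative structure matches the printed layout", {
  st <- default_structure()
  expected <- matrix(c("D,D", "D,i", "I,D", "I,i",
                       "D,i", "D,D", "I,i", "I,D",
                       "I,D", "I,i", "D,D", "D,i",
                       "I,i", "I,D", "D,i", "D,D"), 4, 4, byrow = TRUE)
  expect_identical(unname(st$labels), expected)
  expect_identical(st$classes, c("D,i", "I,D", "I,i"))
})

test_that("the twin-study structure has J = 36 and four block types", {
  g3 <- build_structure_matrix(parse_lineages(fig3_lineages))
  om <- combine_structures(time_structure(2), sample_structure(2))
  st <- build_integrative_structure(g3, om)
  expect_equal(st$dim, 36L)
  # diagonal block: repeat classes paired with D
  blk <- st$labels[1:4, 1:4]
  expect_identical(unname(blk[1, ]), c("D,D", "D,i", "D,ii", "D,iii"))
  # off-diagonal block within the first family pairs with class II
  blk12 <- st$labels[1:4, 5:8]
  expect_identical(unname(blk12[1, ]), c("II,D", "II,i", "II,ii", "II,iii"))
  # across families: class I
  expect_identical(st$labels[1, 17], "I,D")
  tax_parts <- unique(vapply(strsplit(st$classes, ","), `[[`, "", 1L))
  expect_setequal(tax_parts, c("D", "I", "II", "III"))
})

test_that("a single repeat cell reduces the structure to the taxonomy", {
  g <- build_structure_matrix(parse_lineages(fig1_lineages))
  st <- build_integrative_structure(g, NULL)
  expect_equal(st$dim, 6L)
  expect_identical(unname(st$labels[2, 3]), "II,D")
  expect_true(all(grepl(",D$", st$classes)))
})

test_that("realize_correlation substitutes coefficients and defaults to zero", {
  st <- default_structure()
  m <- realize_correlation(st, c("D,i" = 0.3, "I,D" = 0.3))
  expected <- matrix(c(1, .3, .3, 0,
                       .3, 1, 0, .3,
                       .3, 0, 1, .3,
                       0, .3, .3, 1), 4, 4, byrow = TRUE)
  expect_equal(unname(m), expected, tolerance = 1e-12, ignore_attr = TRUE)
  expect_false(attr(m, "repaired"))
  expect_equal(unname(realize_correlation(st, c())), diag(4), ignore_attr = TRUE)
  expect_error(realize_correlation(st, c("D,i" = 1)), "magnitude")
})

test_that("realized entries equal a per-entry table lookup", {
  g3 <- build_structure_matrix(parse_lineages(fig3_lineages))
  st <- build_integrative_structure(g3, time_structure(2))
  set.seed(7)
  rho <- stats::setNames(runif(length(st$classes), -0.05, 0.08), st$classes)
  m <- realize_correlation(st, rho)
  lookup <- matrix(0, st$dim, st$dim)
  for (a in seq_len(st$dim)) for (b in seq_len(st$dim))
    lookup[a, b] <- if (a == b) 1 else rho[[st$labels[a, b]]]
  if (attr(m, "repaired")) skip("random rho produced an indefinite matrix")
  expect_equal(unname(m), lookup, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("indefinite realizations are repaired to valid correlations", {
  st <- default_structure()
  m <- realize_correlation(st, c("D,i" = 0.9, "I,D" = 0.9, "I,i" = -0.9))
  expect_true(attr(m, "repaired"))
  expect_equal(unname(diag(m)), rep(1, 4))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
})

test_that("subsetting preserves labels and commutes with realization", {
  st <- default_structure()
  full <- subset_structure(st, rep(TRUE, 4))
  expect_identical(full$labels, st$labels)
  # dropping OTU2's two cells leaves only the within-OTU time class
  sub <- subset_structure(st, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(unname(sub$labels),
                   matrix(c("D,D", "D,i", "D,i", "D,D"), 2, 2))
  expect_identical(sub$classes, "D,i")
  expect_error(subset_structure(st, rep(FALSE, 4)), "at least one")

  g3 <- build_structure_matrix(parse_lineages(fig3_lineages))
  big <- build_integrative_structure(
    g3, combine_structures(time_structure(2), sample_structure(2)))
  set.seed(8)
  rho <- stats::setNames(runif(length(big$classes), -0.03, 0.06), big$classes)
  for (case in 1:10) {
    mask <- runif(big$dim) < 0.7
    if (!any(mask)) mask[1] <- TRUE
    m1 <- realize_correlation(subset_structure(big, mask), rho,
                              repair = FALSE)
    m2 <- realize_correlation(big, rho, repair = FALSE)[mask, mask]
    expect_equal(unname(m1), unname(m2), tolerance = 1e-12, ignore_attr = TRUE)
  }
})
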