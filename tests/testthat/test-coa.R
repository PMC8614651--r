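test_that("a diagonal 2x2 table decomposes as computed by hand", {
  res <- correspondence_analysis(matrix(c(2, 0, 0, 2), 2, 2))
  expect_equal(res$total_inertia, 1, tolerance = 1e-12)
  expect_length(res$singular_values, 1)
  expect_equal(res$singular_values[1], 1, tolerance = 1e-12)
  # rows at opposite signs, equal magnitude 1
  f1 <- res$row_coords[, "f1"]
  expect_equal(abs(f1), c(row1 = 1, row2 = 1), tolerance = 1e-12)
  expect_equal(sum(f1), 0, tolerance = 1e-12)
})

test_that("identical rows give zero inertia and zero coordinates", {
  m <- matrix(rep(c(3, 1, 2, 6), each = 4), nrow = 4)
  res <- correspondence_analysis(m)
  expect_equal(res$total_inertia, 0)
  expect_true(all(res$row_coords == 0))
  expect_length(res$inertias, 0)
})

test_that("total inertia equals chi-square over grand total", {
  set.seed(21)
  for (i in 1:30) {
    m <- matrix(stats::rpois(48, 4) + 1, nrow = 6)
    res <- correspondence_analysis(m)
    expect_equal(res$total_inertia, oracle_inertia(m), tolerance = 1e-9)
    expect_equal(sum(res$inertias), 1, tolerance = 1e-9)
    expect_true(all(diff(res$singular_values) <= 1e-12))
    expect_equal(sum(res$singular_values^2), res$total_inertia,
                 tolerance = 1e-12)
  }
})

test_that("singular values agree with an independent CA implementation", {
  set.seed(33)
  m <- matrix(stats::rpois(60, 6) + 1, nrow = 10)
  res <- correspondence_analysis(m, n_axes = 3)
  ref <- MASS::corresp(m, nf = 3)
  expect_equal(res$singular_values[1:3], unname(ref$cor), tolerance = 1e-8)
})

test_that("the CA transition formula links row and column coordinates", {
  set.seed(9)
  m <- matrix(stats::rpois(40, 5) + 1, nrow = 5)
  res <- correspondence_analysis(m, n_axes = 3)
  P <- m / sum(m)
  profiles <- P / rowSums(P)
  for (k in seq_len(ncol(res$row_coords))) {
    reconstructed <- (profiles %*% res$col_coords[, k]) / res$singular_values[k]
    expect_equal(unname(reconstructed[, 1]), unname(res$row_coords[, k]),
                 tolerance = 1e-8)
  }
})

test_that("row permutations permute row coordinates and fix column ones", {
  set.seed(14)
  m <- matrix(stats::rpois(50, 5) + 1, nrow = 5)
  rownames(m) <- paste0("s", 1:5)
  perm <- c(3, 1, 5, 2, 4)
  a <- correspondence_analysis(m)
  b <- correspondence_analysis(m[perm, ])
  # coordinates are sign-indeterminate per axis; align signs before comparing
  align <- function(x, ref) x * rep(sign(colSums(x * ref) + 1e-300), each = nrow(x))
  expect_equal(align(b$row_coords, a$row_coords[perm, ]),
               a$row_coords[perm, ], tolerance = 1e-9)
  expect_equal(align(b$col_coords, a$col_coords), a$col_coords,
               tolerance = 1e-9)
  expect_equal(a$inertias, b$inertias, tolerance = 1e-12)
})

test_that("degenerate tables are handled as documented", {
  m <- matrix(c(1, 2, 0, 0, 3, 1), nrow = 2)
  colnames(m) <- c("a", "b", "c")
  expect_warning(res <- correspondence_analysis(m), "all-zero column")
  expect_equal(nrow(res$col_coords), 2)
  m2 <- rbind(c(0, 0, 0), c(1, 2, 3), c(2, 1, 4))
  expect_error(suppressWarnings(correspondence_analysis(m2)), "all-zero row")
  expect_error(correspondence_analysis(matrix(1, 1, 3)), "2 rows")
  expect_error(correspondence_analysis(matrix(-1, 3, 3)), "non-negative")
})

test_that("group centroids are mass-weighted means of row coordinates", {
  set.seed(62)
  m <- matrix(stats::rpois(60, 5) + 1, nrow = 6)
  res <- correspondence_analysis(m)
  groups <- c("a", "a", "a", "b", "b", "b")
  cent <- project_groups(res, groups)
  w <- res$row_masses[1:3] / sum(res$row_masses[1:3])
  expect_equal(unname(cent["a", ]), unname(colSums(res$row_coords[1:3, ] * w)),
               tolerance = 1e-12)
  # single-row group: centroid equals that row
  cent1 <- project_groups(res, c("x", rep("y", 5)))
  expect_equal(unname(cent1["x", ]), unname(res$row_coords[1, ]))
  expect_error(project_groups(res, c("a", "b")), "one group label per row")
})

test_that("mirror-image groups are symmetric about the origin on f1", {
  m <- rbind(c(5, 1), c(1, 5), c(5, 1), c(1, 5))
  res <- correspondence_analysis(m)
  cent <- project_groups(res, c("g1", "g2", "g1", "g2"))
  expect_equal(cent["g1", "f1"], -cent["g2", "f1"], tolerance = 1e-12)
})
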