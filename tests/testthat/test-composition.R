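test_that("closure rescales proportionally, is idempotent, and rejects degenerate input", {
  x <- c(548, 286, 107)
  closed <- close_composition(x)
  expect_equal(closed, x / 941, tolerance = 1e-9)
  expect_equal(sum(close_composition(x, 1440)), 1440, tolerance = 1e-9)
  expect_equal(close_composition(c(1, 1, 1), 3), c(1, 1, 1))
  expect_equal(close_composition(closed, 1), closed, tolerance = 1e-12)
  expect_error(close_composition(c(0, 0, 0)), "all-zero")
  expect_error(close_composition(5), "two parts")
  expect_error(close_composition(c(1, 2), kappa = -1), "positive")
})

test_that("pivot SBP basis matches the hand-evaluated balance coefficients", {
  b <- default_ilr_basis()
  expect_equal(b$contrast[1, ], c(sit = 0.816497, stand = -0.408248, step = -0.408248),
               tolerance = 1e-6)
  expect_equal(b$contrast[2, ], c(sit = 0, stand = 0.707107, step = -0.707107),
               tolerance = 1e-6)
})

test_that("any valid SBP yields orthonormal zero-sum contrast rows", {
  for (sbp in list(pivot_sbp(), alt_sbp(), pivot_sbp(c("step", "sit", "stand")),
                   pivot_sbp(letters[1:5]))) {
    b <- build_ilr_basis(sbp)
    k <- nrow(b$contrast)
    expect_equal(b$contrast %*% t(b$contrast), diag(k), tolerance = 1e-12)
    expect_equal(rowSums(b$contrast), rep(0, k), tolerance = 1e-12)
  }
})

test_that("malformed partitions are rejected", {
  bad <- pivot_sbp()
  bad[, 1] <- 1                               # no denominator group
  expect_error(build_ilr_basis(bad), "\\+1 and a -1")
  expect_error(build_ilr_basis(matrix(1, 3, 3)), "contrast columns")
  nonorth <- matrix(c(1, -1, -1, 1, -1, 1), nrow = 3)  # overlapping groups
  expect_error(build_ilr_basis(nonorth), "not orthonormal|not a sequential")
})

test_that("ILR coordinates match direct log-contrast evaluation and are closure invariant", {
  z <- ilr_transform(paper_base)
  expect_equal(unname(z), c(0.93232884, 0.69520121), tolerance = 1e-7)
  expect_equal(unname(ilr_transform(c(sit = 5, stand = 5, step = 5))), c(0, 0),
               tolerance = 1e-12)
  expect_equal(ilr_transform(close_composition(paper_base)), z, tolerance = 1e-9)
  expect_error(ilr_transform(c(sit = 10, stand = 0, step = 5)), "positive")
})

test_that("inverse ILR round-trips compositions to closure", {
  expect_equal(unname(inverse_ilr(c(0, 0), kappa = 3)), c(1, 1, 1),
               tolerance = 1e-12)
  back <- inverse_ilr(ilr_transform(paper_base), kappa = sum(paper_base))
  expect_equal(unname(back), unname(paper_base), tolerance = 1e-6)

  comps <- random_compositions(1000)
  z <- ilr_transform(comps)
  rec <- inverse_ilr(z, kappa = 1)
  expect_equal(rec, comps / rowSums(comps), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("coordinates from different SBPs are rotations of each other", {
  comps <- random_compositions(200, seed = 5)
  z1 <- ilr_transform(comps, default_ilr_basis())
  z2 <- ilr_transform(comps, build_ilr_basis(alt_sbp()))
  expect_equal(rowSums(z1^2), rowSums(z2^2), tolerance = 1e-9)
})

test_that("reallocation moves exact minutes, conserves the total, and inverts", {
  moved <- reallocate(paper_base, "sit", "step", 60)
  expect_equal(moved, c(sit = 488, stand = 286, step = 167))
  expect_equal(reallocate(paper_base, "step", "sit", 60),
               c(sit = 608, stand = 286, step = 47))
  expect_identical(sum(moved), sum(paper_base))
  expect_equal(reallocate(moved, "step", "sit", 60), paper_base)
  expect_error(reallocate(paper_base, "step", "sit", 107), "107")
  expect_error(reallocate(paper_base, "sit", "sit", 5), "differ")
  expect_error(reallocate(paper_base, "sleep", "sit", 5), "unknown part")
})

test_that("mean composition: identity, arithmetic, and exp-mean-log geometric", {
  one <- matrix(paper_base, 1, dimnames = list(NULL, names(paper_base)))
  expect_equal(mean_composition(one, "geometric"), paper_base,
               ignore_attr = TRUE)
  rows <- rbind(c(400, 300, 100), c(600, 300, 200))
  colnames(rows) <- c("sit", "stand", "step")
  expect_equal(unname(mean_composition(rows, "arithmetic")), c(500, 300, 150))
  # oracle: per-part exp(mean(log)) closed to the mean total 950
  geo <- exp(colMeans(log(rows)))
  expect_equal(unname(mean_composition(rows, "geometric")),
               unname(geo / sum(geo) * 950), tolerance = 1e-9)
  expect_equal(unname(mean_composition(rows, "geometric")),
               c(499.72448, 306.01749, 144.25803), tolerance = 1e-4)
  expect_error(mean_composition(rows[0, , drop = FALSE]), "no compositions")
})

test_that("multiplicative zero replacement preserves totals and positivity", {
  x <- c(sit = 600, stand = 340, step = 0)
  r <- replace_zeros(x, delta = 1)
  expect_equal(sum(r), sum(x))
  expect_true(all(r > 0))
  expect_equal(r[["step"]], 1)
  expect_identical(replace_zeros(paper_base), paper_base)
})
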