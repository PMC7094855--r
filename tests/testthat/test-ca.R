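test_that("degree transform hits its anchor values and range", {
  expect_equal(degree_transform(1), 45)
  expect_equal(degree_transform(sqrt(3)), 30)
  expect_equal(degree_transform(1 / sqrt(3)), 60)
  fc <- 10^seq(-6, 6, by = 0.5)
  d <- degree_transform(fc)
  expect_true(all(d > 0 & d < 90))
  expect_true(all(diff(d) < 0))            # strictly decreasing in FC
  expect_error(degree_transform(-2), "positive")
  expect_error(degree_transform(0), "positive")
})

test_that("up/down complement identity d(fc) + d(1/fc) = 90 holds", {
  fc <- 10^seq(-8, 8, length.out = 200)
  expect_equal(degree_transform(fc) + degree_transform(1 / fc),
               rep(90, 200), tolerance = 1e-12)
})

test_that("degree matrix carries genes x times labels in (0, 90)", {
  fx <- generate_worked_fixture()
  fc <- compute_fold_change(normalize_signals(fx$signal))
  m <- degree_matrix(fc)
  expect_equal(colnames(m), c("t6", "t12", "t24"))
  expect_equal(rownames(m), fc$gene)
  expect_equal(unname(m["g_gm", ]), rep(45, 3))
  expect_true(all(m > 0 & m < 90))
})

test_that("a 3-column CA has exactly two dimensions carrying all inertia", {
  set.seed(404)
  m <- matrix(runif(500 * 3, 1, 89), ncol = 3,
              dimnames = list(sprintf("g%03d", 1:500), c("t6", "t12", "t24")))
  res <- correspondence_analysis(m)
  expect_length(res$eigenvalues, 2L)
  expect_equal(sum(res$contributions), 1, tolerance = 1e-9)
  # mass-weighted centroid of row coordinates is the origin
  expect_equal(colSums(res$row_coords * res$row_mass),
               c(Factor1 = 0, Factor2 = 0), tolerance = 1e-12)
})

test_that("identical rows collapse to a single point with zero inertia", {
  m <- matrix(rep(c(10, 40, 50), each = 6), nrow = 6)
  res <- correspondence_analysis(m)
  expect_equal(res$total_inertia, 0)
  expect_true(all(res$row_coords == 0))
  # soft version: genes with equal degree triples land on the same point
  m2 <- rbind(c(30, 30, 30), c(55, 55, 55), c(10, 50, 30), c(20, 25, 80))
  res2 <- correspondence_analysis(m2)
  expect_equal(res2$row_coords[1, ], res2$row_coords[2, ],
               tolerance = 1e-10)
})

test_that("row principal distances reproduce chi-square profile distances", {
  set.seed(505)
  for (rep in 1:5) {
    m <- matrix(rexp(10 * 3) + 0.1, ncol = 3)
    res <- correspondence_analysis(m)
    expect_equal(unname(as.matrix(dist(res$row_coords))),
                 chisq_row_distances(m), tolerance = 1e-8)
  }
})

test_that("the correspondence matrix reconstitutes exactly at rank 2", {
  set.seed(606)
  m <- matrix(runif(12 * 3, 5, 85), ncol = 3)
  res <- correspondence_analysis(m)
  P <- m / sum(m)
  r <- res$row_mass; cc <- res$col_mass
  recon <- tcrossprod(r, cc) *
    (1 + (res$row_coords / rep(res$sv, each = nrow(m))) %*%
       t(res$col_coords))
  expect_equal(recon, P, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("principal coordinates agree with MASS::corresp", {
  skip_if_not_installed("MASS")
  set.seed(707)
  m <- matrix(runif(30 * 3, 1, 89), ncol = 3,
              dimnames = list(sprintf("g%02d", 1:30), c("a", "b", "c")))
  res <- correspondence_analysis(m)
  mc <- suppressWarnings(MASS::corresp(m, nf = 2))  # non-integer table ok
  expect_equal(unname(res$sv), unname(mc$cor[1:2]), tolerance = 1e-8)
  for (k in 1:2) {                         # sign per axis is arbitrary
    ours <- res$row_coords[, k]
    theirs <- mc$rscore[, k] * mc$cor[k]
    s <- sign(sum(ours * theirs))
    expect_equal(ours, s * theirs, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(res$col_coords[, k],
                 s * mc$cscore[, k] * mc$cor[k],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("transition formulas hold and detect tampering", {
  set.seed(808)
  m <- matrix(runif(40 * 3, 1, 89), ncol = 3)
  res <- correspondence_analysis(m)
  expect_true(transition_check(res, m))
  flipped <- res
  flipped$row_coords[, 1] <- -flipped$row_coords[, 1]   # rows only
  expect_false(transition_check(flipped, m))
  bumped <- res
  bumped$row_coords[3, 2] <- bumped$row_coords[3, 2] + 1e-3
  expect_false(transition_check(bumped, m))
  expect_error(transition_check(res, m[1:10, ]), "shape mismatch")
})

test_that("row permutation permutes scores; axes fixed by orientation rule", {
  set.seed(909)
  m <- matrix(runif(25 * 3, 1, 89), ncol = 3,
              dimnames = list(sprintf("g%02d", 1:25), c("t6", "t12", "t24")))
  res <- correspondence_analysis(m)
  perm <- sample(nrow(m))
  res_p <- correspondence_analysis(m[perm, ])
  expect_equal(res_p$row_coords, res$row_coords[perm, ], tolerance = 1e-9)
  expect_equal(res_p$col_coords, res$col_coords, tolerance = 1e-9)
  # orientation convention: 24 h non-negative on axis 1, 6 h non-positive
  # on axis 2
  expect_gte(res$col_coords["t24", 1], 0)
  expect_lte(res$col_coords["t6", 2], 0)
})

test_that("non-positive degree entries are rejected", {
  m <- matrix(c(1, 2, 3, 0, 5, 6), ncol = 3)
  expect_error(correspondence_analysis(m), "positive")
  expect_error(correspondence_analysis(matrix(1, 2, 3)), "3 rows")
})
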