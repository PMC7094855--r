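test_that("area labels follow the six strict orderings", {
  # printed FC triples of known query genes and their areas
  expect_equal(assign_area(3163.200, 2260.396, 227.743), "D")  # Cxcl5
  expect_equal(assign_area(570.131, 968.934, 806.127), "B")    # Slpi
  expect_equal(assign_area(1190.241, 1237.906, 224.221), "C")  # Clec4d
  expect_equal(assign_area(1, 2, 3), "A")
  expect_equal(assign_area(8, 2, 4), "E")
  expect_equal(assign_area(4, 2, 8), "F")
  # ties return the tie marker, not an arbitrary label
  expect_true(is.na(assign_area(2, 2, 5)))
  expect_true(is.na(assign_area(3, 3, 3)))
})

test_that("area labels are scale-invariant and match the fixture", {
  fx <- generate_worked_fixture()
  fc <- compute_fold_change(normalize_signals(fx$signal))
  lab <- assign_area(fc$FC_t6, fc$FC_t12, fc$FC_t24)
  truth <- fx$truth$genes[match(fc$gene, fx$truth$genes$gene), ]
  expect_equal(lab[!is.na(truth$area)], truth$area[!is.na(truth$area)])
  set.seed(110)
  fct <- random_fc_table(200)
  l1 <- assign_area(fct$FC_t6, fct$FC_t12, fct$FC_t24)
  l2 <- assign_area(fct$FC_t6 * 7.3, fct$FC_t12 * 7.3, fct$FC_t24 * 7.3)
  expect_equal(l1, l2)
})

test_that("line fitting reproduces the printed boundary-2 equation", {
  # anchor row scores (0.023, 0.005) and (0.101, 0.077)
  l2 <- fit_line(c(0.023, 0.005), c(0.101, 0.077))
  expect_equal(round(l2$slope, 3), 0.923)
  expect_equal(round(l2$intercept, 3), -0.016)  # printed -0.017 at 3 d.p.
  l <- fit_line(c(0, 0), c(1, 1))
  expect_equal(l$slope, 1)
  expect_equal(l$intercept, 0)
  # rounded coordinates of boundary 1 give -4.9167, not the full-precision
  # printed -4.903
  l1 <- fit_line(c(0.050, -0.013), c(0.026, 0.105))
  expect_equal(l1$slope, -4.9167, tolerance = 1e-4)
  expect_equal(l1$intercept, 0.2328, tolerance = 1e-3)
  expect_error(fit_line(c(1, 2), c(1, 5)), "vertical")
  expect_error(fit_line(c(1, 2), c(1, 2)), "distinct")
})

test_that("line intersection and least-squares point P behave", {
  la <- structure(list(slope = 1, intercept = 0), class = "boundary_line")
  lb <- structure(list(slope = -1, intercept = 0), class = "boundary_line")
  expect_equal(intersect_lines(la, lb), c(x = 0, y = 0))
  # the two printed line equations cross near (0.0427, 0.0224)
  l1 <- structure(list(slope = -4.903, intercept = 0.232),
                  class = "boundary_line")
  l2 <- structure(list(slope = 0.923, intercept = -0.017),
                  class = "boundary_line")
  xy <- intersect_lines(l1, l2)
  expect_equal(unname(xy), c(0.0427, 0.0224), tolerance = 5e-3)
  expect_error(intersect_lines(la, la), "parallel")
  # three concurrent lines: least-squares point is the common intersection
  lc <- structure(list(slope = 2, intercept = 0), class = "boundary_line")
  p <- least_squares_point(list(la, lb, lc))
  expect_equal(unname(p), c(0, 0), tolerance = 1e-12)
  p2 <- least_squares_point(list(l1, l2))
  expect_equal(unname(p2), unname(xy), tolerance = 1e-9)
})

test_that("anchor selection prefers on-boundary genes at the extremes", {
  # genes planted exactly on boundary 1 (FC6 = FC12) at two far ends
  fc <- data.frame(
    gene = c("end1", "end2", "off1", "off2", "off3"),
    FC_t6 = c(2, 0.2, 5, 9, 0.5),
    FC_t12 = c(2, 0.2, 1, 2, 4),
    FC_t24 = c(1, 3, 2, 3, 1))
  coords <- rbind(end1 = c(-1, 0), end2 = c(1, 0), off1 = c(0, 0.2),
                  off2 = c(0.1, 0.3), off3 = c(0, -0.1))
  colnames(coords) <- c("Factor1", "Factor2")
  expect_equal(select_boundary_anchor_genes(fc, coords, 1, q = 4),
               c("end1", "end2"))
  # q = 2 forces the two smallest-ratio genes regardless of separation
  expect_equal(select_boundary_anchor_genes(fc, coords, 1, q = 2),
               c("end1", "end2"))
  expect_error(select_boundary_anchor_genes(fc, coords[1, , drop = FALSE],
                                            1, q = 4), "fewer than 2")
  expect_error(select_boundary_anchor_genes(fc, coords, 9), "boundary")
})

test_that("query-gene selection is a rank-k prefix of the full sort", {
  fc <- data.frame(gene = paste0("g", 1:6),
                   FC_t6 = c(10, 7, 5, 2, 1, 0.5),
                   FC_t12 = 1, FC_t24 = 1)
  expect_equal(select_query_genes(fc, "t6", "up", 3), c("g1", "g2", "g3"))
  expect_equal(select_query_genes(fc, "t6", "down", 2), c("g6", "g5"))
  expect_equal(select_query_genes(fc, "t6", "up", 6), paste0("g", 1:6))
  expect_error(select_query_genes(fc, "t6", "up", 9), "exceeds")
  expect_error(select_query_genes(fc, "t48", "up", 2), "unknown time")
  # independent full-sort oracle on random data with id tie-breaks
  set.seed(120)
  fct <- random_fc_table(50)
  ids <- fct$gene[order(-fct$FC_t12, fct$gene)][1:5]
  expect_equal(select_query_genes(fct, "t12", "up", 5), ids)
})

test_that("distance sets rank by Euclidean distance with nesting", {
  coords <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 2),
                  d = c(3, 3), e = c(-1, -1))
  ds <- distance_set(coords, c(0, 0), 3)
  expect_equal(ds$gene, c("a", "b", "e"))
  expect_equal(ds$distance, c(0, 1, sqrt(2)))
  ds_self <- distance_set(coords, coords["d", ], 2)
  expect_equal(ds_self$gene[1], "d")
  expect_equal(ds_self$distance[1], 0)
  expect_error(distance_set(coords, c(0, 0), 10), "exceeds")
  # prefix nesting on a bigger random configuration
  set.seed(130)
  big <- matrix(rnorm(400), ncol = 2,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
  s50 <- distance_set(big, c(0.2, -0.1), 50)$gene
  s100 <- distance_set(big, c(0.2, -0.1), 100)$gene
  expect_true(all(s50 %in% s100))
  expect_equal(s100[1:50], s50)
})

test_that("distance sets are invariant under joint axis sign flips", {
  set.seed(140)
  fct <- random_fc_table(300)
  res <- correspondence_analysis(degree_matrix(fct))
  ds <- distance_set(res$row_coords, res$col_coords["t6", ], 30)
  flip <- res$row_coords %*% diag(c(-1, -1))
  rownames(flip) <- rownames(res$row_coords)
  ds_f <- distance_set(flip, -res$col_coords["t6", ], 30)
  expect_equal(ds$gene, ds_f$gene)
  expect_equal(ds$distance, ds_f$distance, tolerance = 1e-12)
})

test_that("full geometry model is coherent on synthetic data", {
  set.seed(150)
  fct <- random_fc_table(800)
  res <- correspondence_analysis(degree_matrix(fct))
  geom <- build_geometry(fct, res, q = 50)
  expect_length(geom$lines, 3L)
  expect_true(all(vapply(geom$lines, function(l) is.finite(l$slope),
                         logical(1))))
  # areas partition the strictly ordered genes
  expect_true(all(geom$area[!is.na(geom$area)] %in% LETTERS[1:6]))
  # distance-1 matrix: distances non-negative, one column per time point
  expect_equal(dim(geom$dist_to_scores), c(800L, 3L))
  expect_true(all(geom$dist_to_scores >= 0))
  # point P off the origin when column masses differ
  expect_gt(sqrt(sum(geom$point_P^2)), 1e-6)
  # boundaries separate the orderings for the vast majority even when the
  # fold-change distribution is continuous and crowds the boundary loci
  deg <- degree_matrix(fct)
  pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  for (b in 1:3) {
    l <- geom$lines[[b]]
    side <- sign(geom$coords[, 2] - (l$slope * geom$coords[, 1] +
                                       l$intercept))
    truth <- sign(deg[, pairs[[b]][1]] - deg[, pairs[[b]][2]])
    agree <- max(mean((side == truth)[truth != 0]),
                 mean((side == -truth)[truth != 0]))
    expect_gte(agree, 0.95)
  }
})

test_that("planted boundary tracers yield exact boundary recovery", {
  set.seed(160)
  fct <- generate_geometry_study(n_genes = 2000L, n_tracer = 40L)
  deg <- degree_matrix(fct)
  res <- correspondence_analysis(deg)
  geom <- build_geometry(fct, res, q = 40)
  # tracers are exact ties: tie-marked, and the anchor pool is exactly them
  tracer <- attr(fct, "tracer_boundary")
  expect_true(all(is.na(geom$area[!is.na(tracer)])))
  for (b in 1:3)
    expect_true(all(geom$lines[[b]]$anchors %in%
                      fct$gene[!is.na(tracer) & tracer == b]))
  # with anchors on the true locus every strictly ordered gene falls on
  # the correct side of its boundary line
  pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  for (b in 1:3) {
    l <- geom$lines[[b]]
    side <- sign(geom$coords[, 2] - (l$slope * geom$coords[, 1] +
                                       l$intercept))
    truth <- sign(deg[, pairs[[b]][1]] - deg[, pairs[[b]][2]])
    agree <- max(mean((side == truth)[truth != 0]),
                 mean((side == -truth)[truth != 0]))
    expect_gte(agree, 0.99)
  }
  # the boundaries miss the origin: point P sits away from (0, 0)
  expect_gt(sqrt(sum(geom$point_P^2)), 1e-4)
})
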