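# ---- fold-change ordering areas --------------------------------------------

# area labels by strict ordering of (FC6, FC12, FC24)
.area_defs <- c(A = "123", B = "132", C = "231", D = "321",
                E = "312", F = "213")
# code: rank string of (FC6, FC12, FC24); e.g. A: FC6<FC12<FC24 -> ranks 123

#' Assign a fold-change-ordering area label
#'
#' The biplot partitions into six regions corresponding to the six strict
#' orderings of the fold-change triple:
#' A: FC6 < FC12 < FC24, B: FC6 < FC24 < FC12, C: FC24 < FC6 < FC12,
#' D: FC24 < FC12 < FC6, E: FC12 < FC24 < FC6, F: FC12 < FC6 < FC24.
#' Exact ties are a valid outcome and return `NA` (tie marker) rather than
#' an arbitrary label. Labels are invariant under scaling all three FCs by
#' a positive constant.
#'
#' @param fc6,fc12,fc24 positive fold changes (vectorized).
#' @return Character vector of labels `"A"`..`"F"`, `NA` for ties.
#' @export
assign_area <- function(fc6, fc12, fc24) {
  n <- length(fc6)
  stopifnot(length(fc12) == n, length(fc24) == n)
  out <- rep(NA_character_, n)
  tie <- fc6 == fc12 | fc12 == fc24 | fc6 == fc24
  m <- cbind(fc6, fc12, fc24)
  code <- apply(m, 1, function(v) paste(rank(v), collapse = ""))
  lab <- names(.area_defs)[match(code, .area_defs)]
  out[!tie] <- lab[!tie]
  out
}

# ---- boundary lines ---------------------------------------------------------

# boundary id -> the FC pair whose equality it represents (column indices
# into the 3 non-control time points, in temporal order)
.boundary_pairs <- list(`1` = c(1L, 2L), `2` = c(2L, 3L), `3` = c(3L, 1L))

#' Select the two anchor genes of a boundary line
#'
#' Boundary `b` approximates the locus where the two fold changes of its
#' pair are equal (1: FC6 = FC12, 2: FC12 = FC24, 3: FC24 = FC6). From the
#' `q` genes with the smallest `|log(FC_a / FC_b)|` the pair with maximal
#' Euclidean separation in the biplot is taken, emulating picking genes at
#' the two far ends of the boundary.
#'
#' @param fc fold-change table from [compute_fold_change()].
#' @param coords genes x 2 matrix of row principal coordinates (rownames =
#'   gene ids).
#' @param boundary 1, 2 or 3.
#' @param q candidate pool size (default 100).
#' @return Character vector of the two anchor gene ids.
#' @export
select_boundary_anchor_genes <- function(fc, coords, boundary, q = 100L) {
  boundary <- as.character(boundary)
  if (!boundary %in% names(.boundary_pairs))
    stop("boundary must be 1, 2 or 3")
  pair <- .boundary_pairs[[boundary]]
  fc_cols <- grep("^FC_", names(fc), value = TRUE)
  ratio <- abs(log(fc[[fc_cols[pair[1]]]] / fc[[fc_cols[pair[2]]]]))
  ord <- order(ratio, fc$gene)
  cand <- fc$gene[ord][seq_len(min(q, length(ord)))]
  cand <- cand[cand %in% rownames(coords)]
  if (length(cand) < 2) stop("fewer than 2 candidate anchor genes")
  xy <- coords[cand, 1:2, drop = FALSE]
  dd <- as.matrix(stats::dist(xy))
  best <- which(dd == max(dd), arr.ind = TRUE)[1, ]
  sort(cand[best])
}

#' Line through two biplot points
#'
#' @param p1,p2 numeric length-2 points (x, y); distinct x required.
#' @return List of class `boundary_line`: `slope`, `intercept`, and the two
#'   `anchors` (points or gene ids if named).
#' @export
fit_line <- function(p1, p2) {
  if (isTRUE(all.equal(p1, p2))) stop("anchor points must be distinct")
  if (p1[1] == p2[1]) stop("vertical boundary line (equal x) not supported")
  slope <- (p2[2] - p1[2]) / (p2[1] - p1[1])
  structure(list(slope = unname(slope),
                 intercept = unname(p1[2] - slope * p1[1]),
                 anchors = list(p1 = p1, p2 = p2)),
            class = "boundary_line")
}

#' Intersection of two boundary lines
#'
#' @param l1,l2 `boundary_line` objects with different slopes.
#' @return Numeric `c(x, y)`.
#' @export
intersect_lines <- function(l1, l2) {
  if (abs(l1$slope - l2$slope) < 1e-12)
    stop("parallel lines have no unique intersection")
  x <- (l2$intercept - l1$intercept) / (l1$slope - l2$slope)
  c(x = x, y = l1$slope * x + l1$intercept)
}

#' Least-squares common point of several lines (point P)
#'
#' The approximate intersection of the area boundaries: the point minimizing
#' the summed squared perpendicular distances to all lines. For concurrent
#' lines this is their common intersection (zero residual).
#'
#' @param lines list of `boundary_line` objects (>= 2).
#' @return Numeric `c(x, y)`.
#' @export
least_squares_point <- function(lines) {
  if (length(lines) < 2) stop("need at least 2 lines")
  # line y = m x + b  ->  (m x - y + b) / sqrt(m^2 + 1) = signed distance
  A <- t(vapply(lines, function(l) {
    w <- 1 / sqrt(l$slope^2 + 1)
    c(l$slope * w, -w, -l$intercept * w)
  }, numeric(3)))
  sol <- qr.solve(A[, 1:2, drop = FALSE], A[, 3])
  c(x = unname(sol[1]), y = unname(sol[2]))
}

# ---- query genes and distance sets -----------------------------------------

#' Top-k most up- or downregulated genes at a time point
#'
#' @param fc fold-change table.
#' @param time non-control time label, e.g. `"t24"`.
#' @param direction `"up"` (largest FC first) or `"down"` (smallest first).
#' @param k number of query genes (default 5).
#' @return Character vector of gene ids ordered by extremity; FC ties break
#'   by gene id.
#' @export
select_query_genes <- function(fc, time, direction = c("up", "down"), k = 5L) {
  direction <- match.arg(direction)
  col <- paste0("FC_", time)
  if (!col %in% names(fc)) stop("unknown time label: ", time)
  if (k > nrow(fc)) stop("k exceeds the number of genes")
  v <- fc[[col]]
  ord <- if (direction == "up") order(-v, fc$gene) else order(v, fc$gene)
  fc$gene[ord][seq_len(k)]
}

#' Top-k genes nearest an anchor point in the biplot
#'
#' Euclidean distance on the first two principal coordinates; ascending,
#' ties broken by gene id. With the anchor at a gene's own coordinates that
#' gene ranks first at distance 0. Prefixes nest: the top-100 set is
#' contained in the top-300 set, etc.
#'
#' @param coords genes x 2 coordinate matrix (rownames = gene ids).
#' @param anchor numeric length-2 point (a column score or a query gene's
#'   coordinates).
#' @param k set size.
#' @return Data frame `gene`, `distance`, `rank`.
#' @export
distance_set <- function(coords, anchor, k) {
  if (k > nrow(coords)) stop("k exceeds the number of genes")
  d <- sqrt((coords[, 1] - anchor[1])^2 + (coords[, 2] - anchor[2])^2)
  ord <- order(d, rownames(coords))
  idx <- ord[seq_len(k)]
  data.frame(gene = rownames(coords)[idx], distance = d[idx],
             rank = seq_len(k), row.names = NULL, stringsAsFactors = FALSE)
}

# ---- full geometry model ----------------------------------------------------

#' Fit the full biplot geometry
#'
#' Assigns area labels from fold-change orderings, fits the three boundary
#' lines from data-driven anchor genes, estimates point P as their
#' least-squares common point, and computes distances from every gene to
#' each time-series column score (distance 1) and to the top-k query genes
#' at each time point (distance 2).
#'
#' @param fc fold-change table from [compute_fold_change()].
#' @param ca a `ca_result` on the matching gene universe.
#' @param q anchor candidate pool size (default 100).
#' @param n_query query genes per time point and direction (default 5).
#' @return Object of class `geometry_model`: list with `area` (per-gene
#'   label, `NA` marks ties), `lines` (3 `boundary_line`s with `anchors`
#'   as gene ids), `point_P`, `dist_to_scores` (genes x time points),
#'   `query_genes` (data frame: time, direction, rank, gene), `coords`,
#'   `col_coords`.
#' @export
build_geometry <- function(fc, ca, q = 100L, n_query = 5L) {
  stopifnot(inherits(ca, "ca_result"))
  coords <- ca$row_coords[, 1:2, drop = FALSE]
  if (!identical(sort(fc$gene), sort(rownames(coords))))
    stop("fold-change table and CA cover different gene universes")
  fc_cols <- grep("^FC_", names(fc), value = TRUE)
  area <- assign_area(fc[[fc_cols[1]]], fc[[fc_cols[2]]], fc[[fc_cols[3]]])
  names(area) <- fc$gene

  lines <- lapply(1:3, function(b) {
    anc <- select_boundary_anchor_genes(fc, coords, b, q = q)
    l <- fit_line(coords[anc[1], ], coords[anc[2], ])
    l$anchors <- anc
    l$boundary <- b
    l
  })
  P <- least_squares_point(lines)

  dist_to_scores <- vapply(seq_len(nrow(ca$col_coords)), function(j)
    sqrt((coords[, 1] - ca$col_coords[j, 1])^2 +
         (coords[, 2] - ca$col_coords[j, 2])^2),
    numeric(nrow(coords)))
  dist_to_scores <- matrix(dist_to_scores, nrow = nrow(coords),
                           dimnames = list(rownames(coords),
                                           rownames(ca$col_coords)))
  times <- sub("^FC_", "", fc_cols)
  qg <- do.call(rbind, lapply(times, function(t)
    do.call(rbind, lapply(c("up", "down"), function(dr)
      data.frame(time = t, direction = dr,
                 rank = seq_len(n_query),
                 gene = select_query_genes(fc, t, dr, n_query),
                 stringsAsFactors = FALSE)))))
  structure(
    list(area = area, lines = lines, point_P = P,
         dist_to_scores = dist_to_scores, query_genes = qg,
         coords = coords, col_coords = ca$col_coords[, 1:2, drop = FALSE]),
    class = "geometry_model")
}

#' @export
print.geometry_model <- function(x, ...) {
  cat("geometry_model:", length(x$area), "genes\n")
  cat("areas:", paste(names(table(x$area, useNA = "ifany")),
                      table(x$area, useNA = "ifany"),
                      sep = "=", collapse = "  "), "\n")
  for (l in x$lines)
    cat(sprintf("line %d: y = %.4f x %+.4f  (anchors %s, %s)\n",
                l$boundary, l$slope, l$intercept,
                l$anchors[1], l$anchors[2]))
  cat(sprintf("point P: (%.4f, %.4f)\n", x$point_P[1], x$point_P[2]))
  invisible(x)
}
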