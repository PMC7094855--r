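# ---- arctangent-degree transform -------------------------------------------

#' Arctangent-degree transform of a fold change
#'
#' Maps a non-log fold change FC in (0, Inf) to
#' `d(FC) = (180/pi) * atan(1/FC)` in degrees. The transform is strictly
#' decreasing: FC = 1 maps to 45 degrees, FC -> Inf approaches 0 degrees and
#' FC -> 0 approaches 90 degrees, and it satisfies the up/down complement
#' identity `d(FC) + d(1/FC) = 90`. Compared with a log transform it
#' compresses extreme ratios (FC > 10 or < 0.1) into a bounded range.
#'
#' @param fc positive numeric vector of fold changes.
#' @return Degree values in the open interval (0, 90).
#' @export
degree_transform <- function(fc) {
  if (!is.numeric(fc)) stop("'fc' must be numeric")
  if (any(!is.finite(fc)) || any(fc <= 0))
    stop("fold changes must be positive and finite")
  (180 / pi) * atan(1 / fc)
}

#' Build the genes-by-time degree matrix from a fold-change table
#'
#' @param fc fold-change data frame from [compute_fold_change()].
#' @return Numeric matrix, genes x (non-control time points), of degree
#'   values; rownames are gene ids, colnames the time labels.
#' @export
degree_matrix <- function(fc) {
  cols <- grep("^FC_", names(fc), value = TRUE)
  if (length(cols) < 2) stop("fold-change table needs >= 2 FC columns")
  m <- as.matrix(fc[cols])
  m <- apply(m, 2, degree_transform)
  dimnames(m) <- list(fc$gene, sub("^FC_", "", cols))
  m
}

# ---- correspondence analysis ------------------------------------------------

#' Correspondence analysis of a degree matrix
#'
#' Classical (simple) correspondence analysis: with correspondence matrix
#' P = m / grand total, row masses r and column masses c, the standardized
#' residuals S with entries `(P_ij - r_i c_j) / sqrt(r_i c_j)` are
#' decomposed by SVD; principal coordinates are the mass-rescaled singular
#' vectors scaled by the singular values, principal inertias (eigenvalues)
#' the squared singular values. For a 3-column matrix there are exactly 2
#' non-trivial dimensions, so the first two dimensions always carry 100% of
#' the inertia. Rows and columns are both returned in principal coordinates
#' (symmetric map), so row-to-column Euclidean distances are meaningful for
#' the distance-based gene sets.
#'
#' Axis orientation (SVD signs are arbitrary) is fixed so that the last
#' column's (24 h) score is non-negative on axis 1 and the first column's
#' (6 h) score is non-positive on axis 2; flipping an axis flips row and
#' column scores together.
#'
#' @param m numeric matrix with positive entries, genes x time points
#'   (>= 3 rows).
#' @return Object of class `ca_result`: list with `row_coords` and
#'   `col_coords` (principal coordinates, columns `Factor1`, `Factor2`, ...),
#'   `sv` (singular values), `eigenvalues`, `contributions` (proportions of
#'   total inertia), `total_inertia`, `row_mass`, `col_mass`.
#' @export
correspondence_analysis <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("degree matrix entries must be positive and finite")
  if (nrow(m) < 3) stop("need at least 3 rows")
  P <- m / sum(m)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - tcrossprod(r, cc)) / sqrt(tcrossprod(r, cc))
  sv <- svd(S)
  ndim <- min(nrow(m), ncol(m)) - 1L
  d <- sv$d[seq_len(ndim)]
  # principal coordinates
  F_ <- sweep(sv$u[, seq_len(ndim), drop = FALSE], 1, sqrt(r), `/`)
  F_ <- sweep(F_, 2, d, `*`)
  G <- sweep(sv$v[, seq_len(ndim), drop = FALSE], 1, sqrt(cc), `/`)
  G <- sweep(G, 2, d, `*`)
  # fixed orientation: last column non-negative on axis 1,
  # first column non-positive on axis 2
  if (ndim >= 1 && G[nrow(G), 1] < 0) { G[, 1] <- -G[, 1]; F_[, 1] <- -F_[, 1] }
  if (ndim >= 2 && G[1, 2] > 0)       { G[, 2] <- -G[, 2]; F_[, 2] <- -F_[, 2] }
  dimnames(F_) <- list(rownames(m), paste0("Factor", seq_len(ndim)))
  dimnames(G) <- list(colnames(m), paste0("Factor", seq_len(ndim)))
  ev <- d^2
  total <- sum(sv$d^2)
  if (total < 1e-20) {                 # all row profiles identical
    ev[] <- 0; total <- 0; F_[] <- 0; G[] <- 0; d[] <- 0
  }
  contrib <- if (total > 0) ev / total else rep(0, ndim)
  structure(
    list(row_coords = F_, col_coords = G, sv = d,
         eigenvalues = ev, contributions = contrib,
         total_inertia = total, row_mass = r, col_mass = cc),
    class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_coords), "rows x",
      nrow(x$col_coords), "columns\n")
  tab <- data.frame(Factor = seq_along(x$eigenvalues),
                    Eigenvalue = signif(x$eigenvalues, 4),
                    Contribution = signif(x$contributions, 4),
                    Cumulative = signif(cumsum(x$contributions), 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Eigenvalue / contribution summary table
#'
#' @param res a `ca_result`.
#' @return Data frame with `factor`, `eigenvalue`, `contribution`,
#'   `cumulative_contribution`.
#' @export
ca_contribution_table <- function(res) {
  stopifnot(inherits(res, "ca_result"))
  data.frame(factor = seq_along(res$eigenvalues),
             eigenvalue = res$eigenvalues,
             contribution = res$contributions,
             cumulative_contribution = cumsum(res$contributions))
}

#' Verify the CA transition formulas
#'
#' Checks the definitional identities linking row and column principal
#' coordinates: each row coordinate must equal the profile-weighted average
#' of the column coordinates divided by the singular value (and symmetrically
#' for columns). A correctly computed `ca_result` satisfies both to high
#' precision; any independent sign flip or perturbation breaks them.
#'
#' @param res a `ca_result` computed from `m`.
#' @param m the degree matrix it was computed from.
#' @param tol tolerance on the maximum absolute deviation.
#' @return `TRUE` or `FALSE`.
#' @export
transition_check <- function(res, m, tol = 1e-8) {
  stopifnot(inherits(res, "ca_result"))
  m <- as.matrix(m)
  if (!identical(dim(m), c(nrow(res$row_coords), nrow(res$col_coords))))
    stop("shape mismatch between CA result and matrix")
  P <- m / sum(m)
  rprof <- P / rowSums(P)
  cprof <- t(P) / colSums(P)
  keep <- res$sv > 1e-12
  if (!any(keep)) return(TRUE)   # degenerate: all points at the origin
  Fhat <- sweep(rprof %*% res$col_coords[, keep, drop = FALSE],
                2, res$sv[keep], `/`)
  Ghat <- sweep(cprof %*% res$row_coords[, keep, drop = FALSE],
                2, res$sv[keep], `/`)
  max(abs(Fhat - res$row_coords[, keep, drop = FALSE]),
      abs(Ghat - res$col_coords[, keep, drop = FALSE])) < tol
}

#' Biplot of a CA result
#'
#' Simple symmetric-map scatter: genes as points, time-point scores as
#' filled triangles.
#'
#' @param x a `ca_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ca_result <- function(x, ...) {
  rc <- x$row_coords
  cc <- x$col_coords
  graphics::plot(rbind(rc[, 1:2], cc[, 1:2]), type = "n",
                 xlab = "Factor 1", ylab = "Factor 2", ...)
  graphics::points(rc[, 1], rc[, 2], pch = 16, cex = 0.4,
                   col = grDevices::adjustcolor("darkorange", 0.5))
  graphics::points(cc[, 1], cc[, 2], pch = 17, cex = 1.4)
  graphics::text(cc[, 1], cc[, 2], rownames(cc), pos = 3)
  invisible(x)
}
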