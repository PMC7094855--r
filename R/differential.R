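# ---- row-wise one-way ANOVA -------------------------------------------------

#' One-way ANOVA across time points, one gene per row
#'
#' Classical fixed-effects one-way ANOVA of per-array normalized log2 values
#' against the time-point factor, computed row-wise over all genes by the
#' sum-of-squares decomposition (p from [stats::pf()]). A gene with zero
#' between-group and zero within-group variance has an undefined F; it is
#' reported as `NA` (no call) with a warning.
#'
#' @param values numeric matrix, genes x arrays.
#' @param groups factor/character of length `ncol(values)` giving each
#'   array's time point.
#' @return Data frame with `gene`, `F`, `p`.
#' @export
anova_per_gene <- function(values, groups) {
  values <- as.matrix(values)
  groups <- as.factor(groups)
  if (length(groups) != ncol(values))
    stop("'groups' must have one entry per array column")
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 replicates each")
  k <- nlevels(groups)
  N <- ncol(values)
  gm <- matrix(vapply(levels(groups), function(g)
    rowMeans(values[, groups == g, drop = FALSE]),
    numeric(nrow(values))), nrow = nrow(values),
    dimnames = list(rownames(values), levels(groups)))
  n_g <- as.vector(table(groups)[levels(groups)])
  overall <- rowMeans(values)
  ssb <- rowSums(sweep(sweep(gm, 1, overall)^2, 2, n_g, `*`))
  sst <- rowSums(sweep(values, 1, overall)^2)
  ssw <- sst - ssb
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  undef <- ssw <= 0 & ssb <= .Machine$double.eps * pmax(sst, 1)
  if (any(undef)) {
    warning(sum(undef), " gene(s) with zero variance: F undefined, no call")
    Fstat[undef] <- NA_real_
  }
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  # zero within-variance but real between-group differences: F = Inf, p = 0
  p[is.infinite(Fstat)] <- 0
  data.frame(gene = rownames(values), F = Fstat, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- Tukey HSD control contrasts -------------------------------------------

#' Tukey HSD p values for control-versus-time contrasts
#'
#' Computes the full all-pairs Honestly Significant Difference procedure
#' (studentized range statistic against [stats::ptukey()] with the number of
#' groups and the pooled within-group degrees of freedom), then returns the
#' contrasts of each post-injury time point against the control together
#' with the mean log2 differences. Balanced designs only.
#'
#' @inheritParams anova_per_gene
#' @param control label of the control group (default: first level in the
#'   order of `unique(groups)`).
#' @return List with `p` (genes x contrasts matrix of HSD p values),
#'   `diff` (mean difference, time minus control, same shape), and
#'   `contrasts` (the non-control labels).
#' @export
tukey_control_contrasts <- function(values, groups, control = NULL) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (is.null(control)) control <- lev[1]
  if (!control %in% lev) stop("unknown control label: ", control)
  n_g <- table(groups)[lev]
  if (length(unique(n_g)) != 1)
    stop("Tukey HSD here requires a balanced design")
  n <- n_g[[1]]
  if (n < 2 || length(lev) < 2)
    stop("need >= 2 groups with >= 2 replicates each")
  k <- length(lev)
  df <- ncol(values) - k
  gm <- matrix(vapply(lev, function(g)
    rowMeans(values[, groups == g, drop = FALSE]),
    numeric(nrow(values))), nrow = nrow(values),
    dimnames = list(rownames(values), lev))
  ssw <- rowSums(matrix(vapply(lev, function(g) {
    v <- values[, groups == g, drop = FALSE]
    rowSums((v - rowMeans(v))^2)
  }, numeric(nrow(values))), nrow = nrow(values)))
  mse <- ssw / df
  others <- setdiff(lev, control)
  se <- sqrt(mse / n)                      # studentized-range denominator
  dmat <- gm[, others, drop = FALSE] - gm[, control]
  pmat <- matrix(NA_real_, nrow(values), length(others),
                 dimnames = list(rownames(values), others))
  for (j in seq_along(others)) {
    q <- abs(dmat[, j]) / se
    pmat[, j] <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    pmat[se == 0 & dmat[, j] != 0, j] <- 0
    pmat[se == 0 & dmat[, j] == 0, j] <- NA_real_
  }
  list(p = pmat, diff = dmat, contrasts = others)
}

# ---- BH correction ----------------------------------------------------------

#' Benjamini-Hochberg adjustment with input validation
#'
#' Thin wrapper around `stats::p.adjust(..., method = "BH")` that rejects
#' out-of-range p values; `NA`s (no-call genes) are passed through.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @param family optional label used in error messages.
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p, family = "p") {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad))
    stop("out-of-range p values in family '", family, "'")
  stats::p.adjust(p, method = "BH")
}

# ---- significance calls and patterns ---------------------------------------

#' ANOVA + Tukey significance calling for every gene
#'
#' Applies the screening procedure: one-way ANOVA per gene with BH
#' correction across genes; genes passing the screen (`adjusted p < alpha`)
#' get Tukey HSD control contrasts, BH-corrected per contrast across the
#' screened genes; a call of `U`/`D` requires adjusted contrast p below
#' `alpha` with the matching sign of the mean difference. Genes failing the
#' ANOVA screen are `-` at every time point.
#'
#' @param normalized a `normalized_table` from [normalize_signals()] (the
#'   per-array track is used so replicates are preserved), or a plain
#'   genes x arrays matrix of per-array log2 values with `groups` given.
#' @param alpha significance level on BH-adjusted p values.
#' @param groups per-array time labels, required when `normalized` is a
#'   matrix; the first label in order of appearance is the control.
#' @return Object of class `significance_calls`: list with `genes`
#'   (data frame: gene, F, p, p_adj), `tukey_p`, `tukey_p_adj`, `tukey_diff`
#'   (genes x contrasts matrices, `NA` for unscreened genes), `calls`
#'   (genes x contrasts character matrix over U/D/-), `pattern` (per-gene
#'   3-character code) and `alpha`.
#' @export
call_significance <- function(normalized, alpha = 0.05, groups = NULL) {
  if (inherits(normalized, "normalized_table")) {
    vals <- normalized$log2_array
    groups <- normalized$array_time
    tps <- normalized$time_points
  } else {
    vals <- as.matrix(normalized)
    if (is.null(groups)) stop("'groups' is required for matrix input")
    tps <- unique(as.character(groups))
  }
  an <- anova_per_gene(vals, groups)
  an$p_adj <- bh_adjust(an$p, family = "anova")
  screened <- !is.na(an$p_adj) & an$p_adj < alpha

  others <- tps[-1]
  ng <- nrow(vals)
  tk_p <- tk_adj <- tk_d <- matrix(NA_real_, ng, length(others),
                                   dimnames = list(rownames(vals), others))
  if (any(screened)) {
    tk <- tukey_control_contrasts(vals[screened, , drop = FALSE], groups,
                                  control = tps[1])
    tk_p[screened, ] <- tk$p[, others]
    tk_d[screened, ] <- tk$diff[, others]
    for (j in seq_along(others))
      tk_adj[screened, j] <- bh_adjust(tk$p[, others[j]],
                                       family = paste0("tukey_", others[j]))
  }
  calls <- matrix("-", ng, length(others),
                  dimnames = list(rownames(vals), others))
  sig <- !is.na(tk_adj) & tk_adj < alpha
  calls[sig & tk_d > 0] <- "U"
  calls[sig & tk_d < 0] <- "D"
  structure(
    list(genes = an, tukey_p = tk_p, tukey_p_adj = tk_adj,
         tukey_diff = tk_d, calls = calls,
         pattern = apply(calls, 1, paste, collapse = ""),
         alpha = alpha),
    class = "significance_calls")
}

#' Pattern code of one gene
#'
#' @param calls a `significance_calls` object.
#' @param gene gene id.
#' @return The gene's 3-character fluctuation code, e.g. `"U-D"`.
#' @export
classify_pattern <- function(calls, gene) {
  stopifnot(inherits(calls, "significance_calls"))
  if (!gene %in% names(calls$pattern)) stop("unknown gene: ", gene)
  unname(calls$pattern[gene])
}

#' Tabulate the 27 fluctuation patterns
#'
#' @param calls a `significance_calls` object.
#' @return Data frame with `pattern` (all 27 codes) and `n`; counts sum to
#'   the number of QC-retained genes.
#' @export
pattern_counts <- function(calls) {
  stopifnot(inherits(calls, "significance_calls"))
  tab <- table(factor(calls$pattern, levels = pattern_codes()))
  data.frame(pattern = names(tab), n = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- fold-threshold gene sets ----------------------------------------------

#' Gene sets fluctuating more than 3- or 5-fold
#'
#' Members must be Tukey-significant in the given direction at the defining
#' time point and exceed the fold threshold strictly: `FC > threshold` for
#' up, `FC < 1/threshold` for down. By construction the 3-fold set contains
#' the 5-fold set in the same direction.
#'
#' @param calls a `significance_calls` object.
#' @param fc fold-change table from [compute_fold_change()].
#' @param threshold fold threshold, conventionally 3 or 5.
#' @param direction `"up"` or `"down"`.
#' @param time non-control time-point label, e.g. `"t6"`.
#' @return Object of class `threshold_gene_set`: list with `genes`
#'   (character vector), `time`, `direction`, `threshold`.
#' @export
build_threshold_sets <- function(calls, fc, threshold, direction, time) {
  stopifnot(inherits(calls, "significance_calls"))
  direction <- match.arg(direction, c("up", "down"))
  if (!time %in% colnames(calls$calls))
    stop("unknown time label: ", time)
  fc_col <- paste0("FC_", time)
  if (!fc_col %in% names(fc)) stop("fold-change table lacks column ", fc_col)
  if (!identical(sort(fc$gene), sort(rownames(calls$calls))))
    stop("calls and fold-change table cover different gene universes")
  fcv <- stats::setNames(fc[[fc_col]], fc$gene)[rownames(calls$calls)]
  member <- if (direction == "up")
    calls$calls[, time] == "U" & fcv > threshold
  else
    calls$calls[, time] == "D" & fcv < 1 / threshold
  structure(list(genes = rownames(calls$calls)[member],
                 time = time, direction = direction, threshold = threshold),
            class = "threshold_gene_set")
}
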