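# ---- signal container -------------------------------------------------------

#' Construct a signal matrix with per-feature per-array flags
#'
#' Bundles a raw gene-by-array signal matrix with its flag matrix and the
#' array design (time point and replicate per array). Arrays are labelled
#' `"<time>_r<replicate>"`, e.g. `"t6_r2"`.
#'
#' @param signal numeric matrix, genes x arrays; rownames are gene ids.
#' @param flags character matrix of identical shape with entries
#'   `"Dt"` (Detected), `"NDt"` (Not Detected) or `"Cm"` (Compromised).
#' @param time_points character vector of time-point labels in temporal
#'   order; the first label is the uninjured control.
#' @param n_replicates replicates per time point.
#' @return An object of class `signal_matrix`: a list with elements
#'   `signal`, `flags`, `time_points`, `n_replicates`, `array_time`
#'   (time label per column) and `array_replicate`.
#' @export
signal_matrix <- function(signal, flags,
                          time_points = c("control", "t6", "t12", "t24"),
                          n_replicates = 4L) {
  signal <- as.matrix(signal)
  flags <- as.matrix(flags)
  if (!is.numeric(signal)) stop("'signal' must be numeric")
  if (!identical(dim(signal), dim(flags)))
    stop("shape mismatch between signals and flags: ",
         paste(dim(signal), collapse = "x"), " vs ",
         paste(dim(flags), collapse = "x"))
  n_arrays <- length(time_points) * n_replicates
  if (ncol(signal) != n_arrays)
    stop("expected ", n_arrays, " arrays (",
         length(time_points), " time points x ", n_replicates,
         " replicates), got ", ncol(signal))
  bad <- setdiff(unique(as.vector(flags)), c("Dt", "NDt", "Cm"))
  if (length(bad))
    stop("unknown flag tokens: ", paste(bad, collapse = ", "))
  if (is.null(rownames(signal)))
    rownames(signal) <- sprintf("gene_%05d", seq_len(nrow(signal)))
  if (anyDuplicated(rownames(signal)))
    stop("duplicate gene ids in signal matrix")
  colnames(signal) <- as.vector(t(outer(time_points, seq_len(n_replicates),
                                        function(t, r) paste0(t, "_r", r))))
  dimnames(flags) <- dimnames(signal)
  structure(
    list(signal = signal, flags = flags,
         time_points = time_points, n_replicates = as.integer(n_replicates),
         array_time = rep(time_points, each = n_replicates),
         array_replicate = rep(seq_len(n_replicates), length(time_points))),
    class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", nrow(x$signal), "features x", ncol(x$signal),
      "arrays (", length(x$time_points), "time points x",
      x$n_replicates, "replicates )\n")
  tab <- table(factor(x$flags, levels = c("Dt", "NDt", "Cm")))
  cat("flags:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# ---- QC & normalization primitives -----------------------------------------

#' Clip below-background signals
#'
#' Scanner signals below background come out negative after background
#' subtraction; they are set to 1 (interpreted as "not expressed") so that
#' log-ratios stay defined. Non-negative values pass through unchanged.
#'
#' @param raw_signal numeric vector or matrix.
#' @return Same shape, with every value below 0 replaced by 1.
#' @export
clip_negative_signals <- function(raw_signal) {
  if (!is.numeric(raw_signal)) stop("'raw_signal' must be numeric")
  raw_signal[raw_signal < 0] <- 1
  raw_signal
}

#' Geometric mean of replicate signals
#'
#' The representative value of a gene at one time point is the geometric
#' mean of its (clipped, hence strictly positive) replicate signals.
#'
#' @param x positive numeric vector.
#' @return The geometric mean `prod(x)^(1/length(x))`, computed on the log
#'   scale for numerical stability.
#' @export
summarize_replicates <- function(x) {
  if (length(x) == 0) stop("empty replicate vector")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("replicate signals must be positive and finite (clip first)")
  exp(mean(log(x)))
}

#' Centre a log2 column on its 75th percentile
#'
#' Between-array correction: the 75th percentile of one time point's (or one
#' array's) log2 signals is subtracted from every gene, under the assumption
#' that most genes do not fluctuate. Percentile uses linear interpolation
#' between order statistics (`stats::quantile` type 7).
#'
#' @param log2_values numeric vector of log2 signals for one column.
#' @return Shifted vector whose 75th percentile is 0.
#' @export
percentile_shift <- function(log2_values) {
  if (length(log2_values) < 2) stop("need at least 2 genes to normalize")
  log2_values - stats::quantile(log2_values, 0.75, names = FALSE, type = 7)
}

#' Collapse per-array flags to a feature status
#'
#' A feature is `"Dt"` only when all arrays flag it Detected; `"Cm"` takes
#' precedence over `"NDt"` when both occur (a single Compromised call
#' excludes the feature). Features with status `"Dt"` or `"NDt"` are
#' retained for analysis.
#'
#' @param flags character vector with one flag per array.
#' @param n_arrays expected number of arrays (default 16).
#' @return One of `"Dt"`, `"NDt"`, `"Cm"`.
#' @export
call_feature_status <- function(flags, n_arrays = 16L) {
  if (length(flags) != n_arrays)
    stop("expected ", n_arrays, " per-array flags, got ", length(flags))
  if (any(flags == "Cm")) return("Cm")
  if (any(flags == "NDt")) return("NDt")
  "Dt"
}

#' Flag-based quality control of a signal matrix
#'
#' @param sm a [signal_matrix()].
#' @return Data frame with one row per feature: `gene`, `status`
#'   (Dt/NDt/Cm) and logical `retained` (status is Dt or NDt).
#' @export
qc_feature_status <- function(sm) {
  stopifnot(inherits(sm, "signal_matrix"))
  any_cm <- rowSums(sm$flags == "Cm") > 0
  any_ndt <- rowSums(sm$flags == "NDt") > 0
  status <- ifelse(any_cm, "Cm", ifelse(any_ndt, "NDt", "Dt"))
  data.frame(gene = rownames(sm$signal), status = status,
             retained = status != "Cm", row.names = NULL,
             stringsAsFactors = FALSE)
}

# ---- normalization pipeline -------------------------------------------------

#' Normalize a signal matrix (representative and per-array tracks)
#'
#' Runs the four-step normalization on QC-retained features. The
#' representative track clips negative signals to 1, collapses replicates by
#' geometric mean, takes log2, and subtracts each time point's 75th
#' percentile; its non-log values (`2^log2`) feed fold changes and the
#' degree transform. A parallel per-array track (clip, log2, per-array 75th
#' percentile shift) preserves replicates for ANOVA / Tukey testing.
#'
#' @param sm a [signal_matrix()].
#' @param qc optional result of [qc_feature_status()]; computed if missing.
#' @return An object of class `normalized_table`: list with
#'   `log2_rep` (genes x time points, shifted log2 representative values),
#'   `nonlog_rep` (`2^log2_rep`), `log2_array` (genes x arrays, per-array
#'   track), `time_points`, `array_time`, and the `qc` table.
#' @export
normalize_signals <- function(sm, qc = NULL) {
  stopifnot(inherits(sm, "signal_matrix"))
  if (is.null(qc)) qc <- qc_feature_status(sm)
  keep <- qc$retained
  sig <- clip_negative_signals(sm$signal[keep, , drop = FALSE])

  # representative track: geometric mean over replicates, then log2
  tp <- sm$time_points
  log2_rep <- sapply(tp, function(t) {
    cols <- sm$array_time == t
    rowMeans(log2(sig[, cols, drop = FALSE]))
  })
  log2_rep <- apply(log2_rep, 2, percentile_shift)
  dimnames(log2_rep) <- list(rownames(sig), tp)

  # per-array track, replicates preserved
  log2_array <- apply(log2(sig), 2, percentile_shift)
  dimnames(log2_array) <- dimnames(sig)

  structure(
    list(log2_rep = log2_rep, nonlog_rep = 2^log2_rep,
         log2_array = log2_array,
         time_points = tp, array_time = sm$array_time, qc = qc),
    class = "normalized_table")
}

#' Fold changes of each time point versus control
#'
#' Non-log ratio of the normalized representative signal at each post-injury
#' time point to the control's.
#'
#' @param normalized a `normalized_table` from [normalize_signals()].
#' @return Data frame with `gene` and one `FC_<time>` column per non-control
#'   time point (e.g. `FC_t6`, `FC_t12`, `FC_t24`); all values strictly
#'   positive.
#' @export
compute_fold_change <- function(normalized) {
  stopifnot(inherits(normalized, "normalized_table"))
  tp <- normalized$time_points
  ctrl <- normalized$nonlog_rep[, tp[1]]
  if (any(ctrl <= 0)) stop("non-positive control signal; cannot form ratios")
  fc <- normalized$nonlog_rep[, tp[-1], drop = FALSE] / ctrl
  out <- data.frame(gene = rownames(normalized$nonlog_rep), fc,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("FC_", tp[-1])
  out
}
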