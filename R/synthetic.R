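# ---- pattern taxonomy -------------------------------------------------------

#' The 27 fluctuation pattern codes
#'
#' A pattern code is a 3-character string giving the call at 6, 12 and 24 h
#' post-injury, each one of `U` (significantly upregulated), `D`
#' (significantly downregulated) or `-` (not fluctuated), e.g. `"UU-"` or
#' `"---"`.
#'
#' @return Character vector of the 27 codes, `"U"`-first lexicographic order.
#' @export
pattern_codes <- function() {
  g <- expand.grid(t24 = c("U", "D", "-"), t12 = c("U", "D", "-"),
                   t6 = c("U", "D", "-"), stringsAsFactors = FALSE)
  sort(paste0(g$t6, g$t12, g$t24))
}

# ---- study configuration ----------------------------------------------------

#' Configuration of a synthetic incision study
#'
#' Describes a microarray study of the standard design (4 time points x 4
#' replicate animals) with planted expression patterns, replicate noise on
#' the log2 scale, scanner flag rates, and an annotation catalog with
#' planted enrichment. All defaults are documented assumptions, not
#' estimates from any dataset.
#'
#' @param n_genes number of features.
#' @param n_replicates replicates (animals) per time point.
#' @param time_points ordered labels; the first is the uninjured control.
#' @param baseline_log2_mean,baseline_log2_sd lognormal baseline: per-gene
#'   control log2 intensity is drawn N(mean, sd).
#' @param noise_log2_sd replicate noise sd on the log2 scale (>= 0).
#' @param pattern_mix named numeric vector of proportions over the 27
#'   pattern codes (see [pattern_codes()]), summing to 1; unnamed entries
#'   are rejected.
#' @param effect_log2fc magnitude of planted shifts: a `U` at a time point
#'   adds `+effect_log2fc` to the gene's log2 mean there, a `D` subtracts it.
#' @param flag_ndt_rate,flag_cm_rate per-feature per-array probabilities of
#'   a Not Detected / Compromised flag.
#' @param n_terms,term_size annotation catalog size.
#' @param n_enriched_terms number of terms constructed to be enriched for
#'   up-pattern genes.
#' @param enrichment_fraction exact fraction of each enriched term's members
#'   taken from genes whose planted pattern contains a `U`.
#' @param seed integer seed governing all randomness.
#' @return Validated list of class `study_config`.
#' @export
study_config <- function(n_genes = 1000L,
                         n_replicates = 4L,
                         time_points = c("control", "t6", "t12", "t24"),
                         baseline_log2_mean = 8,
                         baseline_log2_sd = 2,
                         noise_log2_sd = 0.25,
                         pattern_mix = default_pattern_mix(),
                         effect_log2fc = 3,
                         flag_ndt_rate = 0.05,
                         flag_cm_rate = 0.01,
                         n_terms = 50L,
                         term_size = 25L,
                         n_enriched_terms = 5L,
                         enrichment_fraction = 0.5,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              time_points = time_points,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              noise_log2_sd = noise_log2_sd,
              pattern_mix = pattern_mix,
              effect_log2fc = effect_log2fc,
              flag_ndt_rate = flag_ndt_rate,
              flag_cm_rate = flag_cm_rate,
              n_terms = as.integer(n_terms),
              term_size = as.integer(term_size),
              n_enriched_terms = as.integer(n_enriched_terms),
              enrichment_fraction = enrichment_fraction,
              seed = as.integer(seed))
  for (f in c("n_genes", "n_replicates", "n_terms", "term_size"))
    if (cfg[[f]] < 1L) stop("'", f, "' must be a positive count")
  for (f in c("baseline_log2_sd", "noise_log2_sd"))
    if (cfg[[f]] < 0) stop("'", f, "' must be >= 0")
  for (f in c("flag_ndt_rate", "flag_cm_rate", "enrichment_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must be in [0, 1]")
  if (cfg$flag_ndt_rate + cfg$flag_cm_rate > 1)
    stop("'flag_ndt_rate' + 'flag_cm_rate' must not exceed 1")
  pm <- cfg$pattern_mix
  if (is.null(names(pm)) || !all(names(pm) %in% pattern_codes()))
    stop("'pattern_mix' must be named by pattern codes (see pattern_codes())")
  if (any(pm < 0)) stop("'pattern_mix' proportions must be non-negative")
  if (abs(sum(pm) - 1) > 1e-9)
    stop("'pattern_mix' proportions must sum to 1 (got ", sum(pm), ")")
  if (length(cfg$time_points) < 2) stop("'time_points' needs control + >= 1")
  class(cfg) <- "study_config"
  cfg
}

#' Default planted pattern mix
#'
#' 70% unchanged genes, with the remainder spread over sustained and
#' single-time-point up/down patterns — a deliberately simple emulation of a
#' time course dominated by non-fluctuating genes.
#'
#' @return Named proportions over a subset of the 27 codes, summing to 1.
#' @export
default_pattern_mix <- function() {
  c("---" = 0.70, "UUU" = 0.05, "DDD" = 0.05,
    "U--" = 0.03, "-U-" = 0.03, "--U" = 0.03,
    "D--" = 0.03, "-D-" = 0.03, "--D" = 0.03,
    "UU-" = 0.01, "DD-" = 0.01)
}

# ---- generator --------------------------------------------------------------

shift_from_code <- function(code, effect) {
  calls <- strsplit(code, "")[[1]]
  ifelse(calls == "U", effect, ifelse(calls == "D", -effect, 0))
}

#' Generate a synthetic study with known ground truth
#'
#' Draws per-gene baselines from the configured lognormal, plants per-time
#' mean shifts according to each gene's sampled pattern code, adds Gaussian
#' replicate noise on the log2 scale, and draws per-feature per-array flags
#' independently at the configured rates. An annotation catalog is emitted
#' alongside, with `n_enriched_terms` terms built by construction to contain
#' exactly `enrichment_fraction` up-pattern genes. Identical config (same
#' seed) gives bitwise-identical output.
#'
#' @param config a [study_config()].
#' @return List with `signal` (a [signal_matrix()]), `catalog` (named list of
#'   member-gene vectors with a `category` attribute, GMT-compatible), and
#'   `truth` (list: `genes` data frame with planted `pattern` and true FC per
#'   time point; `enriched_terms` character vector).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  set.seed(cfg$seed)
  tp <- cfg$time_points
  n_arr <- length(tp) * cfg$n_replicates
  genes <- sprintf("gene_%05d", seq_len(cfg$n_genes))

  pattern <- sample(names(cfg$pattern_mix), cfg$n_genes, replace = TRUE,
                    prob = cfg$pattern_mix)
  # planted per-gene per-(non-control)-time log2 shifts
  shift <- t(vapply(pattern, shift_from_code, numeric(length(tp) - 1),
                    effect = cfg$effect_log2fc))
  dimnames(shift) <- list(genes, tp[-1])

  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean,
                           cfg$baseline_log2_sd)
  mu <- cbind(0, shift) + baseline          # genes x time points, log2 means
  colnames(mu) <- tp
  log2sig <- mu[, rep(seq_along(tp), each = cfg$n_replicates)] +
    stats::rnorm(cfg$n_genes * n_arr, 0, cfg$noise_log2_sd)
  signal <- 2^log2sig
  rownames(signal) <- genes

  u <- stats::runif(cfg$n_genes * n_arr)
  flags <- matrix(ifelse(u < cfg$flag_cm_rate, "Cm",
                         ifelse(u < cfg$flag_cm_rate + cfg$flag_ndt_rate,
                                "NDt", "Dt")),
                  nrow = cfg$n_genes)
  sm <- signal_matrix(signal, flags, tp, cfg$n_replicates)

  catalog <- build_planted_catalog(genes, pattern, cfg)
  truth <- list(
    genes = data.frame(gene = genes, pattern = pattern,
                       2^shift, row.names = NULL,
                       stringsAsFactors = FALSE,
                       check.names = FALSE),
    enriched_terms = names(catalog)[seq_len(cfg$n_enriched_terms)])
  names(truth$genes)[-(1:2)] <- paste0("true_FC_", tp[-1])
  list(signal = sm, catalog = catalog, truth = truth)
}

# enriched terms hold exactly round(enrichment_fraction * term_size)
# up-pattern genes by construction; remaining terms are uniform draws
build_planted_catalog <- function(genes, pattern, cfg) {
  up_genes <- genes[grepl("U", pattern)]
  other <- setdiff(genes, up_genes)
  n_up <- round(cfg$enrichment_fraction * cfg$term_size)
  n_enr <- min(cfg$n_enriched_terms, cfg$n_terms)
  if (n_enr > 0 && (length(up_genes) < n_up ||
                    length(other) < cfg$term_size - n_up))
    stop("not enough genes to build the planted-enrichment catalog")
  catalog <- vector("list", cfg$n_terms)
  names(catalog) <- sprintf("TERM_%04d", seq_len(cfg$n_terms))
  for (i in seq_len(cfg$n_terms)) {
    catalog[[i]] <- if (i <= n_enr)
      sort(c(sample(up_genes, n_up),
             sample(other, cfg$term_size - n_up)))
    else
      sort(sample(genes, min(cfg$term_size, length(genes))))
  }
  attr(catalog, "category") <- stats::setNames(
    rep(c("planted", "background"),
        c(n_enr, cfg$n_terms - n_enr)), names(catalog))
  catalog
}

# ---- geometry recovery study ------------------------------------------------

#' Fold-change table with well-separated orderings and boundary tracers
#'
#' Builds a synthetic fold-change table for studying the biplot geometry:
#' most genes draw independent lognormal fold changes (strict orderings
#' almost surely, spanning all six areas), and `n_tracer` genes per boundary
#' are planted with the boundary's two fold changes exactly equal, spread
#' over the full magnitude range. The tracers mark the ends of each
#' between-area boundary, so the anchor-selection rule recovers the exact
#' boundary line; being exact ties, they take the tie marker and stay out of
#' the area tallies.
#'
#' @param n_genes total genes (tracers included).
#' @param n_tracer planted boundary genes per boundary (3 boundaries).
#' @param sdlog2 sd of the log2 fold changes.
#' @return Fold-change data frame (columns `gene`, `FC_t6`, `FC_t12`,
#'   `FC_t24`) with attribute `tracer_boundary` (NA for bulk genes, else the
#'   boundary id 1-3).
#' @export
generate_geometry_study <- function(n_genes = 10000L, n_tracer = 100L,
                                    sdlog2 = 2) {
  n_genes <- as.integer(n_genes)
  n_tracer <- as.integer(n_tracer)
  bulk <- n_genes - 3L * n_tracer
  if (bulk < 0) stop("n_genes too small for 3 x n_tracer planted genes")
  fc <- data.frame(gene = sprintf("g%05d", seq_len(n_genes)),
                   FC_t6 = 2^stats::rnorm(n_genes, 0, sdlog2),
                   FC_t12 = 2^stats::rnorm(n_genes, 0, sdlog2),
                   FC_t24 = 2^stats::rnorm(n_genes, 0, sdlog2),
                   stringsAsFactors = FALSE)
  pairs <- list(c("FC_t6", "FC_t12"), c("FC_t12", "FC_t24"),
                c("FC_t24", "FC_t6"))
  tracer <- rep(NA_integer_, n_genes)
  for (b in 1:3) {
    idx <- bulk + (b - 1L) * n_tracer + seq_len(n_tracer)
    v <- 2^stats::rnorm(n_tracer, 0, sdlog2)
    fc[idx, pairs[[b]][1]] <- v
    fc[idx, pairs[[b]][2]] <- v
    tracer[idx] <- b
  }
  attr(fc, "tracer_boundary") <- tracer
  fc
}

# ---- worked fixture ---------------------------------------------------------

#' A small deterministic fixture with hand-computable values
#'
#' Sixteen genes, 4 time points x 4 replicates, built without randomness so
#' that every downstream quantity can be verified by hand: eight constant
#' "filler" genes pin the 75th percentile of every column to the same value
#' (so percentile shifts cancel in fold changes); `g_gm` has replicates
#' (2, 8, 2, 8) at every time (geometric mean 4); `g_cm` carries a single
#' Compromised flag and must be excluded by QC; `g_ndt` carries one
#' Not Detected flag and must be retained; genes `gA`..`gF` have fold-change
#' triples realizing each of the six strict orderings A-F.
#'
#' @return Same structure as [generate_study()]; `truth$genes` additionally
#'   has an `area` column with the hand-assigned ordering label.
#' @export
generate_worked_fixture <- function() {
  tp <- c("control", "t6", "t12", "t24")
  # per-gene representative value at (control, t6, t12, t24);
  # all replicates equal except g_gm
  reps <- list(
    filler1 = c(256, 256, 256, 256), filler2 = c(256, 256, 256, 256),
    filler3 = c(256, 256, 256, 256), filler4 = c(256, 256, 256, 256),
    filler5 = c(256, 256, 256, 256), filler6 = c(256, 256, 256, 256),
    g_ndt   = c(256, 256, 256, 256), g_cm    = c(64, 64, 64, 64),
    g_gm    = c(4, 4, 4, 4),
    gA = c(8, 16, 32, 64),   # FC (2, 4, 8):  FC6 < FC12 < FC24
    gB = c(8, 16, 64, 32),   # FC (2, 8, 4):  FC6 < FC24 < FC12
    gC = c(8, 32, 64, 16),   # FC (4, 8, 2):  FC24 < FC6 < FC12
    gD = c(8, 64, 32, 16),   # FC (8, 4, 2):  FC24 < FC12 < FC6
    gE = c(8, 64, 16, 32),   # FC (8, 2, 4):  FC12 < FC24 < FC6
    gF = c(8, 32, 16, 64),   # FC (4, 2, 8):  FC12 < FC6 < FC24
    g_neg = c(16, 16, 16, 16))
  genes <- names(reps)
  signal <- t(vapply(reps, function(v) rep(v, each = 4), numeric(16)))
  signal["g_gm", ] <- rep(c(2, 8, 2, 8), times = 4)
  signal["g_neg", 2] <- -12.4              # below background, clipped to 1
  # keep g_neg's control geometric mean at 16: (16 * 1 * 64 * 64)^(1/4) = 16,
  # so FC stays 1 at every time even with the clipped replicate
  signal["g_neg", 3:4] <- 64
  colnames(signal) <- as.vector(t(outer(tp, 1:4,
                                        function(t, r) paste0(t, "_r", r))))
  flags <- matrix("Dt", nrow = length(genes), ncol = 16,
                  dimnames = dimnames(signal))
  flags["g_cm", "t6_r1"] <- "Cm"
  flags["g_ndt", "t24_r4"] <- "NDt"
  sm <- signal_matrix(signal, flags, tp, 4L)

  fc <- t(vapply(reps, function(v) v[-1] / v[1], numeric(3)))
  fc[c("g_gm", "g_neg"), ] <- 1
  area <- c(rep(NA, 9), "A", "B", "C", "D", "E", "F", NA)
  truth <- list(
    genes = data.frame(gene = genes, pattern = NA_character_,
                       true_FC_t6 = fc[, 1], true_FC_t12 = fc[, 2],
                       true_FC_t24 = fc[, 3], area = area,
                       row.names = NULL, stringsAsFactors = FALSE),
    enriched_terms = character(0))
  catalog <- list(AREA_SET = paste0("g", LETTERS[1:6]),
                  FILLER_SET = paste0("filler", 1:6),
                  MIXED_SET = c("gA", "gB", "filler1", "g_gm"))
  attr(catalog, "category") <- stats::setNames(
    rep("fixture", 3), names(catalog))
  list(signal = sm, catalog = catalog, truth = truth)
}
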