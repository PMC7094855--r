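# ---- TSV readers / writers --------------------------------------------------

#' Read a signal matrix and its flag table
#'
#' Both files are TSV with a `gene` id column followed by one column per
#' array, headers encoding time point and replicate as `"<time>_r<rep>"`
#' (e.g. `"t6_r2"`). The two files must agree in shape, gene order and
#' array labels.
#'
#' @param path signals TSV.
#' @param flags_path flags TSV of identical shape with values Dt/NDt/Cm.
#' @return A [signal_matrix()].
#' @export
read_signals <- function(path, flags_path) {
  sig <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  flg <- utils::read.delim(flags_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(sig)[1] != "gene" || names(flg)[1] != "gene")
    stop("first column of signals/flags TSV must be 'gene'")
  if (!identical(dim(sig), dim(flg)) ||
      !identical(names(sig), names(flg)))
    stop("shape mismatch between signals and flags files")
  if (anyDuplicated(sig$gene)) stop("duplicate gene ids in signals file")
  if (!identical(sig$gene, flg$gene))
    stop("gene order differs between signals and flags files")
  arr <- names(sig)[-1]
  m <- regmatches(arr, regexec("^(.+)_r([0-9]+)$", arr))
  if (any(lengths(m) != 3))
    stop("array headers must look like '<time>_r<replicate>'")
  tp <- unique(vapply(m, `[[`, "", 2))
  n_rep <- length(arr) / length(tp)
  sm <- signal_matrix(
    as.matrix(`rownames<-`(sig[-1], sig$gene)),
    as.matrix(`rownames<-`(flg[-1], flg$gene)),
    time_points = tp, n_replicates = n_rep)
  message(nrow(sm$signal), " features x ", ncol(sm$signal),
          " arrays read from ", path)
  sm
}

#' Write a signal matrix to signals + flags TSVs
#'
#' @param sm a [signal_matrix()].
#' @param path,flags_path output files (round-trips with [read_signals()]).
#' @export
write_signals <- function(sm, path, flags_path) {
  stopifnot(inherits(sm, "signal_matrix"))
  write_tsv(data.frame(gene = rownames(sm$signal), sm$signal,
                       check.names = FALSE), path)
  write_tsv(data.frame(gene = rownames(sm$flags), sm$flags,
                       check.names = FALSE), flags_path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# ---- configuration ----------------------------------------------------------

#' Build / validate a pipeline configuration
#'
#' Either `signals`/`flags` paths (with optional `catalog` GMT) or a
#' `simulate` block (arguments for [study_config()]) must be present.
#'
#' @param signals,flags,catalog input file paths, or `NULL` to simulate.
#' @param simulate named list passed to [study_config()].
#' @param alpha significance level.
#' @param fold_thresholds fold-change thresholds for the threshold sets.
#' @param top_k distance-set sizes.
#' @param q anchor candidate pool size.
#' @param n_query query genes per time point and direction.
#' @param out_dir output directory.
#' @param seed integer seed (overrides the simulate block's).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(signals = NULL, flags = NULL, catalog = NULL,
                            simulate = NULL, alpha = 0.05,
                            fold_thresholds = c(3, 5),
                            top_k = c(100, 300, 500, 1000),
                            q = 100L, n_query = 5L,
                            out_dir = tempfile("woundCA_run_"),
                            seed = 1L) {
  if (is.null(simulate) && (is.null(signals) || is.null(flags)))
    stop("either 'signals'+'flags' paths or a 'simulate' block is required")
  if (!is.null(simulate) && !is.null(signals))
    stop("give input paths or a simulate block, not both")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  if (any(fold_thresholds <= 1)) stop("fold thresholds must exceed 1")
  structure(list(signals = signals, flags = flags, catalog = catalog,
                 simulate = simulate, alpha = alpha,
                 fold_thresholds = fold_thresholds, top_k = top_k,
                 q = as.integer(q), n_query = as.integer(n_query),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()]'s arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

# ---- pipeline ---------------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Preprocessing/QC, differential calling, the degree transform and CA,
#' biplot geometry, and enrichment of the threshold gene sets, writing
#' every stage table plus a JSON run manifest to the output directory.
#' Identical configuration (including seed) gives identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, an object of class `pipeline_result`: list with every
#'   stage's in-memory result (`signal`, `qc`, `normalized`, `fold_change`,
#'   `calls`, `degrees`, `ca`, `geometry`, `sets`, `enrichment`, `truth`)
#'   and `out_dir`, the directory holding the stage TSVs and manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    study <- stage("simulate", generate_study(do.call(study_config, sim_args)))
    sm <- study$signal
    catalog <- study$catalog
    truth <- study$truth
    write_signals(sm, file.path(config$out_dir, "signals.tsv"),
                  file.path(config$out_dir, "flags.tsv"))
    write_gmt(catalog, file.path(config$out_dir, "catalog.gmt"))
    write_tsv(truth$genes, file.path(config$out_dir, "truth.tsv"))
  } else {
    sm <- stage("read", read_signals(config$signals, config$flags))
    catalog <- if (!is.null(config$catalog)) read_gmt(config$catalog)
  }

  qc <- stage("qc", qc_feature_status(sm))
  norm <- stage("normalize", normalize_signals(sm, qc))
  message("QC: ", nrow(sm$signal), " features in, ",
          sum(qc$retained), " retained (",
          sum(qc$status == "Cm"), " Cm excluded)")
  fc <- stage("fold_change", compute_fold_change(norm))
  calls <- stage("differential", call_significance(norm, config$alpha))
  deg <- stage("degrees", degree_matrix(fc))
  ca <- stage("ca", correspondence_analysis(deg))
  geom <- stage("geometry",
                build_geometry(fc, ca, q = config$q,
                               n_query = config$n_query))

  times <- sub("^FC_", "", grep("^FC_", names(fc), value = TRUE))
  sets <- list()
  for (t in times) for (dr in c("up", "down"))
    for (th in config$fold_thresholds) {
      ts <- build_threshold_sets(calls, fc, th, dr, t)
      sets[[paste(t, dr, th, sep = "_")]] <- ts$genes
      message("set ", t, "/", dr, "/>", th, "-fold: ",
              length(ts$genes), " genes")
    }
  # distance-based gene sets: top-k genes nearest each time-series score
  # (distance 1) and each query gene (distance 2)
  ks <- config$top_k[config$top_k <= nrow(geom$coords)]
  anchors <- rbind(
    data.frame(anchor = rownames(geom$col_coords),
               kind = "time_score", geom$col_coords[, 1:2],
               stringsAsFactors = FALSE),
    data.frame(anchor = unique(geom$query_genes$gene),
               kind = "query_gene",
               geom$coords[unique(geom$query_genes$gene), , drop = FALSE],
               stringsAsFactors = FALSE))
  names(anchors)[3:4] <- c("x", "y")
  dist_sets <- do.call(rbind, lapply(seq_len(nrow(anchors)), function(i)
    do.call(rbind, lapply(ks, function(k)
      cbind(anchor = anchors$anchor[i], kind = anchors$kind[i], k = k,
            distance_set(geom$coords, c(anchors$x[i], anchors$y[i]), k))))))

  # one enrichment run per time point so PAGE scores are the log2 FC at
  # each set's defining time point
  enr <- NULL
  if (!is.null(catalog)) {
    per_time <- lapply(times, function(t) {
      st <- sets[grepl(paste0("^", t, "_"), names(sets)) & lengths(sets) > 0]
      if (length(st) == 0) return(NULL)
      scores <- stats::setNames(log2(fc[[paste0("FC_", t)]]), fc$gene)
      e <- stage(paste0("enrichment_", t),
                 enrich_all(st, catalog, universe = fc$gene,
                            alpha = config$alpha, scores = scores))
      if (!is.null(e$page)) e$page <- cbind(time = t, e$page)
      e
    })
    per_time <- per_time[!vapply(per_time, is.null, logical(1))]
    if (length(per_time))
      enr <- list(
        fisher = do.call(rbind, lapply(per_time, `[[`, "fisher")),
        page = do.call(rbind, lapply(per_time, `[[`, "page")),
        summary = do.call(rbind, lapply(per_time, `[[`, "summary")))
  }

  # stage outputs
  o <- function(f) file.path(config$out_dir, f)
  write_tsv(data.frame(gene = rownames(norm$log2_rep),
                       norm$log2_rep, check.names = FALSE),
            o("normalized_log2.tsv"))
  write_tsv(fc, o("fold_change.tsv"))
  write_tsv(data.frame(calls$genes,
                       pattern = calls$pattern[calls$genes$gene],
                       check.names = FALSE),
            o("gene_calls.tsv"))
  write_tsv(pattern_counts(calls), o("pattern_counts.tsv"))
  write_tsv(ca_contribution_table(ca), o("ca_eigenvalues.tsv"))
  write_tsv(data.frame(gene = rownames(ca$row_coords),
                       ca$row_coords, check.names = FALSE),
            o("ca_row_scores.tsv"))
  write_tsv(data.frame(time = rownames(ca$col_coords),
                       ca$col_coords, check.names = FALSE),
            o("ca_col_scores.tsv"))
  write_tsv(data.frame(gene = names(geom$area),
                       geom$coords, area = geom$area,
                       geom$dist_to_scores, check.names = FALSE),
            o("geometry.tsv"))
  write_tsv(do.call(rbind, lapply(geom$lines, function(l)
    data.frame(line = l$boundary, slope = l$slope,
               intercept = l$intercept,
               anchor1 = l$anchors[1], anchor2 = l$anchors[2]))),
    o("boundary_lines.tsv"))
  write_tsv(geom$query_genes, o("query_genes.tsv"))
  set_df <- do.call(rbind, lapply(names(sets), function(s)
    if (length(sets[[s]]))
      data.frame(set = s, gene = sets[[s]], stringsAsFactors = FALSE)))
  if (!is.null(set_df)) write_tsv(set_df, o("threshold_sets.tsv"))
  if (!is.null(dist_sets)) write_tsv(dist_sets, o("distance_sets.tsv"))
  if (!is.null(enr)) {
    write_tsv(enr$fisher, o("enrichment_fisher.tsv"))
    if (!is.null(enr$page)) write_tsv(enr$page, o("enrichment_page.tsv"))
    write_tsv(enr$summary, o("enrichment_summary.tsv"))
  }

  manifest <- list(
    package = "woundCA",
    version = as.character(utils::packageVersion("woundCA")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, alpha = config$alpha,
    n_features = nrow(sm$signal), n_retained = sum(qc$retained),
    universe = sum(qc$retained),
    set_sizes = lapply(sets, length))
  jsonlite::write_json(manifest, o("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  result <- structure(
    list(signal = sm, qc = qc, normalized = norm, fold_change = fc,
         calls = calls, degrees = deg, ca = ca, geometry = geom,
         sets = sets, distance_sets = dist_sets, enrichment = enr,
         truth = truth,
         out_dir = config$out_dir),
    class = "pipeline_result")
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("woundCA pipeline result in", x$out_dir, "\n")
  invisible(x)
}
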