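# ---- GMT catalogs -----------------------------------------------------------

#' Read a GMT annotation catalog
#'
#' Tab-separated, one term per line: term id, description, then member gene
#' ids. The description field doubles as the category label (biological
#' process / cellular component / molecular function / pathway / ...), which
#' the enrichment driver uses to form BH families; this is why the reader
#' keeps it.
#'
#' @param path GMT file.
#' @return Named list of member-gene character vectors with a `category`
#'   attribute (named character vector of descriptions).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  ids <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT")
  catalog <- lapply(parts, function(x) x[-(1:2)])
  names(catalog) <- ids
  attr(catalog, "category") <- stats::setNames(
    vapply(parts, `[[`, "", 2), ids)
  catalog
}

#' Write a catalog in GMT format
#'
#' @param catalog named list of member vectors; a `category` attribute (as
#'   from [read_gmt()]) supplies the description field, else `"na"`.
#' @param path output file.
#' @export
write_gmt <- function(catalog, path) {
  cat <- attr(catalog, "category")
  if (is.null(cat)) cat <- stats::setNames(rep("na", length(catalog)),
                                           names(catalog))
  writeLines(vapply(names(catalog), function(id)
    paste(c(id, cat[[id]], catalog[[id]]), collapse = "\t"), ""), path)
}

# ---- Fisher over-representation --------------------------------------------

#' One-sided Fisher exact over-representation test
#'
#' Hypergeometric upper tail P(X >= x) for the overlap between a gene set
#' and a term within a finite universe (the 2x2 table's one-sided exact
#' test, via [stats::phyper()]).
#'
#' @param gene_set character vector of member gene ids.
#' @param term character vector of the term's gene ids.
#' @param universe character vector of all eligible gene ids (QC-retained).
#' @return One-row data frame: `m` (set size), `K` (term size in universe),
#'   `x` (overlap), `N` (universe size), `p`.
#' @export
fisher_enrichment <- function(gene_set, term, universe) {
  if (length(universe) == 0) stop("empty universe")
  gene_set <- intersect(unique(gene_set), universe)
  if (length(gene_set) == 0) stop("empty gene set (after universe filter)")
  term <- intersect(unique(term), universe)
  m <- length(gene_set)
  K <- length(term)
  N <- length(universe)
  x <- length(intersect(gene_set, term))
  p <- stats::phyper(x - 1, K, N - K, m, lower.tail = FALSE)
  data.frame(m = m, K = K, x = x, N = N, p = p)
}

# ---- PAGE -------------------------------------------------------------------

#' Parametric analysis of gene set enrichment (PAGE)
#'
#' Compares a term's mean expression score against the global score
#' distribution: with global mean `mu` and sd `delta` over all universe
#' genes and term mean `Sm` over its `m` members,
#' `Z = (Sm - mu) * sqrt(m) / delta`, with a two-sided normal p value.
#' Scores are conventionally log2 fold changes at the set's defining time
#' point; Z is invariant under affine rescaling of all scores.
#'
#' @param scores named numeric vector of per-gene scores over the universe.
#' @param term character vector of term member ids (must all have scores).
#' @return One-row data frame: `m`, `Sm`, `mu`, `delta`, `Z`, `p`.
#' @export
page_test <- function(scores, term) {
  term <- unique(term)
  if (length(term) == 0) stop("empty term")
  if (!all(term %in% names(scores)))
    stop("term members missing from the score vector")
  mu <- mean(scores)
  delta <- stats::sd(scores)
  if (!is.finite(delta) || delta == 0)
    stop("global score standard deviation is zero")
  m <- length(term)
  Sm <- mean(scores[term])
  Z <- (Sm - mu) * sqrt(m) / delta
  data.frame(m = m, Sm = Sm, mu = mu, delta = delta, Z = Z,
             p = 2 * stats::pnorm(-abs(Z)))
}

# ---- enrichment driver ------------------------------------------------------

#' Enrich a collection of gene sets against a catalog
#'
#' Runs the one-sided Fisher test for every (gene set, term) pair and — for
#' terms in pathway-like categories, when `scores` are supplied — the PAGE
#' test per term. BH correction is applied within each (gene set, category)
#' family. A per-set count of significant terms per category is returned
#' alongside the full table.
#'
#' @param sets named list of gene-id vectors (e.g. threshold or distance
#'   sets).
#' @param catalog annotation catalog as from [read_gmt()].
#' @param universe all QC-retained gene ids.
#' @param alpha significance level on adjusted p values.
#' @param scores optional named score vector for PAGE (log2 FC at the
#'   relevant time point); PAGE is run once per term, not per set.
#' @param page_categories category labels treated as pathways for PAGE.
#' @return List with `fisher` (data frame: set, term, category, m, K, x, N,
#'   p, p_adj, significant), `page` (data frame or NULL), and `summary`
#'   (significant-term counts per set x category).
#' @export
enrich_all <- function(sets, catalog, universe, alpha = 0.05,
                       scores = NULL, page_categories = "pathway") {
  if (length(catalog) == 0) stop("empty annotation catalog")
  if (is.null(names(sets))) stop("'sets' must be a named list")
  category <- attr(catalog, "category")
  if (is.null(category))
    category <- stats::setNames(rep("term", length(catalog)), names(catalog))
  res <- do.call(rbind, lapply(names(sets), function(s) {
    one <- do.call(rbind, lapply(names(catalog), function(tid) {
      f <- fisher_enrichment(sets[[s]], catalog[[tid]], universe)
      cbind(data.frame(set = s, term = tid,
                       category = unname(category[tid]),
                       stringsAsFactors = FALSE), f)
    }))
    one
  }))
  res$p_adj <- NA_real_
  for (key in unique(paste(res$set, res$category))) {
    i <- paste(res$set, res$category) == key
    res$p_adj[i] <- bh_adjust(res$p[i], family = key)
  }
  res$significant <- res$p_adj < alpha

  page <- NULL
  if (!is.null(scores)) {
    ptids <- names(catalog)[category[names(catalog)] %in% page_categories]
    if (length(ptids)) {
      page <- do.call(rbind, lapply(ptids, function(tid) {
        members <- intersect(catalog[[tid]], names(scores))
        if (length(members) == 0) return(NULL)
        cbind(data.frame(term = tid, stringsAsFactors = FALSE),
              page_test(scores, members))
      }))
      page$p_adj <- bh_adjust(page$p, family = "page")
      page$significant <- page$p_adj < alpha
    }
  }
  summary <- stats::aggregate(significant ~ set + category, data = res, sum)
  names(summary)[3] <- "n_significant"
  list(fisher = res, page = page, summary = summary)
}
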