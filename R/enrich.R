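#' Upper-tail hypergeometric probability
#'
#' The enrichment p-value: the probability of observing `k` or more records
#' of a given trait among `n` annotated records, when the database holds `K`
#' records of that trait out of `N` in total and annotation behaves as
#' drawing `n` records without replacement. That is `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.
#'
#' The tail is summed in log space from log-binomial coefficients
#' (`lchoose`) with a log-sum-exp reduction, so probabilities far below the
#' smallest normal double (the example data reach 1e-171, and deeper tails
#' than 1e-300 arise) are computed without underflow.
#'
#' @param k observed successes (records of the trait among the annotated
#'   ones). Vectorized; vectors are recycled.
#' @param K successes in the population (records of the trait in the
#'   database, within scope).
#' @param n draws (total annotated records within scope).
#' @param N population size (total database records within scope).
#' @param log_p return the natural log of the probability instead.
#' @return numeric vector of upper-tail probabilities in `[0, 1]` (or their
#'   logs).
#' @examples
#' hypergeom_upper_tail(4, 5, 12, 3606)   # 3.51e-10
#' hypergeom_upper_tail(0, 5, 12, 3606)   # 1: the certain event
#' @export
hypergeom_upper_tail <- function(k, K, n, N, log_p = FALSE) {
  args <- vctrs_recycle(k = k, K = K, n = n, N = N)
  k <- args$k; K <- args$K; n <- args$n; N <- args$N
  bad <- which(
    is.na(k) | is.na(K) | is.na(n) | is.na(N) |
      k < 0 | K < 0 | n < 0 | K > N | n > N | k > K | k > n |
      k != floor(k) | K != floor(K) | n != floor(n) | N != floor(N)
  )
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid hypergeometric counts (need 0 <= k <= min(K, n), K <= N, n <= N): (k=%s, K=%s, n=%s, N=%s)",
      k[bad[1]], K[bad[1]], n[bad[1]], N[bad[1]]
    ))
  }
  out <- vapply(seq_along(k), function(i) {
    ks <- seq.int(k[i], min(K[i], n[i]))
    lp <- lchoose(K[i], ks) + lchoose(N[i] - K[i], n[i] - ks) -
      lchoose(N[i], n[i])
    min(logsumexp(lp), 0)
  }, numeric(1))
  if (log_p) out else exp(out)
}

# minimal common-length recycling for scalar-or-vector count arguments
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, function(a) {
    if (length(a) == n) a
    else if (length(a) == 1) rep(a, n)
    else abort("count arguments must be length 1 or a common length")
  })
}

#' Multiple-testing correction with validation
#'
#' Thin validated wrapper over [stats::p.adjust()]: input must lie in
#' `[0, 1]`, output keeps the input order and is capped at 1. `m` is the
#' number of p-values supplied — exactly the tests emitted by the calling
#' analysis.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` (Benjamini–Hochberg FDR, the default),
#'   `"bonferroni"`, `"holm"` or `"none"`.
#' @return adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(pvalues, method = c("BH", "bonferroni", "holm", "none")) {
  method <- match.arg(method)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = method)
}

#' QTL enrichment by upper-tail hypergeometric test
#'
#' Tests whether traits (or QTL classes) are over-represented among the QTL
#' records annotated within candidate regions, relative to their
#' representation in the whole database. Databases accumulate records
#' unevenly across traits — heavily studied traits such as milk production
#' dominate — so raw composition is misleading; the hypergeometric model
#' asks whether the observed count is larger than expected when drawing the
#' same number of records at random from the database.
#'
#' For every tested unit the four counts are: `k` = unique annotated records
#' of the trait, `K` = database records of the trait, `n` = all unique
#' annotated records, `N` = all database records — each restricted to one
#' chromosome when `enrich_type = "chromosome"`, or taken genome-wide when
#' `"genome"`. Annotated records are deduplicated by `qtl_id` within scope
#' before counting (several markers hitting one record count it once;
#' without this `k` could exceed `K`). Only traits observed in the
#' annotation (`k >= 1`) are tested; the correction is computed over exactly
#' the emitted tests.
#'
#' @param annotation a QTL [annotate_loci()] result (or any table with
#'   `qtl_id`, `trait_name`, `qtl_class`, `chrom` columns).
#' @param db the QTL `feature_db` the annotation was made against.
#' @param enrich_type `"genome"` (one test per trait, `CHR = "genome"`) or
#'   `"chromosome"` (one test per observed trait-chromosome pair).
#' @param by test individual traits (`"trait"`, default) or coarse QTL
#'   classes (`"class"`).
#' @param chr_subset optional vector of chromosome labels to restrict a
#'   chromosome-wide analysis to.
#' @param padj_method multiple-testing correction, see [adjust_pvalues()].
#'   Default `"BH"` (FDR).
#' @param permutations if `> 0`, also compute a Monte Carlo p-value per row
#'   by simulating this many random draws of `n` records from the scoped
#'   database (column `perm_pvalue`, with a +1 pseudocount). A cross-check
#'   of the analytic tail, not a replacement; default 0.
#' @param seed RNG seed for the permutation cross-check.
#' @return a `qtl_enrichment` tibble sorted by ascending `pvalue` (ties by
#'   trait name) with columns `QTL`, `CHR`, `N_QTLs` (k), `N_QTLs_db` (K),
#'   `Total_annotated_QTLs` (n), `Total_QTLs_db` (N), `pvalue`, `adj.pval`,
#'   `QTL_type`, `richness` (k/K). The number of tests behind the
#'   correction is in `attr(, "n_tests")` and via [glance()].
#' @export
qtl_enrich <- function(annotation, db,
                       enrich_type = c("genome", "chromosome"),
                       by = c("trait", "class"),
                       chr_subset = NULL,
                       padj_method = c("BH", "bonferroni", "holm", "none"),
                       permutations = 0, seed = NULL) {
  enrich_type <- match.arg(enrich_type)
  by <- match.arg(by)
  padj_method <- match.arg(padj_method)
  stopifnot(inherits(db, "feature_db"), db$kind == "qtl")

  ann <- strip_tbl(annotation)
  check_cols(ann, c("qtl_id", "trait_name", "qtl_class", "chrom"), "annotation")
  ann$chrom <- norm_chrom(ann$chrom)
  ann$qtl_id <- as.character(ann$qtl_id)
  unit <- if (by == "trait") "trait_name" else "qtl_class"

  feats <- db$features
  if (enrich_type == "chromosome" && !is.null(chr_subset)) {
    keep <- norm_chrom(chr_subset)
    ann <- dplyr::filter(ann, .data$chrom %in% keep)
    feats <- dplyr::filter(feats, .data$chrom %in% keep)
  }
  if (nrow(ann) == 0) {
    warn("qtl_enrich: no annotated records in scope; empty result")
    return(new_enrichment(empty_enrichment(), padj_method, 0L, enrich_type, by))
  }

  scope_var <- if (enrich_type == "chromosome") "chrom" else character(0)

  # one row per unique annotated record within scope
  ann_u <- dplyr::distinct(ann, dplyr::across(all_of(c(scope_var, "qtl_id"))),
                           .keep_all = TRUE)
  db_scoped <- feats

  totals_ann <- ann_u %>%
    dplyr::count(dplyr::across(all_of(scope_var)), name = "n_total")
  totals_db <- db_scoped %>%
    dplyr::count(dplyr::across(all_of(scope_var)), name = "N_total")

  obs <- ann_u %>%
    dplyr::count(dplyr::across(all_of(c(scope_var, unit))), name = "k")
  db_counts <- db_scoped %>%
    dplyr::count(dplyr::across(all_of(c(scope_var, unit))), name = "K")

  join_scope <- function(x, y) {
    if (length(scope_var) == 0) dplyr::cross_join(x, y)
    else dplyr::left_join(x, y, by = scope_var)
  }
  res <- obs %>%
    dplyr::left_join(db_counts, by = c(scope_var, unit)) %>%
    join_scope(totals_ann) %>%
    join_scope(totals_db)

  if (any(is.na(res$K))) {
    missing <- res[[unit]][is.na(res$K)]
    abort(sprintf(
      "annotated %s(s) absent from the database in scope: %s (annotation/database mismatch)",
      by, paste(unique(missing), collapse = ", ")
    ))
  }

  # dominant class per trait, for the QTL_type column; a class is its own type
  if (unit == "qtl_class") {
    res$type <- res$qtl_class
  } else {
    type_of <- db_scoped %>%
      dplyr::count(.data[[unit]], .data$qtl_class) %>%
      dplyr::group_by(.data[[unit]]) %>%
      dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) %>%
      dplyr::ungroup() %>%
      dplyr::select(all_of(unit), type = "qtl_class")
    res <- dplyr::left_join(res, type_of, by = unit)
  }

  res <- res %>%
    dplyr::mutate(
      pvalue = hypergeom_upper_tail(.data$k, .data$K, .data$n_total, .data$N_total)
    ) %>%
    dplyr::arrange(.data$pvalue, .data[[unit]]) %>%
    dplyr::mutate(adj.pval = adjust_pvalues(.data$pvalue, padj_method))

  out <- tibble(
    QTL = res[[unit]],
    CHR = if (enrich_type == "chromosome") res$chrom else "genome",
    N_QTLs = res$k,
    N_QTLs_db = res$K,
    Total_annotated_QTLs = res$n_total,
    Total_QTLs_db = res$N_total,
    pvalue = res$pvalue,
    adj.pval = res$adj.pval,
    QTL_type = res$type,
    richness = res$k / res$K
  )

  if (permutations > 0) {
    out$perm_pvalue <- perm_pvalues(out, n_sim = permutations, seed = seed)
  }
  new_enrichment(out, padj_method, nrow(out), enrich_type, by)
}

empty_enrichment <- function() {
  tibble(
    QTL = character(), CHR = character(), N_QTLs = integer(),
    N_QTLs_db = integer(), Total_annotated_QTLs = integer(),
    Total_QTLs_db = integer(), pvalue = numeric(), adj.pval = numeric(),
    QTL_type = character(), richness = numeric()
  )
}

new_enrichment <- function(x, padj_method, n_tests, enrich_type, by) {
  structure(
    x,
    padj_method = padj_method, n_tests = n_tests,
    enrich_type = enrich_type, by = by,
    class = c("qtl_enrichment", class(tibble()))
  )
}

# Monte Carlo draw-based cross-check of the analytic upper tail
perm_pvalues <- function(rows, n_sim, seed = NULL) {
  withr::with_seed(seed %||% 1L, {
    vapply(seq_len(nrow(rows)), function(i) {
      sims <- rhyper(
        n_sim,
        m = rows$N_QTLs_db[i],
        n = rows$Total_QTLs_db[i] - rows$N_QTLs_db[i],
        k = rows$Total_annotated_QTLs[i]
      )
      (sum(sims >= rows$N_QTLs[i]) + 1) / (n_sim + 1)
    }, numeric(1))
  })
}

#' Enrichment from a precomputed count table
#'
#' Runs the upper-tail hypergeometric test directly on a table of count
#' quadruples — one row per tested trait/chromosome with `n_hits` (k),
#' `n_db` (K), `total_hits` (n), `total_db` (N) — as produced by an earlier
#' annotation run or bundled as an example. Useful when only the summary
#' counts, not the raw annotation, are at hand.
#'
#' @param counts data frame with columns `trait`, `chrom`, `n_hits`,
#'   `n_db`, `total_hits`, `total_db` and optionally `qtl_type`.
#' @inheritParams qtl_enrich
#' @return a `qtl_enrichment` tibble, sorted by ascending p-value.
#' @examples
#' counts <- tibble::tibble(trait = "Scrotal circumference", chrom = "21",
#'                          n_hits = 4, n_db = 5, total_hits = 12,
#'                          total_db = 3606, qtl_type = "Reproduction")
#' enrich_from_counts(counts)$pvalue  # 3.51e-10
#' @export
enrich_from_counts <- function(counts,
                               padj_method = c("BH", "bonferroni", "holm", "none")) {
  padj_method <- match.arg(padj_method)
  counts <- as_tibble(counts)
  check_cols(counts, c("trait", "chrom", "n_hits", "n_db", "total_hits",
                       "total_db"), "count table")
  out <- tibble(
    QTL = as.character(counts$trait),
    CHR = as.character(counts$chrom),
    N_QTLs = counts$n_hits,
    N_QTLs_db = counts$n_db,
    Total_annotated_QTLs = counts$total_hits,
    Total_QTLs_db = counts$total_db,
    pvalue = hypergeom_upper_tail(counts$n_hits, counts$n_db,
                                  counts$total_hits, counts$total_db),
    QTL_type = if ("qtl_type" %in% names(counts)) as.character(counts$qtl_type)
               else NA_character_,
    richness = counts$n_hits / counts$n_db
  ) %>%
    dplyr::arrange(.data$pvalue, .data$QTL) %>%
    dplyr::mutate(adj.pval = adjust_pvalues(.data$pvalue, padj_method),
                  .after = "pvalue")
  new_enrichment(out, padj_method, nrow(out),
                 if (all(out$CHR == "genome")) "genome" else "chromosome",
                 "trait")
}

#' @export
tidy.qtl_enrichment <- function(x, ...) {
  tibble(
    qtl = x$QTL, chrom = x$CHR, n_hits = x$N_QTLs, n_db = x$N_QTLs_db,
    total_hits = x$Total_annotated_QTLs, total_db = x$Total_QTLs_db,
    pvalue = x$pvalue, adj_pvalue = x$adj.pval, qtl_type = x$QTL_type,
    richness = x$richness
  )
}

#' @export
glance.qtl_enrichment <- function(x, ...) {
  tibble(
    n_tests = attr(x, "n_tests"),
    padj_method = attr(x, "padj_method"),
    enrich_type = attr(x, "enrich_type"),
    by = attr(x, "by"),
    n_significant_05 = sum(x$adj.pval < 0.05)
  )
}

#' Plot-ready table for the enrichment bubble plot
#'
#' Selects the `top` most significant rows and lays out the bubble-plot
#' aesthetics: richness factor `k/K` on x, bubble area proportional to the
#' annotated count `k`, color by `-log10` of the chosen p-value.
#'
#' @param rows a [qtl_enrich()] result.
#' @param top number of rows to keep, by ascending p (ties by trait name);
#'   if larger than the available rows, all rows are used with a warning.
#' @param p_col `"pvalue"` or `"adj.pval"`.
#' @return tibble with `label` (trait, plus chromosome when chromosome-wide),
#'   `richness`, `size`, `neglog10_p`, plus the source count columns.
#' @export
enrichment_bubble_data <- function(rows, top = 10, p_col = c("pvalue", "adj.pval")) {
  p_col <- match.arg(p_col)
  rows <- strip_tbl(rows)
  if (nrow(rows) == 0) abort("no enrichment rows to plot")
  if (top < 1) abort("`top` must be >= 1")
  if (top > nrow(rows)) {
    warn(sprintf("requested top %d rows but only %d available; using all", top, nrow(rows)))
    top <- nrow(rows)
  }
  rows %>%
    dplyr::arrange(.data[[p_col]], .data$QTL) %>%
    dplyr::slice(seq_len(top)) %>%
    dplyr::mutate(
      label = ifelse(.data$CHR == "genome", .data$QTL,
                     paste0(.data$QTL, " (chr ", .data$CHR, ")")),
      richness = .data$N_QTLs / .data$N_QTLs_db,
      size = .data$N_QTLs,
      neglog10_p = -log10(pmax(.data[[p_col]], 1e-320))
    ) %>%
    dplyr::select("label", "richness", "size", "neglog10_p",
                  "N_QTLs", "N_QTLs_db", dplyr::all_of(p_col))
}
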