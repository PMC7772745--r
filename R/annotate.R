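#' Coerce a data frame to candidate loci
#'
#' Applies the same schema detection as [read_candidates()] to an in-memory
#' data frame: `(CHR, BP1, BP2)` columns (case-insensitive) give interval
#' loci, `(CHR, BP)` gives point markers, the interval schema winning when
#' both are present. A frame that already has `chrom`, `start_bp`, `end_bp`
#' is passed through unchanged.
#'
#' @param df data frame of candidate loci.
#' @return tibble with `chrom`, `start_bp`, `end_bp` and passthrough
#'   metadata columns.
#' @export
as_candidates <- function(df) {
  df <- as_tibble(df)
  if (all(c("chrom", "start_bp", "end_bp") %in% names(df))) {
    if (any(df$end_bp < df$start_bp)) abort("candidate loci have end_bp < start_bp")
    return(df)
  }
  detect_candidate_schema(df)
}

feature_payload <- function(db, meta_names) {
  feats <- db$features
  feats$attrs <- NULL
  coord_prefix <- db$kind
  feats <- dplyr::rename(
    feats,
    "{coord_prefix}_start_bp" := "start_bp",
    "{coord_prefix}_end_bp" := "end_bp"
  )
  feats$chrom <- NULL
  clash <- intersect(names(feats), meta_names)
  if (length(clash) > 0) {
    names(feats)[match(clash, names(feats))] <- paste0(clash, "_db")
  }
  feats
}

new_annotation <- function(rows, summary, window, kind) {
  structure(
    rows,
    summary = summary,
    window = window,
    db_kind = kind,
    class = c("qtl_annotation", class(tibble())))
}

#' Annotate candidate loci with overlapping genes or QTLs
#'
#' Joins candidate markers or intervals against a feature database: each
#' candidate interval, widened by `window` base pairs on both sides (clipped
#' at position 1), is intersected with every database record on the same
#' normalized chromosome, and every overlapping pair becomes one output row
#' combining the candidate's columns (including all passthrough metadata)
#' with the feature's columns. Overlap means at least one shared base on the
#' closed 1-based intervals, so a feature touching the widened boundary
#' counts; strand is ignored. Candidates producing no overlap contribute no
#' rows but are retained with a zero count in the hit summary
#' (see [annotation_summary()]).
#'
#' Rows keep the candidates' input order; within one candidate, features are
#' ordered by start position.
#'
#' @param candidates data frame of candidate loci ([read_candidates()] /
#'   [as_candidates()] schema).
#' @param db a [as_feature_db()] object (genes or QTLs).
#' @param window non-negative flank in base pairs added upstream and
#'   downstream of each candidate before overlap testing. No default: the
#'   window is a study-level choice (common values are 50–200 kb) and must
#'   be stated explicitly.
#' @return a `qtl_annotation` tibble: candidate columns, then feature
#'   columns (`gene_*` or `qtl_*` coordinates plus identity fields), with
#'   attributes `summary`, `window` and `db_kind`.
#' @examples
#' db <- as_feature_db(
#'   tibble::tibble(chrom = "1", start_bp = 1100, end_bp = 2000,
#'                  gene_id = "G1", gene_name = "A", biotype = "pc"),
#'   kind = "gene")
#' loci <- tibble::tibble(CHR = 1, BP = 1000)
#' annotate_loci(loci, db, window = 100)
#' @export
annotate_loci <- function(candidates, db, window) {
  stopifnot(inherits(db, "feature_db"))
  if (missing(window) || is.null(window)) {
    abort("`window` is required (base pairs added up/downstream; use 0 for exact intersection)")
  }
  if (!is.numeric(window) || length(window) != 1 || is.na(window) || window < 0) {
    abort("`window` must be a single non-negative number of base pairs")
  }
  cand <- as_candidates(candidates)
  if (nrow(cand) == 0) abort("no candidate loci supplied")

  feats <- db$features
  shared <- intersect(unique(cand$chrom), unique(feats$chrom))
  summary0 <- dplyr::mutate(
    dplyr::select(cand, "chrom", "start_bp", "end_bp"),
    candidate = row_number(), n_hits = 0L, .before = 1
  )
  payload <- feature_payload(db, names(cand))

  if (length(shared) == 0 || nrow(feats) == 0) {
    if (nrow(feats) > 0) {
      warn("annotate_loci: candidates and database share no chromosome labels; check naming")
    }
    empty <- dplyr::bind_cols(cand[0, , drop = FALSE], payload[0, , drop = FALSE])
    return(new_annotation(empty, summary0, window, db$kind))
  }

  q <- GenomicRanges::GRanges(
    seqnames = cand$chrom,
    ranges = IRanges::IRanges(
      start = pmax(1, cand$start_bp - window),
      end = cand$end_bp + window
    )
  )
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q, db$index, ignore.strand = TRUE)
  )
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ord <- order(qi, feats$start_bp[si], si)
  qi <- qi[ord]
  si <- si[ord]

  rows <- dplyr::bind_cols(cand[qi, , drop = FALSE], payload[si, , drop = FALSE])
  counts <- tabulate(qi, nbins = nrow(cand))
  summary0$n_hits <- as.integer(counts)
  new_annotation(rows, summary0, window, db$kind)
}

#' Per-candidate hit counts of an annotation
#'
#' @param annotation result of [annotate_loci()] or [brute_force_overlap()].
#' @return tibble with one row per input candidate (`candidate`, `chrom`,
#'   `start_bp`, `end_bp`, `n_hits`), including zero-hit candidates.
#' @export
annotation_summary <- function(annotation) {
  s <- attr(annotation, "summary")
  if (is.null(s)) abort("object has no annotation summary attribute")
  s
}

#' Reference overlap scan (test oracle)
#'
#' Computes exactly the [annotate_loci()] contract by an O(candidates x
#' features) linear scan over plain vectors, with no interval index. Kept
#' deliberately independent of the indexed implementation so the two can be
#' compared on randomized inputs.
#'
#' @inheritParams annotate_loci
#' @return a `qtl_annotation` tibble, identical in contract to
#'   [annotate_loci()].
#' @export
brute_force_overlap <- function(candidates, db, window) {
  stopifnot(inherits(db, "feature_db"))
  if (!is.numeric(window) || length(window) != 1 || window < 0) {
    abort("`window` must be a single non-negative number of base pairs")
  }
  cand <- as_candidates(candidates)
  feats <- db$features
  payload <- feature_payload(db, names(cand))

  qi_all <- integer(0)
  si_all <- integer(0)
  counts <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    lo <- max(1, cand$start_bp[i] - window)
    hi <- cand$end_bp[i] + window
    hit <- which(feats$chrom == cand$chrom[i] &
                   feats$start_bp <= hi & feats$end_bp >= lo)
    hit <- hit[order(feats$start_bp[hit], hit)]
    counts[i] <- length(hit)
    qi_all <- c(qi_all, rep.int(i, length(hit)))
    si_all <- c(si_all, hit)
  }
  rows <- dplyr::bind_cols(cand[qi_all, , drop = FALSE],
                           payload[si_all, , drop = FALSE])
  summary <- dplyr::mutate(
    dplyr::select(cand, "chrom", "start_bp", "end_bp"),
    candidate = row_number(), n_hits = counts, .before = 1
  )
  new_annotation(rows, summary, window, db$kind)
}
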