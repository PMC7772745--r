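#' Feature database container
#'
#' A `feature_db` bundles a tibble of genomic features (genes or QTLs, with
#' 1-based inclusive coordinates), a per-chromosome interval index
#' ([GenomicRanges::GRanges]) used by [annotate_loci()], and provenance
#' (source path plus counts of records kept and dropped, by reason).
#'
#' @param features tibble with at least `chrom`, `start_bp`, `end_bp` plus the
#'   identity columns of the record kind (`gene_id`, `gene_name`, `biotype`
#'   for genes; `qtl_id`, `trait_name`, `qtl_class` for QTLs).
#' @param kind `"gene"` or `"qtl"`.
#' @param provenance optional list recording `source`, `n_data_lines`,
#'   `n_kept`, `n_dropped` and a `drops` tibble (reason, n).
#' @return an object of class `feature_db`.
#' @export
as_feature_db <- function(features, kind = c("gene", "qtl"), provenance = NULL) {
  kind <- match.arg(kind)
  features <- as_tibble(features)
  need <- c("chrom", "start_bp", "end_bp",
            if (kind == "gene") c("gene_id", "gene_name", "biotype")
            else c("qtl_id", "trait_name", "qtl_class"))
  check_cols(features, need, sprintf("%s feature table", kind))
  if (nrow(features) > 0 && any(features$end_bp < features$start_bp)) {
    abort("feature table has records with end_bp < start_bp")
  }
  index <- GenomicRanges::GRanges(
    seqnames = if (nrow(features)) features$chrom else character(),
    ranges = IRanges::IRanges(
      start = as.integer(features$start_bp),
      end = as.integer(features$end_bp)
    )
  )
  structure(
    list(
      features = features,
      kind = kind,
      index = index,
      provenance = provenance %||% list(
        source = NA_character_, n_data_lines = nrow(features),
        n_kept = nrow(features), n_dropped = 0L,
        drops = tibble(reason = character(), n = integer())
      )
    ),
    class = "feature_db"
  )
}

#' @export
print.feature_db <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf(
    "<feature_db: %d %s record(s) on %d chromosome(s)>\n",
    nrow(x$features), x$kind, dplyr::n_distinct(x$features$chrom)
  ))
  cat(sprintf("  source: %s\n", pv$source))
  cat(sprintf("  kept %d / dropped %d of %d data line(s)\n",
              pv$n_kept, pv$n_dropped, pv$n_data_lines))
  if (nrow(pv$drops) > 0) {
    for (i in seq_len(nrow(pv$drops))) {
      cat(sprintf("    - %s: %d\n", pv$drops$reason[i], pv$drops$n[i]))
    }
  }
  invisible(x)
}

# split raw feature lines into the 9 GTF/GFF columns; returns list(fields=
# character matrix for well-formed lines, n_malformed)
split_gff_fields <- function(lines) {
  parts <- stringr::str_split(lines, "\t")
  ok <- lengths(parts) == 9
  list(
    fields = do.call(rbind, parts[ok]),
    n_malformed = sum(!ok)
  )
}

# parse `key "value"; key "value";` GTF attribute strings into named lists
parse_gtf_attrs <- function(attr_strings) {
  purrr::map(attr_strings, function(s) {
    m <- stringr::str_match_all(s, '(\\w+)\\s+"([^"]*)"')[[1]]
    setNames(as.list(m[, 3]), m[, 2])
  })
}

# parse `key=value;key=value` QTLdb-dialect attribute strings; values are
# percent-decoded exactly once and surrounding quotes stripped
parse_gff_attrs <- function(attr_strings) {
  purrr::map(attr_strings, function(s) {
    pieces <- stringr::str_split(s, ";")[[1]]
    pieces <- pieces[stringr::str_detect(pieces, "=")]
    keys <- stringr::str_trim(stringr::str_extract(pieces, "^[^=]+"))
    vals <- stringr::str_remove(pieces, "^[^=]+=")
    vals <- vapply(vals, function(v) URLdecode(v), character(1), USE.NAMES = FALSE)
    vals <- stringr::str_remove_all(stringr::str_trim(vals), '^"|"$')
    setNames(as.list(vals), keys)
  })
}

read_data_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  lines[!stringr::str_starts(lines, "#") & nzchar(stringr::str_trim(lines))]
}

finish_provenance <- function(path, n_data_lines, n_kept, drops) {
  drops <- drops[drops$n > 0, , drop = FALSE]
  list(
    source = path, n_data_lines = n_data_lines, n_kept = n_kept,
    n_dropped = sum(drops$n), drops = as_tibble(drops)
  )
}

#' Import a gene database from an Ensembl-style GTF file
#'
#' Reads a 9-column tab-delimited GTF, keeps lines whose feature-type column
#' equals `feature_type` (default `"gene"`), and returns a [as_feature_db()]
#' object of gene records. Comment lines are skipped; malformed lines,
#' records with `end < start`, records without a `gene_id` attribute, and
#' duplicated `gene_id`s are dropped with a warning and counted in the
#' provenance. Coordinates are 1-based inclusive; chromosome labels are
#' normalized with [norm_chrom()].
#'
#' @param path path to the GTF file.
#' @param feature_type feature-type (column 3) value treated as the
#'   gene-level record; default `"gene"`.
#' @return a `feature_db` of kind `"gene"` whose `features` tibble has columns
#'   `chrom`, `start_bp`, `end_bp`, `strand`, `gene_id`, `gene_name`,
#'   `biotype`, `attrs` (list-column of all attributes).
#' @export
import_gtf <- function(path, feature_type = "gene") {
  lines <- read_data_lines(path)
  n_data <- length(lines)
  sp <- split_gff_fields(lines)
  f <- sp$fields
  drops <- tibble(reason = character(), n = integer())
  add_drop <- function(reason, n) {
    drops <<- bind_rows(drops, tibble(reason = reason, n = as.integer(n)))
  }
  add_drop("malformed_line", sp$n_malformed)

  if (is.null(f)) f <- matrix(character(), ncol = 9)
  is_type <- f[, 3] == feature_type
  add_drop("feature_type_filtered", sum(!is_type))
  f <- f[is_type, , drop = FALSE]

  start <- suppressWarnings(as.numeric(f[, 4]))
  end <- suppressWarnings(as.numeric(f[, 5]))
  bad_coord <- is.na(start) | is.na(end)
  add_drop("unparsable_coordinates", sum(bad_coord))
  inverted <- !bad_coord & end < start
  add_drop("end_before_start", sum(inverted))
  keep <- !bad_coord & !inverted
  f <- f[keep, , drop = FALSE]

  attrs <- parse_gtf_attrs(f[, 9])
  gene_id <- purrr::map_chr(attrs, ~ .x[["gene_id"]] %||% NA_character_)
  no_id <- is.na(gene_id)
  add_drop("missing_gene_id", sum(no_id))
  dup <- !no_id & duplicated(gene_id)
  add_drop("duplicate_gene_id", sum(dup))
  keep <- !no_id & !dup

  features <- tibble(
    chrom = norm_chrom(f[keep, 1]),
    start_bp = as.numeric(f[keep, 4]),
    end_bp = as.numeric(f[keep, 5]),
    strand = ifelse(f[keep, 7] %in% c("+", "-"), f[keep, 7], "*"),
    gene_id = gene_id[keep],
    gene_name = purrr::map_chr(attrs[keep], ~ .x[["gene_name"]] %||% ""),
    biotype = purrr::map_chr(
      attrs[keep], ~ .x[["gene_biotype"]] %||% .x[["biotype"]] %||% ""
    ),
    attrs = attrs[keep]
  )

  pv <- finish_provenance(path, n_data, nrow(features), drops)
  # non-gene feature types are expected in any GTF; only real problems warn
  n_bad <- pv$n_dropped -
    sum(pv$drops$n[pv$drops$reason == "feature_type_filtered"])
  if (n_bad > 0) {
    warn(sprintf("import_gtf: dropped %d problematic data line(s) from %s",
                 n_bad, path))
  }
  if (nrow(features) == 0 && n_data > 0) {
    abort(sprintf("no usable %s records parsed from %s", feature_type, path))
  }
  as_feature_db(features, "gene", pv)
}

# Milk_QTL -> Milk; Meat_and_Carcass_Association -> Meat and Carcass
class_from_feature_type <- function(type) {
  cls <- stringr::str_remove(type, "_(QTL|Association|Trait)$")
  stringr::str_trim(stringr::str_replace_all(cls, "_", " "))
}

#' Import a QTL database from an Animal-QTLdb-style GFF file
#'
#' Reads the GFF dialect distributed by Animal QTLdb: 9 tab-separated
#' columns, `Chr.N` sequence identifiers, and an attribute column of
#' `key=value` pairs separated by `;` with percent-encoded values (e.g.
#' `Name=Scrotal%20circumference`). Each usable line becomes one QTL record.
#' The QTL class (Milk, Reproduction, Meat and Carcass, ...) is taken from
#' the feature-type column when it encodes one (`Milk_QTL` -> `Milk`,
#' `Reproduction_Association` -> `Reproduction`), else from the attribute
#' named by `class_attr`. Records with unparsable coordinates, `end < start`,
#' a missing trait name or class, or a duplicated `qtl_id` are dropped with a
#' warning and counted in the provenance — never imputed.
#'
#' @param path path to the GFF file.
#' @param class_from where to read the QTL class first: `"feature_type"`
#'   (column 3, the default) or `"attribute"`.
#' @param class_attr attribute key used as the class fallback (default
#'   `"trait_type"`).
#' @return a `feature_db` of kind `"qtl"` whose `features` tibble has columns
#'   `chrom`, `start_bp`, `end_bp`, `qtl_id`, `trait_name`, `qtl_class`,
#'   `attrs` (list-column of all decoded attributes).
#' @export
import_qtl_gff <- function(path, class_from = c("feature_type", "attribute"),
                           class_attr = "trait_type") {
  class_from <- match.arg(class_from)
  lines <- read_data_lines(path)
  n_data <- length(lines)
  sp <- split_gff_fields(lines)
  f <- sp$fields
  drops <- tibble(reason = character(), n = integer())
  add_drop <- function(reason, n) {
    drops <<- bind_rows(drops, tibble(reason = reason, n = as.integer(n)))
  }
  add_drop("malformed_line", sp$n_malformed)
  if (is.null(f)) f <- matrix(character(), ncol = 9)

  start <- suppressWarnings(as.numeric(f[, 4]))
  end <- suppressWarnings(as.numeric(f[, 5]))
  bad_coord <- is.na(start) | is.na(end)
  add_drop("unparsable_coordinates", sum(bad_coord))
  inverted <- !bad_coord & end < start
  add_drop("end_before_start", sum(inverted))
  keep <- !bad_coord & !inverted
  f <- f[keep, , drop = FALSE]

  attrs <- parse_gff_attrs(f[, 9])
  qtl_id <- purrr::map_chr(attrs, ~ .x[["QTL_ID"]] %||% .x[["qtl_id"]] %||%
                             .x[["ID"]] %||% NA_character_)
  trait <- purrr::map_chr(attrs, ~ .x[["Name"]] %||% .x[["trait"]] %||%
                            NA_character_)
  attr_class <- purrr::map_chr(attrs, ~ .x[[class_attr]] %||% NA_character_)
  type_class <- class_from_feature_type(f[, 3])
  type_class[!stringr::str_detect(f[, 3], "_(QTL|Association|Trait)$")] <- NA
  qtl_class <- if (class_from == "feature_type") {
    dplyr::coalesce(type_class, attr_class)
  } else {
    dplyr::coalesce(attr_class, type_class)
  }

  no_trait <- is.na(trait) | !nzchar(trait)
  add_drop("missing_trait_name", sum(no_trait))
  no_class <- !no_trait & (is.na(qtl_class) | !nzchar(qtl_class))
  add_drop("missing_qtl_class", sum(no_class))
  no_id <- !no_trait & !no_class & is.na(qtl_id)
  add_drop("missing_qtl_id", sum(no_id))
  dup <- !no_trait & !no_class & !no_id & duplicated(qtl_id)
  add_drop("duplicate_qtl_id", sum(dup))
  keep <- !no_trait & !no_class & !no_id & !dup

  features <- tibble(
    chrom = norm_chrom(f[keep, 1]),
    start_bp = as.numeric(f[keep, 4]),
    end_bp = as.numeric(f[keep, 5]),
    qtl_id = qtl_id[keep],
    trait_name = trait[keep],
    qtl_class = qtl_class[keep],
    attrs = attrs[keep]
  )

  pv <- finish_provenance(path, n_data, nrow(features), drops)
  if (pv$n_dropped > 0) {
    warn(sprintf("import_qtl_gff: dropped %d of %d data line(s) from %s",
                 pv$n_dropped, n_data, path))
  }
  if (nrow(features) == 0 && n_data > 0) {
    abort(sprintf("no usable QTL records parsed from %s", path))
  }
  as_feature_db(features, "qtl", pv)
}

# pick the delimiter that splits the header into the most fields
sniff_delim <- function(path) {
  header <- readr::read_lines(path, n_max = 1)
  cands <- c("\t", ",", ";")
  counts <- vapply(cands, function(d) length(strsplit(header, d, fixed = TRUE)[[1]]),
                   integer(1))
  cands[which.max(counts)]
}

#' Read a candidate-locus table
#'
#' Reads a delimited text file of candidate markers or intervals. The schema
#' is auto-detected, case-insensitively: a `(CHR, BP1, BP2)` header gives
#' interval loci; a `(CHR, BP)` header gives point markers with
#' `start_bp == end_bp == BP`. If both schemas are present the interval one
#' wins and `BP` is ignored with a message. All other columns are carried
#' through unmodified, in their original order, as per-locus metadata
#' (study, trait, model, ...).
#'
#' @param path path to a CSV/TSV file with a header row (delimiter sniffed
#'   among tab, comma and semicolon).
#' @return tibble with columns `chrom`, `start_bp`, `end_bp` followed by the
#'   passthrough metadata columns.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_delim(path, delim = sniff_delim(path),
                          show_col_types = FALSE, trim_ws = TRUE)
  detect_candidate_schema(df)
}

detect_candidate_schema <- function(df) {
  up <- toupper(names(df))
  chr_i <- match("CHR", up)
  bp_i <- match("BP", up)
  bp1_i <- match("BP1", up)
  bp2_i <- match("BP2", up)

  if (is.na(chr_i) || (is.na(bp_i) && (is.na(bp1_i) || is.na(bp2_i)))) {
    abort(paste0(
      "candidate table must have columns (CHR, BP) for markers or ",
      "(CHR, BP1, BP2) for intervals (case-insensitive); found: ",
      paste(names(df), collapse = ", ")
    ))
  }

  interval <- !is.na(bp1_i) && !is.na(bp2_i)
  if (interval && !is.na(bp_i)) {
    inform("read_candidates: both BP and (BP1, BP2) present; using the interval schema and ignoring BP")
  }
  used <- c(chr_i, if (interval) c(bp1_i, bp2_i, bp_i) else bp_i)
  used <- used[!is.na(used)]

  start <- suppressWarnings(as.numeric(df[[if (interval) bp1_i else bp_i]]))
  end <- suppressWarnings(as.numeric(df[[if (interval) bp2_i else bp_i]]))
  bad <- which(is.na(start) | is.na(end) | start < 1)
  if (length(bad) > 0) {
    abort(sprintf("candidate table row(s) %s have missing/invalid coordinates",
                  paste(head(bad, 5), collapse = ", ")))
  }
  swapped <- which(end < start)
  if (length(swapped) > 0) {
    abort(sprintf("candidate table row(s) %s have BP2 < BP1",
                  paste(head(swapped, 5), collapse = ", ")))
  }

  out <- tibble(chrom = norm_chrom(df[[chr_i]]), start_bp = start, end_bp = end)
  if (any(is.na(out$chrom))) {
    abort("candidate table has empty chromosome labels")
  }
  dplyr::bind_cols(out, df[, setdiff(seq_along(df), used), drop = FALSE])
}

#' Write a tabular result to TSV
#'
#' Writes any tabular result (annotations, overlap matrices in long form,
#' enrichment tables, compositions) as a tab-separated UTF-8 file with a
#' header row and stable column order. Numbers are serialized in full
#' precision with no locale formatting, so p-values at the 1e-171 scale
#' round-trip exactly. List-columns (e.g. `attrs`) are dropped with a
#' message. An empty table writes a header-only file.
#'
#' @param x data frame to write.
#' @param path output path.
#' @param header_lines optional character vector of `# `-prefixed comment
#'   lines written before the header (used by the CLI for provenance).
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path, header_lines = NULL) {
  x <- as_tibble(x)
  is_list <- vapply(x, is.list, logical(1))
  if (any(is_list)) {
    inform(sprintf("write_table: dropping list-column(s): %s",
                   paste(names(x)[is_list], collapse = ", ")))
    x <- x[, !is_list, drop = FALSE]
  }
  ok <- tryCatch({
    if (!is.null(header_lines)) {
      readr::write_lines(header_lines, path)
      readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
    } else {
      readr::write_tsv(x, path)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort(sprintf("cannot write table to %s: %s",
                                 path, conditionMessage(ok)))
  invisible(x)
}
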