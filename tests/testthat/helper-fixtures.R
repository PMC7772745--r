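# Builders for small in-memory databases and candidate sets used across
# the suite. All randomized helpers take an explicit seed.

make_gene_db <- function(n = 50, n_chrom = 2, L = 1e6, seed = 1) {
  withr::with_seed(seed, {
    len <- sample(500:20000, n, replace = TRUE)
    start <- sample.int(L - max(len), n, replace = TRUE)
    as_feature_db(
      tibble::tibble(
        chrom = as.character(sample.int(n_chrom, n, replace = TRUE)),
        start_bp = start,
        end_bp = start + len - 1,
        strand = sample(c("+", "-"), n, replace = TRUE),
        gene_id = sprintf("G%03d", seq_len(n)),
        gene_name = sprintf("sym%d", seq_len(n)),
        biotype = "protein_coding"
      ),
      kind = "gene"
    )
  })
}

make_qtl_db <- function(n = 80, n_chrom = 2, L = 1e6, seed = 1,
                        traits = c(A = "Milk", B = "Reproduction", C = "Health")) {
  withr::with_seed(seed, {
    len <- sample.int(2e5, n, replace = TRUE)
    start <- pmax(1, sample.int(L, n, replace = TRUE) - len)
    tr <- sample(names(traits), n, replace = TRUE)
    as_feature_db(
      tibble::tibble(
        chrom = as.character(sample.int(n_chrom, n, replace = TRUE)),
        start_bp = start,
        end_bp = start + len - 1,
        qtl_id = sprintf("%d", 1000 + seq_len(n)),
        trait_name = paste0("trait_", tr),
        qtl_class = unname(traits[tr])
      ),
      kind = "qtl"
    )
  })
}

make_candidates <- function(n = 10, n_chrom = 2, L = 1e6, width = 0, seed = 1) {
  withr::with_seed(seed, {
    start <- sample.int(L - width - 1, n, replace = TRUE)
    tibble::tibble(
      chrom = as.character(sample.int(n_chrom, n, replace = TRUE)),
      start_bp = start,
      end_bp = start + width,
      study = sample(c("s1", "s2"), n, replace = TRUE)
    )
  })
}

# sorted (candidate row, feature id) pair set, for order-insensitive
# comparison of annotation results
pair_set <- function(ann, id_col) {
  s <- attr(ann, "summary")
  cand_key <- paste(ann$chrom, ann$start_bp, ann$end_bp)
  sort(paste(cand_key, ann[[id_col]]))
}
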