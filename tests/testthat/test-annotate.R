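test_that("three regions with four genes each give exactly twelve rows", {
  ex <- toy_worked_examples()
  db <- suppressWarnings(import_gtf(ex$genes))
  ann <- annotate_loci(read_candidates(ex$regions), db, window = 0)
  expect_equal(nrow(ann), 12)
  s <- annotation_summary(ann)
  expect_equal(s$n_hits, c(4, 4, 4))
  # passthrough metadata appears in every row
  expect_true(all(ann$region %in% c("region_1", "region_2", "region_3")))
  expect_equal(unname(table(ann$region)), c(4L, 4L, 4L), ignore_attr = TRUE)
})

test_that("window expansion is closed-interval and clipped at 1", {
  db <- as_feature_db(
    tibble::tibble(chrom = "1", start_bp = c(1100, 5000), end_bp = c(2000, 6000),
                   strand = "+", gene_id = c("gA", "gB"), gene_name = "",
                   biotype = ""),
    kind = "gene"
  )
  marker <- tibble::tibble(CHR = 1, BP = 1000)
  # touching the widened boundary counts as overlap
  expect_equal(nrow(annotate_loci(marker, db, window = 100)), 1)
  expect_equal(nrow(annotate_loci(marker, db, window = 99)), 0)
  # expansion below position 1 is clipped, not an error
  near_origin <- tibble::tibble(CHR = 1, BP = 5)
  expect_equal(nrow(annotate_loci(near_origin, db, window = 5e6)), 2)
  # window is mandatory
  expect_error(annotate_loci(marker, db), "window")
  expect_error(annotate_loci(marker, db, window = -1), "non-negative")
})

test_that("zero-hit candidates keep a summary row; absent chromosomes warn", {
  db <- make_gene_db(n = 20, n_chrom = 1, seed = 5)
  cand <- tibble::tibble(CHR = c("1", "9"), BP = c(5e5, 5e5))
  ann <- annotate_loci(cand, db, window = 1e5)
  s <- annotation_summary(ann)
  expect_equal(nrow(s), 2)
  expect_equal(s$n_hits[s$chrom == "9"], 0L)
  expect_equal(sum(s$n_hits), nrow(ann))

  off <- tibble::tibble(CHR = "42", BP = 100)
  expect_warning(empty <- annotate_loci(off, db, window = 0), "chromosome")
  expect_equal(nrow(empty), 0)
  expect_equal(annotation_summary(empty)$n_hits, 0L)
})

test_that("indexed join equals the brute-force oracle on randomized fixtures", {
  for (seed in 1:25) {
    db <- make_qtl_db(n = 120, n_chrom = 3, seed = seed)
    cand <- make_candidates(n = 40, n_chrom = 3, width = 20000, seed = seed + 500)
    w <- c(0, 1000, 50000)[seed %% 3 + 1]
    a <- annotate_loci(cand, db, window = w)
    b <- brute_force_overlap(cand, db, window = w)
    expect_equal(pair_set(a, "qtl_id"), pair_set(b, "qtl_id"))
    expect_equal(annotation_summary(a)$n_hits, annotation_summary(b)$n_hits)
  }
})

test_that("hit counts are monotone in the window", {
  db <- make_gene_db(n = 100, seed = 9)
  cand <- make_candidates(n = 20, width = 0, seed = 10)
  counts <- sapply(c(0, 1e3, 1e4, 1e5), function(w) {
    annotation_summary(annotate_loci(cand, db, window = w))$n_hits
  })
  expect_true(all(diff(t(counts)) >= 0))
})

test_that("rows preserve candidate order and order features by start", {
  db <- as_feature_db(
    tibble::tibble(chrom = "1", start_bp = c(900, 100, 500),
                   end_bp = c(950, 150, 550), strand = "+",
                   gene_id = c("g_late", "g_early", "g_mid"),
                   gene_name = "", biotype = ""),
    kind = "gene"
  )
  cand <- tibble::tibble(CHR = c(1, 1), BP1 = c(1, 1), BP2 = c(1000, 600),
                         tag = c("second_listed_first", "b"))
  ann <- annotate_loci(cand, db, window = 0)
  expect_equal(ann$gene_id,
               c("g_early", "g_mid", "g_late", "g_early", "g_mid"))
  expect_equal(ann$tag[1:3], rep("second_listed_first", 3))
})

test_that("duplicate database records are kept in annotation output", {
  feats <- tibble::tibble(
    chrom = "1", start_bp = 100, end_bp = 200, strand = "+",
    gene_id = c("dup", "dup2"), gene_name = "", biotype = ""
  )
  db <- as_feature_db(feats, kind = "gene")
  ann <- annotate_loci(tibble::tibble(CHR = 1, BP = 150), db, window = 0)
  expect_equal(nrow(ann), 2)
})
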