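# independent oracle: upper-tail probability by explicit enumeration of all
# C(N, n) draws from a population whose first K items are successes
enum_upper_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  succ <- colSums(draws <= K)
  mean(succ >= k)
}

test_that("log-space tail matches exhaustive enumeration and phyper", {
  # the spec-level worked case: P(X >= 2) with K=3, n=3, N=6 over C(6,3)=20 draws
  expect_equal(enum_upper_tail(2, 3, 3, 6), 0.5)
  expect_equal(hypergeom_upper_tail(2, 3, 3, 6), 0.5)

  for (N in c(4, 7, 9, 12)) {
    for (n in 0:N) {
      draws_p <- NULL
      for (K in 0:N) {
        for (k in 0:min(K, n)) {
          expect_equal(
            hypergeom_upper_tail(k, K, n, N),
            enum_upper_tail(k, K, n, N),
            tolerance = 1e-12,
            label = sprintf("(k=%d,K=%d,n=%d,N=%d)", k, K, n, N)
          )
        }
      }
    }
  }

  # agreement with the independent stats::phyper route at extreme scales
  withr::with_seed(21, {
    for (i in 1:50) {
      N <- sample(50:6000, 1)
      K <- sample.int(N, 1)
      n <- sample.int(N, 1)
      k <- sample.int(min(K, n), 1)
      mine <- hypergeom_upper_tail(k, K, n, N, log_p = TRUE)
      ref <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
      expect_lt(abs(mine - ref), 1e-9 * max(1, abs(ref)))
    }
  })
})

test_that("tail probability handles edge cases and rejects bad counts", {
  expect_equal(hypergeom_upper_tail(0, 5, 12, 3606), 1)
  expect_equal(hypergeom_upper_tail(0, 0, 0, 10), 1)
  expect_equal(hypergeom_upper_tail(10, 10, 10, 10), 1)
  # monotone non-increasing in k for fixed (K, n, N)
  p <- hypergeom_upper_tail(0:20, 40, 100, 1000)
  expect_true(all(diff(p) <= 0))
  expect_error(hypergeom_upper_tail(5, 4, 10, 100), "invalid")
  expect_error(hypergeom_upper_tail(1, 4, 10, 8), "invalid")
})

test_that("pmf mass sums to one across random parameter sets", {
  withr::with_seed(33, {
    for (i in 1:100) {
      N <- sample(2:400, 1)
      K <- sample.int(N, 1)
      n <- sample.int(N, 1)
      ks <- max(0, n - (N - K)):min(K, n)
      mass <- sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
      expect_equal(mass, 1, tolerance = 1e-12)
    }
  })
})

test_that("BH/holm/bonferroni adjustments match hand-computed cases", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  # BH: sorted p * m / rank, cumulative minimum from the largest
  expect_equal(adjust_pvalues(c(0.03, 0.005, 0.04), "BH"),
               c(0.04, 0.015, 0.04))
  expect_equal(adjust_pvalues(c(0.5, 0.5), "bonferroni"), c(1, 1))
  expect_equal(adjust_pvalues(c(0.02, 0.01), "holm"), c(0.02, 0.02))
  p <- c(0.9, 0.1, 0.5)
  expect_equal(adjust_pvalues(p, "none"), p)
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("enrichment counts records once per qtl_id and shares scope totals", {
  db <- make_qtl_db(n = 100, n_chrom = 2, seed = 4)
  cand <- make_candidates(n = 15, n_chrom = 2, width = 80000, seed = 5)
  ann <- annotate_loci(cand, db, window = 0)
  res <- qtl_enrich(ann, db, enrich_type = "chromosome")

  # per chromosome, one shared (n, N) pair and sum of k equals n
  by_chr <- split(as.data.frame(res), res$CHR)
  for (chr in names(by_chr)) {
    b <- by_chr[[chr]]
    expect_equal(length(unique(b$Total_annotated_QTLs)), 1)
    expect_equal(sum(b$N_QTLs), b$Total_annotated_QTLs[1])
    expect_equal(b$Total_QTLs_db[1], sum(db$features$chrom == chr))
  }
  # k from unique record ids, even though several candidates hit one record
  ids_by <- tapply(ann$qtl_id, list(ann$chrom, ann$trait_name),
                   function(x) length(unique(x)))
  for (i in seq_len(nrow(res))) {
    expect_equal(res$N_QTLs[i], unname(ids_by[res$CHR[i], res$QTL[i]]))
  }
  expect_true(all(res$N_QTLs <= res$N_QTLs_db))
  expect_true(all(res$richness > 0 & res$richness <= 1))
  expect_true(all(diff(res$pvalue) >= 0))
  expect_true(all(res$adj.pval >= res$pvalue))
})

test_that("genome scope, class-level tests and chr_subset behave", {
  db <- make_qtl_db(n = 100, n_chrom = 2, seed = 4)
  cand <- make_candidates(n = 15, n_chrom = 2, width = 80000, seed = 5)
  ann <- annotate_loci(cand, db, window = 0)

  gen <- qtl_enrich(ann, db, enrich_type = "genome")
  expect_true(all(gen$CHR == "genome"))
  expect_equal(unique(gen$Total_QTLs_db), 100)
  expect_equal(sum(gen$N_QTLs), unique(gen$Total_annotated_QTLs))

  cls <- qtl_enrich(ann, db, enrich_type = "genome", by = "class")
  expect_true(all(cls$QTL %in% c("Milk", "Reproduction", "Health")))
  expect_equal(cls$QTL, cls$QTL_type)

  sub <- qtl_enrich(ann, db, enrich_type = "chromosome", chr_subset = "2")
  expect_true(all(sub$CHR == "2"))
  expect_equal(unique(sub$Total_QTLs_db), sum(db$features$chrom == "2"))
  expect_equal(attr(sub, "n_tests"), nrow(sub))
})

test_that("degenerate single-trait scope yields p = 1; mismatches are fatal", {
  feats <- tibble::tibble(
    chrom = "1", start_bp = seq(1, 901, 100), end_bp = seq(1, 901, 100) + 49,
    qtl_id = as.character(1:10), trait_name = "only", qtl_class = "Milk"
  )
  db <- as_feature_db(feats, kind = "qtl")
  ann <- annotate_loci(tibble::tibble(CHR = 1, BP1 = 1, BP2 = 400), db, window = 0)
  res <- qtl_enrich(ann, db, enrich_type = "genome")
  expect_equal(nrow(res), 1)
  expect_equal(res$N_QTLs_db, 10)
  expect_equal(res$pvalue, 1)

  bad <- dplyr::mutate(tibble::as_tibble(ann), trait_name = "phantom")
  expect_error(qtl_enrich(bad, db), "phantom")
  expect_warning(empty <- qtl_enrich(ann[0, ], db), "no annotated")
  expect_equal(nrow(empty), 0)
})

test_that("Monte Carlo cross-check agrees with the analytic tail", {
  counts <- tibble::tibble(
    trait = c("t1", "t2"), chrom = "1", n_hits = c(8, 3), n_db = c(30, 50),
    total_hits = 60, total_db = 500
  )
  e <- enrich_from_counts(counts)
  db <- make_qtl_db(n = 100, seed = 4)
  cand <- make_candidates(n = 15, width = 80000, seed = 5)
  ann <- annotate_loci(cand, db, window = 0)
  res <- qtl_enrich(ann, db, enrich_type = "genome", permutations = 4000,
                    seed = 11)
  moderate <- res$pvalue > 1e-3   # MC resolution
  expect_true(all(abs(res$perm_pvalue[moderate] - res$pvalue[moderate]) <
                    4 * sqrt(res$pvalue[moderate] / 4000) + 2e-3))
  # determinism under a fixed seed
  res2 <- qtl_enrich(ann, db, enrich_type = "genome", permutations = 4000,
                     seed = 11)
  expect_identical(res$perm_pvalue, res2$perm_pvalue)
})

test_that("bubble data ranks by significance and encodes the richness factor", {
  counts <- readr::read_tsv(toy_worked_examples()$counts, show_col_types = FALSE)
  e <- enrich_from_counts(counts)
  d <- enrichment_bubble_data(e, top = 5)
  expect_equal(nrow(d), 5)
  expect_equal(d$richness[1], 132 / 134)
  expect_equal(d$size[1], 132)
  expect_true(all(diff(d$neglog10_p) <= 0))
  expect_warning(all_rows <- enrichment_bubble_data(e, top = 99), "only")
  expect_equal(nrow(all_rows), nrow(e))
  p <- plot_enrichment(e, top = 5)
  expect_s3_class(p, "ggplot")
  gl <- generics::glance(e)
  expect_equal(gl$n_tests, 10)
  expect_equal(gl$padj_method, "BH")
})
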