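ann_fixture <- function() {
  # 3 classes; one record (q1) hit by three markers
  tibble::tibble(
    chrom = "1",
    qtl_id = c("q1", "q1", "q1", "q2", "q3", "q4"),
    trait_name = c("tA", "tA", "tA", "tA", "tB", "tC"),
    qtl_class = c("Milk", "Milk", "Milk", "Milk", "Milk", "Reproduction"),
    study = c("s1", "s1", "s2", "s2", "s1", "s2")
  )
}

test_that("class composition counts unique records by default, rows on request", {
  comp <- qtl_type_composition(ann_fixture())
  expect_equal(comp$label, c("Milk", "Reproduction"))
  expect_equal(comp$count, c(3L, 1L))      # q1 counted once
  expect_equal(comp$percent, c(75, 25))
  expect_equal(sum(comp$percent), 100)

  rows <- qtl_type_composition(ann_fixture(), count = "rows")
  expect_equal(rows$count, c(5L, 1L))

  # duplicating every row changes nothing under record semantics
  doubled <- dplyr::bind_rows(ann_fixture(), ann_fixture())
  expect_equal(as.data.frame(qtl_type_composition(doubled)),
               as.data.frame(comp))
  expect_warning(empty <- qtl_type_composition(ann_fixture()[0, ]), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("trait composition is restricted to one class and sorted descending", {
  tc <- trait_composition(ann_fixture(), "Milk")
  expect_equal(tc$label, c("tA", "tB"))
  expect_equal(tc$percent, c(200 / 3, 100 / 3))
  single <- trait_composition(ann_fixture(), "Reproduction")
  expect_equal(single$percent, 100)
  expect_error(trait_composition(ann_fixture(), "Exterior"), "available")

  # filtering then composing equals composing the filtered class
  pre <- dplyr::filter(ann_fixture(), qtl_class == "Milk")
  expect_equal(as.data.frame(trait_composition(pre, "Milk")),
               as.data.frame(tc))
})

test_that("composition matches an independent tally on a random fixture", {
  fx <- generate_fixture(fixture_spec(seed = 19, n_qtls = 300))
  db <- as_feature_db(fx$qtls, kind = "qtl")
  ann <- annotate_loci(fx$candidates, db, window = 0)
  comp <- qtl_type_composition(ann)
  manual <- table(fx$qtls$qtl_class[match(unique(ann$qtl_id), fx$qtls$qtl_id)])
  for (i in seq_len(nrow(comp))) {
    expect_equal(comp$count[i], unname(manual[[comp$label[i]]]))
  }
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)
})

test_that("chord data is the unique weighted incidence with exact marginals", {
  ch <- relationship_data(ann_fixture(), "study", "trait_name")
  expect_s3_class(ch, "chord_data")
  expect_true(all(ch$weight > 0))
  # marginals equal per-group row counts
  marg <- tapply(ch$weight, ch$x, sum)
  expect_equal(unname(marg[c("s1", "s2")]),
               unname(table(ann_fixture()$study)[c("s1", "s2")]),
               ignore_attr = TRUE)
  # round-trip: expanding the weights reproduces the (x, y) multiset
  rebuilt <- ch[rep(seq_len(nrow(ch)), ch$weight), c("x", "y")]
  src <- ann_fixture()[, c("study", "trait_name")]
  expect_equal(
    sort(paste(rebuilt$x, rebuilt$y)),
    sort(paste(src$study, src$trait_name))
  )
  expect_error(relationship_data(ann_fixture(), "study", "study"), "different")
})

test_that("traits connected to both groups are exactly the shared ones", {
  # structure of a two-study top-traits chord: only some traits occur under
  # both study labels
  df <- tibble::tibble(
    study = c("feu", "feu", "feu", "buz", "buz"),
    trait = c("inhibin", "scrotal", "kappa_casein", "inhibin", "scrotal")
  )
  ch <- relationship_data(df, "study", "trait")
  shared <- names(which(table(ch$y) == 2))
  expect_setequal(shared, c("inhibin", "scrotal"))
})

test_that("renderers write non-empty image files from their worked examples", {
  dir <- withr::local_tempdir()
  g <- readr::read_csv(toy_worked_examples()$groups, show_col_types = FALSE)
  m <- overlap_among_groups(g, "group", "id")
  counts <- readr::read_tsv(toy_worked_examples()$counts, show_col_types = FALSE)
  e <- enrich_from_counts(counts)
  comp <- qtl_type_composition(ann_fixture())
  ch <- relationship_data(ann_fixture(), "study", "trait_name")

  paths <- c(
    render_plot(plot_overlap(m), file.path(dir, "heat.png")),
    render_plot(plot_enrichment(e, top = 5), file.path(dir, "bubble.png")),
    render_plot(plot_composition(comp, "pie"), file.path(dir, "pie.svg")),
    render_plot(plot_composition(comp, "bar"), file.path(dir, "bar.svg")),
    render_plot(ch, file.path(dir, "chord.svg"))
  )
  expect_true(all(file.exists(paths)))
  expect_true(all(file.size(paths) > 500))
  expect_error(render_plot(plot_overlap(m), file.path(dir, "x.pdf")), "png")

  # SVG output is a pure function of the plot data
  p1 <- file.path(dir, "a.svg"); p2 <- file.path(dir, "b.svg")
  render_plot(plot_composition(comp, "bar"), p1)
  render_plot(plot_composition(comp, "bar"), p2)
  expect_identical(readLines(p1), readLines(p2))
})
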