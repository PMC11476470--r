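demo_regions <- function(n_a, n_b, ext = 10) {
  list(intein_n = sprintf("A:%d-%d", n_a - 4, n_a),
       intein_c = sprintf("B:1-5"),
       extein_n = sprintf("A:1-%d", ext),
       extein_c = sprintf("B:%d-%d", n_b - ext + 1, n_b))
}

test_that("evaluation recovers a planted extein interaction fraction", {
  g <- generate_bundle(40, 40, 0.4, seed = 17)
  # planted fraction applies chain-wide; use whole chains as exteins and
  # sub-spans as intein stand-ins in a separate bundle
  ev <- evaluate_design(g$bundle,
                        list(intein_n = "A:31-40", intein_c = "B:1-10",
                             extein_n = "A:1-30", extein_c = "B:11-40"),
                        name = "planted")
  expect_s3_class(ev, "tbl_df")
  g2 <- generate_bundle(30, 30, 0.4, seed = 18)
  ev2 <- evaluate_design(g2$bundle,
                         list(intein_n = "A:21-30", intein_c = "B:1-10",
                              extein_n = "A:1-20", extein_c = "B:11-30"),
                         name = "whole")
  # whole-chain cross pairs carry the planted fraction exactly
  m <- interface_metrics(g2$bundle, "A:1-30", "B:1-30")
  expect_equal(m$pct_pae_below, 40)
  expect_true(ev2$call %in% c("favorable", "unfavorable"))
})

test_that("absent contact probabilities flow through without crashing", {
  b <- random_bundle(20, 20, seed = 3, with_contact = FALSE)
  ev <- evaluate_design(b, demo_regions(20, 20), name = "nocontact")
  expect_true(is.na(ev$extein_contact_cond))
  expect_false(is.na(ev$extein_pct_pae_below))
})

test_that("superposition RMSD against an isolated intein model is filled", {
  g <- generate_bundle(20, 20, 0.2, seed = 8)
  sp <- generate_structure_pair(30, noise_sigma = 0.1, seed = 9)
  ev <- evaluate_design(g$bundle, demo_regions(20, 20), name = "withrmsd",
                        model = sp$model_a, isolated_intein_model = sp$model_b)
  expect_lt(ev$intein_rmsd, 0.5)
  expect_gte(ev$intein_rmsd, 0)
})

test_that("designs rank by extein interaction with documented tie-breaks", {
  evs <- tibble::tibble(
    design = c("md3", "md1", "md2"),
    intein_plddt = 90, intein_pae = 3, intein_rmsd = NA_real_,
    extein_n_pairs = 100L,
    extein_pct_pae_below = c(1.12, 40.74, 12.12),
    extein_mean_pae = 20,
    extein_contact_cond = c(0.000625, 0.00473, 0.00238),
    call_cutoff = 10, call = c("unfavorable", "favorable", "favorable"))
  ranked <- rank_designs(evs)
  expect_equal(ranked$design, c("md1", "md2", "md3"))
  expect_equal(ranked$rank, 1:3)
  # single design
  expect_equal(rank_designs(evs[1, ])$rank, 1L)
  # tie on pct: higher conditional contact first, then name
  tie <- evs
  tie$extein_pct_pae_below <- 10
  tie$extein_contact_cond <- c(0.1, 0.3, 0.1)
  ranked_tie <- rank_designs(tie)
  expect_equal(ranked_tie$design[1], "md1")
  expect_equal(ranked_tie$design[2:3], c("md2", "md3"))
  # ranking invariant to input order
  perm <- rank_designs(evs[c(2, 3, 1), ])
  expect_equal(perm$design, ranked$design)
})

test_that("reports round-trip through TSV and are reproducible", {
  g1 <- generate_bundle(15, 15, 0.4, seed = 1)
  g2 <- generate_bundle(15, 15, 0.05, seed = 2)
  evs <- dplyr::bind_rows(
    evaluate_design(g1$bundle, demo_regions(15, 15, 5), name = "hi"),
    evaluate_design(g2$bundle, demo_regions(15, 15, 5), name = "lo"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  render_report(evs, d1, bundles = list(hi = g1$bundle, lo = g2$bundle))
  render_report(evs, d2, bundles = list(hi = g1$bundle, lo = g2$bundle))
  tsv <- readr::read_tsv(file.path(d1, "evaluations.tsv"),
                         show_col_types = FALSE)
  ranked <- rank_designs(evs)
  expect_equal(tsv$design, ranked$design)
  expect_equal(tsv$extein_pct_pae_below, ranked$extein_pct_pae_below)
  # bit-stable across runs with identical inputs
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_true(file.exists(file.path(d1, "report.md")))
  bands <- readr::read_tsv(file.path(d1, "hi_plddt_bands.tsv"),
                           show_col_types = FALSE)
  expect_equal(sum(bands$n), 30)
})
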