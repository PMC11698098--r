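test_that("extraction correction applies the EF% formula above the 1% floor", {
  expect_equal(correct_extraction(5.0, 100)$conc_media, 5.0)
  expect_true(correct_extraction(5.0, 100)$corrected)
  expect_equal(correct_extraction(2.0, 50)$conc_media, 4.0)
  ## EF% <= 1 stays uncorrected and flagged
  low <- correct_extraction(2.0, 0.5)
  expect_equal(low$conc_media, 2.0)
  expect_false(low$corrected)
  at_one <- correct_extraction(3.0, 1)
  expect_false(at_one$corrected)
  expect_equal(at_one$conc_media, 3.0)
})

test_that("the hypothetical 100x display scales only uncorrectable compounds", {
  out <- correct_extraction(c(2.0, 2.0), c(0.5, 50), hypothetical_100x = TRUE)
  expect_equal(out$conc_media, c(200, 4))
  expect_equal(out$corrected, c(FALSE, TRUE))
  expect_equal(out$hypothetical, c(TRUE, FALSE))
  ## the factor at the EF% = 1 boundary is exactly 100
  expect_identical(extraction_correction_factor(1), 100)
})

test_that("extraction correction validates its inputs", {
  expect_error(correct_extraction(-1, 50), "conc_extract")
  expect_error(correct_extraction(1, 101), "ef_percent")
  expect_error(correct_extraction(1, -5), "ef_percent")
})

test_that("correction round-trips: conc_media * EF%/100 recovers the extract", {
  set.seed(42)
  conc <- runif(200, 0, 50)
  ef <- runif(200, 1.0001, 100)
  media <- correct_extraction(conc, ef)$conc_media
  expect_equal(media * ef / 100, conc, tolerance = 1e-12)
})

test_that("base incorporation matches character counting in a synthetic genome", {
  ctx <- strain_context("toy", genome_length = 2e6, gc_fraction = 0.31)
  ## oracle: build a single strand with exactly that composition and count T
  seq <- composition_sequence(2e6, 0.31)
  n_t <- count_base(seq, "T")
  expect_equal(n_t, 690000)
  expect_equal(base_incorporation(ctx, "T", 1), n_t / 6.02214076e23)
  expect_equal(base_incorporation(ctx, "G", 1),
               count_base(seq, "G") / 6.02214076e23)
})

test_that("base incorporation handles degenerate and zero inputs", {
  all_gc <- strain_context("gc", genome_length = 1e6, gc_fraction = 1)
  expect_equal(base_incorporation(all_gc, "T", 1e9), 0)
  ctx <- strain_context("toy", genome_length = 1e6, gc_fraction = 0.4)
  expect_equal(base_incorporation(ctx, "A", 0), 0)
  expect_error(base_incorporation(ctx, "U", 1), "base")
  ## monotone in cells_new
  expect_true(base_incorporation(ctx, "A", 2e9) >
                base_incorporation(ctx, "A", 1e9))
})

test_that("the four bases sum to one genome equivalent per new cell", {
  ctx <- strain_context("toy", genome_length = 1.7e6, gc_fraction = 0.37,
                        chromosomes_per_cell = 1)
  cells <- 3.2e10
  total <- sum(vapply(c("A", "T", "G", "C"), function(b) {
    base_incorporation(ctx, b, cells)
  }, numeric(1)))
  expect_equal(total, ctx$genome_length * cells / 6.02214076e23,
               tolerance = 1e-12)
  ## per-strand convention counts both strands
  total2 <- sum(vapply(c("A", "T", "G", "C"), function(b) {
    base_incorporation(ctx, b, cells, convention = "per-strand")
  }, numeric(1)))
  expect_equal(total2, 2 * total, tolerance = 1e-12)
})

test_that("exudation ratio is a guarded quotient", {
  expect_equal(exudation_ratio(0, 5), 0)
  expect_equal(exudation_ratio(3e-9, 3e-9), 1)
  expect_error(exudation_ratio(1e-9, 0), "undefined")
})

test_that("exudation ratio is invariant to a common culture-volume rescale", {
  ## both pools are amounts: scaling the culture scales both
  ex <- 2.3e-9
  inc <- 7.1e-9
  for (k in c(0.5, 2, 10)) {
    expect_equal(exudation_ratio(k * ex, k * inc), exudation_ratio(ex, inc))
  }
})

test_that("intracellular molarity converts units correctly", {
  ## hand oracle: 1 ng/mL x 1 mL over 1e6 cells = 1 fg/cell = 1e-15 g;
  ## / 135.13 g/mol = 7.4003e-18 mol; / 0.18e-15 L = 0.041113 M
  m <- intracellular_molarity(1, 1, 1e6, 135.13, 0.18)
  expect_equal(m, 1e-15 / 135.13 / (0.18 * 1e-15), tolerance = 1e-12)
  expect_equal(m, 0.0411, tolerance = 1e-3)
  expect_equal(intracellular_molarity(0, 1, 1e6, 135.13, 0.18), 0)
  ## doubling the cell count halves the molarity
  expect_equal(intracellular_molarity(1, 1, 2e6, 135.13, 0.18), m / 2)
  expect_error(intracellular_molarity(1, 1, 0, 135.13, 0.18), "cells_total")
})

test_that("molarity is dimensionally consistent across unit paths", {
  ## (ng, mL) path vs an explicit (fg, L) path
  conc <- 2.7; vol <- 1.5; cells <- 3e6; mw <- 151.13; cv <- 0.28
  m1 <- intracellular_molarity(conc, vol, cells, mw, cv)
  fg_total <- conc * 1e6 * vol        # ng/mL * mL -> fg
  g_per_cell <- fg_total / cells * 1e-15
  m2 <- g_per_cell / mw / (cv * 1e-15)
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("cell volumes scale by relative dry mass", {
  expect_equal(round(scale_cell_volume(0.2, 66, 60), 2), 0.18)
  expect_equal(round(scale_cell_volume(0.2, 66, 91), 2), 0.28)
  expect_equal(scale_cell_volume(0.44, 158, 158), 0.44)
  expect_error(scale_cell_volume(0.2, 0, 60), "ref_mass")
})

test_that("replicate summaries propagate detection states as missing", {
  meas <- data.frame(
    compound = rep(c("thymidine", "adenine"), each = 3),
    replicate_id = rep(c("r1", "r2", "r3"), 2),
    conc_extract = c(10, 12, 14, 5, 0, 0),
    ef_percent = rep(c(9, 0.6), each = 3),
    detected = c("quantified", "quantified", "quantified",
                 "detected", "nd", "nd")
  )
  s <- summarize_replicates(meas)
  thy <- s[s$compound == "thymidine", ]
  ade <- s[s$compound == "adenine", ]
  expect_equal(thy$mean_conc_extract, 12)
  expect_equal(thy$sd_conc_extract, 2)
  expect_equal(thy$status, "quantified")
  ## "detected"/"nd" never enter as zeros
  expect_true(is.na(ade$mean_conc_extract))
  expect_equal(ade$n_quantified, 0)
  expect_equal(ade$status, "detected")
})

test_that("the budget wrapper recovers planted exudation ratios at zero noise", {
  ctx <- strain_context("MIT9301", genome_length = 1641879,
                        gc_fraction = 0.313, culture_volume = 200,
                        cell_volume = 0.18)
  gm <- gen_metabolites(seed = 11, ctx = ctx, cells_new = 2.8e10,
                        noise_cv = 0)
  b <- exudation_budget(gm$measurements, ctx, 2.8e10,
                        default_compounds()[c("compound", "molar_mass",
                                              "base")])
  b <- b[order(b$compound), ]
  truth <- gm$truth[order(gm$truth$compound), ]
  ## EF% > 1 compounds: correction inverts the planted extraction exactly
  corr <- b$corrected
  expect_equal(b$exudation_ratio[corr], truth$true_ratio[corr],
               tolerance = 1e-10)
  ## EF% < 1 compounds stay uncorrected, so their ratio is scaled by EF%/100
  ef <- default_compounds()$ef_percent[order(default_compounds()$compound)]
  expect_equal(b$exudation_ratio[!corr],
               truth$true_ratio[!corr] * ef[!corr] / 100, tolerance = 1e-10)
})
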