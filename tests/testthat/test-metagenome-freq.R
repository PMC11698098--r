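test_that("genome frequency is gene density over the core median density", {
  s <- toy_sample(gene_count = 50, gene_length = 500,
                  ribo_count = 50, ribo_length = 500)
  expect_equal(unname(genome_frequency(s, "geneA")), 1.0)
  s2 <- toy_sample(gene_count = 25, gene_length = 500,
                   ribo_count = 50, ribo_length = 500)
  expect_equal(unname(genome_frequency(s2, "geneA")), 0.5)
})

test_that("genome frequency is exactly depth-invariant and linear in counts", {
  set.seed(5)
  rn <- sprintf("r%02d", 1:14)
  s <- sample_gene_counts(
    "s", "st", 10,
    counts = c(geneA = 37, geneB = 120),
    hmm_lengths = c(geneA = 410, geneB = 233),
    ribo_counts = stats::setNames(rpois(14, 80), rn),
    ribo_lengths = stats::setNames(sample(90:280, 14), rn)
  )
  f1 <- genome_frequency(s)
  ## common integer rescale of every count leaves frequencies unchanged
  ## (to machine rounding)
  s7 <- s
  s7$counts <- s$counts * 7L
  s7$ribo_counts <- s$ribo_counts * 7L
  expect_equal(genome_frequency(s7), f1, tolerance = 1e-14)
  ## linear in the focal gene count with cores fixed
  s3 <- s
  s3$counts["geneA"] <- s$counts[["geneA"]] * 3
  expect_equal(unname(genome_frequency(s3, "geneA")),
               3 * unname(f1["geneA"]), tolerance = 1e-12)
})

test_that("the 14-core median is the midpoint of the central order statistics", {
  rn <- sprintf("r%02d", 1:14)
  ## densities 1..14 (counts = density * length); median must be 7.5
  lens <- stats::setNames(rep(100, 14), rn)
  s <- sample_gene_counts(
    "s", "st", 10, counts = c(geneA = 750), hmm_lengths = c(geneA = 100),
    ribo_counts = stats::setNames((1:14) * 100, rn), ribo_lengths = lens
  )
  expect_equal(unname(genome_frequency(s, "geneA")), 7.5 / 7.5)
  ## raw-core-median compatibility switch uses raw counts
  expect_equal(unname(genome_frequency(s, "geneA", raw_core_median = TRUE)),
               7.5 / 750)
})

test_that("degenerate cores degrade gracefully", {
  rn <- sprintf("r%02d", 1:14)
  s <- sample_gene_counts(
    "s", "st", 10, counts = c(geneA = 10), hmm_lengths = c(geneA = 100),
    ribo_counts = stats::setNames(rep(0, 14), rn),
    ribo_lengths = stats::setNames(rep(100, 14), rn)
  )
  expect_warning(f <- genome_frequency(s, "geneA"), "zero")
  expect_true(is.nan(f[["geneA"]]))
  ## fewer than 14 ribosomal proteins flags degraded confidence
  expect_warning(
    s13 <- sample_gene_counts(
      "s", "st", 10, counts = c(geneA = 10), hmm_lengths = c(geneA = 100),
      ribo_counts = stats::setNames(rep(5, 13), rn[1:13]),
      ribo_lengths = stats::setNames(rep(100, 13), rn[1:13])
    ), "14 expected")
  expect_true(s13$degraded)
})

test_that("surface aggregation averages the upper water column per station", {
  ft <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    station_id = c("st1", "st1", "st1", "st2"),
    depth = c(5, 50, 120, 130),
    gene = "geneA",
    frequency = c(0.2, 0.4, 0.9, 0.5)
  )
  expect_message(sa <- surface_aggregate(ft), "st2")
  expect_equal(sa$frequency, 0.3)
  expect_equal(sa$n_samples, 2)
  ## single qualifying sample stands for itself
  one <- surface_aggregate(ft[ft$sample_id == "a", ])
  expect_equal(one$frequency, 0.2)
  ## permutation invariance w.r.t. sample order
  perm <- suppressMessages(surface_aggregate(ft[c(3, 1, 4, 2), ]))
  expect_equal(perm, sa)
})

test_that("spearman correlation matches a hand-built average-rank oracle", {
  expect_equal(spearman_env(1:8, (1:8)^3), 1.0)
  expect_equal(spearman_env(1:8, -(1:8)^3), -1.0)
  x <- c(1, 2, 2, 3)
  y <- c(10, 20, 20, 40)
  expect_equal(spearman_env(x, y), spearman_oracle(x, y), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:20) {
    xi <- sample(1:6, 12, replace = TRUE)   # heavy ties
    yi <- sample(1:6, 12, replace = TRUE)
    if (sd(xi) == 0 || sd(yi) == 0) next
    expect_equal(spearman_env(xi, yi), spearman_oracle(xi, yi),
                 tolerance = 1e-12)
  }
})

test_that("spearman correlation guards small and degenerate inputs", {
  expect_warning(r <- spearman_env(c(1, 2), c(3, 4)), "fewer than 3")
  expect_true(is.nan(r))
  expect_warning(r2 <- spearman_env(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_true(is.nan(r2))
  ## missing env values drop pairwise
  expect_equal(spearman_env(c(1, 2, 3, 4), c(10, NA, 30, 40)), 1.0)
})

test_that("correlation grouping joins linked genes and isolates constants", {
  set.seed(9)
  base1 <- rnorm(30)
  base2 <- rnorm(30)
  m <- cbind(
    a1 = base1 + rnorm(30, 0, 0.1),
    a2 = base1 + rnorm(30, 0, 0.1),
    b1 = base2 + rnorm(30, 0, 0.1),
    b2 = base2 + rnorm(30, 0, 0.1),
    flat = rep(2, 30)
  )
  expect_message(grp <- group_by_correlation(m, threshold = 0.7), "flat")
  g_of <- stats::setNames(grp$group, grp$gene)
  expect_equal(g_of[["a1"]], g_of[["a2"]])
  expect_equal(g_of[["b1"]], g_of[["b2"]])
  expect_true(g_of[["a1"]] != g_of[["b1"]])
  expect_true(!g_of[["flat"]] %in% g_of[c("a1", "b1")])
  ## identical columns always share a group; anticorrelated never do
  m2 <- cbind(x = base1, y = base1, z = -base1)
  grp2 <- group_by_correlation(m2)
  g2 <- stats::setNames(grp2$group, grp2$gene)
  expect_equal(g2[["x"]], g2[["y"]])
  expect_true(g2[["z"]] != g2[["x"]])
})

test_that("curated overrides can merge a gene into another gene's group", {
  set.seed(10)
  b1 <- rnorm(40)
  b2 <- rnorm(40)
  m <- cbind(n1 = b1, n2 = b1 + rnorm(40, 0, 0.2), lone = b2)
  grp <- group_by_correlation(m, threshold = 0.7,
                              overrides = c(lone = "n1"))
  g <- stats::setNames(grp$group, grp$gene)
  expect_equal(g[["lone"]], g[["n1"]])
  expect_warning(group_by_correlation(m, overrides = c(ghost = "n1")),
                 "unknown gene")
})

test_that("frequency tables carry station, depth, and environment columns", {
  mg <- gen_metagenome(seed = 21, n_stations = 4, samples_per_station = 2)
  ft <- frequency_table(mg$samples)
  expect_setequal(unique(ft$gene), names(sar11_transect_model()(0)))
  expect_true(all(c("nitrogen_umol_kg", "depth", "station_id") %in%
                    names(ft)))
  expect_equal(nrow(ft), 8 * length(unique(ft$gene)))
  expect_true(all(ft$frequency >= 0))
})
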