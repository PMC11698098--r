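test_that("quality filter implements the completeness - 5x contamination rule", {
  g <- toy_genomes(matrix(1, 4, 1, dimnames = list(NULL, "geneA")),
                   completeness = c(70, 100, 30, 50),
                   contamination = c(9, 0, 0, 4.0001))
  kept <- quality_filter(g)
  ## score 25 excluded; 100 retained; exactly 30 retained (strict < excludes);
  ## 29.9995 excluded
  expect_equal(kept$genome_id, c("g02", "g03"))
  ## idempotent and order-preserving
  expect_identical(quality_filter(kept), kept)
})

test_that("gene frequencies are percentages with absent-means-absent semantics", {
  pres <- matrix(c(rep(1, 7), rep(0, 3)), ncol = 1,
                 dimnames = list(NULL, "geneA"))
  g <- toy_genomes(pres)
  expect_equal(unname(gene_frequency(g, "geneA")), 70)
  ## a gene with no column counts as absent everywhere
  expect_equal(unname(gene_frequency(g, "never_seen")), 0)
  expect_error(gene_frequency(g[0, ], "geneA"), "empty")
})

test_that("frequency of a union is the count-weighted mean of the parts", {
  set.seed(7)
  pres <- matrix(rbinom(30, 1, 0.4), ncol = 1,
                 dimnames = list(NULL, "geneA"))
  g <- toy_genomes(pres)
  a <- g[1:12, ]
  b <- g[13:30, ]
  fu <- unname(gene_frequency(g, "geneA"))
  fa <- unname(gene_frequency(a, "geneA"))
  fb <- unname(gene_frequency(b, "geneA"))
  expect_equal(fu, (12 * fa + 18 * fb) / 30, tolerance = 1e-12)
})

test_that("universality classification matches the completeness heuristic", {
  expect_equal(classify_universality(72, 72), "near-universal")
  expect_equal(classify_universality(3, 72), "subgroup")
  expect_equal(classify_universality(0, 72), "absent")
  ## monotone: raising the frequency never moves away from near-universal
  ranks <- c(absent = 0, subgroup = 1, `near-universal` = 2)
  cls <- ranks[classify_universality(seq(0, 100, by = 0.5), 72)]
  expect_true(all(diff(cls) >= 0))
})

test_that("completeness-corrected frequency estimates the planted truth", {
  gg <- gen_genomes(n = 186, seed = 301,
                    gene_freqs = c(gene_hi = 0.9, gene_lo = 0.2))
  est <- corrected_frequency(gg$genomes)
  expect_equal(unname(est["gene_hi"]), 0.9, tolerance = 0.12)
  expect_equal(unname(est["gene_lo"]), 0.2, tolerance = 0.12)
})

test_that("clade breakdown recovers planted clade-specific traits", {
  catalog <- trait_catalog(list(catab = c("gx", "gy"), transport = "gz"))
  ## dropout-free: clade X carries gx+gy, clade Y only gz
  pres <- rbind(matrix(rep(c(1, 1, 0), each = 5), ncol = 3),
                matrix(rep(c(0, 0, 1), each = 5), ncol = 3))
  colnames(pres) <- c("gx", "gy", "gz")
  g <- toy_genomes(pres, clade = rep(c("X", "Y"), each = 5))
  bd <- clade_breakdown(g, catalog)
  get <- function(cl, nm, un) {
    bd$frequency[bd$clade == cl & bd$name == nm & bd$unit == un]
  }
  expect_equal(get("X", "gx", "gene"), 100)
  expect_equal(get("Y", "gx", "gene"), 0)
  expect_equal(get("X", "catab", "category"), 100)
  expect_equal(get("Y", "transport", "category"), 100)
  ## single-clade input equals whole-set frequencies
  solo <- clade_breakdown(g[1:5, ], catalog)
  expect_equal(solo$frequency[solo$name == "gx" & solo$unit == "gene"],
               unname(gene_frequency(g[1:5, ], "gx")))
})

test_that("category aggregation modes differ as mean vs operon intersection", {
  catalog <- trait_catalog(list(operon = c("g1", "g2")))
  pres <- cbind(g1 = c(1, 1, 0, 0), g2 = c(1, 0, 1, 0))
  g <- toy_genomes(pres)
  bd_mean <- clade_breakdown(g, catalog, aggregate = "mean")
  bd_int <- clade_breakdown(g, catalog, aggregate = "intersection")
  expect_equal(bd_mean$frequency[bd_mean$unit == "category"], 50)
  expect_equal(bd_int$frequency[bd_int$unit == "category"], 25)
})

test_that("clade breakdown omits unlabeled genomes with a notice", {
  pres <- matrix(1, 3, 1, dimnames = list(NULL, "geneA"))
  g <- toy_genomes(pres, clade = c("X", "unknown", "X"))
  expect_message(bd <- clade_breakdown(
    g, trait_catalog(list(cat = "geneA"))), "omitted")
  expect_equal(unique(bd$clade), "X")
  expect_equal(unique(bd$n_genomes), 2)
})

test_that("phylometabolic matrix follows tree leaf order and reports mismatches", {
  pres <- cbind(ga = c(1, 0, 1), gb = c(0, 1, 1))
  g <- toy_genomes(pres)  # ids g01, g02, g03
  ## no tree: input order preserved
  m0 <- phylometabolic_matrix(g)
  expect_equal(rownames(m0), c("g01", "g02", "g03"))
  expect_equal(unname(m0[, "ga"]), c(1, 0, 1))
  ## shuffled star tree dictates the row order
  tree <- ape::read.tree(text = "(g03,g01,g02);")
  m1 <- phylometabolic_matrix(g, tree = tree)
  expect_equal(rownames(m1), c("g03", "g01", "g02"))
  expect_equal(unname(m1["g03", ]), unname(m0["g03", ]))
  ## mismatches are reported, not silently dropped
  tree2 <- ape::read.tree(text = "(g01,g02,g99);")
  m2 <- phylometabolic_matrix(g, tree = tree2)
  rep2 <- attr(m2, "report")
  expect_equal(rep2$tips_without_genome, "g99")
  expect_equal(rep2$genomes_not_in_tree, "g03")
  expect_false("g03" %in% rownames(m2))
})

test_that("phylometabolic matrix groups columns by catalog category", {
  catalog <- trait_catalog(list(first = "gb", second = "ga"))
  pres <- cbind(ga = c(1, 0), gb = c(0, 1))
  m <- phylometabolic_matrix(toy_genomes(pres), catalog = catalog)
  expect_equal(colnames(m), c("gb", "ga"))
  expect_equal(unname(attr(m, "category")), c("first", "second"))
})

test_that("trait catalogs validate and round-trip through JSON", {
  expect_error(trait_catalog(list(empty = character())), "at least one")
  cat1 <- sar11_trait_catalog()
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(categories = cat1$categories,
                            transporters = cat1$transporters), path)
  cat2 <- read_trait_catalog(path)
  expect_equal(cat2$categories, cat1$categories)
  expect_equal(sort(cat2$transporters), sort(cat1$transporters))
})
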