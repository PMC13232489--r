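mkRec <- function(gene, tags, pos, year, allele = NA, source = "literature") {
  data.frame(gene_id = gene, gene_name = gene, allele = allele,
             tags = I(list(tags)), positions = I(list(pos)),
             source = source, year = year, reference = "")
}

test_that("deduplication keeps the earliest representative allele", {
  recs <- rbind(mkRec("geneX", "GFP", "C", 2021, "a2"),
                mkRec("geneX", "GFP", "C", 2018, "a1"),
                mkRec("geneX", "mNG", "C", 2020, "a3"))
  d <- dedupAlleles(recs)
  expect_equal(nrow(d), 2L)
  expect_equal(d$year[vapply(d$tags, `[`, "", 1L) == "GFP"], 2018)
  # different tag kept
  expect_true("mNG" %in% unlist(d$tags))

  # identical records including year: one kept, deterministically
  recs2 <- rbind(mkRec("g", "GFP", "C", 2020, "b2"),
                 mkRec("g", "GFP", "C", 2020, "b1"))
  d2 <- dedupAlleles(recs2)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$allele, "b1")

  # idempotence
  expect_equal(dedupAlleles(d), d)
})

test_that("source merging classifies alleles and genes by overlap", {
  lit <- rbind(mkRec("g1", "GFP", "C", 2020, "q1"),
               mkRec("g2", "GFP", "C", 2021, "q2"),
               mkRec("g3", "HA", "N", 2019, "q3"))
  cgc <- rbind(mkRec("g3", "HA", "N", NA, "q3", source = "CGC"),
               mkRec("g9", "GFP", "C", NA, "q9", source = "CGC"))
  m <- mergeSources(lit, cgc)
  expect_equal(unname(m$geneOverlap), c(2L, 1L, 1L))
  expect_equal(unname(m$alleleOverlap["both"]), 1L)
  expect_equal(nrow(m$records), 4L)   # shared designation collapsed

  # record without designation: matched by gene+tag+position fallback
  lit2 <- mkRec("g1", "GFP", "C", 2020)
  cgc2 <- mkRec("g1", "GFP", "C", NA, source = "CGC")
  m2 <- mergeSources(lit2, cgc2)
  expect_equal(unname(m2$alleleOverlap["both"]), 1L)

  # empty CGC list: everything literature-only
  m3 <- mergeSources(lit, lit[0, ])
  expect_equal(unname(m3$geneOverlap), c(3L, 0L, 0L))
})

test_that("inventory summaries recover constructed distributions", {
  recs <- do.call(rbind, c(
    lapply(1:7, function(i) mkRec(paste0("s", i), "GFP", "C", 2020,
                                  paste0("a", i))),
    lapply(1:2, function(i) rbind(
      mkRec(paste0("d", i), "GFP", "C", 2020, paste0("b", i)),
      mkRec(paste0("d", i), "mNG", "N", 2021, paste0("c", i)))),
    list(rbind(mkRec("t1", "GFP", "C", 2020, "e1"),
               mkRec("t1", "mNG", "N", 2021, "e2"),
               mkRec("t1", "HA", "internal", 2022, "e3")))))
  s <- summarizeInventory(recs)
  expect_equal(unname(s$allelesPerGene), c(70, 20, 10, 0))
  expect_equal(sum(s$positions), 100, tolerance = 0.11)

  # an allele with tags at two positions lands in "multiple"
  recs2 <- rbind(recs, mkRec("m1", c("GFP", "HA"), c("N", "C"), 2020, "mm"))
  s2 <- summarizeInventory(recs2)
  expect_equal(unname(s2$positions["multiple"]),
               roundHalfAway(100 / nrow(recs2), 1))

  # empty inventory: empty distributions, no crash
  s0 <- summarizeInventory(recs[0, ])
  expect_length(s0$allelesPerGene, 0L)
})

test_that("category proportions reproduce printed rounding behavior", {
  expect_equal(categoryProportion(25, 29), 86.2)
  expect_equal(categoryProportion(0, 75), 0.0)
  expect_equal(categoryProportion(29, 29), 100.0)
  # halves round away from zero: 1/16 = 6.25%
  expect_equal(categoryProportion(1, 16), 6.3)
  expect_error(categoryProportion(5, 0))
  expect_error(categoryProportion(6, 5))
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  expect_equal(fisherExactP(3, 1, 1, 3), enumFisherP(3, 1, 1, 3))
  expect_equal(fisherExactP(3, 1, 1, 3),
               fisher.test(matrix(c(3, 1, 1, 3), 2))$p.value)
  set.seed(21)
  for (i in 1:40) {
    N <- sample(10:200, 1)
    a <- sample(0:min(20, N - 3), 1)
    b <- sample(0:(N - a - 2), 1)
    c <- sample(0:(N - a - b - 1), 1)
    d <- N - a - b - c
    expect_equal(fisherExactP(a, b, c, d), enumFisherP(a, b, c, d),
                 tolerance = 1e-12, label = paste(a, b, c, d))
    expect_equal(fisherExactP(a, b, c, d),
                 fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the hand-applied step-up formula", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjaminiHochberg(0.2), 0.2)
  expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
  # hand-applied step-up on an unsorted vector
  p <- c(0.30, 0.001, 0.04, 0.02)
  m <- length(p)
  o <- order(p)
  stepup <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(stepup)))
  expect_equal(benjaminiHochberg(p)[o], pmin(q, 1))
})

test_that("enrichment caps infinite odds ratios at +/-7", {
  cats <- data.frame(term_id = c("full", "none", "mid"),
                     t = c(29L, 0L, 30L), n = c(29L, 75L, 100L))
  e <- enrichmentTable(cats, T = 150L, N = 1000L)
  expect_equal(e$log2_or_capped[e$term_id == "full"], 7)
  expect_equal(e$log2_or_capped[e$term_id == "none"], -7)
  mid <- e[e$term_id == "mid", ]
  or <- (30 * ((1000 - 100) - (150 - 30))) / ((100 - 30) * (150 - 30))
  expect_equal(mid$odds_ratio, or)
  expect_equal(mid$log2_or_capped, log2(or))
  expect_true(all(e$log2_or_capped >= -7 & e$log2_or_capped <= 7))
  expect_equal(e$proportion, categoryProportion(cats$t, cats$n))
  expect_error(enrichmentTable(data.frame(term_id = "x", t = 5L, n = 3L),
                               10L, 100L))
})

test_that("accrual fits recover slopes and count genes once", {
  years <- 2015:2024
  newPerYear <- rep(203L, length(years))
  yr <- rep(years, newPerYear)
  n <- length(yr)
  recs <- data.frame(gene_id = paste0("g", seq_len(n)),
                     gene_name = paste0("g", seq_len(n)),
                     allele = paste0("al", seq_len(n)),
                     tags = I(as.list(rep("GFP", n))),
                     positions = I(as.list(rep("C", n))),
                     source = "literature", year = yr, reference = "")
  acc <- cumulativeAccrual(recs)
  fit <- linearAccrualFit(acc)
  expect_equal(fit$slope, 203, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # gene tagged twice counts once, in its earliest year
  recs2 <- rbind(mkRec("gA", "GFP", "C", 2018, "x1"),
                 mkRec("gA", "GFP", "N", 2021, "x2"),
                 mkRec("gB", "GFP", "C", 2019, "x3"))
  acc2 <- cumulativeAccrual(recs2)
  expect_equal(acc2$new_genes[acc2$year == 2018], 1L)
  expect_equal(acc2$new_genes[acc2$year == 2021], 0L)
  expect_equal(max(acc2$cumulative), 2L)

  expect_error(linearAccrualFit(acc2[1, ]))

  # noisy synthetic accrual: slope recovered within 5%
  set.seed(31)
  yrs <- 2014:2025
  cum <- 150 * seq_along(yrs) + rnorm(length(yrs), 0, 5)
  noisy <- data.frame(year = yrs, cumulative = cum)
  fitN <- linearAccrualFit(noisy)
  expect_lt(abs(fitN$slope - 150) / 150, 0.05)
})

test_that("discovery-curve fits recover saturation parameters", {
  n <- seq(25, 2500, by = 25)
  g <- 1700 * (1 - exp(-n / 1050))
  fit <- discoveryCurveFit(n, g)
  expect_equal(fit$gMax, 1700, tolerance = 1e-4)
  expect_equal(fit$tau, 1050, tolerance = 1e-4)
  expect_equal(fit$papersForFraction(0.9), fit$tau * log(10),
               tolerance = 1e-9)

  series <- makeDiscoverySeries(seed = 5L, gMax = 1713, tau = 1052.7,
                                noiseFrac = 0.02)
  fitN <- discoveryCurveFit(series$papers, series$cumulative)
  expect_lt(abs(fitN$gMax - 1713) / 1713, 0.05)
  expect_lt(abs(fitN$tau - 1052.7) / 1052.7, 0.05)
})
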