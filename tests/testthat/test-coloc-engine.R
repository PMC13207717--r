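test_that("log approximate Bayes factor matches hand arithmetic", {
  r <- 0.0225 / (0.0225 + 0.01)
  expect_equal(labf(0.3, 0.1, 0.0225), 0.5 * (log(1 - r) + r * 9))
  # null variant is penalized by the prior mass
  expect_lt(labf(0, 0.1, 0.0225), 0)
  # depends on beta only through z^2
  expect_equal(labf(-0.3, 0.1, 0.0225), labf(0.3, 0.1, 0.0225))
  # increasing in |z| at fixed se and W
  z <- seq(0, 10, by = 0.5)
  expect_true(all(diff(labf(z * 0.1, 0.1, 0.04)) > 0))
})

mk_region <- function(z1, z2, se1 = 0.01, se2 = 0.005, pos = NULL) {
  k <- length(z1)
  ids <- sprintf("v%03d", seq_len(k))
  if (is.null(pos)) pos <- seq_len(k) * 1000
  list(t1 = mk_gwas(ids, beta = z1 * se1, se = se1, pos = pos),
       t2 = mk_gwas(ids, beta = z2 * se2, se = se2, pos = pos,
                    trait_type = "binary"))
}

test_that("coloc posteriors identify null, shared and distinct architectures", {
  # all-null region: PPH0 dominates
  rg <- mk_region(rep(0, 100), rep(0, 100))
  c0 <- coloc_abf(rg$t1, rg$t2)
  expect_gt(c0$pph[["PPH0"]], 0.99)
  expect_equal(sum(c0$pph), 1, tolerance = 1e-9)
  # one strong shared variant among 99 nulls
  z1 <- c(rep(0, 50), 12, rep(0, 49)); z2 <- z1
  c4 <- coloc_abf(mk_region(z1, z2)$t1, mk_region(z1, z2)$t2)
  expect_gt(c4$pph[["PPH4"]], 0.8)
  expect_gt(c4$snp_posteriors[["v051"]], 0.95)
  expect_equal(c4$evidence_tier, "strong")
  # distinct causal variants
  za <- c(12, rep(0, 99)); zb <- c(rep(0, 99), 12)
  c3 <- coloc_abf(mk_region(za, zb)$t1, mk_region(za, zb)$t2)
  expect_gt(c3$pph[["PPH3"]], 0.8)
  expect_equal(names(which.max(c3$pph)), "PPH3")
})

test_that("per-SNP posteriors are a distribution and priors validate", {
  rg <- mk_region(rnorm(50, 0, 2), rnorm(50, 0, 2))
  cr <- coloc_abf(rg$t1, rg$t2)
  expect_equal(sum(cr$snp_posteriors), 1, tolerance = 1e-9)
  expect_true(all(cr$pph >= 0))
  expect_error(coloc_priors(p12 = 0.5), "p12")
  expect_error(coloc_abf(rg$t1[1, , drop = FALSE], rg$t2), "2 shared")
})

test_that("coloc is invariant under consistent allele flips", {
  set.seed(5)
  rg <- mk_region(c(rep(0, 20), 10, rep(0, 9)), c(rep(0, 20), 9, rep(0, 9)))
  flip <- function(tab, ids) {
    d <- as.data.frame(tab)
    i <- d$snp %in% ids
    tmp <- d$ea[i]; d$ea[i] <- d$oa[i]; d$oa[i] <- tmp
    d$beta[i] <- -d$beta[i]; d$eaf[i] <- 1 - d$eaf[i]
    gwas_table(d, attr(tab, "trait_name"), attr(tab, "trait_type"))
  }
  ids <- sample(rg$t1$snp, 10)
  c1 <- coloc_abf(rg$t1, rg$t2)
  c2 <- coloc_abf(flip(rg$t1, ids), flip(rg$t2, ids))
  expect_equal(c2$pph, c1$pph, tolerance = 1e-12)
})

test_that("increasing p12 never decreases PPH4", {
  rg <- mk_region(c(rep(0, 30), 8, rep(0, 9)), c(rep(0, 30), 7, rep(0, 9)))
  pph4 <- vapply(c(1e-6, 1e-5, 1e-4), function(p12)
    coloc_abf(rg$t1, rg$t2,
              priors = coloc_priors(p12 = p12))$pph[["PPH4"]],
    numeric(1))
  expect_true(all(diff(pph4) >= 0))
})

test_that("regions are built around index SNPs with clipping at 1", {
  dos <- sapply(1:3, function(i) rbinom(300, 2, 0.3) + rnorm(300, 0, 1e-6))
  map <- data.frame(snp = c("i1", "i2", "i3"), chr = "7",
                    pos = c(300000, 100000, 5e6), ea = "A", oa = "G")
  panel <- ld_panel(map, dos)
  ex <- mk_gwas(c("i1", "i2", "i3"), beta = 1, se = 0.01, chr = "7",
                pos = map$pos, p = c(1e-9, 1e-9, 0.5))
  rg <- define_regions(ex, panel, p_threshold = 1e-6, flank = 2.5e5)
  expect_equal(nrow(rg), 2L)
  expect_equal(rg$start[rg$index == "i1"], 50000)
  expect_equal(rg$end[rg$index == "i1"], 550000)
  expect_equal(rg$start[rg$index == "i2"], 1)
  expect_equal(rg$end[rg$index == "i2"], 350000)
})

test_that("interval merging honours inclusive-touch and matches the oracle", {
  r <- data.frame(chrom = "1", start = c(1, 100), end = c(100, 200))
  m <- merge_regions(r)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1, 200))
  # disjoint regions unchanged
  r2 <- data.frame(chrom = "1", start = c(1, 300), end = c(100, 400))
  expect_equal(nrow(merge_regions(r2)), 2L)
  set.seed(6)
  for (i in 1:30) {
    k <- sample(2:50, 1)
    start <- sample.int(500, k, replace = TRUE)
    end <- start + sample.int(60, k, replace = TRUE)
    got <- merge_regions(data.frame(chrom = "9", start = start, end = end))
    want <- merge_oracle(start, end)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("merged loci carry member tiers", {
  r <- data.frame(chrom = "1", start = c(1, 50), end = c(100, 150),
                  exposure = c("a", "b"), pph4 = c(0.9, 0.6))
  m <- merge_regions(r)
  expect_equal(m$best_pph4, 0.9)
  expect_equal(m$tier, "strong")
  expect_equal(m$n_members, 2L)
})

test_that("credible sets take the minimal descending prefix", {
  expect_equal(credible_set(c(a = 1)), "a")
  expect_equal(credible_set(c(a = 0.5, b = 0.3, c = 0.15, d = 0.05)),
               c("a", "b", "c"))
  u <- setNames(rep(1 / 100, 100), sprintf("v%03d", 1:100))
  expect_length(credible_set(u), 95L)
  # ties broken by ascending position
  ps <- c(x = 0.5, y = 0.5)
  expect_equal(credible_set(ps, pos = c(200, 100), mass = 0.5), "y")
})

test_that("BED conversion shifts to 0-based half-open", {
  b <- to_bed(data.frame(chrom = "1", start = 100, end = 200))
  expect_equal(b$start, 99)
  expect_equal(b$end, 200)
})
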