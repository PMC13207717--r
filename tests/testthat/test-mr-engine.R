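test_that("Wald ratio and its delta variance match hand arithmetic", {
  wr <- wald_ratio(0.1, 0.01, 0.02, 0.005)
  expect_equal(wr$bxy, 0.2)
  expect_equal(wr$var, 0.04 * (0.01 + 0.0625))  # 0.0029
  # continuity case at bzy = 0
  wr0 <- wald_ratio(0.2, 0.05, 0, 0.03)
  expect_equal(wr0$bxy, 0)
  expect_equal(wr0$var, 0.03^2 / 0.2^2)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.01), "null instrument")
})

test_that("identity-LD GSMR with equal variances degenerates to the mean", {
  b <- c(0.1, 0.2, 0.3, 0.4)
  s <- 0.05
  ins <- mk_instruments(bzx = rep(1, 4), se_zx = 1e-10, bzy = b, se_zy = s)
  g <- gsmr_fit(ins, heidi_p = 0)
  expect_equal(g$bxy, mean(b), tolerance = 1e-9)
  expect_equal(g$se, sqrt(s^2 / 4), tolerance = 1e-9)
})

test_that("IVW reproduces hand-weighted arithmetic and Q behaviour", {
  # two instruments, equal variances, ratios 0.1 and 0.3 -> mean 0.2
  ins <- mk_instruments(c(1, 1), 1e-10, c(0.1, 0.3), c(1, 1))
  expect_equal(ivw_fit(ins)$bxy, 0.2, tolerance = 1e-9)
  # weights (4, 1) via bzx = (2, 1) at equal outcome se
  ins2 <- mk_instruments(c(2, 1), 1e-10, c(0, 0.5), c(1, 1))
  iv <- ivw_fit(ins2)
  expect_equal(iv$bxy, 0.1, tolerance = 1e-9)
  expect_equal(iv$se, 1 / sqrt(5), tolerance = 1e-9)
  # Q = 0 when all ratios are equal
  ins3 <- mk_instruments(c(1, 2, 4), 1e-10, c(0.2, 0.4, 0.8), 0.3)
  expect_equal(ivw_fit(ins3)$Q, 0, tolerance = 1e-12)
})

test_that("identity-LD GSMR equals fixed-effect IVW to numerical precision", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(5:30, 1)
    ins <- mk_instruments(bzx = rnorm(k, 0.08, 0.02), se_zx = runif(k, 5e-4, 2e-3),
                          bzy = rnorm(k, 0.01, 0.01), se_zy = runif(k, 1e-3, 5e-3))
    g <- gsmr_fit(ins, heidi_p = 0)
    iv <- ivw_fit(ins)
    expect_equal(g$bxy, iv$bxy, tolerance = 1e-10)
    expect_equal(g$se, iv$se, tolerance = 1e-10)
  }
})

test_that("HEIDI removes a planted outlier ratio", {
  set.seed(12)
  k <- 10
  bzx <- rnorm(k, 0.1, 0.005)
  bzy <- 0.1 * bzx + rnorm(k, 0, 1e-4)
  bzy[7] <- 1.0 * bzx[7]  # gross pleiotropic ratio, tiny variance
  ins <- mk_instruments(bzx, 1e-3, bzy, 1e-3)
  g <- gsmr_fit(ins, heidi_p = 0.01)
  expect_true("v07" %in% g$removed_by_heidi)
  expect_equal(g$bxy, 0.1, tolerance = 0.02)
})

test_that("insufficient instruments raise the documented errors", {
  ins <- mk_instruments(0.1, 0.01, 0.02, 0.01)
  expect_error(gsmr_fit(ins), "insufficient instruments")
  expect_error(ivw_fit(ins), "insufficient instruments")
  ins2 <- mk_instruments(c(0.1, 0.1), 0.01, c(0.01, 0.01), 0.01)
  expect_error(egger_fit(ins2), "3 instruments")
})

test_that("MR-Egger recovers exact linear data to machine precision", {
  bzx <- c(0.05, 0.08, 0.1, 0.15, 0.2)
  bzy <- 0.05 + 0.2 * bzx
  ins <- mk_instruments(bzx, 0.01, bzy, 0.01)
  eg <- egger_fit(ins)
  expect_equal(eg$bxy, 0.2, tolerance = 1e-12)
  expect_equal(eg$egger_intercept, 0.05, tolerance = 1e-12)
})

test_that("Egger orients instruments to non-negative exposure effects", {
  bzx <- c(0.05, -0.08, 0.1, -0.15, 0.2)
  bzy <- 0.03 + 0.25 * bzx
  bzy[bzx < 0] <- -0.03 + 0.25 * bzx[bzx < 0]  # pleiotropy follows orientation
  ins <- mk_instruments(bzx, 0.01, bzy, 0.01)
  eg <- egger_fit(ins)
  expect_equal(eg$bxy, 0.25, tolerance = 1e-10)
  expect_equal(eg$egger_intercept, 0.03, tolerance = 1e-10)
  expect_error(egger_fit(mk_instruments(c(0.1, 0.1, -0.1), 0.01,
                                        c(0, 0, 0), 0.01)),
               "degenerate design")
})

test_that("Egger intercept test is calibrated absent directional pleiotropy", {
  set.seed(13)
  n_rep <- 2000
  k <- 30
  rej <- logical(n_rep)
  bzx <- seq(0.05, 0.2, length.out = k)
  for (i in seq_len(n_rep)) {
    bzy <- 0.2 * bzx + rnorm(k, 0, 0.01)
    ins <- mk_instruments(bzx, 1e-6, bzy, 0.01)
    rej[i] <- egger_fit(ins)$intercept_p < 0.05
  }
  err <- 2.58 * sqrt(0.05 * 0.95 / n_rep)
  expect_gt(mean(rej), 0.05 - err)
  expect_lt(mean(rej), 0.05 + err)
})

test_that("Egger recovers a planted directional pleiotropy intercept", {
  set.seed(14)
  k <- 50
  n_rep <- 500
  alpha <- 0.05
  ints <- numeric(n_rep)
  bzx <- runif(k, 0.03, 0.2)
  for (i in seq_len(n_rep)) {
    bzy <- alpha + 0.2 * bzx + rnorm(k, 0, 0.02)
    ints[i] <- egger_fit(mk_instruments(bzx, 1e-6, bzy, 0.02))$egger_intercept
  }
  expect_lt(abs(mean(ints) - alpha) / alpha, 0.1)
})

test_that("locus masking removes the inclusive interval only", {
  tab <- mk_gwas(c("a", "b", "c", "d"), beta = 0.1, se = 0.01, chr = "11",
                 pos = c(61067098, 61067099, 62134286, 62134287))
  m <- mask_locus(tab, "11", 61067099, 62134286)
  expect_equal(m$snp, c("a", "d"))
  expect_equal(attr(m, "n_masked"), 2L)
  # interval covering nothing is the identity
  m2 <- mask_locus(tab, "2", 1, 1e9)
  expect_equal(m2$snp, tab$snp)
  expect_equal(attr(m2, "n_masked"), 0L)
})

test_that("BH q-values in run_panel match p.adjust and the step-up oracle", {
  # hand example: p = (.01,.02,.03,.04), m = 4 -> all q = .04
  expect_equal(p.adjust(c(.01, .02, .03, .04), "BH"), rep(.04, 4))
  set.seed(15)
  for (i in 1:40) {
    m <- sample(3:10, 1)
    p <- runif(m)^2
    q <- p.adjust(p, "BH")
    for (alpha in c(0.05, 0.2, 0.5)) {
      got <- which(q <= alpha)
      expect_setequal(got, bh_reject_oracle(p, alpha))
    }
  }
})

test_that("select_instruments applies the minimum-instrument rule", {
  panel <- make_ld_panel(15, 8, 0.8, 800, seed = 21)
  sim <- simulate_gwas_pair(panel, n_causal = 15, h2_exposure = 0.05,
                            bxy_true = 0.1, seed = 22)
  ins <- select_instruments(sim$exposure, sim$outcome, panel, min_snps = 10)
  expect_s3_class(ins, "instrument_set")
  expect_gte(nrow(ins$data), 15)
  # relaxed mode on a sparse exposure
  sim2 <- simulate_gwas_pair(panel, n_causal = 4, h2_exposure = 0.008,
                             bxy_true = 0.1, seed = 23)
  res10 <- select_instruments(sim2$exposure, sim2$outcome, panel, min_snps = 10)
  expect_match(res10, "^skipped")
  res3 <- select_instruments(sim2$exposure, sim2$outcome, panel, min_snps = 3)
  expect_s3_class(res3, "instrument_set")
  # null exposure: no variant passes the threshold
  null_ex <- mk_gwas(panel$map$snp, beta = 0, se = 1, chr = panel$map$chr,
                     pos = panel$map$pos, p = 0.5)
  expect_equal(select_instruments(null_ex, sim$outcome, panel),
               "skipped: 0 instruments")
})

test_that("estimates are invariant under simultaneous allele flips", {
  panel <- make_ld_panel(12, 6, 0.8, 600, seed = 31)
  sim <- simulate_gwas_pair(panel, n_causal = 12, h2_exposure = 0.04,
                            bxy_true = 0.15, seed = 32)
  flip <- function(tab, snps) {
    d <- as.data.frame(tab)
    i <- d$snp %in% snps
    tmp <- d$ea[i]; d$ea[i] <- d$oa[i]; d$oa[i] <- tmp
    d$beta[i] <- -d$beta[i]; d$eaf[i] <- 1 - d$eaf[i]
    gwas_table(d, attr(tab, "trait_name"), attr(tab, "trait_type"))
  }
  flip_snps <- sample(panel$map$snp, 20)
  g0 <- gsmr_fit(select_instruments(sim$exposure, sim$outcome, panel,
                                    min_snps = 3))
  g1 <- gsmr_fit(select_instruments(flip(sim$exposure, flip_snps),
                                    flip(sim$outcome, flip_snps), panel,
                                    min_snps = 3))
  expect_equal(g1$bxy, g0$bxy, tolerance = 1e-10)
  expect_equal(g1$se, g0$se, tolerance = 1e-10)
})

test_that("run_panel reports per-exposure fits with panel-wide FDR", {
  panel <- make_ld_panel(12, 5, 0.8, 500, seed = 41)
  sim <- simulate_mr_panel(panel, bxy = c(a = 0.2, b = 0, c = 0.2, d = 0),
                           n_causal_per_exposure = 3, seed = 42)
  res <- run_panel(sim$exposures, sim$outcome, panel, min_snps = 3)
  expect_s3_class(res, "mr_panel_result")
  expect_equal(nrow(res), 4L)
  expect_equal(res$q_fdr, p.adjust(res$pval, "BH"))
  expect_true(all(c("bxy_ivw", "bxy_egger", "egger_intercept") %in% names(res)))
  # single tested exposure: q equals p
  res1 <- run_panel(sim$exposures["a"], sim$outcome, panel, min_snps = 3)
  expect_equal(res1$q_fdr, res1$pval)
})

test_that("cross-outcome concordance recovers the generator's correlation", {
  # effects share a common causal component: bxy_a = c + u, bxy_b = c + v,
  # with analytic correlation var(c)/(var(c)+var(u)) = 0.8 at 200 exposures
  panel <- make_ld_panel(n_blocks = 600, block_size = 4,
                         within_block_rho = 0.7, n_individuals = 500,
                         seed = 51)
  set.seed(52)
  cmn <- rnorm(200, 0, 0.15)
  bxy_a <- setNames(cmn + rnorm(200, 0, 0.075), paste0("lip", 1:200))
  bxy_b <- setNames(cmn + rnorm(200, 0, 0.075), names(bxy_a))
  sim <- simulate_mr_panel(panel, bxy_a, bxy_b = bxy_b,
                           n_causal_per_exposure = 3, h2_per_exposure = 0.02,
                           seed = 53)
  ra <- run_panel(sim$exposures, sim$outcome, panel, min_snps = 3)
  rb <- run_panel(sim$exposures, sim$outcome_b, panel, min_snps = 3)
  cc <- concordance(ra, rb)
  analytic <- 0.15^2 / (0.15^2 + 0.075^2)
  expect_equal(cc$n_shared, 200L)
  expect_lt(abs(cc$pearson_r - analytic), 0.1)
  expect_gt(cc$direction_agreement, 0.7)
})

test_that("concordance joins on exposure and reports agreement and r", {
  a <- structure(data.frame(exposure = c("x", "y", "z"), bxy = c(1, -2, 3)),
                 class = c("mr_panel_result", "data.frame"))
  b <- a; b$bxy <- a$bxy
  cc <- concordance(a, b)
  expect_equal(cc$n_shared, 3L)
  expect_equal(cc$direction_agreement, 1)
  expect_equal(cc$pearson_r, 1)
  b$bxy <- -a$bxy
  cc2 <- concordance(a, b)
  expect_equal(cc2$direction_agreement, 0)
  expect_equal(cc2$pearson_r, -1)
  expect_error(concordance(a, a[1:2, ]), "fewer than 3")
})
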