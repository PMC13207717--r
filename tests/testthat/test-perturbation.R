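mk_pbmc <- function(n_batches = 2, spc = 2, n_features = 10, effects = NULL,
                    batch_off = 0, noise = 0, seed = 1) {
  set.seed(seed)
  conds <- c("control", "cortisol", "cortisol_ze10", "cortisol_ze25",
             "cortisol_ze50")
  condition <- rep(rep(conds, each = spc), n_batches)
  batch <- rep(paste0("b", seq_len(n_batches)), each = 5 * spc)
  n <- length(condition)
  A <- matrix(20, n, n_features) + matrix(rnorm(n * n_features, 0, noise),
                                          n, n_features)
  A <- A + batch_off * (batch == "b2")
  if (!is.null(effects))
    for (nm in names(effects))
      A[condition == nm, ] <- A[condition == nm, ] +
        rep(effects[[nm]], each = sum(condition == nm))
  lipid_matrix(A, condition, batch,
               paste0("CE(", 14 + seq_len(n_features), ":0)"))
}

test_that("the missingness filter applies the strict >50% rule", {
  m <- mk_pbmc(n_features = 3)
  A <- m$abundances  # 20 samples
  A[1:11, 1] <- NA   # 55% missing -> dropped
  A[1:10, 2] <- NA   # exactly 50% -> retained, imputed to zero
  m2 <- lipid_matrix(A, m$condition, m$batch, m$feature_names)
  f <- filter_and_impute(m2)
  expect_equal(ncol(f$abundances), 2L)
  expect_equal(attr(f, "dropped_features"), m$feature_names[1])
  expect_equal(sum(f$abundances[1:10, 1]), 0)
  expect_false(anyNA(f$abundances))
  # complete matrix is untouched
  f2 <- filter_and_impute(m)
  expect_equal(f2$abundances, m$abundances)
})

test_that("a planted effect is recovered exactly with batch offsets absorbed", {
  eff <- list(cortisol = rep(-3, 10), cortisol_ze10 = rep(-3, 10),
              cortisol_ze25 = rep(-3, 10), cortisol_ze50 = rep(-3, 10))
  m <- mk_pbmc(effects = eff, batch_off = 7, noise = 0)
  d <- differential(m, list(c("cortisol", "control")))
  expect_equal(d$estimate, rep(-3, 10), tolerance = 1e-10)
})

test_that("differential estimates match the normal-equations oracle", {
  set.seed(2)
  m <- mk_pbmc(n_features = 50, noise = 1, batch_off = 3)
  d <- differential(m, list(c("cortisol_ze50", "cortisol")))
  X <- model.matrix(~ factor(m$condition) + factor(m$batch))
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, m$abundances)
  cn <- colnames(X)
  cv <- as.numeric(cn == "factor(m$condition)cortisol_ze50") -
    as.numeric(cn == "factor(m$condition)cortisol")
  est <- drop(t(cv) %*% B)
  resid <- m$abundances - X %*% B
  s2 <- colSums(resid^2) / (nrow(X) - ncol(X))
  se <- sqrt(drop(t(cv) %*% XtXi %*% cv) * s2)
  expect_equal(d$estimate, unname(est), tolerance = 1e-8)
  expect_equal(d$se, unname(se), tolerance = 1e-8)
})

test_that("confounded designs and undersized contrasts raise errors", {
  m <- mk_pbmc()
  # condition nested in batch
  cond <- rep(c("control", "cortisol"), each = 10)
  batch <- rep(c("b1", "b2"), each = 10)
  m2 <- lipid_matrix(m$abundances, cond, batch, m$feature_names)
  expect_error(differential(m2, list(c("cortisol", "control"))), "aliased|confounded")
  expect_error(differential(m, list(c("cortisol", "absent"))), "absent")
})

test_that("differential analysis is equivariant under sample reordering", {
  set.seed(3)
  m <- mk_pbmc(n_features = 8, noise = 1)
  o <- sample.int(nrow(m$abundances))
  m2 <- lipid_matrix(m$abundances[o, ], m$condition[o], m$batch[o],
                     m$feature_names)
  d1 <- differential(m, list(c("cortisol", "control")))
  d2 <- differential(m2, list(c("cortisol", "control")))
  expect_equal(d2$estimate, d1$estimate, tolerance = 1e-10)
  expect_equal(d2$p, d1$p, tolerance = 1e-10)
})

test_that("no q < 0.05 calls arise under the global null", {
  clean <- 0L
  for (i in 1:20) {
    m <- mk_pbmc(n_features = 500, noise = 1, seed = 100 + i)
    d <- differential(m, list(c("cortisol", "control")))
    clean <- clean + (sum(d$q < 0.05) == 0L)
  }
  expect_gte(clean, 19L)
})

test_that("the reversal summary counts planted effects", {
  # 40 features down in cortisol, 25 of them reversed by the extract
  eff_c <- c(rep(-5, 40), rep(0, 60))
  eff_z <- c(rep(5, 25), rep(0, 75))
  m <- mk_pbmc(n_features = 100, noise = 1, seed = 9,
               effects = list(cortisol = eff_c, cortisol_ze10 = eff_c,
                              cortisol_ze25 = eff_c,
                              cortisol_ze50 = eff_c + eff_z))
  d <- differential(m, list(c("cortisol", "control"),
                            c("cortisol_ze50", "cortisol")))
  rs <- reversal_summary(d[d$contrast == "cortisol:control", ],
                         d[d$contrast == "cortisol_ze50:cortisol", ])
  expect_lte(abs(rs$n_down_cortisol - 40), 3)
  expect_lte(abs(rs$n_reversed - 25), 3)
  # disjoint significant sets give zero reversals; all-null gives no downs
  m0 <- mk_pbmc(n_features = 50, noise = 1, seed = 10)
  d0 <- differential(m0, list(c("cortisol", "control"),
                              c("cortisol_ze50", "cortisol")))
  rs0 <- reversal_summary(d0[d0$contrast == "cortisol:control", ],
                          d0[d0$contrast == "cortisol_ze50:cortisol", ])
  expect_lte(rs0$n_down_cortisol, 2)
})

test_that("within-batch shuffling preserves per-batch condition multisets", {
  set.seed(4)
  cond <- rep(c("a", "a", "b", "c"), 3)
  batch <- rep(c("x", "y", "z"), each = 4)
  for (i in 1:25) {
    sh <- lipidmr:::.shuffle_within_batch(cond, batch)
    for (b in unique(batch))
      expect_equal(sort(sh[batch == b]), sort(cond[batch == b]))
  }
})

test_that("the overlap test degenerates correctly and detects planted overlap", {
  eff_c <- c(rep(-6, 12), rep(0, 48))
  m <- mk_pbmc(n_features = 60, noise = 1, seed = 11,
               effects = list(cortisol = eff_c, cortisol_ze10 = eff_c,
                              cortisol_ze25 = eff_c, cortisol_ze50 = eff_c))
  panel_names <- m$feature_names
  # hits disjoint from the panel: overlap 0, p = 1
  r0 <- overlap_permutation(m, c("cortisol", "control"),
                            gsmr_hits = c("TAG 52:3"), panel_names,
                            n_perm = 50, seed = 1)
  expect_equal(r0$observed_overlap, 0L)
  expect_equal(r0$empirical_p, 1)
  # hits = the planted features: small empirical p
  r1 <- overlap_permutation(m, c("cortisol", "control"),
                            gsmr_hits = panel_names[1:12], panel_names,
                            n_perm = 200, seed = 2)
  expect_gte(r1$observed_overlap, 10L)
  expect_lte(r1$empirical_p, 0.05)
  # p lies on the permutation grid
  expect_true(r1$empirical_p %in% ((0:200) / 200))
  # single-condition batch errors
  bad <- lipid_matrix(m$abundances, rep("cortisol", 20),
                      m$batch, m$feature_names)
  expect_error(overlap_permutation(bad, c("cortisol", "control"),
                                   panel_names[1], panel_names,
                                   n_perm = 10, seed = 1),
               "single condition")
})

test_that("permutation results are reproducible for a fixed seed", {
  m <- mk_pbmc(n_features = 20, noise = 1, seed = 12,
               effects = list(cortisol = c(rep(-6, 5), rep(0, 15)),
                              cortisol_ze10 = c(rep(-6, 5), rep(0, 15)),
                              cortisol_ze25 = c(rep(-6, 5), rep(0, 15)),
                              cortisol_ze50 = c(rep(-6, 5), rep(0, 15))))
  r1 <- overlap_permutation(m, c("cortisol", "control"),
                            m$feature_names[1:5], m$feature_names,
                            n_perm = 100, seed = 7)
  r2 <- overlap_permutation(m, c("cortisol", "control"),
                            m$feature_names[1:5], m$feature_names,
                            n_perm = 100, seed = 7)
  expect_identical(r1$perm_overlaps, r2$perm_overlaps)
  expect_identical(r1$empirical_p, r2$empirical_p)
})
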