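test_that("psiPoint matches the length-normalized inclusion ratio", {
  expect_equal(psiPoint(0, 10), 0)
  expect_equal(psiPoint(20, 0), 100)
  expect_equal(psiPoint(20, 10, lI = 2, lS = 1), 50)
  expect_error(psiPoint(0, 0), "undefined")

  # monotone in I, antitone in S, bounded
  set.seed(1)
  I <- sample(0:100, 200, replace = TRUE)
  S <- sample(0:100, 200, replace = TRUE)
  keep <- I + S >= 1
  p <- psiPoint(I[keep], S[keep], 2, 1)
  expect_true(all(p >= 0 & p <= 100))
  expect_true(all(psiPoint(I[keep] + 5, S[keep], 2, 1) >= p))
  expect_true(all(psiPoint(I[keep], S[keep] + 5, 2, 1) <= p))
})

test_that("computePsi applies the coverage floor per replicate", {
  inc <- matrix(c(10L, 12L, 3L), 1, 3)
  skp <- matrix(c(5L, 6L, 2L), 1, 3)
  pe <- PsiExperiment(inc, skp, exampleEventTable(1),
                      data.frame(group = c("control", "control", "case")))
  psi <- SummarizedExperiment::assay(computePsi(pe, 10), "psi")
  expect_equal(unname(psi[1, 1:2]), c(50, 50))  # (10/2)/(10/2+5)
  expect_true(is.na(psi[1, 3]))                 # coverage 5 < 10
})

test_that("permutation test matches exhaustive enumeration and is reproducible", {
  expect_equal(permutationTestPsi(c(50, 50, 50), c(50, 50, 50))$p_value, 1)
  expect_equal(permutationTestPsi(c(50, 50, 50), c(50, 50, 50))$delta_psi, 0)

  # brute-force enumeration oracle over all 20 label assignments
  g1 <- c(10, 11, 12); g2 <- c(90, 91, 92)
  x <- c(g1, g2)
  obs <- abs(mean(g2) - mean(g1))
  cmb <- combn(6, 3)
  stats <- apply(cmb, 2, function(idx)
    abs(mean(x[-idx]) - mean(x[idx])))
  expect_equal(mean(stats >= obs - 1e-9), 2 / 20)
  pt <- permutationTestPsi(g1, g2)
  expect_equal(pt$p_value, 2 / 20)
  expect_equal(pt$method, "exhaustive")
  expect_equal(pt$n_assignments, 20)

  # Monte-Carlo mode is deterministic given the seed
  a <- rnorm(12); b <- rnorm(12) + 1
  p1 <- permutationTestPsi(a, b, n_perm = 500, seed = 9,
                           max_exhaustive = 10)
  p2 <- permutationTestPsi(a, b, n_perm = 500, seed = 9,
                           max_exhaustive = 10)
  expect_identical(p1$p_value, p2$p_value)
  expect_equal(p1$method, "monte-carlo")
  expect_error(permutationTestPsi(1:3, 5), "insufficient")
})

test_that("BH adjustment agrees with an independent step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.5), 0.5)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bhAdjust(p), bh_oracle(p))
  }
})

test_that("dual significance thresholds are strict", {
  df <- data.frame(
    p_value = c(0.2, 0.04, 0.04, 0.04),
    fdr = c(0.09, 0.2, 0.09, 0.09),
    delta_psi = c(12, -11, 10, -10.5))
  out <- callSignificant(df)
  expect_equal(out$sig_primary, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$sig_secondary, c(FALSE, TRUE, FALSE, TRUE))
  # delta exactly at 10 never passes; fdr exactly at 0.1 never passes
  out2 <- callSignificant(data.frame(p_value = 0.01, fdr = 0.1,
                                     delta_psi = 50))
  expect_false(out2$sig_primary)
})

test_that("composition and direction summaries do the arithmetic", {
  res <- data.frame(event_type = rep(c("SE", "RI", "MXE", "A5SS", "A3SS"),
                                     c(6, 1, 1, 1, 1)))
  comp <- eventTypeComposition(res)
  expect_equal(comp$percent[comp$event_type == "SE"], 60)
  expect_equal(sum(comp$percent), 100)
  empty <- eventTypeComposition(res[0, , drop = FALSE])
  expect_equal(sum(empty$count), 0)
  expect_equal(sum(empty$percent), 0)

  ds <- directionSummary(c(20, 30, -25))
  expect_equal(ds$pct_inclusion, 100 * 2 / 3)
  expect_equal(ds$mean_abs_dpsi_inclusion, 25)
  expect_equal(ds$max_abs_dpsi_inclusion, 30)
  expect_equal(ds$mean_abs_dpsi_exclusion, 25)
  expect_equal(ds$max_abs_dpsi_exclusion, 25)
  expect_equal(ds$pct_inclusion + ds$pct_exclusion, 100)

  all_pos <- directionSummary(c(15, 22))
  expect_true(is.na(all_pos$mean_abs_dpsi_exclusion))
  expect_equal(directionSummary(numeric())$n, 0)
})

test_that("differential splicing recovers large shifts and keeps untested events out of the FDR", {
  cfg <- simConfig(n_events = 300, n_datasets = 1, n_replicates = 4,
                   coverage = 200, affected_fraction = 0.5,
                   effect_size = 30, seed = 101)
  sim <- simulateStudy(cfg)
  res <- diffSplicing(sim$datasets[[1]], seed = 1)
  truth <- sim$truth
  aff <- truth$affected[match(res$event_id, truth$event_id)]
  detect <- mean(res$sig_primary[aff & res$tested])
  expect_gt(detect, 0.8)
  # false positives under the primary rule stay rare
  expect_lt(mean(res$sig_primary[!aff & res$tested]), 0.02)
  expect_true(all(is.na(res$fdr[!res$tested])))
  # delta consistency
  ok <- res$tested
  expect_equal(res$delta_psi[ok],
               res$mean_psi_g2[ok] - res$mean_psi_g1[ok])
})
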