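test_that("config validation rejects inconsistent parameters", {
  expect_error(simConfig(event_type_fractions = c(SE = 0.5, RI = 0.1,
                                                  MXE = 0.1, A5SS = 0.1,
                                                  A3SS = 0.1)), "sum to 1")
  expect_error(simConfig(kappa = 0), "kappa")
  expect_error(simConfig(affected_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simConfig(n_replicates = 1), "replicates")
  expect_error(simulateStudy(simConfig(n_events = 10)), "seed")
})

test_that("simulation is bit-identical given the seed, per dataset", {
  cfg <- simConfig(n_events = 60, n_datasets = 2, seed = 77,
                   treatment = TRUE)
  s1 <- simulateStudy(cfg); s2 <- simulateStudy(cfg)
  for (d in names(s1$datasets)) {
    expect_identical(inclusionCounts(s1$datasets[[d]]),
                     inclusionCounts(s2$datasets[[d]]))
    expect_identical(skippingCounts(s1$datasets[[d]]),
                     skippingCounts(s2$datasets[[d]]))
  }
  expect_identical(s1$truth, s2$truth)
})

test_that("realized event-type composition tracks the configured fractions", {
  cfg <- simConfig(n_events = 1000, n_datasets = 1, seed = 19)
  sim <- simulateStudy(cfg)
  nse <- sum(sim$events$event_type == "SE")
  expect_lt(abs(nse - 600), 3 * sqrt(1000 * 0.6 * 0.4))
  comp <- eventTypeComposition(sim$events)
  expect_gt(comp$percent[comp$event_type == "SE"], 50)
})

test_that("treated-arm truth interpolates the control-disease gap", {
  cfg <- simConfig(n_events = 40, n_datasets = 1, affected_fraction = 1,
                   effect_size = 30, treatment = TRUE,
                   rescue_fraction = 0.8, seed = 23)
  tr <- simulateStudy(cfg)$truth
  expect_equal(tr$mu_treated,
               tr$mu_case + 0.8 * (tr$mu_control - tr$mu_case),
               tolerance = 1e-12)
})

test_that("sharing structure matches the configured shared probability", {
  cfg <- simConfig(n_events = 1500, n_datasets = 3,
                   affected_fraction = 0.4, shared_prob = 0.6, seed = 29)
  sim <- simulateStudy(cfg)
  aff <- sim$events$affected
  p_shared <- mean(sim$events$shared[aff])
  expect_lt(abs(p_shared - 0.6), 3 * sqrt(0.6 * 0.4 / sum(aff)))
  # per-dataset truth: shared events affected everywhere,
  # specific events in exactly one dataset
  hits <- tapply(sim$truth$affected, sim$truth$event_id, sum)
  ek <- sim$events
  expect_true(all(hits[ek$event_id[ek$shared]] == 3))
  spec <- ek$affected & !ek$shared
  expect_true(all(hits[ek$event_id[spec]] == 1))
  expect_true(all(hits[ek$event_id[!ek$affected]] == 0))
})

test_that("null simulation is calibrated for a discrete permutation test", {
  # With 4v4 replicates the exhaustive test has 70 assignments whose
  # |mean difference| is complement-paired, so the smallest attainable
  # p is 2/70 and P(p < 0.05) under the null is 1/35, not 0.05.
  cfg <- simConfig(n_events = 800, n_datasets = 1, n_replicates = 4,
                   coverage = 200, affected_fraction = 0, seed = 37)
  sim <- simulateStudy(cfg)
  res <- diffSplicing(sim$datasets[[1]], seed = 2)
  rate <- mean(res$p_value[res$tested] < 0.05)
  n <- sum(res$tested)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n))  # never anti-conservative
  expect_lt(abs(rate - 1 / 35), 3 * sqrt((1 / 35) * (34 / 35) / n))
  expect_lte(mean(res$sig_primary[res$tested]), 0.02)
})

test_that("detection rate rises with the simulated effect size", {
  rates <- vapply(c(10, 20, 30), function(es) {
    cfg <- simConfig(n_events = 300, n_datasets = 1, n_replicates = 4,
                     coverage = 200, affected_fraction = 0.5,
                     effect_size = es, seed = 43)
    sim <- simulateStudy(cfg)
    res <- diffSplicing(sim$datasets[[1]], seed = 3)
    truth <- sim$truth
    aff <- truth$affected[match(res$event_id, truth$event_id)]
    mean(res$sig_secondary[aff & res$tested])
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("rescue-arm recovery: strongly rescued events are classified rescued", {
  cfg <- simConfig(n_events = 250, n_datasets = 1, n_replicates = 4,
                   coverage = 200, affected_fraction = 1,
                   effect_size = 25, treatment = TRUE,
                   rescue_fraction = 0.8, seed = 53)
  sim <- simulateStudy(cfg)
  pe <- computePsi(sim$datasets[[1]])
  psi <- SummarizedExperiment::assay(pe, "psi")
  g <- as.character(SummarizedExperiment::colData(pe)$group)
  mns <- function(cond) rowMeans(psi[, g == cond, drop = FALSE],
                                 na.rm = TRUE)
  ctrl <- mns("control"); dis <- mns("case"); tr <- mns("treated")
  gap_ok <- abs(ctrl - dis) >= 20 & ctrl != dis
  calls <- classifyRescue(ctrl[gap_ok], dis[gap_ok], tr[gap_ok])
  expect_gte(mean(calls$category == "rescued"), 0.9)
})
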