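test_that("discriminating sites: substitutions and gap runs", {
  s <- findDiscriminatingSites("ACGTACGT", "ACGAACGA")
  expect_equal(nrow(s), 2L)
  expect_equal(s$pos_a, c(3L, 7L))
  expect_equal(s$base_a, c("T", "T"))
  expect_equal(s$base_b, c("A", "A"))
  expect_true(all(s$kind == "sub"))

  expect_equal(nrow(findDiscriminatingSites("ACGT", "ACGT")), 0L)

  # one 6-base insertion in allele B -> exactly one site
  a <- "ACGT------ACGT"
  b <- "ACGTAAAAAAACGT"
  s2 <- findDiscriminatingSites(a, b)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$kind, "indel")
  expect_equal(s2$pos_a, 4L)  # anchors at the next base of the gapped allele
  expect_equal(s2$pos_b, 4L)

  expect_error(findDiscriminatingSites("ACGT", "ACG"), "equal")
})

test_that("window validation follows the fully-inside-span rule", {
  pair <- make_sub_pair(len = 300, step = 10)
  ref <- buildAlleleReference(pair$a, pair$b, read_length = 50)
  v <- validateReference(ref)
  expect_true(v$valid)
  expect_true(window_oracle_valid(pair$positions0, 50, 3))

  # sparse sites: a 50-bp window between distant sites sees too few
  sparse <- make_sub_pair(len = 500, step = 190)  # sites ~5,195,385
  ref2 <- buildAlleleReference(sparse$a, sparse$b, read_length = 50)
  v2 <- validateReference(ref2)
  expect_false(v2$valid)
  expect_false(window_oracle_valid(sparse$positions0, 50, 3))
  # leftmost violating start agrees with the sliding oracle
  pos <- sparse$positions0
  first_bad <- min(Filter(function(s)
    sum(pos >= s & pos <= s + 49) < 3, min(pos):(max(pos) - 49)))
  expect_equal(v2$window_start, first_bad)

  # span shorter than the read: trivially valid (no window fits inside)
  av <- strsplit(paste(rep("ACGT", 75), collapse = ""), "")[[1]]
  bv <- av
  for (p0 in c(100, 110, 120))
    bv[p0 + 1] <- setdiff(c("A", "C", "G", "T"), av[p0 + 1])[1]
  tight <- buildAlleleReference(paste(av, collapse = ""),
                                paste(bv, collapse = ""),
                                read_length = 50)
  expect_equal(discriminatingSites(tight)$pos_a, c(100L, 110L, 120L))
  expect_true(validateReference(tight)$valid)
  ref0 <- buildAlleleReference(sparse$a, sparse$b, read_length = 50,
                               min_sites = 0)
  expect_true(validateReference(ref0)$valid)
})

test_that("read assignment needs enough covered sites and full consistency", {
  pair <- make_sub_pair(len = 300, step = 10)
  ref <- buildAlleleReference(pair$a, pair$b, read_length = 50)
  # error-free read from allele A covering many sites
  readA <- substring(pair$a, 101, 150)
  expect_equal(as.character(assignReads(readA, 100, ref)), "allele_a")
  readB <- substring(pair$b, 101, 150)
  expect_equal(as.character(assignReads(readB, 100, ref)), "allele_b")

  # a short read covering fewer than three sites is ambiguous
  short <- substring(pair$a, 101, 115)
  expect_equal(as.character(assignReads(short, 100, ref)), "ambiguous")

  # chimeric read (A bases at one covered site, B at the rest) is unassigned
  sites <- discriminatingSites(ref)
  cov <- which(sites$pos_a >= 100 & sites$pos_a <= 149)
  chim <- strsplit(readB, "")[[1]]
  chim[sites$pos_a[cov[1]] - 100 + 1] <- sites$cmp_a[cov[1]]
  expect_equal(as.character(assignReads(paste(chim, collapse = ""),
                                        100, ref)), "unassigned")
  expect_error(assignReads(readA, 299, ref), "out of range")
})

test_that("error-free simulated reads are fully and safely assigned", {
  pair <- make_sub_pair(len = 400, step = 12)
  ref <- buildAlleleReference(pair$a, pair$b, read_length = 60)
  expect_true(validateReference(ref)$valid)
  rd <- simulateAlleleReads(ref, depth = 300, error_rate = 0, seed = 5)
  asn <- assignReads(rd$read, rd$offset, ref)
  expect_equal(mean(as.character(asn) == rd$true_allele), 1)

  # safety: no read covering < min_sites informative sites is assigned
  sites <- discriminatingSites(ref)
  ncov <- vapply(rd$offset, function(s)
    sum(sites$pos_a >= s & sites$pos_a <= s + 59), integer(1))
  expect_true(all(as.character(asn)[ncov < 3] %in%
                    c("ambiguous", "unassigned")))
  expect_true(all(!(as.character(asn) %in% c("allele_a", "allele_b")) |
                    ncov >= 3))

  # determinism and Poisson depth tolerance
  rd2 <- simulateAlleleReads(ref, depth = 300, error_rate = 0, seed = 5)
  expect_identical(rd, rd2)
  counts <- table(rd$true_allele)
  expect_true(all(abs(counts - 300) <= 3 * sqrt(300)))
})

test_that("low-rate sequencing errors cause few misassignments", {
  pair <- make_sub_pair(len = 400, step = 12)
  ref <- buildAlleleReference(pair$a, pair$b, read_length = 60)
  e <- 0.01
  rd <- simulateAlleleReads(ref, depth = 500, error_rate = e, seed = 17)
  asn <- as.character(assignReads(rd$read, rd$offset, ref))
  assigned <- asn %in% c("allele_a", "allele_b")
  mis <- mean(asn[assigned] != rd$true_allele[assigned])
  # flipping an assignment needs >= 3 simultaneous site errors hitting
  # the other allele's bases: bounded by C(6,3) e^3 (a read covers <= 6
  # sites here), checked loosely at 3 MC standard errors
  bound <- choose(6, 3) * e^3
  n <- sum(assigned)
  expect_lte(mis, bound + 3 * sqrt(max(bound * (1 - bound), 1e-8) / n) + 1e-4)
})

test_that("TPM, reductions, fold changes and ddCt do the arithmetic", {
  expect_equal(unname(tpmQuantify(c(A = 10, B = 30), c(100, 100))),
               c(250000, 750000))
  expect_equal(unname(tpmQuantify(c(A = 7), 50)), 1e6)
  set.seed(2)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    cts <- rpois(k, 100) + 1; lens <- runif(k, 200, 2000)
    tpm <- tpmQuantify(cts, lens)
    expect_equal(sum(tpm), 1e6, tolerance = 1e-9)
    # ratios invariant to uniform count scaling
    expect_equal(tpmQuantify(cts * 7, lens) / tpm, rep(1, k))
  }
  expect_error(tpmQuantify(c(0, 0), c(1, 1)), "zero")

  expect_equal(relativeReduction(40.84, 18.77), 54.04016, tolerance = 1e-6)
  expect_equal(relativeReduction(24.99, 17.19), 31.21248, tolerance = 1e-6)
  expect_equal(relativeReduction(5, 5), 0)
  expect_error(relativeReduction(0, 1), "> 0")

  expect_equal(log2FoldChange(20, 40), -1)
  expect_equal(log2FoldChange(40, 40), 0)
  expect_equal(log2FoldChange(18.77, 40.84), log2(18.77 / 40.84))
  expect_error(log2FoldChange(-1, 2), "> 0")

  expect_equal(deltaDeltaCt(25, 20, 24, 20), 0.5)
  expect_equal(deltaDeltaCt(20, 20, 20, 20), 1)
  expect_equal(deltaDeltaCt(23, 20, 24, 20), 2)
  expect_error(deltaDeltaCt(Inf, 1, 1, 1), "finite")
})
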