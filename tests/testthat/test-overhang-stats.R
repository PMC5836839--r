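test_that("joint overhang table counts exactly", {
  pairs <- data.frame(basal = c(2, 2, 1), apical = c(2, 2, 3))
  jt <- jointOverhangTable(pairs)
  expect_identical(jt$n_total, 3L)
  expect_identical(jt$counts["2", "2"], 2L)
  expect_identical(jt$counts["1", "3"], 1L)
  empty <- jointOverhangTable(data.frame(basal = numeric(0),
                                         apical = numeric(0)))
  expect_identical(empty$n_total, 0L)
})

test_that("margins of a product-distribution sample match the marginals", {
  set.seed(51)
  q <- c(0.2, 0.7, 0.1)
  n <- 10000
  pairs <- data.frame(basal = sample(1:3, n, TRUE, q),
                      apical = sample(1:3, n, TRUE, q))
  jt <- jointOverhangTable(pairs)
  tol <- 3 * sqrt(q * (1 - q) / n)    # multinomial error
  expect_true(all(abs(jt$row_margin / n - q) < tol))
  expect_true(all(abs(jt$col_margin / n - q) < tol))
})

test_that("rank correlation handles monotone extremes and degenerate input", {
  expect_equal(rankCorrelation(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(rankCorrelation(1:3, c(3, 2, 1))$rho, -1)
  expect_error(rankCorrelation(c(1, 1, 1), 1:3), "undefined correlation")
  expect_error(rankCorrelation(1:2, 1:2), "at least 3")
})

test_that("permutation p-value equals exact enumeration for small n", {
  set.seed(52)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    x <- runif(n); y <- runif(n)
    res <- rankCorrelation(x, y, method = "permutation")
    expect_equal(res$p_value, oracleSpearmanExactP(x, y))
  }
})

test_that("rank correlation is antisymmetric under reversing y", {
  set.seed(53)
  x <- runif(20); y <- runif(20)
  expect_equal(rankCorrelation(x, y)$rho, -rankCorrelation(x, -y)$rho)
})

test_that("near-canonical restriction keeps both lengths in {1,2,3}", {
  pairs <- data.frame(basal = c(2, 1, 0, 4), apical = c(2, 3, 2, 2))
  rc <- restrictNearCanonical(pairs)
  expect_identical(nrow(rc$subset), 2L)
  expect_equal(rc$fraction, 0.5)
  allCanon <- data.frame(basal = rep(2, 5), apical = rep(2, 5))
  expect_equal(restrictNearCanonical(allCanon)$fraction, 1)
})

test_that("independence fit recovers an exact product table with zero residual", {
  q <- c(0.25, 0.5, 0.25)
  counts <- 400 * outer(q, q)
  fit <- fitIndependenceModel(counts)
  expect_equal(unname(fit$p_short), 0.25)
  expect_equal(unname(fit$p_long), 0.25)
  expect_equal(unname(fit$obs_over_exp), matrix(1, 3, 3))
  expect_equal(fit$gof$statistic, 0)
  expect_equal(sum(fit$expected), sum(counts))
})

test_that("closed-form ML equals the grid-search oracle on a coupled table", {
  q <- c(0.25, 0.5, 0.25)
  base <- 400 * outer(q, q)
  counts <- base
  counts[1, 1] <- 2 * counts[1, 1]
  counts[3, 3] <- 2 * counts[3, 3]
  counts <- round(counts)
  fit <- fitIndependenceModel(counts)
  oracle <- oracleGridIndependence(counts)
  expect_equal(unname(fit$p_short), unname(oracle["p_short"]),
               tolerance = 2e-4)
  expect_equal(unname(fit$p_long), unname(oracle["p_long"]),
               tolerance = 2e-4)
  # against the generating marginal the doubled cells sit at ratio 2 ...
  exp0 <- sum(counts) * outer(q, q)
  expect_equal(counts[1, 1] / exp0[1, 1], 2, tolerance = 0.15)
  expect_equal(counts[3, 3] / exp0[3, 3], 2, tolerance = 0.15)
  # ... and stay enriched (with off-diagonals depleted) under the refit,
  # whose marginal absorbs part of the diagonal boost
  expect_gt(fit$obs_over_exp[1, 1], 1.3)
  expect_gt(fit$obs_over_exp[3, 3], 1.3)
  expect_lt(fit$obs_over_exp[1, 3], 1)
  expect_lt(fit$obs_over_exp[3, 1], 1)
  # least-squares route lands close to ML here
  ls <- fitIndependenceModel(counts, method = "ls")
  expect_equal(unname(ls$p_short), unname(fit$p_short), tolerance = 0.05)
  # per-site variant exposes two marginals
  ps <- fitIndependenceModel(counts, shared = FALSE)
  expect_length(ps$p_short, 2L)
})

test_that("fitted marginal count ratios follow (1-ps-pl)/pl and /ps", {
  set.seed(54)
  counts <- matrix(rpois(9, 40) + 1, 3, 3)
  fit <- fitIndependenceModel(counts)
  q <- fit$q
  margin <- rowSums(fit$expected)
  expect_equal(margin[["2"]] / margin[["3"]],
               (1 - fit$p_short - fit$p_long) / fit$p_long,
               ignore_attr = TRUE)
  expect_equal(margin[["2"]] / margin[["1"]],
               (1 - fit$p_short - fit$p_long) / fit$p_short,
               ignore_attr = TRUE)
})

test_that("coupled mixture data show diagonal enrichment and positive rho", {
  set.seed(55)
  n <- 10000
  q <- c(0.2, 0.6, 0.2)
  coherent <- runif(n) < 0.2
  basal <- ifelse(coherent, sample(1:3, n, TRUE, q),
                  sample(1:3, n, TRUE, q))
  apical <- ifelse(coherent, basal, sample(1:3, n, TRUE, q))
  pairs <- data.frame(basal = basal, apical = apical)
  fit <- fitIndependenceModel(nearCanonicalCounts(pairs))
  expect_gt(fit$obs_over_exp[1, 1], 1)
  expect_gt(fit$obs_over_exp[3, 3], 1)
  rc <- rankCorrelation(pairs$basal, pairs$apical)
  expect_gt(rc$rho, 0)
  expect_lt(rc$p_value, 0.01)
})

test_that("boundary base frequencies count per offset with edge dropping", {
  set.seed(56)
  # four hairpins, G at the 3p_start position in exactly one
  recs <- lapply(1:4, function(i) {
    p <- parseDotBracket("((((((....))))))..")
    s <- strsplit(seqForPairing(p), "")[[1]]
    s[12] <- if (i == 1) "G" else "A"   # 3' mature start
    HairpinRecord(paste0("hsa-b", i), paste(s, collapse = ""), pairing = p,
                  matures = data.frame(arm = c("five_prime", "three_prime"),
                                       start = c(1L, 12L), end = c(6L, 17L)))
  })
  bf <- boundaryBaseFrequencies(HairpinSet(recs), "3p_start")
  expect_equal(bf$freq["G", "0"], 0.25)
  # offsets beyond the hairpin edge drop out of the denominator
  bf2 <- boundaryBaseFrequencies(HairpinSet(recs), "5p_start",
                                 offsets = c(-1, 0))
  expect_identical(unname(bf2$denominator), c(0L, 4L))
  expect_true(all(is.na(bf2$freq[, "-1"])))
})

test_that("uniform random sequences give ~uniform boundary composition", {
  set.seed(57)
  recs <- lapply(1:2000, function(i) {
    p <- parseDotBracket("............")
    HairpinRecord(paste0("hsa-u", i), seqForPairing(p), pairing = p,
                  matures = data.frame(arm = "five_prime", start = 4L,
                                       end = 9L))
  })
  bf <- boundaryBaseFrequencies(HairpinSet(recs), "5p_start")
  # binomial error around 0.25 at n = 2000
  expect_true(all(abs(bf$freq - 0.25) < 4 * sqrt(0.25 * 0.75 / 2000)))
})
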