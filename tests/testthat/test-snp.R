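test_that("region partition reproduces the interval arithmetic on T1", {
  p <- partitionRegions(toyT1(), flank_width = 10)
  seed <- p[p$region == "seed", ]
  expect_identical(seed$start, c(2L, 30L))
  expect_identical(seed$end, c(8L, 36L))
  pre <- p[p$region == "premirna_excl_mature", ]
  expect_identical(sum(pre$length), 6L)     # [1,50] minus [1,22] u [29,50]
  # regions are disjoint and the first three classes cover the hairpin
  inner <- p[!startsWith(p$region, "flank"), ]
  covered <- unlist(mapply(seq, inner$start, inner$end, SIMPLIFY = FALSE))
  expect_identical(sort(covered), 1:50)
  expect_false(anyDuplicated(covered) > 0)
  # flanks
  expect_identical(p$length[p$region == "flank_upstream"], 10L)
  expect_identical(p$start[p$region == "flank_downstream"], 51L)
})

test_that("flank width 0 and single-mature hairpins partition as stated", {
  p0 <- partitionRegions(toyT1(), flank_width = 0)
  expect_false(any(startsWith(p0$region, "flank")))
  single <- HairpinRecord("hsa-s", strrep("A", 30),
                          structure = strrep(".", 30),
                          matures = data.frame(arm = "five_prime",
                                               start = 3, end = 24))
  ps <- partitionRegions(single, flank_width = 0)
  expect_identical(sum(ps$region == "seed"), 1L)
  expect_error(partitionRegions(
    HairpinRecord("hsa-n", "AAAA", structure = "....")), "no matures")
})

test_that("SNP density follows N*1000/L with pooling", {
  h <- toyT1()
  parts <- regionPartitions(HairpinSet(list(h)), flank_width = 0)
  snps <- data.frame(hairpin_id = "hsa-T1", position = c(3L, 5L),
                     flag = c("common", "rare"))
  # 2 SNPs in the pooled 5p seed of 7 nt: density restricted to one seed
  oneSeed <- list(`hsa-T1` = data.frame(region = "seed", start = 2L,
                                        end = 8L, length = 7L))
  d <- suppressWarnings(snpDensity(snps, oneSeed))
  expect_equal(d$density[d$region == "seed"], 2 * 1000 / 7)
  expect_equal(d$density[d$region == "seed"], 285.71, tolerance = 1e-4)
  # no SNPs -> all densities 0 (where lengths exist)
  d0 <- suppressWarnings(snpDensity(snps[0, ], parts))
  expect_true(all(d0$density[d0$length > 0] == 0))
  # common-only filter drops the rare SNP
  dc <- suppressWarnings(snpDensity(snps, oneSeed, flag_filter = "common_only"))
  expect_equal(dc$n_snp[dc$region == "seed"], 1)
})

test_that("density is additive under splitting regions (pooling invariance)", {
  snps <- data.frame(hairpin_id = c("a", "a", "b"), position = c(2, 9, 3),
                     flag = "common")
  whole <- list(a = data.frame(region = "seed", start = 2L, end = 10L,
                               length = 9L),
                b = data.frame(region = "seed", start = 2L, end = 6L,
                               length = 5L))
  split <- list(a = data.frame(region = "seed", start = c(2L, 6L),
                               end = c(5L, 10L), length = c(4L, 5L)),
                b = whole$b)
  expect_equal(suppressWarnings(snpDensity(snps, whole))$density[1],
               suppressWarnings(snpDensity(snps, split))$density[1])
})

test_that("planted per-region SNP rates are recovered within binomial error", {
  set.seed(61)
  sim <- generateHairpinSet(cohortSpec(n = 400, mirtron_fraction = 0,
                                       disease_fraction = 0, seed = 61))
  rates <- c(seed = 5, mature_excl_seed = 8, premirna_excl_mature = 15,
             flank = 20)
  snps <- generateSnps(sim$hairpins, rates, flank_width = 50, seed = 62)
  parts <- regionPartitions(sim$hairpins, flank_width = 50)
  d <- snpDensity(snps, parts)
  for (reg in names(rates)) {
    row <- if (reg == "flank") d[d$region == "flank_pooled", ]
           else d[d$region == reg, ]
    p <- rates[[reg]] / 1000
    ciHalf <- 1.96 * sqrt(p * (1 - p) / row$length) * 1000
    expect_lt(abs(row$density - rates[[reg]]), ciHalf + 1e-9)
  }
})

test_that("per-sequence SNP occurrence splits by disease and mirtron status", {
  mk <- function(id, tags) HairpinRecord(id, strrep("A", 20),
                                         structure = strrep(".", 20),
                                         tags = tags)
  set <- HairpinSet(list(mk("hsa-A", character(0)),
                         mk("hsa-B", character(0)),
                         mk("hsa-C", "mirtron")))
  snps <- data.frame(hairpin_id = c(rep("hsa-A", 3), "hsa-B", "hsa-C"),
                     position = c(1, 2, 3, 5, 100), flag = "common")
  occ <- snpOccurrenceByDisease(snps, set, disease_ids = "hsa-A")
  get <- function(d, m) occ$mean_snps[occ$disease == d & occ$mirtron == m]
  expect_equal(get(TRUE, FALSE), 3)
  expect_equal(get(FALSE, FALSE), 1)
  expect_equal(get(FALSE, TRUE), 0)   # position 100 is outside the hairpin
  expect_true(is.na(get(TRUE, TRUE)))
  # all SNP-free -> all-zero means
  occ0 <- snpOccurrenceByDisease(snps[0, ], set, disease_ids = "hsa-A")
  expect_true(all(occ0$mean_snps[occ0$n_hairpins > 0] == 0))
})

test_that("opposed disease effects for mirtrons vs non-mirtrons are recovered", {
  set.seed(63)
  sim <- generateHairpinSet(cohortSpec(n = 600, mirtron_fraction = 0.5,
                                       hs_mm_fraction = 1,
                                       disease_fraction = 0.5, seed = 63))
  snps <- generateSnps(sim$hairpins,
                       c(seed = 10, mature_excl_seed = 10,
                         premirna_excl_mature = 10, flank = 10),
                       flank_width = 0, mirtron_multiplier = 1.6,
                       disease_multiplier = c(non_mirtron = 0.4,
                                              mirtron = 2.5),
                       seed = 64)
  occ <- snpOccurrenceByDisease(snps, sim$hairpins,
                                disease_ids = sim$truth$id[sim$truth$disease])
  get <- function(d, m) occ$mean_snps[occ$disease == d & occ$mirtron == m]
  expect_lt(get(TRUE, FALSE), get(FALSE, FALSE))   # canonical: disease-poor
  expect_gt(get(TRUE, TRUE), get(FALSE, TRUE))     # mirtron: inverted
})
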