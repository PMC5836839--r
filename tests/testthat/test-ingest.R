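writeFixtureFiles <- function(dir, records, extraMatureRows = NULL) {
  fa <- file.path(dir, "h.fa"); st <- file.path(dir, "h.str")
  mt <- file.path(dir, "h.mat")
  writeLines(unlist(lapply(records, function(r) c(paste0(">", r$id), r$seq))),
             fa)
  writeLines(vapply(records, function(r) paste(r$id, r$db, sep = "\t"),
                    character(1)), st)
  rows <- do.call(rbind, lapply(records, function(r) r$mat))
  if (!is.null(extraMatureRows)) rows <- rbind(rows, extraMatureRows)
  write.table(rows, mt, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fa = fa, st = st, mt = mt)
}

simpleRec <- function(id, seq = "GGGGGAAAACCCCC",
                      db = "(((((....)))))",
                      m = data.frame(id = id, mature_id = paste0(id, "-5p"),
                                     start = 1, end = 6)) {
  list(id = id, seq = seq, db = db, mat = m)
}

test_that("stated exclusion rules reject records with reasons", {
  dir <- withr_tempdir <- tempfile(); dir.create(dir)
  recs <- list(simpleRec("hsa-a"),
               simpleRec("hsa-b", seq = "GGGGGANAACCCCC"),
               simpleRec("hsa-c"))
  f <- writeFixtureFiles(dir, recs,
    extraMatureRows = data.frame(id = "hsa-c",
                                 mature_id = paste0("hsa-c-x", 1:2),
                                 start = c(8, 11), end = c(9, 12)))
  set <- loadHairpins(f$fa, f$st, f$mt)
  expect_identical(sort(names(set)), "hsa-a")
  ex <- excludedRecords(set)
  expect_setequal(ex$id, c("hsa-b", "hsa-c"))
  expect_match(ex$reason[ex$id == "hsa-b"], "non-canonical nucleotide")
  expect_match(ex$reason[ex$id == "hsa-c"], "more than two matures")
})

test_that("length mismatch and missing structure reject the record", {
  dir <- tempfile(); dir.create(dir)
  recs <- list(simpleRec("hsa-a", db = "(((....)))"),  # too short
               simpleRec("hsa-b"))
  f <- writeFixtureFiles(dir, recs)
  writeLines(paste("hsa-a", "(((....)))", sep = "\t"), f$st)  # b missing
  set <- loadHairpins(f$fa, f$st, f$mt)
  ex <- excludedRecords(set)
  expect_match(ex$reason[ex$id == "hsa-a"], "length mismatch")
  expect_match(ex$reason[ex$id == "hsa-b"], "missing structure")
})

test_that("T/lowercase input is normalised and records round-trip", {
  dir <- tempfile(); dir.create(dir)
  recs <- list(simpleRec("hsa-a", seq = "gggggaaaTTccccc",
                         db = "((((((...))))))",
                         m = data.frame(id = "hsa-a", mature_id = "a-5p",
                                        start = 2, end = 7)))
  f <- writeFixtureFiles(dir, recs)
  set <- loadHairpins(f$fa, f$st, f$mt)
  expect_identical(hairpinSeq(set[["hsa-a"]]), "GGGGGAAAUUCCCCC")
  # round-trip: write then reload yields the identical record
  out <- file.path(dir, c("o.fa", "o.str", "o.mat"))
  writeHairpinFiles(set, out[1], out[2], out[3])
  set2 <- loadHairpins(out[1], out[2], out[3])
  expect_equal(set2[["hsa-a"]], set[["hsa-a"]])
})

test_that("dataset partition is a disjoint cover with orphan reporting", {
  mk <- function(id) HairpinRecord(id, "GGGGAAAACCCC",
                                   structure = "((((....))))")
  set <- HairpinSet(lapply(c("hsa-1", "hsa-x", "mmu-1", "dme-1", "dme-2"),
                           mk))
  part <- partitionDatasets(set, mirtronIds = c("hsa-x", "xxx-absent"))
  expect_identical(vapply(part[1:4], length, integer(1)),
                   c(all_animal = 5L, animal_minus_hs_mm = 2L,
                     hs_mm_non_mirtrons = 2L, hs_mm_mirtrons = 1L))
  expect_identical(part$orphans, "xxx-absent")
  # disjoint cover of hs+mm
  expect_length(intersect(names(part$hs_mm_mirtrons),
                          names(part$hs_mm_non_mirtrons)), 0)
  expect_identical(length(part$hs_mm_mirtrons) +
                     length(part$hs_mm_non_mirtrons), 3L)
  # empty mirtron list
  part0 <- partitionDatasets(set)
  expect_identical(length(part0$hs_mm_mirtrons), 0L)
  # restriction to a subset shrinks every dataset monotonically
  sub <- set[c("hsa-1", "dme-1")]
  psub <- partitionDatasets(sub, mirtronIds = "hsa-x")
  expect_true(all(vapply(psub[1:4], length, integer(1)) <=
                    vapply(part[1:4], length, integer(1))))
})

test_that("auxiliary tables load with malformed rows skipped", {
  dir <- tempfile(); dir.create(dir)
  snp <- file.path(dir, "snp.tsv")
  writeLines(c("hairpin_id\tposition\tmaf\tflag",
               "hsa-1\t5\t0.2\tcommon",
               "hsa-1\tnotanumber\t0.2\tcommon",
               "hsa-2\t-3\t0.001\trare",
               "hsa-2\t7\t0.005\trare"), snp)
  expect_warning(tab <- loadSnpTable(snp), "1 malformed")
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$flag, c("common", "rare", "rare"))

  # flag derived from maf when absent
  writeLines(c("hairpin_id\tposition\tmaf",
               "hsa-1\t5\t0.2", "hsa-1\t6\t0.001"), snp)
  tab <- loadSnpTable(snp)
  expect_identical(tab$flag, c("common", "rare"))

  rates <- file.path(dir, "rates.tsv")
  writeLines(c("position\trate", paste(1:25, runif(25), sep = "\t")), rates)
  expect_length(loadRateTable(rates), 25L)

  ids <- file.path(dir, "ids.txt")
  writeLines(c("hsa-1", "hsa-2", "hsa-1"), ids)
  expect_message(v <- loadIdList(ids), "1 duplicate")
  expect_identical(v, c("hsa-1", "hsa-2"))

  bp <- file.path(dir, "bp.tsv")
  writeLines(c("intron_id\tbp_offset_from_3ss\thairpin_id",
               "i1\t21\thsa-1", "i2\t-4\t", "i3\t30\t"), bp)
  expect_warning(tab <- loadBranchpointTable(bp), "1 malformed")
  expect_identical(tab$intron_id, c("i1", "i3"))

  expect_error(loadAuxTable("nope", snp))
  expect_identical(orphanIds(HairpinSet(), "x"), "x")
})
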