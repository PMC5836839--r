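#' Specification of one synthetic hairpin
#'
#' Describes a stem-loop with designed duplex overhangs. The generated
#' hairpin consists of (5'->3') an unpaired 5' tail, a Watson-Crick stem of
#' `stem_len` base pairs optionally interrupted by internal loops, the
#' terminal loop of `loop_len` unpaired nucleotides, the mirrored 3' stem
#' strand and an unpaired 3' tail. Matures are placed so that
#' [computeOverhangs()] returns exactly
#' `(basal_overhang, apical_overhang)`.
#'
#' @param stem_len Number of stem base pairs.
#' @param loop_len Terminal loop length, nucleotides; the apical overhang
#'   magnitude must not exceed it.
#' @param internal_loops List of `c(pos, size5, size3)` triples: after stem
#'   pair `pos` (counted from the hairpin base), insert `size5` unpaired
#'   nucleotides on the 5' strand and `size3` on the 3' strand.
#' @param basal_overhang,apical_overhang Signed designed overhangs,
#'   nucleotides (positive = 3' overhang).
#' @param tail5,tail3 Extra unpaired tail beyond what the basal overhang
#'   requires.
#' @param seed RNG seed for the sequence.
#' @return A list of class `HairpinSpec`.
#' @export
hairpinSpec <- function(stem_len = 22L, loop_len = 8L,
                        internal_loops = list(),
                        basal_overhang = 2L, apical_overhang = 2L,
                        tail5 = 2L, tail3 = 2L, seed = 1L) {
  spec <- list(stem_len = as.integer(stem_len), loop_len = as.integer(loop_len),
               internal_loops = internal_loops,
               basal_overhang = as.integer(basal_overhang),
               apical_overhang = as.integer(apical_overhang),
               tail5 = as.integer(tail5), tail3 = as.integer(tail3),
               seed = as.integer(seed))
  if (spec$stem_len < 2L) stop("stem_len must be >= 2")
  if (spec$loop_len < 1L) stop("loop_len must be >= 1")
  if (abs(spec$apical_overhang) > spec$loop_len)
    stop("unrealizable spec: |apical_overhang| exceeds loop clearance")
  class(spec) <- "HairpinSpec"
  spec
}

#' Generate a synthetic hairpin with designed overhangs
#'
#' Builds the structure described by a [hairpinSpec()], samples a
#' Watson-Crick-consistent sequence (stems paired, loops/tails uniform) and
#' places the two matures to realise the designed overhang pair:
#' for a non-negative basal overhang the 3' mature extends that many
#' nucleotides beyond the basal closing pair into the 3' tail, for a
#' negative one the 5' mature extends into the 5' tail; the apical overhang
#' analogously extends one mature into the terminal loop. Deterministic
#' under a fixed `spec$seed`.
#'
#' @param spec A `HairpinSpec` (see [hairpinSpec()]).
#' @param id,species Identifier and species prefix of the record.
#' @param tags Tags to attach.
#' @return A [HairpinRecord-class].
#' @export
generateHairpin <- function(spec, id = "syn-hairpin-1", species = NULL,
                            tags = character()) {
  stopifnot(inherits(spec, "HairpinSpec"))
  S <- spec$stem_len
  ob <- spec$basal_overhang; oa <- spec$apical_overhang
  tail5 <- max(0L, -ob) + spec$tail5
  tail3 <- max(0L, ob) + spec$tail3
  bulge <- list()
  for (b in spec$internal_loops) {
    k <- as.integer(b[[1L]])
    if (k < 1L || k >= S) stop("internal loop position outside stem")
    bulge[[as.character(k)]] <- c(as.integer(b[[2L]]), as.integer(b[[3L]]))
  }
  db <- rep(".", tail5)
  for (k in seq_len(S)) {
    db <- c(db, "(")
    bb <- bulge[[as.character(k)]]
    if (!is.null(bb) && bb[1L] > 0L) db <- c(db, rep(".", bb[1L]))
  }
  db <- c(db, rep(".", spec$loop_len))
  for (k in rev(seq_len(S))) {
    bb <- bulge[[as.character(k)]]
    if (!is.null(bb) && bb[2L] > 0L) db <- c(db, rep(".", bb[2L]))
    db <- c(db, ")")
  }
  db <- c(db, rep(".", tail3))
  structure_str <- paste(db, collapse = "")
  pairing <- parseDotBracket(structure_str)
  opens <- which(db == "(")
  a <- opens[1L]; cc <- opens[length(opens)]
  b <- pairing[a]; d <- pairing[cc]
  s5 <- a + min(0L, ob); e3 <- b + max(0L, ob)
  e5 <- cc + max(0L, oa); s3 <- d + min(0L, oa)
  if (e5 >= s3) stop("unrealizable spec: matures would overlap in the loop")
  seq <- withSeed(spec$seed, {
    s <- character(length(pairing))
    unp <- is.na(pairing)
    s[unp] <- randomBases(sum(unp))
    open <- which(!unp & pairing > seq_along(pairing))
    s[open] <- randomBases(length(open))
    s[pairing[open]] <- rnaComplement[s[open]]
    paste(s, collapse = "")
  })
  HairpinRecord(id, seq, pairing = pairing,
                matures = data.frame(arm = c("five_prime", "three_prime"),
                                     start = c(s5, s3), end = c(e5, e3)),
                species = species, tags = tags)
}

#' Default joint overhang distribution of the study conditions
#'
#' An explicit probability table over overhang values -2..4 nt at both
#' sites. The marginal peaks at the canonical 2 nt with the short (1 nt)
#' and long (3 nt) classes depleted 4-fold and 7-fold relative to the
#' canonical class, and roughly two thirds of the mass in the
#' near-canonical block; the (1,1) and (3,3) cells are doubled relative to
#' the independence product and renormalised, emulating the coherent
#' Drosha-Dicer imprecision the analysis is designed to detect.
#'
#' @return A probability matrix with overhang values as dimnames.
#' @export
defaultOverhangJoint <- function() {
  vals <- -2:4
  marg <- c(0.02, 0.04, 0.09, 0.145, 0.55, 0.079, 0.03)
  marg <- marg / sum(marg)
  joint <- outer(marg, marg)
  dimnames(joint) <- list(basal = vals, apical = vals)
  joint["1", "1"] <- 2 * joint["1", "1"]
  joint["3", "3"] <- 2 * joint["3", "3"]
  joint / sum(joint)
}

#' Specification of a synthetic hairpin cohort
#'
#' Defaults describe the study conditions the analysis expects: a joint
#' overhang distribution with depleted short/long classes and a doubled
#' coherent diagonal ([defaultOverhangJoint()]), region-wise SNP rates with
#' the seed < miRNA < pre-miRNA < flank hierarchy for canonical hairpins
#' and elevated, flank-inverted rates for mirtrons, opposite
#' disease-association effects for mirtrons vs non-mirtrons, and mirtron
#' branchpoint offsets peaked at 18-24 nt upstream of the 3' splice site.
#'
#' @param n Number of hairpins.
#' @param overhang_joint Either `list(kind = "independent", p_short, p_long)`
#'   (lengths 1/2/3 nt, shared marginal) or a probability matrix whose
#'   dimnames give the overhang values.
#' @param stem_len_range,loop_len_range Integer ranges sampled per hairpin.
#' @param bulge_prob Probability that a hairpin carries one internal loop
#'   (sizes 1-3 nt per strand, placed mid-stem).
#' @param hs_mm_fraction Fraction of hairpins assigned to human/mouse.
#' @param mirtron_fraction Fraction of the human/mouse hairpins tagged as
#'   mirtrons.
#' @param disease_fraction Fraction of hairpins tagged disease-associated.
#' @param snp_rates Named per-kilobase SNP rates for regions `seed`,
#'   `mature_excl_seed`, `premirna_excl_mature`, `flank`.
#' @param mirtron_snp_multiplier Rate multiplier applied to mirtron
#'   pre-miRNA regions (flanks unchanged, inverting the pre-miRNA/flank
#'   contrast).
#' @param disease_snp_multiplier Named `c(non_mirtron = , mirtron = )` rate
#'   multipliers for disease-tagged hairpins (below 1 for non-mirtrons,
#'   above 1 for mirtrons: the opposed selection regimes).
#' @param common_fraction Fraction of SNPs flagged `common`.
#' @param bp_offsets List with `values` and `prob` describing the mirtron
#'   branchpoint-offset distribution.
#' @param flank_width Flank width (nt) used when SNPs are generated.
#' @param seed Cohort RNG seed.
#' @return A list of class `CohortSpec`.
#' @export
cohortSpec <- function(n = 1000L,
                       overhang_joint = defaultOverhangJoint(),
                       stem_len_range = c(19L, 25L),
                       loop_len_range = c(6L, 12L),
                       bulge_prob = 0.5,
                       hs_mm_fraction = 0.5,
                       mirtron_fraction = 0.16,
                       disease_fraction = 0.3,
                       snp_rates = c(seed = 8, mature_excl_seed = 9,
                                     premirna_excl_mature = 12, flank = 15),
                       mirtron_snp_multiplier = 1.6,
                       disease_snp_multiplier = c(non_mirtron = 0.6,
                                                  mirtron = 1.5),
                       common_fraction = 0.5,
                       bp_offsets = list(values = 10:40,
                                         prob = stats::dnorm(10:40, 21, 4)),
                       flank_width = 200L,
                       seed = 1L) {
  spec <- as.list(environment())
  if (is.list(overhang_joint)) {
    stopifnot(overhang_joint$kind == "independent",
              overhang_joint$p_short >= 0, overhang_joint$p_long >= 0,
              overhang_joint$p_short + overhang_joint$p_long <= 1)
  } else {
    stopifnot(is.matrix(overhang_joint), all(overhang_joint >= 0))
    spec$overhang_joint <- overhang_joint / sum(overhang_joint)
  }
  stopifnot(all(spec$snp_rates >= 0), n >= 0)
  class(spec) <- "CohortSpec"
  spec
}

# draw n (basal, apical) pairs from the cohort's joint distribution
drawOverhangPairs <- function(spec, n) {
  j <- spec$overhang_joint
  if (is.list(j)) {
    q <- c(j$p_short, 1 - j$p_short - j$p_long, j$p_long)
    basal <- sample(1:3, n, replace = TRUE, prob = q)
    apical <- sample(1:3, n, replace = TRUE, prob = q)
  } else {
    bv <- as.integer(rownames(j)); av <- as.integer(colnames(j))
    cell <- sample(length(j), n, replace = TRUE, prob = as.vector(j))
    basal <- bv[(cell - 1L) %% nrow(j) + 1L]
    apical <- av[(cell - 1L) %/% nrow(j) + 1L]
  }
  data.frame(basal = basal, apical = apical)
}

#' Generate a cohort of synthetic hairpins
#'
#' Draws overhang pairs from the cohort's joint distribution, samples stem
#' and loop sizes (rejecting loop sizes the apical overhang cannot fit),
#' assigns species/mirtron/disease labels per the configured fractions and
#' returns the generated hairpins along with the designed truth for
#' recovery tests. One RNG stream per cohort (`spec$seed`); per-record
#' sequence seeds are drawn from that stream.
#'
#' @param spec A `CohortSpec` (see [cohortSpec()]).
#' @return A list: `hairpins` (a [HairpinSet-class]) and `truth` (a
#'   `data.frame` with `id`, `basal`, `apical`, `species`, `mirtron`,
#'   `disease`, `stem_len`, `loop_len`).
#' @export
generateHairpinSet <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$n
  if (n == 0L)
    return(list(hairpins = HairpinSet(),
                truth = data.frame(id = character(0L), basal = integer(0L),
                                   apical = integer(0L),
                                   species = character(0L),
                                   mirtron = logical(0L),
                                   disease = logical(0L))))
  withSeed(spec$seed, {
    pairs <- drawOverhangPairs(spec, n)
    stem <- sample(spec$stem_len_range[1L]:spec$stem_len_range[2L], n,
                   replace = TRUE)
    minLoop <- pmax(spec$loop_len_range[1L], abs(pairs$apical) + 1L)
    loop <- minLoop + vapply(spec$loop_len_range[2L] - minLoop,
      function(w) if (w > 0L) sample.int(w + 1L, 1L) - 1L else 0L,
      integer(1L))
    hsmm <- stats::runif(n) < spec$hs_mm_fraction
    species <- ifelse(hsmm,
                      sample(c("hsa", "mmu"), n, replace = TRUE),
                      sample(c("dme", "cel", "gga", "dre"), n, replace = TRUE))
    mirtron <- hsmm & stats::runif(n) < spec$mirtron_fraction
    disease <- stats::runif(n) < spec$disease_fraction
    seeds <- sample.int(.Machine$integer.max, n)
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      ils <- list()
      if (stats::runif(1L) < spec$bulge_prob) {
        ils <- list(c(sample(3:(stem[i] - 3L), 1L),
                      sample(0:3, 1L), sample(0:3, 1L)))
        if (ils[[1L]][2L] == 0L && ils[[1L]][3L] == 0L) ils <- list()
      }
      id <- sprintf("%s-syn-mir-%04d", species[i], i)
      hs <- hairpinSpec(stem_len = stem[i], loop_len = loop[i],
                        internal_loops = ils,
                        basal_overhang = pairs$basal[i],
                        apical_overhang = pairs$apical[i],
                        seed = seeds[i])
      tags <- character(0L)
      if (mirtron[i]) tags <- c(tags, "mirtron")
      else if (hsmm[i]) tags <- c(tags, "non_mirtron")
      if (disease[i]) tags <- c(tags, "disease")
      recs[[i]] <- generateHairpin(hs, id = id, species = species[i],
                                   tags = tags)
    }
    truth <- data.frame(id = vapply(recs, hairpinId, character(1L)),
                        basal = pairs$basal, apical = pairs$apical,
                        species = species, mirtron = mirtron,
                        disease = disease, stem_len = stem, loop_len = loop,
                        stringsAsFactors = FALSE)
    list(hairpins = HairpinSet(recs), truth = truth)
  })
}

#' Generate a SNP table for a set of hairpins
#'
#' Places SNPs by independent per-position Bernoulli draws with probability
#' `rate / 1000` per region class (region membership from
#' [partitionRegions()]; flank positions use the `flank` rate). Mirtron-
#' and disease-tagged hairpins have their pre-miRNA (non-flank) rates
#' scaled by the configured multipliers.
#'
#' @param set A [HairpinSet-class].
#' @param snp_rates Named per-kb rates (`seed`, `mature_excl_seed`,
#'   `premirna_excl_mature`, `flank`).
#' @param flank_width Flank width, nucleotides.
#' @param common_fraction Probability that a SNP is flagged `common`.
#' @param mirtron_multiplier,disease_multiplier Rate multipliers (see
#'   [cohortSpec()]).
#' @param seed RNG seed.
#' @return A SNP `data.frame` (`hairpin_id`, `position`, `maf`, `flag`).
#' @export
generateSnps <- function(set,
                         snp_rates = c(seed = 8, mature_excl_seed = 9,
                                       premirna_excl_mature = 12, flank = 15),
                         flank_width = 200L, common_fraction = 0.5,
                         mirtron_multiplier = 1,
                         disease_multiplier = c(non_mirtron = 1, mirtron = 1),
                         seed = 1L) {
  recs <- recordList(set)
  withSeed(seed, {
    rows <- list()
    for (r in recs) {
      p <- tryCatch(partitionRegions(r, flank_width), error = function(e) NULL)
      if (is.null(p)) next
      isMir <- "mirtron" %in% hairpinTags(r)
      isDis <- "disease" %in% hairpinTags(r)
      mult <- if (isMir) mirtron_multiplier else 1
      if (isDis)
        mult <- mult * disease_multiplier[[if (isMir) "mirtron" else
                                           "non_mirtron"]]
      for (k in seq_len(nrow(p))) {
        reg <- p$region[k]
        rate <- if (startsWith(reg, "flank")) snp_rates[["flank"]]
                else snp_rates[[reg]] * mult
        prob <- min(1, rate / 1000)
        if (prob <= 0) next
        pos <- p$start[k]:p$end[k]
        hit <- pos[stats::runif(length(pos)) < prob]
        if (length(hit))
          rows[[length(rows) + 1L]] <- data.frame(
            hairpin_id = hairpinId(r), position = hit,
            stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(hairpin_id = character(0L), position = integer(0L))
    common <- stats::runif(nrow(out)) < common_fraction
    out$maf <- ifelse(common, stats::runif(nrow(out), 0.02, 0.5),
                      stats::runif(nrow(out), 0.0001, 0.009))
    out$flag <- ifelse(common, "common", "rare")
    rownames(out) <- NULL
    out
  })
}

#' Generate a branchpoint table for mirtron hairpins
#'
#' Samples a 3'-splice-site offset per hairpin from the given distribution
#' and derives the hairpin position by 3'-coterminality
#' (`bp_position = hairpin_length - offset`). Offsets that would fall
#' before the hairpin start are skipped with a warning.
#'
#' @param set A [HairpinSet-class] of mirtron hairpins.
#' @param offsets List with `values` (nonnegative integers) and optional
#'   `prob` weights.
#' @param seed RNG seed.
#' @return A branchpoint `data.frame` (`intron_id`, `bp_offset_from_3ss`,
#'   `hairpin_id`, `bp_hairpin_position`).
#' @export
generateBranchpoints <- function(set,
                                 offsets = list(values = 10:40,
                                                prob = stats::dnorm(10:40,
                                                                    21, 4)),
                                 seed = 1L) {
  recs <- recordList(set)
  stopifnot(all(offsets$values >= 0L))
  withSeed(seed, {
    rows <- list(); skipped <- 0L
    for (r in recs) {
      off <- if (length(offsets$values) == 1L) offsets$values else
        sample(offsets$values, 1L, prob = offsets$prob)
      n <- nchar(hairpinSeq(r))
      bp <- n - off
      if (bp < 1L) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        intron_id = paste0(hairpinId(r), "-intron"),
        bp_offset_from_3ss = off, hairpin_id = hairpinId(r),
        bp_hairpin_position = bp, stringsAsFactors = FALSE)
    }
    if (skipped)
      warning(skipped, " hairpin(s) shorter than the sampled offset skipped")
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(intron_id = character(0L), bp_offset_from_3ss = integer(0L),
                 hairpin_id = character(0L), bp_hairpin_position = integer(0L))
    rownames(out) <- NULL
    out
  })
}
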