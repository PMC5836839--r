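#' Find the terminal loop of a hairpin
#'
#' The terminal loop is the maximal unpaired interval enclosed by the
#' innermost base pair of the stem that carries the mature annotations.
#' Candidate loops are all intervals `[p+1, q-1]` whose flanking positions
#' `p` and `q` are paired to each other with everything in between
#' single-stranded. With annotated matures the loop closest to the apical
#' side of the duplex (between the two matures, or nearest the single
#' mature's inner end) is chosen; without matures a unique loop is returned
#' as is and an ambiguous multi-stem structure resolves to the loop nearest
#' the hairpin centre.
#'
#' @param hairpin A [HairpinRecord-class].
#' @return Integer vector `c(start, end)` (1-based, inclusive).
#' @export
findTerminalLoop <- function(hairpin) {
  p <- hairpinPairing(hairpin)
  opens <- which(!is.na(p) & p > seq_along(p))
  if (!length(opens)) stop("no stem: hairpin has no base pairs")
  loops <- lapply(opens, function(i) {
    j <- p[i]
    if (j > i + 1L && all(is.na(p[(i + 1L):(j - 1L)]))) c(i + 1L, j - 1L)
    else NULL
  })
  loops <- loops[!vapply(loops, is.null, logical(1L))]
  if (!length(loops)) stop("no terminal loop (no hairpin loop in structure)")
  if (length(loops) == 1L) return(loops[[1L]])
  m <- hairpinMatures(hairpin)
  target <- if (nrow(m) == 2L) {
    o <- order(m$start)
    (m$end[o[1L]] + m$start[o[2L]]) / 2      # between the two matures
  } else if (nrow(m) == 1L) {
    if (m$arm == "five_prime") m$end + 0.5 else m$start - 0.5
  } else (length(p) + 1) / 2
  centers <- vapply(loops, function(l) mean(l), numeric(1L))
  loops[[which.min(abs(centers - target))]]
}

#' Identify the miRNA duplex within a hairpin
#'
#' The duplex is delimited by its basal and apical closing pairs: the
#' outermost and innermost base pairs joining the two mature intervals.
#' With `five_prime` mature `[s5, e5]` and `three_prime` mature `[s3, e3]`,
#' the basal closing pair is `(a, pairing[a])` where `a` is the smallest
#' 5'-mature position whose partner lies in the 3' mature, and the apical
#' closing pair is `(c, pairing[c])` for the largest such position.
#'
#' @param hairpin A [HairpinRecord-class] with two annotated matures.
#' @return A list with elements `five_p`, `three_p` (each `c(start, end)`),
#'   `basal_pair` and `apical_pair` (each `c(pos5, pos3)`).
#' @export
identifyDuplex <- function(hairpin) {
  m <- hairpinMatures(hairpin)
  if (nrow(m) < 2L) stop("duplex undefined: fewer than two matures")
  p <- hairpinPairing(hairpin)
  m5 <- m[m$arm == "five_prime", ]
  m3 <- m[m$arm == "three_prime", ]
  pos5 <- m5$start:m5$end
  partners <- p[pos5]
  joins <- !is.na(partners) & partners >= m3$start & partners <= m3$end
  if (!any(joins)) stop("no duplex closing pair: matures are not paired to each other")
  a <- pos5[which(joins)[1L]]
  cc <- pos5[which(joins)[sum(joins)]]
  list(five_p = c(m5$start, m5$end), three_p = c(m3$start, m3$end),
       basal_pair = c(a, p[a]), apical_pair = c(cc, p[cc]))
}

#' Signed overhang lengths of a miRNA duplex
#'
#' Measures the number of excessive nucleotides beyond the closing pairs of
#' the duplex, regardless of their structural state. Positive values are 3'
#' overhangs (the canonical RNase III product has `(+2, +2)`), negative
#' values are atypical 5' overhangs. The basal overhang sits at the
#' Drosha-processing (or, for mirtrons, splicing) side, the apical overhang
#' at the Dicer side.
#'
#' With basal closing pair `(a, b)`, apical closing pair `(c, d)` and
#' matures `[s5, e5]`, `[s3, e3]`:
#' \deqn{basal = (e3 - b) - (a - s5), \quad apical = (e5 - c) - (d - s3)}
#'
#' The `hanging_end` variant replaces the duplex closing pairs by the
#' outermost/innermost mature positions paired to *any* partner (not
#' necessarily in the partner mature); it is a robustness check of the
#' overhang definition and agrees with `beyond_closing_pair` whenever the
#' relevant terminal mature nucleotides pair within the duplex.
#'
#' @param hairpin A [HairpinRecord-class] with two matures.
#' @param variant `"beyond_closing_pair"` (default) or `"hanging_end"`.
#' @param suspectThreshold Absolute overhang length beyond which the pair is
#'   flagged as a suspect structure (reported, not dropped).
#' @return A list with elements `basal`, `apical` (signed integers),
#'   `variant` and `suspect` (logical).
#' @examples
#' h <- generateHairpin(hairpinSpec(stem_len = 20, loop_len = 8,
#'                                  basal_overhang = 2, apical_overhang = 2,
#'                                  seed = 1))
#' computeOverhangs(h)
#' @export
computeOverhangs <- function(hairpin,
                             variant = c("beyond_closing_pair", "hanging_end"),
                             suspectThreshold = 15L) {
  variant <- match.arg(variant)
  dx <- identifyDuplex(hairpin)
  s5 <- dx$five_p[1L]; e5 <- dx$five_p[2L]
  s3 <- dx$three_p[1L]; e3 <- dx$three_p[2L]
  if (variant == "beyond_closing_pair") {
    a <- dx$basal_pair[1L]; b <- dx$basal_pair[2L]
    cc <- dx$apical_pair[1L]; d <- dx$apical_pair[2L]
  } else {
    p <- hairpinPairing(hairpin)
    p5 <- (s5:e5)[!is.na(p[s5:e5])]
    p3 <- (s3:e3)[!is.na(p[s3:e3])]
    if (!length(p5) || !length(p3))
      stop("no duplex closing pair: a mature has no paired nucleotide")
    a <- min(p5); cc <- max(p5)
    d <- min(p3); b <- max(p3)
  }
  basal <- (e3 - b) - (a - s5)
  apical <- (e5 - cc) - (d - s3)
  list(basal = as.integer(basal), apical = as.integer(apical),
       variant = variant,
       suspect = abs(basal) > suspectThreshold | abs(apical) > suspectThreshold)
}

#' Overhang table for a dataset
#'
#' Applies [computeOverhangs()] to every hairpin in a set, collecting the
#' per-duplex result and the failure reason for hairpins without a duplex.
#'
#' @param set A [HairpinSet-class] (or list of records).
#' @inheritParams computeOverhangs
#' @return A `data.frame` with columns `hairpin_id`, `basal`, `apical`,
#'   `variant`, `suspect`; hairpins without a computable duplex are absent
#'   and listed in the `"skipped"` attribute (`id`, `reason`).
#' @export
overhangTable <- function(set,
                          variant = c("beyond_closing_pair", "hanging_end"),
                          suspectThreshold = 15L) {
  variant <- match.arg(variant)
  recs <- recordList(set)
  rows <- list(); skipped <- list()
  for (r in recs) {
    ov <- tryCatch(computeOverhangs(r, variant, suspectThreshold),
                   error = function(e) conditionMessage(e))
    if (is.character(ov)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        id = hairpinId(r), reason = ov, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        hairpin_id = hairpinId(r), basal = ov$basal, apical = ov$apical,
        variant = ov$variant, suspect = ov$suspect, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hairpin_id = character(0L), basal = integer(0L),
               apical = integer(0L), variant = character(0L),
               suspect = logical(0L))
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(id = character(0L), reason = character(0L))
  out
}
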