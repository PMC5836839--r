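#' Branchpoint offset statistics relative to the 3' splice site
#'
#' Histogram of branchpoint offsets (nucleotides upstream of the intron's
#' last nucleotide; offset 0 = the last intron nucleotide) and the fraction
#' falling in the expected window, computed separately for mirtron-linked
#' records (those carrying a `hairpin_id`) and plain introns.
#'
#' @param records Branchpoint table (see [loadBranchpointTable()]).
#' @param window Closed offset window, default `c(10, 40)`.
#' @return A list with `histogram` (offset counts), `fraction_in_window`,
#'   `n`, and `by_group` (a `data.frame` with per-group fractions for
#'   `mirtron` and `intron` records).
#' @export
bpOffsetStats <- function(records, window = c(10L, 40L)) {
  if (!nrow(records)) stop("no branchpoint records")
  off <- records$bp_offset_from_3ss
  inWin <- off >= window[1L] & off <= window[2L]
  grp <- ifelse(!is.na(records$hairpin_id) & nzchar(records$hairpin_id),
                "mirtron", "intron")
  byGroup <- do.call(rbind, lapply(unique(grp), function(g) {
    sel <- grp == g
    data.frame(group = g, n = sum(sel),
               fraction_in_window = mean(inWin[sel]),
               stringsAsFactors = FALSE)
  }))
  list(histogram = table(offset = off),
       fraction_in_window = mean(inWin),
       n = length(off), window = window, by_group = byGroup)
}

#' Locate a branchpoint within a mirtron hairpin
#'
#' Assigns the branchpoint to a hairpin compartment relative to the
#' terminal loop `[ls, le]`: `five_prime_strand` (position < ls),
#' `terminal_loop` (inside the loop) or `three_prime_strand` (> le). For
#' branchpoints in the 3' strand, `d_loop = bp - le` counts the first
#' nucleotide after the loop as 1. `d_dicer = s3 - bp` is the signed
#' distance to the Dicer cleavage site (the 5' end `s3` of the 3' mature);
#' negative values place the branchpoint inside the miRNA. `d_3end` is the
#' distance to the hairpin 3' end.
#'
#' @param hairpin A [HairpinRecord-class].
#' @param bp_position 1-based branchpoint position within the hairpin.
#' @return A list: `compartment`, `d_loop` (`NA` outside the 3' strand),
#'   `d_dicer` (`NA` without an annotated 3' mature), `d_3end`.
#' @export
locateBranchpoint <- function(hairpin, bp_position) {
  n <- nchar(hairpinSeq(hairpin))
  bp_position <- as.integer(bp_position)
  if (bp_position < 1L || bp_position > n)
    stop("bp_position outside hairpin")
  loop <- findTerminalLoop(hairpin)
  compartment <- if (bp_position < loop[1L]) "five_prime_strand"
    else if (bp_position <= loop[2L]) "terminal_loop"
    else "three_prime_strand"
  dLoop <- if (compartment == "three_prime_strand")
    bp_position - loop[2L] else NA_integer_
  m <- hairpinMatures(hairpin)
  m3 <- m[m$arm == "three_prime", , drop = FALSE]
  dDicer <- if (nrow(m3)) m3$start - bp_position else NA_integer_
  list(compartment = compartment, d_loop = dLoop, d_dicer = dDicer,
       d_3end = n - bp_position)
}

#' Locate branchpoints for a whole branchpoint table
#'
#' Maps each record with a known hairpin to its compartment and distance
#' metrics. When `bp_hairpin_position` is absent the position is derived by
#' 3'-coterminality (`hairpin_length - offset`), the convention for
#' untailed / 5'-tailed mirtrons whose hairpin ends at the 3' splice site.
#'
#' @param records Branchpoint table (see [loadBranchpointTable()]).
#' @param set A [HairpinSet-class] providing the hairpins.
#' @return A `data.frame` with columns `intron_id`, `hairpin_id`,
#'   `bp_position`, `offset`, `compartment`, `d_loop`, `d_dicer`, `d_3end`;
#'   records whose position cannot be resolved are dropped with a warning.
#' @export
locateBranchpoints <- function(records, set) {
  ids <- hairpinId(set)
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(records))) {
    hid <- records$hairpin_id[i]
    if (is.na(hid) || !hid %in% ids) { dropped <- dropped + 1L; next }
    h <- set[[hid]]
    n <- nchar(hairpinSeq(h))
    bp <- records$bp_hairpin_position[i]
    if (is.na(bp)) bp <- n - records$bp_offset_from_3ss[i]
    if (is.na(bp) || bp < 1L || bp > n) { dropped <- dropped + 1L; next }
    loc <- locateBranchpoint(h, bp)
    rows[[length(rows) + 1L]] <- data.frame(
      intron_id = records$intron_id[i], hairpin_id = hid, bp_position = bp,
      offset = records$bp_offset_from_3ss[i], compartment = loc$compartment,
      d_loop = loc$d_loop, d_dicer = loc$d_dicer, d_3end = loc$d_3end,
      stringsAsFactors = FALSE)
  }
  if (dropped)
    warning(dropped, " branchpoint record(s) without a resolvable hairpin ",
            "position dropped")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(intron_id = character(0L), hairpin_id = character(0L),
               bp_position = integer(0L), offset = integer(0L),
               compartment = character(0L), d_loop = integer(0L),
               d_dicer = integer(0L), d_3end = integer(0L))
  rownames(out) <- NULL
  out
}
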