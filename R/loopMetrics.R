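#' Signed distance from a miRNA end to the nearest single-stranded region
#'
#' Implements the loop-counting distance: from the terminal nucleotide `t`
#' of the chosen end, the backbone is scanned in both directions for the
#' nearest unpaired nucleotide. With `u_out` the nearest unpaired position
#' outside the mature the outside distance is `|u_out - t| - 1` (0 when the
#' end sits immediately at a single-stranded boundary); with `u_in` the
#' nearest unpaired position inside the mature the inside distance is
#' `-|u_in - t|` (the number of nucleotides to cut off to reach the loop).
#' The value of smaller magnitude is returned; ties return the outside
#' (positive) distance. The distance is defined only when the terminal
#' nucleotide itself is paired; otherwise `NA` is returned.
#'
#' @param hairpin A [HairpinRecord-class].
#' @param end_kind One of `"5p_start"`, `"5p_end"`, `"3p_start"`,
#'   `"3p_end"`.
#' @return A list with `d` (signed integer or `NA`), `end_kind`, `position`
#'   (the terminal nucleotide), and `reason` (`NA` when defined).
#' @export
endToLoopDistance <- function(hairpin,
                              end_kind = c("5p_start", "5p_end",
                                           "3p_start", "3p_end")) {
  end_kind <- match.arg(end_kind)
  m <- hairpinMatures(hairpin)
  arm <- if (startsWith(end_kind, "5p")) "five_prime" else "three_prime"
  m <- m[m$arm == arm, , drop = FALSE]
  res <- list(d = NA_integer_, end_kind = end_kind, position = NA_integer_,
              reason = NA_character_)
  if (!nrow(m)) { res$reason <- "mature not annotated"; return(res) }
  isStart <- endsWith(end_kind, "start")
  t <- if (isStart) m$start else m$end
  res$position <- t
  p <- hairpinPairing(hairpin)
  if (is.na(p[t])) { res$reason <- "terminal nucleotide unpaired"; return(res) }
  n <- length(p)
  # outside: away from the mature body; inside: into the mature
  outDir <- if (isStart) -1L else 1L
  unp <- which(is.na(p))
  outCand <- unp[sign(unp - t) == outDir]
  inCand <- unp[sign(unp - t) == -outDir]
  dOut <- if (length(outCand)) min(abs(outCand - t)) - 1L else NA_integer_
  dIn <- if (length(inCand)) -min(abs(inCand - t)) else NA_integer_
  if (is.na(dOut) && is.na(dIn)) {
    res$reason <- "no single-stranded nucleotide in either direction"
    return(res)
  }
  res$d <- if (is.na(dIn)) dOut
           else if (is.na(dOut)) dIn
           else if (abs(dOut) <= abs(dIn)) dOut else dIn
  res
}

#' End-to-loop distances for a dataset
#'
#' @param set A [HairpinSet-class] (or list of records).
#' @param end_kinds Which ends to evaluate.
#' @return A `data.frame` with columns `hairpin_id`, `end_kind`, `position`,
#'   `d`, `reason` (one row per record x end kind; undefined distances keep
#'   `NA` in `d` with the reason).
#' @export
endDistanceTable <- function(set, end_kinds = c("5p_start", "5p_end",
                                                "3p_start", "3p_end")) {
  recs <- recordList(set)
  rows <- lapply(recs, function(r) {
    do.call(rbind, lapply(end_kinds, function(k) {
      e <- endToLoopDistance(r, k)
      data.frame(hairpin_id = hairpinId(r), end_kind = k,
                 position = e$position, d = e$d, reason = e$reason,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unpaired nucleotide frequency (UNF) profile
#'
#' For each aligned miRNA position (1 = the mature's 5' end; negative
#' positions are the 5' flank; there is no position 0) the fraction of
#' matures of the requested arm whose hairpin nucleotide at that position is
#' single-stranded. A record enters a position's denominator only when the
#' position exists for it: flank positions must fall inside the hairpin and
#' positive positions must not exceed that mature's length.
#'
#' @param set A [HairpinSet-class] (or list of records).
#' @param arm `"five_prime"` or `"three_prime"`.
#' @param flank_width Number of 5'-flank positions to include (default 10).
#' @return A `data.frame` with columns `position`, `unpaired`,
#'   `denominator`, `unf`.
#' @export
unfProfile <- function(set, arm = c("five_prime", "three_prime"),
                       flank_width = 10L) {
  arm <- match.arg(arm)
  recs <- recordList(set)
  entries <- lapply(recs, function(r) {
    m <- hairpinMatures(r)
    m <- m[m$arm == arm, , drop = FALSE]
    if (!nrow(m)) return(NULL)
    list(p = hairpinPairing(r), start = m$start, len = m$end - m$start + 1L)
  })
  entries <- entries[!vapply(entries, is.null, logical(1L))]
  if (!length(entries)) stop("empty dataset: no matures on the requested arm")
  maxLen <- max(vapply(entries, `[[`, integer(1L), "len"))
  positions <- c(if (flank_width > 0L) seq(-flank_width, -1L), seq_len(maxLen))
  unpaired <- denom <- integer(length(positions))
  for (e in entries) {
    hp <- e$start - 1L + ifelse(positions >= 1L, positions, positions + 1L)
    exists <- hp >= 1L & hp <= length(e$p) &
      (positions < 1L | positions <= e$len)
    denom <- denom + exists
    unpaired <- unpaired + (exists & is.na(e$p[pmax(hp, 1L)]))
  }
  data.frame(position = positions, unpaired = unpaired, denominator = denom,
             unf = ifelse(denom > 0L, unpaired / denom, NA_real_))
}

#' Correlate a UNF profile with per-position substitution rates
#'
#' Spearman rank correlation over the positions shared by the profile and
#' the rate table (see [rankCorrelation()]).
#'
#' @param profile A `data.frame` from [unfProfile()].
#' @param rates Named numeric vector of relative substitution rates, names
#'   being miRNA positions.
#' @param ... Passed to [rankCorrelation()] (e.g. `method`, `seed`).
#' @return A list with the correlation result plus `points`, the paired
#'   (position, unf, rate) table used.
#' @export
correlateUnfSubstitution <- function(profile, rates, ...) {
  pos <- intersect(profile$position, as.integer(names(rates)))
  if (length(pos) < 3L) stop("fewer than 3 shared positions")
  unf <- profile$unf[match(pos, profile$position)]
  rate <- rates[as.character(pos)]
  res <- rankCorrelation(unf, rate, ...)
  res$points <- data.frame(position = pos, unf = unf, rate = unname(rate))
  res
}
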