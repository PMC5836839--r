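#' @import methods
NULL

emptyMatures <- function() {
  data.frame(arm = character(0L), start = integer(0L), end = integer(0L),
             stringsAsFactors = FALSE)
}

#' HairpinRecord: one pre-miRNA hairpin
#'
#' Holds the sequence, the base-pairing table and the hairpin-relative mature
#' miRNA annotations of a single precursor. Coordinates are 1-based and
#' inclusive throughout. The pairing table is a nested involution (element
#' `i` is the partner of position `i`, `NA` when single-stranded).
#'
#' @slot id Hairpin identifier (e.g. `"hsa-mir-123"`).
#' @slot species Three-letter organism prefix parsed from the id.
#' @slot sequence RNA sequence over `A`, `C`, `G`, `U`.
#' @slot pairing Integer pairing table of the same length as the sequence.
#' @slot matures `data.frame` with columns `arm` (`"five_prime"` /
#'   `"three_prime"`), `start`, `end`; 0, 1 or 2 rows.
#' @slot tags Character vector of labels, a subset of
#'   `c("mirtron", "non_mirtron", "robust", "disease")`.
#' @export
setClass("HairpinRecord",
  representation(id = "character", species = "character",
                 sequence = "character", pairing = "integer",
                 matures = "data.frame", tags = "character"))

validHairpinRecord <- function(object) {
  msg <- character(0L)
  n <- nchar(object@sequence)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (!grepl("^[ACGU]*$", object@sequence))
    msg <- c(msg, "sequence contains non-canonical nucleotide")
  if (length(object@pairing) != n)
    msg <- c(msg, "pairing length differs from sequence length")
  else {
    ok <- tryCatch({ checkPairing(object@pairing); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) msg <- c(msg, ok)
  }
  m <- object@matures
  if (!all(c("arm", "start", "end") %in% names(m)))
    msg <- c(msg, "matures must have columns arm, start, end")
  else {
    if (nrow(m) > 2L) msg <- c(msg, "more than two matures")
    if (nrow(m)) {
      if (!all(m$arm %in% c("five_prime", "three_prime")))
        msg <- c(msg, "unknown mature arm")
      if (any(m$start > m$end)) msg <- c(msg, "mature start > end")
      if (any(m$start < 1L) || any(m$end > n))
        msg <- c(msg, "mature outside hairpin")
      if (nrow(m) == 2L) {
        o <- order(m$start)
        if (m$end[o[1L]] >= m$start[o[2L]])
          msg <- c(msg, "matures overlap")
        if (!identical(m$arm[o], c("five_prime", "three_prime")))
          msg <- c(msg, "arm labels inconsistent with mature order")
      }
    }
  }
  bad <- setdiff(object@tags, c("mirtron", "non_mirtron", "robust", "disease"))
  if (length(bad)) msg <- c(msg, paste("unknown tag:", bad[1L]))
  if (length(msg)) msg else TRUE
}
setValidity("HairpinRecord", validHairpinRecord)

#' Construct a HairpinRecord
#'
#' @param id Hairpin identifier; the species prefix is taken from the text
#'   before the first `-` unless `species` is given.
#' @param sequence RNA (or DNA) sequence; lowercase is uppercased and `T`
#'   is converted to `U`.
#' @param structure Dot-bracket string (alternative to `pairing`).
#' @param pairing Integer pairing table (alternative to `structure`).
#' @param matures `data.frame` with columns `start`, `end` and optionally
#'   `arm`; missing arms are assigned from the mature layout (see Details).
#' @param species Three-letter species prefix; parsed from `id` if `NULL`.
#' @param tags Character vector of record labels.
#' @details With two matures the left one is the 5' arm. With a single
#'   mature the arm is `five_prime` when the mature midpoint lies left of
#'   the hairpin midpoint.
#' @return A validated [HairpinRecord-class] object.
#' @examples
#' HairpinRecord("hsa-toy-1", "GGGAAACCC", structure = "(((...)))")
#' @export
HairpinRecord <- function(id, sequence, structure = NULL, pairing = NULL,
                          matures = NULL, species = NULL, tags = character()) {
  sequence <- normalizeRna(sequence)
  if (is.null(pairing)) {
    if (is.null(structure)) stop("supply 'structure' or 'pairing'")
    pairing <- parseDotBracket(structure)
  } else pairing <- as.integer(pairing)
  if (is.null(matures)) matures <- emptyMatures()
  matures <- as.data.frame(matures, stringsAsFactors = FALSE)
  if (nrow(matures)) {
    matures$start <- as.integer(matures$start)
    matures$end <- as.integer(matures$end)
    if (is.null(matures$arm) || anyNA(matures$arm))
      matures$arm <- assignArms(matures, nchar(sequence))
    matures <- matures[order(matures$start), c("arm", "start", "end"),
                       drop = FALSE]
    rownames(matures) <- NULL
  } else matures <- emptyMatures()
  if (is.null(species)) species <- sub("-.*$", "", id)
  new("HairpinRecord", id = id, species = species, sequence = sequence,
      pairing = pairing, matures = matures, tags = unique(tags))
}

# 'T'->'U', uppercase; keeps other characters for downstream validation.
normalizeRna <- function(x) chartr("tT", "uU", toupper(as.character(x)))
# (toupper first, so the lowercase map is moot but harmless)

assignArms <- function(matures, len) {
  if (nrow(matures) == 2L) {
    ifelse(rank(matures$start, ties.method = "first") == 1L,
           "five_prime", "three_prime")
  } else {
    mid <- (matures$start + matures$end) / 2
    ifelse(mid <= (len + 1) / 2, "five_prime", "three_prime")
  }
}

#' HairpinSet: a collection of hairpin records
#'
#' A list-like container of [HairpinRecord-class] objects, keyed by id, with
#' a record of inputs that were rejected during loading and why.
#'
#' @slot records Named list of `HairpinRecord` objects.
#' @slot excluded `data.frame` with columns `id`, `reason`.
#' @export
setClass("HairpinSet",
  representation(records = "list", excluded = "data.frame"))

setValidity("HairpinSet", function(object) {
  if (!all(vapply(object@records, is, logical(1L), "HairpinRecord")))
    return("all records must be HairpinRecord objects")
  ids <- vapply(object@records, function(r) r@id, character(1L))
  if (anyDuplicated(ids)) return("duplicated hairpin ids")
  if (!all(c("id", "reason") %in% names(object@excluded)))
    return("excluded must have columns id, reason")
  TRUE
})

#' @param records List of [HairpinRecord-class] objects.
#' @param excluded Optional `data.frame` (`id`, `reason`) of rejected inputs.
#' @rdname HairpinSet-class
#' @export
HairpinSet <- function(records = list(), excluded = NULL) {
  if (is(records, "HairpinRecord")) records <- list(records)
  if (is.null(excluded))
    excluded <- data.frame(id = character(0L), reason = character(0L),
                           stringsAsFactors = FALSE)
  names(records) <- vapply(records, function(r) r@id, character(1L))
  new("HairpinSet", records = records, excluded = excluded)
}
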