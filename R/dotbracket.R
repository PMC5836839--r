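#' Parse a Vienna dot-bracket string into a pairing table
#'
#' Converts a secondary structure in dot-bracket notation into an integer
#' pairing table: element `i` holds the 1-based partner of position `i`, or
#' `NA` when position `i` is unpaired. Only plain nested structures are
#' representable (`(`, `)`, `.`); pseudoknot alphabets are rejected.
#'
#' @param db A single dot-bracket string over the alphabet `(`, `)`, `.`.
#' @return An integer vector of `nchar(db)` elements; `NA` marks unpaired
#'   positions. The result is a nested involution: `p[p[i]] == i` for every
#'   paired `i` and no two pairs cross.
#' @examples
#' parseDotBracket("(((...)))")
#' @export
parseDotBracket <- function(db) {
  if (!is.character(db) || length(db) != 1L || is.na(db))
    stop("'db' must be a single dot-bracket string")
  chars <- strsplit(db, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad))
    stop("invalid character '", chars[bad[1L]], "' at position ", bad[1L])
  n <- length(chars)
  pairing <- rep(NA_integer_, n)
  stack <- integer(0L)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack))
        stop("unbalanced ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairing[i] <- j
      pairing[j] <- i
    }
  }
  if (length(stack))
    stop("unbalanced at end: '(' at position ", stack[length(stack)],
         " never closed")
  pairing
}

#' Render a pairing table as a dot-bracket string
#'
#' Inverse of [parseDotBracket()]; the pairing must be a nested involution.
#'
#' @param pairing Integer pairing table (`NA` = unpaired).
#' @return A dot-bracket string.
#' @export
pairingToDotBracket <- function(pairing) {
  checkPairing(pairing)
  chars <- rep(".", length(pairing))
  paired <- which(!is.na(pairing))
  chars[paired[pairing[paired] > paired]] <- "("
  chars[paired[pairing[paired] < paired]] <- ")"
  paste(chars, collapse = "")
}

# Validates that `pairing` is a nested involution; returns invisibly or stops.
checkPairing <- function(pairing) {
  if (!is.integer(pairing)) {
    if (is.numeric(pairing) && all(is.na(pairing) | pairing == round(pairing)))
      pairing <- as.integer(pairing)
    else stop("pairing must be an integer vector")
  }
  n <- length(pairing)
  paired <- which(!is.na(pairing))
  if (any(pairing[paired] < 1L | pairing[paired] > n))
    stop("pairing partner out of range")
  if (any(pairing[paired] == paired))
    stop("position paired to itself")
  if (!all(pairing[pairing[paired]] == paired))
    stop("pairing is not an involution")
  # nestedness: closing a pair must match the most recently opened one
  stack <- integer(0L)
  for (i in paired) {
    if (pairing[i] > i) {
      stack <- c(stack, i)
    } else {
      if (!length(stack) || stack[length(stack)] != pairing[i])
        stop("pairing contains crossing pairs (pseudoknot)")
      stack <- stack[-length(stack)]
    }
  }
  invisible(pairing)
}
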