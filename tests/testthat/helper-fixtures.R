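# Toy hairpins used across tests. T1 is a clean 20-bp stem with an 8-nt
# terminal loop and a 2-nt 3' tail; matures [1,22]/[29,50] give the
# canonical (+2,+2) overhangs. T2 has an internal loop so that mature ends
# sit at known distances from single-stranded regions.

seqForPairing <- function(pairing) {
  s <- character(length(pairing))
  unp <- is.na(pairing)
  s[unp] <- sample(c("A", "C", "G", "U"), sum(unp), replace = TRUE)
  open <- which(!unp & pairing > seq_along(pairing))
  s[open] <- sample(c("A", "C", "G", "U"), length(open), replace = TRUE)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  s[pairing[open]] <- comp[s[open]]
  paste(s, collapse = "")
}

toyT1 <- function(five_p = c(1L, 22L), three_p = c(29L, 50L)) {
  db <- paste0(strrep("(", 20), strrep(".", 8), strrep(")", 20), "..")
  p <- parseDotBracket(db)
  m <- if (is.null(five_p) && is.null(three_p)) NULL else
    data.frame(arm = c("five_prime", "three_prime"),
               start = c(five_p[1], three_p[1]),
               end = c(five_p[2], three_p[2]))
  HairpinRecord("hsa-T1", seqForPairing(p), pairing = p, matures = m)
}

toyT2 <- function() {
  p <- parseDotBracket("((((((..((((....))))..))))))..")
  HairpinRecord("hsa-T2", seqForPairing(p), pairing = p,
                matures = data.frame(arm = c("five_prime", "three_prime"),
                                     start = c(1L, 19L), end = c(12L, 30L)))
}

# Random balanced dot-bracket string of length n (may contain multiloops).
randomDotBracket <- function(n, p_open = 0.35, p_dot = 0.3) {
  open <- 0L
  chars <- character(n)
  for (i in seq_len(n)) {
    remaining <- n - i + 1L
    cand <- c(if (open + 1L <= remaining - 1L) "(",
              if (open > 0L) ")",
              if (open <= remaining - 1L) ".")
    w <- c("(" = p_open, ")" = 0.35, "." = p_dot)[cand]
    ch <- sample(cand, 1L, prob = w)
    chars[i] <- ch
    open <- open + (ch == "(") - (ch == ")")
  }
  paste(chars, collapse = "")
}

# Record with random nested structure and random non-overlapping matures.
randomStructuredRecord <- function(n = 60L, id = "syn-rnd") {
  repeat {
    p <- parseDotBracket(randomDotBracket(n))
    if (sum(!is.na(p)) >= 4L) break
  }
  s1 <- sample.int(n - 10L, 1L)
  e1 <- s1 + sample(5:9, 1L)
  s2 <- e1 + 1L + sample(0:4, 1L)
  e2 <- min(n, s2 + sample(5:9, 1L))
  if (s2 >= e2) return(randomStructuredRecord(n, id))
  HairpinRecord(id, seqForPairing(p), pairing = p,
                matures = data.frame(arm = c("five_prime", "three_prime"),
                                     start = c(s1, s2), end = c(e1, e2)))
}
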