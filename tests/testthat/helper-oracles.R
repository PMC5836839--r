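# Independent brute-force oracles used to validate the implementation.

# dot-bracket matcher written as a plain position loop over an explicit
# character vector, independent of the package parser
oracleParsePairing <- function(db) {
  ch <- substring(db, seq_len(nchar(db)), seq_len(nchar(db)))
  out <- rep(NA_integer_, length(ch))
  stack <- integer(0L)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(i, stack)
    if (ch[i] == ")") {
      out[i] <- stack[1L]
      out[stack[1L]] <- i
      stack <- stack[-1L]
    }
  }
  out
}

# duplex closing pairs by exhaustive enumeration over all base pairs
oracleDuplex <- function(pairing, five_p, three_p) {
  cand <- c()
  for (i in five_p[1]:five_p[2]) {
    j <- pairing[i]
    if (!is.na(j) && j >= three_p[1] && j <= three_p[2]) cand <- c(cand, i)
  }
  if (!length(cand)) return(NULL)
  list(basal = c(min(cand), pairing[min(cand)]),
       apical = c(max(cand), pairing[max(cand)]))
}

# end-to-loop distance by scanning every position and taking minima
oracleEndDistance <- function(pairing, mature, kind) {
  t <- if (endsWith(kind, "start")) mature[1] else mature[2]
  if (is.na(pairing[t])) return(NA_integer_)
  outDir <- if (endsWith(kind, "start")) -1L else 1L
  unp <- which(is.na(pairing))
  dOut <- dIn <- NA_integer_
  bestOut <- bestIn <- Inf
  for (u in unp) {
    if (sign(u - t) == outDir && abs(u - t) < bestOut) bestOut <- abs(u - t)
    if (sign(u - t) == -outDir && abs(u - t) < bestIn) bestIn <- abs(u - t)
  }
  if (is.finite(bestOut)) dOut <- bestOut - 1L
  if (is.finite(bestIn)) dIn <- -bestIn
  if (is.na(dOut) && is.na(dIn)) return(NA_integer_)
  if (is.na(dIn)) return(dOut)
  if (is.na(dOut)) return(dIn)
  if (abs(dOut) <= abs(dIn)) dOut else dIn
}

# exact two-sided permutation p-value for Spearman rho by enumerating all
# n! orderings, with rho computed from first principles on ranks
oracleSpearmanExactP <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rhoOf <- function(a, b) {
    num <- sum((a - mean(a)) * (b - mean(b)))
    num / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  obs <- rhoOf(rx, ry)
  perms <- oracleAllPerms(n)
  rhos <- vapply(perms, function(idx) rhoOf(rx, ry[idx]), numeric(1))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

oracleAllPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (s in oracleAllPerms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[s])
    }
  }
  out
}

# grid-search ML estimate of the shared-marginal independence model
oracleGridIndependence <- function(counts, coarse = 0.01, fine = 1e-4) {
  n <- sum(counts)
  ll <- function(ps, pl) {
    q <- c(ps, 1 - ps - pl, pl)
    if (any(q <= 0)) return(-Inf)
    sum(counts * log(outer(q, q)))
  }
  best <- c(0.1, 0.1); bestLL <- -Inf
  grid <- seq(coarse, 1 - coarse, by = coarse)
  for (ps in grid)
    for (pl in grid[grid <= 1 - ps - coarse]) {
      v <- ll(ps, pl)
      if (v > bestLL) { bestLL <- v; best <- c(ps, pl) }
    }
  lo <- pmax(best - coarse, fine)
  for (ps in seq(lo[1], best[1] + coarse, by = fine))
    for (pl in seq(lo[2], best[2] + coarse, by = fine)) {
      v <- ll(ps, pl)
      if (v > bestLL) { bestLL <- v; best <- c(ps, pl) }
    }
  c(p_short = best[1], p_long = best[2])
}
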