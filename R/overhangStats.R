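#' Joint distribution of basal and apical overhang lengths
#'
#' Exact count table of (basal, apical) overhang pairs, with margins.
#' Suspect-flagged pairs (very long overhangs from dubious structures) are
#' counted but tagged so downstream summaries can exclude them.
#'
#' @param pairs `data.frame` with columns `basal`, `apical` and optionally
#'   `suspect` (as produced by [overhangTable()]), or a 2-column matrix.
#' @param excludeSuspect Drop suspect-flagged pairs before counting.
#' @return A list of class `JointOverhangTable`: `counts` (matrix with
#'   basal values as rows, apical as columns), `row_margin`, `col_margin`,
#'   `n_total`, `n_suspect`.
#' @export
jointOverhangTable <- function(pairs, excludeSuspect = FALSE) {
  pairs <- as.data.frame(pairs)
  nSuspect <- if (!is.null(pairs$suspect)) sum(pairs$suspect) else 0L
  if (excludeSuspect && !is.null(pairs$suspect))
    pairs <- pairs[!pairs$suspect, , drop = FALSE]
  if (!nrow(pairs)) {
    counts <- matrix(integer(0L), 0L, 0L)
  } else {
    b <- factor(pairs$basal, levels = sort(unique(pairs$basal)))
    a <- factor(pairs$apical, levels = sort(unique(pairs$apical)))
    counts <- unclass(table(basal = b, apical = a))
  }
  structure(list(counts = counts,
                 row_margin = if (length(counts)) rowSums(counts) else integer(0L),
                 col_margin = if (length(counts)) colSums(counts) else integer(0L),
                 n_total = sum(counts), n_suspect = nSuspect),
            class = "JointOverhangTable")
}

#' @export
print.JointOverhangTable <- function(x, ...) {
  cat("Joint overhang table, n =", x$n_total,
      "(", x$n_suspect, "suspect )\n")
  print(x$counts)
  invisible(x)
}

#' Spearman rank correlation with asymptotic or permutation p-value
#'
#' Midrank-tied Spearman correlation. The asymptotic p-value uses the
#' large-sample approximation of `stats::cor.test`; the permutation p-value
#' shuffles one variable's labels (two-sided, on `|rho|`), enumerating all
#' orderings exactly when `factorial(n)` does not exceed `n_perm` and
#' otherwise sampling `n_perm` random shuffles with the add-one estimator.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @param method `"asymptotic"` or `"permutation"`.
#' @param n_perm Number of random shuffles for the permutation method.
#' @param seed RNG seed for the permutation method.
#' @return A list of class `CorrelationResult`: `rho`, `p_value`, `n`,
#'   `method`.
#' @export
rankCorrelation <- function(x, y, method = c("asymptotic", "permutation"),
                            n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: constant vector")
  rho <- stats::cor(x, y, method = "spearman")
  if (method == "asymptotic") {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  } else {
    rx <- rank(x); ry <- rank(y)
    eps <- 1e-12
    if (factorial(n) <= n_perm) {
      perms <- allPermutations(n)
      rhos <- vapply(perms, function(idx) stats::cor(rx, ry[idx]), numeric(1L))
      p <- mean(abs(rhos) >= abs(rho) - eps)
    } else {
      hits <- withSeed(seed, {
        sum(vapply(seq_len(n_perm), function(i)
          abs(stats::cor(rx, ry[sample.int(n)])) >= abs(rho) - eps,
          logical(1L)))
      })
      p <- (1 + hits) / (n_perm + 1)
    }
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.3g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

# all permutations of 1..n, built by inserting n into every slot (n small)
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in 0:(n - 1L)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos)
  }
  out
}

#' Restrict overhang pairs to the near-canonical set
#'
#' Keeps duplexes whose basal and apical overhangs are both in `{1, 2, 3}`
#' nucleotides (the canonical 2 nt value and its minimal 1 nt deviations).
#'
#' @param pairs `data.frame` with columns `basal`, `apical`.
#' @return A list: `subset` (the retained rows) and `fraction` (retained /
#'   total; `NaN` on empty input).
#' @export
restrictNearCanonical <- function(pairs) {
  pairs <- as.data.frame(pairs)
  keep <- pairs$basal %in% 1:3 & pairs$apical %in% 1:3
  list(subset = pairs[keep, , drop = FALSE],
       fraction = if (nrow(pairs)) sum(keep) / nrow(pairs) else NaN)
}

#' Fit the independence null model for near-canonical overhang pairs
#'
#' The null model of independent cleavage-site imprecision: both overhang
#' lengths are drawn i.i.d. from one shared three-class marginal
#' `q = (p_short, 1 - p_short - p_long, p_long)` over lengths 1 (short),
#' 2 (canonical) and 3 (long) nt, so `P(i, j) = q_i q_j` — a 2-parameter
#' model. The maximum-likelihood estimate has the closed form
#' `q_i = (row_i + col_i) / (2 n)`. Under `shared = FALSE` each site gets
#' its own marginal (4 free parameters, the classical row x column
#' independence fit). `method = "ls"` instead minimises the squared
#' deviation of the fitted cell frequencies (same parameterisation).
#'
#' @param counts 3x3 matrix of counts (rows = basal length 1/2/3, columns =
#'   apical length 1/2/3), e.g. `nearCanonicalCounts()` output.
#' @param method `"ml"` (maximum likelihood, default) or `"ls"` (least
#'   squares on frequencies).
#' @param shared Use one marginal for both sites (default) or per-site
#'   marginals.
#' @return A list of class `IndependenceFit`: `p_short`, `p_long`, `q`
#'   (the shared marginal; a 2-row matrix when `shared = FALSE`),
#'   `log_likelihood`, `expected`, `obs_over_exp`, `gof` (likelihood-ratio
#'   statistic vs the saturated multinomial, `df`, `p_value`), `method`,
#'   `boundary` (TRUE when the fit lies on the simplex boundary).
#' @export
fitIndependenceModel <- function(counts, method = c("ml", "ls"),
                                 shared = TRUE) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L))) stop("counts must be a 3x3 matrix")
  n <- sum(counts)
  if (n <= 0) stop("empty table")
  r <- rowSums(counts); cl <- colSums(counts)
  if (shared) {
    q <- (r + cl) / (2 * n)
    if (method == "ls") {
      f <- counts / n
      obj <- function(par) {
        qq <- c(par[1L], 1 - par[1L] - par[2L], par[2L])
        if (any(qq < 0)) return(1e6)
        sum((f - outer(qq, qq))^2)
      }
      par <- stats::optim(c(q[1L], q[3L]), obj, method = "Nelder-Mead")$par
      q <- c(par[1L], 1 - sum(par), par[2L])
    }
    expected <- n * outer(q, q)
    pShort <- q[1L]; pLong <- q[3L]
    nPar <- 2L
    qOut <- stats::setNames(q, c("short", "canonical", "long"))
  } else {
    qr <- r / n; qc <- cl / n
    if (method == "ls") {
      f <- counts / n
      obj <- function(par) {
        a <- c(par[1L], 1 - par[1L] - par[2L], par[2L])
        b <- c(par[3L], 1 - par[3L] - par[4L], par[4L])
        if (any(c(a, b) < 0)) return(1e6)
        sum((f - outer(a, b))^2)
      }
      par <- stats::optim(c(qr[1L], qr[3L], qc[1L], qc[3L]), obj,
                          method = "Nelder-Mead")$par
      qr <- c(par[1L], 1 - par[1L] - par[2L], par[2L])
      qc <- c(par[3L], 1 - par[3L] - par[4L], par[4L])
    }
    expected <- n * outer(qr, qc)
    pShort <- c(basal = qr[1L], apical = qc[1L])
    pLong <- c(basal = qr[3L], apical = qc[3L])
    nPar <- 4L
    qOut <- rbind(basal = qr, apical = qc)
    colnames(qOut) <- c("short", "canonical", "long")
  }
  ll <- sum(counts[expected > 0] * log(expected[expected > 0] / n))
  obsExp <- counts / expected
  pos <- counts > 0
  g <- 2 * sum(counts[pos] * log(counts[pos] / expected[pos]))
  df <- 8L - nPar
  dimnames(expected) <- dimnames(obsExp) <-
    list(basal = c("1", "2", "3"), apical = c("1", "2", "3"))
  structure(list(p_short = pShort, p_long = pLong, q = qOut,
                 log_likelihood = ll, expected = expected,
                 obs_over_exp = obsExp,
                 gof = list(statistic = g, df = df,
                            p_value = stats::pchisq(g, df, lower.tail = FALSE)),
                 method = method, shared = shared,
                 boundary = any(qOut <= 0)),
            class = "IndependenceFit")
}

#' @export
print.IndependenceFit <- function(x, ...) {
  cat("Independence fit (", x$method,
      if (x$shared) ", shared marginal)" else ", per-site marginals)",
      "\n", sep = "")
  cat("  p_short =", round(x$p_short, 4),
      " p_long =", round(x$p_long, 4), "\n")
  cat("  G =", round(x$gof$statistic, 3), "df =", x$gof$df,
      "p =", signif(x$gof$p_value, 3), "\n")
  cat("  obs/exp:\n")
  print(round(x$obs_over_exp, 3))
  invisible(x)
}

#' 3x3 near-canonical count table from overhang pairs
#'
#' @param pairs `data.frame` with columns `basal`, `apical`.
#' @return 3x3 integer matrix over overhang lengths 1/2/3 nt.
#' @export
nearCanonicalCounts <- function(pairs) {
  sub <- restrictNearCanonical(pairs)$subset
  b <- factor(sub$basal, levels = 1:3)
  a <- factor(sub$apical, levels = 1:3)
  m <- unclass(table(b, a))
  dimnames(m) <- list(basal = c("1", "2", "3"), apical = c("1", "2", "3"))
  m
}

#' Base composition around a miRNA boundary
#'
#' Frequency of each nucleotide at fixed offsets around the chosen mature
#' end, across a dataset. Offset 0 is the terminal mature nucleotide;
#' negative offsets are 5' of it along the hairpin. Offsets falling outside
#' a hairpin are dropped from that record's denominator.
#'
#' @param set A [HairpinSet-class] (or list of records).
#' @param end_kind One of `"5p_start"`, `"5p_end"`, `"3p_start"`, `"3p_end"`.
#' @param offsets Integer offsets to evaluate (default `-1:1`).
#' @return A list: `freq` (4 x offsets matrix of A/C/G/U frequencies) and
#'   `denominator` (records contributing per offset).
#' @export
boundaryBaseFrequencies <- function(set,
                                    end_kind = c("5p_start", "5p_end",
                                                 "3p_start", "3p_end"),
                                    offsets = -1:1) {
  end_kind <- match.arg(end_kind)
  arm <- if (startsWith(end_kind, "5p")) "five_prime" else "three_prime"
  isStart <- endsWith(end_kind, "start")
  recs <- recordList(set)
  bases <- c("A", "C", "G", "U")
  counts <- matrix(0L, 4L, length(offsets),
                   dimnames = list(bases, as.character(offsets)))
  denom <- stats::setNames(integer(length(offsets)), as.character(offsets))
  for (r in recs) {
    m <- hairpinMatures(r)
    m <- m[m$arm == arm, , drop = FALSE]
    if (!nrow(m)) next
    t <- if (isStart) m$start else m$end
    s <- strsplit(hairpinSeq(r), "", fixed = TRUE)[[1L]]
    for (k in seq_along(offsets)) {
      pos <- t + offsets[k]
      if (pos >= 1L && pos <= length(s)) {
        denom[k] <- denom[k] + 1L
        counts[s[pos], k] <- counts[s[pos], k] + 1L
      }
    }
  }
  freq <- sweep(counts, 2L, pmax(denom, 1L), "/")
  freq[, denom == 0L] <- NA_real_
  list(freq = freq, denominator = denom)
}
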