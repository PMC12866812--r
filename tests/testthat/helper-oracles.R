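## Independent brute-force oracles used to cross-check the implementation.

## Elementary cellular automaton by explicit per-cell truth-table lookup.
ecaOracle <- function(rule, row0, nRows) {
  nCols <- length(row0)
  truth <- integer(8)
  for (k in 0:7) truth[k + 1] <- as.integer((rule %/% 2^k) %% 2)
  m <- matrix(0L, nRows, nCols)
  m[1, ] <- as.integer(row0)
  if (nRows > 1) {
    for (r in 1:(nRows - 1)) {
      for (c in 1:nCols) {
        a <- m[r, if (c == 1) nCols else c - 1]
        b <- m[r, c]
        d <- m[r, if (c == nCols) 1 else c + 1]
        m[r + 1, c] <- truth[4 * a + 2 * b + d + 1]
      }
    }
  }
  m
}

## Logic-scan counts by explicit loops over the measurable region.
logicOracle <- function(m) {
  n0 <- n1 <- integer(8)
  for (r in 1:(nrow(m) - 1)) {
    for (c in 1:(ncol(m) - 2)) {
      inp <- 4 * m[r, c] + 2 * m[r, c + 1] + m[r, c + 2]
      out <- m[r + 1, c + 1]
      if (out == 0) n0[inp + 1] <- n0[inp + 1] + 1
      else          n1[inp + 1] <- n1[inp + 1] + 1
    }
  }
  list(n0 = n0, n1 = n1)
}

## Radix conversion through double-precision integer arithmetic; exact for
## values below 2^53, i.e. payloads up to 50 bits here.
smallBitsToDigits <- function(bits, radix) {
  v <- sum(bits * 2^(rev(seq_along(bits)) - 1))
  if (v == 0) return(0L)
  d <- integer(0)
  while (v > 0) {
    d <- c(v %% radix, d)
    v <- v %/% radix
  }
  as.integer(d)
}

## Squared displacement curve by explicit window loops.
msdOracle <- function(xy, window, nWindows) {
  out <- numeric(window)
  for (lag in 1:window) {
    acc <- 0
    for (w in 1:nWindows) {
      d <- xy[w + lag, ] - xy[w, ]
      acc <- acc + sum(d^2)
    }
    out[lag] <- acc / nWindows
  }
  out
}

randomBitString <- function(n) paste(sample(0:1, n, replace = TRUE),
                                     collapse = "")
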