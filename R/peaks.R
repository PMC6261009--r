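## Local extrema with prominences, shared by the histogram-peak finder
## (white-to-white) and the second-derivative turning-point finder (limbus).

## Indices of interior local maxima of y.  Plateaus count once, at their
## first sample (smaller index).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  d <- diff(y)
  ## resolve flat steps by carrying the previous non-zero slope sign
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(diff(s) < 0) + 1L
  ## shift plateau representatives to the plateau's first sample
  vapply(idx, function(i) {
    while (i > 1 && y[i - 1] == y[i]) i <- i - 1L
    i
  }, integer(1))
}

## Topographic prominence of the maximum at index i: height above the higher
## of the two saddle points separating it from higher terrain (or from the
## array ends).
peak_prominence <- function(y, i) {
  n <- length(y)
  left <- if (i > 1) {
    j <- i - 1L
    lo <- y[j]
    while (j >= 1 && y[j] <= y[i]) {
      lo <- min(lo, y[j])
      j <- j - 1L
    }
    lo
  } else y[i]
  right <- if (i < n) {
    j <- i + 1L
    lo <- y[j]
    while (j <= n && y[j] <= y[i]) {
      lo <- min(lo, y[j])
      j <- j + 1L
    }
    lo
  } else y[i]
  y[i] - max(left, right)
}

## All interior local maxima with prominences, ordered by decreasing
## prominence (ties: smaller index first).
prominent_maxima <- function(y) {
  idx <- local_maxima(y)
  if (length(idx) == 0) {
    return(data.frame(index = integer(0), value = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(idx, function(i) peak_prominence(y, i), numeric(1))
  o <- order(-prom, idx)
  data.frame(index = idx[o], value = y[idx][o], prominence = prom[o])
}

## Interior local minima of y with prominences (of -y), decreasing
## prominence, ties toward smaller index.
prominent_minima <- function(y) {
  m <- prominent_maxima(-y)
  m$value <- -m$value
  m
}
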