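# Independent pure-R reference implementation of the dip statistic, used to
# cross-check the compiled implementation.  Same mathematical construction
# (GCM/LCM on the empirical-CDF jump midpoints with a shrinking modal
# interval), but written separately: hull chains by repeated extreme-slope
# selection (Jarvis march) and interpolation via approx(), rather than the
# Graham scans and manual segment walks of the compiled code.
dip_reference <- function(x) {
  n <- length(x)
  x <- sort(x)
  if (n < 2 || x[1] == x[n]) return(1 / (2 * n))
  cc <- (2 * seq_len(n) - 1) / (2 * n)

  lower_chain <- function(lo, hi) {
    idx <- lo
    while (idx[length(idx)] < hi) {
      i <- idx[length(idx)]
      rest <- (i + 1):hi
      sl <- (cc[rest] - cc[i]) / (x[rest] - x[i])
      tiepts <- rest[sl == min(sl)]
      idx <- c(idx, tiepts[length(tiepts)])
    }
    idx
  }
  upper_chain <- function(lo, hi) {
    idx <- lo
    while (idx[length(idx)] < hi) {
      i <- idx[length(idx)]
      rest <- (i + 1):hi
      sl <- (cc[rest] - cc[i]) / (x[rest] - x[i])
      tiepts <- rest[sl == max(sl)]
      idx <- c(idx, tiepts[length(tiepts)])
    }
    idx
  }
  interp <- function(chain, at) {
    approx(x = x[chain], y = cc[chain], xout = x[at], ties = "ordered")$y
  }

  low <- 1L; high <- n; r <- 0
  repeat {
    g <- lower_chain(low, high)
    l <- upper_chain(low, high)
    verts <- sort(unique(c(g, l)))
    gaps <- interp(l, verts) - interp(g, verts)
    gap <- max(gaps)
    if (gap / 2 <= r) break
    v <- verts[which.max(gaps)]
    if (v %in% g) {
      new_low <- v
      new_high <- l[match(TRUE, x[l] >= x[v] & l >= v)]
    } else {
      new_high <- v
      gl <- rev(g)
      new_low <- gl[match(TRUE, x[gl] <= x[v] & gl <= v)]
    }
    if (new_low == low && new_high == high) { r <- max(r, gap / 2); break }
    dl <- max(cc[low:new_low] - interp(g, low:new_low))
    du <- max(interp(l, new_high:high) - cc[new_high:high])
    r <- max(r, dl / 2, du / 2)
    low <- new_low; high <- new_high
    if (low >= high) break
  }
  r + 1 / (2 * n)
}
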