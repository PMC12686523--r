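# Reference implementation of the dip via the GCM/LCM construction,
# deliberately computed differently from the package's hull-walk: the
# convex minorant / concave majorant values are obtained as min/max over
# all chords between data points (O(n^3)), so only the mathematical
# definition is shared. Valid for samples without ties.

dip_reference <- function(values) {
  x <- sort(values)
  n <- length(x)
  stopifnot(n >= 4, !anyDuplicated(x))
  chord_curve <- function(lo, hi, y, lower) {
    idx <- lo:hi
    vapply(idx, function(j) {
      best <- y[j - lo + 1]
      for (i in idx[idx <= j]) {
        for (k in idx[idx >= j]) {
          if (x[k] > x[i]) {
            v <- y[i - lo + 1] +
              (y[k - lo + 1] - y[i - lo + 1]) * (x[j] - x[i]) / (x[k] - x[i])
            if (lower && v < best) best <- v
            if (!lower && v > best) best <- v
          }
        }
      }
      best
    }, numeric(1))
  }
  low <- 1L; high <- n; D <- 1
  repeat {
    if (high - low < 1L) break
    idx <- low:high
    g <- chord_curve(low, high, idx - 1, lower = TRUE)
    l <- chord_curve(low, high, idx, lower = FALSE)
    gap <- l - g
    d <- max(gap)
    if (d <= D) break
    js <- idx[which.max(gap)]
    g_t <- idx[abs(g - (idx - 1)) < 1e-9]
    l_t <- idx[abs(l - idx) < 1e-9]
    new_low <- max(g_t[g_t <= js])
    new_high <- min(l_t[l_t >= js])
    dl <- max((low:new_low) - g[seq_len(new_low - low + 1)])
    du <- max(l[(new_high - low + 1):(high - low + 1)] -
                ((new_high:high) - 1))
    D <- max(D, dl, du)
    if (new_low == low && new_high == high) break
    low <- new_low; high <- new_high
  }
  D / (2 * n)
}
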