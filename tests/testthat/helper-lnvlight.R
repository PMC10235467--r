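# brute-force Benjamini-Hochberg step-up, independent of p.adjust:
# sort, scale by m/rank, enforce monotonicity from the largest rank down
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# constant-rate profile over `dur` seconds at 1-ms resolution
constProfile <- function(rate, dur, dt = 1e-3) {
  structure(rep(rate, round(dur / dt)), dt = dt, duration = dur)
}

# short protocol for rendering tests (20 s instead of 150 s)
shortProtocol <- function(...) {
  sweepProtocol(preDark = 10, lightOn = 5, postDark = 5, binWidth = 5, ...)
}

# match each true spike to the nearest detected event; returns the
# per-spike distances (Inf when nothing was detected)
matchDistances <- function(detected, truth) {
  if (length(truth) == 0) return(numeric())
  if (length(detected) == 0) return(rep(Inf, length(truth)))
  vapply(truth, function(t) min(abs(detected - t)), 0)
}
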