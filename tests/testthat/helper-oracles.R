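# Brute-force motif scanner used as the independent oracle: scores every
# offset on both strands with plain R loops.
brute_scan <- function(seq_codes, pwm, background = 0.25,
                       pseudocount = 1e-3, floor = -10) {
  lod <- log2((pwm + pseudocount) / (background + pseudocount))
  rc <- lod[4:1, rev(seq_len(ncol(lod))), drop = FALSE]
  w <- ncol(pwm)
  best <- -Inf
  for (off in seq_len(length(seq_codes) - w + 1)) {
    win <- seq_codes[off:(off + w - 1)]
    if (all(win == 0)) next
    for (m in list(lod, rc)) {
      s <- 0
      for (j in seq_len(w)) if (win[j] >= 1) s <- s + m[win[j], j]
      best <- max(best, s)
    }
  }
  if (is.finite(best)) best else floor
}


# Exhaustive threshold-sweep oracle for the area under the precision-recall
# curve: plain loops, strict inequality, rectangle rule over recall
# increments — written independently of the package implementation.
brute_aupr <- function(truth, scores) {
  thr <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  prev_rec <- 0
  area <- 0
  P <- sum(truth)
  for (t in thr) {
    sel <- scores > t
    if (!any(sel)) next
    prec <- sum(truth[sel]) / sum(sel)
    rec <- sum(truth[sel]) / P
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

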