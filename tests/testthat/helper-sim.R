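# Small grids for fast tests: 0-8 min at 0.01 min (481 points), 21 channels.
small_config <- function(seed = 1L, ...) {
  sim_config(wavelength_grid = seq(200, 400, by = 10),
             time_grid = (0:800) / 100,
             seed = seed, ...)
}

# a tiny cube with distinct, easily-tracked values
toy_cube <- function(n = 2L, W = 3L, T = 4L) {
  vals <- array(seq_len(n * W * T), dim = c(n, W, T))
  dad_cube(vals, sprintf("s%02d", seq_len(n)),
           wavelengths = seq(200, by = 10, length.out = W),
           times = seq(1, by = 0.5, length.out = T),
           labels = rep_len(1:2, n))
}

# independent brute-force COW oracle: enumerate all admissible node paths,
# interpolate with approx(), score with cor()
cow_brute_force <- function(smp, tgt, seg_len, slack) {
  Nt <- length(tgt); Ns <- length(smp)
  nSeg <- (Nt - 1) %/% seg_len
  tb <- c((0:(nSeg - 1)) * seg_len, Nt - 1)       # 0-based boundaries
  seg_score <- function(a, c, xs, xe) {
    m <- c - a + 1
    pos <- seq(xs, xe, length.out = m)
    v <- approx(seq_len(Ns) - 1, smp, xout = pos)$y
    y <- tgt[(a:c) + 1]
    if (sd(v) == 0 || sd(y) == 0) return(0)
    cor(v, y)
  }
  best <- list(score = -Inf, nodes = NULL)
  recurse <- function(b, nodes, acc) {
    if (b == nSeg) {
      tlen <- tb[nSeg + 1] - tb[nSeg]
      xe <- Ns - 1
      d <- (xe - nodes[length(nodes)]) - tlen
      if (abs(d) > slack || xe <= nodes[length(nodes)]) return()
      s <- acc + seg_score(tb[nSeg], tb[nSeg + 1], nodes[length(nodes)], xe)
      if (s > best$score + 1e-12) best <<- list(score = s, nodes = c(nodes, xe))
      return()
    }
    tlen <- tb[b + 1] - tb[b]
    for (d in -slack:slack) {
      xe <- nodes[length(nodes)] + tlen + d
      if (xe <= nodes[length(nodes)] || xe >= Ns - 1) next
      recurse(b + 1, c(nodes, xe),
              acc + seg_score(tb[b], tb[b + 1], nodes[length(nodes)], xe))
    }
  }
  if (nSeg == 1L) {
    recurse(1, 0, 0)
  } else {
    recurse(1, 0, 0)
  }
  best
}
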