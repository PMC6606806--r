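# Shared fixtures and independent brute-force oracles.

toy_genome <- function(length_bp = 1000, ori = 1, n_bins = 10) {
  genome_map("toy", length_bp, ori, n_bins = n_bins)
}

# naive per-position binning: walk the offset in a loop
naive_bin <- function(position, genome) {
  vapply(position, function(p) {
    off <- p - genome$ori_position_bp
    while (off < 0) off <- off + genome$length_bp
    while (off >= genome$length_bp) off <- off - genome$length_bp
    b <- 1L
    w <- genome$length_bp / genome$n_bins
    while (off >= b * w) b <- b + 1L
    b
  }, integer(1))
}

# definitional BH step-up: q(i) = min_{j >= i} p_(j) * m / j in sorted
# order, capped at 1, restored to input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[seq.int(i, m)] * m / seq.int(i, m), 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# longhand product-moment correlation
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# strand-aware hot-spot oracle: on each strand independently, is the
# mutated base an A whose 3' neighbour (on that strand) is C?
hotspot_oracle <- function(reference, pos) {
  len <- nchar(reference)
  at <- function(p) substring(reference, ((p - 1) %% len) + 1,
                              ((p - 1) %% len) + 1)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  plus <- at(pos) == "A" && at(pos + 1) == "C"
  # minus strand: base at pos is comp(plus base); its 3' neighbour on the
  # minus strand is the complement of the plus base at pos - 1
  minus <- comp[[at(pos)]] == "A" && comp[[at(pos - 1)]] == "C"
  plus || minus
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / max(sum(b^2), 1e-300))
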