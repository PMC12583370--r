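# shared fixtures: random feasible topologies, brute-force oracles

pick1 <- function(v) v[sample.int(length(v), 1)]

# sample a feasible (B, J, R) topology
random_topology <- function(max_b = 30, max_j = 10) {
  B <- pick1(1:max_b)
  J <- pick1(0:max_j)
  if (J > 0 && B < 2 * J + 1) J <- 0
  m <- if (J == 0) 0 else pick1((2 * J + 1):min(4 * J, B))
  list(B = B, J = J, R = B - m)
}

# brute-force 8-connected component labelling (flood fill in plain R)
label8_bruteforce <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask)) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# draw a Y skeleton: three straight arms from a center pixel
y_skeleton <- function(arm = 10, shape = c(64, 64)) {
  sk <- matrix(FALSE, shape[1], shape[2])
  ctr <- round(shape / 2)
  sk[ctr[1], ctr[2]] <- TRUE
  for (d in list(c(-1, 0), c(1, -1), c(1, 1))) {
    for (t in 1:arm) sk[ctr[1] + t * d[1], ctr[2] + t * d[2]] <- TRUE
  }
  sk
}
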