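# Brute-force oracles, independent of the package kernels: plain double
# loops over patch centers and disc offsets.  Used to freeze expected values
# for the statistics, the total energy, and the two incremental-update
# equivalences.

oracle_disc_offsets <- function(r) {
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
}

# s1, s2, c1, c2 at every pixel by direct summation (zero-clipped patches).
oracle_local_stats <- function(I, u, r, m) {
  nr <- nrow(I); nc <- ncol(I)
  s1 <- s2 <- c1 <- c2 <- matrix(0, nr, nc)
  off <- oracle_disc_offsets(r)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    a1 <- a2 <- b1 <- b2 <- si <- 0; cnt <- 0
    for (t in seq_len(nrow(off))) {
      y <- i + off$dy[t]; x <- j + off$dx[t]
      if (y < 1 || y > nr || x < 1 || x > nc) next
      a1 <- a1 + u[y, x]^m;       b1 <- b1 + u[y, x]^m * I[y, x]
      a2 <- a2 + (1 - u[y, x])^m; b2 <- b2 + (1 - u[y, x])^m * I[y, x]
      si <- si + I[y, x]; cnt <- cnt + 1
    }
    s1[i, j] <- a1; s2[i, j] <- a2
    c1[i, j] <- if (a1 > 0) b1 / a1 else si / cnt
    c2[i, j] <- if (a2 > 0) b2 / a2 else si / cnt
  }
  list(s1 = s1, s2 = s2, c1 = c1, c2 = c2)
}

# Total localized energy by the full quadruple loop (centers x patch pixels),
# given prototype maps.
oracle_total_energy <- function(I, u, r, m, st) {
  nr <- nrow(I); nc <- ncol(I)
  off <- oracle_disc_offsets(r)
  F <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (t in seq_len(nrow(off))) {
      y <- i + off$dy[t]; x <- j + off$dx[t]
      if (y < 1 || y > nr || x < 1 || x > nc) next
      F <- F + u[y, x]^m * (I[y, x] - st$c1[i, j])^2 +
               (1 - u[y, x])^m * (I[y, x] - st$c2[i, j])^2
    }
  }
  F
}

# Direct energy of a membership field (prototypes recomputed from scratch).
oracle_energy_of <- function(I, u, r, m) {
  st <- oracle_local_stats(I, u, r, m)
  oracle_total_energy(I, u, r, m, st)
}

random_instance <- function(n = 16L, seed = 1L) {
  set.seed(seed)
  list(I = matrix(runif(n * n), n, n),
       u = matrix(runif(n * n), n, n))
}

# A clean two-region phantom plus the crisp matching membership.
two_region_fixture <- function(n = 32L, lo = 0.2, hi = 0.8) {
  I <- matrix(lo, n, n)
  truth <- matrix(FALSE, n, n)
  ctr <- n / 2
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - ctr)^2 + (j - ctr)^2 <= (n / 4)^2) truth[i, j] <- TRUE
  I[truth] <- hi
  list(I = I, truth = truth, u = ifelse(truth, 1, 0))
}
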