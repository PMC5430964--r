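# Independent oracles used across tests.

# Brute-force MSD by explicit double loop over frame pairs.
msd_brute <- function(xy, kmax) {
  n <- nrow(xy)
  out <- numeric(kmax)
  for (k in seq_len(kmax)) {
    s <- 0
    for (t in seq_len(n - k)) {
      s <- s + (xy[t + k, 1] - xy[t, 1])^2 + (xy[t + k, 2] - xy[t, 2])^2
    }
    out[k] <- s / (n - k)
  }
  out
}

# Exhaustive maximum-probability path: enumerate all K^T state sequences.
viterbi_brute <- function(log_em, tmat) {
  Tn <- nrow(log_em); K <- ncol(log_em)
  lT <- suppressWarnings(log(tmat))
  grid <- do.call(expand.grid, rep(list(seq_len(K)), Tn))
  best <- -Inf; best_path <- NULL
  for (i in seq_len(nrow(grid))) {
    path <- as.integer(grid[i, ])
    lp <- log_em[1L, path[1L]]
    if (Tn > 1L) for (t in 2:Tn) {
      lp <- lp + lT[path[t - 1L], path[t]] + log_em[t, path[t]]
    }
    if (lp > best) { best <- lp; best_path <- path }
  }
  list(log_prob = best, states = best_path - 1L)
}

# Log-probability of a given state path (0-based) under the model.
path_log_prob <- function(states, log_em, tmat) {
  lT <- suppressWarnings(log(tmat))
  s <- states + 1L
  lp <- log_em[1L, s[1L]]
  if (length(s) > 1L) for (t in 2:length(s)) {
    lp <- lp + lT[s[t - 1L], s[t]] + log_em[t, s[t]]
  }
  lp
}

# Numerical derivative of the bonded pair potential, written out
# independently of the simulator (Kremer-Grest FENE + WCA, k = 30,
# r_max = 1.5, sigma = 1).
bond_potential_ref <- function(r) {
  fene <- -0.5 * 30 * 1.5^2 * log(1 - (r / 1.5)^2)
  wca <- ifelse(r < 2^(1 / 6), 4 * (r^-12 - r^-6) + 1, 0)
  fene + wca
}
bond_force_ref <- function(r, h = 1e-7) {
  -(bond_potential_ref(r + h) - bond_potential_ref(r - h)) / (2 * h)
}
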