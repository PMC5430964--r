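test_that("transition matrices are tridiagonal and row-stochastic", {
  for (p in c(0, 0.3, 0.7, 1)) {
    for (N in c(1, 2, 5, 14)) {
      tm <- transition_matrix(p, N)
      expect_equal(rowSums(tm), rep(1, N + 1), tolerance = 1e-12)
      off <- abs(row(tm) - col(tm)) > 1
      expect_true(all(tm[off] == 0))
      expect_equal(diag(tm), rep(p, N + 1))
    }
  }
})

test_that("emission weights follow the within-trap Gaussian", {
  m <- step_model(0.84, 0.31)
  v <- hmm_emissions(c(2 * 0.84), m, n_steps = 4)
  expect_equal(unname(v[1, 3]), 1)                    # on-level: weight 1, maximal
  expect_equal(unname(which.max(v[1, ])), 3L)
  v_mid <- hmm_emissions(1.5 * 0.84, m, n_steps = 4)  # midway: neighbours tie
  expect_equal(unname(v_mid[1, 2]), unname(v_mid[1, 3]), tolerance = 1e-12)
  v_half <- hmm_emissions(0.42, m, n_steps = 2)
  expect_equal(unname(v_half[1, 1]), exp(-(0.42 / 0.31)^2))
  expect_equal(unname(v_half[1, 1]), exp(-1.8356), tolerance = 1e-4)
})

test_that("Viterbi equals exhaustive path enumeration on small instances", {
  set.seed(2024)
  for (case in 1:25) {
    K <- sample(2:4, 1)           # up to 4 states
    Tn <- sample(2:8, 1)          # up to 8 frames
    p <- runif(1, 0.05, 0.95)
    tm <- transition_matrix(p, K - 1)
    le <- matrix(rnorm(Tn * K, sd = 2), Tn, K)  # generic log emissions
    got <- viterbi_decode(le, tm, log = TRUE)
    ref <- viterbi_brute(le, tm)
    expect_equal(got$log_prob, ref$log_prob, tolerance = 1e-10)
    expect_equal(path_log_prob(got$states, le, tm), ref$log_prob,
                 tolerance = 1e-10)
  }
})

test_that("degenerate decoding contracts hold", {
  m <- step_model(0.84, 0.31)
  r <- rep(2 * 0.84, 10)
  le <- hmm_emissions(r, m, n_steps = 4, log = TRUE)
  # constant displacement, p_trap = 0.9 -> constant path at that level
  path <- viterbi_decode(le, transition_matrix(0.9, 4), log = TRUE)
  expect_true(all(path$states == 2L))
  # p_trap = 1 forbids transitions entirely, whatever later frames prefer
  r2 <- c(0, 0, 0.84, 0.84, 0.84)
  le2 <- hmm_emissions(r2, m, n_steps = 2, log = TRUE)
  path2 <- viterbi_decode(le2, transition_matrix(1, 2), log = TRUE)
  expect_equal(length(unique(path2$states)), 1L)
  # all-zero emission rows are refused in linear space
  expect_error(viterbi_decode(matrix(0, 3, 3), transition_matrix(0.5, 2)),
               "underflow")
})

test_that("empirical transition counting matches direct enumeration", {
  emp <- empirical_transitions(c(0L, 0L, 1L, 1L), n_steps = 1)
  expect_equal(emp$probs[1, ], c(0.5, 0.5))
  expect_equal(emp$probs[2, ], c(0, 1))
  emp2 <- empirical_transitions(rep(2L, 6), n_steps = 3)
  expect_equal(emp2$probs[3, 3], 1)
  expect_equal(emp2$visited, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(empirical_transitions(1L, 1), "length >= 2")

  # long synthetic chain: observed matrix converges to the generator
  gen_chain <- function(n, p, N, seed) {
    set.seed(seed)
    s <- integer(n); s[1] <- N %/% 2
    for (t in 2:n) {
      if (runif(1) < p) s[t] <- s[t - 1]
      else {
        cand <- s[t - 1] + if (s[t - 1] == 0) 1 else if (s[t - 1] == N) -1 else
          sample(c(-1, 1), 1)
        s[t] <- cand
      }
    }
    s
  }
  tm <- transition_matrix(0.6, 4)
  dev_at <- function(n) {
    s <- gen_chain(n, 0.6, 4, seed = n)
    emp <- empirical_transitions(s, 4)
    interior <- which(emp$visited)
    max(abs(emp$probs[interior, ] - tm[interior, ]))
  }
  expect_lt(dev_at(10000), dev_at(1000))  # deviation shrinks with length
})

test_that("p_trap fitting matches grid search and exact cases", {
  # exact tridiagonal observation -> exact recovery
  emp <- list(probs = transition_matrix(0.7, 3), counts = transition_matrix(0.7, 3) * 10,
              row_counts = rep(10, 4), visited = rep(TRUE, 4))
  expect_equal(fit_p_trap(emp, 3), 0.7, tolerance = 1e-6)
  # identity observation -> p_trap = 1
  empI <- list(probs = diag(4), counts = diag(4) * 5, row_counts = rep(5, 4),
               visited = rep(TRUE, 4))
  expect_equal(fit_p_trap(empI, 3), 1, tolerance = 1e-6)

  # hand-built 3-state observation, uniform row weights, grid-search oracle
  Tstar <- rbind(c(0.6, 0.4, 0), c(0.1, 0.8, 0.1), c(0, 0.3, 0.7))
  empH <- list(probs = Tstar, counts = Tstar, row_counts = rep(1, 3),
               visited = rep(TRUE, 3))
  grid <- seq(0, 1, by = 1e-4)
  loss <- vapply(grid, function(p) sum((Tstar - transition_matrix(p, 2))^2), 0)
  expect_equal(fit_p_trap(empH, 2, row_weights = rep(1, 3)),
               grid[which.min(loss)], tolerance = 2e-4)

  empN <- list(probs = diag(2), counts = diag(2) * 0, row_counts = c(0, 0),
               visited = c(FALSE, FALSE))
  expect_error(fit_p_trap(empN, 1), "undefined")
})

test_that("reduced chi-squared reproduces the worked two-state case", {
  tm <- transition_matrix(0.8, 1)    # diag 0.8, off 0.2
  emp <- list(probs = transition_matrix(0.7, 1),
              counts = transition_matrix(0.7, 1) * 10,
              row_counts = c(10, 10), visited = c(TRUE, TRUE))
  # nu = 4 - 3 = 1; chi2 = 2*(0.01/0.7) + 2*(0.01/0.3)
  expect_equal(reduced_chi2(tm, emp), 2 * 0.01 / 0.7 + 2 * 0.01 / 0.3,
               tolerance = 1e-12)
  expect_equal(round(reduced_chi2(tm, emp), 4), 0.0952)
  # perfect agreement -> 0
  emp2 <- list(probs = tm, counts = tm * 10, row_counts = c(10, 10),
               visited = c(TRUE, TRUE))
  expect_equal(reduced_chi2(tm, emp2), 0)
  expect_error(reduced_chi2(tm, list(probs = diag(2), counts = diag(2),
                                     row_counts = c(1, 1),
                                     visited = c(TRUE, FALSE))),
               "degenerate degrees of freedom")
})

test_that("the Viterbi iteration recovers trapping probabilities", {
  est <- vapply(1:5, function(s) {
    tr <- synth_traphop(0.7, duration = 3000, frame_interval = 3,
                        seed = 700 + s)
    viterbi_iterate(tr)$p_trap_star
  }, 0)
  expect_lt(abs(median(est) - 0.7), 0.05)

  # hop-free input -> p_trap* ~ 1 and an infinite-barrier sentinel
  trapped <- synth_trapped(0.31, center = 0.8, duration = 3000, seed = 12)
  fit <- viterbi_iterate(trapped, step_model(0.84, 0.31, n_steps = 2))
  expect_gte(fit$p_trap_star, 0.99)
  if (fit$p_trap_star == 1) expect_identical(fit$delta_G, Inf)

  # start-point independence
  tr <- synth_traphop(0.6, duration = 3000, seed = 61)
  a <- viterbi_iterate(tr, p0 = 0.1)
  b <- viterbi_iterate(tr, p0 = 0.95)
  expect_lt(abs(a$p_trap_star - b$p_trap_star), 1e-3)
})

test_that("chi2/nu is near 1 on self-generated data and greedy is worse", {
  tr <- synth_traphop(0.8, duration = 6000, seed = 88)
  v <- viterbi_iterate(tr)
  g <- viterbi_iterate(tr, decoder = "greedy")
  expect_lt(v$chi2_over_nu, 2)
  expect_gte(g$chi2_over_nu, v$chi2_over_nu)
  # greedy flicker biases the trapping probability low
  expect_gt(abs(g$p_trap_star - 0.8), abs(v$p_trap_star - 0.8))
})

test_that("barrier map and detection floor match their closed forms", {
  expect_equal(barrier_from_p(0.55), 0.80, tolerance = 5e-3)
  expect_equal(barrier_from_p(0.75), 1.39, tolerance = 5e-3)
  expect_equal(barrier_from_p(1 - exp(-1)), 1)
  expect_identical(barrier_from_p(1), Inf)
  # monotone in p_trap
  p <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(barrier_from_p(p)) > 0))

  expect_equal(detection_floor(4, 1), exp(-2))
  expect_equal(detection_floor(4, 1), 0.1353, tolerance = 1e-3)
  expect_equal(detection_floor(0, 2), 1)
  tr <- synth_traphop(0.3, duration = 3000, seed = 5)
  fit <- viterbi_iterate(tr, floor = detection_floor(4, 1))
  expect_false(fit$below_floor)  # 0.3 is above exp(-2)
})

test_that("step-size scan finds the generating scale", {
  tr <- synth_traphop(0.7, duration = 3000, seed = 9)
  sc2 <- scan_step_size(tr, seq(0.5, 1.2, by = 0.1))
  best <- sc2$g[which.min(sc2$chi2_over_nu)]
  expect_lte(abs(best - 0.84), 0.15)  # within one grid step of the true g
  expect_true(any(sc2$is_local_min))
})

test_that("a two-scale hop mixture produces two local optima in the scan", {
  tr <- synth_traphop(0.55, step_size_g = 0.84, g2 = 1.4, g2_prob = 0.4,
                      duration = 9000, seed = 204)
  sc <- scan_step_size(tr, seq(0.6, 1.6, by = 0.1))
  expect_gte(sum(sc$is_local_min), 2)
})
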