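test_that("bonded forces vanish at the mechanical equilibrium length", {
  cfg <- sim_config()
  # independent oracle: bisection on the numerically differentiated
  # reference potential
  lo <- 0.8; hi <- 2^(1 / 6)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (bond_force_ref(mid) > 0) lo <- mid else hi <- mid
  }
  r_star <- (lo + hi) / 2
  expect_gt(r_star, 0.9); expect_lt(r_star, 1.0)
  expect_equal(equilibrium_bond_length(cfg), r_star, tolerance = 1e-5)

  st <- structure(list(positions = rbind(c(0, 0, 0), c(r_star, 0, 0)),
                       velocities = matrix(0, 2, 3), time = 0),
                  class = "chain_state")
  f <- bonded_forces(st, cfg)
  expect_lt(max(abs(f)), 1e-4)
})

test_that("bonded forces are pairwise equal and opposite and diverge near r_max", {
  cfg <- sim_config()
  set.seed(42)
  pos <- cbind(cumsum(c(0, runif(4, 0.8, 1.1))), 0, 0) + rnorm(15, sd = 0.01)
  st <- structure(list(positions = pos, velocities = matrix(0, 5, 3), time = 0),
                  class = "chain_state")
  f <- bonded_forces(st, cfg)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-10)  # internal forces cancel

  st2 <- structure(list(positions = rbind(c(0, 0, 0), c(1.499, 0, 0)),
                        velocities = matrix(0, 2, 3), time = 0),
                   class = "chain_state")
  f2 <- bonded_forces(st2, cfg)
  expect_gt(abs(f2[1, 1]), 1e3)          # FENE divergence approaching r_max
  expect_equal(f2[1, ], -f2[2, ])        # Newton's third law, exactly

  st3 <- structure(list(positions = rbind(c(0, 0, 0), c(1.6, 0, 0)),
                        velocities = matrix(0, 2, 3), time = 0),
                   class = "chain_state")
  expect_error(bonded_forces(st3, cfg), "bond 1-2")
})

test_that("the literal FENE form is exposed and differs from Kremer-Grest", {
  cfg_kg <- sim_config()
  cfg_lit <- sim_config(fene_form = "literal")
  r <- 1.2
  expect_false(isTRUE(all.equal(
    bond_energy_cpp(r, 30, 1.5, 1, FALSE), bond_energy_cpp(r, 30, 1.5, 1, TRUE))))
  # both forms still bind: restoring force at stretched bonds
  expect_gt(bond_dudr_cpp(r, 30, 1.5, 1, FALSE), 0)
  expect_gt(bond_dudr_cpp(r, 30, 1.5, 1, TRUE), 0)
  expect_lt(equilibrium_bond_length(cfg_lit), equilibrium_bond_length(cfg_kg))
})

test_that("post potential has its minimum depth epsilon and vanishes past cutoff", {
  eps <- 0.7
  s_min <- 2^(1 / 6)
  # unshifted depth at the minimum is eps * kT; the cutoff shift raises it
  # by the (small) cutoff value of the potential
  u_min <- post_energy_cpp(s_min, eps, 2.5, 1)
  shift <- -4 * eps * ((1 / 2.5)^12 - (1 / 2.5)^6)
  expect_equal(u_min - shift, -eps, tolerance = 1e-12)
  expect_identical(post_energy_cpp(3, eps, 2.5, 1), 0)

  geom <- build_hex_array(16, 7, 3)
  cfg <- sim_config(posts = "attractive", epsilon = eps, geometry = geom)
  # second bead at the gap midpoint: 19.5 sigma from every post axis,
  # beyond R + r_cutoff = 18.5
  st <- structure(list(positions = rbind(c(16 + s_min, 0, 1.5), c(19.5, 0, 1.5)),
                       velocities = matrix(0, 2, 3), time = 0),
                  class = "chain_state")
  f <- post_forces(st, cfg)
  expect_lt(abs(f[1, 1]), 1e-10)   # radial force zero at the minimum
  expect_equal(f[2, ], c(0, 0, 0)) # beyond cutoff

  # repulsive mode: shifted energy is non-negative on a fine grid
  s_grid <- seq(0.8, 1.12, by = 1e-4)
  u_rep <- vapply(s_grid, post_energy_cpp, 0, eps = eps, rcut = 1.12, sigma = 1)
  expect_gte(min(u_rep), -1e-3 * eps)

  st_in <- structure(list(positions = rbind(c(15, 0, 1.5)),
                          velocities = matrix(0, 1, 3), time = 0),
                     class = "chain_state")
  expect_error(post_forces(st_in, cfg), "inside a post")
})

test_that("free flight, wall reflection and energy conservation behave", {
  # gamma -> 0 limit: single bead, no thermostat -> exact ballistic drift
  cfg <- sim_config(n_beads = 1, slit_height = Inf, dt = 0.01)
  st <- structure(list(positions = matrix(c(0.5, 0.2, 0), 1, 3),
                       velocities = matrix(c(1.5, -2, 0.3), 1, 3), time = 0),
                  class = "chain_state")
  st2 <- langevin_step(st, cfg, thermostat = FALSE)
  expect_equal(st2$positions[1, ], c(0.5, 0.2, 0) + 0.01 * c(1.5, -2, 0.3),
               tolerance = 1e-12)

  # bead crossing z = H in a substep: back in the slit with vz flipped
  cfgw <- sim_config(n_beads = 1, slit_height = 3, dt = 0.01)
  stw <- structure(list(positions = matrix(c(0, 0, 2.995), 1, 3),
                        velocities = matrix(c(0, 0, 2), 1, 3), time = 0),
                   class = "chain_state")
  stw2 <- langevin_step(stw, cfgw, thermostat = FALSE)
  expect_gte(stw2$positions[1, 3], 0); expect_lte(stw2$positions[1, 3], 3)
  expect_equal(stw2$velocities[1, 3], -2, tolerance = 1e-12)

  # microcanonical secular energy drift below 1e-4 relative over 1e4 steps.
  # velocity-Verlet energy oscillates within bounds (~3e-4 here) but must
  # not drift; estimate the secular trend over 2e4 steps with dense
  # sampling so the oscillation averages out of the slope.
  cfg2 <- sim_config(n_beads = 20, slit_height = Inf)
  set.seed(7)
  st <- init_chain(cfg2, seed = 7)
  st <- langevin_step(st, cfg2, n_steps = 2000, thermostat = TRUE)
  e <- numeric(401); e[1] <- total_energy(st, cfg2)
  for (k in 2:401) {
    st <- langevin_step(st, cfg2, n_steps = 50, thermostat = FALSE)
    e[k] <- total_energy(st, cfg2)
  }
  drift_per_1e4 <- abs(unname(coef(lm(e ~ seq_along(e)))[2])) * 200 / abs(mean(e))
  expect_lt(drift_per_1e4, 1e-4)
})

test_that("single-bead diffusion matches the Einstein relation", {
  cfg <- sim_config(n_beads = 1, slit_height = Inf, n_steps = 2e6,
                    sample_every = 100, seed = 3)
  tr <- run_sim(cfg)
  cv <- msd(tr$com_track, max_lag = 1500)
  # inertial regime extends to ~1/gamma = 100 t_D; fit the diffusive tail
  f <- fit_diffusivity(cv, c(500, 1500), dim = 2)
  expect_equal(f$D, 1, tolerance = 0.05)  # D0 = kT/(m gamma) = 1 sigma^2/t_D
})

test_that("a single bead samples exact Boltzmann shell weights around a post", {
  # dual-route check of the post interaction + thermostat: long-run shell
  # occupancies vs direct quadrature of r * exp(-U(s)) over each shell
  geom <- build_hex_array(16, 17, 3)
  cfg <- sim_config(n_beads = 1, posts = "attractive", epsilon = 1.5,
                    geometry = geom, n_steps = 4e6, sample_every = 50,
                    equil_steps = 2e4, seed = 502)
  tr <- run_sim(cfg)
  s <- nearest_post_distance(tr$com_samples, geom) - 16
  breaks <- c(0.9, 1.5, 2.0, 2.5, 4, 8)
  meas <- hist(s[s < 8], breaks = breaks, plot = FALSE)$counts / sum(s < 8)
  shell <- function(lo, hi) {
    stats::integrate(function(x) {
      (16 + x) * exp(-vapply(x, post_energy_cpp, 0, eps = 1.5, rcut = 2.5,
                             sigma = 1))
    }, lo, hi)$value
  }
  ex <- vapply(seq_len(5), function(i) shell(breaks[i], breaks[i + 1]), 0)
  expect_lt(max(abs(meas - ex / sum(ex))), 0.03)
})

test_that("runs are deterministic per seed and respect slit/bond invariants", {
  geom <- build_hex_array(8, 5, 3)
  cfg <- sim_config(n_beads = 30, posts = "attractive", epsilon = 1,
                    geometry = geom, n_steps = 5000, sample_every = 100,
                    snapshot_every = 1000, seed = 11)
  tr1 <- run_sim(cfg)
  tr2 <- run_sim(cfg)
  expect_identical(tr1$com_track$xy, tr2$com_track$xy)
  expect_identical(tr1$rg_samples, tr2$rg_samples)
  for (snap in tr1$snapshots) {
    expect_true(all(snap[, 3] >= 0 & snap[, 3] <= 3))
    b <- sqrt(rowSums((snap[-1, ] - snap[-nrow(snap), ])^2))
    expect_true(all(b < cfg$r_max))
    # no bead inside a post
    expect_true(all(nearest_post_distance(snap[, 1:2], geom) > geom$post_radius))
  }
})

test_that("projected Rg is zero for one bead and scales like sqrt(n)", {
  cfg1 <- sim_config(n_beads = 1)
  st1 <- init_chain(cfg1, seed = 5)
  expect_identical(projected_rg(st1), 0)

  # ideal-chain scaling of the random-walk initial ensemble
  rg_of <- function(n, seeds) {
    cfg <- sim_config(n_beads = n, slit_height = Inf)
    mean(vapply(seeds, function(s) projected_rg(init_chain(cfg, seed = s)), 0))
  }
  ratio <- rg_of(160, 1:150) / rg_of(40, 151:300)
  expect_equal(ratio, 2, tolerance = 0.12)
})

test_that("COM of a free chain diffuses at D0/n (internal forces cancel)", {
  cfg <- sim_config(n_beads = 4, slit_height = Inf, n_steps = 4e6,
                    sample_every = 400, seed = 21)
  tr <- run_sim(cfg)
  cv <- msd(tr$com_track, max_lag = 1200)
  f <- fit_diffusivity(cv, c(400, 1200), dim = 2)
  expect_equal(f$D, 1 / 4, tolerance = 0.25)
})

test_that("weak attraction outpaces repulsive posts in a dense array", {
  # weakly attractive posts (below the adsorption threshold) let the COM
  # approach the surface, freeing volume that repulsive posts deny; the
  # long-term diffusivity in the dense array is higher as a result
  DL <- function(posts, seed) {
    geom <- build_hex_array(16, 7, 3)
    cfg <- sim_config(posts = posts, epsilon = 0.6, geometry = geom,
                      n_steps = 2e6, sample_every = 500, equil_steps = 1e5,
                      seed = seed)
    tr <- run_sim(cfg)
    fit_diffusivity(msd(tr$com_track, max_lag = 1500), c(400, 1500), dim = 2)$D
  }
  expect_gt(DL("attractive", 701), 1.3 * DL("repulsive", 711))
})

test_that("attractive posts gather the COM near the surface, repulsive deplete it", {
  geom <- build_hex_array(16, 7, 3)
  near_frac <- function(posts, eps, seed) {
    cfg <- sim_config(posts = posts, epsilon = eps, geometry = geom,
                      n_steps = 6e5, sample_every = 100, equil_steps = 1e5,
                      seed = seed)
    tr <- run_sim(cfg)
    mean(nearest_post_distance(tr$com_samples, geom) < geom$post_radius + 3)
  }
  # epsilon = 1.5 sits above the chain's adsorption threshold
  fa <- near_frac("attractive", 1.5, 31)
  fr <- near_frac("repulsive", 1.5, 32)
  # uniform-area expectation for the shell R < r < R + 3 in the cell
  a <- geom$lattice_const
  f_unif <- (pi * (19^2 - 16^2)) / (a^2 * sqrt(3) / 2 - pi * 16^2)
  expect_gt(fa, f_unif)
  expect_lt(fr, f_unif)
  expect_gt(fa, 3 * fr)
})
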