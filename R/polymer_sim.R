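# Langevin dynamics of the bead-spring chain ---------------------------------

#' Simulation configuration
#'
#' Parameters of the coarse-grained Langevin model: a Gaussian chain of
#' `n_beads` beads joined by FENE springs (with a WCA core between bonded
#' neighbours only; non-bonded beads do not interact), confined between
#' reflecting walls at `z = 0` and `z = H`, with an optional hexagonal array
#' of cylindrical posts that attract (or repel) every bead through a
#' Lennard-Jones potential in the distance from the post surface.
#'
#' All quantities are in simulation units: bead diameter `sigma`, thermal
#' energy `kT` and bead mass `mass` equal to 1 by default; friction
#' coefficient `gamma = 0.1` gives a bead diffusivity `D0 = kT/(mass*gamma)`
#' and a bead diffusion time `t_D = sigma^2/D0` used as the reporting time
#' unit. The integration step `dt` is 0.1 t_D.
#'
#' @param n_beads Chain length (beads).
#' @param k_s FENE spring constant (kT/sigma^2).
#' @param r_max Maximum bond extension (sigma).
#' @param sigma Bead diameter.
#' @param kT Thermal energy.
#' @param mass Bead mass.
#' @param gamma Friction coefficient (1/time).
#' @param dt Integration time step (time units; default 0.1 t_D).
#' @param posts `"none"`, `"attractive"` or `"repulsive"`.
#' @param epsilon Post-bead attraction strength (kT).
#' @param r_cutoff Post interaction cutoff beyond the post surface (sigma).
#'   Defaults to 2.5 for attractive posts and 1.12 (the potential minimum,
#'   leaving only the repulsive core) for repulsive ones.
#' @param geometry A [build_hex_array()] geometry; required when
#'   `posts != "none"`. Its `slit_height` sets the wall separation.
#' @param slit_height Wall separation when no geometry is given; `Inf`
#'   disables the walls (free 3-D chain).
#' @param fene_form `"kremer-grest"` (standard, argument `(r/r_max)^2` in the
#'   FENE logarithm) or `"literal"` (unsquared argument), kept for
#'   comparison.
#' @param n_steps Number of integration steps of a production run.
#' @param sample_every Sampling stride (steps).
#' @param snapshot_every Full-configuration snapshot stride (steps; 0 = off).
#' @param equil_steps Equilibration steps run before sampling.
#' @param seed RNG seed for the run.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_beads = 160, k_s = 30, r_max = 1.5, sigma = 1,
                       kT = 1, mass = 1, gamma = 0.1, dt = 0.01,
                       posts = c("none", "attractive", "repulsive"),
                       epsilon = 1, r_cutoff = NULL, geometry = NULL,
                       slit_height = 3, fene_form = c("kremer-grest", "literal"),
                       n_steps = 10000L, sample_every = 10L,
                       snapshot_every = 0L, equil_steps = 0L, seed = 1L) {
  posts <- match.arg(posts)
  fene_form <- match.arg(fene_form)
  stopifnot(dt > 0, gamma > 0, epsilon >= 0, n_beads >= 1, k_s > 0,
            r_max > 0, sample_every >= 1)
  if (posts != "none" && is.null(geometry))
    stop("posts require a `geometry` from build_hex_array()", call. = FALSE)
  if (is.null(r_cutoff))
    r_cutoff <- if (posts == "repulsive") 1.12 else 2.5
  stopifnot(r_cutoff > 0)
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "post_array"))
    slit_height <- geometry$slit_height
    reach <- geometry$post_radius + r_cutoff
    if (any(geometry$box / 2 < reach))
      stop("periodic box too small for the post interaction range; ",
           "increase n_cells", call. = FALSE)
  }
  cfg <- list(n_beads = as.integer(n_beads), k_s = k_s, r_max = r_max,
              sigma = sigma, kT = kT, mass = mass, gamma = gamma, dt = dt,
              posts = posts, epsilon = epsilon, r_cutoff = r_cutoff,
              geometry = geometry, slit_height = slit_height,
              fene_form = fene_form, n_steps = as.integer(n_steps),
              sample_every = as.integer(sample_every),
              snapshot_every = as.integer(snapshot_every),
              equil_steps = as.integer(equil_steps), seed = as.integer(seed))
  cfg$D0 <- kT / (mass * gamma)
  cfg$t_D <- sigma^2 / cfg$D0
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Langevin chain:", x$n_beads, "beads, k_s =", x$k_s, ", r_max =", x$r_max,
      ", gamma =", x$gamma, ", dt =", x$dt, "(", x$dt / x$t_D, "t_D )\n")
  cat("  posts:", x$posts,
      if (x$posts != "none") paste0("(epsilon = ", x$epsilon, ", r_cutoff = ",
                                    x$r_cutoff, ")"), "\n")
  cat("  slit height H =", x$slit_height, "; D0 =", x$D0, ", t_D =", x$t_D, "\n")
  invisible(x)
}

#' Mechanical equilibrium bond length
#'
#' Root of the combined FENE + WCA bond force, found by 1-D root bracketing
#' between 0.8 sigma and the WCA cutoff.
#'
#' @param config A [sim_config()].
#' @return Bond length (sigma) at which the bonded force vanishes.
#' @export
equilibrium_bond_length <- function(config) {
  stats::uniroot(function(r)
    bond_dudr_cpp(r, config$k_s, config$r_max, config$sigma,
                  config$fene_form == "literal"),
    interval = c(0.8, 2^(1 / 6) * config$sigma), tol = 1e-12)$root
}

#' Initial chain state
#'
#' Grows a random walk with the mechanical-equilibrium bond length,
#' rejecting growth directions that leave the slit or that would put a bead
#' closer than one bead diameter to a post surface (bond lengths stay
#' exactly at their equilibrium value, so the first integration steps are
#' stable). Velocities are drawn from the Maxwell-Boltzmann distribution.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; defaults to `config$seed`.
#' @return An object of class `chain_state` with `positions` (n x 3),
#'   `velocities` (n x 3) and elapsed `time`.
#' @export
init_chain <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_beads
  b0 <- if (n > 1) equilibrium_bond_length(config) else 0
  H <- config$slit_height
  geom <- config$geometry

  # start in a gap midpoint when posts are present, else at the origin
  if (!is.null(geom)) {
    start <- c(geom$post_radius + geom$gap / 2, 0)
  } else {
    start <- c(0, 0)
  }
  z0 <- if (is.finite(H)) H / 2 else 0
  pos <- matrix(0, n, 3)
  pos[1, ] <- c(start, z0)
  ok_point <- function(p) {
    if (is.finite(H) && (p[3] < 0 || p[3] > H)) return(FALSE)
    if (is.null(geom)) return(TRUE)
    nearest_post_distance(p[1:2], geom) >= geom$post_radius + config$sigma
  }
  i <- 2L
  while (i <= n) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      p <- pos[i - 1L, ] + b0 * u
      if (ok_point(p)) { pos[i, ] <- p; placed <- TRUE; break }
    }
    if (!placed) stop("failed to grow an initial chain avoiding the posts",
                      call. = FALSE)
    i <- i + 1L
  }
  vel <- matrix(stats::rnorm(3 * n, sd = sqrt(config$kT / config$mass)), n, 3)
  structure(list(positions = pos, velocities = vel, time = 0),
            class = "chain_state")
}

.sim_geom_args <- function(config) {
  if (is.null(config$geometry)) {
    list(centers = matrix(0, 0, 2), box = c(1e9, 1e9), post_R = 0,
         has_posts = FALSE)
  } else {
    g <- config$geometry
    list(centers = g$centers, box = g$box, post_R = g$post_radius,
         has_posts = config$posts != "none")
  }
}

#' Bonded (FENE + WCA) forces
#'
#' Forces from the bonded pair potential only; equal and opposite on each
#' bonded pair, zero between non-bonded beads (the chain is Gaussian).
#'
#' @param state A [init_chain()] state.
#' @param config A [sim_config()].
#' @return n x 3 matrix of per-bead force vectors.
#' @export
bonded_forces <- function(state, config) {
  bonded_forces_cpp(state$positions, config$k_s, config$r_max, config$sigma,
                    config$fene_form == "literal")
}

#' Post-bead forces
#'
#' In-plane radial force from the cutoff-shifted Lennard-Jones potential in
#' the distance from the nearest post surface (minimum image); zero beyond
#' the cutoff. The posts are z-invariant cylinders, so the force has no z
#' component.
#'
#' @inheritParams bonded_forces
#' @return n x 3 matrix of per-bead force vectors.
#' @export
post_forces <- function(state, config) {
  if (config$posts == "none" || is.null(config$geometry))
    return(matrix(0, nrow(state$positions), 3))
  ga <- .sim_geom_args(config)
  post_forces_cpp(state$positions, ga$centers, ga$box, ga$post_R,
                  config$epsilon, config$r_cutoff, config$sigma)
}

.run_cpp <- function(state, config, n_steps, sample_every,
                     snapshot_every = 0L, thermostat = TRUE,
                     sample_energy = FALSE) {
  ga <- .sim_geom_args(config)
  run_sim_cpp(state$positions, state$velocities,
              config$k_s, config$r_max, config$sigma, config$kT,
              config$mass, config$gamma, config$dt,
              config$fene_form == "literal",
              ga$centers, ga$box, ga$post_R, config$epsilon, config$r_cutoff,
              config$slit_height, ga$has_posts,
              is.finite(config$slit_height), thermostat,
              as.integer(n_steps), as.integer(sample_every),
              as.integer(snapshot_every), sample_energy)
}

#' Advance the chain by Langevin velocity-Verlet steps
#'
#' One (or a few) velocity-Verlet updates with friction `-m*gamma*v` and a
#' Gaussian random force of zero mean and per-component standard deviation
#' `sqrt(2*m*gamma*kT/dt)`, followed by specular reflection at the slit
#' walls and periodic wrapping in-plane (positions are kept unwrapped; the
#' posts are reached via minimum image). Uses R's RNG stream: call
#' `set.seed()` for reproducibility.
#'
#' @param state A `chain_state`.
#' @param config A [sim_config()].
#' @param n_steps Number of steps to take (default 1).
#' @param thermostat If `FALSE`, friction and random forces are disabled
#'   (microcanonical velocity-Verlet).
#' @return The updated `chain_state`.
#' @export
langevin_step <- function(state, config, n_steps = 1L, thermostat = TRUE) {
  out <- .run_cpp(state, config, n_steps, n_steps, 0L, thermostat)
  structure(list(positions = out$positions, velocities = out$velocities,
                 time = state$time + n_steps * config$dt),
            class = "chain_state")
}

#' Run a Langevin dynamics trial
#'
#' Runs `equil_steps` of unrecorded equilibration followed by `n_steps` of
#' production, sampling the in-plane center of mass (unwrapped and wrapped),
#' the projected radius of gyration and optionally full snapshots.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param state Optional starting `chain_state`; defaults to [init_chain()].
#' @return An object of class `sim_trace` with elements `com_track` (a
#'   [com_trajectory()] of the unwrapped in-plane COM, times in t_D),
#'   `rg_samples`, `com_samples` (wrapped, for PMF analysis), `times_tD`,
#'   `snapshots`, `final_state` and `config`.
#' @export
run_sim <- function(config, state = NULL) {
  set.seed(config$seed)
  if (is.null(state)) state <- init_chain(config, seed = config$seed)
  if (config$equil_steps > 0) {
    out <- .run_cpp(state, config, config$equil_steps, config$equil_steps)
    state <- structure(list(positions = out$positions,
                            velocities = out$velocities,
                            time = state$time + config$equil_steps * config$dt),
                       class = "chain_state")
  }
  out <- .run_cpp(state, config, config$n_steps, config$sample_every,
                  config$snapshot_every)
  times_tD <- out$times / config$t_D
  com <- out$com
  colnames(com) <- c("x", "y")
  track <- com_trajectory(times = times_tD, xy = com, units = "simulation")
  structure(
    list(com_track = track, rg_samples = as.numeric(out$rg),
         com_samples = out$com_wrapped, times_tD = times_tD,
         snapshots = out$snapshots,
         final_state = structure(list(positions = out$positions,
                                      velocities = out$velocities,
                                      time = state$time +
                                        config$n_steps * config$dt),
                                 class = "chain_state"),
         config = config),
    class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat("Langevin trace:", length(x$times_tD), "samples over",
      round(max(x$times_tD), 2), "t_D;", x$config$n_beads, "beads; posts:",
      x$config$posts, "\n")
  cat("  mean projected Rg =", round(mean(x$rg_samples), 3), "sigma\n")
  invisible(x)
}

#' Projected radius of gyration
#'
#' Root-mean-square in-plane distance of the beads from the in-plane center
#' of mass. Positions are stored unwrapped, so no minimum-image unwrap is
#' needed.
#'
#' @param state A `chain_state`.
#' @return Projected Rg (sigma).
#' @export
projected_rg <- function(state) {
  xy <- state$positions[, 1:2, drop = FALSE]
  ctr <- colMeans(xy)
  sqrt(mean((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2))
}

#' Total energy of a state (bonded + post potential + kinetic)
#'
#' Used for integrator order checks with the thermostat disabled.
#'
#' @param state A `chain_state`.
#' @param config A [sim_config()].
#' @return Total energy (kT units).
#' @export
total_energy <- function(state, config) {
  pos <- state$positions
  n <- nrow(pos)
  pe <- 0
  if (n > 1) {
    b <- sqrt(rowSums((pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE])^2))
    pe <- sum(vapply(b, bond_energy_cpp, 0, k_s = config$k_s,
                     r_max = config$r_max, sigma = config$sigma,
                     fene_literal = config$fene_form == "literal"))
  }
  if (config$posts != "none" && !is.null(config$geometry)) {
    s <- nearest_post_distance(pos[, 1:2, drop = FALSE], config$geometry) -
      config$geometry$post_radius
    pe <- pe + sum(vapply(s, post_energy_cpp, 0, eps = config$epsilon,
                          rcut = config$r_cutoff, sigma = config$sigma))
  }
  ke <- 0.5 * config$mass * sum(state$velocities^2)
  pe + ke
}
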