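# Synthetic single-molecule trajectories -------------------------------------

#' Synthetic trap-hop displacement trajectory
#'
#' Inverts the trap-hop observation model: a latent level ladder starting at
#' 0 stays put with probability `p_trap` each frame and otherwise hops one
#' level up or down (split `hop_bias` up), reflecting at level 0 (the
#' displacement ladder is non-negative) and, if set, at `n_levels_max`. The
#' observed displacement is `level * step_size_g` plus Gaussian noise of
#' standard deviation `w_trap / sqrt(2)`, so that the fitted width of
#' `exp(-(r - c)^2 / w^2)` returns `w_trap` and the generator matches the
#' decoder's emission convention exactly.
#'
#' A two-scale variant (`g2`, `g2_prob`) draws each hop magnitude from a
#' mixture of `step_size_g` and `g2`; the latent coordinate is then a
#' continuous ladder, exercising multi-optimum step-size scans.
#'
#' @param p_trap Per-frame trapping probability.
#' @param step_size_g Hop magnitude (um).
#' @param w_trap Within-trap fluctuation width (um).
#' @param frame_interval Frame interval (s): 3 for long-term, 0.5 for
#'   short-term observation settings.
#' @param duration Total duration (s): 3000 long-term, 100 short-term.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param n_levels_max Optional ceiling of the level ladder.
#' @param hop_bias Probability that a hop goes up (default 1/2).
#' @param g2,g2_prob Second hop magnitude and its probability (two-scale
#'   variant; `g2_prob = 0` disables it).
#' @return A displacement-form [com_trajectory()] with the latent level
#'   values stored in `attr(, "latent")`.
#' @export
synth_traphop <- function(p_trap, step_size_g = 0.84, w_trap = 0.31,
                          frame_interval = 3, duration = 3000, seed = 1L,
                          n_levels_max = NULL, hop_bias = 0.5,
                          g2 = NULL, g2_prob = 0) {
  stopifnot(p_trap >= 0, p_trap <= 1, step_size_g > 0, w_trap > 0,
            frame_interval > 0, duration >= frame_interval,
            hop_bias >= 0, hop_bias <= 1, g2_prob >= 0, g2_prob <= 1)
  if (g2_prob > 0 && is.null(g2)) g2 <- 1.4 * step_size_g
  set.seed(seed)
  n <- as.integer(floor(duration / frame_interval)) + 1L
  x <- numeric(n)  # latent displacement value (level * g for one scale)
  top <- if (is.null(n_levels_max)) Inf else n_levels_max * step_size_g
  for (t in 2:n) {
    if (stats::runif(1) < p_trap) {
      x[t] <- x[t - 1L]
    } else {
      gsz <- if (g2_prob > 0 && stats::runif(1) < g2_prob) g2 else step_size_g
      dir <- if (stats::runif(1) < hop_bias) 1 else -1
      xt <- x[t - 1L] + dir * gsz
      if (xt < 0) xt <- -xt              # reflect at the origin
      if (xt > top) xt <- 2 * top - xt   # optional ceiling
      x[t] <- xt
    }
  }
  r <- x + stats::rnorm(n, sd = w_trap / sqrt(2))
  out <- com_trajectory(seq(0, by = frame_interval, length.out = n), r = r,
                        units = "experimental")
  attr(out, "latent") <- x
  out
}

#' Synthetic 2-D Brownian track
#'
#' Gaussian increments of variance `2 D frame_interval` per axis: the null
#' model for MSD slope and displacement-distribution estimators, for which
#' `P(r^2)` is a single exponential with `lambda = 4 D lag`.
#'
#' @param D Diffusivity (um^2/s).
#' @param frame_interval Frame interval (s).
#' @param duration Total duration (s).
#' @param seed RNG seed.
#' @return A track-form [com_trajectory()].
#' @export
synth_brownian <- function(D, frame_interval = 3, duration = 3000, seed = 1L) {
  stopifnot(D >= 0, frame_interval > 0, duration >= frame_interval)
  set.seed(seed)
  n <- as.integer(floor(duration / frame_interval)) + 1L
  sd1 <- sqrt(2 * D * frame_interval)
  xy <- cbind(cumsum(c(0, stats::rnorm(n - 1L, sd = sd1))),
              cumsum(c(0, stats::rnorm(n - 1L, sd = sd1))))
  com_trajectory(seq(0, by = frame_interval, length.out = n), xy = xy,
                 units = "experimental")
}

#' Synthetic trapped (hop-free) displacement trajectory
#'
#' Independent shifted-Gaussian displacement samples about a fixed center:
#' the analogue of a molecule adsorbed on a single post for the whole
#' observation. The noise standard deviation is `w_trap / sqrt(2)` so the
#' shifted-Gaussian width fit returns `w_trap`.
#'
#' @param w_trap Fluctuation width (um).
#' @param center Fixed mean displacement (um).
#' @param frame_interval Frame interval (s).
#' @param duration Total duration (s).
#' @param seed RNG seed.
#' @return A displacement-form [com_trajectory()].
#' @export
synth_trapped <- function(w_trap = 0.31, center = 0.4, frame_interval = 3,
                          duration = 3000, seed = 1L) {
  stopifnot(w_trap > 0, frame_interval > 0, duration >= frame_interval)
  set.seed(seed)
  n <- as.integer(floor(duration / frame_interval)) + 1L
  r <- center + stats::rnorm(n, sd = w_trap / sqrt(2))
  com_trajectory(seq(0, by = frame_interval, length.out = n), r = r,
                 units = "experimental")
}
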