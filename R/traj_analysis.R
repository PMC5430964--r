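# COM trajectory statistics ---------------------------------------------------

#' Center-of-mass trajectory
#'
#' A timestamped single-molecule track: either a 2-D in-plane position
#' series (`xy`, track form) or a scalar displacement-from-origin series
#' (`r`, displacement form, as used by the trap-hop decoder). Times must be
#' strictly increasing and uniformly spaced (lag-based estimators rely on a
#' constant frame interval).
#'
#' @param times Time stamps (seconds for experimental tracks, t_D for
#'   simulation tracks).
#' @param xy n x 2 matrix of in-plane positions (um or sigma), or `NULL`.
#' @param r Displacement series `r(t) = |r(t) - r(0)|`, or `NULL`.
#' @param units `"experimental"` (um, s) or `"simulation"` (sigma, t_D).
#' @return An object of class `com_trajectory`.
#' @export
com_trajectory <- function(times, xy = NULL, r = NULL,
                           units = c("experimental", "simulation")) {
  units <- match.arg(units)
  times <- as.numeric(times)
  if (length(times) < 2L) stop("a trajectory needs at least 2 frames", call. = FALSE)
  dtv <- diff(times)
  if (any(dtv <= 0)) {
    stop("time stamps must be strictly increasing (first violation at frame ",
         which(dtv <= 0)[1L] + 1L, ")", call. = FALSE)
  }
  dt0 <- stats::median(dtv)
  if (any(abs(dtv - dt0) > 1e-6 * dt0)) {
    stop("non-uniform frame spacing (first violation at frame ",
         which(abs(dtv - dt0) > 1e-6 * dt0)[1L] + 1L, ")", call. = FALSE)
  }
  if (is.null(xy) == is.null(r))
    stop("provide exactly one of `xy` (track) or `r` (displacement series)",
         call. = FALSE)
  if (!is.null(xy)) {
    xy <- as.matrix(xy)
    stopifnot(ncol(xy) == 2L, nrow(xy) == length(times))
    obj <- list(times = times, xy = xy, r = NULL, kind = "track")
  } else {
    r <- as.numeric(r)
    stopifnot(length(r) == length(times))
    obj <- list(times = times, xy = NULL, r = r, kind = "displacement")
  }
  obj$frame_interval <- dt0
  obj$units <- units
  structure(obj, class = "com_trajectory")
}

#' @export
print.com_trajectory <- function(x, ...) {
  cat("COM trajectory (", x$kind, "): ", length(x$times), " frames every ",
      signif(x$frame_interval, 6), if (x$units == "experimental") " s" else " t_D",
      ", duration ", signif(max(x$times) - min(x$times), 6), "\n", sep = "")
  invisible(x)
}

#' Displacement-from-origin series of a track
#'
#' `r(t) = |r(t) - r(0)|`, the scalar series analysed by the trap-hop
#' decoder.
#'
#' @param traj A track-form [com_trajectory()].
#' @return A displacement-form `com_trajectory`.
#' @export
displacement_series <- function(traj) {
  stopifnot(inherits(traj, "com_trajectory"))
  if (traj$kind != "track") return(traj)
  r <- sqrt((traj$xy[, 1] - traj$xy[1, 1])^2 + (traj$xy[, 2] - traj$xy[1, 2])^2)
  com_trajectory(traj$times, r = r, units = traj$units)
}

#' Mean squared displacement
#'
#' Time-window (all overlapping pairs) average
#' `MSD(k dt) = mean over t of |r(t + k dt) - r(t)|^2` at every
#' integer-multiple lag up to `max_lag`. The per-lag uncertainty is the
#' absolute difference between the MSD of the first and second halves of the
#' pair population.
#'
#' @param traj A track-form [com_trajectory()].
#' @param max_lag Largest lag, in the trajectory's time units. Defaults to
#'   one quarter of the duration.
#' @param overlapping If `FALSE`, only non-overlapping pairs enter the
#'   average (for error analysis).
#' @return An object of class `msd_curve`: data frame with columns `lag`,
#'   `msd`, `n_pairs`, `half_ensemble_spread`.
#' @export
msd <- function(traj, max_lag = NULL, overlapping = TRUE) {
  stopifnot(inherits(traj, "com_trajectory"))
  if (traj$kind != "track")
    stop("msd() needs a track-form trajectory (2-D positions)", call. = FALSE)
  n <- length(traj$times)
  dt0 <- traj$frame_interval
  if (is.null(max_lag)) max_lag <- (max(traj$times) - min(traj$times)) / 4
  kmax <- floor(max_lag / dt0 + 1e-9)
  if (kmax < 1L)
    stop("max_lag smaller than one frame interval: empty curve", call. = FALSE)
  kmax <- min(kmax, n - 1L)
  x <- traj$xy[, 1]; y <- traj$xy[, 2]
  lag <- numeric(kmax + 1L); m <- numeric(kmax + 1L)
  np <- integer(kmax + 1L); spread <- numeric(kmax + 1L)
  np[1L] <- n
  for (k in seq_len(kmax)) {
    idx <- if (overlapping) seq_len(n - k) else seq(1L, n - k, by = k)
    d2 <- (x[idx + k] - x[idx])^2 + (y[idx + k] - y[idx])^2
    lag[k + 1L] <- k * dt0
    m[k + 1L] <- mean(d2)
    np[k + 1L] <- length(d2)
    h <- length(d2) %/% 2L
    spread[k + 1L] <- if (h >= 1L)
      abs(mean(d2[seq_len(h)]) - mean(d2[seq(h + 1L, length(d2))])) else NA_real_
  }
  structure(data.frame(lag = lag, msd = m, n_pairs = np,
                       half_ensemble_spread = spread),
            class = c("msd_curve", "data.frame"))
}

.window_rows <- function(curve, window, need = 2L, drop_zero_lag = TRUE) {
  sel <- curve$lag >= window[1] - 1e-9 & curve$lag <= window[2] + 1e-9
  if (drop_zero_lag) sel <- sel & curve$lag > 0
  if (sum(sel) < need)
    stop("window [", window[1], ", ", window[2], "] covers fewer than ", need,
         " lags of the curve", call. = FALSE)
  sel
}

#' Diffusivity from an MSD window
#'
#' Least-squares line through MSD vs lag over the window (free intercept);
#' `D = slope / (2 * dim)`. Used for both the short-time window (e.g. 0.5-3
#' s) and the long-time window (3.5-14 s) of experimental tracks.
#'
#' @param curve An [msd()] curve.
#' @param window Length-2 lag range `(lag_min, lag_max)`.
#' @param dim Spatial dimension of the track (2 for slit-plane tracks).
#' @return An object of class `diffusivity_fit`: list with `D`, `slope`,
#'   `intercept`, `window`, `dim`.
#' @export
fit_diffusivity <- function(curve, window, dim = 2) {
  stopifnot(inherits(curve, "msd_curve"), length(window) == 2L, dim %in% c(2, 3))
  sel <- .window_rows(curve, window)
  fit <- stats::lm(msd ~ lag, data = curve[sel, ])
  slope <- unname(stats::coef(fit)[2L])
  structure(list(D = max(slope, 0) / (2 * dim), slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 window = window, dim = dim),
            class = "diffusivity_fit")
}

#' @export
print.diffusivity_fit <- function(x, ...) {
  cat("D =", signif(x$D, 4), "over lags [", x$window[1], ",", x$window[2],
      "] (dim", x$dim, ")\n")
  invisible(x)
}

#' Power-law exponent of an MSD window
#'
#' Slope of `log(MSD)` vs `log(lag)` over the window; 1 for normal
#' diffusion, about 0.5 in the segmental (Rouse) relaxation regime.
#'
#' @inheritParams fit_diffusivity
#' @return The exponent (scalar).
#' @export
powerlaw_exponent <- function(curve, window) {
  stopifnot(inherits(curve, "msd_curve"), length(window) == 2L)
  sel <- .window_rows(curve, window)
  if (any(curve$msd[sel] <= 0))
    stop("non-positive MSD in window: cannot take logarithms", call. = FALSE)
  unname(stats::coef(stats::lm(log(msd) ~ log(lag), data = curve[sel, ]))[2L])
}

#' Displacement distribution at a lag
#'
#' Normalized histogram, over all overlapping frame pairs at lag `lag`, of
#' the squared displacement `r(lag)^2` (`of = "r2"`) or of the displacement
#' magnitude (`of = "r"`). Bin masses sum to one.
#'
#' @param traj A track-form [com_trajectory()].
#' @param lag Time lag; must be an integer multiple of the frame interval.
#' @param bins Number of equal-width bins.
#' @param of `"r2"` or `"r"`.
#' @return An object of class `disp_hist`: list with `breaks`, `mids`,
#'   `mass`, `counts`, `lag`, `n_pairs`, `of`, and `low_stats` flag (fewer
#'   than 50 pairs).
#' @export
displacement_distribution <- function(traj, lag, bins = 50L, of = c("r2", "r")) {
  stopifnot(inherits(traj, "com_trajectory"))
  of <- match.arg(of)
  if (traj$kind != "track")
    stop("displacement_distribution() needs a track-form trajectory", call. = FALSE)
  dt0 <- traj$frame_interval
  k <- lag / dt0
  if (abs(k - round(k)) > 1e-6)
    stop("lag must be an integer multiple of the frame interval", call. = FALSE)
  k <- as.integer(round(k))
  n <- length(traj$times)
  if (k < 1L || k >= n) stop("lag outside the trajectory", call. = FALSE)
  idx <- seq_len(n - k)
  d2 <- (traj$xy[idx + k, 1] - traj$xy[idx, 1])^2 +
    (traj$xy[idx + k, 2] - traj$xy[idx, 2])^2
  v <- if (of == "r2") d2 else sqrt(d2)
  hist_from_samples(v, bins = bins, lag = lag, of = of)
}

#' Build a normalized histogram from raw samples
#'
#' @param v Numeric samples.
#' @param bins Number of equal-width bins.
#' @param lag Optional lag tag carried along for derived diffusivities.
#' @param of Label of the binned quantity.
#' @return A `disp_hist` (see [displacement_distribution()]).
#' @export
hist_from_samples <- function(v, bins = 50L, lag = NA_real_, of = "r2") {
  rng <- range(v)
  if (diff(rng) == 0)
    stop("degenerate sample: all values identical", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  structure(list(breaks = breaks, mids = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
                 mass = counts / sum(counts), counts = counts, lag = lag,
                 n_pairs = length(v), of = of, low_stats = length(v) < 50L),
            class = "disp_hist")
}

#' Exponential-family fits of the squared-displacement distribution
#'
#' Fits `P(r^2)` with a single exponential `C1 exp(-r^2/lambda1)`, a double
#' exponential `C1 exp(-r^2/lambda1) + C2 exp(-r^2/lambda2)` (small-scale
#' transport around a post plus a long inter-post tail), or a stretched
#' exponential `C exp(-(r^2/lambda)^beta)`. Fits are done on `ln P` vs `r^2`
#' weighted by bin counts, mirroring straight-line fits on semilog axes.
#' The characteristic diffusivity of a scale is `lambda / (4 * lag)`.
#'
#' @param hist A `disp_hist` of `r^2`.
#' @param model `"single"`, `"double"` or `"stretched"`.
#' @return An object of class `displacement_fit`: list with `lag`,
#'   `lambda1`, `lambda2`, `c1`, `c2`, `stretch_beta`, `derived_D`,
#'   `derived_D2`, `degenerate` flag and `model`.
#' @export
fit_exponentials <- function(hist, model = c("single", "double", "stretched")) {
  stopifnot(inherits(hist, "disp_hist"))
  model <- match.arg(model)
  nz <- hist$mass > 0
  if (sum(nz) < 5L)
    stop("need at least 5 non-zero bins to fit", call. = FALSE)
  x <- hist$mids[nz]; p <- hist$mass[nz]; w <- hist$counts[nz]

  # weighted single-exponential line on ln p vs x
  lf <- stats::lm(log(p) ~ x, weights = w)
  l1 <- -1 / unname(stats::coef(lf)[2L])
  c1 <- exp(unname(stats::coef(lf)[1L]))
  if (!is.finite(l1) || l1 <= 0)
    stop("single-exponential fit failed: non-decaying distribution", call. = FALSE)

  res <- list(lag = hist$lag, lambda1 = l1, lambda2 = NULL, c1 = c1, c2 = NULL,
              stretch_beta = NULL, degenerate = FALSE, model = model)
  if (model == "double") {
    # head fit for the small scale, tail (x > 3*lambda1_head) for the large
    head <- x <= stats::median(x)
    lh <- stats::lm(log(p[head]) ~ x[head], weights = w[head])
    l1h <- max(-1 / unname(stats::coef(lh)[2L]), min(diff(range(x)) / 10, l1))
    tail <- x > 3 * l1h
    if (sum(tail) >= 3L) {
      lt <- stats::lm(log(p[tail]) ~ x[tail], weights = w[tail])
      l2h <- -1 / unname(stats::coef(lt)[2L])
      c2h <- exp(unname(stats::coef(lt)[1L]))
    } else {
      l2h <- 3 * l1h; c2h <- c1 / 10
    }
    if (!is.finite(l2h) || l2h <= l1h) { l2h <- 3 * l1h; c2h <- c1 / 10 }
    fit <- tryCatch(
      minpack.lm::nlsLM(p ~ a1 * exp(-x / b1) + a2 * exp(-x / b2),
                        start = list(a1 = exp(unname(stats::coef(lh)[1L])),
                                     b1 = l1h, a2 = c2h, b2 = l2h),
                        weights = w,
                        lower = c(0, 1e-12, 0, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      # the two scales collapsed onto one: report the single-exponential
      # solution with the degeneracy flagged rather than failing
      res$lambda2 <- l1; res$c2 <- 0; res$degenerate <- TRUE
    } else {
      cf <- stats::coef(fit)
      if (cf[["b2"]] < cf[["b1"]]) cf <- cf[c("a2", "b2", "a1", "b1")]
      res$lambda1 <- unname(cf[2L]); res$c1 <- unname(cf[1L])
      res$lambda2 <- unname(cf[4L]); res$c2 <- unname(cf[3L])
      # degenerate when the second scale carries no weight or collapses
      res$degenerate <- res$c2 < 1e-3 * res$c1 ||
        res$lambda2 < 1.2 * res$lambda1
    }
  } else if (model == "stretched") {
    fit <- tryCatch(
      minpack.lm::nlsLM(log(p) ~ lc - (x / l)^b,
                        start = list(lc = log(c1), l = l1, b = 1),
                        weights = w,
                        lower = c(-Inf, 1e-12, 0.05), upper = c(Inf, Inf, 2),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("stretched-exponential fit failed to converge: ",
                               conditionMessage(e), call. = FALSE))
    cf <- stats::coef(fit)
    res$lambda1 <- unname(cf[["l"]]); res$c1 <- exp(unname(cf[["lc"]]))
    res$stretch_beta <- unname(cf[["b"]])
  }
  res$derived_D <- res$lambda1 / (4 * hist$lag)
  res$derived_D2 <- if (!is.null(res$lambda2)) res$lambda2 / (4 * hist$lag) else NULL
  structure(res, class = "displacement_fit")
}

#' @export
print.displacement_fit <- function(x, ...) {
  cat("P(r^2) ", x$model, " fit at lag ", x$lag, ": lambda1 = ",
      signif(x$lambda1, 4), sep = "")
  if (!is.null(x$lambda2)) cat(", lambda2 =", signif(x$lambda2, 4))
  if (!is.null(x$stretch_beta)) cat(", beta =", signif(x$stretch_beta, 3))
  if (isTRUE(x$degenerate)) cat(" [degenerate second scale]")
  cat("\n")
  invisible(x)
}

#' Shifted-Gaussian fit of a displacement histogram
#'
#' Fits `A * exp(-(r - c)^2 / w^2)` to a histogram of the displacement
#' magnitude; the width convention has no factor 2 so that `w` maps
#' one-to-one onto the trap-hop emission width `w_trap`. The fit is a
#' count-weighted quadratic regression of the log bin mass (a straight
#' parabola on semilog axes), which is variance-correct for multinomial
#' bin counts and has a closed-form solution.
#'
#' @param hist A `disp_hist` of `r`, or a numeric vector of raw samples
#'   (then binned internally).
#' @param bins Bins used when `hist` is a raw sample vector.
#' @return An object of class `trap_width_fit`: list with `center`, `width`
#'   and `amplitude`.
#' @export
fit_trap_width <- function(hist, bins = 30L) {
  if (is.numeric(hist)) {
    if (diff(range(hist)) == 0)
      stop("degenerate input: all samples identical, width undefined", call. = FALSE)
    hist <- hist_from_samples(hist, bins = bins, of = "r")
  }
  stopifnot(inherits(hist, "disp_hist"))
  nz <- hist$counts > 0
  if (sum(nz) < 4L)
    stop("degenerate histogram: too few occupied bins for a width fit",
         call. = FALSE)
  x <- hist$mids[nz]; lp <- log(hist$mass[nz]); wt <- hist$counts[nz]
  fit <- stats::lm(lp ~ x + I(x^2), weights = wt)
  b <- stats::coef(fit)
  if (!is.finite(b[[3L]]) || b[[3L]] >= 0)
    stop("shifted-Gaussian fit failed: histogram is not unimodal-concave",
         call. = FALSE)
  w0 <- sqrt(-1 / b[[3L]])
  c0 <- b[[2L]] * w0^2 / 2
  structure(list(center = c0, width = w0,
                 amplitude = exp(b[[1L]] + c0^2 / w0^2)),
            class = "trap_width_fit")
}

#' @export
print.trap_width_fit <- function(x, ...) {
  cat("shifted Gaussian: center =", signif(x$center, 4), ", width w =",
      signif(x$width, 4), "\n")
  invisible(x)
}
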