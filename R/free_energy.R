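# Conformational-fluctuation barrier and PMF ---------------------------------

#' Conformational-fluctuation barrier model
#'
#' One-dimensional transition-path picture of a coiled chain crossing the
#' gap between two posts a distance `gap_d` apart: for an ideal coil the
#' end-to-end vector is Gaussian, so each post contributes a half-Gaussian
#' free-energy well with variance `<x^2>_0 = <R_EE^2>_0 / 3 = 2 Rg^2` along
#' the reaction coordinate.
#'
#' @param gap_d Surface-to-surface gap between posts (um).
#' @param r_g Radius of gyration (um).
#' @return An object of class `barrier_model` with `gap_d`, `r_g` and
#'   `x2_0 = 2 r_g^2`.
#' @export
barrier_model <- function(gap_d, r_g) {
  stopifnot(gap_d >= 0, r_g > 0)
  structure(list(gap_d = gap_d, r_g = r_g, x2_0 = 2 * r_g^2),
            class = "barrier_model")
}

#' Free-energy profile along the reaction path
#'
#' `beta F(x) = x^2 / (2 <x^2>_0) + (x - d)^2 / (2 <x^2>_0)`, the sum of the
#' two half-Gaussian contributions centred a distance `d` apart; symmetric
#' about `x = d/2`.
#'
#' @param model A [barrier_model()].
#' @param x Positions along the reaction path (um), vectorized.
#' @return `beta F(x)` in kT.
#' @export
barrier_profile <- function(model, x) {
  stopifnot(inherits(model, "barrier_model"))
  (x^2 + (x - model$gap_d)^2) / (2 * model$x2_0)
}

#' Barrier height of the conformational-fluctuation model
#'
#' The closed form `beta F* = d^2 / (8 Rg^2)`, i.e. the profile evaluated at
#' the midpoint `x = d/2`.
#'
#' @param model A [barrier_model()].
#' @return `beta F*` in kT.
#' @export
barrier_height <- function(model) {
  stopifnot(inherits(model, "barrier_model"))
  model$gap_d^2 / (8 * model$r_g^2)
}

#' @export
print.barrier_model <- function(x, ...) {
  cat("Conformational-fluctuation barrier: d =", x$gap_d, ", Rg =", x$r_g,
      "-> beta F* =", signif(barrier_height(x), 4), "kT\n")
  invisible(x)
}

#' Potential of mean force from COM samples
#'
#' Folds in-plane center-of-mass samples into one primitive cell of the
#' post lattice using the lattice translation symmetry only, histograms
#' them in fractional (lattice) coordinates, and Boltzmann-inverts:
#' `U_eff / kT = -ln P(r_COM)`, shifted so the minimum over populated bins
#' is zero. Bins with zero counts are reported as `NA` (undefined), never
#' as an infinite energy. The per-bin uncertainty is the absolute
#' difference between the maps of the first and second halves of the
#' sample set. A transect is extracted along the line joining two
#' nearest-neighbour post centers (the shortest inter-post path), reported
#' against the distance `dr` from the post surface.
#'
#' Without a geometry the samples are folded into the rectangular `box`
#' instead (useful for validating against known landscapes); no transect
#' is produced.
#'
#' @param samples n x 2 matrix of in-plane COM positions (sigma).
#' @param geometry A [build_hex_array()] geometry, or `NULL`.
#' @param bins Number of bins per lattice direction.
#' @param box Rectangular fold dimensions when `geometry` is `NULL`.
#' @return An object of class `pmf_grid`: list with `u_eff` (bins x bins,
#'   `NA` = unpopulated), `half_ensemble_delta`, `counts`, `frac_centers`,
#'   `cell_vectors`, `transect` (data frame `dr`, `u_eff`, `half_delta`),
#'   `n_samples`.
#' @export
pmf_from_samples <- function(samples, geometry = NULL, bins = 32L, box = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L) stop("empty sample set", call. = FALSE)
  stopifnot(ncol(samples) == 2L)
  bins <- as.integer(bins)

  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "post_array"))
    a <- geometry$lattice_const
    # primitive (rhombic) cell of the triangular lattice
    L <- matrix(c(a, 0, a / 2, a * sqrt(3) / 2), 2L, 2L)
  } else {
    if (is.null(box)) stop("need `geometry` or `box` to fold samples", call. = FALSE)
    L <- diag(box)
  }
  Linv <- solve(L)
  frac <- samples %*% t(Linv)
  h <- 1 / bins
  # fold so that bin centers sit on the cell edges (frac = 0 line), letting
  # the inter-post transect read bins centred on the post-center line
  frac <- (frac + h / 2) %% 1

  ij <- pmin(pmax(floor(frac / h), 0), bins - 1L)
  idx <- ij[, 1L] + bins * ij[, 2L] + 1L

  bin_counts <- function(id) {
    matrix(tabulate(id, nbins = bins * bins), bins, bins)
  }
  u_of <- function(cnt) {
    p <- cnt / sum(cnt)
    u <- -log(p)
    u[cnt == 0] <- NA_real_
    u - min(u, na.rm = TRUE)
  }
  counts <- bin_counts(idx)
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: all samples in one bin", call. = FALSE)
  u <- u_of(counts)
  nh <- nrow(samples) %/% 2L
  if (nh >= 1L && nh < nrow(samples)) {
    u1 <- u_of(bin_counts(idx[seq_len(nh)]))
    u2 <- u_of(bin_counts(idx[seq(nh + 1L, nrow(samples))]))
    half_delta <- abs(u1 - u2)
  } else {
    half_delta <- u * NA_real_
  }
  frac_centers <- (seq_len(bins) - 1L) * h  # first bin centred at frac = 0

  transect <- NULL
  if (!is.null(geometry)) {
    R <- geometry$post_radius
    d <- geometry$gap
    # line from (0,0) to the neighbour at (a, 0): frac2 = 0, frac1 in (R/a, 1 - R/a)
    f1 <- frac_centers
    x_line <- f1 * geometry$lattice_const
    on_gap <- x_line >= R & x_line <= R + d
    i1 <- which(on_gap)
    transect <- data.frame(dr = x_line[i1] - R,
                           u_eff = u[i1, 1L],
                           half_delta = half_delta[i1, 1L])
  }
  structure(list(u_eff = u, half_ensemble_delta = half_delta, counts = counts,
                 frac_centers = frac_centers, cell_vectors = L,
                 transect = transect, n_samples = nrow(samples),
                 bins = bins),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat("PMF grid:", x$bins, "x", x$bins, "bins from", x$n_samples, "samples;",
      sum(is.na(x$u_eff)), "unpopulated bins\n")
  if (!is.null(x$transect)) {
    bh <- transect_barrier(x)
    cat("  gap transect barrier:", signif(bh["barrier"], 3), "+/-",
        signif(bh["uncertainty"], 3), "kT\n")
  }
  invisible(x)
}

#' Barrier read off a PMF gap transect
#'
#' Height of the transect maximum in the middle third of the gap above the
#' transect minimum, together with the half-ensemble uncertainty at the
#' maximum. `NA` values (unpopulated bins) are ignored; an unpopulated
#' mid-gap with populated surroundings is reported as an effectively
#' unsampled (large) barrier.
#'
#' @param grid A [pmf_from_samples()] result with a transect.
#' @return Named numeric: `barrier`, `uncertainty`.
#' @export
transect_barrier <- function(grid) {
  stopifnot(inherits(grid, "pmf_grid"), !is.null(grid$transect))
  tr <- grid$transect
  d <- max(tr$dr) + min(tr$dr)  # symmetric sampling across the gap
  mid <- tr$dr > d / 3 & tr$dr < 2 * d / 3
  u_min <- min(tr$u_eff, na.rm = TRUE)
  if (all(is.na(tr$u_eff[mid]))) {
    return(c(barrier = Inf, uncertainty = NA_real_))
  }
  i_max <- which(mid)[which.max(tr$u_eff[mid])]
  c(barrier = tr$u_eff[i_max] - u_min, uncertainty = tr$half_delta[i_max])
}
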