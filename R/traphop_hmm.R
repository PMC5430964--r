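# Hidden-Markov trap-hop decoder ---------------------------------------------

#' Trapped-step ladder (emission model)
#'
#' The displacement trajectory is modelled as a ladder of `n_steps + 1`
#' trapped levels at `r0(j) = j * g`, `j = 0..n_steps`, with within-trap
#' Gaussian fluctuations of width `w_trap`: the (unnormalized) emission
#' weight of level j at displacement r is `exp(-(r - j g)^2 / w_trap^2)`.
#'
#' @param step_size_g Spacing between trapped displacement levels (um).
#' @param w_trap Emission width (um).
#' @param n_steps Number of trapped steps N (levels `0..N`), or `NULL` to
#'   infer `ceiling(max(r) / g)` from the data.
#' @return An object of class `step_model`.
#' @export
step_model <- function(step_size_g = 0.84, w_trap = 0.31, n_steps = NULL) {
  stopifnot(step_size_g > 0, w_trap > 0)
  if (!is.null(n_steps)) {
    n_steps <- as.integer(n_steps)
    stopifnot(n_steps >= 1L)
  }
  structure(list(step_size_g = step_size_g, w_trap = w_trap,
                 n_steps = n_steps),
            class = "step_model")
}

.resolve_n_steps <- function(model, r) {
  if (!is.null(model$n_steps)) return(model$n_steps)
  max(1L, as.integer(ceiling(max(r) / model$step_size_g)))
}

#' Level centers of a step model
#' @param model A [step_model()].
#' @param n_steps Number of steps (required if not set in the model).
#' @return Numeric vector `j * g`, `j = 0..n_steps`.
#' @export
level_centers <- function(model, n_steps = model$n_steps) {
  stopifnot(!is.null(n_steps))
  (0:n_steps) * model$step_size_g
}

#' Tridiagonal trap-hop transition matrix
#'
#' Diagonal `p_trap`; interior rows split `p_hop = 1 - p_trap` evenly
#' between the two neighbouring levels; the boundary rows (levels 0 and N)
#' put the full `p_hop` on their single neighbour. Every row sums to one.
#'
#' @param p_trap Per-frame trapping probability, in `[0, 1]`.
#' @param n_steps Number of trapped steps N (matrix is `(N+1) x (N+1)`).
#' @return Row-stochastic transition matrix.
#' @export
transition_matrix <- function(p_trap, n_steps) {
  stopifnot(p_trap >= 0, p_trap <= 1, n_steps >= 1)
  K <- n_steps + 1L
  p_hop <- 1 - p_trap
  tm <- diag(rep(p_trap, K))
  if (K == 2L) {
    tm[1L, 2L] <- p_hop
    tm[2L, 1L] <- p_hop
  } else {
    tm[1L, 2L] <- p_hop
    tm[K, K - 1L] <- p_hop
    for (i in 2:(K - 1L)) {
      tm[i, i - 1L] <- p_hop / 2
      tm[i, i + 1L] <- p_hop / 2
    }
  }
  tm
}

#' Emission weights of a displacement series
#'
#' `v_j(t) = exp(-(r(t) - j g)^2 / w_trap^2)` for levels `j = 0..N`
#' (unnormalized likelihood weights; only ratios matter to the decoder).
#'
#' @param r Displacement series (numeric vector, um).
#' @param model A [step_model()].
#' @param n_steps Number of steps; defaults to the model's, else inferred.
#' @param log If `TRUE`, return log weights `-(r - j g)^2 / w_trap^2`
#'   (never underflow; preferred for decoding).
#' @return `length(r) x (N+1)` matrix of emission weights.
#' @export
hmm_emissions <- function(r, model, n_steps = NULL, log = FALSE) {
  stopifnot(inherits(model, "step_model"))
  if (is.null(n_steps)) n_steps <- .resolve_n_steps(model, r)
  ctr <- (0:n_steps) * model$step_size_g
  le <- -outer(r, ctr, function(ri, cj) (ri - cj)^2) / model$w_trap^2
  dimnames(le) <- list(NULL, paste0("j", 0:n_steps))
  if (log) le else exp(le)
}

#' Viterbi decoding of the trapped-step path
#'
#' Maximum-product hidden-state path under the emission weights and the
#' tridiagonal transition matrix, computed by dynamic programming in log
#' space with a uniform prior over the initial level. Ties break toward the
#' lower state index.
#'
#' @param emissions Frames x states matrix of emission weights, or of log
#'   weights if `log = TRUE` (e.g. from [hmm_emissions()]).
#' @param tmat Transition matrix from [transition_matrix()].
#' @param log Whether `emissions` are already logarithms.
#' @return An object of class `decoded_path`: list with `states` (level
#'   index per frame, `0..N`), `log_prob` of the path, and `n_states`.
#' @export
viterbi_decode <- function(emissions, tmat, log = FALSE) {
  emissions <- as.matrix(emissions)
  Tn <- nrow(emissions); K <- ncol(emissions)
  stopifnot(Tn >= 1L, nrow(tmat) == K, ncol(tmat) == K)
  le <- if (log) emissions else {
    bad <- rowSums(emissions > 0) == 0L
    if (any(bad))
      stop("all-zero emission row at frame ", which(bad)[1L],
           ": underflow; supply log emissions", call. = FALSE)
    base::log(emissions)
  }
  lT <- suppressWarnings(base::log(tmat))
  delta <- le[1L, ]  # uniform prior
  psi <- matrix(0L, Tn, K)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      cand <- delta + lT  # cand[i, j]: arrive in j from i
      best <- apply(cand, 2L, which.max)  # first max = lowest previous index
      psi[t, ] <- best
      delta <- cand[cbind(best, seq_len(K))] + le[t, ]
    }
  }
  states <- integer(Tn)
  states[Tn] <- which.max(delta)
  if (Tn > 1L) for (t in (Tn - 1L):1L) states[t] <- psi[t + 1L, states[t + 1L]]
  structure(list(states = states - 1L, log_prob = max(delta), n_states = K),
            class = "decoded_path")
}

#' Greedy nearest-level assignment (no-Viterbi baseline)
#'
#' Assigns every frame to the emission-maximizing (nearest) level with no
#' transition information; kept as the baseline whose fit quality the
#' Viterbi iteration is compared against.
#'
#' @param r Displacement series.
#' @param model A [step_model()].
#' @param n_steps Number of steps; inferred from the data when `NULL`.
#' @return A `decoded_path`.
#' @export
greedy_decode <- function(r, model, n_steps = NULL) {
  if (is.null(n_steps)) n_steps <- .resolve_n_steps(model, r)
  le <- hmm_emissions(r, model, n_steps, log = TRUE)
  states <- max.col(le, ties.method = "first") - 1L
  structure(list(states = states, log_prob = NA_real_, n_states = n_steps + 1L),
            class = "decoded_path")
}

#' Observed transition matrix of a decoded path
#'
#' Counts transitions between consecutive decoded levels and normalizes each
#' row; rows never left (no outgoing transition) are flagged unvisited and
#' left as `NA`.
#'
#' @param path A `decoded_path` (or integer vector of levels `0..N`).
#' @param n_steps Number of trapped steps N.
#' @return List with `probs` (row-normalized matrix, `NA` rows unvisited),
#'   `counts` (transition count matrix), `row_counts` and logical `visited`.
#' @export
empirical_transitions <- function(path, n_steps) {
  states <- if (inherits(path, "decoded_path")) path$states else as.integer(path)
  if (length(states) < 2L)
    stop("need a path of length >= 2 to count transitions", call. = FALSE)
  K <- n_steps + 1L
  from <- states[-length(states)] + 1L
  to <- states[-1L] + 1L
  counts <- matrix(0, K, K)
  for (t in seq_along(from)) counts[from[t], to[t]] <- counts[from[t], to[t]] + 1
  row_counts <- rowSums(counts)
  probs <- counts / ifelse(row_counts > 0, row_counts, NA_real_)
  list(probs = probs, counts = counts, row_counts = row_counts,
       visited = row_counts > 0)
}

#' Best-matching trapping probability for an observed transition matrix
#'
#' Minimizes the row-weighted Frobenius norm `|T* - T(p_trap)|` over
#' `p_trap` in `[0, 1]`, restricted to the rows actually visited by the
#' decoded path (golden-section/Brent search; the norm is unimodal in
#' `p_trap` for this tridiagonal family). By default each row's residual is
#' weighted by its visit count, since the sampling variance of an observed
#' row scales as one over its count; rows crossed only transiently then no
#' longer dominate the estimate. Pass uniform weights for the plain
#' Frobenius norm.
#'
#' @param empirical A result of [empirical_transitions()].
#' @param n_steps Number of trapped steps N.
#' @param row_weights Per-row weights (length `n_steps + 1`), or `NULL` for
#'   the observed row visit counts.
#' @return The minimizing `p_trap` (scalar).
#' @export
fit_p_trap <- function(empirical, n_steps, row_weights = NULL) {
  vis <- empirical$visited
  if (!any(vis)) stop("no visited transitions: p_trap undefined", call. = FALSE)
  if (is.null(row_weights)) row_weights <- empirical$row_counts
  w <- row_weights[vis]
  Tstar <- empirical$probs[vis, , drop = FALSE]
  obj <- function(p) {
    Tm <- transition_matrix(p, n_steps)[vis, , drop = FALSE]
    sum(w * rowSums((Tstar - Tm)^2))
  }
  # exact line search: the objective is quadratic in p_trap
  opt <- stats::optimize(obj, c(0, 1), tol = 1e-9)
  # guard the boundary: optimize() never quite reaches the interval ends
  cands <- c(opt$minimum, 0, 1)
  cands[which.min(vapply(cands, obj, 0))]
}

#' Reduced chi-squared fit quality of a transition model
#'
#' Pearson statistic between the model matrix `T(p_trap)` and the observed
#' matrix, over the non-zero observed entries of visited rows, divided by
#' the degrees of freedom `nu = (number of non-zero observed entries) - 3`.
#'
#' With `counts = TRUE` (default for [viterbi_iterate()]), the statistic is
#' computed on transition counts, `sum((O - E)^2 / O)` with expected counts
#' `E = n_i T_ij`; a correctly specified model then gives values near one
#' regardless of trajectory length, which is the scale on which the fit
#' criterion `chi2/nu = 1` operates. With `counts = FALSE` the probability
#' matrices are compared directly, `sum((T - T*)^2 / T*)`; this quantity
#' shrinks toward zero as sampling grows.
#'
#' @param tmat Model transition matrix.
#' @param empirical A result of [empirical_transitions()].
#' @param counts Use transition counts (Pearson scale) rather than raw
#'   probabilities.
#' @return `chi2 / nu` (scalar).
#' @export
reduced_chi2 <- function(tmat, empirical, counts = FALSE) {
  vis <- empirical$visited
  if (counts) {
    O <- empirical$counts[vis, , drop = FALSE]
    E <- tmat[vis, , drop = FALSE] * empirical$row_counts[vis]
    nz <- O > 0
    chi2 <- sum((O[nz] - E[nz])^2 / O[nz])
  } else {
    Tstar <- empirical$probs[vis, , drop = FALSE]
    Tm <- tmat[vis, , drop = FALSE]
    nz <- Tstar > 0
    chi2 <- sum((Tm[nz] - Tstar[nz])^2 / Tstar[nz])
  }
  nu <- sum(nz) - 3L
  if (nu <= 0)
    stop("degenerate degrees of freedom: ", sum(nz),
         " non-zero entries (need > 3)", call. = FALSE)
  chi2 / nu
}

#' Apparent free-energy barrier from a trapping probability
#'
#' `P_hop ~ exp(-beta dG)` gives `dG = -ln(1 - p_trap)` in units of kT
#' (unit prefactor). `p_trap = 1` (no hop ever observed) returns the
#' infinite-barrier sentinel `Inf`.
#'
#' @param p_trap Trapping probability (vectorized), in `[0, 1]`.
#' @return Barrier(s) in kT.
#' @export
barrier_from_p <- function(p_trap) {
  stopifnot(all(p_trap >= 0), all(p_trap <= 1))
  -log1p(-p_trap)
}

#' Smallest detectable trapping probability
#'
#' Finite frame intervals hide hops faster than the Nyquist frequency
#' `f_Nyq = frame_rate / 2`; the detection floor is
#' `exp(-frame_interval * f_Nyq)`. Fitted trapping probabilities below the
#' floor are unreliable.
#'
#' @param frame_interval Interval between analysed frames.
#' @param frame_rate Acquisition frame rate.
#' @return The minimum resolvable `p_trap`.
#' @export
detection_floor <- function(frame_interval, frame_rate) {
  stopifnot(frame_interval >= 0, frame_rate >= 0)
  exp(-frame_interval * frame_rate / 2)
}

#' Viterbi iteration for the most likely trapping probability
#'
#' Alternates (1) Viterbi decoding of the trapped-step path under the
#' current `T(p_trap)`, (2) counting the observed transition matrix `T*`
#' and (3) re-fitting `p_trap` by minimizing `|T* - T(p_trap)|`, until the
#' change in `p_trap` drops below `tol`. The converged probability is
#' independent of the starting guess `p0` within `tol` for well-posed
#' trajectories.
#'
#' @param r Displacement series: numeric vector or a displacement-form (or
#'   track-form) [com_trajectory()].
#' @param model A [step_model()] (step size g and width w_trap).
#' @param p0 Initial trapping-probability guess.
#' @param tol Convergence tolerance on `p_trap`.
#' @param max_iter Maximum number of iterations.
#' @param decoder `"viterbi"` or `"greedy"` (the nearest-level baseline).
#' @param floor Optional detection floor from [detection_floor()]; fits
#'   below it are flagged.
#' @return An object of class `hmm_result`: list with `p_trap_star`,
#'   `chi2_over_nu` (count-scale Pearson), `chi2_prob` (probability-scale),
#'   `delta_G`, `iterations`, `history`, `empirical_T`, `path`, `n_steps`,
#'   `model`, `converged`, `below_floor`.
#' @export
viterbi_iterate <- function(r, model = step_model(), p0 = 0.5, tol = 1e-3,
                            max_iter = 100L, decoder = c("viterbi", "greedy"),
                            floor = NULL) {
  decoder <- match.arg(decoder)
  if (inherits(r, "com_trajectory")) r <- displacement_series(r)$r
  r <- as.numeric(r)
  stopifnot(tol > 0, p0 >= 0, p0 <= 1)
  n_steps <- .resolve_n_steps(model, r)
  le <- hmm_emissions(r, model, n_steps, log = TRUE)

  p <- p0
  history <- p0
  converged <- FALSE
  path <- NULL; emp <- NULL
  for (k in seq_len(max_iter)) {
    path <- if (decoder == "viterbi") {
      viterbi_decode(le, transition_matrix(p, n_steps), log = TRUE)
    } else {
      greedy_decode(r, model, n_steps)
    }
    emp <- empirical_transitions(path, n_steps)
    p_new <- fit_p_trap(emp, n_steps)
    history <- c(history, p_new)
    done <- abs(p_new - p) < tol
    p <- p_new
    if (done || decoder == "greedy") { converged <- TRUE; break }
  }
  if (!converged)
    stop("Viterbi iteration did not converge in ", max_iter,
         " iterations; p_trap history: ",
         paste(signif(history, 4), collapse = ", "), call. = FALSE)
  tm <- transition_matrix(p, n_steps)
  # a hop-free decode observes too few matrix entries for a chi2: report NA
  chi2_safe <- function(counts) tryCatch(reduced_chi2(tm, emp, counts = counts),
                                         error = function(e) NA_real_)
  structure(list(
    p_trap_star = p,
    chi2_over_nu = chi2_safe(TRUE),
    chi2_prob = chi2_safe(FALSE),
    delta_G = barrier_from_p(p),
    iterations = length(history) - 1L,
    history = history,
    empirical_T = emp,
    path = path,
    n_steps = n_steps,
    model = model,
    decoder = decoder,
    converged = converged,
    below_floor = if (is.null(floor)) NA else p < floor
  ), class = "hmm_result")
}

#' @export
print.hmm_result <- function(x, ...) {
  cat("Trap-hop HMM fit (", x$decoder, "): p_trap* = ",
      signif(x$p_trap_star, 4), ", chi2/nu = ", signif(x$chi2_over_nu, 3),
      ", dG = ", signif(x$delta_G, 3), " kT (N = ", x$n_steps, ", ",
      x$iterations, " iterations)\n", sep = "")
  if (isTRUE(x$below_floor)) cat("  warning: p_trap* below the detection floor\n")
  invisible(x)
}

#' Scan the trapped step size
#'
#' Runs the Viterbi iteration over a grid of candidate step sizes `g` and
#' reports the fit quality per value; local minima of `chi2/nu` mark
#' optimal step sizes (two distinct transport scales show up as two local
#' minima).
#'
#' @param r Displacement series (vector or [com_trajectory()]).
#' @param g_grid Candidate step sizes.
#' @param w_trap Emission width.
#' @param ... Passed to [viterbi_iterate()].
#' @return Data frame with columns `g`, `p_trap_star`, `chi2_over_nu`,
#'   `delta_G`, `n_steps`, `is_local_min`.
#' @export
scan_step_size <- function(r, g_grid, w_trap = 0.31, ...) {
  stopifnot(length(g_grid) >= 1L)
  if (inherits(r, "com_trajectory")) r <- displacement_series(r)$r
  rows <- lapply(g_grid, function(g) {
    fit <- viterbi_iterate(r, step_model(g, w_trap), ...)
    data.frame(g = g, p_trap_star = fit$p_trap_star,
               chi2_over_nu = fit$chi2_over_nu, delta_G = fit$delta_G,
               n_steps = fit$n_steps)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$g)
  out <- out[ord, , drop = FALSE]
  n <- nrow(out)
  chi <- ifelse(is.na(out$chi2_over_nu), Inf, out$chi2_over_nu)
  lm_flag <- rep(FALSE, n)
  for (i in seq_len(n)) {
    left_ok <- i == 1L || chi[i] < chi[i - 1L]
    right_ok <- i == n || chi[i] < chi[i + 1L]
    lm_flag[i] <- left_ok && right_ok && is.finite(chi[i])
  }
  out$is_local_min <- lm_flag
  rownames(out) <- NULL
  out
}
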