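# Unit mapping and post-array geometry ---------------------------------------

#' Simulation-to-physical unit map
#'
#' The coarse-grained chain is a freely jointed (Gaussian) bead-spring model
#' whose bead diameter `sigma` is matched to one Kuhn segment of dye-labeled
#' DNA (about 134 nm). Lengths convert as `sigma_nm` nanometres per sigma;
#' diffusivities additionally require the physical duration of one bead
#' diffusion time `t_D` (the time for a bead to diffuse its own diameter).
#'
#' @param sigma_nm Physical length of one bead diameter, in nanometres.
#' @param n_beads Number of beads in the chain.
#' @param t_D_s Optional physical duration of one diffusion time, in seconds.
#'   Needed only to convert diffusivities.
#' @return An object of class `unit_map`.
#' @examples
#' um <- unit_map()
#' to_physical(um, 3.9, "length")  # projected Rg in nm
#' @export
unit_map <- function(sigma_nm = 134, n_beads = 160, t_D_s = NULL) {
  stopifnot(is.numeric(sigma_nm), length(sigma_nm) == 1L, sigma_nm > 0)
  stopifnot(is.numeric(n_beads), length(n_beads) == 1L, n_beads >= 1)
  if (!is.null(t_D_s)) stopifnot(is.numeric(t_D_s), t_D_s > 0)
  structure(
    list(sigma_nm = sigma_nm, n_beads = as.integer(n_beads), t_D_s = t_D_s),
    class = "unit_map"
  )
}

#' @export
print.unit_map <- function(x, ...) {
  cat("Unit map: 1 sigma =", x$sigma_nm, "nm;", x$n_beads, "beads")
  if (!is.null(x$t_D_s)) cat("; 1 t_D =", x$t_D_s, "s")
  cat("\n")
  cat("  contour length:", contour_length_um(x), "um\n")
  invisible(x)
}

#' Convert a simulation-unit quantity to physical units
#'
#' Lengths (sigma) scale by `sigma_nm`; diffusivities (sigma^2/t_D) scale by
#' `sigma_nm^2 / t_D_s` and therefore require the time calibration.
#'
#' @param um A [unit_map()].
#' @param quantity Numeric value(s) in simulation units.
#' @param kind `"length"` (result in nm) or `"diffusivity"`
#'   (result in nm^2/s).
#' @return Numeric, converted values.
#' @export
to_physical <- function(um, quantity, kind = c("length", "diffusivity")) {
  stopifnot(inherits(um, "unit_map"))
  kind <- match.arg(kind)
  if (kind == "length") {
    quantity * um$sigma_nm
  } else {
    if (is.null(um$t_D_s)) {
      stop("diffusivity conversion requires `t_D_s` to be set in the unit map",
           call. = FALSE)
    }
    quantity * um$sigma_nm^2 / um$t_D_s
  }
}

#' Contour length of the mapped chain in micrometres
#'
#' `(n_beads - 1)` bonds of one Kuhn length each.
#'
#' @param um A [unit_map()].
#' @return Contour length in micrometres.
#' @export
contour_length_um <- function(um) {
  stopifnot(inherits(um, "unit_map"))
  (um$n_beads - 1) * um$sigma_nm / 1000
}

#' Hexagonal post array in a slit
#'
#' Builds the triangular (hexagonal) lattice of cylindrical posts spanning a
#' slit of height `slit_height`. The gap `gap` is surface-to-surface, so the
#' nearest-neighbour center-to-center spacing is `2 * post_radius + gap`.
#' The periodic supercell is the standard rectangular two-post cell of the
#' triangular lattice, dimensions `a x a*sqrt(3)` with lattice constant
#' `a = 2R + d`, repeated `n_cells` times along x and y. All lengths are in
#' simulation units (sigma).
#'
#' @param post_radius Post radius R (sigma).
#' @param gap Surface-to-surface nearest gap d (sigma).
#' @param slit_height Wall separation H (sigma).
#' @param n_cells Integer vector of length 1 or 2: rectangular-cell repeats
#'   along x and y.
#' @return An object of class `post_array` with fields `post_radius`, `gap`,
#'   `slit_height`, `lattice_const`, `centers` (matrix, one post per row),
#'   `box` (periodic in-plane dimensions), `n_cells`.
#' @examples
#' geom <- build_hex_array(16, 7, 3)
#' geom$lattice_const  # 39 sigma
#' @export
build_hex_array <- function(post_radius, gap, slit_height, n_cells = c(1L, 1L)) {
  if (!is.numeric(post_radius) || post_radius <= 0 ||
      !is.numeric(gap) || gap <= 0 ||
      !is.numeric(slit_height) || slit_height <= 0) {
    stop("invalid geometry: post_radius, gap and slit_height must be positive",
         call. = FALSE)
  }
  n_cells <- as.integer(rep_len(n_cells, 2L))
  if (any(n_cells < 1L)) stop("invalid geometry: n_cells must be >= 1", call. = FALSE)

  a <- 2 * post_radius + gap
  box <- c(a * n_cells[1L], a * sqrt(3) * n_cells[2L])

  # two posts per rectangular cell: (0, 0) and (a/2, a*sqrt(3)/2)
  ix <- rep(seq_len(n_cells[1L]) - 1L, each = n_cells[2L])
  iy <- rep(seq_len(n_cells[2L]) - 1L, times = n_cells[1L])
  base <- cbind(ix * a, iy * a * sqrt(3))
  centers <- rbind(base, sweep(base, 2L, c(a / 2, a * sqrt(3) / 2), "+"))
  colnames(centers) <- c("x", "y")

  structure(
    list(post_radius = post_radius, gap = gap, slit_height = slit_height,
         lattice_const = a, centers = centers, box = box, n_cells = n_cells),
    class = "post_array"
  )
}

#' @export
print.post_array <- function(x, ...) {
  cat("Hexagonal post array: R =", x$post_radius, "sigma, gap d =", x$gap,
      "sigma, H =", x$slit_height, "sigma\n")
  cat("  lattice constant 2R + d =", x$lattice_const, "sigma;",
      nrow(x$centers), "posts in a", x$box[1], "x", round(x$box[2], 3),
      "periodic box\n")
  invisible(x)
}

#' Minimum-image in-plane displacement
#'
#' @param dxy Matrix (n x 2) of raw displacement components.
#' @param box Periodic box dimensions, length 2.
#' @return Matrix of wrapped displacement components, each within
#'   `[-box/2, box/2]`.
#' @export
minimum_image <- function(dxy, box) {
  dxy <- rbind(dxy)  # tolerate a bare vector
  dxy[, 1L] <- dxy[, 1L] - box[1L] * round(dxy[, 1L] / box[1L])
  dxy[, 2L] <- dxy[, 2L] - box[2L] * round(dxy[, 2L] / box[2L])
  dxy
}

#' Distance from points to the nearest post axis
#'
#' Minimum-image distance in the slit plane from each point to the nearest
#' post center.
#'
#' @param xy Matrix (n x 2) of in-plane positions (sigma).
#' @param geom A [build_hex_array()] geometry.
#' @return Numeric vector of distances to the nearest post axis.
#' @export
nearest_post_distance <- function(xy, geom) {
  stopifnot(inherits(geom, "post_array"))
  xy <- rbind(xy)
  d2 <- matrix(Inf, nrow(xy), 1L)
  for (k in seq_len(nrow(geom$centers))) {
    d <- minimum_image(cbind(xy[, 1L] - geom$centers[k, 1L],
                             xy[, 2L] - geom$centers[k, 2L]), geom$box)
    d2 <- pmin(d2, d[, 1L]^2 + d[, 2L]^2)
  }
  sqrt(as.numeric(d2))
}

#' Serialize a geometry to a YAML block / write post centers
#'
#' @param geom A [build_hex_array()] geometry.
#' @param path Optional file path; if `NULL` the YAML string is returned.
#' @return `geometry_to_yaml`: YAML string (invisibly if written to file).
#' @export
geometry_to_yaml <- function(geom, path = NULL) {
  stopifnot(inherits(geom, "post_array"))
  y <- yaml::as.yaml(list(
    post_radius = geom$post_radius, gap = geom$gap,
    slit_height = geom$slit_height, n_cells = as.integer(geom$n_cells)
  ))
  if (is.null(path)) return(y)
  writeLines(y, path)
  invisible(y)
}

#' @rdname geometry_to_yaml
#' @export
geometry_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  build_hex_array(cfg$post_radius, cfg$gap, cfg$slit_height,
                  n_cells = cfg$n_cells %||% c(1L, 1L))
}

#' @rdname geometry_to_yaml
#' @export
write_post_centers <- function(geom, path) {
  stopifnot(inherits(geom, "post_array"))
  utils::write.table(geom$centers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
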