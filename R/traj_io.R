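# Trajectory files, snapshots, pipeline --------------------------------------

#' Write a COM trajectory as tab-separated text
#'
#' Track form: header `time<TAB>x<TAB>y`; displacement form:
#' `time<TAB>r`. Comment lines start with `#`; the unit system is stored in
#' a `# units:` header comment so conversions stay explicit.
#'
#' @param traj A [com_trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "com_trajectory"))
  units_tag <- if (traj$units == "experimental") "um,s" else "sigma,tD"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# units: ", units_tag),
               paste0("# kind: ", traj$kind)), con)
  df <- if (traj$kind == "track") {
    data.frame(time = traj$times, x = traj$xy[, 1], y = traj$xy[, 2])
  } else {
    data.frame(time = traj$times, r = traj$r)
  }
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a COM trajectory from tab-separated text
#'
#' Dispatches on the columns: `time, x, y` gives a track,
#' `time, r` a displacement series. Time stamps are validated for
#' monotonicity and uniform spacing; the unit system is taken from the
#' `# units:` header comment unless overridden.
#'
#' @param path Input file.
#' @param units Optional `"experimental"` or `"simulation"` override.
#' @return A [com_trajectory()].
#' @examples
#' # a bundled synthetic displacement trajectory (p_trap = 0.6, g = 0.84 um)
#' f <- system.file("extdata", "synthetic_traphop_example.tsv",
#'                  package = "traphop")
#' read_trajectory(f)
#' @export
read_trajectory <- function(path, units = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 20L)
  units_line <- grep("^#\\s*units:", header, value = TRUE)
  if (is.null(units)) {
    units <- if (length(units_line) &&
                 grepl("sigma", units_line[1L])) "simulation" else "experimental"
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  cols <- tolower(names(df))
  if (!"time" %in% cols)
    stop("missing `time` column in ", path, call. = FALSE)
  if (all(c("x", "y") %in% cols)) {
    com_trajectory(df[["time"]], xy = cbind(df[["x"]], df[["y"]]), units = units)
  } else if ("r" %in% cols) {
    com_trajectory(df[["time"]], r = df[["r"]], units = units)
  } else {
    stop("expected columns time/x/y or time/r in ", path, call. = FALSE)
  }
}

#' Write chain snapshots as extended XYZ
#'
#' One frame per snapshot; beads are tagged "C" so standard molecular
#' viewers open the file, and the periodic in-plane box plus slit height is
#' recorded in the extended-XYZ `Lattice` field of the comment line.
#'
#' @param snapshots List of n x 3 coordinate matrices (e.g.
#'   `sim_trace$snapshots`).
#' @param path Output file.
#' @param box In-plane periodic dimensions, length 2.
#' @param slit_height Wall separation (third lattice vector).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(snapshots, path, box, slit_height) {
  con <- file(path, "w")
  on.exit(close(con))
  lat <- sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3',
                 box[1], box[2], slit_height)
  for (snap in snapshots) {
    writeLines(as.character(nrow(snap)), con)
    writeLines(lat, con)
    writeLines(sprintf("C %.8g %.8g %.8g", snap[, 1], snap[, 2], snap[, 3]), con)
  }
  invisible(path)
}

# --- pipeline ----------------------------------------------------------------

.known_stages <- c("barrier", "synth", "simulate", "msd", "hmm", "scan_g", "pmf")

.stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  path
}

#' Run an analysis pipeline from a YAML config
#'
#' Executes the configured stages in order, writing one JSON result file
#' per stage and a run manifest. Supported stages (top-level YAML keys):
#'
#' * `barrier`: `d_um`, `rg_um` - closed-form conformational barrier.
#' * `synth`: `mode` (`traphop`/`brownian`/`trapped`) plus the generator
#'   arguments and `out` (TSV path) - synthetic trajectory.
#' * `simulate`: Langevin run; geometry plus [sim_config()] arguments,
#'   optional `xyz_out`; writes the COM track TSV.
#' * `msd`: `input` TSV, `max_lag`, optional `window` and `dim` - MSD and
#'   diffusivity fit.
#' * `hmm`: `input` TSV, `g`, `w_trap`, `p0`, `tol` - Viterbi iteration.
#' * `scan_g`: `input` TSV, `g_min`, `g_max`, `g_by`, `w_trap` - step-size
#'   scan.
#' * `pmf`: `input` TSV of wrapped COM samples plus the geometry - PMF map
#'   and gap transect.
#'
#' The whole config is validated before any stage runs.
#'
#' @param config_path Path to the YAML configuration.
#' @param out_dir Output directory (default: the config's directory).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config_path, out_dir = dirname(config_path)) {
  if (!file.exists(config_path))
    stop("no such config: ", config_path, call. = FALSE)
  cfg <- yaml::read_yaml(config_path)
  if (length(cfg) == 0L) stop("empty pipeline config", call. = FALSE)
  bad <- setdiff(names(cfg), .known_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(.known_stages, collapse = ", "), ")", call. = FALSE)
  # validate inputs before any compute
  for (nm in intersect(names(cfg), c("msd", "hmm", "scan_g", "pmf"))) {
    inp <- cfg[[nm]]$input
    if (is.null(inp)) stop("stage `", nm, "` needs an `input` file", call. = FALSE)
    inp <- file.path(out_dir, inp)
    if (!file.exists(inp) && is.null(cfg$synth) && is.null(cfg$simulate))
      stop("stage `", nm, "`: missing input file ", inp, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list(); seeds <- list()
  t_start <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  for (nm in names(cfg)) {
    st <- cfg[[nm]]
    res_path <- file.path(out_dir, paste0(nm, ".json"))
    if (nm == "barrier") {
      bm <- barrier_model(st$d_um, st$rg_um)
      .stage_json(list(d_um = st$d_um, rg_um = st$rg_um,
                       beta_F_star = barrier_height(bm)), res_path)
    } else if (nm == "synth") {
      seed <- st$seed %||% 1L
      seeds[[nm]] <- seed
      traj <- switch(st$mode %||% "traphop",
        traphop = synth_traphop(st$p_trap, st$g %||% 0.84, st$w_trap %||% 0.31,
                                st$frame_interval %||% 3, st$duration %||% 3000,
                                seed = seed),
        brownian = synth_brownian(st$D, st$frame_interval %||% 3,
                                  st$duration %||% 3000, seed = seed),
        trapped = synth_trapped(st$w_trap %||% 0.31, st$center %||% 0.4,
                                st$frame_interval %||% 3,
                                st$duration %||% 3000, seed = seed),
        stop("unknown synth mode: ", st$mode, call. = FALSE))
      tsv <- file.path(out_dir, st$out %||% "synth.tsv")
      write_trajectory(traj, tsv)
      outputs[[paste0(nm, "_tsv")]] <- tsv
      .stage_json(list(mode = st$mode %||% "traphop", seed = seed,
                       frames = length(traj$times), out = basename(tsv)),
                  res_path)
    } else if (nm == "simulate") {
      seed <- st$seed %||% 1L
      seeds[[nm]] <- seed
      geom <- if (!is.null(st$gap))
        build_hex_array(st$post_radius %||% 16, st$gap,
                        st$slit_height %||% 3,
                        n_cells = st$n_cells %||% c(1L, 1L))
      sc <- sim_config(n_beads = st$n_beads %||% 160,
                       posts = st$posts %||% if (is.null(geom)) "none" else "attractive",
                       epsilon = st$epsilon %||% 1,
                       geometry = geom,
                       slit_height = st$slit_height %||% 3,
                       n_steps = st$n_steps %||% 10000L,
                       sample_every = st$sample_every %||% 10L,
                       snapshot_every = st$snapshot_every %||% 0L,
                       equil_steps = st$equil_steps %||% 0L,
                       seed = seed)
      tr <- run_sim(sc)
      tsv <- file.path(out_dir, st$out %||% "com_track.tsv")
      write_trajectory(tr$com_track, tsv)
      outputs[[paste0(nm, "_tsv")]] <- tsv
      if (!is.null(st$xyz_out) && length(tr$snapshots)) {
        xyz <- file.path(out_dir, st$xyz_out)
        write_xyz(tr$snapshots, xyz, sc$geometry$box %||% c(0, 0),
                  sc$slit_height)
        outputs[[paste0(nm, "_xyz")]] <- xyz
      }
      .stage_json(list(seed = seed, n_beads = sc$n_beads, posts = sc$posts,
                       n_steps = sc$n_steps,
                       mean_projected_rg = mean(tr$rg_samples),
                       out = basename(tsv)), res_path)
    } else if (nm == "msd") {
      traj <- read_trajectory(file.path(out_dir, st$input))
      curve <- msd(traj, max_lag = st$max_lag %||% NULL)
      res <- list(n_lags = nrow(curve))
      if (!is.null(st$window)) {
        fit <- fit_diffusivity(curve, unlist(st$window), dim = st$dim %||% 2)
        res$D <- fit$D; res$window <- unlist(st$window); res$dim <- fit$dim
      }
      utils::write.table(curve, file.path(out_dir, paste0(nm, "_curve.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      .stage_json(res, res_path)
    } else if (nm == "hmm") {
      traj <- read_trajectory(file.path(out_dir, st$input))
      fit <- viterbi_iterate(traj,
                             step_model(st$g %||% 0.84, st$w_trap %||% 0.31),
                             p0 = st$p0 %||% 0.5, tol = st$tol %||% 1e-3)
      .stage_json(list(p_trap_star = fit$p_trap_star,
                       chi2_over_nu = fit$chi2_over_nu,
                       delta_G = fit$delta_G, n_steps = fit$n_steps,
                       iterations = fit$iterations), res_path)
    } else if (nm == "scan_g") {
      traj <- read_trajectory(file.path(out_dir, st$input))
      tab <- scan_step_size(traj,
                            seq(st$g_min, st$g_max, by = st$g_by %||% 0.1),
                            w_trap = st$w_trap %||% 0.31)
      .stage_json(tab, res_path)
    } else if (nm == "pmf") {
      df <- utils::read.table(file.path(out_dir, st$input), header = TRUE,
                              sep = "\t", comment.char = "#")
      geom <- build_hex_array(st$post_radius %||% 16, st$gap,
                              st$slit_height %||% 3,
                              n_cells = st$n_cells %||% c(1L, 1L))
      grid <- pmf_from_samples(cbind(df$x, df$y), geom,
                               bins = st$bins %||% 32L)
      tb <- transect_barrier(grid)
      .stage_json(list(bins = grid$bins, n_samples = grid$n_samples,
                       transect = grid$transect,
                       barrier = unname(tb["barrier"]),
                       barrier_uncertainty = unname(tb["uncertainty"])),
                  res_path)
    }
    outputs[[nm]] <- res_path
  }
  manifest <- list(config = cfg, seeds = seeds,
                   package_version = as.character(utils::packageVersion("traphop")),
                   outputs = lapply(outputs, basename),
                   started = t_start,
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  .stage_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
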