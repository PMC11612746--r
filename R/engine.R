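# Driver for the compiled N-MPCD/MD engine.

#' Run a hybrid N-MPCD/MD simulation
#'
#' Executes the full step cycle: MD substeps of the chain (with the
#' director field frozen between collisions), ballistic streaming of the
#' solvent, grid-shifted binning, director kicks accumulated from the
#' polymer's coupling torques, the momentum- and angular-momentum
#' conserving Andersen velocity collision (monomers participate with mass
#' M), the Maier-Saupe orientation collision with Jeffery shear coupling
#' and backflow compensation, and (for the cylinder) wall anchoring.
#' Deterministic given `(config, seed)`: all randomness comes from
#' labelled streams derived from the seed.
#'
#' @param config a `nemapoly_config` (see [sim_config()]).
#' @param steps number of MPCD steps (default `config$steps`).
#' @param seed seed override (default `config$seed`).
#' @param out_every frame cadence in MPCD steps (default
#'   `config$out_every`).
#' @param warmup steps to run before recording starts (default 0).
#' @param force_amp Kolmogorov body-force amplitude for viscosity
#'   fixtures (periodic box only): acceleration `force_amp *
#'   sin(2 pi x / Lx)` applied along the flow axis.
#' @param n_track number of fluid particles whose unwrapped trajectories
#'   are recorded (for self-diffusion measurements).
#' @param check_conservation track the worst per-cell momentum violation
#'   (diagnostic; small cost).
#' @param state resume state from a previous run (`run$state`), which
#'   continues the trajectory and RNG streams exactly.
#' @param init_director `"aligned"` (along the global axis) or
#'   `"random"`.
#' @param init_polymer `"extended"` (cylinder default) or `"coil"` (box
#'   default).
#' @param jeffery,backflow,angular_collision switch individual physics
#'   terms (for control runs).
#' @return An object of class `nemapoly_run`: list with `config`, `seed`,
#'   `frames` (N x 3 x nframes array of unwrapped bead positions), `cm`
#'   (nframes x 3 unwrapped centre of mass), `tracked` (n_track x 3 x
#'   nframes), `scalars` (per-frame data.frame: time, temperature,
#'   bond_mean, S_global, axis_alignment, flow_amplitude, energies),
#'   `diagnostics`, and `state` (for resume).
#' @export
run_simulation <- function(config, steps = NULL, seed = NULL,
                           out_every = NULL, warmup = 0, force_amp = 0,
                           n_track = 0, check_conservation = FALSE,
                           state = NULL, init_director = "aligned",
                           init_polymer = NULL, jeffery = TRUE,
                           backflow = TRUE, angular_collision = TRUE) {
  config <- validate_config(config)
  steps <- as.integer(if (is.null(steps)) config$steps else steps)
  seed <- as.integer(if (is.null(seed)) config$seed else seed)
  out_every <- as.integer(if (is.null(out_every)) config$out_every else out_every)
  if (is.null(init_polymer)) {
    init_polymer <- if (config$geometry == "cylinder") "extended" else "coil"
  }
  cfg <- list(
    d = config$d, geometry = config$geometry,
    Lx = config$Lx, Ly = config$Ly, Lz = config$Lz,
    L = config$L, R = config$R,
    density = config$density, kBT = config$kBT, m = config$m,
    dt = config$dt, U = config$U, lambda = config$lambda,
    alpha = config$alpha, gamma_R = config$gamma_R,
    N = as.integer(config$N), M = config$M, k_FENE = config$k_FENE,
    r0 = config$r0, r_max = config$r_max, epsilon = config$epsilon,
    sigma = config$sigma,
    k = config$k, dt_MD = config$dt_MD,
    md_substeps = config$md_substeps,
    force_amp = force_amp, n_track = as.integer(n_track),
    check_conservation = check_conservation,
    init_director = init_director, init_polymer = init_polymer,
    jeffery = jeffery, backflow = backflow,
    angular_collision = angular_collision)
  if (warmup > 0) {
    pre <- cpp_run(cfg, as.integer(warmup), as.integer(warmup), seed, state)
    state <- pre$state
  }
  res <- cpp_run(cfg, steps, out_every, seed, state)
  nframes <- length(res$time)
  N <- as.integer(config$N)
  # res$frames rows are frame-major blocks of N beads; rebuild as N x 3 x F
  frames <- array(numeric(0), c(0, 3, nframes))
  if (N > 0) {
    frames <- array(0, c(N, 3, nframes))
    for (f in seq_len(nframes)) {
      frames[, , f] <- res$frames[((f - 1) * N + 1):(f * N), , drop = FALSE]
    }
  }
  ntr <- as.integer(n_track)
  tracked <- if (ntr > 0) {
    tr <- array(0, c(ntr, 3, nframes))
    for (f in seq_len(nframes)) {
      tr[, , f] <- res$tracked[((f - 1) * ntr + 1):(f * ntr), , drop = FALSE]
    }
    tr
  } else NULL
  S_global <- vapply(seq_len(nframes), function(f) {
    q <- res$Q_global[f, ]
    M2 <- matrix(c(q[1], q[2], q[3], q[2], q[4], q[5], q[3], q[5], q[6]), 3, 3)
    d <- config$d
    if (d == 2) {
      qxx <- 2 * M2[1, 1] - 1
      qxy <- 2 * M2[1, 2]
      sqrt(qxx^2 + qxy^2)
    } else {
      max(eigen(1.5 * M2 - 0.5 * diag(3), symmetric = TRUE,
                only.values = TRUE)$values)
    }
  }, numeric(1))
  scalars <- data.frame(
    time = res$time, temperature = res$temperature,
    bond_mean = res$bond_mean, S_global = S_global,
    axis_alignment = res$axis_alignment,
    flow_amplitude = res$flow_amplitude,
    epot_fene = res$epot_fene, epot_wca = res$epot_wca,
    epot_npc = res$epot_npc, ekin_polymer = res$ekin_polymer)
  structure(list(config = config, seed = seed, frames = frames, cm = res$cm,
                 tracked = tracked, scalars = scalars,
                 n_fluid = res$n_fluid, diagnostics = res$diagnostics,
                 state = res$state),
            class = "nemapoly_run")
}

#' @export
print.nemapoly_run <- function(x, ...) {
  nf <- dim(x$frames)[3]
  cat("<nemapoly_run>\n")
  cat(sprintf("  %d fluid particles, N = %d beads, %d frames, t = %.4g .. %.4g t0\n",
              x$n_fluid, dim(x$frames)[1], nf,
              if (nf > 0) x$scalars$time[1] else NA,
              if (nf > 0) x$scalars$time[nf] else NA))
  cat(sprintf("  <T> = %.4f  <S> = %.3f", mean(x$scalars$temperature),
              mean(x$scalars$S_global)))
  if (!all(is.na(x$scalars$bond_mean))) {
    cat(sprintf("  <b> = %.4f", mean(x$scalars$bond_mean)))
  }
  cat("\n")
  invisible(x)
}

#' Per-cell director field of a run's final state
#'
#' Reconstructs the collision-grid director field (director components,
#' scalar order parameter, occupancy flag) from the final state of a run,
#' as a tidy table on the cell lattice; write it out with
#' [write_observables()].
#'
#' @param run a `nemapoly_run`.
#' @return data.frame with `ix`, `iy`, `iz` (0-based cell indices in the
#'   final shifted frame), `nx`, `ny`, `nz`, `S`, `occupied`.
#' @export
director_field <- function(run) {
  cfg <- run$config
  if (cfg$geometry == "cylinder") {
    W <- ceiling(cfg$R) + 1
    ncx <- 2 * W
    ncy <- 2 * W
    ncz <- round(cfg$L)
  } else {
    ncx <- round(cfg$Lx)
    ncy <- round(cfg$Ly)
    ncz <- if (cfg$d == 2) 1 else round(cfg$Lz)
  }
  df <- run$state$dir_field
  idx <- seq_len(nrow(df)) - 1
  data.frame(ix = idx %% ncx,
             iy = (idx %/% ncx) %% ncy,
             iz = idx %/% (ncx * ncy),
             nx = df[, 1], ny = df[, 2], nz = df[, 3],
             S = df[, 4], occupied = df[, 5] > 0)
}

#' Ready-made small test fixtures
#'
#' Named configurations (and the property each is meant to exhibit) used
#' by the test-suite and for quick exploration:
#' \describe{
#'   \item{pure_fluid_box}{periodic 3D box of pure solvent at `U = 6`;
#'     steady nematic order `S > 0.5`.}
#'   \item{isotropic_polymer}{solvated chain at `k = 0` in a periodic
#'     box; coil statistics, mean bond length 0.89 a.}
#'   \item{viscosity_channel}{periodic box with a sinusoidal body force;
#'     the steady flow amplitude yields the viscosity.}
#'   \item{self_diffusion_box}{equilibrium box with tracked fluid
#'     particles for the self-diffusion coefficient.}
#'   \item{demo_2d}{2D periodic square, `L = 30`, `N = 20`, `k = 20`:
#'     the strongly-coupled demonstration setup.}
#'   \item{hairpin_toy}{no simulation: hand-built conformations (rod,
#'     U-turn, zigzag) for detector tests, returned in `$conformations`.}
#' }
#'
#' @param name fixture name.
#' @return list with `config` (a `nemapoly_config`, NULL for
#'   `hairpin_toy`), `expected` (named list of the properties the fixture
#'   exhibits) and, for `hairpin_toy`, `conformations`.
#' @export
make_fixture <- function(name = c("pure_fluid_box", "isotropic_polymer",
                                  "viscosity_channel", "self_diffusion_box",
                                  "demo_2d", "hairpin_toy")) {
  name <- match.arg(name)
  switch(name,
    pure_fluid_box = list(
      config = sim_config(geometry = "box", Lx = 6, Ly = 6, Lz = 6, N = 0,
                          steps = 1500, out_every = 10),
      expected = list(S_steady_min = 0.5, temperature = 1)),
    isotropic_polymer = list(
      config = sim_config(geometry = "box", Lx = 8, Ly = 8, Lz = 8, N = 20,
                          k = 0, steps = 6000, out_every = 10),
      expected = list(bond_mean = 0.89, bond_tol = 0.02)),
    viscosity_channel = list(
      config = sim_config(geometry = "box", Lx = 8, Ly = 8, Lz = 8, N = 0,
                          steps = 5000, out_every = 10),
      expected = list(eta = 8.6, eta_tol = 1.0, force_amp = 0.025)),
    self_diffusion_box = list(
      config = sim_config(geometry = "box", Lx = 6, Ly = 6, Lz = 6, N = 0,
                          steps = 2500, out_every = 5),
      expected = list(n_track = 400)),
    demo_2d = list(
      config = sim_config(geometry = "box", d = 2, Lx = 30, Ly = 30, N = 20,
                          k = 20, steps = 2000, out_every = 10),
      expected = list()),
    hairpin_toy = {
      rod <- cbind(0, 0, 0.89 * (0:19))
      uturn <- rbind(cbind(0, 0, 0.89 * (9:0)),
                     cbind(0.9, 0, 0.89 * (0:9) + 0.4))
      zig <- rbind(cbind(0, 0, 0.89 * (0:6)),
                   cbind(0.9, 0, 0.89 * (6:0) + 0.3),
                   cbind(1.8, 0, 0.89 * (0:5) + 0.6))
      list(config = NULL,
           conformations = list(rod = rod, uturn = uturn, zigzag = zig),
           expected = list(rod_NH = 0, uturn_NH = 1, zigzag_NH = 2))
    })
}
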