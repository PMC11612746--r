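#' Simulation configuration
#'
#' Builds a simulation configuration with the model's reference parameter
#' set as defaults: N-MPCD number density 20/a^3, streaming step
#' `dt = 0.1 t0`, nematic interaction constant `U = 6 kBT`, bare tumbling
#' parameter `lambda = 2`, shear susceptibility `alpha = 0.5`, rotational
#' friction `gamma_R = 0.01 kBT t0`, a chain of `N = 20` beads of mass
#' `M = 10 m` with FENE strength `k_FENE = 120 kBT/a^2`, nominal bond
#' length `r0 = 1 a`, WCA parameters `epsilon = 1 kBT`, `sigma = 1 a`, MD substep
#' `dt_MD = 0.002 t0` (50 MD iterations per MPCD iteration), and a cylinder
#' of length `L = 30 a`, radius `R = 10 a`.  The FENE divergence radius is
#' `r_max = 1.5 a` (Kremer-Grest convention), chosen so that the canonical
#' bond statistics of the chain reproduce the reference mean bond length
#' `b = 0.89 a`; `r0 = 1 a` is the nominal (equilibrium) bond length.
#'
#' @param ... named overrides of any configuration field (see Details).
#'
#' @details Fields: `a`, `kBT`, `m` (simulation units, fixed at 1);
#' `density`; `dt`; `U`; `lambda`; `alpha`; `gamma_R`; polymer `N`, `M`,
#' `k_FENE`, `r0`, `epsilon`, `sigma`, coupling `k`, `dt_MD`; geometry
#' `geometry` ("cylinder" or "box"), `L` and `R` (cylinder) or `Lx`, `Ly`,
#' `Lz` (box), dimensionality `d` (2 or 3); `seed`; run length `steps` and
#' output cadence `out_every` (in MPCD steps).  Derived quantities (`t0`,
#' `sigma_CO = 2^(1/6) sigma`, `md_substeps = dt/dt_MD`) are filled by
#' [validate_config()].
#'
#' @return A validated object of class `nemapoly_config`.
#' @seealso [validate_config()], [read_config()], [write_config()]
#' @export
#' @examples
#' cfg <- sim_config(k = 12, geometry = "box", Lx = 8, Ly = 8, Lz = 8)
#' cfg$md_substeps # 50
sim_config <- function(...) {
  cfg <- list(
    a = 1, kBT = 1, m = 1,
    density = 20, dt = 0.1,
    U = 6, lambda = 2, alpha = 0.5, gamma_R = 0.01,
    N = 20, M = 10, k_FENE = 120, r0 = 1, r_max = 1.5, epsilon = 1,
    sigma = 1, k = 0, dt_MD = 0.002,
    geometry = "cylinder", L = 30, R = 10,
    Lx = 10, Ly = 10, Lz = 10, d = 3,
    seed = 1, steps = 1000, out_every = 10
  )
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0) {
      stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

#' Validate and normalize a simulation configuration
#'
#' Checks parameter positivity, geometry, dimensionality and the
#' divisibility of the streaming step by the MD substep, and fills the
#' derived quantities `t0`, `sigma_CO` and `md_substeps`.
#'
#' @param cfg a configuration list (e.g. from [sim_config()] or
#'   [read_config()]).
#' @return The normalized configuration, classed `nemapoly_config`.
#' @export
validate_config <- function(cfg) {
  cfg <- unclass(cfg)
  positive <- c("a", "kBT", "m", "density", "dt", "gamma_R", "M", "k_FENE",
                "r0", "r_max", "epsilon", "sigma", "dt_MD")
  for (nm in positive) {
    if (is.null(cfg[[nm]]) || !is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("configuration field '", nm, "' must be a positive number")
    }
  }
  for (nm in c("U", "lambda", "alpha", "k")) {
    if (is.null(cfg[[nm]]) || !is.numeric(cfg[[nm]])) {
      stop("configuration field '", nm, "' must be numeric")
    }
  }
  if (cfg$k < 0) stop("coupling constant k must be >= 0")
  if (!cfg$d %in% c(2, 3)) stop("dimensionality d must be 2 or 3")
  if (!cfg$geometry %in% c("cylinder", "box")) {
    stop("unknown geometry '", cfg$geometry, "' (use 'cylinder' or 'box')")
  }
  if (cfg$geometry == "cylinder") {
    if (cfg$d != 3) stop("the cylinder geometry is three-dimensional")
    if (cfg$L <= 0 || cfg$R <= 0) stop("cylinder L and R must be positive")
    if (abs(cfg$L - round(cfg$L)) > 1e-9) {
      stop("cylinder length L must be an integer number of cells")
    }
  } else {
    for (nm in c("Lx", "Ly", "Lz")) {
      if (cfg[[nm]] <= 0 || abs(cfg[[nm]] - round(cfg[[nm]])) > 1e-9) {
        stop("box length ", nm, " must be a positive integer number of cells")
      }
    }
  }
  if (cfg$N < 0 || cfg$N != round(cfg$N)) stop("N must be a non-negative integer")
  nsub <- cfg$dt / cfg$dt_MD
  if (abs(nsub - round(nsub)) > 1e-9) {
    stop("dt / dt_MD = ", format(nsub),
         " is not an integer: the MD substep must divide the streaming step")
  }
  cfg$md_substeps <- as.integer(round(nsub))
  cfg$t0 <- sqrt(cfg$m * cfg$a^2 / cfg$kBT)
  cfg$sigma_CO <- 2^(1 / 6) * cfg$sigma
  if (cfg$r_max <= cfg$sigma) {
    stop("FENE divergence radius r_max must exceed the bead diameter sigma")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "nemapoly_config")
}

#' @export
print.nemapoly_config <- function(x, ...) {
  cat("<nemapoly_config>\n")
  geom <- if (x$geometry == "cylinder") {
    sprintf("cylinder L=%g R=%g (3D)", x$L, x$R)
  } else {
    sprintf("box %gx%gx%g (%dD)", x$Lx, x$Ly, if (x$d == 2) 1 else x$Lz, x$d)
  }
  cat("  geometry:  ", geom, "\n")
  cat(sprintf("  fluid:      density=%g  dt=%g  U=%g  lambda=%g  alpha=%g  gamma_R=%g\n",
              x$density, x$dt, x$U, x$lambda, x$alpha, x$gamma_R))
  cat(sprintf("  polymer:    N=%d  M=%g  k_FENE=%g  r0=%g  eps=%g  sigma=%g  k=%g\n",
              as.integer(x$N), x$M, x$k_FENE, x$r0, x$epsilon, x$sigma, x$k))
  cat(sprintf("  MD:         dt_MD=%g (%d substeps per MPCD step)\n",
              x$dt_MD, x$md_substeps))
  cat(sprintf("  run:        steps=%d  out_every=%d  seed=%d\n",
              as.integer(x$steps), as.integer(x$out_every), x$seed))
  invisible(x)
}

# canonical field order for byte-identical round trips
config_field_order <- function() {
  c("a", "kBT", "m", "density", "dt", "U", "lambda", "alpha", "gamma_R",
    "N", "M", "k_FENE", "r0", "r_max", "epsilon", "sigma", "k", "dt_MD",
    "geometry", "L", "R", "Lx", "Ly", "Lz", "d",
    "seed", "steps", "out_every")
}

#' Write a configuration to a plain-text (YAML) file
#'
#' Writes only the primary fields, in a fixed canonical order, so that
#' write -> read -> write round trips are byte-identical.
#'
#' @param cfg a `nemapoly_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  fields <- cfg[config_field_order()]
  yaml::write_yaml(fields, path, precision = 15)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' @param path file written by [write_config()] (or hand-written; missing
#'   fields take their defaults).
#' @return A validated `nemapoly_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw)
}

#' Dimensionless nematic-polymer coupling
#'
#' The coupling constant `k` of the segment-director potential, made
#' dimensionless with the mean bond length: `kappa = -k b / (2 kBT)`.
#' Non-positive for any physical (aligning) coupling `k >= 0`.
#'
#' @param k coupling constant (energy units, kBT).
#' @param b mean bond length (a); the measured value at zero coupling is
#'   0.89 a.
#' @param kBT thermal energy (default 1).
#' @return kappa (dimensionless, <= 0 for k >= 0).
#' @export
dimensionless_coupling <- function(k, b = 0.89, kBT = 1) {
  if (any(b <= 0)) stop("bond length b must be positive")
  -k * b / (2 * kBT)
}
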