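#' Radius of the nuclear confinement sphere
#'
#' The interphase phase confines the fiber to a sphere whose volume is the
#' reference nuclear volume scaled by the fiber's share of the genome:
#' `volume_um3 * bp_fraction`. The default reference volume is the average
#' G1 root-nucleus volume of *C. japonica*, 110.57 um^3.
#'
#' @param volume_um3 Reference nuclear volume in cubic micrometres.
#' @param bp_fraction Fraction of the (2C) genome modelled by the fiber,
#'   in (0, 1].
#' @return Sphere radius in nm.
#' @export
#' @examples
#' sphere_radius(4 * pi / 3, 1)  # 1000 nm
sphere_radius <- function(volume_um3 = 110.57, bp_fraction = 1) {
  stopifnot(volume_um3 > 0, bp_fraction > 0, bp_fraction <= 1)
  v <- volume_um3 * bp_fraction
  (3 * v / (4 * pi))^(1 / 3) * 1000
}

#' Simulation phase protocol
#'
#' Bundles kinetics, phase lengths and confinement settings. The defaults
#' follow the reference protocol: 5,000,000 interphase steps (confined, no
#' extrusion) out of 25,000,000 total, 500 loop extruders during
#' condensation, confinement proportional to the 110.57 um^3 G1 nuclear
#' volume with the fiber's share of the 2C genome (1C = 1368 Mb) as the
#' proportionality fraction. Engine units are reduced: kT = 1, nm, bead
#' mobility 1/friction.
#'
#' @param interphase_steps Steps of the confined, extrusion-free phase.
#' @param total_steps Total steps over both phases.
#' @param coupling_interval 3D steps between successive 1D extrusion sweeps
#'   during condensation.
#' @param confinement_volume_um3 Reference nuclear volume (um^3).
#' @param bp_fraction Fiber share of the 2C genome used to scale the
#'   confinement volume; `NULL` derives it as
#'   `total_bp / (2 * genome_size_bp)` from the layout at run time.
#' @param genome_size_bp 1C genome size in bp (default 1368 Mb).
#' @param timestep Integrator timestep (reduced time units).
#' @param friction Friction coefficient gamma (reduced units).
#' @param temperature Thermal energy kT (reduced units).
#' @param wall_k Harmonic confinement wall constant (kT/nm^2).
#' @param n_extruders Extruders loaded for the condensation phase.
#' @param p_step Per-sweep leg step probability.
#' @param frame_stride Record a frame every this many steps (0: none).
#' @param energy_stride Log energy every this many steps (0: none).
#' @return An object of class `phase_protocol`.
#' @export
phase_protocol <- function(interphase_steps = 5e6, total_steps = 25e6,
                           coupling_interval = 100,
                           confinement_volume_um3 = 110.57,
                           bp_fraction = NULL, genome_size_bp = 1368e6,
                           timestep = 0.01, friction = 1, temperature = 1,
                           wall_k = 10, n_extruders = 500, p_step = 1,
                           frame_stride = 0, energy_stride = 1000) {
  stopifnot(interphase_steps >= 0, total_steps >= interphase_steps,
            coupling_interval >= 1, confinement_volume_um3 > 0,
            timestep > 0, friction > 0, temperature >= 0)
  structure(list(interphase_steps = interphase_steps,
                 total_steps = total_steps,
                 coupling_interval = coupling_interval,
                 confinement_volume_um3 = confinement_volume_um3,
                 bp_fraction = bp_fraction, genome_size_bp = genome_size_bp,
                 timestep = timestep, friction = friction,
                 temperature = temperature, wall_k = wall_k,
                 n_extruders = n_extruders, p_step = p_step,
                 frame_stride = frame_stride, energy_stride = energy_stride),
            class = "phase_protocol")
}

protocol_bp_fraction <- function(protocol, layout) {
  if (!is.null(protocol$bp_fraction)) return(protocol$bp_fraction)
  layout$total_bp / (2 * protocol$genome_size_bp)
}

protocol_radius <- function(protocol, layout) {
  sphere_radius(protocol$confinement_volume_um3,
                protocol_bp_fraction(protocol, layout))
}

#' Initial random conformation
#'
#' Builds a random-walk chain with bond-length steps. In `"confined_random"`
#' mode steps leaving the sphere of the given radius are re-drawn (and, as a
#' last resort, folded back toward the centre), so every bead lies inside.
#'
#' @param layout The `fiber_layout`.
#' @param mode `"random_walk"` or `"confined_random"`.
#' @param radius Confinement radius in nm (confined mode).
#' @param seed Integer seed.
#' @param bond_x0 Step (bond) length in nm.
#' @return An n x 3 position matrix (nm) with attribute `step_index = 0`.
#' @export
init_conformation <- function(layout, mode = c("random_walk",
                                               "confined_random"),
                              radius = NULL, seed = NULL, bond_x0 = 10) {
  mode <- match.arg(mode)
  n <- layout$n_monomers
  if (mode == "confined_random") {
    stopifnot(!is.null(radius), radius > 0)
    # crude packing-limit check: one bead per (bond/2)^3 cube
    if ((4 / 3) * pi * radius^3 < n * (bond_x0 / 2)^3) {
      stop("confinement radius ", radius, " nm cannot hold ", n,
           " beads at the packing limit")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(0, n, 3)
  if (mode == "confined_random") {
    repeat {
      p0 <- runif(3, -radius, radius)
      if (sum(p0^2) < (0.9 * radius)^2) break
    }
    pos[1, ] <- p0
  }
  rand_dir <- function(k) {
    v <- matrix(rnorm(3 * k), k, 3)
    v / sqrt(rowSums(v^2))
  }
  if (n > 1) {
    if (mode == "random_walk") {
      steps <- rand_dir(n - 1) * bond_x0
      cs <- apply(steps, 2, cumsum)
      if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
      pos[-1, ] <- sweep(cs, 2, pos[1, ], `+`)
    } else {
      for (i in 2:n) {
        for (try in 1:50) {
          cand <- pos[i - 1, ] + rand_dir(1)[1, ] * bond_x0
          if (sum(cand^2) <= radius^2) break
          if (try == 50) {
            # fold toward the centre
            dir <- -pos[i - 1, ] / sqrt(sum(pos[i - 1, ]^2))
            cand <- pos[i - 1, ] + dir * bond_x0
          }
        }
        pos[i, ] <- cand
      }
    }
  }
  attr(pos, "step_index") <- 0L
  pos
}

cen_par_vec <- function(p) {
  c(p$a, p$b, p$r_min, p$tail_scale, p$tail_shift, p$r_cut)
}

nn_par_vec <- function(p) {
  c(p$nn_core_height, p$nn_well_depth, p$nn_r_min, nn_cutoff(p))
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647)
}

#' Integrate the fiber with overdamped Langevin dynamics
#'
#' Advances the conformation `n_steps` steps under the module forces
#' (bonds, bending, generic and centromeric pair potentials, optional
#' extruder bonds, optional spherical confinement). The update is the
#' Leimkuhler-Matthews overdamped scheme; trajectories are bit-reproducible
#' for a given seed on one platform.
#'
#' @param conf n x 3 position matrix (nm).
#' @param layout The `fiber_layout`.
#' @param n_steps Number of steps.
#' @param protocol A [phase_protocol()] (kinetic parameters and strides).
#' @param cen_params,gen_params Force parameter objects.
#' @param extruder_bonds Optional 0-based two-column index matrix.
#' @param confine_radius Confinement radius in nm (`NULL` or <= 0: off).
#' @param seed Integer seed for the thermal noise.
#' @return A list of class `fiber_trajectory`: `positions` (final), `energy`
#'   and `energy_steps` (potential-energy trace, cutoff-shifted pair terms),
#'   `max_bond` (per energy checkpoint), and if `frame_stride > 0` `frames`
#'   (n x 3 x n_frames array) with `frame_steps`.
#' @export
integrate_fiber <- function(conf, layout, n_steps,
                            protocol = phase_protocol(),
                            cen_params = cen_potential_params(),
                            gen_params = generic_force_params(),
                            extruder_bonds = NULL, confine_radius = NULL,
                            seed = 1) {
  conf <- as.matrix(conf)
  if (nrow(conf) != layout$n_monomers) {
    stop("conformation length does not match the layout")
  }
  if (is.null(extruder_bonds)) {
    extruder_bonds <- matrix(integer(0), 0, 2)
  }
  storage.mode(extruder_bonds) <- "integer"
  r <- if (is.null(confine_radius) || confine_radius <= 0) -1 else
    confine_radius
  res <- cpp_langevin(conf, layout$centromeric, as.integer(n_steps),
                      protocol$timestep, protocol$friction,
                      protocol$temperature,
                      gen_params$bond_k, gen_params$bond_x0,
                      gen_params$bend_k,
                      cen_par_vec(cen_params), nn_par_vec(gen_params),
                      extruder_bonds, r, protocol$wall_k,
                      as.integer(seed), as.integer(protocol$frame_stride),
                      as.integer(protocol$energy_stride))
  attr(res$positions, "step_index") <-
    (attr(conf, "step_index") %||% 0L) + as.integer(n_steps)
  class(res) <- "fiber_trajectory"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the confined interphase phase
#'
#' Integrates for `protocol$interphase_steps` with spherical confinement ON
#' and loop extrusion OFF, starting from a confined random conformation
#' (or `conf` if given). Centromere units self-attract and collapse into
#' chromocenter-like bodies during this phase.
#'
#' @param layout The `fiber_layout`.
#' @param protocol A [phase_protocol()].
#' @param cen_params,gen_params Force parameters.
#' @param seed Integer seed (initial conformation and noise).
#' @param conf Optional starting conformation.
#' @return The final conformation (n x 3 matrix) with attributes
#'   `step_index`, `radius` (confinement radius, nm) and `trace` (the
#'   `fiber_trajectory` bookkeeping).
#' @export
run_interphase <- function(layout, protocol = phase_protocol(),
                           cen_params = cen_potential_params(),
                           gen_params = generic_force_params(),
                           seed = 1, conf = NULL) {
  radius <- protocol_radius(protocol, layout)
  if (is.null(conf)) {
    conf <- init_conformation(layout, "confined_random", radius = radius,
                              seed = derive_seed(seed, 1),
                              bond_x0 = gen_params$bond_x0)
  }
  if (protocol$interphase_steps == 0) {
    attr(conf, "radius") <- radius
    return(conf)
  }
  tr <- integrate_fiber(conf, layout, protocol$interphase_steps, protocol,
                        cen_params, gen_params, extruder_bonds = NULL,
                        confine_radius = radius,
                        seed = derive_seed(seed, 2))
  out <- tr$positions
  attr(out, "radius") <- radius
  attr(out, "trace") <- tr
  out
}

#' Run the condensation phase with loop extrusion
#'
#' Continues from an interphase conformation with confinement OFF. Loop
#' extruders are seeded on intercentromeric bonds; every
#' `protocol$coupling_interval` 3D steps one 1D extrusion sweep advances the
#' ensemble and the active `(left, right)` leg pairs are refreshed as
#' harmonic bonds (constant `bond_k`, rest length `bond_x0`). Runs for
#' `total_steps - interphase_steps` steps.
#'
#' @param conf Starting conformation (typically from [run_interphase()]).
#' @param layout The `fiber_layout`.
#' @param protocol A [phase_protocol()].
#' @param cen_params,gen_params Force parameters.
#' @param seed Integer seed (extruder seeding, sweep order, noise).
#' @return A list of class `condensation_run`: `conformation` (final),
#'   `ensemble` (final extruder state), `energy` / `energy_steps`
#'   (concatenated trace), `max_bond`, `sweeps` (1D sweeps performed) and
#'   `frames` (list of recorded conformations, if `frame_stride > 0`;
#'   recorded at coupling boundaries closest to the stride).
#' @export
run_condensation <- function(conf, layout, protocol = phase_protocol(),
                             cen_params = cen_potential_params(),
                             gen_params = generic_force_params(), seed = 1) {
  n_steps <- protocol$total_steps - protocol$interphase_steps
  ens <- seed_extruders(layout, protocol$n_extruders,
                        seed = derive_seed(seed, 3))
  set.seed(derive_seed(seed, 4))
  chunk <- protocol$coupling_interval
  done <- 0
  sweeps <- 0L
  energy <- numeric(0)
  energy_steps <- integer(0)
  max_bond <- numeric(0)
  frames <- list()
  sub <- protocol
  sub$frame_stride <- 0
  steady <- nrow(ens) == 0
  k <- 0L
  while (done < n_steps) {
    if (!steady) {
      ens <- extrusion_sweep(ens, layout, protocol$p_step)
      sweeps <- sweeps + 1L
      if (attr(ens, "moved") == 0L) steady <- TRUE
    }
    take <- min(chunk, n_steps - done)
    tr <- integrate_fiber(conf, layout, take, sub, cen_params, gen_params,
                          extruder_bonds = active_bonds(ens),
                          confine_radius = NULL,
                          seed = derive_seed(seed, 100 + k))
    conf <- tr$positions
    done <- done + take
    k <- k + 1L
    if (length(tr$energy) > 0) {
      keep <- tr$energy_steps > 0
      energy <- c(energy, tr$energy[keep])
      energy_steps <- c(energy_steps, done - take + tr$energy_steps[keep])
      max_bond <- c(max_bond, tr$max_bond[keep])
    }
    if (protocol$frame_stride > 0 &&
        (done %% protocol$frame_stride < chunk || done == n_steps)) {
      frames[[as.character(done)]] <- conf
    }
  }
  structure(list(conformation = conf, ensemble = ens, energy = energy,
                 energy_steps = energy_steps, max_bond = max_bond,
                 sweeps = sweeps, frames = frames),
            class = "condensation_run")
}

#' Export a conformation as an XYZ file
#'
#' Centromeric beads are written as element "C", intercentromeric beads as
#' element "N", so molecular viewers can colour them apart.
#'
#' @param conf n x 3 position matrix (nm).
#' @param layout The `fiber_layout`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(conf, layout, path) {
  conf <- as.matrix(conf)
  el <- ifelse(layout$centromeric, "C", "N")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(conf)), "holosim conformation (nm)"), con)
  writeLines(sprintf("%s %.4f %.4f %.4f", el, conf[, 1], conf[, 2],
                     conf[, 3]), con)
  invisible(path)
}
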