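#' Parameters of the centromeric pair potential
#'
#' The attraction between pairs of centromeric nucleosomes is a two-branch
#' quartic in the inter-nucleosome distance `x` (nm):
#' \deqn{U(x) = a + b\left((x/r_{min})^4 - 2 (x/r_{min})^2\right), \quad 0 \le x \le r_{min}}
#' \deqn{U(x) = a + b\left((x/s + c)^4 - 2 (x/s + c)^2\right), \quad x > r_{min}}
#' With the defaults (a = 5, b = 6, r_min = 8 nm, s = 20 nm, c = 0.6) the
#' potential has a finite 5 kT core at contact (so the fiber can cross
#' itself, mimicking topoisomerase II), a global minimum of \eqn{a - b = -1}
#' kT at 8 nm, and a tail branch that rises more slowly than the core branch
#' so that centromeric nucleosomes are attracted from larger distances. The
#' two branches agree in value and slope at `r_min`. Beyond `r_cut` the
#' potential is held constant (zero force), a standard cutoff for the
#' otherwise unbounded quartic tail.
#'
#' @param a Core height at x = 0 (kT).
#' @param b Quartic well coefficient (kT); the minimum value is `a - b`.
#' @param r_min Location of the global minimum (nm).
#' @param tail_scale Distance scale `s` of the tail branch (nm).
#' @param tail_shift Dimensionless shift `c` of the tail branch, in (0, 1).
#' @param r_cut Cutoff beyond which the potential is constant (nm).
#' @return An object of class `cen_potential_params`.
#' @export
#' @examples
#' p <- cen_potential_params()
#' cen_pair_potential(8, p)  # -1 kT at the minimum
cen_potential_params <- function(a = 5, b = 6, r_min = 8, tail_scale = 20,
                                 tail_shift = 0.6, r_cut = 60) {
  stopifnot(a > 0, b > 0, r_min > 0, tail_scale > 0,
            tail_shift > 0, tail_shift < 1, r_cut > r_min)
  structure(list(a = a, b = b, r_min = r_min, tail_scale = tail_scale,
                 tail_shift = tail_shift, r_cut = r_cut),
            class = "cen_potential_params")
}

#' Parameters of the generic fiber forces
#'
#' Three forces give the fiber chromatin-like motion: a harmonic bond
#' between consecutive nucleosomes, a `bend_k * (1 - cos theta)` bending term
#' on consecutive triplets, and a soft-core attractive-repulsive quartic
#' between non-consecutive nucleosomes,
#' \eqn{U(x) = a + b((x/r_{min})^4 - 2(x/r_{min})^2)}, truncated to zero at
#' its outer zero crossing. The finite core (`nn_core_height`, default 5 kT)
#' permits eventual crossing of the fiber; with the default well coefficient
#' `nn_well_depth` = 5.5 kT the minimum is \eqn{a - b = -0.5} kT at 10 nm,
#' strictly shallower and at a larger distance than the centromeric
#' potential's -1 kT at 8 nm, so centromeric pairs interact more firmly and
#' closely than generic pairs.
#'
#' @param bond_k Harmonic bond constant (kT/nm^2).
#' @param bond_x0 Bond rest length (nm); nucleosome scale.
#' @param bend_k Bending constant (kT).
#' @param nn_core_height Pair-potential value at contact (kT).
#' @param nn_well_depth Quartic well coefficient (kT); minimum value is
#'   `nn_core_height - nn_well_depth`. Must stay below the centromeric well
#'   coefficient for the centromeric pairs to be the more attractive ones.
#' @param nn_r_min Distance of the pair-potential minimum (nm).
#' @param nn_r_cut Neighbour cutoff (nm); must lie beyond the potential's
#'   outer zero crossing.
#' @return An object of class `generic_force_params`.
#' @export
generic_force_params <- function(bond_k = 10, bond_x0 = 10, bend_k = 2,
                                 nn_core_height = 5, nn_well_depth = 5.5,
                                 nn_r_min = 10, nn_r_cut = 20) {
  stopifnot(bond_k > 0, bond_x0 > 0, bend_k >= 0, nn_core_height > 0,
            nn_well_depth > 0, nn_r_min > 0, nn_r_cut > nn_r_min)
  if (nn_well_depth <= nn_core_height) {
    warning("nn_well_depth <= nn_core_height: the generic pair potential ",
            "has no attractive well and no zero crossing; it will be ",
            "truncated discontinuously at nn_r_cut")
  }
  structure(list(bond_k = bond_k, bond_x0 = bond_x0, bend_k = bend_k,
                 nn_core_height = nn_core_height,
                 nn_well_depth = nn_well_depth,
                 nn_r_min = nn_r_min, nn_r_cut = nn_r_cut),
            class = "generic_force_params")
}

# distance at which the generic quartic crosses zero (its truncation point);
# falls back to nn_r_cut when there is no crossing
nn_cutoff <- function(params) {
  a <- params$nn_core_height
  b <- params$nn_well_depth
  if (b > a) {
    xz <- params$nn_r_min * sqrt(1 + sqrt(1 - a / b))
    min(xz, params$nn_r_cut)
  } else {
    params$nn_r_cut
  }
}

#' Centromeric pair potential
#'
#' Evaluates the two-branch centromeric nucleosome attraction (see
#' [cen_potential_params()]) at distance `x` nm. Vectorised over `x`.
#'
#' @param x Non-negative distances (nm).
#' @param params A [cen_potential_params()] object.
#' @return Energies in kT.
#' @export
#' @examples
#' p <- cen_potential_params()
#' cen_pair_potential(c(0, 8, 16), p)
cen_pair_potential <- function(x, params = cen_potential_params()) {
  stopifnot(is.numeric(x))
  if (any(x < 0)) stop("distances must be non-negative")
  u <- ifelse(x <= params$r_min,
              x / params$r_min,
              pmin(x, params$r_cut) / params$tail_scale + params$tail_shift)
  params$a + params$b * (u^4 - 2 * u^2)
}

#' Generic non-consecutive pair potential
#'
#' Soft-core quartic between non-consecutive, not-both-centromeric
#' nucleosomes (see [generic_force_params()]). Zero beyond its truncation
#' point. Vectorised over `x`.
#'
#' @param x Non-negative distances (nm).
#' @param params A [generic_force_params()] object.
#' @return Energies in kT.
#' @export
nn_pair_potential <- function(x, params = generic_force_params()) {
  stopifnot(is.numeric(x))
  if (any(x < 0)) stop("distances must be non-negative")
  xcut <- nn_cutoff(params)
  u <- x / params$nn_r_min
  e <- params$nn_core_height + params$nn_well_depth * (u^4 - 2 * u^2)
  ifelse(x >= xcut, 0, e)
}

#' Build a monomer-level chromatid layout
#'
#' Maps a chromatid of `total_bp` base pairs onto a chain of nucleosome-sized
#' monomers (`bp_per_monomer` bp each) and types a fixed number of monomers
#' inside each centromere unit as centromeric.
#'
#' @param total_bp Chromatid length in bp; must be divisible by
#'   `bp_per_monomer`.
#' @param bp_per_monomer DNA per monomer (bp, default 200: one nucleosome
#'   plus linker).
#' @param unit_positions_bp Two-column matrix of half-open unit intervals in
#'   bp (`start`, `end`), disjoint, sorted and aligned to monomer boundaries.
#' @param cen_per_unit Number of centromeric monomers placed in each unit.
#' @param placement `"even"` (deterministic, maximally equispaced; the
#'   default) or `"random"` (uniform without replacement under `seed`).
#' @param seed Integer seed for `placement = "random"`.
#' @return An object of class `fiber_layout` with elements `n_monomers`,
#'   `bp_per_monomer`, `units` (two-column matrix of half-open monomer-index
#'   ranges), `centromeric` (logical mask) and `total_bp`.
#' @export
#' @examples
#' lay <- build_layout(4000, 200, rbind(c(1000, 3000)), cen_per_unit = 5)
#' which(lay$centromeric) - 1L
build_layout <- function(total_bp, bp_per_monomer = 200, unit_positions_bp,
                         cen_per_unit, placement = c("even", "random"),
                         seed = NULL) {
  placement <- match.arg(placement)
  stopifnot(total_bp > 0, bp_per_monomer > 0)
  if (total_bp %% bp_per_monomer != 0) {
    stop("total_bp (", total_bp, ") is not divisible by bp_per_monomer (",
         bp_per_monomer, ")")
  }
  n <- as.integer(total_bp / bp_per_monomer)
  up <- matrix(as.numeric(unit_positions_bp), ncol = 2)
  if (nrow(up) == 0) stop("at least one unit interval is required")
  ord <- order(up[, 1])
  up <- up[ord, , drop = FALSE]
  for (k in seq_len(nrow(up))) {
    if (up[k, 1] < 0 || up[k, 2] > total_bp || up[k, 1] >= up[k, 2]) {
      stop("unit ", k, " [", up[k, 1], ", ", up[k, 2],
           ") is empty or outside [0, ", total_bp, ")")
    }
    if (up[k, 1] %% bp_per_monomer != 0 || up[k, 2] %% bp_per_monomer != 0) {
      stop("unit ", k, " is not aligned to monomer boundaries of ",
           bp_per_monomer, " bp")
    }
    if (k > 1 && up[k, 1] < up[k - 1, 2]) {
      stop("unit ", k, " overlaps unit ", k - 1)
    }
  }
  units <- cbind(start = as.integer(up[, 1] / bp_per_monomer),
                 end = as.integer(up[, 2] / bp_per_monomer))
  cen <- logical(n)
  if (!is.null(seed)) set.seed(seed)
  for (k in seq_len(nrow(units))) {
    m <- units[k, 2] - units[k, 1]
    if (cen_per_unit > m) {
      stop("unit ", k, " holds ", m, " monomers, fewer than cen_per_unit = ",
           cen_per_unit)
    }
    offs <- if (placement == "even") {
      # centred maximal equispacing: slot i gets offset floor((i - 1/2) m / k)
      as.integer(floor(((seq_len(cen_per_unit) - 0.5) * m) / cen_per_unit))
    } else {
      sort(sample.int(m, cen_per_unit)) - 1L
    }
    cen[units[k, 1] + offs + 1L] <- TRUE
  }
  structure(list(n_monomers = n, bp_per_monomer = as.integer(bp_per_monomer),
                 units = units, centromeric = cen,
                 total_bp = as.numeric(total_bp)),
            class = "fiber_layout")
}

# evenly spaced unit intervals: g = non-unit span / n_units, half-gap flanks
evenly_spaced_units_bp <- function(total_bp, n_units, unit_len_bp,
                                   bp_per_monomer) {
  non <- total_bp - n_units * unit_len_bp
  if (non < 0) stop("units do not fit on the chromatid")
  g <- non / n_units
  starts <- g / 2 + (seq_len(n_units) - 1) * (unit_len_bp + g)
  starts <- round(starts / bp_per_monomer) * bp_per_monomer
  cbind(starts, starts + unit_len_bp)
}

#' Reference chromatid layout
#'
#' The default model chromatid: a ~20 Mb fiber of 100,000 monomers (200 bp
#' each, a reduced-scale model of an average 85 Mb chromatid) carrying 8
#' evenly spaced centromere units of 442 kb, each with 1325 centromeric
#' monomers placed equispaced (~60% of the unit's 2210 monomers). Units are
#' spaced so the internal gaps are equal and each terminal flank is half a
#' gap.
#'
#' @return A `fiber_layout`.
#' @export
#' @examples
#' lay <- default_chromatid_layout()
#' lay$n_monomers
default_chromatid_layout <- function() {
  up <- evenly_spaced_units_bp(2e7, 8, 442000, 200)
  build_layout(2e7, 200, up, cen_per_unit = 1325, placement = "even")
}

#' Proportionally scaled-down chromatid layout
#'
#' Shrinks the reference layout to `n_monomers` beads while keeping 8 units
#' whose length and centromeric occupancy are proportional to the reference
#' (units ~2.2% of the fiber each, ~60% centromeric monomers inside).
#' Intended for desk-scale simulations and tests.
#'
#' @param n_monomers Number of monomers of the scaled fiber.
#' @param n_units Number of centromere units (default 8).
#' @return A `fiber_layout`.
#' @export
scaled_chromatid_layout <- function(n_monomers = 2000, n_units = 8) {
  scale <- n_monomers / 1e5
  unit_m <- max(2L, as.integer(round(2210 * scale)))
  cen_m <- max(1L, as.integer(round(1325 * scale)))
  bp <- 200
  up <- evenly_spaced_units_bp(n_monomers * bp, n_units, unit_m * bp, bp)
  build_layout(n_monomers * bp, bp, up, cen_per_unit = cen_m,
               placement = "even")
}

#' @export
print.fiber_layout <- function(x, ...) {
  cat("fiber_layout:", x$n_monomers, "monomers x", x$bp_per_monomer,
      "bp =", x$total_bp / 1e6, "Mb\n")
  cat("  units:", nrow(x$units), "| centromeric monomers:",
      sum(x$centromeric), "\n")
  invisible(x)
}

# monomers strictly covered by units, as a logical mask
unit_mask <- function(layout) {
  m <- logical(layout$n_monomers)
  for (k in seq_len(nrow(layout$units))) {
    m[(layout$units[k, 1] + 1L):layout$units[k, 2]] <- TRUE
  }
  m
}

validate_layout <- function(layout) {
  stopifnot(inherits(layout, "fiber_layout"))
  u <- layout$units
  stopifnot(all(u[, 1] < u[, 2]), all(u >= 0), all(u <= layout$n_monomers))
  if (nrow(u) > 1) stopifnot(all(u[-1, 1] >= u[-nrow(u), 2]))
  stopifnot(!any(layout$centromeric & !unit_mask(layout)))
  stopifnot(layout$total_bp == layout$n_monomers * layout$bp_per_monomer)
  invisible(layout)
}

#' Bonded (stretch and bend) energies of a conformation
#'
#' `stretch` is \eqn{\sum \frac{1}{2} k (|r_{i+1}-r_i| - x_0)^2} over
#' consecutive pairs and `bend` is \eqn{\sum k_b (1 - \cos\theta)} over
#' interior triplets.
#'
#' @param conf n x 3 matrix of positions (nm).
#' @param layout The `fiber_layout` the conformation belongs to.
#' @param params A [generic_force_params()] object.
#' @return A list with elements `stretch` and `bend` (kT).
#' @export
bonded_energies <- function(conf, layout, params = generic_force_params()) {
  conf <- as.matrix(conf)
  if (nrow(conf) != layout$n_monomers) {
    stop("conformation has ", nrow(conf), " beads but the layout has ",
         layout$n_monomers)
  }
  n <- nrow(conf)
  stretch <- 0
  bend <- 0
  if (n >= 2) {
    d <- conf[-1, , drop = FALSE] - conf[-n, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    stretch <- sum(0.5 * params$bond_k * (len - params$bond_x0)^2)
    if (n >= 3) {
      a <- d[-(n - 1), , drop = FALSE]
      b <- d[-1, , drop = FALSE]
      ct <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
      bend <- sum(params$bend_k * (1 - ct))
    }
  }
  list(stretch = stretch, bend = bend)
}

#' Decomposed total potential energy of a conformation
#'
#' Sums bonded terms, generic non-consecutive pair energies, centromeric
#' pair energies (centromeric-centromeric pairs use the centromeric
#' potential, all other non-consecutive pairs the generic one) and harmonic
#' extruder-bond energies.
#'
#' @param conf n x 3 matrix of positions (nm).
#' @param layout The `fiber_layout`.
#' @param extruder_bonds Optional two-column matrix of 0-based monomer index
#'   pairs bridged by loop extruders.
#' @param cen_params A [cen_potential_params()] object.
#' @param gen_params A [generic_force_params()] object.
#' @return A list with `stretch`, `bend`, `nn`, `cen`, `extruder`, `total`
#'   (kT).
#' @export
total_energy <- function(conf, layout, extruder_bonds = NULL,
                         cen_params = cen_potential_params(),
                         gen_params = generic_force_params()) {
  conf <- as.matrix(conf)
  n <- nrow(conf)
  if (n != layout$n_monomers) {
    stop("conformation length does not match the layout")
  }
  be <- bonded_energies(conf, layout, gen_params)
  nn_e <- 0
  cen_e <- 0
  if (n >= 3) {
    dm <- as.matrix(dist(conf))
    idx <- which(upper.tri(dm), arr.ind = TRUE)
    idx <- idx[idx[, 2] - idx[, 1] >= 2, , drop = FALSE]
    if (nrow(idx) > 0) {
      dd <- dm[idx]
      both_cen <- layout$centromeric[idx[, 1]] & layout$centromeric[idx[, 2]]
      if (any(both_cen)) {
        cen_e <- sum(cen_pair_potential(dd[both_cen], cen_params))
      }
      if (any(!both_cen)) {
        nn_e <- sum(nn_pair_potential(dd[!both_cen], gen_params))
      }
    }
  }
  ex_e <- 0
  if (!is.null(extruder_bonds) && nrow(extruder_bonds) > 0) {
    eb <- matrix(as.integer(extruder_bonds), ncol = 2)
    if (any(eb < 0) || any(eb >= n)) stop("extruder bond index out of range")
    d <- sqrt(rowSums((conf[eb[, 1] + 1L, , drop = FALSE] -
                         conf[eb[, 2] + 1L, , drop = FALSE])^2))
    ex_e <- sum(0.5 * gen_params$bond_k * (d - gen_params$bond_x0)^2)
  }
  total <- be$stretch + be$bend + nn_e + cen_e + ex_e
  list(stretch = be$stretch, bend = be$bend, nn = nn_e, cen = cen_e,
       extruder = ex_e, total = total)
}

#' Export centromere units of a layout as BED intervals
#'
#' @param layout A `fiber_layout`.
#' @param chrom Chromosome name used in the BED records.
#' @return A `data.frame` with `chrom`, `start`, `end` in bp (0-based
#'   half-open), one row per unit.
#' @export
layout_units_bed <- function(layout, chrom = "chr1") {
  data.frame(chrom = chrom,
             start = layout$units[, 1] * layout$bp_per_monomer,
             end = layout$units[, 2] * layout$bp_per_monomer,
             stringsAsFactors = FALSE)
}

#' Serialize a layout to / from a YAML config
#'
#' The YAML stores the bp-level description (total bp, bp per monomer, unit
#' intervals in bp, centromeric monomer indices), sufficient to rebuild the
#' layout bit-for-bit.
#'
#' @param layout A `fiber_layout`.
#' @param path File to write / read.
#' @return `read_layout_yaml` returns a `fiber_layout`;
#'   `write_layout_yaml` returns `path` invisibly.
#' @export
write_layout_yaml <- function(layout, path) {
  obj <- list(total_bp = layout$total_bp,
              bp_per_monomer = layout$bp_per_monomer,
              units_bp = lapply(seq_len(nrow(layout$units)), function(k) {
                list(start = layout$units[k, 1] * layout$bp_per_monomer,
                     end = layout$units[k, 2] * layout$bp_per_monomer)
              }),
              centromeric_monomers = which(layout$centromeric) - 1L)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_layout_yaml
#' @export
read_layout_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  up <- do.call(rbind, lapply(obj$units_bp, function(u) c(u$start, u$end)))
  lay <- build_layout(obj$total_bp, obj$bp_per_monomer, up, cen_per_unit = 1L)
  cen <- logical(lay$n_monomers)
  cen[unlist(obj$centromeric_monomers) + 1L] <- TRUE
  lay$centromeric <- cen
  validate_layout(lay)
}
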