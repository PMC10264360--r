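#' Seed loop extruders on the intercentromeric lattice
#'
#' Places `n` SMC-like loop extruders on uniformly random, distinct
#' intercentromeric bonds: each extruder starts with its two legs on
#' adjacent monomers `(i, i + 1)`, both outside every centromere unit.
#' Extruders are prohibited inside the units; during extrusion a leg that
#' reaches a unit boundary anchors there permanently.
#'
#' @param layout A [build_layout()] `fiber_layout`.
#' @param n Number of extruders.
#' @param seed Integer seed; placement is reproducible under it.
#' @return An object of class `extruder_ensemble`: a `data.frame` with
#'   0-based columns `left`, `right`, logical `left_anchored`,
#'   `right_anchored`, and `loaded_at` (sweep index).
#' @export
seed_extruders <- function(layout, n, seed = NULL) {
  stopifnot(n >= 0)
  inside <- unit_mask(layout)
  # eligible bond i: monomers i and i+1 (0-based) both outside units
  ok <- !inside[-layout$n_monomers] & !inside[-1]
  eligible <- which(ok) - 1L
  if (n > length(eligible)) {
    stop("only ", length(eligible), " intercentromeric bonds available for ",
         n, " extruders")
  }
  if (!is.null(seed)) set.seed(seed)
  pick <- if (n > 0) sort(sample(eligible, n)) else integer(0)
  ens <- data.frame(left = pick, right = pick + 1L,
                    left_anchored = logical(n), right_anchored = logical(n),
                    loaded_at = integer(n))
  class(ens) <- c("extruder_ensemble", "data.frame")
  ens
}

# 0-based monomer index -> is it the first monomer outside a unit that a
# further outward step would enter? Legs halt (anchored) on the monomer
# adjacent to the unit boundary and never enter the unit.
leg_would_enter_unit <- function(target, inside) {
  inside[target + 1L]
}

#' Advance the 1D loop-extrusion lattice by one sweep
#'
#' Each non-anchored leg attempts one outward step (left legs decrement,
#' right legs increment) with probability `p_step`. A leg whose target
#' monomer lies inside a centromere unit instead stays on its current,
#' boundary-adjacent monomer and becomes permanently anchored. A leg whose
#' target is occupied by another leg, or which would run off the fiber end,
#' is blocked for this sweep and retries later. Legs are updated in an order
#' randomized by the R RNG (seed it for reproducibility).
#'
#' @param ensemble An `extruder_ensemble`.
#' @param layout The `fiber_layout`.
#' @param p_step Per-sweep step probability for each leg (default 1:
#'   deterministic outward motion).
#' @return The updated ensemble, with attribute `moved` (how many legs
#'   moved or changed state this sweep).
#' @export
extrusion_sweep <- function(ensemble, layout, p_step = 1) {
  n_mono <- layout$n_monomers
  inside <- unit_mask(layout)
  k <- nrow(ensemble)
  if (k == 0) {
    attr(ensemble, "moved") <- 0L
    return(ensemble)
  }
  occ <- logical(n_mono)
  occ[ensemble$left + 1L] <- TRUE
  occ[ensemble$right + 1L] <- TRUE
  # (extruder, side) pairs in random order
  legs <- cbind(rep(seq_len(k), 2), rep(c(1L, 2L), each = k))
  legs <- legs[sample.int(nrow(legs)), , drop = FALSE]
  moved <- 0L
  for (r in seq_len(nrow(legs))) {
    e <- legs[r, 1]
    side <- legs[r, 2]
    if (side == 1L) {
      if (ensemble$left_anchored[e]) next
      cur <- ensemble$left[e]
      tgt <- cur - 1L
      if (tgt < 0L) next                       # fiber end: blocked, stays free
      if (p_step < 1 && runif(1) > p_step) next
      if (leg_would_enter_unit(tgt, inside)) { # anchor on boundary-adjacent
        ensemble$left_anchored[e] <- TRUE
        moved <- moved + 1L
        next
      }
      if (occ[tgt + 1L]) next                  # collision: blocked
      occ[cur + 1L] <- FALSE
      occ[tgt + 1L] <- TRUE
      ensemble$left[e] <- tgt
      moved <- moved + 1L
    } else {
      if (ensemble$right_anchored[e]) next
      cur <- ensemble$right[e]
      tgt <- cur + 1L
      if (tgt >= n_mono) next
      if (p_step < 1 && runif(1) > p_step) next
      if (leg_would_enter_unit(tgt, inside)) {
        ensemble$right_anchored[e] <- TRUE
        moved <- moved + 1L
        next
      }
      if (occ[tgt + 1L]) next
      occ[cur + 1L] <- FALSE
      occ[tgt + 1L] <- TRUE
      ensemble$right[e] <- tgt
      moved <- moved + 1L
    }
  }
  attr(ensemble, "moved") <- moved
  ensemble
}

#' Run 1D extrusion until no leg can move
#'
#' Iterates [extrusion_sweep()] until a full sweep produces no movement or
#' state change, or `max_sweeps` is reached. With `p_step = 1` and a single
#' extruder on a gap of g monomers, steady state is reached within g sweeps.
#'
#' @param ensemble An `extruder_ensemble`.
#' @param layout The `fiber_layout`.
#' @param max_sweeps Sweep budget.
#' @param seed Integer seed for the per-sweep update order.
#' @param p_step Per-leg step probability.
#' @param stride Record the ensemble every `stride` sweeps (0: only final).
#' @return A list with `ensemble` (final state), `steady` (flag), `sweeps`
#'   (sweeps executed) and `trajectory` (list of recorded ensembles, named
#'   by sweep index; always includes the final state).
#' @export
run_to_steady <- function(ensemble, layout, max_sweeps = 100000, seed = NULL,
                          p_step = 1, stride = 0) {
  if (!is.null(seed)) set.seed(seed)
  traj <- list()
  sweeps <- 0L
  steady <- nrow(ensemble) == 0
  while (!steady && sweeps < max_sweeps) {
    ensemble <- extrusion_sweep(ensemble, layout, p_step)
    sweeps <- sweeps + 1L
    if (stride > 0 && sweeps %% stride == 0) {
      traj[[as.character(sweeps)]] <- ensemble
    }
    if (attr(ensemble, "moved") == 0L) steady <- TRUE
  }
  traj[[as.character(sweeps)]] <- ensemble
  list(ensemble = ensemble, steady = steady, sweeps = sweeps,
       trajectory = traj)
}

#' Extruder bond list for the 3D engine
#'
#' @param ensemble An `extruder_ensemble`.
#' @return A two-column integer matrix of 0-based `(left, right)` monomer
#'   pairs, one row per extruder.
#' @export
active_bonds <- function(ensemble) {
  cbind(left = as.integer(ensemble$left), right = as.integer(ensemble$right))
}

#' Write an ensemble trajectory as a tab-separated table
#'
#' One row per (sweep, extruder): columns `sweep`, `extruder`, `left`,
#' `right`, `left_anchored`, `right_anchored`.
#'
#' @param trajectory The `trajectory` element of [run_to_steady()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_tsv <- function(trajectory, path) {
  rows <- lapply(names(trajectory), function(sw) {
    e <- trajectory[[sw]]
    if (nrow(e) == 0) return(NULL)
    data.frame(sweep = as.integer(sw), extruder = seq_len(nrow(e)) - 1L,
               left = e$left, right = e$right,
               left_anchored = e$left_anchored,
               right_anchored = e$right_anchored)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sweep = integer(0), extruder = integer(0),
                      left = integer(0), right = integer(0),
                      left_anchored = logical(0),
                      right_anchored = logical(0))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
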