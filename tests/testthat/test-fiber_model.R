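test_that("centromeric pair potential matches its closed form and branches", {
  p <- cen_potential_params()
  expect_identical(cen_pair_potential(0, p), 5)
  expect_equal(cen_pair_potential(8, p), -1)
  # both branches give the same value at the branch point
  u1 <- p$a + p$b * ((8 / p$r_min)^4 - 2 * (8 / p$r_min)^2)
  u2 <- p$a + p$b * ((8 / p$tail_scale + p$tail_shift)^4 -
                       2 * (8 / p$tail_scale + p$tail_shift)^2)
  expect_equal(u1, u2)
  # tail value frozen from substituting u = 16/20 + 0.6 = 1.4
  expect_equal(cen_pair_potential(16, p), 4.5296)
  # held constant beyond the cutoff
  expect_equal(cen_pair_potential(61, p), cen_pair_potential(60, p))
  expect_equal(cen_pair_potential(200, p), cen_pair_potential(60, p))
  expect_error(cen_pair_potential(-1, p), "non-negative")
})

test_that("centromeric potential is C1 at the branch point with a slower tail", {
  p <- cen_potential_params()
  h <- 1e-6
  slope_left <- (cen_pair_potential(8, p) - cen_pair_potential(8 - h, p)) / h
  slope_right <- (cen_pair_potential(8 + h, p) - cen_pair_potential(8, p)) / h
  expect_lt(abs(slope_left - slope_right), 1e-6)
  # the tail rises more slowly than an extrapolated core branch would
  x <- 9
  core_extrap <- p$a + p$b * ((x / p$r_min)^4 - 2 * (x / p$r_min)^2)
  core_slope <- (core_extrap -
                   (p$a + p$b * (((x - h) / p$r_min)^4 -
                                   2 * ((x - h) / p$r_min)^2))) / h
  tail_slope <- (cen_pair_potential(x, p) -
                   cen_pair_potential(x - h, p)) / h
  expect_lt(tail_slope, core_slope)
})

test_that("centromeric minimum sits at r_min with value a - b", {
  p <- cen_potential_params()
  grid <- seq(0, p$r_cut, by = 1e-4)
  vals <- cen_pair_potential(grid, p)
  expect_equal(grid[which.min(vals)], p$r_min, tolerance = 1e-3)
  expect_equal(min(vals), p$a - p$b, tolerance = 1e-9)
})

test_that("generic pair potential honours its construction contract", {
  g <- generic_force_params()
  expect_equal(nn_pair_potential(0, g), g$nn_core_height)
  expect_equal(nn_pair_potential(g$nn_r_min, g),
               g$nn_core_height - g$nn_well_depth)
  expect_equal(nn_pair_potential(g$nn_r_cut, g), 0)
  expect_equal(nn_pair_potential(100, g), 0)
  # centromeric pairs are strictly more attractive and act closer
  p <- cen_potential_params()
  expect_lt(p$a - p$b, g$nn_core_height - g$nn_well_depth)
  expect_lt(p$r_min, g$nn_r_min)
  expect_lte(cen_pair_potential(p$r_min, p), nn_pair_potential(p$r_min, g))
  expect_error(nn_pair_potential(-0.5, g), "non-negative")
})

test_that("reference layout reproduces the model chromatid", {
  lay <- default_chromatid_layout()
  expect_equal(lay$n_monomers, 100000)
  expect_equal(nrow(lay$units), 8)
  expect_equal(lay$total_bp, 2e7)
  per_unit <- vapply(seq_len(8), function(k) {
    sum(lay$centromeric[(lay$units[k, 1] + 1):lay$units[k, 2]])
  }, numeric(1))
  expect_true(all(per_unit == 1325))
  expect_equal(sum(lay$centromeric), 8 * 1325)
  expect_true(all(lay$units[, 2] - lay$units[, 1] == 2210))
  # internal gaps equal, terminal flanks half a gap
  gaps <- lay$units[-1, 1] - lay$units[-8, 2]
  expect_true(all(gaps == gaps[1]))
  expect_equal(unname(lay$units[1, 1]) * 2, unname(gaps[1]))
})

test_that("build_layout places, validates and errors as specified", {
  # full occupancy
  l1 <- build_layout(2000, 200, rbind(c(0, 2000)), 10)
  expect_equal(l1$n_monomers, 10)
  expect_true(all(l1$centromeric))
  # deterministic centred equispacing on monomers 5..14
  l2 <- build_layout(4000, 200, rbind(c(1000, 3000)), 5)
  expect_identical(which(l2$centromeric) - 1L, c(6L, 8L, 10L, 12L, 14L))
  # every centromeric monomer lies inside a unit
  expect_true(all(which(l2$centromeric) - 1L >= 5 &
                    which(l2$centromeric) - 1L < 15))
  # random placement is reproducible and confined to the unit
  l3a <- build_layout(4000, 200, rbind(c(1000, 3000)), 5,
                      placement = "random", seed = 9)
  l3b <- build_layout(4000, 200, rbind(c(1000, 3000)), 5,
                      placement = "random", seed = 9)
  expect_identical(l3a$centromeric, l3b$centromeric)
  expect_equal(sum(l3a$centromeric), 5)
  expect_true(all(which(l3a$centromeric) - 1L >= 5 &
                    which(l3a$centromeric) - 1L < 15))
  # errors name the offending unit / condition
  expect_error(build_layout(4000, 200,
                            rbind(c(0, 2000), c(1000, 3000)), 2),
               "overlaps")
  expect_error(build_layout(4000, 200, rbind(c(0, 400)), 5), "fewer")
  expect_error(build_layout(1999, 200, rbind(c(0, 1000)), 2),
               "divisible")
})

test_that("bonded energies match geometry and a brute-force sum", {
  g <- generic_force_params()
  lay <- build_layout(600, 200, rbind(c(0, 200)), 1)
  straight <- cbind(c(0, 10, 20), 0, 0)
  be <- bonded_energies(straight, lay, g)
  expect_equal(be$stretch, 0)
  expect_equal(be$bend, 0)
  right_angle <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0))
  be2 <- bonded_energies(right_angle, lay, g)
  expect_equal(be2$stretch, 0)
  expect_equal(be2$bend, g$bend_k)
  # random 10-bead chain vs direct summation
  lay10 <- build_layout(2000, 200, rbind(c(0, 400)), 2)
  set.seed(5)
  conf <- matrix(rnorm(30, sd = 12), 10, 3)
  be3 <- bonded_energies(conf, lay10, g)
  oracle <- oracle_total_energy(conf, rep(FALSE, 10))  # pair terms excluded
  # recompute oracle pieces separately
  o_stretch <- sum(vapply(1:9, function(i) {
    0.5 * g$bond_k * (sqrt(sum((conf[i + 1, ] - conf[i, ])^2)) -
                        g$bond_x0)^2
  }, numeric(1)))
  expect_equal(be3$stretch, o_stretch, tolerance = 1e-12)
  expect_error(bonded_energies(conf[1:5, ], lay10, g), "5")
})

test_that("total energy decomposes and matches the brute-force oracle", {
  # two non-consecutive centromeric beads at the potential minimum
  lay3 <- build_layout(600, 200, rbind(c(0, 600)), 2)  # beads 0, 2 cen
  expect_identical(which(lay3$centromeric) - 1L, c(0L, 2L))
  conf <- rbind(c(0, 0, 0), c(4, sqrt(100 - 16), 0), c(8, 0, 0))
  te <- total_energy(conf, lay3)
  expect_equal(te$cen, -1)
  expect_equal(te$stretch, 0, tolerance = 1e-9)
  expect_equal(te$nn, 0)
  # two non-centromeric beads beyond the generic cutoff interact not at all
  layn <- build_layout(600, 200, rbind(c(0, 200)), 1)
  conf2 <- rbind(c(0, 0, 0), c(10, 0, 0), c(40, 0, 0))
  expect_equal(total_energy(conf2, layn)$nn, 0)
  # 20-bead mixed system equals the O(n^2) oracle
  lay20 <- build_layout(4000, 200, rbind(c(0, 1000), c(2000, 3000)), 3)
  set.seed(11)
  conf3 <- matrix(rnorm(60, sd = 9), 20, 3)
  bonds <- rbind(c(0L, 10L), c(3L, 17L))
  te3 <- total_energy(conf3, lay20, extruder_bonds = bonds)
  expect_equal(te3$total,
               oracle_total_energy(conf3, lay20$centromeric, bonds),
               tolerance = 1e-10)
  expect_error(total_energy(conf3, lay20,
                            extruder_bonds = rbind(c(0L, 25L))),
               "range")
})

test_that("layouts serialize to BED and YAML and back", {
  lay <- scaled_chromatid_layout(500)
  bed <- layout_units_bed(lay)
  expect_equal(nrow(bed), 8)
  expect_true(all(bed$end - bed$start ==
                    (lay$units[, 2] - lay$units[, 1]) * 200))
  f <- tempfile(fileext = ".yaml")
  write_layout_yaml(lay, f)
  lay2 <- read_layout_yaml(f)
  expect_identical(lay2$units, lay$units)
  expect_identical(lay2$centromeric, lay$centromeric)
  expect_equal(lay2$total_bp, lay$total_bp)
})
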