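# 20-bead layout with two 4-monomer units, all unit monomers centromeric
metric_layout <- function() {
  build_layout(4000, 200, rbind(c(800, 1600), c(2400, 3200)), 4)
}

test_that("density ratio is 1 on a grid and large for collapsed units", {
  lay <- metric_layout()
  # all beads equally spaced on a line: same neighbourhood everywhere
  # (interior beads); use a circle to remove edge effects
  th <- 2 * pi * (0:19) / 20
  ring <- cbind(cos(th), sin(th), 0) * 50
  r_uniform <- local_density_ratio(ring, lay, r_nbr = 40)
  expect_equal(r_uniform, 1, tolerance = 0.2)
  # unit beads collapsed to points, others spread far apart
  conf <- matrix(0, 20, 3)
  spread <- which(!lay$centromeric)
  conf[spread, ] <- cbind(1e4 * seq_along(spread), 0, 0)
  conf[lay$centromeric & seq_len(20) <= 8, ] <-
    matrix(rep(c(0, 0, 0), 4), ncol = 3, byrow = TRUE)
  conf[lay$centromeric & seq_len(20) > 8, ] <-
    matrix(rep(c(0, 5, 0), 4), ncol = 3, byrow = TRUE)
  expect_gt(local_density_ratio(conf, lay, r_nbr = 10), 10)
})

test_that("density ratio matches a brute-force count on random conformations", {
  lay <- metric_layout()
  set.seed(21)
  for (i in 1:10) {
    conf <- matrix(rnorm(60, sd = 20), 20, 3)
    r_nbr <- runif(1, 10, 40)
    counts <- vapply(1:20, function(i) {
      sum(vapply(1:20, function(j) {
        if (abs(i - j) <= 1) return(FALSE)
        sqrt(sum((conf[i, ] - conf[j, ])^2)) <= r_nbr
      }, logical(1)))
    }, numeric(1))
    want <- mean(counts[lay$centromeric]) / mean(counts[!lay$centromeric])
    expect_equal(local_density_ratio(conf, lay, r_nbr), want)
  }
})

test_that("unit clustering follows single linkage and is monotone in d_link", {
  lay <- metric_layout()
  # coincident centroids -> one cluster
  conf <- matrix(rep(c(1, 2, 3), each = 20), 20, 3)
  expect_equal(cluster_units(conf, lay, 24)$n_clusters, 1)
  # distinct centroids at d_link = 0 -> one cluster per unit
  conf2 <- matrix(0, 20, 3)
  conf2[5:8, 1] <- 0
  conf2[13:16, 1] <- 500
  expect_equal(cluster_units(conf2, lay, 0)$n_clusters, 2)
  expect_equal(cluster_units(conf2, lay, 1000)$n_clusters, 1)
  # two groups of units: intra 10 nm, inter 500 nm, threshold 50 -> 2
  lay8 <- scaled_chromatid_layout(400)
  set.seed(4)
  conf8 <- matrix(rnorm(1200, sd = 1), 400, 3)
  cents <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 0),
                 c(500, 0, 0), c(510, 0, 0), c(500, 10, 0), c(510, 10, 0))
  for (k in 1:8) {
    idx <- (lay8$units[k, 1] + 1):lay8$units[k, 2]
    conf8[idx, ] <- sweep(matrix(0, length(idx), 3), 2, cents[k, ], `+`)
  }
  cl <- cluster_units(conf8, lay8, 50)
  expect_equal(cl$n_clusters, 2)
  expect_equal(cl$n_clusters,
               oracle_single_linkage(holosim:::unit_centroids(conf8, lay8),
                                     50))
  # monotonicity in the linkage threshold
  set.seed(8)
  confr <- matrix(rnorm(1200, sd = 60), 400, 3)
  ks <- vapply(c(0, 10, 30, 60, 120, 1e4), function(d) {
    cluster_units(confr, lay8, d)$n_clusters
  }, numeric(1))
  expect_true(all(diff(ks) <= 0))
  # random instances vs the connectivity oracle
  for (i in 1:15) {
    confx <- matrix(rnorm(1200, sd = 40), 400, 3)
    d <- runif(1, 5, 80)
    expect_equal(cluster_units(confx, lay8, d)$n_clusters,
                 oracle_single_linkage(
                   holosim:::unit_centroids(confx, lay8), d))
  }
})

test_that("linearity is 1 on a line, ~1/3 on a sphere, matches eigen oracle", {
  lay <- metric_layout()
  conf <- matrix(0, 20, 3)
  conf[, 1] <- seq_len(20) * 7
  expect_equal(linearity_score(conf, lay), 1)
  # uniform points on a sphere surface: isotropic, score ~ 1/3
  n <- 1e4
  lay_s <- build_layout(n * 200, 200, rbind(c(0, n * 200)), n)
  set.seed(12)
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  expect_equal(linearity_score(v * 100, lay_s), 1 / 3, tolerance = 0.05)
  # 20 arbitrary beads vs direct covariance eigenvalues
  set.seed(13)
  confr <- matrix(rnorm(60, sd = 30), 20, 3)
  ev <- eigen(cov(confr[lay$centromeric, ]))$values
  expect_equal(linearity_score(confr, lay), max(ev) / sum(ev))
  expect_error(linearity_score(conf[1:3, ],
                               build_layout(600, 200, rbind(c(0, 600)), 2)),
               "3 centromeric")
})

test_that("radius of gyration has its closed-form values", {
  conf <- matrix(5, 10, 3)
  expect_equal(radius_of_gyration(conf), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  set.seed(14)
  confr <- matrix(rnorm(30), 10, 3)
  ctr <- colMeans(confr)
  want <- sqrt(mean(rowSums(sweep(confr, 2, ctr)^2)))
  expect_equal(radius_of_gyration(confr), want)
  expect_equal(radius_of_gyration(confr, 1:4),
               radius_of_gyration(confr[1:4, ]))
})

test_that("contact maps are symmetric and match a brute-force count", {
  # straight chain with contact radius below the bond length
  conf <- cbind(seq_len(30) * 10, 0, 0)
  m <- contact_map(conf, bin_size = 5, r_contact = 5)
  expect_identical(m, t(m))
  offdiag <- m
  diag(offdiag) <- 0L
  expect_true(all(offdiag == 0))
  set.seed(15)
  confr <- matrix(rnorm(90, sd = 10), 30, 3)
  m2 <- contact_map(confr, bin_size = 7, r_contact = 12)
  expect_identical(m2, t(m2))
  want <- matrix(0L, nrow(m2), ncol(m2))
  bins <- ((seq_len(30) - 1) %/% 7) + 1
  for (i in 1:29) {
    for (j in (i + 1):30) {
      if (sqrt(sum((confr[i, ] - confr[j, ])^2)) <= 12) {
        bi <- bins[i]; bj <- bins[j]
        want[bi, bj] <- want[bi, bj] + 1L
        if (bi != bj) want[bj, bi] <- want[bj, bi] + 1L
      }
    }
  }
  expect_identical(m2, want)
})

test_that("metrics are invariant under rigid motion", {
  lay <- metric_layout()
  set.seed(16)
  conf <- matrix(rnorm(60, sd = 25), 20, 3)
  rot <- random_rotation()
  shift <- c(40, -25, 13)
  conf2 <- sweep(conf %*% rot, 2, shift, `+`)
  expect_equal(local_density_ratio(conf2, lay, 20),
               local_density_ratio(conf, lay, 20), tolerance = 1e-8)
  expect_equal(cluster_units(conf2, lay, 30)$n_clusters,
               cluster_units(conf, lay, 30)$n_clusters)
  expect_equal(linearity_score(conf2, lay), linearity_score(conf, lay),
               tolerance = 1e-8)
  expect_equal(radius_of_gyration(conf2), radius_of_gyration(conf),
               tolerance = 1e-8)
})

test_that("the tidy metric table carries every standard metric", {
  lay <- metric_layout()
  set.seed(17)
  conf <- matrix(rnorm(60, sd = 25), 20, 3)
  tab <- conformation_metrics(conf, lay, frame = 3L)
  expect_equal(nrow(tab), 5)
  expect_true(all(c("local_density_ratio", "linearity_score") %in%
                    tab$metric))
  expect_true(all(is.finite(tab$value)))
})
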