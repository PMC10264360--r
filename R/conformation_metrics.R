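#' Centromeric vs intercentromeric local-density ratio
#'
#' For every bead, counts neighbours within `r_nbr` nm, excluding the two
#' chain neighbours (i - 1, i + 1) and the bead itself. The metric is the
#' mean count over centromeric beads divided by the mean count over
#' intercentromeric beads; in an interphase-like conformation the collapsed
#' centromere units give ratios well above 1.
#'
#' @param conf n x 3 position matrix (nm).
#' @param layout The `fiber_layout`.
#' @param r_nbr Neighbourhood radius (nm).
#' @return The density ratio (dimensionless).
#' @export
local_density_ratio <- function(conf, layout, r_nbr = 30) {
  stopifnot(r_nbr > 0)
  conf <- as.matrix(conf)
  n <- nrow(conf)
  cen <- layout$centromeric
  if (!any(cen) || all(cen)) stop("both bead classes must be non-empty")
  dm <- as.matrix(dist(conf))
  within <- dm <= r_nbr
  diag(within) <- FALSE
  if (n > 1) {
    chain <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
    within[chain] <- FALSE
    within[chain[, 2:1, drop = FALSE]] <- FALSE
  }
  counts <- rowSums(within)
  mean(counts[cen]) / mean(counts[!cen])
}

unit_centroids <- function(conf, layout) {
  conf <- as.matrix(conf)
  t(vapply(seq_len(nrow(layout$units)), function(k) {
    idx <- (layout$units[k, 1] + 1L):layout$units[k, 2]
    idx <- idx[layout$centromeric[idx]]
    colMeans(conf[idx, , drop = FALSE])
  }, numeric(3)))
}

#' Cluster centromere units into chromocenters
#'
#' Single-linkage clustering of the unit centroids (unweighted means of each
#' unit's centromeric bead positions) at linkage threshold `d_link`; two
#' units fall in the same chromocenter when a chain of centroid pairs at
#' most `d_link` nm apart connects them.
#'
#' @param conf n x 3 position matrix (nm).
#' @param layout The `fiber_layout` (>= 1 unit).
#' @param d_link Linkage threshold (nm). Default 24 nm = 3 x the
#'   centromeric-potential minimum distance: beyond direct attraction range
#'   but well below the confinement scale.
#' @return A list of class `cluster_result`: `assignment` (0-based cluster
#'   id per unit), `n_clusters`, `linkage_threshold`.
#' @export
cluster_units <- function(conf, layout, d_link = 24) {
  stopifnot(nrow(layout$units) >= 1)
  cent <- unit_centroids(conf, layout)
  k <- nrow(cent)
  if (k == 1) {
    assignment <- 0L
  } else {
    d <- dist(cent)
    if (all(d == 0)) {
      assignment <- rep(0L, k)
    } else {
      hc <- hclust(d, method = "single")
      grp <- cutree(hc, h = d_link)
      assignment <- as.integer(match(grp, unique(grp)) - 1L)
    }
  }
  structure(list(assignment = assignment,
                 n_clusters = length(unique(assignment)),
                 linkage_threshold = d_link),
            class = "cluster_result")
}

#' Linearity of the centromeric bead cloud
#'
#' The share of positional variance along the principal axis: the largest
#' eigenvalue of the centromeric-bead covariance matrix divided by the
#' eigenvalue sum. 1 for beads exactly on a line, about 1/3 for an
#' isotropic cloud. Rises as centromere units stretch into a line-like
#' holocentromere during condensation.
#'
#' @param conf n x 3 position matrix (nm).
#' @param layout The `fiber_layout` (>= 3 centromeric beads).
#' @return A fraction in `[1/3, 1]`.
#' @export
linearity_score <- function(conf, layout) {
  conf <- as.matrix(conf)
  idx <- which(layout$centromeric)
  if (length(idx) < 3) stop("need at least 3 centromeric beads")
  p <- conf[idx, , drop = FALSE]
  ev <- eigen(stats::cov(p), symmetric = TRUE, only.values = TRUE)$values
  max(ev) / sum(ev)
}

#' Radius of gyration of a bead subset
#'
#' @param conf n x 3 position matrix (nm).
#' @param subset Integer indices (1-based) of beads; default all.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(conf, subset = NULL) {
  conf <- as.matrix(conf)
  if (!is.null(subset)) conf <- conf[subset, , drop = FALSE]
  ctr <- colMeans(conf)
  sqrt(mean(rowSums(sweep(conf, 2, ctr)^2)))
}

#' Binned spatial contact map
#'
#' Counts bead pairs closer than `r_contact` nm, aggregated into
#' `bin_size`-monomer bins along the chain; the Hi-C-style symmetric count
#' matrix (self-pairs of a bead are not counted; a bead pair contributes to
#' its (bin_i, bin_j) and (bin_j, bin_i) cells).
#'
#' @param conf n x 3 position matrix (nm).
#' @param bin_size Monomers per bin.
#' @param r_contact Contact radius (nm).
#' @return A symmetric integer matrix of contact counts.
#' @export
contact_map <- function(conf, bin_size = 10, r_contact = 15) {
  conf <- as.matrix(conf)
  n <- nrow(conf)
  bins <- ((seq_len(n) - 1L) %/% bin_size) + 1L
  nb <- max(bins)
  dm <- as.matrix(dist(conf)) <= r_contact
  diag(dm) <- FALSE
  m <- matrix(0L, nb, nb)
  idx <- which(dm & upper.tri(dm), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    for (r in seq_len(nrow(idx))) {
      bi <- bins[idx[r, 1]]
      bj <- bins[idx[r, 2]]
      m[bi, bj] <- m[bi, bj] + 1L
      if (bi != bj) m[bj, bi] <- m[bj, bi] + 1L
    }
  }
  m
}

#' Tidy table of standard conformation metrics
#'
#' @param conf n x 3 position matrix (nm).
#' @param layout The `fiber_layout`.
#' @param frame Frame label stored in the output.
#' @param r_nbr,d_link Metric parameters.
#' @return A `data.frame` with columns `frame`, `metric`, `value`.
#' @export
conformation_metrics <- function(conf, layout, frame = 0L, r_nbr = 30,
                                 d_link = 24) {
  data.frame(
    frame = frame,
    metric = c("local_density_ratio", "n_clusters", "linearity_score",
               "rg_all", "rg_centromeric"),
    value = c(local_density_ratio(conf, layout, r_nbr),
              cluster_units(conf, layout, d_link)$n_clusters,
              linearity_score(conf, layout),
              radius_of_gyration(conf),
              radius_of_gyration(conf, which(layout$centromeric))),
    stringsAsFactors = FALSE)
}
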