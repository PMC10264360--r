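# Independent brute-force oracles used to cross-check the implementation.

# --- energies -------------------------------------------------------------

# O(n^2) double-loop energy, written without reusing package internals
# beyond the scalar potential definitions re-stated here.
oracle_ucc <- function(x, a = 5, b = 6, rmin = 8, s = 20, cc = 0.6,
                       rcut = 60) {
  if (x > rcut) x <- rcut
  u <- if (x <= rmin) x / rmin else x / s + cc
  a + b * (u^4 - 2 * u^2)
}

oracle_unn <- function(x, a = 5, b = 5.5, rmin = 10, rcut = 20) {
  xz <- if (b > a) rmin * sqrt(1 + sqrt(1 - a / b)) else rcut
  if (x >= min(xz, rcut)) return(0)
  u <- x / rmin
  a + b * (u^4 - 2 * u^2)
}

oracle_total_energy <- function(conf, cen_mask, bonds = NULL, bond_k = 10,
                                bond_x0 = 10, bend_k = 2) {
  n <- nrow(conf)
  e <- 0
  for (i in seq_len(n - 1)) {
    d <- sqrt(sum((conf[i + 1, ] - conf[i, ])^2))
    e <- e + 0.5 * bond_k * (d - bond_x0)^2
  }
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      a <- conf[i, ] - conf[i - 1, ]
      b <- conf[i + 1, ] - conf[i, ]
      ct <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
      e <- e + bend_k * (1 - ct)
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i < 2) next
      d <- sqrt(sum((conf[j, ] - conf[i, ])^2))
      e <- e + if (cen_mask[i] && cen_mask[j]) oracle_ucc(d) else
        oracle_unn(d)
    }
  }
  if (!is.null(bonds) && nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      d <- sqrt(sum((conf[bonds[r, 1] + 1, ] - conf[bonds[r, 2] + 1, ])^2))
      e <- e + 0.5 * bond_k * (d - bond_x0)^2
    }
  }
  e
}

# --- interval sets --------------------------------------------------------

# domains -> per-base logical coverage over [0, len)
per_base <- function(d, len) {
  v <- logical(len)
  for (r in seq_len(nrow(d))) {
    if (d$start[r] < len) {
      v[(d$start[r] + 1):min(d$end[r], len)] <- TRUE
    }
  }
  v
}

# per-base logical coverage -> sorted disjoint domains
runs_to_domains <- function(v, chrom = "chr1") {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
             end = ends[keep], stringsAsFactors = FALSE)
}

oracle_intersect <- function(a, b, len) {
  runs_to_domains(per_base(a, len) & per_base(b, len))
}

oracle_merge <- function(d, len, max_gap) {
  v <- per_base(d, len)
  # fill every gap strictly shorter than max_gap between covered runs
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  for (k in seq_along(r$values)) {
    if (!r$values[k] && k > 1 && k < length(r$values) &&
        r$lengths[k] < max_gap) {
      v[(starts[k] + 1):ends[k]] <- TRUE
    }
  }
  runs_to_domains(v)
}

oracle_filter <- function(d, min_len) {
  d[d$end - d$start >= min_len, , drop = FALSE]
}

random_domains <- function(len, n_max = 8, chrom = "chr1") {
  n <- sample.int(n_max, 1)
  s <- sort(sample.int(len - 1, n))
  e <- pmin(s + sample.int(max(2, len %/% 4), n), len)
  d <- data.frame(chrom = chrom, start = s, end = e,
                  stringsAsFactors = FALSE)
  d[d$start < d$end, , drop = FALSE]
}

# --- dyad symmetries ------------------------------------------------------

COMP_BASE <- c(A = "T", C = "G", G = "C", T = "A")

# full O(n^3) enumeration of maximal dyads: every (left_start, arm, loop)
# triple is tested for arm pairing, then outward and inward maximality
oracle_dyads <- function(seq, min_arm, max_loop) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  pairs <- function(i, j) s[i] == COMP_BASE[[s[j]]]
  hits <- list()
  for (ls in seq_len(n)) {            # 1-based left arm start
    for (arm in min_arm:n) {
      for (loop in 0:max_loop) {
        re <- ls + 2 * arm + loop - 1
        if (re > n) next
        ok <- all(vapply(seq_len(arm), function(k) {
          pairs(ls + k - 1, re - k + 1)
        }, logical(1)))
        if (!ok) next
        outward <- ls > 1 && re < n && pairs(ls - 1, re + 1)
        inward <- loop >= 2 && pairs(ls + arm, ls + arm + loop - 1)
        if (outward || inward) next
        hits[[length(hits) + 1]] <- data.frame(
          left_start = ls - 1, arm_len = arm, loop_len = loop)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(left_start = integer(0), arm_len = integer(0),
                      loop_len = integer(0)))
  }
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$left_start, out$loop_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- clustering -----------------------------------------------------------

# connected components of the "distance <= d_link" graph (single linkage)
oracle_single_linkage <- function(points, d_link) {
  k <- nrow(points)
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i == j) next
        d <- sqrt(sum((points[i, ] - points[j, ])^2))
        if (d <= d_link && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# random rotation matrix via QR of a gaussian matrix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
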