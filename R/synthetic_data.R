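#' Generate a synthetic holocentric genome truth
#'
#' Samples, per chromosome, a centromere-unit architecture in the regime of
#' a few evenly spaced megabase-scale units: 7-11 units per chromosome,
#' unit lengths from a truncated lognormal with mean ~1.89 Mb bounded to
#' [0.24, 4.46] Mb, and inter-unit gaps from a truncated normal with mean
#' ~9.97 Mb. The chromosome length is the exact sum of units and gaps
#' (including the two terminal flanks).
#'
#' @param n_chrom Number of chromosomes.
#' @param units_per_chrom Integer range `c(min, max)` of units per
#'   chromosome.
#' @param unit_len_mean Mean unit length in bp.
#' @param unit_len_sdlog Lognormal sd (log scale); 0 gives constant lengths.
#' @param unit_len_range Truncation bounds for unit lengths (bp).
#' @param gap_mean Mean inter-unit gap in bp.
#' @param gap_sd Normal sd of gaps (bp); 0 gives constant gaps.
#' @param gap_min Lower truncation of gaps (bp). Must stay above the unit
#'   caller's merge threshold so that distinct units remain separable.
#' @param seed Integer seed; the truth is a pure function of the parameters
#'   and the seed.
#' @return A list of class `synthetic_genome`: `chrom_lengths` (named
#'   vector, bp), `units` (domain `data.frame`), `params`.
#' @export
gen_genome_truth <- function(n_chrom = 12, units_per_chrom = c(7, 11),
                             unit_len_mean = 1.89e6, unit_len_sdlog = 0.55,
                             unit_len_range = c(0.24e6, 4.46e6),
                             gap_mean = 9.97e6, gap_sd = 2.5e6,
                             gap_min = 1e6, seed = 1) {
  stopifnot(n_chrom >= 1, units_per_chrom[1] >= 1,
            units_per_chrom[2] >= units_per_chrom[1],
            unit_len_range[1] <= unit_len_mean,
            unit_len_mean <= unit_len_range[2],
            gap_min > 0, gap_mean > gap_min)
  set.seed(seed)
  meanlog <- log(unit_len_mean) - unit_len_sdlog^2 / 2
  draw_len <- function(k) {
    if (unit_len_sdlog == 0) return(rep(unit_len_mean, k))
    out <- numeric(0)
    while (length(out) < k) {
      x <- rlnorm(k, meanlog, unit_len_sdlog)
      out <- c(out, x[x >= unit_len_range[1] & x <= unit_len_range[2]])
    }
    out[seq_len(k)]
  }
  draw_gap <- function(k) {
    if (gap_sd == 0) return(rep(gap_mean, k))
    out <- numeric(0)
    while (length(out) < k) {
      x <- rnorm(k, gap_mean, gap_sd)
      out <- c(out, x[x >= gap_min])
    }
    out[seq_len(k)]
  }
  units <- list()
  lens <- numeric(n_chrom)
  names(lens) <- paste0("chr", seq_len(n_chrom))
  ks <- seq(units_per_chrom[1], units_per_chrom[2])
  for (c_i in seq_len(n_chrom)) {
    k <- ks[sample.int(length(ks), 1)]
    ul <- round(draw_len(k))
    gl <- round(draw_gap(k + 1))
    starts <- cumsum(gl[seq_len(k)] + c(0, ul[-k]))
    ends <- starts + ul
    lens[c_i] <- sum(ul) + sum(gl)
    units[[c_i]] <- data.frame(chrom = names(lens)[c_i], start = starts,
                               end = ends, stringsAsFactors = FALSE)
  }
  structure(list(chrom_lengths = lens,
                 units = do.call(rbind, units),
                 params = list(n_chrom = n_chrom,
                               units_per_chrom = units_per_chrom,
                               unit_len_mean = unit_len_mean,
                               unit_len_sdlog = unit_len_sdlog,
                               unit_len_range = unit_len_range,
                               gap_mean = gap_mean, gap_sd = gap_sd,
                               gap_min = gap_min, seed = seed)),
            class = "synthetic_genome")
}

#' Fragment planted units into raw CENH3-domain peaks
#'
#' Splits each planted unit by Poisson-placed interruptions -- fragmented
#' satellite arrays or transposon insertions -- each strictly shorter than
#' the unit caller's merge threshold, with every resulting piece at least
#' `min_piece` long, so that merging gaps below `max_gap` and dropping
#' pieces below 1 kb recovers the planted truth exactly.
#'
#' @param truth A [gen_genome_truth()] object.
#' @param break_rate Expected interruptions per Mb of unit.
#' @param interruption_len Length range `c(min, max)` of interruptions (bp);
#'   `max` must be < `max_gap`.
#' @param min_piece Minimum retained piece length (bp, >= 1 kb so pieces
#'   survive the short-domain filter).
#' @param max_gap The merge threshold the caller will use (bp).
#' @param seed Integer seed.
#' @return A domain `data.frame` of raw (fragmented) peaks.
#' @export
fragment_truth <- function(truth, break_rate = 1,
                           interruption_len = c(5e3, 4e5), min_piece = 1e3,
                           max_gap = 500000, seed = 1) {
  stopifnot(inherits(truth, "synthetic_genome"))
  if (interruption_len[2] >= max_gap) {
    stop("interruptions of ", interruption_len[2],
         " bp would reach the merge threshold (", max_gap,
         "); truth would not be recoverable")
  }
  if (min_piece < 1000) {
    stop("min_piece below 1 kb: pieces would be discarded by the short-",
         "domain filter and truth would not be recoverable")
  }
  set.seed(seed)
  rows <- list()
  for (r in seq_len(nrow(truth$units))) {
    u <- truth$units[r, ]
    len <- u$end - u$start
    nb <- rpois(1, break_rate * len / 1e6)
    # feasibility: nb interruptions + (nb + 1) pieces must fit
    repeat {
      il <- if (nb > 0) {
        round(runif(nb, interruption_len[1], interruption_len[2]))
      } else {
        numeric(0)
      }
      if (sum(il) + (nb + 1) * min_piece <= len) break
      nb <- nb - 1
    }
    if (nb == 0) {
      rows[[length(rows) + 1]] <- u
      next
    }
    slack <- len - sum(il) - (nb + 1) * min_piece
    w <- diff(c(0, sort(runif(nb)), 1))
    pieces <- min_piece + round(w * slack)
    pieces[nb + 1] <- len - sum(il) - sum(pieces[-(nb + 1)])
    pos <- u$start
    for (p in seq_len(nb + 1)) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = u$chrom, start = pos, end = pos + pieces[p],
        stringsAsFactors = FALSE)
      pos <- pos + pieces[p] + if (p <= nb) il[p] else 0
    }
  }
  as_domain_set(do.call(rbind, rows))
}

#' Simulate two noisy peak-caller views of the same raw domains
#'
#' Produces two perturbed copies of the raw peak set, emulating two
#' independent peak callers. Boundary jitter moves each record edge by a
#' rounded normal deviate; false negatives drop whole records; false
#' positives add caller-specific records placed in disjoint halves of the
#' inter-peak space (caller A in left halves, caller B in right halves), so
#' that with jitter-free, drop-free noise the base-pair intersection of the
#' two callers equals the raw set exactly.
#'
#' @param raw Domain `data.frame` of raw peaks.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param boundary_jitter Sd of the edge jitter (bp; 0 = exact edges).
#' @param fp_rate Expected false-positive peaks per Mb of inter-peak space.
#' @param fn_rate Probability that a caller misses a raw peak.
#' @param fp_len Length range of false-positive peaks (bp).
#' @param seed Integer seed.
#' @return A list with elements `a` and `b` (domain `data.frame`s).
#' @export
gen_two_callers <- function(raw, chrom_lengths, boundary_jitter = 0,
                            fp_rate = 0, fn_rate = 0, fp_len = c(1e3, 5e4),
                            seed = 1) {
  raw <- as_domain_set(raw)
  set.seed(seed)
  perturb <- function(side) {
    d <- raw
    if (boundary_jitter > 0 && nrow(d) > 0) {
      d$start <- pmax(0, round(d$start + rnorm(nrow(d), 0, boundary_jitter)))
      d$end <- round(d$end + rnorm(nrow(d), 0, boundary_jitter))
      d <- d[d$start < d$end, , drop = FALSE]
    }
    if (fn_rate > 0 && nrow(d) > 0) {
      d <- d[runif(nrow(d)) >= fn_rate, , drop = FALSE]
    }
    if (fp_rate > 0) {
      fps <- list()
      for (ch in names(chrom_lengths)) {
        u <- raw[raw$chrom == ch, , drop = FALSE]
        bounds <- c(0, as.vector(rbind(u$start, u$end)), chrom_lengths[[ch]])
        gs <- bounds[seq(1, length(bounds), 2)]
        ge <- bounds[seq(2, length(bounds), 2)]
        for (g in seq_along(gs)) {
          lo <- gs[g]
          hi <- ge[g]
          if (hi - lo < 4) next
          mid <- (lo + hi) / 2
          # caller-specific half-gaps keep A and B false positives disjoint
          h_lo <- if (side == "a") lo + 1 else mid
          h_hi <- if (side == "a") mid else hi - 1
          cap <- min(fp_len[2], (h_hi - h_lo) / 2)
          if (cap < fp_len[1]) next
          n_fp <- rpois(1, fp_rate * (hi - lo) / 1e6)
          for (f in seq_len(n_fp)) {
            l <- round(runif(1, fp_len[1], cap))
            if (l < 1) next
            st <- round(runif(1, h_lo, h_hi - l))
            fps[[length(fps) + 1]] <- data.frame(
              chrom = ch, start = st, end = st + l,
              stringsAsFactors = FALSE)
          }
        }
      }
      if (length(fps) > 0) d <- rbind(d, do.call(rbind, fps))
    }
    as_domain_set(d)
  }
  list(a = perturb("a"), b = perturb("b"))
}

#' Generate gene positions in intercentromeric space
#'
#' Places genes uniformly in the intercentromeric regions, at least
#' `min_offset` bp away from every centromere unit, with a Poisson count of
#' `density` genes per Mb of eligible space.
#'
#' @param truth A [gen_genome_truth()] object.
#' @param density Genes per Mb of eligible intercentromeric space.
#' @param min_offset Minimum distance from any unit (bp; 0 lets genes abut
#'   units).
#' @param gene_len Length range of genes (bp).
#' @param seed Integer seed.
#' @return A domain `data.frame` of genes.
#' @export
gen_genes <- function(truth, density = 5, min_offset = 1e4,
                      gene_len = c(1e3, 5e3), seed = 1) {
  stopifnot(inherits(truth, "synthetic_genome"), density >= 0,
            min_offset >= 0)
  set.seed(seed)
  rows <- list()
  for (ch in names(truth$chrom_lengths)) {
    u <- truth$units[truth$units$chrom == ch, , drop = FALSE]
    bounds <- c(0, as.vector(rbind(u$start, u$end)),
                truth$chrom_lengths[[ch]])
    gs <- bounds[seq(1, length(bounds), 2)]
    ge <- bounds[seq(2, length(bounds), 2)]
    # shrink segments by the offset on the sides that touch a unit
    n_seg <- length(gs)
    for (g in seq_len(n_seg)) {
      lo <- gs[g] + if (g > 1) min_offset else 0
      hi <- ge[g] - if (g < n_seg) min_offset else 0
      if (hi - lo < gene_len[1]) next
      n_g <- rpois(1, density * (hi - lo) / 1e6)
      for (f in seq_len(n_g)) {
        l <- round(runif(1, gene_len[1], min(gene_len[2], hi - lo)))
        st <- round(runif(1, lo, hi - l))
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, start = st, end = st + l, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  as_domain_set(do.call(rbind, rows))
}

#' Generate a satellite monomer with planted dyad symmetries
#'
#' Builds a random background sequence and plants exact, maximal dyad
#' symmetries at requested positions: the right arm is the reverse
#' complement of the left arm, innermost loop bases are made non-pairing,
#' and the bases flanking the arms are made non-pairing, so that a scanner
#' reports exactly the planted (position, arm, loop). With `junction_arm`
#' set, the monomer suffix is the reverse complement of its prefix of that
#' length, so the head-to-tail dimer carries a junction-spanning dyad of
#' exactly that arm length.
#'
#' @param length Monomer length in bases.
#' @param planted List of `c(arm, loop, position)` triples; `position` is
#'   the 0-based start of the left arm.
#' @param junction_arm Optional arm length of the planted inter-monomer
#'   hairpin.
#' @param alphabet Background alphabet (default A/C/G/T; a single-letter
#'   alphabet gives a dyad-free background).
#' @param seed Integer seed.
#' @return A character scalar.
#' @export
gen_monomer_with_dyads <- function(length, planted = list(),
                                   junction_arm = NULL,
                                   alphabet = c("A", "C", "G", "T"),
                                   seed = 1) {
  stopifnot(length >= 1)
  set.seed(seed)
  s <- sample(alphabet, length, replace = TRUE)
  not_comp <- function(base) {
    # any base that does not pair with `base`
    setdiff(c("A", "C", "G", "T"), COMP[[base]])[1]
  }
  for (p in planted) {
    arm <- p[1]
    loop <- p[2]
    pos <- p[3] + 1  # 1-based left-arm start
    endr <- pos + 2 * arm + loop - 1
    if (pos < 1 || endr > length) {
      stop("planted dyad (arm ", arm, ", loop ", loop, ", position ",
           p[3], ") does not fit in a ", length, "-base monomer")
    }
    left <- s[pos:(pos + arm - 1)]
    s[(pos + arm + loop):(endr)] <-
      rev(vapply(left, function(b) COMP[[b]], character(1)))
    if (loop >= 2) {
      i1 <- pos + arm
      i2 <- pos + arm + loop - 1
      if (s[i1] == COMP[[s[i2]]]) s[i2] <- not_comp(s[i1])
    }
    if (pos > 1 && endr < length) {
      if (s[pos - 1] == COMP[[s[endr + 1]]]) {
        s[endr + 1] <- not_comp(s[pos - 1])
      }
    }
  }
  if (!is.null(junction_arm)) {
    ja <- junction_arm
    if (2 * ja > length) stop("junction_arm too long for the monomer")
    pre <- s[seq_len(ja)]
    s[(length - ja + 1):length] <-
      rev(vapply(pre, function(b) COMP[[b]], character(1)))
    # stop the junction dyad from extending beyond ja on either side
    if (ja + 1 <= length - ja) {
      if (s[ja + 1] == COMP[[s[length - ja]]]) {
        s[ja + 1] <- not_comp(s[length - ja])
      }
    }
  }
  paste(s, collapse = "")
}

#' Write the full synthetic fixture tree
#'
#' Materialises one synthetic study input set from a master seed: truth
#' units, fragmented raw peaks, two caller tracks, genes (all BED),
#' chromosome sizes (TSV) and satellite monomers with planted dyads
#' (FASTA).
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param n_chrom Number of chromosomes.
#' @return The directory, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1, n_chrom = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- gen_genome_truth(n_chrom = n_chrom, seed = seed)
  raw <- fragment_truth(truth, seed = seed + 1)
  callers <- gen_two_callers(raw, truth$chrom_lengths,
                             boundary_jitter = 0, fp_rate = 0.05,
                             seed = seed + 2)
  genes <- gen_genes(truth, seed = seed + 3)
  write_bed(truth$units, file.path(dir, "truth_units.bed"))
  write_bed(raw, file.path(dir, "raw_peaks.bed"))
  write_bed(callers$a, file.path(dir, "caller_a.bed"))
  write_bed(callers$b, file.path(dir, "caller_b.bed"))
  write_bed(genes, file.path(dir, "genes.bed"))
  writeLines(sprintf("%s\t%d", names(truth$chrom_lengths),
                     as.integer(truth$chrom_lengths)),
             file.path(dir, "chrom.sizes"))
  m1 <- gen_monomer_with_dyads(23, planted = list(c(4, 2, 3)),
                               junction_arm = 8, seed = seed + 4)
  m2 <- gen_monomer_with_dyads(28, planted = list(c(4, 2, 3), c(5, 1, 16)),
                               junction_arm = 8, seed = seed + 5)
  writeLines(c(">monomer1_synthetic", m1, ">monomer2_synthetic", m2),
             file.path(dir, "monomers_synthetic.fasta"))
  invisible(dir)
}
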