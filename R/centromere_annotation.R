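#' Normalize a set of genomic domains
#'
#' A domain set is a `data.frame` with `chrom`, `start`, `end` (bp, 0-based
#' half-open) and an optional `score`. Normalization sorts by
#' `(chrom, start)` and merges overlapping or book-ended records, so that
#' records within a chromosome are disjoint.
#'
#' @param d A `data.frame` with at least `chrom`, `start`, `end`.
#' @return A normalized domain `data.frame`.
#' @export
as_domain_set <- function(d) {
  stopifnot(is.data.frame(d), all(c("chrom", "start", "end") %in% names(d)))
  if (nrow(d) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  if (any(d$start < 0)) stop("negative start coordinate")
  if (any(d$start >= d$end)) {
    bad <- which(d$start >= d$end)[1]
    stop("record ", bad, " has start >= end")
  }
  gr_to_domains(GenomicRanges::reduce(domains_to_gr(d)))
}

domains_to_gr <- function(d) {
  GenomicRanges::GRanges(
    seqnames = as.character(d$chrom),
    ranges = IRanges::IRanges(start = d$start + 1, end = d$end))
}

gr_to_domains <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read / write BED interval files
#'
#' `read_bed` parses BED3+ (tab- or whitespace-separated; 0-based half-open
#' coordinates; a 5th column, when present, is kept as `score`). Malformed
#' lines are rejected with their line number. `write_bed` writes BED3 (or
#' BED5 with a placeholder name when a `score` column is present).
#'
#' @param path File path.
#' @return `read_bed`: a domain `data.frame` sorted by `(chrom, start)`
#'   (not merged, so round-trips are exact).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "[\t ]+")[[1]]
    if (length(f) < 3) {
      stop("line ", i, " of ", path, ": fewer than 3 fields")
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || s != floor(s) || e != floor(e)) {
      stop("line ", i, " of ", path, ": non-integer coordinates")
    }
    if (s >= e) stop("line ", i, " of ", path, ": start >= end")
    rec <- data.frame(chrom = f[1], start = s, end = e,
                      stringsAsFactors = FALSE)
    if (length(f) >= 5) {
      sc <- suppressWarnings(as.numeric(f[5]))
      rec$score <- sc
    }
    out[[length(out) + 1]] <- rec
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  has_score <- vapply(out, function(r) "score" %in% names(r), logical(1))
  if (any(has_score) && !all(has_score)) {
    for (j in which(!has_score)) out[[j]]$score <- NA_real_
  }
  d <- do.call(rbind, out)
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' @rdname read_bed
#' @param d A domain `data.frame`.
#' @export
write_bed <- function(d, path) {
  if (!is.null(d$score)) {
    txt <- sprintf("%s\t%d\t%d\t.\t%s", d$chrom, as.integer(d$start),
                   as.integer(d$end), format(d$score, trim = TRUE))
  } else {
    txt <- sprintf("%s\t%d\t%d", d$chrom, as.integer(d$start),
                   as.integer(d$end))
  }
  writeLines(txt, path)
  invisible(path)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path Tab-separated file with chromosome name and length (bp).
#' @return A named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  t <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "length"),
                  stringsAsFactors = FALSE)
  stats::setNames(as.numeric(t$length), t$chrom)
}

#' Base-pair intersection of two caller tracks
#'
#' Returns the genomic regions covered by both domain sets: the CENH3
#' domains supported by both peak callers. Base-pair (not whole-peak)
#' intersection.
#'
#' @param a,b Domain `data.frame`s.
#' @return A normalized domain `data.frame`.
#' @export
intersect_callers <- function(a, b) {
  a <- as_domain_set(a)
  b <- as_domain_set(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(as_domain_set(a[0, ]))
  gr <- GenomicRanges::intersect(domains_to_gr(a), domains_to_gr(b))
  gr_to_domains(gr)
}

#' Merge domains separated by small gaps
#'
#' Consecutive same-chromosome domains whose gap is strictly smaller than
#' `max_gap` are merged into their spanning interval, eliminating gaps
#' caused by fragmented satellite arrays or transposon insertions inside a
#' centromere unit. A gap of exactly `max_gap` is NOT merged. Idempotent.
#'
#' @param d A domain `data.frame`.
#' @param max_gap Merge threshold in bp (default 500 kb).
#' @return A normalized domain `data.frame`.
#' @export
merge_close <- function(d, max_gap = 500000) {
  d <- as_domain_set(d)
  if (nrow(d) == 0) return(d)
  gr <- GenomicRanges::reduce(domains_to_gr(d), min.gapwidth = max_gap)
  gr_to_domains(gr)
}

#' Discard short domains
#'
#' Removes records shorter than `min_len` bp; a record of exactly `min_len`
#' is kept. Idempotent.
#'
#' @param d A domain `data.frame`.
#' @param min_len Minimum length in bp (default 1 kb).
#' @return A normalized domain `data.frame`.
#' @export
drop_short <- function(d, min_len = 1000) {
  d <- as_domain_set(d)
  d <- d[d$end - d$start >= min_len, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Call centromere units from CENH3 domain tracks
#'
#' The unit-calling pipeline: keep only regions detected by both callers
#' (base-pair intersection; skipped when `b` is absent), merge domains
#' separated by less than `max_gap`, then discard domains shorter than
#' `min_len` -- in that order.
#'
#' @param a Primary caller domains (`data.frame`).
#' @param b Optional second caller domains.
#' @param max_gap Merge threshold in bp.
#' @param min_len Minimum unit length in bp.
#' @return A normalized domain `data.frame` of centromere units.
#' @export
call_units <- function(a, b = NULL, max_gap = 500000, min_len = 1000) {
  d <- if (is.null(b)) as_domain_set(a) else intersect_callers(a, b)
  drop_short(merge_close(d, max_gap), min_len)
}

#' Summary statistics of a centromere-unit set
#'
#' Computes the per-chromosome and global descriptors of a holocentromere's
#' unit organisation: unit counts, lengths, inter-unit gaps (distance
#' between the end of one unit and the start of the next on the same
#' chromosome), units per Mb of assembly, the Pearson correlation between
#' unit length and the mean of its flanking gaps (terminal units use their
#' single internal gap), and the mean distance from each unit to its
#' nearest gene (0 for overlapping or book-ended genes).
#'
#' @param units A normalized domain `data.frame` of centromere units.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp
#'   (must cover every chromosome present in `units`).
#' @param genes Optional domain `data.frame` of genes.
#' @return A list of class `unit_stats`; see Details for fields.
#' @details Fields: `per_chrom` (data.frame: chrom, n_units, mean_length,
#'   mean_gap), `lengths`, `gaps`, `n_units`, `mean_length`, `min_length`,
#'   `max_length`, `mean_gap`, `units_per_mb`, `length_gap_cor`,
#'   `mean_nearest_gene_distance`.
#' @export
unit_stats <- function(units, chrom_lengths, genes = NULL) {
  units <- as_domain_set(units)
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths[[2]]),
                                     chrom_lengths[[1]])
  }
  missing_chr <- setdiff(unique(units$chrom), names(chrom_lengths))
  if (length(missing_chr) > 0) {
    stop("chromosome(s) absent from chrom_lengths: ",
         paste(missing_chr, collapse = ", "))
  }
  chroms <- unique(units$chrom)
  lengths <- units$end - units$start
  gaps <- numeric(0)
  per_rows <- list()
  flank_len <- numeric(0)
  flank_gap <- numeric(0)
  for (ch in chroms) {
    u <- units[units$chrom == ch, , drop = FALSE]
    k <- nrow(u)
    g <- if (k >= 2) u$start[-1] - u$end[-k] else numeric(0)
    gaps <- c(gaps, g)
    per_rows[[ch]] <- data.frame(
      chrom = ch, n_units = k,
      mean_length = mean(u$end - u$start),
      mean_gap = if (length(g)) mean(g) else NA_real_,
      stringsAsFactors = FALSE)
    if (k >= 2) {
      fg <- vapply(seq_len(k), function(j) {
        if (j == 1) g[1]
        else if (j == k) g[k - 1]
        else mean(c(g[j - 1], g[j]))
      }, numeric(1))
      flank_len <- c(flank_len, u$end - u$start)
      flank_gap <- c(flank_gap, fg)
    }
  }
  cor_lg <- if (length(flank_len) >= 3 && stats::sd(flank_len) > 0 &&
                stats::sd(flank_gap) > 0) {
    cor(flank_len, flank_gap)
  } else {
    NA_real_
  }
  gene_dist <- NA_real_
  if (!is.null(genes) && nrow(units) > 0) {
    genes <- as_domain_set(genes)
    if (nrow(genes) > 0) {
      hit <- GenomicRanges::distanceToNearest(domains_to_gr(units),
                                              domains_to_gr(genes))
      dd <- S4Vectors::mcols(hit)$distance
      if (length(dd) > 0) gene_dist <- mean(dd)
    }
  }
  structure(list(
    per_chrom = do.call(rbind, unname(per_rows)),
    lengths = lengths, gaps = gaps,
    n_units = nrow(units),
    mean_length = if (nrow(units)) mean(lengths) else NA_real_,
    min_length = if (nrow(units)) min(lengths) else NA_real_,
    max_length = if (nrow(units)) max(lengths) else NA_real_,
    mean_gap = if (length(gaps)) mean(gaps) else NA_real_,
    units_per_mb = nrow(units) / (sum(chrom_lengths) / 1e6),
    length_gap_cor = cor_lg,
    mean_nearest_gene_distance = gene_dist), class = "unit_stats")
}

#' @export
print.unit_stats <- function(x, ...) {
  cat("Centromere-unit statistics\n")
  cat(sprintf("  units: %d | mean length: %.3f Mb (%.2f-%.2f Mb)\n",
              x$n_units, x$mean_length / 1e6, x$min_length / 1e6,
              x$max_length / 1e6))
  if (!is.na(x$mean_gap)) {
    cat(sprintf("  mean inter-unit gap: %.2f Mb\n", x$mean_gap / 1e6))
  }
  cat(sprintf("  units per Mb: %.3f\n", x$units_per_mb))
  if (!is.na(x$length_gap_cor)) {
    cat(sprintf("  unit length vs flanking gap: r = %.2f\n",
                x$length_gap_cor))
  }
  if (!is.na(x$mean_nearest_gene_distance)) {
    cat(sprintf("  mean nearest-gene distance: %.1f kb\n",
                x$mean_nearest_gene_distance / 1e3))
  }
  invisible(x)
}

#' Write unit statistics as a tab-separated table
#'
#' @param stats A [unit_stats()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_unit_stats <- function(stats, path) {
  glob <- data.frame(
    key = c("n_units", "mean_length", "min_length", "max_length",
            "mean_gap", "units_per_mb", "length_gap_cor",
            "mean_nearest_gene_distance"),
    value = c(stats$n_units, stats$mean_length, stats$min_length,
              stats$max_length, stats$mean_gap, stats$units_per_mb,
              stats$length_gap_cor, stats$mean_nearest_gene_distance))
  write.table(glob, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
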