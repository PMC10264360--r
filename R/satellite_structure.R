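#' Reverse complement of a DNA sequence
#'
#' @param seq A character scalar over A/C/G/T (case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(seq) {
  seq <- check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

check_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains characters outside {A, C, G, T}")
  }
  seq
}

COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Find maximal dyad symmetries (inverted repeats) in a sequence
#'
#' A dyad symmetry is a pair of arms where the left arm equals the reverse
#' complement of the right arm, separated by a loop; such sites can extrude
#' hairpin or cruciform structures. All maximal, mismatch-free dyads with
#' `arm_len >= min_arm` and `loop_len <= max_loop` are reported: a dyad is
#' maximal when its arms can be extended neither outward (flanking bases do
#' not pair, or a sequence end is reached) nor inward (the two loop bases
#' adjacent to the arms do not pair, or the loop is shorter than 2).
#'
#' @param seq A character scalar over A/C/G/T.
#' @param min_arm Minimum arm length in bases (>= 2).
#' @param max_loop Maximum loop length in bases.
#' @return A `data.frame` sorted by position with columns `left_start`
#'   (0-based index of the left arm), `arm_len`, `loop_len`, `left_arm`
#'   (arm sequence; the right arm is its reverse complement).
#' @export
#' @examples
#' find_dyads("GAATTC", min_arm = 3, max_loop = 0)
find_dyads <- function(seq, min_arm = 4, max_loop = 10) {
  seq <- check_dna(seq)
  stopifnot(min_arm >= 2, max_loop >= 0)
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  res <- list()
  for (i in seq_len(n)) {          # i = 1-based index of left arm's last base
    for (loop in 0:max_loop) {
      j0 <- i + loop + 1           # right arm's first base
      if (j0 > n) break
      a <- 0L
      while (i - a >= 1 && j0 + a <= n &&
             s[i - a] == COMP[[s[j0 + a]]]) {
        a <- a + 1L
      }
      if (a < min_arm) next
      # inward maximality: the innermost loop bases must not pair
      if (loop >= 2 && s[i + 1] == COMP[[s[i + loop]]]) next
      res[[length(res) + 1]] <- data.frame(
        left_start = i - a, arm_len = a, loop_len = loop,
        left_arm = paste(s[(i - a + 1):i], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(left_start = integer(0), arm_len = integer(0),
                      loop_len = integer(0), left_arm = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$left_start, out$loop_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Junction-spanning dyads in a head-to-tail satellite dimer
#'
#' Scans the tandem dimer `monomer + monomer` for dyad symmetries whose
#' arms straddle the monomer junction -- the configuration that lets two
#' neighbouring satellite monomers fold into a hairpin with each other.
#' Dyads lying entirely within one monomer copy are excluded.
#'
#' @param monomer A character scalar over A/C/G/T.
#' @param arm_len Minimum arm length of the junction dyad (default 8, the
#'   conserved inter-monomer hairpin arm).
#' @param max_loop Maximum loop length in bases.
#' @return As [find_dyads()], with coordinates on the dimer and an added
#'   logical `junction_spanning` column (all `TRUE`).
#' @export
dimer_hairpin <- function(monomer, arm_len = 8, max_loop = 10) {
  monomer <- check_dna(monomer)
  L <- nchar(monomer)
  d <- find_dyads(paste0(monomer, monomer), min_arm = arm_len,
                  max_loop = max_loop)
  span <- d$left_start < L & (d$left_start + 2 * d$arm_len + d$loop_len) > L
  d <- d[span, , drop = FALSE]
  d$junction_spanning <- rep(TRUE, nrow(d))
  rownames(d) <- NULL
  d
}

#' Write a dyad report as a tab-separated table
#'
#' @param dyads Output of [find_dyads()] or [dimer_hairpin()].
#' @param path Output file.
#' @param seq_id Sequence identifier written in the first column.
#' @return `path`, invisibly.
#' @export
write_dyad_report <- function(dyads, path, seq_id = "seq") {
  out <- data.frame(seq_id = rep(seq_id, nrow(dyads)), dyads)
  if (is.null(out$junction_spanning)) {
    out$junction_spanning <- rep(FALSE, nrow(out))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
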