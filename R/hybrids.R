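#' Enumerate the 9-bp RNA-DNA hybrid constructs
#'
#' Builds the full panel of short RNA-DNA hybrid duplexes used to derive
#' per-base-pair-type interaction features. Each construct is 9 base pairs
#' long: a 3-bp core flanked on both sides by rG-dC padding pairs (the most
#' stable pair, which keeps duplex termini from fraying in simulation). The
#' central core position may be any of the 16 base-pair types (match or
#' mismatch); the two positions flanking it are restricted to the 4
#' Watson-Crick matches each, giving 4 x 16 x 4 = 256 distinct constructs.
#'
#' Constructs are returned in canonical order: upstream flank slowest, then
#' central guide base, central target base, downstream flank fastest, each
#' A < C < G < T.
#'
#' @return A data frame with one row per construct and columns `up`,
#'   `central_rna`, `central_dna`, `down` (single bases; flanks named by
#'   their RNA base), `rna_strand` (9-mer, 5'->3') and `dna_strand` (the
#'   physically paired DNA strand written 3'->5', index-aligned with the
#'   RNA strand so column i of one strand pairs with column i of the
#'   other). Note `central_dna` is in protospacer-strand representation:
#'   the paired target-strand base is its complement, so a "match"
#'   (identical letters) is a Watson-Crick pair.
#' @examples
#' h <- design_hybrids()
#' nrow(h)  # 256
#' @export
design_hybrids <- function() {
  grid <- expand.grid(down = DNA_BASES, central_dna = DNA_BASES,
                      central_rna = DNA_BASES, up = DNA_BASES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("up", "central_rna", "central_dna", "down")]
  pad <- "GGG"
  rna <- paste0(pad, grid$up, grid$central_rna, grid$down, pad)
  # paired DNA strand: per-position complement of the protospacer-strand
  # representation (flanks and padding are matches by construction)
  dna_repr <- paste0(pad, grid$up, grid$central_dna, grid$down, pad)
  dna <- vapply(dna_repr, wc_complement, character(1), USE.NAMES = FALSE)
  out <- data.frame(grid, rna_strand = rna, dna_strand = dna,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
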