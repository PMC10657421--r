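#' Read / write genomes as FASTA
#'
#' A genome is represented as a named character vector of upper-case
#' A/C/G/T/N sequences, one element per chromosome or contig.
#'
#' @param path FASTA file (multi-record, wrapped or unwrapped).
#' @return `read_genome`: named character vector.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  # FASTA descriptions may carry comments after the record name
  names(g) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  validate_genome(g)
  g
}

#' @rdname read_genome
#' @param genome Named character vector of sequences.
#' @param width Line-wrap width for the FASTA output.
#' @return `write_genome`: `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70) {
  validate_genome(genome)
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

validate_genome <- function(genome) {
  if (!is.character(genome) || length(genome) == 0) {
    stop("genome must be a non-empty named character vector", call. = FALSE)
  }
  if (is.null(names(genome)) || anyDuplicated(names(genome)) ||
      any(!nzchar(names(genome)))) {
    stop("genome sequences must have unique non-empty names", call. = FALSE)
  }
  if (any(nchar(genome) == 0)) stop("empty genome sequence", call. = FALSE)
  invisible(genome)
}

#' Enumerate candidate off-target sites for a guide
#'
#' Exhaustively scans both strands of a genome for 20-nt windows whose
#' 3'-adjacent trinucleotide matches the PAM pattern (NGG for SpCas9) and
#' which carry at most `max_mismatches` letter mismatches to the guide.
#' This is the candidate universe over which off-target scores and the
#' specificity aggregate are computed; the PAM is a hard constraint and is
#' never counted as mismatch. Windows containing the ambiguity code N in
#' protospacer or PAM are skipped. Bulges (insertions/deletions) are not
#' considered.
#'
#' @param genome Named character vector of sequences (see [read_genome()]).
#' @param guide 20-mer guide sequence.
#' @param max_mismatches Mismatch ceiling, 0..20 (default 6, the
#'   conventional radius for genome-wide candidate enumeration).
#' @param pam_pattern 3-mer over A/C/G/T/N; N matches any resolved base.
#' @return Data frame sorted by (chrom, start, strand) with columns
#'   `chrom`, `start`, `end` (0-based half-open protospacer coordinates on
#'   the forward strand), `strand` (`+`/`-`), `protospacer` (20-mer in
#'   guide orientation), `pam` (3-mer in guide orientation), `mismatches`
#'   and `mismatch_positions` (comma-joined 1-based guide positions,
#'   position 1 = PAM-distal).
#' @examples
#' g <- simulate_genome(2000, seed = 3,
#'                      plant = data.frame(pos = 501, strand = "+",
#'                                         protospacer = "GAGTCCGAGCAGAAGAAGAA",
#'                                         pam = "AGG"))
#' find_candidates(g, "GAGTCCGAGCAGAAGAAGAA", max_mismatches = 3)
#' @export
find_candidates <- function(genome, guide, max_mismatches = 6,
                            pam_pattern = "NGG") {
  validate_genome(genome)
  guide <- normalize_seq(guide, 20, what = "guide")
  stopifnot(max_mismatches >= 0, max_mismatches <= 20)
  pam_pattern <- normalize_seq(pam_pattern, 3, allow_n = TRUE,
                               what = "pam_pattern")
  gcode <- base_codes(strsplit(guide, "", fixed = TRUE)[[1]])

  res <- list()
  for (chrom in names(genome)) {
    seq_f <- genome[[chrom]]
    L <- nchar(seq_f)
    if (L < 23) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_f else revcomp(seq_f)
      hits <- scan_strand(s, gcode, max_mismatches, pam_pattern)
      if (nrow(hits) == 0) next
      if (strand == "+") {
        start0 <- hits$pos - 1L
      } else {
        start0 <- L - hits$pos - 19L
      }
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = start0, end = start0 + 20L, strand = strand,
        protospacer = hits$protospacer, pam = hits$pam,
        mismatches = hits$mismatches,
        mismatch_positions = hits$mismatch_positions,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      protospacer = character(), pam = character(),
                      mismatches = integer(),
                      mismatch_positions = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# vectorized single-strand scan; s is the strand sequence 5'->3', pos is
# the 1-based window start on that strand
scan_strand <- function(s, gcode, max_mm, pam_pattern) {
  empty <- data.frame(pos = integer(), protospacer = character(),
                      pam = character(), mismatches = integer(),
                      mismatch_positions = character(),
                      stringsAsFactors = FALSE)
  L <- nchar(s)
  nwin <- L - 22L
  if (nwin < 1) return(empty)
  code <- base_codes(strsplit(s, "", fixed = TRUE)[[1]])
  mm <- integer(nwin)
  bad <- logical(nwin)
  for (j in 1:20) {
    cj <- code[j:(j + nwin - 1L)]
    na <- is.na(cj)
    bad <- bad | na
    neq <- cj != gcode[j]
    neq[na] <- FALSE
    mm <- mm + neq
  }
  pam_ok <- !logical(nwin)
  pcode <- base_codes(strsplit(pam_pattern, "", fixed = TRUE)[[1]])
  pchars <- strsplit(pam_pattern, "", fixed = TRUE)[[1]]
  for (j in 1:3) {
    cj <- code[(20L + j):(19L + j + nwin)]
    na <- is.na(cj)
    bad <- bad | na
    if (pchars[j] != "N") {
      ok <- cj == pcode[j]
      ok[na] <- FALSE
      pam_ok <- pam_ok & ok
    }
  }
  keep <- which(!bad & pam_ok & mm <= max_mm)
  if (!length(keep)) return(empty)
  proto <- substring(s, keep, keep + 19L)
  pam <- substring(s, keep + 20L, keep + 22L)
  mmpos <- vapply(keep, function(p) {
    d <- which(code[p:(p + 19L)] != gcode)
    paste(d, collapse = ",")
  }, character(1))
  data.frame(pos = keep, protospacer = proto, pam = pam,
             mismatches = mm[keep], mismatch_positions = mmpos,
             stringsAsFactors = FALSE)
}

#' Write / read candidate-site tables
#'
#' Tab-delimited with a header; the first columns are BED6-compatible
#' (chrom, start, end get name/score/strand ordering on read-back via
#' the full column set).
#'
#' @param sites Data frame as returned by [find_candidates()].
#' @param path Output TSV path.
#' @return `write_sites`: `path` invisibly; `read_sites`: the data frame.
#' @export
write_sites <- function(sites, path) {
  write_tsv_atomic(sites, path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
             colClasses = c(mismatch_positions = "character"))
}
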