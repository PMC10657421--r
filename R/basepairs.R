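DNA_BASES <- c("A", "C", "G", "T")

#' The 16 RNA-DNA base-pair types
#'
#' A base-pair type pairs one guide (sgRNA) base with one off-target base.
#' The guide base is written in the DNA alphabet (U is represented as T);
#' the off-target base is the protospacer-strand (non-target strand) base
#' written 5'->3' in guide orientation, so a pair is a Watson-Crick match
#' iff the two letters are identical. Types are ordered guide-base major,
#' A < C < G < T, giving the canonical 16-level key `rA_dA` ... `rT_dT`.
#'
#' @return Character vector of the 16 base-pair type labels, in canonical
#'   order.
#' @examples
#' bp_types()
#' @export
bp_types <- function() {
  paste0("r", rep(DNA_BASES, each = 4), "_d", rep(DNA_BASES, times = 4))
}

# canonical index 1..16 of a (guide base, target base) pair; inputs are
# integer codes 1..4 (A,C,G,T)
bp_index_codes <- function(r_code, d_code) {
  (r_code - 1L) * 4L + d_code
}

base_codes <- function(x) {
  match(x, DNA_BASES)
}

#' Normalize a nucleotide sequence
#'
#' Upper-cases the input and maps U to T so guides may be given as RNA.
#' Errors (naming the first offending position) if any character falls
#' outside A/C/G/T after mapping, unless `allow_n` permits N.
#'
#' @param seq Character scalar.
#' @param width Required width, or `NULL` to accept any length.
#' @param allow_n Accept the ambiguity code N?
#' @param what Label used in error messages.
#' @return The normalized sequence (character scalar).
#' @examples
#' normalize_seq("gagucCGAGCAGAAGAAGAa", width = 20)
#' @export
normalize_seq <- function(seq, width = NULL, allow_n = FALSE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  seq <- chartr("u", "T", toupper(seq))
  seq <- chartr("U", "T", seq)
  if (!is.null(width) && nchar(seq) != width) {
    stop(what, " must have length ", width, ", got ", nchar(seq), call. = FALSE)
  }
  ok <- c(DNA_BASES, if (allow_n) "N")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% ok)
  if (length(bad)) {
    stop("invalid character '", chars[bad[1]], "' at position ", bad[1],
         " of ", what, " (alphabet ", paste(ok, collapse = ""), ")",
         call. = FALSE)
  }
  seq
}

# reverse complement of an A/C/G/T/N string
revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

wc_complement <- function(base) {
  chartr("ACGTN", "TGCAN", base)
}

# integer bp-type indices (1..16) for each of the 20 positions of a
# guide/target pair, guide-base major
pair_bp_indices <- function(guide, target) {
  g <- base_codes(strsplit(guide, "", fixed = TRUE)[[1]])
  t <- base_codes(strsplit(target, "", fixed = TRUE)[[1]])
  bp_index_codes(g, t)
}
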