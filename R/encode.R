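#' Encode one guide/off-target pair as an interaction fingerprint
#'
#' Looks up, for each of the 20 positions of the pair, the feature-table
#' row of the base-pair type formed at that position, and concatenates the
#' rows position-major (all features of position 1, then position 2, ...).
#' With the canonical 193-feature table this yields a vector of
#' 20 x 193 = 3860 values. Position 1 is the PAM-distal (5') end of the
#' guide; position 20 is PAM-proximal. The PAM itself is not encoded.
#'
#' @param guide 20-mer guide sequence (U accepted and mapped to T).
#' @param target 20-mer protospacer-strand off-target sequence in guide
#'   orientation, so a match is letter identity.
#' @param table A `feature_table`.
#' @return Named numeric vector of length `20 * n_features(table)`; names
#'   are `p{i}.{feature_name}`.
#' @examples
#' tab <- simulate_feature_table(seed = 1)
#' fp <- encode_pair("GAGTCCGAGCAGAAGAAGAA", "GAGTCCGAGCAGAAGAAGAA", tab)
#' length(fp)
#' @export
encode_pair <- function(guide, target, table) {
  fp <- encode_pairs(guide, target, table)
  setNames(fp[1, ], colnames(fp))
}

#' Encode many guide/off-target pairs as a fingerprint matrix
#'
#' Vectorized form of [encode_pair()]: row i of the result is the
#' fingerprint of `guides[i]` vs `targets[i]`.
#'
#' @param guides,targets Character vectors of equal length (or one guide
#'   recycled against many targets), each element a 20-mer.
#' @param table A `feature_table`.
#' @return Numeric matrix, `length(targets)` rows by
#'   `20 * n_features(table)` columns, with `p{i}.{feature}` column names.
#' @export
encode_pairs <- function(guides, targets, table) {
  stopifnot(inherits(table, "feature_table"))
  if (length(guides) == 1L) guides <- rep(guides, length(targets))
  if (length(guides) != length(targets)) {
    stop("guides and targets must have equal length", call. = FALSE)
  }
  guides <- vapply(guides, normalize_seq, character(1),
                   width = 20, what = "guide", USE.NAMES = FALSE)
  targets <- vapply(targets, normalize_seq, character(1),
                    width = 20, what = "target", USE.NAMES = FALSE)
  n <- length(guides)
  FF <- n_features(table)
  idx <- matrix(0L, n, 20)
  for (i in seq_len(n)) idx[i, ] <- pair_bp_indices(guides[i], targets[i])
  out <- matrix(0, n, 20L * FF)
  V <- table$values
  for (p in 1:20) {
    out[, ((p - 1L) * FF + 1L):(p * FF)] <- V[idx[, p], , drop = FALSE]
  }
  colnames(out) <- fingerprint_names(table)
  out
}

#' Fingerprint slot names for a feature table
#'
#' @param table A `feature_table`.
#' @return Character vector `p1.{f1} ... p20.{fF}` of length
#'   `20 * n_features(table)`.
#' @export
fingerprint_names <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  as.vector(vapply(1:20, function(p) paste0("p", p, ".", table$features$name),
                   character(n_features(table))))
}

#' One-hot and two-hot baseline encoders
#'
#' Sequence-only baselines for comparison with the interaction
#' fingerprint. The one-hot encoder writes a 16-bit indicator of the
#' base-pair type at each position (length 320); within a position block
#' the set bit is at index `4 * index(guide base) + index(target base)`
#' under A < C < G < T (0-based). The two-hot encoder writes a 4-bit guide
#' base indicator followed by a 4-bit target base indicator per position
#' (length 160).
#'
#' @param guide,target 20-mers as in [encode_pair()].
#' @return Numeric 0/1 vector of length 320 (`encode_onehot`) or 160
#'   (`encode_twohot`).
#' @examples
#' sum(encode_onehot("GAGTCCGAGCAGAAGAAGAA", "GAGTCCGAGCAGAAGAAGAA"))  # 20
#' @export
encode_onehot <- function(guide, target) {
  guide <- normalize_seq(guide, 20, what = "guide")
  target <- normalize_seq(target, 20, what = "target")
  idx <- pair_bp_indices(guide, target)
  out <- numeric(320)
  out[(0:19) * 16L + idx] <- 1
  names(out) <- as.vector(vapply(
    1:20, function(p) paste0("p", p, ".", bp_types()), character(16)))
  out
}

#' @rdname encode_onehot
#' @export
encode_twohot <- function(guide, target) {
  guide <- normalize_seq(guide, 20, what = "guide")
  target <- normalize_seq(target, 20, what = "target")
  g <- base_codes(strsplit(guide, "", fixed = TRUE)[[1]])
  t <- base_codes(strsplit(target, "", fixed = TRUE)[[1]])
  out <- numeric(160)
  out[(0:19) * 8L + g] <- 1
  out[(0:19) * 8L + 4L + t] <- 1
  names(out) <- as.vector(vapply(
    1:20, function(p) paste0("p", p, ".",
                             c(paste0("r", DNA_BASES), paste0("d", DNA_BASES))),
    character(8)))
  out
}

# encode a labeled dataset with a named encoder; returns the design matrix
encode_dataset <- function(data, encoder = c("fp", "onehot", "twohot"),
                           table = NULL) {
  encoder <- match.arg(encoder)
  if (encoder == "fp") {
    if (is.null(table)) stop("the fingerprint encoder needs a feature_table",
                             call. = FALSE)
    return(encode_pairs(data$guide, data$target, table))
  }
  fun <- if (encoder == "onehot") encode_onehot else encode_twohot
  X <- t(mapply(fun, data$guide, data$target))
  rownames(X) <- NULL
  X
}
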