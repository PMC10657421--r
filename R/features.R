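FEATURE_CATEGORIES <- c("hydrogen_bond", "binding_energy", "atom_position",
                        "geometry")

#' Construct a per-base-pair-type feature table
#'
#' A feature table is the lookup core of the fingerprint encoder: for each
#' of the 16 RNA-DNA base-pair types it stores one engineered value per
#' interaction feature. Engineered values are dimensionless, lie in
#' [-1, 1], and every feature varies across the 16 types (variance >= the
#' floor used at engineering time, 0.01 by default).
#'
#' @param features Data frame describing the features, with columns
#'   `name` (unique), `category` (one of `hydrogen_bond`, `binding_energy`,
#'   `atom_position`, `geometry`) and `is_angle_derived` (logical; `TRUE` for the
#'   sin/cos components derived from raw angles).
#' @param values Numeric matrix, 16 rows (base-pair types in canonical
#'   `bp_types()` order) by `nrow(features)` columns.
#' @param validate Check invariants on construction?
#' @return An object of class `feature_table`.
#' @seealso [engineer_features()], [simulate_feature_table()],
#'   [read_feature_table()]
#' @export
feature_table <- function(features, values, validate = TRUE) {
  stopifnot(is.data.frame(features), is.matrix(values))
  rownames(values) <- bp_types()
  colnames(values) <- features$name
  x <- structure(list(features = features, values = values),
                 class = "feature_table")
  if (validate) validate_feature_table(x)
  x
}

#' Validate feature-table invariants
#'
#' Checks that all 16 base-pair types are present in canonical order, that
#' feature names are unique and categories known, that all values are
#' finite and within [-1, 1], and that no feature is near-constant across
#' the 16 types (variance below `variance_floor`).
#'
#' @param x A `feature_table`.
#' @param variance_floor Minimum per-feature variance across the 16 types.
#' @return `x`, invisibly; errors describe the first violation found.
#' @export
validate_feature_table <- function(x, variance_floor = 0.01) {
  if (!inherits(x, "feature_table")) stop("not a feature_table", call. = FALSE)
  f <- x$features
  v <- x$values
  if (!all(c("name", "category", "is_angle_derived") %in% names(f))) {
    stop("feature descriptor columns must be name, category, is_angle_derived",
         call. = FALSE)
  }
  if (anyDuplicated(f$name)) {
    stop("duplicated feature name: ", f$name[duplicated(f$name)][1],
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(f$category), FEATURE_CATEGORIES)
  if (length(bad_cat)) stop("unknown feature category: ", bad_cat[1],
                            call. = FALSE)
  if (!identical(rownames(v), bp_types())) {
    stop("value rows must be the 16 base-pair types in canonical order",
         call. = FALSE)
  }
  if (ncol(v) != nrow(f)) stop("values/features dimension mismatch",
                               call. = FALSE)
  if (!all(is.finite(v))) stop("non-finite feature value", call. = FALSE)
  if (any(v < -1 - 1e-9 | v > 1 + 1e-9)) {
    j <- which(apply(v < -1 - 1e-9 | v > 1 + 1e-9, 2, any))[1]
    stop("feature '", f$name[j], "' has values outside [-1, 1]",
         call. = FALSE)
  }
  vars <- apply(v, 2, var)
  if (any(vars < variance_floor)) {
    j <- which(vars < variance_floor)[1]
    stop("feature '", f$name[j], "' has variance ", signif(vars[j], 3),
         " < ", variance_floor, " across the 16 base-pair types",
         call. = FALSE)
  }
  invisible(x)
}

#' Number of features in a feature table
#' @param x A `feature_table`.
#' @return Integer feature count.
#' @export
n_features <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  nrow(x$features)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", n_features(x), " features x 16 bp types\n", sep = "")
  print(table(x$features$category))
  invisible(x)
}

#' Engineer a per-base-pair-type feature table from raw context measurements
#'
#' Raw interaction measurements are taken per 3-bp sequence context: a
#' central base pair (any of the 16 types) flanked by one Watson-Crick
#' match on each side, i.e. 4 x 16 x 4 = 256 contexts. This function
#' collapses the contexts into the 16-type table used by the encoder:
#'
#' 1. angle-valued raw features (degrees) are replaced by their (sin, cos)
#'    component pair, computed per context so that circular quantities are
#'    averaged on the circle rather than on raw degrees;
#' 2. each feature is averaged over the 16 flank contexts of every central
#'    base-pair type;
#' 3. non-angle features are min-max rescaled to [-1, 1] across the 16
#'    type means (sin/cos components are already in [-1, 1] and are left
#'    untouched);
#' 4. features whose variance across the 16 types falls below
#'    `variance_floor` are dropped.
#'
#' @param raw A `raw_context_table` (see [raw_context_table()]).
#' @param variance_floor Variance threshold for step 4.
#' @return A validated `feature_table`.
#' @examples
#' raw <- simulate_raw_contexts(seed = 1)
#' tab <- engineer_features(raw)
#' @export
engineer_features <- function(raw, variance_floor = 0.01) {
  stopifnot(inherits(raw, "raw_context_table"))
  ctx <- raw$contexts
  vals <- raw$values
  if (!is.numeric(vals)) stop("raw feature values must be numeric", call. = FALSE)

  # completeness: all 256 (up, central, down) contexts exactly once
  key <- paste(ctx$up, ctx$central_rna, ctx$central_dna, ctx$down)
  full <- expand.grid(down = DNA_BASES, central_dna = DNA_BASES,
                      central_rna = DNA_BASES, up = DNA_BASES,
                      stringsAsFactors = FALSE)
  want <- paste(full$up, full$central_rna, full$central_dna, full$down)
  missing <- setdiff(want, key)
  if (length(missing)) {
    stop("missing raw context (up central_rna central_dna down): ",
         missing[1], call. = FALSE)
  }
  if (anyDuplicated(key)) {
    stop("duplicated raw context: ", key[duplicated(key)][1], call. = FALSE)
  }

  # expand angles to sin/cos per context, keep other features as-is
  fdesc <- raw$features
  cols <- vector("list", nrow(fdesc))
  desc <- vector("list", nrow(fdesc))
  for (j in seq_len(nrow(fdesc))) {
    v <- vals[, j]
    if (!is.numeric(v) || anyNA(v)) {
      stop("non-numeric raw value in feature '", fdesc$name[j], "'",
           call. = FALSE)
    }
    if (isTRUE(fdesc$is_angle[j])) {
      rad <- v * pi / 180
      cols[[j]] <- cbind(sin(rad), cos(rad))
      desc[[j]] <- data.frame(
        name = paste0(fdesc$name[j], c("_sin", "_cos")),
        category = fdesc$category[j],
        is_angle_derived = TRUE, stringsAsFactors = FALSE)
    } else {
      cols[[j]] <- matrix(v, ncol = 1)
      desc[[j]] <- data.frame(name = fdesc$name[j],
                              category = fdesc$category[j],
                              is_angle_derived = FALSE,
                              stringsAsFactors = FALSE)
    }
  }
  expanded <- do.call(cbind, cols)
  features <- do.call(rbind, desc)

  # mean over the 16 flank contexts of each central bp type
  type_of <- bp_index_codes(base_codes(ctx$central_rna),
                            base_codes(ctx$central_dna))
  sums <- rowsum(expanded, group = type_of)
  counts <- as.vector(table(factor(type_of, levels = 1:16)))
  means <- sums / counts
  means <- means[order(as.integer(rownames(sums))), , drop = FALSE]

  # min-max rescale non-angle features to [-1, 1] across the 16 means
  for (j in seq_len(ncol(means))) {
    if (features$is_angle_derived[j]) next
    lo <- min(means[, j]); hi <- max(means[, j])
    means[, j] <- if (hi > lo) 2 * (means[, j] - lo) / (hi - lo) - 1 else 0
  }

  keep <- apply(means, 2, var) >= variance_floor
  if (!any(keep)) stop("all features fall below the variance floor",
                       call. = FALSE)
  out <- feature_table(features[keep, , drop = FALSE],
                       means[, keep, drop = FALSE], validate = FALSE)
  validate_feature_table(out, variance_floor = variance_floor)
  out
}

#' Construct a raw context table
#'
#' Container for per-context raw interaction measurements (pre-engineering
#' units: hydrogen-bond counts, kcal/mol energies, Angstrom distances,
#' degree angles) over the 256 3-bp hybrid contexts.
#'
#' @param contexts Data frame with columns `up`, `central_rna`,
#'   `central_dna`, `down` (single bases; flanks are Watson-Crick matches
#'   named by their RNA base), 256 rows.
#' @param features Data frame with columns `name`, `category`, `is_angle`
#'   (logical: value is an angle in degrees).
#' @param values Numeric matrix, one row per context, one column per raw
#'   feature.
#' @return An object of class `raw_context_table`.
#' @export
raw_context_table <- function(contexts, features, values) {
  stopifnot(is.data.frame(contexts), is.data.frame(features),
            is.matrix(values),
            nrow(values) == nrow(contexts),
            ncol(values) == nrow(features))
  structure(list(contexts = contexts, features = features, values = values),
            class = "raw_context_table")
}

#' @export
print.raw_context_table <- function(x, ...) {
  cat("<raw_context_table> ", nrow(x$contexts), " contexts x ",
      nrow(x$features), " raw features\n", sep = "")
  invisible(x)
}

#' The packaged canonical feature table
#'
#' Returns the engineered feature table the package treats as canonical:
#' 193 features (1 hydrogen-bond, 42 binding-energy, 114 atom-position and
#' 36 base-pair/step geometry descriptors) per base-pair type. The table
#' is simulated deterministically (see [simulate_feature_table()]) with a
#' fixed seed; it reproduces the structure and scale of a table derived
#' from molecular-dynamics measurements, not any particular published
#' values.
#'
#' @return A `feature_table` with 193 features.
#' @examples
#' tab <- canonical_feature_table()
#' n_features(tab)  # 193
#' @export
canonical_feature_table <- function() {
  simulate_feature_table(seed = 101L)
}
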