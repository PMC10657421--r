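# atomic TSV write: build in a sibling temp file, then rename into place.
# doubles are written with 17 significant digits so numeric round-trips
# are bit-exact
write_tsv_atomic <- function(df, path, row.names = FALSE) {
  df <- as.data.frame(df, check.names = FALSE)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tsv.tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = row.names,
              col.names = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read / write feature tables as TSV
#'
#' One row per feature; columns `name`, `category`, `is_angle_derived`,
#' then the 16 base-pair-type columns `rA_dA` ... `rT_dT` in canonical
#' order.
#'
#' @param table A `feature_table`.
#' @param path TSV path.
#' @return `write_feature_table`: `path` invisibly; `read_feature_table`:
#'   a validated `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- cbind(table$features, as.data.frame(t(table$values)))
  write_tsv_atomic(df, path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   check.names = FALSE)
  need <- c("name", "category", "is_angle_derived", bp_types())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature table TSV missing column: ", miss[1],
                         call. = FALSE)
  feats <- df[, c("name", "category", "is_angle_derived")]
  vals <- t(as.matrix(df[, bp_types()]))
  if (!is.numeric(vals)) stop("non-numeric feature value in ", path,
                              call. = FALSE)
  feature_table(feats, vals)
}

#' Read / write labeled off-target datasets as TSV
#'
#' Columns: `guide`, `target`, `pam`, `label` (0/1), `group` (guide
#' identifier), `dataset_name`, and optionally `weight` and generator
#' bookkeeping columns such as `mismatches`.
#'
#' @param data Data frame.
#' @param path TSV path.
#' @return `write_dataset`: `path` invisibly; `read_dataset`: the data
#'   frame.
#' @export
write_dataset <- function(data, path) {
  write_tsv_atomic(data, path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("guide", "target", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dataset TSV missing column: ", miss[1],
                         call. = FALSE)
  if (is.null(df$group)) df$group <- df$guide
  df
}

#' Write a fingerprint (or fingerprint matrix) as TSV
#'
#' Position-major layout with a `p{i}.{feature}` header row, one data row
#' per pair, so the file round-trips bit-exactly through [read_fingerprints()].
#'
#' @param fp Named numeric vector from [encode_pair()] or matrix from
#'   [encode_pairs()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fp, path) {
  if (is.null(dim(fp))) fp <- matrix(fp, 1, dimnames = list(NULL, names(fp)))
  write_tsv_atomic(as.data.frame(fp, check.names = FALSE), path)
}

#' @rdname write_fingerprints
#' @return `read_fingerprints`: a numeric matrix with the header as column
#'   names.
#' @export
read_fingerprints <- function(path) {
  as.matrix(read.delim(path, check.names = FALSE, comment.char = "#"))
}

# run manifest written beside every CLI output
write_manifest <- function(out_path, subcommand, params) {
  manifest <- list(
    tool = "guidefp",
    version = as.character(utils::packageVersion("guidefp")),
    subcommand = subcommand,
    parameters = params,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  mpath <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mpath)
}
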