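#' Build a per-position, per-base-pair-type score map from SHAP summaries
#'
#' For every guide position i, the `top_n` fingerprint features with the
#' largest mean-absolute SHAP importance at that position are selected
#' (ties broken by feature catalogue order). The raw score of base-pair
#' type RD at position i is the sum, over the selected features, of the
#' mean signed attribution among training samples carrying RD at position
#' i. Cells never observed in training contribute 0. The resulting
#' 20 x 16 map is uncalibrated; pass it to [calibrate_score_map()] before
#' scoring.
#'
#' @param summary A `shap_summary`.
#' @param top_n Features retained per position (default 24).
#' @return An object of class `score_map` with fields `raw` (20 x 16
#'   matrix, rows `p1..p20`, columns [bp_types()]), `top_n`, `selected`
#'   (20 x `top_n` matrix of selected feature names), and calibration
#'   constants `a`, `b` (`NA` until calibrated).
#' @export
build_score_map <- function(summary, top_n = 24) {
  stopifnot(inherits(summary, "shap_summary"))
  FF <- nrow(summary$importance)
  if (top_n > FF) {
    stop("top_n = ", top_n, " exceeds the ", FF, " available features",
         call. = FALSE)
  }
  raw <- matrix(0, 20, 16, dimnames = list(paste0("p", 1:20), bp_types()))
  selected <- matrix(NA_character_, 20, top_n)
  for (p in 1:20) {
    ord <- order(-summary$importance[, p], seq_len(FF))
    sel <- ord[seq_len(top_n)]
    selected[p, ] <- summary$feature_names[sel]
    vals <- summary$per_type_mean[p, , sel, drop = FALSE]
    vals[is.na(vals)] <- 0
    raw[p, ] <- apply(vals, 2, sum)
  }
  structure(list(raw = raw, top_n = top_n, selected = selected,
                 a = NA_real_, b = NA_real_),
            class = "score_map")
}

#' Construct a score map directly from a raw matrix
#'
#' Mostly useful for loading released/externally derived maps and for
#' constructing analytic test maps.
#'
#' @param raw 20 x 16 numeric matrix (positions x base-pair types).
#' @param a,b Optional affine calibration constants.
#' @param top_n Bookkeeping: number of features the map was built from.
#' @return A `score_map`.
#' @export
score_map <- function(raw, a = NA_real_, b = NA_real_, top_n = NA_integer_) {
  stopifnot(is.matrix(raw), nrow(raw) == 20, ncol(raw) == 16,
            all(is.finite(raw)))
  dimnames(raw) <- list(paste0("p", 1:20), bp_types())
  structure(list(raw = raw, top_n = top_n, selected = NULL, a = a, b = b),
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat("<score_map> 20 positions x 16 bp types; a=",
      format(x$a), " b=", format(x$b),
      if (is.na(x$a)) " (uncalibrated)", "\n", sep = "")
  invisible(x)
}

#' Calibrate a score map to the exact [0, 1] range
#'
#' The pair score is a sum of independent per-position table lookups, so
#' its extrema over all possible 20-position base-pair assignments are
#' exact: `S_min = sum_i min_RD S[i, RD]` and `S_max = sum_i max_RD
#' S[i, RD]`. The affine constants `a = 1 / (S_max - S_min)` and
#' `b = -S_min / (S_max - S_min)` then place every achievable score in
#' \[0, 1\], with both endpoints attained by the per-position
#' argmin/argmax assignments.
#'
#' @param map An uncalibrated (or previously calibrated) `score_map`.
#' @return The map with `a` and `b` set.
#' @export
calibrate_score_map <- function(map) {
  stopifnot(inherits(map, "score_map"))
  s_min <- sum(apply(map$raw, 1, min))
  s_max <- sum(apply(map$raw, 1, max))
  if (s_max <= s_min) {
    stop("degenerate score map: max and min achievable sums coincide",
         call. = FALSE)
  }
  map$a <- 1 / (s_max - s_min)
  map$b <- -s_min / (s_max - s_min)
  map
}

#' Score guide/off-target pairs with a calibrated score map
#'
#' The raw score of a pair is the sum over the 20 positions of the map
#' entry for the base-pair type formed at that position; the reported
#' score is the affine-calibrated `a * S + b`, guaranteed to lie in
#' \[0, 1\]. Higher scores mean the site is more likely to be cleaved.
#'
#' @param guide 20-mer guide.
#' @param targets One or more 20-mer protospacer-strand sequences in guide
#'   orientation.
#' @param map A calibrated `score_map`.
#' @return Numeric vector of scores, one per target.
#' @export
ot_score <- function(guide, targets, map) {
  stopifnot(inherits(map, "score_map"))
  if (is.na(map$a) || is.na(map$b)) {
    stop("score map is not calibrated; run calibrate_score_map() first",
         call. = FALSE)
  }
  guide <- normalize_seq(guide, 20, what = "guide")
  gcode <- base_codes(strsplit(guide, "", fixed = TRUE)[[1]])
  n <- length(targets)
  s <- numeric(n)
  tmat <- matrix(0L, n, 20)
  for (i in seq_len(n)) {
    t <- normalize_seq(targets[i], 20, what = "target")
    tmat[i, ] <- base_codes(strsplit(t, "", fixed = TRUE)[[1]])
  }
  for (p in 1:20) {
    s <- s + map$raw[p, bp_index_codes(gcode[p], tmat[, p])]
  }
  as.vector(map$a * s + map$b)
}

#' The 20 equal-width score bins
#'
#' Half-open intervals `[lo, hi)` of width 0.05 partitioning \[0, 1\]; the
#' final bin is closed so a score of exactly 1 falls in bin 20.
#'
#' @return Data frame with columns `bin_lo`, `bin_hi`.
#' @export
score_bins <- function() {
  # edges as exact divisions, not accumulated sums, so scores that are
  # double representations of bin boundaries bin correctly
  data.frame(bin_lo = (0:19) / 20, bin_hi = (1:20) / 20)
}

# bin index 1..20 for scores in [0, 1]
score_bin_index <- function(scores) {
  pmin(pmax(findInterval(scores, (0:20) / 20, rightmost.closed = TRUE),
            1L), 20L)
}

#' Estimate per-bin active-off-target probabilities from scored sites
#'
#' Bins scored candidate sites into the 20 score bins and estimates, per
#' bin, the probability that a site in that bin is an active (validated)
#' off-target: within each dataset the fraction of active sites per bin is
#' computed, and the table entry is the unweighted mean of those fractions
#' across datasets, skipping datasets with no sites in the bin. Bins empty
#' in every dataset get probability 0.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels 0/1 activity labels.
#' @param datasets Dataset identifier per site (single dataset if omitted).
#' @return An object of class `prob_table`: data frame with `bin_lo`,
#'   `bin_hi`, `p`.
#' @export
estimate_prob_table <- function(scores, labels, datasets = NULL) {
  if (length(scores) == 0) stop("no scored sites supplied", call. = FALSE)
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (is.null(datasets)) datasets <- rep("all", length(scores))
  bin <- score_bin_index(scores)
  per_ds <- matrix(NA_real_, nrow = length(unique(datasets)), ncol = 20)
  for (d in seq_along(unique(datasets))) {
    sel <- datasets == unique(datasets)[d]
    for (k in unique(bin[sel])) {
      per_ds[d, k] <- mean(labels[sel & bin == k])
    }
  }
  p <- apply(per_ds, 2, function(col) {
    if (all(is.na(col))) 0 else mean(col, na.rm = TRUE)
  })
  prob_table(p)
}

#' Construct a probability table from 20 bin probabilities
#'
#' @param p Numeric vector of 20 per-bin probabilities in \[0, 1\],
#'   ordered from bin \[0, 0.05) up to \[0.95, 1\].
#' @return A `prob_table`.
#' @export
prob_table <- function(p) {
  stopifnot(length(p) == 20, all(is.finite(p)), all(p >= 0), all(p <= 1))
  structure(cbind(score_bins(), data.frame(p = as.numeric(p))),
            class = c("prob_table", "data.frame"))
}

#' Genome-wide specificity of a guide
#'
#' Scores every candidate off-target site of the guide, counts candidates
#' per score bin (`N_k`), weights the counts by the per-bin probability of
#' being an active off-target (`P_k`), and aggregates
#' `P_off = sum_k N_k * P_k`. The specificity score is
#' `10 / (10 + P_off)`, a value in (0, 1\] (a soft variant of the MIT
#' aggregation rule): 1 means no expected active off-target anywhere, and
#' every additional candidate falling in a positive-probability bin
#' strictly lowers it. The intended on-target locus, when its coordinates
#' are supplied, is excluded from the candidate set before aggregation.
#'
#' @param guide 20-mer guide.
#' @param map Calibrated `score_map`.
#' @param prob A `prob_table`.
#' @param candidates Candidate site table from [find_candidates()];
#'   alternatively supply `genome` to search here.
#' @param genome Genome to search when `candidates` is missing.
#' @param max_mismatches,pam_pattern Passed to [find_candidates()].
#' @param on_target Optional `list(chrom =, start =, strand =)` (0-based
#'   protospacer start) naming the intended locus to exclude.
#' @return An object of class `spec_result`: list with `spec`, `p_off`,
#'   `bin_counts` (20 integers) and `sites` (the scored candidates).
#' @export
ot_spec <- function(guide, map, prob, candidates = NULL, genome = NULL,
                    max_mismatches = 6, pam_pattern = "NGG",
                    on_target = NULL) {
  stopifnot(inherits(map, "score_map"), inherits(prob, "prob_table"))
  if (is.null(candidates)) {
    if (is.null(genome)) {
      stop("supply either candidates or a genome to search", call. = FALSE)
    }
    candidates <- find_candidates(genome, guide, max_mismatches, pam_pattern)
  }
  if (!is.null(on_target) && nrow(candidates)) {
    drop <- candidates$chrom == on_target$chrom &
      candidates$start == on_target$start &
      candidates$strand == on_target$strand
    candidates <- candidates[!drop, , drop = FALSE]
  }
  bin_counts <- integer(20)
  if (nrow(candidates)) {
    candidates$score <- ot_score(guide, candidates$protospacer, map)
    tab <- table(factor(score_bin_index(candidates$score), levels = 1:20))
    bin_counts <- as.integer(tab)
  } else {
    candidates$score <- numeric(0)
  }
  p_off <- sum(bin_counts * prob$p)
  structure(list(spec = 10 / (10 + p_off), p_off = p_off,
                 bin_counts = bin_counts, sites = candidates),
            class = "spec_result")
}

#' @export
print.spec_result <- function(x, ...) {
  cat("<spec_result> spec=", format(x$spec, digits = 4),
      " p_off=", format(x$p_off, digits = 4),
      " sites=", sum(x$bin_counts), "\n", sep = "")
  invisible(x)
}

#' Single-nucleotide guide optimization
#'
#' Enumerates all 60 single-nucleotide substitutions of the 20-nt guide
#' (3 per position; mutation labels such as `"A11>C"` use 1-based guide
#' positions with position 1 PAM-distal). Each mutant is scored against
#' the intended (wild-type) target; mutants whose score falls below
#' `score_threshold` are discarded as likely to lose on-target cleavage.
#' For the surviving mutants the genome-wide candidate set is
#' re-evaluated and the specificity recomputed; candidates are returned
#' sorted by specificity (descending), ties by score (descending) then
#' mutation label. The wild-type guide's own score and specificity are
#' always reported for comparison.
#'
#' @param guide Wild-type 20-mer guide.
#' @param target Intended target protospacer (20-mer); defaults to the
#'   guide itself (perfect match).
#' @param map Calibrated `score_map`.
#' @param prob A `prob_table`.
#' @param genome Genome searched for each evaluated guide's candidates.
#' @param candidates Optional precomputed wild-type candidate table; when
#'   given together with `reuse_candidates = TRUE`, mutants are rescored
#'   over the same genomic site universe instead of re-searching (faster,
#'   but sites that only satisfy the mismatch ceiling for the mutant are
#'   missed).
#' @param score_threshold Minimum mutant-vs-target score (default 0.85; a
#'   floor of 0.8 is the lowest setting still expected to cleave reliably).
#' @param max_mismatches,pam_pattern,on_target Passed to [ot_spec()].
#' @param reuse_candidates Rescore the wild-type candidate universe for
#'   every mutant instead of re-searching the genome.
#' @return An object of class `opti_result`: list with `wt_score`,
#'   `wt_spec`, `threshold`, `status` (`"ok"` or `"no_candidates"`), and
#'   `candidates` (data frame `mutation`, `guide`, `score`, `spec`).
#' @export
optimize_guide <- function(guide, target = guide, map, prob,
                           genome = NULL, candidates = NULL,
                           score_threshold = 0.85, max_mismatches = 6,
                           pam_pattern = "NGG", on_target = NULL,
                           reuse_candidates = FALSE) {
  stopifnot(score_threshold > 0, score_threshold <= 1)
  guide <- normalize_seq(guide, 20, what = "guide")
  target <- normalize_seq(target, 20, what = "target")
  if (is.null(genome) && is.null(candidates)) {
    stop("supply a genome (or precomputed candidates with reuse_candidates)",
         call. = FALSE)
  }

  spec_of <- function(g) {
    if (reuse_candidates) {
      if (is.null(candidates)) {
        candidates <<- find_candidates(genome, guide, max_mismatches,
                                       pam_pattern)
      }
      ot_spec(g, map, prob, candidates = candidates, on_target = on_target)
    } else {
      ot_spec(g, map, prob, genome = genome,
              max_mismatches = max_mismatches, pam_pattern = pam_pattern,
              on_target = on_target)
    }
  }

  wt_score <- ot_score(guide, target, map)
  wt_spec <- spec_of(guide)$spec

  bases <- strsplit(guide, "", fixed = TRUE)[[1]]
  muts <- data.frame(mutation = character(), guide = character(),
                     score = numeric(), stringsAsFactors = FALSE)
  for (p in 1:20) {
    for (b in setdiff(DNA_BASES, bases[p])) {
      mg <- bases
      mg[p] <- b
      mg <- paste(mg, collapse = "")
      muts <- rbind(muts, data.frame(
        mutation = sprintf("%s%d>%s", bases[p], p, b), guide = mg,
        score = ot_score(mg, target, map), stringsAsFactors = FALSE))
    }
  }

  keep <- muts[muts$score >= score_threshold, , drop = FALSE]
  status <- "ok"
  if (nrow(keep) == 0) {
    warning("no mutated guide reaches the score threshold ",
            score_threshold, "; returning wild-type statistics only",
            call. = FALSE)
    status <- "no_candidates"
    keep$spec <- numeric(0)
  } else {
    keep$spec <- vapply(keep$guide, function(g) spec_of(g)$spec, numeric(1))
    keep <- keep[order(-keep$spec, -keep$score, keep$mutation), ,
                 drop = FALSE]
  }
  rownames(keep) <- NULL
  structure(list(wt_score = wt_score, wt_spec = wt_spec,
                 threshold = score_threshold, status = status,
                 candidates = keep[, c("mutation", "guide", "score", "spec")]),
            class = "opti_result")
}

#' @export
print.opti_result <- function(x, ...) {
  cat("<opti_result> wt score=", format(x$wt_score, digits = 4),
      " wt spec=", format(x$wt_spec, digits = 4), "; ",
      nrow(x$candidates), " mutants above threshold ", x$threshold, "\n",
      sep = "")
  if (nrow(x$candidates)) print(head(x$candidates, 5))
  invisible(x)
}

#' Read / write score maps
#'
#' The map is stored as a 20 x 16 TSV (rows `p1..p20`, columns the
#' base-pair types) plus a JSON sidecar `<path>.json` holding the
#' calibration constants and `top_n`.
#'
#' @param map A `score_map`.
#' @param path TSV path; the sidecar is written next to it.
#' @return `write_score_map`: `path` invisibly; `read_score_map`: a
#'   `score_map`.
#' @export
write_score_map <- function(map, path) {
  stopifnot(inherits(map, "score_map"))
  df <- data.frame(position = rownames(map$raw), map$raw,
                   check.names = FALSE)
  write_tsv_atomic(df, path)
  side <- list(a = map$a, b = map$b, top_n = map$top_n)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_score_map
#' @export
read_score_map <- function(path) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  raw <- as.matrix(df[, bp_types()])
  side_path <- paste0(path, ".json")
  a <- NA_real_; b <- NA_real_; top_n <- NA_integer_
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    json_num <- function(x) {
      if (is.null(x) || length(x) == 0 || is.na(x)) NA_real_ else as.numeric(x)
    }
    a <- json_num(side$a); b <- json_num(side$b)
    top_n <- as.integer(json_num(side$top_n))
  }
  score_map(raw, a = a, b = b, top_n = top_n)
}

#' Read / write probability tables
#'
#' TSV with columns `bin_lo`, `bin_hi`, `p`.
#'
#' @param prob A `prob_table`.
#' @param path TSV path.
#' @return `write_prob_table`: `path` invisibly; `read_prob_table`: a
#'   `prob_table`.
#' @export
write_prob_table <- function(prob, path) {
  stopifnot(inherits(prob, "prob_table"))
  write_tsv_atomic(as.data.frame(prob), path)
}

#' @rdname write_prob_table
#' @export
read_prob_table <- function(path) {
  df <- read.delim(path, comment.char = "#")
  stopifnot(all(c("bin_lo", "bin_hi", "p") %in% names(df)))
  prob_table(df$p)
}
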