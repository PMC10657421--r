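# Independent oracles and tiny fixtures used across the suite. Oracles are
# deliberately written in the most naive style possible (per-character
# loops, O(n^2) comparisons) so they share no code path with the package.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_pair <- function(n_mismatch = NULL) {
  g <- random_seq(20)
  t <- strsplit(g, "")[[1]]
  m <- if (is.null(n_mismatch)) sample(0:6, 1) else n_mismatch
  if (m > 0) {
    for (p in sample(20, m)) t[p] <- sample(setdiff(c("A","C","G","T"), t[p]), 1)
  }
  list(guide = g, target = paste(t, collapse = ""))
}

# character-by-character genome scan, both strands, no vectorization
naive_site_scan <- function(genome, guide, max_mm, pam = "NGG") {
  rc1 <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  gch <- strsplit(guide, "")[[1]]
  pch <- strsplit(pam, "")[[1]]
  rows <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    L <- nchar(s)
    for (strand in c("+", "-")) {
      str <- if (strand == "+") s else rc1(s)
      if (L < 23) next
      for (p in 1:(L - 22)) {
        win <- strsplit(substr(str, p, p + 22), "")[[1]]
        if (any(!win %in% c("A", "C", "G", "T"))) next
        pam_ok <- TRUE
        for (j in 1:3) {
          if (pch[j] != "N" && win[20 + j] != pch[j]) pam_ok <- FALSE
        }
        if (!pam_ok) next
        mm <- sum(win[1:20] != gch)
        if (mm > max_mm) next
        start0 <- if (strand == "+") p - 1 else L - p - 19
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, start = start0, strand = strand,
          protospacer = paste(win[1:20], collapse = ""),
          pam = paste(win[21:23], collapse = ""), mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame(chrom = character(), start = integer(),
                                       strand = character()))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# exhaustive pairwise-comparison ROC-AUC
pairwise_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# hand-stepped precision-recall area over unique thresholds
stepwise_pr_auc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  prev_recall <- 0
  area <- 0
  for (th in ths) {
    sel <- scores >= th
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / n1
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

# sum-then-affine score oracle: per-position lookups done one at a time
score_pair_oracle <- function(guide, target, map) {
  g <- strsplit(guide, "")[[1]]
  t <- strsplit(target, "")[[1]]
  s <- 0
  for (i in 1:20) {
    s <- s + map$raw[paste0("p", i), paste0("r", g[i], "_d", t[i])]
  }
  map$a * s + map$b
}

# small calibrated analytic score map: raw entries depend on position and
# match status only, so expected scores are easy to reason about
toy_score_map <- function() {
  raw <- matrix(0, 20, 16)
  types <- guidefp::bp_types()
  is_match <- types %in% c("rA_dA", "rC_dC", "rG_dG", "rT_dT")
  for (p in 1:20) raw[p, ] <- ifelse(is_match, 0.05 * p, -0.02 * p)
  guidefp::calibrate_score_map(guidefp::score_map(raw))
}

tiny_labeled_dataset <- function(n_guides = 6, per_guide = 40, seed = 42) {
  simulate_offtarget_dataset(n_guides = n_guides,
                             candidates_per_guide = per_guide,
                             prevalence = 0.15, seed = seed)
}
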