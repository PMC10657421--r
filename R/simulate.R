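#' Simulate an engineered per-base-pair-type feature table
#'
#' Generates a deterministic (per seed) stand-in for a feature table
#' derived from molecular-dynamics measurements of short RNA-DNA hybrids:
#' 193 features with the canonical category composition (1 hydrogen-bond,
#' 42 binding-energy, 114 atom-position, 36 base-pair/step geometry
#' descriptors). For every feature the four Watson-Crick match types are
#' systematically offset from the twelve mismatch types, so fingerprints
#' built from the table carry a learnable match/mismatch signal; each
#' feature is then min-max rescaled to span exactly \[-1, 1\] across the
#' 16 types, which also guarantees the variance floor.
#'
#' @param seed Integer seed; same seed, same table.
#' @return A validated `feature_table` with 193 features.
#' @examples
#' tab <- simulate_feature_table(seed = 1)
#' table(tab$features$category)
#' @export
simulate_feature_table <- function(seed) {
  features <- canonical_feature_descriptors()
  FF <- nrow(features)
  match_type <- rep(bp_types() %in% paste0("r", DNA_BASES, "_d", DNA_BASES),
                    times = 1)
  vals <- with_seed(seed, "simulate_feature_table", {
    v <- matrix(0, 16, FF)
    direction <- sample(c(-1, 1), FF, replace = TRUE)
    for (j in seq_len(FF)) {
      mu <- ifelse(match_type, 0.5 * direction[j], -0.35 * direction[j])
      v[, j] <- mu + runif(16, -0.4, 0.4)
    }
    v
  })
  # exact [-1, 1] span per feature
  for (j in seq_len(FF)) {
    lo <- min(vals[, j]); hi <- max(vals[, j])
    vals[, j] <- 2 * (vals[, j] - lo) / (hi - lo) - 1
  }
  feature_table(features, vals)
}

# the canonical 193-descriptor catalogue: 1 + 42 + 114 + 36
canonical_feature_descriptors <- function() {
  atoms <- c("P", "C5'", "C3'", "O5'", "C1'", "N9", "N1")

  hb <- data.frame(name = "hbond_bp5", category = "hydrogen_bond",
                   is_angle_derived = FALSE, stringsAsFactors = FALSE)

  energy_terms <- c("E_vdw", "E_ele", "E_gb", "E_surf", "dG_gas", "dG_solv",
                    "dG_total", paste0("dG_decomp_", sprintf("%02d", 1:35)))
  en <- data.frame(name = energy_terms, category = "binding_energy",
                   is_angle_derived = FALSE, stringsAsFactors = FALSE)

  # atom position: 88 interatomic distances + 13 angles as sin/cos pairs
  cross <- expand.grid(a = atoms, b = atoms, stringsAsFactors = FALSE)
  dist_names <- c(
    paste0("resA@", cross$a, " resB@", cross$b),                    # 49
    apply(utils::combn(atoms, 2), 2,
          function(p) paste0("resB@", p[1], " resB@", p[2])),        # 21
    apply(utils::combn(atoms, 2), 2,
          function(p) paste0("resA@", p[1], " resA@", p[2]))[1:18]   # 18
  )
  ang_triples <- utils::combn(atoms, 3)[, 1:13]
  ang_names <- apply(ang_triples, 2,
                     function(t) paste0("ang:resB@", t[1], " resB@", t[2],
                                        " resB@", t[3]))
  ap <- rbind(
    data.frame(name = dist_names, category = "atom_position",
               is_angle_derived = FALSE, stringsAsFactors = FALSE),
    data.frame(name = as.vector(rbind(paste0(ang_names, "_sin"),
                                      paste0(ang_names, "_cos"))),
               category = "atom_position", is_angle_derived = TRUE,
               stringsAsFactors = FALSE)
  )

  # geometry: 9 translational params (mean, sd) + 9 angular params (sin, cos)
  trans <- c("shear", "stretch", "stagger", "shift", "slide", "rise",
             "x_disp", "y_disp", "h_rise")
  angular <- c("buckle", "propeller", "opening", "tilt", "roll", "twist",
               "h_twist", "inclination", "tip")
  geo <- rbind(
    data.frame(name = as.vector(rbind(paste0(trans, "_mean"),
                                      paste0(trans, "_sd"))),
               category = "geometry", is_angle_derived = FALSE,
               stringsAsFactors = FALSE),
    data.frame(name = as.vector(rbind(paste0(angular, "_sin"),
                                      paste0(angular, "_cos"))),
               category = "geometry", is_angle_derived = TRUE,
               stringsAsFactors = FALSE)
  )

  out <- rbind(hb, en, ap, geo)
  rownames(out) <- NULL
  out
}

#' Simulate raw per-context interaction measurements
#'
#' Generates a small `raw_context_table` over all 256 3-bp hybrid
#' contexts, for exercising and demonstrating [engineer_features()]:
#' per-base-pair-type latent means plus flank-context noise, in raw units
#' (counts, kcal/mol, Angstroms, degrees). Includes angle-valued features
#' so the sin/cos expansion is covered.
#'
#' @param seed Integer seed.
#' @param context_sd Standard deviation of the flank-context noise around
#'   each type's latent mean, in each feature's raw units.
#' @return A `raw_context_table` with 256 contexts and 12 raw features
#'   (3 of them angles).
#' @export
simulate_raw_contexts <- function(seed, context_sd = 0.15) {
  contexts <- expand.grid(down = DNA_BASES, central_dna = DNA_BASES,
                          central_rna = DNA_BASES, up = DNA_BASES,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  contexts <- contexts[, c("up", "central_rna", "central_dna", "down")]
  features <- data.frame(
    name = c("hbond_bp5", "E_vdw", "E_ele", "E_surf", "dG_total",
             "resA@N1 resB@N1", "resB@P resB@C5'", "rise_mean", "slide_mean",
             "ang:resB@C1' resB@O5' resB@C3'", "twist", "roll"),
    category = c("hydrogen_bond", rep("binding_energy", 4),
                 rep("atom_position", 2), rep("geometry", 2),
                 "atom_position", "geometry", "geometry"),
    is_angle = c(rep(FALSE, 9), TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  scale_of <- c(2, 30, 40, 8, 25, 4, 3, 1.5, 1.2, 40, 15, 10)
  center_of <- c(2.5, -45, -60, -12, -35, 9, 6, 3.3, -1.8, 110, 32, 4)

  type_of <- bp_index_codes(base_codes(contexts$central_rna),
                            base_codes(contexts$central_dna))
  vals <- with_seed(seed, "simulate_raw_contexts", {
    v <- matrix(0, nrow(contexts), nrow(features))
    for (j in seq_len(nrow(features))) {
      type_mean <- center_of[j] + scale_of[j] * runif(16, -0.5, 0.5)
      v[, j] <- type_mean[type_of] +
        rnorm(nrow(contexts), sd = context_sd * scale_of[j])
    }
    v
  })
  colnames(vals) <- features$name
  raw_context_table(contexts, features, vals)
}

#' Simulate a genome, optionally with planted protospacer sites
#'
#' Bases are drawn i.i.d. at the requested GC fraction. Sites can be
#' planted on either strand: for a `+` site the protospacer occupies
#' forward positions `pos..pos+19` with the PAM immediately 3'; for a `-`
#' site the reverse complement is written so that a guide-orientation scan
#' of the minus strand recovers the protospacer with its PAM.
#'
#' @param length Sequence length in bp (> 23).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param plant Optional data frame with columns `pos` (1-based forward
#'   start of the 20-nt protospacer slice), `strand` (`+`/`-`),
#'   `protospacer` (20-mer in guide orientation) and `pam` (3-mer). Minus
#'   strand sites need `pos >= 4`; plus strand sites need
#'   `pos + 22 <= length`.
#' @param name Sequence name in the returned genome.
#' @return Named character vector of length 1 (see [read_genome()] for
#'   the representation).
#' @export
simulate_genome <- function(length, gc = 0.41, seed = 1, plant = NULL,
                            name = "chr1") {
  stopifnot(length > 23, gc > 0, gc < 1)
  seq <- with_seed(seed, "simulate_genome", {
    paste(sample(DNA_BASES, length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
  if (!is.null(plant)) {
    for (i in seq_len(nrow(plant))) {
      proto <- normalize_seq(plant$protospacer[i], 20, what = "protospacer")
      pam <- normalize_seq(plant$pam[i], 3, what = "pam")
      pos <- plant$pos[i]
      if (plant$strand[i] == "+") {
        if (pos < 1 || pos + 22 > length) {
          stop("planted + site at pos ", pos, " falls outside the genome",
               call. = FALSE)
        }
        substr(seq, pos, pos + 19) <- proto
        substr(seq, pos + 20, pos + 22) <- pam
      } else {
        if (pos < 4 || pos + 19 > length) {
          stop("planted - site at pos ", pos, " falls outside the genome",
               call. = FALSE)
        }
        substr(seq, pos, pos + 19) <- revcomp(proto)
        substr(seq, pos - 3, pos - 1) <- revcomp(pam)
      }
    }
  }
  setNames(seq, name)
}

#' Simulate an imbalanced labeled off-target dataset
#'
#' Emulates the structure of genome-wide off-target benchmark data: for
#' each guide a large candidate set is enumerated of which only a small
#' fraction is experimentally active. Candidates carry 0-6 mismatches at
#' random positions; the latent activity of a candidate follows a logistic
#' model `plogis(intercept - sum(weight[pos]) + noise)` over its mismatch
#' positions, with position weights increasing toward the PAM-proximal end
#' (mismatches near the PAM are most disruptive, the seed-region effect).
#' The intercept is tuned automatically so the realized mean activity
#' probability matches `prevalence`; labels are then Bernoulli draws.
#' Ground-truth parameters are attached as attributes for recovery tests.
#'
#' @param n_guides Number of distinct guides.
#' @param candidates_per_guide Candidate sites per guide.
#' @param prevalence Target active fraction in (0, 1).
#' @param position_weights 20 non-negative mismatch penalties (logit units
#'   per mismatch), PAM-distal first; the default ramps linearly threefold
#'   from 0.8 to 2.4, so a single PAM-proximal mismatch is strongly
#'   disruptive while PAM-distal mismatches are well tolerated.
#' @param noise_sd Standard deviation of the latent logit noise.
#' @param mismatch_probs Probabilities for mismatch counts 0..6.
#' @param seed Integer seed.
#' @return Data frame with columns `guide`, `target`, `pam`, `label`,
#'   `group`, `dataset_name`, `mismatches`; attributes `position_weights`,
#'   `intercept`, `noise_sd`, `latent_p`.
#' @examples
#' d <- simulate_offtarget_dataset(n_guides = 4, candidates_per_guide = 50,
#'                                 prevalence = 0.1, seed = 1)
#' mean(d$label)
#' @export
simulate_offtarget_dataset <- function(n_guides = 20,
                                       candidates_per_guide = 250,
                                       prevalence = 0.05,
                                       position_weights =
                                         seq(0.8, 2.4, length.out = 20),
                                       noise_sd = 0.5,
                                       mismatch_probs =
                                         c(0.02, 0.05, 0.09, 0.14,
                                           0.20, 0.25, 0.25),
                                       seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1,
            length(position_weights) == 20, all(position_weights >= 0),
            length(mismatch_probs) == 7)
  with_seed(seed, "simulate_offtarget_dataset", {
    n <- n_guides * candidates_per_guide
    guides <- vapply(seq_len(n_guides), function(i) {
      paste(sample(DNA_BASES, 20, replace = TRUE), collapse = "")
    }, character(1))
    guide <- rep(guides, each = candidates_per_guide)
    mm <- sample(0:6, n, replace = TRUE, prob = mismatch_probs)
    target <- character(n)
    load <- numeric(n)
    for (i in seq_len(n)) {
      bases <- strsplit(guide[i], "", fixed = TRUE)[[1]]
      if (mm[i] > 0) {
        pos <- sample.int(20, mm[i])
        for (p in pos) bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1)
        load[i] <- sum(position_weights[pos])
      }
      target[i] <- paste(bases, collapse = "")
    }
    noise <- rnorm(n, sd = noise_sd)
    lat <- function(intercept) plogis(intercept - load + noise)
    f <- function(intercept) mean(lat(intercept)) - prevalence
    sol <- tryCatch(uniroot(f, c(-30, 30))$root, error = function(e) {
      warning("target prevalence ", prevalence,
              " unattainable; using closest achievable", call. = FALSE)
      if (f(-30) > 0) -30 else 30
    })
    p <- lat(sol)
    label <- rbinom(n, 1, p)
    out <- data.frame(guide = guide, target = target,
                      pam = paste0(sample(DNA_BASES, n, replace = TRUE),
                                   "GG"),
                      label = label, group = guide,
                      dataset_name = "synthetic", mismatches = mm,
                      stringsAsFactors = FALSE)
    attr(out, "position_weights") <- position_weights
    attr(out, "intercept") <- sol
    attr(out, "noise_sd") <- noise_sd
    attr(out, "latent_p") <- p
    out
  })
}

#' Simulate a per-bin active-off-target probability table
#'
#' Generates a monotone non-decreasing probability curve over the 20 score
#' bins with the shape observed for calibrated off-target scores: bins
#' below 0.5 are essentially never active (p < 0.01) and bins above 0.8
#' are almost always active (p > 0.9), with a smooth logistic transition
#' between. Seeded jitter varies the transition without violating those
#' constraints.
#'
#' @param seed Integer seed.
#' @return A `prob_table`.
#' @export
simulate_prob_table <- function(seed = 1) {
  bins <- score_bins()
  mid <- (bins$bin_lo + bins$bin_hi) / 2
  p <- with_seed(seed, "simulate_prob_table", {
    x <- (mid - 0.65) / 0.03 + rnorm(20, sd = 0.25)
    cummax(plogis(x))
  })
  prob_table(p)
}
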