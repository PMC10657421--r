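test_that("top-N selection matches an independent sort-and-slice oracle", {
  d <- tiny_labeled_dataset(n_guides = 8, per_guide = 40, seed = 6)
  plan <- split_dataset(d, "lgo", k = 3, seed = 6)
  ens <- train_ensemble(d, plan, encoder = "onehot", nrounds = 20, seed = 6)
  sm <- shap_summary(ens, d)
  top_n <- 5
  map <- build_score_map(sm, top_n = top_n)
  expect_equal(dim(map$raw), c(20, 16))  # 320 cells
  for (p in c(1, 12, 20)) {
    imp <- sm$importance[, p]
    # oracle: stable sort by decreasing importance, catalogue order ties
    want <- sm$feature_names[sort.list(-imp, method = "radix")][1:top_n]
    expect_setequal(map$selected[p, ], want)
  }
  expect_error(build_score_map(sm, top_n = 17), "exceeds")
})

test_that("map cells sum the selected per-type mean attributions", {
  d <- tiny_labeled_dataset(n_guides = 8, per_guide = 40, seed = 7)
  plan <- split_dataset(d, "lgo", k = 3, seed = 7)
  ens <- train_ensemble(d, plan, encoder = "onehot", nrounds = 15, seed = 7)
  sm <- shap_summary(ens, d)
  map <- build_score_map(sm, top_n = 4)
  p <- 10
  sel <- match(map$selected[p, ], sm$feature_names)
  for (t in c(1, 6, 16)) {
    vals <- sm$per_type_mean[p, t, sel]
    vals[is.na(vals)] <- 0
    expect_equal(unname(map$raw[p, t]), sum(vals))
  }
})

test_that("calibration attains exactly 0 and 1 at argmin/argmax assignments", {
  set.seed(19)
  raw <- matrix(rnorm(320, sd = 0.3), 20, 16)
  map <- calibrate_score_map(score_map(raw))
  types <- bp_types()
  # guide fixed to all A so the target base picks any of 4 types per position
  sub <- map$raw[, paste0("rA_d", c("A", "C", "G", "T"))]
  best <- paste(c("A", "C", "G", "T")[apply(sub, 1, which.max)], collapse = "")
  worst <- paste(c("A", "C", "G", "T")[apply(sub, 1, which.min)], collapse = "")
  guide <- paste(rep("A", 20), collapse = "")
  # restricted argmax/argmin: scores inside [0,1] but not necessarily 0/1;
  # exact endpoints need the unrestricted per-position extrema
  s_min <- sum(apply(map$raw, 1, min))
  s_max <- sum(apply(map$raw, 1, max))
  expect_equal(map$a * s_max + map$b, 1)
  expect_equal(map$a * s_min + map$b, 0)
  expect_gte(ot_score(guide, worst, map), 0)
  expect_lte(ot_score(guide, best, map), 1)
  flat <- score_map(matrix(1, 20, 16))
  expect_error(calibrate_score_map(flat), "degenerate")
})

test_that("scores equal the sum-then-affine oracle on random pairs", {
  map <- toy_score_map()
  set.seed(27)
  for (rep in 1:100) {
    p <- random_pair()
    expect_equal(ot_score(p$guide, p$target, map),
                 unname(score_pair_oracle(p$guide, p$target, map)))
  }
})

test_that("random pairs always score within [0, 1]", {
  set.seed(41)
  raw <- matrix(rnorm(320), 20, 16)
  map <- calibrate_score_map(score_map(raw))
  pairs <- replicate(500, random_pair(sample(0:20, 1)), simplify = FALSE)
  scores <- vapply(pairs, function(p) ot_score(p$guide, p$target, map),
                   numeric(1))
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("a constant map with a=1, b=0.5 scores every pair 0.5", {
  map <- score_map(matrix(0, 20, 16), a = 1, b = 0.5)
  set.seed(5)
  for (rep in 1:5) {
    p <- random_pair()
    expect_equal(ot_score(p$guide, p$target, map), 0.5)
  }
  uncal <- score_map(matrix(0, 20, 16))
  expect_error(ot_score("GAGTCCGAGCAGAAGAAGAA", "GAGTCCGAGCAGAAGAAGAA", uncal),
               "not calibrated")
})

test_that("probability-table estimation matches a hand-counting oracle", {
  scores <- c(0.02, 0.03, 0.52, 0.53, 0.54, 0.55, 0.91, 0.92, 0.93, 0.99,
              0.12, 0.13, 0.56, 0.57, 0.58, 0.59, 0.94, 0.95, 0.96, 1.00)
  labels <- c(0, 0, 0, 1, 0, 0, 1, 1, 1, 1,
              0, 0, 1, 1, 0, 1, 1, 1, 0, 1)
  datasets <- rep(c("d1", "d2"), each = 10)
  pt <- estimate_prob_table(scores, labels, datasets)
  # bin 11 = [0.50, 0.55): d1 has 0.53->1,0.52->0,0.54->0 => 1/3; d2 empty
  expect_equal(pt$p[11], 1 / 3)
  # bin 12 = [0.55, 0.60): d1 {0.55->0} = 0; d2 {0.56,0.57,0.58,0.59} = 3/4
  expect_equal(pt$p[12], mean(c(0, 3 / 4)))
  # bin 19 = [0.90, 0.95): d1 {0.91,0.92,0.93}=1; d2 {0.94}=1
  expect_equal(pt$p[19], 1)
  # final closed bin holds score 1.00: d1 {0.99->1}; d2 {0.95->1, 0.96->0, 1.00->1}
  expect_equal(pt$p[20], mean(c(1, 2 / 3)))
  # bins empty in every dataset default to 0
  expect_equal(pt$p[5], 0)
  # one dataset, one bin all-active
  expect_equal(estimate_prob_table(c(0.81, 0.82), c(1, 1))$p[17], 1)
  expect_error(estimate_prob_table(numeric(0), numeric(0)), "no scored")
})

test_that("specificity follows the aggregation rule analytically", {
  map <- toy_score_map()
  prob <- prob_table(rep(0.25, 20))
  # zero candidates: P_off = 0, spec = 1
  empty <- find_candidates(simulate_genome(100, seed = 1),
                           "GAGTCCGAGCAGAAGAAGAA", max_mismatches = 0)
  res0 <- ot_spec("GAGTCCGAGCAGAAGAAGAA", map, prob, candidates = empty)
  expect_equal(res0$spec, 1)
  expect_equal(res0$p_off, 0)
  # 40 sites, every bin probability 0.25: P_off = 10, spec = 0.5
  g <- "GAGTCCGAGCAGAAGAAGAA"
  cand <- data.frame(chrom = "chr1", start = seq(0, 39 * 30, by = 30),
                     end = seq(0, 39 * 30, by = 30) + 20, strand = "+",
                     protospacer = rep(g, 40), pam = "AGG",
                     mismatches = 0, mismatch_positions = "",
                     stringsAsFactors = FALSE)
  res40 <- ot_spec(g, map, prob, candidates = cand)
  expect_equal(res40$p_off, 10)
  expect_equal(res40$spec, 0.5)
  expect_equal(sum(res40$bin_counts), 40)
})

test_that("appending a positively weighted site strictly decreases spec", {
  map <- toy_score_map()
  prob <- simulate_prob_table(seed = 2)
  g <- "GAGTCCGAGCAGAAGAAGAA"
  cand <- data.frame(chrom = "chr1", start = 100, end = 120, strand = "+",
                     protospacer = g, pam = "AGG", mismatches = 0,
                     mismatch_positions = "", stringsAsFactors = FALSE)
  specs <- numeric(5)
  for (n in 1:5) {
    cc <- cand[rep(1, n), ]
    cc$start <- cand$start + (seq_len(n) - 1) * 50
    specs[n] <- ot_spec(g, map, prob, candidates = cc)$spec
  }
  # a perfect-match site scores high, landing in a positive-probability bin
  expect_true(all(diff(specs) < 0))
  expect_true(all(specs > 0 & specs <= 1))
})

test_that("the on-target locus is excluded by coordinates", {
  map <- toy_score_map()
  prob <- prob_table(rep(1, 20))
  g <- "GAGTCCGAGCAGAAGAAGAA"
  genome <- simulate_genome(5000, seed = 23,
                            plant = data.frame(pos = c(1001, 3001),
                                               strand = c("+", "-"),
                                               protospacer = g,
                                               pam = c("AGG", "TGG")))
  with_on <- ot_spec(g, map, prob, genome = genome)
  without <- ot_spec(g, map, prob, genome = genome,
                     on_target = list(chrom = "chr1", start = 1000,
                                      strand = "+"))
  expect_equal(sum(with_on$bin_counts) - sum(without$bin_counts), 1)
  expect_gt(without$spec, with_on$spec)
})

test_that("guide optimization enumerates 60 mutants and ranks by spec", {
  map <- toy_score_map()
  prob <- simulate_prob_table(seed = 3)
  g <- "GAGTCCGAGCAGAAGAAGAA"
  genome <- simulate_genome(4000, seed = 29,
                            plant = data.frame(pos = 2001, strand = "+",
                                               protospacer = g, pam = "AGG"))
  res <- optimize_guide(g, g, map, prob, genome = genome,
                        score_threshold = 0.05)
  expect_equal(nrow(res$candidates), 60)
  expect_false(g %in% res$candidates$guide)
  expect_true(all(res$candidates$score >= 0.05))
  # labels are wild-type base + 1-based position + replacement
  expect_true(all(grepl("^[ACGT][0-9]+>[ACGT]$", res$candidates$mutation)))
  expect_equal(sum(grepl("^G1>", res$candidates$mutation)), 3)
  # independent sort oracle over (spec desc, score desc, label asc)
  o <- order(-res$candidates$spec, -res$candidates$score,
             res$candidates$mutation)
  expect_equal(o, seq_len(60))

  strict <- suppressWarnings(
    optimize_guide(g, g, map, prob, genome = genome, score_threshold = 1))
  expect_equal(nrow(strict$candidates), 0)
  expect_equal(strict$status, "no_candidates")
  expect_false(is.na(strict$wt_score))
})

test_that("score maps and probability tables round-trip with calibration", {
  d <- tiny_labeled_dataset(n_guides = 6, per_guide = 30, seed = 9)
  plan <- split_dataset(d, "lgo", k = 3, seed = 9)
  ens <- train_ensemble(d, plan, encoder = "onehot", nrounds = 10, seed = 9)
  map <- calibrate_score_map(build_score_map(shap_summary(ens, d), 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_map(map, path)
  back <- read_score_map(path)
  expect_equal(unname(back$raw), unname(map$raw), tolerance = 1e-12)
  expect_equal(back$a, map$a, tolerance = 1e-12)
  expect_equal(back$b, map$b, tolerance = 1e-12)
  expect_equal(back$top_n, map$top_n)

  prob <- simulate_prob_table(seed = 4)
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_prob_table(prob, ppath)
  expect_equal(read_prob_table(ppath)$p, prob$p, tolerance = 1e-12)
})
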