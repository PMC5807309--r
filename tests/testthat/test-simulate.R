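# Simulator: exact pattern distributions, seeded sampling, the two noise
# mechanisms, bootstrap, and recovery scoring.

test_that("without modification or noise all mass is on the complete read", {
  cands <- toy_candidates(2)
  truth <- ground_truth(cands, c(0.5, 0.5), eta = 0, gamma = 0, mode = "truncation")
  d <- pattern_distribution(truth)
  expect_equal(d$prob[d$stop == 41], 1)
  expect_equal(sum(d$prob), 1, tolerance = 1e-14)
})

test_that("a mixture distribution is the abundance-weighted mean of its columns", {
  cands <- toy_candidates(2)
  t1 <- ground_truth(cands, c(1, 0), eta = 0.2, gamma = 0.02, mode = "truncation")
  t2 <- ground_truth(cands, c(0, 1), eta = 0.2, gamma = 0.02, mode = "truncation")
  mix <- ground_truth(cands, c(0.5, 0.5), eta = 0.2, gamma = 0.02, mode = "truncation")
  expect_equal(
    pattern_distribution(mix)$prob,
    0.5 * pattern_distribution(t1)$prob + 0.5 * pattern_distribution(t2)$prob,
    tolerance = 1e-14
  )
})

test_that("the single open-chain structure gives the sequential stop distribution", {
  L <- 8
  eta <- 0.17
  open_chain <- candidate_set(list(rna_structure(strrep(".", L), strrep("A", L))))
  truth <- ground_truth(open_chain, 1, eta = eta, gamma = 0, mode = "truncation")
  d <- pattern_distribution(truth)
  # geometric-like: stop at p after reading through p-1 unmodified sites
  expect_equal(d$prob[seq_len(L)], (1 - eta)^(seq_len(L) - 1) * eta, tolerance = 1e-14)
  expect_equal(d$prob[L + 1], (1 - eta)^L, tolerance = 1e-14)
})

test_that("multinomial draws are seeded, reproducible and consistent with the distribution", {
  cands <- toy_candidates(2)
  truth <- ground_truth(cands, c(0.6, 0.4), eta = 0.2, gamma = 0.01, mode = "truncation")
  d <- pattern_distribution(truth)
  pc1 <- draw_reads(d, 1e5, seed = 99)
  pc2 <- draw_reads(d, 1e5, seed = 99)
  expect_identical(as.data.frame(pc1), as.data.frame(pc2))
  expect_equal(total_reads(pc1), 1e5)
  pc3 <- draw_reads(d, 1, seed = 1)
  expect_equal(nrow(pc3), 1)
  # chi-square goodness of fit against the generating distribution
  obs <- numeric(nrow(d))
  obs[match(pc1$stop, d$stop)] <- pc1$count
  keep <- d$prob > 1e-6
  chisq <- suppressWarnings(
    stats::chisq.test(obs[keep], p = d$prob[keep] / sum(d$prob[keep]))
  )
  expect_gt(chisq$p.value, 1e-4)
})

test_that("per-read Bernoulli sampling matches the enumerated mutation distribution", {
  seqs <- substr(toy_sequence(), 1, 10)
  a <- rna_structure("((....))..", seqs, id = "a")
  b <- rna_structure("..((....))", seqs, id = "b")
  truth <- ground_truth(
    candidate_set(list(a, b)), c(0.6, 0.4),
    eta = 0.25, gamma = 0.01, mode = "mutation"
  )
  d <- pattern_distribution(truth)
  pc <- draw_reads_bernoulli(truth, 5e4, seed = 17)
  keys_d <- vapply(d$sites, paste, character(1), collapse = ",")
  keys_o <- vapply(pc$sites, paste, character(1), collapse = ",")
  obs <- numeric(length(keys_d))
  obs[match(keys_o, keys_d)] <- pc$count
  keep <- d$prob > 1e-5
  chisq <- suppressWarnings(stats::chisq.test(
    c(obs[keep], sum(obs[!keep])),
    p = c(d$prob[keep], 1 - sum(d$prob[keep]))
  ))
  expect_gt(chisq$p.value, 1e-4)
})

test_that("count noise is relative, floored at zero, and seeded", {
  pc <- bin_truncation(c(rep(1, 100), rep(3, 5), rep(4, 1000)), L = 3)
  expect_identical(add_count_noise(pc, 0), pc)
  noisy <- add_count_noise(pc, sigma = 2, seed = 42)
  expect_true(all(noisy$count >= 0))
  expect_identical(noisy$count, add_count_noise(pc, 2, seed = 42)$count)
  # large relative noise changes the big count with overwhelming probability
  expect_false(identical(noisy$count, pc$count))
})

test_that("heavier count noise degrades recovery on average", {
  cands <- toy_candidates(2)
  truth <- ground_truth(cands, c(0.6, 0.4), eta = 0.2, gamma = 0.01, mode = "truncation")
  d <- pattern_distribution(truth)
  err_at <- function(sigma) {
    errs <- vapply(1:6, function(k) {
      pc <- add_count_noise(draw_reads(d, 2e4, seed = 100 + k), sigma, seed = 200 + k)
      X <- build_design_truncation(cands, 0.2, 0.01)
      fit <- fit_abundances(X, pc, candidates = cands)
      score_recovery(fit, truth)$mean_abs_error
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(0), err_at(2))
})

test_that("decoys take an equal share of the stated ensemble fraction", {
  cands <- toy_candidates(2)
  truth <- ground_truth(cands, c(0.6, 0.4), eta = 0.2, mode = "truncation")
  decoys <- random_structures(toy_sequence(), 10, seed = 55)
  out <- add_decoys(truth, decoys, fraction = 0.1)
  expect_equal(sum(out$abundances), 1, tolerance = 1e-12)
  expect_equal(out$abundances[1:2], c(0.54, 0.36))
  expect_equal(out$abundances[3:12], rep(0.01, 10))
  expect_equal(length(out$decoy_ids), 10)
  expect_identical(add_decoys(truth, decoys, fraction = 0), truth)
})

test_that("bootstrap replicates resample at the observed depth", {
  pc <- bin_truncation(c(rep(1, 30), rep(4, 70)), L = 3)
  reps <- bootstrap_counts(pc, 5, seed = 8)
  expect_length(reps, 5)
  for (r in reps) expect_equal(total_reads(r), 100)
  expect_identical(
    lapply(bootstrap_counts(pc, 5, seed = 8), as.data.frame),
    lapply(reps, as.data.frame)
  )
  # a degenerate single-pattern dataset resamples to itself
  one <- bin_truncation(rep(2, 50), L = 3)
  expect_identical(as.data.frame(bootstrap_counts(one, 3, seed = 1)[[1]]), as.data.frame(one))
})

test_that("bootstrap abundance spread shrinks with sequencing depth", {
  cands <- toy_candidates(2)
  truth <- ground_truth(cands, c(0.6, 0.4), eta = 0.2, mode = "truncation")
  d <- pattern_distribution(truth)
  X <- build_design_truncation(cands, 0.2, 0)
  spread <- function(n, seed) {
    pc <- draw_reads(d, n, seed = seed)
    est <- vapply(bootstrap_counts(pc, 12, seed = seed + 1), function(b) {
      fit_abundances(X, b, candidates = cands)$abundances$rho_norm[1]
    }, numeric(1))
    stats::sd(est)
  }
  expect_lt(spread(1e5, 71), spread(1e3, 72))
})

test_that("recovery scoring matches structures by informative-site states", {
  cands <- toy_candidates(2)
  truth <- ground_truth(cands, c(0.7, 0.3), eta = 0.2, mode = "truncation")
  X <- build_design_truncation(cands, eta = 0.2, gamma = 0)
  perfect <- fit_abundances(X, y = as.numeric(X$values %*% c(0.7, 0.3)), candidates = cands)
  sc <- score_recovery(perfect, truth)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
  expect_lt(sc$l1_error, 1e-6)

  # empty selection: recall 0
  none <- perfect
  none$abundances$selected <- FALSE
  expect_equal(score_recovery(none, truth)$recall, 0)

  # decoy-only candidates: precision 0
  decoys <- candidate_set(random_structures(toy_sequence(), 5, seed = 66))
  Xd <- build_design_truncation(decoys, eta = 0.2, gamma = 0)
  pc <- draw_reads(pattern_distribution(truth), 2e4, seed = 3)
  dfit <- suppressWarnings(fit_abundances(Xd, pc, candidates = decoys))
  expect_equal(score_recovery(dfit, truth)$precision, 0)
})

test_that("the noiseless closed loop returns the generating abundances", {
  cands <- toy_candidates(3)
  rho <- c(0.5, 0.3, 0.2)
  truth <- ground_truth(cands, rho, eta = 0.2, gamma = 0.02, mode = "truncation")
  d <- pattern_distribution(truth)
  X <- build_design_truncation(cands, eta = 0.2, gamma = 0.02)
  fit <- fit_abundances(X, y = d$prob, candidates = cands)
  expect_equal(fit$abundances$rho, rho, tolerance = 1e-8)
})

test_that("ground truths round-trip through YAML", {
  cands <- toy_candidates(2, chemistry = "dms")
  truth <- ground_truth(cands, c(0.6, 0.4), eta = 0.2, gamma = 0.03, mode = "mutation")
  truth <- add_decoys(truth, random_structures(toy_sequence(), 2, seed = 4), 0.1)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth_yaml(truth, f)
  back <- read_ground_truth_yaml(f)
  expect_equal(back$abundances, truth$abundances, tolerance = 1e-12)
  expect_equal(back$eta, truth$eta)
  expect_equal(back$gamma, truth$gamma)
  expect_equal(back$mode, truth$mode)
  expect_equal(back$candidates$state, truth$candidates$state)
  expect_equal(back$decoy_ids, truth$decoy_ids)
})
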