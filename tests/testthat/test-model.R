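# Design-matrix construction against brute-force enumeration oracles,
# candidate pre-filtering, and the NNLS fit.

test_that("single-site truncation columns match the generative probabilities", {
  sequence <- "A"
  unc <- candidate_set(list(rna_structure(".", sequence, id = "u")))
  X <- build_design_truncation(unc, eta = 0.2, gamma = 0)$values
  expect_equal(as.numeric(X), c(0.2, 0.8), tolerance = 1e-15)

  con <- candidate_set(list(
    rna_structure(".", sequence, id = "c", extra_constrained = 1)
  ))
  Xc <- build_design_truncation(con, eta = 0.2, gamma = 0.05)$values
  expect_equal(as.numeric(Xc), c(0.05, 0.95), tolerance = 1e-15)
})

test_that("truncation columns are exact distributions matching the enumeration oracle", {
  withr::with_seed(101, {
    for (rep in 1:12) {
      L <- sample(2:12, 1)
      state <- random_state(L)
      eta <- runif(1, 0, 0.9)
      gamma <- runif(L, 0, 0.5)
      cands <- candidate_set(list(state_to_candidate(state)))
      col <- build_design_truncation(cands, eta, gamma)$values[, 1]
      expect_lt(abs(sum(col) - 1), 1e-12)
      expect_equal(col, oracle_truncation_dist(state, eta, gamma), tolerance = 1e-12)
    }
  })
})

test_that("single- and two-site mutation columns match the product form", {
  sequence <- "AC"
  s <- candidate_set(list(rna_structure("..", sequence, id = "u")))
  pats <- list(integer(0), 1L, 2L, c(1L, 2L))
  X <- build_design_mutation(s, eta = 0.2, gamma = 0, pats)$values[, 1]
  expect_equal(X, c(0.8^2, 0.2 * 0.8, 0.2 * 0.8, 0.2^2), tolerance = 1e-15)
})

test_that("mutation columns under full enumeration sum to 1 and match the oracle", {
  withr::with_seed(202, {
    for (rep in 1:10) {
      L <- sample(4:12, 1)
      K <- sample(2:min(8, L), 1)
      informative <- sort(sample(L, K))
      state <- random_state(L)
      eta <- runif(1, 0, 0.9)
      gamma <- runif(L, 0, 0.3)
      s <- state_to_candidate(state)
      cands <- candidate_set(list(s), informative = spdeconv::flip_sites(informative, L))
      pats <- spdeconv:::enumerate_patterns(informative)
      col <- build_design_mutation(cands, eta, gamma, pats)$values[, 1]
      expect_lt(abs(sum(col) - 1), 1e-12)
      oracle <- oracle_mutation_dist(state, eta, gamma, informative)
      keys <- vapply(pats, paste, character(1), collapse = ",")
      expect_equal(
        unname(col), unname(oracle[match(keys, names(oracle))]),
        tolerance = 1e-12
      )
    }
  })
})

test_that("degenerate model parameters are rejected", {
  cands <- toy_candidates(1)
  expect_error(build_design_truncation(cands, eta = 1, gamma = 0), "eta")
  expect_error(build_design_truncation(cands, eta = 0.2, gamma = 1), "gamma")
})

test_that("the all-unconstrained candidate reproduces the average-profile stop model", {
  # with every site unconstrained, stop probabilities follow the classic
  # profile model with beta_k = eta at every site
  L <- 10
  eta <- 0.13
  gamma <- withr::with_seed(5, runif(L, 0, 0.1))
  open_chain <- candidate_set(list(
    rna_structure(strrep(".", L), strrep("A", L), id = "open")
  ))
  col <- build_design_truncation(open_chain, eta, gamma)$values[, 1]
  closed_form <- vapply(seq_len(L), function(p) {
    (1 - (1 - gamma[p]) * (1 - eta)) * prod((1 - gamma[seq_len(p - 1)]) * (1 - eta))
  }, numeric(1))
  expect_equal(col[seq_len(L)], closed_form, tolerance = 1e-14)
  expect_equal(col[L + 1], prod((1 - gamma) * (1 - eta)), tolerance = 1e-14)
})

test_that("prefilter removes structures contradicting highly reactive sites", {
  L <- 40
  cands <- toy_candidates(4)
  # hp5 constrains display sites 1-6 and 11-16 -> internal 25..40 (flip)
  beta <- rep(0, L)
  eta <- 0.1
  # four highly reactive sites, three constrained in hp5 only
  hot_disp <- c(1, 2, 3, 20)
  beta[spdeconv::flip_sites(hot_disp, L)] <- 0.3
  out <- suppressMessages(prefilter(cands, beta, eta))
  expect_false("hp5" %in% out$id) # 3 of 4 hot sites constrained: removed
  expect_true(all(c("hp3", "hpmid") %in% out$id))
  expect_equal(attr(out, "removed")$id, c("hp5", "longstem"))

  # constrained at 1 of 4: kept
  beta2 <- rep(0, L)
  beta2[spdeconv::flip_sites(c(1, 20, 21, 22), L)] <- 0.3
  out2 <- prefilter(cands, beta2, eta)
  expect_true("hp5" %in% out2$id)

  # a single highly reactive site never removes ("more than a single nucleotide")
  beta3 <- rep(0, L)
  beta3[spdeconv::flip_sites(1, L)] <- 0.3
  out3 <- prefilter(cands, beta3, eta)
  expect_equal(nrow(out3), 4)

  # no highly reactive sites: warning, no-op
  expect_warning(out4 <- prefilter(cands, rep(0, L), eta), "no-op")
  expect_equal(nrow(out4), 4)
})

test_that("noiseless frequencies are recovered exactly for distinguishable structures", {
  cands <- toy_candidates(2)
  X <- build_design_truncation(cands, eta = 0.2, gamma = 0.01)
  rho_star <- c(0.7, 0.3)
  y <- as.numeric(X$values %*% rho_star)
  fit <- fit_abundances(X, y = y, candidates = cands)
  expect_equal(fit$abundances$rho, rho_star, tolerance = 1e-8)
  expect_lt(fit$residual, 1e-10)
})

test_that("a single candidate is selected with abundance one", {
  cands <- toy_candidates(1)
  truth <- ground_truth(cands, 1, eta = 0.2, mode = "truncation")
  pc <- draw_reads(pattern_distribution(truth), 1e4, seed = 3)
  X <- build_design_truncation(cands, eta = 0.2, gamma = 0)
  fit <- fit_abundances(X, pc, candidates = cands)
  expect_equal(fit$abundances$abundance, 1)
  expect_true(fit$abundances$selected)
})

test_that("the NNLS solution matches a support-enumeration oracle", {
  withr::with_seed(77, {
    for (rep in 1:8) {
      cands <- toy_candidates(sample(2:4, 1))
      eta <- runif(1, 0.1, 0.3)
      X <- build_design_truncation(cands, eta, gamma = 0.01)
      truth_rho <- as.numeric(stats::rgamma(nrow(cands), 1))
      truth_rho <- truth_rho / sum(truth_rho)
      y <- as.numeric(X$values %*% truth_rho) + rnorm(nrow(X$values), 0, 1e-3)
      fit <- fit_abundances(X, y = pmax(y, 0), candidates = cands)
      oracle <- oracle_nnls(X$values, pmax(y, 0))
      expect_equal(fit$abundances$rho, oracle$rho, tolerance = 1e-6)
    }
  })
})

test_that("the NNLS residual never exceeds any single-candidate fit", {
  cands <- toy_candidates(4)
  truth <- ground_truth(cands, c(0.4, 0.3, 0.2, 0.1), eta = 0.2, mode = "truncation")
  pc <- draw_reads(pattern_distribution(truth), 5e4, seed = 13)
  X <- build_design_truncation(cands, eta = 0.2, gamma = 0)
  y <- spdeconv:::design_response(X, pc)
  full <- fit_abundances(X, pc, candidates = cands)
  for (k in seq_len(nrow(cands))) {
    sub <- new_candidate_set(
      tibble::as_tibble(cands)[k, ], spdeconv:::cs_sequence(cands), NULL, NULL
    )
    Xk <- build_design_truncation(sub, eta = 0.2, gamma = 0)
    single <- fit_abundances(Xk, pc, candidates = sub)
    expect_lte(full$residual, single$residual + 1e-12)
  }
})

test_that("the fit is invariant to candidate ordering", {
  cands <- toy_candidates(3)
  truth <- ground_truth(cands, c(0.5, 0.3, 0.2), eta = 0.2, mode = "truncation")
  pc <- draw_reads(pattern_distribution(truth), 5e4, seed = 21)
  X <- build_design_truncation(cands, eta = 0.2, gamma = 0)
  fit <- fit_abundances(X, pc, candidates = cands)
  perm <- c(3, 1, 2)
  cands_p <- new_candidate_set(
    tibble::as_tibble(cands)[perm, ], spdeconv:::cs_sequence(cands),
    spdeconv:::cs_region(cands), spdeconv:::cs_informative(cands)
  )
  Xp <- build_design_truncation(cands_p, eta = 0.2, gamma = 0)
  fit_p <- fit_abundances(Xp, pc, candidates = cands_p)
  reord <- match(fit$abundances$id, fit_p$abundances$id)
  expect_equal(fit$abundances$rho, fit_p$abundances$rho[reord], tolerance = 1e-9)
})

test_that("indistinguishable structures are merged and reported as a group", {
  seqs <- toy_sequence()
  a <- rna_structure("((((((....))))))........................", seqs, id = "a")
  b <- rna_structure("((((((....))))))........................", seqs, id = "b")
  c_ <- rna_structure("........................((((((....))))))", seqs, id = "c")
  cands <- new_candidate_set(
    dplyr::bind_rows(
      tibble::as_tibble(candidate_set(list(a))),
      tibble::as_tibble(candidate_set(list(b))),
      tibble::as_tibble(candidate_set(list(c_)))
    ),
    seqs, NULL, seq_len(40)
  )
  truth <- ground_truth(candidate_set(list(a, c_)), c(0.6, 0.4),
    eta = 0.2, mode = "truncation"
  )
  pc <- draw_reads(pattern_distribution(truth), 2e4, seed = 5)
  X <- build_design_truncation(cands, eta = 0.2, gamma = 0)
  fit <- suppressMessages(fit_abundances(X, pc, candidates = cands))
  expect_equal(fit$diagnostics$merged_groups, list(a = c("a", "b")))
  expect_equal(fit$abundances$rho[fit$abundances$id == "b"], 0)
  expect_gt(fit$abundances$rho[fit$abundances$id == "a"], 0.5)
})

test_that("mutation-mode fits report captured pattern mass", {
  cands <- toy_candidates(2, chemistry = "dms")
  truth <- ground_truth(cands, c(0.6, 0.4), eta = 0.25, mode = "mutation")
  pc <- draw_reads_bernoulli(truth, 2e4, seed = 31)
  X <- build_design_mutation(cands, eta = 0.25, gamma = 0, patterns = pc)
  fit <- fit_abundances(X, pc, candidates = cands)
  expect_true(all(fit$diagnostics$captured_mass <= 1 + 1e-12))
  expect_true(all(fit$diagnostics$captured_mass > 0.5)) # observed patterns dominate
  expect_equal(fit$abundances$abundance[fit$abundances$selected],
    c(0.6, 0.4),
    tolerance = 0.05
  )
})

test_that("a single observed pattern triggers the under-determination warning", {
  cands <- toy_candidates(2)
  X <- build_design_truncation(cands, eta = 0.2, gamma = 0)
  pc <- bin_truncation(rep(41, 50), L = 40) # all complete reads
  expect_warning(fit_abundances(X, pc, candidates = cands), "under-determined")
})

test_that("ideal profiles reflect the selected ensemble's unconstrained sites", {
  cands <- toy_candidates(2)
  truth <- ground_truth(cands, c(0.7, 0.3), eta = 0.2, mode = "truncation")
  X <- build_design_truncation(cands, eta = 0.2, gamma = 0)
  fit <- fit_abundances(X, y = as.numeric(X$values %*% c(0.7, 0.3)), candidates = cands)
  prof <- ideal_profile(fit)
  # sites unconstrained in both structures show full eta
  both_open <- which(cands$state[[1]] == 0 & cands$state[[2]] == 0)
  expect_equal(prof[both_open], rep(0.2, length(both_open)), tolerance = 1e-6)
  # sites constrained only in the dominant structure show 0.3 * eta
  only_hp3 <- which(cands$state[[1]] == 1 & cands$state[[2]] == 0)
  expect_equal(prof[only_hp3], rep(0.3 * 0.2, length(only_hp3)), tolerance = 1e-6)
})
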