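# Shared toy fixtures: a 40-nt RNA with four mutually distinguishable
# hairpin structures (bistable-switch style), used across module tests and
# the simulation-recovery suites.

toy_sequence <- function() {
  # 40 nt; bases are irrelevant to the model except for DMS site selection
  "GGCAGCAUUGGAACCGCUUAACGGCAUCCAAGGUUCCGAC"
}

toy_structures <- function() {
  seqs <- toy_sequence()
  db <- c(
    hp5 = "((((((....))))))........................",
    hp3 = "........................((((((....))))))",
    hpmid = "............((((((....))))))............",
    longstem = "((((((((............))))))))............"
  )
  unname(purrr::imap(as.list(db), function(s, nm) rna_structure(s, seqs, id = nm)))
}

toy_candidates <- function(n = 4, chemistry = "shape") {
  candidate_set(toy_structures()[seq_len(n)], chemistry = chemistry)
}

# distinguishability guard used when decoys are added to a candidate set
distinct_states <- function(cands) {
  keys <- vapply(cands$state, paste, character(1), collapse = "")
  !anyDuplicated(keys)
}

# ---------------------------------------------------------------------------
# Bistable 36-nt toy: a stored (deduplicated) Boltzmann sample provides the
# candidate/decoy pool, as a statistical sampler would in a real analysis.

bistable_sample <- function() {
  path <- system.file("extdata", "bistable36_sample.db", package = "spdeconv")
  read_vienna(path)
}

# the four dominant, mutually distinguishable folds used as ground truths
bistable_truth_db <- function() {
  c(
    "((((((......))))))..................",
    "............((((((......))))))......",
    "((((((......)))))).....((.........))",
    "........((..((((((......))))))..)).."
  )
}

# one seeded mixture-recovery run: a 2-4 structure ground truth diluted by
# 10 decoys drawn from the sampler pool (10% of the ensemble), treated and
# control samples at the given depth, full estimation pipeline, scoring
mixture_run <- function(seed, n_reads = 1e5) {
  pool_cs <- bistable_sample()
  truth_rows <- match(bistable_truth_db(), pool_cs$dotbracket)
  stopifnot(!anyNA(truth_rows))
  withr::with_seed(seed, {
    n_true <- sample(2:4, 1)
    eta <- runif(1, 0.05, 0.3)
    ab <- as.numeric(stats::rgamma(n_true, 1)) # flat Dirichlet draw
    ab <- ab / sum(ab)
    truths <- lapply(
      truth_rows[seq_len(n_true)],
      function(r) spdeconv:::cs_structure(pool_cs, r)
    )
    truth <- ground_truth(
      candidate_set(truths), ab,
      eta = eta, gamma = 0.01, mode = "truncation"
    )
    pool <- setdiff(seq_len(nrow(pool_cs)), truth_rows)
    decoys <- lapply(
      sample(pool, 10),
      function(r) spdeconv:::cs_structure(pool_cs, r)
    )
    truth <- add_decoys(truth, decoys, fraction = 0.10)
    pc <- draw_reads(pattern_distribution(truth), n_reads)
    ctrl_truth <- truth
    ctrl_truth$eta <- 0 # mock-treated control: noise only
    ctrl <- draw_reads(pattern_distribution(ctrl_truth), n_reads)
    fit <- suppressMessages(suppressWarnings(
      deconvolve(pc, truth$candidates, control = ctrl)
    ))
    list(truth = truth, fit = fit, score = score_recovery(fit, truth))
  })
}
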