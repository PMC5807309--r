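# Read simulation from a known ground truth, the two noise mechanisms
# (Gaussian count perturbation and decoy structures), bootstrap resampling,
# and recovery scoring. This is the validation harness for the whole tool:
# for noiseless, identifiable ground truths the simulator-estimator closed
# loop must return the generating abundances to solver tolerance.

#' Define a simulation ground truth
#'
#' @param structures a [candidate_set()] or list of [rna_structure()].
#' @param abundances non-negative vector summing to 1, one per structure.
#' @param eta unconstrained-site modification probability.
#' @param gamma per-site noise (scalar recycled).
#' @param mode `"truncation"` or `"mutation"`.
#' @param chemistry `"shape"` or `"dms"`; ignored when `structures` is
#'   already a `candidate_set` (its informative sites are kept).
#' @return a `ground_truth` object.
#' @export
ground_truth <- function(structures, abundances, eta, gamma = 0,
                         mode = c("truncation", "mutation"),
                         chemistry = c("shape", "dms")) {
  mode <- match.arg(mode)
  if (!inherits(structures, "candidate_set")) {
    structures <- candidate_set(structures, chemistry = match.arg(chemistry))
  }
  if (nrow(structures) != length(abundances)) {
    abort("one abundance per structure is required")
  }
  if (any(abundances < 0) || abs(sum(abundances) - 1) > 1e-8) {
    abort("abundances must be non-negative and sum to 1")
  }
  L <- cs_L(structures)
  if (length(gamma) == 1) gamma <- rep(gamma, L)
  assert_prob(eta, "eta", upper_open = TRUE)
  assert_prob(gamma, "gamma", upper_open = TRUE)
  structure(
    list(
      candidates = structures, abundances = abundances, eta = eta,
      gamma = gamma, mode = mode, decoy_ids = character(0)
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %s mode: %d structure(s) (%d decoys), eta = %.3g\n",
    x$mode, nrow(x$candidates), length(x$decoy_ids), x$eta
  ))
  invisible(x)
}

# all subsets of `informative` in binary-counter order (bit k = k-th site)
enumerate_patterns <- function(informative) {
  K <- length(informative)
  lapply(seq_len(2^K) - 1L, function(b) {
    informative[bitwAnd(b, bitwShiftL(1L, seq_len(K) - 1L)) > 0]
  })
}

#' Exact pattern distribution of a ground truth
#'
#' Mixes the per-structure pattern probabilities (the design-matrix columns)
#' by the ground-truth abundances. Truncation mode covers all L + 1
#' patterns; mutation mode enumerates every subset of the informative sites
#' (feasible up to 20 sites -- beyond that, sample reads directly with
#' [draw_reads_bernoulli()]).
#'
#' @param truth a [ground_truth()].
#' @return a `pattern_dist` tibble (`stop` or `sites` column plus `prob`)
#'   summing to 1.
#' @export
pattern_distribution <- function(truth) {
  cands <- truth$candidates
  if (truth$mode == "truncation") {
    X <- build_design_truncation(cands, truth$eta, truth$gamma)
    df <- tibble(
      stop = X$patterns$stop,
      prob = as.numeric(X$values %*% truth$abundances)
    )
  } else {
    informative <- cs_informative(cands) %||% seq_len(cs_L(cands))
    if (length(informative) > 20) {
      abort(paste(
        "full pattern enumeration is limited to 20 informative sites;",
        "use draw_reads_bernoulli() for per-read sampling"
      ))
    }
    pats <- enumerate_patterns(informative)
    X <- build_design_mutation(cands, truth$eta, truth$gamma, pats)
    df <- tibble(
      sites = pats,
      prob = as.numeric(X$values %*% truth$abundances)
    )
  }
  structure(
    df,
    mode = truth$mode, L = cs_L(cands),
    informative = cs_informative(cands),
    class = c("pattern_dist", class(tibble()))
  )
}

# turn a count vector aligned to a pattern_dist into pattern_counts
dist_counts_to_pc <- function(dist, counts) {
  mode <- attr(dist, "mode", exact = TRUE)
  L <- attr(dist, "L", exact = TRUE)
  informative <- attr(dist, "informative", exact = TRUE)
  if (mode == "truncation") {
    keep <- counts > 0
    df <- tibble(stop = dist$stop[keep], count = as.integer(counts[keep]))
    new_pattern_counts(df[order(df$stop), ], "truncation", L, informative)
  } else {
    keep <- counts > 0 | lengths(dist$sites) == 0 # empty pattern always kept
    df <- tibble(sites = dist$sites[keep], count = as.integer(counts[keep]))
    new_pattern_counts(df, "mutation", L, informative)
  }
}

#' Draw sequencing reads from a pattern distribution
#'
#' A single multinomial draw of `n` reads; bit-reproducible given `seed`.
#'
#' @param dist a `pattern_dist` from [pattern_distribution()].
#' @param n number of reads.
#' @param seed optional integer seed.
#' @return a `pattern_counts` object.
#' @export
draw_reads <- function(dist, n, seed = NULL) {
  stopifnot(n >= 1)
  counts <- with_seed_if(seed, rmultinom(1, n, dist$prob)[, 1])
  dist_counts_to_pc(dist, counts)
}

#' Per-read Bernoulli sampling for large mutation pattern spaces
#'
#' Distributionally identical to [draw_reads()] (site events are independent
#' given the structure) but avoids enumerating `2^K` patterns.
#'
#' @inheritParams draw_reads
#' @param truth a mutation-mode [ground_truth()].
#' @export
draw_reads_bernoulli <- function(truth, n, seed = NULL) {
  if (truth$mode != "mutation") abort("per-read sampling is for mutation mode")
  cands <- truth$candidates
  informative <- cs_informative(cands) %||% seq_len(cs_L(cands))
  with_seed_if(seed, {
    per_struct <- rmultinom(1, n, truth$abundances)[, 1]
    sets <- vector("list", n)
    pos <- 0
    for (s in seq_along(per_struct)) {
      ns <- per_struct[s]
      if (ns == 0) next
      e <- event_probs(cands$state[[s]], truth$eta, truth$gamma)[informative]
      hits <- matrix(runif(ns * length(e)) < rep(e, each = ns), nrow = ns)
      for (r in seq_len(ns)) {
        sets[[pos + r]] <- informative[hits[r, ]]
      }
      pos <- pos + ns
    }
    bin_mutation(sets, informative, cs_L(cands))
  })
}

#' Perturb pattern counts with Gaussian noise
#'
#' Each count c is replaced by `max(0, round(c + N(0, sigma * c)))`: the
#' perturbation scales with the count so one sigma is meaningful across
#' patterns of very different frequency.
#'
#' @param pc a `pattern_counts`.
#' @param sigma relative noise level, `>= 0` (0 = identity).
#' @param seed optional integer seed.
#' @export
add_count_noise <- function(pc, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(pc)
  noisy <- with_seed_if(seed, {
    pmax(0, round(pc$count + rnorm(nrow(pc), 0, sigma * pc$count)))
  })
  out <- pc
  out$count <- as.integer(noisy)
  out
}

#' Dilute a ground truth with decoy structures
#'
#' Scales the original abundances by `1 - fraction` and splits `fraction`
#' equally among the decoys, mimicking unmodeled structural dynamics in
#' solution.
#'
#' @param truth a [ground_truth()].
#' @param decoys list of [rna_structure()] over the same sequence.
#' @param fraction total ensemble fraction populated by decoys, in `[0, 1)`.
#' @export
add_decoys <- function(truth, decoys, fraction = 0.10) {
  stopifnot(fraction >= 0, fraction < 1)
  if (inherits(decoys, "rna_structure")) decoys <- list(decoys)
  if (length(decoys) == 0 || fraction == 0) return(truth)
  cands <- truth$candidates
  extra_df <- tibble(
    id = vapply(decoys, function(s) s$id, character(1)),
    dotbracket = vapply(decoys, function(s) s$dotbracket, character(1)),
    source = vapply(decoys, function(s) s$source, character(1)),
    energy = vapply(decoys, function(s) s$energy, numeric(1)),
    pairs = lapply(decoys, function(s) s$pairs),
    state = lapply(decoys, function(s) s$state)
  )
  for (s in decoys) {
    if (s$sequence != cs_sequence(cands)) abort("decoys must share the sequence")
  }
  df <- dplyr::bind_rows(as_tibble(cands), extra_df)
  if (anyDuplicated(df$id)) df$id <- make.unique(df$id, sep = "_")
  out <- truth
  out$candidates <- new_candidate_set(
    df, cs_sequence(cands), cs_region(cands), cs_informative(cands)
  )
  out$abundances <- c(
    truth$abundances * (1 - fraction),
    rep(fraction / length(decoys), length(decoys))
  )
  out$decoy_ids <- c(truth$decoy_ids, utils::tail(df$id, length(decoys)))
  out
}

#' Multinomial bootstrap of a pattern table
#'
#' Resamples reads at the observed depth to capture technical variation at a
#' given sequencing depth; feed the replicates through the fit to report the
#' spread of abundance estimates.
#'
#' @param pc a `pattern_counts`.
#' @param replicates number of bootstrap replicates.
#' @param seed optional integer seed.
#' @return list of `pattern_counts`.
#' @export
bootstrap_counts <- function(pc, replicates, seed = NULL) {
  stopifnot(replicates >= 1)
  n <- total_reads(pc)
  prob <- pc$count / n
  draws <- with_seed_if(seed, rmultinom(replicates, n, prob))
  lapply(seq_len(replicates), function(b) {
    out <- pc
    out$count <- as.integer(draws[, b])
    if (pc_mode(pc) == "truncation") out <- out[out$count > 0, , drop = FALSE]
    out
  })
}

# state key over the assayed informative sites, used for structure matching
state_match_key <- function(state, informative) {
  paste(state[informative], collapse = "")
}

#' Score a reconstruction against the ground truth
#'
#' A selected structure matches a truth structure when their
#' constrained/unconstrained states agree at every informative site (the
#' assay cannot distinguish finer detail). Estimated abundance of a truth
#' structure is the summed normalized abundance (`rho_norm`) of all matching
#' candidates.
#'
#' @param fit an `sp_fit` carrying its candidate set.
#' @param truth the generating [ground_truth()].
#' @return a `recovery_score`: per-structure tibble plus `l1_error`,
#'   `mean_abs_error` (over non-decoy truth structures), `precision`,
#'   `recall`, and `max_decoy_abundance`.
#' @export
score_recovery <- function(fit, truth) {
  cands <- fit$candidates
  if (is.null(cands)) abort("fit carries no candidate set")
  informative <- cs_informative(cands) %||% seq_len(cs_L(cands))
  truth_keys <- vapply(
    truth$candidates$state, state_match_key, character(1),
    informative = informative
  )
  cand_keys <- vapply(
    cands$state, state_match_key, character(1),
    informative = informative
  )
  ab <- fit$abundances
  est <- vapply(truth_keys, function(k) {
    sum(ab$rho_norm[match(cands$id, ab$id)][cand_keys == k])
  }, numeric(1))
  is_decoy <- truth$candidates$id %in% truth$decoy_ids
  per <- tibble(
    id = truth$candidates$id,
    decoy = is_decoy,
    true_abundance = truth$abundances,
    est_abundance = unname(est),
    abs_error = abs(truth$abundances - unname(est)),
    matched = truth_keys %in% cand_keys[ab$selected[match(cands$id, ab$id)]]
  )
  sel_keys <- cand_keys[ab$selected[match(cands$id, ab$id)]]
  precision <- if (length(sel_keys) == 0) 0 else mean(sel_keys %in% truth_keys[!is_decoy])
  structure(
    list(
      per_structure = per,
      l1_error = sum(per$abs_error[!per$decoy]),
      mean_abs_error = mean(per$abs_error[!per$decoy]),
      precision = precision,
      recall = mean(per$matched[!per$decoy]),
      max_decoy_abundance = if (any(is_decoy)) max(per$est_abundance[is_decoy]) else NA_real_
    ),
    class = "recovery_score"
  )
}

#' @export
print.recovery_score <- function(x, ...) {
  cat(sprintf(
    "<recovery_score> L1 = %.4g, mean |err| = %.4g, precision = %.2f, recall = %.2f\n",
    x$l1_error, x$mean_abs_error, x$precision, x$recall
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Toy structure sampler (fixtures and decoys; not a thermodynamic sampler)

#' Sample random nested secondary structures
#'
#' A stochastic stack walk over the sequence: at each position open a pair,
#' close the innermost open pair (only when the enclosed loop has at least
#' `min_loop` nucleotides), or stay unpaired. Unclosed openings become
#' unpaired sites. The sampler is a convenience for simulations and decoy
#' generation -- it carries no thermodynamics and ignores base
#' complementarity.
#'
#' @param sequence RNA sequence.
#' @param n number of structures.
#' @param seed optional integer seed.
#' @param p_open,p_close probabilities of opening/closing at each position.
#' @param min_loop minimum hairpin loop length.
#' @param prefix id prefix.
#' @return list of [rna_structure()] with `source = "sampled"`.
#' @export
random_structures <- function(sequence, n, seed = NULL, p_open = 0.3,
                              p_close = 0.4, min_loop = 3, prefix = "d") {
  L <- nchar(sequence)
  with_seed_if(seed, {
    lapply(seq_len(n), function(k) {
      chars <- rep(".", L)
      open <- integer(0)
      for (pos in seq_len(L)) {
        u <- runif(1)
        can_close <- length(open) > 0 && (pos - open[length(open)] - 1) >= min_loop
        if (can_close && u < p_close) {
          chars[open[length(open)]] <- "("
          chars[pos] <- ")"
          open <- open[-length(open)]
        } else if (u < p_close + p_open && pos + min_loop + 1 <= L) {
          open <- c(open, pos)
        }
      }
      # unmatched openings were never written; they remain '.'
      rna_structure(
        paste(chars, collapse = ""), sequence,
        id = sprintf("%s%03d", prefix, k), source = "sampled"
      )
    })
  })
}

# ---------------------------------------------------------------------------
# Ground-truth YAML round trip

#' Read and write ground-truth YAML files
#'
#' Fields: `sequence`, `structures` (named dot-bracket strings, 5'->3'),
#' `abundances`, `eta`, `gamma` (scalar or per-site list, 5'->3'), `mode`,
#' `chemistry`.
#'
#' @param truth a [ground_truth()].
#' @param path YAML path.
#' @export
write_ground_truth_yaml <- function(truth, path) {
  cands <- truth$candidates
  L <- cs_L(cands)
  gamma <- truth$gamma
  gamma_out <- if (length(unique(gamma)) == 1) gamma[1] else rev(gamma) # 5'->3'
  informative <- cs_informative(cands)
  chem <- if (is.null(informative) || length(informative) == L) "shape" else "dms"
  yaml::write_yaml(
    list(
      sequence = cs_sequence(cands),
      structures = as.list(setNames(cands$dotbracket, cands$id)),
      abundances = as.numeric(truth$abundances),
      eta = truth$eta,
      gamma = gamma_out,
      mode = truth$mode,
      chemistry = chem,
      decoys = as.list(truth$decoy_ids)
    ),
    path
  )
  invisible(path)
}

#' @rdname write_ground_truth_yaml
#' @export
read_ground_truth_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  structures <- lapply(names(spec$structures), function(id) {
    rna_structure(spec$structures[[id]], spec$sequence, id = id)
  })
  gamma <- spec$gamma %||% 0
  if (length(gamma) > 1) gamma <- rev(as.numeric(gamma)) # back to 3'->5'
  truth <- ground_truth(
    structures,
    abundances = as.numeric(spec$abundances),
    eta = spec$eta, gamma = gamma,
    mode = spec$mode %||% "truncation",
    chemistry = spec$chemistry %||% "shape"
  )
  truth$decoy_ids <- as.character(unlist(spec$decoys))
  truth
}
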