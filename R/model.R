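# The linear model y = X rho + eps.
#
# Each design-matrix entry x_ps = Pr(pattern p | structure s) follows from a
# read-level generative model with two parameters: eta, the modification
# probability of a structurally unconstrained site (constrained sites cannot
# be modified), and gamma_l, the per-site noise probability (natural RT
# drop-off, or background mutation). Per site the detectable-event
# probability is therefore
#
#   e_l = 1 - (1 - eta)(1 - gamma_l)   if l is unconstrained in s,
#   e_l = gamma_l                      if l is constrained in s,
#   e_l = 0                            if l is not assayable by the chemistry.
#
# Truncation mode: a read stops at the first event site counted from the
# priming site, x_ps = e_p * prod_{l < p} (1 - e_l), and the complete-read
# pattern takes the remaining mass prod_l (1 - e_l) -- each column is an
# exact probability distribution over the L + 1 patterns. Mutation mode:
# events at different sites are independent within a read, so a pattern (a
# mutated-site set M) has probability prod_{l in M} e_l *
# prod_{l informative, not in M} (1 - e_l).
#
# Non-negative least squares on the pattern frequencies then yields a sparse
# abundance vector; structures above a user threshold are selected and their
# abundances renormalized.

# per-site detectable-event probabilities for one structure
event_probs <- function(state, eta, gamma, informative = NULL) {
  e <- ifelse(state == 1L, gamma, 1 - (1 - eta) * (1 - gamma))
  if (!is.null(informative)) e[setdiff(seq_along(state), informative)] <- 0
  e
}

new_design <- function(values, mode, patterns, structure_ids, eta, gamma,
                       informative, L) {
  structure(
    list(
      values = values, mode = mode, patterns = patterns,
      structure_ids = structure_ids, eta = eta, gamma = gamma,
      informative = informative, L = L
    ),
    class = "sp_design"
  )
}

#' @export
print.sp_design <- function(x, ...) {
  cat(sprintf(
    "<sp_design> %s mode: %d pattern(s) x %d structure(s), eta = %.4g\n",
    x$mode, nrow(x$values), ncol(x$values), x$eta
  ))
  invisible(x)
}

#' Build the truncation-mode design matrix
#'
#' Columns cover the full pattern space: stops at sites 1..L (model
#' coordinates) plus the complete-read pattern, and each column sums to 1.
#'
#' @param candidates a [candidate_set()].
#' @param eta unconstrained-site modification probability, in `[0, 1)`.
#' @param gamma per-site noise vector (scalar recycled), each in `[0, 1)`.
#' @return an `sp_design` object.
#' @export
build_design_truncation <- function(candidates, eta, gamma = 0) {
  L <- cs_L(candidates)
  if (length(gamma) == 1) gamma <- rep(gamma, L)
  stopifnot(length(gamma) == L)
  assert_prob(eta, "eta", upper_open = TRUE)
  assert_prob(gamma, "gamma", upper_open = TRUE)
  informative <- cs_informative(candidates)
  X <- vapply(candidates$state, function(state) {
    e <- event_probs(state, eta, gamma, informative)
    surv <- cumprod(c(1, 1 - e)) # surv[p] = Pr(read through sites 1..p-1)
    c(surv[seq_len(L)] * e, surv[L + 1])
  }, numeric(L + 1))
  X <- matrix(X, nrow = L + 1, dimnames = list(NULL, candidates$id))
  new_design(
    X, "truncation",
    patterns = tibble(stop = seq_len(L + 1L)),
    structure_ids = candidates$id, eta = eta, gamma = gamma,
    informative = informative, L = L
  )
}

#' Build the mutation-mode design matrix
#'
#' Rows are the supplied patterns (usually the observed ones plus the empty
#' pattern); entries multiply event probabilities over mutated sites and
#' their complements over unmutated informative sites. Under full pattern
#' enumeration each column sums to 1; over a restricted pattern list the
#' column sum is the "captured probability mass" diagnostic.
#'
#' @inheritParams build_design_truncation
#' @param patterns list of mutated-site sets (model coordinates), or a
#'   mutation-mode `pattern_counts` whose patterns are used.
#' @export
build_design_mutation <- function(candidates, eta, gamma = 0, patterns) {
  L <- cs_L(candidates)
  if (length(gamma) == 1) gamma <- rep(gamma, L)
  stopifnot(length(gamma) == L)
  assert_prob(eta, "eta", upper_open = TRUE)
  assert_prob(gamma, "gamma", upper_open = TRUE)
  informative <- cs_informative(candidates) %||% seq_len(L)
  if (inherits(patterns, "pattern_counts")) patterns <- patterns$sites
  ok <- vapply(patterns, function(m) all(m %in% informative), logical(1))
  if (!all(ok)) abort("pattern lists sites outside the informative set")
  # membership matrix of patterns over informative sites; per-structure
  # columns are exp(sum log(1-e) + M (log e - log(1-e)))
  K <- length(informative)
  M <- matrix(0, nrow = length(patterns), ncol = K)
  idx <- match(unlist(patterns), informative)
  if (length(idx) > 0) {
    M[cbind(rep(seq_along(patterns), lengths(patterns)), idx)] <- 1
  }
  X <- vapply(candidates$state, function(state) {
    e <- event_probs(state, eta, gamma)[informative]
    # log-domain accumulation keeps 2^K-scale products stable
    w <- log(e) - log1p(-e)
    impossible <- e == 0 # avoid 0 * -Inf in the matrix product
    w[impossible] <- 0
    base <- sum(log1p(-e))
    out <- exp(base + as.numeric(M %*% w))
    if (any(impossible)) {
      out[M[, impossible, drop = FALSE] %*% rep(1, sum(impossible)) > 0] <- 0
    }
    out
  }, numeric(length(patterns)))
  X <- matrix(X, nrow = length(patterns), dimnames = list(NULL, candidates$id))
  new_design(
    X, "mutation",
    patterns = tibble(sites = patterns),
    structure_ids = candidates$id, eta = eta, gamma = gamma,
    informative = informative, L = L
  )
}

#' @rdname build_design_truncation
#' @param mode `"truncation"` or `"mutation"`.
#' @param patterns passed to [build_design_mutation()] in mutation mode.
#' @export
build_design <- function(candidates, mode = c("truncation", "mutation"),
                         eta, gamma = 0, patterns = NULL) {
  mode <- match.arg(mode)
  if (mode == "truncation") {
    build_design_truncation(candidates, eta, gamma)
  } else {
    if (is.null(patterns)) abort("mutation mode needs an explicit pattern list")
    build_design_mutation(candidates, eta, gamma, patterns)
  }
}

#' Remove candidates inconsistent with highly reactive sites
#'
#' Sites with reactivity above eta are expected to be predominantly
#' unpaired; a structure that keeps many of them constrained contradicts the
#' data. A structure is removed when its constrained highly reactive sites
#' exceed both a single nucleotide and half of the highly reactive set --
#' i.e. more than `max(1, |H| / 2)` violations, with
#' `H = {l : beta_l > eta}`.
#'
#' @param candidates a [candidate_set()].
#' @param beta per-site reactivity vector (model coordinates; `NA` at
#'   unassayed sites), or a `reactivity_profile`.
#' @param eta unconstrained-site modification probability.
#' @return filtered `candidate_set`; removals (with their violating sites)
#'   in `attr(, "removed")`.
#' @export
prefilter <- function(candidates, beta, eta) {
  if (inherits(beta, "reactivity_profile")) {
    eta <- attr(beta, "eta", exact = TRUE) %||% eta
    beta <- beta$beta[order(beta$site)]
  }
  stopifnot(length(beta) == cs_L(candidates))
  H <- which(!is.na(beta) & beta > eta)
  if (length(H) == 0) {
    warn("no highly reactive sites (beta > eta); prefilter is a no-op")
    attr(candidates, "removed") <- tibble(id = character(0), n_violations = integer(0))
    return(candidates)
  }
  allowance <- max(1, length(H) / 2)
  violations <- vapply(candidates$state, function(st) sum(st[H]), integer(1))
  drop <- violations > allowance
  removed <- tibble(
    id = candidates$id[drop],
    n_violations = violations[drop],
    violating_sites = lapply(
      candidates$state[drop],
      function(st) H[st[H] == 1L]
    )
  )
  if (any(drop)) {
    inform(sprintf(
      "prefilter: removed %d of %d structure(s) (> %.3g constrained highly reactive sites of %d)",
      sum(drop), length(drop), allowance, length(H)
    ))
  }
  out <- new_candidate_set(
    candidates[!drop, , drop = FALSE],
    cs_sequence(candidates), cs_region(candidates), cs_informative(candidates)
  )
  attr(out, "removed") <- removed
  out
}

# align observed pattern frequencies to the design's rows
design_response <- function(design, pc) {
  if (pc_mode(pc) != design$mode) {
    abort("pattern counts and design matrix disagree on the detection mode")
  }
  freq <- pattern_frequencies(pc)
  if (design$mode == "truncation") {
    y <- numeric(nrow(design$values))
    y[freq$stop] <- freq$freq
  } else {
    keys_design <- vapply(design$patterns$sites, sites_key, character(1))
    keys_obs <- vapply(freq$sites, sites_key, character(1))
    idx <- match(keys_design, keys_obs)
    y <- ifelse(is.na(idx), 0, freq$freq[idx])
    if (any(is.na(idx) & keys_design != "")) {
      # rows for never-observed patterns carry zero frequency
    }
    unmatched <- setdiff(keys_obs, keys_design)
    if (length(unmatched) > 0) {
      abort("observed patterns missing from the design matrix; rebuild it from the data")
    }
  }
  y
}

#' Fit structure abundances by non-negative least squares
#'
#' Solves `min || y - X rho ||` subject to `rho >= 0` (Lawson-Hanson NNLS),
#' selects structures whose normalized abundance exceeds the threshold, and
#' renormalizes the selected abundances to sum to 1.
#'
#' @param design an `sp_design`.
#' @param pc the observed `pattern_counts` (converted to frequencies and
#'   aligned to the design rows).
#' @param threshold selection threshold on normalized abundance
#'   (default 1 %).
#' @param candidates optional [candidate_set()] matching the design, carried
#'   along for post-processing.
#' @param y optional frequency vector aligned to the design rows, overriding
#'   `pc` (e.g. exact pattern probabilities for noiseless analyses).
#' @return an `sp_fit` object; see [tidy.sp_fit()] and [glance.sp_fit()].
#' @export
fit_abundances <- function(design, pc = NULL, threshold = 0.01,
                           candidates = NULL, y = NULL) {
  stopifnot(threshold >= 0, threshold < 1)
  if (is.null(y)) {
    if (is.null(pc)) abort("either `pc` or `y` is required")
    y <- design_response(design, pc)
  } else {
    stopifnot(length(y) == nrow(design$values))
  }
  X <- design$values
  S <- ncol(X)
  ids <- design$structure_ids
  if (sum(y > 0) == 1) {
    warn("a single observed pattern: the linear system is severely under-determined")
  }

  # drop all-zero columns (structures that cannot generate any included pattern)
  colmass <- colSums(X)
  dropped <- which(colmass == 0)
  if (length(dropped) > 0) {
    warn(sprintf(
      "%d structure(s) generate none of the included patterns; dropped from the fit",
      length(dropped)
    ))
  }
  keep <- setdiff(seq_len(S), dropped)

  # merge exact-duplicate columns: structures the assay cannot distinguish
  merged_groups <- list()
  if (length(keep) > 1) {
    keys <- apply(X[, keep, drop = FALSE], 2, paste, collapse = "\r")
    first <- !duplicated(keys)
    for (k in unique(keys[!first])) {
      members <- keep[keys == k]
      merged_groups[[ids[members[1]]]] <- ids[members]
    }
    keep <- keep[first]
    if (length(merged_groups) > 0) {
      inform(sprintf(
        "%d group(s) of indistinguishable structures merged; abundance is attributed to the first member",
        length(merged_groups)
      ))
    }
  }

  Xk <- X[, keep, drop = FALSE]
  sol <- pracma::lsqnonneg(Xk, y)
  rho <- numeric(S)
  rho[keep] <- pmax(sol$x, 0)
  fitted <- as.numeric(Xk %*% sol$x)
  residual <- sqrt(sum((y - fitted)^2))

  total <- sum(rho)
  rho_norm <- if (total > 0) rho / total else rho
  if (total == 0) warn("NNLS returned the zero solution; no structure selected")
  selected <- rho_norm > threshold
  abundance <- rep(0, S)
  if (any(selected)) {
    abundance[selected] <- rho_norm[selected] / sum(rho_norm[selected])
  }

  structure(
    list(
      abundances = tibble(
        id = ids, rho = rho, rho_norm = rho_norm,
        selected = selected, abundance = abundance
      ),
      residual = residual, threshold = threshold, mode = design$mode,
      eta = design$eta, gamma = design$gamma,
      y = y, fitted = fitted,
      candidates = candidates,
      diagnostics = list(
        captured_mass = setNames(colmass, ids),
        dropped = ids[dropped],
        merged_groups = merged_groups,
        n_patterns = nrow(design$values),
        n_reads = if (is.null(pc)) NA_integer_ else total_reads(pc)
      )
    ),
    class = "sp_fit"
  )
}

#' @export
print.sp_fit <- function(x, ...) {
  sel <- dplyr::filter(x$abundances, .data$selected)
  cat(sprintf(
    "<sp_fit> %s mode: %d candidate(s), %d selected (threshold %.3g), residual %.4g\n",
    x$mode, nrow(x$abundances), nrow(sel), x$threshold, x$residual
  ))
  if (nrow(sel) > 0) {
    print(dplyr::arrange(sel[, c("id", "abundance")], dplyr::desc(.data$abundance)))
  }
  invisible(x)
}

#' Tidy a structure-abundance fit
#'
#' @param x an `sp_fit`.
#' @param ... unused.
#' @return one row per candidate structure: raw NNLS coefficient (`rho`),
#'   its normalized value, the selection flag and the renormalized abundance
#'   of selected structures (plus the dot-bracket when candidates were
#'   attached).
#' @method tidy sp_fit
#' @export
tidy.sp_fit <- function(x, ...) {
  out <- x$abundances
  if (!is.null(x$candidates)) {
    out <- dplyr::left_join(
      out, as_tibble(x$candidates)[, c("id", "dotbracket", "source")],
      by = "id"
    )
  }
  out
}

#' @rdname tidy.sp_fit
#' @method glance sp_fit
#' @export
glance.sp_fit <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$abundances),
    n_selected = sum(x$abundances$selected),
    residual = x$residual,
    threshold = x$threshold,
    eta = x$eta,
    mode = x$mode,
    min_captured_mass = min(x$diagnostics$captured_mass),
    n_reads = x$diagnostics$n_reads
  )
}

#' Selected structures with their final abundances
#'
#' @param fit an `sp_fit` carrying its candidate set.
#' @return a tibble of selected structures (id, dot-bracket, abundance),
#'   sorted by decreasing abundance.
#' @export
selected_structures <- function(fit) {
  if (is.null(fit$candidates)) abort("fit carries no candidate set")
  sel <- dplyr::filter(tidy(fit), .data$selected)
  dplyr::arrange(
    sel[, c("id", "dotbracket", "abundance", "source")],
    dplyr::desc(.data$abundance)
  )
}

#' Model-implied ideal reactivity profile
#'
#' The reactivity profile the selected ensemble would produce under the
#' generative model: `beta_l = eta * sum_s rho_s [l unconstrained in s]`.
#' Comparing it with the measured profile flags regions where the candidate
#' set may miss a key structure.
#'
#' @param fit an `sp_fit` carrying its candidate set.
#' @return numeric vector of length L (model coordinates).
#' @export
ideal_profile <- function(fit) {
  if (is.null(fit$candidates)) abort("fit carries no candidate set")
  ab <- fit$abundances
  sel <- which(ab$selected)
  if (length(sel) == 0) return(rep(0, cs_L(fit$candidates)))
  cands <- as_tibble(fit$candidates)
  states <- do.call(cbind, cands$state[match(ab$id[sel], cands$id)])
  as.numeric(fit$eta * ((1 - states) %*% ab$abundance[sel]))
}

#' Write a fit result to JSON
#'
#' Per selected structure: id, dot-bracket (5'->3') and abundance, plus the
#' residual, threshold and diagnostics.
#'
#' @param fit an `sp_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  sel <- selected_structures(fit)
  jsonlite::write_json(
    list(
      mode = fit$mode,
      eta = fit$eta,
      threshold = fit$threshold,
      residual = fit$residual,
      selected = lapply(seq_len(nrow(sel)), function(k) {
        list(
          id = sel$id[k], dotbracket = sel$dotbracket[k],
          abundance = sel$abundance[k]
        )
      }),
      diagnostics = list(
        dropped = as.list(fit$diagnostics$dropped),
        merged_groups = fit$diagnostics$merged_groups,
        min_captured_mass = min(fit$diagnostics$captured_mass),
        n_reads = fit$diagnostics$n_reads
      )
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
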