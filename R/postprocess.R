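# Ensemble summaries: pairing probabilities, base-pairing Shannon entropy,
# trajectory smoothing, motif-based clusters, and the structure-function fit.

#' Abundance-weighted pairing probabilities
#'
#' For a reconstructed ensemble, `P[i, j]` is the probability that sites i
#' and j are paired and the diagonal `P[i, i]` the probability that site i
#' is unpaired; each row is a probability distribution over the pairing
#' outcomes of its site. Indices are 5'->3'.
#'
#' @param selected a [candidate_set()] (or list of [rna_structure()]) of the
#'   selected structures.
#' @param abundances abundance vector summing to 1 (tolerance `1e-8`).
#' @return an `sp_ensemble` object: the `L x L` pairing matrix plus the
#'   per-site entropy profile (bits) and its mean.
#' @export
pairing_probabilities <- function(selected, abundances) {
  if (inherits(selected, "candidate_set")) {
    L <- cs_L(selected)
    pair_list <- selected$pairs
  } else {
    if (inherits(selected, "rna_structure")) selected <- list(selected)
    L <- selected[[1]]$L
    pair_list <- lapply(selected, function(s) s$pairs)
  }
  if (length(pair_list) != length(abundances)) {
    abort("one abundance per structure is required")
  }
  if (abs(sum(abundances) - 1) > 1e-8) {
    abort("abundances must sum to 1 (renormalize the selected structures first)")
  }
  P <- matrix(0, L, L)
  unpaired <- rep(0, L)
  for (k in seq_along(pair_list)) {
    pr <- pair_list[[k]]
    disp <- flip_pairs(pr, L) # display coordinates
    for (m in seq_len(nrow(disp))) {
      i <- disp[m, 1]; j <- disp[m, 2]
      P[i, j] <- P[i, j] + abundances[k]
      P[j, i] <- P[j, i] + abundances[k]
    }
    up <- setdiff(seq_len(L), as.vector(disp))
    unpaired[up] <- unpaired[up] + abundances[k]
  }
  diag(P) <- unpaired
  H <- entropy_profile(P)
  structure(
    list(
      pairing = P, entropy = H, mean_entropy = mean(H), L = L,
      n_structures = length(pair_list)
    ),
    class = "sp_ensemble"
  )
}

#' Per-site base-pairing Shannon entropy
#'
#' `H_i = -sum_j P_ij log2(P_ij)` with `0 log 0 := 0`, over each site's
#' pairing-outcome distribution (partners plus the unpaired outcome on the
#' diagonal).
#'
#' @param pairing row-stochastic pairing matrix (or an `sp_ensemble`).
#' @return numeric vector of entropies in bits.
#' @export
entropy_profile <- function(pairing) {
  if (inherits(pairing, "sp_ensemble")) pairing <- pairing$pairing
  if (any(pairing < 0)) abort("pairing probabilities must be non-negative")
  apply(pairing, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
}

#' Ensemble summary of a fit
#'
#' @param fit an `sp_fit` carrying its candidate set.
#' @return an `sp_ensemble`; see [pairing_probabilities()].
#' @export
ensemble_summary <- function(fit) {
  if (is.null(fit$candidates)) abort("fit carries no candidate set")
  ab <- fit$abundances
  sel <- which(ab$selected)
  if (length(sel) == 0) abort("no structures selected; nothing to summarize")
  cands <- fit$candidates
  idx <- match(ab$id[sel], cands$id)
  sub <- new_candidate_set(
    as_tibble(cands)[idx, , drop = FALSE],
    cs_sequence(cands), cs_region(cands), cs_informative(cands)
  )
  pairing_probabilities(sub, ab$abundance[sel])
}

#' @export
print.sp_ensemble <- function(x, ...) {
  cat(sprintf(
    "<sp_ensemble> %d structure(s), %d nt, mean pairing entropy %.4g bit(s)\n",
    x$n_structures, x$L, x$mean_entropy
  ))
  invisible(x)
}

#' @rdname pairing_probabilities
#' @param x an `sp_ensemble`.
#' @param ... unused.
#' @return `tidy()`: long tibble (`i`, `j`, `p`) of non-zero pairing
#'   probabilities (diagonal rows carry the unpaired probability);
#'   `glance()`: one row with the mean entropy.
#' @method tidy sp_ensemble
#' @export
tidy.sp_ensemble <- function(x, ...) {
  nz <- which(x$pairing > 0 & upper.tri(x$pairing, diag = TRUE), arr.ind = TRUE)
  tibble(
    i = as.integer(nz[, 1]), j = as.integer(nz[, 2]),
    p = x$pairing[nz]
  )
}

#' @rdname pairing_probabilities
#' @method glance sp_ensemble
#' @export
glance.sp_ensemble <- function(x, ...) {
  tibble(
    n_structures = x$n_structures, L = x$L,
    mean_entropy = x$mean_entropy, max_entropy = max(x$entropy)
  )
}

#' Write pairing probabilities as a 3-column TSV
#'
#' Columns `i`, `j`, `p` in 5'->3' indices; rows with `i == j` carry the
#' unpaired probability.
#'
#' @param ensemble an `sp_ensemble`.
#' @param path output path.
#' @export
write_pairing_tsv <- function(ensemble, path) {
  df <- tidy(ensemble)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean-filter smoothing of a trajectory
#'
#' Centered moving mean of odd window size; at the boundaries the window
#' shrinks to the available neighbors (default) or, with
#' `edges = "valid"`, boundary values are returned unsmoothed as `NA`.
#'
#' @param series numeric vector.
#' @param window odd window size (default 3).
#' @param edges `"shrink"` or `"valid"`.
#' @return smoothed vector of the same length.
#' @export
#' @examples
#' smooth_series(c(0, 3, 0)) # middle value becomes 1
smooth_series <- function(series, window = 3, edges = c("shrink", "valid")) {
  edges <- match.arg(edges)
  if (window %% 2 != 1 || window < 1) abort("`window` must be odd and positive")
  half <- (window - 1) / 2
  n <- length(series)
  out <- vapply(seq_len(n), function(i) {
    lo <- i - half; hi <- i + half
    if (edges == "valid" && (lo < 1 || hi > n)) return(NA_real_)
    mean(series[max(1, lo):min(n, hi)])
  }, numeric(1))
  out
}

#' Motif-based cluster abundances across conditions
#'
#' Assigns each selected structure of each fit to the first motif cluster
#' (in declared priority order) whose base pairs it contains, or to
#' `"OTHER"`, and sums abundances per cluster.
#'
#' @param fits named list of `sp_fit` objects (names identify the
#'   condition / transcript length), or a tibble with columns `condition`
#'   and `fit` (list-column).
#' @param motifs named list of motif specifications, each a list with
#'   elements `pairs` (two-column 5'->3' matrix) and optionally
#'   `min_fraction` (default 1). Order = priority: a structure matching
#'   several motifs is assigned to the first.
#' @return tibble with columns `condition`, `cluster`, `abundance`;
#'   abundances sum to 1 per condition.
#' @export
cluster_abundances <- function(fits, motifs) {
  if (is.data.frame(fits)) {
    conditions <- fits$condition
    fit_list <- fits$fit
  } else {
    if (is.null(names(fits))) abort("`fits` must be named by condition")
    conditions <- names(fits)
    fit_list <- fits
  }
  if (length(motifs) > 0 && is.null(names(motifs))) {
    abort("motifs must be named; names define cluster labels and priority")
  }
  clusters <- c(names(motifs), "OTHER")
  purrr::map2_dfr(conditions, fit_list, function(cond, fit) {
    sel <- dplyr::filter(fit$abundances, .data$selected)
    cands <- fit$candidates
    if (is.null(cands)) abort("each fit must carry its candidate set")
    idx <- match(sel$id, cands$id)
    assigned <- vapply(seq_along(idx), function(k) {
      s <- cs_structure(cands, idx[k])
      for (m in names(motifs)) {
        spec <- motifs[[m]]
        if (motif_contains(s, spec$pairs, spec$min_fraction %||% 1)) return(m)
      }
      "OTHER"
    }, character(1))
    ab <- vapply(
      clusters, function(cl) sum(sel$abundance[assigned == cl]),
      numeric(1)
    )
    tibble(condition = cond, cluster = clusters, abundance = unname(ab))
  })
}

#' Link cluster abundances to functional readout
#'
#' Fits `level = alpha * ON + beta * DEF_OFF` with non-negative
#' coefficients and reports the normalized relative contributions
#' `alpha / (alpha + beta)` and `beta / (alpha + beta)`.
#'
#' @param abundance_on,abundance_def_off cluster abundance vectors over the
#'   observations (e.g. mutants).
#' @param levels measured functional readout (e.g. reporter protein levels).
#' @return an `sp_function_fit` with elements `alpha`, `beta`,
#'   `contributions`, `fitted`, `residual`.
#' @export
fit_function_model <- function(abundance_on, abundance_def_off, levels) {
  n <- length(levels)
  if (n < 2) abort("at least two observations are required")
  stopifnot(length(abundance_on) == n, length(abundance_def_off) == n)
  D <- cbind(on = abundance_on, def_off = abundance_def_off)
  if (qr(D)$rank < 2) abort("rank-deficient design: the two cluster trajectories are collinear")
  sol <- pracma::lsqnonneg(D, levels)
  coefs <- pmax(sol$x, 0)
  if (sum(coefs) == 0) abort("both coefficients are zero; levels carry no signal")
  fitted <- as.numeric(D %*% coefs)
  structure(
    list(
      alpha = coefs[1], beta = coefs[2],
      contributions = coefs / sum(coefs),
      fitted = fitted,
      residual = sqrt(sum((levels - fitted)^2)),
      n = n
    ),
    class = "sp_function_fit"
  )
}

#' @export
print.sp_function_fit <- function(x, ...) {
  cat(sprintf(
    "<sp_function_fit> alpha = %.4g, beta = %.4g; relative contributions %.2f / %.2f\n",
    x$alpha, x$beta, x$contributions[1], x$contributions[2]
  ))
  invisible(x)
}

#' @rdname fit_function_model
#' @param x an `sp_function_fit`.
#' @param ... unused.
#' @method tidy sp_function_fit
#' @export
tidy.sp_function_fit <- function(x, ...) {
  tibble(
    term = c("on", "def_off"),
    estimate = c(x$alpha, x$beta),
    contribution = as.numeric(x$contributions)
  )
}

#' @rdname fit_function_model
#' @method glance sp_function_fit
#' @export
glance.sp_function_fit <- function(x, ...) {
  tibble(residual = x$residual, n = x$n)
}

#' Mean pairing entropy across transcript lengths
#'
#' Computes the mean per-site base-pairing entropy of each fit and smooths
#' the trajectory with a mean filter (window 3 by default). Mean per-site
#' entropy is used -- rather than a joint structural entropy -- so that
#' ensembles over transcripts of different lengths remain comparable.
#'
#' @param fits named list of `sp_fit` objects or tibble with `condition` and
#'   `fit` columns (see [cluster_abundances()]).
#' @param window smoothing window; 1 disables smoothing.
#' @return tibble with `condition`, `mean_entropy`, `smoothed`.
#' @export
entropy_trajectory <- function(fits, window = 3) {
  if (is.data.frame(fits)) {
    conditions <- fits$condition
    fit_list <- fits$fit
  } else {
    conditions <- names(fits)
    fit_list <- fits
  }
  h <- vapply(
    fit_list, function(f) ensemble_summary(f)$mean_entropy,
    numeric(1)
  )
  tibble(
    condition = conditions,
    mean_entropy = unname(h),
    smoothed = if (window > 1) smooth_series(unname(h), window) else unname(h)
  )
}
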