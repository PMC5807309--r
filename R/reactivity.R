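# Closed-form reactivity and noise estimation.
#
# With X_l / C_l+ the event count and local coverage at site l in the
# treated sample and Y_l / C_l- their control counterparts, the
# maximum-likelihood estimates are
#
#   gamma_l = Y_l / C_l-          (per-site noise)
#   beta_l  = (X_l / C_l+ - gamma_l) / (1 - gamma_l)   (reactivity)
#
# and the unconstrained-site modification probability eta is estimated from
# the beta profile as the median of the values strictly exceeding their mean
# (high-reactivity sites are expected to be predominantly unpaired in the
# ensemble; the median confers robustness to outliers).

#' Estimate per-site noise from a control sample
#'
#' @param control a control `count_profile` (see [site_counts()]), or `NULL`
#'   when no control was run (all noise set to 0, with a message).
#' @param L transcript length, required only when `control` is `NULL`.
#' @return numeric vector of noise probabilities, model coordinates.
#' @export
estimate_gamma <- function(control, L = NULL) {
  if (is.null(control)) {
    if (is.null(L)) abort("`L` is required when no control sample is given")
    inform("no control sample: noise levels cannot be estimated, setting gamma to 0")
    return(rep(0, L))
  }
  if (any(control$events > control$coverage)) {
    abort("control events exceed local coverage; corrupt count profile")
  }
  gamma <- rep(0, nrow(control))
  covered <- control$coverage > 0
  gamma[covered] <- control$events[covered] / control$coverage[covered]
  if (any(!covered)) {
    warn(sprintf(
      "%d site(s) with zero control coverage; their noise set to 0",
      sum(!covered)
    ))
  }
  gamma[order(control$site)]
}

#' Estimate per-site reactivities
#'
#' @param treated a treated-sample `count_profile`.
#' @param gamma per-site noise vector (model coordinates), e.g. from
#'   [estimate_gamma()].
#' @return tibble with columns `site`, `beta`, `gamma`, `clamped` and
#'   `missing` (zero-coverage sites, `beta = NA`); the number of negative
#'   estimates clamped to 0 is attached as `attr(, "n_clamped")` -- a
#'   data-quality signal.
#' @export
estimate_beta <- function(treated, gamma) {
  L <- nrow(treated)
  stopifnot(length(gamma) == L)
  if (any(gamma >= 1)) abort("noise estimates must be < 1")
  ord <- order(treated$site)
  events <- treated$events[ord]; coverage <- treated$coverage[ord]
  rate <- rep(NA_real_, L)
  covered <- coverage > 0
  rate[covered] <- events[covered] / coverage[covered]
  beta <- (rate - gamma) / (1 - gamma)
  clamped_lo <- !is.na(beta) & beta < 0
  clamped_hi <- !is.na(beta) & beta > 1
  beta[clamped_lo] <- 0
  beta[clamped_hi] <- 1
  out <- tibble(
    site = seq_len(L), beta = beta, gamma = gamma,
    clamped = clamped_lo | clamped_hi, missing = !covered
  )
  attr(out, "n_clamped") <- sum(clamped_lo | clamped_hi)
  out
}

#' Estimate the unconstrained-site modification probability
#'
#' Sorting the reactivities from high to low, eta is the median of those
#' strictly exceeding their mean. When no value exceeds the mean (a constant
#' profile) the maximum is returned with a warning.
#'
#' @param beta reactivity vector; `NA` entries (missing sites) are ignored.
#'   For base-selective chemistries pass reactivities at informative sites
#'   only.
#' @return scalar eta estimate.
#' @export
#' @examples
#' estimate_eta(c(0.30, 0.28, 0.02, 0)) # median of {0.30, 0.28}
estimate_eta <- function(beta) {
  beta <- beta[!is.na(beta)]
  if (length(beta) == 0 || all(beta <= 0)) {
    abort("no signal: all reactivities are zero")
  }
  high <- beta[beta > mean(beta)]
  if (length(high) == 0) {
    warn("no reactivity strictly exceeds the mean; falling back to max(beta)")
    return(max(beta))
  }
  median(high)
}

#' Full reactivity profile estimation
#'
#' Convenience wrapper running [estimate_gamma()], [estimate_beta()] and
#' [estimate_eta()]; eta is estimated over informative sites only.
#'
#' @param treated treated-sample `count_profile`.
#' @param control optional control `count_profile`.
#' @return a `reactivity_profile` tibble (columns as [estimate_beta()]) with
#'   attributes `eta`, `mode` and `n_clamped`.
#' @export
estimate_reactivity <- function(treated, control = NULL) {
  L <- nrow(treated)
  gamma <- estimate_gamma(control, L = L)
  prof <- estimate_beta(treated, gamma)
  informative <- attr(treated, "informative", exact = TRUE) %||% seq_len(L)
  eta <- estimate_eta(prof$beta[prof$site %in% informative])
  structure(
    prof,
    eta = eta,
    mode = attr(treated, "mode", exact = TRUE),
    informative = informative,
    class = c("reactivity_profile", class(prof))
  )
}

#' 2-8 % reactivity normalization (display only)
#'
#' Excludes the top 2 % of values as outliers and divides the whole vector
#' by the mean of the next 8 %. A monotone rescaling used for plotting and
#' cross-sample comparison; never used inside the model.
#'
#' @param reactivities numeric vector, length at least 13 (shorter vectors
#'   make the percentile rule meaningless).
#' @return the rescaled vector.
#' @export
normalize_2_8 <- function(reactivities) {
  ok <- !is.na(reactivities)
  n <- sum(ok)
  if (n < 13) abort("2-8% normalization needs at least 13 finite values")
  srt <- sort(reactivities[ok], decreasing = TRUE)
  k_out <- ceiling(0.02 * n)
  k_norm <- ceiling(0.08 * n)
  denom <- mean(srt[(k_out + 1):(k_out + k_norm)])
  if (!is.finite(denom) || denom <= 0) {
    abort("normalizer is not positive; the profile carries no signal")
  }
  reactivities / denom
}

#' Write a reactivity profile to TSV (+ JSON sidecar)
#'
#' Sites are written 5'->3'; `eta` and the mode tag go to a small JSON
#' sidecar at `paste0(path, ".json")`.
#'
#' @param profile a `reactivity_profile` from [estimate_reactivity()].
#' @param path TSV path.
#' @export
write_reactivity_tsv <- function(profile, path) {
  L <- nrow(profile)
  df <- data.frame(
    site = flip_sites(profile$site, L),
    beta = profile$beta, gamma = profile$gamma,
    clamped = as.integer(profile$clamped)
  )
  df <- df[order(df$site), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(
      eta = attr(profile, "eta", exact = TRUE),
      mode = attr(profile, "mode", exact = TRUE),
      n_clamped = attr(profile, "n_clamped", exact = TRUE)
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
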