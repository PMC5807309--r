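# End-to-end orchestration: bin -> estimate gamma/beta/eta -> prefilter ->
# design -> NNLS fit -> selection, plus the YAML run configuration consumed
# by the command-line wrapper (inst/cli/spdeconv.R).

#' Deconvolve a structure ensemble from pattern counts
#'
#' Runs the full inference chain: per-site counts and coverages, closed-form
#' noise/reactivity estimation, eta estimation, candidate pre-filtering,
#' design-matrix construction and the non-negative least-squares fit.
#'
#' @param pc observed `pattern_counts` (treated sample).
#' @param candidates a [candidate_set()].
#' @param control optional control-sample `pattern_counts` for noise
#'   estimation; without it gamma is set to 0.
#' @param threshold abundance selection threshold (default 1 %).
#' @param prefilter drop candidates contradicting highly reactive sites
#'   before fitting (default `TRUE`).
#' @param eta override the estimated unconstrained-site modification
#'   probability (e.g. a literature value); `NULL` estimates it from the
#'   reactivity profile.
#' @return an `sp_fit` with the reactivity profile attached as
#'   `$reactivity`.
#' @export
#' @examples
#' cands <- parse_dotbracket(c("((((....))))........", "........((((....))))"),
#'   sequence = paste(rep("ACGU", 5), collapse = "")
#' )
#' truth <- ground_truth(cands, c(0.7, 0.3), eta = 0.2, mode = "truncation")
#' pc <- draw_reads(pattern_distribution(truth), 5e4, seed = 1)
#' fit <- deconvolve(pc, cands)
#' tidy(fit)
deconvolve <- function(pc, candidates, control = NULL, threshold = 0.01,
                       prefilter = TRUE, eta = NULL) {
  if (!is.null(cs_informative(candidates)) && is.null(pc_informative(pc))) {
    attr(pc, "informative") <- cs_informative(candidates)
  }
  treated <- site_counts(pc, "treated")
  control_profile <- if (is.null(control)) NULL else site_counts(control, "control")
  profile <- estimate_reactivity(treated, control_profile)
  eta_hat <- eta %||% attr(profile, "eta", exact = TRUE)
  gamma_hat <- profile$gamma[order(profile$site)]
  cands <- if (isTRUE(prefilter)) {
    prefilter(candidates, profile, eta_hat)
  } else {
    candidates
  }
  if (nrow(cands) == 0) abort("prefilter removed every candidate; relax it or check eta")
  design <- if (pc_mode(pc) == "truncation") {
    build_design_truncation(cands, eta_hat, gamma_hat)
  } else {
    build_design_mutation(cands, eta_hat, gamma_hat, pc)
  }
  fit <- fit_abundances(design, pc, threshold = threshold, candidates = cands)
  fit$reactivity <- profile
  fit$diagnostics$prefilter_removed <- attr(cands, "removed", exact = TRUE)
  fit
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `mode`, `chemistry`, `structures` (Vienna/dbn path),
#' `treated`, `control` (pattern TSV paths), `length`, `region`
#' (`[start, end]`, 5'->3'), `threshold`, `seed`, `outdir`. Command-line
#' flags of the bundled CLI mirror these keys one-to-one.
#'
#' @param path YAML file.
#' @param overrides named list overriding config values.
#' @return a `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  config <- if (is.null(path)) list() else yaml::read_yaml(path)
  config <- modifyList(config, overrides[!vapply(overrides, is.null, logical(1))])
  defaults <- list(
    mode = "truncation", chemistry = "shape", control = NULL,
    region = NULL, threshold = 0.01, seed = 1L, outdir = "."
  )
  config <- modifyList(defaults, config)
  if (!config$mode %in% c("truncation", "mutation")) {
    abort("config: mode must be 'truncation' or 'mutation'")
  }
  if (!config$chemistry %in% c("shape", "dms")) {
    abort("config: chemistry must be 'shape' or 'dms'")
  }
  if (config$threshold < 0 || config$threshold >= 1) {
    abort("config: threshold must lie in [0, 1)")
  }
  structure(config, class = "run_config")
}

#' Run a configured deconvolution and write result files
#'
#' Reads the candidate structures and pattern TSVs named in the config,
#' runs [deconvolve()], and writes `result.json`, `reactivity.tsv`,
#' `pairing.tsv` and a provenance log (`run.json`: config hash, seed,
#' package version) into the output directory.
#'
#' @param config a `run_config` from [read_run_config()].
#' @return the `sp_fit`, invisibly.
#' @export
run_deconvolution <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cands <- read_vienna(
    config$structures,
    region = config$region, chemistry = config$chemistry
  )
  L <- cs_L(cands)
  informative_disp <- flip_sites(cs_informative(cands), L)
  pc <- read_pattern_tsv(config$treated, config$mode, L, informative = informative_disp)
  control <- if (is.null(config$control)) {
    NULL
  } else {
    read_pattern_tsv(config$control, config$mode, L, informative = informative_disp)
  }
  cands <- dedup(cands)
  fit <- deconvolve(pc, cands, control = control, threshold = config$threshold)
  write_fit_json(fit, file.path(config$outdir, "result.json"))
  write_reactivity_tsv(fit$reactivity, file.path(config$outdir, "reactivity.tsv"))
  if (any(fit$abundances$selected)) {
    write_pairing_tsv(ensemble_summary(fit), file.path(config$outdir, "pairing.tsv"))
  }
  write_provenance(config, file.path(config$outdir, "run.json"))
  invisible(fit)
}

# machine-readable provenance sufficient to reproduce a run bit-exactly
write_provenance <- function(config, path) {
  jsonlite::write_json(
    list(
      config = unclass(config),
      config_hash = rlang::hash(unclass(config)),
      seed = config$seed,
      package = "spdeconv",
      package_version = as.character(utils::packageVersion("spdeconv")),
      r_version = as.character(getRversion())
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}
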