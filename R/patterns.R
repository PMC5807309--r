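# Binning reads into modification patterns.
#
# A pattern is the modification signature of one read: in truncation mode a
# single stop index p in 1..L (model coordinates, counted from the priming
# site) or p = L + 1 for a complete read; in mutation mode the (possibly
# empty) set of mutated informative sites. Pattern counts are the observation
# vector y of the linear model once converted to frequencies.

new_pattern_counts <- function(df, mode, L, informative = NULL) {
  structure(
    df,
    mode = mode, L = as.integer(L), informative = informative,
    class = c("pattern_counts", class(tibble()))
  )
}

pc_mode <- function(pc) attr(pc, "mode", exact = TRUE)
pc_L <- function(pc) attr(pc, "L", exact = TRUE)
pc_informative <- function(pc) attr(pc, "informative", exact = TRUE)

#' Total read count of a pattern table
#' @param pc a `pattern_counts` object.
#' @export
total_reads <- function(pc) sum(pc$count)

#' Pattern frequencies (the observation vector y)
#'
#' @param pc a `pattern_counts` object.
#' @return the table with a `freq` column; frequencies sum to 1 exactly over
#'   the included patterns.
#' @export
pattern_frequencies <- function(pc) {
  n <- total_reads(pc)
  if (n == 0) abort("pattern table contains no reads")
  dplyr::mutate(pc, freq = .data$count / n)
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat(sprintf(
    "# pattern_counts: %s mode, %d pattern(s), %d read(s), L = %d\n",
    pc_mode(x), nrow(x), total_reads(x), pc_L(x)
  ))
  NextMethod()
}

#' Bin truncation-mode reads into stop patterns
#'
#' @param read_stops integer vector of per-read stop indices in model
#'   coordinates (1..L counted from the priming site), with `L + 1` marking a
#'   complete read.
#' @param L transcript length.
#' @param informative optional internal informative-site indices (set when
#'   the stops derive from projected base-selective data); `NULL` means all
#'   sites are assayable.
#' @return a `pattern_counts` tibble with columns `stop`, `count`.
#' @export
#' @examples
#' bin_truncation(c(1, 1, 3, 4), L = 3)
bin_truncation <- function(read_stops, L, informative = NULL) {
  if (length(read_stops) == 0) abort("no reads to bin")
  read_stops <- as.integer(read_stops)
  if (any(read_stops < 1 | read_stops > L + 1)) {
    abort(sprintf("stop indices must lie in 1..%d (L + 1 = complete read)", L + 1))
  }
  tab <- table(read_stops)
  df <- tibble(
    stop = as.integer(names(tab)),
    count = as.integer(tab)
  )
  new_pattern_counts(df[order(df$stop), ], "truncation", L, informative)
}

#' Bin mutation-mode reads into mutated-site-set patterns
#'
#' @param read_mutation_sets list with one integer vector per read: the
#'   mutated site indices in model coordinates (empty vector = unmutated
#'   read). Sites must belong to `informative`.
#' @param informative internal informative-site indices of the chemistry.
#' @param L transcript length.
#' @return a `pattern_counts` tibble with list-column `sites` and `count`;
#'   the empty (no-mutation) pattern is always present.
#' @export
bin_mutation <- function(read_mutation_sets, informative, L) {
  if (length(read_mutation_sets) == 0) abort("no reads to bin")
  informative <- sort(as.integer(informative))
  keys <- vapply(read_mutation_sets, function(s) {
    s <- as.integer(s)
    if (length(s) > 0 && !all(s %in% informative)) {
      abort(paste0(
        "read reports a mutation outside the informative sites (",
        sites_key(setdiff(s, informative)),
        "); check the declared chemistry"
      ))
    }
    if (length(s) == 0) "none" else sites_key(s)
  }, character(1))
  tab <- table(keys)
  all_keys <- union("none", names(tab)) # empty pattern always present
  counts <- as.integer(tab[all_keys])
  counts[is.na(counts)] <- 0L
  df <- tibble(
    sites = lapply(all_keys, function(k) {
      if (k == "none") integer(0) else as.integer(strsplit(k, ",")[[1]])
    }),
    count = counts
  )
  ord <- order(lengths(df$sites), vapply(df$sites, sites_key, character(1)))
  new_pattern_counts(df[ord, ], "mutation", L, informative)
}

#' Project mutation patterns onto truncation patterns
#'
#' Recording only the first modification of each read (the one closest to
#' the priming site, i.e. the minimum model-coordinate index) maps mutation
#' data onto the singleton patterns a truncation experiment would produce;
#' unmutated reads map to the complete-read pattern. The projection conserves
#' the total read count and is irreversible.
#'
#' @param pc a mutation-mode `pattern_counts`.
#' @return a truncation-mode `pattern_counts`.
#' @export
project_mutation_to_truncation <- function(pc) {
  if (pc_mode(pc) != "mutation") {
    abort("projection applies to mutation-mode pattern counts only")
  }
  L <- pc_L(pc)
  stops <- vapply(pc$sites, function(s) {
    if (length(s) == 0) L + 1L else min(s)
  }, integer(1))
  agg <- rowsum(pc$count, stops)
  df <- tibble(stop = as.integer(rownames(agg)), count = as.integer(agg[, 1]))
  new_pattern_counts(df[order(df$stop), ], "truncation", L, pc_informative(pc))
}

#' Per-site event counts and local coverages
#'
#' In truncation mode the events at site l are the reads stopping there and
#' the local coverage is the number of reads that stop at or read through l
#' (complete reads pass through every site). In mutation mode (full-overlap
#' reads) events are reads mutated at l and every read covers every site.
#'
#' @param pc a `pattern_counts` object.
#' @param sample sample tag, `"treated"` or `"control"`.
#' @return a `count_profile` tibble with columns `site` (model coordinates),
#'   `events`, `coverage`.
#' @export
site_counts <- function(pc, sample = c("treated", "control")) {
  sample <- match.arg(sample)
  L <- pc_L(pc)
  events <- integer(L)
  if (pc_mode(pc) == "truncation") {
    internal <- pc$stop <= L
    if (any(internal)) {
      agg <- rowsum(pc$count[internal], pc$stop[internal])
      events[as.integer(rownames(agg))] <- as.integer(agg[, 1])
    }
    # reads with stop index >= l either stop at or pass through l
    coverage <- as.integer(
      rev(cumsum(rev(events))) + sum(pc$count[pc$stop == L + 1L])
    )
  } else {
    for (k in seq_len(nrow(pc))) {
      s <- pc$sites[[k]]
      events[s] <- events[s] + pc$count[k]
    }
    coverage <- rep(total_reads(pc), L)
  }
  structure(
    tibble(site = seq_len(L), events = events, coverage = coverage),
    mode = pc_mode(pc), sample = sample, L = L,
    informative = pc_informative(pc),
    class = c("count_profile", class(tibble()))
  )
}

#' Distribution of modifications per read
#'
#' @param pc a mutation-mode `pattern_counts`.
#' @return tibble with columns `n_mutations`, `count`, `fraction`; the mean
#'   modification load per read is attached as `attr(, "mean")`.
#' @export
mutation_load <- function(pc) {
  if (pc_mode(pc) != "mutation") abort("mutation_load() needs mutation-mode data")
  n <- lengths(pc$sites)
  agg <- rowsum(pc$count, n)
  out <- tibble(
    n_mutations = as.integer(rownames(agg)),
    count = as.integer(agg[, 1])
  )
  out$fraction <- out$count / sum(out$count)
  attr(out, "mean") <- sum(out$n_mutations * out$fraction)
  out
}

# ---------------------------------------------------------------------------
# Pattern and count-profile TSV I/O (5'->3' display coordinates)

key_from_stop <- function(stop, L) {
  ifelse(stop == L + 1L, "full", as.character(L + 1L - stop))
}

key_from_sites <- function(sites_list, L) {
  vapply(sites_list, function(s) {
    if (length(s) == 0) "none" else paste(sort(flip_sites(s, L)), collapse = ",")
  }, character(1))
}

#' Read and write pattern tables as TSV
#'
#' Files carry two columns: `pattern` (comma-separated 5'->3' site indices;
#' `full` for a complete truncation-mode read, `none` for an unmutated
#' mutation-mode read) and `count`. Round-trips are bit-exact.
#'
#' @param pc a `pattern_counts` object.
#' @param path file path.
#' @export
write_pattern_tsv <- function(pc, path) {
  key <- if (pc_mode(pc) == "truncation") {
    key_from_stop(pc$stop, pc_L(pc))
  } else {
    key_from_sites(pc$sites, pc_L(pc))
  }
  utils::write.table(
    data.frame(pattern = key, count = pc$count),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_pattern_tsv
#' @param mode `"truncation"` or `"mutation"`.
#' @param L transcript length.
#' @param informative optional 5'->3' informative site indices (defaults to
#'   all sites).
#' @export
read_pattern_tsv <- function(path, mode = c("truncation", "mutation"), L,
                             informative = NULL) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, colClasses = c("character", "integer"))
  informative_int <- if (is.null(informative)) NULL else sort(flip_sites(informative, L))
  if (mode == "truncation") {
    stop <- rep(L + 1L, nrow(df))
    internal <- df$pattern != "full"
    disp <- suppressWarnings(as.integer(df$pattern[internal]))
    if (anyNA(disp) || any(disp < 1) || any(disp > L)) {
      abort("malformed truncation pattern key")
    }
    stop[internal] <- flip_sites(disp, L)
    out <- tibble(stop = as.integer(stop), count = df$count)
    new_pattern_counts(out[order(out$stop), ], "truncation", L, informative_int)
  } else {
    sites <- lapply(df$pattern, function(k) {
      if (k == "none") integer(0) else sort(flip_sites(as.integer(strsplit(k, ",")[[1]]), L))
    })
    out <- tibble(sites = sites, count = df$count)
    if (!any(lengths(out$sites) == 0)) {
      out <- dplyr::bind_rows(tibble(sites = list(integer(0)), count = 0L), out)
    }
    new_pattern_counts(out, "mutation", L, informative_int)
  }
}

#' Read per-read modification records and bin them
#'
#' The TSV has one row per read with a single `sites` column holding the
#' pattern key of that read (same dialect as [write_pattern_tsv()]).
#'
#' @inheritParams read_pattern_tsv
#' @export
read_reads_tsv <- function(path, mode = c("truncation", "mutation"), L,
                           informative = NULL) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, colClasses = "character")
  informative_int <- if (is.null(informative)) {
    if (mode == "mutation") seq_len(L) else NULL
  } else {
    sort(flip_sites(informative, L))
  }
  if (mode == "truncation") {
    stops <- rep(L + 1L, nrow(df))
    internal <- df$sites != "full"
    disp <- suppressWarnings(as.integer(df$sites[internal]))
    if (anyNA(disp) || any(disp < 1) || any(disp > L)) {
      abort("malformed per-read stop record")
    }
    stops[internal] <- flip_sites(disp, L)
    bin_truncation(stops, L, informative_int)
  } else {
    sets <- lapply(df$sites, function(k) {
      if (k == "none") integer(0) else sort(flip_sites(as.integer(strsplit(k, ",")[[1]]), L))
    })
    bin_mutation(sets, informative_int, L)
  }
}

#' Read and write per-site count profiles as TSV
#'
#' Columns `site` (5'->3'), `events`, `coverage`; round-trips are bit-exact.
#'
#' @param profile a `count_profile` tibble.
#' @param path file path.
#' @export
write_count_profile_tsv <- function(profile, path) {
  L <- attr(profile, "L", exact = TRUE)
  df <- data.frame(
    site = flip_sites(profile$site, L),
    events = profile$events, coverage = profile$coverage
  )
  df <- df[order(df$site), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_profile_tsv
#' @param mode,sample,informative metadata tags restored on read.
#' @export
read_count_profile_tsv <- function(path, mode = c("truncation", "mutation"),
                                   sample = c("treated", "control"),
                                   informative = NULL) {
  mode <- match.arg(mode); sample <- match.arg(sample)
  df <- utils::read.delim(path)
  L <- nrow(df)
  out <- tibble(
    site = flip_sites(df$site, L),
    events = as.integer(df$events),
    coverage = as.integer(df$coverage)
  )
  out <- out[order(out$site), ]
  structure(
    out,
    mode = mode, sample = sample, L = L,
    informative = if (is.null(informative)) NULL else sort(flip_sites(informative, L)),
    class = c("count_profile", class(tibble()))
  )
}
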