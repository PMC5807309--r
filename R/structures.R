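# Candidate structures: parsing, validation, deduplication and motif queries.
#
# A structure is held as a per-site binary susceptibility state
# (constrained = 1 / unconstrained = 0) plus its base-pair list. Pairs and
# states are stored in model coordinates (1..L from the 3' end, see utils.R);
# dot-bracket text, FASTA, and every exported table use 5'->3' coordinates,
# converted exactly once at the I/O boundary.

DB_OPENERS <- c("(", "[", "{", "<", LETTERS)
DB_CLOSERS <- c(")", "]", "}", ">", letters)
DB_UNPAIRED <- c(".", ",", ":", "-", "_", "~")

#' Create a single candidate structure
#'
#' @param dotbracket structure in dot-bracket notation, written 5'->3'.
#'   Pseudoknots may use the additional bracket alphabets `[]`, `{}`, `<>`
#'   and `Aa`..`Zz`.
#' @param sequence RNA sequence (5'->3') of the same length.
#' @param id structure identifier; autogenerated when `NULL`.
#' @param extra_constrained optional 5'->3' site indices to mark constrained
#'   beyond base pairing (ligand contacts, tertiary interactions).
#' @param source provenance tag: `"sampled"`, `"spiked"` or `"manual"`.
#' @param energy optional free energy in kcal/mol.
#' @return an object of class `rna_structure` with fields `pairs` (internal
#'   coordinates, column `i` < column `j`) and `state` (length-L 0/1 vector,
#'   internal order).
#' @export
#' @examples
#' s <- rna_structure("((..))", "GGAACC")
#' s$pairs # internal 3'->5' indices
rna_structure <- function(dotbracket, sequence, id = NULL,
                          extra_constrained = NULL,
                          source = c("manual", "sampled", "spiked"),
                          energy = NA_real_) {
  source <- match.arg(source)
  sequence <- paste(seq_chars(sequence), collapse = "")
  L <- nchar(sequence)
  if (nchar(dotbracket) != L) {
    abort(sprintf(
      "structure length %d does not match sequence length %d",
      nchar(dotbracket), L
    ))
  }
  pairs_disp <- parse_db_pairs(dotbracket)
  pairs <- flip_pairs(pairs_disp, L)
  state <- integer(L)
  state[as.vector(pairs)] <- 1L
  if (!is.null(extra_constrained)) {
    state[flip_sites(extra_constrained, L)] <- 1L
  }
  structure(
    list(
      id = id %||% paste0("s", substr(rlang::hash(list(dotbracket, sequence)), 1, 8)),
      sequence = sequence, L = L, dotbracket = dotbracket,
      pairs = pairs, state = state, source = source, energy = energy
    ),
    class = "rna_structure"
  )
}

# stack-matching over the multi-alphabet bracket convention; returns a
# matrix of display-coordinate pairs (i < j)
parse_db_pairs <- function(dotbracket, line = NA) {
  chars <- strsplit(dotbracket, "")[[1]]
  stacks <- vector("list", length(DB_OPENERS))
  out_i <- integer(0); out_j <- integer(0)
  where <- if (is.na(line)) "" else sprintf(" (line %s)", line)
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    k <- match(ch, DB_OPENERS)
    if (!is.na(k)) {
      stacks[[k]] <- c(stacks[[k]], pos)
      next
    }
    k <- match(ch, DB_CLOSERS)
    if (!is.na(k)) {
      n <- length(stacks[[k]])
      if (n == 0) {
        abort(sprintf(
          "unbalanced '%s' at position %d%s: no matching '%s'",
          ch, pos, where, DB_OPENERS[k]
        ))
      }
      out_i <- c(out_i, stacks[[k]][n]); out_j <- c(out_j, pos)
      stacks[[k]] <- stacks[[k]][-n]
      next
    }
    if (!ch %in% DB_UNPAIRED) {
      abort(sprintf("unrecognized character '%s' at position %d%s", ch, pos, where))
    }
  }
  open_left <- which(lengths(stacks) > 0)
  if (length(open_left) > 0) {
    abort(sprintf(
      "unbalanced '%s'%s: %d unmatched opening bracket(s)",
      DB_OPENERS[open_left[1]], where, sum(lengths(stacks))
    ))
  }
  ord <- order(out_i)
  cbind(i = out_i[ord], j = out_j[ord])
}

# flip a display-coordinate pair matrix into internal coordinates (i < j kept)
flip_pairs <- function(pairs, L) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(cbind(i = integer(0), j = integer(0)))
  }
  i <- flip_sites(pairs[, 2], L); j <- flip_sites(pairs[, 1], L)
  ord <- order(i)
  cbind(i = i[ord], j = j[ord])
}

pairs_keys <- function(pairs) {
  if (nrow(pairs) == 0) return(character(0))
  paste(pairs[, 1], pairs[, 2], sep = "-")
}

#' @export
format.rna_structure <- function(x, ...) {
  sprintf(
    "<rna_structure %s> %d nt, %d pairs, %d constrained sites [%s]",
    x$id, x$L, nrow(x$pairs), sum(x$state), x$source
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(format(x), "\n", x$sequence, "\n", x$dotbracket, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Candidate sets

new_candidate_set <- function(df, sequence, region = NULL, informative = NULL) {
  structure(
    df,
    sequence = sequence,
    region = region,
    informative = informative,
    class = c("candidate_set", class(tibble()))
  )
}

#' Assemble a candidate set from structures
#'
#' A candidate set is a tibble with one row per structure (columns `id`,
#' `dotbracket`, `source`, `energy`, and list-columns `pairs`, `state` in
#' model coordinates) carrying the shared sequence, the analysis region and
#' the chemistry's informative sites as attributes.
#'
#' @param structures list of [rna_structure()] objects sharing one sequence.
#' @param region optional 5'->3' interval `c(start, end)` over which
#'   structure identity is judged (e.g. the region covered by the reads).
#' @param chemistry probing chemistry: `"shape"` (all sites assayable) or
#'   `"dms"` (adenines and cytosines only).
#' @param informative optional explicit 5'->3' site indices assayable by the
#'   chemistry; overrides `chemistry`.
#' @return a `candidate_set` tibble.
#' @export
candidate_set <- function(structures, region = NULL,
                          chemistry = c("shape", "dms"), informative = NULL) {
  chemistry <- match.arg(chemistry)
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  if (length(structures) == 0) abort("candidate set cannot be empty")
  seqs <- unique(vapply(structures, function(s) s$sequence, character(1)))
  if (length(seqs) != 1) {
    abort("all structures in a candidate set must share one sequence")
  }
  L <- nchar(seqs)
  df <- tibble(
    id = vapply(structures, function(s) s$id, character(1)),
    dotbracket = vapply(structures, function(s) s$dotbracket, character(1)),
    source = vapply(structures, function(s) s$source, character(1)),
    energy = vapply(structures, function(s) s$energy, numeric(1)),
    pairs = lapply(structures, function(s) s$pairs),
    state = lapply(structures, function(s) s$state)
  )
  if (anyDuplicated(df$id)) df$id <- make.unique(df$id, sep = "_")
  region_int <- NULL
  if (!is.null(region)) {
    stopifnot(length(region) == 2, region[1] <= region[2])
    region_int <- sort(flip_sites(seq(region[1], region[2]), L))
  }
  informative_int <-
    if (!is.null(informative)) sort(flip_sites(informative, L))
    else chemistry_sites(seqs, chemistry)
  new_candidate_set(df, seqs, region_int, informative_int)
}

#' Sites assayable by a probing chemistry
#'
#' @param sequence RNA sequence, 5'->3'.
#' @param chemistry `"shape"` (every nucleotide) or `"dms"` (A and C only).
#' @return sorted internal (3'->5') site indices.
#' @export
chemistry_sites <- function(sequence, chemistry = c("shape", "dms")) {
  chemistry <- match.arg(chemistry)
  L <- nchar(sequence)
  if (chemistry == "shape") return(seq_len(L))
  disp <- which(seq_chars(sequence) %in% c("A", "C"))
  sort(flip_sites(disp, L))
}

cs_sequence <- function(cs) attr(cs, "sequence", exact = TRUE)
cs_L <- function(cs) nchar(cs_sequence(cs))
cs_region <- function(cs) attr(cs, "region", exact = TRUE)
cs_informative <- function(cs) attr(cs, "informative", exact = TRUE)

# the sites over which two structures are distinguishable by the assay
cs_assayed_sites <- function(cs) {
  sites <- seq_len(cs_L(cs))
  if (!is.null(cs_region(cs))) sites <- intersect(sites, cs_region(cs))
  if (!is.null(cs_informative(cs))) sites <- intersect(sites, cs_informative(cs))
  sort(sites)
}

# rebuild one rna_structure from a candidate-set row
cs_structure <- function(cs, row) {
  structure(
    list(
      id = cs$id[row], sequence = cs_sequence(cs), L = cs_L(cs),
      dotbracket = cs$dotbracket[row], pairs = cs$pairs[[row]],
      state = cs$state[[row]], source = cs$source[row], energy = cs$energy[row]
    ),
    class = "rna_structure"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "# candidate_set: %d structure(s), %d nt, %d assayed site(s)\n",
    nrow(x), cs_L(x), length(cs_assayed_sites(x))
  ))
  NextMethod()
}

#' Parse a multi-structure dot-bracket document
#'
#' Each non-empty line (after an optional `>` header and an optional sequence
#' line) is one structure; a trailing parenthesized number is read as its
#' free energy.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @param sequence RNA sequence (5'->3'); when `NULL` the first
#'   non-header line of `text` is taken as the sequence.
#' @param source provenance tag applied to all parsed structures.
#' @inheritParams candidate_set
#' @return a [candidate_set()].
#' @export
#' @examples
#' parse_dotbracket(c("((..))", "([)].."), sequence = "GGAACC")
parse_dotbracket <- function(text, sequence = NULL, region = NULL,
                             chemistry = c("shape", "dms"), informative = NULL,
                             source = c("sampled", "spiked", "manual")) {
  source <- match.arg(source)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ">") & !startsWith(lines, "#")]
  if (is.null(sequence)) {
    if (length(lines) == 0) abort("no sequence line found")
    sequence <- lines[1]
    lines <- lines[-1]
  }
  if (length(lines) == 0) abort("no structure lines found")
  energy_re <- "\\s+\\(\\s*(-?[0-9]+\\.?[0-9]*)\\s*\\)\\s*$"
  energies <- rep(NA_real_, length(lines))
  has_e <- grepl(energy_re, lines)
  energies[has_e] <- as.numeric(sub(paste0(".*", energy_re), "\\1", lines[has_e]))
  lines[has_e] <- sub(energy_re, "", lines[has_e])
  structures <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    if (nchar(lines[k]) != nchar(sequence)) {
      abort(sprintf(
        "structure line %d has length %d but the sequence has length %d",
        k, nchar(lines[k]), nchar(sequence)
      ))
    }
    parse_db_pairs(lines[k], line = k) # error messages carry the line number
    structures[[k]] <- rna_structure(
      lines[k], sequence,
      id = sprintf("s%03d", k),
      source = source, energy = energies[k]
    )
  }
  candidate_set(structures,
    region = region, chemistry = chemistry,
    informative = informative
  )
}

# ---------------------------------------------------------------------------
# Deduplication, spike-in, motifs

#' Remove structures indistinguishable by the assay
#'
#' Two structures are duplicates when their constrained/unconstrained states
#' agree over the assayed sites (analysis region intersected with the
#' chemistry's informative sites); the model cannot tell them apart there.
#' The first occurrence is kept, input order is otherwise preserved.
#'
#' @param candidates a [candidate_set()].
#' @param scope `"assayed"` (default) or `"full"` for strict whole-sequence
#'   state identity.
#' @return the deduplicated `candidate_set`; the number of removals is
#'   available as `attr(, "n_removed")`.
#' @export
dedup <- function(candidates, scope = c("assayed", "full")) {
  scope <- match.arg(scope)
  if (nrow(candidates) == 0) abort("cannot deduplicate an empty candidate set")
  idx <- if (scope == "assayed") cs_assayed_sites(candidates) else seq_len(cs_L(candidates))
  keys <- vapply(
    candidates$state, function(st) paste(st[idx], collapse = ""), character(1)
  )
  keep <- !duplicated(keys)
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    inform(sprintf("dedup: removed %d duplicate structure(s)", n_removed))
  }
  out <- new_candidate_set(
    candidates[keep, , drop = FALSE],
    cs_sequence(candidates), cs_region(candidates), cs_informative(candidates)
  )
  attr(out, "n_removed") <- n_removed
  out
}

#' Spike structures of interest into a candidate set
#'
#' Statistical samplers exclude pseudoknots; spiking appends externally
#' modeled structures (tagged `source = "spiked"`) and re-deduplicates.
#'
#' @param candidates a [candidate_set()].
#' @param extras list of [rna_structure()] objects (or a `candidate_set`)
#'   over the same sequence.
#' @inheritParams dedup
#' @return the augmented, deduplicated `candidate_set`.
#' @export
spike_in <- function(candidates, extras, scope = c("assayed", "full")) {
  scope <- match.arg(scope)
  if (inherits(extras, "rna_structure")) extras <- list(extras)
  if (inherits(extras, "candidate_set")) {
    extras <- lapply(seq_len(nrow(extras)), function(k) cs_structure(extras, k))
  }
  if (length(extras) == 0) return(candidates)
  for (s in extras) {
    if (s$sequence != cs_sequence(candidates)) {
      abort(sprintf("spiked structure '%s' has a different sequence", s$id))
    }
  }
  extra_df <- tibble(
    id = vapply(extras, function(s) s$id, character(1)),
    dotbracket = vapply(extras, function(s) s$dotbracket, character(1)),
    source = "spiked",
    energy = vapply(extras, function(s) s$energy, numeric(1)),
    pairs = lapply(extras, function(s) s$pairs),
    state = lapply(extras, function(s) s$state)
  )
  df <- dplyr::bind_rows(as_tibble(candidates), extra_df)
  if (anyDuplicated(df$id)) df$id <- make.unique(df$id, sep = "_")
  dedup(
    new_candidate_set(
      df, cs_sequence(candidates), cs_region(candidates), cs_informative(candidates)
    ),
    scope = scope
  )
}

#' Test whether a structure contains (most of) a base-pair motif
#'
#' @param structure an [rna_structure()], or a `candidate_set` (then a
#'   logical vector over its rows is returned).
#' @param motif two-column matrix (or list of length-2 vectors) of base
#'   pairs in 5'->3' coordinates.
#' @param min_fraction minimum fraction of motif pairs that must be present,
#'   in (0, 1].
#' @return logical.
#' @export
motif_contains <- function(structure, motif, min_fraction = 1) {
  if (is.list(motif) && !is.matrix(motif)) motif <- do.call(rbind, motif)
  motif <- matrix(as.integer(motif), ncol = 2)
  if (nrow(motif) == 0) abort("motif must contain at least one base pair")
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    abort("`min_fraction` must be in (0, 1]")
  }
  motif <- cbind(pmin(motif[, 1], motif[, 2]), pmax(motif[, 1], motif[, 2]))
  if (inherits(structure, "candidate_set")) {
    L <- cs_L(structure)
    keys <- pairs_keys(flip_pairs(motif, L))
    return(vapply(
      structure$pairs,
      function(p) sum(keys %in% pairs_keys(p)) >= min_fraction * nrow(motif),
      logical(1)
    ))
  }
  keys <- pairs_keys(flip_pairs(motif, structure$L))
  sum(keys %in% pairs_keys(structure$pairs)) >= min_fraction * nrow(motif)
}

# ---------------------------------------------------------------------------
# Serialization back to dot-bracket (pseudoknot-aware) and file I/O

# assign each pair the lowest bracket alphabet under which it does not cross
# a previously assigned pair of the same alphabet
db_from_pairs <- function(pairs_disp, L) {
  chars <- rep(".", L)
  if (nrow(pairs_disp) > 0) {
    ord <- order(pairs_disp[, 1])
    pairs_disp <- pairs_disp[ord, , drop = FALSE]
    alphabet <- integer(nrow(pairs_disp))
    for (k in seq_len(nrow(pairs_disp))) {
      a <- 1L
      repeat {
        prev <- which(alphabet[seq_len(k - 1)] == a)
        crossing <- any(vapply(prev, function(m) {
          i1 <- pairs_disp[m, 1]; j1 <- pairs_disp[m, 2]
          i2 <- pairs_disp[k, 1]; j2 <- pairs_disp[k, 2]
          (i1 < i2 && i2 < j1 && j1 < j2) || (i2 < i1 && i1 < j2 && j2 < j1)
        }, logical(1)))
        if (!crossing) break
        a <- a + 1L
        if (a > length(DB_OPENERS)) abort("pseudoknot order exceeds bracket alphabets")
      }
      alphabet[k] <- a
      chars[pairs_disp[k, 1]] <- DB_OPENERS[a]
      chars[pairs_disp[k, 2]] <- DB_CLOSERS[a]
    }
  }
  paste(chars, collapse = "")
}

# dot-bracket (5'->3') regenerated from a structure's internal pair list
serialize_structure <- function(s) {
  db_from_pairs(flip_pairs(s$pairs, s$L), s$L)
}

#' Read and write multi-structure dot-bracket (Vienna) files
#'
#' The file layout is: an optional `>` header line, the sequence, then one
#' structure per line with an optional trailing free energy in parentheses.
#' `read_dbn()` reads the one-structure-per-record dialect
#' (`>name / sequence / structure` triplets).
#'
#' @param path file path.
#' @inheritParams candidate_set
#' @inheritParams parse_dotbracket
#' @return a [candidate_set()].
#' @export
read_vienna <- function(path, region = NULL, chemistry = c("shape", "dms"),
                        informative = NULL, source = c("sampled", "spiked", "manual")) {
  parse_dotbracket(readLines(path),
    region = region, chemistry = chemistry,
    informative = informative, source = source
  )
}

#' @rdname read_vienna
#' @param candidates a [candidate_set()] to write.
#' @param header header text (without the leading `>`).
#' @export
write_vienna <- function(candidates, path, header = "candidate structures") {
  lines <- c(
    paste0(">", header),
    cs_sequence(candidates),
    ifelse(
      is.na(candidates$energy),
      candidates$dotbracket,
      sprintf("%s (%.2f)", candidates$dotbracket, candidates$energy)
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_vienna
#' @export
read_dbn <- function(path, region = NULL, chemistry = c("shape", "dms"),
                     informative = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0) abort("no '>' records found in dbn file")
  structures <- lapply(heads, function(h) {
    if (h + 2 > length(lines)) abort("truncated dbn record at end of file")
    rna_structure(lines[h + 2], lines[h + 1],
      id = sub("^>\\s*", "", lines[h]), source = "manual"
    )
  })
  candidate_set(structures,
    region = region, chemistry = chemistry,
    informative = informative
  )
}

#' Read an RNA sequence from a FASTA file
#'
#' @param path FASTA file path.
#' @param n which record to return (default the first).
#' @return the sequence as an upper-case RNA string.
#' @export
read_fasta <- function(path, n = 1) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < n) abort(sprintf("FASTA file has only %d record(s)", length(set)))
  paste(seq_chars(as.character(set[[n]])), collapse = "")
}
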