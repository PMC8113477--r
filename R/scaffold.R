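## Data model for the cyclic 14-mer peptide scaffold, its mutants, and the
## mutational-activity table used for residue-essentiality queries.

#' Construct a peptide scaffold object
#'
#' A `peptide_scaffold` records the residue sequence (one-letter codes,
#' 1-based positions), the disulfide topology, the redox state and which
#' positions are synthetic placeholders (positions whose true identity is not
#' part of the data model and is filled with a stand-in residue).
#'
#' @param residues character vector of one-letter amino-acid codes.
#' @param disulfide_pairs list of integer pairs (positions) bridged by a
#'   disulfide; must reference Cys positions, each position at most once.
#' @param redox_state `"oxidized"` or `"reduced"`; a reduced scaffold cannot
#'   carry disulfide pairs.
#' @param placeholder_positions integer vector of positions whose identity is
#'   a synthetic stand-in.
#' @param cyclic logical; FALSE marks a scaffold whose ring has been opened
#'   (e.g. by mutating a bridging cysteine).
#' @return an object of class `peptide_scaffold`.
#' @export
peptide_scaffold <- function(residues, disulfide_pairs = list(),
                             redox_state = c("oxidized", "reduced"),
                             placeholder_positions = integer(),
                             cyclic = length(disulfide_pairs) > 0) {
  redox_state <- match.arg(redox_state)
  residues <- toupper(as.character(residues))
  if (!all(residues %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])) {
    stop("residues must be one-letter amino-acid codes", call. = FALSE)
  }
  if (redox_state == "reduced" && length(disulfide_pairs) > 0) {
    stop("a reduced scaffold cannot carry disulfide pairs", call. = FALSE)
  }
  used <- integer()
  for (p in disulfide_pairs) {
    p <- as.integer(p)
    if (length(p) != 2 || any(p < 1 | p > length(residues))) {
      stop("disulfide pair positions out of range", call. = FALSE)
    }
    if (any(residues[p] != "C")) {
      stop("disulfide pairs must reference Cys positions", call. = FALSE)
    }
    if (any(p %in% used)) stop("a position appears in two disulfide pairs", call. = FALSE)
    used <- c(used, p)
  }
  structure(
    list(
      residues = residues,
      disulfide_pairs = lapply(disulfide_pairs, function(p) sort(as.integer(p))),
      redox_state = redox_state,
      placeholder_positions = sort(as.integer(placeholder_positions)),
      cyclic = isTRUE(cyclic)
    ),
    class = "peptide_scaffold"
  )
}

#' The canonical cyclic 14-residue ice-binding scaffold
#'
#' Returns the 14-residue scaffold with Cys at positions 2, 3, 7 and 13, Thr
#' at 4, 10 and 14, Asp at 8, and a single disulfide bridge between Cys3 and
#' Cys13 (oxidized state). The six remaining positions (1, 5, 6, 9, 11, 12)
#' are not determined by the data model and are filled with glycine; they are
#' flagged in `placeholder_positions` and every analysis that depends on them
#' is a synthetic stand-in.
#'
#' @return a `peptide_scaffold` of length 14.
#' @examples
#' sc <- build_canonical_scaffold()
#' length(sc$residues)           # 14
#' sum(sc$residues == "C")       # 4 cysteines
#' sc$disulfide_pairs            # list(c(3, 13))
#' @export
build_canonical_scaffold <- function() {
  res <- rep("G", 14)
  res[c(2, 3, 7, 13)] <- "C"
  res[c(4, 10, 14)] <- "T"
  res[8] <- "D"
  peptide_scaffold(
    residues = res,
    disulfide_pairs = list(c(3L, 13L)),
    redox_state = "oxidized",
    placeholder_positions = c(1L, 5L, 6L, 9L, 11L, 12L),
    cyclic = TRUE
  )
}

#' @export
print.peptide_scaffold <- function(x, ...) {
  cat(sprintf(
    "<peptide_scaffold> %d residues, %s, %s\n  sequence: %s\n",
    length(x$residues), x$redox_state,
    if (x$cyclic) "cyclic" else "acyclic",
    paste(x$residues, collapse = "")
  ))
  if (length(x$disulfide_pairs)) {
    cat("  disulfides:",
        paste(vapply(x$disulfide_pairs, function(p) sprintf("%d-%d", p[1], p[2]), ""),
              collapse = ", "), "\n")
  }
  if (length(x$placeholder_positions)) {
    cat("  placeholder positions:", paste(x$placeholder_positions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Apply point substitutions to a scaffold
#'
#' Substitutions are given as `(position, to_aa)` pairs. If a cysteine that is
#' part of a disulfide pair is substituted, the pair is removed and the result
#' is flagged acyclic. Substituting a placeholder position emits a warning,
#' since the residue there is a synthetic stand-in.
#'
#' @param scaffold a `peptide_scaffold`.
#' @param substitutions a list of `c(position, to_aa)` pairs, or a data.frame
#'   with columns `position` and `to_aa`.
#' @return a new `peptide_scaffold`.
#' @examples
#' sc <- build_canonical_scaffold()
#' apply_mutation(sc, list(c(10, "S")))          # Thr10 -> Ser
#' @export
apply_mutation <- function(scaffold, substitutions) {
  stopifnot(inherits(scaffold, "peptide_scaffold"))
  subs <- normalize_substitutions(substitutions)
  res <- scaffold$residues
  pairs <- scaffold$disulfide_pairs
  cyclic <- scaffold$cyclic
  for (i in seq_len(nrow(subs))) {
    pos <- subs$position[i]
    if (pos < 1 || pos > length(res)) {
      stop(sprintf("substitution position %d out of range 1..%d", pos, length(res)),
           call. = FALSE)
    }
    if (pos %in% scaffold$placeholder_positions) {
      warning(sprintf("position %d is a synthetic placeholder; substituting it", pos),
              call. = FALSE)
    }
    if (res[pos] == "C" && subs$to_aa[i] != "C") {
      keep <- vapply(pairs, function(p) !(pos %in% p), logical(1))
      if (!all(keep)) {
        pairs <- pairs[keep]
        cyclic <- FALSE
      }
    }
    res[pos] <- subs$to_aa[i]
  }
  peptide_scaffold(res, pairs, scaffold$redox_state,
                   scaffold$placeholder_positions, cyclic = cyclic)
}

## Accepts list(c(10,"S")), list(list(10,"S")) or data.frame(position,to_aa);
## returns a data.frame(position, to_aa).
normalize_substitutions <- function(substitutions) {
  if (is.data.frame(substitutions)) {
    out <- data.frame(position = as.integer(substitutions$position),
                      to_aa = toupper(as.character(substitutions$to_aa)))
  } else {
    out <- do.call(rbind, lapply(substitutions, function(s) {
      data.frame(position = as.integer(s[[1]]), to_aa = toupper(as.character(s[[2]])))
    }))
  }
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(position = integer(), to_aa = character()))
  }
  out
}

#' Parse a substitution string such as "T10S;T14S"
#'
#' Each token is `<from><position><to>` in one-letter codes; the empty string
#' means no substitutions (parent peptide).
#'
#' @param s character scalar.
#' @return data.frame with columns `position`, `from_aa`, `to_aa`.
#' @export
parse_substitutions <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) {
    return(data.frame(position = integer(), from_aa = character(), to_aa = character()))
  }
  toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  m <- regmatches(toks, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", toks))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("malformed substitution token: ", toks[bad][1], call. = FALSE)
  data.frame(
    position = vapply(m, function(g) as.integer(g[3]), 0L),
    from_aa = toupper(vapply(m, function(g) g[2], "")),
    to_aa = toupper(vapply(m, function(g) g[4], ""))
  )
}

format_substitutions <- function(df) {
  if (nrow(df) == 0) return("")
  paste(sprintf("%s%d%s", df$from_aa, df$position, df$to_aa), collapse = ";")
}

#' Build a mutational activity table
#'
#' One row per (variant, concentration). `mga_ratio` is the mean grain area of
#' the sample relative to the buffer control; the boolean activity call is
#' `mga_ratio < activity_threshold`. Every substitution's from-residue is
#' validated against the canonical scaffold.
#'
#' @param df data.frame with columns `variant_id`, `substitutions` (string,
#'   e.g. `"T10S;T14S"`, empty for the parent), `redox_state`,
#'   `concentration` (mg/mL) and `mga_ratio`.
#' @param activity_threshold activity cutoff on the mean-grain-area ratio;
#'   default 0.8 (the call is qualitative in splat-assay practice, so the
#'   cutoff is configurable).
#' @param scaffold scaffold used to validate from-residues.
#' @return data.frame of class `activity_table` with an added `active` column
#'   and the threshold stored as an attribute.
#' @export
activity_table <- function(df, activity_threshold = 0.8,
                           scaffold = build_canonical_scaffold()) {
  need <- c("variant_id", "substitutions", "redox_state", "concentration", "mga_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("activity table missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(!is.finite(df$mga_ratio)) || any(df$mga_ratio <= 0)) {
    stop("mga_ratio values must be finite and > 0", call. = FALSE)
  }
  df$substitutions <- ifelse(is.na(df$substitutions), "", as.character(df$substitutions))
  for (i in seq_len(nrow(df))) {
    subs <- parse_substitutions(df$substitutions[i])
    if (nrow(subs)) {
      got <- scaffold$residues[subs$position]
      if (any(got != subs$from_aa)) {
        stop(sprintf("variant %s: from-residue mismatch at position %d (scaffold has %s)",
                     df$variant_id[i], subs$position[which(got != subs$from_aa)[1]],
                     got[which(got != subs$from_aa)[1]]), call. = FALSE)
      }
    }
  }
  df$active <- df$mga_ratio < activity_threshold
  structure(df, class = c("activity_table", "data.frame"),
            activity_threshold = activity_threshold)
}

#' Read a mutational activity table from CSV
#'
#' @param path CSV path with the columns documented in [activity_table()].
#' @param ... passed on to [activity_table()].
#' @export
read_activity_table <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  activity_table(df, ...)
}

#' The packaged mutational-activity fixture
#'
#' Loads the activity table shipped with the package: the parent peptide under
#' oxidizing and reducing conditions, the four Thr-to-Ser mutants, the
#' Asp8-to-Ser mutant, the two cysteine double mutants, and a scrambled
#' control, each with a mean-grain-area ratio at 1 mg/mL (plus a dose series
#' for the parent). Ratios are synthetic round numbers consistent with the
#' qualitative active/inactive outcomes; the outcome pattern is the datum.
#'
#' @param ... passed on to [activity_table()] (e.g. `activity_threshold`).
#' @export
packaged_activity_table <- function(...) {
  read_activity_table(
    system.file("extdata", "mutational_activity.csv", package = "icebindr",
                mustWork = TRUE), ...)
}

#' Positions essential for activity
#'
#' A position is called essential when some variant carrying exactly one
#' substitution at that position is inactive at the queried concentration.
#' Multi-substitution variants (all-Thr, cysteine pairs, scrambles) never
#' contribute: they cannot localize a loss of activity to one residue. The
#' parent (oxidized, no substitutions) must be present and active at that
#' concentration, otherwise essentiality is undefined.
#'
#' @param table an `activity_table`.
#' @param concentration mg/mL at which to evaluate the calls.
#' @return sorted integer vector of essential positions.
#' @examples
#' tab <- packaged_activity_table()
#' essential_residues(tab, 1)   # 8, 10, 14
#' @export
essential_residues <- function(table, concentration) {
  stopifnot(inherits(table, "activity_table"))
  at_c <- table[table$concentration == concentration, , drop = FALSE]
  parent <- at_c[at_c$substitutions == "" & at_c$redox_state == "oxidized", , drop = FALSE]
  if (nrow(parent) == 0) {
    stop("parent (oxidized, unsubstituted) missing at this concentration", call. = FALSE)
  }
  if (!any(parent$active)) {
    stop("parent is inactive at this concentration; essentiality undefined", call. = FALSE)
  }
  ess <- integer()
  for (i in seq_len(nrow(at_c))) {
    subs <- parse_substitutions(at_c$substitutions[i])
    if (nrow(subs) == 1 && !at_c$active[i]) ess <- c(ess, subs$position)
  }
  sort(unique(ess))
}

## --- serialization -------------------------------------------------------

#' Serialize a scaffold to a one-line text record and back
#'
#' The record is `sequence|pairs|redox|placeholders|cyclic` with pairs as
#' `3-13` tokens; [scaffold_from_record()] inverts it exactly.
#'
#' @param scaffold a `peptide_scaffold`.
#' @export
scaffold_to_record <- function(scaffold) {
  paste(
    paste(scaffold$residues, collapse = ""),
    paste(vapply(scaffold$disulfide_pairs, function(p) sprintf("%d-%d", p[1], p[2]), ""),
          collapse = ","),
    scaffold$redox_state,
    paste(scaffold$placeholder_positions, collapse = ","),
    if (scaffold$cyclic) "cyclic" else "acyclic",
    sep = "|"
  )
}

#' @rdname scaffold_to_record
#' @param record a record produced by [scaffold_to_record()].
#' @export
scaffold_from_record <- function(record) {
  f <- strsplit(record, "|", fixed = TRUE)[[1]]
  if (length(f) < 5) stop("malformed scaffold record", call. = FALSE)
  pairs <- if (nzchar(f[2])) {
    lapply(strsplit(f[2], ",")[[1]], function(s) as.integer(strsplit(s, "-")[[1]]))
  } else list()
  ph <- if (nzchar(f[4])) as.integer(strsplit(f[4], ",")[[1]]) else integer()
  peptide_scaffold(strsplit(f[1], "")[[1]], pairs, f[3], ph, cyclic = f[5] == "cyclic")
}

#' Write a scaffold as JSON
#' @param scaffold a `peptide_scaffold`.
#' @param path output path.
#' @export
write_scaffold_json <- function(scaffold, path) {
  jsonlite::write_json(unclass(scaffold), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
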