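# Cysteine frameworks and disulfide-connectivity families.
#
# Cysteine-rich arthropod peptides are classified by the ordinal pattern of
# their disulfide bonds (cysteines numbered C1..Cn by sequence order), not
# by sequence homology.  The registry below holds the main structural
# scaffolds: the inhibitor cystine knot (ICK), the disulfide-directed
# beta-hairpin (DDH), the Kunitz and Kazal protease-inhibitor folds, the
# arthropod HAND motif (cysteine count known, pairing unsettled), and the
# five-disulfide colipase-like/MIT1 fold.

#' Disulfide connectivity pattern
#'
#' @param bonds list of length-2 integer vectors, or a 2-column matrix, of
#'   cysteine ordinals; each pair is stored with the smaller ordinal first
#'   and the pair list sorted, so input order never matters.
#' @return a `connectivity_pattern`: sorted list of ordered pairs.
#' @export
connectivity_pattern <- function(bonds) {
  if (is.matrix(bonds)) bonds <- asplit(bonds, 1L)
  bonds <- lapply(bonds, function(b) {
    b <- as.integer(b)
    if (length(b) != 2L || any(b < 1L) || b[1L] == b[2L]) {
      stop("each bond must pair two distinct positive ordinals",
           call. = FALSE)
    }
    sort(b)
  })
  ords <- unlist(bonds)
  if (anyDuplicated(ords)) {
    stop("malformed pattern: cysteine ordinal ",
         ords[duplicated(ords)][1L], " appears in more than one bond",
         call. = FALSE)
  }
  key <- vapply(bonds, function(b) b[1L] * 1000L + b[2L], integer(1L))
  structure(bonds[order(key)], class = "connectivity_pattern")
}

bond_labels <- function(pattern) {
  vapply(pattern, function(b) paste0("C", b[1L], "-C", b[2L]), character(1L))
}

#' @export
print.connectivity_pattern <- function(x, ...) {
  cat("<connectivity_pattern>", paste(bond_labels(x), collapse = ", "), "\n")
  invisible(x)
}

# Family registry ------------------------------------------------------------

#' Registered disulfide-scaffold family templates
#'
#' Families with their cysteine counts and (where settled) canonical
#' connectivities:
#' \itemize{
#'   \item ICK, 6 Cys, C1-C4 C2-C5 C3-C6;
#'   \item DDH, 4 Cys, recorded verbatim as "C1-C2, C2-C4" from the source
#'     literature although that notation reuses C2 and therefore cannot be
#'     a valid pairing; flagged `valid = FALSE` and excluded from exact
#'     matching;
#'   \item Kunitz, 6 Cys, C1-C6 C2-C4 C3-C5;
#'   \item Kazal, 6 Cys, C1-C5 C2-C4 C3-C6;
#'   \item HAND, 6 Cys, connectivity unspecified (count pre-screen only);
#'   \item MIT1-colipase, 10 Cys, C1-C4 C2-C5 C3-C7 C6-C9 C8-C10.
#' }
#'
#' @return named list of `family_template` objects (`name`, `n_cys`,
#'   `connectivity` or NULL, `valid`, `source_note`).
#' @export
family_templates <- function() {
  tmpl <- function(name, n_cys, bonds, valid, note) {
    structure(list(name = name, n_cys = n_cys,
                   connectivity = if (is.null(bonds)) NULL
                                  else connectivity_pattern(bonds),
                   valid = valid, source_note = note),
              class = "family_template")
  }
  list(
    "ICK" = tmpl("ICK", 6L, list(c(1, 4), c(2, 5), c(3, 6)), TRUE,
                 "inhibitor cystine knot, three disulfides"),
    "DDH" = structure(list(name = "DDH", n_cys = 4L,
                           connectivity = NULL, valid = FALSE,
                           connectivity_verbatim = "C1-C2, C2-C4",
                           source_note = paste("disulfide-directed",
                             "beta-hairpin; published notation reuses C2",
                             "and is stored verbatim, unmatched")),
                      class = "family_template"),
    "HAND" = tmpl("HAND", 6L, NULL, TRUE,
                  "arthropod HAND motif; pairing unspecified"),
    "Kazal" = tmpl("Kazal", 6L, list(c(1, 5), c(2, 4), c(3, 6)), TRUE,
                   "Kazal-type serine-protease inhibitor domain"),
    "Kunitz" = tmpl("Kunitz", 6L, list(c(1, 6), c(2, 4), c(3, 5)), TRUE,
                    "Kunitz-type serine-protease inhibitor domain"),
    "MIT1-colipase" = tmpl("MIT1-colipase", 10L,
                           list(c(1, 4), c(2, 5), c(3, 7), c(6, 9),
                                c(8, 10)), TRUE,
                           "colipase-like/MIT1 toxin-like fold, five disulfides")
  )
}

family_template <- function(name) {
  reg <- family_templates()
  if (!name %in% names(reg)) {
    stop("unknown family template: ", name, " (known: ",
         paste(names(reg), collapse = ", "), ")", call. = FALSE)
  }
  reg[[name]]
}

# Operations ------------------------------------------------------------------

#' Extract the cysteine framework of a sequence
#'
#' @param seq a [protein_sequence()] or residue string.
#' @return a `cys_framework`: list with `positions` (1-based indices of C),
#'   `count`, and `spacings` (residue gaps between consecutive cysteines).
#' @export
extract_framework <- function(seq) {
  seq <- as_protein_sequence(seq)
  pos <- which(seq_chars(seq) == "C")
  structure(list(positions = pos, count = length(pos),
                 spacings = if (length(pos) > 1L) diff(pos) - 1L
                            else integer()),
            class = "cys_framework")
}

#' Classify a disulfide connectivity against the family registry
#'
#' Exact match against every registered template with a settled, valid
#' connectivity; otherwise the nearest template(s) by Jaccard similarity of
#' the bond sets, with the mismatching bonds listed.  Ties for nearest are
#' reported as ambiguous.
#'
#' @param pattern a [connectivity_pattern()] (or list/matrix coercible to
#'   one).
#' @return a `family_match`: list with `name` (or vector of names when
#'   ambiguous), `match` (`"exact"`, `"partial"`, or `"ambiguous"`),
#'   `jaccard`, and `mismatches` (bonds present in exactly one of the two
#'   sets).
#' @export
classify_connectivity <- function(pattern) {
  if (!inherits(pattern, "connectivity_pattern")) {
    pattern <- connectivity_pattern(pattern)
  }
  reg <- Filter(function(t) !is.null(t$connectivity) && t$valid,
                family_templates())
  q <- bond_labels(pattern)
  scores <- vapply(reg, function(t) {
    r <- bond_labels(t$connectivity)
    length(intersect(q, r)) / length(union(q, r))
  }, numeric(1L))
  exact <- names(scores)[scores == 1]
  if (length(exact) == 1L) {
    return(structure(list(name = exact, match = "exact", jaccard = 1,
                          mismatches = character()),
                     class = "family_match"))
  }
  best <- max(scores)
  nearest <- names(scores)[scores == best]
  mism <- if (length(nearest) == 1L) {
    r <- bond_labels(reg[[nearest]]$connectivity)
    c(setdiff(q, r), setdiff(r, q))
  } else character()
  structure(list(name = nearest,
                 match = if (length(nearest) > 1L) "ambiguous" else "partial",
                 jaccard = best, mismatches = mism),
            class = "family_match")
}

#' @export
print.family_match <- function(x, ...) {
  cat(sprintf("<family_match> %s (%s, Jaccard %.2f)\n",
              paste(x$name, collapse = " | "), x$match, x$jaccard))
  if (length(x$mismatches)) {
    cat("  mismatched bonds:", paste(x$mismatches, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Families compatible with a cysteine count
#'
#' Sequence-only pre-screen: before any connectivity is known, the cysteine
#' count alone restricts the candidate scaffolds.
#'
#' @param framework a `cys_framework` from [extract_framework()], or an
#'   integer cysteine count.
#' @return list of `family_template`s whose `n_cys` equals the count,
#'   ordered by name; empty when none matches.
#' @export
candidate_families <- function(framework) {
  count <- if (inherits(framework, "cys_framework")) framework$count
           else as.integer(framework)
  reg <- family_templates()
  hits <- Filter(function(t) t$n_cys == count, reg)
  hits[order(names(hits))]
}

#' Alignment columns fully conserved as cysteine
#'
#' @param alignment character vector of >= 2 aligned sequences (equal
#'   lengths, `-` or `.` as gaps), or a `Biostrings::AAMultipleAlignment`.
#' @param max_gap_frac maximum tolerated fraction of gap symbols in a
#'   column (default 0: no gaps allowed).
#' @return 1-based indices of columns in which every non-gap symbol is C
#'   (subject to the gap tolerance).
#' @export
conserved_cys_columns <- function(alignment, max_gap_frac = 0) {
  if (inherits(alignment, "AAMultipleAlignment")) {
    alignment <- as.character(alignment)
  }
  alignment <- toupper(alignment)
  if (length(alignment) < 2L) {
    stop("need at least 2 aligned sequences", call. = FALSE)
  }
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequences differ in aligned length",
         call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(alignment, ""))
  which(apply(mat, 2L, function(col) {
    gaps <- col %in% c("-", ".")
    if (mean(gaps) > max_gap_frac) return(FALSE)
    all(col[!gaps] == "C") && any(!gaps)
  }))
}
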