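# PEST motif detection and scoring.
#
# PEST regions are stretches rich in Pro, Glu/Asp, Ser/Thr flanked by
# positively charged residues (K/R/H); they mark proteins for rapid
# turnover.  The score follows the classic PEST-find recipe:
#
#   score = 0.55 * DEPST - 0.5 * HI
#
# where DEPST is the enrichment of D/E/P/S/T in the candidate stretch
# (by default in mass percent, corrected for one obligatory equivalent
# each of D-or-E, P, and S-or-T) and HI is the Kyte-Doolittle hydropathy
# of the stretch rescaled from [-4.5, 4.5] to [0, 90] via 10*h + 45 and
# averaged over residues (mole fractions).  Scores above zero flag
# potential PEST regions; above +5 is commonly read as significant.

#' Score one PEST candidate window
#'
#' Scores a candidate stretch with the PEST-find formula.  When the window
#' is passed with its positively charged flanks (K/R/H at either end), the
#' flanks are stripped before scoring (`flanks = "strip"`, the default);
#' the printed form of a motif conventionally includes the flank.
#'
#' @param window residue string (or [protein_sequence()]) of the candidate.
#' @param flanks `"strip"` (drop K/R/H at the window edges before scoring,
#'   default) or `"keep"`.
#' @param weighting DEPST enrichment as `"mass"` percent (w/w, default) or
#'   `"mole"` percent.
#' @param correct_equivalents subtract one obligatory equivalent each of
#'   D/E, of P, and of S/T (the lightest member present) before computing
#'   the enrichment (default TRUE).
#' @return the PEST score (dimensionless; higher = stronger PEST
#'   character).
#' @examples
#' pest_score("KCQQDSGEEPSEE") # ~13.3
#' @export
pest_score <- function(window, flanks = c("strip", "keep"),
                       weighting = c("mass", "mole"),
                       correct_equivalents = TRUE) {
  flanks <- match.arg(flanks)
  weighting <- match.arg(weighting)
  if (inherits(window, "protein_sequence")) window <- window$residues
  chars <- strsplit(toupper(window), "")[[1L]]
  if (flanks == "strip") {
    while (length(chars) && chars[1L] %in% c("K", "R", "H")) {
      chars <- chars[-1L]
    }
    while (length(chars) && chars[length(chars)] %in% c("K", "R", "H")) {
      chars <- chars[-length(chars)]
    }
  }
  chars <- chars[chars != "X"]
  if (!length(chars)) stop("empty window after flank handling", call. = FALSE)
  depst <- c("D", "E", "P", "S", "T")
  if (weighting == "mass") {
    num <- sum(AA_AVERAGE_MASS[chars[chars %in% depst]])
    den <- sum(AA_AVERAGE_MASS[chars])
    if (correct_equivalents) {
      for (grp in list(c("D", "E"), "P", c("S", "T"))) {
        present <- intersect(grp, chars)
        if (length(present)) num <- num - min(AA_AVERAGE_MASS[present])
      }
    }
    enrich <- 100 * max(num, 0) / den
  } else {
    num <- sum(chars %in% depst)
    if (correct_equivalents) num <- num - 3L
    enrich <- 100 * max(num, 0) / length(chars)
  }
  hi <- mean(10 * KYTE_DOOLITTLE[chars] + 45)
  0.55 * enrich - 0.5 * hi
}

#' Find and score PEST motifs in a protein
#'
#' Candidate windows are the maximal stretches between positively charged
#' flanks (K, R, H; sequence termini also act as boundaries) whose core is
#' at least `min_core` residues long and contains at least one P, one D or
#' E, and one S or T.  Each qualifying core is scored with [pest_score()];
#' the stored `window_sequence` includes the flanking positive residues for
#' display, while the score is computed on the core alone.
#'
#' @param seq a [protein_sequence()] or residue string, length >= 14.
#' @param min_core minimum core length (default 12).
#' @param ... passed to [pest_score()] (weighting, correction).
#' @return data frame with columns `start`, `end` (1-based inclusive core
#'   coordinates), `window_sequence` (flanked form) and `score`; zero rows
#'   when nothing qualifies.
#' @export
find_pest <- function(seq, min_core = 12L, ...) {
  seq <- as_protein_sequence(seq)
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < 14L) stop("sequence too short for PEST analysis", call. = FALSE)
  flank_pos <- which(chars %in% c("K", "R", "H"))
  bounds <- sort(unique(c(0L, flank_pos, n + 1L)))
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i] + 1L
    e <- bounds[i + 1L] - 1L
    if (e - s + 1L < min_core) next
    core <- chars[s:e]
    if (!any(core == "P")) next
    if (!any(core %in% c("D", "E"))) next
    if (!any(core %in% c("S", "T"))) next
    disp_s <- max(s - 1L, 1L)
    disp_e <- min(e + 1L, n)
    out[[length(out) + 1L]] <- data.frame(
      start = s, end = e,
      window_sequence = paste(chars[disp_s:disp_e], collapse = ""),
      score = pest_score(paste(core, collapse = ""), flanks = "keep", ...))
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      window_sequence = character(), score = numeric()))
  }
  do.call(rbind, out)
}
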