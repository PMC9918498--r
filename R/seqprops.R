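# Residue-level constants ----------------------------------------------------

# Average and monoisotopic residue masses (Da); a chain adds one water.
AA_AVERAGE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

AA_MONO_MASS <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

WATER_AVERAGE <- 18.01528
WATER_MONO <- 18.010565

# Kyte-Doolittle hydropathy
KYTE_DOOLITTLE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Protein sequence container -------------------------------------------------

#' Protein sequence with optional processing annotations
#'
#' @param id sequence identifier.
#' @param residues string over the 20-letter amino-acid alphabet; `X`
#'   (unknown) is allowed but excluded from mass and pI computation.
#' @param cleavage_site optional 1-based index of the last signal-peptide
#'   residue (cleavage occurs after it); must be < sequence length.
#' @return a `protein_sequence` list with `id`, `residues`,
#'   `cleavage_site`.
#' @export
protein_sequence <- function(id, residues, cleavage_site = NULL) {
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("sequence must be non-empty", call. = FALSE)
  bad <- setdiff(unique(strsplit(residues, "")[[1L]]),
                 c(names(AA_AVERAGE_MASS), "X"))
  if (length(bad)) {
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cleavage_site)) {
    if (cleavage_site < 1 || cleavage_site >= nchar(residues)) {
      stop("`cleavage_site` must lie strictly inside the sequence",
           call. = FALSE)
    }
    cleavage_site <- as.integer(cleavage_site)
  }
  structure(list(id = as.character(id), residues = residues,
                 cleavage_site = cleavage_site),
            class = "protein_sequence")
}

as_protein_sequence <- function(x, id = "seq") {
  if (inherits(x, "protein_sequence")) return(x)
  if (is.character(x) && length(x) == 1L) return(protein_sequence(id, x))
  stop("cannot interpret input as a protein sequence", call. = FALSE)
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n", x$id, nchar(x$residues)))
  if (!is.null(x$cleavage_site)) {
    cat(sprintf("  signal-peptide cleavage after residue %d\n",
                x$cleavage_site))
  }
  cat(" ", x$residues, "\n")
  invisible(x)
}

seq_chars <- function(seq) strsplit(seq$residues, "")[[1L]]

chain_mass <- function(seq, table, water, allow_x) {
  ch <- seq_chars(seq)
  if (any(ch == "X")) {
    if (!allow_x) {
      stop("sequence contains unknown residues (X); set `allow_x = TRUE` ",
           "to skip them", call. = FALSE)
    }
    ch <- ch[ch != "X"]
  }
  if (!length(ch)) stop("no massable residues in sequence", call. = FALSE)
  sum(table[ch]) + water
}

#' Average molecular mass of a protein
#'
#' Sum of isotope-abundance-weighted residue masses plus one water
#' (18.01528 Da).
#'
#' @param seq a [protein_sequence()] or plain residue string.
#' @param allow_x skip unknown (`X`) residues instead of failing.
#' @return mass in Da.
#' @export
average_mass <- function(seq, allow_x = FALSE) {
  chain_mass(as_protein_sequence(seq), AA_AVERAGE_MASS, WATER_AVERAGE,
             allow_x)
}

#' Monoisotopic molecular mass of a protein
#'
#' As [average_mass()] but with lightest-isotope residue masses and water
#' 18.010565 Da.
#'
#' @inheritParams average_mass
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(seq, allow_x = FALSE) {
  chain_mass(as_protein_sequence(seq), AA_MONO_MASS, WATER_MONO, allow_x)
}

# Isoelectric point ----------------------------------------------------------

#' Bjellqvist pKa set
#'
#' The pKa values used by the ExPASy Compute pI/Mw tool: side-chain pKa for
#' D, E, C, Y, H, K, R, a C-terminal pKa with D/E-specific variants, and
#' residue-specific N-terminal pKa values.
#'
#' @return a list with components `positive`, `negative`, `nterm`
#'   (named by first residue, `default` otherwise) and `cterm`
#'   (named by last residue, `default` otherwise).
#' @export
pka_bjellqvist <- function() {
  list(
    positive = c(K = 10.0, R = 12.0, H = 5.98),
    negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
    nterm = c(default = 7.5, A = 7.59, M = 7.0, S = 6.93, P = 8.36,
              T = 6.82, V = 7.44, E = 7.7),
    cterm = c(default = 3.55, D = 4.55, E = 4.75)
  )
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum: positive terms for the N-terminus and K/R/H
#' side chains, negative terms for the C-terminus and D/E/C/Y side chains.
#' Strictly decreasing in pH.
#'
#' @inheritParams average_mass
#' @param ph pH value (vectorised).
#' @param pka_set a pKa set as returned by [pka_bjellqvist()] (the default).
#' @return net charge in elementary units.
#' @export
net_charge <- function(seq, ph, pka_set = pka_bjellqvist()) {
  seq <- as_protein_sequence(seq)
  ch <- seq_chars(seq)
  ch_known <- ch[ch != "X"]
  if (!length(ch_known)) stop("no ionisable residues", call. = FALSE)
  counts <- table(factor(ch_known, levels = names(AA_AVERAGE_MASS)))
  first <- ch[1L]
  last <- ch[length(ch)]
  nt_pka <- pka_set$nterm[[if (first %in% names(pka_set$nterm)) first
                           else "default"]]
  ct_pka <- pka_set$cterm[[if (last %in% names(pka_set$cterm)) last
                           else "default"]]
  vapply(ph, function(p) {
    pos <- 1 / (1 + 10^(p - nt_pka)) +
      sum(vapply(names(pka_set$positive), function(aa) {
        counts[[aa]] / (1 + 10^(p - pka_set$positive[[aa]]))
      }, numeric(1L)))
    neg <- 1 / (1 + 10^(ct_pka - p)) +
      sum(vapply(names(pka_set$negative), function(aa) {
        counts[[aa]] / (1 + 10^(pka_set$negative[[aa]] - p))
      }, numeric(1L)))
    pos - neg
  }, numeric(1L))
}

#' Theoretical isoelectric point
#'
#' pH at which the net charge ([net_charge()]) vanishes, found by bisection
#' on `[0, 14]` to 1e-4 pH units; the charge is strictly decreasing in pH so
#' the root is unique.
#'
#' @inheritParams net_charge
#' @param tol bisection tolerance in pH units.
#' @return the pI in pH units.
#' @export
isoelectric_point <- function(seq, pka_set = pka_bjellqvist(), tol = 1e-4) {
  seq <- as_protein_sequence(seq)
  lo <- 0
  hi <- 14
  if (net_charge(seq, lo, pka_set) < 0) return(lo)
  if (net_charge(seq, hi, pka_set) > 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, pka_set) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Maturation, identity, coverage, gel ----------------------------------------

#' Mature chain after signal-peptide cleavage
#'
#' @param seq a [protein_sequence()] carrying a `cleavage_site` annotation.
#' @return a [protein_sequence()] with the residues after the cleavage site
#'   and id suffixed `"_mature"`.
#' @export
mature_sequence <- function(seq) {
  seq <- as_protein_sequence(seq)
  if (is.null(seq$cleavage_site)) {
    stop("no signal-peptide cleavage annotation on this sequence",
         call. = FALSE)
  }
  mat <- substring(seq$residues, seq$cleavage_site + 1L)
  protein_sequence(paste0(seq$id, "_mature"), mat)
}

#' Percent identity from a global alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps: open 10,
#' extend 0.5) via Biostrings; identity is 100 x matches over a
#' configurable denominator, by default the number of alignment columns
#' (gaps included), the convention of common alignment viewers.
#'
#' @param a,b [protein_sequence()]s or residue strings.
#' @param gap_opening,gap_extension affine gap penalties.
#' @param denominator `"columns"` (alignment length, default),
#'   `"shortest"` (length of the shorter sequence) or `"aligned"`
#'   (columns without gaps).
#' @return percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5,
                              denominator = c("columns", "shortest",
                                              "aligned")) {
  denominator <- match.arg(denominator)
  a <- as_protein_sequence(a, "a")
  b <- as_protein_sequence(b, "b")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    type = "global", substitutionMatrix = BLOSUM62,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pid_type <- switch(denominator, columns = "PID4", shortest = "PID3",
                     aligned = "PID2")
  # PID4 uses mean sequence length; compute the column convention directly
  if (denominator == "columns") {
    100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
  } else {
    Biostrings::pid(aln, type = pid_type)
  }
}

#' Peptide coverage of a protein sequence
#'
#' Maps each peptide to every exact substring occurrence in the protein and
#' reports the percentage of protein residues covered by the union of all
#' matched spans.  Unmatched peptides contribute nothing and are reported
#' with a warning.
#'
#' @param peptides character vector of peptide sequences.
#' @param protein a [protein_sequence()] or residue string.
#' @return percent coverage in `[0, 100]`, with attributes `covered`
#'   (logical mask per residue) and `unmatched` (peptides never found).
#' @export
sequence_coverage <- function(peptides, protein) {
  protein <- as_protein_sequence(protein)
  if (length(peptides) < 1L || any(!nzchar(peptides))) {
    stop("`peptides` must be non-empty strings", call. = FALSE)
  }
  n <- nchar(protein$residues)
  covered <- logical(n)
  unmatched <- character()
  for (p in unique(toupper(peptides))) {
    hits <- gregexpr(p, protein$residues, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) {
      unmatched <- c(unmatched, p)
      next
    }
    for (h in hits) covered[seq(h, h + nchar(p) - 1L)] <- TRUE
  }
  if (length(unmatched)) {
    warning(length(unmatched), " peptide(s) not found in the protein: ",
            paste(utils::head(unmatched, 5L), collapse = ", "),
            call. = FALSE)
  }
  structure(100 * sum(covered) / n, covered = covered,
            unmatched = unmatched)
}

#' Molecular mass from SDS-PAGE relative migration
#'
#' Relative migration (Rm) is the distance migrated by a band divided by the
#' distance migrated by the dye front; log10 of molecular mass is linear in
#' Rm over the resolving range.  Fits the standards by least squares and
#' evaluates the line at `rm`.
#'
#' @param rm relative migration of the unknown band, in `(0, 1]`.
#' @param standards data frame with columns `mass_kda` and `rm` for at
#'   least two marker proteins.
#' @return estimated mass in kDa.
#' @examples
#' mass_from_relative_migration(
#'   0.5, data.frame(mass_kda = c(97, 14), rm = c(0.1, 0.9)))
#' @export
mass_from_relative_migration <- function(rm, standards) {
  standards <- as.data.frame(standards)
  if (!all(c("mass_kda", "rm") %in% names(standards)) ||
      nrow(standards) < 2L) {
    stop("need >= 2 standards with columns `mass_kda` and `rm`",
         call. = FALSE)
  }
  if (any(rm <= 0) || any(rm > 1)) {
    stop("`rm` must lie in (0, 1]", call. = FALSE)
  }
  fit <- stats::lm(log10(mass_kda) ~ rm, data = standards)
  unname(10^stats::predict(fit, data.frame(rm = rm)))
}
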