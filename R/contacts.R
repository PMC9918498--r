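# Geometry of enzyme-inhibitor structure models: PDB I/O (via bio3d),
# hydrogen-bond detection on heavy atoms, interface residues, and
# reactive-site loop candidates.

# Heavy-atom donor/acceptor typing per residue.  Models rarely carry
# hydrogens, so donors are N/O heavy atoms that bear hydrogens in the
# standard residue templates; acceptors are N/O lone-pair carriers.
DONOR_SIDE <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH")
ACCEPTOR_SIDE <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
  GLN = "OE1", HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1",
  TYR = "OH")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Atomic structure model
#'
#' @param atoms data frame with columns `chain`, `resname`, `resno`,
#'   `atom`, `x`, `y`, `z` (Angstrom).  Coordinates must be finite and
#'   `(chain, resno, atom)` unique.
#' @return a `structure_model` data frame.
#' @export
structure_model <- function(atoms) {
  atoms <- as.data.frame(atoms)
  needed <- c("chain", "resname", "resno", "atom", "x", "y", "z")
  if (!all(needed %in% names(atoms))) {
    stop("`atoms` needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) < 1L) stop("model has no atoms", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) {
    stop("non-finite coordinates in model", call. = FALSE)
  }
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key)) {
    stop("duplicate atom record: ", key[duplicated(key)][1L], call. = FALSE)
  }
  structure(atoms, class = c("structure_model", "data.frame"))
}

#' Chains present in a model
#' @param model a [structure_model()].
#' @return character vector of chain identifiers.
#' @export
model_chains <- function(model) sort(unique(model$chain))

#' Parse a PDB-format structure
#'
#' Reads ATOM (and optionally HETATM) records from a PDB file or from
#' in-memory PDB text, delegating the format handling to bio3d.
#'
#' @param input path to a PDB file, or a character scalar/vector of PDB
#'   text lines.
#' @param include_hetatm keep HETATM records (default FALSE).
#' @return a [structure_model()].
#' @export
parse_structure <- function(input, include_hetatm = FALSE) {
  lines <- if (length(input) == 1L && !grepl("\n", input) &&
               file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE))
  }
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM records in input", call. = FALSE)
  # validate coordinate fields before handing off, to report line numbers
  for (i in which(is_atom)) {
    coords <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31L, 38L), substr(lines[i], 39L, 46L),
      substr(lines[i], 47L, 54L))))
    if (any(is.na(coords))) {
      stop("malformed coordinate field at line ", i, call. = FALSE)
    }
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  at <- pdb$atom
  if (!include_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in input", call. = FALSE)
  at$chain[is.na(at$chain)] <- " "
  structure_model(data.frame(
    chain = at$chain, resname = at$resid, resno = at$resno,
    atom = at$elety, x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE))
}

#' Write a model as PDB text
#'
#' @param model a [structure_model()].
#' @param file output path; when `NULL` the PDB text lines are returned
#'   invisibly instead.
#' @return the file path, or the text lines when `file` is `NULL`.
#' @export
write_structure <- function(model, file = NULL) {
  tf <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = tf,
                   xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
                   resno = model$resno, resid = model$resname,
                   chain = model$chain, elety = model$atom,
                   eleno = seq_len(nrow(model)))
  if (is.null(file)) {
    out <- readLines(tf, warn = FALSE)
    unlink(tf)
    invisible(out)
  } else {
    invisible(file)
  }
}

# Resolve an atom reference: list(chain=, resno=, atom=) or "A/12/NZ".
resolve_atom <- function(model, ref) {
  if (is.character(ref) && length(ref) == 1L) {
    parts <- strsplit(ref, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 3L) {
      stop("atom reference string must be 'chain/resno/atom'", call. = FALSE)
    }
    ref <- list(chain = parts[1L], resno = as.integer(parts[2L]),
                atom = parts[3L])
  }
  hit <- which(model$chain == ref$chain & model$resno == ref$resno &
               model$atom == ref$atom)
  if (length(hit) != 1L) {
    stop("cannot resolve atom ", ref$chain, "/", ref$resno, "/", ref$atom,
         call. = FALSE)
  }
  hit
}

#' Euclidean distance between two atoms
#'
#' @param model a [structure_model()].
#' @param ref1,ref2 atom references: `list(chain=, resno=, atom=)` or a
#'   string `"chain/resno/atom"`.
#' @return distance in Angstrom.
#' @export
measure_distance <- function(model, ref1, ref2) {
  i <- resolve_atom(model, ref1)
  j <- resolve_atom(model, ref2)
  sqrt(sum((as.numeric(model[i, c("x", "y", "z")]) -
            as.numeric(model[j, c("x", "y", "z")]))^2))
}

is_donor <- function(resname, atom) {
  (atom == "N" & resname != "PRO") |
    mapply(function(rn, at) at %in% (DONOR_SIDE[[rn]] %||% character()),
           resname, atom)
}

is_acceptor <- function(resname, atom) {
  atom %in% c("O", "OXT") |
    mapply(function(rn, at) at %in% (ACCEPTOR_SIDE[[rn]] %||% character()),
           resname, atom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hydrogen bonds across a two-chain interface
#'
#' Enumerates heavy-atom donor/acceptor pairs between two chains with
#' donor-acceptor distance at or below `cutoff` (PIC-style distance
#' criterion; hydrogens are inferred from residue templates, not required
#' in the model).  Both directions are considered: donors of either chain
#' against acceptors of the other.
#'
#' @param model a [structure_model()].
#' @param chain_a,chain_b chain identifiers, both present in the model.
#' @param cutoff donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @return data frame (class `hydrogen_bonds`) sorted by distance with
#'   donor/acceptor chain, residue name, residue number, atom name, and
#'   `distance`; the bond class (`main-main`, `main-side`, `side-side`) in
#'   `class`.
#' @export
find_hbonds <- function(model, chain_a, chain_b, cutoff = 3.5) {
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% model$chain) stop("chain ", ch, " not in model",
                                   call. = FALSE)
  }
  pairs <- list()
  for (dir in list(c(chain_a, chain_b), c(chain_b, chain_a))) {
    don <- model[model$chain == dir[1L] &
                   is_donor(model$resname, model$atom), , drop = FALSE]
    acc <- model[model$chain == dir[2L] &
                   is_acceptor(model$resname, model$atom), , drop = FALSE]
    if (nrow(don) == 0L || nrow(acc) == 0L) next
    for (i in seq_len(nrow(don))) {
      d <- sqrt((acc$x - don$x[i])^2 + (acc$y - don$y[i])^2 +
                (acc$z - don$z[i])^2)
      hit <- which(d <= cutoff)
      for (j in hit) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          donor_chain = don$chain[i], donor_resname = don$resname[i],
          donor_resno = don$resno[i], donor_atom = don$atom[i],
          acceptor_chain = acc$chain[j], acceptor_resname = acc$resname[j],
          acceptor_resno = acc$resno[j], acceptor_atom = acc$atom[j],
          distance = d[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(pairs)) {
    out <- data.frame(donor_chain = character(), donor_resname = character(),
                      donor_resno = integer(), donor_atom = character(),
                      acceptor_chain = character(),
                      acceptor_resname = character(),
                      acceptor_resno = integer(), acceptor_atom = character(),
                      distance = numeric())
    return(structure(out, class = c("hydrogen_bonds", "data.frame")))
  }
  out <- do.call(rbind, pairs)
  # one record per unordered atom pair: keep the first (deterministic) role
  key <- apply(cbind(
    paste(out$donor_chain, out$donor_resno, out$donor_atom),
    paste(out$acceptor_chain, out$acceptor_resno, out$acceptor_atom)),
    1L, function(r) paste(sort(r), collapse = "|"))
  out <- out[!duplicated(key), , drop = FALSE]
  out$class <- paste0(
    ifelse(out$donor_atom %in% BACKBONE_ATOMS, "main", "side"), "-",
    ifelse(out$acceptor_atom %in% BACKBONE_ATOMS, "main", "side"))
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hydrogen_bonds", "data.frame"))
}

#' Residue pairs at a two-chain interface
#'
#' All residue pairs across two chains whose closest atom-atom distance is
#' at or below `cutoff`, classified by the atoms achieving that minimum
#' (`main-main`, `main-side`, `side-side`).  An optional list of residue
#' numbers (catalytic or specificity-pocket residues) marks pairs that
#' touch them.
#'
#' @inheritParams find_hbonds
#' @param cutoff any-atom distance cutoff in Angstrom (default 4.0).
#' @param flag_residues optional integer residue numbers to flag (matched
#'   on either chain).
#' @return data frame (class `interface_report`) with residue identities,
#'   `min_distance`, contact `class`, and logical `flagged`.
#' @export
interface_residues <- function(model, chain_a, chain_b, cutoff = 4.0,
                               flag_residues = NULL) {
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% model$chain) stop("chain ", ch, " not in model",
                                   call. = FALSE)
  }
  a <- model[model$chain == chain_a, , drop = FALSE]
  b <- model[model$chain == chain_b, , drop = FALSE]
  rows <- list()
  for (ra in unique(a$resno)) {
    aa <- a[a$resno == ra, , drop = FALSE]
    for (rb in unique(b$resno)) {
      bb <- b[b$resno == rb, , drop = FALSE]
      dm <- outer(seq_len(nrow(aa)), seq_len(nrow(bb)),
                  Vectorize(function(i, j) {
                    sqrt((aa$x[i] - bb$x[j])^2 + (aa$y[i] - bb$y[j])^2 +
                         (aa$z[i] - bb$z[j])^2)
                  }))
      mn <- min(dm)
      if (mn > cutoff) next
      idx <- which(dm == mn, arr.ind = TRUE)[1L, ]
      cls <- paste0(
        ifelse(aa$atom[idx[1L]] %in% BACKBONE_ATOMS, "main", "side"), "-",
        ifelse(bb$atom[idx[2L]] %in% BACKBONE_ATOMS, "main", "side"))
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = chain_a, resname_a = aa$resname[1L], resno_a = ra,
        chain_b = chain_b, resname_b = bb$resname[1L], resno_b = rb,
        min_distance = mn, class = cls,
        flagged = !is.null(flag_residues) &&
          (ra %in% flag_residues || rb %in% flag_residues),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(chain_a = character(), resname_a = character(),
                      resno_a = integer(), chain_b = character(),
                      resname_b = character(), resno_b = integer(),
                      min_distance = numeric(), class = character(),
                      flagged = logical())
    return(structure(out, class = c("interface_report", "data.frame")))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$min_distance), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("interface_report", "data.frame"))
}

#' Candidate reactive-site loops of an inhibitor sequence
#'
#' Canonical (Laskowski-mechanism) serine-protease inhibitors insert a
#' substrate-like surface loop into the enzyme's S1 pocket; for trypsin the
#' P1 residue is Lys or Arg.  Candidate loops are the contiguous segments
#' annotated as coil (when a secondary-structure string is supplied) or the
#' segments between consecutive cysteines (sequence-only fallback, since
#' disulfide-anchored inter-cysteine stretches are the exposed loops of a
#' knottin scaffold), retaining only segments that contain at least one K
#' or R.  Loops are labelled `A`, `B`, ... in order of position.
#'
#' @param seq a [protein_sequence()] or residue string.
#' @param ss optional secondary-structure string of the same length; `H`,
#'   `G`, `I` (helix), `E`, `B` (strand) are structured, anything else is
#'   coil.
#' @param framework optional `cys_framework` (computed from `seq` when
#'   absent).
#' @return data frame with columns `label`, `start`, `end`, and a list
#'   column `basic_residues` of K/R positions; zero rows when no segment
#'   qualifies.
#' @export
reactive_loop_candidates <- function(seq, ss = NULL, framework = NULL) {
  seq <- as_protein_sequence(seq)
  chars <- seq_chars(seq)
  n <- length(chars)
  if (!is.null(ss)) {
    if (nchar(ss) != n) {
      stop("secondary-structure string length differs from sequence",
           call. = FALSE)
    }
    sschars <- strsplit(toupper(ss), "")[[1L]]
    coil <- !(sschars %in% c("H", "G", "I", "E", "B"))
    r <- rle(coil)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- data.frame(start = starts[r$values], end = ends[r$values])
  } else {
    if (is.null(framework)) framework <- extract_framework(seq)
    cys <- framework$positions
    bounds <- c(0L, cys, n + 1L)
    segs <- data.frame(start = utils::head(bounds, -1L) + 1L,
                       end = utils::tail(bounds, -1L) - 1L)
    segs <- segs[segs$end >= segs$start, , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(segs))) {
    span <- segs$start[i]:segs$end[i]
    basics <- span[chars[span] %in% c("K", "R")]
    if (!length(basics)) next
    out[[length(out) + 1L]] <- data.frame(label = "", start = segs$start[i],
                                          end = segs$end[i])
    out[[length(out)]]$basic_residues <- I(list(basics))
  }
  if (!length(out)) {
    return(data.frame(label = character(), start = integer(),
                      end = integer(),
                      basic_residues = I(list())))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  res$label <- LETTERS[seq_len(nrow(res))]
  rownames(res) <- NULL
  res
}
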