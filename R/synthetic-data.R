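#' Simulation specification for a tight-binding titration
#'
#' Ground-truth conditions for [gen_titration()].  Defaults reproduce the
#' study conditions of a spider digestive-tract trypsin inhibitor titrated
#' against bovine trypsin: enzyme at 515 nM (12 ng/uL at MW 23,300 Da),
#' inhibitor dilution series from 0.25 to 4 uM plus the uninhibited control,
#' triplicate assays with 2% multiplicative read-out noise.
#'
#' @param true_kd ground-truth dissociation constant (nM), >= 0.
#' @param enzyme_total total enzyme concentration (nM), > 0.
#' @param inhibitor_grid strictly increasing inhibitor concentrations (nM)
#'   including 0.
#' @param noise_cv coefficient of variation of the multiplicative read-out
#'   noise, in `[0, 0.5]`.
#' @param n_replicates number of replicate titrations, >= 1.
#' @param seed integer seed; every simulation from the same spec is
#'   bit-reproducible.
#' @return a `titration_sim_spec` list.
#' @export
titration_sim_spec <- function(true_kd = 30.25,
                               enzyme_total = 515,
                               inhibitor_grid = seq(0, 4000, by = 250),
                               noise_cv = 0.02,
                               n_replicates = 3,
                               seed = 1L) {
  if (!is.finite(true_kd) || true_kd < 0) {
    stop("invalid `true_kd`: must be a concentration >= 0", call. = FALSE)
  }
  if (!is.finite(enzyme_total) || enzyme_total <= 0) {
    stop("invalid `enzyme_total`: must be a concentration > 0", call. = FALSE)
  }
  if (any(inhibitor_grid < 0)) {
    stop("invalid `inhibitor_grid`: concentrations must be >= 0",
         call. = FALSE)
  }
  if (is.unsorted(inhibitor_grid, strictly = TRUE)) {
    stop("invalid `inhibitor_grid`: must be strictly increasing",
         call. = FALSE)
  }
  if (inhibitor_grid[1L] != 0) {
    stop("invalid `inhibitor_grid`: must include 0 (the control)",
         call. = FALSE)
  }
  if (noise_cv < 0 || noise_cv > 0.5) {
    stop("invalid `noise_cv`: must lie in [0, 0.5]", call. = FALSE)
  }
  if (n_replicates < 1) {
    stop("invalid `n_replicates`: must be >= 1", call. = FALSE)
  }
  structure(list(true_kd = true_kd, enzyme_total = enzyme_total,
                 inhibitor_grid = inhibitor_grid, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "titration_sim_spec")
}

#' Simulate a residual-activity titration with known ground truth
#'
#' Forward model is the tight-binding equilibrium ([morrison_activity()]);
#' multiplicative Gaussian noise `a * (1 + eps)`, `eps ~ N(0, noise_cv)`,
#' emulates rate read-outs normalised to an uninhibited control, clipped to
#' `[0, 1.05]` to allow slight super-control noise.
#'
#' @param spec a [titration_sim_spec()].
#' @return a [titration_series()] with `n_replicates` replicates and the
#'   true enzyme total attached.
#' @export
gen_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_sim_spec"))
  withr::with_seed(spec$seed, {
    parts <- lapply(seq_len(spec$n_replicates), function(r) {
      a <- morrison_activity(spec$enzyme_total, spec$inhibitor_grid,
                             spec$true_kd)
      if (spec$noise_cv > 0) {
        a <- a * (1 + stats::rnorm(length(a), 0, spec$noise_cv))
        a <- pmin(pmax(a, 0), 1.05)
      }
      data.frame(inhibitor_total = spec$inhibitor_grid,
                 activity_fraction = a, replicate = r)
    })
    d <- do.call(rbind, parts)
    titration_series(d$inhibitor_total, d$activity_fraction, d$replicate,
                     enzyme_total = spec$enzyme_total)
  })
}

#' Simulation specification for an electrospray charge-state envelope
#'
#' @param true_mass neutral (uncharged) mass in Da, > 0.
#' @param charges distinct positive integer charge states.
#' @param adduct_mass mass of the charge-carrying adduct (default the
#'   proton, 1.007276 Da).
#' @param mz_noise_sd Gaussian noise on each m/z peak (Da), >= 0.
#' @param seed integer seed.
#' @return an `envelope_sim_spec` list.
#' @export
envelope_sim_spec <- function(true_mass, charges,
                              adduct_mass = 1.007276,
                              mz_noise_sd = 0, seed = 1L) {
  if (!is.finite(true_mass) || true_mass <= 0) {
    stop("invalid `true_mass`: must be > 0", call. = FALSE)
  }
  if (length(charges) < 1L) {
    stop("invalid `charges`: must supply at least one charge state",
         call. = FALSE)
  }
  if (any(charges < 1) || any(charges != round(charges)) ||
      anyDuplicated(charges)) {
    stop("invalid `charges`: must be distinct positive integers",
         call. = FALSE)
  }
  if (mz_noise_sd < 0) stop("invalid `mz_noise_sd`", call. = FALSE)
  structure(list(true_mass = true_mass, charges = as.integer(charges),
                 adduct_mass = adduct_mass, mz_noise_sd = mz_noise_sd,
                 seed = as.integer(seed)),
            class = "envelope_sim_spec")
}

#' Simulate a multi-charge ESI envelope from a true neutral mass
#'
#' Each charge state `z` contributes a peak at
#' `(true_mass + z * adduct_mass) / z` plus optional Gaussian m/z noise;
#' peaks are returned sorted by ascending m/z.
#'
#' @param spec an [envelope_sim_spec()].
#' @return an [ion_envelope()].
#' @export
gen_envelope <- function(spec) {
  stopifnot(inherits(spec, "envelope_sim_spec"))
  withr::with_seed(spec$seed, {
    mz <- (spec$true_mass + spec$charges * spec$adduct_mass) / spec$charges
    if (spec$mz_noise_sd > 0) {
      mz <- mz + stats::rnorm(length(mz), 0, spec$mz_noise_sd)
    }
    ion_envelope(sort(mz))
  })
}

#' Generate a random sequence carrying a prescribed cysteine framework
#'
#' Builds a protein sequence with exactly the cysteine count of a registered
#' disulfide-scaffold family, the cysteines separated by random non-cysteine
#' spacers of prescribed lengths (`n_cys + 1` spacers: before the first C,
#' between consecutive C's, and after the last C).
#'
#' @param template_name family name in the scaffold registry (see
#'   [family_templates()]), e.g. `"ICK"` or `"MIT1-colipase"`.
#' @param spacer_lengths integer vector of `n_cys + 1` spacer lengths >= 0.
#' @param seed integer seed.
#' @return a [protein_sequence()].
#' @export
gen_framework_sequence <- function(template_name, spacer_lengths, seed = 1L) {
  tmpl <- family_template(template_name)
  n_cys <- tmpl$n_cys
  if (length(spacer_lengths) != n_cys + 1L) {
    stop("need ", n_cys + 1L, " spacer lengths for the ", template_name,
         " framework (", n_cys, " cysteines), got ", length(spacer_lengths),
         call. = FALSE)
  }
  if (any(spacer_lengths < 0)) stop("spacer lengths must be >= 0",
                                    call. = FALSE)
  non_cys <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "C")
  withr::with_seed(seed, {
    spacers <- vapply(spacer_lengths, function(len) {
      paste(sample(non_cys, len, replace = TRUE), collapse = "")
    }, character(1L))
    residues <- paste0(paste0(spacers[seq_len(n_cys)], "C", collapse = ""),
                       spacers[n_cys + 1L])
    protein_sequence(paste0("synthetic_", template_name), residues)
  })
}

#' Generate a toy two-chain complex with prescribed donor-acceptor distances
#'
#' Builds a minimal two-chain coordinate model in which each requested
#' donor/acceptor atom pair lies at exactly the requested distance: donors
#' go to chain A, acceptors to chain B, successive pairs are separated by
#' 20 Angstrom along z so they cannot interfere.  The result is a valid
#' [structure_model()] that survives a PDB round trip (coordinates are laid
#' out on the 0.001 Angstrom grid of the fixed-width PDB format).
#'
#' @param pairs a data frame (or list coercible to one) with columns
#'   `donor_resname`, `donor_atom`, `acceptor_resname`, `acceptor_atom`,
#'   `distance` (Angstrom, > 0).
#' @param seed integer seed (reserved for jitter extensions; the layout
#'   itself is deterministic).
#' @return a [structure_model()] with chains `"A"` and `"B"`.
#' @export
gen_toy_complex <- function(pairs, seed = 1L) {
  pairs <- as.data.frame(pairs)
  needed <- c("donor_resname", "donor_atom", "acceptor_resname",
              "acceptor_atom", "distance")
  if (!all(needed %in% names(pairs))) {
    stop("`pairs` needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(pairs$distance <= 0)) {
    stop("conflicting constraints: distances must be > 0", call. = FALSE)
  }
  if (any(pairs$distance != round(pairs$distance * 1000) / 1000)) {
    stop("conflicting constraints: distances must be representable at ",
         "0.001 Angstrom (PDB precision)", call. = FALSE)
  }
  n <- nrow(pairs)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    z <- 20 * (i - 1)
    data.frame(
      chain = c("A", "B"),
      resname = c(pairs$donor_resname[i], pairs$acceptor_resname[i]),
      resno = c(i, i),
      atom = c(pairs$donor_atom[i], pairs$acceptor_atom[i]),
      x = c(0, pairs$distance[i]),
      y = c(0, 0),
      z = c(z, z),
      stringsAsFactors = FALSE
    )
  }))
  structure_model(atoms)
}
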