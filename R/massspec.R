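#' Centroided ion envelope
#'
#' A charge-state envelope: the set of centroid m/z peaks that one molecule
#' produces at consecutive protonation states in electrospray ionisation.
#'
#' @param mz peak positions in Thomson (m/z), > 0; stored sorted ascending.
#' @param intensity optional peak intensities (arbitrary units).
#' @return an `ion_envelope` data frame with columns `mz`, `intensity`.
#' @export
ion_envelope <- function(mz, intensity = NULL) {
  if (length(mz) < 1L) stop("need at least one peak", call. = FALSE)
  if (any(!is.finite(mz)) || any(mz <= 0)) {
    stop("m/z values must be finite and > 0", call. = FALSE)
  }
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  if (length(intensity) != length(mz)) {
    stop("`intensity` must match `mz` in length", call. = FALSE)
  }
  o <- order(mz)
  structure(data.frame(mz = mz[o], intensity = intensity[o]),
            class = c("ion_envelope", "data.frame"))
}

as_ion_envelope <- function(x) {
  if (inherits(x, "ion_envelope")) return(x)
  if (is.numeric(x)) return(ion_envelope(x))
  if (is.data.frame(x) && "mz" %in% names(x)) {
    return(ion_envelope(x$mz, x$intensity))
  }
  stop("cannot interpret input as an ion envelope", call. = FALSE)
}

#' Neutral mass of one ion
#'
#' The electrospray relation `M = z * (m/z) - z * m_adduct`: an ion observed
#' at `mz` carrying `z` adducts of mass `adduct_mass` (protons by default)
#' implies a neutral mass `M`.
#'
#' @param mz observed m/z in Thomson (vectorised).
#' @param z charge state, positive integer (vectorised with `mz`).
#' @param adduct_mass adduct mass in Da (default proton, 1.007276).
#' @return neutral mass in Da.
#' @examples
#' neutral_mass(1102.4051, 9) # ~9912.58
#' @export
neutral_mass <- function(mz, z, adduct_mass = 1.007276) {
  if (any(z < 1) || any(z != round(z))) {
    stop("`z` must be a positive integer charge", call. = FALSE)
  }
  if (any(mz <= adduct_mass)) {
    stop("m/z must exceed the adduct mass", call. = FALSE)
  }
  z * mz - z * adduct_mass
}

#' Assign consecutive charge states to an envelope
#'
#' Searches all assignments of consecutive descending charges (ascending
#' m/z peaks carry descending z) with every charge inside `[z_min, z_max]`,
#' and keeps the assignment whose implied per-peak neutral masses have the
#' smallest variance.  An envelope is accepted only if that best assignment
#' is self-consistent: the relative spread (sample SD over mean) of the
#' implied masses must fall below `max_rel_spread`.
#'
#' Intensities play no role; the assignment depends only on peak positions.
#'
#' @param env an [ion_envelope()] (or bare numeric m/z vector); >= 2 peaks
#'   for an unambiguous assignment.
#' @param z_min,z_max inclusive charge search range (defaults 1 and 30).
#' @param adduct_mass adduct mass in Da (default proton).
#' @param max_rel_spread acceptance threshold on sd(mass)/mean(mass)
#'   (default 0.01).
#' @return a `charge_assignment`: list with `charges` (aligned with the
#'   sorted peaks), `adduct_mass`, `per_peak_mass`, and `variance`.
#' @examples
#' assign_charges(c(1102.4051, 1239.9110, 1417.0741))$charges # 9 8 7
#' @export
assign_charges <- function(env, z_min = 1L, z_max = 30L,
                           adduct_mass = 1.007276, max_rel_spread = 0.01) {
  env <- as_ion_envelope(env)
  n <- nrow(env)
  if (n < 2L) {
    stop("need at least 2 peaks for an unambiguous charge assignment",
         call. = FALSE)
  }
  if (z_min < 1L || z_max < z_min) stop("invalid charge range", call. = FALSE)
  if (z_max - z_min + 1L < n) {
    stop("charge range [", z_min, ", ", z_max, "] cannot hold ", n,
         " consecutive charges", call. = FALSE)
  }
  best <- NULL
  for (z_top in seq(z_min + n - 1L, z_max)) {
    zs <- seq(z_top, by = -1L, length.out = n) # lowest m/z gets highest z
    if (any(env$mz <= adduct_mass)) next
    masses <- neutral_mass(env$mz, zs, adduct_mass)
    v <- stats::var(masses)
    if (is.null(best) || v < best$variance) {
      best <- list(charges = zs, adduct_mass = adduct_mass,
                   per_peak_mass = masses, variance = v)
    }
  }
  if (is.null(best)) stop("no candidate charge assignment", call. = FALSE)
  rel <- sqrt(best$variance) / mean(best$per_peak_mass)
  if (rel >= max_rel_spread) {
    stop("no consistent envelope: best assignment has relative mass spread ",
         signif(100 * rel, 3), "%", call. = FALSE)
  }
  structure(best, class = "charge_assignment")
}

#' Deconvolve an ion envelope to a neutral mass
#'
#' Assigns consecutive charge states ([assign_charges()]) and averages the
#' implied per-peak neutral masses.  The unweighted mean is the default;
#' `intensity_weighted = TRUE` weights each peak's mass by its intensity.
#'
#' @inheritParams assign_charges
#' @param intensity_weighted use intensity-weighted mean (default FALSE).
#' @return a `deconvolution_result`: list with `mass` (Da), `spread`
#'   (sample SD of the per-peak masses, Da), and `assignment`.
#' @examples
#' deconvolve(c(1102.4051, 1239.9110, 1417.0741))
#' @export
deconvolve <- function(env, z_min = 1L, z_max = 30L,
                       adduct_mass = 1.007276, max_rel_spread = 0.01,
                       intensity_weighted = FALSE) {
  env <- as_ion_envelope(env)
  if (nrow(env) == 1L) {
    stop("a single peak cannot be deconvolved; use neutral_mass() with a ",
         "known charge", call. = FALSE)
  }
  asg <- assign_charges(env, z_min, z_max, adduct_mass, max_rel_spread)
  m <- if (intensity_weighted) {
    stats::weighted.mean(asg$per_peak_mass, env$intensity)
  } else {
    mean(asg$per_peak_mass)
  }
  structure(list(mass = m,
                 spread = stats::sd(asg$per_peak_mass),
                 assignment = asg),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("Deconvolved neutral mass: %.4f Da (sd %.4f, n = %d peaks)\n",
              x$mass, x$spread, length(x$assignment$charges)))
  cat("  charges:", paste(x$assignment$charges, collapse = ", "), "\n")
  invisible(x)
}

#' Neutral-mass candidates for a singly charged MALDI peak
#'
#' A singly charged peak at `observed_mz` may carry any of several adducts
#' (proton, sodium, ...); each candidate neutral mass is the observed mass
#' minus one adduct mass.
#'
#' @param observed_mz observed singly-charged peak position (Da).
#' @param adducts named numeric vector of adduct masses (Da); default
#'   proton and sodium.
#' @return data frame with columns `adduct` and `neutral_mass`; empty when
#'   no adducts are supplied.
#' @examples
#' adduct_candidates(10039.0455)
#' @export
adduct_candidates <- function(observed_mz,
                              adducts = c("H+" = 1.007276,
                                          "Na+" = 22.989218)) {
  if (length(adducts) == 0L) {
    return(data.frame(adduct = character(), neutral_mass = numeric()))
  }
  if (is.null(names(adducts)) || any(names(adducts) == "")) {
    stop("`adducts` must be a named vector of masses", call. = FALSE)
  }
  data.frame(adduct = names(adducts),
             neutral_mass = observed_mz - unname(adducts))
}
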