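# Shared fixtures, all built in code.

# Noise-free Morrison titration as a titration_series.
morrison_series <- function(enzyme_total = 515, kd = 30.25,
                            grid = seq(0, 4000, by = 250)) {
  titration_series(grid, morrison_activity(enzyme_total, grid, kd),
                   enzyme_total = enzyme_total)
}

# Independent oracle for the tight-binding activity: root of the
# free-enzyme mass balance Ef = Et - Ef*I/(K + Ef), solved numerically.
morrison_oracle <- function(enzyme_total, inhibitor_total, kd) {
  vapply(inhibitor_total, function(I) {
    if (I == 0) return(1)
    f <- function(Ef) Ef + Ef * I / (kd + Ef) - enzyme_total
    Ef <- stats::uniroot(f, c(0, enzyme_total), tol = 1e-12)$root
    Ef / enzyme_total
  }, numeric(1L))
}

# Two-chain toy pose with one Lys NZ -> Ser OG contact at `dist` Angstrom.
toy_pair_model <- function(dist) {
  gen_toy_complex(data.frame(
    donor_resname = "LYS", donor_atom = "NZ",
    acceptor_resname = "SER", acceptor_atom = "OG",
    distance = dist))
}
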