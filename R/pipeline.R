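# One-shot orchestration of the characterization stages.

#' Configuration for a characterization run
#'
#' A flat key/value configuration naming the inputs and parameters of each
#' stage.  Only stages whose inputs are supplied run; at least one stage
#' must be enabled.
#'
#' @param fasta path to a FASTA file with the inhibitor sequence (enables
#'   the sequence and cysteine-framework stages).
#' @param cleavage_site optional 1-based signal-peptide cleavage index
#'   applied to the first FASTA record.
#' @param titration_csv path to a titration CSV (enables the kinetics
#'   stage).
#' @param enzyme_total optional known total enzyme concentration (nM) for
#'   the kinetics stage.
#' @param envelope_csv path to an m/z peak-list CSV (enables the
#'   deconvolution stage).
#' @param pdb path to an enzyme-inhibitor pose (enables the contacts
#'   stage).
#' @param chain_a,chain_b chain identifiers for the contacts stage.
#' @param bonds optional disulfide connectivity, e.g.
#'   `"1-4,2-5,3-7,6-9,8-10"` (enables connectivity classification).
#' @param pka_set pKa set for the pI computation.
#' @param z_min,z_max charge search range for deconvolution.
#' @param adduct_mass adduct mass (Da).
#' @param hbond_cutoff hydrogen-bond cutoff (Angstrom).
#' @param rect_floor rectilinear-region floor for the kinetics stage.
#' @param seed integer seed recorded in the report and used for any
#'   stochastic step.
#' @return a `run_config` list.
#' @export
run_config <- function(fasta = NULL, cleavage_site = NULL,
                       titration_csv = NULL, enzyme_total = NULL,
                       envelope_csv = NULL, pdb = NULL,
                       chain_a = "A", chain_b = "B", bonds = NULL,
                       pka_set = pka_bjellqvist(),
                       z_min = 1L, z_max = 30L, adduct_mass = 1.007276,
                       hbond_cutoff = 3.5, rect_floor = 0.5, seed = 1L) {
  cfg <- list(fasta = fasta, cleavage_site = cleavage_site,
              titration_csv = titration_csv, enzyme_total = enzyme_total,
              envelope_csv = envelope_csv, pdb = pdb,
              chain_a = chain_a, chain_b = chain_b, bonds = bonds,
              pka_set = pka_set, z_min = z_min, z_max = z_max,
              adduct_mass = adduct_mass, hbond_cutoff = hbond_cutoff,
              rect_floor = rect_floor, seed = as.integer(seed))
  stages <- enabled_stages(cfg)
  if (!length(stages)) {
    stop("configuration enables no stage: supply at least one of `fasta`, ",
         "`titration_csv`, `envelope_csv`, `pdb`, `bonds`", call. = FALSE)
  }
  for (p in c(cfg$fasta, cfg$titration_csv, cfg$envelope_csv, cfg$pdb)) {
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

enabled_stages <- function(cfg) {
  c(if (!is.null(cfg$fasta)) c("sequence", "cysframe"),
    if (!is.null(cfg$titration_csv)) "kinetics",
    if (!is.null(cfg$envelope_csv)) "massspec",
    if (!is.null(cfg$bonds)) "connectivity",
    if (!is.null(cfg$pdb)) "contacts")
}

parse_bonds <- function(text) {
  parts <- strsplit(trimws(strsplit(text, ",")[[1L]]), "-")
  connectivity_pattern(lapply(parts, as.integer))
}

run_stage <- function(name, expr) {
  tryCatch(list(ok = TRUE, result = expr),
           error = function(e) list(ok = FALSE,
                                    error = conditionMessage(e)))
}

#' Run the full characterization pipeline
#'
#' Executes every enabled stage, isolating failures per stage: a stage
#' error is recorded in the report and never disturbs the other stages.
#' Given identical inputs and seed, the serialized report
#' ([write_report()]) is byte-identical between runs.
#'
#' @param config a [run_config()].
#' @return a `characterization_report`: list of per-stage results (or
#'   recorded failures) plus provenance (`seed`, enabled stages, input
#'   digests).
#' @export
run_characterization <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- enabled_stages(config)
  report <- list()

  if ("sequence" %in% stages) {
    report$sequence <- run_stage("sequence", {
      seqs <- read_fasta_sequences(config$fasta)
      s <- seqs[[1L]]
      if (!is.null(config$cleavage_site)) {
        s <- protein_sequence(s$id, s$residues, config$cleavage_site)
      }
      prof <- list(id = s$id,
                   length = nchar(s$residues),
                   average_mass = average_mass(s, allow_x = TRUE),
                   monoisotopic_mass = monoisotopic_mass(s, allow_x = TRUE),
                   pi = isoelectric_point(s, config$pka_set))
      if (!is.null(s$cleavage_site)) {
        m <- mature_sequence(s)
        prof$mature <- list(length = nchar(m$residues),
                            average_mass = average_mass(m, allow_x = TRUE),
                            pi = isoelectric_point(m, config$pka_set))
      }
      prof$pest <- find_pest(s)
      prof
    })
  }
  if ("cysframe" %in% stages) {
    report$cysframe <- run_stage("cysframe", {
      s <- read_fasta_sequences(config$fasta)[[1L]]
      fw <- extract_framework(s)
      list(count = fw$count, positions = fw$positions,
           spacings = fw$spacings,
           candidate_families = names(candidate_families(fw)))
    })
  }
  if ("connectivity" %in% stages) {
    report$connectivity <- run_stage("connectivity", {
      m <- classify_connectivity(parse_bonds(config$bonds))
      list(name = m$name, match = m$match, jaccard = m$jaccard,
           mismatches = m$mismatches)
    })
  }
  if ("kinetics" %in% stages) {
    report$kinetics <- run_stage("kinetics", {
      series <- read_titration_csv(config$titration_csv,
                                   enzyme_total = config$enzyme_total)
      est <- kd_stoichiometric(series, rect_floor = config$rect_floor,
                               n_boot = 100, seed = config$seed)
      list(kd = est$kd, se_kd = est$se_kd,
           equivalence_point = est$equivalence_point,
           free_enzyme = est$free_enzyme,
           complex_conc = est$complex_conc, method = est$method)
    })
  }
  if ("massspec" %in% stages) {
    report$massspec <- run_stage("massspec", {
      env <- read_envelope_csv(config$envelope_csv)
      dec <- deconvolve(env, config$z_min, config$z_max, config$adduct_mass)
      list(mass = dec$mass, spread = dec$spread,
           charges = dec$assignment$charges)
    })
  }
  if ("contacts" %in% stages) {
    report$contacts <- run_stage("contacts", {
      model <- parse_structure(config$pdb)
      hb <- find_hbonds(model, config$chain_a, config$chain_b,
                        config$hbond_cutoff)
      list(n_hbonds = nrow(hb), hbonds = as.data.frame(hb))
    })
  }

  structure(list(stages = report,
                 provenance = list(
                   seed = config$seed,
                   enabled = stages,
                   inputs = input_digests(config))),
            class = "characterization_report")
}

input_digests <- function(config) {
  paths <- Filter(Negate(is.null),
                  list(fasta = config$fasta,
                       titration_csv = config$titration_csv,
                       envelope_csv = config$envelope_csv,
                       pdb = config$pdb))
  lapply(paths, function(p) {
    # cheap content digest with no extra dependency: size + checksum of bytes
    bytes <- readBin(p, "raw", file.info(p)$size)
    sprintf("size=%d;sum=%.0f", length(bytes),
            sum(as.integer(bytes) * rep_len(c(1, 3, 7, 11), length(bytes))))
  })
}

# Reduce bespoke S3 containers to plain lists/data frames for JSON.
strip_classes <- function(x) {
  if (is.data.frame(x)) {
    class(x) <- "data.frame"
    return(x)
  }
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, strip_classes))
  }
  x
}

#' Serialize a characterization report to JSON
#'
#' Deterministic: no timestamps, stable key order, fixed precision.
#'
#' @param report a `characterization_report`.
#' @param path output path; when `NULL`, the JSON string is returned.
#' @return the path (invisibly), or the JSON string.
#' @export
write_report <- function(report, path = NULL) {
  js <- jsonlite::toJSON(strip_classes(report), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("<characterization_report>\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-12s %s\n", nm,
                if (st$ok) "ok" else paste("FAILED:", st$error)))
  }
  cat("  stages:", paste(x$provenance$enabled, collapse = ", "), "\n")
  invisible(x)
}
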