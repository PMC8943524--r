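# Physicochemical featurization of cross-linked peptide pairs for CV
# regression: masses, m/z, solution charge, hydropathy and composition.

#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses, one water for the intact chain
#' termini (optional) and any modification mass deltas.
#'
#' @param sequence Amino-acid string (canonical residues only); vectorised.
#' @param modifications Optional data frame with a `mass_delta` column (Da)
#'   applied to a single sequence, or a list of such frames (one per
#'   sequence).
#' @param include_water Add the terminal water (default TRUE).
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("G")   # 75.03203
#' monoisotopic_mass("", include_water = TRUE)  # water only
monoisotopic_mass <- function(sequence, modifications = NULL,
                              include_water = TRUE) {
  res_mass <- vapply(strsplit(sequence, ""), function(chars) {
    if (length(chars) == 0L) return(0)
    bad <- setdiff(chars, names(AA_MONO_MASS))
    if (length(bad) > 0L) {
      stop("unknown residue(s): ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    }
    sum(AA_MONO_MASS[chars])
  }, numeric(1))
  mass <- res_mass + if (include_water) WATER_MASS else 0
  if (!is.null(modifications)) {
    if (is.data.frame(modifications)) modifications <- list(modifications)
    stopifnot(length(modifications) == length(sequence))
    mass <- mass + vapply(modifications, function(m) {
      if (is.null(m)) 0 else sum(m$mass_delta)
    }, numeric(1))
  }
  mass
}

#' Mass of a cross-linked peptide pair
#'
#' Both chains stay intact (each keeps its terminal water); the cross-linker
#' bridge mass is added once.
#'
#' @param seq_alpha,seq_beta Peptide sequences; vectorised in parallel.
#' @param crosslinker_mass Bridge mass in Da (default DSS/BS3, 138.06808).
#' @param mods_alpha,mods_beta Optional modifications as in
#'   [monoisotopic_mass()].
#' @return Mass in Da.
#' @export
crosslinked_mass <- function(seq_alpha, seq_beta,
                             crosslinker_mass = crosslinker_masses()[["DSS"]],
                             mods_alpha = NULL, mods_beta = NULL) {
  monoisotopic_mass(seq_alpha, mods_alpha) +
    monoisotopic_mass(seq_beta, mods_beta) + crosslinker_mass
}

#' Mass-to-charge ratio
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param z Positive integer charge state.
#' @return m/z in Thomson.
#' @export
mz <- function(mass, z) {
  if (any(z < 1)) stop("charge must be >= 1", call. = FALSE)
  (mass + z * PROTON_MASS) / z
}

#' Charge model for solution net charge
#'
#' @param pH Solution pH (default 2.7, the acidic reversed-phase mobile
#'   phase regime).
#' @param pka Named vector of group pKa values for `nterm`, `cterm`, and the
#'   ionisable side chains K, R, H, D, E, C, Y.
#' @return A list of class `charge_model`.
#' @export
default_charge_model <- function(pH = 2.7,
                                 pka = c(nterm = 8.6, cterm = 3.6, K = 10.8,
                                         R = 12.5, H = 6.5, D = 3.9, E = 4.1,
                                         C = 8.5, Y = 10.1)) {
  stopifnot(pH > 0, pH < 14, all(pka > 0), all(pka < 14),
            all(c("nterm", "cterm", "K", "R", "H", "D", "E", "C", "Y") %in%
                  names(pka)))
  structure(list(pH = pH, pka = pka), class = "charge_model")
}

#' Henderson-Hasselbalch net solution charge of a peptide
#'
#' Each basic group (N-terminus, K, R, H) contributes
#' 1 / (1 + 10^(pH - pKa)) positive charge; each acidic group (C-terminus,
#' D, E, C, Y) contributes 1 / (1 + 10^(pKa - pH)) negative charge.
#'
#' @param sequence Peptide sequence; vectorised.
#' @param charge_model A [default_charge_model()] object.
#' @param termini Count the chain termini (default TRUE; set FALSE for
#'   chains whose termini are blocked).
#' @return Net charge in elementary charges (float).
#' @export
solution_charge <- function(sequence, charge_model = default_charge_model(),
                            termini = TRUE) {
  pH <- charge_model$pH
  pka <- charge_model$pka
  basic_frac <- function(pk) 1 / (1 + 10^(pH - pk))
  acid_frac <- function(pk) 1 / (1 + 10^(pk - pH))
  counts <- residue_counts(sequence, c("K", "R", "H", "D", "E", "C", "Y"))
  pos <- counts[, "K"] * basic_frac(pka[["K"]]) +
    counts[, "R"] * basic_frac(pka[["R"]]) +
    counts[, "H"] * basic_frac(pka[["H"]])
  neg <- counts[, "D"] * acid_frac(pka[["D"]]) +
    counts[, "E"] * acid_frac(pka[["E"]]) +
    counts[, "C"] * acid_frac(pka[["C"]]) +
    counts[, "Y"] * acid_frac(pka[["Y"]])
  if (termini) {
    pos <- pos + basic_frac(pka[["nterm"]])
    neg <- neg + acid_frac(pka[["cterm"]])
  }
  unname(pos - neg)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the residues of a sequence.
#'
#' @param sequence Peptide sequence; vectorised.
#' @return Dimensionless GRAVY score.
#' @export
gravy <- function(sequence) {
  vapply(strsplit(sequence, ""), function(chars) {
    if (length(chars) == 0L) return(NA_real_)
    mean(KYTE_DOOLITTLE[chars])
  }, numeric(1))
}

residue_counts <- function(sequence, residues) {
  out <- vapply(residues, function(r) {
    nchar(sequence) - nchar(gsub(r, "", sequence, fixed = TRUE))
  }, integer(length(sequence)))
  if (length(sequence) == 1L) out <- matrix(out, nrow = 1L,
                                            dimnames = list(NULL, residues))
  out
}

#' Default feature configuration
#'
#' The ordered list of 32 physicochemical features computed per CSM:
#' mass-to-charge ratio and masses, chain lengths, precursor and calculated
#' solution charges, GRAVY hydropathy, residue-class counts and fractions,
#' derived densities, modification count and cross-linker mass.
#'
#' @return Character vector of 32 feature names, in column order.
#' @export
default_feature_config <- function() {
  c("mz", "mass", "mass_alpha", "mass_beta",
    "length_total", "length_alpha", "length_beta",
    "precursor_charge", "solution_charge",
    "solution_charge_alpha", "solution_charge_beta",
    "gravy_total", "gravy_alpha", "gravy_beta",
    "basic_count", "acidic_count", "aromatic_count", "proline_count",
    "glycine_count", "hydroxyl_count", "sulfur_count", "amide_count",
    "aliphatic_count",
    "basic_frac", "acidic_frac", "aromatic_frac", "proline_frac",
    "glycine_frac",
    "charge_density", "mass_per_residue", "n_modifications",
    "crosslinker_mass")
}

RESIDUE_CLASSES <- list(
  basic = c("K", "R", "H"), acidic = c("D", "E"),
  aromatic = c("F", "W", "Y"), proline = "P", glycine = "G",
  hydroxyl = c("S", "T", "Y"), sulfur = c("C", "M"),
  amide = c("N", "Q"), aliphatic = c("A", "V", "I", "L")
)

#' Compute the feature matrix for a CSM table
#'
#' Builds one named numeric feature vector per CSM. Alpha/beta chains are
#' order-normalised (lexicographically) first, so a cross-link and its
#' chain swap featurize identically. The computation is a pure function of
#' its inputs.
#'
#' @param csms CSM tibble (see [csm_columns()]).
#' @param feature_config Character vector of feature names defining vector
#'   length and order; default [default_feature_config()] (32 features).
#' @param charge_model Charge model for solution charge.
#' @param crosslinker_mass Bridge mass in Da.
#' @return A tibble with `length(feature_config)` numeric columns, one row
#'   per CSM, columns in configured order.
#' @export
featurize_csms <- function(csms, feature_config = default_feature_config(),
                           charge_model = default_charge_model(),
                           crosslinker_mass = crosslinker_masses()[["DSS"]]) {
  csms <- normalize_pair_order(csms)
  a <- csms$pep_seq_a
  b <- csms$pep_seq_b
  total <- paste0(a, b)
  mass_a <- monoisotopic_mass(a)
  mass_b <- monoisotopic_mass(b)
  mass <- mass_a + mass_b + crosslinker_mass
  len_a <- nchar(a)
  len_b <- nchar(b)
  len <- len_a + len_b
  feats <- tibble::tibble(
    mz = mz(mass, csms$charge),
    mass = mass, mass_alpha = mass_a, mass_beta = mass_b,
    length_total = as.numeric(len), length_alpha = as.numeric(len_a),
    length_beta = as.numeric(len_b),
    precursor_charge = as.numeric(csms$charge),
    solution_charge = solution_charge(a, charge_model) +
      solution_charge(b, charge_model),
    solution_charge_alpha = solution_charge(a, charge_model),
    solution_charge_beta = solution_charge(b, charge_model),
    gravy_total = gravy(total), gravy_alpha = gravy(a), gravy_beta = gravy(b)
  )
  for (cls in names(RESIDUE_CLASSES)) {
    counts <- rowSums(residue_counts(total, RESIDUE_CLASSES[[cls]]))
    feats[[paste0(cls, "_count")]] <- as.numeric(counts)
    if (cls %in% c("basic", "acidic", "aromatic", "proline", "glycine")) {
      feats[[paste0(cls, "_frac")]] <- counts / len
    }
  }
  feats$charge_density <- feats$precursor_charge / feats$length_total
  feats$mass_per_residue <- feats$mass / feats$length_total
  feats$n_modifications <- 0
  feats$crosslinker_mass <- crosslinker_mass
  unknown <- setdiff(feature_config, names(feats))
  if (length(unknown) > 0L) {
    stop("unknown feature(s) in feature_config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  feats[, feature_config]
}

#' Write a feature matrix to delimited text
#'
#' @param features Feature tibble from [featurize_csms()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  readr::write_delim(features, path, delim = "\t")
  invisible(path)
}
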