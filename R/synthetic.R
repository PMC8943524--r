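# Seeded synthetic CSM generator: tryptic cross-linked peptide pairs,
# mass-coupled SEC fractionation, a linear true-CV model and Gaussian
# transmission on a discrete CV grid.

#' Configuration for the synthetic-data generator
#'
#' Defines the generative model: random proteins digested into tryptic
#' peptides, cross-linked pairs with link sites at K/S/T/Y or the
#' N-terminus, SEC fractions assigned by analyte mass (heaviest elute
#' first), a true optimal CV that is linear in m/z and size (charge
#' optional) with additive Gaussian noise, and Bernoulli detection with a
#' Gaussian transmission window around that optimum on the CV grid.
#'
#' @param n_proteins Number of synthetic proteins to digest.
#' @param n_pairs Number of cross-linked peptide-pair analytes.
#' @param seed Integer master seed; every operation derives its stream
#'   from it.
#' @param cv_beta0 Intercept of the true-CV model (V).
#' @param cv_beta1 m/z coefficient (V/Th); positive by default — smaller
#'   (low-m/z) ions transmit at more negative CV, which is what produces
#'   the drift of the per-fraction CV optimum towards more negative values
#'   in later (smaller-analyte) SEC fractions.
#' @param cv_beta2 Size coefficient (V/residue); positive by default.
#' @param cv_beta3 Charge coefficient (V/e); 0 by default (charge plays a
#'   minor role in the observed range).
#' @param noise_sd SD of the analyte-level CV noise (V).
#' @param transmission_width SD of the Gaussian transmission window (V).
#' @param p_max Detection probability at the transmission optimum.
#' @param cv_grid Acquisition CV grid (volts), see [cv_grid()].
#' @param n_fractions Number of SEC fractions.
#' @param fraction_labels Fraction numbers, earliest (heaviest) first.
#' @param pH Solution pH used when featurizing.
#' @param crosslinker_mass Bridge mass in Da (default DSS/BS3).
#' @param score_location,score_shape,score_rate Shifted-gamma score model:
#'   `score = location + Gamma(shape, rate)`.
#' @param score_transmission_bonus Score increment per unit transmission
#'   probability (better-transmitted ions give cleaner spectra and thus
#'   slightly higher scores).
#' @param site_multiplicity Mean number of link-site variants emitted per
#'   detected peptide pair (>= 1); the extra variants share sequences and
#'   charge and are what deduplication collapses.
#' @param charge_range Allowed precursor charges.
#' @param charge_weights Sampling weights over `charge_range`.
#' @param couple_size_to_fraction Assign SEC fractions by analyte mass
#'   (TRUE, the physical coupling) or uniformly at random (FALSE, the null
#'   model used to check that fraction-specific gains vanish).
#' @param decoy_rate Fraction of emitted CSMs flagged as decoys.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 10, n_pairs = 3000, seed = 1,
                             cv_beta0 = -100, cv_beta1 = 0.035,
                             cv_beta2 = 0.25, cv_beta3 = 0,
                             noise_sd = 5, transmission_width = 7,
                             p_max = 0.85,
                             cv_grid = NULL,
                             n_fractions = 6, fraction_labels = 5:10,
                             pH = 2.7,
                             crosslinker_mass = crosslinker_masses()[["DSS"]],
                             score_location = 5, score_shape = 4,
                             score_rate = 0.5,
                             score_transmission_bonus = 3,
                             site_multiplicity = 1.3,
                             charge_range = 3:7,
                             charge_weights = c(0.30, 0.35, 0.20, 0.10, 0.05),
                             couple_size_to_fraction = TRUE,
                             decoy_rate = 0.02) {
  if (is.null(cv_grid)) cv_grid <- faimscv_default_grid()
  stopifnot(n_pairs >= 1, noise_sd >= 0, transmission_width > 0,
            p_max > 0, p_max <= 1, site_multiplicity >= 1,
            length(charge_weights) == length(charge_range),
            length(fraction_labels) == n_fractions,
            decoy_rate >= 0, decoy_rate < 1)
  structure(as.list(environment()), class = "synthetic_config")
}

# Per-operation RNG streams derived from the master seed.
op_seed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

#' Generate cross-linked peptide-pair analytes
#'
#' Draws random protein sequences, digests them trypsin-like (cleavage
#' after K/R, up to 2 missed cleavages, peptide length 5-30), and samples
#' `n_pairs` cross-linked pairs with link sites restricted to K, S, T, Y
#' or the peptide N-terminus. Alpha/beta chains are order-normalised.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return Tibble with one row per analyte: `analyte_id`, peptide columns
#'   (`pep_seq_a/b`, `link_site_a/b`, `protein_a/b`, `pos_a/b`), `charge`,
#'   `mass` (cross-linked, Da), `mz` (Th) and `length_total`.
#' @export
generate_peptide_pairs <- function(config) {
  withr::with_seed(op_seed(config, 0L), {
    peptides <- generate_tryptic_peptides(config$n_proteins)
    idx_a <- sample.int(nrow(peptides), config$n_pairs, replace = TRUE)
    idx_b <- sample.int(nrow(peptides), config$n_pairs, replace = TRUE)
    site_a <- vapply(peptides$sites[idx_a], function(s) s[sample.int(length(s), 1L)],
                     integer(1))
    site_b <- vapply(peptides$sites[idx_b], function(s) s[sample.int(length(s), 1L)],
                     integer(1))
    charge <- sample(config$charge_range, config$n_pairs, replace = TRUE,
                     prob = config$charge_weights)
    analytes <- tibble::tibble(
      analyte_id = seq_len(config$n_pairs),
      pep_seq_a = peptides$sequence[idx_a], pep_seq_b = peptides$sequence[idx_b],
      link_site_a = site_a, link_site_b = site_b,
      protein_a = peptides$protein_id[idx_a], protein_b = peptides$protein_id[idx_b],
      pos_a = peptides$start[idx_a], pos_b = peptides$start[idx_b],
      charge = as.integer(charge)
    )
    analytes <- normalize_pair_order(analytes)
    analytes$mass <- crosslinked_mass(analytes$pep_seq_a, analytes$pep_seq_b,
                                      config$crosslinker_mass)
    analytes$mz <- mz(analytes$mass, analytes$charge)
    analytes$length_total <- nchar(analytes$pep_seq_a) + nchar(analytes$pep_seq_b)
    analytes
  })
}

# Average vertebrate amino-acid frequencies (K/R kept realistic so tryptic
# sites are frequent).
AA_FREQ <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.053, C = 0.025,
             Q = 0.040, E = 0.063, G = 0.074, H = 0.026, I = 0.053,
             L = 0.091, K = 0.058, M = 0.018, F = 0.040, P = 0.050,
             S = 0.073, T = 0.059, W = 0.013, Y = 0.033, V = 0.064)

generate_tryptic_peptides <- function(n_proteins, min_len = 5L, max_len = 30L,
                                      max_missed = 2L) {
  out <- list()
  for (p in seq_len(n_proteins)) {
    prot_id <- sprintf("SYNP%02d", p)
    prot_len <- sample(200:600, 1L)
    seq_chars <- sample(names(AA_FREQ), prot_len, replace = TRUE,
                        prob = AA_FREQ)
    protein <- paste(seq_chars, collapse = "")
    cuts <- c(0L, which(seq_chars %in% c("K", "R")), prot_len)
    cuts <- unique(cuts)
    n_seg <- length(cuts) - 1L
    for (i in seq_len(n_seg)) {
      for (m in 0:max_missed) {
        if (i + m > n_seg) break
        start <- cuts[i] + 1L
        end <- cuts[i + m + 1L]
        len <- end - start + 1L
        if (len < min_len || len > max_len) next
        pep <- substr(protein, start, end)
        # fully tryptic only: the chain must end at a cleavage site
        if (!substr(pep, len, len) %in% c("K", "R")) next
        chars <- strsplit(pep, "")[[1]]
        sites <- unique(c(1L, which(chars %in% c("K", "S", "T", "Y"))))
        out[[length(out) + 1L]] <- tibble::tibble(
          protein_id = prot_id, start = start, sequence = pep,
          sites = list(sites))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Assign SEC fractions to analytes
#'
#' Bins analytes into `n_fractions` equal-size groups by cross-linked mass
#' and labels the heaviest bin with the lowest fraction number (largest
#' analytes elute earliest from SEC). Ties are broken by analyte order.
#' With `by_mass = FALSE` fractions are assigned uniformly at random — the
#' null model with no size coupling.
#'
#' @param analytes Tibble from [generate_peptide_pairs()].
#' @param config A [synthetic_config()]; supplies `n_fractions`,
#'   `fraction_labels` and the coupling switch (overridable via `by_mass`).
#' @param by_mass Override for `config$couple_size_to_fraction`.
#' @return The analytes tibble with a `sec_fraction` column.
#' @export
assign_sec_fraction <- function(analytes, config,
                                by_mass = config$couple_size_to_fraction) {
  n <- nrow(analytes)
  stopifnot(n >= config$n_fractions)
  labels <- sort(config$fraction_labels)
  if (by_mass) {
    ord <- order(-analytes$mass, seq_len(n))
    bin <- ceiling(seq_len(n) / (n / config$n_fractions))
    bin[bin > config$n_fractions] <- config$n_fractions
    frac <- integer(n)
    frac[ord] <- labels[bin]
  } else {
    frac <- withr::with_seed(op_seed(config, 1L),
                             sample(labels, n, replace = TRUE))
  }
  analytes$sec_fraction <- as.integer(frac)
  analytes
}

#' True optimal CV of each analyte
#'
#' `cv* = beta0 + beta1 * m/z + beta2 * length + beta3 * charge + noise`,
#' clamped to the CV grid range. The noise is analyte-level Gaussian with
#' SD `config$noise_sd`, drawn reproducibly from the master seed.
#'
#' @param analytes Tibble from [generate_peptide_pairs()].
#' @param config A [synthetic_config()].
#' @return The analytes tibble with a `cv_true` column (volts).
#' @export
true_cv <- function(analytes, config) {
  eps <- withr::with_seed(op_seed(config, 2L),
                          stats::rnorm(nrow(analytes), 0, config$noise_sd))
  raw <- config$cv_beta0 + config$cv_beta1 * analytes$mz +
    config$cv_beta2 * analytes$length_total +
    config$cv_beta3 * analytes$charge + eps
  analytes$cv_true <- pmin(pmax(raw, min(config$cv_grid)), max(config$cv_grid))
  analytes
}

#' Acquisition schedule constructors
#'
#' A schedule is a tibble with one row per (run, applied CV): `run_id`,
#' `sec_fraction` (`NA` = the run sees all analytes) and `cv` (`NA` = a
#' no-FAIMS run). `default_sec_schedule()` acquires every fraction in six
#' internal-stepping runs (one balanced CV pair each, see
#' [balanced_pairing()]) plus `n_replicates` no-FAIMS runs — the
#' SEC-coupled design. `single_cv_schedule()` is the external-stepping
#' survey: one run per CV over all analytes.
#'
#' @param config A [synthetic_config()].
#' @param offset Pairing offset in volts (default 30).
#' @param n_replicates No-FAIMS replicate runs per fraction (default 3).
#' @return A schedule tibble.
#' @export
default_sec_schedule <- function(config, offset = 30, n_replicates = 3) {
  pairs <- balanced_pairing(config$cv_grid, offset)
  rows <- list()
  for (f in sort(config$fraction_labels)) {
    for (i in seq_len(nrow(pairs))) {
      run <- sprintf("F%02d_CV%+d%+d", f, pairs$cv_rich[i], pairs$cv_poor[i])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        run_id = run, sec_fraction = f,
        cv = c(pairs$cv_rich[i], pairs$cv_poor[i]))
    }
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        run_id = sprintf("F%02d_noFAIMS_r%d", f, r), sec_fraction = f,
        cv = NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}

#' @rdname default_sec_schedule
#' @param cvs CVs for the single-CV survey (default the full config grid).
#' @export
single_cv_schedule <- function(config, cvs = config$cv_grid) {
  tibble::tibble(run_id = sprintf("CV%+d", as.integer(round(cvs))),
                 sec_fraction = NA_integer_, cv = as.numeric(cvs))
}

#' Simulate FAIMS acquisition of analytes under a schedule
#'
#' For every schedule row and every analyte visible to that run (matching
#' fraction, or all analytes when the run's fraction is `NA`), detection
#' is Bernoulli with `p = p_max * exp(-(cv - cv*)^2 / (2 * width^2))` for
#' FAIMS rows and `p = p_max` for no-FAIMS rows. Detected analytes are
#' emitted as CSMs with shifted-gamma scores (plus a small
#' transmission-dependent bonus), sampled fragment counts and delta
#' scores, and occasional extra link-site variants of the same peptide
#' pair and charge (the redundancy that [deduplicate_csms()] collapses).
#'
#' @param analytes Tibble with `cv_true` and `sec_fraction` columns (see
#'   [true_cv()] and [assign_sec_fraction()]).
#' @param schedule Schedule tibble (see [default_sec_schedule()]).
#' @param config A [synthetic_config()].
#' @return A list of class `faims_simulation`: `csms` (canonical CSM
#'   tibble) and `ground_truth` (the analytes tibble).
#' @export
simulate_acquisition <- function(analytes, schedule, config) {
  if (!"cv_true" %in% names(analytes)) {
    stop("analytes lack cv_true; call true_cv() first", call. = FALSE)
  }
  on_grid <- is.na(schedule$cv) | schedule$cv %in% config$cv_grid
  if (!all(on_grid)) {
    stop("schedule CV(s) off the grid: ",
         paste(unique(schedule$cv[!on_grid]), collapse = ", "), call. = FALSE)
  }
  out <- withr::with_seed(op_seed(config, 3L), {
    rows <- vector("list", nrow(schedule))
    for (i in seq_len(nrow(schedule))) {
      run <- schedule[i, ]
      vis <- if (is.na(run$sec_fraction)) analytes else
        analytes[!is.na(analytes$sec_fraction) &
                   analytes$sec_fraction == run$sec_fraction, , drop = FALSE]
      if (nrow(vis) == 0L) next
      p <- if (is.na(run$cv)) rep(config$p_max, nrow(vis)) else
        config$p_max *
          exp(-(run$cv - vis$cv_true)^2 / (2 * config$transmission_width^2))
      hit <- stats::runif(nrow(vis)) < p
      if (!any(hit)) next
      rows[[i]] <- emit_csms(vis[hit, , drop = FALSE], p[hit], run, config)
    }
    dplyr::bind_rows(rows)
  })
  structure(list(csms = out, ground_truth = analytes),
            class = "faims_simulation")
}

# Emit CSM rows for detected analytes, expanding link-site variants.
emit_csms <- function(detected, p, run, config) {
  n_var <- 1L + stats::rpois(nrow(detected), config$site_multiplicity - 1)
  idx <- rep(seq_len(nrow(detected)), n_var)
  d <- detected[idx, , drop = FALSE]
  p <- p[idx]
  # Variant copies get a re-sampled alpha link site where the chain offers
  # an alternative K/S/T/Y position.
  variant <- duplicated(idx)
  if (any(variant)) {
    d$link_site_a[variant] <- vapply(which(variant), function(j) {
      chars <- strsplit(d$pep_seq_a[j], "")[[1]]
      sites <- unique(c(1L, which(chars %in% c("K", "S", "T", "Y"))))
      sites[sample.int(length(sites), 1L)]
    }, integer(1))
  }
  n <- nrow(d)
  score <- config$score_location +
    stats::rgamma(n, shape = config$score_shape, rate = config$score_rate) +
    config$score_transmission_bonus * p
  csm_table(
    run_id = run$run_id,
    sec_fraction = if (is.na(run$sec_fraction)) d$sec_fraction else
      as.integer(run$sec_fraction),
    cv = run$cv,
    score = score,
    delta_score = round(stats::runif(n, 0.02, 0.6), 3),
    pep_seq_a = d$pep_seq_a, pep_seq_b = d$pep_seq_b,
    link_site_a = d$link_site_a, link_site_b = d$link_site_b,
    protein_a = d$protein_a, protein_b = d$protein_b,
    pos_a = d$pos_a, pos_b = d$pos_b,
    charge = d$charge,
    frags_a = 2L + stats::rpois(n, 3), frags_b = 2L + stats::rpois(n, 3),
    is_decoy = stats::runif(n) < config$decoy_rate
  )
}

#' One-call synthetic experiments
#'
#' `simulate_sec_experiment()` runs the full SEC-coupled design: generate
#' analytes, assign mass-coupled fractions, draw true CVs, and acquire
#' under [default_sec_schedule()]. `simulate_ml_dataset()` runs the
#' single-CV survey over the config grid, applies the pre-FDR filters and
#' leakage-free deduplication, and returns the regression-ready feature
#' matrix with applied-CV labels.
#'
#' @param config A [synthetic_config()].
#' @param offset Pairing offset for the SEC schedule (volts).
#' @param n_replicates No-FAIMS replicates per fraction.
#' @return `simulate_sec_experiment()`: a `faims_simulation` list (see
#'   [simulate_acquisition()]). `simulate_ml_dataset()`: a list with
#'   `features` (tibble), `labels` (applied CV, volts), `csms` and
#'   `ground_truth`.
#' @export
simulate_sec_experiment <- function(config, offset = 30, n_replicates = 3) {
  analytes <- generate_peptide_pairs(config)
  analytes <- assign_sec_fraction(analytes, config)
  analytes <- true_cv(analytes, config)
  simulate_acquisition(analytes, default_sec_schedule(config, offset,
                                                      n_replicates), config)
}

#' @rdname simulate_sec_experiment
#' @export
simulate_ml_dataset <- function(config) {
  analytes <- generate_peptide_pairs(config)
  analytes <- assign_sec_fraction(analytes, config)
  analytes <- true_cv(analytes, config)
  sim <- simulate_acquisition(analytes, single_cv_schedule(config), config)
  csms <- prefilter_csms(sim$csms)
  csms <- csms[!csms$is_decoy, , drop = FALSE]
  csms <- deduplicate_csms(csms)
  features <- featurize_csms(csms,
                             charge_model = default_charge_model(config$pH),
                             crosslinker_mass = config$crosslinker_mass)
  list(features = features, labels = csms$cv, csms = csms,
       ground_truth = analytes)
}
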