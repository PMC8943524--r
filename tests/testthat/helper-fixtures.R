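# In-code fixtures: small CSM tables with controllable URP structure.

# A minimal valid CSM row set; override any column by name.
make_csms <- function(n = 1, ...) {
  defaults <- list(
    run_id = "run1", sec_fraction = 5L, cv = -50, score = 10,
    delta_score = 0.2, pep_seq_a = "ACDEK", pep_seq_b = "GHILK",
    link_site_a = 5L, link_site_b = 5L, protein_a = "P1", protein_b = "P2",
    pos_a = 1L, pos_b = 1L, charge = 3L, frags_a = 5L, frags_b = 5L,
    is_decoy = FALSE)
  args <- utils::modifyList(defaults, list(...))
  args <- lapply(args, function(v) rep_len(v, n))
  do.call(csm_table, args)
}

# Random CSM table over a CV grid: n CSMs drawn from a pool of n_urps
# distinct residue pairs, CVs/fractions sampled uniformly.
random_csm_table <- function(n = 200, cvs = cv_grid(-85, -30, 5),
                             fractions = 5:10, n_urps = 60, seed = 1) {
  withr::with_seed(seed, {
    pool_prot <- sprintf("P%d", sample(1:6, n_urps, replace = TRUE))
    pool_pos <- sample(1:400, n_urps, replace = TRUE)
    pick <- sample(n_urps, n, replace = TRUE)
    pick2 <- sample(n_urps, n, replace = TRUE)
    seqs <- c("ACDEK", "GHILK", "MNPQR", "STVWK", "YYACK", "DDEEK",
              "FFGGK", "HHIIK")
    make_csms(
      n,
      run_id = sprintf("r%d", sample(1:3, n, replace = TRUE)),
      sec_fraction = sample(fractions, n, replace = TRUE),
      cv = sample(cvs, n, replace = TRUE),
      score = round(stats::runif(n, 5, 20), 3),
      pep_seq_a = sample(seqs, n, replace = TRUE),
      pep_seq_b = sample(seqs, n, replace = TRUE),
      link_site_a = 1L, link_site_b = 1L,
      protein_a = pool_prot[pick], protein_b = pool_prot[pick2],
      pos_a = pool_pos[pick], pos_b = pool_pos[pick2],
      charge = sample(3:7, n, replace = TRUE)
    )
  })
}

# Small labeled regression set with a known linear signal.
make_labeled_set <- function(n = 300, seed = 1, noise_sd = 0) {
  withr::with_seed(seed, {
    x <- tibble::tibble(
      mz = stats::runif(n, 400, 1600),
      length_total = stats::runif(n, 10, 60),
      precursor_charge = sample(3:7, n, replace = TRUE))
    y <- -100 + 0.035 * x$mz + 0.25 * x$length_total +
      stats::rnorm(n, 0, noise_sd)
    list(features = x, labels = y)
  })
}
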