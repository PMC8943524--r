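test_that("CSM tables round-trip through delimited text, including gzip", {
  csms <- random_csm_table(n = 25, seed = 3)
  for (ext in c(".tsv", ".csv.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_csm_table(csms, path, delim = if (grepl("csv", ext)) "," else "\t")
    back <- read_csm_table(path)
    expect_equal(as.data.frame(back), as.data.frame(csms))
  }
})

test_that("reader parses signed CVs, maps dialects, and reports bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_csm_table(make_csms(3, cv = c(-50.0, NA, -30), sec_fraction = c(5L, NA, 7L)),
                  path)
  csms <- read_csm_table(path)
  expect_identical(csms$cv, c(-50, NA, -30))
  expect_identical(csms$sec_fraction, c(5L, NA, 7L))

  # foreign headers resolved through a dialect mapping
  foreign <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("PepSeq1,PepSeq2,z,Score,dScore,site1,site2,prot1,prot2,start1,start2,nA,nB",
               "ACDEK,GHILK,3,10,0.2,5,5,P1,P2,1,1,5,5"), foreign)
  dialect <- c(pep_seq_a = "PepSeq1", pep_seq_b = "PepSeq2", charge = "z",
               score = "Score", delta_score = "dScore", link_site_a = "site1",
               link_site_b = "site2", protein_a = "prot1", protein_b = "prot2",
               pos_a = "start1", pos_b = "start2", frags_a = "nA", frags_b = "nB")
  mapped <- read_csm_table(foreign, dialect = dialect)
  expect_equal(mapped$pep_seq_a, "ACDEK")
  expect_true(is.na(mapped$cv))

  # unknown column named in the error
  bad_dialect <- c(dialect, not_a_column = "z")
  expect_error(read_csm_table(foreign, dialect = bad_dialect), "not_a_column")

  # row missing a beta sequence is a row-level error
  broken <- withr::local_tempfile(fileext = ".tsv")
  tbl <- make_csms(2)
  tbl$pep_seq_b[2] <- NA_character_
  readr::write_tsv(tbl, broken, na = "")
  expect_error(read_csm_table(broken), "row")

  # malformed numeric reported with its row
  malformed <- withr::local_tempfile(fileext = ".tsv")
  lines <- readr::read_lines(path)
  lines[2] <- sub("-50", "minusfifty", lines[2])
  readr::write_lines(lines, malformed)
  expect_error(read_csm_table(malformed), "cv")
})

test_that("peptide constructor enforces the domain invariants", {
  p <- peptide("ACDEFK", link_site = 6, protein_id = "P1", protein_start = 10)
  expect_s3_class(p, "faims_peptide")
  expect_error(peptide("ACDE", 1), "length")
  expect_error(peptide("ACDEFK", 7), "link_site")
  expect_error(peptide("ACDEZK", 1), "Z")
  expect_error(
    peptide("ACDEFK", 1,
            modifications = data.frame(position = 7, mass_delta = 57)),
    "position")
  # position 0 = N-terminus is allowed
  expect_silent(peptide("ACDEFK", 1,
                        modifications = data.frame(position = 0,
                                                   mass_delta = 57)))
})

test_that("prefilter requires both peptides to pass and is inclusive at the boundary", {
  csms <- make_csms(3, frags_a = c(3L, 3L, 5L), frags_b = c(2L, 3L, 5L),
                    delta_score = c(0.2, 0.1, 0.05))
  kept <- prefilter_csms(csms, 3, 0.1)
  expect_equal(nrow(kept), 1L)         # beta of row 1 fails, delta of row 3 fails
  expect_equal(kept$frags_b, 3L)       # the boundary row survives
  expect_equal(prefilter_csms(csms, 0, 0), csms)
})

test_that("prefilter is monotone in both thresholds", {
  csms <- random_csm_table(n = 150, seed = 9)
  csms$frags_a <- sample(1:6, 150, replace = TRUE)
  csms$frags_b <- sample(1:6, 150, replace = TRUE)
  csms$delta_score <- runif(150, 0, 0.5)
  counts <- sapply(0:6, function(th) nrow(prefilter_csms(csms, th, 0)))
  expect_true(all(diff(counts) <= 0))
  counts <- sapply(seq(0, 0.5, 0.1),
                   function(th) nrow(prefilter_csms(csms, 0, th)))
  expect_true(all(diff(counts) <= 0))
})

test_that("deduplication keeps the top-scoring pair per sequence/charge key", {
  csms <- make_csms(3, score = c(5, 9, 7))
  expect_equal(deduplicate_csms(csms)$score, 9)

  # different charge states are different keys
  two_z <- make_csms(2, charge = c(3L, 4L))
  expect_equal(nrow(deduplicate_csms(two_z)), 2L)

  # link-site variants share a key (no leakage through sites)
  variants <- make_csms(2, link_site_a = c(1L, 5L), score = c(4, 8))
  dd <- deduplicate_csms(variants)
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$link_site_a, 5L)

  # alpha/beta swap shares a key
  swapped <- make_csms(2, pep_seq_a = c("ACDEK", "GHILK"),
                       pep_seq_b = c("GHILK", "ACDEK"), score = c(3, 6))
  expect_equal(nrow(deduplicate_csms(swapped)), 1L)

  # score ties break to the first occurrence
  tied <- make_csms(2, score = 7, run_id = c("first", "second"))
  expect_equal(deduplicate_csms(tied)$run_id, "first")
})

test_that("deduplication is idempotent and never grows the table", {
  for (seed in 1:5) {
    csms <- random_csm_table(n = 120, seed = seed)
    once <- deduplicate_csms(csms)
    expect_lte(nrow(once), nrow(csms))
    expect_equal(deduplicate_csms(once), once)
  }
})

test_that("urp_key maps to protein coordinates and is symmetric", {
  csms <- make_csms(1, protein_a = "P1", pos_a = 10L, link_site_a = 3L,
                    protein_b = "P2", pos_b = 1L, link_site_b = 1L)
  expect_equal(urp_key(csms), "P1:000012--P2:000001")

  swapped <- make_csms(1, pep_seq_a = "GHILK", pep_seq_b = "ACDEK",
                       protein_a = "P2", pos_a = 1L, link_site_a = 1L,
                       protein_b = "P1", pos_b = 10L, link_site_b = 3L)
  expect_equal(urp_key(swapped), urp_key(csms))

  intra <- make_csms(2, protein_a = "P1", protein_b = "P1",
                     pos_a = c(10L, 38L), link_site_a = c(3L, 3L),
                     pos_b = c(38L, 10L), link_site_b = c(3L, 3L))
  expect_equal(urp_key(intra)[1], urp_key(intra)[2])

  unmapped <- make_csms(1, protein_a = NA_character_)
  expect_error(urp_key(unmapped), "protein")
})

test_that("urp_key is symmetric for random (protein, site) pairs", {
  withr::with_seed(4, {
    for (i in 1:20) {
      pa <- sample(sprintf("P%d", 1:4), 1)
      pb <- sample(sprintf("P%d", 1:4), 1)
      sa <- sample(1:200, 1); sb <- sample(1:200, 1)
      k1 <- urp_key(make_csms(1, protein_a = pa, pos_a = sa, link_site_a = 1L,
                              protein_b = pb, pos_b = sb, link_site_b = 1L))
      k2 <- urp_key(make_csms(1, protein_a = pb, pos_a = sb, link_site_a = 1L,
                              protein_b = pa, pos_b = sa, link_site_b = 1L))
      expect_identical(k1, k2)
    }
  })
})

test_that("knee detection finds a planted two-slope breakpoint", {
  i <- seq_len(500)
  logv <- ifelse(i <= 100, 10 - 0.01 * i, 10 - 0.01 * 100 - 0.5 * (i - 100))
  res <- ibaq_knee_cutoff(10^logv)
  expect_false(res$degenerate)
  expect_lte(abs(res$knee_index - 100), 5)
  expect_equal(res$n_retained, res$knee_index)

  # oracle: independent exhaustive scan of discrete curvature
  brute_knee <- function(vals) {
    y <- log10(sort(vals, decreasing = TRUE))
    y <- (y - min(y)) / diff(range(y))
    x <- seq(0, 1, length.out = length(y))
    h <- x[2] - x[1]
    best <- 1; best_k <- -Inf
    for (j in 2:(length(y) - 1)) {
      d1 <- (y[j + 1] - y[j - 1]) / (2 * h)
      d2 <- (y[j + 1] - 2 * y[j] + y[j - 1]) / h^2
      k <- abs(d2) / (1 + d1^2)^1.5
      if (k > best_k) { best_k <- k; best <- j }
    }
    best
  }
  expect_equal(res$knee_index, brute_knee(10^logv))
  withr::with_seed(5, {
    for (rep in 1:5) {
      vals <- 10^(stats::runif(300, 4, 9))
      expect_equal(ibaq_knee_cutoff(vals)$knee_index, brute_knee(vals))
    }
  })
})

test_that("knee detection flags degenerate inputs and rejects tiny ones", {
  linear <- 10^seq(8, 4, length.out = 50)
  res <- ibaq_knee_cutoff(linear)
  expect_true(res$degenerate)
  expect_equal(res$n_retained, 50)
  expect_equal(res$cutoff_value, min(linear))

  const <- rep(1e6, 20)
  expect_true(ibaq_knee_cutoff(const)$degenerate)

  expect_error(ibaq_knee_cutoff(c(1, 2)), "at least 3")
  expect_warning(ibaq_knee_cutoff(c(10^seq(8, 4, length.out = 10), -5, 0)),
                 "non-positive")
})
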