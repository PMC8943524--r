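test_that("balanced pairing reproduces the 30 V internal-stepping design", {
  pairs <- balanced_pairing(cv_grid(-85, -30, 5), offset = 30)
  expect_equal(nrow(pairs), 6L)
  expect_equal(pairs$cv_rich, c(-30, -35, -40, -45, -50, -55))
  expect_equal(pairs$cv_poor, c(-60, -65, -70, -75, -80, -85))
  expect_true(all(pairs$cv_rich - pairs$cv_poor == 30))
  # every grid value appears exactly once
  expect_setequal(c(pairs$cv_rich, pairs$cv_poor), cv_grid(-85, -30, 5))

  expect_equal(balanced_pairing(c(-60, -30), 30),
               tibble::tibble(cv_rich = -30, cv_poor = -60))
  expect_error(balanced_pairing(cv_grid(-85, -30, 5), 32), "multiple")
  expect_error(balanced_pairing(cv_grid(-85, -30, 5), 60), "span")
})

test_that("the external-stepping survey schedule has 17 CVs", {
  cvs <- external_stepping_cvs()
  expect_length(cvs, 17L)
  expect_setequal(cvs, c(seq(-20, -90, by = -5), -100, -110))
})

test_that("fraction summaries count CSMs/URPs per CV with weighted mean CV", {
  csms <- make_csms(4, cv = c(-40, -40, -60, -60), sec_fraction = 5L,
                    pos_a = c(1L, 1L, 7L, 9L))
  s <- summarize_fraction(csms, 5)
  expect_equal(s$mean_cv, -50)
  expect_equal(s$by_cv$n_csms, c(2L, 2L))

  # two CSMs mapping to the same URP at one CV count once
  dup <- make_csms(2, cv = -50)
  s2 <- summarize_fraction(dup, 5)
  expect_equal(s2$by_cv$n_csms, 2L)
  expect_equal(s2$by_cv$n_urps, 1L)

  all_same <- make_csms(3, cv = -50)
  expect_equal(summarize_fraction(all_same, 5)$mean_cv, -50)

  empty <- summarize_fraction(make_csms(2, sec_fraction = 6L), 5)
  expect_equal(nrow(empty$by_cv), 0L)
  expect_true(is.na(empty$mean_cv))

  # decoys are excluded from counting by default
  mix <- make_csms(2, cv = -50, is_decoy = c(FALSE, TRUE), pos_a = c(1L, 9L))
  expect_equal(summarize_fraction(mix, 5)$by_cv$n_csms, 1L)
  expect_equal(summarize_fraction(mix, 5, include_decoys = TRUE)$by_cv$n_csms, 2L)
})

test_that("pair yield does set arithmetic with a Jaccard overlap", {
  # A = {u1,u2,u3} at -40; B = {u2,u3,u4} at -60
  csms <- make_csms(6, cv = c(-40, -40, -40, -60, -60, -60),
                    pos_a = c(1L, 2L, 3L, 2L, 3L, 4L))
  py <- pair_yield(csms, -40, -60)
  expect_equal(py$urps_union, 4L)
  expect_equal(py$overlap_pct, 50)
  expect_equal(py$urps_a, 3L)  # cv_a is the less negative CV

  # identity pair
  self <- pair_yield(csms, -40, -40)
  expect_equal(self$urps_union, 3L)
  expect_equal(self$overlap_pct, 100)

  # disjoint sets
  dis <- make_csms(4, cv = c(-40, -40, -60, -60), pos_a = c(1L, 2L, 3L, 4L))
  pyd <- pair_yield(dis, -40, -60)
  expect_equal(pyd$urps_union, 4L)
  expect_equal(pyd$overlap_pct, 0)

  # absent CV contributes an empty set; empty union has 0 overlap
  expect_equal(pair_yield(csms, -30, -35)$overlap_pct, 0)
  expect_equal(pair_yield(csms, -40, -35)$urps_union, 3L)

  # min-normalised overlap alternative
  expect_equal(pair_yield(csms, -40, -60, overlap = "min")$overlap_pct,
               100 * 2 / 3, tolerance = 1e-9)
})

test_that("pair yield symmetry and union bounds hold for random tables", {
  for (seed in 1:8) {
    csms <- random_csm_table(n = 150, seed = seed)
    cvs <- sample(unique(csms$cv), 2)
    a <- pair_yield(csms, cvs[1], cvs[2])
    b <- pair_yield(csms, cvs[2], cvs[1])
    expect_equal(a, b)
    expect_gte(a$urps_union, max(a$urps_a, a$urps_b))
    expect_lte(a$urps_union, a$urps_a + a$urps_b)
    expect_gte(a$overlap_pct, 0); expect_lte(a$overlap_pct, 100)
  }
})

test_that("best_pair equals exhaustive enumeration with deterministic ties", {
  brute_best <- function(csms, cvs) {
    best <- NULL
    for (i in seq_along(cvs)) for (j in seq_along(cvs)) {
      if (j <= i) next
      y <- pair_yield(csms, cvs[i], cvs[j])
      if (is.null(best) || y$urps_union > best$urps_union ||
          (y$urps_union == best$urps_union &&
             (y$overlap_pct < best$overlap_pct ||
                (y$overlap_pct == best$overlap_pct &&
                   (abs(y$cv_a - y$cv_b) < abs(best$cv_a - best$cv_b) ||
                      (abs(y$cv_a - y$cv_b) == abs(best$cv_a - best$cv_b) &&
                         y$cv_a > best$cv_a)))))) {
        best <- y
      }
    }
    best
  }
  for (seed in 1:10) {
    k <- sample(3:8, 1)
    cvs <- sort(sample(cv_grid(-110, -20, 5), k))
    csms <- random_csm_table(n = 150, cvs = cvs, seed = seed)
    expect_equal(best_pair(csms, cvs), brute_best(csms, cvs),
                 info = paste("seed", seed))
  }
  two <- random_csm_table(n = 40, cvs = c(-50, -60), seed = 1)
  bp <- best_pair(two, c(-50, -60))
  expect_equal(c(bp$cv_a, bp$cv_b), c(-50, -60))
  expect_error(best_pair(two, -50), "at least 2")
})

test_that("identical per-fraction CV content gives zero fraction gains", {
  base <- random_csm_table(n = 120, fractions = 5L, seed = 13)
  clones <- lapply(5:8, function(f) { b <- base; b$sec_fraction <- f; b })
  csms <- dplyr::bind_rows(clones)
  fg <- fraction_gain(csms, cv_grid(-85, -30, 5))
  expect_true(all(fg$per_fraction$gain_pct == 0))
  expect_equal(fg$median_gain_pct, 0)
  expect_equal(fg$sd_gain_pct, 0)
})

test_that("fraction gain arithmetic and dispersion match direct recomputation", {
  csms <- random_csm_table(n = 500, seed = 14)
  fg <- fraction_gain(csms, cv_grid(-85, -30, 5))
  expect_equal(nrow(fg$per_fraction), 6L)
  # arithmetic: gain = 100 * (best - global) / global, recomputed per row
  for (i in seq_len(6)) {
    row <- fg$per_fraction[i, ]
    bp <- best_pair(csms, cv_grid(-85, -30, 5), row$sec_fraction)
    gp <- pair_yield(csms, fg$global_pair$cv_a, fg$global_pair$cv_b,
                     row$sec_fraction)
    expect_equal(row$urps_best, bp$urps_union)
    expect_equal(row$gain_pct,
                 100 * (bp$urps_union - gp$urps_union) / gp$urps_union)
  }
  expect_equal(fg$median_gain_pct, stats::median(fg$per_fraction$gain_pct))
  expect_equal(fg$sd_gain_pct, stats::sd(fg$per_fraction$gain_pct))
  expect_error(fraction_gain(make_csms(3), cv_grid(-85, -30, 5)),
               "2 fractions")
})

test_that("top-k merging is monotone and reduces to best_pair at k = 1", {
  faims <- random_csm_table(n = 400, seed = 15)
  nofaims <- random_csm_table(n = 200, seed = 16)
  nofaims$cv <- NA_real_
  grid <- cv_grid(-85, -30, 5)
  res <- topk_vs_replicates(faims, nofaims, grid, k = 3)
  for (f in unique(res$per_fraction$sec_fraction)) {
    sub <- res$per_fraction[res$per_fraction$sec_fraction == f, ]
    expect_true(all(diff(sub$urps_faims) >= 0))   # union monotone in k
    expect_equal(sub$urps_faims[sub$n_runs == 1],
                 best_pair(faims, grid, f)$urps_union)
  }

  # identical URP universes on both arms at full replication -> ~0 %
  mirrored <- faims
  mirrored$cv <- NA_real_
  mirrored$run_id <- "nf_r1"
  res2 <- topk_vs_replicates(faims, mirrored, grid, k = 15)
  last <- res2$per_fraction[res2$per_fraction$n_runs ==
                              max(res2$per_fraction$n_runs), ]
  expect_true(all(last$gain_pct <= 0))

  # fractions lacking no-FAIMS data are skipped with a warning
  nf_partial <- nofaims[nofaims$sec_fraction != 5L, ]
  expect_warning(topk_vs_replicates(faims, nf_partial, grid, k = 2),
                 "fraction 5")
})

test_that("schedule figures build from simulated data", {
  cfg <- synthetic_config(n_pairs = 300, seed = 20)
  sim <- simulate_sec_experiment(cfg)
  faims <- sim$csms[!is.na(sim$csms$cv), ]
  p1 <- plot_fraction_summary(faims)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_pair_heatmap(pair_yield_matrix(faims, cfg$cv_grid))
  expect_s3_class(p2, "ggplot")
})
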