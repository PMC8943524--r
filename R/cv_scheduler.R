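# SEC-fraction-aware CV-schedule analysis: per-fraction summaries,
# exhaustive two-CV combination, balanced pairing and gain computations.

#' A compensation-voltage grid
#'
#' @param from,to Grid endpoints in volts (order-free).
#' @param step Grid step in volts (default 5).
#' @return Sorted (increasing) numeric vector of CVs.
#' @export
#' @examples
#' cv_grid(-85, -30)  # the internal-stepping survey grid
cv_grid <- function(from = -85, to = -30, step = 5) {
  stopifnot(step > 0)
  sort(seq(min(from, to), max(from, to), by = step))
}

#' The single-CV external-stepping survey schedule
#'
#' The 17 compensation voltages used to survey FAIMS transmission one CV
#' per run: -20 to -90 V in 5 V steps, plus -100 and -110 V.
#'
#' @return Sorted numeric vector of 17 CVs (volts).
#' @export
external_stepping_cvs <- function() {
  sort(c(seq(-90, -20, by = 5), -100, -110))
}

#' Balanced two-CV pairing with a fixed offset
#'
#' Pairs each grid value `v` with `v - offset` where both lie on the grid.
#' With an even grid and `offset = step * length(grid) / 2` this pairs a
#' precursor-rich CV with a precursor-poor one and covers every grid value
#' exactly once — the internal-stepping acquisition design.
#'
#' @param cv_values Sorted CV grid (volts), strictly increasing.
#' @param offset Positive pairing offset in volts; must be a multiple of
#'   the grid step and smaller than the grid span.
#' @return Tibble with columns `cv_rich` (less negative) and `cv_poor`
#'   (= `cv_rich - offset`), ordered from least negative `cv_rich` down.
#' @export
#' @examples
#' balanced_pairing(cv_grid(-85, -30), offset = 30)
balanced_pairing <- function(cv_values, offset = 30) {
  stopifnot(length(cv_values) >= 2L, !is.unsorted(cv_values, strictly = TRUE))
  step <- min(diff(cv_values))
  span <- diff(range(cv_values))
  if (offset <= 0 || offset > span) {
    stop("offset must lie in (0, grid span]", call. = FALSE)
  }
  if (abs(offset / step - round(offset / step)) > 1e-9) {
    stop("offset ", offset, " V is not a multiple of the grid step ", step,
         " V", call. = FALSE)
  }
  rich <- cv_values[(cv_values - offset) %in% cv_values]
  tibble::tibble(cv_rich = rev(rich), cv_poor = rev(rich) - offset)
}

filter_counting <- function(csms, fraction = NULL, include_decoys = FALSE) {
  if (!include_decoys) csms <- csms[!csms$is_decoy, , drop = FALSE]
  if (!is.null(fraction)) {
    csms <- csms[!is.na(csms$sec_fraction) & csms$sec_fraction %in% fraction, ,
                 drop = FALSE]
  }
  csms
}

# URP key sets observed at each CV (list named by CV value).
urp_sets_by_cv <- function(csms, fraction = NULL, include_decoys = FALSE) {
  csms <- filter_counting(csms, fraction, include_decoys)
  csms <- csms[!is.na(csms$cv), , drop = FALSE]
  if (nrow(csms) == 0L) return(list())
  keys <- urp_key(csms)
  lapply(split(keys, csms$cv), unique)
}

#' Per-fraction CSM/URP summary
#'
#' Counts CSMs and distinct unique residue pairs (URPs) per applied CV
#' within one SEC fraction, and the CSM-count-weighted mean CV of the
#' fraction.
#'
#' @param csms CSM tibble (FAIMS rows, i.e. non-missing `cv`, are counted).
#' @param fraction SEC fraction number.
#' @param include_decoys Count decoy CSMs (default FALSE).
#' @return A list with `fraction`, `by_cv` (tibble `cv`, `n_csms`,
#'   `n_urps`) and `mean_cv` (`NA` for an empty fraction).
#' @export
summarize_fraction <- function(csms, fraction, include_decoys = FALSE) {
  csms <- filter_counting(csms, fraction, include_decoys)
  csms <- csms[!is.na(csms$cv), , drop = FALSE]
  if (nrow(csms) == 0L) {
    return(list(fraction = fraction,
                by_cv = tibble::tibble(cv = numeric(0), n_csms = integer(0),
                                       n_urps = integer(0)),
                mean_cv = NA_real_))
  }
  keys <- urp_key(csms)
  by_cv <- tibble::tibble(
    cv = as.numeric(names(split(keys, csms$cv))),
    n_csms = as.integer(table(csms$cv)),
    n_urps = vapply(split(keys, csms$cv), function(k) length(unique(k)),
                    integer(1), USE.NAMES = FALSE)
  )
  list(fraction = fraction, by_cv = by_cv, mean_cv = mean(csms$cv))
}

#' Summary table across all fractions
#'
#' @param csms CSM tibble.
#' @param include_decoys Count decoy CSMs (default FALSE).
#' @return Tibble with one row per (fraction, cv): `sec_fraction`, `cv`,
#'   `n_csms`, `n_urps`, `mean_cv` (per fraction).
#' @export
summarize_fractions <- function(csms, include_decoys = FALSE) {
  fracs <- sort(unique(csms$sec_fraction[!is.na(csms$sec_fraction)]))
  out <- lapply(fracs, function(f) {
    s <- summarize_fraction(csms, f, include_decoys)
    if (nrow(s$by_cv) == 0L) return(NULL)
    tibble::tibble(sec_fraction = f, s$by_cv, mean_cv = s$mean_cv)
  })
  dplyr::bind_rows(out)
}

#' Yield of combining two CVs
#'
#' Collects the URP sets observed at each of two CVs (within one fraction,
#' or globally) and reports the union count plus the percentage overlap.
#'
#' @param csms CSM tibble.
#' @param cv_a,cv_b The two CVs (volts). A CV absent from the data
#'   contributes an empty set.
#' @param fraction SEC fraction, or `NULL` for all fractions pooled.
#' @param overlap `"jaccard"` (default): 100 * |A n B| / |A u B|;
#'   `"min"`: 100 * |A n B| / min(|A|, |B|).
#' @param include_decoys Count decoy CSMs (default FALSE).
#' @return One-row tibble: `cv_a`, `cv_b`, `urps_a`, `urps_b`,
#'   `urps_union`, `overlap_pct`.
#' @export
pair_yield <- function(csms, cv_a, cv_b, fraction = NULL,
                       overlap = c("jaccard", "min"),
                       include_decoys = FALSE) {
  overlap <- match.arg(overlap)
  sets <- urp_sets_by_cv(csms, fraction, include_decoys)
  pair_yield_from_sets(sets, cv_a, cv_b, overlap)
}

pair_yield_from_sets <- function(sets, cv_a, cv_b, overlap = "jaccard") {
  set_a <- sets[[as.character(cv_a)]] %||% character(0)
  set_b <- sets[[as.character(cv_b)]] %||% character(0)
  n_union <- length(union(set_a, set_b))
  n_inter <- length(intersect(set_a, set_b))
  denom <- switch(overlap,
                  jaccard = n_union,
                  min = min(length(set_a), length(set_b)))
  hi_first <- cv_a >= cv_b
  cv_hi <- if (hi_first) cv_a else cv_b
  cv_lo <- if (hi_first) cv_b else cv_a
  set_hi <- if (hi_first) set_a else set_b
  set_lo <- if (hi_first) set_b else set_a
  tibble::tibble(
    cv_a = cv_hi, cv_b = cv_lo,
    urps_a = length(set_hi), urps_b = length(set_lo),
    urps_union = n_union,
    overlap_pct = if (denom == 0) 0 else 100 * n_inter / denom
  )
}

#' All pairwise two-CV yields
#'
#' Exhaustively evaluates every unordered pair of grid CVs (the material
#' for the two-triangle heatmap: overlap percentage on one side, union URP
#' count on the other).
#'
#' @inheritParams pair_yield
#' @param cv_values CV grid to combine.
#' @return Tibble of all `choose(K, 2)` pairs with the [pair_yield()]
#'   columns.
#' @export
pair_yield_matrix <- function(csms, cv_values, fraction = NULL,
                              overlap = c("jaccard", "min"),
                              include_decoys = FALSE) {
  overlap <- match.arg(overlap)
  stopifnot(length(cv_values) >= 2L)
  sets <- urp_sets_by_cv(csms, fraction, include_decoys)
  combos <- utils::combn(sort(cv_values), 2)
  dplyr::bind_rows(lapply(seq_len(ncol(combos)), function(i) {
    pair_yield_from_sets(sets, combos[2, i], combos[1, i], overlap)
  }))
}

# Deterministic ranking of pair yields: union desc, overlap asc,
# spacing asc, less-negative cv_a first.
order_pair_yields <- function(yields) {
  order(-yields$urps_union, yields$overlap_pct,
        abs(yields$cv_a - yields$cv_b), -yields$cv_a)
}

#' Best two-CV combination
#'
#' Maximises the union URP count over all unordered pairs of grid CVs.
#' Ties are broken deterministically: lower overlap percentage, then
#' smaller CV spacing, then less negative `cv_a`.
#'
#' @inheritParams pair_yield_matrix
#' @return One-row tibble with the [pair_yield()] columns.
#' @export
best_pair <- function(csms, cv_values, fraction = NULL,
                      overlap = c("jaccard", "min"), include_decoys = FALSE) {
  if (length(cv_values) < 2L) {
    stop("need at least 2 CVs to combine", call. = FALSE)
  }
  yields <- pair_yield_matrix(csms, cv_values, fraction, overlap,
                              include_decoys)
  yields[order_pair_yields(yields)[1L], , drop = FALSE]
}

#' Gain of fraction-specific over global two-CV combinations
#'
#' Finds the globally optimal CV pair (all fractions pooled), evaluates it
#' within each fraction, and compares it to that fraction's own optimal
#' pair: `gain_pct = 100 * (URPs_fraction_pair - URPs_global_pair) /
#' URPs_global_pair`.
#'
#' @inheritParams pair_yield_matrix
#' @return A list with `global_pair` (one-row tibble), `per_fraction`
#'   (tibble: fraction, both pairs' CVs and URP unions, `gain_pct`,
#'   `degenerate` flag where the global pair yields zero URPs), and
#'   `median_gain_pct` / `sd_gain_pct` across non-degenerate fractions.
#' @export
fraction_gain <- function(csms, cv_values, overlap = c("jaccard", "min"),
                          include_decoys = FALSE) {
  overlap <- match.arg(overlap)
  fracs <- sort(unique(csms$sec_fraction[!is.na(csms$sec_fraction)]))
  if (length(fracs) < 2L) stop("need at least 2 fractions", call. = FALSE)
  global_pair <- best_pair(csms, cv_values, NULL, overlap, include_decoys)
  rows <- lapply(fracs, function(f) {
    bp <- best_pair(csms, cv_values, f, overlap, include_decoys)
    gp <- pair_yield(csms, global_pair$cv_a, global_pair$cv_b, f, overlap,
                     include_decoys)
    degenerate <- gp$urps_union == 0
    tibble::tibble(
      sec_fraction = f,
      best_cv_a = bp$cv_a, best_cv_b = bp$cv_b,
      urps_best = bp$urps_union, urps_global = gp$urps_union,
      gain_pct = if (degenerate) NA_real_ else
        100 * (bp$urps_union - gp$urps_union) / gp$urps_union,
      degenerate = degenerate
    )
  })
  per_fraction <- dplyr::bind_rows(rows)
  gains <- per_fraction$gain_pct[!per_fraction$degenerate]
  list(global_pair = global_pair, per_fraction = per_fraction,
       median_gain_pct = stats::median(gains),
       sd_gain_pct = stats::sd(gains))
}

#' Top-k two-CV combinations versus no-FAIMS replicates
#'
#' Per fraction, ranks all two-CV combinations by union URP count (ties as
#' in [best_pair()]), merges the URP sets of the best `j` pairs in silico
#' for `j = 1..k`, and compares each merged set to the URP union of the
#' first `j` no-FAIMS replicate runs (replicates ordered by `run_id`) —
#' i.e. `j` injections with FAIMS against `j` injections without.
#'
#' @param faims_csms CSM tibble from FAIMS runs (non-missing `cv`).
#' @param nofaims_csms CSM tibble from no-FAIMS replicate runs (missing
#'   `cv`), replicates distinguished by `run_id`.
#' @param cv_values CV grid to combine.
#' @param k Number of injections to compare (default 3).
#' @param include_decoys Count decoy CSMs (default FALSE).
#' @return A list with `per_fraction` (tibble: `sec_fraction`, `n_runs`
#'   = j, `urps_faims`, `urps_nofaims`, `gain_pct`) and
#'   `median_gain_pct` / `sd_gain_pct` across fractions at `j = k`.
#'   Fractions without no-FAIMS data are skipped with a warning.
#' @export
topk_vs_replicates <- function(faims_csms, nofaims_csms, cv_values, k = 3,
                               include_decoys = FALSE) {
  stopifnot(k >= 1)
  fracs <- sort(unique(faims_csms$sec_fraction[!is.na(faims_csms$sec_fraction)]))
  rows <- list()
  for (f in fracs) {
    nf <- filter_counting(nofaims_csms, f, include_decoys)
    nf <- nf[is.na(nf$cv), , drop = FALSE]
    if (nrow(nf) == 0L) {
      warning("no no-FAIMS data for fraction ", f, "; skipped")
      next
    }
    yields <- pair_yield_matrix(faims_csms, cv_values, f,
                                include_decoys = include_decoys)
    yields <- yields[order_pair_yields(yields), , drop = FALSE]
    top <- utils::head(yields, k)
    sets <- urp_sets_by_cv(faims_csms, f, include_decoys)
    rep_ids <- sort(unique(nf$run_id))
    nf_sets <- lapply(split(urp_key(nf), nf$run_id), unique)
    faims_union <- character(0)
    nofaims_union <- character(0)
    for (j in seq_len(min(k, nrow(top)))) {
      faims_union <- union(faims_union,
                           union(sets[[as.character(top$cv_a[j])]] %||% character(0),
                                 sets[[as.character(top$cv_b[j])]] %||% character(0)))
      if (j <= length(rep_ids)) {
        nofaims_union <- union(nofaims_union, nf_sets[[rep_ids[j]]])
      }
      n_no <- length(nofaims_union)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sec_fraction = f, n_runs = j,
        urps_faims = length(faims_union), urps_nofaims = n_no,
        gain_pct = if (n_no == 0) NA_real_ else
          100 * (length(faims_union) - n_no) / n_no
      )
    }
  }
  per_fraction <- dplyr::bind_rows(rows)
  if (nrow(per_fraction) == 0L) {
    stop("no fraction had both FAIMS and no-FAIMS data", call. = FALSE)
  }
  at_k <- per_fraction[per_fraction$n_runs == min(k, max(per_fraction$n_runs)), ]
  list(per_fraction = per_fraction,
       median_gain_pct = stats::median(at_k$gain_pct, na.rm = TRUE),
       sd_gain_pct = stats::sd(at_k$gain_pct, na.rm = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

faimscv_default_grid <- function() cv_grid(-85, -30, 5)
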