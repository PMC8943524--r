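# CSM table data model, delimited-text I/O, pre-FDR filters, leakage-free
# deduplication and the iBAQ database-reduction heuristic.

# Canonical CSM table schema: column name -> readr column type.
CSM_SCHEMA <- c(
  run_id = "c", sec_fraction = "i", cv = "d", score = "d", delta_score = "d",
  pep_seq_a = "c", pep_seq_b = "c", link_site_a = "i", link_site_b = "i",
  protein_a = "c", protein_b = "c", pos_a = "i", pos_b = "i",
  charge = "i", frags_a = "i", frags_b = "i", is_decoy = "l"
)

#' Canonical CSM table column names
#'
#' The package-wide schema for cross-link spectrum match (CSM) tables: one
#' row per matched spectrum, alpha/beta peptide sequences with 1-based link
#' sites, protein accessions with the 1-based protein position of each
#' peptide's first residue (`pos_a`, `pos_b`), precursor charge, search
#' score and delta score, matched fragment counts per peptide, the applied
#' compensation voltage (`cv`, signed volts; `NA` for runs acquired without
#' FAIMS), the SEC fraction (`NA` if unfractionated), run identifier and a
#' target/decoy flag.
#'
#' @return Character vector of canonical column names.
#' @export
csm_columns <- function() names(CSM_SCHEMA)

#' Construct one peptide chain of a cross-link
#'
#' @param sequence Uppercase amino-acid string (canonical residues only),
#'   length >= 5.
#' @param link_site 1-based position of the cross-linked residue within
#'   `sequence`.
#' @param protein_id Protein accession.
#' @param protein_start 1-based position of residue 1 in the protein.
#' @param modifications Optional data frame with columns `position`
#'   (1-based; 0 denotes the N-terminus), `mass_delta` (Da) and `name`.
#' @return A list of class `faims_peptide`.
#' @export
#' @examples
#' peptide("ACDEFK", link_site = 6, protein_id = "P1", protein_start = 10)
peptide <- function(sequence, link_site, protein_id = NA_character_,
                    protein_start = NA_integer_, modifications = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n < 5L) {
    stop("peptide sequence must have length >= 5, got ", n, call. = FALSE)
  }
  bad <- setdiff(strsplit(sequence, "")[[1]], names(AA_MONO_MASS))
  if (length(bad) > 0L) {
    stop("unknown residue(s) in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (link_site < 1L || link_site > n) {
    stop("link_site must lie in [1, ", n, "], got ", link_site, call. = FALSE)
  }
  if (!is.null(modifications)) {
    stopifnot(all(c("position", "mass_delta") %in% names(modifications)))
    if (any(modifications$position < 0L | modifications$position > n)) {
      stop("modification positions must lie in [0, ", n, "]", call. = FALSE)
    }
  }
  structure(
    list(sequence = sequence, link_site = as.integer(link_site),
         protein_id = protein_id, protein_start = as.integer(protein_start),
         modifications = modifications),
    class = "faims_peptide"
  )
}

#' Assemble a CSM table from vectors
#'
#' Light-weight constructor used by the simulator and in tests; validates
#' against the canonical schema.
#'
#' @param ... Name-value pairs for the columns in [csm_columns()]. Missing
#'   columns are filled with `NA` (`is_decoy` with `FALSE`).
#' @return A tibble with the canonical CSM columns.
#' @export
csm_table <- function(...) {
  tbl <- tibble::tibble(...)
  unknown <- setdiff(names(tbl), csm_columns())
  if (length(unknown) > 0L) {
    stop("unknown CSM column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(csm_columns(), names(tbl))) {
    tbl[[col]] <- if (col == "is_decoy") FALSE else NA
  }
  tbl <- tbl[, csm_columns()]
  validate_csm_table(tbl)
  tbl
}

#' Validate a CSM table against the schema invariants
#'
#' Checks column presence, positive charges, link sites within sequences,
#' and that non-missing CVs lie in the FAIMS operating range [-110, -20] V.
#'
#' @param csms CSM tibble.
#' @param cv_step Expected CV grid step in volts; non-missing CVs must be a
#'   multiple of it (default 5 V). Use `NULL` to skip.
#' @return The input, invisibly; errors describe the offending rows.
#' @export
validate_csm_table <- function(csms, cv_step = 5) {
  missing_cols <- setdiff(csm_columns(), names(csms))
  if (length(missing_cols) > 0L) {
    stop("CSM table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fail <- function(what, idx) {
    stop(what, " in row(s): ",
         paste(utils::head(idx, 5L), collapse = ", "),
         if (length(idx) > 5L) " ..." else "", call. = FALSE)
  }
  bad <- which(is.na(csms$pep_seq_a) | is.na(csms$pep_seq_b) |
                 csms$pep_seq_a == "" | csms$pep_seq_b == "")
  if (length(bad)) fail("missing peptide sequence", bad)
  bad <- which(!is.na(csms$charge) & csms$charge < 1L)
  if (length(bad)) fail("precursor charge < 1", bad)
  bad <- which(csms$link_site_a < 1L | csms$link_site_a > nchar(csms$pep_seq_a) |
                 csms$link_site_b < 1L | csms$link_site_b > nchar(csms$pep_seq_b))
  if (length(bad)) fail("link site outside peptide sequence", bad)
  cv <- csms$cv[!is.na(csms$cv)]
  if (length(cv)) {
    if (any(cv < -110 | cv > -20)) {
      fail("CV outside [-110, -20] V", which(!is.na(csms$cv) &
                                               (csms$cv < -110 | csms$cv > -20)))
    }
    if (!is.null(cv_step) && any(abs(cv / cv_step - round(cv / cv_step)) > 1e-6)) {
      fail("CV not a multiple of the grid step",
           which(!is.na(csms$cv) &
                   abs(csms$cv / cv_step - round(csms$cv / cv_step)) > 1e-6))
    }
  }
  invisible(csms)
}

#' Read a CSM table from delimited text
#'
#' Reads tab- or comma-delimited CSM exports (compression-transparent, e.g.
#' `.gz`) into the canonical schema. Foreign headers are translated through
#' a dialect mapping, so xiSEARCH/xiFDR-style exports with different column
#' names can be consumed without editing the file.
#'
#' @param path File path.
#' @param dialect Either `NULL` (file already uses canonical headers), a
#'   named character vector `c(canonical = "source header", ...)`, or the
#'   path to a two-column tab-delimited file with columns `canonical` and
#'   `source`.
#' @param delim Field delimiter; guessed from the first line when `NULL`.
#' @param validate Run [validate_csm_table()] after parsing (default TRUE).
#' @return A tibble with the canonical CSM columns.
#' @export
read_csm_table <- function(path, dialect = NULL, delim = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dialect <- load_dialect(dialect)
  if (is.null(delim)) {
    first <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = c("", "NA"), progress = FALSE)
  if (!is.null(dialect)) {
    missing_src <- setdiff(unname(dialect), names(raw))
    if (length(missing_src) > 0L) {
      stop("dialect refers to column(s) absent from the file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    raw <- raw[, unname(dialect)]
    names(raw) <- names(dialect)
  }
  unknown <- setdiff(names(raw), csm_columns())
  if (length(unknown) > 0L) {
    stop("unknown column(s) in CSM table: ", paste(unknown, collapse = ", "),
         "; map or drop them via the dialect", call. = FALSE)
  }
  out <- tibble::tibble(.rows = nrow(raw))
  for (col in csm_columns()) {
    if (!col %in% names(raw)) {
      out[[col]] <- if (col == "is_decoy") FALSE else NA
      next
    }
    out[[col]] <- parse_csm_column(raw[[col]], CSM_SCHEMA[[col]], col)
  }
  out$is_decoy[is.na(out$is_decoy)] <- FALSE
  if (validate) validate_csm_table(out)
  out
}

parse_csm_column <- function(x, type, col) {
  parsed <- switch(type,
    c = x,
    i = suppressWarnings(as.integer(x)),
    d = suppressWarnings(as.numeric(x)),
    l = as.logical(toupper(x) %in% c("TRUE", "T", "1")) & !is.na(x)
  )
  if (type %in% c("i", "d")) {
    bad <- which(!is.na(x) & is.na(parsed))
    if (length(bad) > 0L) {
      stop("malformed value in column '", col, "' at data row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "", call. = FALSE)
    }
  }
  parsed
}

load_dialect <- function(dialect) {
  if (is.null(dialect)) return(NULL)
  if (is.character(dialect) && is.null(names(dialect)) &&
      length(dialect) == 1L && file.exists(dialect)) {
    map <- utils::read.delim(dialect, stringsAsFactors = FALSE)
    stopifnot(all(c("canonical", "source") %in% names(map)))
    dialect <- stats::setNames(map$source, map$canonical)
  }
  unknown <- setdiff(names(dialect), csm_columns())
  if (length(unknown) > 0L) {
    stop("dialect maps unknown canonical column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dialect
}

#' Write a CSM table to delimited text
#'
#' @param csms CSM tibble.
#' @param path Output path; a `.gz` suffix writes compressed text.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_csm_table <- function(csms, path, delim = "\t") {
  validate_csm_table(csms)
  readr::write_delim(csms, path, delim = delim, na = "")
  invisible(path)
}

#' Pre-FDR quality filters for CSMs
#'
#' Keeps CSMs with at least `min_fragments` matched fragments on *both*
#' peptides and a delta score of at least `min_delta_score` (both bounds
#' inclusive). Row order is preserved.
#'
#' @param csms CSM tibble.
#' @param min_fragments Minimum matched fragments per peptide (default 3).
#' @param min_delta_score Minimum delta score (default 0.1).
#' @return Filtered CSM tibble (possibly empty).
#' @export
prefilter_csms <- function(csms, min_fragments = 3, min_delta_score = 0.1) {
  stopifnot(min_fragments >= 0, min_delta_score >= 0)
  keep <- csms$frags_a >= min_fragments & csms$frags_b >= min_fragments &
    csms$delta_score >= min_delta_score
  keep[is.na(keep)] <- FALSE
  csms[keep, , drop = FALSE]
}

# Order-normalised (alpha, beta) sequence pair: the lexicographically
# smaller sequence first, carrying its companion columns along.
normalize_pair_order <- function(csms) {
  swap <- csms$pep_seq_b < csms$pep_seq_a
  if (!any(swap)) return(csms)
  pairs <- list(c("pep_seq_a", "pep_seq_b"), c("link_site_a", "link_site_b"),
                c("protein_a", "protein_b"), c("pos_a", "pos_b"),
                c("frags_a", "frags_b"))
  for (p in pairs) {
    tmp <- csms[[p[1]]][swap]
    csms[[p[1]]][swap] <- csms[[p[2]]][swap]
    csms[[p[2]]][swap] <- tmp
  }
  csms
}

#' Collapse CSMs to the highest-scoring peptide pair per charge state
#'
#' Groups CSMs by the combination of alpha-peptide sequence, beta-peptide
#' sequence and precursor charge (alpha/beta order-normalised first) and
#' retains the single highest-scoring CSM per group, ties broken by first
#' occurrence. Link sites are deliberately ignored in the key so that
#' link-site variants of the same peptide pair cannot leak near-identical
#' sequences across a train/validation split.
#'
#' @param csms CSM tibble with finite scores.
#' @return Deduplicated CSM tibble, in order of first group occurrence.
#' @export
deduplicate_csms <- function(csms) {
  if (nrow(csms) == 0L) return(csms)
  stopifnot(all(is.finite(csms$score)))
  norm <- normalize_pair_order(csms)
  key <- paste(norm$pep_seq_a, norm$pep_seq_b, norm$charge, sep = "\r")
  ord <- order(match(key, unique(key)), -norm$score, seq_len(nrow(norm)))
  keep <- ord[!duplicated(key[ord])]
  csms[sort(keep), , drop = FALSE]
}

#' Unique residue pair (URP) keys
#'
#' Maps each CSM to its protein-level residue pair: the linked position is
#' `pos + link_site - 1` on each protein, and the two (protein, site) pairs
#' are order-normalised so that a link and its alpha/beta swap produce the
#' same key.
#'
#' @param csms CSM tibble; both peptides must carry a protein mapping.
#' @return Character vector of keys, one per row, of the form
#'   `"P1:12--P2:40"`.
#' @export
urp_key <- function(csms) {
  if (nrow(csms) == 0L) return(character(0))
  bad <- which(is.na(csms$protein_a) | is.na(csms$protein_b) |
                 is.na(csms$pos_a) | is.na(csms$pos_b))
  if (length(bad) > 0L) {
    stop("missing protein mapping in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  site_a <- csms$pos_a + csms$link_site_a - 1L
  site_b <- csms$pos_b + csms$link_site_b - 1L
  ka <- sprintf("%s:%06d", csms$protein_a, site_a)
  kb <- sprintf("%s:%06d", csms$protein_b, site_b)
  first <- pmin(ka, kb)
  second <- pmax(ka, kb)
  paste(first, second, sep = "--")
}

#' Count unique residue pairs in a CSM table
#'
#' @param csms CSM tibble.
#' @param include_decoys Count decoy CSMs as well (default FALSE).
#' @return Number of distinct URP keys.
#' @export
count_urps <- function(csms, include_decoys = FALSE) {
  if (!include_decoys) csms <- csms[!csms$is_decoy, , drop = FALSE]
  length(unique(urp_key(csms)))
}

#' Abundance cutoff at the knee of a sorted iBAQ distribution
#'
#' Sorts iBAQ values in descending order, takes log10, min-max normalises
#' both axes, and places the cutoff at the interior point of maximum
#' discrete curvature (Kneedle-style knee). Proteins with iBAQ at or above
#' the cutoff would be retained in a reduced search database.
#'
#' @param ibaq_values Numeric vector of per-protein iBAQ values; must
#'   contain at least 3 positive values. Non-positive values are dropped
#'   with a warning.
#' @return A list with `cutoff_value`, `n_retained`, `knee_index` (into the
#'   descending-sorted positive values), `degenerate` (TRUE when the sorted
#'   curve has no curvature maximum, in which case everything is retained)
#'   and `n_nonpositive`.
#' @export
ibaq_knee_cutoff <- function(ibaq_values) {
  n_nonpos <- sum(!is.finite(ibaq_values) | ibaq_values <= 0)
  vals <- ibaq_values[is.finite(ibaq_values) & ibaq_values > 0]
  if (n_nonpos > 0L) {
    warning(n_nonpos, " non-positive/non-finite iBAQ value(s) excluded")
  }
  if (length(vals) < 3L) {
    stop("need at least 3 positive iBAQ values, got ", length(vals),
         call. = FALSE)
  }
  sorted <- sort(vals, decreasing = TRUE)
  kappa <- sorted_curve_curvature(log10(sorted))
  if (max(kappa, na.rm = TRUE) < 1e-8) {
    return(list(cutoff_value = sorted[length(sorted)],
                n_retained = length(sorted), knee_index = length(sorted),
                degenerate = TRUE, n_nonpositive = n_nonpos))
  }
  knee <- which.max(kappa)
  list(cutoff_value = sorted[knee], n_retained = knee, knee_index = knee,
       degenerate = FALSE, n_nonpositive = n_nonpos)
}

# Discrete curvature |y''| / (1 + y'^2)^(3/2) of a curve y over index x,
# both axes min-max normalised; endpoints get curvature 0.
sorted_curve_curvature <- function(y) {
  n <- length(y)
  x <- seq(0, 1, length.out = n)
  rng <- diff(range(y))
  yn <- if (rng > 0) (y - min(y)) / rng else rep(0, n)
  kappa <- numeric(n)
  if (n < 3L) return(kappa)
  i <- 2:(n - 1L)
  h <- x[2] - x[1]
  d1 <- (yn[i + 1L] - yn[i - 1L]) / (2 * h)
  d2 <- (yn[i + 1L] - 2 * yn[i] + yn[i - 1L]) / h^2
  kappa[i] <- abs(d2) / (1 + d1^2)^1.5
  kappa
}
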