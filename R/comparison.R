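#' Offset-tolerant genotype comparison (GCA)
#'
#' Decides whether two effective diploid locus genotypes are the same allowing
#' an allele-size offset of up to `n` bp. Two genotypes \[a1, b1\] and
#' \[a2, b2\] are "same" if either the direct pairing (|a1 - a2| <= n and
#' |b1 - b2| <= n) or the crossed pairing (|a1 - b2| <= n and |a2 - b1| <= n)
#' matches. The offset absorbs the 1--2 bp fragment-sizing error of capillary
#' electrophoresis, so reads of the same allele binned 1--2 bp apart do not
#' create spurious differences.
#'
#' @param g1,g2 Numeric vectors of length 2 (the two allele sizes in bp) or
#'   one-row data frames with `allele_low`/`allele_high` columns.
#' @param n Allowed offset in bp, >= 0.
#' @return `0L` if the genotypes are the same within the offset, `1L` if they
#'   differ. Missing genotypes are rejected; classify missingness first with
#'   [classify_locus()].
#' @examples
#' gca(c(100, 102), c(101, 103), n = 2)  # 0: direct pairing within 2 bp
#' gca(c(100, 104), c(104, 100), n = 0)  # 0: crossed pairing is exact
#' gca(c(100, 110), c(104, 106), n = 2)  # 1: no pairing within 2 bp
#' @export
gca <- function(g1, g2, n = 2) {
  g1 <- as_allele_pair(g1)
  g2 <- as_allele_pair(g2)
  stopifnot(is.numeric(n), length(n) == 1, n >= 0)
  if (anyNA(g1) || anyNA(g2)) {
    stop("gca() requires two effective genotypes; use classify_locus() for missing data")
  }
  gca_vec(g1[1], g1[2], g2[1], g2[2], n)
}

as_allele_pair <- function(g) {
  if (is.data.frame(g)) {
    stopifnot(nrow(g) == 1)
    return(c(g$allele_low, g$allele_high))
  }
  if (is.logical(g) && all(is.na(g))) g <- as.numeric(g)  # NA pair = missing
  stopifnot(is.numeric(g), length(g) == 2)
  g
}

# Vectorised core of Algorithm GCA: 0 = same, 1 = different.
gca_vec <- function(a1, b1, a2, b2, n) {
  direct <- abs(a1 - a2) <= n & abs(b1 - b2) <= n
  crossed <- abs(a1 - b2) <= n & abs(a2 - b1) <= n
  ifelse(direct | crossed, 0L, 1L)
}

#' Classify one locus of a fingerprint pair
#'
#' A locus pair is `MISSING` when fewer than two effective genotypes are
#' present (either side missing), otherwise `SAME` or `DIFFERENT` by [gca()]
#' at offset `n`.
#'
#' @inheritParams gca
#' @param marker_id Optional pair of marker ids; when supplied they must agree.
#' @return One of `"SAME"`, `"DIFFERENT"`, `"MISSING"`.
#' @export
classify_locus <- function(g1, g2, n = 2, marker_id = NULL) {
  if (!is.null(marker_id)) {
    marker_id <- as.character(marker_id)
    if (length(unique(marker_id)) != 1) {
      stop("classify_locus() compares one locus: marker ids must match")
    }
  }
  g1 <- as_allele_pair(g1)
  g2 <- as_allele_pair(g2)
  if (anyNA(g1) || anyNA(g2)) return("MISSING")
  if (gca(g1, g2, n) == 0L) "SAME" else "DIFFERENT"
}

# Classify all p loci of one pair given two aligned allele matrices.
classify_vec <- function(a1, b1, a2, b2, n) {
  cls <- rep("MISSING", length(a1))
  eff <- !is.na(a1) & !is.na(a2)
  cls[eff] <- ifelse(gca_vec(a1[eff], b1[eff], a2[eff], b2[eff], n) == 0L,
                     "SAME", "DIFFERENT")
  cls
}

#' Compare one fingerprint pair
#'
#' Tallies the p panel loci of a pending/reference fingerprint pair into
#' different (D), non-different (S) and missing (M) loci using
#' [classify_locus()] at the configured base offset, and reports the
#' differential fraction x = D/p. The conservation p = D + S + M always holds.
#'
#' @param f1 Pending fingerprint (tibble, one `entity_id`).
#' @param f2 Reference fingerprint (tibble, one `entity_id`).
#' @param params [comparison_params()].
#' @return One-row tibble: `id_pending`, `id_reference`, `p`, `D`, `S`, `M`, `x`.
#' @export
compare_pair <- function(f1, f2, params = comparison_params()) {
  stopifnot(inherits(params, "comparison_params"))
  stopifnot(length(unique(f1$entity_id)) == 1, length(unique(f2$entity_id)) == 1)
  if (!setequal(f1$marker_id, f2$marker_id) || nrow(f1) != nrow(f2)) {
    stop("fingerprints must share an identical marker panel")
  }
  j <- dplyr::inner_join(
    dplyr::select(f1, "marker_id", a1 = "allele_low", b1 = "allele_high"),
    dplyr::select(f2, "marker_id", a2 = "allele_low", b2 = "allele_high"),
    by = "marker_id"
  )
  cls <- classify_vec(j$a1, j$b1, j$a2, j$b2, params$base_offset_bp)
  comparison_result(
    id_pending = f1$entity_id[1], id_reference = f2$entity_id[1],
    p = nrow(j),
    D = sum(cls == "DIFFERENT"), S = sum(cls == "SAME"), M = sum(cls == "MISSING")
  )
}

#' Compare a pending queue against a reference queue (FCPP)
#'
#' The pairwise queue comparison: every fingerprint in the pending queue is
#' scored against every fingerprint in the reference queue, yielding exactly
#' `length(reference) x length(pending)` results in reference-major order
#' (all pending against reference 1, then reference 2, ...), matching the
#' nested-loop order of the underlying algorithm.
#'
#' @param pending Fingerprint tibble; each distinct `entity_id` is one queue
#'   member.
#' @param reference Fingerprint tibble, same panel.
#' @param params [comparison_params()].
#' @return Tibble of class `ssr_comparison`, one row per ordered pair, with a
#'   `verdict` column (`"retained"`/`"filtered"`) from the report filters.
#' @export
compare_fingerprints <- function(pending, reference, params = comparison_params()) {
  stopifnot(inherits(params, "comparison_params"))
  p_ids <- unique(pending$entity_id)
  r_ids <- unique(reference$entity_id)
  if (length(p_ids) == 0 || length(r_ids) == 0) {
    stop("both queues must contain at least one fingerprint")
  }
  panel_ids <- sort(unique(pending$marker_id))
  chk <- function(fps) {
    all(vapply(split(fps$marker_id, fps$entity_id),
               function(m) identical(sort(m), panel_ids), logical(1)))
  }
  if (!chk(pending) || !chk(reference)) {
    stop("all fingerprints in both queues must share one marker panel")
  }

  # wide allele matrices, markers in fixed order, for vectorised pair scoring
  widen <- function(fps, ids) {
    fps <- fps[order(match(fps$entity_id, ids), match(fps$marker_id, panel_ids)), ]
    list(
      a = matrix(fps$allele_low, nrow = length(panel_ids), dimnames = list(panel_ids, ids)),
      b = matrix(fps$allele_high, nrow = length(panel_ids), dimnames = list(panel_ids, ids))
    )
  }
  P <- widen(pending, p_ids)
  R <- widen(reference, r_ids)
  n <- params$base_offset_bp

  grid <- tidyr::expand_grid(id_reference = r_ids, id_pending = p_ids)
  res <- purrr::pmap_dfr(grid, function(id_reference, id_pending) {
    cls <- classify_vec(P$a[, id_pending], P$b[, id_pending],
                        R$a[, id_reference], R$b[, id_reference], n)
    comparison_result(id_pending, id_reference, length(cls),
                      sum(cls == "DIFFERENT"), sum(cls == "SAME"),
                      sum(cls == "MISSING"))
  })
  res$verdict <- ifelse(keep_mask(res, params), "retained", "filtered")
  class(res) <- c("ssr_comparison", class(res))
  attr(res, "params") <- params
  res
}

keep_mask <- function(results, params) {
  (results$p - results$M) >= params$min_comparison_loci &
    results$D <= params$max_diff_loci &
    results$x <= params$max_diff_fraction
}

#' Filter comparison results for reporting
#'
#' Keeps a pair when it has at least `min_comparison_loci` loci effective on
#' both sides (p - M), at most `max_diff_loci` differential loci, and a
#' differential fraction x at most `max_diff_fraction`. Proper control of
#' these values suppresses uninformative pairs from large database scans.
#'
#' @param results Output of [compare_fingerprints()] or [compare_pair()].
#' @param params [comparison_params()].
#' @return The retained subset, same columns.
#' @export
filter_comparisons <- function(results, params = comparison_params()) {
  stopifnot(is.data.frame(results), inherits(params, "comparison_params"))
  out <- results[keep_mask(results, params), , drop = FALSE]
  out$verdict <- rep("retained", nrow(out))
  out
}

#' Select comparison scopes from the local fingerprint database
#'
#' Builds the pending and reference queues for the five comparison modes:
#' \describe{
#'   \item{DATABASE}{reference = the entire local fingerprint database (LFD).}
#'   \item{HOMONYMY}{reference = LFD entries whose name or synonyms exactly
#'     match the pending name (after whitespace trimming).}
#'   \item{NON_HOMONYMY}{the LFD complement of the homonymy set, so that
#'     homonymy + non-homonymy = the entire database.}
#'   \item{SUB_DATABASE}{reference = the assigned member list.}
#'   \item{PAIRED}{explicit (pending, reference) pairs; use
#'     [compare_assigned_pairs()] to score them.}
#' }
#'
#' @param store An [fp_store()] with a non-empty LFD (modes DATABASE,
#'   HOMONYMY, NON_HOMONYMY).
#' @param mode One of `"DATABASE"`, `"HOMONYMY"`, `"NON_HOMONYMY"`,
#'   `"SUB_DATABASE"`, `"PAIRED"`.
#' @param pending Fingerprint tibble to be compared.
#' @param pending_name Name used for homonymy matching (defaults to the
#'   pending entity id).
#' @param assignment For SUB_DATABASE: data frame with `member_id`, `role`
#'   (`"pending"`/`"reference"`); for PAIRED: data frame with `pending_id`,
#'   `reference_id`. Forbidden for the other modes.
#' @return List with elements `pending` and `reference` (fingerprint tibbles),
#'   plus `pairs` for PAIRED mode.
#' @export
select_scope <- function(store, mode, pending = NULL, pending_name = NULL,
                         assignment = NULL) {
  mode <- match.arg(mode, c("DATABASE", "HOMONYMY", "NON_HOMONYMY",
                            "SUB_DATABASE", "PAIRED"))
  needs_assignment <- mode %in% c("SUB_DATABASE", "PAIRED")
  if (needs_assignment && is.null(assignment)) {
    stop(mode, " comparison requires an external assignment table")
  }
  if (!needs_assignment && !is.null(assignment)) {
    stop(mode, " comparison does not take an assignment table")
  }

  if (mode == "PAIRED") {
    stopifnot(all(c("pending_id", "reference_id") %in% names(assignment)))
    ids <- unique(c(assignment$pending_id, assignment$reference_id))
    fps <- store_fingerprints(store, tier = "LFD", entity_ids = ids)
    return(list(pending = fps[fps$entity_id %in% assignment$pending_id, ],
                reference = fps[fps$entity_id %in% assignment$reference_id, ],
                pairs = tibble::as_tibble(assignment)))
  }
  if (mode == "SUB_DATABASE") {
    stopifnot(all(c("member_id", "role") %in% names(assignment)))
    ref_ids <- assignment$member_id[assignment$role == "reference"]
    pen_ids <- assignment$member_id[assignment$role == "pending"]
    fps <- store_fingerprints(store, tier = "LFD",
                              entity_ids = unique(c(ref_ids, pen_ids)))
    pen <- if (length(pen_ids) > 0) fps[fps$entity_id %in% pen_ids, ] else pending
    return(list(pending = pen, reference = fps[fps$entity_id %in% ref_ids, ]))
  }

  recs <- store_records(store, tier = "LFD")
  if (nrow(recs) == 0) stop("the local fingerprint database is empty")
  if (is.null(pending)) stop("a pending fingerprint is required for ", mode)
  if (mode == "DATABASE") {
    reference <- store_fingerprints(store, tier = "LFD")
  } else {
    nm <- trimws(pending_name %||% unique(pending$entity_id)[1])
    matches <- vapply(seq_len(nrow(recs)), function(i) {
      cand <- trimws(c(recs$name[i], strsplit(recs$synonyms[i] %||% "", ";")[[1]]))
      nm %in% cand[nzchar(cand)]
    }, logical(1))
    ids <- if (mode == "HOMONYMY") recs$entity_id[matches] else recs$entity_id[!matches]
    if (length(ids) == 0) {
      stop("no LFD entries in the ", mode, " scope for name '", nm, "'")
    }
    reference <- store_fingerprints(store, tier = "LFD", entity_ids = ids)
  }
  list(pending = pending, reference = reference)
}

#' Score explicitly assigned fingerprint pairs
#'
#' @param store An [fp_store()].
#' @param pairs Data frame with columns `pending_id`, `reference_id`.
#' @param params [comparison_params()].
#' @return `ssr_comparison` tibble, one row per assigned pair.
#' @export
compare_assigned_pairs <- function(store, pairs, params = comparison_params()) {
  stopifnot(all(c("pending_id", "reference_id") %in% names(pairs)))
  fps <- store_fingerprints(
    store, tier = "LFD",
    entity_ids = unique(c(pairs$pending_id, pairs$reference_id))
  )
  res <- purrr::pmap_dfr(pairs[c("pending_id", "reference_id")],
                         function(pending_id, reference_id) {
    compare_pair(fps[fps$entity_id == pending_id, ],
                 fps[fps$entity_id == reference_id, ], params)
  })
  res$verdict <- ifelse(keep_mask(res, params), "retained", "filtered")
  class(res) <- c("ssr_comparison", class(res))
  attr(res, "params") <- params
  res
}

#' Write a comparison report
#'
#' @param results `ssr_comparison` tibble.
#' @param file Output path; `.json` extension selects JSON, anything else CSV
#'   with columns pending_id, reference_id, p, D, S, M, x, verdict.
#' @return `file`, invisibly.
#' @export
write_comparison_report <- function(results, file) {
  out <- tibble::tibble(
    pending_id = results$id_pending, reference_id = results$id_reference,
    p = results$p, D = results$D, S = results$S, M = results$M,
    x = results$x, verdict = results$verdict
  )
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(out, file, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(out, file)
  }
  invisible(file)
}

#' Read a sub-database or paired comparison assignment
#'
#' @param file CSV (or XLSX, if readxl is installed) with columns
#'   `pending_id`, `reference_id` (paired mode) or `member_id`, `role`
#'   (sub-database mode).
#' @return Tibble of the assignment.
#' @export
read_assignment <- function(file) {
  tbl <- read_table_any(file)
  if (all(c("pending_id", "reference_id") %in% names(tbl)) ||
      all(c("member_id", "role") %in% names(tbl))) {
    return(tbl)
  }
  stop("assignment needs columns pending_id/reference_id or member_id/role")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a
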