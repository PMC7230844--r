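#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a peer-merge outcome
#'
#' @param x An `ssr_merge`.
#' @param ... Unused.
#' @return One row per locus: genotype, support, flag, candidates, note.
#' @export
tidy.ssr_merge <- function(x, ...) {
  dplyr::left_join(x$genotypes, x$loci, by = "marker_id")
}

#' One-row summary of a peer-merge outcome
#'
#' @param x An `ssr_merge`.
#' @param ... Unused.
#' @return Tibble with replicate count, effective/flagged locus counts,
#'   minimum support, offset and threshold used.
#' @export
glance.ssr_merge <- function(x, ...) {
  tibble::tibble(
    n_fingerprints = length(x$entities),
    n_loci = nrow(x$loci),
    effective_loci = sum(!is.na(x$genotypes$allele_low)),
    flagged_loci = sum(x$loci$flag == "AUDIT_REQUIRED"),
    min_support = min(x$loci$support),
    offset = x$offset,
    threshold = x$threshold
  )
}

#' Tidy a cross-layer merge
#'
#' @param x An `ssr_variety_merge`.
#' @param ... Unused.
#' @return The audit tibble (non-OK loci with their layer of origin).
#' @export
tidy.ssr_variety_merge <- function(x, ...) x$audit

#' One-row summary of a cross-layer merge
#'
#' @param x An `ssr_variety_merge`.
#' @param ... Unused.
#' @export
glance.ssr_variety_merge <- function(x, ...) {
  tibble::tibble(
    variety_id = x$fingerprint$entity_id[1],
    n_loci = nrow(x$fingerprint),
    effective_loci = sum(!is.na(x$fingerprint$allele_low)),
    audit_flags = nrow(x$audit),
    n_experiments = length(x$provenance)
  )
}

#' Tidy a comparison result set
#'
#' @param x An `ssr_comparison`.
#' @param ... Unused.
#' @return The underlying tibble (already one row per pair).
#' @export
tidy.ssr_comparison <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a comparison result set
#'
#' @param x An `ssr_comparison`.
#' @param ... Unused.
#' @export
glance.ssr_comparison <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_retained = sum(x$verdict == "retained"),
    min_x = min(x$x), median_x = stats::median(x$x), max_x = max(x$x)
  )
}

#' Tidy a noise-tolerance scan
#'
#' @param x An `ssr_qc_scan`.
#' @param ... Unused.
#' @return The scan grid, one row per (replicate count, fraction).
#' @export
tidy.ssr_qc_scan <- function(x, ...) x$grid

#' One-row summary of a noise-tolerance scan
#'
#' @param x An `ssr_qc_scan`.
#' @param ... Unused.
#' @export
glance.ssr_qc_scan <- function(x, ...) {
  tibble::tibble(
    threshold_pct = x$threshold_pct,
    n_configurations = nrow(x$grid),
    n_degraded = sum(x$grid$degraded)
  )
}
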