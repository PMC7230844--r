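#' Reference-sample check of a genotyping run
#'
#' Standard samples with known fingerprints are run alongside the test
#' samples; any differential locus between an in-run reference and its stored
#' standard (at the default offset) signals an overall error in the detection
#' experiment, and the whole run is flagged suspect.
#'
#' @param run_fps Fingerprint tibble of the in-run reference samples (entity
#'   ids matching the standards).
#' @param standards Fingerprint tibble of stored standard fingerprints.
#' @param params [comparison_params()].
#' @return List of class `ssr_reference_check`: `$details` (tibble
#'   `reference_id`, `p`, `D`, `M`, `pass`), `$run_flagged` (TRUE if any
#'   reference shows D > 0).
#' @export
reference_check <- function(run_fps, standards, params = comparison_params()) {
  ref_ids <- unique(run_fps$entity_id)
  absent <- setdiff(ref_ids, unique(standards$entity_id))
  if (length(absent) > 0) {
    stop("no stored standard for reference(s): ", paste(absent, collapse = ", "))
  }
  details <- purrr::map_dfr(sort(ref_ids), function(id) {
    r <- compare_pair(run_fps[run_fps$entity_id == id, ],
                      standards[standards$entity_id == id, ], params)
    tibble::tibble(reference_id = id, p = r$p, D = r$D, M = r$M, pass = r$D == 0)
  })
  structure(list(details = details, run_flagged = any(!details$pass)),
            class = "ssr_reference_check")
}

#' @export
print.ssr_reference_check <- function(x, ...) {
  cat("Reference-sample check:",
      if (x$run_flagged) "RUN FLAGGED" else "pass", "\n")
  print(x$details)
  invisible(x)
}

#' Replicate-audit consistency report
#'
#' Runs the peer merge over each sample's repeated experiments (three repeats
#' are the canonical design) and reports per-sample consistency: the number
#' of effective loci in the merged fingerprint, and the flagged and missing
#' locus counts. Fully consistent replicate sets yield zero flags; a single
#' noise set among three consistent repeats (33% < 40% noise) still merges
#' cleanly.
#'
#' @param replicates Fingerprint tibble with a `sample_id` column grouping the
#'   replicate `entity_id`s.
#' @param offset,effective_threshold Merge parameters (see [peer_merge()]).
#' @return Tibble of class `ssr_replicate_audit`: `sample_id`, `n_replicates`,
#'   `effective_loci`, `flagged_loci`, `missing_loci`, `consistent`.
#' @export
replicate_audit <- function(replicates, offset = 2, effective_threshold = 0.6) {
  stopifnot("sample_id" %in% names(replicates))
  out <- purrr::map_dfr(unique(replicates$sample_id), function(sid) {
    fps <- replicates[replicates$sample_id == sid,
                      c("entity_id", "marker_id", "allele_low", "allele_high")]
    n_rep <- length(unique(fps$entity_id))
    if (n_rep < 2) {
      warning("sample ", sid, " has a single replicate; trivially consistent")
    }
    m <- peer_merge(fps, offset = offset, effective_threshold = effective_threshold)
    tibble::tibble(
      sample_id = sid, n_replicates = n_rep,
      effective_loci = sum(!is.na(m$genotypes$allele_low)),
      flagged_loci = sum(m$loci$flag == "AUDIT_REQUIRED"),
      missing_loci = sum(is.na(m$genotypes$allele_low)),
      consistent = all(m$loci$flag == "OK")
    )
  })
  class(out) <- c("ssr_replicate_audit", class(out))
  out
}

#' Noise-tolerance scan of the replicate audit
#'
#' Determines empirically up to which noise proportion the automated
#' replicate audit preserves the full effective-locus count. For every odd
#' replicate count and requested noise fraction, a synthetic replicate set is
#' built (clean truth copies plus `round(fraction * count)` noise replicates),
#' merged, and checked for lost effective loci. The reported threshold is the
#' largest percentage strictly below which no configuration degrades — the
#' maximum boundary for effective data.
#'
#' @param replicate_counts Odd replicate counts to scan (default 3, 5, 7).
#' @param noise_fractions Noise proportions to scan (default 0.2, 1/3, 0.4,
#'   3/7, 0.6); each is realised as `round(fraction * count)` noise replicates
#'   and recorded at its realised proportion.
#' @param p Panel size for the synthetic truth (default 20 loci).
#' @param seed Integer seed.
#' @param offset,effective_threshold Merge parameters.
#' @return List of class `ssr_qc_scan`: `$threshold_pct` (percentage),
#'   `$grid` (tibble `replicate_count`, `requested_fraction`,
#'   `realised_fraction`, `n_noise`, `effective_loci`, `degraded`).
#' @export
noise_tolerance_scan <- function(replicate_counts = c(3L, 5L, 7L),
                                 noise_fractions = c(0.2, 1 / 3, 0.4, 3 / 7, 0.6),
                                 p = 20L, seed = 1L, offset = 2,
                                 effective_threshold = 0.6) {
  if (any(replicate_counts %% 2 == 0)) {
    stop("the scan is defined for odd replicate counts only")
  }
  if (any(noise_fractions <= 0 | noise_fractions >= 1)) {
    stop("noise fractions must lie strictly between 0 and 1")
  }
  grid <- tidyr::expand_grid(replicate_count = as.integer(replicate_counts),
                             requested_fraction = noise_fractions)
  rows <- purrr::pmap_dfr(grid, function(replicate_count, requested_fraction) {
    cfg <- sim_config(p = p, i = replicate_count,
                      noise_fraction = requested_fraction,
                      dropout = 0, err_1bp = 0, err_2bp = 0,
                      seed = seed + replicate_count)
    truth <- generate_truth(cfg)
    leaves <- generate_replicates(truth, cfg)
    res <- cross_layer_merge(leaves, offset = offset,
                             effective_threshold = effective_threshold)
    eff <- sum(!is.na(res$fingerprint$allele_low))
    n_noise <- as.integer(round(requested_fraction * replicate_count))
    tibble::tibble(
      replicate_count = replicate_count,
      requested_fraction = requested_fraction,
      realised_fraction = n_noise / replicate_count,
      n_noise = n_noise,
      effective_loci = eff,
      degraded = eff < p
    )
  })
  degraded_fracs <- rows$realised_fraction[rows$degraded]
  if (length(degraded_fracs) == 0) {
    stop("no configuration degraded; widen the scanned fractions")
  }
  threshold <- min(degraded_fracs)
  below <- rows$realised_fraction < threshold - 1e-12
  if (any(rows$degraded[below])) {
    stop("inconsistent scan: degradation below the boundary")
  }
  structure(list(threshold_pct = 100 * threshold, grid = rows),
            class = "ssr_qc_scan")
}

#' @export
print.ssr_qc_scan <- function(x, ...) {
  cat("Noise-tolerance scan: effective data preserved strictly below ",
      format(x$threshold_pct), "% noise\n", sep = "")
  print(x$grid)
  invisible(x)
}

#' Write a QC report as JSON or text
#'
#' @param x An `ssr_reference_check`, `ssr_replicate_audit` or `ssr_qc_scan`.
#' @param file Output path; `.json` selects JSON, anything else a
#'   human-readable text rendering.
#' @return `file`, invisibly.
#' @export
write_qc_report <- function(x, file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    payload <- if (inherits(x, "ssr_reference_check")) {
      list(kind = "reference_check", run_flagged = x$run_flagged,
           details = x$details)
    } else if (inherits(x, "ssr_qc_scan")) {
      list(kind = "noise_tolerance_scan", threshold_pct = x$threshold_pct,
           grid = x$grid)
    } else {
      list(kind = "replicate_audit", details = tibble::as_tibble(x))
    }
    jsonlite::write_json(payload, file, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    writeLines(utils::capture.output(print(x)), file)
  }
  invisible(file)
}
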