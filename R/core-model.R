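#' Define an SSR marker panel
#'
#' A panel is the fixed set of SSR markers over which every fingerprint in a
#' database is scored. Each marker has an expected allele-size window (in bp)
#' and a repeat-unit length; allele calls outside the window are flagged by
#' [validate_fingerprints()], and the repeat unit defines the allele grid used
#' for frequency tables and the synthetic generator.
#'
#' @param markers Data frame with columns `marker_id`, `size_min`, `size_max`
#'   and optionally `panel_id` (default `"P1"`) and `repeat_unit` (default 2,
#'   the dinucleotide motif typical of high-polymorphism SSR panels).
#' @return A tibble of class `ssr_panel` with columns `marker_id`, `panel_id`,
#'   `repeat_unit`, `size_min`, `size_max`.
#' @examples
#' ssr_panel(data.frame(marker_id = c("M1", "M2"), size_min = 100, size_max = 140))
#' @export
ssr_panel <- function(markers) {
  stopifnot(is.data.frame(markers))
  need <- c("marker_id", "size_min", "size_max")
  miss <- setdiff(need, names(markers))
  if (length(miss) > 0) {
    stop("panel is missing required columns: ", paste(miss, collapse = ", "))
  }
  pan <- tibble::as_tibble(markers)
  if (!"panel_id" %in% names(pan)) pan$panel_id <- "P1"
  if (!"repeat_unit" %in% names(pan)) pan$repeat_unit <- 2L
  pan <- dplyr::select(
    pan, "marker_id", "panel_id", "repeat_unit", "size_min", "size_max"
  )
  pan$marker_id <- as.character(pan$marker_id)
  pan$repeat_unit <- as.integer(pan$repeat_unit)
  if (anyDuplicated(pan$marker_id)) {
    stop("marker_id values must be unique within the panel set")
  }
  if (any(pan$repeat_unit < 1L)) stop("repeat_unit must be >= 1")
  if (any(!(pan$size_min < pan$size_max))) stop("size_min must be < size_max")
  class(pan) <- c("ssr_panel", class(pan))
  pan
}

#' Construct a single diploid locus genotype
#'
#' A locus call is either EFFECTIVE (two allele sizes, stored low/high so that
#' heterozygote order never matters) or MISSING (no sizes). Exactly one size is
#' rejected: a half-called locus does not meet the two-effective-allele
#' definition and must be imported either as missing or, under an explicit
#' importer flag, duplicated to a homozygote.
#'
#' @param marker_id Marker identifier.
#' @param alleles Numeric vector of length 0 (missing) or 2 (sizes in bp,
#'   0.1 bp resolution).
#' @return One-row tibble with columns `marker_id`, `allele_low`,
#'   `allele_high`, `status` (`"EFFECTIVE"` or `"MISSING"`).
#' @examples
#' make_genotype("M1", c(102, 100))  # normalised to [100, 102]
#' make_genotype("M1", numeric(0))   # MISSING
#' @export
make_genotype <- function(marker_id, alleles = numeric(0)) {
  stopifnot(length(marker_id) == 1)
  alleles <- as.numeric(alleles)
  if (length(alleles) == 1) {
    stop("a diploid locus needs zero or two allele sizes, got one (half call)")
  }
  if (length(alleles) > 2) {
    stop("a diploid locus needs zero or two allele sizes, got ", length(alleles))
  }
  if (length(alleles) == 2) {
    if (any(is.na(alleles))) stop("allele sizes must not be NA; omit both for a missing locus")
    if (any(alleles <= 0)) stop("allele sizes must be positive")
    alleles <- sort(alleles)
    tibble::tibble(
      marker_id = as.character(marker_id),
      allele_low = alleles[1], allele_high = alleles[2],
      status = "EFFECTIVE"
    )
  } else {
    tibble::tibble(
      marker_id = as.character(marker_id),
      allele_low = NA_real_, allele_high = NA_real_,
      status = "MISSING"
    )
  }
}

#' Assemble a fingerprint table for one entity
#'
#' Fingerprints are stored long: one row per panel marker with columns
#' `entity_id`, `marker_id`, `allele_low`, `allele_high` (both `NA` for a
#' missing locus). Markers of the panel not present in `genotypes` are filled
#' as missing so that every fingerprint covers the full panel.
#'
#' @param entity_id Identifier of the sample/experiment/variety.
#' @param genotypes Data frame with columns `marker_id`, `allele_low`,
#'   `allele_high` (built e.g. by row-binding [make_genotype()] results).
#' @param panel An [ssr_panel()]; defines the marker universe.
#' @param layer Optional hierarchy layer tag (`"EXPERIMENT"`, `"DNA"`,
#'   `"EXPERIMENTER"`, `"SAMPLE"`, `"VARIETY"`).
#' @return Fingerprint tibble covering all panel markers.
#' @export
fingerprint <- function(entity_id, genotypes, panel, layer = "EXPERIMENT") {
  stopifnot(length(entity_id) == 1, is.data.frame(genotypes))
  layer <- match.arg(layer, c("EXPERIMENT", "DNA", "EXPERIMENTER", "SAMPLE", "VARIETY"))
  g <- tibble::as_tibble(genotypes)
  if (nrow(g) == 0) {
    g <- tibble::tibble(marker_id = character(), allele_low = numeric(),
                        allele_high = numeric())
  }
  unknown <- setdiff(g$marker_id, panel$marker_id)
  if (length(unknown) > 0) {
    stop("genotypes reference markers outside the panel: ", paste(unknown, collapse = ", "))
  }
  bad <- !is.na(g$allele_low) & !is.na(g$allele_high) & g$allele_low > g$allele_high
  if (any(bad)) {
    lo <- g$allele_low[bad]
    g$allele_low[bad] <- g$allele_high[bad]
    g$allele_high[bad] <- lo
  }
  out <- dplyr::left_join(
    tibble::tibble(entity_id = as.character(entity_id), marker_id = panel$marker_id),
    dplyr::select(g, "marker_id", "allele_low", "allele_high"),
    by = "marker_id"
  )
  out$layer <- layer
  out
}

#' Validate fingerprints against a panel
#'
#' Checks that every fingerprint keys all panel markers exactly once, that
#' allele pairs are complete (no half calls) and ordered, and that effective
#' allele sizes lie within each marker's expected \[size_min, size_max\] range.
#' Violations are returned as data, not raised as errors, so that an import
#' can report all problems at once.
#'
#' @param fps Fingerprint tibble (columns `entity_id`, `marker_id`,
#'   `allele_low`, `allele_high`).
#' @param panel An [ssr_panel()].
#' @return Tibble of violations with columns `entity_id`, `marker_id`,
#'   `violation`; zero rows when everything is valid.
#' @export
validate_fingerprints <- function(fps, panel) {
  stopifnot(is.data.frame(fps), nrow(panel) > 0)
  fps <- tibble::as_tibble(fps)
  v <- list()
  for (eid in unique(fps$entity_id)) {
    f <- fps[fps$entity_id == eid, ]
    absent <- setdiff(panel$marker_id, f$marker_id)
    if (length(absent) > 0) {
      v[[length(v) + 1]] <- tibble::tibble(
        entity_id = eid, marker_id = absent, violation = "marker absent from fingerprint"
      )
    }
    dup <- unique(f$marker_id[duplicated(f$marker_id)])
    if (length(dup) > 0) {
      v[[length(v) + 1]] <- tibble::tibble(
        entity_id = eid, marker_id = dup, violation = "marker keyed more than once"
      )
    }
    unknown <- setdiff(f$marker_id, panel$marker_id)
    if (length(unknown) > 0) {
      v[[length(v) + 1]] <- tibble::tibble(
        entity_id = eid, marker_id = unknown, violation = "marker not in panel"
      )
    }
    half <- f$marker_id[xor(is.na(f$allele_low), is.na(f$allele_high))]
    if (length(half) > 0) {
      v[[length(v) + 1]] <- tibble::tibble(
        entity_id = eid, marker_id = half, violation = "half call (one allele of two)"
      )
    }
    disord <- f$marker_id[!is.na(f$allele_low) & !is.na(f$allele_high) &
                            f$allele_low > f$allele_high]
    if (length(disord) > 0) {
      v[[length(v) + 1]] <- tibble::tibble(
        entity_id = eid, marker_id = disord, violation = "allele pair not ordered low <= high"
      )
    }
    fe <- dplyr::inner_join(f[!is.na(f$allele_low) & !is.na(f$allele_high), ],
                            panel, by = "marker_id")
    oor <- fe$marker_id[fe$allele_low < fe$size_min | fe$allele_high > fe$size_max]
    if (length(oor) > 0) {
      v[[length(v) + 1]] <- tibble::tibble(
        entity_id = eid, marker_id = oor, violation = "allele size outside expected range"
      )
    }
  }
  if (length(v) == 0) {
    tibble::tibble(entity_id = character(), marker_id = character(), violation = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Comparison parameters
#'
#' The four tunables of the fingerprint comparison algorithm, with the
#' standard defaults: a base offset of 2 bp (the tolerance absorbing the
#' 1--2 bp capillary-electrophoresis sizing error of dinucleotide SSRs), a
#' floor of 20 shared non-missing loci per reported pair, a ceiling of 20
#' differential loci, and a ceiling of 0.05 on the differential-locus
#' fraction x = D/p.
#'
#' @param base_offset_bp Maximum allele-size difference (bp) still counted as
#'   the same allele; must lie in \[0, 2\].
#' @param min_comparison_loci Minimum number of loci effective on both sides
#'   (p - M) for a comparison to be reported; >= 0.
#' @param max_diff_loci Maximum differential-locus count D retained; >= 0.
#' @param max_diff_fraction Maximum differential fraction x retained; in \[0, 1\].
#' @return List of class `comparison_params`.
#' @examples
#' comparison_params()
#' @export
comparison_params <- function(base_offset_bp = 2, min_comparison_loci = 20L,
                              max_diff_loci = 20L, max_diff_fraction = 0.05) {
  if (!is.numeric(base_offset_bp) || length(base_offset_bp) != 1 ||
      base_offset_bp < 0 || base_offset_bp > 2) {
    stop("base_offset_bp must be a single value in [0, 2] bp")
  }
  if (min_comparison_loci < 0) stop("min_comparison_loci must be >= 0")
  if (max_diff_loci < 0) stop("max_diff_loci must be >= 0")
  if (max_diff_fraction < 0 || max_diff_fraction > 1) {
    stop("max_diff_fraction must be in [0, 1]")
  }
  structure(
    list(
      base_offset_bp = as.numeric(base_offset_bp),
      min_comparison_loci = as.integer(min_comparison_loci),
      max_diff_loci = as.integer(max_diff_loci),
      max_diff_fraction = as.numeric(max_diff_fraction)
    ),
    class = "comparison_params"
  )
}

#' @export
print.comparison_params <- function(x, ...) {
  cat("SSR fingerprint comparison parameters\n")
  cat("  base offset:          ", x$base_offset_bp, "bp\n")
  cat("  min comparison loci:  ", x$min_comparison_loci, "\n")
  cat("  max differential loci:", x$max_diff_loci, "\n")
  cat("  max differential frac:", x$max_diff_fraction, "\n")
  invisible(x)
}

# Constructor enforcing the locus-count conservation p = D + S + M and x = D/p.
# Used by compare_pair(); exported so reports can be rebuilt from raw counts.

#' Construct a pairwise comparison result
#'
#' @param id_pending,id_reference Entity ids of the compared fingerprints.
#' @param p Total panel loci. @param D Different loci. @param S Non-different
#'   (same) loci. @param M Missing loci (pairs with fewer than two effective
#'   sides).
#' @return One-row tibble with the counts and the differential fraction
#'   `x = D/p`. Fails unless `p == D + S + M`.
#' @export
comparison_result <- function(id_pending, id_reference, p, D, S, M) {
  if (p != D + S + M) {
    stop("locus counts do not conserve: p must equal D + S + M")
  }
  if (min(p, D, S, M) < 0 || p == 0) stop("counts must be non-negative and p > 0")
  tibble::tibble(
    id_pending = as.character(id_pending),
    id_reference = as.character(id_reference),
    p = as.integer(p), D = as.integer(D), S = as.integer(S), M = as.integer(M),
    x = D / p
  )
}
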