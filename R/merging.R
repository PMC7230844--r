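#' Assign hierarchical merge weights to experiment-layer leaves
#'
#' Replicate genotyping runs form a tree: variety -> samples (m) ->
#' experimenters (k) -> DNA extractions (j) -> experiments (i). Every
#' experiment-layer leaf receives weight 1/(i x j x k x m), computed with the
#' branch counts on its own path, so the leaves under any internal node sum to
#' that node's weight (1/(j k m) for a DNA node, 1/(k m) for an experimenter,
#' 1/m for a sample) and the whole tree sums to 1. The accumulated weights
#' localise which stage (instrument run, extraction, analyst, sampling batch)
#' contributed an error.
#'
#' @param leaves Tibble with hierarchy columns `variety_id`, `sample_id`,
#'   `experimenter_id`, `dna_id`, `experiment_id` and genotype columns
#'   `marker_id`, `allele_low`, `allele_high` (one row per leaf x marker).
#' @return `leaves` with a `weight` column added (constant across the marker
#'   rows of one leaf).
#' @export
assign_weights <- function(leaves) {
  need <- c("variety_id", "sample_id", "experimenter_id", "dna_id", "experiment_id")
  miss <- setdiff(need, names(leaves))
  if (length(miss) > 0) stop("leaf table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(leaves) == 0) stop("leaf table is empty")
  leaves |>
    dplyr::group_by(.data$variety_id) |>
    dplyr::mutate(m = dplyr::n_distinct(.data$sample_id)) |>
    dplyr::group_by(.data$variety_id, .data$sample_id) |>
    dplyr::mutate(k = dplyr::n_distinct(.data$experimenter_id)) |>
    dplyr::group_by(.data$variety_id, .data$sample_id, .data$experimenter_id) |>
    dplyr::mutate(j = dplyr::n_distinct(.data$dna_id)) |>
    dplyr::group_by(.data$variety_id, .data$sample_id, .data$experimenter_id, .data$dna_id) |>
    dplyr::mutate(i = dplyr::n_distinct(.data$experiment_id)) |>
    dplyr::ungroup() |>
    dplyr::mutate(weight = 1 / (.data$i * .data$j * .data$k * .data$m)) |>
    dplyr::select(-"i", -"j", -"k", -"m")
}

#' Summed leaf weights of every internal node
#'
#' @param leaves Weighted leaf table from [assign_weights()].
#' @return Tibble with `level` (`"DNA"`, `"EXPERIMENTER"`, `"SAMPLE"`,
#'   `"VARIETY"`), `node_id`, `weight` (sum of leaf weights under the node).
#' @export
node_weights <- function(leaves) {
  if (!"weight" %in% names(leaves)) leaves <- assign_weights(leaves)
  one <- dplyr::distinct(
    leaves, .data$variety_id, .data$sample_id, .data$experimenter_id,
    .data$dna_id, .data$experiment_id, .data$weight
  )
  lev <- function(df, cols, level) {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(cols))) |>
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop") |>
      dplyr::mutate(level = level,
                    node_id = do.call(paste, c(dplyr::pick(dplyr::all_of(cols)), sep = "/"))) |>
      dplyr::select("level", "node_id", "weight")
  }
  dplyr::bind_rows(
    lev(one, c("variety_id", "sample_id", "experimenter_id", "dna_id"), "DNA"),
    lev(one, c("variety_id", "sample_id", "experimenter_id"), "EXPERIMENTER"),
    lev(one, c("variety_id", "sample_id"), "SAMPLE"),
    lev(one, "variety_id", "VARIETY")
  )
}

# Merge one locus: greedy offset-tolerant clustering + weighted majority.
# Returns list(allele_low, allele_high, support, flag, candidates).
merge_locus <- function(a_low, a_high, weight, offset, threshold) {
  total_w <- sum(weight)
  eff <- which(!is.na(a_low) & !is.na(a_high))
  if (length(eff) == 0) {
    return(list(allele_low = NA_real_, allele_high = NA_real_, support = 0,
                flag = "DROPPED_TO_MISSING", candidates = ""))
  }
  lo <- a_low[eff]; hi <- a_high[eff]; w <- weight[eff]
  # greedy clusters in input order; a genotype joins the first cluster whose
  # founding genotype it gca-matches at the given offset
  founders_lo <- numeric(0); founders_hi <- numeric(0)
  assignment <- integer(length(eff))
  for (t in seq_along(eff)) {
    hit <- 0L
    if (length(founders_lo) > 0) {
      same <- gca_vec(lo[t], hi[t], founders_lo, founders_hi, offset) == 0L
      if (any(same)) hit <- which(same)[1]
    }
    if (hit == 0L) {
      founders_lo <- c(founders_lo, lo[t]); founders_hi <- c(founders_hi, hi[t])
      hit <- length(founders_lo)
    }
    assignment[t] <- hit
  }
  cl_w <- vapply(seq_along(founders_lo),
                 function(cl) sum(w[assignment == cl]), numeric(1))
  candidates <- paste(sprintf("%g/%g", founders_lo, founders_hi), collapse = ";")
  top <- max(cl_w)
  winners <- which(cl_w >= top - 1e-9)
  support <- top / total_w
  if (length(winners) > 1) {
    return(list(allele_low = NA_real_, allele_high = NA_real_, support = support,
                flag = "AUDIT_REQUIRED", candidates = candidates))
  }
  members <- which(assignment == winners)
  key <- paste(lo[members], hi[members])
  kw <- tapply(w[members], key, sum)
  best <- names(kw)[kw >= max(kw) - 1e-9]
  if (length(best) > 1) {
    parts <- do.call(rbind, lapply(strsplit(best, " "), as.numeric))
    best <- best[order(parts[, 1], parts[, 2])][1]
  }
  rep_g <- as.numeric(strsplit(best, " ")[[1]])
  if (support - threshold > 1e-9) {  # strict >, robust to 1/r rounding
    list(allele_low = rep_g[1], allele_high = rep_g[2], support = support,
         flag = "OK", candidates = candidates)
  } else {
    list(allele_low = NA_real_, allele_high = NA_real_, support = support,
         flag = "AUDIT_REQUIRED", candidates = candidates)
  }
}

#' Merge fingerprints within one hierarchy layer
#'
#' Locus-by-locus consensus of replicate fingerprints at the same layer.
#' Missing inputs are excluded from voting but stay in the support
#' denominator, so heavy dropout forces an audit. Effective genotypes are
#' clustered by offset-tolerant identity ([gca()]); the cluster with the
#' greatest summed weight wins and its exact modal genotype is retained.
#' The winning support fraction must strictly exceed `effective_threshold`
#' (default 0.6, the complement of the 40% noise boundary): at or below it —
#' including ties — the locus is flagged `AUDIT_REQUIRED` and set missing
#' pending [manual_reselect()]. A locus with no effective input at all is
#' `DROPPED_TO_MISSING`.
#'
#' @param fps Fingerprint tibble with >= 1 distinct `entity_id`, all on one
#'   shared panel.
#' @param offset Allele-size offset in bp (default 2).
#' @param effective_threshold Minimum exclusive winning support (default 0.6).
#' @param weights Optional named numeric vector (entity_id -> weight). Must be
#'   equal across entities within the layer; defaults to 1/n each.
#' @return An `ssr_merge` object: `$genotypes` (merged fingerprint tibble),
#'   `$loci` (per-marker `support`, `flag`, `candidates`, `note`),
#'   `$entities`, `$offset`, `$threshold`.
#' @export
peer_merge <- function(fps, offset = 2, effective_threshold = 0.6, weights = NULL) {
  ids <- unique(fps$entity_id)
  if (length(ids) == 0) stop("peer_merge() needs at least one fingerprint")
  panel_ids <- sort(unique(fps$marker_id))
  by_ent <- split(fps$marker_id, fps$entity_id)
  if (!all(vapply(by_ent, function(m) identical(sort(m), panel_ids), logical(1)))) {
    stop("all fingerprints must share one marker panel")
  }
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1 / length(ids), length(ids)), ids)
  }
  w <- weights[ids]
  if (anyNA(w)) stop("weights must be named by entity_id and cover all entities")
  if (diff(range(w)) > 1e-9) {
    stop("peer merging requires equal weights within a layer")
  }

  fps <- fps[order(match(fps$marker_id, panel_ids), match(fps$entity_id, ids)), ]
  loci <- purrr::map_dfr(panel_ids, function(mk) {
    rows <- fps[fps$marker_id == mk, ]
    rows <- rows[match(ids, rows$entity_id), ]
    r <- merge_locus(rows$allele_low, rows$allele_high, unname(w), offset,
                     effective_threshold)
    tibble::tibble(marker_id = mk, allele_low = r$allele_low,
                   allele_high = r$allele_high, support = r$support,
                   flag = r$flag, candidates = r$candidates, note = "")
  })
  structure(
    list(
      genotypes = dplyr::select(loci, "marker_id", "allele_low", "allele_high"),
      loci = dplyr::select(loci, "marker_id", "support", "flag", "candidates", "note"),
      entities = ids, offset = offset, threshold = effective_threshold
    ),
    class = "ssr_merge"
  )
}

#' @export
print.ssr_merge <- function(x, ...) {
  n_ok <- sum(x$loci$flag == "OK")
  cat("Peer fingerprint merge of", length(x$entities), "fingerprint(s):",
      n_ok, "of", nrow(x$loci), "loci OK\n")
  bad <- x$loci[x$loci$flag != "OK", ]
  if (nrow(bad) > 0) {
    cat("Flagged loci:\n")
    print(tibble::as_tibble(bad))
  }
  invisible(x)
}

#' Resolve an audited locus by manual genotype reselection
#'
#' Mirrors the manual verification path of the audit workflow: a locus the
#' automatic merge could not decide (tie, or support at/below the threshold)
#' is resolved by an operator choosing one of the observed cluster
#' representatives, or overriding with an unobserved genotype under `force`.
#'
#' @param outcome An `ssr_merge`.
#' @param marker_id Locus to resolve; must be flagged `AUDIT_REQUIRED` unless
#'   `force = TRUE`.
#' @param genotype Numeric length-2 allele pair. Must be one of the observed
#'   cluster representatives unless `force = TRUE` (then noted `"override"`).
#' @param force Allow overriding an OK locus or an unobserved genotype.
#' @return The updated `ssr_merge` with the locus set and flagged `OK`.
#' @export
manual_reselect <- function(outcome, marker_id, genotype, force = FALSE) {
  stopifnot(inherits(outcome, "ssr_merge"))
  i <- match(marker_id, outcome$loci$marker_id)
  if (is.na(i)) stop("unknown marker: ", marker_id)
  if (outcome$loci$flag[i] == "OK" && !force) {
    stop("locus ", marker_id, " is not flagged for audit; use force = TRUE to override")
  }
  genotype <- sort(as.numeric(genotype))
  stopifnot(length(genotype) == 2)
  cand <- strsplit(outcome$loci$candidates[i], ";")[[1]]
  observed <- sprintf("%g/%g", genotype[1], genotype[2]) %in% cand
  if (!observed && !force) {
    stop("genotype not among observed candidates at ", marker_id,
         "; use force = TRUE for an explicit override")
  }
  gi <- match(marker_id, outcome$genotypes$marker_id)
  outcome$genotypes$allele_low[gi] <- genotype[1]
  outcome$genotypes$allele_high[gi] <- genotype[2]
  outcome$loci$flag[i] <- "OK"
  outcome$loci$note[i] <- if (observed) "manual" else "override"
  outcome
}

#' Cross-layer merge up to the variety fingerprint
#'
#' Staged consensus along experiment -> DNA -> experimenter -> sample ->
#' variety: peer merging is applied at the experiment layer within each DNA
#' node, then across DNA nodes per experimenter, across experimenters per
#' sample, and across samples to yield the variety's standard fingerprint.
#' A locus flagged at any stage enters the next stage as missing, so the audit
#' report traces every unresolved locus to the layer where agreement broke
#' down.
#'
#' @param leaves Leaf table as for [assign_weights()]; weights are assigned if
#'   absent. Must contain exactly one `variety_id`.
#' @param offset Allele-size offset in bp.
#' @param effective_threshold Support threshold (default 0.6).
#' @return List of class `ssr_variety_merge`: `$fingerprint` (VARIETY-layer
#'   fingerprint tibble), `$audit` (tibble `marker_id`, `layer`, `node_id`,
#'   `flag`, `support`, `candidates` of all non-OK loci), `$provenance`
#'   (contributing experiment ids), `$outcome` (final-stage `ssr_merge`).
#' @export
cross_layer_merge <- function(leaves, offset = 2, effective_threshold = 0.6) {
  if (!"weight" %in% names(leaves)) leaves <- assign_weights(leaves)
  vids <- unique(leaves$variety_id)
  if (length(vids) != 1) stop("cross_layer_merge() merges one variety at a time")
  audit <- list()
  note_flags <- function(m, layer, node_id) {
    bad <- m$loci[m$loci$flag != "OK", ]
    if (nrow(bad) > 0) {
      audit[[length(audit) + 1]] <<- tibble::tibble(
        marker_id = bad$marker_id, layer = layer, node_id = node_id,
        flag = bad$flag, support = bad$support, candidates = bad$candidates
      )
    }
  }
  merge_children <- function(df, child_col, layer, node_id) {
    fps <- dplyr::select(df, entity_id = dplyr::all_of(child_col),
                         "marker_id", "allele_low", "allele_high")
    if (any(duplicated(fps[c("entity_id", "marker_id")]))) {
      stop("duplicate genotype rows under node ", node_id)
    }
    m <- peer_merge(fps, offset = offset, effective_threshold = effective_threshold)
    note_flags(m, layer, node_id)
    m$genotypes
  }

  dna_fp <- leaves |>
    dplyr::group_by(.data$variety_id, .data$sample_id, .data$experimenter_id, .data$dna_id) |>
    dplyr::group_modify(~ merge_children(
      .x, "experiment_id", "EXPERIMENT",
      paste(.y$sample_id, .y$experimenter_id, .y$dna_id, sep = "/"))) |>
    dplyr::ungroup()
  exp_fp <- dna_fp |>
    dplyr::group_by(.data$variety_id, .data$sample_id, .data$experimenter_id) |>
    dplyr::group_modify(~ merge_children(
      .x, "dna_id", "DNA", paste(.y$sample_id, .y$experimenter_id, sep = "/"))) |>
    dplyr::ungroup()
  sample_fp <- exp_fp |>
    dplyr::group_by(.data$variety_id, .data$sample_id) |>
    dplyr::group_modify(~ merge_children(
      .x, "experimenter_id", "EXPERIMENTER", .y$sample_id)) |>
    dplyr::ungroup()
  final <- peer_merge(
    dplyr::select(sample_fp, entity_id = "sample_id",
                  "marker_id", "allele_low", "allele_high"),
    offset = offset, effective_threshold = effective_threshold
  )
  note_flags(final, "SAMPLE", vids)

  fp <- final$genotypes
  fp <- tibble::tibble(entity_id = vids, fp, layer = "VARIETY")
  audit_tbl <- if (length(audit) > 0) dplyr::bind_rows(audit) else
    tibble::tibble(marker_id = character(), layer = character(),
                   node_id = character(), flag = character(),
                   support = numeric(), candidates = character())
  structure(
    list(fingerprint = fp, audit = audit_tbl,
         provenance = unique(leaves$experiment_id), outcome = final),
    class = "ssr_variety_merge"
  )
}

#' @export
print.ssr_variety_merge <- function(x, ...) {
  cat("Variety fingerprint for", x$fingerprint$entity_id[1], "—",
      sum(!is.na(x$fingerprint$allele_low)), "of", nrow(x$fingerprint),
      "loci effective;", nrow(x$audit), "audit flag(s)\n")
  invisible(x)
}

#' Write a merge audit report
#'
#' @param audit Audit tibble from [cross_layer_merge()] (or `$loci` of an
#'   `ssr_merge`).
#' @param file Output path; `.json` selects JSON, else CSV.
#' @return `file`, invisibly.
#' @export
write_audit_report <- function(audit, file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(audit, file, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(audit, file)
  }
  invisible(file)
}
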