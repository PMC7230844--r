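#' Snap allele sizes to a marker's repeat-unit grid
#'
#' Frequency tables and allele-sharing measures need discrete allele
#' identities, but capillary-electrophoresis sizes carry 1--2 bp read error.
#' Each size is rounded to the nearest point of the grid
#' `size_min + repeat_unit * {0, 1, 2, ...}` of its marker.
#'
#' @param fps Fingerprint tibble.
#' @param panel An [ssr_panel()].
#' @return `fps` with snapped `allele_low`/`allele_high`.
#' @export
snap_to_grid <- function(fps, panel) {
  j <- dplyr::left_join(fps, panel[c("marker_id", "repeat_unit", "size_min")],
                        by = "marker_id")
  snap <- function(x) j$size_min + j$repeat_unit * round((x - j$size_min) / j$repeat_unit)
  fps$allele_low <- snap(j$allele_low)
  fps$allele_high <- snap(j$allele_high)
  fps
}

#' Allele ("gene") frequency table
#'
#' Counts both alleles of every effective genotype per marker and normalises;
#' missing loci are excluded from that marker's denominator, so the allele
#' count basis is 2 x (number of non-missing fingerprints at the marker).
#'
#' @param fps Fingerprint tibble (>= 1 fingerprint, shared panel).
#' @param panel Optional [ssr_panel()]; when given, sizes are snapped to the
#'   repeat-unit grid first (see [snap_to_grid()]).
#' @return Tibble `marker_id`, `allele`, `count`, `freq`; frequencies sum to 1
#'   within each marker that has any observed allele. Markers observed nowhere
#'   are absent from the table.
#' @examples
#' fps <- dplyr::bind_rows(
#'   tibble::tibble(entity_id = "a", marker_id = "M1", allele_low = 100, allele_high = 100),
#'   tibble::tibble(entity_id = "b", marker_id = "M1", allele_low = 100, allele_high = 102)
#' )
#' allele_frequencies(fps)  # 100: 0.75, 102: 0.25
#' @export
allele_frequencies <- function(fps, panel = NULL) {
  if (nrow(fps) == 0 || length(unique(fps$entity_id)) < 1) {
    stop("allele_frequencies() needs at least one fingerprint")
  }
  if (!is.null(panel)) fps <- snap_to_grid(fps, panel)
  eff <- fps[!is.na(fps$allele_low) & !is.na(fps$allele_high), ]
  long <- tidyr::pivot_longer(eff, c("allele_low", "allele_high"),
                              values_to = "allele")
  out <- long |>
    dplyr::count(.data$marker_id, .data$allele, name = "count") |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$marker_id, .data$allele)
  attr(out, "n_fingerprints") <- length(unique(fps$entity_id))
  out
}

#' The implemented genetic distance measures
#'
#' @return Character vector of the 12 registry method names accepted by
#'   [genetic_distance()].
#' @export
distance_methods <- function() {
  c("shared_allele", "nei_standard", "nei_da", "rogers", "modified_rogers",
    "cavalli_sforza", "simple_matching", "jaccard", "dice", "euclidean_freq",
    "diff_count", "diff_ratio")
}

# per-entity per-marker allele frequency vectors (one-individual populations:
# homozygote -> 1, heterozygote -> 0.5/0.5), as a nested list [entity][marker]
entity_freqs <- function(fps) {
  eff <- fps[!is.na(fps$allele_low) & !is.na(fps$allele_high), ]
  split_ent <- split(eff, eff$entity_id)
  lapply(split_ent, function(f) {
    out <- lapply(seq_len(nrow(f)), function(r) {
      a <- c(f$allele_low[r], f$allele_high[r])
      tab <- table(a) / 2
      stats::setNames(as.numeric(tab), names(tab))
    })
    stats::setNames(out, f$marker_id)
  })
}

pair_freq_stat <- function(fx, fy, fun) {
  shared <- intersect(names(fx), names(fy))
  if (length(shared) == 0) return(NA_real_)
  vals <- vapply(shared, function(mk) {
    alleles <- union(names(fx[[mk]]), names(fy[[mk]]))
    x <- fx[[mk]][alleles]; x[is.na(x)] <- 0
    y <- fy[[mk]][alleles]; y[is.na(y)] <- 0
    fun(x, y)
  }, numeric(1))
  vals
}

#' Pairwise genetic distance matrix
#'
#' Twelve standard measures over a set of fingerprints, each fingerprint
#' treated as a one-individual population (allele frequencies 1 or 0.5/0.5
#' per locus). Loci missing on either side of a pair are excluded from that
#' pair. Methods:
#' \describe{
#'   \item{shared_allele}{1 - mean proportion of shared alleles per locus.}
#'   \item{nei_standard}{Nei (1972) standard distance -ln(Jxy/sqrt(Jx Jy)).}
#'   \item{nei_da}{Nei et al. (1983) DA: 1 - mean locus sum of sqrt(x y).}
#'   \item{rogers}{Rogers (1972): mean locus sqrt(0.5 * sum (x - y)^2).}
#'   \item{modified_rogers}{Wright's modified Rogers:
#'     sqrt(sum (x - y)^2 / (2L)).}
#'   \item{cavalli_sforza}{Cavalli-Sforza & Edwards chord, averaged per locus:
#'     (2/pi) mean sqrt(2 (1 - sum sqrt(x y))).}
#'   \item{simple_matching}{Fraction of mutually effective loci that are
#'     gca-different at `offset`.}
#'   \item{jaccard}{1 - |A intersect B| / |A union B| on marker:allele
#'     presence sets.}
#'   \item{dice}{1 - 2|A intersect B| / (|A| + |B|) on the same sets.}
#'   \item{euclidean_freq}{Euclidean norm of the allele-frequency difference
#'     vector over mutually effective loci.}
#'   \item{diff_count}{The raw differential-locus count D of [compare_pair()].}
#'   \item{diff_ratio}{The differential fraction x = D/p of [compare_pair()].}
#' }
#'
#' @param fps Fingerprint tibble with >= 2 entities on one panel.
#' @param method One of [distance_methods()].
#' @param panel Optional [ssr_panel()] for grid snapping of allele
#'   identities (recommended for the frequency/sharing measures).
#' @param offset Offset in bp for the gca-based measures (`simple_matching`,
#'   `diff_count`, `diff_ratio`); default 2.
#' @return A `dist` object (symmetric, zero diagonal) with a `method`
#'   attribute.
#' @export
genetic_distance <- function(fps, method = "shared_allele", panel = NULL,
                             offset = 2) {
  if (!method %in% distance_methods()) {
    stop("unknown method '", method, "'; available: ",
         paste(distance_methods(), collapse = ", "))
  }
  ids <- unique(fps$entity_id)
  if (length(ids) < 2) stop("need at least two fingerprints")
  if (!is.null(panel) && !method %in% c("simple_matching", "diff_count", "diff_ratio")) {
    fps <- snap_to_grid(fps, panel)
  }
  fr <- entity_freqs(fps)
  params <- comparison_params(base_offset_bp = offset, min_comparison_loci = 0,
                              max_diff_loci = length(unique(fps$marker_id)),
                              max_diff_fraction = 1)

  pair_dist <- function(e1, e2) {
    f1 <- fps[fps$entity_id == e1, ]
    f2 <- fps[fps$entity_id == e2, ]
    switch(method,
      shared_allele = {
        sh <- pair_freq_stat(fr[[e1]], fr[[e2]], function(x, y) sum(pmin(x, y)))
        1 - mean(sh)
      },
      nei_standard = {
        shared <- intersect(names(fr[[e1]]), names(fr[[e2]]))
        jxy <- mean(pair_freq_stat(fr[[e1]], fr[[e2]], function(x, y) sum(x * y)))
        jx <- mean(vapply(shared, function(mk) sum(fr[[e1]][[mk]]^2), numeric(1)))
        jy <- mean(vapply(shared, function(mk) sum(fr[[e2]][[mk]]^2), numeric(1)))
        -log(jxy / sqrt(jx * jy))
      },
      nei_da = 1 - mean(pair_freq_stat(fr[[e1]], fr[[e2]],
                                       function(x, y) sum(sqrt(x * y)))),
      rogers = mean(pair_freq_stat(fr[[e1]], fr[[e2]],
                                   function(x, y) sqrt(0.5 * sum((x - y)^2)))),
      modified_rogers = {
        ss <- pair_freq_stat(fr[[e1]], fr[[e2]], function(x, y) sum((x - y)^2))
        sqrt(sum(ss) / (2 * length(ss)))
      },
      cavalli_sforza = {
        f <- pair_freq_stat(fr[[e1]], fr[[e2]],
                            function(x, y) sum(sqrt(x * y)))
        (2 / pi) * mean(sqrt(2 * pmax(0, 1 - f)))
      },
      simple_matching = {
        r <- compare_pair(f1, f2, params)
        if (r$p - r$M == 0) NA_real_ else r$D / (r$p - r$M)
      },
      jaccard = {
        A <- allele_set(f1); B <- allele_set(f2)
        1 - length(intersect(A, B)) / length(union(A, B))
      },
      dice = {
        A <- allele_set(f1); B <- allele_set(f2)
        1 - 2 * length(intersect(A, B)) / (length(A) + length(B))
      },
      euclidean_freq = {
        ss <- pair_freq_stat(fr[[e1]], fr[[e2]], function(x, y) sum((x - y)^2))
        sqrt(sum(ss))
      },
      diff_count = as.numeric(compare_pair(f1, f2, params)$D),
      diff_ratio = compare_pair(f1, f2, params)$x
    )
  }

  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in seq_along(ids)) {
    for (b in seq_len(a - 1L)) {
      d <- pair_dist(ids[a], ids[b])
      m[a, b] <- d
      m[b, a] <- d
    }
  }
  d <- stats::as.dist(m)
  attr(d, "method") <- method
  d
}

allele_set <- function(f) {
  eff <- f[!is.na(f$allele_low) & !is.na(f$allele_high), ]
  unique(c(paste(eff$marker_id, eff$allele_low),
           paste(eff$marker_id, eff$allele_high)))
}

#' Build a cluster tree from a distance matrix
#'
#' @param dm A `dist` object or symmetric matrix with zero diagonal.
#' @param method `"upgma"` (average-linkage hierarchical clustering, yields an
#'   ultrametric tree) or `"nj"` (neighbour joining, >= 3 taxa).
#' @return An `ape::phylo` tree with the input entity ids as tip labels.
#' @seealso [write_newick()]
#' @export
build_tree <- function(dm, method = c("upgma", "nj")) {
  method <- match.arg(method)
  m <- as.matrix(dm)
  if (!isSymmetric(unname(m), tol = 1e-9)) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (nrow(m) < 2) stop("need at least two entities")
  if (method == "upgma") {
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    phy <- ape::as.phylo(hc)
    # hclust heights are node heights; as.phylo already halves edges so that
    # tip-to-root path equals height/..., keep as produced (ultrametric)
    phy
  } else {
    if (nrow(m) < 3) stop("neighbour joining needs at least three entities")
    ape::nj(m)
  }
}

#' Serialise a tree to a Newick string or file
#'
#' @param tree An `ape::phylo`.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = file)
    invisible(ape::write.tree(tree))
  }
}

#' Write a distance matrix as CSV
#'
#' @param dm A `dist` or matrix.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_distance_matrix <- function(dm, file) {
  m <- as.matrix(dm)
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(entity_id = rownames(m)), out)
  readr::write_csv(out, file)
  invisible(file)
}

#' Render a plain-text dendrogram
#'
#' @param tree An `ape::phylo` (from [build_tree()]).
#' @return Character vector of lines, printed invisibly.
#' @export
text_dendrogram <- function(tree) {
  lines <- utils::capture.output(ape::print.phylo(tree))
  c(lines, utils::capture.output(cat(ape::write.tree(tree), "\n")))
}
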