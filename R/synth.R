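#' Configuration for the synthetic SSR campaign generator
#'
#' The generator emulates a dinucleotide-SSR genotyping campaign: a panel of
#' `p` markers each with `n_alleles` alleles on a `repeat_unit` grid, diploid
#' variety truth fingerprints, and replicate experiment-layer reads carrying
#' capillary-electrophoresis sizing error (symmetric +/-1 bp and +/-2 bp
#' miscalls), locus dropout, and optional whole-replicate noise sets (every
#' locus re-drawn off-truth, the construction used to probe the 40% noise
#' boundary of the replicate audit).
#'
#' @param p Panel size (markers), >= 1.
#' @param n_alleles Alleles per marker on the repeat-unit grid.
#' @param repeat_unit Repeat motif length in bp (default 2).
#' @param size_min Smallest allele of the first marker (markers are staggered).
#' @param heterozygosity Probability a truth locus is heterozygous.
#' @param dropout Per-locus probability a replicate read is missing.
#' @param err_1bp,err_2bp Per-allele probabilities of a +/-1 bp and +/-2 bp
#'   size read error (defaults 0.05 and 0.01).
#' @param noise_fraction Fraction of each DNA node's replicates replaced by
#'   noise sets (realised as `round(noise_fraction * i)` replicates).
#' @param i,j,k,m Hierarchy counts: experiments per DNA, DNA per experimenter,
#'   experimenters per sample, samples per variety. Defaults 3, 1, 1, 1 —
#'   the canonical three-repeat design.
#' @param n_varieties Number of varieties to simulate.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(p = 20L, n_alleles = 8L, repeat_unit = 2L, size_min = 100,
                       heterozygosity = 0.5, dropout = 0, err_1bp = 0.05,
                       err_2bp = 0.01, noise_fraction = 0, i = 3L, j = 1L,
                       k = 1L, m = 1L, n_varieties = 1L, seed = 1L) {
  probs <- c(heterozygosity, dropout, err_1bp, err_2bp, noise_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p < 1) stop("p must be >= 1")
  if (n_alleles < 2) stop("need at least two alleles per marker")
  if (min(i, j, k, m, n_varieties) < 1) stop("hierarchy counts must be >= 1")
  structure(
    list(p = as.integer(p), n_alleles = as.integer(n_alleles),
         repeat_unit = as.integer(repeat_unit), size_min = size_min,
         heterozygosity = heterozygosity, dropout = dropout,
         err_1bp = err_1bp, err_2bp = err_2bp, noise_fraction = noise_fraction,
         i = as.integer(i), j = as.integer(j), k = as.integer(k),
         m = as.integer(m), n_varieties = as.integer(n_varieties),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

sim_panel <- function(config) {
  span <- config$repeat_unit * (config$n_alleles - 1)
  # stagger marker windows; pad by two repeat units so +/-2 bp reads stay in range
  pad <- 2 * config$repeat_unit
  origin <- config$size_min + (seq_len(config$p) - 1) * (span + 10)
  ssr_panel(tibble::tibble(
    marker_id = sprintf("M%02d", seq_len(config$p)),
    panel_id = "SIM",
    repeat_unit = config$repeat_unit,
    size_min = origin - pad,
    size_max = origin + span + pad
  ))
}

marker_grid <- function(panel, config) {
  pad <- 2 * config$repeat_unit
  lapply(stats::setNames(seq_len(nrow(panel)), panel$marker_id), function(r) {
    seq(panel$size_min[r] + pad, panel$size_max[r] - pad, by = panel$repeat_unit[r])
  })
}

#' Generate ground-truth variety fingerprints
#'
#' Truth allele sizes lie exactly on each marker's repeat-unit grid; a locus
#' is heterozygous with the configured probability (two distinct grid
#' alleles), homozygous otherwise.
#'
#' @param config A [sim_config()].
#' @return List: `panel` (an [ssr_panel()]), `truth` (VARIETY-layer
#'   fingerprint tibble, entities `V1`, `V2`, ...), `grid` (per-marker allele
#'   grids), `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- sim_panel(config)
  grid <- marker_grid(panel, config)
  set.seed(config$seed)
  truth <- purrr::map_dfr(seq_len(config$n_varieties), function(v) {
    purrr::map_dfr(panel$marker_id, function(mk) {
      g <- grid[[mk]]
      if (stats::runif(1) < config$heterozygosity) {
        a <- sort(sample(g, 2, replace = FALSE))
      } else {
        a <- rep(sample(g, 1), 2)
      }
      tibble::tibble(entity_id = paste0("V", v), marker_id = mk,
                     allele_low = a[1], allele_high = a[2])
    })
  })
  truth$layer <- "VARIETY"
  list(panel = panel, truth = truth, grid = grid, config = config)
}

# one genotype drawn uniformly off-truth from the marker grid
sample_off_truth <- function(grid, truth_low, truth_high) {
  repeat {
    a <- sort(sample(grid, 2, replace = TRUE))
    if (!(a[1] == truth_low && a[2] == truth_high)) return(a)
  }
}

#' Generate replicate experiment leaves from truth
#'
#' Expands each variety into its m x k x j x i replicate tree. Ordinary
#' leaves are the truth perturbed by per-allele size error (+/-1 or +/-2 bp)
#' and per-locus dropout; the last `round(noise_fraction * i)` experiments of
#' every DNA node are noise replicates, re-drawn uniformly off-truth at every
#' locus.
#'
#' @param truth Output of [generate_truth()].
#' @param config Optional [sim_config()] override (defaults to the one inside
#'   `truth`).
#' @return Leaf tibble ready for [assign_weights()] / [cross_layer_merge()]:
#'   hierarchy columns, `is_noise`, and genotype columns.
#' @export
generate_replicates <- function(truth, config = NULL) {
  config <- config %||% truth$config
  panel <- truth$panel
  grid <- truth$grid
  set.seed(config$seed + 1L)
  n_noise <- round(config$noise_fraction * config$i)
  out <- list()
  for (v in unique(truth$truth$entity_id)) {
    tv <- truth$truth[truth$truth$entity_id == v, ]
    for (s in seq_len(config$m)) for (kk in seq_len(config$k)) {
      for (jj in seq_len(config$j)) for (ii in seq_len(config$i)) {
        noisy <- ii > config$i - n_noise
        g <- tv
        if (noisy) {
          for (r in seq_len(nrow(g))) {
            a <- sample_off_truth(grid[[g$marker_id[r]]],
                                  g$allele_low[r], g$allele_high[r])
            g$allele_low[r] <- a[1]; g$allele_high[r] <- a[2]
          }
        } else {
          shift <- function(x) {
            u <- stats::runif(length(x))
            sgn <- sample(c(-1, 1), length(x), replace = TRUE)
            x + sgn * ifelse(u < config$err_2bp, 2,
                             ifelse(u < config$err_2bp + config$err_1bp, 1, 0))
          }
          lo <- shift(g$allele_low); hi <- shift(g$allele_high)
          g$allele_low <- pmin(lo, hi); g$allele_high <- pmax(lo, hi)
          drop <- stats::runif(nrow(g)) < config$dropout
          g$allele_low[drop] <- NA_real_; g$allele_high[drop] <- NA_real_
        }
        out[[length(out) + 1]] <- tibble::tibble(
          variety_id = v,
          sample_id = sprintf("%s-S%d", v, s),
          experimenter_id = sprintf("E%d", kk),
          dna_id = sprintf("%s-S%d-E%d-D%d", v, s, kk, jj),
          experiment_id = sprintf("%s-S%d-E%d-D%d-R%d", v, s, kk, jj, ii),
          is_noise = noisy,
          marker_id = g$marker_id,
          allele_low = g$allele_low, allele_high = g$allele_high
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Write a synthetic campaign through the standard import formats
#'
#' Exercises the real import path: the replicate leaves are written as a
#' GeneMapper-style genotype table and the hierarchy as a sample information
#' table.
#'
#' @param truth Output of [generate_truth()].
#' @param dir Target directory.
#' @param config Optional [sim_config()] override.
#' @return List of written paths: `genotypes`, `sit`, `panel`, plus the leaf
#'   tibble (`leaves`), invisibly.
#' @export
write_campaign <- function(truth, dir, config = NULL) {
  config <- config %||% truth$config
  leaves <- generate_replicates(truth, config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gpath <- file.path(dir, "genotypes.csv")
  spath <- file.path(dir, "sit.csv")
  ppath <- file.path(dir, "panel.csv")
  fps <- dplyr::select(leaves, entity_id = "experiment_id", "marker_id",
                       "allele_low", "allele_high")
  write_genotype_table(fps, gpath, panel = truth$panel)
  sit <- dplyr::distinct(leaves, variety = .data$variety_id,
                         sample_id = .data$sample_id,
                         experimenter_id = .data$experimenter_id,
                         dna_id = .data$dna_id,
                         experiment_id = .data$experiment_id)
  readr::write_csv(sit, spath)
  readr::write_csv(as.data.frame(truth$panel), ppath)
  invisible(list(genotypes = gpath, sit = spath, panel = ppath, leaves = leaves))
}
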