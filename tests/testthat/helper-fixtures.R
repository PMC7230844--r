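# Shared fixtures: a small panel and hand-built fingerprints.

toy_panel <- function(p = 3, size_min = 100, size_max = 160) {
  ssr_panel(tibble::tibble(
    marker_id = sprintf("M%d", seq_len(p)),
    size_min = size_min, size_max = size_max
  ))
}

# fingerprint from a named list marker -> c(low, high) or NULL (missing)
fp_from_list <- function(entity_id, genos, panel) {
  g <- dplyr::bind_rows(lapply(names(genos), function(mk) {
    make_genotype(mk, genos[[mk]])
  }))
  fingerprint(entity_id, g, panel)
}

# brute-force pairing oracle, independent of gca(): a bijection between the
# two allele pairs with every |difference| <= n exists?
pairing_oracle <- function(g1, g2, n) {
  perms <- list(c(1, 2), c(2, 1))
  for (pm in perms) {
    if (all(abs(g1 - g2[pm]) <= n)) return(0L)
  }
  1L
}

# independent per-pair locus tally for D/S/M, looping scalar calls
tally_oracle <- function(f1, f2, n) {
  mks <- sort(unique(f1$marker_id))
  cls <- vapply(mks, function(mk) {
    r1 <- f1[f1$marker_id == mk, ]
    r2 <- f2[f2$marker_id == mk, ]
    if (is.na(r1$allele_low) || is.na(r2$allele_low)) return("M")
    if (pairing_oracle(c(r1$allele_low, r1$allele_high),
                       c(r2$allele_low, r2$allele_high), n) == 0L) "S" else "D"
  }, character(1))
  c(D = sum(cls == "D"), S = sum(cls == "S"), M = sum(cls == "M"))
}

# random fingerprint set on a shared panel (alleles on an even-bp grid)
random_fps <- function(n_entities, p = 10, missing_rate = 0.1,
                       alleles = seq(100, 130, by = 2)) {
  panel <- toy_panel(p, size_min = 90, size_max = 140)
  fps <- purrr::map_dfr(seq_len(n_entities), function(e) {
    g <- purrr::map_dfr(panel$marker_id, function(mk) {
      if (stats::runif(1) < missing_rate) return(make_genotype(mk))
      make_genotype(mk, sample(alleles, 2, replace = TRUE))
    })
    fingerprint(sprintf("ent%02d", e), g, panel)
  })
  list(panel = panel, fps = fps)
}

# leaf table for one sample built from per-experiment genotype lists
leaves_from_lists <- function(genos_by_exp, panel, sample_id = "S1",
                              experimenter_id = "E1", dna_id = "D1",
                              variety_id = "V1") {
  purrr::imap_dfr(genos_by_exp, function(genos, eid) {
    fp <- fp_from_list(eid, genos, panel)
    tibble::tibble(
      variety_id = variety_id, sample_id = sample_id,
      experimenter_id = experimenter_id, dna_id = dna_id, experiment_id = eid,
      marker_id = fp$marker_id, allele_low = fp$allele_low,
      allele_high = fp$allele_high
    )
  })
}
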