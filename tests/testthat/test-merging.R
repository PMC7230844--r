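make_tree_leaves <- function(i, j, k, m, panel, genos) {
  out <- list()
  for (s in seq_len(m)) for (e in seq_len(k)) for (d in seq_len(j)) {
    for (r in seq_len(i)) {
      eid <- sprintf("S%d-E%d-D%d-R%d", s, e, d, r)
      fp <- fp_from_list(eid, genos, panel)
      out[[length(out) + 1]] <- tibble::tibble(
        variety_id = "V1", sample_id = paste0("S", s),
        experimenter_id = paste0("E", e), dna_id = sprintf("S%d-E%d-D%d", s, e, d),
        experiment_id = eid, marker_id = fp$marker_id,
        allele_low = fp$allele_low, allele_high = fp$allele_high
      )
    }
  }
  dplyr::bind_rows(out)
}

basic_genos <- list(M1 = c(100, 102), M2 = c(110, 110), M3 = c(120, 124))

test_that("leaf weights follow 1/(i j k m) and conserve at every node", {
  panel <- toy_panel(3)

  w1 <- assign_weights(make_tree_leaves(2, 1, 2, 1, panel, basic_genos))
  leaf_w <- dplyr::distinct(w1, .data$experiment_id, .data$weight)
  expect_equal(nrow(leaf_w), 4)
  expect_true(all(leaf_w$weight == 1 / 4))
  nw <- node_weights(w1)
  expect_true(all(nw$weight[nw$level == "DNA"] == 1 / 2))
  expect_equal(nw$weight[nw$level == "VARIETY"], 1)

  w2 <- assign_weights(make_tree_leaves(1, 1, 1, 1, panel, basic_genos))
  expect_equal(unique(w2$weight), 1)

  w3 <- assign_weights(make_tree_leaves(3, 2, 1, 1, panel, basic_genos))
  expect_true(all(dplyr::distinct(w3, .data$experiment_id, .data$weight)$weight == 1 / 6))
  expect_equal(sum(dplyr::distinct(w3, .data$experiment_id, .data$weight)$weight), 1)

  expect_error(assign_weights(w3[0, ]), "empty")
})

test_that("weight conservation holds for random hierarchies", {
  panel <- toy_panel(2)
  set.seed(21)
  for (rep in 1:8) {
    i <- sample(1:4, 1); j <- sample(1:3, 1)
    k <- sample(1:3, 1); m <- sample(1:2, 1)
    leaves <- assign_weights(make_tree_leaves(i, j, k, m, panel,
                                              list(M1 = c(100, 100), M2 = c(102, 104))))
    nw <- node_weights(leaves)
    expect_equal(nw$weight[nw$level == "VARIETY"], 1, tolerance = 1e-12)
    expect_true(all(abs(nw$weight[nw$level == "SAMPLE"] - 1 / m) < 1e-12))
    expect_true(all(abs(nw$weight[nw$level == "EXPERIMENTER"] - 1 / (k * m)) < 1e-12))
    expect_true(all(abs(nw$weight[nw$level == "DNA"] - 1 / (j * k * m)) < 1e-12))
  }
})

peer_fps <- function(genos_list, panel) {
  purrr::imap_dfr(genos_list, function(genos, nm) fp_from_list(nm, genos, panel))
}

test_that("peer merge retains the majority genotype with its support", {
  panel <- toy_panel(1)
  unanimous <- peer_fps(list(a = list(M1 = c(100, 102)),
                             b = list(M1 = c(100, 102)),
                             c = list(M1 = c(100, 102))), panel)
  m1 <- peer_merge(unanimous)
  expect_equal(m1$loci$support, 1)
  expect_equal(m1$loci$flag, "OK")
  expect_equal(c(m1$genotypes$allele_low, m1$genotypes$allele_high), c(100, 102))

  majority <- peer_fps(list(a = list(M1 = c(100, 102)),
                            b = list(M1 = c(100, 102)),
                            c = list(M1 = c(140, 140))), panel)
  m2 <- peer_merge(majority)
  expect_equal(m2$loci$support, 2 / 3, tolerance = 1e-12)
  expect_equal(m2$loci$flag, "OK")
  expect_equal(c(m2$genotypes$allele_low, m2$genotypes$allele_high), c(100, 102))

  # 3 agree, 2 noise: support exactly 0.6 is NOT strictly above the boundary
  boundary <- peer_fps(list(a = list(M1 = c(100, 102)),
                            b = list(M1 = c(100, 102)),
                            c = list(M1 = c(100, 102)),
                            d = list(M1 = c(140, 140)),
                            e = list(M1 = c(120, 126))), panel)
  m3 <- peer_merge(boundary)
  expect_equal(m3$loci$support, 0.6, tolerance = 1e-12)
  expect_equal(m3$loci$flag, "AUDIT_REQUIRED")
  expect_true(is.na(m3$genotypes$allele_low))

  tie <- peer_fps(list(a = list(M1 = c(100, 102)),
                       b = list(M1 = c(140, 140))), panel)
  m4 <- peer_merge(tie)
  expect_equal(m4$loci$flag, "AUDIT_REQUIRED")
})

test_that("missing inputs vote in the denominator and all-missing drops", {
  panel <- toy_panel(1)
  heavy_dropout <- peer_fps(list(a = list(M1 = c(100, 102)),
                                 b = list(M1 = NULL),
                                 c = list(M1 = NULL)), panel)
  m <- peer_merge(heavy_dropout)
  expect_equal(m$loci$support, 1 / 3, tolerance = 1e-12)
  expect_equal(m$loci$flag, "AUDIT_REQUIRED")

  none <- peer_fps(list(a = list(M1 = NULL), b = list(M1 = NULL)), panel)
  expect_equal(peer_merge(none)$loci$flag, "DROPPED_TO_MISSING")
})

test_that("peer merge is idempotent and permutation invariant off ties", {
  panel <- toy_panel(3)
  single <- fp_from_list("only", basic_genos, panel)
  m <- peer_merge(single)
  expect_equal(m$genotypes[c("allele_low", "allele_high")],
               single[c("allele_low", "allele_high")])
  expect_true(all(m$loci$flag == "OK"))

  set.seed(31)
  for (rep in 1:10) {
    fps <- peer_fps(list(a = basic_genos, b = basic_genos,
                         c = list(M1 = c(104, 106), M2 = c(110, 110),
                                  M3 = c(140, 140))), panel)
    perm <- sample(c("a", "b", "c"))
    shuffled <- dplyr::bind_rows(lapply(perm, function(e) fps[fps$entity_id == e, ]))
    expect_equal(peer_merge(shuffled)$genotypes, peer_merge(fps)$genotypes)
  }
})

test_that("cross-layer merge reproduces identical leaves and single paths", {
  panel <- toy_panel(3)
  leaves <- make_tree_leaves(3, 2, 2, 1, panel, basic_genos)
  res <- cross_layer_merge(leaves)
  expect_equal(res$fingerprint$layer, rep("VARIETY", 3))
  expect_equal(res$fingerprint[c("allele_low", "allele_high")],
               fp_from_list("x", basic_genos, panel)[c("allele_low", "allele_high")])
  expect_equal(nrow(res$audit), 0)
  expect_equal(sort(res$provenance), sort(unique(leaves$experiment_id)))

  solo <- make_tree_leaves(1, 1, 1, 1, panel, basic_genos)
  res1 <- cross_layer_merge(solo)
  expect_equal(res1$fingerprint[c("allele_low", "allele_high")],
               fp_from_list("x", basic_genos, panel)[c("allele_low", "allele_high")])
})

test_that("noise below 40% is absorbed; at or above it loci are flagged", {
  panel <- toy_panel(4)
  truth <- list(M1 = c(100, 102), M2 = c(110, 114), M3 = c(120, 120),
                M4 = c(130, 136))
  noise <- list(M1 = c(140, 146), M2 = c(150, 150), M3 = c(100, 104),
                M4 = c(110, 110))
  for (r in c(3, 5, 7)) {
    n_noise_ok <- ceiling(0.4 * r) - 1        # largest count strictly below 40%
    genos <- c(rep(list(truth), r - n_noise_ok), rep(list(noise), n_noise_ok))
    names(genos) <- sprintf("R%d", seq_len(r))
    leaves <- leaves_from_lists(genos, panel)
    res <- cross_layer_merge(leaves)
    expect_equal(nrow(res$audit), 0, label = paste("r =", r))
    expect_equal(sum(!is.na(res$fingerprint$allele_low)), 4)
  }
  # at >= 40%: r = 5 with 2 noise sets -> support 0.6, flagged
  genos <- c(rep(list(truth), 3), rep(list(noise), 2))
  names(genos) <- sprintf("R%d", 1:5)
  res <- cross_layer_merge(leaves_from_lists(genos, panel))
  expect_gt(nrow(res$audit), 0)
  expect_lt(sum(!is.na(res$fingerprint$allele_low)), 4)
})

test_that("replicates perturbed by 1 bp merge to a gca-equal fingerprint", {
  panel <- toy_panel(3)
  truth <- list(M1 = c(100, 102), M2 = c(110, 114), M3 = c(120, 120))
  shift <- function(genos, by) lapply(genos, function(a) a + by)
  genos <- list(R1 = shift(truth, 1), R2 = shift(truth, -1), R3 = shift(truth, 1))
  res <- cross_layer_merge(leaves_from_lists(genos, panel))
  expect_equal(nrow(res$audit), 0)
  truth_fp <- fp_from_list("t", truth, panel)
  for (mk in panel$marker_id) {
    got <- res$fingerprint[res$fingerprint$marker_id == mk, ]
    want <- truth_fp[truth_fp$marker_id == mk, ]
    expect_equal(gca(c(got$allele_low, got$allele_high),
                     c(want$allele_low, want$allele_high), 2), 0L)
  }
})

test_that("manual reselection clears flags under its guard rails", {
  panel <- toy_panel(1)
  tie <- peer_fps(list(a = list(M1 = c(100, 102)),
                       b = list(M1 = c(140, 140))), panel)
  m <- peer_merge(tie)
  fixed <- manual_reselect(m, "M1", c(100, 102))
  expect_equal(fixed$loci$flag, "OK")
  expect_equal(fixed$loci$note, "manual")
  expect_equal(c(fixed$genotypes$allele_low, fixed$genotypes$allele_high),
               c(100, 102))

  expect_error(manual_reselect(fixed, "M1", c(100, 102)), "not flagged")
  expect_error(manual_reselect(m, "M1", c(555, 555)), "candidates")
  forced <- manual_reselect(m, "M1", c(555, 555), force = TRUE)
  expect_equal(forced$loci$note, "override")
})
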