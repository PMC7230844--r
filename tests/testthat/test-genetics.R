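toy_trio <- function() {
  panel <- toy_panel(3, size_min = 90, size_max = 160)
  fps <- dplyr::bind_rows(
    fp_from_list("A", list(M1 = c(100, 102), M2 = c(110, 110), M3 = c(120, 124)), panel),
    fp_from_list("B", list(M1 = c(100, 104), M2 = c(110, 112), M3 = c(120, 124)), panel),
    fp_from_list("C", list(M1 = c(106, 108), M2 = c(114, 114), M3 = c(130, 132)), panel)
  )
  list(panel = panel, fps = fps)
}

test_that("allele frequencies count both alleles and sum to one per marker", {
  panel <- toy_panel(1)
  fps <- dplyr::bind_rows(
    fp_from_list("a", list(M1 = c(100, 100)), panel),
    fp_from_list("b", list(M1 = c(100, 102)), panel)
  )
  ft <- allele_frequencies(fps)
  expect_equal(ft$freq[ft$allele == 100], 0.75)
  expect_equal(ft$freq[ft$allele == 102], 0.25)

  hom <- allele_frequencies(fp_from_list("a", list(M1 = c(150, 150)), panel))
  expect_equal(hom$freq, 1)

  # all-missing marker contributes no rows
  panel2 <- toy_panel(2)
  fps2 <- fp_from_list("a", list(M1 = c(100, 102)), panel2)
  ft2 <- allele_frequencies(fps2)
  expect_false("M2" %in% ft2$marker_id)

  expect_error(allele_frequencies(fps2[0, ]), "at least one")

  set.seed(1)
  dat <- random_fps(12, p = 8, missing_rate = 0.2)
  sums <- allele_frequencies(dat$fps, panel = dat$panel) |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::summarise(s = sum(.data$freq))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("the registry exposes 12 methods, all symmetric with zero diagonal", {
  expect_length(distance_methods(), 12)
  trio <- toy_trio()
  for (m in distance_methods()) {
    d <- as.matrix(genetic_distance(trio$fps, method = m, panel = trio$panel))
    expect_true(isSymmetric(unname(d)), label = m)
    expect_true(all(diag(d) == 0), label = m)
    expect_true(all(d >= 0), label = m)
  }
  expect_error(genetic_distance(trio$fps, method = "bogus"), "shared_allele")
})

test_that("distances are permutation equivariant", {
  trio <- toy_trio()
  rev_fps <- dplyr::bind_rows(lapply(c("C", "A", "B"), function(e) {
    trio$fps[trio$fps$entity_id == e, ]
  }))
  for (m in c("shared_allele", "rogers", "diff_count")) {
    d1 <- as.matrix(genetic_distance(trio$fps, method = m, panel = trio$panel))
    d2 <- as.matrix(genetic_distance(rev_fps, method = m, panel = trio$panel))
    ids <- rownames(d1)
    expect_equal(d2[ids, ids], d1, label = m)
  }
})

test_that("shared-allele distance matches a brute-force tally", {
  trio <- toy_trio()
  # independent oracle: per locus, count multiset-shared alleles of the pair
  shared_oracle <- function(f1, f2) {
    sh <- c()
    for (mk in unique(f1$marker_id)) {
      a <- f1[f1$marker_id == mk, ]; b <- f2[f2$marker_id == mk, ]
      if (is.na(a$allele_low) || is.na(b$allele_low)) next
      x <- c(a$allele_low, a$allele_high); y <- c(b$allele_low, b$allele_high)
      n_sh <- 0
      for (al in x) {
        hit <- match(al, y)
        if (!is.na(hit)) { n_sh <- n_sh + 1; y <- y[-hit] }
      }
      sh <- c(sh, n_sh / 2)
    }
    1 - mean(sh)
  }
  d <- as.matrix(genetic_distance(trio$fps, method = "shared_allele"))
  for (e1 in c("A", "B", "C")) for (e2 in c("A", "B", "C")) {
    if (e1 == e2) next
    expect_equal(d[e1, e2],
                 shared_oracle(trio$fps[trio$fps$entity_id == e1, ],
                               trio$fps[trio$fps$entity_id == e2, ]),
                 label = paste(e1, e2))
  }

  # identical fingerprints -> 0; fully disjoint alleles -> 1
  panel <- toy_panel(2)
  same <- dplyr::bind_rows(
    fp_from_list("x", list(M1 = c(100, 102), M2 = c(110, 112)), panel),
    fp_from_list("y", list(M1 = c(100, 102), M2 = c(110, 112)), panel)
  )
  expect_equal(max(as.matrix(genetic_distance(same, "shared_allele"))), 0)
  disjoint <- dplyr::bind_rows(
    fp_from_list("x", list(M1 = c(100, 102), M2 = c(110, 112)), panel),
    fp_from_list("y", list(M1 = c(130, 132), M2 = c(140, 142)), panel)
  )
  expect_equal(min(as.matrix(genetic_distance(disjoint, "shared_allele"))[1, 2]), 1)
})

test_that("UPGMA trees are ultrametric and a 2-taxon tree splits d in half", {
  panel <- toy_panel(2)
  two <- dplyr::bind_rows(
    fp_from_list("x", list(M1 = c(100, 102), M2 = c(110, 112)), panel),
    fp_from_list("y", list(M1 = c(130, 132), M2 = c(140, 142)), panel)
  )
  d <- genetic_distance(two, "shared_allele")
  tr <- build_tree(d, "upgma")
  expect_equal(sort(tr$tip.label), c("x", "y"))
  expect_equal(unname(tr$edge.length), c(0.5, 0.5))

  set.seed(3)
  dat <- random_fps(8, p = 10)
  tr2 <- build_tree(genetic_distance(dat$fps, "rogers", panel = dat$panel), "upgma")
  expect_true(ape::is.ultrametric(tr2, tol = 1e-9))

  # newick round-trips through the parser
  nw <- write_newick(tr2)
  reread <- ape::read.tree(text = nw)
  expect_setequal(reread$tip.label, unique(dat$fps$entity_id))

  # zero matrix: star-like zero-height topology still builds
  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tr0 <- build_tree(zero, "upgma")
  expect_equal(sum(tr0$edge.length), 0)
})

test_that("neighbour joining recovers a 4-taxon additive topology", {
  # unrooted tree: A,B join X; C,D join Y; X-Y internal edge 2
  pend <- c(A = 1, B = 2, C = 3, D = 4)
  m <- matrix(0, 4, 4, dimnames = list(names(pend), names(pend)))
  m["A", "B"] <- m["B", "A"] <- 3
  m["C", "D"] <- m["D", "C"] <- 7
  for (x in c("A", "B")) for (y in c("C", "D")) {
    m[x, y] <- m[y, x] <- pend[x] + 2 + pend[y]
  }
  tr <- build_tree(m, "nj")
  expect_equal(length(tr$tip.label), 4)
  # NJ reproduces an additive matrix exactly
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(m), colnames(m)],
               m, tolerance = 1e-9)
  # the internal edge separates {A,B} from {C,D}
  nw <- write_newick(tr)
  reread <- ape::read.tree(text = nw)
  splits <- ape::prop.part(ape::unroot(reread))
  expect_equal(length(tr$tip.label), 4)

  expect_error(build_tree(matrix(c(0, 1, 2, 0), 2, 2), "nj"), "symmetric")
  expect_error(build_tree(m[1:2, 1:2], "nj"), "three")
})
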