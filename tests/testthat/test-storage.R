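# a small campaign: 1 sample, 2 experimenters x 1 DNA x 3 runs = 6 experiments
campaign_fixture <- function(noise_for = character(0)) {
  panel <- toy_panel(3)
  genos <- list(M1 = c(100, 102), M2 = c(110, 110), M3 = c(120, 124))
  noise <- list(M1 = c(140, 140), M2 = c(130, 134), M3 = c(100, 100))
  sit <- tidyr::expand_grid(
    variety_id = "VAR1", sample_id = "S1",
    experimenter_id = c("E1", "E2"), run = 1:3
  ) |>
    dplyr::mutate(dna_id = paste0(.data$experimenter_id, "-D1"),
                  experiment_id = sprintf("%s-R%d", .data$dna_id, .data$run)) |>
    dplyr::select(-"run")
  fps <- purrr::map_dfr(sit$experiment_id, function(eid) {
    fp_from_list(eid, if (eid %in% noise_for) noise else genos, panel)
  })
  list(panel = panel, sit = sit, fps = fps, genos = genos)
}

test_that("EFD submissions are validated, owned and kept as repeats", {
  fx <- campaign_fixture()
  store <- fp_store(fx$panel)
  ids <- submit_efd(store, fx$fps, owner = "E1")
  expect_length(ids, 6)

  # round-trip: re-query returns identical genotypes
  back <- store_fingerprints(store, "EFD")
  expect_equal(
    dplyr::arrange(back, .data$entity_id, .data$marker_id),
    dplyr::arrange(fx$fps[names(back)], .data$entity_id, .data$marker_id)
  )

  # re-upload of the same experiment creates a second record, not an overwrite
  submit_efd(store, fx$fps[fx$fps$entity_id == "E1-D1-R1", ], owner = "E1")
  expect_equal(sum(store_records(store, "EFD")$entity_id == "E1-D1-R1"), 2)

  # invalid upload (panel marker absent) is rejected with the violation
  bad <- fx$fps[fx$fps$marker_id != "M3", ]
  expect_error(submit_efd(store, bad[bad$entity_id == "E1-D1-R2", ], "E1"),
               "validation")

  # visibility: an experimenter queries only their own records
  submit_efd(store, fx$fps[fx$fps$entity_id == "E2-D1-R1", ], owner = "E2")
  expect_true(all(store_records(store, "EFD", owner = "E2")$owner == "E2"))
})

test_that("audit merges replicates into the SFD and enforces ownership", {
  fx <- campaign_fixture()
  store <- fp_store(fx$panel)
  submit_efd(store, fx$fps, owner = "E1")
  sid <- register_sit(store, fx$sit, owner = "E1")

  expect_error(audit_efd_to_sfd(store, sid, auditor = "E9"), "permission")

  res <- audit_efd_to_sfd(store, sid, auditor = "E1")
  expect_equal(names(res$promoted), "S1")
  expect_equal(nrow(res$blocked), 0)
  sfd <- store_fingerprints(store, "SFD")
  expect_equal(sfd$allele_low, fx$fps$allele_low[fx$fps$entity_id == "E1-D1-R1"])
})

test_that("a tied locus blocks its sample until manual reselection", {
  fx <- campaign_fixture()
  panel <- fx$panel
  store <- fp_store(panel)
  # second sample whose two experimenters disagree at M1 -> 1 vs 1 tie
  sit2 <- dplyr::bind_rows(
    fx$sit,
    tibble::tibble(variety_id = "VAR1", sample_id = "S2",
                   experimenter_id = c("E1", "E2"),
                   dna_id = c("S2-E1-D1", "S2-E2-D1"),
                   experiment_id = c("S2-E1-D1-R1", "S2-E2-D1-R1"))
  )
  fps2 <- dplyr::bind_rows(
    fx$fps,
    fp_from_list("S2-E1-D1-R1", list(M1 = c(100, 102), M2 = c(110, 110),
                                     M3 = c(120, 124)), panel),
    fp_from_list("S2-E2-D1-R1", list(M1 = c(140, 140), M2 = c(110, 110),
                                     M3 = c(120, 124)), panel)
  )
  submit_efd(store, fps2, owner = "E1")
  sid <- register_sit(store, sit2, owner = "E1")
  res <- audit_efd_to_sfd(store, sid, auditor = "E1")
  expect_equal(names(res$promoted), "S1")        # others promoted
  expect_equal(unique(res$blocked$sample_id), "S2")
  expect_equal(res$blocked$marker_id, "M1")

  store_reselect(store, sid, "S2", "M1", c(100, 102))
  res2 <- audit_efd_to_sfd(store, sid, auditor = "E1")
  expect_true("S2" %in% names(res2$promoted))
  expect_equal(nrow(res2$blocked), 0)
})

test_that("promotion gating, locking and tier monotonicity hold", {
  fx <- campaign_fixture()
  store <- fp_store(fx$panel)
  submit_efd(store, fx$fps, owner = "E1")
  sid <- register_sit(store, fx$sit, owner = "E1")

  # promoting before any audit fails: no SFD record exists
  expect_error(promote_sfd_to_lfd(store, "S1"), "no SFD record")

  audit_efd_to_sfd(store, sid, auditor = "E1")
  lfd_ids <- promote_sfd_to_lfd(store, "S1", name = "GoldenVariety",
                                synonyms = "GV;Gold")
  expect_length(lfd_ids, 1)

  # comparison sees only promoted records
  expect_equal(unique(store_fingerprints(store, "LFD")$entity_id), "S1")

  lock_lfd(store, lfd_ids)
  expect_error(update_record(store, lfd_ids, name = "Renamed"), "locked")
  expect_error(lock_lfd(store, "EFD-000001"), "LFD")

  expect_equal(nrow(store_check(store)), 0)
})

test_that("trace expands the full LFD -> SFD -> EFD chain", {
  fx <- campaign_fixture()
  store <- fp_store(fx$panel)
  layout <- design_plates(dplyr::distinct(fx$sit, sample_id = .data$sample_id,
                                          dna_id = .data$dna_id))
  store_add_wells(store, layout)
  submit_efd(store, fx$fps, owner = "E1",
             image_refs = tibble::tibble(entity_id = "E1-D1-R1",
                                         marker_id = "M1",
                                         path = "img/E1-D1-R1_M1.png"))
  sid <- register_sit(store, fx$sit, owner = "E1")
  audit_efd_to_sfd(store, sid, auditor = "E1")
  lfd <- promote_sfd_to_lfd(store, "S1")

  tr <- trace(store, lfd)
  expect_s3_class(tr, "fp_trace")
  expect_equal(trace_leaves(tr), 6)  # 2 experimenters x 3 runs
  expect_equal(tr$sources[[1]]$tier, "SFD")

  efd_leaf <- trace(store, "EFD-000001")
  expect_equal(trace_leaves(efd_leaf), 1)
  expect_equal(nrow(efd_leaf$images), 1)
  expect_error(trace(store, "LFD-999999"), "not found")
})

test_that("a store round-trips identically through its CSV directory", {
  fx <- campaign_fixture()
  store <- fp_store(fx$panel)
  submit_efd(store, fx$fps, owner = "E1")
  sid <- register_sit(store, fx$sit, owner = "E1")
  audit_efd_to_sfd(store, sid, auditor = "E1")
  promote_sfd_to_lfd(store, "S1", name = "GoldenVariety", synonyms = "GV")

  dir <- withr::local_tempdir()
  store_save(store, dir)
  back <- store_load(dir)
  expect_equal(back$records, store$records)
  expect_equal(dplyr::arrange(back$genotypes, .data$record_id, .data$marker_id),
               dplyr::arrange(store$genotypes, .data$record_id, .data$marker_id))
  expect_equal(back$sit_rows, store$sit_rows)
  expect_equal(nrow(store_check(back)), 0)

  # byte-stable: saving the reloaded store reproduces the same records file
  dir2 <- withr::local_tempdir()
  store_save(back, dir2)
  expect_identical(readLines(file.path(dir, "records.csv")),
                   readLines(file.path(dir2, "records.csv")))
})

test_that("comparison scopes partition the LFD by homonymy", {
  panel <- toy_panel(2)
  store <- fp_store(panel)
  genos <- function(a) list(M1 = c(a, a + 2), M2 = c(110, 110))
  sit_rows <- purrr::map_dfr(1:10, function(v) tibble::tibble(
    variety_id = paste0("VAR", v), sample_id = paste0("S", v),
    experimenter_id = "E1", dna_id = paste0("S", v, "-D1"),
    experiment_id = paste0("S", v, "-D1-R1")
  ))
  fps <- purrr::map_dfr(1:10, function(v) {
    fp_from_list(paste0("S", v, "-D1-R1"), genos(100 + 4 * v), panel)
  })
  submit_efd(store, fps, owner = "E1")
  sid <- register_sit(store, sit_rows, owner = "E1")
  audit_efd_to_sfd(store, sid, auditor = "E1")
  # three entries share the name "Dent", the rest are unique
  promote_sfd_to_lfd(store, paste0("S", 1:10),
                     name = c(rep("Dent", 2), paste0("N", 3:9), "Other"),
                     synonyms = c(rep("", 9), "Dent"))

  pending <- fp_from_list("query", genos(104), panel)
  hom <- select_scope(store, "HOMONYMY", pending, pending_name = "Dent")
  non <- select_scope(store, "NON_HOMONYMY", pending, pending_name = "Dent")
  all_ids <- unique(store_fingerprints(store, "LFD")$entity_id)
  hom_ids <- unique(hom$reference$entity_id)
  non_ids <- unique(non$reference$entity_id)
  expect_length(hom_ids, 3)   # two named Dent + one synonym
  expect_length(non_ids, 7)
  expect_length(intersect(hom_ids, non_ids), 0)
  expect_setequal(c(hom_ids, non_ids), all_ids)

  db <- select_scope(store, "DATABASE", pending)
  expect_setequal(unique(db$reference$entity_id), all_ids)

  # paired mode: exactly the assigned comparisons
  pairs <- tibble::tibble(pending_id = c("S1", "S2", "S3", "S4"),
                          reference_id = c("S5", "S6", "S7", "S8"))
  res <- compare_assigned_pairs(store, pairs)
  expect_equal(nrow(res), 4)

  expect_error(select_scope(store, "PAIRED", pending), "assignment")
  expect_error(select_scope(store, "DATABASE", pending,
                            assignment = pairs), "does not take")

  empty <- fp_store(panel)
  expect_error(select_scope(empty, "DATABASE", pending), "empty")
})
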