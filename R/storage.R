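#' Create a three-tier fingerprint store
#'
#' The store holds fingerprint records in three tiers with audit-gated
#' promotion: raw per-experiment uploads land in the Experimental Fingerprint
#' Database (EFD, state UNAUDITED); the replicate audit merges each sample's
#' EFD records into a Sample Fingerprint Database record (SFD, state AUDITED);
#' audited sample fingerprints are promoted to the Local Fingerprint Database
#' (LFD), the tier comparisons and reports run against. LFD records can be
#' locked, after which any mutation fails. Original EFD data are never
#' altered, so every merged fingerprint can be traced back to its runs, plate
#' wells and trace-image paths.
#'
#' The store is an environment-backed object (reference semantics: operations
#' mutate it in place) and persists as a directory of plain CSV tables with
#' fingerprint payloads in sidecar files referenced by path — see
#' [store_save()] / [store_load()].
#'
#' @param panel An [ssr_panel()] shared by all fingerprints in the store.
#' @return An object of class `fp_store`.
#' @export
fp_store <- function(panel) {
  stopifnot(inherits(panel, "ssr_panel"))
  s <- new.env(parent = emptyenv())
  s$panel <- panel
  s$records <- tibble::tibble(
    record_id = character(), tier = character(), entity_id = character(),
    state = character(), owner = character(), sit_id = character(),
    name = character(), synonyms = character(),
    created = character(), audited = character(), provenance = character()
  )
  s$genotypes <- tibble::tibble(
    record_id = character(), marker_id = character(),
    allele_low = numeric(), allele_high = numeric()
  )
  s$sits <- tibble::tibble(sit_id = character(), owner = character())
  s$sit_rows <- tibble::tibble(
    sit_id = character(), variety_id = character(), sample_id = character(),
    experimenter_id = character(), dna_id = character(), experiment_id = character()
  )
  s$wells <- tibble::tibble(
    plate_barcode = character(), well = character(), sample_id = character(),
    dna_id = character(), panel_id = character(), role = character()
  )
  s$image_refs <- tibble::tibble(
    record_id = character(), marker_id = character(), path = character()
  )
  s$reselects <- tibble::tibble(
    sit_id = character(), sample_id = character(), marker_id = character(),
    allele_low = numeric(), allele_high = numeric(), force = logical()
  )
  s$counter <- 0L
  class(s) <- "fp_store"
  s
}

#' @export
print.fp_store <- function(x, ...) {
  tally <- table(factor(x$records$tier, levels = c("EFD", "SFD", "LFD")))
  cat("SSR fingerprint store —", nrow(x$panel), "panel markers;",
      "EFD:", tally[["EFD"]], " SFD:", tally[["SFD"]], " LFD:", tally[["LFD"]], "\n")
  invisible(x)
}

store_stamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

next_record_id <- function(store, tier) {
  store$counter <- store$counter + 1L
  sprintf("%s-%06d", tier, store$counter)
}

#' Submit experiment fingerprints to the EFD
#'
#' Each distinct `entity_id` (one genotyping experiment) becomes one UNAUDITED
#' EFD record owned by `owner`. Re-submitting the same experiment creates a
#' new record — repeats are kept, never overwritten. Fingerprints failing
#' [validate_fingerprints()] are rejected with the violation list.
#'
#' @param store An [fp_store()].
#' @param fps Fingerprint tibble (experiment layer).
#' @param owner Experimenter id of the uploader.
#' @param image_refs Optional tibble `entity_id`, `marker_id`, `path` binding
#'   capillary-electrophoresis image files to loci.
#' @return Character vector of new EFD record ids, named by entity_id.
#' @export
submit_efd <- function(store, fps, owner, image_refs = NULL) {
  stopifnot(inherits(store, "fp_store"))
  viol <- validate_fingerprints(fps, store$panel)
  if (nrow(viol) > 0) {
    stop("fingerprint validation failed:\n",
         paste(utils::capture.output(print(viol)), collapse = "\n"))
  }
  ids <- character(0)
  for (eid in unique(fps$entity_id)) {
    rid <- next_record_id(store, "EFD")
    store$records <- dplyr::bind_rows(store$records, tibble::tibble(
      record_id = rid, tier = "EFD", entity_id = eid, state = "UNAUDITED",
      owner = owner, sit_id = NA_character_, name = eid, synonyms = "",
      created = store_stamp(), audited = NA_character_, provenance = ""
    ))
    f <- fps[fps$entity_id == eid, c("marker_id", "allele_low", "allele_high")]
    store$genotypes <- dplyr::bind_rows(
      store$genotypes, tibble::tibble(record_id = rid, f)
    )
    if (!is.null(image_refs)) {
      ir <- image_refs[image_refs$entity_id == eid, ]
      if (nrow(ir) > 0) {
        store$image_refs <- dplyr::bind_rows(
          store$image_refs,
          tibble::tibble(record_id = rid, marker_id = ir$marker_id, path = ir$path)
        )
      }
    }
    ids[eid] <- rid
  }
  ids
}

#' Register a sample information table (SIT)
#'
#' The SIT declares which samples an experimenter is responsible for and the
#' replicate hierarchy (sample, experimenter, DNA, experiment) used by the
#' audit merge. Only the SIT owner may audit its samples.
#'
#' @param store An [fp_store()].
#' @param sit Tibble from [read_sit()] (columns `variety_id`, `sample_id`,
#'   `experimenter_id`, `dna_id`, `experiment_id`).
#' @param owner Experimenter id owning the SIT.
#' @return The new sit_id.
#' @export
register_sit <- function(store, sit, owner) {
  need <- c("variety_id", "sample_id", "experimenter_id", "dna_id", "experiment_id")
  miss <- setdiff(need, names(sit))
  if (length(miss) > 0) stop("SIT is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sit$experiment_id)) stop("duplicate experiment ids in SIT")
  sid <- sprintf("SIT-%04d", nrow(store$sits) + 1L)
  store$sits <- dplyr::bind_rows(store$sits, tibble::tibble(sit_id = sid, owner = owner))
  store$sit_rows <- dplyr::bind_rows(
    store$sit_rows, tibble::tibble(sit_id = sid, sit[need])
  )
  sid
}

#' Query records of one tier
#'
#' @param store An [fp_store()].
#' @param tier `"EFD"`, `"SFD"` or `"LFD"`.
#' @param owner Optional: restrict EFD queries to one experimenter's own
#'   uploads (the per-experimenter visibility rule).
#' @return Records tibble.
#' @export
store_records <- function(store, tier = c("EFD", "SFD", "LFD"), owner = NULL) {
  tier <- match.arg(tier)
  r <- store$records[store$records$tier == tier, ]
  if (!is.null(owner)) r <- r[r$owner == owner, ]
  r
}

#' Fetch fingerprints of one tier as a tidy table
#'
#' @param store An [fp_store()].
#' @param tier Tier to read.
#' @param entity_ids Optional subset of entity ids.
#' @return Fingerprint tibble (`entity_id`, `marker_id`, `allele_low`,
#'   `allele_high`), the most recent record per entity.
#' @export
store_fingerprints <- function(store, tier = c("EFD", "SFD", "LFD"), entity_ids = NULL) {
  tier <- match.arg(tier)
  recs <- store_records(store, tier)
  if (!is.null(entity_ids)) {
    absent <- setdiff(entity_ids, recs$entity_id)
    if (length(absent) > 0) {
      stop("no ", tier, " record for: ", paste(absent, collapse = ", "))
    }
    recs <- recs[recs$entity_id %in% entity_ids, ]
  }
  recs <- recs |>
    dplyr::group_by(.data$entity_id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  dplyr::inner_join(
    dplyr::select(recs, "record_id", "entity_id"),
    store$genotypes, by = "record_id"
  ) |>
    dplyr::select("entity_id", "marker_id", "allele_low", "allele_high")
}

#' Record a manual genotype reselection for a blocked sample
#'
#' Registered choices are applied by the next [audit_efd_to_sfd()] run via
#' [manual_reselect()], clearing the corresponding audit flag.
#'
#' @param store An [fp_store()].
#' @param sit_id SIT whose audit is blocked.
#' @param sample_id,marker_id Locus to resolve.
#' @param genotype Numeric length-2 allele pair.
#' @param force Allow an unobserved genotype (recorded as an override).
#' @return The store, invisibly.
#' @export
store_reselect <- function(store, sit_id, sample_id, marker_id, genotype, force = FALSE) {
  genotype <- sort(as.numeric(genotype))
  stopifnot(length(genotype) == 2)
  store$reselects <- dplyr::bind_rows(store$reselects, tibble::tibble(
    sit_id = sit_id, sample_id = sample_id, marker_id = marker_id,
    allele_low = genotype[1], allele_high = genotype[2], force = force
  ))
  invisible(store)
}

#' Audit EFD records into the SFD
#'
#' Runs the hierarchical merge over each SIT sample's EFD replicates
#' (experiment -> DNA -> experimenter -> sample). Samples whose merge leaves
#' `AUDIT_REQUIRED` loci — after applying any registered
#' [store_reselect()] choices — are blocked; the rest become AUDITED SFD
#' records with full provenance to their EFD records.
#'
#' @param store An [fp_store()].
#' @param sit_id A registered SIT.
#' @param auditor Must be the SIT owner (permission rule).
#' @param offset,effective_threshold Merge parameters (see [peer_merge()]).
#' @return List: `promoted` (named SFD record ids), `blocked` (tibble
#'   `sample_id`, `marker_id`, `layer`, `support`, `candidates`).
#' @export
audit_efd_to_sfd <- function(store, sit_id, auditor, offset = 2,
                             effective_threshold = 0.6) {
  si <- store$sits[store$sits$sit_id == sit_id, ]
  if (nrow(si) == 0) stop("unknown SIT: ", sit_id)
  if (si$owner != auditor) {
    stop("permission denied: ", auditor, " does not own ", sit_id)
  }
  rows <- store$sit_rows[store$sit_rows$sit_id == sit_id, ]
  efd <- store_records(store, "EFD")
  absent <- setdiff(rows$experiment_id, efd$entity_id)
  if (length(absent) > 0) {
    stop("EFD records missing for experiments: ", paste(absent, collapse = ", "))
  }
  promoted <- character(0)
  blocked <- list()
  for (sid in unique(rows$sample_id)) {
    sub <- rows[rows$sample_id == sid, ]
    fps <- store_fingerprints(store, "EFD", entity_ids = sub$experiment_id)
    leaves <- dplyr::inner_join(
      dplyr::select(sub, "sample_id", "experimenter_id", "dna_id",
                    entity_id = "experiment_id"),
      fps, by = "entity_id"
    ) |>
      dplyr::rename(experiment_id = "entity_id") |>
      dplyr::mutate(variety_id = sid)  # audit merges within one sample (m = 1)
    res <- cross_layer_merge(leaves, offset = offset,
                             effective_threshold = effective_threshold)
    sel <- store$reselects[store$reselects$sit_id == sit_id &
                             store$reselects$sample_id == sid, ]
    if (nrow(sel) > 0) {
      # resolve flags wherever in the hierarchy they arose: the chosen
      # genotype must be among the candidates observed at that layer
      for (r in seq_len(nrow(sel))) {
        mk <- sel$marker_id[r]
        cand <- unique(unlist(strsplit(
          res$audit$candidates[res$audit$marker_id == mk], ";")))
        chosen <- sprintf("%g/%g", sel$allele_low[r], sel$allele_high[r])
        if (!(chosen %in% cand) && !sel$force[r]) {
          stop("reselected genotype ", chosen, " not among observed candidates",
               " at ", mk, " for sample ", sid, "; register with force = TRUE",
               " for an explicit override")
        }
        gi <- match(mk, res$fingerprint$marker_id)
        if (is.na(gi)) stop("unknown marker in reselection: ", mk)
        res$fingerprint$allele_low[gi] <- sel$allele_low[r]
        res$fingerprint$allele_high[gi] <- sel$allele_high[r]
        res$audit <- res$audit[res$audit$marker_id != mk, ]
      }
    }
    open_flags <- res$audit[res$audit$flag == "AUDIT_REQUIRED", ]
    if (nrow(open_flags) > 0) {
      blocked[[sid]] <- tibble::tibble(
        sample_id = sid, marker_id = open_flags$marker_id,
        layer = open_flags$layer, support = open_flags$support,
        candidates = open_flags$candidates
      )
      next
    }
    rid <- next_record_id(store, "SFD")
    src <- efd$record_id[efd$entity_id %in% sub$experiment_id]
    store$records <- dplyr::bind_rows(store$records, tibble::tibble(
      record_id = rid, tier = "SFD", entity_id = sid, state = "AUDITED",
      owner = auditor, sit_id = sit_id, name = sid, synonyms = "",
      created = store_stamp(), audited = store_stamp(),
      provenance = paste(src, collapse = ";")
    ))
    store$genotypes <- dplyr::bind_rows(store$genotypes, tibble::tibble(
      record_id = rid,
      res$fingerprint[c("marker_id", "allele_low", "allele_high")]
    ))
    promoted[sid] <- rid
  }
  list(
    promoted = promoted,
    blocked = if (length(blocked) > 0) dplyr::bind_rows(blocked) else
      tibble::tibble(sample_id = character(), marker_id = character(),
                     layer = character(), support = numeric(),
                     candidates = character())
  )
}

#' Promote audited sample fingerprints to the LFD
#'
#' @param store An [fp_store()].
#' @param sample_ids Entity ids of AUDITED SFD records.
#' @param name,synonyms Optional variety names for homonymy matching
#'   (vectors recycled along `sample_ids`; synonyms as `;`-separated strings).
#' @return Named character vector of LFD record ids.
#' @export
promote_sfd_to_lfd <- function(store, sample_ids, name = NULL, synonyms = "") {
  sfd <- store_records(store, "SFD")
  ids <- character(0)
  name <- rep_len(name %||% sample_ids, length(sample_ids))
  synonyms <- rep_len(synonyms, length(sample_ids))
  for (idx in seq_along(sample_ids)) {
    sid <- sample_ids[idx]
    rec <- sfd[sfd$entity_id == sid, ]
    rec <- rec[nrow(rec), ]
    if (nrow(rec) == 0) stop("no SFD record for sample ", sid)
    if (rec$state != "AUDITED") stop("SFD record for ", sid, " is not AUDITED")
    rid <- next_record_id(store, "LFD")
    store$records <- dplyr::bind_rows(store$records, tibble::tibble(
      record_id = rid, tier = "LFD", entity_id = sid, state = "AUDITED",
      owner = rec$owner, sit_id = rec$sit_id, name = name[idx],
      synonyms = synonyms[idx], created = store_stamp(),
      audited = rec$audited, provenance = rec$record_id
    ))
    g <- store$genotypes[store$genotypes$record_id == rec$record_id, ]
    store$genotypes <- dplyr::bind_rows(store$genotypes, tibble::tibble(
      record_id = rid, g[c("marker_id", "allele_low", "allele_high")]
    ))
    ids[sid] <- rid
  }
  ids
}

#' Lock LFD records
#'
#' Locked records are immutable: any later mutation attempt errors.
#'
#' @param store An [fp_store()].
#' @param record_ids LFD record ids to lock.
#' @return The store, invisibly.
#' @export
lock_lfd <- function(store, record_ids) {
  i <- match(record_ids, store$records$record_id)
  if (anyNA(i)) stop("unknown record id(s): ",
                     paste(record_ids[is.na(i)], collapse = ", "))
  if (any(store$records$tier[i] != "LFD")) stop("only LFD records can be locked")
  store$records$state[i] <- "LOCKED"
  invisible(store)
}

assert_unlocked <- function(store, record_id) {
  i <- match(record_id, store$records$record_id)
  if (is.na(i)) stop("unknown record id: ", record_id)
  if (store$records$state[i] == "LOCKED") {
    stop("record ", record_id, " is locked and cannot be changed")
  }
  i
}

#' Edit metadata or genotypes of an unlocked record
#'
#' @param store An [fp_store()].
#' @param record_id Record to modify.
#' @param name,synonyms New metadata (optional).
#' @param genotypes Optional replacement genotype tibble (`marker_id`,
#'   `allele_low`, `allele_high`).
#' @return The store, invisibly. Errors if the record is LOCKED.
#' @export
update_record <- function(store, record_id, name = NULL, synonyms = NULL,
                          genotypes = NULL) {
  i <- assert_unlocked(store, record_id)
  if (!is.null(name)) store$records$name[i] <- name
  if (!is.null(synonyms)) store$records$synonyms[i] <- synonyms
  if (!is.null(genotypes)) {
    keep <- store$genotypes$record_id != record_id
    store$genotypes <- dplyr::bind_rows(
      store$genotypes[keep, ],
      tibble::tibble(record_id = record_id,
                     genotypes[c("marker_id", "allele_low", "allele_high")])
    )
  }
  invisible(store)
}

#' Trace a record back to its sources
#'
#' Expands the provenance chain LFD -> SFD -> EFD -> (plate wells, image
#' paths) as a nested tree.
#'
#' @param store An [fp_store()].
#' @param record_id Any record id.
#' @return A list of class `fp_trace`: `record_id`, `tier`, `entity_id`,
#'   `wells`, `images`, `sources` (list of child traces). Leaf count of an
#'   LFD trace equals the number of contributing experiments.
#' @export
trace <- function(store, record_id) {
  i <- match(record_id, store$records$record_id)
  if (is.na(i)) stop("record not found: ", record_id)
  rec <- store$records[i, ]
  src_ids <- strsplit(rec$provenance, ";")[[1]]
  src_ids <- src_ids[nzchar(src_ids)]
  node <- list(
    record_id = rec$record_id, tier = rec$tier, entity_id = rec$entity_id,
    state = rec$state,
    images = store$image_refs[store$image_refs$record_id == rec$record_id, ],
    wells = store$wells[store$wells$sample_id == rec$entity_id |
                          store$wells$dna_id == rec$entity_id, ],
    sources = lapply(src_ids, function(s) trace(store, s))
  )
  class(node) <- "fp_trace"
  node
}

#' Count the experiment-level leaves of a trace
#' @param x An `fp_trace`.
#' @return Integer leaf count.
#' @export
trace_leaves <- function(x) {
  stopifnot(inherits(x, "fp_trace"))
  if (length(x$sources) == 0) return(1L)
  sum(vapply(x$sources, trace_leaves, integer(1)))
}

#' @export
print.fp_trace <- function(x, ..., indent = 0) {
  cat(strrep("  ", indent), x$tier, " ", x$record_id, " (", x$entity_id, ", ",
      x$state, ")\n", sep = "")
  for (s in x$sources) print(s, indent = indent + 1)
  invisible(x)
}

#' Persist a store to a directory of CSV tables
#'
#' Tables (records, SITs, wells, image refs, panel) are written as CSV;
#' fingerprint payloads go to one sidecar CSV per record under
#' `fingerprints/`, indexed by path in `fingerprint_files.csv` — payloads are
#' never stored inline in the record table.
#'
#' @param store An [fp_store()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
store_save <- function(store, dir) {
  dir.create(file.path(dir, "fingerprints"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(store$records, file.path(dir, "records.csv"), na = "")
  readr::write_csv(as.data.frame(store$panel), file.path(dir, "panel.csv"))
  readr::write_csv(store$sits, file.path(dir, "sits.csv"))
  readr::write_csv(store$sit_rows, file.path(dir, "sit_rows.csv"))
  readr::write_csv(store$wells, file.path(dir, "wells.csv"))
  readr::write_csv(store$image_refs, file.path(dir, "image_refs.csv"))
  readr::write_csv(store$reselects, file.path(dir, "reselects.csv"))
  idx <- tibble::tibble(record_id = unique(store$genotypes$record_id))
  idx$path <- file.path("fingerprints", paste0(idx$record_id, ".csv"))
  for (r in seq_len(nrow(idx))) {
    g <- store$genotypes[store$genotypes$record_id == idx$record_id[r],
                         c("marker_id", "allele_low", "allele_high")]
    readr::write_csv(g, file.path(dir, idx$path[r]), na = "")
  }
  readr::write_csv(idx, file.path(dir, "fingerprint_files.csv"))
  jsonlite::write_json(list(counter = store$counter), file.path(dir, "meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Load a store saved by [store_save()]
#'
#' @param dir Directory written by [store_save()].
#' @return An [fp_store()].
#' @export
store_load <- function(dir) {
  panel <- ssr_panel(readr::read_csv(file.path(dir, "panel.csv"),
                                     show_col_types = FALSE))
  s <- fp_store(panel)
  chr <- function(x) as.character(x)
  rec <- readr::read_csv(file.path(dir, "records.csv"), na = character(),
                         col_types = readr::cols(.default = readr::col_character()))
  rec[rec == ""] <- NA
  rec$synonyms[is.na(rec$synonyms)] <- ""
  rec$provenance[is.na(rec$provenance)] <- ""
  s$records <- rec
  s$sits <- readr::read_csv(file.path(dir, "sits.csv"), show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
  s$sit_rows <- readr::read_csv(file.path(dir, "sit_rows.csv"), show_col_types = FALSE,
                                col_types = readr::cols(.default = readr::col_character()))
  s$wells <- readr::read_csv(file.path(dir, "wells.csv"), show_col_types = FALSE,
                             col_types = readr::cols(.default = readr::col_character()))
  s$image_refs <- readr::read_csv(file.path(dir, "image_refs.csv"), show_col_types = FALSE,
                                  col_types = readr::cols(.default = readr::col_character()))
  s$reselects <- readr::read_csv(
    file.path(dir, "reselects.csv"), show_col_types = FALSE,
    col_types = readr::cols(sit_id = "c", sample_id = "c", marker_id = "c",
                            allele_low = "d", allele_high = "d", force = "l")
  )
  idx <- readr::read_csv(file.path(dir, "fingerprint_files.csv"), show_col_types = FALSE)
  gl <- lapply(seq_len(nrow(idx)), function(r) {
    g <- readr::read_csv(file.path(dir, idx$path[r]), na = "",
                         col_types = readr::cols(marker_id = "c", allele_low = "d",
                                                 allele_high = "d"))
    tibble::tibble(record_id = chr(idx$record_id[r]), g)
  })
  if (length(gl) > 0) s$genotypes <- dplyr::bind_rows(gl)
  s$counter <- as.integer(jsonlite::read_json(file.path(dir, "meta.json"))$counter)
  s
}

#' Register plate wells with the store
#'
#' @param store An [fp_store()].
#' @param layout Plate layout tibble from [design_plates()].
#' @return The store, invisibly.
#' @export
store_add_wells <- function(store, layout) {
  if (any(layout$plate_barcode %in% store$wells$plate_barcode)) {
    stop("plate barcode(s) already registered; barcodes must be unique")
  }
  store$wells <- dplyr::bind_rows(
    store$wells,
    layout[c("plate_barcode", "well", "sample_id", "dna_id", "panel_id", "role")]
  )
  invisible(store)
}

#' Verify referential integrity of a store
#'
#' Checks that every SFD record's provenance points to existing EFD records,
#' every LFD record's to existing SFD records, every genotype payload to an
#' existing record, and every genotype to a panel marker.
#'
#' @param store An [fp_store()].
#' @return Tibble of violations (zero rows when sound).
#' @export
store_check <- function(store) {
  v <- list()
  r <- store$records
  for (i in seq_len(nrow(r))) {
    src <- strsplit(r$provenance[i], ";")[[1]]
    src <- src[nzchar(src)]
    want <- switch(r$tier[i], EFD = character(0), SFD = "EFD", LFD = "SFD")
    if (r$tier[i] != "EFD") {
      if (length(src) == 0) {
        v[[length(v) + 1]] <- tibble::tibble(
          record_id = r$record_id[i], problem = "non-EFD record without provenance")
      }
      bad <- src[!(src %in% r$record_id[r$tier == want])]
      if (length(bad) > 0) {
        v[[length(v) + 1]] <- tibble::tibble(
          record_id = r$record_id[i],
          problem = paste("dangling provenance:", paste(bad, collapse = ",")))
      }
    }
  }
  orphan <- setdiff(unique(store$genotypes$record_id), r$record_id)
  if (length(orphan) > 0) {
    v[[length(v) + 1]] <- tibble::tibble(
      record_id = orphan, problem = "genotype payload without record")
  }
  badmk <- setdiff(unique(store$genotypes$marker_id), store$panel$marker_id)
  if (length(badmk) > 0) {
    v[[length(v) + 1]] <- tibble::tibble(
      record_id = NA_character_,
      problem = paste("genotype marker not in panel:", paste(badmk, collapse = ",")))
  }
  if (length(v) == 0) tibble::tibble(record_id = character(), problem = character())
  else dplyr::bind_rows(v)
}
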