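#' Genotype table dialect
#'
#' Column mapping for tabular genotype files. The canonical dialect is the
#' GeneMapper genotypes-table style: a header row with columns
#' `Sample Name`, `Marker`, `Allele 1`, `Allele 2`, one row per sample x
#' marker, blank allele cells for missing loci.
#'
#' @param sample_col,marker_col,allele1_col,allele2_col Column names.
#' @param header Whether the file carries a header row.
#' @return List of class `genotype_dialect`.
#' @export
genotype_dialect <- function(sample_col = "Sample Name", marker_col = "Marker",
                             allele1_col = "Allele 1", allele2_col = "Allele 2",
                             header = TRUE) {
  structure(list(sample_col = sample_col, marker_col = marker_col,
                 allele1_col = allele1_col, allele2_col = allele2_col,
                 header = isTRUE(header)),
            class = "genotype_dialect")
}

read_table_any <- function(file, header = TRUE) {
  if (grepl("\\.xlsx?$", file, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package; supply CSV instead")
    }
    tibble::as_tibble(readxl::read_excel(file, col_names = header))
  } else {
    readr::read_csv(file, col_names = header, show_col_types = FALSE,
                    na = c("", "NA"))
  }
}

#' Read a genotype table into fingerprints
#'
#' One fingerprint per sample id over the declared panel. Rows with both
#' allele cells blank become missing loci; markers absent for a sample are
#' filled missing against the panel. A row with exactly one allele is
#' rejected (a half call is not a diploid genotype) unless
#' `duplicate_single = TRUE`, which duplicates the single call to a
#' homozygote.
#'
#' @param file CSV path (or XLSX when readxl is installed).
#' @param panel An [ssr_panel()].
#' @param dialect A [genotype_dialect()].
#' @param duplicate_single Treat one-allele rows as homozygotes (default off).
#' @return Fingerprint tibble covering the full panel per sample.
#' @export
read_genotype_table <- function(file, panel, dialect = genotype_dialect(),
                                duplicate_single = FALSE) {
  raw <- read_table_any(file, header = dialect$header)
  if (!dialect$header) {
    names(raw)[1:4] <- c(dialect$sample_col, dialect$marker_col,
                         dialect$allele1_col, dialect$allele2_col)
  }
  need <- c(dialect$sample_col, dialect$marker_col,
            dialect$allele1_col, dialect$allele2_col)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("genotype table is missing columns: ", paste(miss, collapse = ", "))
  }
  tbl <- tibble::tibble(
    entity_id = as.character(raw[[dialect$sample_col]]),
    marker_id = as.character(raw[[dialect$marker_col]]),
    a1 = as.numeric(raw[[dialect$allele1_col]]),
    a2 = as.numeric(raw[[dialect$allele2_col]])
  )
  unknown <- which(!(tbl$marker_id %in% panel$marker_id))
  if (length(unknown) > 0) {
    stop("rows with markers not in the panel: ",
         paste(utils::head(unknown, 20), collapse = ", "),
         " (markers ", paste(unique(tbl$marker_id[unknown]), collapse = ", "), ")")
  }
  half <- which(xor(is.na(tbl$a1), is.na(tbl$a2)))
  if (length(half) > 0) {
    if (duplicate_single) {
      one <- ifelse(is.na(tbl$a1[half]), tbl$a2[half], tbl$a1[half])
      tbl$a1[half] <- one
      tbl$a2[half] <- one
    } else {
      stop("rows with exactly one allele call (half calls): ",
           paste(utils::head(half, 20), collapse = ", "),
           "; re-import with duplicate_single = TRUE to treat them as homozygotes")
    }
  }
  tbl$allele_low <- pmin(tbl$a1, tbl$a2)
  tbl$allele_high <- pmax(tbl$a1, tbl$a2)
  out <- purrr::map_dfr(unique(tbl$entity_id), function(eid) {
    fingerprint(eid, tbl[tbl$entity_id == eid,
                         c("marker_id", "allele_low", "allele_high")],
                panel)
  })
  dplyr::select(out, "entity_id", "marker_id", "allele_low", "allele_high")
}

#' Write fingerprints as a genotype table
#'
#' Deterministic row order (sample, then panel marker order); missing loci are
#' written as blank allele cells, homozygotes as equal values in both allele
#' columns. Round-trips with [read_genotype_table()].
#'
#' @param fps Fingerprint tibble (shared panel).
#' @param file Output CSV path.
#' @param panel Optional [ssr_panel()] fixing the marker order (defaults to
#'   sorted marker ids).
#' @param dialect A [genotype_dialect()].
#' @return `file`, invisibly.
#' @export
write_genotype_table <- function(fps, file, panel = NULL,
                                 dialect = genotype_dialect()) {
  marker_order <- if (is.null(panel)) sort(unique(fps$marker_id)) else panel$marker_id
  fps <- fps[order(fps$entity_id, match(fps$marker_id, marker_order)), ]
  out <- tibble::tibble(fps$entity_id, fps$marker_id, fps$allele_low, fps$allele_high)
  names(out) <- c(dialect$sample_col, dialect$marker_col,
                  dialect$allele1_col, dialect$allele2_col)
  readr::write_csv(out, file, na = "")
  invisible(file)
}

#' Read a sample information table (SIT)
#'
#' The SIT declares the replicate hierarchy: which samples an experimenter is
#' responsible for, their DNA extractions and experiment runs. Multiple DNA
#' ids extracted by one experimenter from a single plant are collapsed to one
#' DNA node (they are repeats of the same extraction, whatever their labels),
#' which requires an optional `plant_id` column.
#'
#' @param file CSV path (or XLSX) with columns `sample_id`, `variety` (or
#'   `variety_id`), `experimenter_id`, `dna_id`, `experiment_id`, and
#'   optionally `plant_id`.
#' @return SIT tibble with columns `variety_id`, `sample_id`,
#'   `experimenter_id`, `dna_id`, `experiment_id`.
#' @export
read_sit <- function(file) {
  raw <- read_table_any(file)
  if ("variety" %in% names(raw) && !"variety_id" %in% names(raw)) {
    raw <- dplyr::rename(raw, variety_id = "variety")
  }
  need <- c("variety_id", "sample_id", "experimenter_id", "dna_id", "experiment_id")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("SIT is missing required columns: ", paste(miss, collapse = ", "))
  }
  sit <- dplyr::mutate(raw, dplyr::across(dplyr::all_of(need), as.character))
  if (anyDuplicated(sit$experiment_id)) {
    stop("duplicate experiment ids in SIT: ",
         paste(unique(sit$experiment_id[duplicated(sit$experiment_id)]),
               collapse = ", "))
  }
  if ("plant_id" %in% names(sit)) {
    sit <- sit |>
      dplyr::group_by(.data$sample_id, .data$experimenter_id, .data$plant_id) |>
      dplyr::mutate(dna_id = dplyr::first(.data$dna_id)) |>
      dplyr::ungroup()
  }
  dplyr::select(sit, dplyr::all_of(need))
}

#' Write a SIT
#'
#' @param sit SIT tibble.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_sit <- function(sit, file) {
  readr::write_csv(sit, file)
  invisible(file)
}

well_names <- function() {
  paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
}

#' Design 96-well electrophoresis plates
#'
#' Deterministic automatic plate layout: wells are filled row-major (A1, A2,
#' ..., A12, B1, ...), the first `refs_per_plate` wells of every plate are
#' reserved for reference samples, jobs follow in input order, and remaining
#' wells are blank. The number of plates is
#' `ceiling(nrow(jobs) / (96 - refs_per_plate))`.
#'
#' @param jobs Tibble with columns `sample_id`, `dna_id` and optionally
#'   `panel_id`.
#' @param refs_per_plate Reference wells per plate (>= 0, < 96).
#' @param barcode_prefix Prefix of the generated unique plate barcodes.
#' @return Layout tibble: `plate_barcode`, `well`, `sample_id`, `dna_id`,
#'   `panel_id`, `role` (`"SAMPLE"`, `"REFERENCE"`, `"BLANK"`); 96 rows per
#'   plate, no well double-booked.
#' @export
design_plates <- function(jobs, refs_per_plate = 0L, barcode_prefix = "PLT") {
  if (nrow(jobs) == 0) stop("no jobs to place")
  if (refs_per_plate >= 96) stop("refs_per_plate must be < 96")
  stopifnot(all(c("sample_id", "dna_id") %in% names(jobs)))
  if (!"panel_id" %in% names(jobs)) jobs$panel_id <- "P1"
  usable <- 96L - as.integer(refs_per_plate)
  n_plates <- ceiling(nrow(jobs) / usable)
  wells <- well_names()
  layout <- purrr::map_dfr(seq_len(n_plates), function(pl) {
    chunk <- jobs[(pl - 1L) * usable + seq_len(usable), ]
    chunk <- chunk[!is.na(chunk$sample_id), , drop = FALSE]
    roles <- c(rep("REFERENCE", refs_per_plate),
               rep("SAMPLE", nrow(chunk)),
               rep("BLANK", 96L - refs_per_plate - nrow(chunk)))
    tibble::tibble(
      plate_barcode = sprintf("%s-%04d", barcode_prefix, pl),
      well = wells,
      sample_id = c(rep(NA_character_, refs_per_plate), chunk$sample_id,
                    rep(NA_character_, 96L - refs_per_plate - nrow(chunk))),
      dna_id = c(rep(NA_character_, refs_per_plate), chunk$dna_id,
                 rep(NA_character_, 96L - refs_per_plate - nrow(chunk))),
      panel_id = c(rep(NA_character_, refs_per_plate), chunk$panel_id,
                   rep(NA_character_, 96L - refs_per_plate - nrow(chunk))),
      role = roles
    )
  })
  class(layout) <- c("ssr_plate_layout", class(layout))
  layout
}

#' Write a printable plate layout table
#'
#' @param layout Output of [design_plates()].
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_plate_layout <- function(layout, file) {
  readr::write_csv(layout, file, na = "")
  invisible(file)
}
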