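# Readers/writers and validators for the tabular formats shared by all
# analysis stages. Matrices travel as tibbles: first column "cpg_id", one
# column per sample. All categorical labels are normalised to
# lower_snake_case at read time; values are validated, never silently coerced.

validate_value_matrix <- function(tbl, what = c("beta", "detection_p", "m")) {
  what <- match.arg(what)
  if (!"cpg_id" %in% names(tbl)) abort("first column must be `cpg_id`")
  ids <- as.character(tbl$cpg_id)
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "duplicated cpg_id: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  samples <- setdiff(names(tbl), "cpg_id")
  if (anyDuplicated(samples)) abort("duplicated sample ids in header")
  m <- meth_matrix(tbl)
  if (what %in% c("beta", "detection_p")) {
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      abort(sprintf(
        "%s value out of [0,1] at CpG %s, sample %s (value %g)",
        what, rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
        m[bad[1, , drop = FALSE]]
      ))
    }
  }
  tibble::as_tibble(tbl)
}

#' Read a CpG-by-sample beta-value matrix
#'
#' Expects a delimited file whose first column (`cpg_id`) holds unique CpG
#' identifiers and whose header names the samples. Beta values are the
#' methylated-signal fraction and must lie in `[0, 1]`; empty cells are read
#' as missing and kept missing (never zero-filled).
#'
#' @param path Path to a CSV or TSV file.
#' @param dialect `"csv"` or `"tsv"`; guessed from the file extension by
#'   default.
#' @return A validated beta tibble (`cpg_id` + one numeric column per sample).
#' @export
read_beta_matrix <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  tbl <- reader(path, show_col_types = FALSE, progress = FALSE,
                na = c("", "NA", "NaN"))
  names(tbl)[1] <- "cpg_id"
  tbl$cpg_id <- as.character(tbl$cpg_id)
  validate_value_matrix(tbl, "beta")
}

#' Read a detection p-value matrix
#'
#' Same layout as [read_beta_matrix()]; values are per-probe detection
#' p-values in `[0, 1]` (high = failed measurement).
#'
#' @inheritParams read_beta_matrix
#' @return A validated detection-p tibble.
#' @export
read_detection_p <- function(path, dialect = c("auto", "csv", "tsv")) {
  tbl <- read_beta_matrix(path, dialect)
  validate_value_matrix(tbl, "detection_p")
}

sheet_required_cols <- c("sample_id", "patient_id", "timepoint",
                         "survival_group", "survival_time", "event")

#' Validate a sample sheet tibble
#'
#' Checks the invariants of the clinical sample sheet: unique sample ids, at
#' most one pre and one post sample per patient, known categorical levels,
#' nonnegative survival time, event in \{0, 1\}. Labels are normalised to
#' lower_snake_case and a logical `paired` column is added.
#'
#' @param sheet A data frame with at least the columns `sample_id`,
#'   `patient_id`, `timepoint` (pre/post), `survival_group`
#'   (survivor/non_survivor), `survival_time` (years) and `event` (0/1).
#'   Optional columns (`response`, `treatment`, `subtype`, `tumor_stage`, ...)
#'   are carried through.
#' @return The validated sample sheet as a tibble.
#' @export
validate_sample_sheet <- function(sheet) {
  sheet <- tibble::as_tibble(sheet)
  missing_cols <- setdiff(sheet_required_cols, names(sheet))
  if (length(missing_cols) > 0L) {
    abort(paste0("sample sheet is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$patient_id <- as.character(sheet$patient_id)
  for (col in intersect(c("timepoint", "survival_group", "response",
                          "treatment", "subtype", "tumor_stage"),
                        names(sheet))) {
    sheet[[col]] <- normalize_label(sheet[[col]])
  }
  if (anyDuplicated(sheet$sample_id)) abort("duplicated sample_id in sheet")
  bad_tp <- setdiff(unique(sheet$timepoint), c("pre", "post"))
  if (length(bad_tp) > 0L) {
    abort(paste0("unknown timepoint label: ", paste(bad_tp, collapse = ", ")))
  }
  bad_grp <- setdiff(unique(sheet$survival_group), c("survivor", "non_survivor"))
  if (length(bad_grp) > 0L) {
    abort(paste0("unknown survival_group label: ", paste(bad_grp, collapse = ", ")))
  }
  if (!all(sheet$event %in% c(0, 1))) abort("event must be 0 or 1")
  if (any(is.na(sheet$survival_time)) || any(sheet$survival_time < 0)) {
    abort("survival_time must be >= 0")
  }
  dup <- sheet |>
    dplyr::count(.data$patient_id, .data$timepoint) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("patient %s has %d '%s' samples (at most one allowed)",
                  dup$patient_id[1], dup$n[1], dup$timepoint[1]))
  }
  n_tp <- sheet |>
    dplyr::count(.data$patient_id) |>
    dplyr::rename(n_samples = "n")
  sheet |>
    dplyr::left_join(n_tp, by = "patient_id") |>
    dplyr::mutate(paired = .data$n_samples == 2L) |>
    dplyr::select(-"n_samples")
}

#' Read the clinical sample sheet
#'
#' @param path Path to a CSV file with the columns described in
#'   [validate_sample_sheet()].
#' @return A validated sample sheet tibble with a `paired` flag.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
}

#' Patient pairing index
#'
#' One row per patient with the pre and post sample ids (NA when absent).
#'
#' @param sheet A validated sample sheet.
#' @return A tibble with `patient_id`, `pre`, `post`, `paired`.
#' @export
pairing_index <- function(sheet) {
  wide <- sheet |>
    dplyr::select("patient_id", "timepoint", "sample_id") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "sample_id")
  for (col in c("pre", "post")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_character_
  }
  wide |>
    dplyr::mutate(paired = !is.na(.data$pre) & !is.na(.data$post)) |>
    dplyr::select("patient_id", "pre", "post", "paired")
}

#' Validate a CpG annotation table
#'
#' @param annot A data frame with columns `cpg_id`, `gene`,
#'   `genomic_context` (promoter / gene_body / intergenic), `island`
#'   (cgi / non_cgi), `probe_type` (I / II) and optional 1-based `chrom`/`pos`.
#' @return The validated annotation tibble.
#' @export
validate_cpg_annotation <- function(annot) {
  annot <- tibble::as_tibble(annot)
  needed <- c("cpg_id", "gene", "genomic_context", "island")
  missing_cols <- setdiff(needed, names(annot))
  if (length(missing_cols) > 0L) {
    abort(paste0("annotation is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"probe_type" %in% names(annot)) {
    warn("annotation has no probe_type column; defaulting all probes to type II")
    annot$probe_type <- "II"
  }
  annot$cpg_id <- as.character(annot$cpg_id)
  if (anyDuplicated(annot$cpg_id)) abort("duplicated cpg_id in annotation")
  annot$gene <- ifelse(is.na(annot$gene), "", as.character(annot$gene))
  annot$genomic_context <- normalize_label(annot$genomic_context)
  island <- normalize_label(annot$island)
  island[island %in% c("cgi", "island")] <- "cgi"
  island[island %in% c("non_cgi", "noncgi", "opensea", "open_sea")] <- "non_cgi"
  bad <- setdiff(unique(island), c("cgi", "non_cgi"))
  if (length(bad) > 0L) {
    abort(paste0("unknown island label: ", paste(bad, collapse = ", ")))
  }
  annot$island <- island
  bad_ctx <- setdiff(unique(annot$genomic_context),
                     c("promoter", "gene_body", "intergenic"))
  if (length(bad_ctx) > 0L) {
    abort(paste0("unknown genomic_context: ", paste(bad_ctx, collapse = ", ")))
  }
  pt <- toupper(trimws(as.character(annot$probe_type)))
  pt[is.na(pt) | pt == ""] <- NA_character_
  if (anyNA(pt)) {
    warn("missing probe_type entries defaulted to type II")
    pt[is.na(pt)] <- "II"
  }
  if (!all(pt %in% c("I", "II"))) abort("probe_type must be 'I' or 'II'")
  annot$probe_type <- pt
  offending <- annot$genomic_context == "intergenic" & annot$gene != ""
  if (any(offending)) {
    abort(sprintf("intergenic CpG %s has a non-empty gene",
                  annot$cpg_id[which(offending)[1]]))
  }
  annot
}

#' Read a CpG annotation table
#'
#' @param path Path to a CSV file (see [validate_cpg_annotation()] for the
#'   required columns).
#' @return A validated annotation tibble.
#' @export
read_cpg_annotation <- function(path) {
  validate_cpg_annotation(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("NA"))
  )
}

#' Read a normal-tissue reference of per-CpG mean beta values
#'
#' @param path CSV with columns `cpg_id`, `mean_beta`.
#' @return A tibble with `cpg_id` and `mean_beta` in `[0, 1]`.
#' @export
read_normal_reference <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("cpg_id", "mean_beta") %in% names(tbl))) {
    abort("normal reference needs columns cpg_id, mean_beta")
  }
  if (any(tbl$mean_beta < 0 | tbl$mean_beta > 1, na.rm = TRUE)) {
    abort("normal reference mean_beta out of [0,1]")
  }
  tbl$cpg_id <- as.character(tbl$cpg_id)
  tibble::as_tibble(tbl[c("cpg_id", "mean_beta")])
}

#' Read gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name`, `description`, genes...
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set`, `description` and a list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) abort(sprintf("GMT line %d has fewer than 3 fields", which(bad)[1]))
  tibble::tibble(
    set = vapply(parts, `[[`, "", 1L),
    description = vapply(parts, `[[`, "", 2L),
    genes = lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  )
}

#' Write gene sets in GMT format
#'
#' @param sets A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set[i], sets$description[i], sets$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table as round-trippable CSV
#'
#' Columns are written in their existing (deterministic) order; numeric
#' values use the shortest lossless decimal representation, and missing
#' values (including NaN p-values) serialise as empty cells.
#'
#' @param records A data frame of homogeneous records (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  records <- tibble::as_tibble(records)
  num <- vapply(records, is.numeric, TRUE)
  records[num] <- lapply(records[num], function(x) ifelse(is.nan(x), NA, x))
  readr::write_csv(records, path, na = "")
  invisible(path)
}
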