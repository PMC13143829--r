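#' Exclude patients with too few quantified cells
#'
#' Removes every patient with fewer than `min_cells` quantified cells in the
#' stromal OR the epithelial compartment (the boundary is inclusive: exactly
#' `min_cells` cells is retained), to ensure a representative quantification
#' of cellular phenotypes.  Cell counts are distinct `cell_id`s per patient
#' and compartment (falling back to rows of the first marker when no
#' `cell_id` column exists).
#'
#' @param cells per-cell long-format table with `patient_id`, `compartment`
#'   and (ideally) `cell_id` columns.
#' @param min_cells minimum cells per compartment, default 100.
#' @return list with `cells` (filtered table), `excluded` (data.frame of
#'   excluded `patient_id`, `n_epithelial`, `n_stromal`) and `counts`
#'   (per-patient counts for all patients).
#' @export
exclude_low_cell_patients <- function(cells, min_cells = 100L) {
  if (nrow(cells) == 0) stop_input("empty cell table", "collmot_input_error")
  stopifnot(all(c("patient_id", "compartment") %in% names(cells)))
  bad_comp <- setdiff(unique(cells$compartment), c("epithelial", "stromal"))
  if (length(bad_comp)) {
    stop_input(paste0("unknown compartment label(s): ",
                      paste(bad_comp, collapse = ", ")), "collmot_schema_error")
  }
  sub <- if ("cell_id" %in% names(cells)) {
    unique(cells[, c("patient_id", "compartment", "cell_id")])
  } else {
    m1 <- cells$marker == cells$marker[1]
    cells[m1, c("patient_id", "compartment")]
  }
  tab <- table(sub$patient_id, sub$compartment)
  ids <- rownames(tab)
  n_epi <- as.integer(tab[, "epithelial"])
  n_str <- as.integer(tab[, "stromal"])
  counts <- data.frame(patient_id = ids, n_epithelial = n_epi,
                       n_stromal = n_str, stringsAsFactors = FALSE)
  keep <- counts$patient_id[n_epi >= min_cells & n_str >= min_cells]
  excluded <- counts[!counts$patient_id %in% keep, , drop = FALSE]
  rownames(excluded) <- NULL
  list(cells = cells[cells$patient_id %in% keep, , drop = FALSE],
       excluded = excluded, counts = counts)
}

#' Aggregate per-cell intensities to per-patient summaries
#'
#' Pools all cells and all cores of a patient, then computes the median
#' stromal extranuclear intensity for each ECM marker and the mean nuclear
#' YAP intensity over tumour-epithelial cells (plus, when present, the mean
#' junctional — extranuclear — beta-catenin of epithelial cells).
#'
#' @param cells filtered per-cell table (see [exclude_low_cell_patients()]).
#' @param ecm_markers marker names scored stromally; default [ECM_MARKERS].
#' @param yap_marker nuclear marker scored in the epithelium, default "YAP".
#' @param bcatenin_marker optional junctional marker, default "bcatenin"
#'   (skipped when absent from the table).
#' @return data.frame with one row per patient: the five ECM medians (columns
#'   named after the markers), `yap_nuclear`, optionally `bcatenin_junctional`,
#'   and cell counts per compartment.
#' @export
patient_aggregate <- function(cells, ecm_markers = ECM_MARKERS,
                              yap_marker = "YAP",
                              bcatenin_marker = "bcatenin") {
  need <- c("patient_id", "compartment", "marker", "nuclear_mean", "extranuclear_mean")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols)) {
    stop_input(paste0("cell table lacks column(s): ",
                      paste(missing_cols, collapse = ", ")), "collmot_schema_error")
  }
  missing_markers <- setdiff(c(ecm_markers, yap_marker), unique(cells$marker))
  if (length(missing_markers)) {
    stop_input(paste0("cell table lacks marker(s): ",
                      paste(missing_markers, collapse = ", ")), "collmot_schema_error")
  }
  ids <- sort(unique(cells$patient_id))
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  stromal <- cells[cells$compartment == "stromal", ]
  epith <- cells[cells$compartment == "epithelial", ]
  for (m in ecm_markers) {
    sm <- stromal[stromal$marker == m, ]
    med <- tapply(sm$extranuclear_mean, sm$patient_id, stats::median)
    out[[m]] <- as.numeric(med[ids])
  }
  ym <- epith[epith$marker == yap_marker, ]
  yap <- tapply(ym$nuclear_mean, ym$patient_id, mean)
  out$yap_nuclear <- as.numeric(yap[ids])
  if (bcatenin_marker %in% unique(cells$marker)) {
    bm <- epith[epith$marker == bcatenin_marker, ]
    bc <- tapply(bm$extranuclear_mean, bm$patient_id, mean)
    out$bcatenin_junctional <- as.numeric(bc[ids])
  }
  cnt <- function(df) {
    s <- if ("cell_id" %in% names(df)) {
      unique(df[, c("patient_id", "cell_id")])
    } else df[df$marker == df$marker[1], "patient_id", drop = FALSE]
    tab <- table(s$patient_id)
    as.integer(tab[ids])
  }
  out$n_stromal <- cnt(stromal)
  out$n_epithelial <- cnt(epith)
  rownames(out) <- NULL
  out
}

#' ECM score (0-5) and ECM-low/high groups
#'
#' For each of the five stromal markers, the across-patient median of the
#' per-patient values defines the dataset threshold; a patient gains one
#' point per marker whose value lies strictly above it.  Ties at the median
#' score no point.  Scores 0-2 are classed ECM-low, 3-5 ECM-high.
#'
#' @param summaries output of [patient_aggregate()] (>= 2 patients).
#' @param ecm_markers marker columns to score; default [ECM_MARKERS].
#' @return `summaries` with added `ecm_score` and `ecm_group` columns.
#' @export
ecm_score <- function(summaries, ecm_markers = ECM_MARKERS) {
  if (nrow(summaries) < 2) {
    stop_input("need at least 2 patients to define dataset medians", "collmot_cohort_error")
  }
  score <- integer(nrow(summaries))
  for (m in ecm_markers) {
    thr <- stats::median(summaries[[m]], na.rm = TRUE)
    score <- score + as.integer(summaries[[m]] > thr)
  }
  summaries$ecm_score <- score
  summaries$ecm_group <- ifelse(score <= 2, "low", "high")
  summaries
}

#' YAP-high/low grouping at the dataset median
#'
#' Patients whose mean nuclear YAP in the tumour epithelium lies strictly
#' above the across-patient median are YAP-high; all others (including exact
#' ties) are YAP-low.
#'
#' @param summaries output of [patient_aggregate()] (>= 2 patients).
#' @param yap_column column holding the per-patient YAP value.
#' @return `summaries` with an added `yap_group` column.
#' @export
yap_group <- function(summaries, yap_column = "yap_nuclear") {
  if (nrow(summaries) < 2) {
    stop_input("need at least 2 patients to define the dataset median", "collmot_cohort_error")
  }
  thr <- stats::median(summaries[[yap_column]], na.rm = TRUE)
  summaries$yap_group <- ifelse(summaries[[yap_column]] > thr, "high", "low")
  summaries
}

#' Score a cell table end to end
#'
#' Applies the cell-count exclusion, patient aggregation, ECM scoring and
#' YAP grouping, and (when a survival table is given) joins the survival
#' records to the scored cohort.
#'
#' @param cells per-cell long-format table.
#' @param survival optional data.frame with `patient_id`, `time_months`,
#'   `event`.
#' @param min_cells exclusion threshold, default 100.
#' @return list with `cohort` (scored per-patient table), `excluded`, and
#'   `survival` (scored survival records, if provided).
#' @export
score_cohort <- function(cells, survival = NULL, min_cells = 100L) {
  filt <- exclude_low_cell_patients(cells, min_cells = min_cells)
  summaries <- patient_aggregate(filt$cells)
  cohort <- yap_group(ecm_score(summaries))
  out <- list(cohort = cohort, excluded = filt$excluded)
  if (!is.null(survival)) {
    sv <- merge(survival, cohort[, c("patient_id", "ecm_score", "ecm_group", "yap_group")],
                by = "patient_id")
    out$survival <- sv
  }
  out
}
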