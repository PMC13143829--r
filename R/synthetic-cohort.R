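#' Stromal ECM marker panel used for the 0-5 ECM score
#'
#' Fibronectin, collagen I, SMA, laminin and vinculin, scored from stromal
#' extranuclear intensities.
#' @export
ECM_MARKERS <- c("fibronectin", "collagen1", "SMA", "laminin", "vinculin")

#' Specification for a synthetic tissue-microarray cohort
#'
#' Defines a cohort of patients with multiplexed per-cell marker intensities
#' and survival follow-up, with known ground truth: which patients are
#' above-median for each stromal ECM marker (hence their true ECM score),
#' which are YAP-high, and which fall below the 100-cell quantification
#' threshold.  Defaults mirror the cohort the scoring pipeline is aimed at:
#' 198 patients of whom 5 fail the cell-count rule.
#'
#' Marker intensities are drawn lognormally around well-separated per-group
#' levels, so patient-level medians of "high" and "low" patients form two
#' clusters with the dataset median falling in the gap between them; the
#' assigned groups are therefore recoverable exactly, which is what makes the
#' cohort usable as a scoring oracle.
#'
#' @param n_patients number of patients (>= 2).
#' @param n_low_cell number of patients forced below the 100-cell threshold
#'   in their stromal compartment.
#' @param cells_per_compartment typical cell count per patient and
#'   compartment (lognormal location).
#' @param hazard_ratio hazard ratio of ECM-high (true score >= 3) relative to
#'   ECM-low patients; must be positive.
#' @param censoring_rate probability that a patient's follow-up is censored
#'   before the event, in \[0, 1\].
#' @param baseline_median_months median disease-specific survival of the
#'   ECM-low group, months.
#' @param marker_correlation correlation of the latent propensities that make
#'   a patient high for several ECM markers at once (spreads scores over 0-5).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 198L, n_low_cell = 5L,
                        cells_per_compartment = 250,
                        hazard_ratio = 2, censoring_rate = 0.3,
                        baseline_median_months = 60,
                        marker_correlation = 0.8, seed = 1L) {
  if (n_patients < 2) stop_input("n_patients must be >= 2", "collmot_parameter_error")
  if (hazard_ratio <= 0) stop_input("hazard_ratio must be > 0", "collmot_parameter_error")
  if (censoring_rate < 0 || censoring_rate > 1) {
    stop_input("censoring_rate must be in [0, 1]", "collmot_parameter_error")
  }
  if (n_low_cell < 0 || n_low_cell > n_patients) {
    stop_input("n_low_cell must be in [0, n_patients]", "collmot_parameter_error")
  }
  structure(
    list(n_patients = as.integer(n_patients), n_low_cell = as.integer(n_low_cell),
         cells_per_compartment = cells_per_compartment,
         hazard_ratio = hazard_ratio, censoring_rate = censoring_rate,
         baseline_median_months = baseline_median_months,
         marker_correlation = marker_correlation, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic multiplexed TMA cohort with known ground truth
#'
#' Produces a per-cell long-format table (one row per cell and marker, with
#' nuclear and extranuclear mean intensities), a patient-level survival
#' table, and the generator's ground truth.  Stromal ECM marker levels and
#' epithelial nuclear YAP are bimodal across patients; survival times are
#' exponential with the hazard of true ECM-high patients scaled by the
#' specified ratio.
#'
#' @param spec a [cohort_spec()].
#' @return list with `cells` (data.frame: patient_id, core_id, cell_id,
#'   compartment, marker, nuclear_mean, extranuclear_mean), `survival`
#'   (data.frame: patient_id, time_months, event, t_status) and `truth`
#'   (data.frame: patient_id, per-marker high flags, true_score,
#'   true_ecm_group, true_yap_group, low_cell).
#' @export
make_tma_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  with_seed(spec$seed, {
    ids <- sprintf("P%03d", seq_len(n))

    low_cell_ids <- sample(ids, spec$n_low_cell)
    passing <- !(ids %in% low_cell_ids)

    # latent ECM propensity shared across markers; per-marker high flags are
    # rank-based so exactly half of the patients PASSING the cell-count
    # filter are high for every marker — the scoring medians are computed on
    # the filtered cohort, so this pins each dataset median into the gap
    # between the two intensity levels and makes the truth recoverable
    rho <- spec$marker_correlation
    u <- stats::rnorm(n)
    split_half <- function(z) {
      out <- z > stats::median(z[passing])
      # with an odd passing count the cohort median sits on a low-cluster
      # patient, so the strictly-above rule still recovers every flag
      out[passing] <- rank(z[passing]) > ceiling(sum(passing) / 2)
      out
    }
    high <- sapply(ECM_MARKERS, function(m) {
      split_half(rho * u + sqrt(1 - rho^2) * stats::rnorm(n))
    })
    yap_high <- split_half(stats::rnorm(n))
    true_score <- rowSums(high)
    ecm_high <- true_score >= 3

    n_strom <- pmax(120L, as.integer(round(stats::rlnorm(
      n, log(spec$cells_per_compartment), 0.35))))
    n_epi <- pmax(120L, as.integer(round(stats::rlnorm(
      n, log(spec$cells_per_compartment), 0.35))))
    n_strom[ids %in% low_cell_ids] <- sample(30:99, spec$n_low_cell, replace = TRUE)

    cells <- rbind(
      data.frame(
        patient_id = rep(ids, n_strom),
        compartment = "stromal",
        stringsAsFactors = FALSE
      ),
      data.frame(
        patient_id = rep(ids, n_epi),
        compartment = "epithelial",
        stringsAsFactors = FALSE
      )
    )
    n_cells <- nrow(cells)
    cells$core_id <- paste0(cells$patient_id, "_c", sample(1:2, n_cells, replace = TRUE))
    cells$cell_id <- sprintf("cell%06d", seq_len(n_cells))

    pat_idx <- match(cells$patient_id, ids)
    stromal <- cells$compartment == "stromal"

    # one block of rows per marker; only the scoring-relevant channel of the
    # scoring-relevant compartment carries the patient's high/low signal
    marker_blocks <- lapply(c(ECM_MARKERS, "YAP"), function(m) {
      blk <- cells
      blk$marker <- m
      blk$nuclear_mean <- stats::rlnorm(n_cells, log(0.8), 0.3)
      blk$extranuclear_mean <- stats::rlnorm(n_cells, log(0.8), 0.3)
      if (m == "YAP") {
        sel <- !stromal
        lvl <- ifelse(yap_high[pat_idx[sel]], log(3), log(1))
        blk$nuclear_mean[sel] <- stats::rlnorm(sum(sel), lvl, 0.2)
      } else {
        sel <- stromal
        lvl <- ifelse(high[pat_idx[sel], m], log(3), log(1))
        blk$extranuclear_mean[sel] <- stats::rlnorm(sum(sel), lvl, 0.2)
      }
      blk
    })
    cells_long <- do.call(rbind, marker_blocks)
    cells_long <- cells_long[, c("patient_id", "core_id", "cell_id",
                                 "compartment", "marker",
                                 "nuclear_mean", "extranuclear_mean")]
    rownames(cells_long) <- NULL

    surv <- simulate_survival(
      n, group = ifelse(ecm_high, "high", "low"),
      hazard_ratio = spec$hazard_ratio,
      baseline_median_months = spec$baseline_median_months,
      censoring_rate = spec$censoring_rate,
      seed = spec$seed + 1L
    )
    surv$patient_id <- ids
    surv$t_status <- sample(paste0("T", 1:4), n, replace = TRUE)
    surv <- surv[, c("patient_id", "time_months", "event", "t_status")]

    truth <- data.frame(patient_id = ids, high, yap_high = yap_high,
                        true_score = true_score,
                        true_ecm_group = ifelse(ecm_high, "high", "low"),
                        true_yap_group = ifelse(yap_high, "high", "low"),
                        low_cell = ids %in% low_cell_ids,
                        stringsAsFactors = FALSE)
    list(cells = cells_long, survival = surv, truth = truth)
  })
}

#' Simulate exponential survival with a two-group hazard ratio
#'
#' Event times are exponential with the ECM-low (reference) median set by
#' `baseline_median_months`; the hazard of the `"high"` group is multiplied
#' by `hazard_ratio`.  With probability `censoring_rate` a record is censored
#' uniformly before its event time.
#'
#' @param n number of patients.
#' @param group character vector of `"low"`/`"high"` per patient, or a single
#'   value recycled.
#' @param hazard_ratio hazard multiplier for the `"high"` group (> 0).
#' @param baseline_median_months reference-group median survival, months.
#' @param censoring_rate probability of censoring, in \[0, 1\].
#' @param seed integer seed.
#' @return data.frame with `time_months`, `event` (1 = death observed,
#'   0 = censored) and `group`.
#' @export
simulate_survival <- function(n, group = "low", hazard_ratio = 1,
                              baseline_median_months = 60,
                              censoring_rate = 0.3, seed = 1L) {
  if (hazard_ratio <= 0) stop_input("hazard_ratio must be > 0", "collmot_parameter_error")
  group <- rep_len(as.character(group), n)
  with_seed(seed, {
    rate <- log(2) / baseline_median_months *
      ifelse(group == "high", hazard_ratio, 1)
    t_event <- stats::rexp(n, rate)
    censored <- stats::runif(n) < censoring_rate
    time <- ifelse(censored, stats::runif(n) * t_event, t_event)
    data.frame(time_months = time, event = as.integer(!censored),
               group = group, stringsAsFactors = FALSE)
  })
}
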