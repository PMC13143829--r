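# compact builder for hand-crafted long-format cell tables
make_cells <- function(per_patient) {
  rows <- lapply(names(per_patient), function(pid) {
    p <- per_patient[[pid]]
    do.call(rbind, lapply(names(p), function(key) {
      # key: "<compartment>.<marker>", value: vector of relevant intensities
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      vals <- p[[key]]
      n <- length(vals)
      is_yap <- parts[2] == "YAP"
      data.frame(
        patient_id = pid,
        core_id = paste0(pid, "_c1"),
        cell_id = paste0(pid, "_", parts[1], "_", parts[2], "_", seq_len(n)),
        compartment = parts[1],
        marker = parts[2],
        nuclear_mean = if (is_yap) vals else 0.5,
        extranuclear_mean = if (is_yap) 0.5 else vals,
        stringsAsFactors = FALSE
      )
    }))
  })
  do.call(rbind, rows)
}

test_that("the 100-cell exclusion rule is inclusive at the boundary", {
  cells <- rbind(
    data.frame(patient_id = "A", compartment = "stromal",
               cell_id = paste0("a", 1:99), marker = "fibronectin",
               nuclear_mean = 1, extranuclear_mean = 1),
    data.frame(patient_id = "A", compartment = "epithelial",
               cell_id = paste0("ae", 1:500), marker = "fibronectin",
               nuclear_mean = 1, extranuclear_mean = 1),
    data.frame(patient_id = "B", compartment = "stromal",
               cell_id = paste0("b", 1:100), marker = "fibronectin",
               nuclear_mean = 1, extranuclear_mean = 1),
    data.frame(patient_id = "B", compartment = "epithelial",
               cell_id = paste0("be", 1:100), marker = "fibronectin",
               nuclear_mean = 1, extranuclear_mean = 1)
  )
  out <- exclude_low_cell_patients(cells)
  expect_identical(unique(out$cells$patient_id), "B")
  expect_identical(out$excluded$patient_id, "A")
  expect_equal(out$excluded$n_stromal, 99)
})

test_that("patient aggregation pools cores and uses the stated statistics", {
  cells <- rbind(
    make_cells(list(P1 = list(
      "stromal.fibronectin" = c(1, 2, 9),
      "stromal.collagen1" = 1, "stromal.SMA" = 1, "stromal.laminin" = 1,
      "stromal.vinculin" = 1,
      "epithelial.YAP" = c(10, 20, 30)
    ))),
    make_cells(list(P2 = list(
      "stromal.fibronectin" = c(1, 2, 3, 4),
      "stromal.collagen1" = 2, "stromal.SMA" = 2, "stromal.laminin" = 2,
      "stromal.vinculin" = 2,
      "epithelial.YAP" = c(5, 15)
    )))
  )
  # second core for P2 pooled with the first: {1,2} from c1, {3,4} from c2
  cells$core_id[cells$patient_id == "P2" & cells$marker == "fibronectin" &
                  cells$extranuclear_mean >= 3] <- "P2_c2"
  agg <- patient_aggregate(cells)
  expect_equal(agg$fibronectin[agg$patient_id == "P1"], 2)   # median {1,2,9}
  expect_equal(agg$fibronectin[agg$patient_id == "P2"], 2.5) # median {1,2,3,4}
  expect_equal(agg$yap_nuclear[agg$patient_id == "P1"], 20)  # mean {10,20,30}

  broken <- cells[cells$marker != "SMA", ]
  expect_error(patient_aggregate(broken), class = "collmot_schema_error")
})

test_that("cell-row order never changes patient summaries", {
  spec <- cohort_spec(n_patients = 8, n_low_cell = 0,
                      cells_per_compartment = 130, seed = 3)
  cells <- make_tma_cohort(spec)$cells
  a <- patient_aggregate(cells)
  set.seed(1)
  b <- patient_aggregate(cells[sample(nrow(cells)), ])
  expect_equal(a, b)
})

test_that("ECM scores match exhaustive hand enumeration on a 4-patient table", {
  # per-patient marker levels chosen so medians are unambiguous
  lv <- list(
    P1 = c(fibronectin = 10, collagen1 = 10, SMA = 10, laminin = 10, vinculin = 10),
    P2 = c(fibronectin = 8,  collagen1 = 1,  SMA = 9,  laminin = 1,  vinculin = 9),
    P3 = c(fibronectin = 2,  collagen1 = 9,  SMA = 2,  laminin = 2,  vinculin = 2),
    P4 = c(fibronectin = 1,  collagen1 = 2,  SMA = 1,  laminin = 9,  vinculin = 1)
  )
  cells <- make_cells(lapply(lv, function(v) {
    c(lapply(as.list(v), identity) |>
        stats::setNames(paste0("stromal.", names(v))),
      list("epithelial.YAP" = 1))
  }))
  agg <- patient_aggregate(cells)
  scored <- ecm_score(agg)

  # independent enumeration: count markers strictly above the column median
  hand <- sapply(names(lv), function(p) {
    sum(sapply(names(lv[[p]]), function(m) {
      thr <- median(sapply(lv, `[[`, m))
      lv[[p]][[m]] > thr
    }))
  })
  expect_equal(scored$ecm_score[match(names(lv), scored$patient_id)],
               unname(hand))
  expect_equal(scored$ecm_group, ifelse(scored$ecm_score <= 2, "low", "high"))
  expect_true(all(scored$ecm_score >= 0 & scored$ecm_score <= 5))
})

test_that("a patient below every marker median scores 0 and is ECM-low", {
  spec <- cohort_spec(n_patients = 12, n_low_cell = 0,
                      cells_per_compartment = 130, seed = 21)
  ch <- make_tma_cohort(spec)
  scored <- score_cohort(ch$cells)$cohort
  zero <- ch$truth$patient_id[ch$truth$true_score == 0]
  if (length(zero)) {
    expect_true(all(scored$ecm_score[scored$patient_id %in% zero] == 0))
    expect_true(all(scored$ecm_group[scored$patient_id %in% zero] == "low"))
  }
  expect_setequal(unique(scored$ecm_group[scored$ecm_score >= 3]), "high")
})

test_that("YAP grouping is strictly above the dataset median", {
  agg <- data.frame(patient_id = c("A", "B", "C"),
                    yap_nuclear = c(1, 2, 2))
  out <- yap_group(agg)
  # median is 2: the tie stays low, only values strictly above would be high
  expect_equal(out$yap_group, c("low", "low", "low"))

  two <- yap_group(data.frame(patient_id = c("A", "B"),
                              yap_nuclear = c(1, 3)))
  expect_equal(sort(two$yap_group), c("high", "low"))
})

test_that("Kaplan-Meier matches closed forms without censoring", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival[km$time > 0], c(2/3, 1/3, 0))

  allc <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(allc$survival == 1))

  # with no censoring the estimator is the empirical survivor function
  set.seed(9)
  t <- round(rexp(40, 0.2), 2)
  km2 <- km_estimate(t, rep(1, 40))
  emp <- vapply(km2$time, function(u) mean(t > u), numeric(1))
  expect_equal(km2$survival, emp, tolerance = 1e-12)
})

test_that("Kaplan-Meier matches the hand-computed censored table", {
  time <- c(1, 2, 3, 4, 4, 5, 6, 8, 9, 10)
  event <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  km <- km_estimate(time, event)
  # hand-computed product-limit values at the event times
  expect_equal(km$survival[km$time == 1], 0.9, tolerance = 1e-12)
  expect_equal(km$survival[km$time == 3], 0.9 * 7/8, tolerance = 1e-12)
  expect_equal(km$survival[km$time == 4], 0.9 * 7/8 * 6/7, tolerance = 1e-12)
  expect_equal(km$survival[km$time == 6], 0.9 * 7/8 * 6/7 * 3/4, tolerance = 1e-12)
  expect_equal(km$survival[km$time == 9], 0.9 * 7/8 * 6/7 * 3/4 * 1/2,
               tolerance = 1e-12)
  expect_equal(km_by_hand(time, event)$survival,
               km$survival[km$time > 0], tolerance = 1e-12)
})

test_that("Kaplan-Meier agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(31)
  t <- rexp(60, 0.1)
  e <- rbinom(60, 1, 0.7)
  km <- km_estimate(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  ours <- km$survival[match(sf$time, km$time)]
  expect_equal(ours, sf$surv, tolerance = 1e-12)
})

test_that("log-rank is null on identical groups and matches survdiff", {
  t <- c(1, 3, 5, 7, 9, 2, 4, 6)
  e <- c(1, 1, 0, 1, 1, 1, 0, 1)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 8))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  skip_if_not_installed("survival")
  set.seed(13)
  tt <- rexp(80, rep(c(0.1, 0.25), each = 40))
  ee <- rbinom(80, 1, 0.8)
  gg <- rep(c("a", "b"), each = 40)
  ours <- logrank_test(tt, ee, gg)
  ref <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  expect_equal(ours$statistic, ref$chisq, tolerance = 1e-8)
})

test_that("log-rank input validation", {
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")),
               class = "collmot_input_error")
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")),
               class = "collmot_input_error")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), class = "collmot_input_error")
})

test_that("the scored pipeline joins survival records coherently", {
  spec <- cohort_spec(n_patients = 30, n_low_cell = 2,
                      cells_per_compartment = 130, seed = 5)
  ch <- make_tma_cohort(spec)
  out <- score_cohort(ch$cells, ch$survival)
  expect_equal(nrow(out$cohort), 28)
  expect_equal(nrow(out$survival), 28)
  expect_true(all(out$survival$ecm_group %in% c("low", "high")))
  expect_true(all(table(out$cohort$ecm_group)) > 0)
})
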