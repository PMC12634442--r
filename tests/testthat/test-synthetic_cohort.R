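test_that("cohort generation is reproducible and validates its config", {
  cfg <- cohort_config(n_cases = 30, seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_identical(length(c1), 30L)
  expect_true(all(vapply(c1, function(p) {
    nrow(validate_case_profile(p)) == 0
  }, logical(1))))

  expect_error(cohort_config(subtype_weights = c(who_fusion = 0.5,
                                                 nos = 0.4)),
               "sum to 1")
  expect_error(cohort_config(subtype_weights = c(who_fusion = 0.5,
                                                 mystery = 0.5)),
               "unknown")
})

test_that("subtype draws follow the configured weights", {
  cfg <- cohort_config(
    n_cases = 2000,
    subtype_weights = c(who_fusion = 0.5, who_mutation = 0.5),
    seed = 123
  )
  coh <- generate_cohort(cfg)
  cats <- vapply(coh, function(p) attr(p, "truth")$subtype, character(1))
  p_hat <- mean(cats == "who_fusion")
  sd3 <- 3 * sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(p_hat - 0.5), sd3)
})

test_that("platform observation respects size, clone, and cryptic floors", {
  model <- cytogenetics_model()
  base <- case_profile(
    "obs1",
    cnvs = dplyr::bind_rows(
      cnv_segment("obs1", "5", 100e6, 112e6, "loss", clone_fraction = 0.8),
      cnv_segment("obs1", "5", 120e6, 124e6, "loss", clone_fraction = 0.8),
      cnv_segment("obs1", "7", 1e6, 30e6, "loss", clone_fraction = 0.1)
    )
  )
  obs <- observe_with_platform(base, model, seed = 4)
  # 12 Mb clonal deletion seen; 4 Mb below band resolution and the 10%
  # subclone both invisible
  expect_identical(nrow(obs$cnvs), 1L)
  expect_identical(obs$cnvs$start, 100e6)

  # a fully cryptic fusion is always missed by cytogenetics
  fus_case <- case_profile("obs2",
                           svs = in_frame_fusion("NUP98", "NSD1",
                                                 cid = "obs2"))
  attr(fus_case, "truth") <- list(subtype = "who_fusion",
                                  lesion_label = "NUP98::NSD1")
  for (s in 1:10) {
    expect_identical(nrow(observe_with_platform(fus_case, model,
                                                seed = s)$svs), 0L)
  }
  # and a never-cryptic fusion is always seen
  attr(fus_case, "truth") <- list(subtype = "who_fusion",
                                  lesion_label = "RUNX1::RUNX1T1")
  for (s in 1:10) {
    expect_identical(nrow(observe_with_platform(fus_case, model,
                                                seed = s)$svs), 1L)
  }
})

test_that("WGS read sampling enforces the VAF floor stochastically", {
  model <- wgs_model(depth = 60)
  prof <- case_profile(
    "obs3",
    variants = dplyr::bind_rows(
      somatic_p(c(wgs = 0.45), cid = "obs3"),
      somatic_p(c(wgs = 0.001), gene = "NRAS", cid = "obs3")
    )
  )
  seen_high <- 0
  seen_low <- 0
  for (s in 1:50) {
    obs <- observe_with_platform(prof, model, seed = s)
    seen_high <- seen_high + ("WT1" %in% obs$variants$gene)
    seen_low <- seen_low + ("NRAS" %in% obs$variants$gene)
  }
  expect_equal(seen_high, 50)
  expect_lt(seen_low, 10)
})

test_that("an ideal platform recovers every simulated event", {
  ideal <- platform_model("cytogenetics", min_cnv_bp = 0,
                          min_clone_fraction = 0)
  coh <- generate_cohort(cohort_config(n_cases = 60, seed = 21))
  with_fusion <- Filter(function(p) nrow(p$svs) > 0, coh)
  seen <- vapply(seq_along(with_fusion), function(i) {
    nrow(observe_with_platform(with_fusion[[i]], ideal,
                               seed = 500 + i)$svs) > 0
  }, logical(1))
  truth <- data.frame(
    category = vapply(with_fusion,
                      function(p) attr(p, "truth")$lesion_label,
                      character(1)))
  dt <- detection_table(truth, seen)
  expect_identical(dt$pct_missed_b[dt$category == "Total"], 0)
})

test_that("the dilution series is monotone and errors out of domain", {
  set.seed(8)
  cnvs <- dplyr::bind_rows(lapply(1:40, function(i) {
    cnv_segment(paste0("d", i), "7", 1e5, 60e6, "loss",
                clone_fraction = stats::runif(1, 0.2, 1))
  }))
  tab <- dilution_series(cnvs, c(1.0, 0.4, 0.3))
  expect_true(all(diff(tab$fraction_detected) <= 0))
  full <- dplyr::bind_rows(lapply(1:10, function(i) {
    cnv_segment(paste0("f", i), "7", 1e5, 60e6, "loss", clone_fraction = 1)
  }))
  expect_identical(dilution_series(full, 1.0)$fraction_detected, 1)
  expect_error(dilution_series(cnvs, c(1, 0)), "\\(0, 1\\]")
})
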