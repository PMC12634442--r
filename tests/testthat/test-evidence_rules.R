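cfg <- rule_config()

test_that("somatic small-variant reportability follows the VAF rules", {
  # direct genomic pass
  d <- assess_snv_reportability(somatic_p(c(wgs = 0.06)), cfg)
  expect_identical(d$status, "reportable")
  expect_identical(d$rationale_codes, "VAF_PASS")
  # transcriptome rescue of a sub-threshold AML driver
  d <- assess_snv_reportability(
    somatic_p(c(wgs = 0.03, wts = 0.30), driver = TRUE), cfg)
  expect_identical(d$status, "reportable")
  expect_identical(d$rationale_codes, "WTS_RESCUE")
  # non-driver below threshold never rescued, regardless of WES evidence
  d <- assess_snv_reportability(somatic_p(c(wgs = 0.031, wes = 0.07)), cfg)
  expect_identical(d$status, "not_reportable")
  # the rescue threshold is strict: exactly 25% in WTS fails
  d <- assess_snv_reportability(
    somatic_p(c(wgs = 0.03, wts = 0.25), driver = TRUE), cfg)
  expect_identical(d$status, "not_reportable")
  # boundary: exactly 5% in WGS passes
  d <- assess_snv_reportability(somatic_p(c(wgs = 0.05)), cfg)
  expect_identical(d$status, "reportable")
  # insufficient WGS coverage with a strong driver WTS signal still rescues
  d <- assess_snv_reportability(
    somatic_p(c(wgs = NA, wts = 0.40), driver = TRUE), cfg)
  expect_identical(d$rationale_codes, "WTS_RESCUE")
  # VUS and germline are never reportable here; absent WGS entry errors
  expect_identical(
    assess_snv_reportability(somatic_p(c(wgs = 0.4),
                                       pathogenicity = "VUS"), cfg)$status,
    "not_reportable")
  expect_error(assess_snv_reportability(somatic_p(c(wts = 0.4)), cfg),
               "WGS evidence")
})

test_that("reportability is monotone in WGS VAF", {
  for (driver in c(TRUE, FALSE)) {
    for (wts in c(0, 0.2, 0.5)) {
      statuses <- vapply(seq(0, 1, by = 0.01), function(w) {
        assess_snv_reportability(
          somatic_p(c(wgs = w, wts = wts), driver = driver), cfg)$status
      }, character(1))
      reportable <- statuses == "reportable"
      # once reportable, raising the WGS VAF never un-reports
      expect_true(all(diff(reportable) >= 0))
    }
  }
})

test_that("germline findings filter to P/LP calls in panel genes", {
  gcfg <- rule_config(germline_gene_list = c("TP53", "RUNX1", "GATA2"))
  mk <- function(gene, path) {
    variant_call("G1", gene, "17", 7.6e6, "G", "A", origin = "germline",
                 pathogenicity = path, vaf = c(wgs = 0.5))
  }
  vars <- dplyr::bind_rows(mk("TP53", "P"), mk("TP53", "VUS"),
                           mk("BRCA1", "P"), mk("RUNX1", "LP"))
  out <- filter_germline_findings(vars, gcfg)
  expect_setequal(out$gene, c("TP53", "RUNX1"))
  expect_setequal(out$pathogenicity, c("P", "LP"))
  expect_error(filter_germline_findings(vars, rule_config()),
               "germline_gene_list")
})

test_that("CNV scale classes follow the size thresholds", {
  segs <- dplyr::bind_rows(
    cnv_segment("c", "11", 1e6, 1e6 + 7199, "loss", gene = "CBL"),
    cnv_segment("c", "5", 1e6, 6e6 - 1, "loss"),     # exactly 5 Mb
    cnv_segment("c", "17", 1e6, 10e6 - 1, "cnloh"),  # 9 Mb cnLOH
    cnv_segment("c", "17", 1e6, 11e6, "cnloh"),      # 10 Mb cnLOH
    cnv_segment("c", "8", 1e6, 3e6, "gain")
  )
  out <- classify_cnv_event(segs, cfg)
  expect_identical(out$scale_class,
                   c("focal", "large_scale", "sub_threshold", "large_scale",
                     "focal"))
  expect_identical(out$sub50kb_flag, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("gain/loss events always partition into focal vs large-scale", {
  set.seed(42)
  for (i in 1:50) {
    size <- round(10^stats::runif(1, 2, 8))
    seg <- cnv_segment("c", "1", 1e6, 1e6 + size - 1,
                       kind = sample(c("gain", "loss"), 1))
    out <- classify_cnv_event(seg, cfg)
    expect_true(out$scale_class %in% c("focal", "large_scale"))
  }
})

test_that("the ITD combiner matches the full 16-entry decision oracle", {
  oracle <- tibble::tribble(
    ~wgs,                    ~wts,                    ~status,
    "strong",                "strong",                "reportable",
    "strong",                "weak",                  "reportable",
    "strong",                "none",                  "reportable",
    "strong",                "insufficient_coverage", "reportable",
    "weak",                  "strong",                "borderline",
    "none",                  "strong",                "borderline",
    "insufficient_coverage", "strong",                "borderline",
    "weak",                  "weak",                  "borderline",
    "weak",                  "none",                  "borderline",
    "weak",                  "insufficient_coverage", "borderline",
    "none",                  "weak",                  "borderline",
    "insufficient_coverage", "weak",                  "borderline",
    "none",                  "none",                  "not_reportable",
    "none",                  "insufficient_coverage", "not_reportable",
    "insufficient_coverage", "none",                  "not_reportable",
    "insufficient_coverage", "insufficient_coverage", "not_reportable"
  )
  for (i in seq_len(nrow(oracle))) {
    d <- combine_itd_evidence(itd_evidence("x", wgs_strength = oracle$wgs[i],
                                           wts_strength = oracle$wts[i]))
    expect_identical(d$status, oracle$status[i],
                     label = paste(oracle$wgs[i], oracle$wts[i]))
  }
})

test_that("partial tandem duplication calling needs gain plus junction", {
  gain <- classify_cnv_event(
    cnv_segment("P1", "11", 118.40e6, 118.40e6 + 2e4, "gain",
                gene = "KMT2A"), cfg)
  jx_good <- structural_event("P1", "11", 118.40e6, "11", 118.42e6,
                              geneA = "KMT2A", geneB = "KMT2A",
                              exonA = 8L, exonB = 2L, frame = "in_frame",
                              event_class = "ptd")
  out <- call_kmt2a_ptd(gain, jx_good, cfg = cfg)
  expect_identical(out$status, "reportable")

  out2 <- call_kmt2a_ptd(gain, empty_jx <- jx_good[0, ], cfg = cfg)
  expect_identical(out2$status, "borderline")

  jx_off <- jx_good
  jx_off$exonA <- 5L
  expect_identical(nrow(call_kmt2a_ptd(gain[0, ], jx_off, cfg = cfg)), 0L)
  out3 <- call_kmt2a_ptd(gain, jx_off, cfg = cfg)
  expect_identical(out3$status, "borderline")

  jx_na <- jx_good
  jx_na$exonA <- NA_integer_
  expect_warning(out4 <- call_kmt2a_ptd(gain, jx_na, cfg = cfg),
                 "exon annotation")
  expect_identical(out4$status, "borderline")
})

test_that("SV mechanism classification separates fusion from hijack", {
  regions <- default_oncogene_regions()
  # in-frame exon junction wins regardless of window geometry
  fus <- in_frame_fusion("KMT2A", "MLLT3")
  tiny <- rule_config(enhancer_window_bp = 1)
  expect_identical(classify_sv_mechanism(fus, regions, tiny)$mechanism,
                   "in_frame_fusion")
  # breakpoint 100 kb upstream of MECOM: candidate
  eh <- structural_event("x", "3", 169.08e6 - 1e5, "3", 128.5e6,
                         frame = "non_coding")
  out <- classify_sv_mechanism(eh, regions, cfg)
  expect_identical(out$mechanism, "enhancer_hijack_candidate")
  expect_identical(out$hijack_target, "MECOM")
  # 600 kb away with a 500 kb window: other
  far <- structural_event("x", "3", 169.08e6 - 6e5, "3", 128.5e6,
                          frame = "non_coding")
  expect_identical(classify_sv_mechanism(far, regions, cfg)$mechanism,
                   "other")
  expect_error(classify_sv_mechanism(eh, NULL, cfg), "gene model")
})
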