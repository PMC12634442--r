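cfg <- rule_config()
rules <- default_classification_rules()

test_that("complex karyotype means three or more clonal abnormalities", {
  expect_true(is_complex_karyotype(
    parse_iscn("46,XX,del(5)(q31),add(12)(p13),-7"), cfg))
  expect_false(is_complex_karyotype(parse_iscn("46,XX"), cfg))
  expect_false(is_complex_karyotype(
    parse_iscn("46,XX,del(5)(q31),-7"), cfg))
})

test_that("AML-MR evidence matches karyotype, WGS losses, and genes", {
  # monosomy 7 by karyotype
  mr <- evaluate_aml_mr(parse_iscn("45,XY,-7[20]")$lesions, empty_cnvs(),
                        empty_variants(), rules, cfg)
  expect_true(mr$flag)
  expect_true("mono7" %in% mr$matched$pattern)
  # a 25 Mb del(11q) seen only by WGS still counts
  seg <- classify_cnv_event(cnv_segment("c", "11", 80e6, 105e6, "loss"), cfg)
  mr2 <- evaluate_aml_mr(cyto_lesion_tbl_empty(), seg, empty_variants(),
                         rules, cfg)
  expect_true(mr2$flag)
  expect_identical(mr2$matched$pattern, "11q-")
  # trisomy 8 alone does not
  mr3 <- evaluate_aml_mr(parse_iscn("47,XX,+8[20]")$lesions, empty_cnvs(),
                         empty_variants(), rules, cfg)
  expect_false(mr3$flag)
  # an AML-MR gene mutation does
  mr4 <- evaluate_aml_mr(cyto_lesion_tbl_empty(), empty_cnvs(),
                         somatic_p(c(wgs = 0.3), gene = "ASXL1"), rules, cfg)
  expect_true(mr4$flag)
})

test_that("classification follows the tier hierarchy", {
  # WHO fusion
  s <- classify_case(case_profile("c1",
                                  svs = in_frame_fusion("RUNX1", "RUNX1T1",
                                                        cid = "c1")),
                     rules, cfg)
  expect_identical(s$category, "who_fusion")
  expect_identical(s$report_phase, "phase1_day7")
  # complex karyotype plus NPM1: the mutation outranks AML-MR
  npm1 <- variant_call("c2", "NPM1", "5", 171.41e6, "C", "CTCTG",
                       origin = "somatic", pathogenicity = "P",
                       is_aml_driver = TRUE, vaf = c(wgs = 0.4))
  s2 <- classify_case(case_profile(
    "c2", variants = npm1,
    karyotype = parse_iscn("46,XX,del(5)(q31),add(12)(p13),-7")), rules, cfg)
  expect_identical(s2$category, "who_mutation")
  expect_identical(s2$defining_lesion$label, "NPM1")
  # del(7q) alone: AML-MR
  seg <- cnv_segment("c3", "7", 70e6, 140e6, "loss")
  s3 <- classify_case(case_profile("c3", cnvs = seg), rules, cfg)
  expect_identical(s3$category, "aml_mr")
  # nothing reportable: NOS with null defining lesion
  s4 <- classify_case(case_profile("c4"), rules, cfg)
  expect_identical(s4$category, "nos")
  expect_null(s4$defining_lesion)
  # two fusions in one case: the WHO fusion defines, the other is secondary
  two <- dplyr::bind_rows(in_frame_fusion("CBFB", "MYH11", cid = "c5"),
                          in_frame_fusion("CNTRL", "KIT", cid = "c5"))
  s5 <- classify_case(case_profile("c5", svs = two), rules, cfg)
  expect_identical(s5$category, "who_fusion")
  expect_identical(s5$defining_lesion$label, "CBFB::MYH11")
  expect_true("CNTRL::KIT" %in% s5$secondary_drivers)
  # biallelic TP53: variant plus 17p loss
  tp53 <- variant_call("c6", "TP53", "17", 7.67e6, "G", "A",
                       origin = "somatic", pathogenicity = "P",
                       is_aml_driver = TRUE, vaf = c(wgs = 0.7))
  s6 <- classify_case(case_profile(
    "c6", variants = tp53,
    cnvs = cnv_segment("c6", "17", 1e5, 22e6, "loss")), rules, cfg)
  expect_identical(s6$category, "who_mutation")
  expect_identical(s6$defining_lesion$label, "biTP53")
  # a single TP53 hit is not WHO-defining; 17p loss makes it AML-MR instead
  s7 <- classify_case(case_profile("c7", variants = tp53), rules, cfg)
  expect_false(s7$category == "who_mutation")
})

test_that("a refuted enhancer hijack never defines the subtype", {
  fx <- enhancer_hijack_fixture()
  ev <- classify_sv_mechanism(fx$events, default_oncogene_regions(), cfg)
  bcl <- which(ev$case_id == "SJ030153")
  prof <- case_profile("SJ030153", svs = fx$events[bcl, ],
                       expression = fx$case_expression[["SJ030153"]])
  evid <- evaluate_case_evidence(
    prof, cfg, reference_expression = fx$reference_expression)
  expect_identical(evid$svs$hijack_status, "refuted")
  s <- classify_case(prof, rules, cfg, evidence = evid)
  expect_true(is.null(s$defining_lesion) ||
                s$defining_lesion$label != "BCL11B-r")
  # the same candidate with confirming expression would define a subtype
  mec <- which(ev$case_id == "MECOM_case_1")
  prof2 <- case_profile("MECOM_case_1", svs = fx$events[mec, ],
                        expression = fx$case_expression[["MECOM_case_1"]])
  evid2 <- evaluate_case_evidence(
    prof2, cfg, reference_expression = fx$reference_expression)
  expect_identical(evid2$svs$hijack_status, "confirmed")
  s2 <- classify_case(prof2, rules, cfg, evidence = evid2)
  expect_identical(s2$category, "who_fusion")
  expect_identical(s2$defining_lesion$label, "MECOM-r")
})

test_that("classification is total, deterministic, and demotes on lesion loss", {
  cohort <- c(classification_stub_cohort(), complex_karyotype_fixture())
  tier_rank <- c(ds_aml = 1, who_fusion = 2, who_mutation = 3,
                 proposed_class = 4, rare_novel_fusion = 5, aml_mr = 6,
                 nos = 7)
  for (p in cohort) {
    s <- classify_case(p, rules, cfg)
    expect_true(s$category %in% names(tier_rank))
    expect_identical(classify_case(p, rules, cfg)$category, s$category)
    if (s$category == "nos") next
    # strip the defining lesion and reclassify: never a higher tier
    p2 <- p
    if (s$defining_lesion$type == "fusion") {
      labels <- vapply(seq_len(nrow(p2$svs)), function(i) {
        paste0(p2$svs$geneA[i], "::", p2$svs$geneB[i])
      }, character(1))
      drop <- labels == s$defining_lesion$label
      if (!any(drop)) drop <- rep(TRUE, nrow(p2$svs))  # hijack label
      p2$svs <- p2$svs[!drop, , drop = FALSE]
    } else if (s$defining_lesion$type == "mutation") {
      gene <- sub("^bi", "", s$defining_lesion$label)
      p2$variants <- p2$variants[p2$variants$gene != gene, , drop = FALSE]
    } else {
      p2$cnvs <- empty_cnvs()
      p2$karyotype <- NULL
    }
    s2 <- classify_case(p2, rules, cfg)
    expect_gte(tier_rank[[s2$category]], tier_rank[[s$category]])
  }
})

test_that("the stub cohort reproduces the published category breakdown", {
  stubs <- classification_stub_cohort()
  cats <- vapply(stubs, function(p) classify_case(p, rules, cfg)$category,
                 character(1))
  counts <- classification_counts_fixture()
  observed <- table(factor(cats, levels = counts$category))
  expect_identical(as.integer(observed), counts$n)
})

test_that("report phases follow the phased-reporting scheme", {
  expect_identical(assign_report_phase("who_fusion"), "phase1_day7")
  expect_identical(assign_report_phase("ls_cnv"), "phase1_day7")
  expect_identical(assign_report_phase("rare_novel_fusion"), "phase2_day14")
  expect_identical(assign_report_phase("cooperating_variant"),
                   "phase2_day14")
  expect_identical(assign_report_phase("germline"), "phase3_day21")
  expect_error(assign_report_phase("mystery"), "unknown")
})
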