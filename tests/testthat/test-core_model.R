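test_that("a consistent case profile validates cleanly", {
  p <- case_profile(
    "SJ_ok", sex = "F", age_years = 11, blast_percent = 63,
    variants = somatic_p(c(wgs = 0.42), cid = "SJ_ok"),
    cnvs = cnv_segment("SJ_ok", "7", 1e5, 60e6, kind = "loss"),
    karyotype = parse_iscn("45,XY,-7[18]/46,XY[2]")
  )
  expect_identical(nrow(validate_case_profile(p)), 0L)
})

test_that("violations are reported as data, one row per broken rule", {
  p <- case_profile("SJ_bad", blast_percent = 120)
  v <- validate_case_profile(p)
  expect_identical(v$field, "blast_percent")

  p2 <- case_profile("SJ_bad2",
                     cnvs = cnv_segment("SJ_bad2", "7", 1e5, 60e6, "loss"))
  p2$cnvs$end <- 1  # tamper: end before start
  v2 <- validate_case_profile(p2)
  expect_true("cnvs.coordinates" %in% v2$field)
})

test_that("validation is idempotent and order-insensitive", {
  p <- case_profile(
    "SJ_mix", blast_percent = 150,
    variants = dplyr::bind_rows(somatic_p(c(wgs = 0.2), cid = "SJ_mix"),
                                somatic_p(c(wgs = 0.4), gene = "NRAS",
                                          cid = "SJ_mix"))
  )
  v1 <- validate_case_profile(p)
  p$variants <- p$variants[2:1, ]
  v2 <- validate_case_profile(p)
  expect_identical(v1, v2)
  expect_identical(v1, validate_case_profile(p))
})

test_that("constructors reject invariant violations outright", {
  expect_error(variant_call("x", "g", "1", 5, "A", "A"), "ref must differ")
  expect_error(variant_call("x", "g", "1", 0, "A", "C"), "pos")
  expect_error(variant_call("x", "g", "1", 5, "A", "C", vaf = c(wgs = 1.2)),
               "\\[0, 1\\]")
  expect_error(cnv_segment("x", "1", 10, 5, "loss"), "end")
  expect_error(structural_event("x", "1", 5, "1", 9, geneA = "A",
                                geneB = "B", event_class = "itd"),
               "intragenic")
  expect_error(itd_evidence("x", wgs_strength = "strong",
                            wts_strength = "strong", pcr_ratio = -1),
               "nonnegative")
})

test_that("insufficient platform evidence is distinct from absent and zero", {
  v <- somatic_p(c(wgs = 0, wts = NA))
  expect_identical(platform_vaf(v, "wgs"), 0)
  expect_true(is.na(platform_vaf(v, "wts")))
  expect_null(platform_vaf(v, "wes"))
})

test_that("structural events canonicalize breakpoint order with annotations", {
  sv <- structural_event("x", chromA = "9", posA = 20400000,
                         chromB = "11", posB = 118400000,
                         geneA = "MLLT3", geneB = "KMT2A",
                         exonA = 2L, exonB = 8L, frame = "in_frame")
  expect_identical(sv$chromA, "11")
  expect_identical(sv$geneA, "KMT2A")
  expect_identical(sv$exonA, 8L)
  expect_identical(sv$geneB, "MLLT3")
})
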