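cfg <- rule_config()

ref_profiles <- function(gene = "MECOM", n = 12, base = 5) {
  lapply(seq_len(n), function(i) {
    flat_expression(paste0("R", i),
                    stats::setNames(base * exp(seq(-0.4, 0.4,
                                                   length.out = n))[i],
                                    gene))
  })
}

test_that("overexpression is a log-scale z-score against the reference", {
  ref <- ref_profiles()
  hot <- flat_expression("case_hot", MECOM = 5 * exp(5))
  call <- overexpression_call("MECOM", hot, ref, cfg)
  expect_identical(call$flag, "overexpressed")
  expect_gt(call$z_score, cfg$overexpression_z)

  # a case exactly at the reference geometric mean scores z ~ 0
  m <- mean(vapply(ref, function(p) log1p(p$values[["MECOM"]]), 1))
  mid <- flat_expression("case_mid", MECOM = expm1(m))
  call0 <- overexpression_call("MECOM", mid, ref, cfg)
  expect_equal(call0$z_score, 0, tolerance = 1e-8)
  expect_identical(call0$flag, "not_overexpressed")

  expect_error(overexpression_call("MECOM", hot, list(), cfg), "empty")
  flatref <- lapply(1:5, function(i) flat_expression(paste0("F", i),
                                                     MECOM = 5))
  expect_error(overexpression_call("MECOM", hot, flatref, cfg),
               "variance")
})

test_that("the call is invariant to uniform multiplicative rescaling", {
  ref <- ref_profiles(base = 50)
  case <- flat_expression("c", MECOM = 50 * exp(3))
  z1 <- overexpression_call("MECOM", case, ref, cfg)$z_score
  scale_up <- function(p, k) expression_profile(p$case_id, p$values * k,
                                                p$cohort_id)
  z2 <- overexpression_call("MECOM", scale_up(case, 40),
                            lapply(ref, scale_up, k = 40), cfg)$z_score
  # log1p is only asymptotically scale-free; at these abundances the two
  # z-scores agree closely
  expect_equal(z1, z2, tolerance = 0.05)
})

test_that("reference sets exclude cases rearranged at the gene", {
  svs <- dplyr::bind_rows(
    in_frame_fusion("CDK6", "HOXA13", cid = "R3"),
    structural_event("R5", "3", 169.0e6, "3", 128.5e6,
                     frame = "non_coding")
  )
  svs <- classify_sv_mechanism(svs, default_oncogene_regions(), cfg)
  profiles <- ref_profiles("MECOM")
  kept <- reference_profiles_for_gene("MECOM", profiles, svs)
  expect_setequal(vapply(kept, function(p) p$case_id, ""),
                  setdiff(vapply(profiles, function(p) p$case_id, ""),
                          "R5"))
  kept2 <- reference_profiles_for_gene("HOXA13", profiles, svs)
  expect_false("R3" %in% vapply(kept2, function(p) p$case_id, ""))
})

test_that("expression confirms or refutes an enhancer-hijack candidate", {
  fx <- enhancer_hijack_fixture()
  ev <- classify_sv_mechanism(fx$events, default_oncogene_regions(), cfg)
  verdicts <- vapply(seq_len(nrow(ev)), function(i) {
    cid <- ev$case_id[i]
    call <- overexpression_call(ev$hijack_target[i],
                                fx$case_expression[[cid]],
                                fx$reference_expression, cfg)
    validate_enhancer_hijack(ev[i, ], call)
  }, character(1))
  expect_identical(verdicts[ev$hijack_target == "MECOM"], rep("confirmed", 6))
  expect_identical(verdicts[ev$hijack_target %in% c("HOXA13", "HOXA10")],
                   rep("confirmed", 2))
  expect_identical(verdicts[ev$hijack_target == "BCL11B"],
                   rep("refuted", 2))
  # gene mismatch between the candidate target and the call is an error
  wrong <- overexpression_call("MECOM", fx$case_expression[["SJ030153"]],
                               fx$reference_expression, cfg)
  expect_error(validate_enhancer_hijack(ev[ev$case_id == "SJ030153", ],
                                        wrong),
               "target")
})

test_that("allele-specific expression classifies DNA/RNA VAF skew", {
  expect_identical(allele_specific_expression(0.35, 0.97), "mutant_ase")
  expect_identical(allele_specific_expression(0.50, 0.50), "balanced")
  expect_identical(allele_specific_expression(0.50, 0.02), "wildtype_ase")
  expect_error(allele_specific_expression(-0.1, 0.5), "\\[0, 1\\]")
  # antisymmetry under swapping the two VAFs
  set.seed(11)
  for (i in 1:25) {
    d <- stats::runif(1)
    r <- stats::runif(1)
    a <- allele_specific_expression(d, r)
    b <- allele_specific_expression(r, d)
    expect_identical(
      b,
      switch(a, mutant_ase = "wildtype_ase", wildtype_ase = "mutant_ase",
             balanced = "balanced"))
  }
})
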