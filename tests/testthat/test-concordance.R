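test_that("variant set matching partitions exhaustively and disjointly", {
  mk <- function(cid, pos, ref = "G", alt = "A") {
    variant_call(cid, "WT1", "11", pos, ref, alt, origin = "somatic",
                 pathogenicity = "P", vaf = c(wgs = 0.3))
  }
  a <- dplyr::bind_rows(mk("c1", 100), mk("c1", 200), mk("c2", 100))
  m <- match_variant_sets(a, a)
  expect_identical(nrow(m$both), 3L)
  expect_identical(nrow(m$only_a), 0L)

  b <- dplyr::bind_rows(mk("c3", 100), mk("c3", 200), mk("c3", 300))
  a2 <- dplyr::bind_rows(mk("c1", 100), mk("c1", 200))
  m2 <- match_variant_sets(a2, b)
  expect_identical(c(nrow(m2$both), nrow(m2$only_a), nrow(m2$only_b)),
                   c(0L, 2L, 3L))
  # conservation
  set.seed(5)
  positions_a <- sample(1:50, 20)
  positions_b <- sample(1:50, 20)
  pa <- dplyr::bind_rows(lapply(positions_a, function(p) mk("cx", p)))
  pb <- dplyr::bind_rows(lapply(positions_b, function(p) mk("cx", p)))
  m3 <- match_variant_sets(pa, pb)
  expect_identical(nrow(m3$both) + nrow(m3$only_a), nrow(pa))
  expect_identical(nrow(m3$both) + nrow(m3$only_b), nrow(pb))
  expect_error(match_variant_sets(dplyr::bind_rows(pa, pa[1, ]), pb),
               "duplicate")
})

test_that("the same indel in two raw forms matches after normalization", {
  # CA deletion inside the repeat context ACACACAG starting at position 101
  ctx <- "ACACACAG"
  raw1 <- normalize_variant("1", 103L, "ACA", "A", context = ctx,
                            context_start = 101L)
  raw2 <- normalize_variant("1", 101L, "ACAC", "AC", context = ctx,
                            context_start = 101L)
  expect_identical(raw1[c("pos", "ref", "alt")],
                   raw2[c("pos", "ref", "alt")])
  mk <- function(n) {
    variant_call("c1", "G", "1", n$pos, n$ref, n$alt, origin = "somatic",
                 pathogenicity = "P", vaf = c(wgs = 0.3))
  }
  m <- match_variant_sets(mk(raw1), mk(raw2))
  expect_identical(nrow(m$both), 1L)
  # without normalization the two raw keys differ
  raw_a <- variant_call("c1", "G", "1", 103, "ACA", "A", origin = "somatic",
                        pathogenicity = "P", vaf = c(wgs = 0.3))
  raw_b <- variant_call("c1", "G", "1", 101, "ACAC", "AC",
                        origin = "somatic", pathogenicity = "P",
                        vaf = c(wgs = 0.3))
  expect_identical(nrow(match_variant_sets(raw_a, raw_b)$both), 0L)
})

test_that("VAF concordance equals closed-form least squares", {
  ident <- data.frame(a = c(0.1, 0.3, 0.5, 0.8), b = c(0.1, 0.3, 0.5, 0.8))
  s <- vaf_concordance(ident)
  expect_equal(s$r, 1)
  expect_equal(s$slope, 1)

  a <- c(0.1, 0.2, 0.3)
  b <- c(0.1, 0.4, 0.5)
  # independent closed-form normal equations
  slope_o <- sum((a - mean(a)) * (b - mean(b))) / sum((a - mean(a))^2)
  r_o <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  s2 <- vaf_concordance(data.frame(a, b))
  expect_equal(s2$slope, slope_o, tolerance = 1e-12)
  expect_equal(s2$r, r_o, tolerance = 1e-12)
  expect_identical(s2$n_pairs, 3L)

  expect_error(vaf_concordance(data.frame(a = a, b = c(0.2, 0.2, 0.2))),
               "constant")
  expect_error(vaf_concordance(data.frame(a = a[1:2], b = b[1:2])),
               "3 pairs")
})

test_that("r is affine-invariant while the slope scales with the b axis", {
  set.seed(9)
  a <- stats::runif(20)
  b <- 0.8 * a + stats::rnorm(20, sd = 0.05)
  s <- vaf_concordance(data.frame(a, b))
  s_scaled <- vaf_concordance(data.frame(a = 100 * a + 3, b))
  expect_equal(s$r, s_scaled$r, tolerance = 1e-12)
  s_b <- vaf_concordance(data.frame(a, b = 100 * b))
  expect_equal(s_b$slope, 100 * s$slope, tolerance = 1e-9)
  expect_equal(s_b$r, s$r, tolerance = 1e-12)
})

test_that("agreement rates match the published arithmetic", {
  expect_identical(agreement_rate(80, 9, 15), 77)
  expect_identical(agreement_rate(28, 3, 0), 90)
  expect_identical(agreement_rate(5, 0, 0), 100)
  expect_identical(agreement_rate(3, 1, 2), agreement_rate(3, 2, 1))
  expect_error(agreement_rate(0, 0, 0), "zero")
  set.seed(2)
  for (i in 1:20) {
    k <- sample(0:30, 3)
    if (sum(k) == 0) next
    r <- agreement_rate(k[1], k[2], k[3])
    expect_gte(r, 0)
    expect_lte(r, 100)
    if (r == 100) expect_identical(k[2] + k[3], 0L)
  }
})

test_that("detection tables conserve counts and sum to the Total row", {
  fx <- fusion_detection_fixture()
  truth <- fx[rep(seq_len(nrow(fx)), fx$total), "category"]
  obs <- unlist(lapply(seq_len(nrow(fx)), function(i) {
    c(rep(TRUE, fx$both[i]), rep(FALSE, fx$only_a[i]))
  }))
  dt <- detection_table(truth, obs)
  tot <- dt[dt$category == "Total", ]
  body <- dt[dt$category != "Total", ]
  expect_identical(tot$both, sum(body$both))
  expect_identical(tot$only_a, sum(body$only_a))
  expect_identical(tot$total, tot$both + tot$only_a)
  # empty input yields a zero Total
  empty <- detection_table(data.frame(category = character()), logical())
  expect_identical(empty$total, 0L)
})

test_that("diagnostic yield counts detectable defining lesions", {
  all_nos <- replicate(10, molecular_subtype("nos"), simplify = FALSE)
  expect_identical(diagnostic_yield(all_nos), 0)
  mixed <- c(
    replicate(3, molecular_subtype("who_fusion",
                                   list(type = "fusion", label = "X::Y")),
              simplify = FALSE),
    all_nos[1]
  )
  expect_identical(diagnostic_yield(mixed), 75.0)
  # a modality blind to fusions scores zero on a fusion-only cohort
  expect_identical(
    diagnostic_yield(mixed,
                     modality_detectable = function(s)
                       s$defining_lesion$type != "fusion"),
    0)
  expect_error(diagnostic_yield(list()), "empty")
})
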