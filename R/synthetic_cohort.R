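#' Gene locus lookup for simulated breakpoints
#'
#' Approximate GRCh38 loci of the genes recurrently involved in pediatric
#' AML fusions. Only arm-scale accuracy matters: simulated breakpoints must
#' land on the right chromosome and respect the enhancer-window geometry.
#'
#' @param gene Gene symbol.
#' @return A list with `chrom` and `pos`.
#' @export
gene_locus <- function(gene) {
  tab <- GENE_LOCI
  i <- match(gene, tab$gene)
  if (is.na(i)) {
    stop("gene_locus: no locus recorded for `", gene, "`", call. = FALSE)
  }
  list(chrom = tab$chrom[i], pos = tab$pos[i])
}

GENE_LOCI <- tibble::tribble(
  ~gene,       ~chrom, ~pos,
  "RUNX1",      "21",  34.8e6,
  "RUNX1T1",    "8",   92.0e6,
  "CBFB",       "16",  67.1e6,
  "MYH11",      "16",  15.7e6,
  "KMT2A",      "11", 118.4e6,
  "MLLT3",      "9",   20.4e6,
  "MLLT10",     "10",  21.5e6,
  "MLLT4",      "6", 167.80e6,
  "MLLT1",      "19",   6.2e6,
  "MLLT6",      "17",  38.9e6,
  "MLLT11",     "1", 151.0e6,
  "ELL",        "19",  18.5e6,
  "NUP98",      "11",   3.7e6,
  "NSD1",       "5", 177.2e6,
  "KDM5A",      "12",   0.39e6,
  "PML",        "15",  73.9e6,
  "RARA",       "17",  40.3e6,
  "RARB",       "3",   25.2e6,
  "TBL1XR1",    "3",  177.0e6,
  "DEK",        "6",   18.2e6,
  "NUP214",     "9",  131.1e6,
  "RBM15",      "1",  110.3e6,
  "MRTFA",      "22",  40.2e6,
  "PICALM",     "11",  85.9e6,
  "KAT6A",      "8",   41.8e6,
  "CREBBP",     "16",   3.7e6,
  "FUS",        "16",  31.1e6,
  "ERG",        "21",  38.4e6,
  "CBFA2T3",    "16",  88.9e6,
  "GLIS2",      "16",   4.3e6,
  "MYB",        "6",  135.2e6,
  "GATA1",      "X",   48.8e6,
  "GATA2",      "3",  128.5e6,
  "CDK6",       "7",   92.2e6,
  "HOXA13",     "7",   27.195e6,
  "HOXA10",     "7",   27.175e6,
  "TEC",        "4",   48.1e6,
  "HSPA8",      "11", 123.0e6,
  "PRDM16",     "1",    3.1e6,
  "POU2F2",     "19",  42.1e6,
  "ZEB2",       "2",  144.3e6,
  "USP42",      "7",    6.1e6,
  "EVX1",       "7",   27.3e6,
  "MECOM",      "3",  169.4e6,
  "BCL11B",     "14",  99.2e6,
  "TLX3",       "5",  171.3e6,
  "NPM1",       "5",  171.41e6,
  "CEBPA",      "19",  33.3e6,
  "TP53",       "17",   7.67e6,
  "FLT3",       "13",  28.0e6,
  "WT1",        "11",  32.4e6,
  "NRAS",       "1",  114.7e6,
  "KRAS",       "12",  25.2e6,
  "KIT",        "4",   54.7e6,
  "CNTRL",      "9",  121.0e6
)

# Per-subtype defining-lesion templates. Fusion weights follow the observed
# per-fusion multiplicities; cryptic-miss probabilities follow the observed
# cytogenetic miss rates. MECOM-r is generated as an enhancer-hijack event.
subtype_templates <- function() {
  tab <- fusion_detection_fixture()
  who <- c("RUNX1::RUNX1T1", "CBFB::MYH11", "KMT2A::MLLT3", "KMT2A::MLLT10",
           "KMT2A::ELL", "KMT2A::MLLT4", "KMT2A::MLLT1", "KMT2A::MLLT6",
           "KMT2A::MLLT11", "PML::RARA", "NUP98::KDM5A", "NUP98::NSD1",
           "MECOM-r", "DEK::NUP214", "RBM15::MRTFA", "PICALM::MLLT10",
           "KAT6A::CREBBP", "FUS::ERG")
  proposed <- c("CBFA2T3::GLIS2", "MYB::GATA1", "CDK6::HOXA13",
                "TBL1XR1::RARB", "RUNX1::CBFA2T3")
  rare <- c("TEC::MLLT10", "HSPA8::PRDM16", "RUNX1::POU2F2", "RUNX1::ZEB2",
            "RUNX1::USP42", "RUNX1::EVX1")
  pick <- function(labels) {
    sub <- tab[tab$category %in% labels, ]
    tibble(label = sub$category, weight = sub$total,
           miss_prob = sub$pct_missed_b / 100)
  }
  list(
    who_fusion = pick(who),
    proposed_class = pick(proposed),
    rare_novel_fusion = pick(rare),
    who_mutation = tibble(label = c("NPM1", "CEBPA", "TP53:biallelic"),
                          weight = c(10, 8, 3), miss_prob = 1),
    aml_mr = tibble(label = c("mono7", "5q-", "7q-"),
                    weight = c(3, 1, 1), miss_prob = NA_real_),
    ds_aml = tibble(label = "GATA1", weight = 1, miss_prob = 1),
    nos = tibble(label = character(), weight = numeric(),
                 miss_prob = numeric())
  )
}

#' Cohort simulation configuration
#'
#' Defaults emulate the clinical cohort: ~150 cases with subtype proportions
#' matching the published breakdown (86:26:21:5:6:4:5 over 153 cases),
#' per-fusion cryptic-miss probabilities matching the observed cytogenetic
#' miss rates, WGS read-sampling depth of 60x, cooperating-lesion rates in
#' the range the cohort reports (FLT3-ITD in ~12% of patients, a cooperating
#' driver SNV in about half, an incidental large-scale CNV in a quarter),
#' and a +4-standard-deviation log-scale expression shift for
#' enhancer-hijacked oncogenes.
#'
#' @param n_cases Number of cases to simulate.
#' @param subtype_weights Named probabilities over subtype categories
#'   (must sum to 1).
#' @param seed Integer seed; the generator is fully reproducible given the
#'   configuration and seed.
#' @param depth Sequencing depth for binomial VAF jitter.
#' @param itd_rate,coop_snv_rate,coop_cnv_rate Cooperating-lesion rates.
#' @param hijack_shift_sd Log-scale expression shift (in reference standard
#'   deviations) applied to an enhancer-hijacked oncogene.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 150,
                          subtype_weights = NULL,
                          seed = 1L,
                          depth = 60,
                          itd_rate = 0.12,
                          coop_snv_rate = 0.5,
                          coop_cnv_rate = 0.25,
                          hijack_shift_sd = 4) {
  if (is.null(subtype_weights)) {
    counts <- classification_counts_fixture()
    subtype_weights <- stats::setNames(counts$n / sum(counts$n),
                                       counts$category)
  }
  if (abs(sum(subtype_weights) - 1) > 1e-8) {
    stop("cohort_config: subtype_weights must sum to 1", call. = FALSE)
  }
  if (any(subtype_weights < 0) || any(subtype_weights > 1)) {
    stop("cohort_config: subtype_weights must lie in [0, 1]", call. = FALSE)
  }
  unknown <- setdiff(names(subtype_weights), SUBTYPE_CATEGORIES)
  if (length(unknown)) {
    stop("cohort_config: unknown subtype(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_cases = n_cases, subtype_weights = subtype_weights,
         seed = as.integer(seed), depth = depth, itd_rate = itd_rate,
         coop_snv_rate = coop_snv_rate, coop_cnv_rate = coop_cnv_rate,
         hijack_shift_sd = hijack_shift_sd),
    class = "cohort_config"
  )
}

# Build one fusion (or enhancer-hijack) structural event from its label.
make_fusion_event <- function(label, case_id) {
  if (label == "MECOM-r") {
    up <- stats::runif(1, 3.8e3, 3.0e5)
    partner <- sample(list(list(chrom = "3", pos = 128.5e6),
                           list(chrom = "7", pos = 92.2e6),
                           list(chrom = "2", pos = 45.0e6)), 1)[[1]]
    return(structural_event(
      case_id = case_id, chromA = "3", posA = round(169.08e6 - up),
      chromB = partner$chrom, posB = round(partner$pos),
      frame = "non_coding", event_class = "fusion",
      fusion_category = "who_defining"
    ))
  }
  genes <- strsplit(label, "::", fixed = TRUE)[[1]]
  a <- gene_locus(genes[1])
  b <- gene_locus(genes[2])
  structural_event(
    case_id = case_id, chromA = a$chrom, posA = round(a$pos),
    chromB = b$chrom, posB = round(b$pos),
    geneA = genes[1], geneB = genes[2],
    exonA = sample(3:8, 1), exonB = 2L, frame = "in_frame",
    event_class = "fusion"
  )
}

EXPRESSION_PANEL <- c("MECOM", "HOXA13", "HOXA10", "BCL11B", "TLX3",
                      "NKX2-5", "CDK6", "GATA2")
# Log-normal expression baselines (meanlog, sdlog shared)
EXPRESSION_MEANLOG <- c(MECOM = 1.2, HOXA13 = 1.0, HOXA10 = 1.0,
                        BCL11B = 3.5, TLX3 = -0.5, `NKX2-5` = -0.5,
                        CDK6 = 3.0, GATA2 = 2.5)
EXPRESSION_SDLOG <- 0.35

#' Generate a truth cohort
#'
#' Draws each case's subtype from the configured weights, a defining lesion
#' from the subtype's template (fusions with the published per-fusion
#' multiplicities; MECOM-r as an enhancer-hijack rearrangement with a shifted
#' MECOM expression value), cooperating lesions at the configured rates,
#' blast percentage, and a panel expression profile. Identical configuration
#' and seed reproduce the identical cohort.
#'
#' @param cfg A [cohort_config()].
#' @return A list of `case_profile`s; each carries a `truth` attribute with
#'   the drawn subtype and defining-lesion label.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  set.seed(cfg$seed)
  templates <- subtype_templates()
  cats <- sample(names(cfg$subtype_weights), cfg$n_cases, replace = TRUE,
                 prob = cfg$subtype_weights)
  lapply(seq_len(cfg$n_cases), function(i) {
    cid <- sprintf("SIM_case_%04d", i)
    cat <- cats[i]
    blast <- round(5 + 91 * stats::rbeta(1, 2.6, 1.6), 1)
    svs <- NULL
    variants <- NULL
    cnvs <- NULL
    itds <- NULL
    lesion_label <- NA_character_
    expr <- stats::rlnorm(length(EXPRESSION_PANEL),
                          EXPRESSION_MEANLOG[EXPRESSION_PANEL],
                          EXPRESSION_SDLOG)
    names(expr) <- EXPRESSION_PANEL

    tpl <- templates[[cat]]
    if (cat %in% c("who_fusion", "proposed_class", "rare_novel_fusion")) {
      lesion_label <- sample(tpl$label, 1, prob = tpl$weight)
      svs <- make_fusion_event(lesion_label, cid)
      if (lesion_label == "MECOM-r") {
        expr["MECOM"] <- exp(log(expr[["MECOM"]]) +
                               cfg$hijack_shift_sd * EXPRESSION_SDLOG)
      }
    } else if (cat == "who_mutation") {
      lesion_label <- sample(tpl$label, 1, prob = tpl$weight)
      gene <- sub(":biallelic$", "", lesion_label)
      loc <- gene_locus(gene)
      v <- variant_call(cid, gene, loc$chrom, round(loc$pos),
                        "C", "T", origin = "somatic", pathogenicity = "P",
                        is_aml_driver = TRUE,
                        vaf = c(wgs = stats::runif(1, 0.2, 0.48)))
      variants <- v
      if (lesion_label == "TP53:biallelic") {
        cnvs <- cnv_segment(cid, "17", 1e5, 22e6, kind = "loss",
                            clone_fraction = stats::runif(1, 0.5, 1))
      }
    } else if (cat == "aml_mr") {
      lesion_label <- sample(tpl$label, 1, prob = tpl$weight)
      cnvs <- switch(lesion_label,
        mono7 = cnv_segment(cid, "7", 1e5, 159.2e6, kind = "loss",
                            clone_fraction = stats::runif(1, 0.4, 1)),
        `5q-` = cnv_segment(cid, "5", 100e6, 160e6, kind = "loss",
                            clone_fraction = stats::runif(1, 0.4, 1)),
        `7q-` = cnv_segment(cid, "7", 70e6, 140e6, kind = "loss",
                            clone_fraction = stats::runif(1, 0.4, 1))
      )
    } else if (cat == "ds_aml") {
      lesion_label <- "GATA1"
      loc <- gene_locus("GATA1")
      variants <- variant_call(cid, "GATA1", loc$chrom, round(loc$pos),
                               "G", "GA", origin = "somatic",
                               pathogenicity = "P", is_aml_driver = TRUE,
                               vaf = c(wgs = stats::runif(1, 0.2, 0.45)))
    }

    if (stats::runif(1) < cfg$itd_rate) {
      strata <- list(c("strong", "strong"), c("strong",
                                              "insufficient_coverage"),
                     c("weak", "strong"), c("none", "strong"),
                     c("weak", "weak"))
      s <- sample(strata, 1, prob = c(15, 2, 5, 5, 1))[[1]]
      itds <- itd_evidence(cid, "FLT3", wgs_strength = s[1],
                           wts_strength = s[2])
    }
    if (stats::runif(1) < cfg$coop_snv_rate) {
      gene <- sample(c("WT1", "NRAS", "KRAS", "KIT", "FLT3"), 1)
      loc <- gene_locus(gene)
      coop <- variant_call(cid, gene, loc$chrom, round(loc$pos), "G", "T",
                           origin = "somatic", pathogenicity = "P",
                           is_aml_driver = TRUE,
                           vaf = c(wgs = stats::runif(1, 0.06, 0.45)))
      variants <- if (is.null(variants)) coop else
        dplyr::bind_rows(variants, coop)
    }
    if (stats::runif(1) < cfg$coop_cnv_rate) {
      chrom <- sample(c("8", "13", "16", "20"), 1)
      start <- stats::runif(1, 1e6, 40e6)
      coop_cnv <- cnv_segment(cid, chrom, round(start),
                              round(start + stats::runif(1, 10e6, 50e6)),
                              kind = sample(c("gain", "loss"), 1),
                              clone_fraction = stats::runif(1, 0.2, 1))
      cnvs <- if (is.null(cnvs)) coop_cnv else dplyr::bind_rows(cnvs,
                                                                coop_cnv)
    }
    profile <- case_profile(
      case_id = cid,
      sex = sample(c("M", "F"), 1),
      age_years = round(stats::runif(1, 0.1, 20), 1),
      down_syndrome = cat == "ds_aml",
      blast_percent = blast,
      variants = variants, svs = svs, itds = itds, cnvs = cnvs,
      expression = expression_profile(cid, expr, "simulated")
    )
    attr(profile, "truth") <- list(subtype = cat,
                                   lesion_label = lesion_label)
    profile
  })
}

#' Observe a truth case through a platform's sensitivity model
#'
#' Cytogenetics reports a CNV only when it is at least the band-resolution
#' size and its clone fraction clears the metaphase-sampling floor, and
#' reports a fusion with probability one minus its cryptic-miss probability
#' (looked up by defining-lesion label, default 0). Sequencing platforms
#' report a large-scale CNV only when clone fraction times purity clears the
#' subclonal floor, and report a small variant when its binomially resampled
#' VAF (depth-limited read sampling at `purity`-diluted allele fraction)
#' reaches the platform's VAF floor.
#'
#' @param truth A `case_profile` from [generate_cohort()].
#' @param model A [platform_model()].
#' @param seed Integer seed for the observation draw, or `NULL` to draw from
#'   the current RNG stream (recommended when observing many cases: seed the
#'   stream once outside the loop).
#' @return A list with `case_id`, `svs`, `cnvs`, `variants` — the platform's
#'   observed call set.
#' @export
observe_with_platform <- function(truth, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  svs <- truth$svs
  lesion_label <- (attr(truth, "truth") %||% list())$lesion_label
  if (!is.null(svs) && nrow(svs)) {
    keep <- vapply(seq_len(nrow(svs)), function(i) {
      miss <- 0
      if (!is.null(lesion_label) && !is.na(lesion_label) &&
          lesion_label %in% names(model$cryptic_miss_prob)) {
        miss <- model$cryptic_miss_prob[[lesion_label]]
      }
      stats::runif(1) >= miss
    }, logical(1))
    svs <- svs[keep, , drop = FALSE]
  }
  cnvs <- truth$cnvs
  if (!is.null(cnvs) && nrow(cnvs)) {
    keep <- if (model$platform == "cytogenetics") {
      cnvs$size_bp >= model$min_cnv_bp &
        cnvs$clone_fraction >= model$min_clone_fraction
    } else {
      big <- cnvs$size_bp >= 5e6
      (!big & cnvs$sv_supported) |
        (cnvs$size_bp >= model$min_cnv_bp &
           cnvs$clone_fraction * model$purity >= model$min_clone_fraction)
    }
    cnvs <- cnvs[keep, , drop = FALSE]
  }
  variants <- truth$variants
  if (!is.null(variants) && nrow(variants) &&
      model$platform %in% c("wgs", "wes", "wts", "panel")) {
    obs_vaf <- numeric(nrow(variants))
    for (i in seq_len(nrow(variants))) {
      true_vaf <- platform_vaf(variants[i, ], "wgs")
      true_vaf <- if (is.null(true_vaf) || is.na(true_vaf)) 0 else true_vaf
      obs_vaf[i] <- stats::rbinom(1, model$depth,
                                  min(1, true_vaf * model$purity)) /
        model$depth
    }
    keep <- obs_vaf >= model$vaf_floor
    variants <- variants[keep, , drop = FALSE]
    if (nrow(variants)) {
      variants$vaf <- lapply(which(keep), function(i) {
        stats::setNames(obs_vaf[i], model$platform)
      })
    }
  } else if (model$platform == "cytogenetics") {
    variants <- empty_variants()
  }
  list(case_id = truth$case_id, svs = svs %||% empty_svs(),
       cnvs = cnvs %||% empty_cnvs(), variants = variants %||%
         empty_variants())
}

#' Large-scale CNV detection across a tumor-purity dilution series
#'
#' Re-observes a truth set of large-scale CNVs under the WGS sensitivity
#' model at each purity: a segment is detected when clone fraction times
#' purity clears the subclonal detection floor. Detection is monotone
#' nonincreasing as purity falls.
#'
#' @param cnvs A `cnv_segment_tbl` of truth large-scale CNVs.
#' @param purities Purity fractions in `(0, 1]`.
#' @param model A [platform_model()] (WGS-type); its `purity` field is
#'   overridden per dilution point.
#' @param seed Integer seed (kept for interface symmetry; the threshold model
#'   is deterministic).
#' @return A tibble with columns `purity`, `n_truth`, `n_detected`,
#'   `fraction_detected`.
#' @export
dilution_series <- function(cnvs, purities, model = wgs_model(),
                            seed = NULL) {
  if (any(purities <= 0) || any(purities > 1)) {
    stop("dilution_series: purities must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(purities, function(p) {
    detected <- cnvs$clone_fraction * p >= model$min_clone_fraction
    tibble(purity = p, n_truth = nrow(cnvs), n_detected = sum(detected),
           fraction_detected = if (nrow(cnvs)) mean(detected) else
             NA_real_)
  })
}
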