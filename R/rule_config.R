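#' Reporting-rule configuration
#'
#' Thresholds governing variant reportability, CNV scale classes, the
#' enhancer-hijack search window, and platform sensitivity modelling. Defaults
#' are the clinically used values: small somatic variants are reportable at
#' WGS VAF >= 5%, with an RNA rescue for AML drivers whose WTS VAF strictly
#' exceeds 25%; focal CNVs are < 5 Mb, large-scale CNVs >= 5 Mb, large-scale
#' cnLOH >= 10 Mb; G-banded karyotyping at 400-band resolution sees copy-number
#' changes of roughly 9 Mb or larger and clones present in at least ~35% of
#' cells.
#'
#' @param wgs_vaf_min Minimum WGS VAF (fraction) for direct reportability.
#' @param wts_rescue_vaf WTS VAF (fraction) a sub-threshold AML-driver variant
#'   must strictly exceed to be rescued.
#' @param focal_cnv_max_bp Focal CNVs are strictly smaller than this (bp).
#' @param ls_cnv_min_bp Large-scale CNVs are at least this large (bp).
#' @param cnloh_min_bp Large-scale copy-neutral LOH is at least this large (bp).
#' @param sub50kb_bp Size below which a focal CNV is flagged for intragenic
#'   review (bp).
#' @param enhancer_window_bp Window on either side of an oncogene within which
#'   a non-coding breakpoint is an enhancer-hijack candidate (bp).
#' @param cyto_visible_min_bp Minimum CNV size visible to conventional
#'   cytogenetics at 400-band resolution (bp).
#' @param subclonal_cnv_min_fraction Minimum effective clone fraction
#'   (clone fraction x tumor purity) at which WGS detects a large-scale CNV.
#' @param complex_karyotype_min Number of distinct clonal abnormalities that
#'   makes a karyotype complex.
#' @param overexpression_z z-score (log scale) at or above which an oncogene is
#'   called overexpressed.
#' @param germline_gene_list Character vector of genes evaluated for germline
#'   predisposition findings (the clinical panel holds 220 genes; content is
#'   configurable).
#'
#' @return An object of class `rule_config` (a named list).
#' @export
rule_config <- function(wgs_vaf_min = 0.05,
                        wts_rescue_vaf = 0.25,
                        focal_cnv_max_bp = 5e6,
                        ls_cnv_min_bp = 5e6,
                        cnloh_min_bp = 10e6,
                        sub50kb_bp = 5e4,
                        enhancer_window_bp = 5e5,
                        cyto_visible_min_bp = 9e6,
                        subclonal_cnv_min_fraction = 0.35,
                        complex_karyotype_min = 3,
                        overexpression_z = 2.0,
                        germline_gene_list = character()) {
  cfg <- list(
    wgs_vaf_min = wgs_vaf_min,
    wts_rescue_vaf = wts_rescue_vaf,
    focal_cnv_max_bp = focal_cnv_max_bp,
    ls_cnv_min_bp = ls_cnv_min_bp,
    cnloh_min_bp = cnloh_min_bp,
    sub50kb_bp = sub50kb_bp,
    enhancer_window_bp = enhancer_window_bp,
    cyto_visible_min_bp = cyto_visible_min_bp,
    subclonal_cnv_min_fraction = subclonal_cnv_min_fraction,
    complex_karyotype_min = complex_karyotype_min,
    overexpression_z = overexpression_z,
    germline_gene_list = germline_gene_list
  )
  numeric_fields <- setdiff(names(cfg), "germline_gene_list")
  for (f in numeric_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("rule_config: `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (cfg$wgs_vaf_min >= cfg$wts_rescue_vaf) {
    stop("rule_config: wgs_vaf_min must be below wts_rescue_vaf", call. = FALSE)
  }
  structure(cfg, class = "rule_config")
}

#' Platform observation model
#'
#' Sensitivity parameters governing what a simulated testing platform observes
#' from a truth case: minimum CNV size and clone fraction (karyotype band
#' resolution and metaphase sampling), a VAF floor with read-sampling depth for
#' sequencing platforms, per-fusion-type cryptic miss probabilities (cryptic
#' rearrangements are invisible to banded karyotyping), and tumor purity.
#'
#' @param platform One of `"cytogenetics"`, `"fish"`, `"panel"`, `"wgs"`,
#'   `"wes"`, `"wts"`.
#' @param min_cnv_bp Minimum detectable CNV size (bp).
#' @param min_clone_fraction Minimum clone fraction of a detectable CNV.
#' @param vaf_floor VAF below which small variants go unreported.
#' @param cryptic_miss_prob Named numeric vector: probability that a fusion of
#'   the named type is missed by this platform.
#' @param purity Tumor purity of the assayed sample, fraction in (0, 1].
#' @param depth Sequencing depth used for binomial read-sampling jitter.
#'
#' @return An object of class `platform_model`.
#' @export
platform_model <- function(platform,
                           min_cnv_bp = 0,
                           min_clone_fraction = 0,
                           vaf_floor = 0,
                           cryptic_miss_prob = numeric(),
                           purity = 1,
                           depth = 60) {
  platform <- match.arg(platform,
                        c("cytogenetics", "fish", "panel", "wgs", "wes", "wts"))
  if (length(cryptic_miss_prob) &&
      (any(cryptic_miss_prob < 0) || any(cryptic_miss_prob > 1))) {
    stop("platform_model: cryptic_miss_prob values must lie in [0, 1]",
         call. = FALSE)
  }
  if (purity <= 0 || purity > 1) {
    stop("platform_model: purity must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(platform = platform, min_cnv_bp = min_cnv_bp,
         min_clone_fraction = min_clone_fraction, vaf_floor = vaf_floor,
         cryptic_miss_prob = cryptic_miss_prob, purity = purity, depth = depth),
    class = "platform_model"
  )
}

#' Default cytogenetics platform model
#'
#' Band resolution ~9 Mb, clones below ~35% of cells missed, and per-fusion
#' cryptic miss probabilities seeded from the observed cytogenetic miss rates
#' of the fusion detection comparison (see [fusion_detection_fixture()]).
#'
#' @param cfg A [rule_config()].
#' @return A `platform_model`.
#' @export
cytogenetics_model <- function(cfg = rule_config()) {
  tab <- fusion_detection_fixture()
  miss <- stats::setNames(tab$pct_missed_b / 100, tab$category)
  platform_model("cytogenetics",
                 min_cnv_bp = cfg$cyto_visible_min_bp,
                 min_clone_fraction = cfg$subclonal_cnv_min_fraction,
                 cryptic_miss_prob = miss)
}

#' Default WGS platform model
#'
#' @param cfg A [rule_config()].
#' @param purity Tumor purity of the sequenced sample.
#' @param depth Mean coverage used for binomial VAF jitter (the clinical assay
#'   averages ~60x genome coverage).
#' @return A `platform_model`.
#' @export
wgs_model <- function(cfg = rule_config(), purity = 1, depth = 60) {
  platform_model("wgs",
                 min_cnv_bp = 0,
                 min_clone_fraction = cfg$subclonal_cnv_min_fraction,
                 vaf_floor = cfg$wgs_vaf_min,
                 purity = purity,
                 depth = depth)
}
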