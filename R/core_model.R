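#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

PLATFORMS <- c("cytogenetics", "fish", "panel", "wgs", "wes", "wts")
PATHOGENICITY_LEVELS <- c("P", "LP", "VUS", "B/LB")
ITD_STRENGTHS <- c("strong", "weak", "none", "insufficient_coverage")
SUBTYPE_CATEGORIES <- c("who_fusion", "who_mutation", "proposed_class",
                        "aml_mr", "ds_aml", "rare_novel_fusion", "nos")
REPORT_PHASES <- c("phase1_day7", "phase2_day14", "phase3_day21")

#' Construct a small-variant call
#'
#' One somatic or germline SNV/indel with per-platform VAF evidence. VAFs are
#' fractions in `[0, 1]`; percent appears only at I/O boundaries. A platform
#' key present with value `NA` means the platform was assayed but had
#' insufficient coverage — distinct from an absent key (not assayed) and from
#' VAF 0 (assayed, negative).
#'
#' @param case_id,gene,chrom Identifiers.
#' @param pos 1-based genomic position.
#' @param ref,alt Reference and alternate allele strings (must differ).
#' @param origin `"somatic"` or `"germline"`.
#' @param pathogenicity One of `"P"`, `"LP"`, `"VUS"`, `"B/LB"`.
#' @param is_aml_driver Is the variant a recognized AML driver?
#' @param vaf Named numeric vector of per-platform VAFs, names from
#'   `cytogenetics|fish|panel|wgs|wes|wts`; `NA` means insufficient coverage.
#'
#' @return A one-row tibble of class `variant_call_tbl`.
#' @export
variant_call <- function(case_id, gene, chrom, pos, ref, alt,
                         origin = c("somatic", "germline"),
                         pathogenicity = c("P", "LP", "VUS", "B/LB"),
                         is_aml_driver = FALSE,
                         vaf = c(wgs = NA_real_)) {
  origin <- match.arg(origin)
  pathogenicity <- match.arg(pathogenicity)
  stopifnot(length(pos) == 1, length(ref) == 1, length(alt) == 1)
  if (pos < 1) stop("variant_call: pos must be >= 1", call. = FALSE)
  if (identical(ref, alt)) stop("variant_call: ref must differ from alt",
                                call. = FALSE)
  if (is.null(names(vaf)) || !all(names(vaf) %in% PLATFORMS)) {
    stop("variant_call: vaf must be named with known platforms", call. = FALSE)
  }
  bad <- !is.na(vaf) & (vaf < 0 | vaf > 1)
  if (any(bad)) stop("variant_call: VAF fractions must lie in [0, 1]",
                     call. = FALSE)
  out <- tibble(case_id = case_id, gene = gene, chrom = as.character(chrom),
                pos = as.integer(pos), ref = ref, alt = alt, origin = origin,
                pathogenicity = pathogenicity, is_aml_driver = is_aml_driver,
                vaf = list(vaf))
  class(out) <- c("variant_call_tbl", class(out))
  out
}

#' Extract one platform's VAF from a variant row
#'
#' @param v A one-row `variant_call_tbl`.
#' @param platform Platform name.
#' @return The VAF fraction; `NA` if the platform was assayed with
#'   insufficient coverage; `NULL` if the platform was never assayed.
#' @export
platform_vaf <- function(v, platform) {
  vv <- v$vaf[[1]]
  if (!platform %in% names(vv)) return(NULL)
  unname(vv[[platform]])
}

#' Construct a structural event (fusion, ITD, PTD, or other SV)
#'
#' Breakpoints are stored in canonical order (lexicographic chromosome, then
#' position); inputs given the other way round are swapped, together with
#' their gene/exon annotations.
#'
#' @param case_id Case identifier.
#' @param chromA,posA,strandA,chromB,posB,strandB Breakpoint pair (1-based).
#' @param geneA,geneB Partner gene symbols, or `"intergenic"`.
#' @param gene5p,gene3p Optional biological 5'/3' partner order; defaults to
#'   the order the genes were supplied in (kept through breakpoint
#'   canonicalization).
#' @param exonA,exonB Optional exon numbers flanking the junction.
#' @param frame `"in_frame"`, `"out_of_frame"`, `"non_coding"`, `"unknown"`.
#' @param event_class `"fusion"`, `"itd"`, `"ptd"`, `"other_sv"`.
#' @param fusion_category Driver tier annotation:
#'   `"who_defining"`, `"proposed_class_defining"`, `"rare_novel"`,
#'   `"non_driver"`.
#'
#' @return A one-row tibble of class `structural_event_tbl`; the `mechanism`
#'   column is `"unset"` until [classify_sv_mechanism()] runs.
#' @export
structural_event <- function(case_id, chromA, posA, chromB, posB,
                             geneA = "intergenic", geneB = "intergenic",
                             strandA = "+", strandB = "+",
                             exonA = NA_integer_, exonB = NA_integer_,
                             frame = c("unknown", "in_frame", "out_of_frame",
                                       "non_coding"),
                             event_class = c("fusion", "itd", "ptd",
                                             "other_sv"),
                             fusion_category = c("non_driver", "who_defining",
                                                 "proposed_class_defining",
                                                 "rare_novel"),
                             gene5p = NULL, gene3p = NULL) {
  frame <- match.arg(frame)
  event_class <- match.arg(event_class)
  fusion_category <- match.arg(fusion_category)
  if (event_class %in% c("itd", "ptd") && !identical(geneA, geneB)) {
    stop("structural_event: itd/ptd events are intragenic (geneA == geneB)",
         call. = FALSE)
  }
  # biological orientation as supplied by the caller (5' partner first),
  # preserved independently of breakpoint canonicalization
  if (is.null(gene5p)) gene5p <- geneA
  if (is.null(gene3p)) gene3p <- geneB
  chromA <- as.character(chromA); chromB <- as.character(chromB)
  swap <- (chromA > chromB) || (chromA == chromB && posA > posB)
  if (swap) {
    tmp <- list(chromA, posA, strandA, geneA, exonA)
    chromA <- chromB; posA <- posB; strandA <- strandB
    geneA <- geneB; exonA <- exonB
    chromB <- tmp[[1]]; posB <- tmp[[2]]; strandB <- tmp[[3]]
    geneB <- tmp[[4]]; exonB <- tmp[[5]]
  }
  out <- tibble(case_id = case_id,
                chromA = chromA, posA = as.integer(posA), strandA = strandA,
                chromB = chromB, posB = as.integer(posB), strandB = strandB,
                geneA = geneA, geneB = geneB,
                gene5p = gene5p, gene3p = gene3p,
                exonA = as.integer(exonA), exonB = as.integer(exonB),
                frame = frame, event_class = event_class,
                mechanism = "unset", fusion_category = fusion_category)
  class(out) <- c("structural_event_tbl", class(out))
  out
}

#' Construct FLT3-ITD (or other intragenic tandem duplication) evidence
#'
#' @param case_id Case identifier.
#' @param gene Gene symbol (clinically, FLT3).
#' @param wgs_strength,wts_strength Evidence strength on each platform:
#'   `"strong"`, `"weak"`, `"none"`, or `"insufficient_coverage"`.
#' @param pcr_ratio Optional ITD:wild-type ratio from orthogonal PCR fragment
#'   analysis (nonnegative).
#' @return A one-row tibble of class `itd_evidence_tbl`.
#' @export
itd_evidence <- function(case_id, gene = "FLT3",
                         wgs_strength, wts_strength, pcr_ratio = NA_real_) {
  wgs_strength <- match.arg(wgs_strength, ITD_STRENGTHS)
  wts_strength <- match.arg(wts_strength, ITD_STRENGTHS)
  if (!is.na(pcr_ratio) && pcr_ratio < 0) {
    stop("itd_evidence: pcr_ratio must be nonnegative", call. = FALSE)
  }
  out <- tibble(case_id = case_id, gene = gene,
                wgs_strength = wgs_strength, wts_strength = wts_strength,
                pcr_ratio = as.numeric(pcr_ratio))
  class(out) <- c("itd_evidence_tbl", class(out))
  out
}

#' Construct a copy-number / cnLOH segment
#'
#' Coordinates are 1-based inclusive (SEG convention after conversion);
#' `size_bp` is derived as `end - start + 1`.
#'
#' @param case_id,chrom Identifiers.
#' @param start,end 1-based inclusive segment bounds, `end >= start`.
#' @param kind `"gain"`, `"loss"`, or `"cnloh"`.
#' @param clone_fraction Fraction of tumor cells carrying the segment.
#' @param sv_supported Is the segment supported by breakpoint-level SV reads?
#' @param gene Optional gene annotation for intragenic events.
#' @return A one-row tibble of class `cnv_segment_tbl`; `scale_class` is
#'   `"unset"` until [classify_cnv_event()] runs.
#' @export
cnv_segment <- function(case_id, chrom, start, end,
                        kind = c("gain", "loss", "cnloh"),
                        clone_fraction = 1, sv_supported = FALSE,
                        gene = NA_character_) {
  kind <- match.arg(kind)
  if (end < start) stop("cnv_segment: end must be >= start", call. = FALSE)
  if (clone_fraction < 0 || clone_fraction > 1) {
    stop("cnv_segment: clone_fraction must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble(case_id = case_id, chrom = as.character(chrom),
                start = as.numeric(start), end = as.numeric(end),
                kind = kind, size_bp = as.numeric(end) - as.numeric(start) + 1,
                clone_fraction = clone_fraction, sv_supported = sv_supported,
                gene = as.character(gene), scale_class = "unset",
                sub50kb_flag = FALSE)
  class(out) <- c("cnv_segment_tbl", class(out))
  out
}

#' Construct a cytogenetic lesion record
#'
#' @param kind `"monosomy"`, `"trisomy"`, `"deletion"`, `"addition"`,
#'   `"translocation"`, `"isochromosome"`, `"marker"`, or `"other"`.
#' @param chrom Chromosome (empty for markers).
#' @param arm_or_band Band/arm descriptor, e.g. `"q31"` or `"q22q36"`.
#' @param chrom2,band2 Second chromosome/band for translocations.
#' @param size_mb Optional lesion extent in Mb where known.
#' @param clonal Is the lesion clonal?
#' @return A one-row tibble of class `cyto_lesion_tbl`.
#' @export
cyto_lesion <- function(kind, chrom = NA_character_, arm_or_band = "",
                        chrom2 = NA_character_, band2 = NA_character_,
                        size_mb = NA_real_, clonal = TRUE) {
  kind <- match.arg(kind, c("monosomy", "trisomy", "deletion", "addition",
                            "translocation", "isochromosome", "marker",
                            "other"))
  if (kind == "translocation" && (is.na(chrom2) || is.na(band2))) {
    stop("cyto_lesion: translocations need both chromosome/band pairs",
         call. = FALSE)
  }
  out <- tibble(kind = kind, chrom = as.character(chrom),
                arm_or_band = arm_or_band, chrom2 = as.character(chrom2),
                band2 = band2, size_mb = size_mb, clonal = clonal)
  class(out) <- c("cyto_lesion_tbl", class(out))
  out
}

#' Construct a parsed karyotype record
#'
#' @param iscn The source ISCN string.
#' @param lesions A `cyto_lesion_tbl` (zero or more rows).
#' @param metaphases_total,metaphases_abnormal Metaphase counts.
#' @return A list of class `karyotype_record`.
#' @export
karyotype_record <- function(iscn, lesions = cyto_lesion_tbl_empty(),
                             metaphases_total = NA_integer_,
                             metaphases_abnormal = NA_integer_) {
  if (!is.na(metaphases_total) && !is.na(metaphases_abnormal) &&
      metaphases_abnormal > metaphases_total) {
    stop("karyotype_record: abnormal metaphases exceed total", call. = FALSE)
  }
  structure(
    list(iscn = iscn, lesions = lesions,
         n_abnormalities = sum(lesions$clonal),
         metaphases_total = metaphases_total,
         metaphases_abnormal = metaphases_abnormal),
    class = "karyotype_record"
  )
}

#' @rdname cyto_lesion
#' @export
cyto_lesion_tbl_empty <- function() {
  out <- tibble(kind = character(), chrom = character(),
                arm_or_band = character(), chrom2 = character(),
                band2 = character(), size_mb = numeric(), clonal = logical())
  class(out) <- c("cyto_lesion_tbl", class(out))
  out
}

#' Construct an expression profile
#'
#' @param case_id Case identifier.
#' @param values Named numeric vector of nonnegative normalized abundances,
#'   one per gene (unique names).
#' @param cohort_id Reference-grouping identifier.
#' @return A list of class `expression_profile`.
#' @export
expression_profile <- function(case_id, values, cohort_id = "default") {
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop("expression_profile: values need unique gene names", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("expression_profile: abundances must be nonnegative", call. = FALSE)
  }
  structure(list(case_id = case_id, values = values, cohort_id = cohort_id),
            class = "expression_profile")
}

#' Assemble a per-case evidence bundle
#'
#' The unit of analysis: one patient's small variants, structural events,
#' ITD evidence, CNV segments, optional karyotype, and optional expression
#' profile, with clinical context (disease setting, Down syndrome status,
#' blast percentage as a tumor-content proxy).
#'
#' @param case_id Case identifier (unique within a cohort).
#' @param sex `"M"`, `"F"`, or `NA`.
#' @param age_years Age at diagnosis.
#' @param disease_context `"de_novo"`, `"post_cytotoxic"`, or `"relapse"`.
#' @param down_syndrome Down syndrome status.
#' @param blast_percent Bone-marrow blast percentage in `[0, 100]`.
#' @param variants,svs,itds,cnvs Record tibbles (possibly empty) built with
#'   the respective constructors.
#' @param karyotype Optional [karyotype_record()].
#' @param expression Optional [expression_profile()].
#' @return A list of class `case_profile`.
#' @export
case_profile <- function(case_id, sex = NA_character_, age_years = NA_real_,
                         disease_context = c("de_novo", "post_cytotoxic",
                                             "relapse"),
                         down_syndrome = FALSE, blast_percent = NA_real_,
                         variants = NULL, svs = NULL, itds = NULL,
                         cnvs = NULL, karyotype = NULL, expression = NULL) {
  disease_context <- match.arg(disease_context)
  structure(
    list(case_id = case_id, sex = sex, age_years = age_years,
         disease_context = disease_context, down_syndrome = down_syndrome,
         blast_percent = blast_percent,
         variants = variants %||% empty_variants(),
         svs = svs %||% empty_svs(),
         itds = itds %||% empty_itds(),
         cnvs = cnvs %||% empty_cnvs(),
         karyotype = karyotype, expression = expression),
    class = "case_profile"
  )
}

empty_variants <- function() variant_call("x", "g", "1", 1, "A", "C")[0, ]
empty_svs <- function() structural_event("x", "1", 1, "2", 1)[0, ]
empty_itds <- function() itd_evidence("x", wgs_strength = "none",
                                      wts_strength = "none")[0, ]
empty_cnvs <- function() cnv_segment("x", "1", 1, 2, "loss")[0, ]

#' Validate a case profile against the domain invariants
#'
#' Violations are data, not exceptions: each is a row naming the field and the
#' broken rule, so a cohort can be linted wholesale. An empty result means the
#' profile satisfies every invariant. The check is idempotent and insensitive
#' to the order of records within each evidence table.
#'
#' @param profile A [case_profile()].
#' @return A tibble with columns `field` and `rule` (zero rows when valid).
#' @export
validate_case_profile <- function(profile) {
  v <- list()
  add <- function(field, rule) {
    v[[length(v) + 1]] <<- tibble(field = field, rule = rule)
  }
  bp <- profile$blast_percent
  if (!is.na(bp) && (bp < 0 || bp > 100)) {
    add("blast_percent", "must lie in [0, 100]")
  }
  vars <- profile$variants
  if (nrow(vars)) {
    for (i in seq_len(nrow(vars))) {
      vv <- vars$vaf[[i]]
      if (length(vv) == 0) add("variants.vaf", "at least one platform entry")
      if (any(!is.na(vv) & (vv < 0 | vv > 1))) {
        add("variants.vaf", "VAF fractions must lie in [0, 1]")
      }
    }
    if (any(vars$ref == vars$alt)) add("variants.ref", "ref must differ from alt")
    if (any(vars$pos < 1)) add("variants.pos", "positions are 1-based (>= 1)")
  }
  cnvs <- profile$cnvs
  if (nrow(cnvs)) {
    if (any(cnvs$end < cnvs$start)) add("cnvs.coordinates", "end must be >= start")
    if (any(cnvs$size_bp != cnvs$end - cnvs$start + 1)) {
      add("cnvs.size_bp", "size_bp must equal end - start + 1")
    }
    if (any(cnvs$clone_fraction < 0 | cnvs$clone_fraction > 1)) {
      add("cnvs.clone_fraction", "must lie in [0, 1]")
    }
  }
  svs <- profile$svs
  if (nrow(svs)) {
    bad_order <- svs$chromA > svs$chromB |
      (svs$chromA == svs$chromB & svs$posA > svs$posB)
    if (any(bad_order)) add("svs.breakpoints", "must be canonically ordered")
    intragenic <- svs$event_class %in% c("itd", "ptd")
    if (any(intragenic & svs$geneA != svs$geneB)) {
      add("svs.genes", "itd/ptd events must have geneA == geneB")
    }
  }
  itds <- profile$itds
  if (nrow(itds)) {
    if (!all(itds$wgs_strength %in% ITD_STRENGTHS) ||
        !all(itds$wts_strength %in% ITD_STRENGTHS)) {
      add("itds.strength", "unknown evidence strength value")
    }
  }
  k <- profile$karyotype
  if (!is.null(k)) {
    if (k$n_abnormalities != sum(k$lesions$clonal)) {
      add("karyotype.n_abnormalities", "must equal count of clonal lesions")
    }
    if (!is.na(k$metaphases_total) && !is.na(k$metaphases_abnormal) &&
        k$metaphases_abnormal > k$metaphases_total) {
      add("karyotype.metaphases", "abnormal count exceeds total")
    }
  }
  e <- profile$expression
  if (!is.null(e)) {
    if (any(e$values < 0, na.rm = TRUE)) add("expression.values", "must be >= 0")
    if (anyDuplicated(names(e$values))) add("expression.values", "genes must be unique")
  }
  if (length(v)) dplyr::bind_rows(v) else tibble(field = character(),
                                                 rule = character())
}
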