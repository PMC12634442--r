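#' Molecular subtype outcome
#'
#' @param category One of `who_fusion`, `who_mutation`, `proposed_class`,
#'   `aml_mr`, `ds_aml`, `rare_novel_fusion`, `nos`.
#' @param defining_lesion A list describing the defining lesion (`type`,
#'   `label`), or `NULL`; `NULL` iff category is `nos`.
#' @param secondary_drivers Character labels of non-defining reportable
#'   driver lesions.
#' @param report_phase Reporting phase for the defining finding.
#' @return A list of class `molecular_subtype`.
#' @export
molecular_subtype <- function(category, defining_lesion = NULL,
                              secondary_drivers = character(),
                              report_phase = NA_character_) {
  category <- match.arg(category, SUBTYPE_CATEGORIES)
  if ((category == "nos") != is.null(defining_lesion)) {
    stop("molecular_subtype: defining_lesion must be NULL iff category is nos",
         call. = FALSE)
  }
  structure(
    list(category = category, defining_lesion = defining_lesion,
         secondary_drivers = secondary_drivers, report_phase = report_phase),
    class = "molecular_subtype"
  )
}

#' Is a karyotype complex?
#'
#' Complex means at least `complex_karyotype_min` (default 3) distinct clonal
#' chromosomal abnormalities.
#'
#' @param k A [karyotype_record()].
#' @param cfg A [rule_config()].
#' @return Logical.
#' @export
is_complex_karyotype <- function(k, cfg = rule_config()) {
  sum(k$lesions$clonal) >= cfg$complex_karyotype_min
}

# Approximate GRCh38 centromere positions and lengths for the chromosomes
# carrying AML-MR defining arm-level lesions. Arm assignment only needs to be
# correct at the arm scale; band-level precision is irrelevant here.
ARM_TABLE <- tibble::tribble(
  ~chrom, ~cen_bp, ~len_bp,
  "5",  48.8e6, 181.5e6,
  "7",  60.1e6, 159.3e6,
  "11", 53.4e6, 135.1e6,
  "12", 35.5e6, 133.3e6,
  "17", 25.1e6,  83.3e6
)

# Map one large-scale WGS loss to an AML-MR arm pattern ("5q-", "mono7",
# "7q-", "11q-", "12p-", "17p-") or NA. A loss spanning >= 80% of the
# chromosome counts as a monosomy.
aml_mr_pattern_of_loss <- function(chrom, start, end) {
  chrom <- sub("^chr", "", as.character(chrom))
  row <- ARM_TABLE[ARM_TABLE$chrom == chrom, ]
  if (nrow(row) == 0) return(NA_character_)
  if ((end - start + 1) >= 0.8 * row$len_bp) {
    return(if (chrom == "7") "mono7" else NA_character_)
  }
  arm <- if ((start + end) / 2 < row$cen_bp) "p" else "q"
  pat <- paste0(chrom, arm, "-")
  if (pat %in% c("5q-", "7q-", "11q-", "12p-", "17p-")) pat else NA_character_
}

# Map one cytogenetic lesion to an AML-MR pattern or NA.
aml_mr_pattern_of_lesion <- function(kind, chrom, arm_or_band) {
  chrom <- as.character(chrom)
  first_arm <- substr(sub("^[^pq]*", "", arm_or_band), 1, 1)
  if (kind == "monosomy" && chrom == "7") return("mono7")
  if (kind == "isochromosome" && chrom == "17" && first_arm == "q") {
    return("i17q")
  }
  if (kind == "deletion") {
    pat <- paste0(chrom, first_arm, "-")
    if (pat %in% c("5q-", "7q-", "11q-", "12p-", "17p-")) return(pat)
  }
  NA_character_
}

#' Evaluate myelodysplasia-related (AML-MR) defining evidence
#'
#' A case carries AML-MR defining evidence when any karyotype lesion or
#' large-scale WGS loss maps to an AML-MR cytogenetic pattern (5q-, monosomy
#' 7 / 7q-, 11q-, 12p-, 17p-, i(17q)), the karyotype is complex, or a somatic
#' P/LP mutation hits an AML-MR defining gene. WGS losses are mapped to
#' arm-level patterns, so segmental deletions invisible to banded karyotyping
#' still count.
#'
#' @param lesions A `cyto_lesion_tbl` (karyotype lesions; may be empty).
#' @param cnvs A scale-classified `cnv_segment_tbl`.
#' @param muts A `variant_call_tbl` of somatic mutations.
#' @param rules A `classification_rules` object.
#' @param cfg A [rule_config()].
#' @return A list with `flag` (logical) and `matched` (tibble of `source`,
#'   `pattern` rows).
#' @export
evaluate_aml_mr <- function(lesions, cnvs, muts, rules, cfg = rule_config()) {
  matched <- list()
  note <- function(source, pattern) {
    matched[[length(matched) + 1]] <<- tibble(source = source,
                                              pattern = pattern)
  }
  if (!is.null(lesions) && nrow(lesions)) {
    for (i in seq_len(nrow(lesions))) {
      p <- aml_mr_pattern_of_lesion(lesions$kind[i], lesions$chrom[i],
                                    lesions$arm_or_band[i])
      if (!is.na(p) && p %in% rules$aml_mr_cyto) note("karyotype", p)
    }
    if ("complex" %in% rules$aml_mr_cyto &&
        sum(lesions$clonal) >= cfg$complex_karyotype_min) {
      note("karyotype", "complex")
    }
  }
  if (!is.null(cnvs) && nrow(cnvs)) {
    big_loss <- cnvs$kind == "loss" & cnvs$scale_class == "large_scale"
    for (i in which(big_loss)) {
      p <- aml_mr_pattern_of_loss(cnvs$chrom[i], cnvs$start[i], cnvs$end[i])
      if (!is.na(p) && p %in% rules$aml_mr_cyto) note("wgs_cnv", p)
    }
  }
  if (!is.null(muts) && nrow(muts)) {
    hits <- muts$origin == "somatic" & muts$pathogenicity %in% c("P", "LP") &
      muts$gene %in% rules$aml_mr_genes
    for (g in unique(muts$gene[hits])) note("mutation", g)
  }
  matched <- if (length(matched)) dplyr::bind_rows(matched) else
    tibble(source = character(), pattern = character())
  list(flag = nrow(matched) > 0, matched = matched)
}

#' Run all evidence rules over one case
#'
#' Computes everything [classify_case()] consumes: per-variant reportability,
#' scale-classified CNVs, ITD decisions, SV mechanism classification, and
#' expression-based validation of enhancer-hijack candidates (candidates stay
#' `unevaluated` when no expression data or reference cohort is supplied; an
#' unevaluated candidate remains eligible as a defining lesion — only an
#' expression-refuted one is excluded).
#'
#' @param profile A [case_profile()].
#' @param cfg A [rule_config()].
#' @param oncogene_regions Oncogene coding spans for mechanism classification
#'   (default [default_oncogene_regions()]).
#' @param reference_expression Optional list of [expression_profile()]s used
#'   as the overexpression reference; cases rearranged at the target gene are
#'   excluded per call.
#' @param cohort_svs Optional cohort-wide `structural_event_tbl` used to
#'   exclude rearranged cases from the reference.
#' @return A list of class `case_evidence` with elements `variants` (with
#'   `status`/`code` columns), `cnvs`, `itds` (with `status`/`code`), `svs`
#'   (with `mechanism`, `hijack_target`, `hijack_status`).
#' @export
evaluate_case_evidence <- function(profile, cfg = rule_config(),
                                   oncogene_regions =
                                     default_oncogene_regions(),
                                   reference_expression = NULL,
                                   cohort_svs = NULL) {
  vars <- profile$variants
  if (nrow(vars)) {
    dec <- purrr::map(seq_len(nrow(vars)), function(i) {
      if (vars$origin[i] != "somatic") {
        return(list(status = "not_reportable", code = "GERMLINE_ORIGIN"))
      }
      d <- assess_snv_reportability(vars[i, ], cfg)
      list(status = d$status, code = d$rationale_codes[1])
    })
    vars$status <- purrr::map_chr(dec, "status")
    vars$code <- purrr::map_chr(dec, "code")
  } else {
    vars$status <- character(0)
    vars$code <- character(0)
  }
  cnvs <- classify_cnv_event(profile$cnvs, cfg)
  itds <- profile$itds
  if (nrow(itds)) {
    dec <- purrr::map(seq_len(nrow(itds)),
                      function(i) combine_itd_evidence(itds[i, ]))
    itds$status <- purrr::map_chr(dec, "status")
    itds$code <- purrr::map_chr(dec, function(d) d$rationale_codes[1])
  } else {
    itds$status <- character(0)
    itds$code <- character(0)
  }
  svs <- profile$svs
  if (nrow(svs) && all(svs$mechanism == "unset")) {
    svs <- classify_sv_mechanism(svs, oncogene_regions, cfg)
  }
  if (!"hijack_target" %in% names(svs)) svs$hijack_target <- NA_character_
  svs$hijack_status <- ifelse(svs$mechanism == "enhancer_hijack_candidate",
                              "unevaluated", NA_character_)
  cand <- which(svs$mechanism == "enhancer_hijack_candidate")
  if (length(cand) && !is.null(profile$expression) &&
      !is.null(reference_expression)) {
    for (i in cand) {
      target <- svs$hijack_target[i]
      if (is.na(target) || !target %in% names(profile$expression$values)) next
      ref <- reference_profiles_for_gene(target, reference_expression,
                                         cohort_svs %||% svs)
      if (length(ref) < 2) next
      call <- tryCatch(
        overexpression_call(target, profile$expression, ref, cfg),
        error = function(e) NULL
      )
      if (is.null(call)) next
      svs$hijack_status[i] <- validate_enhancer_hijack(svs[i, ], call)
    }
  }
  structure(list(variants = vars, cnvs = cnvs, itds = itds, svs = svs),
            class = "case_evidence")
}

#' Default oncogene coding spans for enhancer-hijack surveillance
#'
#' Approximate GRCh38 spans of the oncogenes recurrently activated by
#' enhancer hijacking in AML (MECOM, HOXA cluster genes, BCL11B, TLX3,
#' NKX2-5). Coordinates only need arm-scale accuracy relative to the
#' configured enhancer window.
#'
#' @return Named list of `c(chrom, start, end)` vectors.
#' @export
default_oncogene_regions <- function() {
  list(
    MECOM   = list("3", 169.08e6, 169.66e6),
    HOXA13  = list("7", 27.19e6, 27.20e6),
    HOXA10  = list("7", 27.17e6, 27.18e6),
    BCL11B  = list("14", 99.17e6, 99.27e6),
    TLX3    = list("5", 171.30e6, 171.31e6),
    `NKX2-5` = list("5", 173.23e6, 173.24e6)
  )
}

fusion_label <- function(sv_row) {
  if (sv_row$mechanism == "enhancer_hijack_candidate" &&
      !is.na(sv_row$hijack_target)) {
    return(paste0(sv_row$hijack_target, "-r"))
  }
  paste0(sv_row$gene5p, "::", sv_row$gene3p)
}

# Reportable TP53 hit count: P/LP reportable TP53 variants, plus 17p
# large-scale loss, plus cnLOH over the TP53 locus (17p13, ~7.6 Mb).
tp53_hits <- function(vars, cnvs) {
  n <- sum(vars$gene == "TP53" & vars$status == "reportable")
  if (nrow(cnvs)) {
    loss17p <- cnvs$kind == "loss" & cnvs$scale_class == "large_scale" &
      sub("^chr", "", cnvs$chrom) == "17" &
      (cnvs$start + cnvs$end) / 2 < 25.1e6
    n <- n + as.integer(any(loss17p))
    cnloh17p <- cnvs$kind == "cnloh" &
      sub("^chr", "", cnvs$chrom) == "17" &
      cnvs$start <= 7.6e6 & cnvs$end >= 7.6e6
    n <- n + as.integer(any(cnloh17p))
  }
  n
}

#' Assign a case its molecular subtype
#'
#' Tiered, deterministic classification; the first matching tier wins:
#' \enumerate{
#'   \item Down syndrome with a reportable pathogenic GATA1 variant: DS-AML.
#'   \item A reportable WHO AML-defining fusion (including a non-refuted
#'     enhancer hijack of a WHO-listed gene such as MECOM).
#'   \item A WHO AML-defining mutation (NPM1, CEBPA, biallelic TP53 counted
#'     as two P/LP hits among variants, 17p loss, or cnLOH over TP53).
#'   \item A proposed class-defining lesion (fusion or mutation pattern).
#'   \item AML-MR defining evidence with no tier 1-4 driver.
#'   \item Any remaining reportable in-frame fusion (rare/novel).
#'   \item Otherwise NOS (no defining lesion).
#' }
#' Within a tier, candidate fusions are considered alphabetically by 5'
#' partner, so within-tier conflicts (a case carrying two class-defining
#' fusions) resolve reproducibly. Non-defining reportable lesions are
#' recorded as secondary drivers.
#'
#' @param profile A [case_profile()].
#' @param rules A `classification_rules` object.
#' @param cfg A [rule_config()].
#' @param evidence Optional precomputed [evaluate_case_evidence()] output.
#' @return A [molecular_subtype()].
#' @export
classify_case <- function(profile, rules = default_classification_rules(),
                          cfg = rule_config(), evidence = NULL) {
  ev <- evidence %||% evaluate_case_evidence(profile, cfg)
  vars <- ev$variants
  cnvs <- ev$cnvs
  svs <- ev$svs
  itds <- ev$itds

  # Candidate driver fusions: reportable in-frame fusions plus non-refuted
  # enhancer-hijack candidates, alphabetical by 5' partner (then target).
  fus <- svs[svs$event_class %in% c("fusion", "other_sv") &
               (svs$mechanism == "in_frame_fusion" |
                  (svs$mechanism == "enhancer_hijack_candidate" &
                     svs$hijack_status != "refuted")), , drop = FALSE]
  if (nrow(fus)) fus <- fus[order(fus$geneA, fus$geneB), , drop = FALSE]

  rep_vars <- vars[vars$status == "reportable", , drop = FALSE]
  mut_genes <- unique(rep_vars$gene)

  secondary <- character()
  add_secondary <- function(labels) {
    secondary <<- unique(c(secondary, labels))
  }
  fusion_labels <- if (nrow(fus)) {
    vapply(seq_len(nrow(fus)), function(i) fusion_label(fus[i, ]),
           character(1))
  } else character()
  driver_mut_labels <- rep_vars$gene[rep_vars$is_aml_driver]
  itd_labels <- if (nrow(itds)) {
    paste0(itds$gene, "-ITD")[itds$status %in% c("reportable", "borderline")]
  } else character()

  finish <- function(category, lesion, phase) {
    keep <- setdiff(unique(c(fusion_labels, driver_mut_labels, itd_labels)),
                    if (is.null(lesion)) character() else lesion$label)
    molecular_subtype(category, lesion, keep, phase)
  }

  # Tier 1: Down syndrome AML
  if (isTRUE(profile$down_syndrome) &&
      any(rep_vars$gene == "GATA1")) {
    return(finish("ds_aml", list(type = "mutation", label = "GATA1"),
                  "phase1_day7"))
  }
  # Tier 2: WHO-defining fusion
  if (nrow(fus)) {
    for (i in seq_len(nrow(fus))) {
      if (!is.na(match_fusion_tier(fus[i, ], rules$who_fusions))) {
        return(finish("who_fusion",
                      list(type = "fusion", label = fusion_label(fus[i, ])),
                      "phase1_day7"))
      }
    }
  }
  # Tier 3: WHO-defining mutation
  plain_who <- setdiff(rules$who_mutations, "TP53:biallelic")
  for (g in plain_who) {
    if (g %in% mut_genes) {
      return(finish("who_mutation", list(type = "mutation", label = g),
                    "phase1_day7"))
    }
  }
  if ("TP53:biallelic" %in% rules$who_mutations &&
      tp53_hits(vars, cnvs) >= 2) {
    return(finish("who_mutation",
                  list(type = "mutation", label = "biTP53"), "phase1_day7"))
  }
  # Tier 4: proposed class-defining lesion
  if (nrow(fus)) {
    for (i in seq_len(nrow(fus))) {
      if (!is.na(match_fusion_tier(fus[i, ], rules$proposed_class_fusions))) {
        return(finish("proposed_class",
                      list(type = "fusion", label = fusion_label(fus[i, ])),
                      "phase1_day7"))
      }
    }
  }
  for (g in rules$proposed_class_mutations) {
    if (g %in% mut_genes) {
      return(finish("proposed_class", list(type = "mutation", label = g),
                    "phase1_day7"))
    }
  }
  # Remaining candidate driver fusions (rare/novel in-frame fusions or a
  # confirmed hijack of an unlisted oncogene)
  eligible <- if (nrow(fus)) {
    fus[fus$mechanism == "in_frame_fusion" |
          fus$hijack_status %in% "confirmed", , drop = FALSE]
  } else fus
  # Tier 5: AML-MR requires the absence of any other known or potential
  # genetic driver, including a rare/novel fusion
  lesions <- if (!is.null(profile$karyotype)) profile$karyotype$lesions else
    cyto_lesion_tbl_empty()
  mr <- evaluate_aml_mr(lesions, cnvs, vars, rules, cfg)
  if (mr$flag && nrow(eligible) == 0) {
    return(finish("aml_mr",
                  list(type = "cyto",
                       label = paste(unique(mr$matched$pattern),
                                     collapse = "+")),
                  "phase1_day7"))
  }
  # Tier 6: rare / novel in-frame fusion
  if (nrow(eligible)) {
    return(finish("rare_novel_fusion",
                  list(type = "fusion",
                       label = fusion_label(eligible[1, ])),
                  "phase2_day14"))
  }
  finish("nos", NULL, "phase3_day21")
}

#' Assign a reporting phase to a finding
#'
#' Phased reporting: WHO or proposed class-defining driver fusions, driver
#' mutations, and large-scale CNVs go out in the rapid tumor report (day 7);
#' rare or novel fusions and cooperating somatic variants follow in the
#' integrated report (day 14); germline findings wait for the paired
#' tumor-normal report (day 21).
#'
#' @param category One of `"who_fusion"`, `"proposed_fusion"`,
#'   `"driver_mutation"`, `"ls_cnv"`, `"rare_novel_fusion"`,
#'   `"cooperating_variant"`, `"germline"`.
#' @return `"phase1_day7"`, `"phase2_day14"`, or `"phase3_day21"`.
#' @export
assign_report_phase <- function(category) {
  phase <- switch(category,
    who_fusion = , proposed_fusion = , driver_mutation = ,
    ls_cnv = "phase1_day7",
    rare_novel_fusion = , cooperating_variant = "phase2_day14",
    germline = "phase3_day21",
    NULL
  )
  if (is.null(phase)) {
    stop("assign_report_phase: unknown finding category `", category, "`",
         call. = FALSE)
  }
  phase
}
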