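#' Report decision helper
#'
#' @param status `"reportable"`, `"borderline"`, or `"not_reportable"`.
#' @param rationale_codes Character vector of short codes explaining the
#'   decision (non-empty unless the finding is not reportable).
#' @return A list of class `report_decision`.
#' @export
report_decision <- function(status, rationale_codes = character()) {
  status <- match.arg(status, c("reportable", "borderline", "not_reportable"))
  if (status != "not_reportable" && length(rationale_codes) == 0) {
    stop("report_decision: rationale required for (borderline-)reportable",
         call. = FALSE)
  }
  structure(list(status = status, rationale_codes = rationale_codes),
            class = "report_decision")
}

#' Assess reportability of a somatic small variant
#'
#' A somatic P/LP variant is reportable when its WGS VAF reaches the genomic
#' threshold (default 5%). A sub-threshold somatic P/LP variant is rescued by
#' the transcriptome when it is a recognized AML driver and its WTS VAF
#' strictly exceeds the rescue threshold (default 25%): high mutant-allele
#' abundance in RNA is taken as independent confirmation that the subclone is
#' transcriptionally active. Evidence from WES or panel platforms never
#' triggers a rescue.
#'
#' @param v A one-row `variant_call_tbl` with a WGS evidence entry (possibly
#'   `NA`, meaning insufficient coverage).
#' @param cfg A [rule_config()].
#' @return A [report_decision()] whose codes are drawn from `VAF_PASS`,
#'   `WTS_RESCUE`, `VAF_FAIL`, `NOT_PLP`, `GERMLINE_ORIGIN`.
#' @export
assess_snv_reportability <- function(v, cfg = rule_config()) {
  stopifnot(nrow(v) == 1)
  if (is.na(v$pathogenicity) || !v$pathogenicity %in% PATHOGENICITY_LEVELS) {
    stop("assess_snv_reportability: pathogenicity annotation is required",
         call. = FALSE)
  }
  if (is.null(platform_vaf(v, "wgs"))) {
    stop("assess_snv_reportability: a WGS evidence entry is required",
         call. = FALSE)
  }
  if (v$origin != "somatic") {
    return(report_decision("not_reportable", "GERMLINE_ORIGIN"))
  }
  if (!v$pathogenicity %in% c("P", "LP")) {
    return(report_decision("not_reportable", "NOT_PLP"))
  }
  wgs <- platform_vaf(v, "wgs")
  if (!is.na(wgs) && wgs >= cfg$wgs_vaf_min) {
    return(report_decision("reportable", "VAF_PASS"))
  }
  wts <- platform_vaf(v, "wts")
  if (isTRUE(v$is_aml_driver) && !is.null(wts) && !is.na(wts) &&
      wts > cfg$wts_rescue_vaf) {
    return(report_decision("reportable", "WTS_RESCUE"))
  }
  report_decision("not_reportable", "VAF_FAIL")
}

#' Filter germline variants to reportable predisposition findings
#'
#' Retains pathogenic/likely pathogenic germline variants in genes on the
#' configured predisposition panel (clinically, 220 genes associated with
#' cancer predisposition and bone marrow failure).
#'
#' @param variants A `variant_call_tbl` of germline-origin variants.
#' @param cfg A [rule_config()] with a non-empty `germline_gene_list`.
#' @return The reportable subset, same columns.
#' @export
filter_germline_findings <- function(variants, cfg) {
  if (length(cfg$germline_gene_list) == 0) {
    stop("filter_germline_findings: germline_gene_list must be configured",
         call. = FALSE)
  }
  dplyr::filter(variants,
                .data$origin == "germline",
                .data$pathogenicity %in% c("P", "LP"),
                .data$gene %in% cfg$germline_gene_list)
}

#' Classify a CNV / cnLOH segment into its scale class
#'
#' Gains and losses partition into focal (strictly below 5 Mb) versus
#' large-scale (>= 5 Mb). Copy-neutral LOH is only reported at large scale
#' (>= 10 Mb); shorter cnLOH stays sub-threshold. Focal events below 50 kb
#' are additionally flagged for intragenic review, where recurrent
#' exon-truncating deletions (e.g. CBL exons 8/9) and KMT2A partial tandem
#' duplications live.
#'
#' @param seg A `cnv_segment_tbl` (any number of rows).
#' @param cfg A [rule_config()].
#' @return `seg` with `scale_class` and `sub50kb_flag` filled in.
#' @export
classify_cnv_event <- function(seg, cfg = rule_config()) {
  if (nrow(seg) == 0) return(seg)
  stopifnot(all(seg$size_bp > 0))
  seg$scale_class <- ifelse(
    seg$kind == "cnloh",
    ifelse(seg$size_bp >= cfg$cnloh_min_bp, "large_scale", "sub_threshold"),
    ifelse(seg$size_bp < cfg$focal_cnv_max_bp, "focal", "large_scale")
  )
  seg$sub50kb_flag <- seg$kind != "cnloh" & seg$scale_class == "focal" &
    seg$size_bp < cfg$sub50kb_bp
  seg
}

#' Combine WGS and WTS evidence for an internal tandem duplication
#'
#' Decision table over the two evidence strengths. Strong genomic evidence is
#' sufficient on its own (the transcriptome may simply lack coverage of the
#' duplicated exons); transcriptome-only strong evidence is a borderline
#' finding pending orthogonal confirmation (PCR fragment analysis); weak
#' evidence on both platforms is likewise borderline rather than dismissed,
#' because orthogonal confirmation has validated such events.
#'
#' @param e A one-row `itd_evidence_tbl`.
#' @return A [report_decision()] with codes from `ITD_BOTH_STRONG`,
#'   `ITD_WGS_STRONG`, `ITD_WTS_ONLY`, `ITD_WEAK_BOTH`, `ITD_NO_EVIDENCE`.
#' @export
combine_itd_evidence <- function(e) {
  stopifnot(nrow(e) == 1)
  wgs <- e$wgs_strength
  wts <- e$wts_strength
  if (wgs == "strong" && wts == "strong") {
    return(report_decision("reportable", "ITD_BOTH_STRONG"))
  }
  if (wgs == "strong") {
    return(report_decision("reportable", "ITD_WGS_STRONG"))
  }
  if (wts == "strong") {
    # wgs is weak / none / insufficient: RNA-only evidence is borderline
    return(report_decision("borderline", "ITD_WTS_ONLY"))
  }
  if (wgs == "weak" || wts == "weak") {
    return(report_decision("borderline", "ITD_WEAK_BOTH"))
  }
  report_decision("not_reportable", "ITD_NO_EVIDENCE")
}

#' Call KMT2A-type partial tandem duplications
#'
#' A PTD is called when an intragenic tandem gain (below the sub-50 kb review
#' size, confined to one gene) co-occurs with an in-frame chimeric junction
#' joining a downstream exon (7 or 8) upstream of an early 5' exon (2, 3, or
#' 4) — the transcript signature of a partial tandem duplication. A
#' qualifying gain without junction support is emitted as a borderline PTD
#' rather than suppressed, since transcriptome coverage of the junction may be
#' insufficient; the junction pattern alone (no gain) is not called.
#'
#' @param segs A `cnv_segment_tbl`, scale-classified, with `gene` annotation.
#' @param junctions A `structural_event_tbl` of intragenic junctions with exon
#'   numbering (`exonA` = 3'-side donor exon, `exonB` = 5'-side acceptor).
#' @param gene Target gene symbol (default `"KMT2A"`).
#' @param cfg A [rule_config()].
#' @return A tibble of PTD calls: columns `case_id`, `gene`, `status`,
#'   `rationale` (zero rows when nothing qualifies).
#' @export
call_kmt2a_ptd <- function(segs, junctions, gene = "KMT2A",
                           cfg = rule_config()) {
  gains <- dplyr::filter(segs, .data$kind == "gain",
                         !is.na(.data$gene), .data$gene == !!gene,
                         .data$size_bp < cfg$sub50kb_bp)
  if (nrow(gains) == 0) {
    return(tibble(case_id = character(), gene = character(),
                  status = character(), rationale = character()))
  }
  jx <- dplyr::filter(junctions, .data$geneA == !!gene, .data$geneB == !!gene,
                      .data$frame == "in_frame")
  no_exon <- is.na(jx$exonA) | is.na(jx$exonB)
  if (any(no_exon)) {
    warning("call_kmt2a_ptd: skipping ", sum(no_exon),
            " junction(s) lacking exon annotation", call. = FALSE)
    jx <- jx[!no_exon, ]
  }
  # donor exon 7/8 joined upstream of acceptor exon 2/3/4, either orientation
  ptd_pattern <- (jx$exonA %in% c(7L, 8L) & jx$exonB %in% c(2L, 3L, 4L)) |
    (jx$exonB %in% c(7L, 8L) & jx$exonA %in% c(2L, 3L, 4L))
  purrr::map_dfr(seq_len(nrow(gains)), function(i) {
    g <- gains[i, ]
    supported <- any(ptd_pattern & jx$case_id == g$case_id)
    tibble(case_id = g$case_id, gene = gene,
           status = if (supported) "reportable" else "borderline",
           rationale = if (supported) "PTD_JUNCTION_SUPPORT" else
             "PTD_GAIN_ONLY")
  })
}

#' Classify the oncogenic mechanism of a structural event
#'
#' In-frame exon-exon junctions between two genes produce fusion oncogenes.
#' Rearrangements whose breakpoints fall outside an oncogene's coding region
#' but within a configurable window of it (default 500 kb either side),
#' juxtaposing foreign sequence next to the gene, are enhancer-hijack
#' candidates — they activate the intact oncogene without a chimeric protein
#' and therefore require expression-level validation
#' (see [validate_enhancer_hijack()]). Everything else is `other`.
#'
#' @param sv A `structural_event_tbl` (any number of rows).
#' @param oncogene_regions Named list: gene -> `c(chrom, start, end)` coding
#'   spans of the oncogenes under surveillance (e.g. MECOM, HOXA cluster,
#'   BCL11B, TLX3).
#' @param cfg A [rule_config()].
#' @return `sv` with `mechanism` set to `"in_frame_fusion"`,
#'   `"enhancer_hijack_candidate"`, or `"other"`, plus a `hijack_target`
#'   column naming the candidate oncogene where applicable.
#' @export
classify_sv_mechanism <- function(sv, oncogene_regions, cfg = rule_config()) {
  if (is.null(oncogene_regions)) {
    stop("classify_sv_mechanism: an oncogene gene model is required",
         call. = FALSE)
  }
  if (nrow(sv) == 0) {
    sv$hijack_target <- character(0)
    return(sv)
  }
  # Nearest oncogene whose window (but not coding span) contains the
  # breakpoint; clustered genes (e.g. the HOXA locus) resolve to the closest.
  target_of <- function(chrom, pos) {
    best <- NA_character_
    best_d <- Inf
    for (g in names(oncogene_regions)) {
      r <- oncogene_regions[[g]]
      r_chrom <- as.character(r[[1]])
      r_start <- as.numeric(r[[2]]); r_end <- as.numeric(r[[3]])
      if (chrom != r_chrom) next
      if (pos >= r_start && pos <= r_end) next
      d <- if (pos < r_start) r_start - pos else pos - r_end
      if (d <= cfg$enhancer_window_bp && d < best_d) {
        best <- g
        best_d <- d
      }
    }
    best
  }
  mech <- character(nrow(sv))
  target <- rep(NA_character_, nrow(sv))
  for (i in seq_len(nrow(sv))) {
    row <- sv[i, ]
    has_junction <- !is.na(row$exonA) && !is.na(row$exonB)
    if (row$frame == "in_frame" && has_junction) {
      mech[i] <- "in_frame_fusion"
      next
    }
    tA <- target_of(row$chromA, row$posA)
    tB <- target_of(row$chromB, row$posB)
    hit <- stats::na.omit(c(tA, tB))
    if (length(hit)) {
      mech[i] <- "enhancer_hijack_candidate"
      target[i] <- hit[[1]]
    } else {
      mech[i] <- "other"
    }
  }
  sv$mechanism <- mech
  sv$hijack_target <- target
  sv
}
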