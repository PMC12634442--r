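#' Call oncogene overexpression against a reference cohort
#'
#' The case's normalized abundance for the gene is compared to a reference of
#' cases lacking rearrangements of that gene, on the log(1 + x) scale, as a
#' z-score. The call is `overexpressed` when the z-score reaches the
#' configured threshold (default 2). Log-scale scoring makes the call
#' invariant to uniform multiplicative rescaling of all profiles (library
#' size).
#'
#' @param gene Gene symbol, present in the case and all reference profiles.
#' @param profile The case's [expression_profile()].
#' @param reference A list of reference [expression_profile()]s; callers are
#'   responsible for excluding cases rearranged at `gene`
#'   (see [reference_profiles_for_gene()]).
#' @param cfg A [rule_config()].
#' @return A list of class `overexpression_call` with fields `gene`,
#'   `case_value`, `reference_summary` (mean/sd/n on log scale), `z_score`,
#'   `flag`.
#' @export
overexpression_call <- function(gene, profile, reference,
                                cfg = rule_config()) {
  if (length(reference) == 0) {
    stop("overexpression_call: reference cohort is empty", call. = FALSE)
  }
  get_val <- function(p) {
    if (!gene %in% names(p$values)) {
      stop("overexpression_call: gene `", gene, "` absent from profile ",
           p$case_id, call. = FALSE)
    }
    p$values[[gene]]
  }
  case_log <- log1p(get_val(profile))
  ref_log <- vapply(reference, function(p) log1p(get_val(p)), numeric(1))
  m <- mean(ref_log)
  s <- stats::sd(ref_log)
  if (!is.finite(s) || s == 0) {
    stop("overexpression_call: reference variance is zero; ",
         "enlarge the reference cohort", call. = FALSE)
  }
  z <- (case_log - m) / s
  structure(
    list(gene = gene, case_value = profile$values[[gene]],
         reference_summary = c(mean = m, sd = s, n = length(reference)),
         z_score = z,
         flag = if (z >= cfg$overexpression_z) "overexpressed" else
           "not_overexpressed"),
    class = "overexpression_call"
  )
}

#' Build the reference set for a gene's overexpression call
#'
#' Excludes any case with a structural event touching the gene (as partner or
#' hijack target), so rearranged cases cannot contaminate the null
#' distribution.
#'
#' @param gene Gene symbol.
#' @param profiles List of [expression_profile()]s for the cohort.
#' @param svs A `structural_event_tbl` for the whole cohort (may be empty).
#' @return The subset of `profiles` usable as reference.
#' @export
reference_profiles_for_gene <- function(gene, profiles, svs) {
  rearranged <- character()
  if (!is.null(svs) && nrow(svs)) {
    hit <- svs$geneA == gene | svs$geneB == gene
    if ("hijack_target" %in% names(svs)) {
      hit <- hit | (!is.na(svs$hijack_target) & svs$hijack_target == gene)
    }
    rearranged <- unique(svs$case_id[hit])
  }
  purrr::keep(profiles, function(p) !p$case_id %in% rearranged)
}

#' Validate or refute an enhancer-hijack candidate by expression
#'
#' Enhancer hijacking leaves no chimeric transcript; its only transcriptome
#' footprint is ectopic overexpression of the intact target oncogene. A
#' candidate is confirmed when the target is overexpressed relative to
#' non-rearranged reference cases and refuted otherwise; refuted candidates
#' are excluded from classification as defining lesions.
#'
#' @param sv A one-row `structural_event_tbl` with
#'   `mechanism == "enhancer_hijack_candidate"`.
#' @param call An [overexpression_call()] for the candidate's target oncogene.
#' @return `"confirmed"` or `"refuted"`.
#' @export
validate_enhancer_hijack <- function(sv, call) {
  stopifnot(nrow(sv) == 1)
  if (sv$mechanism != "enhancer_hijack_candidate") {
    stop("validate_enhancer_hijack: event is not an enhancer-hijack candidate",
         call. = FALSE)
  }
  target <- sv$hijack_target
  if (is.na(target) || !identical(call$gene, target)) {
    stop("validate_enhancer_hijack: expression call targets `", call$gene,
         "` but the candidate oncogene is `", target, "`", call. = FALSE)
  }
  if (call$flag == "overexpressed") "confirmed" else "refuted"
}

#' Classify allele-specific expression from paired DNA/RNA VAFs
#'
#' A large positive RNA-minus-DNA VAF skew indicates preferential expression
#' of the mutant allele (e.g. DNA VAF 35% with RNA VAF 97% implies exclusive
#' mutant-allele expression); the mirror-image skew indicates silencing of
#' the mutant allele. The rule is antisymmetric under swapping the two VAFs.
#'
#' @param dna_vaf,rna_vaf VAF fractions in `[0, 1]`.
#' @param skew_threshold Minimum absolute skew to call imbalance
#'   (default 0.30).
#' @return `"mutant_ase"`, `"balanced"`, or `"wildtype_ase"`.
#' @export
allele_specific_expression <- function(dna_vaf, rna_vaf,
                                       skew_threshold = 0.30) {
  if (dna_vaf < 0 || dna_vaf > 1 || rna_vaf < 0 || rna_vaf > 1) {
    stop("allele_specific_expression: VAFs must lie in [0, 1]", call. = FALSE)
  }
  skew <- rna_vaf - dna_vaf
  if (skew >= skew_threshold) return("mutant_ase")
  if (-skew >= skew_threshold) return("wildtype_ase")
  "balanced"
}
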