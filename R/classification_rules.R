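#' Classification rule content
#'
#' Pattern sets defining the molecular classification tiers: WHO AML-defining
#' fusions and mutations, newly proposed class-defining lesions, and the
#' myelodysplasia-related (AML-MR) gene and cytogenetic-lesion lists. The
#' content ships as an editable JSON data file so new diagnostic markers can
#' be adopted by a bioinformatics update without code changes.
#'
#' Fusion patterns take three forms: `"A::B"` (gene pair, partner order
#' ignored), `"GENE::*"` (any fusion involving the gene), and `"GENE-r"`
#' (any rearrangement of the gene, including validated enhancer hijack).
#'
#' @param who_fusions,who_mutations,proposed_class_fusions,
#'   proposed_class_mutations,aml_mr_genes,aml_mr_cyto Character vectors of
#'   patterns.
#' @return A list of class `classification_rules`.
#' @export
classification_rules <- function(who_fusions = character(),
                                 who_mutations = character(),
                                 proposed_class_fusions = character(),
                                 proposed_class_mutations = character(),
                                 aml_mr_genes = character(),
                                 aml_mr_cyto = character()) {
  structure(
    list(who_fusions = who_fusions,
         who_mutations = who_mutations,
         proposed_class_fusions = proposed_class_fusions,
         proposed_class_mutations = proposed_class_mutations,
         aml_mr_genes = aml_mr_genes,
         aml_mr_cyto = aml_mr_cyto),
    class = "classification_rules"
  )
}

#' Load classification rules from a JSON file
#'
#' @param path Path to a rules JSON file; defaults to the packaged rule set.
#' @return A `classification_rules` object.
#' @export
load_classification_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "classification_rules.json",
                                package = "amlintegrate", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  classification_rules(
    who_fusions = raw$who_fusions %||% character(),
    who_mutations = raw$who_mutations %||% character(),
    proposed_class_fusions = raw$proposed_class_fusions %||% character(),
    proposed_class_mutations = raw$proposed_class_mutations %||% character(),
    aml_mr_genes = raw$aml_mr_genes %||% character(),
    aml_mr_cyto = raw$aml_mr_cyto %||% character()
  )
}

#' @rdname load_classification_rules
#' @export
default_classification_rules <- function() load_classification_rules()

# Does one fusion pattern match a structural event's gene pair (and, for
# "-r" patterns, its hijack target)?
fusion_pattern_matches <- function(pattern, geneA, geneB,
                                   hijack_target = NA_character_) {
  genes <- c(geneA, geneB)
  if (grepl("-r$", pattern)) {
    g <- sub("-r$", "", pattern)
    return(g %in% genes || (!is.na(hijack_target) && hijack_target == g))
  }
  if (grepl("::\\*$", pattern)) {
    g <- sub("::\\*$", "", pattern)
    return(g %in% genes)
  }
  parts <- strsplit(pattern, "::", fixed = TRUE)[[1]]
  if (length(parts) != 2) return(FALSE)
  setequal(parts, genes) ||
    (parts[1] %in% genes && parts[2] %in% genes)
}

# First pattern (in list order) matching the event, or NA. Pattern lists are
# kept in a fixed, documented order; within a tier, candidate events are
# offered sorted alphabetically by 5' partner, so tie-breaking is
# reproducible.
match_fusion_tier <- function(sv_row, patterns) {
  for (p in patterns) {
    if (fusion_pattern_matches(p, sv_row$geneA, sv_row$geneB,
                               sv_row$hijack_target %||% NA_character_)) {
      return(p)
    }
  }
  NA_character_
}
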