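#' Match two variant call sets by genomic key
#'
#' Partitions two call sets by exact key `(case_id, chrom, pos, ref, alt)`.
#' Callers should normalize indel representation first
#' (see [normalize_variant()]); the partition is exhaustive and disjoint, so
#' `|a| = both + only_a` and `|b| = both + only_b`.
#'
#' @param a,b `variant_call_tbl` tables.
#' @return A list with elements `both`, `only_a`, `only_b` (tibbles; `both`
#'   carries `a`'s rows).
#' @export
match_variant_sets <- function(a, b) {
  key <- function(x) paste(x$case_id, x$chrom, x$pos, x$ref, x$alt, sep = "|")
  ka <- key(a)
  kb <- key(b)
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("match_variant_sets: duplicate variant keys within one set",
         call. = FALSE)
  }
  list(both = a[ka %in% kb, , drop = FALSE],
       only_a = a[!ka %in% kb, , drop = FALSE],
       only_b = b[!kb %in% ka, , drop = FALSE])
}

#' VAF concordance between two platforms
#'
#' Pearson correlation and ordinary least-squares slope of the second
#' platform's VAF on the first's, over matched variant pairs.
#'
#' @param pairs A two-column data frame / matrix (or tibble with columns
#'   `vaf_a`, `vaf_b`) of matched VAF pairs; at least 3 rows.
#' @return A list of class `concordance_stats`: `r`, `slope`, `n_pairs`.
#' @export
vaf_concordance <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(ncol(pairs) >= 2)
  a <- pairs[[1]]
  b <- pairs[[2]]
  if (length(a) < 3) {
    stop("vaf_concordance: at least 3 pairs required", call. = FALSE)
  }
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("vaf_concordance: a coordinate is constant", call. = FALSE)
  }
  structure(
    list(r = stats::cor(a, b),
         slope = unname(stats::coef(stats::lm(b ~ a))[2]),
         n_pairs = length(a)),
    class = "concordance_stats"
  )
}

#' Overall agreement rate between two platforms
#'
#' `100 * both / (both + only_a + only_b)`, rounded to the nearest integer
#' percent (reporting convention). Symmetric in the two only-counts and equal
#' to 100 exactly when the platforms agree on every event.
#'
#' @param both,only_a,only_b Nonnegative event counts, not all zero.
#' @param digits Rounding digits (default 0).
#' @return Percentage in `[0, 100]`.
#' @export
agreement_rate <- function(both, only_a, only_b, digits = 0) {
  stopifnot(both >= 0, only_a >= 0, only_b >= 0)
  total <- both + only_a + only_b
  if (total == 0) {
    stop("agreement_rate: all counts are zero", call. = FALSE)
  }
  round(100 * both / total, digits)
}

#' Per-category detection table (platform B against truth)
#'
#' Tabulates, per truth category, how many events platform B (typically
#' conventional cytogenetics) detected out of those established by the
#' reference approach. Follows the clinical-table convention: `total` counts
#' truth events only (`both + only_a`); events seen only by B would be listed
#' separately, not folded into the total. A `Total` row sums the categories.
#'
#' @param truth A data frame with a `category` column, one row per truth
#'   event.
#' @param observed_by_b Logical vector (same length) or predicate function
#'   over rows: did platform B see the event?
#' @return A tibble of class `concordance_table` with columns `category`,
#'   `both`, `only_a`, `total`, `pct_missed_b`.
#' @export
detection_table <- function(truth, observed_by_b) {
  if (nrow(truth) == 0) {
    return(structure(
      tibble(category = "Total", both = 0L, only_a = 0L, total = 0L,
             pct_missed_b = NA_real_),
      class = c("concordance_table", class(tibble()))
    ))
  }
  obs <- if (is.function(observed_by_b)) {
    vapply(seq_len(nrow(truth)), function(i) isTRUE(observed_by_b(truth[i, ])),
           logical(1))
  } else {
    as.logical(observed_by_b)
  }
  stopifnot(length(obs) == nrow(truth))
  rows <- truth |>
    dplyr::mutate(.obs = obs) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(both = sum(.data$.obs), only_a = sum(!.data$.obs),
                     .groups = "drop") |>
    dplyr::mutate(total = .data$both + .data$only_a,
                  pct_missed_b = round(100 * .data$only_a / .data$total))
  total_row <- tibble(
    category = "Total",
    both = sum(rows$both), only_a = sum(rows$only_a),
    total = sum(rows$total),
    pct_missed_b = round(100 * sum(rows$only_a) / sum(rows$total))
  )
  out <- dplyr::bind_rows(rows, total_row)
  class(out) <- c("concordance_table", class(out))
  out
}

#' Diagnostic yield of a modality over a classified cohort
#'
#' Fraction of cases whose defining lesion exists and is detectable under the
#' modality. For the integrated WGS+WTS modality itself, detectable means the
#' defining lesion is non-null (the case is not NOS).
#'
#' @param cohort A list of [molecular_subtype()] outcomes.
#' @param modality_detectable Predicate over a `molecular_subtype`: can the
#'   modality detect this case's defining lesion? Defaults to "defining
#'   lesion exists".
#' @param digits Rounding digits (the headline yield is conventionally
#'   reported to one decimal).
#' @return Percentage in `[0, 100]`.
#' @export
diagnostic_yield <- function(cohort,
                             modality_detectable = function(s)
                               !is.null(s$defining_lesion),
                             digits = 1) {
  if (length(cohort) == 0) {
    stop("diagnostic_yield: empty cohort", call. = FALSE)
  }
  hit <- vapply(cohort, function(s) {
    !is.null(s$defining_lesion) && isTRUE(modality_detectable(s))
  }, logical(1))
  round(100 * sum(hit) / length(cohort), digits)
}
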