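#' Parse an ISCN karyotype string
#'
#' Supports the grammar subset needed for lesion-class comparison: modal
#' number, sex chromosomes, whole-chromosome gains/losses (`+8`, `-7`),
#' `del(N)(bands)`, `add(N)(band)`, `t(N;M)(band;band)`, `i(N)(arm)`,
#' marker chromosomes (`+mar`/`mar`), multi-clone notation separated by `/`
#' with `idem`/`sl` stem-line references, and per-clone metaphase counts in
#' square brackets. Unrecognized lesion tokens are collected as `other` with
#' a warning rather than failing: clinical strings are heterogeneous and the
#' downstream comparison only needs lesion classes.
#'
#' @param iscn Non-empty karyotype string, e.g.
#'   `"45,XY,-7[18]/46,XY[2]"`.
#' @return A [karyotype_record()]; `n_abnormalities` counts distinct clonal
#'   lesions across clones, and metaphase totals are summed over clones
#'   (abnormal = clones carrying at least one lesion).
#' @export
parse_iscn <- function(iscn) {
  if (is.null(iscn) || !nzchar(trimws(iscn))) {
    stop("parse_iscn: empty karyotype string", call. = FALSE)
  }
  clones <- strsplit(trimws(iscn), "/", fixed = TRUE)[[1]]
  all_lesions <- list()
  lesion_keys <- character()
  first_clone_idx <- integer()
  metaphases_total <- 0L
  metaphases_abnormal <- 0L
  any_counts <- FALSE

  for (ci in seq_along(clones)) {
    clone <- trimws(clones[ci])
    n_meta <- NA_integer_
    m <- regmatches(clone, regexec("\\[(\\d+)\\]\\s*$", clone))[[1]]
    if (length(m) == 2) {
      n_meta <- as.integer(m[2])
      clone <- sub("\\[\\d+\\]\\s*$", "", clone)
      any_counts <- TRUE
    }
    tokens <- trimws(strsplit(clone, ",", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0) {
      stop("parse_iscn: clone with no modal section: `", clones[ci], "`",
           call. = FALSE)
    }
    modal <- tokens[1]
    if (!grepl("^\\d+([~-]\\d+)?$", modal)) {
      stop("parse_iscn: unparseable modal number `", modal, "`",
           call. = FALSE)
    }
    tokens <- tokens[-1]
    if (length(tokens) && grepl("^[XY]+$", tokens[1])) {
      tokens <- tokens[-1]
    }
    clone_lesions <- integer()
    for (tok in tokens) {
      if (tok %in% c("idem", "sl")) {
        clone_lesions <- union(clone_lesions, first_clone_idx)
        next
      }
      parsed <- parse_iscn_token(tok)
      key <- parsed$key
      idx <- match(key, lesion_keys)
      if (is.na(idx)) {
        all_lesions[[length(all_lesions) + 1]] <- parsed$lesion
        lesion_keys <- c(lesion_keys, key)
        idx <- length(lesion_keys)
      }
      clone_lesions <- union(clone_lesions, idx)
    }
    if (ci == 1) first_clone_idx <- clone_lesions
    if (!is.na(n_meta)) {
      metaphases_total <- metaphases_total + n_meta
      if (length(clone_lesions)) {
        metaphases_abnormal <- metaphases_abnormal + n_meta
      }
    }
  }
  lesions <- if (length(all_lesions)) dplyr::bind_rows(all_lesions) else
    cyto_lesion_tbl_empty()
  karyotype_record(
    iscn = iscn, lesions = lesions,
    metaphases_total = if (any_counts) metaphases_total else NA_integer_,
    metaphases_abnormal = if (any_counts) metaphases_abnormal else NA_integer_
  )
}

parse_iscn_token <- function(tok) {
  lesion <- NULL
  if (grepl("^\\+mar$", tok) || tok == "mar") {
    lesion <- cyto_lesion("marker")
  } else if (grepl("^[+]([0-9]+|X|Y)$", tok)) {
    lesion <- cyto_lesion("trisomy", chrom = sub("^[+]", "", tok))
  } else if (grepl("^-([0-9]+|X|Y)$", tok)) {
    lesion <- cyto_lesion("monosomy", chrom = sub("^-", "", tok))
  } else {
    m <- regmatches(tok, regexec(
      "^del\\(([0-9XY]+)\\)\\(([pq][0-9.]*(?:[pq][0-9.]*)?)\\)$", tok))[[1]]
    if (length(m) == 3) {
      lesion <- cyto_lesion("deletion", chrom = m[2], arm_or_band = m[3])
    }
    if (is.null(lesion)) {
      m <- regmatches(tok, regexec(
        "^add\\(([0-9XY]+)\\)\\(([pq][0-9.]*)\\)$", tok))[[1]]
      if (length(m) == 3) {
        lesion <- cyto_lesion("addition", chrom = m[2], arm_or_band = m[3])
      }
    }
    if (is.null(lesion)) {
      m <- regmatches(tok, regexec(
        "^t\\(([0-9XY]+);([0-9XY]+)\\)\\(([pq][0-9.]*);([pq][0-9.]*)\\)$",
        tok))[[1]]
      if (length(m) == 5) {
        lesion <- cyto_lesion("translocation", chrom = m[2],
                              arm_or_band = m[4], chrom2 = m[3],
                              band2 = m[5])
      }
    }
    if (is.null(lesion)) {
      m <- regmatches(tok, regexec(
        "^i\\(([0-9XY]+)\\)\\(([pq][0-9.]*)\\)$", tok))[[1]]
      if (length(m) == 3) {
        lesion <- cyto_lesion("isochromosome", chrom = m[2],
                              arm_or_band = m[3])
      }
    }
  }
  if (is.null(lesion)) {
    warning("parse_iscn: unrecognized token `", tok,
            "` collected as `other`", call. = FALSE)
    lesion <- cyto_lesion("other", arm_or_band = tok)
  }
  list(lesion = lesion, key = tok)
}

#' Render lesions back to a canonical ISCN string
#'
#' Inverse of [parse_iscn()] on the supported grammar subset (single clone,
#' no metaphase counts). The modal number is 46 adjusted by whole-chromosome
#' gains/losses and markers.
#'
#' @param lesions A `cyto_lesion_tbl`.
#' @param sex Sex-chromosome token (default `"XX"`).
#' @return The canonical ISCN string.
#' @export
iscn_string <- function(lesions, sex = "XX") {
  toks <- character()
  modal <- 46L
  if (nrow(lesions)) {
    for (i in seq_len(nrow(lesions))) {
      l <- lesions[i, ]
      tok <- switch(l$kind,
        monosomy = { modal <- modal - 1L; paste0("-", l$chrom) },
        trisomy = { modal <- modal + 1L; paste0("+", l$chrom) },
        deletion = sprintf("del(%s)(%s)", l$chrom, l$arm_or_band),
        addition = sprintf("add(%s)(%s)", l$chrom, l$arm_or_band),
        translocation = sprintf("t(%s;%s)(%s;%s)", l$chrom, l$chrom2,
                                l$arm_or_band, l$band2),
        isochromosome = sprintf("i(%s)(%s)", l$chrom, l$arm_or_band),
        marker = { modal <- modal + 1L; "+mar" },
        stop("iscn_string: lesion kind `", l$kind,
             "` has no canonical token", call. = FALSE)
      )
      toks <- c(toks, tok)
    }
  }
  paste(c(modal, sex, toks), collapse = ",")
}
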