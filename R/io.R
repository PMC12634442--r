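#' Normalize a small-variant representation
#'
#' Reduces a variant to minimal representation (shared suffix then shared
#' prefix trimmed, keeping at least one base per allele) and, when local
#' reference context is supplied, left-aligns indels by repeatedly shifting
#' through repeat copies. Complex indels written in different raw forms are
#' the main cause of cross-platform key mismatches, so both call sets are
#' normalized before matching.
#'
#' @param chrom Chromosome.
#' @param pos 1-based position.
#' @param ref,alt Allele strings.
#' @param context Optional local reference sequence containing the variant
#'   site.
#' @param context_start 1-based genomic position of `context`'s first base.
#' @return A list with `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, context = NULL,
                              context_start = 1L) {
  ref_v <- strsplit(ref, "")[[1]]
  alt_v <- strsplit(alt, "")[[1]]
  ctx <- if (!is.null(context)) strsplit(context, "")[[1]] else NULL
  base_at <- function(p) {
    i <- p - context_start + 1L
    if (is.null(ctx) || i < 1 || i > length(ctx)) NA_character_ else ctx[i]
  }
  repeat {
    # trim a shared trailing base; extend left from context when an allele
    # would empty out (the left-shift through a repeat)
    if (length(ref_v) && length(alt_v) &&
        ref_v[length(ref_v)] == alt_v[length(alt_v)]) {
      if (length(ref_v) == 1 || length(alt_v) == 1) {
        prev <- base_at(pos - 1L)
        if (is.na(prev)) break
        ref_v <- c(prev, ref_v[-length(ref_v)])
        alt_v <- c(prev, alt_v[-length(alt_v)])
        pos <- pos - 1L
      } else {
        ref_v <- ref_v[-length(ref_v)]
        alt_v <- alt_v[-length(alt_v)]
      }
    } else break
  }
  while (length(ref_v) > 1 && length(alt_v) > 1 && ref_v[1] == alt_v[1]) {
    ref_v <- ref_v[-1]
    alt_v <- alt_v[-1]
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = as.integer(pos),
       ref = paste(ref_v, collapse = ""), alt = paste(alt_v, collapse = ""))
}

#' Normalize every variant in a call table (minimal representation)
#'
#' @param variants A `variant_call_tbl`.
#' @return The table with `pos`, `ref`, `alt` minimized.
#' @export
normalize_variants <- function(variants) {
  if (nrow(variants) == 0) return(variants)
  for (i in seq_len(nrow(variants))) {
    n <- normalize_variant(variants$chrom[i], variants$pos[i],
                           variants$ref[i], variants$alt[i])
    variants$pos[i] <- n$pos
    variants$ref[i] <- n$ref
    variants$alt[i] <- n$alt
  }
  variants
}

fmt_num <- function(x) {
  ifelse(is.na(x), ".", formatC(x, digits = 10, format = "g"))
}

#' Write a variant table as VCF
#'
#' One sample column per platform; per-sample FORMAT `AF:ST` where `ST` is
#' `A` (assayed), `I` (assayed, insufficient coverage), `N` (not assayed).
#' Annotations travel in INFO (`GENE`, `ORIGIN`, `PATH`, `DRIVER`).
#'
#' @param variants A `variant_call_tbl` (one case).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  platforms <- unique(unlist(lapply(variants$vaf, names)))
  if (length(platforms) == 0) platforms <- "wgs"
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"somatic|germline\">",
    "##INFO=<ID=PATH,Number=1,Type=String,Description=\"P|LP|VUS|B/LB\">",
    "##INFO=<ID=DRIVER,Number=0,Type=Flag,Description=\"AML driver\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    paste0("##FORMAT=<ID=ST,Number=1,Type=Character,Description=",
           "\"A assayed, I insufficient coverage, N not assayed\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", platforms), collapse = "\t")
  )
  body <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    info <- paste0("GENE=", v$gene, ";ORIGIN=", v$origin, ";PATH=",
                   gsub("/", "_", v$pathogenicity),
                   if (isTRUE(v$is_aml_driver)) ";DRIVER" else "")
    vv <- v$vaf[[1]]
    cells <- vapply(platforms, function(p) {
      if (!p %in% names(vv)) return(".:N")
      if (is.na(vv[[p]])) return(".:I")
      paste0(fmt_num(vv[[p]]), ":A")
    }, character(1))
    body[i] <- paste(c(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                       "AF:ST", cells), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Read a VCF into a variant call table
#'
#' Per-sample VAFs come from the `AF` FORMAT tag; when `AF` is absent the VAF
#' is derived from allelic depths (`AD`, ref/alt). Multi-allelic records are
#' split into one row per alternate allele and reduced to minimal
#' representation. Sample column names are taken as platform labels.
#'
#' @param path VCF path.
#' @param case_id Case identifier for the resulting rows.
#' @return A `variant_call_tbl`.
#' @export
read_variants_vcf <- function(path, case_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_variants())
  gt <- v@gt
  platforms <- colnames(gt)[-1]
  has_af <- function(fmt) "AF" %in% strsplit(fmt, ":", fixed = TRUE)[[1]]
  get_tag <- function(fmt, cell, tag) {
    keys <- strsplit(fmt, ":", fixed = TRUE)[[1]]
    vals <- strsplit(cell, ":", fixed = TRUE)[[1]]
    i <- match(tag, keys)
    if (is.na(i) || i > length(vals)) NA_character_ else vals[i]
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    info <- fix$INFO[i] %||% ""
    gene <- info_field(info, "GENE")
    origin <- info_field(info, "ORIGIN")
    pathv <- gsub("_", "/", info_field(info, "PATH"))
    driver <- grepl("(^|;)DRIVER(;|$)", info)
    fmt <- gt[i, 1]
    for (ai in seq_along(alts)) {
      vafs <- numeric()
      for (p in platforms) {
        cell <- gt[i, p]
        if (is.na(cell)) next
        st <- get_tag(fmt, cell, "ST")
        if (!is.na(st) && st == "N") next
        af_raw <- get_tag(fmt, cell, "AF")
        af <- NA_real_
        if (!is.na(af_raw) && af_raw != ".") {
          af <- suppressWarnings(as.numeric(
            strsplit(af_raw, ",", fixed = TRUE)[[1]][ai]))
        } else if (is.na(st)) {
          ad_raw <- get_tag(fmt, cell, "AD")
          if (!is.na(ad_raw) && ad_raw != ".") {
            ad <- suppressWarnings(as.numeric(
              strsplit(ad_raw, ",", fixed = TRUE)[[1]]))
            if (length(ad) >= ai + 1 && sum(ad, na.rm = TRUE) > 0) {
              af <- ad[ai + 1] / sum(ad, na.rm = TRUE)
            }
          }
        }
        vafs[p] <- af
      }
      if (length(vafs) == 0) vafs <- c(wgs = NA_real_)
      n <- normalize_variant(fix$CHROM[i], as.integer(fix$POS[i]),
                             fix$REF[i], alts[ai])
      rows[[length(rows) + 1]] <- variant_call(
        case_id = case_id, gene = gene %||% NA_character_,
        chrom = n$chrom, pos = n$pos, ref = n$ref, alt = n$alt,
        origin = if (!is.na(origin)) origin else "somatic",
        pathogenicity = if (!is.na(pathv)) pathv else "VUS",
        is_aml_driver = driver, vaf = vafs
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write structural events as BEDPE
#'
#' Standard six mandatory columns (0-based half-open, single-base intervals)
#' plus name/score/strands and annotation columns.
#'
#' @param svs A `structural_event_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svs_bedpe <- function(svs, path) {
  df <- tibble(
    chrom1 = svs$chromA, start1 = svs$posA - 1L, end1 = svs$posA,
    chrom2 = svs$chromB, start2 = svs$posB - 1L, end2 = svs$posB,
    name = paste0(svs$gene5p, "__", svs$gene3p),
    score = ".", strand1 = svs$strandA, strand2 = svs$strandB,
    geneA = svs$geneA, geneB = svs$geneB,
    gene5p = svs$gene5p, gene3p = svs$gene3p,
    exonA = svs$exonA, exonB = svs$exonB,
    frame = svs$frame, event_class = svs$event_class,
    fusion_category = svs$fusion_category
  )
  readr::write_tsv(df, path, na = ".")
  invisible(path)
}

#' Read a BEDPE file of structural events
#'
#' @param path BEDPE path (with header, as written by [write_svs_bedpe()]).
#' @param case_id Case identifier.
#' @return A `structural_event_tbl` with 1-based internal coordinates.
#' @export
read_svs_bedpe <- function(path, case_id) {
  df <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0) return(empty_svs())
  if (any(df$start1 > df$end1 | df$start2 > df$end2)) {
    stop("read_svs_bedpe: ", path, ": interval start exceeds end",
         call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    structural_event(
      case_id = case_id,
      chromA = r$chrom1, posA = r$start1 + 1L,
      chromB = r$chrom2, posB = r$start2 + 1L,
      geneA = r$geneA %||% "intergenic", geneB = r$geneB %||% "intergenic",
      gene5p = r$gene5p %||% NULL, gene3p = r$gene3p %||% NULL,
      strandA = r$strand1 %||% "+", strandB = r$strand2 %||% "+",
      exonA = r$exonA %||% NA_integer_, exonB = r$exonB %||% NA_integer_,
      frame = r$frame %||% "unknown",
      event_class = r$event_class %||% "fusion",
      fusion_category = r$fusion_category %||% "non_driver"
    )
  })
}

#' Write CNV/cnLOH segments as an extended SEG table
#'
#' Standard SEG columns (`ID`, `chrom`, `loc.start`, `loc.end`, `seg.mean`)
#' plus the copy-state annotations this framework carries.
#'
#' @param cnvs A `cnv_segment_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnvs_seg <- function(cnvs, path) {
  seg_mean <- c(gain = 0.58, loss = -1, cnloh = 0)[cnvs$kind]
  df <- tibble(ID = cnvs$case_id, chrom = cnvs$chrom,
               loc.start = cnvs$start, loc.end = cnvs$end,
               seg.mean = unname(seg_mean), kind = cnvs$kind,
               clone_fraction = cnvs$clone_fraction,
               sv_supported = cnvs$sv_supported, gene = cnvs$gene)
  readr::write_tsv(df, path, na = ".")
  invisible(path)
}

#' Read an extended SEG table
#'
#' @param path SEG path.
#' @param case_id Case identifier.
#' @return A `cnv_segment_tbl`.
#' @export
read_cnvs_seg <- function(path, case_id) {
  df <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                        progress = FALSE)
  if (nrow(df) == 0) return(empty_cnvs())
  if (any(df$loc.end < df$loc.start)) {
    stop("read_cnvs_seg: ", path, ": segment end precedes start",
         call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    cnv_segment(case_id = case_id, chrom = r$chrom, start = r$loc.start,
                end = r$loc.end, kind = r$kind,
                clone_fraction = r$clone_fraction %||% 1,
                sv_supported = isTRUE(r$sv_supported),
                gene = r$gene %||% NA_character_)
  })
}

#' Write an expression profile as TSV (gene rows, one column per case)
#'
#' @param profiles A list of [expression_profile()]s sharing a gene set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(profiles, path) {
  if (!length(profiles)) stop("write_expression_tsv: no profiles",
                              call. = FALSE)
  genes <- names(profiles[[1]]$values)
  df <- tibble(gene = genes)
  for (p in profiles) {
    df[[p$case_id]] <- unname(p$values[genes])
  }
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read an expression TSV
#'
#' @param path TSV path (header row of case ids, first column `gene`).
#' @param cohort_id Reference-grouping identifier for the profiles.
#' @return A named list of [expression_profile()]s, one per case column.
#' @export
read_expression_tsv <- function(path, cohort_id = "default") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cases <- setdiff(names(df), "gene")
  profiles <- lapply(cases, function(cid) {
    expression_profile(cid, stats::setNames(df[[cid]], df$gene), cohort_id)
  })
  stats::setNames(profiles, cases)
}

#' Write a full case bundle (manifest + standard-format files)
#'
#' Emits `variants.vcf`, `svs.bedpe`, `cnvs.seg`, optionally
#' `expression.tsv`, and a JSON manifest holding clinical context, the ISCN
#' karyotype string, and the ITD evidence rows.
#'
#' @param profile A [case_profile()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_case_bundle <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    case_id = profile$case_id, sex = profile$sex,
    age_years = profile$age_years,
    disease_context = profile$disease_context,
    down_syndrome = profile$down_syndrome,
    blast_percent = profile$blast_percent,
    files = list()
  )
  if (nrow(profile$variants)) {
    write_variants_vcf(profile$variants, file.path(dir, "variants.vcf"))
    manifest$files$variants <- "variants.vcf"
  }
  if (nrow(profile$svs)) {
    write_svs_bedpe(profile$svs, file.path(dir, "svs.bedpe"))
    manifest$files$svs <- "svs.bedpe"
  }
  if (nrow(profile$cnvs)) {
    write_cnvs_seg(profile$cnvs, file.path(dir, "cnvs.seg"))
    manifest$files$cnvs <- "cnvs.seg"
  }
  if (!is.null(profile$expression)) {
    write_expression_tsv(list(profile$expression),
                         file.path(dir, "expression.tsv"))
    manifest$files$expression <- "expression.tsv"
  }
  if (!is.null(profile$karyotype)) {
    manifest$karyotype_iscn <- profile$karyotype$iscn
  }
  if (nrow(profile$itds)) {
    manifest$itds <- as.data.frame(profile$itds)
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a case bundle from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_case_bundle()].
#' @return A validated [case_profile()]; malformed component files raise
#'   errors naming the file and rule.
#' @export
load_case_bundle <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  fp <- function(rel) file.path(dir, rel)
  variants <- if (!is.null(m$files$variants)) {
    read_variants_vcf(fp(m$files$variants), m$case_id)
  }
  svs <- if (!is.null(m$files$svs)) read_svs_bedpe(fp(m$files$svs), m$case_id)
  cnvs <- if (!is.null(m$files$cnvs)) read_cnvs_seg(fp(m$files$cnvs),
                                                    m$case_id)
  expression <- if (!is.null(m$files$expression)) {
    read_expression_tsv(fp(m$files$expression))[[m$case_id]]
  }
  karyotype <- if (!is.null(m$karyotype_iscn)) parse_iscn(m$karyotype_iscn)
  itds <- if (!is.null(m$itds)) {
    purrr::map_dfr(seq_len(nrow(m$itds)), function(i) {
      r <- m$itds[i, ]
      itd_evidence(r$case_id, r$gene, r$wgs_strength, r$wts_strength,
                   r$pcr_ratio %||% NA_real_)
    })
  }
  profile <- case_profile(
    case_id = m$case_id, sex = m$sex %||% NA_character_,
    age_years = as.numeric(m$age_years %||% NA_real_),
    disease_context = m$disease_context %||% "de_novo",
    down_syndrome = isTRUE(m$down_syndrome),
    blast_percent = as.numeric(m$blast_percent %||% NA_real_),
    variants = variants, svs = svs, itds = itds, cnvs = cnvs,
    karyotype = karyotype, expression = expression
  )
  violations <- validate_case_profile(profile)
  if (nrow(violations)) {
    stop("load_case_bundle: ", manifest_path, ": invalid bundle (",
         paste(violations$field, collapse = ", "), ")", call. = FALSE)
  }
  profile
}
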