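# Shared builders for compact test cases.

somatic_p <- function(vaf, gene = "WT1", driver = FALSE, cid = "T1",
                      pathogenicity = "P") {
  variant_call(cid, gene, "11", 32400000, "G", "A", origin = "somatic",
               pathogenicity = pathogenicity, is_aml_driver = driver,
               vaf = vaf)
}

in_frame_fusion <- function(geneA, geneB, cid = "T1", exonA = 5L,
                            exonB = 2L) {
  a <- gene_locus(geneA)
  b <- gene_locus(geneB)
  structural_event(cid, chromA = a$chrom, posA = round(a$pos),
                   chromB = b$chrom, posB = round(b$pos),
                   geneA = geneA, geneB = geneB, exonA = exonA,
                   exonB = exonB, frame = "in_frame",
                   event_class = "fusion")
}

flat_expression <- function(cid, ...) {
  expression_profile(cid, c(...))
}

empty_variants <- function() variant_call("x", "g", "1", 1, "A", "C")[0, ]
empty_svs <- function() structural_event("x", "1", 1, "2", 1)[0, ]
empty_cnvs <- function() cnv_segment("x", "1", 1, 2, "loss")[0, ]
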