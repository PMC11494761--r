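# Hand-built miniature fixtures shared across tests. Everything is
# constructed in code; no files beyond the packaged extdata are read.

# Single-exon plus-strand gene: CDS = positions 11..40 of a 60-bp contig.
# CDS: ATG AAA CCC GGG TTT AAA GAT GAA TGG TAG -> peptide MKPGFKDEW*
tiny_ref <- function() {
  reference_sequence("c1", paste0(
    "GGGGGGGGGG",
    "ATGAAACCCGGGTTTAAAGATGAATGGTAG",
    "GGGGGGGGGGGGGGGGGGGG"))
}

tiny_tx <- function(strand = "+") {
  transcript("T1", "G1", "c1", strand,
             data.frame(start = 5L, end = 46L),
             cds_start = 11L, cds_end = 40L, canonical = TRUE)
}

# Three-exon plus-strand transcript with introns; CDS spans all exons.
# Exon layout on a 220-bp contig: [21,60] [101,150] [181,210]
three_exon_locus <- function(strand = "+") {
  cds <- paste0("ATG",
                paste(rep("GAT", 31), collapse = ""),  # 31 x Asp
                "TAA")                                  # 99 nt total
  utr5 <- "ACGTACGTAC"                                 # 10 nt
  utr3 <- "CGTACGTACGT"                                # 11 nt
  spliced <- paste0(utr5, cds, utr3)                   # 120 nt
  stopifnot(nchar(spliced) == 120L)
  exon_lens <- c(40L, 50L, 30L)
  seg <- function(a, b) substr(spliced, a, b)
  intron1 <- paste(rep("T", 40), collapse = "")
  intron2 <- paste(rep("C", 30), collapse = "")
  contig <- paste0(paste(rep("A", 20), collapse = ""),
                   seg(1, 40), intron1, seg(41, 90), intron2, seg(91, 120),
                   paste(rep("A", 10), collapse = ""))
  ref <- reference_sequence("c3", contig)
  ex <- data.frame(start = c(21L, 101L, 181L), end = c(60L, 150L, 210L))
  # CDS starts at spliced offset 11 -> genomic 31; ends spliced 109 ->
  # genomic 199
  tx <- transcript("T3", "G3", "c3", "+", ex,
                   cds_start = 31L, cds_end = 199L, canonical = TRUE)
  if (strand == "-") return(mirror_locus(ref, tx))
  list(ref = ref, tx = tx)
}

# Mirror a locus to the opposite strand: reverse-complement the contig and
# reflect all coordinates, preserving transcript content.
mirror_locus <- function(ref, tx) {
  n <- nchar(ref$sequence)
  m_ref <- reference_sequence(ref$contig, reverse_complement(ref$sequence))
  mir <- function(p) n - p + 1L
  ex <- data.frame(start = mir(tx$exons$end), end = mir(tx$exons$start))
  ex <- ex[order(ex$start), , drop = FALSE]
  m_tx <- transcript(tx$id, tx$gene_id, tx$contig,
                     if (tx$strand == "+") "-" else "+",
                     ex, cds_start = mir(tx$cds_end),
                     cds_end = mir(tx$cds_start), canonical = tx$canonical)
  list(ref = m_ref, tx = m_tx)
}

# Mirror a variant on the same locus (SNVs only).
mirror_snv <- function(v, n) {
  variant(v$contig, n - v$pos + 1L,
          chartr("ACGTN", "TGCAN", v$ref), chartr("ACGTN", "TGCAN", v$alt))
}

# Assemble an annotated variant with a single prescribed annotation, for
# rule-engine tests that bypass the annotator.
stub_annotated <- function(consequence, lof = FALSE, nmd = FALSE,
                           aa_ref = "-", aa_alt = "-",
                           gene_symbol = "TTN", transcript_id = "T1",
                           pos = 100L) {
  v <- variant("c1", pos, "A", "G")
  pa <- protein_annotation(aa_ref = aa_ref, aa_alt = aa_alt,
                           aa_pos = if (aa_ref == "-") NA_integer_ else 5L,
                           lof = lof, nmd = nmd)
  ga <- gene_annotation(gene_symbol, transcript_id, consequence)
  annotated_variant(v, list(list(gene = ga, protein = pa)))
}
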