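test_that("impact classes follow the consequence table", {
  expect_identical(impact_of("stop_gained"), "HIGH")
  expect_identical(impact_of("splice_donor_variant"), "HIGH")
  expect_identical(impact_of("missense_variant"), "MODERATE")
  expect_identical(impact_of("initiator_codon_variant"), "MODERATE")
  expect_identical(impact_of("synonymous_variant"), "LOW")
  expect_identical(impact_of("intron_variant"), "MODIFIER")
  expect_error(impact_of("made_up_variant"), "unknown consequence")
})

test_that("SNV consequences are called from the affected codon", {
  ref <- tiny_ref(); tx <- tiny_tx()
  # CDS 11..40 = ATG AAA CCC GGG TTT AAA GAT GAA TGG TAG
  call <- function(pos, r, a) consequence(variant("c1", pos, r, a), tx, ref)
  expect_identical(call(14, "A", "G"), "missense_variant")    # AAA->GAA
  expect_identical(call(16, "A", "G"), "synonymous_variant")  # AAA->AAG
  expect_identical(call(37, "G", "A"), "stop_gained")         # TGG->TGA
  expect_identical(call(39, "A", "C"), "stop_lost")           # TAG->TCG
  expect_identical(call(40, "G", "A"), "stop_retained_variant") # TAG->TAA
  expect_identical(call(12, "T", "C"), "start_lost")          # ATG->ACG
  expect_identical(call(11, "A", "C"), "initiator_codon_variant") # ATG->CTG
})

test_that("variants outside genes are classified by distance and strand", {
  n <- 12000L
  ref <- reference_sequence("c1", strrep("ACGT", n / 4L))
  tx <- transcript("T", "G", "c1", "+",
                   data.frame(start = 11001L, end = 11060L),
                   cds_start = 11011L, cds_end = 11040L)
  base <- function(p) substr(ref$sequence, p, p)
  mk <- function(p) variant("c1", p, base(p),
                            setdiff(c("A", "C", "G", "T"), base(p))[1])
  expect_identical(consequence(mk(100L), tx, ref), "intergenic_variant")
  expect_identical(consequence(mk(7000L), tx, ref), "upstream_gene_variant")
  tx_minus <- transcript("T", "G", "c1", "-",
                         data.frame(start = 11001L, end = 11060L),
                         cds_start = 11011L, cds_end = 11040L)
  expect_identical(consequence(mk(7000L), tx_minus, ref),
                   "downstream_gene_variant")
  expect_error(consequence(variant("cX", 5, "A", "G"), tx, ref), "contig")
})

test_that("intronic positions resolve to splice site, region or intron", {
  loc <- three_exon_locus()   # introns [61,100] (T run) and [151,180] (C run)
  call <- function(pos, r, a)
    consequence(variant("c3", pos, r, a), loc$tx, loc$ref)
  expect_identical(call(61, "T", "A"), "splice_donor_variant")
  expect_identical(call(62, "T", "A"), "splice_donor_variant")
  expect_identical(call(100, "T", "A"), "splice_acceptor_variant")
  expect_identical(call(99, "T", "A"), "splice_acceptor_variant")
  expect_identical(call(65, "T", "A"), "splice_region_variant")   # 4 nt in
  expect_identical(call(75, "T", "A"), "intron_variant")          # mid-intron
  expect_identical(call(152, "C", "A"), "splice_donor_variant")
  expect_identical(call(179, "C", "A"), "splice_acceptor_variant")
})

test_that("exonic non-CDS positions resolve to UTRs by strand", {
  loc <- three_exon_locus()
  base <- function(p) substr(loc$ref$sequence, p, p)
  mk <- function(p) variant("c3", p, base(p),
                            setdiff(c("A", "C", "G", "T"), base(p))[1])
  expect_identical(consequence(mk(25L), loc$tx, loc$ref),
                   "5_prime_UTR_variant")
  expect_identical(consequence(mk(205L), loc$tx, loc$ref),
                   "3_prime_UTR_variant")
})

test_that("indels are classified by frame and codon alignment", {
  ref <- tiny_ref(); tx <- tiny_tx()
  s <- ref$sequence
  sl <- function(a, b) substr(s, a, b)
  # CDS 11..40 = ATG AAA CCC GGG ...; codon 3 (CCC) at genomic 17..19
  # whole-codon deletion anchored at 16
  v_if <- variant("c1", 16L, sl(16, 19), sl(16, 16))
  expect_identical(consequence(v_if, tx, ref), "inframe_deletion")
  # 3-bp deletion straddling the codon boundary (offsets 8..10)
  v_dis <- variant("c1", 17L, sl(17, 20), sl(17, 17))
  expect_identical(consequence(v_dis, tx, ref),
                   "disruptive_inframe_deletion")
  # 1-bp deletion shifts the frame
  v_fs <- variant("c1", 16L, sl(16, 17), sl(16, 16))
  expect_identical(consequence(v_fs, tx, ref), "frameshift_variant")
  # codon insertion at the codon-3/codon-4 boundary (after offset 9)
  v_ins <- variant("c1", 19L, sl(19, 19), paste0(sl(19, 19), "AAA"))
  expect_identical(consequence(v_ins, tx, ref), "inframe_insertion")
  # same insertion one base later straddles the boundary
  v_insd <- variant("c1", 20L, sl(20, 20), paste0(sl(20, 20), "AAA"))
  expect_identical(consequence(v_insd, tx, ref),
                   "disruptive_inframe_insertion")
  # 2-bp insertion shifts the frame
  v_fsi <- variant("c1", 19L, sl(19, 19), paste0(sl(19, 19), "AA"))
  expect_identical(consequence(v_fsi, tx, ref), "frameshift_variant")
})

test_that("amino-acid changes report residue, alternates and position", {
  ref <- tiny_ref(); tx <- tiny_tx()
  aac <- amino_acid_change(variant("c1", 14, "A", "G"), tx, ref)
  expect_identical(aac[c("aa_ref", "aa_alt")], list(aa_ref = "K",
                                                    aa_alt = "E"))
  expect_identical(aac$aa_pos, 2L)
  syn <- amino_acid_change(variant("c1", 16, "A", "G"), tx, ref)
  expect_identical(syn$aa_ref, syn$aa_alt)
  loc <- three_exon_locus()
  expect_null(amino_acid_change(variant("c3", 75, "T", "A"), loc$tx,
                                loc$ref))
})

test_that("LOF prediction applies the truncation-fraction rule", {
  expect_true(predict_lof("stop_gained", 10L, 100L))
  expect_false(predict_lof("stop_gained", 99L, 100L))
  expect_true(predict_lof("stop_gained", 95L, 100L))
  expect_false(predict_lof("stop_gained", 96L, 100L))
  expect_false(predict_lof("missense_variant", 10L, 100L))
  expect_true(predict_lof("splice_acceptor_variant"))
  expect_true(predict_lof("splice_donor_variant"))
  expect_true(predict_lof("start_lost"))
  expect_true(predict_lof("frameshift_variant", 10L, 100L))
})

test_that("NMD prediction applies the 50-nt last-junction rule", {
  loc <- three_exon_locus()
  # last junction at spliced offset 90; CDS offset o sits at spliced 10 + o
  expect_true(predict_nmd("stop_gained", 13L, loc$tx))    # 67 nt upstream
  expect_true(predict_nmd("stop_gained", 30L, loc$tx))    # exactly 50 nt
  expect_false(predict_nmd("stop_gained", 31L, loc$tx))   # 49 nt
  expect_false(predict_nmd("stop_gained", 85L, loc$tx))   # downstream-ish
  expect_false(predict_nmd("missense_variant", 13L, loc$tx))
  expect_false(predict_nmd("stop_gained", 5L, tiny_tx())) # single exon
})

test_that("ANN field entries parse, split on severity and round trip", {
  val <- paste0("G|missense_variant|MODERATE|TTN|TTN|transcript|T1|",
                "protein_coding|1/1||p.Lys100Glu|||||")
  out <- parse_ann_field(val)
  expect_identical(out$skipped, 0L)
  expect_length(out$annotations, 1L)
  a <- out$annotations[[1]]
  expect_identical(a$gene$gene_symbol, "TTN")
  expect_identical(a$gene$consequence, "missense_variant")
  expect_identical(a$protein[c("aa_ref", "aa_alt", "aa_pos")],
                   list(aa_ref = "K", aa_alt = "E", aa_pos = 100L))
  # two entries -> two pairs
  out2 <- parse_ann_field(paste(val, val, sep = ","))
  expect_length(out2$annotations, 2L)
  # ampersand-joined terms keep the most severe
  val3 <- paste0("G|stop_gained&splice_region_variant|HIGH|TTN|TTN|",
                 "transcript|T1|protein_coding|1/1||p.Lys100Ter|||||")
  expect_identical(parse_ann_field(val3)$annotations[[1]]$gene$consequence,
                   "stop_gained")
  # short entries are skipped with a warning and counted
  expect_warning(out4 <- parse_ann_field("G|missense_variant|MODERATE"),
                 "skipped")
  expect_identical(out4$skipped, 1L)
  # LOF / NMD companion keys
  out5 <- parse_ann_field(val3, lof_info = "(TTN|TTN|1|1.00)",
                          nmd_info = "(TTN|TTN|1|1.00)")
  expect_true(out5$annotations[[1]]$protein$lof)
  expect_true(out5$annotations[[1]]$protein$nmd)
  # writer + parser is the identity on retained fields
  v <- variant("c1", 14, "A", "G")
  ga <- gene_annotation("TTN", "T1", "missense_variant")
  pa <- protein_annotation("K", "E", 2L, "p.Lys2Glu")
  rt <- parse_ann_field(format_ann_field(v, list(list(gene = ga,
                                                      protein = pa))))
  expect_identical(rt$annotations[[1]]$gene, ga)
  expect_identical(rt$annotations[[1]]$protein[c("aa_ref", "aa_alt",
                                                 "aa_pos", "hgvs_p")],
                   pa[c("aa_ref", "aa_alt", "aa_pos", "hgvs_p")])
})

test_that("representative annotation prefers canonical, then severity,
           then transcript id", {
  pa <- protein_annotation()
  ann <- function(cons, tx_id) list(gene = gene_annotation("G", tx_id, cons),
                                    protein = pa)
  # canonical MODERATE beats non-canonical HIGH
  idx <- representative_annotation(
    list(ann("stop_gained", "T9"), ann("missense_variant", "T1")),
    canonical_ids = "T1")
  expect_identical(idx, 2L)
  # severity when no canonical
  idx2 <- representative_annotation(
    list(ann("synonymous_variant", "T1"), ann("stop_gained", "T9")))
  expect_identical(idx2, 2L)
  # tie -> smallest id
  idx3 <- representative_annotation(
    list(ann("missense_variant", "T9"), ann("missense_variant", "T2")))
  expect_identical(idx3, 2L)
  expect_error(representative_annotation(list()), "no annotations")
})

test_that("normalization trims, anchors and left-aligns indels", {
  ref <- tiny_ref()
  v <- normalize_variant(variant("c1", 14, "AAA", "AGA"), ref)
  expect_identical(list(v$pos, v$ref, v$alt), list(15L, "A", "G"))
  # deletion in the poly-G run left-aligns to the run start (pos 41..46 = G)
  v2 <- normalize_variant(variant("c1", 44, "GG", "G"), ref)
  expect_lt(v2$pos, 44L)
  expect_identical(nchar(v2$ref) - nchar(v2$alt), 1L)
  expect_error(variant("c1", 14, "A", "A"), "identical")
})

test_that("consequence terms are invariant under locus mirroring", {
  loc <- three_exon_locus()
  m <- mirror_locus(loc$ref, loc$tx)
  n <- nchar(loc$ref$sequence)
  bases <- strsplit(loc$ref$sequence, "")[[1]]
  set.seed(42)
  positions <- sample(seq_len(n), 80L)
  for (p in positions) {
    for (alt in setdiff(c("A", "C", "G", "T"), bases[p])) {
      v <- variant("c3", p, bases[p], alt)
      expect_identical(consequence(mirror_snv(v, n), m$tx, m$ref),
                       consequence(v, loc$tx, loc$ref),
                       info = paste("pos", p, "alt", alt))
    }
  }
})

test_that("SNV calls agree with whole-CDS re-translation via Biostrings", {
  for (strand in c("+", "-")) {
    loc <- three_exon_locus(strand)
    bases <- strsplit(loc$ref$sequence, "")[[1]]
    for (p in sort(cds_genomic_positions(loc$tx))) {
      for (alt in setdiff(c("A", "C", "G", "T"), bases[p])) {
        v <- variant("c3", p, bases[p], alt)
        expect_identical(consequence(v, loc$tx, loc$ref),
                         brute_snv_consequence(v, loc$tx, loc$ref),
                         info = paste(strand, p, alt))
      }
    }
  }
})
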