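test_that("toy GFF3 fixture loads into the expected gene/transcript model", {
  path <- system.file("extdata", "toy_models.gff3",
                      package = "cardiorelevance")
  genes <- load_gene_models(path)
  expect_length(genes, 2L)
  expect_setequal(vapply(genes, function(g) g$symbol, character(1)),
                  c("GA", "GB"))
  expect_identical(sum(vapply(genes, function(g) length(g$transcripts),
                              integer(1))), 3L)
  ga <- Filter(function(g) g$symbol == "GA", genes)[[1]]
  expect_identical(select_canonical(ga)$id, "GA_T1")
  expect_identical(ga$transcripts[[1]]$strand, "+")
})

test_that("packaged 13-gene JSON fixture carries the chromosome map", {
  genes <- load_gene_models(
    system.file("extdata", "gene_models_cardiomyopathy_synthetic.json",
                package = "cardiorelevance"))
  expect_length(genes, 13L)
  chrom <- vapply(genes, function(g) g$contig, character(1))
  names(chrom) <- vapply(genes, function(g) g$symbol, character(1))
  expect_identical(unname(chrom[c("TNNT2", "CAPZA1")]), rep("chr1", 2))
  expect_identical(unname(chrom[c("MYL1", "DES", "TTN")]), rep("chr2", 3))
  expect_identical(unname(chrom[c("ACTN1", "MYH7", "MYH6")]), rep("chr14", 3))
  expect_identical(unname(chrom[c("TPM1", "ACTC1")]), rep("chr15", 2))
  expect_identical(unname(chrom["TNNC1"]), "chr3")
  expect_identical(unname(chrom["MYBPC3"]), "chr11")
  expect_identical(unname(chrom["MYL2"]), "chr12")
})

test_that("transcript invariants are enforced", {
  expect_error(
    transcript("T", "G", "c1", "+",
               data.frame(start = c(1L, 40L), end = c(50L, 90L)),
               cds_start = 10L, cds_end = 80L),
    "non-overlapping")
  expect_error(
    transcript("T", "G", "c1", "+", data.frame(start = 10L, end = 50L),
               cds_start = 5L, cds_end = 40L),
    "CDS boundaries")
  expect_error(
    gene("G", "c1", 1, 100,
         list(tiny_tx(), transcript("T2", "G1", "c1", "+",
                                    data.frame(start = 5L, end = 46L),
                                    cds_start = 11L, cds_end = 40L,
                                    canonical = TRUE))),
    "more than one canonical")
})

test_that("canonical selection prefers flag, then CDS length, then id", {
  mk <- function(id, cds_end, canonical = FALSE) {
    transcript(id, "G", "c1", "+", data.frame(start = 1L, end = 400L),
               cds_start = 1L, cds_end = cds_end, canonical = canonical)
  }
  g1 <- gene("G", "c1", 1, 400, list(mk("T1", 300)))
  expect_identical(select_canonical(g1)$id, "T1")
  g2 <- gene("G", "c1", 1, 400, list(mk("TA", 150), mk("TB", 300)))
  expect_identical(select_canonical(g2)$id, "TB")
  g3 <- gene("G", "c1", 1, 400, list(mk("T2", 300), mk("T1", 300)))
  expect_identical(select_canonical(g3)$id, "T1")
  g4 <- gene("G", "c1", 1, 400,
             list(mk("T2", 150, canonical = TRUE), mk("T1", 300)))
  expect_identical(select_canonical(g4)$id, "T2")
  expect_error(select_canonical(gene("G", "c1", 1, 400, list())),
               "no transcripts")
})

test_that("cds_sequence slices, splices and reverse-complements", {
  ref <- tiny_ref()
  tx <- tiny_tx("+")
  expect_identical(substr(cds_sequence(tx, ref), 1, 6), "ATGAAA")
  # explicit minus-strand definition on a dedicated locus
  m <- mirror_locus(ref, tx)
  expect_identical(cds_sequence(m$tx, m$ref), cds_sequence(tx, ref))
  # multi-exon splice against a per-base walk
  loc <- three_exon_locus()
  got <- cds_sequence(loc$tx, loc$ref)
  walk <- unlist(lapply(seq_len(nrow(loc$tx$exons)), function(i)
    loc$tx$exons$start[i]:loc$tx$exons$end[i]))
  walk <- walk[walk >= loc$tx$cds_start & walk <= loc$tx$cds_end]
  manual <- paste(strsplit(loc$ref$sequence, "")[[1]][walk], collapse = "")
  expect_identical(got, manual)
  expect_identical(nchar(got), 99L)
  expect_error(cds_sequence(loc$tx, ref), "contig")
})

test_that("translation follows the standard code with N -> X", {
  expect_identical(translate_cds("ATGAAATAG"), "MK*")
  expect_identical(translate_cds("ATG"), "M")
  expect_match(translate_cds("ATGANA"), "^MX$")
  expect_warning(out <- translate_cds("ATGAAAT"), "multiple of 3")
  expect_identical(out, "MK")
  expect_error(translate_cds("AT"), "shorter")
  expect_error(translate_cds("ATGXXX"), "non-ACGTN")
  set.seed(99)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    expect_identical(translate_cds(s), bio_translate(s))
  }
})

test_that("genomic_to_cds matches exhaustive enumeration on both strands", {
  for (strand in c("+", "-")) {
    loc <- three_exon_locus(strand)
    for (p in seq_len(nchar(loc$ref$sequence))) {
      expect_identical(genomic_to_cds(loc$tx, p),
                       brute_genomic_to_cds(loc$tx, p),
                       info = paste("strand", strand, "pos", p))
    }
    expect_identical(genomic_to_cds(loc$tx, 70L), NA_integer_)  # intronic
  }
})

test_that("CDS base lookup is consistent with the reference", {
  for (strand in c("+", "-")) {
    loc <- three_exon_locus(strand)
    cds <- cds_sequence(loc$tx, loc$ref)
    bases <- strsplit(loc$ref$sequence, "")[[1]]
    for (p in sort(cds_genomic_positions(loc$tx))) {
      off <- genomic_to_cds(loc$tx, p)
      expected <- if (strand == "-") chartr("ACGTN", "TGCAN", bases[p])
        else bases[p]
      expect_identical(substr(cds, off, off), expected)
    }
  }
})

test_that("packaged fixtures translate M...* on the canonical transcript", {
  genes <- load_gene_models(system.file("extdata", "toy_models.gff3",
                                        package = "cardiorelevance"))
  fa <- Biostrings::readDNAStringSet(
    system.file("extdata", "toy_ref.fa", package = "cardiorelevance"))
  ref <- reference_sequence("chrT", as.character(fa[[1]]))
  for (g in genes) {
    pep <- translate_cds(cds_sequence(select_canonical(g), ref))
    expect_identical(substr(pep, 1, 1), "M")
    expect_identical(substr(pep, nchar(pep), nchar(pep)), "*")
    expect_false(grepl("\\*", substr(pep, 1, nchar(pep) - 1L)))
  }
})

test_that("gene-model JSON round trip is the identity", {
  genes <- load_gene_models(
    system.file("extdata", "gene_models_cardiomyopathy_synthetic.json",
                package = "cardiorelevance"))
  tmp <- withr::local_tempfile(fileext = ".json")
  save_gene_models(genes, tmp)
  again <- load_gene_models(tmp, format = "json")
  expect_equal(again, genes)
})

test_that("reference sequence bounds and alphabet are checked", {
  expect_error(reference_sequence("c", ""), "empty")
  expect_error(reference_sequence("c", "ACGU"), "non-ACGTN")
  ref <- tiny_ref()
  expect_error(ref_slice(ref, 0, 5), "outside")
  expect_error(ref_slice(ref, 55, 70), "outside")
  expect_identical(ref_slice(ref, 11, 13), "ATG")
})

test_that("panels load from JSON and BED and reject empties", {
  p <- packaged_panel("cardiomyopathy")
  expect_identical(p$name, "cardiomyopathy")
  expect_length(p$gene_symbols, 13L)
  expect_true(all(c("TTN", "MYH7", "MYBPC3") %in% p$gene_symbols))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t100\t200\tTTN", "chr14\t5\t50\tMYH7"), bed)
  pb <- load_panel(bed)
  expect_setequal(pb$gene_symbols, c("TTN", "MYH7"))
  expect_error(gene_panel("empty", character(0)), "empty")
})
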