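test_that("VCF parsing splits alternates and skips malformed records", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=1000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "c1\t10\t.\tA\tG\t50\tPASS\tDP=12",
    "c1\t20\t.\tC\tT,G\t.\t.\t.",
    "c1\t30\t.\tT\tT\t.\t.\t."), tmp)
  expect_warning(vars <- parse_vcf(tmp), "skipped")
  expect_length(vars, 3L)              # 1 + 2 alternates; ref==alt dropped
  expect_identical(attr(vars, "skipped"), 1L)
  expect_identical(vars[[1]]$info$DP, "12")
  expect_identical(vars[[1]]$qual, 50)
  expect_identical(vapply(vars[2:3], function(v) v$alt, character(1)),
                   c("T", "G"))
  # missing header is an error
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines("c1\t10\t.\tA\tG\t.\t.\t.", bad)
  expect_error(parse_vcf(bad), "header")
  expect_error(parse_vcf("/nonexistent.vcf"), "not found")
})

test_that("toy discovery run retains 8 panel variants, 3 of them relevant", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  ts <- toy_discovery_set(11L, vcf_path = tmp)
  res <- suppressMessages(
    run_discovery(tmp, ts$genes, packaged_graph("cardiomyopathy"),
                  discovery_options(ts$panel), ref = ts$ref))
  expect_identical(nrow(res$summary), 8L)
  expect_identical(nrow(res$relevant), 3L)
  expect_setequal(res$relevant$consequence,
                  c("stop_gained", "splice_donor_variant",
                    "disruptive_inframe_deletion"))
  # relevant rows are exactly the summary rows with non-empty criteria
  expect_identical(res$relevant$key,
                   res$summary$key[nzchar(res$summary$criteria)])
  # contexts attached for each relevant variant
  expect_setequal(names(res$contexts), res$relevant$key)
  expect_true(all(c("structural", "functional") %in%
                  names(res$contexts[[1]])))
})

test_that("aggregate maps each conserve the retained-variant count", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  ts <- toy_discovery_set(11L, vcf_path = tmp)
  res <- suppressMessages(
    run_discovery(tmp, ts$genes, NULL, discovery_options(ts$panel),
                  ref = ts$ref))
  n <- nrow(res$summary)
  for (m in names(res$aggregates)) {
    expect_identical(sum(res$aggregates[[m]]), n, info = m)
  }
  expect_identical(unname(res$aggregates$by_chromosome["chrS"]), 8L)
  # empty aggregation
  empty <- aggregate_assessed(list())
  expect_true(all(vapply(empty, length, integer(1)) == 0L))
})

test_that("the pipeline is deterministic given inputs and options", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  ts <- toy_discovery_set(11L, vcf_path = tmp)
  opt <- discovery_options(ts$panel)
  r1 <- suppressMessages(run_discovery(tmp, ts$genes, NULL, opt,
                                       ref = ts$ref))
  r2 <- suppressMessages(run_discovery(tmp, ts$genes, NULL, opt,
                                       ref = ts$ref))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$aggregates, r2$aggregates)
})

test_that("an empty VCF body yields an empty result with zero aggregates", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(list(), tmp, contig = "chrS", contig_length = 100L)
  ts <- toy_discovery_set(11L)
  res <- suppressMessages(
    run_discovery(tmp, ts$genes, NULL, discovery_options(ts$panel),
                  ref = ts$ref))
  expect_identical(nrow(res$summary), 0L)
  expect_identical(nrow(res$relevant), 0L)
  expect_true(all(vapply(res$aggregates, sum, numeric(1)) == 0))
})

test_that("ANN-field annotation source reproduces the builtin calls", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  ts <- toy_discovery_set(11L)
  # annotate with the builtin path, serialize as ANN INFO, re-discover
  anns <- lapply(ts$variants, annotate_variant, genes = ts$genes,
                 ref = ts$ref)
  info <- vapply(seq_along(anns), function(i) {
    av <- anns[[i]]
    lof_genes <- unique(unlist(lapply(av$annotations, function(a)
      if (a$protein$lof) a$gene$gene_symbol else NULL)))
    nmd_genes <- unique(unlist(lapply(av$annotations, function(a)
      if (a$protein$nmd) a$gene$gene_symbol else NULL)))
    parts <- paste0("ANN=", format_ann_field(ts$variants[[i]],
                                             av$annotations))
    if (length(lof_genes)) {
      parts <- paste0(parts, ";LOF=",
                      paste0("(", lof_genes, "|", lof_genes, "|1|1.00)",
                             collapse = ","))
    }
    if (length(nmd_genes)) {
      parts <- paste0(parts, ";NMD=",
                      paste0("(", nmd_genes, "|", nmd_genes, "|1|1.00)",
                             collapse = ","))
    }
    parts
  }, character(1))
  write_vcf(ts$variants, tmp, contig = "chrS", info_strings = info)
  res_ann <- suppressMessages(
    run_discovery(tmp, graph = NULL,
                  options = discovery_options(ts$panel,
                                              annotation_source =
                                                "ann_field")))
  write_vcf(ts$variants, tmp, contig = "chrS")
  res_bi <- suppressMessages(
    run_discovery(tmp, ts$genes, NULL, discovery_options(ts$panel),
                  ref = ts$ref))
  expect_identical(res_ann$summary$consequence, res_bi$summary$consequence)
  expect_identical(res_ann$summary$relevant, res_bi$summary$relevant)
  expect_identical(res_ann$summary$lof, res_bi$summary$lof)
})

test_that("detail records expose residue classes, contexts and gene info", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  ts <- toy_discovery_set(11L, vcf_path = tmp)
  graph <- packaged_graph("cardiomyopathy")
  res <- suppressMessages(
    run_discovery(tmp, ts$genes, graph, discovery_options(ts$panel),
                  ref = ts$ref))
  mis <- res$summary$key[res$summary$consequence == "missense_variant"][1]
  det <- variation_detail(res, mis)
  expect_identical(det$consequence$effect, "missense_variant")
  expect_true(!is.null(det$amino_acid_change$reference$hydropathy))
  expect_true(!is.null(det$amino_acid_change$alternate$polarity))
  expect_error(variation_detail(res, "nope:1:A:G"), "unknown variant")
  # gene detail from the packaged 13-gene fixture: TTN sits on chr2
  genes13 <- load_gene_models(
    system.file("extdata", "gene_models_cardiomyopathy_synthetic.json",
                package = "cardiorelevance"))
  gd <- gene_detail(genes13, graph, "TTN")
  expect_identical(gd$location$chromosome, "chr2")
  expect_true(nzchar(gd$description))
  expect_true("myocardium" %in% gd$structural_context$id)
  expect_error(gene_detail(genes13, graph, "NOPE"), "unknown gene")
})

test_that("exports write stable files with a checksum manifest", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  ts <- toy_discovery_set(11L, vcf_path = tmp)
  res <- suppressMessages(
    run_discovery(tmp, ts$genes, packaged_graph("cardiomyopathy"),
                  discovery_options(ts$panel), ref = ts$ref))
  dir1 <- withr::local_tempdir()
  m1 <- export_result(res, dir1)
  expect_setequal(m1$file, c("summary.tsv", "relevant.tsv",
                             "aggregates.json", "contexts.json"))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  tsv <- utils::read.table(file.path(dir1, "summary.tsv"), header = TRUE,
                           sep = "\t")
  expect_identical(nrow(tsv), nrow(res$summary))
  # re-export is checksum-identical
  dir2 <- withr::local_tempdir()
  m2 <- export_result(res, dir2)
  expect_identical(m1$md5, m2$md5)
  # empty result -> headers-only TSVs
  emptyv <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(list(), emptyv, contig = "chrS")
  res0 <- suppressMessages(
    run_discovery(emptyv, ts$genes, NULL, discovery_options(ts$panel),
                  ref = ts$ref))
  dir3 <- withr::local_tempdir()
  export_result(res0, dir3)
  expect_identical(length(readLines(file.path(dir3, "summary.tsv"))), 1L)
})
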