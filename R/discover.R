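# End-to-end discovery pipeline: parse -> annotate (built-in or ANN field)
# -> panel filter -> relevance assessment -> knowledge-graph context ->
# aggregation -> export.

#' Discovery options
#'
#' @param panel A `gene_panel`.
#' @param annotation_source `"builtin"` (the mini-annotator) or
#'   `"ann_field"` (parse pre-computed SnpEff-style ANN INFO fields).
#' @param canonical_only Annotate only each gene's canonical transcript.
#' @param ann `ann_options` (windows and thresholds).
#' @param any_transcript Evaluate relevance over all annotations rather
#'   than the representative one.
#' @return List of class `discovery_options`.
#' @export
discovery_options <- function(panel,
                              annotation_source = c("builtin", "ann_field"),
                              canonical_only = FALSE,
                              ann = ann_options(),
                              any_transcript = FALSE) {
  structure(list(panel = panel,
                 annotation_source = match.arg(annotation_source),
                 canonical_only = canonical_only, ann = ann,
                 any_transcript = any_transcript),
            class = "discovery_options")
}

#' Parse a VCF 4.2 file into variants
#'
#' One `variant` per (record, alternate allele). QUAL, FILTER, INFO and
#' genotype columns are retained verbatim; malformed records (e.g.
#' ref == alt, symbolic alleles) are skipped with a warning and counted.
#'
#' @param path VCF path.
#' @return List of `variant` objects; the skipped-record count is attached
#'   as attribute `"skipped"`.
#' @export
parse_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^##fileformat=VCF", first)) {
    stop("'", path, "' has no VCF header")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  out <- list(); skipped <- 0L
  if (is.null(fix) || nrow(fix) == 0L) {
    attr(out, "skipped") <- 0L
    return(out)
  }
  gt <- if (ncol(vcf@gt) > 1L) vcf@gt else NULL
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    info <- parse_info_string(fix[i, "INFO"])
    samples <- if (!is.null(gt)) {
      as.list(gt[i, -1, drop = TRUE])
    } else NULL
    for (alt in alts) {
      v <- tryCatch(
        variant(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                fix[i, "REF"], alt,
                qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
                filter = ifelse(is.na(fix[i, "FILTER"]), ".",
                                fix[i, "FILTER"]),
                info = info, samples = samples),
        error = function(e) {
          warning("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
                  " skipped: ", conditionMessage(e))
          NULL
        })
      if (is.null(v)) skipped <- skipped + 1L else out <- c(out, list(v))
    }
  }
  attr(out, "skipped") <- skipped
  out
}

parse_info_string <- function(s) {
  if (is.na(s) || s == "." || !nzchar(s)) return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    out[[kv[1]]] <- if (length(kv) > 1L)
      paste(kv[-1], collapse = "=") else TRUE
  }
  out
}

#' Run the discovery pipeline
#'
#' Composition: parse the VCF, annotate each variant (built-in annotator
#' or the record's ANN field), keep variants on panel genes, assess the
#' four relevance criteria, attach structural and functional context for
#' relevant variants, and aggregate counts. Deterministic given inputs
#' and options.
#'
#' @param vcf_path Input VCF.
#' @param gene_models List of `gene` objects (required for the built-in
#'   annotator).
#' @param graph A `knowledge_graph` (or `NULL` to skip contexts).
#' @param options A `discovery_options`.
#' @param ref A `reference_sequence` (required for the built-in annotator).
#' @return Object of class `discovery_result` with fields `summary`
#'   (`data.frame`, one row per retained variant), `relevant`, `aggregates`,
#'   `contexts`, `provenance`.
#' @export
run_discovery <- function(vcf_path, gene_models = NULL, graph = NULL,
                          options, ref = NULL) {
  stopifnot(inherits(options, "discovery_options"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  variants <- stage("parse", parse_vcf(vcf_path))
  annotated <- stage("annotate", {
    if (options$annotation_source == "builtin") {
      if (is.null(gene_models) || is.null(ref)) {
        stop("built-in annotation needs gene models and a reference")
      }
      lapply(variants, annotate_variant, genes = gene_models, ref = ref,
             opts = options$ann, canonical_only = options$canonical_only)
    } else {
      lapply(variants, function(v) {
        ann_val <- v$info[["ANN"]]
        if (is.null(ann_val)) {
          anns <- list(list(
            gene = gene_annotation(NA_character_, NA_character_,
                                   "intergenic_variant"),
            protein = protein_annotation()))
        } else {
          anns <- parse_ann_field(ann_val,
                                  lof_info = v$info[["LOF"]],
                                  nmd_info = v$info[["NMD"]])$annotations
        }
        annotated_variant(v, anns)
      })
    }
  })
  retained <- stage("filter", filter_to_panel(annotated, options$panel))
  assessed <- stage("assess",
                    assess_all(retained, options$any_transcript))
  summary_df <- stage("summarize", summary_table(assessed))
  aggregates <- stage("aggregate", aggregate_assessed(assessed))
  contexts <- stage("contextualize", {
    if (is.null(graph)) list() else {
      rel <- assessed[vapply(assessed, function(a)
        a$decision$relevant, logical(1))]
      out <- list()
      for (a in rel) {
        sym <- a$variant$annotations[[a$variant$representative]]$gene$gene_symbol
        key <- variant_key(a$variant$variant)
        out[[key]] <- tryCatch(
          list(structural = structural_context(graph, sym),
               functional = functional_context(graph, sym)),
          error = function(e) list(structural = NULL, functional = NULL))
      }
      out
    }
  })
  structure(list(
    summary = summary_df,
    relevant = summary_df[summary_df$relevant, , drop = FALSE],
    aggregates = aggregates,
    contexts = contexts,
    provenance = list(
      input = vcf_path,
      options = list(panel = options$panel$name,
                     annotation_source = options$annotation_source,
                     canonical_only = options$canonical_only,
                     lof_fraction = options$ann$lof_fraction,
                     nmd_distance = options$ann$nmd_distance),
      tool_version = as.character(utils::packageVersion("cardiorelevance")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "discovery_result")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat("<discovery_result>", nrow(x$summary), "variant(s) retained,",
      nrow(x$relevant), "relevant\n")
  invisible(x)
}

summary_table <- function(assessed) {
  cols <- c("key", "contig", "pos", "ref", "alt", "qual", "filter", "gene",
            "transcript", "consequence", "impact", "aa_ref", "aa_alt",
            "aa_pos", "hgvs_p", "lof", "nmd", "relevant", "criteria")
  if (!length(assessed)) {
    df <- as.data.frame(stats::setNames(
      lapply(cols, function(x) character(0)), cols),
      stringsAsFactors = FALSE)
    df$pos <- integer(0); df$qual <- numeric(0); df$aa_pos <- integer(0)
    df$lof <- logical(0); df$nmd <- logical(0); df$relevant <- logical(0)
    return(df)
  }
  rows <- lapply(assessed, function(a) {
    v <- a$variant$variant
    rep <- a$variant$annotations[[a$variant$representative]]
    data.frame(
      key = variant_key(v), contig = v$contig, pos = v$pos, ref = v$ref,
      alt = v$alt, qual = v$qual, filter = v$filter,
      gene = rep$gene$gene_symbol, transcript = rep$gene$transcript_id,
      consequence = rep$gene$consequence, impact = rep$gene$impact,
      aa_ref = rep$protein$aa_ref, aa_alt = rep$protein$aa_alt,
      aa_pos = rep$protein$aa_pos, hgvs_p = rep$protein$hgvs_p,
      lof = rep$protein$lof, nmd = rep$protein$nmd,
      relevant = a$decision$relevant,
      criteria = paste(a$decision$criteria, collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate assessed variants
#'
#' Counts grouped by chromosome, gene, predicted impact and predicted
#' effect (one vote per variant, keyed on the representative annotation).
#' Each map sums to the number of assessed variants.
#'
#' @param assessed Output of [assess_all()].
#' @return List of four named integer vectors: `by_chromosome`, `by_gene`,
#'   `by_impact`, `by_effect`.
#' @export
aggregate_assessed <- function(assessed) {
  count_by <- function(f) {
    vals <- vapply(assessed, f, character(1))
    if (!length(vals)) return(stats::setNames(integer(0), character(0)))
    tab <- table(vals)
    stats::setNames(as.integer(tab), names(tab))
  }
  rep_of <- function(a) a$variant$annotations[[a$variant$representative]]
  list(
    by_chromosome = count_by(function(a) a$variant$variant$contig),
    by_gene = count_by(function(a) {
      g <- rep_of(a)$gene$gene_symbol
      if (is.na(g)) "(none)" else g
    }),
    by_impact = count_by(function(a) rep_of(a)$gene$impact),
    by_effect = count_by(function(a) rep_of(a)$gene$consequence))
}

#' Detail record for one variant
#'
#' Variant basics, its consequence on gene and transcript, the amino-acid
#' change with both residues' hydropathy and polarity classes, and the
#' structural/functional context where available.
#'
#' @param result A `discovery_result`.
#' @param key A variant key (`contig:pos:ref:alt`).
#' @return Named list.
#' @export
variation_detail <- function(result, key) {
  row <- result$summary[result$summary$key == key, , drop = FALSE]
  if (nrow(row) == 0L) stop("unknown variant key: ", key)
  aa_class <- function(code) {
    if (is.na(code) || !code %in% rownames(aa_property_table())) return(NULL)
    p <- property_of(code)
    list(code = code, hydropathy = p$hydropathy_class,
         polarity = p$polarity_class)
  }
  ctx <- result$contexts[[key]]
  list(
    variant = list(contig = row$contig, pos = row$pos, ref = row$ref,
                   alt = row$alt, qual = row$qual, filter = row$filter),
    consequence = list(gene = row$gene, transcript = row$transcript,
                       effect = row$consequence, impact = row$impact),
    amino_acid_change = if (!is.na(row$aa_pos)) {
      list(position = row$aa_pos, reference = aa_class(row$aa_ref),
           alternate = aa_class(row$aa_alt), hgvs_p = row$hgvs_p)
    } else NULL,
    relevance = list(relevant = row$relevant, criteria = row$criteria),
    structural_context = if (!is.null(ctx)) ctx$structural else NULL,
    functional_context = if (!is.null(ctx)) ctx$functional else NULL)
}

#' Detail record for one gene
#'
#' Chromosome placement, description, and the gene's structural and
#' functional context in the knowledge graph.
#'
#' @param gene_models List of `gene` objects.
#' @param graph A `knowledge_graph` (or `NULL`).
#' @param symbol Gene symbol.
#' @return Named list.
#' @export
gene_detail <- function(gene_models, graph, symbol) {
  hit <- Filter(function(g) g$symbol == symbol, gene_models)
  if (!length(hit)) stop("unknown gene symbol: ", symbol)
  g <- hit[[1]]
  list(symbol = g$symbol,
       location = list(chromosome = g$contig, start = g$start, end = g$end),
       description = g$description,
       n_transcripts = length(g$transcripts),
       structural_context = if (!is.null(graph))
         tryCatch(structural_context(graph, symbol), error = function(e) NULL)
       else NULL,
       functional_context = if (!is.null(graph))
         tryCatch(functional_context(graph, symbol), error = function(e) NULL)
       else NULL)
}

#' Export a discovery result
#'
#' Writes `summary.tsv` (one row per retained variant), `relevant.tsv`
#' (with the criteria column), `aggregates.json`, `contexts.json` and a
#' `manifest.json` listing the files with their MD5 checksums. The
#' provenance timestamp is not part of any hashed payload, so re-exporting
#' the same result yields identical checksums.
#'
#' @param result A `discovery_result`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("json", "tsv")`.
#' @return The manifest as a `data.frame` (`file`, `md5`), invisibly
#'   written to `manifest.json`.
#' @export
export_result <- function(result, dir, formats = c("json", "tsv")) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  files <- character(0)
  if ("tsv" %in% formats) {
    f1 <- file.path(dir, "summary.tsv")
    utils::write.table(result$summary, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f2 <- file.path(dir, "relevant.tsv")
    utils::write.table(result$relevant, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f1, f2)
  }
  if ("json" %in% formats) {
    f3 <- file.path(dir, "aggregates.json")
    jsonlite::write_json(lapply(result$aggregates, as.list), f3,
                         auto_unbox = TRUE, pretty = TRUE)
    f4 <- file.path(dir, "contexts.json")
    jsonlite::write_json(result$contexts, f4, auto_unbox = TRUE,
                         pretty = TRUE, dataframe = "rows")
    files <- c(files, f3, f4)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
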