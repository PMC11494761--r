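# Gene, transcript and reference-sequence models underlying the annotator.
# Coordinates are 1-based inclusive throughout (VCF / GFF3 convention).

#' Reference sequence
#'
#' A named nucleotide sequence for a single contig. Sequences are stored
#' uppercase over the alphabet {A, C, G, T, N}.
#'
#' @param contig Contig identifier.
#' @param sequence Nucleotide string.
#' @return An object of class `reference_sequence`.
#' @export
reference_sequence <- function(contig, sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) {
    stop("reference sequence for contig '", contig, "' is empty")
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference sequence for contig '", contig,
         "' contains non-ACGTN characters")
  }
  structure(list(contig = as.character(contig), sequence = sequence),
            class = "reference_sequence")
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat("<reference_sequence>", x$contig, ":", nchar(x$sequence), "bp\n")
  invisible(x)
}

#' Extract bases from a reference sequence
#'
#' @param ref A `reference_sequence`.
#' @param start,end 1-based inclusive genomic positions.
#' @return Nucleotide string.
#' @export
ref_slice <- function(ref, start, end) {
  stopifnot(inherits(ref, "reference_sequence"))
  n <- nchar(ref$sequence)
  if (start < 1L || end > n || start > end) {
    stop("requested slice [", start, ", ", end, "] outside reference '",
         ref$contig, "' bounds [1, ", n, "]")
  }
  substr(ref$sequence, start, end)
}

#' Transcript model
#'
#' An exon/CDS model on one contig. Exons are 1-based inclusive, sorted
#' ascending and non-overlapping; `cds_start`/`cds_end` must fall inside the
#' exon union. At most one transcript per gene may carry `canonical = TRUE`.
#'
#' @param id Transcript identifier.
#' @param gene_id Parent gene identifier.
#' @param contig Contig identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `start`, `end`.
#' @param cds_start,cds_end Genomic CDS span (inclusive).
#' @param canonical Logical flag.
#' @return An object of class `transcript`.
#' @export
transcript <- function(id, gene_id, contig, strand, exons,
                       cds_start, cds_end, canonical = FALSE) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  tx <- structure(
    list(id = as.character(id), gene_id = as.character(gene_id),
         contig = as.character(contig), strand = strand, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         canonical = isTRUE(canonical)),
    class = "transcript")
  validate_transcript(tx)
  tx
}

validate_transcript <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 1L) stop("transcript '", tx$id, "': no exons")
  if (any(ex$start > ex$end)) {
    stop("transcript '", tx$id, "': exon with start > end")
  }
  if (is.unsorted(ex$start, strictly = TRUE) ||
      any(ex$start[-1] <= ex$end[-nrow(ex)])) {
    stop("transcript '", tx$id,
         "': exons must be sorted ascending and non-overlapping")
  }
  if (!tx$strand %in% c("+", "-")) {
    stop("transcript '", tx$id, "': strand must be '+' or '-'")
  }
  in_exon <- function(p) any(p >= ex$start & p <= ex$end)
  if (!in_exon(tx$cds_start) || !in_exon(tx$cds_end)) {
    stop("transcript '", tx$id, "': CDS boundaries outside exon union")
  }
  if (tx$cds_start > tx$cds_end) {
    stop("transcript '", tx$id, "': cds_start > cds_end")
  }
  invisible(tx)
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript>", x$id, "gene", x$gene_id, sprintf("(%s)", x$strand),
      nrow(x$exons), "exons, CDS", x$cds_start, "-", x$cds_end,
      if (x$canonical) "[canonical]" else "", "\n")
  invisible(x)
}

#' Gene model
#'
#' @param symbol Gene symbol (e.g. `"TTN"`).
#' @param contig Contig identifier.
#' @param start,end Genomic span.
#' @param transcripts List of `transcript` objects.
#' @param description Free-text description.
#' @return An object of class `gene`.
#' @export
gene <- function(symbol, contig, start, end, transcripts,
                 description = "") {
  if (sum(vapply(transcripts, function(t) isTRUE(t$canonical), logical(1))) > 1L) {
    stop("gene '", symbol, "': more than one canonical transcript")
  }
  structure(
    list(symbol = as.character(symbol), contig = as.character(contig),
         start = as.integer(start), end = as.integer(end),
         transcripts = transcripts, description = as.character(description)),
    class = "gene")
}

#' @export
print.gene <- function(x, ...) {
  cat("<gene>", x$symbol, "on", x$contig, x$start, "-", x$end, "with",
      length(x$transcripts), "transcript(s)\n")
  invisible(x)
}

#' Gene panel
#'
#' A named set of gene symbols defining the panel filter (cardiomyopathy,
#' channelopathy, genetic aortic disease, or a custom set).
#'
#' @param name Panel name.
#' @param gene_symbols Character vector of gene symbols.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(name, gene_symbols) {
  gene_symbols <- unique(as.character(gene_symbols))
  if (length(gene_symbols) == 0L) stop("panel '", name, "' is empty")
  structure(list(name = as.character(name), gene_symbols = gene_symbols),
            class = "gene_panel")
}

#' Load a gene panel from JSON or BED
#'
#' JSON panels look like `{"name": ..., "genes": [...]}`; BED panels are
#' 4-column with the gene symbol in column 4.
#'
#' @param path File path.
#' @return A `gene_panel`.
#' @export
load_panel <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(bed) < 4L) stop("BED panel '", path, "' needs >= 4 columns")
    gene_panel(tools::file_path_sans_ext(basename(path)), bed[[4]])
  } else {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    gene_panel(j$name, j$genes)
  }
}

#' Load one of the packaged disorder-group panels
#'
#' @param name One of `"cardiomyopathy"`, `"channelopathy"`, `"aortic"`.
#' @return A `gene_panel`.
#' @export
packaged_panel <- function(name = c("cardiomyopathy", "channelopathy", "aortic")) {
  name <- match.arg(name)
  load_panel(system.file("extdata", paste0("panel_", name, ".json"),
                         package = "cardiorelevance", mustWork = TRUE))
}

# ---- loading -----------------------------------------------------------

#' Load gene models from GFF3 or the packaged JSON dialect
#'
#' GFF3 files must use the gene/mRNA/exon/CDS feature hierarchy with
#' ID/Parent attributes. The JSON dialect is documented by the schema file
#' shipped at `inst/extdata/gene_models.schema.json`.
#'
#' @param path File path.
#' @param format `"gff3"` or `"json"` (guessed from the extension by default).
#' @return List of `gene` objects.
#' @export
load_gene_models <- function(path, format = c("auto", "gff3", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE))
      "gff3" else "json"
  }
  if (!file.exists(path)) stop("gene model file not found: ", path)
  switch(format,
         gff3 = load_gene_models_gff3(path),
         json = load_gene_models_json(path))
}

load_gene_models_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   stop("failed to parse GFF3 '", path, "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), ]
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$ID
    gm <- mrnas[mrnas$Parent == gid, ]
    txs <- lapply(seq_len(nrow(gm)), function(j) {
      m <- gm[j, ]
      ex <- df[df$type == "exon" & df$Parent == m$ID,
               c("start", "end"), drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      cds <- df[df$type == "CDS" & df$Parent == m$ID, , drop = FALSE]
      if (nrow(cds) == 0L) {
        stop("transcript '", m$ID, "' in '", path, "' has no CDS features")
      }
      canon <- "canonical" %in% names(df) &&
        isTRUE(tolower(as.character(m$canonical)) == "true")
      transcript(id = m$ID, gene_id = gid, contig = as.character(m$seqnames),
                 strand = as.character(m$strand), exons = ex,
                 cds_start = min(cds$start), cds_end = max(cds$end),
                 canonical = canon)
    })
    sym <- if ("Name" %in% names(g) && !is.na(g$Name)) g$Name else gid
    out[[i]] <- gene(symbol = sym, contig = as.character(g$seqnames),
                     start = g$start, end = g$end, transcripts = txs,
                     description = if ("description" %in% names(g) &&
                                       !is.na(g$description))
                       g$description else "")
  }
  out
}

load_gene_models_json <- function(path) {
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) {
                  stop("failed to parse JSON gene models '", path, "': ",
                       conditionMessage(e), call. = FALSE)
                })
  lapply(j$genes, function(g) {
    txs <- lapply(g$transcripts, function(t) {
      ex <- do.call(rbind, lapply(t$exons, function(e)
        data.frame(start = e$start, end = e$end)))
      transcript(id = t$id, gene_id = g$symbol, contig = g$contig,
                 strand = t$strand, exons = ex, cds_start = t$cds_start,
                 cds_end = t$cds_end, canonical = isTRUE(t$canonical))
    })
    gene(symbol = g$symbol, contig = g$contig, start = g$start, end = g$end,
         transcripts = txs,
         description = if (is.null(g$description)) "" else g$description)
  })
}

#' Save gene models in the JSON dialect
#'
#' `load_gene_models(save_gene_models(x))` is the identity on all fields.
#'
#' @param genes List of `gene` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_gene_models <- function(genes, path) {
  payload <- list(genes = lapply(genes, function(g) {
    list(symbol = g$symbol, contig = g$contig, start = g$start, end = g$end,
         description = g$description,
         transcripts = lapply(g$transcripts, function(t) {
           list(id = t$id, strand = t$strand, canonical = t$canonical,
                cds_start = t$cds_start, cds_end = t$cds_end,
                exons = lapply(seq_len(nrow(t$exons)), function(i)
                  list(start = t$exons$start[i], end = t$exons$end[i])))
         }))
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# ---- canonical selection ----------------------------------------------

#' Select a gene's reporting transcript
#'
#' The explicitly flagged canonical transcript wins; failing that the
#' transcript with the longest CDS; ties broken by lexicographically
#' smallest transcript id.
#'
#' @param gene A `gene`.
#' @return A `transcript`.
#' @export
select_canonical <- function(gene) {
  txs <- gene$transcripts
  if (length(txs) == 0L) stop("gene '", gene$symbol, "' has no transcripts")
  flagged <- Filter(function(t) isTRUE(t$canonical), txs)
  if (length(flagged) == 1L) return(flagged[[1]])
  lens <- vapply(txs, function(t) length(cds_genomic_positions(t)), integer(1))
  ids <- vapply(txs, function(t) t$id, character(1))
  txs[[order(-lens, ids)[1]]]
}

# ---- coordinate machinery ----------------------------------------------

#' Genomic positions of the spliced CDS, in transcript orientation
#'
#' @param tx A `transcript`.
#' @return Integer vector: element i is the genomic position of CDS base i.
#' @export
cds_genomic_positions <- function(tx) {
  pos <- integer(0)
  for (i in seq_len(nrow(tx$exons))) {
    s <- max(tx$exons$start[i], tx$cds_start)
    e <- min(tx$exons$end[i], tx$cds_end)
    if (s <= e) pos <- c(pos, s:e)
  }
  if (tx$strand == "-") rev(pos) else pos
}

#' Extract the coding sequence of a transcript
#'
#' Exon segments intersected with the CDS span, concatenated 5'→3' in
#' transcript orientation (reverse-complemented on the minus strand).
#'
#' @param tx A `transcript`.
#' @param ref Matching `reference_sequence`.
#' @return Nucleotide string.
#' @export
cds_sequence <- function(tx, ref) {
  if (tx$contig != ref$contig) {
    stop("transcript '", tx$id, "' is on contig '", tx$contig,
         "', reference is '", ref$contig, "'")
  }
  pos <- cds_genomic_positions(tx)
  if (max(pos) > nchar(ref$sequence)) {
    stop("transcript '", tx$id, "' CDS extends beyond reference bounds")
  }
  bases <- strsplit(ref$sequence, "")[[1]][if (tx$strand == "-") rev(pos) else pos]
  s <- paste(bases, collapse = "")
  if (tx$strand == "-") reverse_complement(s) else s
}

#' Reverse complement of a nucleotide string
#' @param s Nucleotide string over {A,C,G,T,N}.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Project a genomic position onto the spliced CDS
#'
#' @param tx A `transcript`.
#' @param pos Genomic position.
#' @return 1-based CDS offset, or `NA_integer_` when `pos` is intronic,
#'   UTR, or outside the transcript.
#' @export
genomic_to_cds <- function(tx, pos) {
  cds <- cds_genomic_positions(tx)
  i <- match(as.integer(pos), cds)
  if (is.na(i)) NA_integer_ else i
}

# ---- translation -------------------------------------------------------

# Standard genetic code, keyed by codon. Codons containing N yield 'X'.
CODON_TABLE <- c(
  TTT="F", TTC="F", TTA="L", TTG="L", CTT="L", CTC="L", CTA="L", CTG="L",
  ATT="I", ATC="I", ATA="I", ATG="M", GTT="V", GTC="V", GTA="V", GTG="V",
  TCT="S", TCC="S", TCA="S", TCG="S", CCT="P", CCC="P", CCA="P", CCG="P",
  ACT="T", ACC="T", ACA="T", ACG="T", GCT="A", GCC="A", GCA="A", GCG="A",
  TAT="Y", TAC="Y", TAA="*", TAG="*", CAT="H", CAC="H", CAA="Q", CAG="Q",
  AAT="N", AAC="N", AAA="K", AAG="K", GAT="D", GAC="D", GAA="E", GAG="E",
  TGT="C", TGC="C", TGA="*", TGG="W", CGT="R", CGC="R", CGA="R", CGG="R",
  AGT="S", AGC="S", AGA="R", AGG="R", GGT="G", GGC="G", GGA="G", GGG="G")

#' Translate a coding sequence
#'
#' Standard genetic code; `*` marks stop codons; any codon containing `N`
#' translates to `X`. A trailing partial codon is dropped with a warning.
#'
#' @param cds Nucleotide string, length >= 3.
#' @return Peptide string (one letter per codon).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  if (grepl("[^ACGTN]", cds)) stop("CDS contains non-ACGTN characters")
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    warning("CDS length ", n, " is not a multiple of 3; trailing ",
            n %% 3L, " base(s) ignored")
    cds <- substr(cds, 1L, n - n %% 3L)
  }
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"   # codons containing N
  paste(aa, collapse = "")
}
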