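# Independent brute-force oracles used to cross-check the implementation.

# Translation via Biostrings' genetic-code machinery (independent of the
# package's codon table).
bio_translate <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3L
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(substr(cds, 1, n)),
                          no.init.codon = TRUE, if.fuzzy.codon = "X")))
}

# Exhaustive per-base enumeration of the genomic -> CDS projection.
brute_genomic_to_cds <- function(tx, pos) {
  walk <- integer(0)
  for (i in seq_len(nrow(tx$exons))) {
    for (p in tx$exons$start[i]:tx$exons$end[i]) {
      if (p >= tx$cds_start && p <= tx$cds_end) walk <- c(walk, p)
    }
  }
  if (tx$strand == "-") walk <- rev(walk)
  i <- which(walk == pos)
  if (length(i)) i else NA_integer_
}

# SNV consequence by whole-CDS string surgery + Biostrings translation
# (independent of both the codon-local annotator and the package's
# re-translation oracle).
brute_snv_consequence <- function(v, tx, ref,
                                  alt_starts = c("CTG", "GTG", "TTG")) {
  off <- brute_genomic_to_cds(tx, v$pos)
  if (is.na(off)) return(NA_character_)
  cds <- cds_sequence(tx, ref)
  alt_tx <- if (tx$strand == "-") chartr("ACGT", "TGCA", v$alt) else v$alt
  mut <- cds
  substr(mut, off, off) <- alt_tx
  pep_ref <- bio_translate(cds)
  pep_alt <- bio_translate(mut)
  idx <- (off - 1L) %/% 3L + 1L
  r <- substr(pep_ref, idx, idx); a <- substr(pep_alt, idx, idx)
  if (idx == 1L) {
    if (a == "M") return("synonymous_variant")
    return(if (substr(mut, 1, 3) %in% alt_starts)
      "initiator_codon_variant" else "start_lost")
  }
  if (r == "*") return(if (a == "*") "stop_retained_variant" else "stop_lost")
  if (a == "*") return("stop_gained")
  if (r == a) "synonymous_variant" else "missense_variant"
}

# ---- knowledge-graph path enumeration ----------------------------------

kg_edges_df <- function(graph) {
  do.call(rbind, lapply(graph$edges, function(e)
    data.frame(source = e$source, target = e$target, kind = e$kind,
               role = e$role, stringsAsFactors = FALSE)))
}

# All nodes reachable from `from` by an edge-kind sequence matching
# codes_for component_of* located_in part_of*, via exhaustive DFS.
brute_structural <- function(graph, gene_symbol) {
  ed <- kg_edges_df(graph)
  step <- function(ids, kind) {
    unique(ed$target[ed$kind == kind & ed$source %in% ids])
  }
  star <- function(ids, kind) {
    all <- ids
    repeat {
      nxt <- setdiff(step(all, kind), all)
      if (!length(nxt)) break
      all <- c(all, nxt)
    }
    all
  }
  gid <- kg_find_gene_id(graph, gene_symbol)
  proteins <- step(gid, "codes_for")
  entities <- star(proteins, "component_of")
  anchors <- step(entities, "located_in")
  sort(star(anchors, "part_of"))
}

brute_functional <- function(graph, gene_symbol) {
  ed <- kg_edges_df(graph)
  gid <- kg_find_gene_id(graph, gene_symbol)
  proteins <- unique(ed$target[ed$kind == "codes_for" & ed$source == gid])
  pa <- ed[ed$kind == "takes_part_in" & ed$source %in% proteins, ,
           drop = FALSE]
  up <- function(id) {
    anc <- character(0); frontier <- id
    repeat {
      parents <- unique(ed$source[ed$kind == "decomposes_into" &
                                  ed$target %in% frontier])
      parents <- setdiff(parents, anc)
      if (!length(parents)) break
      anc <- c(anc, parents); frontier <- parents
    }
    anc
  }
  rows <- list()
  for (i in seq_len(nrow(pa))) {
    anc <- up(pa$target[i])
    if (!length(anc)) anc <- NA_character_
    for (p in anc) {
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = p, process = pa$target[i], role = pa$role[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pathway = character(0), process = character(0),
                      role = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$pathway, out$process, out$role), , drop = FALSE]
}

kg_find_gene_id <- function(graph, gene_symbol) {
  for (n in graph$nodes) {
    if (n$kind != "GeneElement") next
    sym <- if (!is.null(n$attributes$symbol)) n$attributes$symbol else n$label
    if (identical(sym, gene_symbol) || identical(n$id, gene_symbol)) {
      return(n$id)
    }
  }
  stop("gene not in graph: ", gene_symbol)
}

all_fixture_genes <- function(graph) {
  unlist(lapply(graph$nodes, function(n)
    if (n$kind == "GeneElement") n$id else NULL), use.names = FALSE)
}
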