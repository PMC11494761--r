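# Built-in mini-annotator: consequence calling, impact classification,
# amino-acid change, LOF and NMD prediction for variant-transcript pairs,
# plus a parser for pre-computed SnpEff-style ANN INFO fields.

# Consequence inventory, ordered most-severe-first within each impact class.
SO_TERMS <- c(
  "stop_gained", "stop_lost", "start_lost", "frameshift_variant",
  "splice_acceptor_variant", "splice_donor_variant",
  "missense_variant", "inframe_insertion", "inframe_deletion",
  "disruptive_inframe_insertion", "disruptive_inframe_deletion",
  "initiator_codon_variant",
  "synonymous_variant", "splice_region_variant", "stop_retained_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant", "intron_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant")

IMPACT_TABLE <- c(
  stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  frameshift_variant = "HIGH", splice_acceptor_variant = "HIGH",
  splice_donor_variant = "HIGH",
  missense_variant = "MODERATE", inframe_insertion = "MODERATE",
  inframe_deletion = "MODERATE", disruptive_inframe_insertion = "MODERATE",
  disruptive_inframe_deletion = "MODERATE",
  initiator_codon_variant = "MODERATE",
  synonymous_variant = "LOW", splice_region_variant = "LOW",
  stop_retained_variant = "LOW",
  `5_prime_UTR_variant` = "MODIFIER", `3_prime_UTR_variant` = "MODIFIER",
  intron_variant = "MODIFIER", upstream_gene_variant = "MODIFIER",
  downstream_gene_variant = "MODIFIER", intergenic_variant = "MODIFIER")

IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Impact class of a consequence term
#'
#' SnpEff-style four-level severity summary.
#'
#' @param consequence A Sequence Ontology term from the supported inventory.
#' @return One of `"HIGH"`, `"MODERATE"`, `"LOW"`, `"MODIFIER"`.
#' @export
impact_of <- function(consequence) {
  if (length(consequence) != 1L || !consequence %in% names(IMPACT_TABLE)) {
    stop("unknown consequence term: '", consequence, "'")
  }
  unname(IMPACT_TABLE[consequence])
}

# Total severity rank: impact class first, then inventory position.
severity_rank <- function(consequence) {
  imp <- impact_of(consequence)
  match(imp, IMPACT_LEVELS) * 100L + match(consequence, SO_TERMS)
}

#' Annotation options
#'
#' Tunable constants of the annotator. Splice sites cover 2 intronic nt at
#' each intron end; the splice region covers 3 exonic / 3-8 intronic nt.
#' LOF uses the 95 percent truncation rule and NMD the 50-nt last-junction
#' rule; both thresholds are exposed here.
#'
#' @param splice_site_nt Intronic nt at each intron end called
#'   acceptor/donor.
#' @param splice_region_intronic Intronic distance range (nt) called
#'   splice_region.
#' @param splice_region_exonic Exonic distance (nt) from a junction called
#'   splice_region for non-CDS exonic bases.
#' @param upstream_window Window (nt) for upstream/downstream calls.
#' @param lof_fraction Truncations removing more than this fraction of the
#'   protein (PTC at residue <= lof_fraction * length) count as LOF.
#' @param nmd_distance Minimum distance (nt) of a PTC upstream of the last
#'   exon-exon junction for predicted NMD.
#' @param alt_start_codons Codons treated as alternative initiation codons:
#'   a start-codon SNV producing one of these is called
#'   initiator_codon_variant rather than start_lost.
#' @return List of class `ann_options`.
#' @export
ann_options <- function(splice_site_nt = 2L,
                        splice_region_intronic = c(3L, 8L),
                        splice_region_exonic = 3L,
                        upstream_window = 5000L,
                        lof_fraction = 0.95,
                        nmd_distance = 50L,
                        alt_start_codons = c("CTG", "GTG", "TTG")) {
  stopifnot(lof_fraction > 0, nmd_distance > 0)
  structure(list(splice_site_nt = splice_site_nt,
                 splice_region_intronic = splice_region_intronic,
                 splice_region_exonic = splice_region_exonic,
                 upstream_window = upstream_window,
                 lof_fraction = lof_fraction,
                 nmd_distance = nmd_distance,
                 alt_start_codons = alt_start_codons),
            class = "ann_options")
}

# ---- variants ----------------------------------------------------------

#' Construct a variant
#'
#' One record per alternate allele; `ref`/`alt` follow VCF conventions
#' (non-empty, anchored for indels).
#'
#' @param contig Contig identifier.
#' @param pos 1-based position.
#' @param ref,alt Allele strings over {A,C,G,T,N}.
#' @param qual Phred quality or `NA`.
#' @param filter FILTER string.
#' @param info Named list of INFO keys.
#' @param samples Optional named list of per-sample genotype strings.
#' @return Object of class `variant`.
#' @export
variant <- function(contig, pos, ref, alt, qual = NA_real_, filter = ".",
                    info = list(), samples = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt)) stop("ref and alt must be non-empty")
  if (grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt)) {
    stop("alleles must be over {A,C,G,T,N}: ", ref, ">", alt)
  }
  if (ref == alt) stop("ref and alt are identical at ", contig, ":", pos)
  structure(list(contig = as.character(contig), pos = as.integer(pos),
                 ref = ref, alt = alt, qual = as.numeric(qual),
                 filter = as.character(filter), info = info,
                 samples = samples),
            class = "variant")
}

#' @export
print.variant <- function(x, ...) {
  cat("<variant>", paste0(x$contig, ":", x$pos), x$ref, ">", x$alt, "\n")
  invisible(x)
}

variant_key <- function(v) paste(v$contig, v$pos, v$ref, v$alt, sep = ":")

#' Normalize a variant
#'
#' Trims the shared suffix then the shared prefix of ref/alt (keeping one
#' anchor base for indels, VCF style) and left-aligns pure indels against
#' the reference.
#'
#' @param v A `variant`.
#' @param ref Optional `reference_sequence` enabling left-alignment.
#' @return Normalized `variant`.
#' @export
normalize_variant <- function(v, ref = NULL) {
  r <- v$ref; a <- v$alt; pos <- v$pos
  # trim shared suffix
  while (nchar(r) > 1L && nchar(a) > 1L &&
         substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
    r <- substr(r, 1L, nchar(r) - 1L)
    a <- substr(a, 1L, nchar(a) - 1L)
  }
  # trim shared prefix, keeping an anchor base for indels
  while (nchar(r) > 1L && nchar(a) > 1L &&
         substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
    r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
    pos <- pos + 1L
  }
  # left-align pure indels when the reference is available
  if (!is.null(ref) && nchar(r) != nchar(a) &&
      substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
    longer <- if (nchar(r) > nchar(a)) r else a
    repeat {
      last <- substr(longer, nchar(longer), nchar(longer))
      if (pos <= 1L) break
      prev <- ref_slice(ref, pos - 1L, pos - 1L)
      if (prev != last) break
      pos <- pos - 1L
      longer <- paste0(prev, substr(longer, 1L, nchar(longer) - 1L))
      shorter <- substr(longer, 1L, nchar(if (nchar(r) > nchar(a)) a else r))
      if (nchar(r) > nchar(a)) { r <- longer; a <- shorter }
      else { a <- longer; r <- shorter }
    }
  }
  variant(v$contig, pos, r, a, v$qual, v$filter, v$info, v$samples)
}

# Minimal changed-allele representation: drops the shared anchor base so
# SNV / pure insertion / pure deletion cases are explicit.
changed_alleles <- function(v) {
  r <- v$ref; a <- v$alt; pos <- v$pos
  if (nchar(r) > 0L && nchar(a) > 0L && substr(r, 1, 1) == substr(a, 1, 1) &&
      nchar(r) != nchar(a)) {
    r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
    pos <- pos + 1L
  }
  list(pos = pos, ref = r, alt = a)
}

# ---- consequence calling ----------------------------------------------

# Intron table in transcript orientation: for each intron, the genomic
# positions flanking it and which side is donor (5') vs acceptor (3').
intron_table <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L) return(NULL)
  tab <- data.frame(left_exon_end = ex$end[-n], right_exon_start = ex$start[-1])
  tab$donor_side <- if (tx$strand == "+") "left" else "right"
  tab
}

#' Consequence of a variant on a transcript
#'
#' Calls a single Sequence Ontology term from the supported inventory by
#' locating the changed bases relative to the transcript's exon/CDS
#' structure and, for coding positions, comparing the affected codons.
#'
#' @param v A `variant` (same contig as the transcript).
#' @param tx A `transcript`.
#' @param ref A `reference_sequence`.
#' @param opts `ann_options`.
#' @return A consequence term (character scalar).
#' @export
consequence <- function(v, tx, ref, opts = ann_options()) {
  if (v$contig != tx$contig) {
    stop("variant on contig '", v$contig, "' vs transcript on '",
         tx$contig, "'")
  }
  v <- normalize_variant(v, ref)
  ch <- changed_alleles(v)
  span_start <- min(tx$exons$start)
  span_end <- max(tx$exons$end)
  ch_start <- ch$pos
  ch_end <- ch$pos + max(nchar(ch$ref) - 1L, 0L)
  if (nchar(ch$ref) == 0L) ch_end <- ch_start  # insertion point

  # outside transcript span: upstream / downstream / intergenic
  if (ch_end < span_start || ch_start > span_end) {
    d <- if (ch_end < span_start) span_start - ch_end else ch_start - span_end
    if (d > opts$upstream_window) return("intergenic_variant")
    before <- ch_end < span_start
    upstream <- (before && tx$strand == "+") || (!before && tx$strand == "-")
    return(if (upstream) "upstream_gene_variant" else "downstream_gene_variant")
  }

  # coding if any changed base (or the insertion point interior) is in CDS
  cds_pos <- cds_genomic_positions(tx)
  if (nchar(ch$ref) > 0L) {
    hit_cds <- any(ch_start:ch_end %in% cds_pos)
  } else {
    # insertion counts as coding when it lands between two CDS bases
    hit_cds <- (ch$pos %in% cds_pos) && ((ch$pos - 1L) %in% cds_pos)
  }
  if (hit_cds) return(coding_consequence(v, ch, tx, ref, opts))

  # intronic positions: splice site / region / intron
  exonic <- function(p) any(p >= tx$exons$start & p <= tx$exons$end)
  positions <- ch_start:ch_end
  intronic <- positions[!vapply(positions, exonic, logical(1))]
  if (length(intronic)) {
    it <- intron_table(tx)
    best <- "intron_variant"; best_rank <- severity_rank(best)
    for (p in intronic) {
      row <- it[p > it$left_exon_end & p < it$right_exon_start, ]
      if (nrow(row) != 1L) next
      d_left <- p - row$left_exon_end
      d_right <- row$right_exon_start - p
      d <- min(d_left, d_right)
      side <- if (d_left <= d_right) "left" else "right"
      term <- if (d <= opts$splice_site_nt) {
        if (side == row$donor_side) "splice_donor_variant"
        else "splice_acceptor_variant"
      } else if (d >= opts$splice_region_intronic[1] &&
                 d <= opts$splice_region_intronic[2]) {
        "splice_region_variant"
      } else "intron_variant"
      if (severity_rank(term) < best_rank) {
        best <- term; best_rank <- severity_rank(term)
      }
    }
    return(best)
  }

  # exonic non-CDS: UTR, possibly splice_region near a junction
  p <- ch_start
  ex <- tx$exons
  near_junction <- any(
    (abs(p - ex$end) < opts$splice_region_exonic & ex$end != span_end) |
    (abs(p - ex$start) < opts$splice_region_exonic & ex$start != span_start))
  if (near_junction) return("splice_region_variant")
  five_prime <- if (tx$strand == "+") p < tx$cds_start else p > tx$cds_end
  if (five_prime) "5_prime_UTR_variant" else "3_prime_UTR_variant"
}

# Coding consequence via local codon comparison (indels by length rule).
coding_consequence <- function(v, ch, tx, ref, opts) {
  len_r <- nchar(ch$ref); len_a <- nchar(ch$alt)
  if (len_r == len_a && len_r == 1L) {
    return(snv_consequence(ch, tx, ref, opts))
  }
  if (len_r == len_a) {
    # multi-nucleotide substitution: classify by re-coding the codons touched
    return(mnv_consequence(ch, tx, ref))
  }
  delta <- len_a - len_r
  if (delta %% 3L != 0L) return("frameshift_variant")
  if (len_r == 0L) {  # insertion between ch$pos - 1 and ch$pos
    c_after <- genomic_to_cds(tx, if (tx$strand == "+") ch$pos else ch$pos - 1L)
    aligned <- !is.na(c_after) && (c_after - 1L) %% 3L == 0L
    return(if (aligned) "inframe_insertion" else "disruptive_inframe_insertion")
  }
  # deletion of whole codons <=> CDS offsets of the deleted span tile codons
  offs <- vapply(ch$pos:(ch$pos + len_r - 1L),
                 function(p) genomic_to_cds(tx, p), integer(1))
  offs <- sort(offs[!is.na(offs)])
  aligned <- length(offs) %% 3L == 0L && length(offs) > 0L &&
    (offs[1] - 1L) %% 3L == 0L && all(diff(offs) == 1L)
  if (aligned) "inframe_deletion" else "disruptive_inframe_deletion"
}

snv_consequence <- function(ch, tx, ref, opts) {
  cds <- cds_sequence(tx, ref)
  off <- genomic_to_cds(tx, ch$pos)
  codon_idx <- (off - 1L) %/% 3L + 1L
  within <- (off - 1L) %% 3L + 1L
  codon_ref <- substr(cds, 3L * codon_idx - 2L, 3L * codon_idx)
  alt_tx <- if (tx$strand == "-") chartr("ACGTN", "TGCAN", ch$alt) else ch$alt
  codon_alt <- codon_ref
  substr(codon_alt, within, within) <- alt_tx
  aa_ref <- unname(CODON_TABLE[codon_ref]); if (is.na(aa_ref)) aa_ref <- "X"
  aa_alt <- unname(CODON_TABLE[codon_alt]); if (is.na(aa_alt)) aa_alt <- "X"
  if (codon_idx == 1L) {
    if (aa_alt == "M") return("synonymous_variant")
    return(if (codon_alt %in% opts$alt_start_codons)
      "initiator_codon_variant" else "start_lost")
  }
  if (aa_ref == "*") {
    return(if (aa_alt == "*") "stop_retained_variant" else "stop_lost")
  }
  if (aa_alt == "*") return("stop_gained")
  if (aa_ref == aa_alt) return("synonymous_variant")
  "missense_variant"
}

mnv_consequence <- function(ch, tx, ref) {
  cds <- cds_sequence(tx, ref)
  offs <- vapply(ch$pos:(ch$pos + nchar(ch$ref) - 1L),
                 function(p) genomic_to_cds(tx, p), integer(1))
  keep <- !is.na(offs)
  offs <- offs[keep]
  alt_bases <- strsplit(ch$alt, "")[[1]][keep]
  if (tx$strand == "-") alt_bases <- chartr("ACGTN", "TGCAN", alt_bases)
  mutated <- strsplit(cds, "")[[1]]
  mutated[offs] <- alt_bases
  pep_ref <- translate_cds(cds)
  pep_alt <- translate_cds(paste(mutated, collapse = ""))
  first_codon <- (min(offs) - 1L) %/% 3L + 1L
  r <- substr(pep_ref, first_codon, first_codon)
  a <- substr(pep_alt, first_codon, first_codon)
  if (first_codon == 1L && a != "M") return("start_lost")
  if (grepl("\\*", substr(pep_alt, 1, nchar(pep_ref) - 1L)) &&
      !grepl("\\*", substr(pep_ref, 1, nchar(pep_ref) - 1L))) {
    return("stop_gained")
  }
  if (r == a) "synonymous_variant" else "missense_variant"
}

#' Amino-acid change of a coding variant
#'
#' @param v A `variant`.
#' @param tx A `transcript`.
#' @param ref A `reference_sequence`.
#' @param opts `ann_options`.
#' @return List with `aa_ref`, `aa_alt`, `aa_pos` (residue index,
#'   `ceil(cds_offset / 3)`), or `NULL` for non-coding consequences.
#' @export
amino_acid_change <- function(v, tx, ref, opts = ann_options()) {
  cons <- consequence(v, tx, ref, opts)
  coding <- c("synonymous_variant", "missense_variant", "stop_gained",
              "stop_lost", "start_lost", "stop_retained_variant",
              "initiator_codon_variant", "frameshift_variant",
              "inframe_insertion", "inframe_deletion",
              "disruptive_inframe_insertion", "disruptive_inframe_deletion")
  if (!cons %in% coding) return(NULL)
  vn <- normalize_variant(v, ref)
  ch <- changed_alleles(vn)
  cds <- cds_sequence(tx, ref)
  positions <- if (nchar(ch$ref) > 0L) ch$pos:(ch$pos + nchar(ch$ref) - 1L)
    else c(ch$pos - 1L, ch$pos)
  offs <- vapply(positions, function(p) genomic_to_cds(tx, p), integer(1))
  offs <- offs[!is.na(offs)]
  if (!length(offs)) return(NULL)
  off <- min(offs)
  aa_pos <- (off - 1L) %/% 3L + 1L
  pep_ref <- translate_cds(cds)
  aa_ref <- substr(pep_ref, aa_pos, aa_pos)
  if (nchar(ch$ref) == 1L && nchar(ch$alt) == 1L) {
    codon_idx <- aa_pos
    within <- (off - 1L) %% 3L + 1L
    codon <- substr(cds, 3L * codon_idx - 2L, 3L * codon_idx)
    alt_tx <- if (tx$strand == "-") chartr("ACGTN", "TGCAN", ch$alt) else ch$alt
    substr(codon, within, within) <- alt_tx
    aa_alt <- unname(CODON_TABLE[codon]); if (is.na(aa_alt)) aa_alt <- "X"
  } else {
    aa_alt <- "-"
  }
  list(aa_ref = aa_ref, aa_alt = aa_alt, aa_pos = aa_pos)
}

# ---- LOF / NMD ---------------------------------------------------------

LOF_ALWAYS <- c("splice_acceptor_variant", "splice_donor_variant", "start_lost")
PTC_TERMS <- c("stop_gained", "frameshift_variant")

#' Loss-of-function prediction
#'
#' Splice-site and start-loss variants are always LOF; truncating variants
#' (stop gained, frameshift) are LOF when the new termination falls within
#' the first `lof_fraction` of the protein.
#'
#' @param consequence Consequence term.
#' @param aa_pos Residue index of the change (`NA` allowed for
#'   splice/start terms).
#' @param protein_length Reference protein length in residues.
#' @param lof_fraction Truncation-position threshold (default 0.95).
#' @return Logical.
#' @export
predict_lof <- function(consequence, aa_pos = NA_integer_,
                        protein_length = NA_integer_, lof_fraction = 0.95) {
  if (consequence %in% LOF_ALWAYS) return(TRUE)
  if (consequence %in% PTC_TERMS) {
    if (is.na(aa_pos) || is.na(protein_length)) return(FALSE)
    stopifnot(protein_length >= 1L)
    return(aa_pos <= lof_fraction * protein_length)
  }
  FALSE
}

#' Nonsense-mediated decay prediction (50-nt rule)
#'
#' A premature termination codon triggers predicted NMD when the transcript
#' has at least two exons and the PTC lies at least `nmd_distance`
#' nucleotides upstream of the last exon-exon junction in spliced
#' coordinates.
#'
#' @param consequence Consequence term (only PTC-introducing terms can be
#'   NMD-positive).
#' @param ptc_cds_offset 1-based CDS nucleotide offset of the PTC.
#' @param tx A `transcript`.
#' @param nmd_distance Threshold in nt (default 50).
#' @return Logical.
#' @export
predict_nmd <- function(consequence, ptc_cds_offset, tx, nmd_distance = 50L) {
  if (!consequence %in% PTC_TERMS) return(FALSE)
  if (nrow(tx$exons) < 2L) return(FALSE)
  if (is.na(ptc_cds_offset)) return(FALSE)
  # spliced (mRNA) coordinates in transcript orientation
  exon_lengths <- tx$exons$end - tx$exons$start + 1L
  if (tx$strand == "-") exon_lengths <- rev(exon_lengths)
  last_junction <- sum(exon_lengths) - exon_lengths[length(exon_lengths)]
  ptc_genomic <- cds_genomic_positions(tx)[ptc_cds_offset]
  ptc_spliced <- spliced_offset(tx, ptc_genomic)
  !is.na(ptc_spliced) && (last_junction - ptc_spliced >= nmd_distance)
}

# 1-based offset of a genomic position in the spliced transcript.
spliced_offset <- function(tx, pos) {
  ex <- tx$exons
  segs <- lapply(seq_len(nrow(ex)), function(i) ex$start[i]:ex$end[i])
  walk <- unlist(segs)
  if (tx$strand == "-") walk <- rev(walk)
  i <- match(as.integer(pos), walk)
  if (is.na(i)) NA_integer_ else i
}

# ---- full annotation of one variant ------------------------------------

#' Construct a gene-level annotation
#'
#' @param gene_symbol,transcript_id Identifiers (`NA` for intergenic).
#' @param consequence Consequence term; the impact class is derived.
#' @return Named list (gene annotation).
#' @export
gene_annotation <- function(gene_symbol, transcript_id, consequence) {
  list(gene_symbol = gene_symbol, transcript_id = transcript_id,
       consequence = consequence, impact = impact_of(consequence))
}

#' Construct a protein-level annotation
#'
#' @param aa_ref,aa_alt One-letter residues or `"-"`.
#' @param aa_pos Residue index or `NA`.
#' @param hgvs_p HGVS.p string or `NA`.
#' @param lof,nmd Predicted loss-of-function / nonsense-mediated decay
#'   flags (`nmd` requires `lof`).
#' @return Named list (protein annotation).
#' @export
protein_annotation <- function(aa_ref = "-", aa_alt = "-",
                               aa_pos = NA_integer_, hgvs_p = NA_character_,
                               lof = FALSE, nmd = FALSE) {
  if (nmd && !lof) stop("nmd = TRUE requires lof = TRUE")
  list(aa_ref = aa_ref, aa_alt = aa_alt, aa_pos = aa_pos, hgvs_p = hgvs_p,
       lof = lof, nmd = nmd)
}

#' Annotate a variant against a set of gene models
#'
#' Computes, for each transcript within the upstream/downstream window, the
#' consequence, impact, amino-acid change, LOF and NMD flags, and selects a
#' representative annotation (canonical transcript preferred, then most
#' severe, then smallest transcript id).
#'
#' @param v A `variant`.
#' @param genes List of `gene` objects.
#' @param ref A `reference_sequence`.
#' @param opts `ann_options`.
#' @param canonical_only Restrict to each gene's canonical transcript.
#' @return Object of class `annotated_variant`: the variant, its annotation
#'   pairs, and the representative index.
#' @export
annotate_variant <- function(v, genes, ref, opts = ann_options(),
                             canonical_only = FALSE) {
  # the original (un-normalized) variant is kept for reporting and keying;
  # consequence/amino_acid_change normalize internally
  anns <- list()
  canonical_ids <- character(0)
  for (g in genes) {
    if (g$contig != v$contig) next
    txs <- if (canonical_only) list(select_canonical(g)) else g$transcripts
    canonical_ids <- c(canonical_ids, select_canonical(g)$id)
    for (tx in txs) {
      cons <- consequence(v, tx, ref, opts)
      if (cons == "intergenic_variant") next
      aac <- amino_acid_change(v, tx, ref, opts)
      cds <- cds_sequence(tx, ref)
      prot_len <- nchar(translate_cds(cds))
      if (is.null(aac)) {
        lof <- predict_lof(cons, NA_integer_, prot_len, opts$lof_fraction)
        pa <- protein_annotation(lof = lof, nmd = FALSE)
      } else {
        lof <- predict_lof(cons, aac$aa_pos, prot_len, opts$lof_fraction)
        ptc_off <- (aac$aa_pos - 1L) * 3L + 1L
        nmd <- lof && predict_nmd(cons, ptc_off, tx, opts$nmd_distance)
        pa <- protein_annotation(aa_ref = aac$aa_ref, aa_alt = aac$aa_alt,
                                 aa_pos = aac$aa_pos,
                                 hgvs_p = hgvs_p_of(aac), lof = lof, nmd = nmd)
      }
      anns <- c(anns, list(list(gene = gene_annotation(g$symbol, tx$id, cons),
                                protein = pa)))
    }
  }
  if (length(anns) == 0L) {
    anns <- list(list(gene = gene_annotation(NA_character_, NA_character_,
                                             "intergenic_variant"),
                      protein = protein_annotation()))
  }
  annotated_variant(v, anns, canonical_ids)
}

#' Assemble an annotated variant
#'
#' @param v A `variant`.
#' @param annotations List of `list(gene=, protein=)` pairs.
#' @param canonical_ids Transcript ids flagged canonical (used for
#'   representative selection).
#' @return Object of class `annotated_variant`.
#' @export
annotated_variant <- function(v, annotations, canonical_ids = character(0)) {
  structure(list(variant = v, annotations = annotations,
                 representative = representative_annotation(annotations,
                                                            canonical_ids)),
            class = "annotated_variant")
}

#' @export
print.annotated_variant <- function(x, ...) {
  rep <- x$annotations[[x$representative]]
  cat("<annotated_variant>", variant_key(x$variant), "->",
      rep$gene$consequence,
      if (!is.na(rep$gene$gene_symbol)) paste0("(", rep$gene$gene_symbol, ")")
      else "", "\n")
  invisible(x)
}

#' Pick the reporting annotation
#'
#' Canonical-transcript annotations are preferred; otherwise the most
#' severe (impact class, then inventory order); ties broken by smallest
#' transcript id.
#'
#' @param annotations List of annotation pairs.
#' @param canonical_ids Character vector of canonical transcript ids.
#' @return Index into `annotations`.
#' @export
representative_annotation <- function(annotations,
                                      canonical_ids = character(0)) {
  if (length(annotations) == 0L) stop("no annotations to choose from")
  is_canon <- vapply(annotations, function(a)
    !is.na(a$gene$transcript_id) && a$gene$transcript_id %in% canonical_ids,
    logical(1))
  ranks <- vapply(annotations, function(a)
    severity_rank(a$gene$consequence), integer(1))
  ids <- vapply(annotations, function(a) {
    id <- a$gene$transcript_id
    if (is.na(id)) "~" else id
  }, character(1))
  order(!is_canon, ranks, ids)[1]
}

# ---- ANN field adapter -------------------------------------------------

AA3TO1 <- c(Ala="A", Arg="R", Asn="N", Asp="D", Cys="C", Gln="Q", Glu="E",
            Gly="G", His="H", Ile="I", Leu="L", Lys="K", Met="M", Phe="F",
            Pro="P", Ser="S", Thr="T", Trp="W", Tyr="Y", Val="V", Ter="*")
AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

hgvs_p_of <- function(aac) {
  if (is.na(aac$aa_pos) || !aac$aa_ref %in% names(AA1TO3)) return(NA_character_)
  alt3 <- if (aac$aa_alt %in% names(AA1TO3)) AA1TO3[[aac$aa_alt]] else "?"
  paste0("p.", AA1TO3[[aac$aa_ref]], aac$aa_pos, alt3)
}

parse_hgvs_p <- function(s) {
  m <- regmatches(s, regexec("^p\\.([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2}|\\*)", s))[[1]]
  if (length(m) != 4L) return(NULL)
  r <- AA3TO1[m[2]]; a <- if (m[4] == "*") "*" else AA3TO1[m[4]]
  if (is.na(r) || is.na(a)) return(NULL)
  list(aa_ref = unname(r), aa_alt = unname(a), aa_pos = as.integer(m[3]))
}

#' Parse a SnpEff-style ANN INFO value
#'
#' Entries are comma-separated; sub-fields pipe-separated
#' (`allele|annotation|impact|gene|gene_id|feature_type|feature_id|biotype|
#' rank|HGVS.c|HGVS.p|...`). Ampersand-joined consequence terms are split
#' and the most severe kept. LOF/NMD flags are read from companion
#' `LOF=`/`NMD=` INFO keys (SnpEff's parenthesized gene lists) when given.
#'
#' @param info_value The ANN value string.
#' @param lof_info,nmd_info Optional companion LOF/NMD INFO values.
#' @return List with `annotations` (list of annotation pairs) and
#'   `skipped` (count of malformed entries).
#' @export
parse_ann_field <- function(info_value, lof_info = NULL, nmd_info = NULL) {
  entries <- strsplit(info_value, ",", fixed = TRUE)[[1]]
  lof_genes <- parse_lof_genes(lof_info)
  nmd_genes <- parse_lof_genes(nmd_info)
  out <- list(); skipped <- 0L
  for (e in entries) {
    f <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(f) < 10L) {
      warning("ANN entry with fewer than 10 sub-fields skipped: ", e)
      skipped <- skipped + 1L
      next
    }
    terms <- strsplit(f[2], "&", fixed = TRUE)[[1]]
    terms <- terms[terms %in% SO_TERMS]
    if (!length(terms)) {
      warning("ANN entry with no recognized consequence skipped: ", e)
      skipped <- skipped + 1L
      next
    }
    cons <- terms[which.min(vapply(terms, severity_rank, integer(1)))]
    gene_sym <- f[4]
    tx_id <- f[7]
    hp <- if (length(f) >= 11L && nzchar(f[11])) f[11] else NA_character_
    aac <- if (!is.na(hp)) parse_hgvs_p(hp) else NULL
    lof <- gene_sym %in% lof_genes
    nmd <- lof && gene_sym %in% nmd_genes
    pa <- if (!is.null(aac)) {
      protein_annotation(aac$aa_ref, aac$aa_alt, aac$aa_pos, hp, lof, nmd)
    } else {
      protein_annotation(hgvs_p = hp, lof = lof, nmd = nmd)
    }
    out <- c(out, list(list(gene = gene_annotation(gene_sym, tx_id, cons),
                            protein = pa)))
  }
  list(annotations = out, skipped = skipped)
}

# SnpEff LOF/NMD INFO format: (GENE|GENE_ID|N_tx|fraction),(...)
parse_lof_genes <- function(value) {
  if (is.null(value) || !length(value) || is.na(value)) return(character(0))
  entries <- strsplit(gsub("[()]", "", value), ",", fixed = TRUE)[[1]]
  vapply(strsplit(entries, "|", fixed = TRUE),
         function(f) f[1], character(1))
}

#' Format annotation pairs as a SnpEff-style ANN value
#'
#' Writer used by the fixture generator; `parse_ann_field()` inverts it on
#' the retained fields.
#'
#' @param v The `variant` (for the allele sub-field).
#' @param annotations List of annotation pairs.
#' @return ANN value string.
#' @export
format_ann_field <- function(v, annotations) {
  paste(vapply(annotations, function(a) {
    hp <- a$protein$hgvs_p
    paste(v$alt, a$gene$consequence, a$gene$impact, a$gene$gene_symbol,
          a$gene$gene_symbol, "transcript", a$gene$transcript_id,
          "protein_coding", "1/1", "",
          if (is.na(hp)) "" else hp,
          sep = "|")
  }, character(1)), collapse = ",")
}
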