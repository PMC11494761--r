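# Seeded synthetic-data generators: reference sequences, multi-exon gene
# models, VCFs with a controlled consequence spectrum, and labeled cohorts
# for the concordance harness. Everything is bit-reproducible for a fixed
# seed, so the whole package tests without downloads.

#' Synthetic-data specification
#'
#' @param seed Integer seed (one RNG stream per generator call).
#' @param n_genes Number of genes on the contig.
#' @param exons_per_gene Integer range `c(min, max)`.
#' @param cds_length Range `c(min, max)` in nt; values are rounded to
#'   multiples of 3.
#' @param variant_mix Named integer vector, consequence term -> count.
#' @param pathogenic_enrichment Probability that a pathogenic-labeled
#'   cohort variant is drawn from the HIGH/LOF consequence pool.
#' @param n_cohort Cohort size for [generate_labeled_cohort()].
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, n_genes = 2L, exons_per_gene = c(2L, 4L),
                       cds_length = c(150L, 300L),
                       variant_mix = c(missense_variant = 5L,
                                       stop_gained = 2L,
                                       intron_variant = 3L),
                       pathogenic_enrichment = 0.8,
                       n_cohort = 500L) {
  stopifnot(all(variant_mix >= 0),
            pathogenic_enrichment >= 0, pathogenic_enrichment <= 1,
            n_genes >= 1)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 cds_length = as.integer(cds_length),
                 variant_mix = variant_mix,
                 pathogenic_enrichment = pathogenic_enrichment,
                 n_cohort = as.integer(n_cohort)),
            class = "synth_spec")
}

# Run expr under a private Mersenne-Twister stream, restoring global state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
NONSTOP_CODONS <- setdiff(names(CODON_TABLE), STOP_CODONS)

#' Generate a synthetic locus
#'
#' Places `n_genes` non-overlapping multi-exon genes (alternating strand)
#' on one contig, each with a single canonical transcript whose CDS starts
#' ATG, ends with a stop, and is a multiple of 3. Deterministic for a
#' fixed seed.
#'
#' @param spec A `synth_spec`.
#' @param gene_symbols Optional gene symbols (recycled from `GENE1`, ...).
#' @param intergenic_gap Gap between genes in nt (also flanks the contig).
#' @return List with `ref` (a `reference_sequence`) and `genes` (list of
#'   `gene`).
#' @export
generate_locus <- function(spec, gene_symbols = NULL,
                           intergenic_gap = 12000L) {
  if (is.null(gene_symbols)) {
    gene_symbols <- paste0("GENE", seq_len(spec$n_genes))
  }
  stopifnot(length(gene_symbols) == spec$n_genes)
  with_local_seed(spec$seed, {
    utr_len <- 12L
    blocks <- list()
    for (i in seq_len(spec$n_genes)) {
      n_ex <- sample(spec$exons_per_gene[1]:spec$exons_per_gene[2], 1L)
      n_codons <- sample(spec$cds_length[1]:spec$cds_length[2], 1L) %/% 3L
      if (n_codons < 4L) n_codons <- 4L
      cds <- paste0("ATG",
                    paste(sample(NONSTOP_CODONS, n_codons - 2L,
                                 replace = TRUE), collapse = ""),
                    sample(STOP_CODONS, 1L))
      spliced <- paste0(rand_bases(utr_len), cds, rand_bases(utr_len))
      sp_len <- nchar(spliced)
      # partition the spliced sequence into n_ex exon chunks (each >= 20 nt
      # where possible, so splice-region tests have room)
      if (n_ex > 1L) {
        cuts <- sort(sample(seq(20L, sp_len - 20L), n_ex - 1L))
        while (any(diff(c(0L, cuts, sp_len)) < 15L)) {
          cuts <- sort(sample(seq(20L, sp_len - 20L), n_ex - 1L))
        }
      } else cuts <- integer(0)
      bounds <- c(0L, cuts, sp_len)
      exon_lens <- diff(bounds)
      intron_lens <- if (n_ex > 1L) sample(60:120, n_ex - 1L, replace = TRUE)
        else integer(0)
      # + strand layout within the block
      block_seq <- ""
      exon_start <- integer(n_ex); exon_end <- integer(n_ex)
      cursor <- 1L
      for (k in seq_len(n_ex)) {
        exon_start[k] <- cursor
        exon_end[k] <- cursor + exon_lens[k] - 1L
        block_seq <- paste0(block_seq,
                            substr(spliced, bounds[k] + 1L, bounds[k + 1L]))
        cursor <- exon_end[k] + 1L
        if (k < n_ex) {
          block_seq <- paste0(block_seq, rand_bases(intron_lens[k]))
          cursor <- cursor + intron_lens[k]
        }
      }
      block_len <- nchar(block_seq)
      # spliced coordinates of the CDS within the block (+ orientation)
      cds_sp <- c(utr_len + 1L, utr_len + nchar(cds))
      sp_to_genomic <- integer(sp_len)
      for (k in seq_len(n_ex)) {
        sp_to_genomic[(bounds[k] + 1L):bounds[k + 1L]] <-
          exon_start[k]:exon_end[k]
      }
      strand <- if (i %% 2L == 1L) "+" else "-"
      if (strand == "-") {
        block_seq <- reverse_complement(block_seq)
        mirror <- function(p) block_len - p + 1L
        new_start <- mirror(exon_end); new_end <- mirror(exon_start)
        o <- order(new_start)
        exon_start <- new_start[o]; exon_end <- new_end[o]
        g1 <- mirror(sp_to_genomic[cds_sp[1]])
        g2 <- mirror(sp_to_genomic[cds_sp[2]])
        cds_g <- sort(c(g1, g2))
      } else {
        cds_g <- c(sp_to_genomic[cds_sp[1]], sp_to_genomic[cds_sp[2]])
      }
      blocks[[i]] <- list(seq = block_seq, exon_start = exon_start,
                          exon_end = exon_end, cds_g = cds_g,
                          strand = strand, symbol = gene_symbols[i])
    }
    # lay blocks along the contig separated by intergenic gaps
    contig_seq <- rand_bases(intergenic_gap)
    genes <- list()
    for (b in blocks) {
      offset <- nchar(contig_seq)
      contig_seq <- paste0(contig_seq, b$seq, rand_bases(intergenic_gap))
      tx <- transcript(id = paste0(b$symbol, "_T1"), gene_id = b$symbol,
                       contig = "chrS", strand = b$strand,
                       exons = data.frame(start = b$exon_start + offset,
                                          end = b$exon_end + offset),
                       cds_start = b$cds_g[1] + offset,
                       cds_end = b$cds_g[2] + offset, canonical = TRUE)
      genes[[length(genes) + 1L]] <-
        gene(symbol = b$symbol, contig = "chrS",
             start = min(b$exon_start) + offset,
             end = max(b$exon_end) + offset, transcripts = list(tx),
             description = paste("synthetic gene", b$symbol))
    }
    ref <- reference_sequence("chrS", contig_seq)
    for (g in genes) {
      pep <- translate_cds(cds_sequence(g$transcripts[[1]], ref))
      if (substr(pep, 1, 1) != "M" ||
          substr(pep, nchar(pep), nchar(pep)) != "*" ||
          grepl("\\*", substr(pep, 1, nchar(pep) - 1L))) {
        stop("internal error: generated CDS for ", g$symbol,
             " does not translate M...*")
      }
    }
    list(ref = ref, genes = genes)
  })
}

# ---- brute-force re-translation oracle ---------------------------------

#' Brute-force consequence by full CDS re-translation
#'
#' Reference procedure that rebuilds the entire mutated CDS base-by-base,
#' translates it, and classifies the change by comparing the two peptides.
#' Used to verify generated fixtures and as the independent check of the
#' codon-local annotator. Positions outside the CDS fall back to the same
#' feature-location rules.
#'
#' @param v A `variant`.
#' @param tx A `transcript`.
#' @param ref A `reference_sequence`.
#' @param opts `ann_options`.
#' @return List with `consequence`, `aa_ref`, `aa_alt`, `aa_pos`, `lof`,
#'   `nmd`.
#' @export
retranslation_annotation <- function(v, tx, ref, opts = ann_options()) {
  v <- normalize_variant(v, ref)
  ch <- changed_alleles(v)
  cds_pos <- cds_genomic_positions(tx)
  in_cds <- if (nchar(ch$ref) > 0L) {
    any(ch$pos:(ch$pos + nchar(ch$ref) - 1L) %in% cds_pos)
  } else {
    (ch$pos %in% cds_pos) && ((ch$pos - 1L) %in% cds_pos)
  }
  if (!in_cds) {
    cons <- consequence(v, tx, ref, opts)  # non-coding rules shared
    lof <- cons %in% c("splice_acceptor_variant", "splice_donor_variant")
    return(list(consequence = cons, aa_ref = NA_character_,
                aa_alt = NA_character_, aa_pos = NA_integer_,
                lof = lof, nmd = FALSE))
  }
  # rebuild the mutated spliced CDS base-by-base
  contig <- strsplit(ref$sequence, "")[[1]]
  alt_bases <- strsplit(ch$alt, "")[[1]]
  mutated_cds <- character(0)
  walk <- if (tx$strand == "-") rev(cds_pos) else cds_pos  # genomic asc order
  walk <- sort(cds_pos)
  del_span <- if (nchar(ch$ref) > 0L) ch$pos:(ch$pos + nchar(ch$ref) - 1L)
    else integer(0)
  for (p in walk) {
    if (p %in% del_span) {
      if (p == del_span[1]) mutated_cds <- c(mutated_cds, alt_bases)
      next
    }
    if (nchar(ch$ref) == 0L && p == ch$pos) {
      mutated_cds <- c(mutated_cds, alt_bases, contig[p])
      next
    }
    mutated_cds <- c(mutated_cds, contig[p])
  }
  mut <- paste(mutated_cds, collapse = "")
  if (tx$strand == "-") mut <- reverse_complement(mut)
  cds_ref <- cds_sequence(tx, ref)
  pep_ref <- translate_cds(cds_ref)
  offs <- if (length(del_span)) {
    o <- vapply(del_span, function(p) genomic_to_cds(tx, p), integer(1))
    o[!is.na(o)]
  } else {
    o <- vapply(c(ch$pos - 1L, ch$pos), function(p) genomic_to_cds(tx, p),
                integer(1))
    o[!is.na(o)]
  }
  first_off <- min(offs)
  aa_pos <- (first_off - 1L) %/% 3L + 1L
  delta <- nchar(ch$alt) - nchar(ch$ref)
  cons <- if (delta %% 3L != 0L) {
    "frameshift_variant"
  } else if (delta != 0L) {
    offs_sorted <- sort(offs)
    aligned <- if (delta < 0L) {
      length(offs_sorted) %% 3L == 0L && (offs_sorted[1] - 1L) %% 3L == 0L &&
        all(diff(offs_sorted) == 1L)
    } else {
      # insertion between CDS offsets k and k+1 is codon-aligned iff k %% 3 == 0
      k <- genomic_to_cds(tx, if (tx$strand == "+") ch$pos - 1L else ch$pos)
      !is.na(k) && k %% 3L == 0L
    }
    if (delta < 0L) {
      if (aligned) "inframe_deletion" else "disruptive_inframe_deletion"
    } else {
      if (aligned) "inframe_insertion" else "disruptive_inframe_insertion"
    }
  } else {
    classify_substitution(cds_ref, mut, pep_ref, aa_pos, opts)
  }
  # aa change from the two translations
  aa_ref <- substr(pep_ref, aa_pos, aa_pos)
  aa_alt <- if (delta == 0L) {
    pep_alt <- suppressWarnings(translate_cds(mut))
    substr(pep_alt, aa_pos, aa_pos)
  } else "-"
  prot_len <- nchar(pep_ref)
  # PTC residue for truncating variants: first new stop in the mutated frame
  lof <- if (cons %in% c("splice_acceptor_variant", "splice_donor_variant",
                         "start_lost")) {
    TRUE
  } else if (cons == "stop_gained") {
    aa_pos <= opts$lof_fraction * prot_len
  } else if (cons == "frameshift_variant") {
    aa_pos <= opts$lof_fraction * prot_len
  } else FALSE
  nmd <- FALSE
  if (cons %in% c("stop_gained", "frameshift_variant") && lof) {
    nmd <- oracle_nmd(tx, (aa_pos - 1L) * 3L + 1L, opts$nmd_distance)
  }
  list(consequence = cons, aa_ref = aa_ref, aa_alt = aa_alt,
       aa_pos = aa_pos, lof = lof, nmd = nmd)
}

classify_substitution <- function(cds_ref, cds_alt, pep_ref, aa_pos, opts) {
  pep_alt <- suppressWarnings(translate_cds(cds_alt))
  if (aa_pos == 1L) {
    if (substr(pep_alt, 1, 1) == "M") return("synonymous_variant")
    codon1 <- substr(cds_alt, 1, 3)
    return(if (codon1 %in% opts$alt_start_codons)
      "initiator_codon_variant" else "start_lost")
  }
  r <- substr(pep_ref, aa_pos, aa_pos)
  a <- substr(pep_alt, aa_pos, aa_pos)
  if (r == "*") return(if (a == "*") "stop_retained_variant" else "stop_lost")
  if (a == "*") return("stop_gained")
  if (r == a) "synonymous_variant" else "missense_variant"
}

# 50-nt rule by explicit splice walk, independent of predict_nmd's
# arithmetic shortcut.
oracle_nmd <- function(tx, ptc_cds_offset, nmd_distance = 50L) {
  if (nrow(tx$exons) < 2L) return(FALSE)
  segs <- lapply(seq_len(nrow(tx$exons)),
                 function(i) tx$exons$start[i]:tx$exons$end[i])
  walk <- unlist(segs)
  exon_of <- rep(seq_along(segs), lengths(segs))
  if (tx$strand == "-") { walk <- rev(walk); exon_of <- rev(exon_of) }
  junctions <- which(diff(exon_of) != 0L)  # spliced offset of junction base
  ptc_genomic <- cds_genomic_positions(tx)[ptc_cds_offset]
  ptc_spliced <- match(ptc_genomic, walk)
  if (is.na(ptc_spliced)) return(FALSE)
  max(junctions) - ptc_spliced >= nmd_distance
}

# ---- variant construction ----------------------------------------------

# Each maker returns a variant whose oracle consequence equals the target
# term, or NULL when no admissible site was found in `tries` draws.
make_variant <- function(term, tx, ref, opts, tries = 50L) {
  for (i in seq_len(tries)) {
    v <- try_make_variant(term, tx, ref, opts)
    if (is.null(v)) next
    ann <- retranslation_annotation(v, tx, ref, opts)
    if (ann$consequence == term) return(v)
  }
  NULL
}

try_make_variant <- function(term, tx, ref, opts) {
  cds_pos <- cds_genomic_positions(tx)  # tx orientation
  cds_ref <- cds_sequence(tx, ref)
  n_aa <- nchar(cds_ref) %/% 3L
  base_at <- function(p) ref_slice(ref, p, p)
  snv_at_cds_offset <- function(off, alt_tx_base) {
    g <- cds_pos[off]
    alt_g <- if (tx$strand == "-") chartr("ACGT", "TGCA", alt_tx_base)
      else alt_tx_base
    if (alt_g == base_at(g)) return(NULL)
    variant("chrS", g, base_at(g), alt_g)
  }
  codon_at <- function(idx) substr(cds_ref, 3L * idx - 2L, 3L * idx)

  if (term %in% c("missense_variant", "synonymous_variant", "stop_gained")) {
    idx <- sample(2:(n_aa - 1L), 1L)
    if (term == "stop_gained") idx <- sample(2:max(2L, floor(0.9 * n_aa)), 1L)
    codon <- codon_at(idx)
    within <- sample(1:3, 1L)
    for (b in sample(setdiff(c("A", "C", "G", "T"),
                             substr(codon, within, within)))) {
      cand <- codon
      substr(cand, within, within) <- b
      aa_old <- CODON_TABLE[codon]; aa_new <- CODON_TABLE[cand]
      ok <- switch(term,
        missense_variant = aa_new != "*" && aa_new != aa_old,
        synonymous_variant = aa_new == aa_old,
        stop_gained = aa_new == "*")
      if (ok) {
        return(snv_at_cds_offset(3L * (idx - 1L) + within, b))
      }
    }
    return(NULL)
  }
  if (term == "stop_lost") {
    codon <- codon_at(n_aa)
    within <- sample(1:3, 1L)
    for (b in sample(setdiff(c("A", "C", "G", "T"),
                             substr(codon, within, within)))) {
      cand <- codon; substr(cand, within, within) <- b
      if (CODON_TABLE[cand] != "*") {
        return(snv_at_cds_offset(3L * (n_aa - 1L) + within, b))
      }
    }
    return(NULL)
  }
  if (term == "start_lost") return(snv_at_cds_offset(2L, "C"))   # ATG -> ACG
  if (term == "initiator_codon_variant") {
    return(snv_at_cds_offset(1L, "C"))                           # ATG -> CTG
  }
  if (term %in% c("intron_variant", "splice_region_variant",
                  "splice_donor_variant", "splice_acceptor_variant")) {
    it <- intron_table(tx)
    if (is.null(it)) return(NULL)
    i <- sample(nrow(it), 1L)
    L <- it$left_exon_end[i]; R <- it$right_exon_start[i]
    if (term == "intron_variant") {
      lo <- L + opts$splice_region_intronic[2] + 2L
      hi <- R - opts$splice_region_intronic[2] - 2L
      if (lo > hi) return(NULL)
      p <- sample(lo:hi, 1L)
    } else if (term == "splice_region_variant") {
      d <- sample(opts$splice_region_intronic[1]:opts$splice_region_intronic[2], 1L)
      p <- if (stats::runif(1) < 0.5) L + d else R - d
    } else {
      donor_left <- it$donor_side[i] == "left"
      d <- sample(seq_len(opts$splice_site_nt), 1L)
      p <- if ((term == "splice_donor_variant") == donor_left) L + d else R - d
    }
    b <- sample(setdiff(c("A", "C", "G", "T"), base_at(p)), 1L)
    return(variant("chrS", p, base_at(p), b))
  }
  if (term %in% c("frameshift_variant", "inframe_deletion",
                  "disruptive_inframe_deletion")) {
    # deletion anchored one base left of the deleted run; run must be
    # genomically consecutive (single exon)
    run_len <- if (term == "frameshift_variant") sample(c(1L, 2L, 4L), 1L)
      else 3L
    gs <- sort(cds_pos)
    start_off <- if (term == "inframe_deletion") {
      3L * (sample(2:(n_aa - 1L), 1L) - 1L) + 1L
    } else if (term == "disruptive_inframe_deletion") {
      3L * (sample(2:(n_aa - 2L), 1L) - 1L) + 1L + sample(1:2, 1L)
    } else {
      sample(4:(length(cds_pos) - run_len - 3L), 1L)
    }
    # offsets are in tx orientation; convert to genomic ascending run
    g_span <- cds_pos[start_off:(start_off + run_len - 1L)]
    g_span <- sort(g_span)
    if (any(diff(g_span) != 1L)) return(NULL)  # straddles an intron
    anchor <- g_span[1] - 1L
    if (anchor < 1L) return(NULL)
    return(variant("chrS", anchor,
                   ref_slice(ref, anchor, g_span[length(g_span)]),
                   base_at(anchor)))
  }
  if (term %in% c("inframe_insertion", "disruptive_inframe_insertion")) {
    idx <- sample(2:(n_aa - 1L), 1L)
    off <- if (term == "inframe_insertion") 3L * (idx - 1L)
      else 3L * (idx - 1L) + sample(1:2, 1L)
    # insert after CDS offset `off` (tx orientation)
    g_before <- if (tx$strand == "+") cds_pos[off] else cds_pos[off + 1L]
    ins <- paste(sample(NONSTOP_CODONS, 1L), collapse = "")
    if (tx$strand == "-") ins <- reverse_complement(ins)
    return(variant("chrS", g_before, base_at(g_before),
                   paste0(base_at(g_before), ins)))
  }
  if (term %in% c("5_prime_UTR_variant", "3_prime_UTR_variant")) {
    ex <- tx$exons
    exonic <- unlist(lapply(seq_len(nrow(ex)),
                            function(i) ex$start[i]:ex$end[i]))
    utr <- setdiff(exonic, cds_pos)
    five <- if (tx$strand == "+") utr[utr < tx$cds_start]
      else utr[utr > tx$cds_end]
    pool <- if (term == "5_prime_UTR_variant") five else setdiff(utr, five)
    # keep clear of exonic splice-region flanks
    near <- unlist(lapply(seq_len(nrow(ex)), function(i)
      c(ex$start[i] + 0:(opts$splice_region_exonic - 1L),
        ex$end[i] - 0:(opts$splice_region_exonic - 1L))))
    inner <- setdiff(pool, near)
    pool <- if (length(inner)) inner else pool
    if (!length(pool)) return(NULL)
    p <- sample(pool, 1L)
    b <- sample(setdiff(c("A", "C", "G", "T"), base_at(p)), 1L)
    return(variant("chrS", p, base_at(p), b))
  }
  if (term %in% c("upstream_gene_variant", "downstream_gene_variant",
                  "intergenic_variant")) {
    span <- c(min(tx$exons$start), max(tx$exons$end))
    # intergenic sites must clear the window of the neighbouring gene too
    # (genes are laid out >= 12 kb apart)
    d <- if (term == "intergenic_variant") opts$upstream_window + 800L
      else sample(100:(opts$upstream_window - 50L), 1L)
    before <- if (term == "upstream_gene_variant") tx$strand == "+"
      else if (term == "downstream_gene_variant") tx$strand == "-"
      else stats::runif(1) < 0.5
    p <- if (before) span[1] - d else span[2] + d
    if (p < 1L || p > nchar(ref$sequence)) return(NULL)
    b <- sample(setdiff(c("A", "C", "G", "T"), base_at(p)), 1L)
    return(variant("chrS", p, base_at(p), b))
  }
  stop("unsupported consequence term for generation: ", term)
}

#' Generate a VCF with a controlled consequence mix
#'
#' Draws each requested variant on a random gene of the locus, verifies it
#' against the re-translation oracle, and (optionally) writes a VCF 4.2
#' file. Errors after bounded retries when a request is unsatisfiable.
#'
#' @param spec A `synth_spec` (the `variant_mix` field is the request).
#' @param locus Output of [generate_locus()].
#' @param path Optional output path; when `NULL` no file is written.
#' @param opts `ann_options`.
#' @return List with `variants` (list of `variant`, shuffled by position),
#'   `expected` (character vector of intended consequence terms, parallel
#'   to `variants`), and `path`.
#' @export
generate_vcf <- function(spec, locus, path = NULL, opts = ann_options()) {
  with_local_seed(spec$seed + 1L, {
    variants <- list(); expected <- character(0)
    for (term in names(spec$variant_mix)) {
      n <- spec$variant_mix[[term]]
      made <- 0L; attempts <- 0L
      while (made < n) {
        attempts <- attempts + 1L
        if (attempts > 60L * n) {
          stop("could not generate ", n, " '", term,
               "' variant(s) on this locus")
        }
        g <- locus$genes[[sample(length(locus$genes), 1L)]]
        tx <- select_canonical(g)
        v <- make_variant(term, tx, locus$ref, opts)
        if (is.null(v)) next
        key <- variant_key(v)
        if (key %in% vapply(variants, variant_key, character(1))) next
        variants <- c(variants, list(v)); expected <- c(expected, term)
        made <- made + 1L
      }
    }
    o <- order(vapply(variants, function(v) v$pos, integer(1)))
    variants <- variants[o]; expected <- expected[o]
    if (!is.null(path)) {
      write_vcf(variants, path, contig = locus$ref$contig,
                contig_length = nchar(locus$ref$sequence),
                seed = spec$seed)
    }
    list(variants = variants, expected = expected, path = path)
  })
}

#' Write variants as a VCF 4.2 file
#'
#' @param variants List of `variant` objects.
#' @param path Output path.
#' @param contig,contig_length Contig header fields.
#' @param seed Generator seed recorded in the header.
#' @param info_strings Optional character vector of INFO column values
#'   (parallel to `variants`; default `"."`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contig = "chrS",
                      contig_length = NULL, seed = NULL,
                      info_strings = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contig_length))
             sprintf("##contig=<ID=%s,length=%d>", contig, contig_length)
           else sprintf("##contig=<ID=%s>", contig),
           if (!is.null(seed)) sprintf("##synthSeed=%d", seed),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- vapply(seq_along(variants), function(i) {
    v <- variants[[i]]
    info <- if (is.null(info_strings)) "." else info_strings[i]
    paste(v$contig, v$pos, ".", v$ref, v$alt,
          if (is.na(v$qual)) "." else format(v$qual), v$filter, info,
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Deterministic toy discovery set
#'
#' A four-gene locus (two panel genes, two off-panel) with 20 variants of
#' which 8 fall in panel genes and exactly 3 satisfy a relevance rule
#' (a stop gained, a disruptive inframe deletion, and a splice-donor
#' SNV). Missense variants placed on panel genes are
#' constrained to be non-critical so the relevant count is fixed by
#' construction.
#'
#' @param seed Integer seed.
#' @param vcf_path Optional path for the VCF.
#' @return List with `ref`, `genes`, `panel`, `variants`, `expected`
#'   (intended consequence terms) and `vcf_path`.
#' @export
toy_discovery_set <- function(seed = 11L, vcf_path = NULL) {
  spec <- synth_spec(seed = seed, n_genes = 4L, exons_per_gene = c(2L, 3L),
                     cds_length = c(210L, 360L))
  locus <- generate_locus(spec, gene_symbols = c("TTN", "ZZZ1", "MYH7",
                                                 "ZZZ2"))
  panel <- gene_panel("custom", c("TTN", "MYH7"))
  opts <- ann_options()
  by_symbol <- stats::setNames(locus$genes,
                               vapply(locus$genes, function(g) g$symbol,
                                      character(1)))
  with_local_seed(seed + 3L, {
    want <- list(
      list("TTN", "stop_gained"), list("MYH7",
                                       "disruptive_inframe_deletion"),
      list("TTN", "splice_donor_variant"),
      list("TTN", "synonymous_variant"), list("MYH7", "synonymous_variant"),
      list("TTN", "intron_variant"), list("MYH7", "intron_variant"),
      list("MYH7", "missense_variant"),
      list("ZZZ1", "missense_variant"), list("ZZZ1", "missense_variant"),
      list("ZZZ2", "missense_variant"), list("ZZZ2", "missense_variant"),
      list("ZZZ1", "synonymous_variant"), list("ZZZ2", "synonymous_variant"),
      list("ZZZ1", "synonymous_variant"),
      list("ZZZ1", "stop_gained"), list("ZZZ2", "stop_gained"),
      list("ZZZ1", "intron_variant"), list("ZZZ2", "intron_variant"),
      list("ZZZ2", "intron_variant"))
    variants <- list(); expected <- character(0)
    for (w in want) {
      g <- by_symbol[[w[[1]]]]
      tx <- select_canonical(g)
      repeat {
        v <- make_variant(w[[2]], tx, locus$ref, opts)
        if (is.null(v)) next
        if (variant_key(v) %in% vapply(variants, variant_key, character(1)))
          next
        if (w[[2]] == "missense_variant" && w[[1]] %in% panel$gene_symbols) {
          # keep panel missense non-critical so the relevant count is fixed
          aac <- amino_acid_change(v, tx, locus$ref, opts)
          std <- rownames(aa_property_table())
          if (!aac$aa_ref %in% std || !aac$aa_alt %in% std ||
              is_critical_change(aac$aa_ref, aac$aa_alt)) next
        }
        break
      }
      variants <- c(variants, list(v)); expected <- c(expected, w[[2]])
    }
    o <- order(vapply(variants, function(v) v$pos, integer(1)))
    variants <- variants[o]; expected <- expected[o]
    if (!is.null(vcf_path)) {
      write_vcf(variants, vcf_path, contig = locus$ref$contig,
                contig_length = nchar(locus$ref$sequence), seed = seed)
    }
    list(ref = locus$ref, genes = locus$genes, panel = panel,
         variants = variants, expected = expected, vcf_path = vcf_path)
  })
}

#' Generate a labeled cohort for the concordance harness
#'
#' Each variant is assigned a clinical label (pathogenic-group or
#' benign-group, balanced in expectation). Pathogenic-labeled variants are
#' drawn from the HIGH/LOF consequence pool (stop gained, splice site,
#' frameshift) with
#' probability `pathogenic_enrichment`, otherwise from the benign pool
#' (synonymous / intronic); benign-labeled variants always come from the
#' benign pool. The pipeline's expected sensitivity on the cohort is
#' therefore the enrichment probability, with binomial noise.
#'
#' @param spec A `synth_spec` (`n_cohort`, `pathogenic_enrichment`).
#' @param locus Output of [generate_locus()].
#' @param vcf_path,labels_path Optional output paths.
#' @return List with `variants`, `labels` (`data.frame` of `variant_key`,
#'   `label`, `condition`), `vcf_path`, `labels_path`.
#' @export
generate_labeled_cohort <- function(spec, locus, vcf_path = NULL,
                                    labels_path = NULL) {
  opts <- ann_options()
  with_local_seed(spec$seed + 2L, {
    high_pool <- c("stop_gained", "splice_donor_variant",
                   "splice_acceptor_variant", "frameshift_variant")
    benign_pool <- c("synonymous_variant", "intron_variant")
    conditions <- c("Cardiomyopathy", "Long QT syndrome", "Marfan syndrome")
    variants <- list(); labels <- character(0); conds <- character(0)
    seen <- character(0)
    while (length(variants) < spec$n_cohort) {
      pathogenic <- stats::runif(1) < 0.5
      # the pool choice is fixed before site sampling so that a pathogenic
      # label draws from the HIGH/LOF pool with exactly the requested
      # probability, independent of per-pool site availability
      from_high <- pathogenic &&
        stats::runif(1) < spec$pathogenic_enrichment
      pool <- if (from_high) high_pool else benign_pool
      v <- NULL
      for (try in seq_len(200L)) {
        term <- sample(pool, 1L)
        g <- locus$genes[[sample(length(locus$genes), 1L)]]
        tx <- select_canonical(g)
        cand <- make_variant(term, tx, locus$ref, opts)
        if (is.null(cand) || variant_key(cand) %in% seen) next
        v <- cand
        break
      }
      if (is.null(v)) {
        stop("could not draw a unique cohort variant from the ",
             if (from_high) "HIGH/LOF" else "benign", " pool")
      }
      seen <- c(seen, variant_key(v))
      variants <- c(variants, list(v))
      labels <- c(labels, if (pathogenic)
        sample(c("Pathogenic", "Likely_pathogenic"), 1L)
        else sample(c("Benign", "Likely_benign"), 1L))
      conds <- c(conds, sample(conditions, 1L))
    }
    o <- order(vapply(variants, function(v) v$pos, integer(1)))
    variants <- variants[o]
    labels_df <- data.frame(
      variant_key = vapply(variants, variant_key, character(1)),
      label = labels[o], condition = conds[o], stringsAsFactors = FALSE)
    if (!is.null(vcf_path)) {
      write_vcf(variants, vcf_path, contig = locus$ref$contig,
                contig_length = nchar(locus$ref$sequence), seed = spec$seed)
    }
    if (!is.null(labels_path)) {
      utils::write.table(labels_df, labels_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(variants = variants, labels = labels_df, vcf_path = vcf_path,
         labels_path = labels_path)
  })
}
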