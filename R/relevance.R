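# Panel filtering and the four-criterion relevance classification.
#
# A variant is relevant when its representative annotation satisfies any of:
#   HIGH_IMPACT               predicted HIGH impact on the transcript
#   DISRUPTIVE_PROTEIN_CHANGE disruptive inframe insertion/deletion
#   LOF_OR_NMD                predicted loss-of-function or NMD
#   CRITICAL_AA_CHANGE        missense changing both hydropathy and polarity

RELEVANCE_CRITERIA <- c("HIGH_IMPACT", "DISRUPTIVE_PROTEIN_CHANGE",
                        "LOF_OR_NMD", "CRITICAL_AA_CHANGE")

#' Restrict annotated variants to a gene panel
#'
#' Keeps exactly those variants carrying at least one annotation on a panel
#' gene, preserving input order. The number of removed variants is reported
#' as a message.
#'
#' @param annotated List of `annotated_variant` objects.
#' @param panel A `gene_panel`.
#' @return Filtered list.
#' @export
filter_to_panel <- function(annotated, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  keep <- vapply(annotated, function(av) {
    any(vapply(av$annotations, function(a)
      !is.na(a$gene$gene_symbol) &&
        a$gene$gene_symbol %in% panel$gene_symbols, logical(1)))
  }, logical(1))
  removed <- sum(!keep)
  if (removed > 0L) {
    message(removed, " variant(s) outside panel '", panel$name, "' removed")
  }
  annotated[keep]
}

#' Assess the relevance of one annotated variant
#'
#' Criteria are evaluated on the representative annotation (canonical
#' transcript preferred); set `any_transcript = TRUE` to grant a criterion
#' satisfied by any annotation.
#'
#' @param av An `annotated_variant`.
#' @param any_transcript Evaluate over all annotations instead of the
#'   representative one.
#' @return Object of class `relevance_decision`: `relevant` flag plus the
#'   satisfied `criteria`.
#' @export
assess <- function(av, any_transcript = FALSE) {
  anns <- if (any_transcript) av$annotations
    else av$annotations[av$representative]
  crit <- character(0)
  for (a in anns) {
    if (a$gene$impact == "HIGH") crit <- c(crit, "HIGH_IMPACT")
    if (a$gene$consequence %in% c("disruptive_inframe_insertion",
                                  "disruptive_inframe_deletion")) {
      crit <- c(crit, "DISRUPTIVE_PROTEIN_CHANGE")
    }
    if (a$protein$lof || a$protein$nmd) crit <- c(crit, "LOF_OR_NMD")
    if (a$gene$consequence == "missense_variant" &&
        a$protein$aa_ref %in% rownames(aa_property_table()) &&
        a$protein$aa_alt %in% rownames(aa_property_table()) &&
        is_critical_change(a$protein$aa_ref, a$protein$aa_alt)) {
      crit <- c(crit, "CRITICAL_AA_CHANGE")
    }
  }
  crit <- intersect(RELEVANCE_CRITERIA, unique(crit))
  structure(list(relevant = length(crit) > 0L, criteria = crit),
            class = "relevance_decision")
}

#' @export
print.relevance_decision <- function(x, ...) {
  cat("<relevance_decision>",
      if (x$relevant) paste("relevant:", paste(x$criteria, collapse = ", "))
      else "not relevant", "\n")
  invisible(x)
}

#' Assess a list of annotated variants
#'
#' Element-wise, stateless application of [assess()]; order preserved.
#'
#' @param annotated List of `annotated_variant` objects.
#' @param any_transcript Passed through to [assess()].
#' @return List of `list(variant = annotated_variant,
#'   decision = relevance_decision)`.
#' @export
assess_all <- function(annotated, any_transcript = FALSE) {
  lapply(annotated, function(av)
    list(variant = av, decision = assess(av, any_transcript)))
}
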