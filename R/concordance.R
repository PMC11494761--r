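# Concordance evaluation against ClinVar-style clinical labels: CLNSIG
# mapping, eligibility filtering, the confusion matrix under the
# relevant-vs-pathogenic concordance definition, and
# sensitivity/specificity/accuracy.

BENIGN_GROUP <- c("benign", "likely_benign")
PATHOGENIC_GROUP <- c("pathogenic", "likely_pathogenic")

#' Map a CLNSIG string to a clinical label
#'
#' Case-insensitive token matching. Conflicting interpretations map to
#' `conflicting`, uncertain significance to `uncertain`, composite values
#' such as `Benign/Likely_benign` to the likely tier of their group, and
#' anything unrecognized to `other`.
#'
#' @param clnsig CLNSIG value string.
#' @return One of `benign`, `likely_benign`, `uncertain`,
#'   `likely_pathogenic`, `pathogenic`, `conflicting`, `other`.
#' @export
map_clnsig <- function(clnsig) {
  if (is.na(clnsig) || !nzchar(clnsig)) return("other")
  s <- tolower(clnsig)
  if (grepl("conflicting", s)) return("conflicting")
  if (grepl("uncertain", s)) return("uncertain")
  if (grepl("pathogenic/likely_pathogenic", s)) return("likely_pathogenic")
  if (grepl("benign/likely_benign", s)) return("likely_benign")
  if (grepl("likely_pathogenic", s)) return("likely_pathogenic")
  if (grepl("likely_benign", s)) return("likely_benign")
  if (grepl("pathogenic", s)) return("pathogenic")
  if (grepl("benign", s)) return("benign")
  "other"
}

#' Eligibility of a labeled variant for the concordance evaluation
#'
#' Keeps variants with a known effect on disease (benign/likely benign or
#' pathogenic/likely pathogenic - no VUS, no conflicting records) whose
#' reported condition matches the phenotype filter by case-insensitive
#' substring.
#'
#' @param label A clinical label from [map_clnsig()].
#' @param condition CLNDN-style condition string.
#' @param conditions_filter Character vector of phenotype substrings.
#' @return Logical.
#' @export
eligible <- function(label, condition,
                     conditions_filter = c("cardiomyopathy", "long qt",
                                           "marfan")) {
  if (!label %in% c(BENIGN_GROUP, PATHOGENIC_GROUP)) return(FALSE)
  if (is.na(condition)) return(FALSE)
  any(vapply(conditions_filter, function(f)
    grepl(f, tolower(condition), fixed = TRUE), logical(1)))
}

#' Confusion matrix constructor
#'
#' The positive class is "relevant and pathogenic-group": tp counts
#' relevant calls on pathogenic/likely-pathogenic variants, tn irrelevant
#' calls on benign/likely-benign variants.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion-matrix counts must be non-negative")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("called relevant", "called irrelevant"),
                              c("pathogenic-group", "benign-group")))
  print(m)
  invisible(x)
}

#' Build the confusion matrix from calls and labels
#'
#' @param calls Named logical vector: variant key -> relevant.
#' @param labels Named character vector: variant key -> clinical label
#'   (benign-group or pathogenic-group values only; filter with
#'   [eligible()] first).
#' @return A `confusion_matrix`.
#' @export
build_confusion <- function(calls, labels) {
  if (!setequal(names(calls), names(labels))) {
    stop("calls and labels must cover the same variant keys")
  }
  labels <- labels[names(calls)]
  if (!all(labels %in% c(BENIGN_GROUP, PATHOGENIC_GROUP))) {
    bad <- unique(labels[!labels %in% c(BENIGN_GROUP, PATHOGENIC_GROUP)])
    stop("labels outside the eligible groups: ", paste(bad, collapse = ", "))
  }
  pathogenic <- labels %in% PATHOGENIC_GROUP
  confusion_matrix(tp = sum(calls & pathogenic),
                   fp = sum(calls & !pathogenic),
                   tn = sum(!calls & !pathogenic),
                   fn = sum(!calls & pathogenic))
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' Reported as percentages rounded to two decimals; a metric whose
#' denominator is zero is returned as `NA` (undefined).
#'
#' @param cm A `confusion_matrix`.
#' @return Named list `sensitivity`, `specificity`, `accuracy`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pct <- function(num, den) if (den > 0) round(100 * num / den, 2) else NA_real_
  list(sensitivity = pct(cm$tp, cm$tp + cm$fn),
       specificity = pct(cm$tn, cm$tn + cm$fp),
       accuracy = pct(cm$tp + cm$tn, cm$tp + cm$fp + cm$tn + cm$fn))
}

#' Read a labels table
#'
#' Accepts either a 3-column TSV (`variant_key`, `label`, `condition`) or
#' a ClinVar-style VCF carrying CLNSIG/CLNDN INFO keys (keys are built as
#' `contig:pos:ref:alt`).
#'
#' @param path File path.
#' @return `data.frame` with columns `variant_key`, `label` (mapped via
#'   [map_clnsig()]), `condition`.
#' @export
read_labels <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    variants <- parse_vcf(path)
    rows <- lapply(variants, function(v) {
      data.frame(
        variant_key = variant_key(v),
        label = map_clnsig(info_chr(v$info[["CLNSIG"]])),
        condition = info_chr(v$info[["CLNDN"]]),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    stopifnot(all(c("variant_key", "label", "condition") %in% names(df)))
    df$label <- vapply(df$label, map_clnsig, character(1), USE.NAMES = FALSE)
    df[, c("variant_key", "label", "condition")]
  }
}

info_chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)

#' Run the concordance evaluation
#'
#' Filters the labeled set to eligible variants, joins it with the
#' pipeline's relevance calls, and reports the confusion matrix, the
#' metrics, and a discordance breakdown by consequence term.
#'
#' @param calls_df `data.frame` with columns `key`, `relevant`, and
#'   optionally `consequence` (a `discovery_result$summary` works as is).
#' @param labels_df `data.frame` from [read_labels()] (columns
#'   `variant_key`, `label`, `condition`).
#' @param conditions_filter Phenotype substrings for [eligible()].
#' @return List with `confusion` (a `confusion_matrix`), `metrics`,
#'   `n_eligible`, `discordant_total`, and `discordance_by_effect` (named
#'   counts over discordant variants' consequence terms).
#' @export
evaluate_concordance <- function(calls_df, labels_df,
                                 conditions_filter = c("cardiomyopathy",
                                                       "long qt", "marfan")) {
  keep <- vapply(seq_len(nrow(labels_df)), function(i)
    eligible(labels_df$label[i], labels_df$condition[i], conditions_filter),
    logical(1))
  lab <- labels_df[keep, , drop = FALSE]
  lab <- lab[lab$variant_key %in% calls_df$key, , drop = FALSE]
  calls <- stats::setNames(calls_df$relevant, calls_df$key)[lab$variant_key]
  labels <- stats::setNames(lab$label, lab$variant_key)
  cm <- build_confusion(calls, labels)
  discordant <- names(calls)[(calls & labels %in% BENIGN_GROUP) |
                             (!calls & labels %in% PATHOGENIC_GROUP)]
  by_effect <- if ("consequence" %in% names(calls_df)) {
    eff <- stats::setNames(calls_df$consequence, calls_df$key)[discordant]
    tab <- table(eff)
    stats::setNames(as.integer(tab), names(tab))
  } else NULL
  list(confusion = cm, metrics = metrics(cm), n_eligible = nrow(lab),
       discordant_total = cm$fp + cm$fn,
       discordance_by_effect = by_effect)
}
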