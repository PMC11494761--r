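# Amino-acid hydropathy / polarity classification and the "critical
# amino acid change" predicate (relevance rule iv).
#
# Hydropathy class is the sign of the Kyte-Doolittle score (hydrophobic
# iff KD > 0); polarity uses the four textbook side-chain classes. The
# table ships as a versioned TSV so alternative schemes can be swapped in.

aa_env <- new.env(parent = emptyenv())

#' Amino-acid property table
#'
#' @param path Optional path to an alternative TSV (columns `code`, `name`,
#'   `hydropathy_class`, `polarity_class`, `kd_value`).
#' @return `data.frame` with one row per standard residue (20 rows).
#' @export
aa_property_table <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(aa_env$table)) {
      path <- system.file("extdata", "aa_properties.tsv",
                          package = "cardiorelevance", mustWork = TRUE)
      aa_env$table <- load_aa_table(path)
    }
    return(aa_env$table)
  }
  load_aa_table(path)
}

load_aa_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 20L, !anyDuplicated(tab$code))
  bad <- tab$code[(tab$kd_value > 0) != (tab$hydropathy_class == "hydrophobic")]
  if (length(bad)) {
    stop("hydropathy class inconsistent with KD sign for: ",
         paste(bad, collapse = ", "))
  }
  rownames(tab) <- tab$code
  tab
}

#' Look up the properties of one residue
#'
#' @param code One-letter amino-acid code (standard 20 only).
#' @return One-row `data.frame` with name, hydropathy class, polarity class
#'   and Kyte-Doolittle value.
#' @export
property_of <- function(code) {
  tab <- aa_property_table()
  if (length(code) != 1L || !code %in% rownames(tab)) {
    stop("'", code, "' is not a standard amino-acid one-letter code")
  }
  tab[code, ]
}

#' Critical amino-acid change predicate
#'
#' A substitution is critical when it changes *both* the hydropathy class
#' and the polarity class of the residue. Symmetric, and false on the
#' diagonal.
#'
#' @param aa_ref,aa_alt One-letter codes of the reference and alternate
#'   residues.
#' @return Logical.
#' @export
is_critical_change <- function(aa_ref, aa_alt) {
  p1 <- property_of(aa_ref)
  p2 <- property_of(aa_alt)
  (p1$hydropathy_class != p2$hydropathy_class) &&
    (p1$polarity_class != p2$polarity_class)
}

#' The full 20x20 criticality matrix
#'
#' @return Logical matrix with residues as row/column names.
#' @export
criticality_matrix <- function() {
  codes <- rownames(aa_property_table())
  m <- matrix(FALSE, 20L, 20L, dimnames = list(codes, codes))
  for (a in codes) for (b in codes) m[a, b] <- is_critical_change(a, b)
  m
}
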