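#' Flag a UTR variant by functional-element change
#'
#' A UTR variant is predicted to be functionally significant when the
#' functional element recognized in the reference UTR sequence differs from
#' the one recognized in the variant sequence. "No pattern" is a first-class
#' state (represented as `NA` or the string `"no pattern"`), distinct from an
#' empty annotation: an element appearing or disappearing is a change.
#'
#' @param element_before,element_after character vectors of functional
#'   elements (e.g. `"IRES"`, `"15-LOX-DICE"`); `NA` or `"no pattern"` means
#'   none recognized.
#' @return logical vector: `TRUE` where the pattern changed.
#' @examples
#' flag_utr_pattern_change("IRES", NA)
#' flag_utr_pattern_change("IRES", "IRES")
#' @export
flag_utr_pattern_change <- function(element_before, element_after) {
  canon <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (tolower(trimws(x)) %in% c("", "no pattern", "none"))] <-
      NA_character_
    x
  }
  b <- canon(element_before)
  a <- canon(element_after)
  (is.na(b) != is.na(a)) | (!is.na(b) & !is.na(a) & b != a)
}

#' Flag a polymorphic miRNA target site by function class
#'
#' Polymorphic miRNA target sites fall into four classes: `D`, the derived
#' allele disrupts a conserved site (possible loss of normal repression);
#' `N`, it disrupts a non-conserved site; `C`, it creates a new site
#' (possible abnormal repression); `O`, the ancestral allele cannot be
#' determined. Classes `D` and `C` are the ones most likely to have a
#' functional impact and are flagged.
#'
#' @param function_class character vector over `D`, `N`, `C`, `O`.
#' @return character vector: `"likely_functional"` or `"not_flagged"`.
#' @examples
#' flag_mirna_site(c("C", "N", "O", "D"))
#' @export
flag_mirna_site <- function(function_class) {
  fc <- toupper(trimws(as.character(function_class)))
  bad <- !is.na(fc) & !(fc %in% c("D", "N", "C", "O"))
  if (any(bad)) {
    stop("unknown miRNA-site function class: ",
         paste(unique(function_class[bad]), collapse = ", "), call. = FALSE)
  }
  out <- ifelse(fc %in% c("C", "D"), "likely_functional", "not_flagged")
  out[is.na(fc)] <- NA_character_
  out
}

#' Annotate UTR variant tables with functional flags
#'
#' Adds a `functional` column to a UTR pattern-change table (columns
#' `element_before`, `element_after`) and/or a `flag` column to a miRNA-site
#' table (column `function_class`). Either table may be `NULL`.
#'
#' @param patterns data frame of UTR pattern records (see
#'   `load_paper_table("table5")` for the dialect).
#' @param mirna data frame of polymorphic miRNA-site records
#'   (`load_paper_table("table6")`).
#' @return list with annotated `patterns` and `mirna` data frames.
#' @export
annotate_utr <- function(patterns = NULL, mirna = NULL) {
  if (!is.null(patterns)) {
    need <- setdiff(c("element_before", "element_after"), names(patterns))
    if (length(need)) stop("patterns table lacks column(s): ",
                           paste(need, collapse = ", "), call. = FALSE)
    patterns$functional <- flag_utr_pattern_change(patterns$element_before,
                                                   patterns$element_after)
  }
  if (!is.null(mirna)) {
    if (!"function_class" %in% names(mirna)) {
      stop("mirna table lacks a 'function_class' column", call. = FALSE)
    }
    mirna$flag <- flag_mirna_site(mirna$function_class)
  }
  list(patterns = patterns, mirna = mirna)
}
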