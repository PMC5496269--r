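.severity_levels <- c("mild", "intermediate", "severe", "unknown")
.phenotypes <- c("Hurler", "Hurler-Scheie", "Scheie")

#' Look up the severity of a known mutation
#'
#' Exact (case-sensitive) match on the normalized name; if that fails, a
#' case-insensitive match is attempted with a warning. A miss returns
#' `found = FALSE` with severity `unknown`.
#'
#' @param name a single mutation name in legacy nomenclature.
#' @param kb a `severity_kb` data frame (default: the packaged one).
#' @return list with `found`, `severities` (character vector over
#'   mild/intermediate/severe, or `"unknown"`), `low_reliability`, `class`.
#' @examples
#' lookup_severity("W402X")
#' lookup_severity("R89Q")
#' @export
lookup_severity <- function(name, kb = load_severity_kb()) {
  stopifnot(length(name) == 1)
  n <- normalize_mutation_name(name)
  i <- match(n, kb$name)
  if (is.na(i)) {
    j <- match(tolower(n), tolower(kb$name))
    if (!is.na(j)) {
      warning("'", name, "' matched '", kb$name[j],
              "' case-insensitively", call. = FALSE)
      i <- j
    }
  }
  if (is.na(i)) {
    return(list(found = FALSE, severities = "unknown",
                low_reliability = FALSE, class = NA_character_))
  }
  list(found = TRUE,
       severities = strsplit(kb$severities[i], ",", fixed = TRUE)[[1]],
       low_reliability = kb$low_reliability[i],
       class = kb$class[i])
}

# The four combination rules on a single (atomic) severity pair. Rule
# precedence: unknown propagates; any mild allele forces Scheie (rule 4,
# which subsumes the mild branches of rules 2 and 3); two severe alleles
# give Hurler (rule 1); intermediate + severe gives Hurler-Scheie (rule 2);
# two intermediates give Hurler-Scheie or Scheie (rule 3).
combine_atomic <- function(a, b) {
  if (a == "unknown" || b == "unknown") {
    return(list(phenotypes = "unknown", rule = "unknown-propagation"))
  }
  if (a == "mild" || b == "mild") {
    return(list(phenotypes = "Scheie", rule = "rule4: any mild -> Scheie"))
  }
  if (a == "severe" && b == "severe") {
    return(list(phenotypes = "Hurler", rule = "rule1: severe x severe -> Hurler"))
  }
  if (a == "intermediate" && b == "intermediate") {
    return(list(phenotypes = c("Hurler-Scheie", "Scheie"),
                rule = "rule3: intermediate x intermediate -> Hurler-Scheie or Scheie"))
  }
  list(phenotypes = "Hurler-Scheie",
       rule = "rule2: intermediate x severe -> Hurler-Scheie")
}

#' Combine two allele severities into a clinical phenotype call
#'
#' MPS I is autosomal recessive, so the phenotype follows from the severity
#' of both alleles. The combination rules: (1) only when both alleles are
#' severe is the phenotype Hurler; (2) a severe allele with a mild
#' (intermediate) partner gives Scheie (Hurler-Scheie); (3) two intermediate
#' alleles give Hurler-Scheie or Scheie; (4) even a single mild allele gives
#' Scheie — rule 4 takes precedence, so mild + intermediate is Scheie, not
#' ambiguous. Any unknown allele makes the call unknown.
#'
#' Knowledge-base severities may be set-valued (`c("mild","intermediate")`).
#' Set inputs propagate by Cartesian closure: the result is the union of the
#' atomic results over every pair of input severities, never a collapse to a
#' single worst case.
#'
#' @param a,b character vectors of severities for the two alleles (subsets
#'   of mild/intermediate/severe, or the singleton `"unknown"`).
#' @return A `phenotype_call`: list with `phenotypes` (subset of
#'   Hurler/Hurler-Scheie/Scheie, or `"unknown"`) and `provenance` (data
#'   frame of the atomic pairs and the rule each fired).
#' @examples
#' combine_alleles("severe", "severe")
#' combine_alleles(c("mild", "intermediate"), "severe")
#' @export
combine_alleles <- function(a, b) {
  check <- function(x, which) {
    if (length(x) == 0) stop("empty severity set for allele ", which,
                             call. = FALSE)
    bad <- setdiff(x, .severity_levels)
    if (length(bad)) stop("invalid severit(ies) for allele ", which, ": ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if ("unknown" %in% x && length(unique(x)) > 1) {
      stop("'unknown' cannot co-occur with another severity", call. = FALSE)
    }
    unique(x)
  }
  a <- check(a, 1L); b <- check(b, 2L)
  grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
  res <- Map(combine_atomic, grid$a, grid$b)
  prov <- data.frame(
    a = grid$a, b = grid$b,
    rule = vapply(res, `[[`, character(1), "rule"),
    result = vapply(res, function(r) paste(r$phenotypes, collapse = "|"),
                    character(1)),
    stringsAsFactors = FALSE)
  phen <- unique(unlist(lapply(res, `[[`, "phenotypes")))
  ord <- c(.phenotypes, "unknown")
  structure(list(phenotypes = ord[ord %in% phen], provenance = prov),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat("Predicted phenotype:", paste(x$phenotypes, collapse = " or "), "\n")
  if (!is.null(x$trace)) cat(paste0("  ", x$trace, collapse = "\n"), "\n")
  invisible(x)
}

#' Predict the clinical phenotype of a diallelic genotype
#'
#' Step-by-step workflow for a genotype given as two mutation names: for
#' each allele, (1) if the mutation is in the severity knowledge base, use
#' its curated severity; (2) otherwise, if a predictor profile for it is
#' supplied, classify it pathogenic/benign with the ensemble score — the
#' ensemble tools cannot grade severity, so the severity stays unknown;
#' (3) otherwise the severity is unknown. The two allele severities are then
#' combined with [combine_alleles()]. The trace records the path taken per
#' allele. Computational evidence counts only as a single supporting
#' criterion for pathogenicity; confirmation requires biochemical or
#' clinical follow-up.
#'
#' @param allele1,allele2 mutation names (legacy nomenclature).
#' @param profiles optional `predictor_profiles` with a `mutation` column,
#'   consulted for alleles missing from the knowledge base.
#' @param kb severity knowledge base.
#' @param cutoff ensemble cutoff for the fallback classification.
#' @return a `phenotype_call` with elements `phenotypes`, `provenance`,
#'   `alleles` (per-allele detail) and `trace`.
#' @examples
#' predict_phenotype("W402X", "W402X")
#' predict_phenotype("W402X", "IVS5-7G>A")
#' @export
predict_phenotype <- function(allele1, allele2, profiles = NULL,
                              kb = load_severity_kb(), cutoff = "0.43") {
  names_in <- c(allele1, allele2)
  if (length(names_in) != 2 || any(is.na(names_in)) ||
      !all(nzchar(trimws(names_in)))) {
    stop("both alleles must be non-empty mutation names (allele ",
         which(is.na(names_in) | !nzchar(trimws(names_in)))[1],
         " is not)", call. = FALSE)
  }
  eval_allele <- function(name, idx) {
    hit <- lookup_severity(name, kb)
    if (hit$found) {
      return(list(severities = hit$severities,
                  low_reliability = hit$low_reliability,
                  trace = sprintf(
                    "allele %d (%s): knowledge-base hit, severity %s%s",
                    idx, name, paste(hit$severities, collapse = "/"),
                    if (hit$low_reliability) " (low reliability)" else "")))
    }
    if (!is.null(profiles) && "mutation" %in% names(profiles)) {
      i <- match(normalize_mutation_name(name), profiles$mutation)
      if (!is.na(i)) {
        calls <- damaging_calls(profiles)[i, ]
        p <- compute_pi(calls)
        cls <- suppressWarnings(classify_pi(p, cutoff))
        return(list(severities = "unknown", low_reliability = FALSE,
                    trace = sprintf(
                      paste0("allele %d (%s): not in KB; ensemble PI %.2f ",
                             "-> %s (severity unknown; computational ",
                             "evidence is supporting-level only)"),
                      idx, name, p$pi_display, cls)))
      }
    }
    list(severities = "unknown", low_reliability = FALSE,
         trace = sprintf("allele %d (%s): not in KB, no scores", idx, name))
  }
  a1 <- eval_allele(allele1, 1L)
  a2 <- eval_allele(allele2, 2L)
  call <- combine_alleles(a1$severities, a2$severities)
  call$alleles <- list(a1, a2)
  call$trace <- c(a1$trace, a2$trace,
                  sprintf("combined: %s",
                          paste(call$phenotypes, collapse = " or ")))
  call
}
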