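#' Parse legacy IDUA mutation nomenclature
#'
#' The MPS I literature predates current HGVS usage and names mutations in a
#' legacy style: protein substitutions as `<ref><position><alt>` (`P533R`),
#' nonsense mutations with a trailing `X` (`W402X`), splice-site mutations in
#' intervening-sequence notation (`IVS5-7G>A`), and small deletions or
#' insertions as `<position><del|ins><bases>` (`1995del11`, `396insAC`).
#' Printed tables frequently insert spurious whitespace inside names
#' (`F247 L`); this is typography, not semantics, so all internal whitespace
#' (including non-breaking spaces) is removed before pattern matching.
#'
#' Classification is by pattern, in this order:
#' * names beginning `IVS`, or coding names with an intronic/flanking offset
#'   (`c.<pos><+/-><offset><base>><base>`), are `splicing`;
#' * names containing `del`, `ins` or `dup` are `deletion_insertion`, as is
#'   the residue-range shorthand `D444/445`;
#' * `<AA><pos>X` is `nonsense` (the alternate residue is a stop);
#' * `<AA><pos><AA>` is `missense` — this deliberately covers stop-loss
#'   (`X654C`) and start-loss (`M1T`) substitutions, which the severity
#'   tables group with missense mutations;
#' * anything else is `unknown`, never an error.
#'
#' Protein-level fields (`position`, `ref`, `alt`) are populated only for
#' missense and nonsense records.
#'
#' @param raw character vector of mutation names as printed.
#' @return A data frame with one row per input and columns `raw_name`,
#'   `normalized_name`, `class`, `position`, `ref`, `alt`.
#' @examples
#' parse_mutation_name(c("W402X", "F247 L", "IVS5-7G > A", "1995del11"))
#' @export
parse_mutation_name <- function(raw) {
  if (length(raw) == 0) {
    return(data.frame(raw_name = character(), normalized_name = character(),
                      class = character(), position = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  if (!is.character(raw)) raw <- as.character(raw)
  if (any(is.na(raw) | !nzchar(raw))) {
    stop("mutation names must be non-empty text", call. = FALSE)
  }
  nn <- normalize_mutation_name(raw)
  cls <- vapply(nn, classify_mutation_name, character(1), USE.NAMES = FALSE)
  pos <- rep(NA_integer_, length(nn))
  ref <- rep(NA_character_, length(nn))
  alt <- rep(NA_character_, length(nn))
  prot <- cls %in% c("missense", "nonsense")
  if (any(prot)) {
    m <- regmatches(nn[prot], regexec("^([A-Z])([0-9]+)([A-Z])$", nn[prot]))
    pos[prot] <- as.integer(vapply(m, `[`, character(1), 3L))
    ref[prot] <- vapply(m, `[`, character(1), 2L)
    alt[prot] <- vapply(m, `[`, character(1), 4L)
  }
  data.frame(raw_name = raw, normalized_name = nn, class = cls,
             position = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Normalize a mutation name
#'
#' Strips all internal and flanking whitespace (ordinary and non-breaking).
#' Matching elsewhere in the package is case-sensitive after normalization.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_mutation_name <- function(x) {
  gsub("[[:space:] ]+", "", x)
}

# Pattern rules over a single normalized name.
classify_mutation_name <- function(n) {
  if (grepl("^IVS", n)) return("splicing")
  if (grepl("^c\\.[0-9]+[+-][0-9]+[ACGT]>[ACGT]$", n)) return("splicing")
  if (grepl("del|ins|dup", n)) return("deletion_insertion")
  if (grepl("^[A-Z][0-9]+/[0-9]+$", n)) return("deletion_insertion")
  if (grepl("^[A-Z][0-9]+X$", n)) return("nonsense")
  if (grepl("^[A-Z][0-9]+[A-Z]$", n)) return("missense")
  "unknown"
}
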