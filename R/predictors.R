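#' The seven ensemble predictors
#'
#' Returns the tool identifiers used throughout the package, in the order in
#' which the screening funnel applies them: `sift`, `polyphen`, `imutant`,
#' `provean`, then the three disease-probability classifiers `panther`,
#' `snpsgo`, `phdsnp`.
#'
#' @return character vector of length 7.
#' @export
saamp_tools <- function() {
  c("sift", "polyphen", "imutant", "provean", "panther", "snpsgo", "phdsnp")
}

#' Categorize a predictor score
#'
#' Applies each tool's published decision threshold to a numeric score and
#' returns the tool's categorical call. Thresholds are strict inequalities,
#' so boundary values fall in the non-extreme class (SIFT 0.05 is
#' `tolerated`, PROVEAN -2.5 and I-Mutant DDG -0.5 are `neutral`).
#'
#' * `sift` — tolerance index in \[0, 1\]; `deleterious` if < 0.05, else
#'   `tolerated`.
#' * `polyphen` — PSIC-based score in \[0, 1\]; `probably_damaging` if
#'   > 0.85, `possibly_damaging` if > 0.15, else `benign`.
#' * `imutant` — stability change DDG in kcal/mol; `large_decrease` if
#'   < -0.5, `large_increase` if > 0.5, else `neutral`.
#' * `provean` — `deleterious` if < -2.5, else `neutral`.
#' * `panther` — subPSEC conservation score; `deleterious` if < -3, else
#'   `neutral`. Use `panther_p` for PANTHER's disease probability.
#' * `panther_p`, `snpsgo`, `phdsnp` — disease probability in \[0, 1\];
#'   `disease` if > 0.5, else `neutral`.
#'
#' @param tool a single tool identifier (see above).
#' @param score numeric vector of scores on the tool's scale.
#' @return character vector of categorical calls (`NA` where `score` is
#'   `NA`).
#' @examples
#' categorize_score("sift", c(0, 0.05))
#' categorize_score("imutant", -0.75)
#' @export
categorize_score <- function(tool, score) {
  tool <- match.arg(tool, c(saamp_tools(), "panther_p"))
  if (!is.numeric(score)) {
    stop("score must be numeric for tool '", tool, "'", call. = FALSE)
  }
  unit <- tool %in% c("sift", "polyphen", "panther_p", "snpsgo", "phdsnp")
  if (unit && any(score < 0 | score > 1, na.rm = TRUE)) {
    stop("scores for '", tool, "' must lie in [0, 1]", call. = FALSE)
  }
  out <- switch(tool,
    sift = ifelse(score < 0.05, "deleterious", "tolerated"),
    polyphen = ifelse(score > 0.85, "probably_damaging",
               ifelse(score > 0.15, "possibly_damaging", "benign")),
    imutant = ifelse(score < -0.5, "large_decrease",
              ifelse(score > 0.5, "large_increase", "neutral")),
    provean = ifelse(score < -2.5, "deleterious", "neutral"),
    panther = ifelse(score < -3, "deleterious", "neutral"),
    ifelse(score > 0.5, "disease", "neutral"))
  out[is.na(score)] <- NA_character_
  out
}

# Vocabulary of categorical calls per tool, with the binary "damaging"
# meaning used by the funnel and the pathogenic index.
.tool_vocab <- list(
  sift      = c(deleterious = TRUE,  tolerated = FALSE),
  polyphen  = c(probably_damaging = TRUE, possibly_damaging = FALSE,
                benign = FALSE),
  imutant   = c(large_decrease = TRUE, large_increase = FALSE,
                neutral = FALSE),
  provean   = c(deleterious = TRUE, neutral = FALSE),
  panther   = c(deleterious = TRUE, disease = TRUE, neutral = FALSE),
  panther_p = c(disease = TRUE, neutral = FALSE),
  snpsgo    = c(disease = TRUE, neutral = FALSE),
  phdsnp    = c(disease = TRUE, neutral = FALSE))

#' Map a categorical call onto the binary damaging scale
#'
#' The funnel and the pathogenic index operate on a single binary axis:
#' `deleterious`, `probably_damaging`, `large_decrease` and `disease` count
#' as damaging; `possibly_damaging`, `large_increase`, `tolerated`, `benign`
#' and `neutral` do not. PolyPhen's `possibly_damaging` is deliberately
#' non-damaging because the screen retains only probably-damaging variants,
#' and I-Mutant's `large_increase` is non-damaging because only
#' large-decrease variants pass that stage.
#'
#' Calls are matched case-insensitively with internal whitespace folded to
#' underscores, so printed labels such as `"Probably damaging"` are accepted.
#'
#' @param tool a single tool identifier.
#' @param call character vector of categorical calls in the tool's
#'   vocabulary.
#' @return logical vector (`NA` in, `NA` out).
#' @examples
#' is_damaging("polyphen", c("probably_damaging", "possibly_damaging"))
#' @export
is_damaging <- function(tool, call) {
  tool <- match.arg(tool, names(.tool_vocab))
  vocab <- .tool_vocab[[tool]]
  key <- gsub("[[:space:]]+", "_", tolower(trimws(call)))
  bad <- !is.na(key) & !(key %in% names(vocab))
  if (any(bad)) {
    stop("call(s) not in the '", tool, "' vocabulary: ",
         paste(unique(call[bad]), collapse = ", "), call. = FALSE)
  }
  unname(vocab[key])
}

# Columns the score-table reader understands.
.score_columns <- c(sift = "sift", polyphen = "polyphen",
                    imutant = "imutant_ddg", provean = "provean",
                    panther = "panther_p", snpsgo = "snpsgo_p",
                    phdsnp = "phdsnp_p")

#' Read a per-variant predictor score table
#'
#' Reads a TSV or CSV of per-variant predictor scores into a profile table.
#' The documented dialect has one row per variant and columns `snp_id`
#' and/or `mutation` (at least one is mandatory), numeric score columns
#' `sift`, `polyphen`, `imutant_ddg`, `provean`, `panther_p`, `snpsgo_p`,
#' `phdsnp_p`, and optional printed-label columns `<tool>_label`. Absent
#' cells become absent predictor slots. Lines starting `#` are ignored.
#'
#' Where a printed label and the score-derived category disagree (as for the
#' PHD-SNP call on G265R, labelled disease at probability 0.12), the printed
#' label wins and the conflict is recorded in the `"conflicts"` attribute of
#' the result rather than silently resolved.
#'
#' @param path file path.
#' @param format `"tsv"` or `"csv"`; default guesses from the extension.
#' @return A `predictor_profiles` data frame; attributes `n` (rows read) and
#'   `conflicts` (data frame of label/threshold disagreements).
#' @export
read_score_table <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = c("NA", ""), check.names = TRUE,
                          quote = "\"")
  if (!any(c("snp_id", "mutation") %in% names(df))) {
    stop("score table '", path, "' lacks both 'snp_id' and 'mutation' ",
         "columns; found: ", paste(names(df), collapse = ", "),
         call. = FALSE)
  }
  if ("mutation" %in% names(df)) {
    df$mutation <- normalize_mutation_name(df$mutation)
  }
  as_predictor_profiles(df)
}

#' Construct a profile table from a data frame
#'
#' Validates score columns, reconciles labels against score-derived
#' categories and stamps the `predictor_profiles` class. See
#' [read_score_table()] for the column dialect.
#'
#' @param df data frame in the score-table dialect.
#' @return a `predictor_profiles` data frame.
#' @export
as_predictor_profiles <- function(df) {
  stopifnot(is.data.frame(df))
  conflicts <- NULL
  for (tool in saamp_tools()) {
    sc <- .score_columns[[tool]]
    lab <- paste0(tool, "_label")
    if (sc %in% names(df) && !is.numeric(df[[sc]])) {
      bad <- which(!is.na(df[[sc]]) & is.na(suppressWarnings(as.numeric(df[[sc]]))))
      if (length(bad)) {
        stop("non-numeric '", sc, "' values at row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      df[[sc]] <- as.numeric(df[[sc]])
    }
    if (sc %in% names(df) && lab %in% names(df)) {
      ctool <- if (tool %in% c("panther", "snpsgo", "phdsnp")) {
        if (tool == "panther") "panther_p" else tool
      } else tool
      derived <- is_damaging(tool, categorize_score(ctool, df[[sc]]))
      printed <- is_damaging(tool, df[[lab]])
      off <- which(!is.na(derived) & !is.na(printed) & derived != printed)
      if (length(off)) {
        conflicts <- rbind(conflicts, data.frame(
          row = off,
          variant = variant_ids(df)[off],
          tool = tool,
          score = df[[sc]][off],
          label = df[[lab]][off],
          stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(conflicts)) {
    warning("printed label and score-derived category disagree for ",
            nrow(conflicts), " call(s) (kept the printed label): ",
            paste(unique(paste0(conflicts$variant, "/", conflicts$tool)),
                  collapse = ", "), call. = FALSE)
  }
  structure(df, class = c("predictor_profiles", "data.frame"),
            n = nrow(df), conflicts = conflicts)
}

# Stable display/report identifier per row.
variant_ids <- function(df) {
  if ("variant" %in% names(df)) return(df$variant)
  has_snp <- "snp_id" %in% names(df)
  has_mut <- "mutation" %in% names(df)
  if (has_snp && has_mut) {
    ifelse(is.na(df$mutation), df$snp_id,
           paste(df$snp_id, df$mutation, sep = ":"))
  } else if (has_snp) df$snp_id else df$mutation
}

#' Merge two profile tables on variant identity
#'
#' Left-joins the predictor slots of `y` onto `x` by the identifier columns
#' the two tables share (`snp_id` and/or `mutation`). Variants of `x` absent
#' from `y` keep empty slots for `y`'s tools. Used to assemble a full
#' seven-tool profile from per-tool-set score tables.
#'
#' @param x,y `predictor_profiles` data frames.
#' @return a `predictor_profiles` data frame with `x`'s row order.
#' @examples
#' full <- merge_profiles(load_paper_table("table1"), load_paper_table("table2"))
#' @export
merge_profiles <- function(x, y) {
  by <- intersect(c("snp_id", "mutation"), intersect(names(x), names(y)))
  if (length(by) == 0) stop("no shared identifier columns", call. = FALSE)
  x <- as.data.frame(x)
  x$.order <- seq_len(nrow(x))
  m <- merge(x, as.data.frame(y), by = by, all.x = TRUE, sort = FALSE)
  m <- m[order(m$.order), , drop = FALSE]
  m$.order <- NULL
  rownames(m) <- NULL
  suppressWarnings(as_predictor_profiles(m))
}

#' Binary damaging calls for a profile table
#'
#' Collapses a profile table to an n-by-7 logical matrix of damaging calls,
#' one column per ensemble tool, `NA` where a tool's slot is absent.
#'
#' @param profiles a `predictor_profiles` data frame (or any data frame in
#'   the score-table dialect).
#' @param mode `"labels"` uses printed `<tool>_label` columns where present,
#'   falling back to score thresholds; `"thresholds"` ignores labels and
#'   re-derives every call from the numeric scores (probabilities are called
#'   disease when > 0.5).
#' @return logical matrix with `rownames` set to the variant identifiers.
#' @export
damaging_calls <- function(profiles, mode = c("labels", "thresholds")) {
  mode <- match.arg(mode)
  tools <- saamp_tools()
  out <- matrix(NA, nrow = nrow(profiles), ncol = length(tools),
                dimnames = list(variant_ids(profiles), tools))
  for (tool in tools) {
    sc <- .score_columns[[tool]]
    lab <- paste0(tool, "_label")
    call_col <- paste0(tool, "_call")
    ctool <- if (tool == "panther") "panther_p" else tool
    val <- rep(NA, nrow(profiles))
    if (sc %in% names(profiles)) {
      val <- is_damaging(tool, categorize_score(ctool, profiles[[sc]]))
    }
    if (mode == "labels" && lab %in% names(profiles)) {
      printed <- is_damaging(tool, profiles[[lab]])
      val <- ifelse(is.na(printed), val, printed)
    }
    if (call_col %in% names(profiles) && is.logical(profiles[[call_col]])) {
      val <- profiles[[call_col]]
    }
    out[, tool] <- val
  }
  out
}

#' @export
print.predictor_profiles <- function(x, ...) {
  cat("Predictor profiles: ", nrow(x), " variant(s)\n", sep = "")
  avail <- colSums(!is.na(damaging_calls(x)))
  cat("  tool slots present: ",
      paste(names(avail)[avail > 0], collapse = ", "), "\n", sep = "")
  conf <- attr(x, "conflicts")
  if (!is.null(conf)) {
    cat("  label/threshold conflicts: ", nrow(conf), "\n", sep = "")
  }
  print(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}
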