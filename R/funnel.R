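#' Sequential screening funnel over the ensemble predictors
#'
#' Applies the published screen in order: SIFT (deleterious), PolyPhen
#' (probably damaging), I-Mutant (large stability decrease), PROVEAN
#' (deleterious), then a consensus stage that requires all three of PANTHER,
#' SNPs&GO and PHD-SNP to call disease. A variant survives a stage only if
#' its call at that stage is damaging; each stage therefore acts as an
#' independent predicate and the final survivor set does not depend on the
#' order of the first four stages.
#'
#' A profile with no call at a stage (absent slot) is eliminated there with
#' reason `"not_evaluated"` — distinct from `"not_damaging"` — unless
#' `strict = TRUE`, in which case it is an error naming the variant and the
#' stage. The source study always had complete score sets; real inputs often
#' do not.
#'
#' @param profiles a `predictor_profiles` data frame.
#' @param mode `"labels"` honours printed categorical labels,
#'   `"thresholds"` re-derives calls from numeric scores; see
#'   [damaging_calls()].
#' @param strict error (rather than eliminate) on a missing slot.
#' @return A `funnel_report`: list with `stages` (data frame of
#'   `stage`, `entering`, `surviving`), `survivors` (list of variant-id
#'   vectors per stage), `eliminated` (data frame of `variant`, `stage`,
#'   `reason`) and `mode`.
#' @examples
#' prof <- load_paper_table("table1")
#' run_funnel(prof)
#' @export
run_funnel <- function(profiles, mode = c("labels", "thresholds"),
                       strict = FALSE) {
  mode <- match.arg(mode)
  calls <- damaging_calls(profiles, mode = mode)
  stages <- list(sift = "sift", polyphen = "polyphen", imutant = "imutant",
                 provean = "provean",
                 consensus = c("panther", "snpsgo", "phdsnp"))
  ids <- rownames(calls)
  alive <- ids
  entering <- surviving <- integer(length(stages))
  survivors <- vector("list", length(stages))
  names(survivors) <- names(stages)
  eliminated <- data.frame(variant = character(), stage = character(),
                           reason = character(), stringsAsFactors = FALSE)
  for (k in seq_along(stages)) {
    tools <- stages[[k]]
    entering[k] <- length(alive)
    sub <- calls[match(alive, ids), tools, drop = FALSE]
    miss <- apply(sub, 1L, anyNA)
    if (strict && any(miss)) {
      stop("variant '", alive[which(miss)[1]], "' has no ",
           paste(tools[is.na(sub[which(miss)[1], ])], collapse = "/"),
           " call at stage '", names(stages)[k], "'", call. = FALSE)
    }
    pass <- !miss & apply(sub, 1L, function(z) all(z))
    if (any(miss)) {
      eliminated <- rbind(eliminated, data.frame(
        variant = alive[miss], stage = names(stages)[k],
        reason = "not_evaluated", stringsAsFactors = FALSE))
    }
    drop <- !pass & !miss
    if (any(drop)) {
      eliminated <- rbind(eliminated, data.frame(
        variant = alive[drop], stage = names(stages)[k],
        reason = "not_damaging", stringsAsFactors = FALSE))
    }
    alive <- alive[pass]
    surviving[k] <- length(alive)
    survivors[[k]] <- alive
  }
  structure(list(
    stages = data.frame(stage = names(stages), entering = entering,
                        surviving = surviving, stringsAsFactors = FALSE),
    survivors = survivors, eliminated = eliminated, mode = mode),
    class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Screening funnel (", x$mode, " mode)\n", sep = "")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.funnel_report <- function(x, ...) x$stages
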