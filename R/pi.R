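#' Round half away from zero
#'
#' Reported metrics follow the source's display convention (0.43, 0.57,
#' 94\%), which is ordinary half-up rounding, not the round-half-even rule of
#' base [round()].
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Compute the pathogenic index of a variant profile
#'
#' The pathogenic index (PI) is the fraction of damaging calls among the
#' ensemble tools that returned a prediction for the variant:
#' `PI = damaging_count / available_count`. The higher the PI, the more
#' pathogenic the variant. A two-decimal half-up rounding is attached for
#' display, matching the published cutoff spellings (3/7 prints as 0.43,
#' 4/7 as 0.57); classification never uses the rounded value.
#'
#' @param damaging logical vector of per-tool damaging calls, `NA` marking
#'   tools that returned no prediction. Typically one row of
#'   [damaging_calls()].
#' @return A `pathogenic_index`: list with `damaging_count`,
#'   `available_count`, `pi` (exact fraction) and `pi_display`.
#' @examples
#' compute_pi(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
#' @export
compute_pi <- function(damaging) {
  stopifnot(is.logical(damaging))
  available <- sum(!is.na(damaging))
  if (available == 0) stop("no predictions", call. = FALSE)
  d <- sum(damaging, na.rm = TRUE)
  structure(list(damaging_count = d, available_count = available,
                 pi = d / available,
                 pi_display = round_half_up(d / available, 2)),
            class = "pathogenic_index")
}

#' @export
print.pathogenic_index <- function(x, ...) {
  cat(sprintf("PI = %d/%d = %.4f (display %.2f)\n", x$damaging_count,
              x$available_count, x$pi, x$pi_display))
  invisible(x)
}

# Resolve a cutoff spec to its exact fraction numerator out of 7, or to a
# fixed integer count.
resolve_cutoff <- function(cutoff) {
  if (is.numeric(cutoff) && length(cutoff) == 1 && cutoff == as.integer(cutoff)
      && cutoff >= 1 && cutoff <= 7 && !identical(cutoff, 0.43)
      && !identical(cutoff, 0.57)) {
    return(list(kind = "count", k = as.integer(cutoff)))
  }
  key <- tolower(as.character(cutoff))
  if (key %in% c("0.43", "sensitive", "sensitive_0.43")) {
    return(list(kind = "fraction", num = 3L))
  }
  if (key %in% c("0.57", "specific", "specific_0.57")) {
    return(list(kind = "fraction", num = 4L))
  }
  if (grepl("^k:[0-9]+$", key)) {
    k <- as.integer(sub("^k:", "", key))
    if (k >= 1 && k <= 7) return(list(kind = "count", k = k))
  }
  stop("invalid cutoff '", cutoff, "': use 0.43, 0.57, or an integer 1-7",
       call. = FALSE)
}

#' Classify a variant as pathogenic or benign
#'
#' Classification is an integer count rule, not a comparison against the
#' rounded decimals: at the sensitive cutoff (spelled 0.43) a variant is
#' pathogenic when at least 3 of 7 tools call it damaging, at the specific
#' cutoff (spelled 0.57) when at least 4 of 7 do. The spellings 0.43 and
#' 0.57 are display roundings of the exact fractions 3/7 and 4/7; with all
#' seven tools available the count rule and the exact fraction rule
#' (`PI >= 3/7`, `PI >= 4/7`) coincide. When fewer than 7 tools returned
#' predictions the threshold generalizes to
#' `k = ceiling(fraction * available_count)` (with a warning), which
#' preserves the 7-tool behaviour.
#'
#' @param x a `pathogenic_index` from [compute_pi()].
#' @param cutoff `"0.43"`/`"sensitive"`, `"0.57"`/`"specific"`, an integer
#'   minimum damaging count 1-7, or `"k:<int>"`.
#' @return `"pathogenic"` or `"benign"`.
#' @examples
#' pi3 <- compute_pi(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
#' classify_pi(pi3, "0.43")
#' classify_pi(pi3, "0.57")
#' @export
classify_pi <- function(x, cutoff = "0.43") {
  stopifnot(inherits(x, "pathogenic_index"))
  spec <- resolve_cutoff(cutoff)
  if (spec$kind == "count") {
    k <- spec$k
  } else {
    if (x$available_count < 7) {
      warning("only ", x$available_count, " of 7 tools available; ",
              "threshold generalized as ceiling(", spec$num, "/7 * ",
              x$available_count, ")", call. = FALSE)
    }
    # exact rational ceiling(num/7 * available), integer arithmetic
    k <- (spec$num * x$available_count + 6L) %/% 7L
  }
  if (x$damaging_count >= k) "pathogenic" else "benign"
}

#' Score and classify every variant of a profile table
#'
#' Convenience wrapper: computes per-variant damaging calls, the pathogenic
#' index and the classification at the requested cutoff.
#'
#' @inheritParams damaging_calls
#' @inheritParams classify_pi
#' @return data frame with columns `variant`, `damaging_count`,
#'   `available_count`, `pi`, `pi_display`, `classification`.
#' @examples
#' saamp_classify(load_paper_table("table2"))
#' @export
saamp_classify <- function(profiles, cutoff = "0.43",
                           mode = c("labels", "thresholds")) {
  calls <- damaging_calls(profiles, mode = match.arg(mode))
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    p <- compute_pi(calls[i, ])
    data.frame(variant = rownames(calls)[i],
               damaging_count = p$damaging_count,
               available_count = p$available_count,
               pi = p$pi, pi_display = p$pi_display,
               classification = suppressWarnings(classify_pi(p, cutoff)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Confusion-matrix evaluation of pathogenic/benign predictions
#'
#' Tallies true/false positives and negatives against labelled truth and
#' reports sensitivity `tp / (tp + fn)` and specificity `tn / (tn + fp)`.
#' Percentages are half-up rounded to the whole percent for display. If a
#' truth class is empty the corresponding metric is undefined and reported
#' as `NA`, not as 0.
#'
#' @param predicted character vector of `"pathogenic"`/`"benign"` calls.
#' @param truth character vector of true labels, same length and vocabulary.
#' @param cutoff optional record of the cutoff that produced `predicted`.
#' @return A `benchmark_result`: list with `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `sensitivity_pct`, `specificity_pct`,
#'   `cutoff`.
#' @examples
#' evaluate_benchmark(c("pathogenic", "benign"), c("pathogenic", "pathogenic"))
#' @export
evaluate_benchmark <- function(predicted, truth, cutoff = NA) {
  lv <- c("pathogenic", "benign")
  if (!all(truth %in% lv)) {
    stop("truth labels must be 'pathogenic' or 'benign'", call. = FALSE)
  }
  if (!all(predicted %in% lv)) {
    stop("predictions must be 'pathogenic' or 'benign'", call. = FALSE)
  }
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted == "pathogenic" & truth == "pathogenic")
  fn <- sum(predicted == "benign" & truth == "pathogenic")
  tn <- sum(predicted == "benign" & truth == "benign")
  fp <- sum(predicted == "pathogenic" & truth == "benign")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 sensitivity_pct = round_half_up(100 * sens),
                 specificity_pct = round_half_up(100 * spec),
                 cutoff = cutoff),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d | sensitivity %s%% specificity %s%%\n",
              x$tp, x$fp, x$tn, x$fn,
              format(x$sensitivity_pct), format(x$specificity_pct)))
  invisible(x)
}

#' Sweep the integer cutoff over all seven counts
#'
#' Classifies a labelled benchmark at every integer threshold `k = 1..7`
#' damaging calls and evaluates each. Sensitivity is non-increasing and
#' specificity non-decreasing in `k`.
#'
#' @param calls logical matrix of per-tool damaging calls
#'   ([damaging_calls()] or a generated benchmark's call columns).
#' @param truth character vector of true labels per row.
#' @return data frame with one row per `k`: confusion counts, sensitivity
#'   and specificity (exact and whole-percent display).
#' @export
cutoff_sweep <- function(calls, truth) {
  stopifnot(is.matrix(calls) || is.data.frame(calls))
  calls <- as.matrix(calls)
  d <- rowSums(calls, na.rm = TRUE)
  out <- lapply(1:7, function(k) {
    pred <- ifelse(d >= k, "pathogenic", "benign")
    r <- evaluate_benchmark(pred, truth, cutoff = k)
    data.frame(k = k, tp = r$tp, fp = r$fp, tn = r$tn, fn = r$fn,
               sensitivity = r$sensitivity, specificity = r$specificity,
               sensitivity_pct = r$sensitivity_pct,
               specificity_pct = r$specificity_pct)
  })
  do.call(rbind, out)
}
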