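#' Configuration for the synthetic benchmark generator
#'
#' Validates and bundles generator settings. The defaults emulate the
#' structure of the published evaluation set — a labelled panel of known
#' pathogenic mutations and benign polymorphisms scored by all seven tools —
#' with per-tool sensitivity and specificity of 0.85, a plausible middle of
#' the accuracy range reported for this class of predictors.
#'
#' @param n_pathogenic,n_benign non-negative integer panel sizes.
#' @param sensitivity,specificity per-tool accuracies in \[0, 1\]; scalars
#'   or length-7 vectors (one per tool).
#' @param missingness per-tool probability in \[0, 1\] that a call is absent.
#' @param correlation non-negative scale of a shared per-variant latent
#'   "difficulty" that tilts all seven tools together on the logit scale;
#'   0 (the default) makes calls independent given the true label. Real
#'   predictors correlate, so this knob exists for sensitivity analyses; it
#'   is an extension beyond the published design.
#' @param seed optional integer seed.
#' @return a validated `benchmark_config` list.
#' @export
benchmark_config <- function(n_pathogenic, n_benign,
                             sensitivity = 0.85, specificity = 0.85,
                             missingness = 0, correlation = 0,
                             seed = NULL) {
  stopifnot(n_pathogenic >= 0, n_benign >= 0,
            all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1),
            all(missingness >= 0 & missingness <= 1),
            correlation >= 0)
  rep7 <- function(x) if (length(x) == 1) rep(x, 7) else {
    stopifnot(length(x) == 7); x
  }
  structure(list(n_pathogenic = as.integer(n_pathogenic),
                 n_benign = as.integer(n_benign),
                 sensitivity = rep7(sensitivity),
                 specificity = rep7(specificity),
                 missingness = rep7(missingness),
                 correlation = correlation, seed = seed),
            class = "benchmark_config")
}

# Synthesize mutation names in legacy style for parser fuzzing: protein
# substitutions, nonsense, IVS splice notation and small indels.
synth_mutation_names <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  style <- sample(c("missense", "nonsense", "splicing", "indel"), n,
                  replace = TRUE, prob = c(0.55, 0.15, 0.15, 0.15))
  pos <- sample.int(653, n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    switch(style[i],
      missense = paste0(sample(aa, 1), pos[i], sample(aa, 1)),
      nonsense = paste0(sample(aa, 1), pos[i], "X"),
      splicing = sprintf("IVS%d%s%dG>A", sample.int(13, 1),
                         sample(c("+", "-"), 1), sample.int(9, 1)),
      sprintf("%d%s%d", pos[i], sample(c("del", "ins", "dup"), 1),
              sample.int(12, 1)))
  }, character(1))
}

#' Generate a labelled synthetic benchmark of binary tool calls
#'
#' Draws a panel of `n_pathogenic + n_benign` variants (the label balance is
#' exact, not sampled) with seven binary predictor calls each. Conditional
#' on the true label, each tool calls damaging with probability equal to its
#' sensitivity (pathogenic variants) or one minus its specificity (benign
#' variants), independently across tools unless `correlation > 0`, in which
#' case a per-variant standard-normal latent difficulty shifts every tool's
#' logit by `correlation * z`. Missing calls (`NA`) are injected at the
#' per-tool missingness rate. Mutation names are synthesized in legacy
#' nomenclature so the panel doubles as parser fuzz input.
#'
#' Runs are reproducible: the same config and seed give identical output.
#'
#' @param config a [benchmark_config()], or the first argument to it (the
#'   remaining arguments are then forwarded).
#' @param ... passed to [benchmark_config()] when `config` is not already
#'   one.
#' @return data frame with columns `variant`, `mutation`, `truth`
#'   (`"pathogenic"`/`"benign"`) and logical call columns
#'   `sift_call` ... `phdsnp_call`; also a valid profile table for
#'   [damaging_calls()] and [saamp_classify()].
#' @examples
#' bench <- generate_benchmark(benchmark_config(10, 5, seed = 1))
#' table(bench$truth)
#' @export
generate_benchmark <- function(config, ...) {
  if (!inherits(config, "benchmark_config")) {
    config <- benchmark_config(config, ...)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_pathogenic + config$n_benign
  truth <- rep(c("pathogenic", "benign"),
               c(config$n_pathogenic, config$n_benign))
  tools <- saamp_tools()
  calls <- matrix(NA, nrow = n, ncol = 7,
                  dimnames = list(NULL, paste0(tools, "_call")))
  if (n > 0) {
    z <- if (config$correlation > 0) stats::rnorm(n) else numeric(n)
    for (j in seq_along(tools)) {
      p_damaging <- ifelse(truth == "pathogenic",
                           config$sensitivity[j],
                           1 - config$specificity[j])
      if (config$correlation > 0) {
        p_damaging <- stats::plogis(stats::qlogis(
          pmin(pmax(p_damaging, 1e-12), 1 - 1e-12)) +
            config$correlation * z)
      }
      calls[, j] <- stats::runif(n) < p_damaging
      if (config$missingness[j] > 0) {
        calls[stats::runif(n) < config$missingness[j], j] <- NA
      }
    }
  }
  out <- data.frame(variant = if (n > 0) sprintf("synthetic_%04d", seq_len(n))
                    else character(),
                    mutation = if (n > 0) synth_mutation_names(n)
                    else character(),
                    truth = truth, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(calls))
  attr(out, "config") <- config
  out
}
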