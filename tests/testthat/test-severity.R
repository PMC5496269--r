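test_that("knowledge-base lookups return curated severities", {
  expect_equal(lookup_severity("W402X", kb)$severities, "severe")
  expect_equal(lookup_severity("P533R", kb)$severities, "unknown")
  expect_setequal(lookup_severity("R89Q", kb)$severities,
                  c("mild", "intermediate"))
  hit <- lookup_severity("396insAC", kb)
  expect_equal(hit$severities, "mild")
  expect_true(hit$low_reliability)
  # printed names with spurious whitespace resolve after normalization
  expect_equal(lookup_severity("N348 K", kb)$severities, "mild")
  # case-insensitive fallback warns
  expect_warning(hit2 <- lookup_severity("w402x", kb), "case-insensitively")
  expect_equal(hit2$severities, "severe")
  miss <- lookup_severity("NOVEL999Z", kb)
  expect_false(miss$found)
  expect_equal(miss$severities, "unknown")
})

test_that("KB structure follows the column-placement convention", {
  expect_equal(nrow(kb), 183)
  expect_equal(sum(kb$class == "nonsense"), 22)
  expect_true(all(kb$severities[kb$class == "nonsense"] == "severe"))
  expect_equal(sum(kb$class == "splicing"), 32)
  expect_equal(sum(kb$class == "deletion_insertion"), 45)
  expect_equal(sum(kb$class == "missense"), 84)
  mild_splice <- kb$name[kb$class == "splicing" & kb$severities == "mild"]
  expect_equal(mild_splice, "IVS5-7G>A")
})

test_that("duplicate KB names are rejected", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("name\tclass\tseverities\tlow_reliability\tsource_table",
               "W402X\tnonsense\tsevere\tFALSE\ttable7",
               "W402 X\tnonsense\tsevere\tFALSE\ttable7"), f)
  expect_error(load_severity_kb(f), "duplicate.*W402X")
})

test_that("the validation report flags prose-versus-table conflicts", {
  rep <- kb_validation_report(kb)
  expect_false(all(rep$agree))
  total <- rep[rep$check == "total entries", ]
  expect_equal(total$kb_value, 183)
  expect_equal(total$prose_value, 185)
  expect_false(total$agree)
  expect_true(rep$agree[rep$check == "nonsense"])
  expect_true(rep$agree[rep$check == "splicing"])
  expect_true(rep$agree[rep$check == "deletions/insertions"])
  expect_true(rep$agree[rep$check == "splicing mild"])
})

test_that("atomic severity pairs follow the four combination rules, symmetrically", {
  # independent oracle: the rule table written out pair by pair
  expected <- list(
    "mild|mild" = "Scheie",
    "mild|intermediate" = "Scheie",
    "mild|severe" = "Scheie",
    "mild|unknown" = "unknown",
    "intermediate|intermediate" = c("Hurler-Scheie", "Scheie"),
    "intermediate|severe" = "Hurler-Scheie",
    "intermediate|unknown" = "unknown",
    "severe|severe" = "Hurler",
    "severe|unknown" = "unknown",
    "unknown|unknown" = "unknown")
  lv <- c("mild", "intermediate", "severe", "unknown")
  for (a in lv) for (b in lv) {
    key <- paste(c(a, b)[order(match(c(a, b), lv))], collapse = "|")
    got <- combine_alleles(a, b)$phenotypes
    expect_setequal(got, expected[[key]])
    # symmetry in allele order
    expect_setequal(got, combine_alleles(b, a)$phenotypes)
  }
})

test_that("rule 4 and rule 2's mild branch agree on mild + severe", {
  call <- combine_alleles("mild", "severe")
  expect_equal(call$phenotypes, "Scheie")
  expect_match(call$provenance$rule, "rule4")
})

test_that("set-valued severities combine by Cartesian closure", {
  expect_setequal(combine_alleles(c("mild", "intermediate"), "severe")$phenotypes,
                  c("Scheie", "Hurler-Scheie"))
  expect_setequal(
    combine_alleles(c("mild", "intermediate"), c("mild", "intermediate"))$phenotypes,
    c("Scheie", "Hurler-Scheie"))
  # symmetric also for sets
  expect_setequal(combine_alleles("severe", c("mild", "intermediate"))$phenotypes,
                  c("Scheie", "Hurler-Scheie"))
})

test_that("invalid severity sets are rejected", {
  expect_error(combine_alleles(character(), "severe"), "empty")
  expect_error(combine_alleles("bad", "severe"), "invalid")
  expect_error(combine_alleles(c("unknown", "mild"), "severe"), "co-occur")
})

test_that("genotype prediction walks KB, ensemble and unknown paths", {
  expect_equal(predict_phenotype("W402X", "W402X", kb = kb)$phenotypes,
               "Hurler")
  expect_equal(predict_phenotype("W402X", "IVS5-7G>A", kb = kb)$phenotypes,
               "Scheie")
  expect_equal(predict_phenotype("Q70X", "IVS8+4G>A", kb = kb)$phenotypes,
               "Hurler-Scheie")

  novel <- predict_phenotype("W402X", "NOVEL999Z", kb = kb)
  expect_equal(novel$phenotypes, "unknown")
  expect_match(novel$trace[2], "not in KB, no scores")

  scored <- predict_phenotype("W402X", "P533A", profiles = table1, kb = kb)
  expect_equal(scored$phenotypes, "unknown")
  expect_match(scored$trace[2], "PI 1.00 -> pathogenic")
  expect_match(scored$trace[2], "supporting-level only")

  expect_error(predict_phenotype("W402X", ""), "allele 2")
})
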