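test_that("thresholds categorize scores with boundaries in the non-extreme class", {
  expect_equal(categorize_score("sift", c(0, 0.049, 0.05, 0.5)),
               c("deleterious", "deleterious", "tolerated", "tolerated"))
  expect_equal(categorize_score("polyphen", c(0.9, 0.851, 0.85, 0.16, 0.15, 0)),
               c("probably_damaging", "probably_damaging", "possibly_damaging",
                 "possibly_damaging", "benign", "benign"))
  expect_equal(categorize_score("imutant", c(-0.75, -0.5, 0, 0.5, 0.51)),
               c("large_decrease", "neutral", "neutral", "neutral",
                 "large_increase"))
  expect_equal(categorize_score("provean", c(-7.1, -2.5, -2.51, 0)),
               c("deleterious", "neutral", "deleterious", "neutral"))
  expect_equal(categorize_score("panther", c(-3.5, -3, 0)),
               c("deleterious", "neutral", "neutral"))
  expect_equal(categorize_score("snpsgo", c(0.51, 0.5, 0.12)),
               c("disease", "neutral", "neutral"))
})

test_that("categorize rejects unknown tools and non-numeric scores", {
  expect_error(categorize_score("cadd", 1))
  expect_error(categorize_score("sift", "high"), "numeric")
  expect_error(categorize_score("sift", 1.2), "\\[0, 1\\]")
})

test_that("categorization is monotone in each tool's damaging direction", {
  grid <- seq(0, 1, by = 0.01)
  # damaging flags must be non-increasing as the score moves away from the
  # damaging extreme
  down <- function(flags) all(diff(flags) <= 0)
  expect_true(down(is_damaging("sift", categorize_score("sift", grid))))
  expect_true(down(rev(is_damaging("polyphen", categorize_score("polyphen", grid)))))
  ddg <- seq(-3, 3, by = 0.05)
  expect_true(down(is_damaging("imutant", categorize_score("imutant", ddg))))
  prv <- seq(-10, 5, by = 0.1)
  expect_true(down(is_damaging("provean", categorize_score("provean", prv))))
})

test_that("is_damaging maps each vocabulary onto the binary axis", {
  expect_true(is_damaging("polyphen", "probably_damaging"))
  expect_false(is_damaging("polyphen", "possibly_damaging"))
  expect_true(is_damaging("phdsnp", "disease"))
  expect_false(is_damaging("imutant", "large_increase"))
  # printed-style labels are accepted
  expect_true(is_damaging("polyphen", "Probably damaging"))
  expect_true(is_damaging("imutant", "Large decrease"))
  expect_error(is_damaging("sift", "disease"), "vocabulary")
})

test_that("packaged score tables read with the expected shape", {
  expect_equal(nrow(table1), 93)
  expect_equal(nrow(table2), 28)
  avail1 <- rowSums(!is.na(damaging_calls(table1)))
  avail2 <- rowSums(!is.na(damaging_calls(table2)))
  expect_true(all(avail1 == 4))
  expect_true(all(avail2 == 3))
})

test_that("score-derived categories reproduce the printed Table 1 labels except one cell", {
  # Table 1 prints SIFT "Deleterious 0.05" for F143L; the published
  # threshold makes 0.05 tolerated, so exactly that one label cannot be
  # reproduced. The reader records it as a conflict and keeps the label.
  conf <- attr(table1, "conflicts")
  expect_equal(nrow(conf), 1)
  expect_equal(conf$tool, "sift")
  expect_match(conf$variant, "F143L")
  checks <- list(c("sift", "sift", "sift_label"),
                 c("polyphen", "polyphen", "polyphen_label"),
                 c("imutant", "imutant_ddg", "imutant_label"),
                 c("provean", "provean", "provean_label"))
  mismatches <- 0L
  for (ch in checks) {
    derived <- is_damaging(ch[1], categorize_score(ch[1], table1[[ch[2]]]))
    printed <- is_damaging(ch[1], table1[[ch[3]]])
    mismatches <- mismatches + sum(derived != printed)
  }
  expect_equal(mismatches, 1L)
})

test_that("Table 2's printed labels beat the one conflicting probability", {
  conf <- attr(table2, "conflicts")
  expect_equal(nrow(conf), 1)
  expect_equal(conf$tool, "phdsnp")
  expect_match(conf$variant, "G265R")
  expect_equal(conf$score, 0.12)
  # label mode keeps G265R damaging, threshold mode drops it
  lab <- damaging_calls(table2, mode = "labels")
  thr <- damaging_calls(table2, mode = "thresholds")
  g <- grep("G265R", rownames(lab))
  expect_true(lab[g, "phdsnp"])
  expect_false(thr[g, "phdsnp"])
})

test_that("reader validates inputs and handles empty tables", {
  empty <- tempfile(fileext = ".tsv")
  writeLines("snp_id\tmutation\tsift", empty)
  expect_equal(nrow(read_score_table(empty)), 0)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("foo\tbar", "1\t2"), bad)
  expect_error(read_score_table(bad), "snp_id")

  nonnum <- tempfile(fileext = ".tsv")
  writeLines(c("mutation\tsift", "P533R\thigh"), nonnum)
  expect_error(read_score_table(nonnum), "non-numeric")
})

test_that("csv dialect and merge are supported", {
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(snp_id = "rs1", mutation = "P533 R",
                              sift = 0.01), csv, row.names = FALSE)
  prof <- read_score_table(csv)
  expect_equal(prof$mutation, "P533R")
  m <- merged12
  expect_equal(nrow(m), 93)
  avail <- rowSums(!is.na(damaging_calls(m)))
  expect_equal(sum(avail == 7), 28)
  expect_equal(sum(avail == 4), 65)
})
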