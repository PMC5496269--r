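# Build a 7-tool logical call vector with k damaging calls.
calls_with <- function(k, available = 7) {
  stopifnot(k <= available, available <= 7)
  out <- rep(NA, 7)
  out[seq_len(available)] <- c(rep(TRUE, k), rep(FALSE, available - k))
  names(out) <- saamp_tools()
  out
}

# Packaged tables, loaded once per test run; the label/threshold conflicts
# they carry are a documented property, not a test-relevant warning.
table1 <- suppressWarnings(load_paper_table("table1"))
table2 <- suppressWarnings(load_paper_table("table2"))
merged12 <- suppressWarnings(merge_profiles(table1, table2))
kb <- load_severity_kb()

# ids of the Table 2 membership in the merged table's id scheme
table2_ids <- paste(table2$snp_id, table2$mutation, sep = ":")
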