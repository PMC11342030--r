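# Shared fixtures: small in-code concentration tables and the published
# reference means, used across module tests.

ref_means <- function() {
  ref <- reference_summary()
  m <- ref$mean
  names(m) <- ref$abbreviation
  m
}

# 3-location table with simple hand-checkable numbers over 4 compounds
tiny_table <- function(registry = pah_registry()) {
  m <- rbind(L1 = c(1, 2, 4, 0),
             L2 = c(3, 2, 8, 0),
             L3 = c(5, 2, 0, 0))
  colnames(m) <- c("Naph", "Pyr", "BaP", "BgP")
  concentration_table(m, registry)
}

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
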