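# Shared fixture builders for the test suite. Everything is generated in
# code; the only files touched are the package's bundled example tables and
# per-test temp files.

table3 <- function() read_binding_matrix(bindweight_example("binding"))
table4 <- function() read_weighted_energy_table(bindweight_example("weighted"))
table2 <- function() read_potency_table(bindweight_example("ic50"))

# isotype labels of the bundled binding table, ASCII-escaped
iso_labels <- function() {
  paste0("αβ", c("I", "IIa", "IIb", "III", "IVa", "IVb", "V", "VI", "VIII"))
}

tiny_matrix <- function() {
  binding_matrix(rbind(c(-8, -10), c(-6, -8)),
                 compound_ids = c("c1", "c2"), isotype_ids = c("i1", "i2"))
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path, useBytes = TRUE)
  path
}

# independent brute-force Pearson correlation (sum formulas only)
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# pre-build closed-form oracle values: OLS R^2 of log10(IC50) on the
# published BE_w columns, right-censored entries excluded
own_r2_oracle <- c(SW480 = 0.0403735, SW620 = 0.156141, PC3 = 0.0614673,
                   HepG2 = 0.2120436, MDA = 0.3191331, A549 = 0.3927152,
                   HaCaT = 0.1591949)
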