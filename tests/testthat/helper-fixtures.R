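# tiny hand-built internode tables used across test files

# one tree: root with two daughters, one of which has two daughters
toy_internodes <- function() {
  data.frame(
    tree_id = "T1",
    internode_id = c("A", "B", "C", "D", "E"),
    parent_id = c(NA, "A", "A", "B", "B"),
    length_mm = c(500, 400, 300, 200, 150),
    diameter_mm = c(2 * sqrt(2), 2, 2, sqrt(2), sqrt(2)),
    stringsAsFactors = FALSE)
}

write_toy_csv <- function(df = toy_internodes()) {
  p <- tempfile(fileext = ".csv")
  write_internode_table(df, p)
  p
}

# collinear data on log axes: log10(y) = slope*log10(x) + intercept
loglinear_xy <- function(slope, intercept = 0, n = 50) {
  t <- seq(-1, 1, length.out = n)
  list(x = 10^t, y = 10^(slope * t + intercept))
}
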