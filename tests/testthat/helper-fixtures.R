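# Small fixture builders shared across test files. Everything is generated
# in code; files go to tempdir().

# A 3-gene x 4-sample expression matrix with simple integer-ish values.
tiny_expr <- function() {
  m <- matrix(c(1.5, 2.5, 3.5, 4.5,
                5.0, 5.0, 6.0, 6.0,
                2.0, 8.0, 4.0, 6.0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"),
                              c("s1", "s2", "s3", "s4")))
  m
}

write_expr_tsv <- function(m, path = tempfile(fileext = ".tsv"),
                           extra_lines = NULL) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  lines <- c(paste(colnames(df), collapse = "\t"),
             apply(df, 1, paste, collapse = "\t"))
  if (!is.null(extra_lines)) lines <- c(extra_lines, lines)
  writeLines(lines, path)
  path
}

write_design_tsv <- function(sample_ids, groups,
                             path = tempfile(fileext = ".tsv")) {
  writeLines(c("sample_id\tgroup", paste(sample_ids, groups, sep = "\t")),
             path)
  path
}

tiny_design_df <- function() {
  data.frame(sample_id = c("s1", "s2", "s3", "s4"),
             group = c("case", "case", "control", "control"),
             stringsAsFactors = FALSE)
}

# design for a single-gene matrix built from two explicit group vectors
two_group_expr <- function(case_vals, control_vals, gene = "g1") {
  k1 <- length(case_vals); k2 <- length(control_vals)
  m <- matrix(c(case_vals, control_vals), nrow = 1,
              dimnames = list(gene, c(sprintf("c%d", seq_len(k1)),
                                      sprintf("t%d", seq_len(k2)))))
  design <- data.frame(sample_id = colnames(m),
                       group = rep(c("case", "control"), c(k1, k2)),
                       stringsAsFactors = FALSE)
  list(expr = m, design = design)
}

# boolean matrix from explicit column supports over n genes
boolean_from_supports <- function(supports, n) {
  B <- matrix(0L, n, length(supports),
              dimnames = list(sprintf("g%d", seq_len(n)),
                              sprintf("a%d", seq_along(supports))))
  for (j in seq_along(supports)) B[supports[[j]], j] <- 1L
  B
}

# exact rational equality of two (numerator, denominator) Shapley results
rational_equal <- function(a, b) {
  all(a$numerator * b$denominator == b$numerator * a$denominator)
}

# independent brute-force BH step-up (sorted adjusted = cummin from the top)
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m / i * p[ord[i]])
    adj[ord[i]] <- running
  }
  pmin(adj, 1)
}

write_gmt <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}
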