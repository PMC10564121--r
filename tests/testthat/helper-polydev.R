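# Shared fixtures, built in code at test time.

# Standardized bivariate-normal pairs with population correlation rho.
make_pairs <- function(n, rho, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  standardized_pairs(paste0("id", seq_len(n)), standardize(x), standardize(y))
}

# Write a small weight TSV and return its path.
write_weight_file <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "weights.tsv")
  writeLines(lines, path)
  path
}

weight_lines_ok <- c(
  "variant_id\teffect_allele\tbeta\tmaf",
  "rs1\tA\t0.10\t0.25",
  "rs2\tC\t-0.20\t0.40",
  "rs3\tG\t0.30\t0.05"
)

# A minimal rank-null store with a known matrix, for enumeration oracles.
toy_rank_null <- function(mat) {
  structure(list(n = ncol(mat), B = nrow(mat), mat = mat, config = NULL),
            class = "rank_null")
}
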