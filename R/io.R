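#' Read a per-variant weight table
#'
#' Expects a tab-separated file with header columns `variant_id`,
#' `effect_allele`, `beta` and optionally `maf`. Dosages are assumed to count
#' the effect allele: no allele flipping or harmonisation is attempted, so
#' weights and dosages must be pre-harmonised.
#'
#' @param path Path to a TSV file.
#' @return A `weight_table` data frame with one row per variant.
#' @export
read_weights <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("variant_id", "effect_allele", "beta")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    stop("weight file ", path, " missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  beta <- suppressWarnings(as.numeric(raw$beta))
  bad <- which(is.na(beta) | !is.finite(beta))
  if (length(bad) > 0) {
    # +1 for the header line so the reported number matches the file
    stop("non-numeric or non-finite beta on line ", bad[1] + 1,
         " of ", path, " (value '", raw$beta[bad[1]], "')", call. = FALSE)
  }
  wt <- data.frame(variant_id = raw$variant_id,
                   effect_allele = raw$effect_allele,
                   beta = beta,
                   stringsAsFactors = FALSE)
  if ("maf" %in% names(raw)) {
    maf <- suppressWarnings(as.numeric(raw$maf))
    if (any(is.na(maf))) {
      stop("non-numeric maf on line ", which(is.na(maf))[1] + 1, " of ", path,
           call. = FALSE)
    }
    wt$maf <- maf
  }
  as_weight_table(wt)
}

#' Validate a weight table
#'
#' @param x Data frame with columns `variant_id`, `effect_allele`, `beta`,
#'   optionally `maf` in (0, 0.5].
#' @return `x` with class `weight_table`.
#' @export
as_weight_table <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("variant_id", "effect_allele", "beta") %in% names(x)))
  dup <- unique(x$variant_id[duplicated(x$variant_id)])
  if (length(dup) > 0) {
    stop("duplicated variant_id in weight table: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$beta))) stop("beta must be finite", call. = FALSE)
  if (!is.null(x$maf) && any(x$maf <= 0 | x$maf > 0.5)) {
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  }
  class(x) <- c("weight_table", "data.frame")
  x
}

#' Read a dosage matrix
#'
#' Tab-separated file: first column `individual_id`, one column per variant,
#' values in \[0, 2\] or `NA`.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, rownames individual ids, colnames variant ids.
#' @export
read_dosages <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(raw)[1] != "individual_id") {
    stop("dosage file must have 'individual_id' as its first column",
         call. = FALSE)
  }
  ids <- as.character(raw$individual_id)
  mat <- as.matrix(raw[-1])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  validate_dosages(mat)
  mat
}

validate_dosages <- function(mat) {
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate individual ids in dosage matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate variant ids in dosage matrix", call. = FALSE)
  }
  rng <- range(mat, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]; observed range [",
         rng[1], ", ", rng[2], "]", call. = FALSE)
  }
  invisible(mat)
}

#' Read a phenotype / covariate table
#'
#' Tab-separated, keyed by `individual_id`; remaining columns are phenotypes
#' or covariates (age, sex, centre, pc1..pc5, ...).
#'
#' @param path Path to a TSV file.
#' @return Data frame with one row per individual.
#' @export
read_covariates <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(raw)) {
    stop("covariate file must contain an 'individual_id' column", call. = FALSE)
  }
  raw$individual_id <- as.character(raw$individual_id)
  if (anyDuplicated(raw$individual_id)) {
    stop("duplicate individual ids in covariate table", call. = FALSE)
  }
  raw
}

# Fixed-format numeric rendering so repeated runs write byte-identical tables.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], format_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
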