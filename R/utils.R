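# Shared validation helpers. All user-facing errors go through stop_config()
# or stop_validation() so callers can distinguish bad configuration from bad
# data programmatically (classes "ct5hmc_config_error" / "ct5hmc_validation_error").

stop_config <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("[config field '%s'] %s", field, msg)
  stop(errorCondition(msg, class = c("ct5hmc_config_error", "error")))
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("ct5hmc_validation_error", "error")))
}

assert_beta_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_validation(sprintf("%s must be a numeric matrix", name))
  rng <- suppressWarnings(range(x, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stop_validation(sprintf("%s has values outside [0,1]", name))
  invisible(x)
}

assert_same_index <- function(a, b, name_a, name_b) {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b)))
    stop_validation(sprintf("%s and %s must share probe and sample indexing",
                            name_a, name_b))
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators are deterministic
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}

# Stage-specific sub-seed derived from a master seed; keeps independent
# stages reproducible in isolation. Result stays below 2^31.
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(master) * 1009L + as.integer(h %% 100000L)) %% 2147483647L
}

#' Write a probes/genes-by-samples matrix as (optionally gzipped) TSV
#'
#' First column `id` carries row names; remaining columns are samples.
#'
#' @param mat numeric matrix with row and column names
#' @param path output path; a `.gz` suffix triggers gzip compression
#' @export
write_matrix_tsv <- function(mat, path) {
  dt <- data.table::data.table(id = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path, sep = "\t", compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV (optionally gzipped) with an `id` column
#' @return numeric matrix with row names from `id`
#' @export
read_matrix_tsv <- function(path) {
  df <- if (grepl("\\.gz$", path))
    utils::read.table(gzfile(path), header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
  else
    data.table::fread(path, sep = "\t", data.table = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Read a tidy TSV table, transparently handling gzip
#'
#' @param path TSV file, optionally `.gz`
#' @return data.frame
#' @export
read_tsv_file <- function(path) {
  if (grepl("\\.gz$", path))
    utils::read.table(gzfile(path), header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
  else data.table::fread(path, sep = "\t", data.table = FALSE)
}

clamp01 <- function(x, eps = 0) pmin(1 - eps, pmax(eps, x))
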