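# Shared validation helpers and the read-table representation.
#
# A read table is a tibble whose first column is `species` (canonical
# "Genus epithet" strings) and whose remaining columns are sites holding
# non-negative integer read counts. Dataset identity travels in the
# "dataset_id" attribute so tables survive dplyr verbs that keep attributes.

#' Construct a read table
#'
#' @param x data frame with a `species` column and one column of non-negative
#'   integer read counts per site.
#' @param dataset_id optional dataset identifier stored as an attribute.
#' @return A `read_table` tibble.
#' @export
as_read_table <- function(x, dataset_id = NULL) {
  x <- as_tibble(x)
  if (!"species" %in% names(x) || names(x)[1] != "species") {
    abort("a read table needs `species` as its first column")
  }
  if (ncol(x) < 2) abort("a read table needs at least one site column")
  counts <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(counts) && nrow(x) > 0) {
    abort("site columns must be numeric read counts")
  }
  if (anyNA(counts)) abort("read counts must not be missing")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative read count for species '%s' at site '%s'",
                  x$species[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != round(counts))) abort("read counts must be integers")
  if (anyDuplicated(x$species)) abort("species names must be unique")
  if (!is.null(dataset_id)) attr(x, "dataset_id") <- dataset_id
  class(x) <- c("read_table", class(x))
  x
}

#' @export
print.read_table <- function(x, ...) {
  id <- attr(x, "dataset_id")
  cat("# read table", if (!is.null(id)) paste0("(dataset ", id, ")"),
      ":", nrow(x), "species x", ncol(x) - 1, "sites\n")
  NextMethod()
}

read_counts <- function(table) {
  m <- as.matrix(table[, -1, drop = FALSE])
  rownames(m) <- table$species
  m
}

site_totals <- function(table) colSums(read_counts(table))

#' Per-site species richness
#'
#' Counts, for every site column, the species with at least one read.
#'
#' @param table a read table (see [as_read_table()]).
#' @return tibble with columns `site` and `richness`.
#' @export
richness_per_site <- function(table) {
  m <- read_counts(table)
  tibble(site = colnames(m), richness = as.integer(colSums(m > 0)))
}

# Seed spacing for hierarchical streams: one collection-level stream, each
# dataset re-seeded from a derived value so appending datasets never perturbs
# earlier ones. Kept strictly below 2^31.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 10007 + index * 7919) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate with a local seed; the caller's RNG stream is restored afterwards.
# seed = NULL draws from the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

check_prob <- function(x, name, right_open = FALSE) {
  hi_ok <- if (right_open) all(x < 1) else all(x <= 1)
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || !hi_ok) {
    abort(sprintf("`%s` must lie in [0,%s)", name, if (right_open) "1" else "1]"))
  }
  invisible(x)
}
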