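# Internal helpers shared across modules.

# Uppercase and validate systematic gene names. Comparisons throughout the
# package are on uppercased systematic names only.
normalize_gene_ids <- function(x, context = "gene") {
  if (!is.character(x)) x <- as.character(x)
  if (any(is.na(x) | !nzchar(x))) {
    abort(sprintf("empty or NA %s identifier", context))
  }
  toupper(x)
}

assert_unique_genes <- function(x, context = "table") {
  dup <- unique(x[duplicated(x)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene id(s) in %s: %s", context,
                  paste(head(dup, 5), collapse = ", ")))
  }
  invisible(x)
}

# Geometric mean of two values on [0, 1]; NA-propagating.
geo_mean2 <- function(a, b) sqrt(a * b)

# Geometric mean of two MCC values via the shift transform to [0, 1]:
# gm = 2 * sqrt(((a+1)/2) * ((b+1)/2)) - 1. Identical inputs are returned
# unchanged; negative values are handled without complex arithmetic.
geo_mean_mcc <- function(a, b) 2 * sqrt(((a + 1) / 2) * ((b + 1) / 2)) - 1

# Stage seeds are derived from the single run seed by fixed small offsets so
# any stage can be replayed in isolation. Offsets documented in the vignette.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 0L, controls = 1L, bins_mbp1 = 2L, bins_swi4 = 3L)
  if (!stage %in% names(offsets)) abort(sprintf("unknown stage '%s'", stage))
  s <- as.double(seed) + offsets[[stage]]
  if (s >= 2^31 - 1) abort("seed too large; must leave room for stage offsets below 2^31")
  as.integer(s)
}

# MD5 of an in-memory character payload (used for config hashes and
# artifact digests without extra dependencies).
md5_of_text <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(x, f)
  unname(tools::md5sum(f))
}
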