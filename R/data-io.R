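#' Read a validated gene-level TSV table
#'
#' Reads a tab-separated table with a header row and validates it against a
#' simple column schema. Gene identifiers are uppercased; unknown genes are
#' preserved and row order is kept. Missing values are encoded as the literal
#' `NA` (missing is never silently zero).
#'
#' @param path Path to a TSV file with a header row.
#' @param schema Named character vector mapping mandatory column names to
#'   types, e.g. `c(gene = "character", t20 = "numeric")`. Columns not listed
#'   are read as character and preserved.
#' @return A tibble with typed columns, rows in file order.
#' @export
read_gene_table <- function(path, schema) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = "NA", comment = "#", progress = FALSE)
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("schema error: missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      vals <- raw[[col]]
      parsed <- suppressWarnings(as.numeric(vals))
      bad <- which(!is.na(vals) & is.na(parsed))
      if (length(bad) > 0) {
        abort(sprintf("parse error: non-numeric value '%s' in column '%s' at row %d",
                      vals[bad[1]], col, bad[1]))
      }
      raw[[col]] <- parsed
    }
  }
  if ("gene" %in% names(raw)) raw$gene <- normalize_gene_ids(raw$gene)
  raw
}

#' Read and write expression panels
#'
#' An expression panel holds log2 induction values (relative to time 0) per
#' gene, genotype and timepoint. On disk the panel is a wide TSV with columns
#' `gene`, `strain`, `t20`, `t40`, `t60`, `t80`; in memory it is a long tibble
#' with columns `gene`, `strain`, `time`, `value`. Every (gene, strain) pair
#' carries all four timepoints or is wholly absent.
#'
#' @param panel Long-format expression tibble (`gene`, `strain`, `time`,
#'   `value`).
#' @param path File path.
#' @return `read_expression_panel()` returns the long tibble;
#'   `write_expression_panel()` returns `path` invisibly.
#' @export
write_expression_panel <- function(panel, path) {
  wide <- panel |>
    dplyr::mutate(time = paste0("t", .data$time)) |>
    tidyr::pivot_wider(id_cols = c("gene", "strain"),
                       names_from = "time", values_from = "value") |>
    dplyr::arrange(.data$gene, .data$strain)
  readr::write_tsv(wide, path, na = "NA")
  invisible(path)
}

#' @rdname write_expression_panel
#' @export
read_expression_panel <- function(path) {
  tp_cols <- c(t20 = "numeric", t40 = "numeric", t60 = "numeric", t80 = "numeric")
  wide <- read_gene_table(path, schema = c(gene = "character", strain = "character", tp_cols))
  long <- wide |>
    tidyr::pivot_longer(dplyr::all_of(names(tp_cols)),
                        names_to = "time", values_to = "value") |>
    dplyr::mutate(time = as.integer(sub("^t", "", .data$time)))
  incomplete <- long |>
    dplyr::summarise(n_missing = sum(is.na(.data$value)), .by = c("gene", "strain")) |>
    dplyr::filter(.data$n_missing > 0 & .data$n_missing < 4)
  if (nrow(incomplete) > 0) {
    abort(sprintf("expression panel invariant violated: %d (gene, strain) pairs have partial timepoints",
                  nrow(incomplete)))
  }
  long |> dplyr::filter(!is.na(.data$value))
}

#' Read and write promoter sequence sets
#'
#' Promoters are stored as FASTA with headers `geneId|anchor|length`. The
#' sequence runs 5' to 3' with its last base immediately upstream of the
#' anchor (TSS or start codon); upstream position 1 is that last base.
#' Sequences are uppercased on read; the alphabet is restricted to A, C, G,
#' T, N; duplicate gene ids are rejected.
#'
#' @param path FASTA file path.
#' @param promoters Tibble with columns `gene`, `anchor`, `sequence`.
#' @return `read_promoters_fasta()` returns a tibble with columns `gene`,
#'   `anchor`, `length`, `sequence`.
#' @export
read_promoters_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(sprintf("could not parse FASTA '%s': %s", path, conditionMessage(e)))
  )
  headers <- names(set)
  parts <- stringr::str_split_fixed(headers, stringr::fixed("|"), 3)
  if (any(!nzchar(parts[, 1]) | !nzchar(parts[, 2]))) {
    abort("promoter FASTA headers must be 'geneId|anchor|length'")
  }
  genes <- normalize_gene_ids(parts[, 1], "promoter")
  assert_unique_genes(genes, context = path)
  anchors <- parts[, 2]
  bad_anchor <- setdiff(unique(anchors), c("tss", "start_codon"))
  if (length(bad_anchor) > 0) {
    abort(sprintf("unknown promoter anchor(s): %s", paste(bad_anchor, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  illegal <- regexpr("[^ACGTN]", seqs)
  if (any(illegal > 0)) {
    i <- which(illegal > 0)[1]
    abort(sprintf("illegal character in promoter sequence for %s at position %d",
                  genes[i], illegal[i]))
  }
  tibble::tibble(gene = genes, anchor = anchors,
                 length = unname(nchar(seqs)), sequence = unname(seqs))
}

#' @rdname read_promoters_fasta
#' @export
write_promoters_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- sprintf("%s|%s|%d", promoters$gene, promoters$anchor,
                         nchar(promoters$sequence))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Write and re-read a ranked score table
#'
#' Serializes a score table for one transcription factor as TSV: one row per
#' gene, one column per classifier log-likelihood contribution, a `sum`
#' column equal to the row-wise total, and a dense `rank` column. Rows are
#' ordered by descending `sum` with ties broken lexicographically by
#' systematic name, so output is deterministic across platforms.
#'
#' @param scores A score table as produced by [total_scores()].
#' @param path Output TSV path.
#' @param provenance Optional named character vector written as `#key=value`
#'   header lines.
#' @return `write_ranked_scores()` returns `path` invisibly;
#'   `read_ranked_scores()` returns the score tibble.
#' @export
write_ranked_scores <- function(scores, path, provenance = NULL) {
  out <- scores |> dplyr::arrange(.data$rank)
  header <- character(0)
  if (!is.null(provenance)) {
    header <- sprintf("#%s=%s", names(provenance), unname(provenance))
  }
  writeLines(header, path)
  readr::write_tsv(out, path, na = "NA", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_ranked_scores
#' @export
read_ranked_scores <- function(path) {
  tab <- read_gene_table(path, schema = c(gene = "character", sum = "numeric", rank = "numeric"))
  num_cols <- setdiff(names(tab), "gene")
  for (col in num_cols) tab[[col]] <- as.numeric(tab[[col]])
  tab$rank <- as.integer(tab$rank)
  contrib <- setdiff(names(tab), c("gene", "sum", "rank"))
  resid <- abs(rowSums(tab[contrib], na.rm = TRUE) - tab$sum)
  if (any(resid > 1e-9)) {
    abort("ranked score file violates sum = row-wise classifier total")
  }
  class(tab) <- c("lls_scores", class(tab))
  tab
}
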