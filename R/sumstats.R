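#' GWAS summary statistics as a validated tibble
#'
#' A summary-statistics table holds one row per variant with the marginal
#' association of that variant with a single trait: identifiers, alleles,
#' effect-allele frequency, effect size (`beta`), its standard error,
#' p-value and study sample size. `as_sumstats()` validates a data frame
#' against the invariants every downstream stage relies on and attaches
#' trait metadata; rows violating an invariant are dropped with a warning
#' naming the count.
#'
#' Invariants enforced per row: effect and other allele in {A,C,G,T} and
#' distinct; `se > 0`; `pval` in (0, 1]; `eaf` missing or in \[0, 1\];
#' `n` missing or positive. Across rows `variant_id` must be unique.
#'
#' @param x A data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_id Identifier of the trait the statistics describe.
#' @param trait_type `"microbe_taxon"` or `"protein"`.
#' @param drop_invalid Drop rows that violate row invariants (with a
#'   warning) instead of erroring. Duplicated `variant_id`s always error.
#' @return A tibble of class `mr_sumstats` with attributes `trait_id` and
#'   `trait_type`.
#' @examples
#' ss <- as_sumstats(tibble::tibble(
#'   variant_id = "rs1", chrom = "1", pos = 1000L,
#'   effect_allele = "A", other_allele = "G",
#'   eaf = 0.3, beta = 0.1, se = 0.02, pval = 5e-7, n = 18340
#' ), trait_id = "genus_Holdemanella", trait_type = "microbe_taxon")
#' @export
as_sumstats <- function(x, trait_id = "trait", trait_type = "microbe_taxon",
                        drop_invalid = TRUE) {
  trait_type <- match.arg(trait_type, c("microbe_taxon", "protein"))
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing required columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)[required]
  x$variant_id <- as.character(x$variant_id)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    x[[col]] <- as.numeric(x[[col]])
  }

  ok <- x$effect_allele %in% names(DNA_COMPLEMENT) &
    x$other_allele %in% names(DNA_COMPLEMENT) &
    x$effect_allele != x$other_allele &
    !is.na(x$beta) &
    !is.na(x$se) & x$se > 0 &
    !is.na(x$pval) & x$pval > 0 & x$pval <= 1 &
    (is.na(x$eaf) | (x$eaf >= 0 & x$eaf <= 1)) &
    (is.na(x$n) | x$n > 0) &
    !is.na(x$variant_id) & !is.na(x$pos)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    if (!drop_invalid) abort(sprintf("%d rows violate invariants", n_bad))
    warn(sprintf("dropped %d of %d rows violating summary-statistic invariants",
                 n_bad, nrow(x)))
    x <- x[ok, ]
  }
  if (nrow(x) == 0) abort("no valid rows remain")
  dup <- x$variant_id[duplicated(x$variant_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated variant_id: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  structure(x,
            trait_id = trait_id, trait_type = trait_type,
            class = c("mr_sumstats", class(x)))
}

#' @export
print.mr_sumstats <- function(x, ...) {
  cat(sprintf("<mr_sumstats> trait %s (%s), %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  NextMethod()
}

#' Trait metadata accessors
#' @param x An `mr_sumstats` object.
#' @return A length-one character vector.
#' @export
trait_id <- function(x) attr(x, "trait_id") %||% "trait"

#' @rdname trait_id
#' @export
trait_type <- function(x) attr(x, "trait_type") %||% "microbe_taxon"

#' Default column mapping for summary-statistic files
#'
#' Maps canonical field names to the column headers of a source file.
#' Override individual entries to adapt arbitrary GWAS exports.
#'
#' @param ... Named overrides, e.g. `pval = "P_VALUE"`.
#' @return Named character vector (canonical name -> file column).
#' @export
sumstats_schema <- function(...) {
  schema <- c(variant_id = "SNP", chrom = "CHR", pos = "POS",
              effect_allele = "EA", other_allele = "OA", eaf = "EAF",
              beta = "BETA", se = "SE", pval = "P", n = "N")
  dots <- c(...)
  schema[names(dots)] <- dots
  schema
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' The file must be UTF-8, tab-separated, with a header row. Missing
#' `eaf` or `n` are encoded as `NA`. Rows violating the row invariants
#' (see [as_sumstats()]) are rejected with a warning reporting the count;
#' a file yielding zero valid rows is an error, as is a duplicated
#' variant identifier.
#'
#' @param path Path to the TSV file.
#' @param schema Column mapping from [sumstats_schema()].
#' @inheritParams as_sumstats
#' @return An `mr_sumstats` tibble.
#' @export
read_sumstats <- function(path, schema = sumstats_schema(),
                          trait_id = "trait", trait_type = "microbe_taxon") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = "NA", progress = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("mapped columns absent from header: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  mapped <- raw[unname(schema)]
  names(mapped) <- names(schema)
  as_sumstats(mapped, trait_id = trait_id, trait_type = trait_type)
}

#' Write summary statistics as TSV
#'
#' Inverse of [read_sumstats()] under the default schema; numeric values
#' round-trip to at least 6 significant digits.
#'
#' @param stats An `mr_sumstats` tibble (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  out <- as_tibble(stats)
  names(out) <- unname(sumstats_schema())[match(names(out),
                                                names(sumstats_schema()))]
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write an MR results table as TSV
#'
#' One row per (exposure, outcome, direction, profile, method) with the
#' causal estimate, its standard error, 95% confidence bounds, raw and
#' FDR-adjusted p-values, the number of instruments and diagnostic
#' columns — the layout of a published MR results table.
#'
#' @param results A non-empty results tibble such as produced by
#'   [run_bidirectional()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    abort("results table is empty; nothing to write")
  }
  readr::write_tsv(as_tibble(results), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_tsv(path, na = "NA", progress = FALSE,
                  show_col_types = FALSE)
}
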