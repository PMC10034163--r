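#' Variant annotation catalogs
#'
#' A local, file-based stand-in for online variant annotation services:
#' per-variant trait associations (for confounder screening), eQTL and
#' regulatory-annotation flags (for cis-pQTL filtering) and reference
#' allele frequencies (for frequency supplementation). Stored long: one
#' row per (variant, trait association), so a variant may span several
#' rows; the flag and frequency columns must agree within a variant.
#'
#' File columns: `SNP`, `TRAIT`, `P`, `IS_EQTL`, `REGULOME_ANNOTATED`,
#' `EAF_REF`, and optionally `EAF_ALLELE` (the allele `EAF_REF` refers
#' to; when absent the frequency is assumed to be on the effect allele
#' of whatever summary statistics it is matched against).
#'
#' @param x A data frame with columns `variant_id`, `trait`, `pval`,
#'   `is_eqtl`, `regulome_annotated`, `eaf_ref` and optionally
#'   `eaf_allele`.
#' @return A tibble of class `mr_catalog`.
#' @export
as_catalog <- function(x) {
  x <- as_tibble(x)
  required <- c("variant_id", "trait", "pval", "is_eqtl",
                "regulome_annotated", "eaf_ref")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing catalog columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"eaf_allele" %in% names(x)) x$eaf_allele <- NA_character_
  x$variant_id <- as.character(x$variant_id)
  x$trait <- as.character(x$trait)
  x$pval <- as.numeric(x$pval)
  x$is_eqtl <- as.logical(x$is_eqtl)
  x$regulome_annotated <- as.logical(x$regulome_annotated)
  x$eaf_ref <- as.numeric(x$eaf_ref)
  x$eaf_allele <- toupper(as.character(x$eaf_allele))
  bad_p <- !is.na(x$pval) & (x$pval <= 0 | x$pval > 1)
  if (any(bad_p)) abort("catalog p-values must lie in (0, 1]")
  structure(x, class = c("mr_catalog", class(x)))
}

#' @rdname as_catalog
#' @param path Path to the catalog TSV.
#' @export
read_annotation_catalog <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, na = "NA", progress = FALSE,
                         show_col_types = FALSE)
  schema <- c(variant_id = "SNP", trait = "TRAIT", pval = "P",
              is_eqtl = "IS_EQTL", regulome_annotated = "REGULOME_ANNOTATED",
              eaf_ref = "EAF_REF")
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("mapped columns absent from header: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- raw[unname(schema)]
  names(out) <- names(schema)
  if ("EAF_ALLELE" %in% names(raw)) out$eaf_allele <- raw$EAF_ALLELE
  as_catalog(out)
}
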