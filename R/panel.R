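#' Reference genotype panels for LD computation
#'
#' A reference panel supplies genotypes (0/1/2 copies of one allele per
#' individual) from which pairwise linkage disequilibrium is estimated
#' during clumping, standing in for an external haplotype reference such
#' as the 1000 Genomes European panel. `as_panel()` builds one from a
#' variants-by-individuals matrix; `read_reference_panel()` reads the
#' TSV interchange format (columns `SNP`, `CHR`, `POS`, then one 0/1/2
#' column per individual). Monomorphic variants (no variation across
#' individuals) are flagged but retained; their LD with anything is
#' undefined and treated as zero.
#'
#' @param genotypes Integer matrix, variants in rows (rownames =
#'   variant ids), individuals in columns; entries 0, 1 or 2, no missing
#'   values.
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos`
#'   matching the matrix rows.
#' @return An object of class `mr_panel`: a list with elements
#'   `genotypes` and `variants` (the latter gains a `monomorphic` flag).
#' @export
as_panel <- function(genotypes, variants) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% c(0, 1, 2))) {
    abort("panel genotypes must be coded 0/1/2 with no missing values")
  }
  variants <- as_tibble(variants)
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)),
            nrow(variants) == nrow(genotypes))
  rownames(genotypes) <- variants$variant_id
  variants$monomorphic <- unname(apply(genotypes, 1,
                                       function(g) length(unique(g)) == 1))
  structure(list(genotypes = genotypes, variants = variants),
            class = "mr_panel")
}

#' @export
print.mr_panel <- function(x, ...) {
  cat(sprintf("<mr_panel> %d variants x %d individuals (%d monomorphic)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$variants$monomorphic)))
  invisible(x)
}

#' @rdname as_panel
#' @param path Path to the panel TSV.
#' @export
read_reference_panel <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  if (!all(c("SNP", "CHR", "POS") %in% names(raw)[1:3])) {
    abort("panel file must start with columns SNP, CHR, POS")
  }
  geno_cols <- setdiff(names(raw), c("SNP", "CHR", "POS"))
  if (length(geno_cols) == 0) abort("panel file has no genotype columns")
  geno <- as.matrix(raw[geno_cols])
  if (anyNA(geno) || !all(geno %in% c(0, 1, 2))) {
    abort("panel genotypes must be coded 0/1/2 with no missing values")
  }
  as_panel(geno, tibble(variant_id = as.character(raw$SNP),
                        chrom = as.character(raw$CHR),
                        pos = as.integer(raw$POS)))
}

#' Write a reference panel in the TSV interchange format
#' @param panel An `mr_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_panel <- function(panel, path) {
  out <- dplyr::bind_cols(
    tibble(SNP = panel$variants$variant_id,
           CHR = panel$variants$chrom,
           POS = panel$variants$pos),
    as_tibble(panel$genotypes, .name_repair = ~ paste0("IND", seq_along(.x)))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Squared Pearson correlation of 0/1/2 genotype codes between two panel
# variants; 0 when either is monomorphic (no LD information).
panel_r2 <- function(panel, id1, id2) {
  g1 <- panel$genotypes[id1, ]
  g2 <- panel$genotypes[id2, ]
  if (sd(g1) == 0 || sd(g2) == 0) return(0)
  cor(g1, g2)^2
}
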