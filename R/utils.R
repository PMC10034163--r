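# Internal helpers shared across modules.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_alleles <- function(x) {
  unname(DNA_COMPLEMENT[x])
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Two-sided normal p-value for an estimate and its standard error
#' @noRd
normal_pval <- function(beta, se) {
  2 * pnorm(-abs(beta / se))
}

# Run `code` under a temporary RNG state seeded with `seed`; when `seed`
# is NULL the current stream is used (and advanced).
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (allow_na && length(x) == 1 && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
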