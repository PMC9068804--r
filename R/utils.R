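# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_sl <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "spliceLesion_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

# Normalize Unicode minus (U+2212) to ASCII hyphen.
norm_minus <- function(x) gsub("−", "-", x, fixed = TRUE)

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a DNA string in frame 1
#'
#' Trailing bases that do not complete a codon are ignored.  Returns the full
#' amino-acid string including any internal or terminal `*` stop characters.
#' @noRd
translate_dna <- function(x) {
  n <- nchar(x)
  n <- n - n %% 3L
  if (n < 3L) return("")
  aa <- Biostrings::translate(Biostrings::DNAString(substr(x, 1L, n)),
                              no.init.codon = TRUE)
  as.character(aa)
}

# Translate up to (and excluding) the first stop codon; attribute "stop_codon"
# gives the 1-based nucleotide position of the first stop, or NA if none.
translate_orf <- function(x) {
  aa <- translate_dna(x)
  stop_at <- as.integer(regexpr("*", aa, fixed = TRUE))
  if (stop_at > 0L) {
    structure(substr(aa, 1L, stop_at - 1L), stop_codon = (stop_at - 1L) * 3L + 1L)
  } else {
    structure(aa, stop_codon = NA_integer_)
  }
}

# Round half away from zero to `digits` decimals (printed tables in this field
# use half-up rounding; base round() rounds half to even).
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == as.integer(x)
}
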