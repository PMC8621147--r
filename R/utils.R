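# Small sequence helpers shared across modules.

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

split_codons <- function(dna) {
  n <- nchar(dna)
  if (n %% 3L != 0L) abort("sequence length is not a multiple of 3")
  if (n == 0L) return(character(0))
  substring(dna, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

is_nt_string <- function(x) {
  nchar(x) > 0L && !grepl("[^ACGTN]", toupper(x))
}

check_nt <- function(x, allow_n = TRUE) {
  x <- toupper(x)
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  if (grepl(pat, x)) {
    bad <- unique(split_chars(gsub(if (allow_n) "[ACGTN]" else "[ACGT]", "", x)))
    abort(paste0("non-nucleotide characters in sequence: ",
                 paste(bad, collapse = ", ")))
  }
  x
}

check_aa <- function(x, allow_stop = FALSE, allow_x = TRUE) {
  x <- toupper(x)
  allowed <- paste0(paste(names(AA_AVG_MASS), collapse = ""),
                    if (allow_stop) "*" else "",
                    if (allow_x) "X" else "")
  pat <- paste0("[^", gsub("\\*", "\\\\*", allowed), "]")
  if (grepl(pat, x)) {
    abort("sequence contains characters outside the amino-acid alphabet")
  }
  x
}

reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# All start positions of `pattern` in `x` (overlapping, exact).
find_all_starts <- function(x, pattern) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(x)) return(integer(0))
  hits <- gregexpr(paste0("(?=", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", pattern), ")"),
                   x, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  sum(split_chars(a) != split_chars(b))
}

# named-vector lookup with a default for absent names
vec_get <- function(x, nm, default = 0L) {
  if (!is.null(names(x)) && nm %in% names(x)) x[[nm]] else default
}

new_interval <- function(start, end) {
  # empty intervals encoded as (NA, NA)
  if (is.na(start) || is.na(end) || end < start) c(start = NA_integer_, end = NA_integer_)
  else c(start = as.integer(start), end = as.integer(end))
}

interval_width <- function(iv) {
  if (any(is.na(iv))) 0L else iv[["end"]] - iv[["start"]] + 1L
}
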