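#' @keywords internal
"_PACKAGE"

#' @importFrom stats pt rnorm runif setNames cor phyper p.adjust sd
#' @importFrom utils head
NULL

# Internal error helper: all user-facing errors carry a class so callers (and
# the pipeline driver) can map them to exit conditions.
mp_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "mirpair_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

format_error <- function(fmt, ...) mp_stop("mirpair_format_error", fmt, ...)
config_error <- function(fmt, ...) mp_stop("mirpair_config_error", fmt, ...)

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. All sequence arithmetic in the package is
#' done in the RNA alphabet (A, C, G, U); DNA representations are re-derived
#' on demand.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector in the RNA alphabet.
#' @export
as_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of RNA sequences (A/C/G/U).
#' @return character vector of reverse complements, 5' to 3'.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGU", "UGCA", as_rna(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Split a sequence into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Watson-Crick or GU wobble pairing test for single bases (RNA alphabet).
is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

is_gu_pair <- function(a, b) {
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

can_pair <- function(a, b) is_wc_pair(a, b) | is_gu_pair(a, b)

# Deterministic float formatting used by every writer: 6 decimals, plain
# notation, so that write -> read round-trips are byte-stable.
fmt_num <- function(x) sprintf("%.6f", x)
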