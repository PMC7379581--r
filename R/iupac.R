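## IUPAC nucleotide ambiguity codes and set arithmetic shared by the
## in-silico PCR and primer-design modules. Inosine ('I') is not an IUPAC
## code; its pairing behaviour is mode-dependent and resolved at lookup time.

.DNA_BASES <- c("A", "C", "G", "T")

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", I = "I"
)

## code for a set of concrete bases, keyed by sorted concatenation
.SET_TO_CODE <- local({
  keys <- vapply(.IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(.IUPAC_SETS), keys)
})

.INOSINE_MODES <- c("as_N", "as_H")

#' Bases denoted by one primer letter
#'
#' @param code single IUPAC letter (or `"I"` for inosine).
#' @param inosine_mode `"as_N"` (inosine pairs with all four bases) or
#'   `"as_H"` (pairs with A, C and T only).
#' @return character vector of concrete bases.
#' @keywords internal
.iupac_bases <- function(code, inosine_mode = "as_N") {
  if (code == "I") {
    if (inosine_mode == "as_N") return(.DNA_BASES)
    return(c("A", "C", "T"))
  }
  set <- .IUPAC_SETS[[code]]
  if (is.null(set)) {
    stop("not an IUPAC nucleotide code: '", code, "'", call. = FALSE)
  }
  set
}

.check_inosine_mode <- function(inosine_mode) {
  match.arg(inosine_mode, .INOSINE_MODES)
}

.seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

## encode a template sequence as integers 1..4 (A,C,G,T); anything else
## (N, ambiguity codes, gaps) becomes 5 and never matches a primer
.encode_dna <- function(x) {
  code <- match(.seq_chars(x), .DNA_BASES)
  code[is.na(code)] <- 5L
  code
}

## 5 x L logical matrix: allowed[b, j] is TRUE when template base b may pair
## with primer position j. Row 5 (non-ACGT template characters) is all FALSE.
.allowed_matrix <- function(primer_seq, inosine_mode = "as_N",
                            complement = FALSE, reverse = FALSE) {
  chars <- .seq_chars(primer_seq)
  sets <- lapply(chars, .iupac_bases, inosine_mode = inosine_mode)
  if (complement) {
    sets <- lapply(sets, function(b) unname(.IUPAC_COMPLEMENT[b]))
  }
  if (reverse) sets <- rev(sets)
  m <- matrix(FALSE, nrow = 5L, ncol = length(sets))
  for (j in seq_along(sets)) {
    m[match(sets[[j]], .DNA_BASES), j] <- TRUE
  }
  m
}

#' Expand a degenerate primer into all concrete sequences
#'
#' Enumerates every oligonucleotide denoted by an IUPAC-degenerate primer.
#' Inosine expands according to the pairing mode in force.
#'
#' @param x primer sequence (IUPAC letters, optionally `"I"`).
#' @param inosine_mode inosine pairing mode, see [.iupac_bases()].
#' @param max_expansions guard against runaway enumeration.
#' @return character vector of concrete sequences over A/C/G/T.
#' @examples
#' expand_iupac("ACRT")
#' @export
expand_iupac <- function(x, inosine_mode = c("as_N", "as_H"),
                         max_expansions = 1e6) {
  inosine_mode <- match.arg(inosine_mode)
  sets <- lapply(.seq_chars(x), .iupac_bases, inosine_mode = inosine_mode)
  n <- prod(lengths(sets))
  if (n > max_expansions) {
    stop("primer expands to ", n, " sequences (> max_expansions)",
         call. = FALSE)
  }
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  unname(apply(grid, 1L, paste, collapse = ""))
}

#' Reverse complement of an IUPAC (primer) sequence
#'
#' Unlike a plain DNA reverse complement this maps every ambiguity code to
#' the code of the complemented base set (R <-> Y, B <-> V, ...); inosine is
#' carried through unchanged.
#'
#' @param x sequence over IUPAC letters plus `"I"`.
#' @return reverse-complemented sequence, written 5'->3'.
#' @examples
#' revcomp_iupac("ACRT")  # "AYGT"
#' @export
revcomp_iupac <- function(x) {
  chars <- .seq_chars(x)
  comp <- .IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) {
    stop("not an IUPAC nucleotide sequence: '", x, "'", call. = FALSE)
  }
  paste(rev(unname(comp)), collapse = "")
}

## plain DNA reverse complement for templates (IUPAC-aware via Biostrings)
.revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## IUPAC code for a set of concrete bases
.code_for_set <- function(bases) {
  code <- .SET_TO_CODE[[paste(sort(unique(bases)), collapse = "")]]
  if (is.null(code)) stop("invalid base set", call. = FALSE)
  code
}
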