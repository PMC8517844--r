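# Internal sequence helpers shared across modules.
#
# Sequences are plain character strings over A/C/G/T/N. Hot paths work on
# integer matrices (one column per sequence, utf8 codes) so that mismatch
# counting is vectorised. N never counts as a mismatch and never votes in
# a consensus.

DNA_BASES <- c("A", "C", "G", "T")
DNA_CODE <- c(A = 65L, C = 67L, G = 71L, T = 84L, N = 78L)
STOP_CODONS <- c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Equal-length strings -> L x n integer matrix (utf8 codes).
#' @noRd
seqs_to_mat <- function(x) {
  stopifnot(length(x) > 0L)
  L <- nchar(x[[1L]])
  vapply(x, utf8ToInt, integer(L), USE.NAMES = FALSE)
}

# Hamming distance of every column of mat (L x n) to the integer vector ref,
# ignoring masked rows and N on either side. `check_n = FALSE` skips the N
# handling when the caller knows neither side contains N.
#' @noRd
col_hamming <- function(mat, ref, mask = NULL, check_n = TRUE) {
  d <- mat != ref
  if (check_n) {
    d <- d & (mat != DNA_CODE[["N"]]) & (ref != DNA_CODE[["N"]])
  }
  if (!is.null(mask) && any(mask)) d[mask, ] <- FALSE
  colSums(d)
}

#' @noRd
allele_name <- function(gene, allele) paste0(gene, "*", allele)

# "IGKV1-8*01_T31C" -> list(gene = "IGKV1-8", allele = "01_T31C")
#' @noRd
split_allele_name <- function(name) {
  gene <- sub("\\*.*$", "", name)
  allele <- sub("^[^*]*\\*", "", name)
  list(gene = gene, allele = allele)
}

#' @noRd
gene_of <- function(name) sub("\\*.*$", "", name)

# First in-frame stop codon of `seq` translated from 1-based offset `from`
# (the A of the initiator ATG). Returns the 1-based codon index, or NA when
# no complete codon is a stop.
#' @noRd
first_stop_codon <- function(seq, from) {
  coding <- substr(seq, from, nchar(seq))
  n_codon <- nchar(coding) %/% 3L
  if (n_codon == 0L) return(NA_integer_)
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(coding, starts, starts + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit) == 0L) NA_integer_ else hit[[1L]]
}

#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
assert_fraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    stop(sprintf("`%s` must be a fraction in %s, got %s",
                 name, if (open) "(0, 1)" else "[0, 1]",
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x == trunc(x) && (if (positive) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(as.integer(x))
}
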