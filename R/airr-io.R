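# data model: germline allele tables, AIRR Rearrangement TSV and FASTA I/O.
#
# Conventions. Rearrangement tables are tibbles with AIRR-style columns;
# v_call/j_call hold comma-delimited allele names ("IGKV1E-12*01,IGKV1E-12*02")
# as the AIRR standard writes them; split_calls() turns them into lists.
# Internal coordinates are 0-based half-open (v_region_start is the offset of
# the V-REGION within sequence); user-facing variant labels are 1-based on the
# ungapped reference allele ("T31C" counts from position 1 of the V-REGION).

#' Construct a germline allele table
#'
#' A germline reference is a tibble with one row per allele. `gene_name` and
#' `allele_id` follow IMGT-style naming (`"IGKV1-8"`, `"01"`); novel alleles
#' get suffixed ids such as `"01_T31C"`. `extended_5p_len`/`extended_3p_len`
#' count terminal bases synthesised by consensus extension (see
#' [extend_short_alleles()]); `collapsed_from` records the original
#' gene*allele names merged into a collapsed allele (comma-delimited, empty
#' string if none).
#'
#' @param gene_name,allele_id,sequence Character vectors of equal length.
#' @param locus,segment Optional; derived from `gene_name` when missing.
#' @param extended_5p_len,extended_3p_len Integer vectors, default 0.
#' @param collapsed_from Character vector, default `""`.
#' @param functional Logical vector, default `TRUE`.
#' @return A tibble of class `germline_set`.
#' @export
#' @examples
#' germline_alleles(c("IGKV1-8", "IGKV1-8"), c("01", "02"),
#'                  c("ACGTACGT", "ACGTACGA"))
germline_alleles <- function(gene_name, allele_id, sequence,
                             locus = NULL, segment = NULL,
                             extended_5p_len = 0L, extended_3p_len = 0L,
                             collapsed_from = "", functional = TRUE) {
  n <- length(gene_name)
  out <- tibble(
    gene_name = as.character(gene_name),
    allele_id = as.character(allele_id),
    name = allele_name(gene_name, allele_id),
    locus = if (is.null(locus)) substr(gene_name, 1L, 3L) else rep_len(locus, n),
    segment = if (is.null(segment)) substr(gene_name, 4L, 4L) else rep_len(segment, n),
    sequence = toupper(as.character(sequence)),
    extended_5p_len = rep_len(as.integer(extended_5p_len), n),
    extended_3p_len = rep_len(as.integer(extended_3p_len), n),
    collapsed_from = rep_len(as.character(collapsed_from), n),
    functional = rep_len(as.logical(functional), n)
  )
  validate_germline(out)
}

#' @noRd
validate_germline <- function(alleles) {
  stopifnot(is.data.frame(alleles))
  if (nrow(alleles) == 0L) return(structure(as_tibble(alleles), class = c("germline_set", class(as_tibble(alleles)))))
  if (any(!nzchar(alleles$sequence))) {
    stop("germline sequences must be non-empty", call. = FALSE)
  }
  if (any(grepl("[^ACGTRYSWKMBDHVN]", alleles$sequence))) {
    stop("germline sequences may only contain IUPAC DNA symbols", call. = FALSE)
  }
  bad <- alleles$extended_5p_len + alleles$extended_3p_len >= nchar(alleles$sequence)
  if (any(bad)) {
    stop("extension lengths must be shorter than the allele: ",
         paste(alleles$name[bad], collapse = ", "), call. = FALSE)
  }
  merged <- nzchar(alleles$collapsed_from)
  if (any(merged & !grepl("E", alleles$gene_name))) {
    stop("collapsed alleles must carry the 'E' marker in gene_name",
         call. = FALSE)
  }
  if (anyDuplicated(alleles$name)) {
    stop("duplicate allele names: ",
         paste(unique(alleles$name[duplicated(alleles$name)]), collapse = ", "),
         call. = FALSE)
  }
  cls <- unique(c("germline_set", class(as_tibble(alleles))))
  structure(as_tibble(alleles), class = cls)
}

#' Read an AIRR Rearrangement table
#'
#' Reads a tab-separated AIRR Rearrangement file. The header must contain at
#' least `sequence_id`, `sequence`, `v_call` and `j_call`; a missing
#' mandatory column is a format error naming the column. Optional columns
#' (`individual_id`, `v_mutation_count`, `v_region_start`) are carried
#' through when present and default to `NA` ("uncomputed") otherwise. An
#' empty file (header only) yields an empty table.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per rearrangement.
#' @seealso [write_airr()], [split_calls()]
#' @export
read_airr <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  required <- c("sequence_id", "sequence", "v_call", "j_call")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("AIRR format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- as_tibble(df)
  if (!"individual_id" %in% names(out)) out$individual_id <- NA_character_
  out$v_mutation_count <- if ("v_mutation_count" %in% names(df)) {
    suppressWarnings(as.integer(df$v_mutation_count))
  } else NA_integer_
  out$v_region_start <- if ("v_region_start" %in% names(df)) {
    suppressWarnings(as.integer(df$v_region_start))
  } else NA_integer_
  out
}

#' Write an AIRR Rearrangement table
#'
#' @param reads A rearrangement tibble (as returned by [read_airr()],
#'   [make_repertoire()] or [assign_calls()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(reads, path) {
  stopifnot(is.data.frame(reads))
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Split comma-delimited allele calls
#'
#' AIRR tables store ambiguous calls as comma-delimited strings; this turns
#' a `v_call`/`j_call` column into a list of character vectors.
#'
#' @param calls Character vector of comma-delimited allele names.
#' @return A list of character vectors (empty for `NA` input).
#' @export
#' @examples
#' split_calls("IGKV1E-12*01,IGKV1E-12*02")
split_calls <- function(calls) {
  out <- strsplit(as.character(calls), ",", fixed = TRUE)
  out[is.na(calls)] <- list(character(0))
  out
}

#' Write germline alleles to FASTA
#'
#' Headers are `gene_name*allele_id`; sequences are wrapped at 60 columns.
#' Duplicate allele names are an error.
#'
#' @param alleles A germline allele table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alleles, path) {
  dup <- alleles$name[duplicated(alleles$name)]
  if (length(dup) > 0L) {
    stop("duplicate allele names: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  set <- Biostrings::DNAStringSet(setNames(alleles$sequence, alleles$name))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read germline alleles from FASTA
#'
#' Headers must be `gene_name*allele_id` (anything after the first
#' whitespace is ignored). Provenance fields (`extended_*`,
#' `collapsed_from`) are initialised empty; use [prepare_reference()] to
#' fill them.
#'
#' @param path Path to a FASTA file.
#' @return A germline allele tibble.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    return(germline_alleles(character(0), character(0), character(0)))
  }
  nm <- sub("\\s.*$", "", names(set))
  parts <- split_allele_name(nm)
  germline_alleles(parts$gene, parts$allele, as.character(set))
}
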