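# reference_prep: turn a raw germline reference into the analysis reference.
#
# Two transformations, in the order they are applied:
#  1. collapse_duplicates(): duplicated genes (large duplications in the
#     kappa locus produce gene pairs with identical sequences) that share at
#     least one identical allele are merged into one "E"-marked gene, so the
#     annotator never has to guess which duplicate a sequence came from.
#  2. extend_short_alleles(): reference alleles truncated at the 5'/3' ends
#     cause length-driven misannotation; every allele is brought to its
#     gene's maximal extent with a position-wise consensus over the gene's
#     other alleles. Extended spans are flagged and later suppressed from
#     candidate reporting (they are synthetic bases).

#' Collapse duplicated genes that share an identical allele
#'
#' Genes are grouped by the relation "share at least one identical allele
#' sequence", closed transitively. Each group of two or more genes is
#' renamed by inserting `E` after the family token (`IGKV1-12` +
#' `IGKV1D-12` become `IGKV1E-12`); identical sequences within a group are
#' deduplicated to a single allele, and distinct sequences are renumbered
#' consecutively from `01`, ordered by (original gene name, original allele
#' id). `collapsed_from` records the provenance of every merged allele.
#' Collapsing never changes a sequence, only names and multiplicity, and is
#' idempotent. Only genes of the same locus and segment are ever grouped.
#'
#' @param alleles A germline allele table with ungapped sequences.
#' @return A list with `alleles` (the collapsed table) and `report`
#'   (a tibble `old_gene`, `old_allele`, `new_gene`, `new_allele`).
#' @export
#' @examples
#' ref <- germline_alleles(c("IGKV1-12", "IGKV1D-12"), c("01", "01"),
#'                         c("ACGTACGTAC", "ACGTACGTAC"))
#' collapse_duplicates(ref)$alleles$name
collapse_duplicates <- function(alleles) {
  alleles <- validate_germline(alleles)
  n <- nrow(alleles)
  if (n == 0L) {
    return(list(alleles = alleles,
                report = tibble(old_gene = character(0), old_allele = character(0),
                                new_gene = character(0), new_allele = character(0))))
  }

  # union-find over genes; genes sharing an identical sequence are unioned
  genes <- unique(alleles$gene_name)
  parent <- setNames(seq_along(genes), genes)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  key <- paste(alleles$locus, alleles$segment, alleles$sequence, sep = "|")
  for (grp in split(match(alleles$gene_name, genes), key)) {
    grp <- unique(grp)
    if (length(grp) > 1L) {
      roots <- vapply(grp, find, integer(1))
      parent[roots] <- min(roots)
    }
  }
  root <- vapply(match(alleles$gene_name, genes), find, integer(1))

  report <- list()
  keep <- list()
  for (r in unique(root)) {
    idx <- which(root == r)
    members <- alleles[idx, , drop = FALSE]
    if (length(unique(members$gene_name)) == 1L) {
      keep[[length(keep) + 1L]] <- members
      next
    }
    new_gene <- merged_gene_name(unique(members$gene_name))
    ord <- order(members$gene_name, members$allele_id)
    members <- members[ord, , drop = FALSE]
    seq_first <- !duplicated(members$sequence)
    new_id <- sprintf("%02d", match(members$sequence, unique(members$sequence)))
    prov <- vapply(split(members$name, new_id),
                   function(x) paste(sort(x), collapse = ","), character(1))
    merged <- members[seq_first, , drop = FALSE]
    ids <- sprintf("%02d", seq_len(nrow(merged)))
    merged$gene_name <- new_gene
    merged$allele_id <- ids
    merged$name <- allele_name(new_gene, ids)
    merged$collapsed_from <- unname(prov[ids])
    keep[[length(keep) + 1L]] <- merged
    report[[length(report) + 1L]] <- tibble(
      old_gene = gene_of(members$name), old_allele = sub("^[^*]*\\*", "", members$name),
      new_gene = new_gene, new_allele = new_id
    )
  }
  out <- bind_rows(keep)
  out <- out[order(out$segment, out$gene_name, out$allele_id), , drop = FALSE]
  list(alleles = validate_germline(out),
       report = if (length(report) > 0L) bind_rows(report) else
         tibble(old_gene = character(0), old_allele = character(0),
                new_gene = character(0), new_allele = character(0)))
}

# IGKV1-12 + IGKV1D-12 -> IGKV1E-12: the "E" is inserted after the family
# token, before the hyphenated position. Falls back to tagging the first
# member when names do not share a family/position decomposition.
#' @noRd
merged_gene_name <- function(gene_names) {
  m <- regmatches(gene_names,
                  regexec("^((?:IG|TR)[A-Z][VJ][0-9]+)([A-Z]*)-(.+)$", gene_names))
  ok <- lengths(m) == 4L
  if (all(ok)) {
    fam <- unique(vapply(m, `[[`, character(1), 2L))
    pos <- unique(vapply(m, `[[`, character(1), 4L))
    if (length(fam) == 1L && length(pos) == 1L) {
      return(paste0(fam, "E-", pos))
    }
  }
  base <- sort(gene_names)[[1L]]
  if (grepl("-", base, fixed = TRUE)) {
    sub("-", "E-", base)
  } else {
    paste0(base, "E")
  }
}

#' Consensus-extend truncated reference alleles
#'
#' Brings every allele of a gene to the gene's maximal length. Each short
#' allele is end-anchored at the offset that minimises mismatches against
#' the position-wise majority of the gene's full-length alleles (ties break
#' toward the smaller offset); missing terminal bases are then filled with
#' the position-wise majority base over the gene's other alleles covering
#' that position, ties breaking to the base contributed by the
#' lowest-numbered covering allele. `extended_5p_len`/`extended_3p_len`
#' record the filled spans; non-extended positions are byte-identical to
#' the input.
#'
#' @param alleles A germline allele table (typically after
#'   [collapse_duplicates()]). Every gene must have at least one allele
#'   spanning its maximal extent.
#' @return The extended allele table.
#' @export
extend_short_alleles <- function(alleles) {
  alleles <- validate_germline(alleles)
  if (nrow(alleles) == 0L) return(alleles)
  parts <- split(seq_len(nrow(alleles)), alleles$gene_name)
  for (idx in parts) {
    lens <- nchar(alleles$sequence[idx])
    lmax <- max(lens)
    if (all(lens == lmax)) next
    full <- idx[lens == lmax]
    if (length(full) == 0L) {
      stop("cannot extend gene ", alleles$gene_name[idx[1L]],
           ": no allele spans its maximal extent", call. = FALSE)
    }
    mats <- lapply(alleles$sequence[idx], utf8ToInt)
    full_mat <- do.call(cbind, mats[lens == lmax])
    anchor_profile <- apply(full_mat, 1L, function(r) {
      tb <- table(r[r != DNA_CODE[["N"]]])
      if (length(tb) == 0L) DNA_CODE[["N"]] else as.integer(names(tb)[which.max(tb)])
    })
    # placement of every allele within the gene span (full alleles at 0)
    offs <- integer(length(idx))
    for (k in seq_along(idx)) {
      L <- lens[[k]]
      if (L == lmax) next
      cand <- 0:(lmax - L)
      score <- vapply(cand, function(o) {
        sum(mats[[k]] != anchor_profile[(o + 1L):(o + L)])
      }, numeric(1))
      offs[[k]] <- cand[[which.min(score)]]
    }
    for (k in seq_along(idx)) {
      L <- lens[[k]]
      if (L == lmax) next
      o <- offs[[k]]
      filled <- integer(lmax)
      filled[(o + 1L):(o + L)] <- mats[[k]]
      for (p in setdiff(seq_len(lmax), (o + 1L):(o + L))) {
        votes <- integer(0)
        voters <- character(0)
        for (j in seq_along(idx)) {
          if (j == k) next
          oj <- offs[[j]]
          if (p > oj && p <= oj + lens[[j]]) {
            b <- mats[[j]][[p - oj]]
            if (b != DNA_CODE[["N"]]) {
              votes <- c(votes, b)
              voters <- c(voters, alleles$allele_id[idx[[j]]])
            }
          }
        }
        if (length(votes) == 0L) {
          stop("cannot extend ", alleles$name[idx[[k]]],
               ": position ", p, " is covered by no other allele", call. = FALSE)
        }
        tb <- table(votes)
        best <- as.integer(names(tb)[tb == max(tb)])
        if (length(best) == 1L) {
          filled[[p]] <- best
        } else {
          ord <- order(voters)
          filled[[p]] <- votes[ord][votes[ord] %in% best][[1L]]
        }
      }
      alleles$sequence[idx[[k]]] <- intToUtf8(filled)
      alleles$extended_5p_len[idx[[k]]] <- o
      alleles$extended_3p_len[idx[[k]]] <- lmax - L - o
    }
  }
  validate_germline(alleles)
}

#' Prepare an analysis reference
#'
#' Runs [collapse_duplicates()] then [extend_short_alleles()].
#'
#' @param alleles A raw germline allele table.
#' @return A list with `alleles` and the collapse `report`.
#' @export
prepare_reference <- function(alleles) {
  col <- collapse_duplicates(alleles)
  list(alleles = extend_short_alleles(col$alleles), report = col$report)
}

#' Write a collapse report as TSV
#'
#' @param report The `report` component of [collapse_duplicates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collapse_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
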