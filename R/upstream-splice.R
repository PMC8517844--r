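# upstream_splice: cluster upstream sequences (5'UTR + L-PART1 + L-PART2)
# per allele, build consensus variants, and classify alternative splicing.
#
# All upstream sequences are anchored at their 3' (V-proximal) end, because
# every read is trimmed at the V-REGION start; comparisons, trimming and
# suffix matching against the genomic model all respect that anchor.
# Intron retention is matched only as an intron *prefix* adjacent to the
# donor site; a retention that shifts the leader reading frame typically
# introduces a premature termination codon (PTC).

#' Extract upstream sequences per individual and allele
#'
#' Takes the portion of each read before the V-REGION, grouped by
#' individual and unambiguous `v_call`; ambiguous calls and empty
#' upstream portions are dropped.
#'
#' @param reads Annotated rearrangements with `v_region_start`.
#' @return A tibble `individual_id`, `allele`, `upstream` (one row per
#'   read).
#' @export
extract_upstream <- function(reads) {
  keep <- !is.na(reads$v_call) & !grepl(",", reads$v_call, fixed = TRUE) &
    !is.na(reads$v_region_start) & reads$v_region_start > 0L
  rr <- reads[keep, , drop = FALSE]
  up <- substr(rr$sequence, 1L, rr$v_region_start)
  nz <- nzchar(up)
  tibble(individual_id = rr$individual_id[nz], allele = rr$v_call[nz],
         upstream = up[nz])
}

#' Filter upstream length classes
#'
#' Length classes with relative frequency below `min_freq` are removed
#' (short, incompletely sequenced 5'UTRs); survivors are trimmed at the 5'
#' end to the shortest surviving length so all share one coordinate
#' system anchored at the V-REGION start.
#'
#' @param seqs Character vector of upstream sequences (one group).
#' @param min_freq Minimum relative frequency of a length class.
#' @return The filtered, trimmed character vector (possibly empty).
#' @export
length_filter <- function(seqs, min_freq = 0.05) {
  if (length(seqs) == 0L) return(character(0))
  lens <- nchar(seqs)
  tb <- table(lens) / length(seqs)
  keep_lens <- as.integer(names(tb)[tb >= min_freq])
  if (length(keep_lens) == 0L) return(character(0))
  s <- seqs[lens %in% keep_lens]
  m <- min(keep_lens)
  substr(s, nchar(s) - m + 1L, nchar(s))
}

#' Cluster upstream sequences and build consensus
#'
#' Single-linkage clustering where two sequences are linked when their
#' identity over the 3'-anchored overlap is at least `ident` and the
#' overlap covers at least `length_cov` of the shorter sequence. Per
#' cluster, the position-wise consensus keeps the majority base when its
#' frequency (among covering, non-N bases) reaches `cons_freq` and writes
#' N otherwise. Clusters with within-group frequency below `min_freq` or
#' fewer than `min_size` sequences are discarded. Output order is fixed
#' (size descending, then consensus lexicographically), so the pipeline
#' is deterministic.
#'
#' @param seqs Character vector (one individual x allele group, after
#'   [length_filter()]).
#' @param ident,length_cov,cons_freq,min_freq,min_size Thresholds; see
#'   [cohort_config()].
#' @return A tibble `consensus`, `size`, `freq`.
#' @export
cluster_and_consensus <- function(seqs, ident = 0.999, length_cov = 0.5,
                                  cons_freq = 0.6, min_freq = 0.01,
                                  min_size = 5L) {
  if (length(seqs) == 0L) {
    return(tibble(consensus = character(0), size = integer(0), freq = numeric(0)))
  }
  total <- length(seqs)
  tb <- table(seqs)
  uniq <- names(tb)
  counts <- as.integer(tb)
  nu <- length(uniq)
  mats <- lapply(uniq, utf8ToInt)
  lens <- nchar(uniq)

  parent <- seq_len(nu)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  if (nu > 1L) {
    for (i in 1:(nu - 1L)) {
      for (j in (i + 1L):nu) {
        ov <- min(lens[[i]], lens[[j]])
        if (ov < length_cov * min(lens[[i]], lens[[j]])) next
        a <- mats[[i]][(lens[[i]] - ov + 1L):lens[[i]]]
        b <- mats[[j]][(lens[[j]] - ov + 1L):lens[[j]]]
        same <- a == b | a == DNA_CODE[["N"]] | b == DNA_CODE[["N"]]
        if (sum(same) / ov >= ident) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[[max(ri, rj)]] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(nu), find, integer(1))

  out <- list()
  for (r in unique(root)) {
    members <- which(root == r)
    size <- sum(counts[members])
    freq <- size / total
    if (freq < min_freq || size < min_size) next
    lmax <- max(lens[members])
    cons <- integer(lmax)
    for (p in seq_len(lmax)) {
      votes <- numeric(0)
      for (m in members) {
        q <- lens[[m]] - lmax + p
        if (q >= 1L) {
          b <- mats[[m]][[q]]
          if (b != DNA_CODE[["N"]]) {
            votes <- c(votes, setNames(counts[[m]], b))
          }
        }
      }
      if (length(votes) == 0L) {
        cons[[p]] <- DNA_CODE[["N"]]
      } else {
        agg <- tapply(votes, names(votes), sum)
        best <- which.max(agg)
        cons[[p]] <- if (agg[[best]] / sum(agg) >= cons_freq) {
          as.integer(names(agg)[[best]])
        } else DNA_CODE[["N"]]
      }
    }
    out[[length(out) + 1L]] <- tibble(consensus = intToUtf8(cons),
                                      size = size, freq = freq)
  }
  if (length(out) == 0L) {
    return(tibble(consensus = character(0), size = integer(0), freq = numeric(0)))
  }
  out <- bind_rows(out)
  out[order(-out$size, out$consensus), , drop = FALSE]
}

#' Collapse per-individual consensus variants across the cohort
#'
#' Exact-identity collapse: per allele, identical consensus sequences from
#' different individuals become one cohort variant, counting the number of
#' individuals and the fraction of the allele's sequences they represent.
#'
#' @param variants A tibble `individual_id`, `allele`, `consensus`,
#'   `size` (per-individual clusters).
#' @param allele_totals Named numeric vector: total upstream sequences per
#'   allele across the cohort (denominator of `cohort_fraction`).
#' @return A tibble `allele`, `consensus_seq`, `n_individuals`,
#'   `cohort_fraction`.
#' @export
collapse_cohort <- function(variants, allele_totals) {
  if (nrow(variants) == 0L) {
    return(tibble(allele = character(0), consensus_seq = character(0),
                  n_individuals = integer(0), cohort_fraction = numeric(0)))
  }
  key <- paste0(variants$allele, "|", variants$consensus)
  out <- lapply(split(seq_len(nrow(variants)), key), function(ii) {
    al <- variants$allele[[ii[[1L]]]]
    tibble(allele = al,
           consensus_seq = variants$consensus[[ii[[1L]]]],
           n_individuals = length(unique(variants$individual_id[ii])),
           cohort_fraction = sum(variants$size[ii]) / allele_totals[[al]])
  })
  out <- bind_rows(out)
  out[order(out$allele, -out$cohort_fraction), , drop = FALSE]
}

# does `cons` equal the 3'-anchored suffix of `model` (N in the consensus
# matches anything)?
#' @noRd
suffix_matches <- function(cons, model) {
  lc <- nchar(cons)
  lm <- nchar(model)
  if (lc > lm) return(FALSE)
  a <- utf8ToInt(cons)
  b <- utf8ToInt(substr(model, lm - lc + 1L, lm))
  all(a == b | a == DNA_CODE[["N"]] | b == DNA_CODE[["N"]])
}

#' Classify splice structure of cohort upstream variants
#'
#' A variant is *canonical* when its consensus equals the (3'-anchored)
#' spliced exon + L-PART2 junction of its gene model, and
#' *intron_retained* when it matches the model with a prefix of the intron
#' (length `retained_len >= 1`) inserted between the exon end and L-PART2;
#' the smallest matching prefix is reported. For retained variants the
#' full retained transcript is translated from the leader ATG and
#' `ptc_codon_index` records the 1-based codon index of the first stop, if
#' any. Variants matching neither model are reported `unclassified` with
#' the first mismatching position against the canonical model; variants of
#' genes without a model are left unclassified with a notice.
#'
#' @param variants A [collapse_cohort()] result.
#' @param genomic A genomic V-gene table (`gene_name`, `utr5_exon`,
#'   `intron`, `lpart2`, `leader_start_offset`).
#' @return `variants` with `splice_class`, `retained_len`,
#'   `ptc_codon_index` and `note` columns added.
#' @export
classify_splice <- function(variants, genomic) {
  n <- nrow(variants)
  variants$splice_class <- rep("unclassified", n)
  variants$retained_len <- rep(0L, n)
  variants$ptc_codon_index <- rep(NA_integer_, n)
  variants$note <- rep(NA_character_, n)
  for (r in seq_len(n)) {
    gene <- gene_of(variants$allele[[r]])
    gi <- which(genomic$gene_name == gene)
    if (length(gi) != 1L) {
      message("no genomic model for ", gene, "; variant left unclassified")
      variants$note[[r]] <- "missing_gene_model"
      next
    }
    gm <- genomic[gi, ]
    cons <- variants$consensus_seq[[r]]
    canonical <- paste0(gm$utr5_exon, gm$lpart2)
    if (suffix_matches(cons, canonical)) {
      variants$splice_class[[r]] <- "canonical"
      next
    }
    matched <- FALSE
    for (ret in seq_len(nchar(gm$intron))) {
      model <- paste0(gm$utr5_exon, substr(gm$intron, 1L, ret), gm$lpart2)
      if (suffix_matches(cons, model)) {
        variants$splice_class[[r]] <- "intron_retained"
        variants$retained_len[[r]] <- ret
        variants$ptc_codon_index[[r]] <-
          first_stop_codon(model, gm$leader_start_offset + 1L)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      a <- utf8ToInt(cons)
      lc <- length(a)
      lm <- nchar(canonical)
      b <- utf8ToInt(substr(canonical, max(1L, lm - lc + 1L), lm))
      if (length(a) == length(b)) {
        d <- which(a != b & a != DNA_CODE[["N"]])
        variants$note[[r]] <- paste0("mismatch_at_", if (length(d)) d[[1L]] else NA)
      } else {
        variants$note[[r]] <- "length_mismatch"
      }
    }
  }
  variants
}

#' Infer cohort upstream variants
#'
#' Full upstream pipeline: [extract_upstream()], per-(individual, allele)
#' [length_filter()] and [cluster_and_consensus()], cohort-level
#' [collapse_cohort()] and [classify_splice()].
#'
#' @param reads Annotated rearrangements.
#' @param genomic Genomic V-gene table (see [classify_splice()]).
#' @param cfg A [cohort_config()].
#' @return A classified cohort variant tibble (see [classify_splice()]).
#' @export
infer_upstream_variants <- function(reads, genomic, cfg = cohort_config()) {
  cfg <- as_cohort_config(cfg)
  up <- extract_upstream(reads)
  if (nrow(up) == 0L) {
    return(classify_splice(collapse_cohort(
      tibble(individual_id = character(0), allele = character(0),
             consensus = character(0), size = integer(0)), numeric(0)), genomic))
  }
  totals <- table(up$allele)
  groups <- split(up$upstream, paste0(up$individual_id, "|", up$allele))
  rows <- list()
  for (key in names(groups)) {
    filtered <- length_filter(groups[[key]], cfg$upstream_len_class_min_freq)
    if (length(filtered) == 0L) {
      message("upstream group ", key, " empty after length filtering; dropped")
      next
    }
    cl <- cluster_and_consensus(filtered,
                                ident = cfg$upstream_ident,
                                length_cov = cfg$upstream_length_cov,
                                cons_freq = cfg$upstream_cons_freq,
                                min_freq = cfg$upstream_min_cluster_freq,
                                min_size = cfg$upstream_min_cluster_size)
    if (nrow(cl) == 0L) next
    cl$individual_id <- sub("\\|.*$", "", key)
    cl$allele <- sub("^[^|]*\\|", "", key)
    rows[[length(rows) + 1L]] <- cl
  }
  variants <- if (length(rows)) bind_rows(rows) else
    tibble(individual_id = character(0), allele = character(0),
           consensus = character(0), size = integer(0))
  cohort <- collapse_cohort(variants,
                            setNames(as.numeric(totals), names(totals)))
  classify_splice(cohort, genomic)
}
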