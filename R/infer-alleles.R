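# infer_alleles: the core computation.
#
# For every (individual, allele) pair the package tallies, position by
# position, the bases observed across all sequences annotated to that
# allele (fractionally for ambiguous calls). A novel-allele candidate is a
# (base allele, position, ref -> alt) hypothesis whose per-individual
# mismatch frequency -- the fraction of an individual's sequences carrying
# alt at the position -- reaches the candidate floor in someone. True
# germline polymorphisms produce a multimodal cohort pattern (carriers
# cluster near 0.5 or 1.0, non-carriers near 0); MiSeq-style artefacts
# produce a sub-cutoff "stack" shared by everyone. The 0.25 cutoff admits
# equal expression of up to four variants of one gene.

#' Build per-individual mismatch profiles
#'
#' Takes all annotated sequences of each individual, applies the depth
#' floor (individuals with fewer sequences are excluded with a warning)
#' and the naive filter (`v_mutation_count < max_v_mutations`), and counts
#' the observed base at every V-REGION position for every assigned allele.
#' A k-way ambiguous call contributes 1/k of a sequence to each of its
#' alleles. N bases are never counted.
#'
#' @param reads Annotated rearrangements (see [assign_calls()]).
#' @param reference The prepared germline allele table.
#' @param cfg A [cohort_config()].
#' @return An object of class `profile_set`: a list of profiles keyed
#'   `individual|allele`, each holding a 4 x L base-count matrix (rows
#'   A/C/G/T), the per-position `depth`, and `n_assigned` (the summed
#'   fractional sequence count).
#' @export
build_profiles <- function(reads, reference, cfg = cohort_config()) {
  cfg <- as_cohort_config(cfg)
  reference <- validate_germline(reference)
  keep <- !is.na(reads$v_call)
  per_ind <- table(reads$individual_id[keep])
  low <- names(per_ind)[per_ind < cfg$min_sequences_per_individual]
  if (length(low) > 0L) {
    warning("excluding individual(s) below the sequence floor: ",
            paste(low, collapse = ", "), call. = FALSE)
  }
  keep <- keep & !(reads$individual_id %in% low) &
    !is.na(reads$v_mutation_count) &
    reads$v_mutation_count < cfg$max_v_mutations
  reads <- reads[keep, , drop = FALSE]

  calls <- split_calls(reads$v_call)
  k <- lengths(calls)
  ridx <- rep.int(seq_len(nrow(reads)), k)
  allele <- unlist(calls, use.names = FALSE)
  w <- rep.int(1 / k, k)

  len_of <- setNames(nchar(reference$sequence), reference$name)
  unknown <- setdiff(unique(allele), names(len_of))
  if (length(unknown) > 0L) {
    stop("annotated calls not found in reference: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  profiles <- list()
  grp_key <- paste0(reads$individual_id[ridx], "|", allele)
  for (g in split(seq_along(ridx), grp_key)) {
    al <- allele[[g[[1L]]]]
    ind <- reads$individual_id[[ridx[[g[[1L]]]]]]
    L <- len_of[[al]]
    rr <- ridx[g]
    win <- substr(reads$sequence[rr], reads$v_region_start[rr] + 1L,
                  reads$v_region_start[rr] + L)
    # short windows are N-padded on the right: N never counts, so the
    # uncovered tail simply has zero depth
    short <- nchar(win) < L
    if (any(short)) {
      win[short] <- paste0(win[short], strrep("N", L - nchar(win[short])))
    }
    M <- seqs_to_mat(win)
    ww <- w[g]
    counts <- matrix(0, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
    for (b in DNA_BASES) {
      counts[b, ] <- as.numeric((M == DNA_CODE[[b]]) %*% ww)
    }
    profiles[[paste0(ind, "|", al)]] <- list(
      individual_id = ind, allele = al, counts = counts,
      depth = colSums(counts), n_assigned = sum(ww)
    )
  }
  structure(list(profiles = profiles, reference = reference, cfg = cfg),
            class = "profile_set")
}

#' Extract one profile from a profile set
#'
#' @param profiles A [build_profiles()] result.
#' @param individual_id,allele Profile key.
#' @return The profile, or `NULL` if the pair has no assigned sequences.
#' @export
get_profile <- function(profiles, individual_id, allele) {
  stopifnot(inherits(profiles, "profile_set"))
  profiles$profiles[[paste0(individual_id, "|", allele)]]
}

#' Mismatch frequency at a position
#'
#' The fraction of an individual's sequences (assigned to one allele)
#' carrying `alt_base` at a 1-based V-REGION position. 1.00 corresponds to
#' a homozygous carrier, about 0.50 to a balanced heterozygote, 0.00 to a
#' non-carrier. Undefined (zero depth) is reported as `NA`, not 0.
#'
#' @param profile One profile (see [get_profile()]).
#' @param position 1-based position on the ungapped reference allele.
#' @param alt_base One of A/C/G/T.
#' @return A fraction in \[0, 1\], or `NA` at zero depth.
#' @export
mismatch_frequency <- function(profile, position, alt_base) {
  stopifnot(is.list(profile), alt_base %in% DNA_BASES)
  d <- profile$depth[[position]]
  if (is.na(d) || d == 0) return(NA_real_)
  unname(profile$counts[alt_base, position] / d)
}

#' Classify a cohort mismatch-frequency pattern
#'
#' Deterministic surrogate for the visual multimodal / stack-like
#' judgement. With `S` the defined frequencies above the noise floor,
#' sorted ascending: *multimodal* when someone reaches the mismatch cutoff
#' and the gap separating sub-cutoff from supra-cutoff members of
#' `{0} U S` is at least `multimodal_gap`; *stack-like* when all of `S`
#' sits below the cutoff within a span smaller than `multimodal_gap`;
#' otherwise (or with fewer than 3 defined frequencies) *indeterminate*.
#'
#' @param freqs Named numeric vector of per-individual mismatch
#'   frequencies (`NA` = undefined).
#' @param cfg A [cohort_config()].
#' @return One of `"multimodal"`, `"stack_like"`, `"indeterminate"`.
#' @export
classify_pattern <- function(freqs, cfg = cohort_config()) {
  cfg <- as_cohort_config(cfg)
  freqs <- freqs[!is.na(freqs)]
  if (length(freqs) < 3L) return("indeterminate")
  S <- sort(freqs[freqs > cfg$noise_floor])
  if (length(S) == 0L) return("indeterminate")
  if (max(S) >= cfg$mismatch_cutoff) {
    v <- c(0, S)
    i <- which(v[-length(v)] < cfg$mismatch_cutoff &
                 v[-1L] >= cfg$mismatch_cutoff)
    if (length(i) == 1L && v[[i + 1L]] - v[[i]] >= cfg$multimodal_gap) {
      return("multimodal")
    }
    return("indeterminate")
  }
  if (max(S) - min(S) < cfg$multimodal_gap) return("stack_like")
  "indeterminate"
}

#' Detect novel-allele candidates
#'
#' Emits a candidate for every (allele, position, alt) whose mismatch
#' frequency reaches the candidate floor in at least one individual
#' (default cutoff/2, so borderline artefact positions are classified and
#' rejected with a reason rather than silently missed). Positions inside
#' consensus-extended reference spans are suppressed. Per gene, at most
#' `max_novel_per_gene` candidates are retained, ranked by cohort support
#' (ties to the lower position).
#'
#' @param profiles A [build_profiles()] result.
#' @param cfg A [cohort_config()].
#' @return A tibble with one row per candidate: `gene_name`,
#'   `base_allele`, `position` (1-based), `ref`, `alt`, `label`
#'   (`"IGKV1-8*01_T31C"` style), `support_count`, `pattern`, `flag_ac`,
#'   `flag_repeat`, `passes_cutoff` and a `per_individual_freq`
#'   list-column.
#' @export
detect_candidates <- function(profiles, cfg = NULL) {
  stopifnot(inherits(profiles, "profile_set"))
  cfg <- as_cohort_config(cfg %||% profiles$cfg)
  ref <- profiles$reference
  by_allele <- split(profiles$profiles,
                     vapply(profiles$profiles, `[[`, character(1), "allele"))

  rows <- list()
  for (al in names(by_allele)) {
    i <- match(al, ref$name)
    if (is.na(i) || ref$segment[[i]] != "V") next
    rseq <- utf8ToInt(ref$sequence[[i]])
    L <- length(rseq)
    e5 <- ref$extended_5p_len[[i]]
    e3 <- ref$extended_3p_len[[i]]
    ok_pos <- seq_len(L) > e5 & seq_len(L) <= L - e3
    prof <- by_allele[[al]]
    inds <- vapply(prof, `[[`, character(1), "individual_id")
    depth <- vapply(prof, `[[`, numeric(L), "depth")  # L x n_ind
    if (is.null(dim(depth))) depth <- matrix(depth, ncol = length(prof))
    for (b in DNA_BASES) {
      cnt <- vapply(prof, function(p) p$counts[b, ], numeric(L))
      if (is.null(dim(cnt))) cnt <- matrix(cnt, ncol = length(prof))
      fr <- cnt / depth
      fr[depth < cfg$min_candidate_depth] <- NA_real_
      cand_pos <- which(ok_pos & rseq != DNA_CODE[[b]] &
                          apply(fr, 1L, max, na.rm = TRUE) >= cfg$candidate_floor)
      for (p in cand_pos) {
        freqs <- setNames(fr[p, ], inds)
        ref_b <- intToUtf8(rseq[[p]])
        flag_repeat <- p > 1L && p < L &&
          rseq[[p - 1L]] == DNA_CODE[[b]] && rseq[[p + 1L]] == DNA_CODE[[b]]
        rows[[length(rows) + 1L]] <- tibble(
          gene_name = ref$gene_name[[i]],
          base_allele = al,
          position = p,
          ref = ref_b,
          alt = b,
          label = paste0(al, "_", ref_b, p, b),
          support_count = sum(cnt[p, ]),
          pattern = classify_pattern(freqs, cfg),
          flag_ac = ref_b == "A" && b == "C",
          flag_repeat = flag_repeat,
          passes_cutoff = any(freqs >= cfg$mismatch_cutoff, na.rm = TRUE),
          per_individual_freq = list(freqs)
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(gene_name = character(0), base_allele = character(0),
                  position = integer(0), ref = character(0), alt = character(0),
                  label = character(0), support_count = numeric(0),
                  pattern = character(0), flag_ac = logical(0),
                  flag_repeat = logical(0), passes_cutoff = logical(0),
                  per_individual_freq = list()))
  }
  out <- bind_rows(rows)
  out <- out[order(out$gene_name, -out$support_count, out$position), ]
  kept <- unlist(lapply(split(seq_len(nrow(out)), out$gene_name), function(ii) {
    ii[seq_len(min(length(ii), cfg$max_novel_per_gene))]
  }), use.names = FALSE)
  out[sort(kept), , drop = FALSE]
}

#' Filter candidates by cutoff and pattern
#'
#' A candidate is accepted when at least one individual reaches the
#' mismatch cutoff and the cohort pattern is not stack-like. The A>C and
#' repeat-motif flags annotate but never reject on their own (flagged
#' candidates have been validated as real). Rejected candidates carry a
#' reason (`below_cutoff` or `stack_like`).
#'
#' @param candidates A [detect_candidates()] result.
#' @param cfg A [cohort_config()] (kept for interface symmetry).
#' @return A list with `accepted` and `rejected` tibbles (the latter with
#'   a `reason` column).
#' @export
filter_candidates <- function(candidates, cfg = cohort_config()) {
  ok <- candidates$passes_cutoff & candidates$pattern != "stack_like"
  rejected <- candidates[!ok, , drop = FALSE]
  rejected$reason <- ifelse(rejected$pattern == "stack_like", "stack_like",
                            "below_cutoff")
  list(accepted = candidates[ok, , drop = FALSE], rejected = rejected)
}

#' Infer per-individual genotypes
#'
#' For each individual and gene, includes every allele (known, plus
#' accepted novel variants) whose expression share among the gene's
#' sequences reaches the mismatch cutoff, at most 4 per gene, ranked by
#' share. A novel variant's share is measured by its diagnostic alternate
#' base within the base allele's profile.
#'
#' @param profiles A [build_profiles()] result.
#' @param accepted The `accepted` tibble from [filter_candidates()].
#' @param cfg A [cohort_config()].
#' @return A tibble `individual_id`, `gene_name`, `alleles`
#'   (comma-delimited allele ids ranked by share), with list-columns
#'   `allele_ids` and `shares`.
#' @export
infer_genotype <- function(profiles, accepted, cfg = NULL) {
  stopifnot(inherits(profiles, "profile_set"))
  cfg <- as_cohort_config(cfg %||% profiles$cfg)
  prof <- profiles$profiles
  if (length(prof) == 0L) {
    return(tibble(individual_id = character(0), gene_name = character(0),
                  alleles = character(0), allele_ids = list(), shares = list()))
  }
  tab <- tibble(
    individual_id = vapply(prof, `[[`, character(1), "individual_id"),
    allele = vapply(prof, `[[`, character(1), "allele"),
    weight = vapply(prof, `[[`, numeric(1), "n_assigned")
  )
  tab$gene_name <- gene_of(tab$allele)
  tab$allele_id <- sub("^[^*]*\\*", "", tab$allele)

  # split novel variants out of their base allele by diagnostic-base count
  extra <- list()
  for (r in seq_len(nrow(accepted))) {
    base <- accepted$base_allele[[r]]
    p <- accepted$position[[r]]
    alt <- accepted$alt[[r]]
    novel_id <- paste0(sub("^[^*]*\\*", "", base), "_",
                       accepted$ref[[r]], p, alt)
    hit <- which(tab$allele == base)
    for (i in hit) {
      pr <- prof[[paste0(tab$individual_id[[i]], "|", base)]]
      nv <- pr$counts[alt, p]
      if (nv <= 0) next
      tab$weight[[i]] <- tab$weight[[i]] - nv
      extra[[length(extra) + 1L]] <- tibble(
        individual_id = tab$individual_id[[i]], allele = paste0(base, "_x"),
        weight = nv, gene_name = tab$gene_name[[i]], allele_id = novel_id
      )
    }
  }
  tab <- bind_rows(tab, if (length(extra)) bind_rows(extra))

  out <- list()
  for (g in split(seq_len(nrow(tab)),
                  paste0(tab$individual_id, "|", tab$gene_name))) {
    total <- sum(tab$weight[g])
    if (total <= 0) next
    share <- tab$weight[g] / total
    keep <- which(share >= cfg$mismatch_cutoff)
    if (length(keep) == 0L) next
    keep <- keep[order(-share[keep])]
    keep <- keep[seq_len(min(4L, length(keep)))]
    out[[length(out) + 1L]] <- tibble(
      individual_id = tab$individual_id[[g[[1L]]]],
      gene_name = tab$gene_name[[g[[1L]]]],
      alleles = paste(tab$allele_id[g][keep], collapse = ","),
      allele_ids = list(tab$allele_id[g][keep]),
      shares = list(share[keep])
    )
  }
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(individual_id = character(0), gene_name = character(0),
                  alleles = character(0), allele_ids = list(), shares = list()))
  }
  out[order(out$individual_id, out$gene_name), , drop = FALSE]
}

#' Long-format candidate frequency table
#'
#' One row per (candidate, individual), convenient for strip charts of
#' per-individual mismatch frequencies.
#'
#' @param candidates A [detect_candidates()] result.
#' @return A tibble `label`, `individual_id`, `freq`.
#' @export
candidate_frequency_table <- function(candidates) {
  bind_rows(lapply(seq_len(nrow(candidates)), function(r) {
    f <- candidates$per_individual_freq[[r]]
    tibble(label = candidates$label[[r]], individual_id = names(f),
           freq = unname(f))
  }))
}
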