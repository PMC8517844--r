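# usage_haplotype: relative gene usage, the binomial double-deletion test
# with Benjamini-Hochberg correction, J-anchored haplotype inference with
# Bayes-factor single-deletion calls, and allele-bias summaries.
#
# Double deletions show up as individuals whose relative usage of a gene
# sits far below the cohort; the binomial test asks how surprising the
# observed count X out of N sequences is under the lowest "normal" usage P
# of that gene. Single deletions are invisible in usage but visible in
# linkage: in an individual heterozygous at the anchor J gene, every V
# allele pairs with both anchor alleles unless it sits on one chromosome
# only.

#' Relative gene usage per individual
#'
#' Computes per-individual, per-gene usage fractions for V and J segments
#' independently. Individuals below the sequence floor are omitted; the
#' naive filter (`v_mutation_count < max_v_mutations`) is applied; a read
#' ambiguous between k genes contributes 1/k to each. Fractions per
#' individual and segment sum to 1.
#'
#' @param reads Annotated rearrangements.
#' @param cfg A [cohort_config()].
#' @return A tibble `individual_id`, `segment`, `gene_name`,
#'   `assigned_count`, `total_count`, `fraction`.
#' @export
relative_usage <- function(reads, cfg = cohort_config()) {
  cfg <- as_cohort_config(cfg)
  keep <- !is.na(reads$v_call) & !is.na(reads$j_call)
  per_ind <- table(reads$individual_id[keep])
  low <- names(per_ind)[per_ind < cfg$min_sequences_per_individual]
  keep <- keep & !(reads$individual_id %in% low) &
    !is.na(reads$v_mutation_count) &
    reads$v_mutation_count < cfg$max_v_mutations
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0L) {
    return(tibble(individual_id = character(0), segment = character(0),
                  gene_name = character(0), assigned_count = numeric(0),
                  total_count = integer(0), fraction = numeric(0)))
  }

  tally <- function(call_col, segment) {
    calls <- split_calls(reads[[call_col]])
    genes <- lapply(calls, function(x) unique(gene_of(x)))
    k <- lengths(genes)
    df <- data.frame(individual_id = rep.int(reads$individual_id, k),
                     gene_name = unlist(genes, use.names = FALSE),
                     w = rep.int(1 / k, k))
    agg <- stats::aggregate(w ~ individual_id + gene_name, data = df, FUN = sum)
    tot <- table(reads$individual_id)
    tibble(individual_id = agg$individual_id, segment = segment,
           gene_name = agg$gene_name, assigned_count = agg$w,
           total_count = as.integer(tot[agg$individual_id]),
           fraction = agg$w / as.integer(tot[agg$individual_id]))
  }
  out <- bind_rows(tally("v_call", "V"), tally("j_call", "J"))
  out[order(out$segment, out$gene_name, out$individual_id), , drop = FALSE]
}

#' Binomial test for double chromosome deletions
#'
#' For each gene, the test frequency P is the lowest relative usage among
#' individuals above the segment floor (0.001 for V, 0.005 for J) that are
#' not themselves flagged as deleted; since that set is circular on the
#' first pass, the test is iterated once: preliminary calls are made with
#' P from all above-floor individuals, then P is recomputed excluding the
#' preliminarily deleted and the test repeated. Each individual's p-value
#' is the one-sided binomial tail Pr(count <= X | N, P) with X the floored
#' assigned count and N the individual's total; p-values are
#' Benjamini-Hochberg adjusted across all tests and a gene is called
#' deleted at adjusted p below the significance level. Genes whose cohort
#' mean usage is below the segment floor are undetermined (`unknown`).
#'
#' @param usage A [relative_usage()] result.
#' @param cfg A [cohort_config()].
#' @return A tibble `individual_id`, `gene_name`, `segment`, `x`, `n`,
#'   `p_used`, `p_value`, `p_adjusted`, `call`
#'   (deleted/present/unknown).
#' @export
deletion_test <- function(usage, cfg = cohort_config()) {
  cfg <- as_cohort_config(cfg)
  res <- list()
  for (seg in unique(usage$segment)) {
    u <- usage[usage$segment == seg, , drop = FALSE]
    floor_f <- if (seg == "V") cfg$v_usage_floor else cfg$j_usage_floor
    inds <- unique(u$individual_id)
    totals <- setNames(u$total_count[match(inds, u$individual_id)], inds)
    for (g in unique(u$gene_name)) {
      ug <- u[u$gene_name == g, , drop = FALSE]
      frac <- setNames(rep(0, length(inds)), inds)
      cnt <- frac
      frac[ug$individual_id] <- ug$fraction
      cnt[ug$individual_id] <- ug$assigned_count
      row <- tibble(individual_id = inds, gene_name = g, segment = seg,
                    x = as.integer(floor(cnt)), n = as.integer(totals[inds]),
                    p_used = NA_real_, p_value = NA_real_,
                    p_adjusted = NA_real_, call = "unknown",
                    fraction = unname(frac))
      if (mean(frac) >= floor_f && any(frac > floor_f)) {
        row$call <- "testable"
        row$p_used <- min(frac[frac > floor_f])
      }
      res[[length(res) + 1L]] <- row
    }
  }
  res <- bind_rows(res)
  testable <- res$call == "testable"
  if (any(testable)) {
    # pass 1: preliminary calls with P from all above-floor individuals
    p1 <- pbinom(res$x[testable], res$n[testable], res$p_used[testable])
    prelim <- p.adjust(p1, method = "BH") < cfg$significance
    flagged <- paste0(res$gene_name, "|", res$individual_id)[testable][prelim]
    # pass 2: recompute P excluding preliminarily deleted individuals
    for (key in unique(paste0(res$segment, "|", res$gene_name)[testable])) {
      seg <- sub("\\|.*$", "", key)
      g <- sub("^[^|]*\\|", "", key)
      sel <- which(res$segment == seg & res$gene_name == g)
      floor_f <- if (seg == "V") cfg$v_usage_floor else cfg$j_usage_floor
      ok <- res$fraction[sel] > floor_f &
        !(paste0(res$gene_name[sel], "|", res$individual_id[sel]) %in% flagged)
      if (any(ok)) res$p_used[sel] <- min(res$fraction[sel][ok])
    }
    res$p_value[testable] <- pbinom(res$x[testable], res$n[testable],
                                    res$p_used[testable])
    res$p_adjusted[testable] <- p.adjust(res$p_value[testable], method = "BH")
    res$call[testable] <- ifelse(res$p_adjusted[testable] < cfg$significance,
                                 "deleted", "present")
  }
  res$fraction <- NULL
  res
}

# Bayes factor for "allele on one chromosome only (with leak rate eps)"
# against "allele on both chromosomes (balanced binomial)", with a uniform
# prior over which chromosome. Computed in log space.
#' @noRd
haplotype_bayes_factor <- function(k1, k2, eps) {
  n <- k1 + k2
  if (n == 0L) return(1)
  l1 <- dbinom(k1, n, 1 - eps, log = TRUE)
  l2 <- dbinom(k1, n, eps, log = TRUE)
  exp(log_sum_exp(c(l1, l2)) - log(2) - dbinom(k1, n, 0.5, log = TRUE))
}

#' Infer anchored haplotypes and single-chromosome deletions
#'
#' Individuals heterozygous at the anchor J gene (minor-allele ratio at
#' least `het_min_ratio`, the 30:70 rule) have their V alleles assigned to
#' chromosomes by linkage: for each V allele, k1/k2 count unambiguous
#' sequences pairing it with anchor allele 1/2 (chromosome 1 carries the
#' lexicographically lower anchor allele). The Bayes factor of
#' [haplotype_bayes_factor()] assigns the allele to one chromosome when
#' BF exceeds the threshold, to both when 1/BF exceeds it, and leaves it
#' unknown otherwise. A chromosome carrying no allele of a gene, with
#' every allele of that gene assigned to the other chromosome above the
#' threshold, is called single-chromosome deleted.
#'
#' @param reads Annotated rearrangements.
#' @param cfg A [cohort_config()].
#' @param anchor_gene Anchor J gene name; when `NULL`, the J gene
#'   heterozygous in most individuals is used.
#' @return A list with `assignments` (per individual x V allele: `k1`,
#'   `k2`, `bayes_factor`, `assignment`), `gene_calls` (per individual x
#'   gene: `chrom1_call`/`chrom2_call` in present/deleted/unknown with
#'   `min_bf`), and `anchor` (per-individual anchor alleles and ratio).
#' @export
infer_haplotype <- function(reads, cfg = cohort_config(), anchor_gene = NULL) {
  cfg <- as_cohort_config(cfg)
  keep <- !is.na(reads$v_call) & !is.na(reads$j_call) &
    !grepl(",", reads$v_call, fixed = TRUE) &
    !grepl(",", reads$j_call, fixed = TRUE) &
    !is.na(reads$v_mutation_count) &
    reads$v_mutation_count < cfg$max_v_mutations
  reads <- reads[keep, , drop = FALSE]
  reads$j_gene <- gene_of(reads$j_call)

  inds <- unique(reads$individual_id)
  # anchor auto-selection: the J gene with most 30:70 heterozygotes
  if (is.null(anchor_gene)) {
    het_count <- vapply(unique(reads$j_gene), function(g) {
      sum(vapply(inds, function(ind) {
        tb <- sort(table(reads$j_call[reads$individual_id == ind &
                                        reads$j_gene == g]), decreasing = TRUE)
        length(tb) >= 2L && tb[[2L]] / (tb[[1L]] + tb[[2L]]) >= cfg$het_min_ratio
      }, logical(1)))
    }, numeric(1))
    if (all(het_count == 0)) {
      stop("no heterozygous anchor J gene found", call. = FALSE)
    }
    anchor_gene <- names(het_count)[which.max(het_count)]
  }

  assignments <- list()
  gene_calls <- list()
  anchor_rows <- list()
  for (ind in inds) {
    ri <- reads[reads$individual_id == ind, , drop = FALSE]
    tb <- sort(table(ri$j_call[ri$j_gene == anchor_gene]), decreasing = TRUE)
    if (length(tb) < 2L) {
      message("skipping ", ind, ": not heterozygous at ", anchor_gene)
      next
    }
    ratio <- tb[[2L]] / (tb[[1L]] + tb[[2L]])
    if (ratio < cfg$het_min_ratio) {
      message("skipping ", ind, ": anchor ratio ", signif(ratio, 3),
              " below ", cfg$het_min_ratio)
      next
    }
    anchors <- sort(names(tb)[1:2])
    anchor_rows[[length(anchor_rows) + 1L]] <-
      tibble(individual_id = ind, anchor_gene = anchor_gene,
             anchor_allele_1 = anchors[[1L]], anchor_allele_2 = anchors[[2L]],
             ratio = ratio)
    linked <- ri[ri$j_call %in% anchors, , drop = FALSE]
    for (v in unique(linked$v_call)) {
      k1 <- sum(linked$v_call == v & linked$j_call == anchors[[1L]])
      k2 <- sum(linked$v_call == v & linked$j_call == anchors[[2L]])
      bf <- haplotype_bayes_factor(k1, k2, cfg$leak_rate)
      assignment <- if (bf > cfg$bayes_factor_threshold) {
        if (k1 >= k2) "chrom1" else "chrom2"
      } else if (is.finite(bf) && 1 / bf > cfg$bayes_factor_threshold) {
        "both"
      } else "unknown"
      assignments[[length(assignments) + 1L]] <- tibble(
        individual_id = ind, gene_name = gene_of(v), allele = v,
        k1 = k1, k2 = k2, bayes_factor = bf, assignment = assignment
      )
    }
  }
  assignments <- if (length(assignments)) bind_rows(assignments) else
    tibble(individual_id = character(0), gene_name = character(0),
           allele = character(0), k1 = integer(0), k2 = integer(0),
           bayes_factor = numeric(0), assignment = character(0))

  groups <- if (nrow(assignments) > 0L) {
    split(seq_len(nrow(assignments)),
          paste0(assignments$individual_id, "|", assignments$gene_name))
  } else list()
  for (g in groups) {
    a <- assignments[g, , drop = FALSE]
    on1 <- any(a$assignment %in% c("chrom1", "both"))
    on2 <- any(a$assignment %in% c("chrom2", "both"))
    all_conf <- all(a$bayes_factor > cfg$bayes_factor_threshold |
                      (is.finite(a$bayes_factor) &
                         1 / a$bayes_factor > cfg$bayes_factor_threshold))
    chrom1_call <- if (on1) "present" else if (all_conf && on2) "deleted" else "unknown"
    chrom2_call <- if (on2) "present" else if (all_conf && on1) "deleted" else "unknown"
    gene_calls[[length(gene_calls) + 1L]] <- tibble(
      individual_id = a$individual_id[[1L]], gene_name = a$gene_name[[1L]],
      chrom1_call = chrom1_call, chrom2_call = chrom2_call,
      min_bf = min(a$bayes_factor)
    )
  }
  list(
    assignments = assignments,
    gene_calls = if (length(gene_calls)) bind_rows(gene_calls) else
      tibble(individual_id = character(0), gene_name = character(0),
             chrom1_call = character(0), chrom2_call = character(0),
             min_bf = numeric(0)),
    anchor = if (length(anchor_rows)) bind_rows(anchor_rows) else
      tibble(individual_id = character(0), anchor_gene = character(0),
             anchor_allele_1 = character(0), anchor_allele_2 = character(0),
             ratio = numeric(0))
  )
}

#' Allele-bias analysis for one gene
#'
#' Groups individuals by their genotype at a focal gene and summarises the
#' gene's relative usage per group (homozygotes for each allele,
#' heterozygote classes). For heterozygotes, within-individual allele
#' shares are additionally broken down by the J gene each sequence
#' recombined with: a germline-level expression bias shows the same
#' skewed share across all J partners.
#'
#' @param usage A [relative_usage()] result.
#' @param genotypes An [infer_genotype()] result.
#' @param reads Annotated rearrangements.
#' @param gene_name The focal gene.
#' @param cfg A [cohort_config()].
#' @return A list with `group_usage` (individual-level), `group_summary`
#'   and `het_shares` (per individual x J gene x allele).
#' @export
allele_bias <- function(usage, genotypes, reads, gene_name,
                        cfg = cohort_config()) {
  cfg <- as_cohort_config(cfg)
  gt <- genotypes[genotypes$gene_name == gene_name, , drop = FALSE]
  if (nrow(gt) == 0L) {
    stop("no genotypes available for ", gene_name, call. = FALSE)
  }
  gt$group <- vapply(gt$allele_ids, function(x) paste(sort(x), collapse = "_"),
                     character(1))
  ug <- usage[usage$segment == "V" & usage$gene_name == gene_name, , drop = FALSE]
  group_usage <- tibble(
    individual_id = gt$individual_id,
    group = gt$group,
    fraction = ug$fraction[match(gt$individual_id, ug$individual_id)]
  )
  group_usage <- group_usage[!is.na(group_usage$fraction), , drop = FALSE]
  gs <- split(group_usage$fraction, group_usage$group)
  group_summary <- tibble(
    group = names(gs),
    n_individuals = lengths(gs),
    mean_usage = vapply(gs, mean, numeric(1)),
    median_usage = vapply(gs, stats::median, numeric(1))
  )

  het <- gt$individual_id[lengths(gt$allele_ids) == 2L]
  keep <- reads$individual_id %in% het &
    !is.na(reads$v_call) & !is.na(reads$j_call) &
    !grepl(",", reads$v_call, fixed = TRUE) &
    gene_of(reads$v_call) == gene_name &
    !grepl(",", reads$j_call, fixed = TRUE)
  rr <- reads[keep, , drop = FALSE]
  het_shares <- if (nrow(rr) > 0L) {
    rr$j_gene <- gene_of(rr$j_call)
    rr$allele_id <- sub("^[^*]*\\*", "", rr$v_call)
    cnt <- stats::aggregate(rep(1L, nrow(rr)),
                            by = list(individual_id = rr$individual_id,
                                      j_gene = rr$j_gene,
                                      allele_id = rr$allele_id), FUN = sum)
    names(cnt)[[4L]] <- "count"
    tot <- stats::aggregate(cnt$count,
                            by = list(individual_id = cnt$individual_id,
                                      j_gene = cnt$j_gene), FUN = sum)
    names(tot)[[3L]] <- "total"
    m <- merge(cnt, tot)
    m$share <- m$count / m$total
    as_tibble(m[order(m$individual_id, m$j_gene, m$allele_id),
                c("individual_id", "j_gene", "allele_id", "count", "total",
                  "share")])
  } else {
    tibble(individual_id = character(0), j_gene = character(0),
           allele_id = character(0), count = integer(0), total = integer(0),
           share = numeric(0))
  }
  list(group_usage = group_usage, group_summary = group_summary,
       het_shares = het_shares)
}
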