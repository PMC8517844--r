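# Relative usage, binomial deletion test, anchored haplotypes, allele bias.

usage_reads <- function(v_calls, j_calls = "IGKJ1*01",
                        individual_id = "S001") {
  tibble::tibble(
    sequence_id = sprintf("%s_%05d", individual_id, seq_along(v_calls)),
    individual_id = individual_id,
    v_call = v_calls, j_call = rep_len(j_calls, length(v_calls)),
    v_mutation_count = 0L, v_region_start = 50L
  )
}

test_that("relative usage is the fractional per-gene share and conserves mass", {
  calls <- c(rep("IGKV1-1*01", 400), rep("IGKV2-2*01", 3599),
             "IGKV1-1*01,IGKV2-2*01")
  u <- relative_usage(usage_reads(calls), cohort_config())
  uv <- u[u$segment == "V", ]
  expect_equal(uv$fraction[uv$gene_name == "IGKV1-1"], 400.5 / 4000)
  expect_equal(uv$assigned_count[uv$gene_name == "IGKV2-2"], 3599.5)
  expect_equal(sum(uv$fraction), 1)
  expect_equal(sum(u$fraction[u$segment == "J"]), 1)
})

test_that("individuals below the sequence floor are omitted from usage", {
  few <- usage_reads(rep("IGKV1-1*01", 100), individual_id = "S_low")
  many <- usage_reads(rep("IGKV1-1*01", 2500))
  u <- relative_usage(rbind(few, many), cohort_config())
  expect_setequal(unique(u$individual_id), "S001")
})

# a usage table in the shape relative_usage() emits: two genes per
# individual, gene G at the given fractions, the remainder on gene H
usage_table <- function(fracs, n = 5000L) {
  inds <- sprintf("I%02d", seq_along(fracs))
  dplyr::bind_rows(
    tibble::tibble(individual_id = inds, segment = "V", gene_name = "IGKV1-1",
                   assigned_count = fracs * n, total_count = n,
                   fraction = fracs),
    tibble::tibble(individual_id = inds, segment = "V", gene_name = "IGKV2-2",
                   assigned_count = (1 - fracs) * n, total_count = n,
                   fraction = 1 - fracs)
  )
}

test_that("the deletion p-value equals the exact binomial tail", {
  fracs <- c(0, 0.004, seq(0.01, 0.18, length.out = 18))
  dt <- deletion_test(usage_table(fracs), cohort_config())
  g <- dt[dt$gene_name == "IGKV1-1", ]
  expect_equal(g$p_used[g$individual_id == "I01"], 0.004)
  p1 <- g$p_value[g$individual_id == "I01"]
  expect_equal(p1, (1 - 0.004)^5000, tolerance = 1e-12)
  expect_equal(p1, sum(dbinom(0, 5000, 0.004)), tolerance = 1e-12)
  expect_equal(g$call[g$individual_id == "I01"], "deleted")
  expect_lt(g$p_adjusted[g$individual_id == "I01"], 0.01)
  # the individual sitting exactly at P is unremarkable
  i2 <- g[g$individual_id == "I02", ]
  expect_gte(i2$p_value, 0.5)
  expect_equal(i2$call, "present")
  expect_true(all(g$p_adjusted >= g$p_value))
})

test_that("genes with cohort mean usage below the floor are undetermined", {
  low <- usage_table(rep(0.0005, 10))
  dt <- deletion_test(low, cohort_config())
  expect_true(all(dt$call[dt$gene_name == "IGKV1-1"] == "unknown"))
  expect_true(all(is.na(dt$p_value[dt$gene_name == "IGKV1-1"])))
  expect_true(all(dt$call[dt$gene_name == "IGKV2-2"] == "present"))
})

test_that("binomial tails agree with an exact summation oracle to 1e-12", {
  set.seed(8)
  for (N in c(10L, 250L, 2000L, 10000L)) {
    for (P in c(0.001, 0.004, 0.05, 0.3)) {
      X <- sort(unique(c(0L, sample(0:N, 5L), as.integer(round(N * P)))))
      expect_equal(pbinom(X, N, P),
                   vapply(X, function(x) sum(dbinom(0:x, N, P)), numeric(1)),
                   tolerance = 1e-12)
    }
  }
})

haplotype_reads <- function() {
  rows <- list(
    c("IGKV1-1*01", "IGKJ2*01", 60), c("IGKV1-1*01", "IGKJ2*02", 0),
    c("IGKV2-2*01", "IGKJ2*01", 30), c("IGKV2-2*01", "IGKJ2*02", 30),
    c("IGKV3-3*01", "IGKJ2*01", 3),  c("IGKV3-3*01", "IGKJ2*02", 1),
    c("IGKV4-4*01", "IGKJ2*01", 0),  c("IGKV4-4*01", "IGKJ2*02", 60)
  )
  do.call(rbind, lapply(rows, function(r) {
    usage_reads(rep(r[[1]], as.integer(r[[3]])), j_calls = r[[2]])
  }))
}

test_that("haplotype Bayes factors assign, share, or withhold chromosomes", {
  hap <- suppressMessages(infer_haplotype(haplotype_reads(), cohort_config(),
                                          anchor_gene = "IGKJ2"))
  a <- hap$assignments
  get <- function(v) a[a$allele == v, ]
  expect_equal(get("IGKV1-1*01")$assignment, "chrom1")
  expect_gt(get("IGKV1-1*01")$bayes_factor, 1000)
  expect_equal(get("IGKV4-4*01")$assignment, "chrom2")
  expect_equal(get("IGKV2-2*01")$assignment, "both")
  expect_gt(1 / get("IGKV2-2*01")$bayes_factor, 1000)
  expect_equal(get("IGKV3-3*01")$assignment, "unknown")
  # direct likelihood-ratio oracle at eps = 0.01
  bf_oracle <- function(k1, k2, eps = 0.01) {
    n <- k1 + k2
    (dbinom(k1, n, 1 - eps) + dbinom(k1, n, eps)) / 2 / dbinom(k1, n, 0.5)
  }
  expect_equal(get("IGKV3-3*01")$bayes_factor, bf_oracle(3, 1))
  expect_equal(get("IGKV1-1*01")$bayes_factor, bf_oracle(60, 0),
               tolerance = 1e-9)
  # single-chromosome deletion call for the fully one-sided genes
  gc <- hap$gene_calls
  expect_equal(gc$chrom2_call[gc$gene_name == "IGKV1-1"], "deleted")
  expect_equal(gc$chrom1_call[gc$gene_name == "IGKV4-4"], "deleted")
  expect_equal(gc$chrom1_call[gc$gene_name == "IGKV2-2"], "present")
  expect_equal(gc$chrom2_call[gc$gene_name == "IGKV2-2"], "present")
  expect_equal(gc$chrom1_call[gc$gene_name == "IGKV3-3"], "unknown")
})

test_that("haplotype assignments are insensitive to the leak rate", {
  base <- suppressMessages(infer_haplotype(haplotype_reads(),
                                           cohort_config(leak_rate = 0.01),
                                           anchor_gene = "IGKJ2"))
  for (eps in c(0.001, 0.005, 0.02, 0.05)) {
    alt <- suppressMessages(infer_haplotype(haplotype_reads(),
                                            cohort_config(leak_rate = eps),
                                            anchor_gene = "IGKJ2"))
    expect_identical(alt$assignments$assignment, base$assignments$assignment)
  }
})

test_that("individuals without a sufficiently heterozygous anchor are skipped", {
  reads <- usage_reads(rep("IGKV1-1*01", 100),
                       j_calls = c(rep("IGKJ2*01", 90), rep("IGKJ2*02", 10)))
  expect_message(
    hap <- infer_haplotype(reads, cohort_config(), anchor_gene = "IGKJ2"),
    "below 0.3")
  expect_equal(nrow(hap$assignments), 0L)
})

test_that("a planted expression bias is recovered in heterozygote allele shares", {
  sim <- shared_sim()
  cfg <- cohort_config()
  prof <- build_profiles(sim$ann, sim$prep$alleles, cfg)
  gt <- infer_genotype(prof, filter_candidates(detect_candidates(prof), cfg)$accepted, cfg)
  usage <- relative_usage(sim$ann, cfg)
  bias_gene <- sim$sim$truth$bias_gene
  bias <- allele_bias(usage, gt, sim$ann, bias_gene, cfg)
  het <- bias$het_shares[bias$het_shares$allele_id == "01", ]
  het <- het[het$total >= 20, ]
  expect_gt(nrow(het), 0L)
  # generator expresses allele 01 at 2x allele 02 in heterozygotes -> 2/3
  expect_lt(abs(mean(het$share) - 2 / 3), 0.08)
  # the bias is consistent across J partners
  by_j <- tapply(het$share, het$j_gene, mean)
  expect_true(all(abs(by_j - 2 / 3) < 0.15))
})
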