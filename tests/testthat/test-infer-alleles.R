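# Mismatch profiles, candidate detection, pattern classification, genotypes.

small_cfg <- function(...) {
  cohort_config(min_sequences_per_individual = 50L, ...)
}

# one-gene reference and pre-annotated reads for profile unit tests
profile_fixture_ref <- function() {
  set.seed(31)
  v <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  germline_alleles(c("IGKV6-3", "IGKJ1"), c("01", "01"),
                   c(v, "GGGTTTCCCAAA"))
}

annotated_reads <- function(windows, v_call, individual_id = "S001") {
  tibble::tibble(
    sequence_id = sprintf("r%05d", seq_along(windows)),
    individual_id = individual_id,
    sequence = windows,
    v_call = v_call,
    j_call = "IGKJ1*01",
    v_mutation_count = 0L,
    v_region_start = 0L
  )
}

test_that("profiles count germline and alternate bases exactly", {
  ref <- profile_fixture_ref()
  v <- ref$sequence[[1]]
  ref_base <- substr(v, 31, 31)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[[1]]

  reads <- annotated_reads(rep(v, 100), "IGKV6-3*01")
  prof <- build_profiles(reads, ref, small_cfg())
  p <- get_profile(prof, "S001", "IGKV6-3*01")
  expect_equal(unname(p$counts[ref_base, 31]), 100)
  expect_equal(sum(p$counts[, 31]), 100)
  expect_equal(unname(p$depth), rep(100, 40))

  v_alt <- substitute_at(v, 31, alt)
  reads2 <- annotated_reads(c(rep(v, 60), rep(v_alt, 40)), "IGKV6-3*01")
  prof2 <- build_profiles(reads2, ref, small_cfg())
  p2 <- get_profile(prof2, "S001", "IGKV6-3*01")
  expect_equal(mismatch_frequency(p2, 31, alt), 0.40)
  expect_equal(mismatch_frequency(p2, 31, ref_base), 0.60)
  # frequencies over the four bases sum to 1 at every position
  freq_sum <- colSums(p2$counts) / p2$depth
  expect_true(all(abs(freq_sum - 1) < 1e-12))
})

test_that("an ambiguous call contributes half a sequence to each profile", {
  ref <- profile_fixture_ref()
  v <- ref$sequence[[1]]
  reads <- annotated_reads(rep(v, 60), "IGKV6-3*01")
  reads$v_call[[1]] <- "IGKV6-3*01,IGKV6-9*01"
  ref2 <- rbind(ref, germline_alleles("IGKV6-9", "01", substitute_at(v, 5, setdiff(c("A","C","G","T"), substr(v, 5, 5))[[1]])))
  prof <- build_profiles(reads, ref2, small_cfg())
  expect_equal(get_profile(prof, "S001", "IGKV6-3*01")$n_assigned, 59.5)
  expect_equal(get_profile(prof, "S001", "IGKV6-9*01")$n_assigned, 0.5)
  expect_equal(get_profile(prof, "S001", "IGKV6-9*01")$depth[[10]], 0.5)
})

test_that("mismatch frequency reports NA (not zero) at zero depth", {
  ref <- profile_fixture_ref()
  reads <- annotated_reads(rep(substr(ref$sequence[[1]], 1, 35), 60),
                           "IGKV6-3*01")
  prof <- build_profiles(reads, ref, small_cfg())
  p <- get_profile(prof, "S001", "IGKV6-3*01")
  expect_true(is.na(mismatch_frequency(p, 38, "A")))
})

test_that("the naive filter and sequence floor are applied", {
  ref <- profile_fixture_ref()
  v <- ref$sequence[[1]]
  reads <- annotated_reads(rep(v, 60), "IGKV6-3*01")
  reads$v_mutation_count[1:10] <- 3L   # somatically mutated, dropped
  prof <- build_profiles(reads, ref, small_cfg())
  expect_equal(get_profile(prof, "S001", "IGKV6-3*01")$n_assigned, 50)
  tiny <- annotated_reads(rep(v, 10), "IGKV6-3*01", individual_id = "S_low")
  expect_warning(build_profiles(rbind(reads, tiny), ref, small_cfg()),
                 "S_low")
})

test_that("pattern classification follows the deterministic rule", {
  cfg <- cohort_config()
  expect_equal(classify_pattern(c(0.01, 0.02, 0.49, 0.51, 0.98), cfg),
               "multimodal")
  expect_equal(classify_pattern(c(0.08, 0.10, 0.11, 0.12, 0.13), cfg),
               "stack_like")
  expect_equal(classify_pattern(c(0.0, 0.0), cfg), "indeterminate")
  expect_equal(classify_pattern(c(0.2, NA, 0.3), cfg), "indeterminate")
  # a stack crossing the cutoff is neither clean multimodal nor stack-like
  expect_equal(classify_pattern(c(0.18, 0.20, 0.22, 0.24, 0.27), cfg),
               "indeterminate")
})

test_that("per-gene candidates are capped by support with lower positions first", {
  ref <- profile_fixture_ref()
  v <- ref$sequence[[1]]
  alt_at <- function(p) {
    b <- setdiff(c("A", "C", "G", "T"), substr(v, p, p))[[1]]
    substitute_at(v, p, b)
  }
  reads <- annotated_reads(
    c(rep(alt_at(5), 900), rep(alt_at(9), 500), rep(alt_at(15), 300),
      rep(v, 300)), "IGKV6-3*01")
  prof <- build_profiles(reads, ref, small_cfg())
  cand <- detect_candidates(prof)
  expect_equal(nrow(cand), 2L)
  expect_setequal(cand$position, c(5L, 9L))
  expect_equal(cand$support_count[order(cand$position)], c(900, 500))
})

test_that("candidate filtering accepts by cutoff and pattern, never by flags", {
  cfg <- cohort_config()
  cand <- tibble::tibble(
    gene_name = "IGLV7-46", base_allele = "IGLV7-46*01",
    position = c(213L, 207L, 101L), ref = c("A", "A", "T"),
    alt = c("C", "C", "G"),
    label = c("IGLV7-46*01_A213C", "IGLV7-46*01_A207C", "IGLV7-46*01_T101G"),
    support_count = c(500, 400, 60),
    pattern = c("multimodal", "stack_like", "indeterminate"),
    flag_ac = c(TRUE, TRUE, FALSE), flag_repeat = c(TRUE, FALSE, FALSE),
    passes_cutoff = c(TRUE, TRUE, FALSE)
  )
  out <- filter_candidates(cand, cfg)
  expect_equal(out$accepted$label, "IGLV7-46*01_A213C")
  expect_equal(out$rejected$reason[out$rejected$label == "IGLV7-46*01_A207C"],
               "stack_like")
  expect_equal(out$rejected$reason[out$rejected$label == "IGLV7-46*01_T101G"],
               "below_cutoff")
})

test_that("genotypes include alleles at expression share above the cutoff", {
  set.seed(33)
  v1 <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  v3 <- substitute_at(v1, 7, setdiff(c("A", "C", "G", "T"), substr(v1, 7, 7))[[1]])
  ref <- germline_alleles(c("IGKV6-3", "IGKV6-3", "IGKJ1"), c("01", "03", "01"),
                          c(v1, v3, "GGGTTTCCCAAA"))
  reads <- annotated_reads(c(rep(v1, 55), rep(v3, 45)),
                           c(rep("IGKV6-3*01", 55), rep("IGKV6-3*03", 45)))
  prof <- build_profiles(reads, ref, small_cfg())
  gt <- infer_genotype(prof, tibble::tibble(), small_cfg())
  expect_equal(gt$alleles, "01,03")
  reads2 <- annotated_reads(c(rep(v1, 97), rep(v3, 3)),
                            c(rep("IGKV6-3*01", 97), rep("IGKV6-3*03", 3)))
  gt2 <- infer_genotype(build_profiles(reads2, ref, small_cfg()),
                        tibble::tibble(), small_cfg())
  expect_equal(gt2$alleles, "01")
})

test_that("raising the mismatch cutoff never grows the accepted set", {
  sim <- shared_sim()
  acc <- lapply(c(0.25, 0.35, 0.45), function(cut) {
    cfg <- cohort_config(mismatch_cutoff = cut)
    prof <- suppressWarnings(build_profiles(sim$ann, sim$prep$alleles, cfg))
    filter_candidates(detect_candidates(prof, cfg), cfg)$accepted$label
  })
  expect_true(all(acc[[2]] %in% acc[[1]]))
  expect_true(all(acc[[3]] %in% acc[[2]]))
})

test_that("candidate frequency tables expand one row per individual", {
  sim <- shared_sim()
  prof <- build_profiles(sim$ann, sim$prep$alleles, cohort_config())
  cand <- detect_candidates(prof)
  tab <- candidate_frequency_table(cand)
  expect_setequal(unique(tab$label), cand$label)
  expect_true(all(tab$freq >= 0 & tab$freq <= 1, na.rm = TRUE))
})
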