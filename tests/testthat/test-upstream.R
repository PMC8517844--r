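# Upstream clustering, consensus, and splice classification.

# toy genomic model engineered so that a 7-base intron retention places an
# in-frame TAA stop at codon 5 of the leader frame, while a 3-base
# retention preserves the frame with no stop
toy_genomic <- function() {
  tibble::tibble(
    gene_name = "IGKV7-7",
    promoter = strrep("T", 20),
    utr5_exon = paste0("CCCCC", "ATGGCTGCTGC"),
    intron = "GTAAGTCAG",
    lpart2 = "TACGTAC",
    v_region = strrep("ACGT", 10),
    leader_start_offset = 5L
  )
}

toy_canonical <- function() paste0("CCCCC", "ATGGCTGCTGC", "TACGTAC")
toy_retained <- function(r) {
  paste0("CCCCC", "ATGGCTGCTGC", substr("GTAAGTCAG", 1, r), "TACGTAC")
}

test_that("upstream extraction takes the pre-V segment of unambiguous reads", {
  reads <- tibble::tibble(
    sequence_id = c("a", "b", "c"),
    individual_id = "S001",
    sequence = c(paste0(strrep("A", 45), strrep("G", 20)),
                 paste0(strrep("C", 45), strrep("G", 20)),
                 strrep("G", 30)),
    v_call = c("IGKV7-7*01", "IGKV7-7*01,IGKV8-8*01", "IGKV7-7*01"),
    j_call = "IGKJ1*01",
    v_mutation_count = 0L,
    v_region_start = c(45L, 45L, 0L)
  )
  up <- extract_upstream(reads)
  expect_equal(nrow(up), 1L)   # ambiguous and empty-upstream reads dropped
  expect_equal(nchar(up$upstream), 45L)
  expect_equal(up$upstream, strrep("A", 45))
})

test_that("rare length classes are removed and survivors trimmed to a shared
           coordinate", {
  seqs <- c(rep(strrep("A", 60), 97), rep(strrep("A", 20), 3))
  out <- length_filter(seqs, 0.05)
  expect_length(out, 97L)
  expect_true(all(nchar(out) == 60L))

  half <- c(rep(paste0("GGGG", strrep("C", 56)), 50), rep(strrep("C", 56), 50))
  out2 <- length_filter(half, 0.05)
  expect_length(out2, 100L)
  expect_true(all(nchar(out2) == 56L))
  expect_true(all(out2 == strrep("C", 56)))

  uniform <- rep(strrep("T", 40), 10)
  expect_equal(length_filter(uniform, 0.05), uniform)
})

test_that("identical sequences form one cluster whose consensus is the sequence", {
  out <- cluster_and_consensus(rep(toy_canonical(), 100))
  expect_equal(nrow(out), 1L)
  expect_equal(out$consensus, toy_canonical())
  expect_equal(out$size, 100L)
  expect_equal(out$freq, 1)
})

test_that("a minority retained form survives the cluster filters as its own
           cluster", {
  seqs <- c(rep(toy_canonical(), 95), rep(toy_retained(7), 5))
  # trim to the shared 3' coordinate first, as the pipeline does
  seqs <- length_filter(seqs, 0.05)
  out <- cluster_and_consensus(seqs)
  expect_equal(nrow(out), 2L)
  expect_equal(out$size, c(95L, 5L))
  lc <- nchar(toy_canonical())
  expect_equal(out$consensus[[2]],
               substr(toy_retained(7), nchar(toy_retained(7)) - lc + 1,
                      nchar(toy_retained(7))))
})

test_that("sub-threshold majorities become N in the consensus", {
  a <- strrep("A", 10)
  g <- substitute_at(a, 4, "G")
  out <- cluster_and_consensus(c(rep(a, 55), rep(g, 45)), ident = 0.85,
                               cons_freq = 0.6)
  expect_equal(nrow(out), 1L)
  expect_equal(substr(out$consensus, 4, 4), "N")
  expect_equal(substr(out$consensus, 1, 3), "AAA")
})

test_that("clusters below the frequency or size floor are discarded", {
  a <- strrep("A", 30)
  b <- strrep("C", 30)
  out <- cluster_and_consensus(c(rep(a, 96), rep(b, 4)))
  expect_equal(nrow(out), 1L)   # size 4 < 5
  out2 <- cluster_and_consensus(c(rep(a, 700), rep(b, 5)))
  expect_equal(nrow(out2), 1L)  # freq 5/705 < 0.01
  out3 <- cluster_and_consensus(c(rep(a, 95), rep(b, 5)))
  expect_equal(nrow(out3), 2L)
})

test_that("cohort collapse is exact and conserves fractions", {
  v <- dplyr::bind_rows(lapply(sprintf("S%03d", 1:8), function(ind) {
    tibble::tibble(individual_id = ind, allele = "IGKV7-7*01",
                   consensus = toy_canonical(), size = 90L)
  }))
  v2 <- tibble::tibble(individual_id = "S001", allele = "IGKV7-7*01",
                       consensus = substitute_at(toy_canonical(), 2, "T"),
                       size = 10L)
  out <- collapse_cohort(dplyr::bind_rows(v, v2),
                         c("IGKV7-7*01" = 8 * 100))
  expect_equal(nrow(out), 2L)
  expect_equal(out$n_individuals, c(8L, 1L))
  expect_equal(out$cohort_fraction, c(720 / 800, 10 / 800))
  expect_lte(sum(out$cohort_fraction), 1)
})

test_that("splice classification separates canonical, retained and PTC status", {
  gm <- toy_genomic()
  variants <- tibble::tibble(
    allele = rep("IGKV7-7*01", 4),
    consensus_seq = c(toy_canonical(), toy_retained(7), toy_retained(3),
                      substitute_at(toy_canonical(), 8, "T")),
    n_individuals = 1L, cohort_fraction = 0.25
  )
  out <- classify_splice(variants, gm)
  expect_equal(out$splice_class,
               c("canonical", "intron_retained", "intron_retained",
                 "unclassified"))
  expect_equal(out$retained_len, c(0L, 7L, 3L, 0L))
  # hand-derived: leader codons ATG GCT GCT GC|G TAA ... -> stop at codon 5
  expect_equal(out$ptc_codon_index[[2]], 5L)
  # 3-base retention preserves the frame and has no stop
  expect_true(is.na(out$ptc_codon_index[[3]]))
  expect_match(out$note[[4]], "mismatch_at_8")
})

test_that("the upstream pipeline is deterministic and recovers planted
           retention with the exact retained length", {
  sim <- shared_sim()
  cfg <- cohort_config()
  a <- suppressMessages(infer_upstream_variants(sim$ann, sim$sim$genomic, cfg))
  b <- suppressMessages(infer_upstream_variants(sim$ann, sim$sim$genomic, cfg))
  expect_identical(as.data.frame(a), as.data.frame(b))
  truth <- sim$sim$truth$splice
  ret <- a[a$splice_class == "intron_retained", ]
  ret$gene <- sub("\\*.*$", "", ret$allele)
  for (g in truth$gene_name) {
    hit <- ret[ret$gene == g, ]
    expect_gt(nrow(hit), 0L)
    expect_true(all(hit$retained_len ==
                      truth$retained_len[truth$gene_name == g]))
    expect_true(all(hit$ptc_codon_index ==
                      truth$ptc_codon[truth$gene_name == g]))
  }
  # no retention call on genes simulated canonical-only
  expect_true(all(ret$gene %in% truth$gene_name))
})
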