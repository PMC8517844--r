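# Reference collapsing and consensus extension.

test_that("a duplicated gene pair with identical alleles collapses to one E gene", {
  seq1 <- strrep("ACGT", 10)
  ref <- germline_alleles(c("IGKV1-12", "IGKV1D-12"), c("01", "01"),
                          c(seq1, seq1))
  out <- collapse_duplicates(ref)
  expect_equal(out$alleles$name, "IGKV1E-12*01")
  expect_equal(out$alleles$sequence, seq1)
  expect_setequal(strsplit(out$alleles$collapsed_from, ",")[[1]],
                  c("IGKV1-12*01", "IGKV1D-12*01"))
  expect_equal(sort(out$report$old_gene), c("IGKV1-12", "IGKV1D-12"))
  expect_equal(unique(out$report$new_gene), "IGKV1E-12")
})

test_that("genes with no shared identical allele pass through unchanged", {
  ref <- germline_alleles(c("IGKV1-12", "IGKV1D-12"), c("01", "01"),
                          c(strrep("ACGT", 10), strrep("TGCA", 10)))
  out <- collapse_duplicates(ref)
  expect_equal(out$alleles$name, ref$name)
  expect_equal(out$alleles$sequence, ref$sequence)
  expect_equal(nrow(out$report), 0L)
})

test_that("gene grouping is the transitive closure of shared alleles", {
  x <- strrep("ACGT", 10); y <- strrep("GGCC", 10); z <- strrep("TTAA", 10)
  ref <- germline_alleles(
    c("IGKV1-12", "IGKV1D-12", "IGKV1D-12", "IGKV1P-12"),
    c("01", "01", "02", "01"),
    c(x, x, y, y)
  )
  # brute-force union oracle: merge gene sets sharing a sequence until fixpoint
  sets <- lapply(unique(ref$gene_name), function(g) g)
  repeat {
    merged <- FALSE
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (j <= i) next
        si <- ref$sequence[ref$gene_name %in% sets[[i]]]
        sj <- ref$sequence[ref$gene_name %in% sets[[j]]]
        if (length(intersect(si, sj)) > 0) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets <- sets[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  expect_length(sets, 1L)  # oracle: A-B via x, B-C via y -> one group
  out <- collapse_duplicates(ref)
  expect_equal(unique(out$alleles$gene_name), "IGKV1E-12")
  # distinct sequences renumbered consecutively; renumbering is a bijection
  expect_setequal(out$alleles$sequence, c(x, y, z)[1:2])
  expect_equal(out$alleles$allele_id, c("01", "02"))
  expect_equal(nrow(out$report), 4L)
  expect_equal(length(unique(paste(out$report$old_gene, out$report$old_allele))),
               4L)
})

test_that("collapsing is idempotent and never changes sequences", {
  sim <- shared_sim()
  once <- collapse_duplicates(sim$sim$reference)
  twice <- collapse_duplicates(once$alleles)
  expect_equal(as.data.frame(twice$alleles), as.data.frame(once$alleles))
  expect_setequal(once$alleles$sequence, unique(sim$sim$reference$sequence))
})

test_that("a truncated allele is extended from its single donor", {
  ref <- germline_alleles(c("IGKV3-7", "IGKV3-7"), c("01", "02"),
                          c("ACGTACGT", "GTACGT"))
  out <- extend_short_alleles(ref)
  expect_equal(nchar(out$sequence), c(8L, 8L))
  expect_equal(out$sequence[[2]], "ACGTACGT")
  expect_equal(out$extended_5p_len, c(0L, 2L))
  expect_equal(out$extended_3p_len, c(0L, 0L))
})

test_that("terminal fill uses the majority base with deterministic tie-break", {
  # three full alleles vote A, A, G at the missing 5' position -> A
  base <- strrep("CGTA", 5)
  ref <- germline_alleles(
    c("IGKV3-7", "IGKV3-7", "IGKV3-7", "IGKV3-7"),
    c("01", "02", "03", "04"),
    c(paste0("A", base), paste0("A", base), paste0("G", base), base)
  )
  out <- extend_short_alleles(ref)
  expect_equal(substr(out$sequence[[4]], 1, 1), "A")
  # two voters tie A vs G -> base of the lowest-numbered covering allele
  ref2 <- germline_alleles(
    c("IGKV3-9", "IGKV3-9", "IGKV3-9"), c("01", "02", "03"),
    c(paste0("G", base), paste0("A", base), base)
  )
  out2 <- extend_short_alleles(ref2)
  expect_equal(substr(out2$sequence[[3]], 1, 1), "G")
})

test_that("full-length alleles pass through extension unchanged", {
  ref <- germline_alleles(c("IGKV3-7", "IGKV3-7"), c("01", "02"),
                          c(strrep("ACGT", 8), strrep("ACGA", 8)))
  out <- extend_short_alleles(ref)
  expect_equal(out$sequence, ref$sequence)
  expect_true(all(out$extended_5p_len == 0L & out$extended_3p_len == 0L))
})

test_that("after extension all alleles of a gene share the maximal length and
           non-extended spans are byte-identical", {
  sim <- shared_sim()
  raw <- collapse_duplicates(sim$sim$reference)$alleles
  ext <- extend_short_alleles(raw)
  for (g in unique(ext$gene_name)) {
    lens <- nchar(ext$sequence[ext$gene_name == g])
    expect_true(all(lens == max(lens)))
  }
  for (i in seq_len(nrow(raw))) {
    j <- match(raw$name[[i]], ext$name)
    e5 <- ext$extended_5p_len[[j]]
    expect_equal(substr(ext$sequence[[j]], e5 + 1L, e5 + nchar(raw$sequence[[i]])),
                 raw$sequence[[i]])
  }
})
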