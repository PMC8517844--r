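# Shared fixtures and independent oracles, built in code at test time.

# small V/J reference for annotation tests: 3 V alleles over 2 genes,
# 2 J alleles; V length 30, J length 12
toy_reference <- function() {
  v1 <- "ACGTACGTACGTACGTACGTACGTACGTAC"
  v2 <- v1
  substr(v2, 10, 10) <- "G"   # IGKV1-1*02 differs at position 10
  v3 <- "TTGGCCAATTGGCCAATTGGCCAATTGGCC"
  j1 <- "GGGTTTCCCAAA"
  j2 <- "GGGTTTCCCAAT"
  germline_alleles(
    gene_name = c("IGKV1-1", "IGKV1-1", "IGKV2-2", "IGKJ1", "IGKJ1"),
    allele_id = c("01", "02", "01", "01", "02"),
    sequence = c(v1, v2, v3, j1, j2)
  )
}

# build an annotatable read: upstream + V + J
toy_read <- function(v_seq, j_seq = "GGGTTTCCCAAA", upstream = "TTTTT") {
  paste0(upstream, v_seq, j_seq)
}

make_reads <- function(sequences, individual_id = "S001") {
  tibble::tibble(
    sequence_id = sprintf("%s_%04d", individual_id, seq_along(sequences)),
    individual_id = individual_id,
    sequence = sequences,
    v_call = NA_character_, j_call = NA_character_,
    v_mutation_count = NA_integer_, v_region_start = NA_integer_
  )
}

substitute_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# independent brute-force annotator: all offsets x all alleles, simple loops;
# same tie rules as documented (min distance, then most compared positions,
# then smallest offset)
brute_annotate_v <- function(sequence, v_ref) {
  best <- list(dist = Inf, call = NA_character_, start = NA_integer_, cov = -1L)
  for (o in 0:(nchar(sequence) - min(nchar(v_ref$sequence)))) {
    for (cl in unique(nchar(v_ref$sequence))) {
      if (o + cl > nchar(sequence)) next
      win <- strsplit(substr(sequence, o + 1, o + cl), "")[[1]]
      idx <- which(nchar(v_ref$sequence) == cl)
      d <- cov <- numeric(length(idx))
      for (k in seq_along(idx)) {
        i <- idx[[k]]
        al <- strsplit(v_ref$sequence[[i]], "")[[1]]
        use <- rep(TRUE, cl)
        e5 <- v_ref$extended_5p_len[[i]]; e3 <- v_ref$extended_3p_len[[i]]
        if (e5 > 0) use[1:e5] <- FALSE
        if (e3 > 0) use[(cl - e3 + 1):cl] <- FALSE
        use <- use & win != "N" & al != "N"
        d[[k]] <- sum(win[use] != al[use])
        cov[[k]] <- cl - e5 - e3
      }
      dmin <- min(d)
      cmax <- max(cov[d == dmin])
      better <- dmin < best$dist ||
        (dmin == best$dist && cmax > best$cov) ||
        (dmin == best$dist && cmax == best$cov && !is.na(best$start) &&
           o < best$start)
      if (better) {
        best <- list(dist = dmin,
                     call = paste(sort(v_ref$name[idx[d == dmin & cov == cmax]]),
                                  collapse = ","),
                     start = o, cov = cmax)
      }
    }
  }
  best
}

# one small simulated study, computed once and shared across test files
shared_sim_env <- new.env()
shared_sim <- function() {
  if (is.null(shared_sim_env$sim)) {
    cfg <- sim_config(seed = 7, n_individuals = 6, seqs_per_individual = 2200)
    sim <- simulate_study(cfg)
    prep <- prepare_reference(sim$reference)
    ann <- suppressMessages(assign_calls(sim$reads, prep$alleles))
    shared_sim_env$sim <- list(cfg = cfg, sim = sim, prep = prep, ann = ann)
  }
  shared_sim_env$sim
}

planted_labels <- function(sim) {
  with(sim$truth$novel_snps, paste0(gene_name, "*01_", ref, position, alt))
}
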