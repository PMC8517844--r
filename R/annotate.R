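# annotate: assign V and J calls by anchored Hamming distance.
#
# A deliberately simple substitution-only annotator standing in for a full
# aligner: adequate for naive light-chain amplicons whose variants are all
# single-nucleotide substitutions, and a documented limitation for real
# indel-bearing data. The V-REGION is located by an anchoring scan (exact
# full-length matches first, then exact 5'-seed matches, then a brute-force
# offset scan for the few reads whose seed carries an error); the J-REGION
# is anchored at the 3' end of the read. Mismatch counting ignores N bases
# and positions inside consensus-extended reference spans.

SEED_LEN <- 24L

#' Assign V and J allele calls
#'
#' Every read receives `v_call` = all alleles achieving the minimal
#' Hamming distance over the anchored V-REGION window (ties preserved as a
#' comma-delimited multi-call, sorted by name), `v_mutation_count` = that
#' minimal distance, `v_region_start` = the best-scoring 0-based offset,
#' and analogously `j_call`/`j_mutation_count` anchored at the read's 3'
#' end. Because consensus-extended reference spans are excluded from
#' mismatch counting, alleles can tie at equal mismatch counts compared
#' over different numbers of positions; such ties break to the alleles
#' compared over the most positions (the lowest mismatch *rate*), so an
#' extended allele never absorbs reads from its full-length neighbours.
#' Reads shorter than the shortest reference V are left unannotated
#' (`NA` calls) and are excluded by downstream filters.
#'
#' The result is deterministic and invariant to the order of the reference
#' table.
#'
#' @param reads A rearrangement tibble with `sequence`.
#' @param reference A prepared germline allele table (see
#'   [prepare_reference()]); alleles of one gene must be
#'   length-harmonised.
#' @return `reads` with `v_call`, `j_call`, `v_mutation_count`,
#'   `j_mutation_count`, `v_region_start` replaced by inferred values.
#' @export
assign_calls <- function(reads, reference) {
  stopifnot(is.data.frame(reads), is.data.frame(reference))
  reference <- validate_germline(reference)
  v_ref <- reference[reference$segment == "V", , drop = FALSE]
  j_ref <- reference[reference$segment == "J", , drop = FALSE]
  if (nrow(v_ref) == 0L || nrow(j_ref) == 0L) {
    stop("reference must contain both V and J alleles", call. = FALSE)
  }
  seqs <- reads$sequence
  lens <- nchar(seqs)

  has_n <- any(grepl("N", seqs, fixed = TRUE)) ||
    any(grepl("N", reference$sequence, fixed = TRUE))
  v <- match_v(seqs, lens, v_ref, has_n)
  j <- match_j(seqs, lens, j_ref, has_n)

  reads$v_call <- v$call
  reads$v_mutation_count <- v$dist
  reads$v_region_start <- v$start
  reads$j_call <- j$call
  reads$j_mutation_count <- j$dist
  n_bad <- sum(is.na(v$call) | is.na(j$call))
  if (n_bad > 0L) {
    message(n_bad, " read(s) could not be annotated and will be excluded")
  }
  reads
}

# Exact occurrences of each pattern inside each read, found in one C-level
# scan over the concatenated reads (N separators cannot be matched by
# ACGT-only patterns). Returns a data.frame (read, offset0, width, pattern).
#' @noRd
concat_match <- function(seqs, patterns) {
  keep <- !grepl("N", patterns, fixed = TRUE)
  patterns <- unique(patterns[keep])
  empty <- data.frame(read = integer(0), offset0 = integer(0),
                      width = integer(0), pattern = character(0))
  if (length(patterns) == 0L || length(seqs) == 0L) return(empty)
  sep <- strrep("N", 40L)
  big <- Biostrings::DNAString(paste(seqs, collapse = sep))
  starts <- cumsum(c(1L, nchar(seqs) + 40L))[seq_along(seqs)]
  out <- list()
  for (w in unique(nchar(patterns))) {
    pats <- patterns[nchar(patterns) == w]
    pd <- Biostrings::PDict(pats)
    m <- Biostrings::matchPDict(pd, big)
    st <- Biostrings::startIndex(m)
    hits <- lengths(st) > 0L
    if (!any(hits)) next
    pos <- unlist(st[hits], use.names = FALSE)
    pat <- rep.int(pats[hits], lengths(st[hits]))
    ri <- findInterval(pos, starts)
    out[[length(out) + 1L]] <- data.frame(read = ri, offset0 = pos - starts[ri],
                                          width = w, pattern = pat)
  }
  if (length(out) == 0L) return(empty)
  unique(do.call(rbind, out))
}

#' @noRd
match_v <- function(seqs, lens, v_ref, has_n = TRUE) {
  n <- length(seqs)
  best_dist <- rep(Inf, n)
  best_call <- rep(NA_character_, n)
  best_start <- rep(NA_integer_, n)

  best_cov0 <- rep(-1L, n)
  classes <- split(seq_len(nrow(v_ref)), nchar(v_ref$sequence))
  unmasked <- v_ref$extended_5p_len == 0L & v_ref$extended_3p_len == 0L
  # candidate offsets per class: exact full matches, then 5'-seed matches.
  # Exact matches to unmasked alleles are unbeatable (distance 0 at full
  # coverage) and are resolved directly, skipping the distance scan.
  cand <- vector("list", length(classes))
  names(cand) <- names(classes)
  exact <- list()
  for (cl in names(classes)) {
    idx <- classes[[cl]]
    Lv <- as.integer(cl)
    elig <- which(lens >= Lv)
    if (length(elig) == 0L) {
      cand[[cl]] <- data.frame(read = integer(0), offset0 = integer(0))
      next
    }
    hits <- concat_match(seqs[elig], v_ref$sequence[idx])
    hits$read <- elig[hits$read]
    full <- hits$pattern %in% v_ref$sequence[idx][unmasked[idx]]
    exact[[cl]] <- hits[full, , drop = FALSE]
    covered <- unique(hits$read)
    rest <- setdiff(elig, covered)
    if (length(rest) > 0L) {
      seeds <- unique(substr(v_ref$sequence[idx], 1L, min(SEED_LEN, Lv)))
      sh <- concat_match(seqs[rest], seeds)
      sh$read <- rest[sh$read]
      sh <- sh[sh$offset0 + Lv <= lens[sh$read], , drop = FALSE]
      hits <- rbind(hits[, c("read", "offset0")], sh[, c("read", "offset0")])
    } else {
      hits <- hits[, c("read", "offset0")]
    }
    resolved <- unique(exact[[cl]]$read)
    cand[[cl]] <- unique(hits[!(hits$read %in% resolved), , drop = FALSE])
  }
  for (cl in names(classes)) {
    ex <- exact[[cl]]
    if (is.null(ex) || nrow(ex) == 0L) next
    Lv <- as.integer(cl)
    nm <- setNames(v_ref$name[classes[[cl]]], v_ref$sequence[classes[[cl]]])
    for (g in split(seq_len(nrow(ex)), ex$read)) {
      r <- ex$read[[g[[1L]]]]
      best_dist[[r]] <- 0
      best_call[[r]] <- paste(sort(unname(nm[ex$pattern[g]])), collapse = ",")
      best_start[[r]] <- min(ex$offset0[g])
      best_cov0[[r]] <- Lv
    }
  }
  # brute-force scan for reads with no candidate anywhere (seed errors)
  covered <- unique(c(unlist(lapply(cand, `[[`, "read")),
                      unlist(lapply(exact, `[[`, "read"))))
  min_lv <- min(as.integer(names(classes)))
  orphans <- setdiff(which(lens >= min_lv), covered)
  for (cl in names(classes)) {
    Lv <- as.integer(cl)
    oo <- orphans[lens[orphans] >= Lv]
    if (length(oo) == 0L) next
    extra <- do.call(rbind, lapply(oo, function(r) {
      data.frame(read = r, offset0 = 0:(lens[[r]] - Lv))
    }))
    cand[[cl]] <- rbind(cand[[cl]], extra)
  }

  best_cov <- best_cov0
  for (cl in names(classes)) {
    idx <- classes[[cl]]
    Lv <- as.integer(cl)
    pairs <- cand[[cl]]
    if (nrow(pairs) == 0L) next
    amat <- lapply(v_ref$sequence[idx], utf8ToInt)
    masks <- lapply(idx, function(i) {
      m <- logical(Lv)
      e5 <- v_ref$extended_5p_len[[i]]
      e3 <- v_ref$extended_3p_len[[i]]
      if (e5 > 0L) m[seq_len(e5)] <- TRUE
      if (e3 > 0L) m[(Lv - e3 + 1L):Lv] <- TRUE
      m
    })
    cov <- Lv - vapply(masks, sum, integer(1))
    for (grp in split(seq_len(nrow(pairs)), pairs$offset0)) {
      o <- pairs$offset0[[grp[[1L]]]]
      rds <- pairs$read[grp]
      win <- substr(seqs[rds], o + 1L, o + Lv)
      M <- seqs_to_mat(win)
      D <- vapply(seq_along(idx), function(a) {
        col_hamming(M, amat[[a]], masks[[a]], check_n = has_n)
      }, numeric(length(rds)))
      if (length(rds) == 1L) D <- matrix(D, nrow = 1L)
      dmin <- apply(D, 1L, min)
      for (k in seq_along(rds)) {
        r <- rds[[k]]
        d <- dmin[[k]]
        # equal-distance ties break to the alleles compared over the most
        # positions (lowest mismatch rate); then to the smaller offset
        tied <- D[k, ] == d
        cmax <- max(cov[tied])
        upd <- d < best_dist[[r]] ||
          (d == best_dist[[r]] && cmax > best_cov[[r]]) ||
          (d == best_dist[[r]] && cmax == best_cov[[r]] &&
             !is.na(best_start[[r]]) && o < best_start[[r]])
        if (upd) {
          hit <- idx[tied & cov == cmax]
          best_dist[[r]] <- d
          best_call[[r]] <- paste(sort(v_ref$name[hit]), collapse = ",")
          best_start[[r]] <- o
          best_cov[[r]] <- cmax
        }
      }
    }
  }
  list(call = best_call,
       dist = as.integer(ifelse(is.finite(best_dist), best_dist, NA_real_)),
       start = best_start)
}

#' @noRd
match_j <- function(seqs, lens, j_ref, has_n = TRUE) {
  n <- length(seqs)
  best_dist <- rep(Inf, n)
  best_call <- rep(NA_character_, n)
  classes <- split(seq_len(nrow(j_ref)), nchar(j_ref$sequence))
  for (cl in names(classes)) {
    idx <- classes[[cl]]
    Lj <- as.integer(cl)
    rds <- which(lens >= Lj)
    if (length(rds) == 0L) next
    win <- substr(seqs[rds], lens[rds] - Lj + 1L, lens[rds])
    M <- seqs_to_mat(win)
    amat <- lapply(j_ref$sequence[idx], utf8ToInt)
    masks <- lapply(idx, function(i) {
      m <- logical(Lj)
      e5 <- j_ref$extended_5p_len[[i]]
      e3 <- j_ref$extended_3p_len[[i]]
      if (e5 > 0L) m[seq_len(e5)] <- TRUE
      if (e3 > 0L) m[(Lj - e3 + 1L):Lj] <- TRUE
      m
    })
    cov <- Lj - vapply(masks, sum, integer(1))
    D <- vapply(seq_along(idx), function(a) {
      col_hamming(M, amat[[a]], masks[[a]], check_n = has_n)
    }, numeric(length(rds)))
    if (length(rds) == 1L) D <- matrix(D, nrow = 1L)
    dmin <- apply(D, 1L, min)
    for (k in seq_along(rds)) {
      r <- rds[[k]]
      if (dmin[[k]] < best_dist[[r]]) {
        tied <- D[k, ] == dmin[[k]]
        best_dist[[r]] <- dmin[[k]]
        best_call[[r]] <- paste(sort(j_ref$name[idx[tied & cov == max(cov[tied])]]),
                                collapse = ",")
      }
    }
  }
  list(call = best_call,
       dist = as.integer(ifelse(is.finite(best_dist), best_dist, NA_real_)))
}
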