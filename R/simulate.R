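# simulate: seeded synthetic-repertoire generator.
#
# The generator emulates the statistical structure the downstream analyses
# assume: per-individual genotypes over a small kappa-like V/J reference
# (with a duplicated gene pair sharing an identical allele and terminally
# truncated reference alleles), planted novel SNPs at controlled zygosity,
# double- and single-chromosome deletions, MiSeq-like substitution errors
# with an elevated A->C channel, repeat-motif errors and positionally fixed
# error hotspots, and per-transcript upstream regions (5'UTR + L-PART1 +
# L-PART2) where a minority of transcripts of selected genes retain an
# intron prefix that introduces a premature stop codon.
#
# Everything is deterministic under cfg$seed; make_reference/make_cohort/
# make_repertoire use seed, seed+1, seed+2 so the stages can be re-run
# independently.

#' @noRd
non_stop_codons <- function() {
  all64 <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                 paste, collapse = "")
  setdiff(all64, STOP_CODONS)
}

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the
#' package's tests: 20 individuals x 5000 sequences over 10 V genes and 5 J
#' genes, 5 planted novel SNPs (carrier fraction 0.4, heterozygous carriers
#' express the variant at share 0.5), 3 fixed error hotspots at sub-cutoff
#' stack-like frequency 0.15, 2 double and 2 single chromosome deletions,
#' one duplicated gene pair, two truncated reference alleles, and intron
#' retention in 2 low-usage genes at probability 0.12 with a 7-base
#' retained prefix. The substitution error model uses a per-base rate of
#' 0.001 with a 3x multiplier on the A->C channel and an extra rate when
#' the substituted base would equal both neighbours.
#'
#' @param seed Integer seed controlling the entire generation.
#' @param n_individuals,n_v_genes,n_j_genes Cohort and reference sizes.
#' @param v_len,j_len Lengths of V-REGION and J-REGION (nt).
#' @param seqs_per_individual Transcripts generated per individual.
#' @param base_error_rate Per-base substitution probability.
#' @param ac_error_multiplier Multiplier (>= 1) on the A->C error channel.
#' @param repeat_hotspot_rate Extra substitution probability when the
#'   erroneous base would equal both neighbours (CCAC -> CCCC style).
#' @param n_error_hotspots,hotspot_error_rate Number of positionally fixed
#'   per-gene error hotspots and their per-read error rate; hotspots are
#'   drawn once per run on genes without planted SNPs so that artefact and
#'   true-polymorphism candidates live on different genes.
#' @param n_novel_snps,novel_carrier_fraction,novel_hom_fraction Planted
#'   novel SNPs, the exact fraction of individuals carrying each, and the
#'   probability a carrier is homozygous.
#' @param novel_snp_table Optional explicit table (`gene_name`, `position`,
#'   `ref`, `alt`, `carrier_fraction`, `hom_fraction`) overriding the drawn
#'   defaults.
#' @param n_double_deletions,double_deletion_carriers,double_deletion_table
#'   Double-chromosome deletions: number of affected genes, individuals per
#'   gene, or an explicit (`gene_name`, `individual_id`) table.
#' @param n_single_deletions,single_deletion_table Single-chromosome
#'   deletions: number of (gene, individual) events, or an explicit
#'   (`gene_name`, `individual_id`, `chrom`) table. Affected individuals
#'   are forced into the anchor-heterozygous set, since single deletions
#'   are only observable through anchored linkage.
#' @param duplicated_gene_pairs Gene pairs sharing an identical allele
#'   (exercises reference collapsing).
#' @param truncated_allele_count,truncation_len Reference alleles shortened
#'   at one end (exercises consensus extension).
#' @param n_splice_genes,upstream_retention_prob,retained_intron_len Genes
#'   with alternative splicing, the fraction of their transcripts retaining
#'   an intron prefix, and the retained prefix length.
#' @param anchor_het_fraction Exact fraction of individuals heterozygous at
#'   the anchor J gene.
#' @param anchor_gene_index Which J gene is the haplotype anchor.
#' @param bias_ratio Expression ratio of allele 01 over allele 02 in
#'   heterozygotes of the first V gene (allele-usage bias); 1 disables it.
#' @param linker Fixed junction linker between V and J (light chains lack
#'   D segments, and junction diversity plays no role in these analyses).
#' @param utr5_len,leader1_len,intron_len,lpart2_len,promoter_len Upstream
#'   region lengths (nt).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 20L,
                       n_v_genes = 10L,
                       n_j_genes = 5L,
                       v_len = 296L,
                       j_len = 38L,
                       seqs_per_individual = 5000L,
                       base_error_rate = 0.001,
                       ac_error_multiplier = 3,
                       repeat_hotspot_rate = 0.002,
                       n_error_hotspots = 3L,
                       hotspot_error_rate = 0.15,
                       n_novel_snps = 5L,
                       novel_carrier_fraction = 0.4,
                       novel_hom_fraction = 0.3,
                       novel_snp_table = NULL,
                       n_double_deletions = 2L,
                       double_deletion_carriers = 3L,
                       double_deletion_table = NULL,
                       n_single_deletions = 2L,
                       single_deletion_table = NULL,
                       duplicated_gene_pairs = 1L,
                       truncated_allele_count = 2L,
                       truncation_len = 6L,
                       n_splice_genes = 2L,
                       upstream_retention_prob = 0.12,
                       retained_intron_len = 7L,
                       anchor_het_fraction = 0.25,
                       anchor_gene_index = 2L,
                       bias_ratio = 2,
                       linker = "TTCGGC",
                       utr5_len = 30L,
                       leader1_len = 28L,
                       intron_len = 90L,
                       lpart2_len = 11L,
                       promoter_len = 50L) {
  cfg <- as.list(environment())
  assert_count(cfg$seed, "seed", positive = FALSE)
  for (nm in c("n_individuals", "n_v_genes", "n_j_genes", "v_len", "j_len",
               "seqs_per_individual")) {
    assert_count(cfg[[nm]], nm)
  }
  for (nm in c("base_error_rate", "repeat_hotspot_rate", "hotspot_error_rate",
               "upstream_retention_prob", "novel_carrier_fraction",
               "novel_hom_fraction", "anchor_het_fraction")) {
    assert_fraction(cfg[[nm]], nm, open = FALSE)
  }
  if (cfg$ac_error_multiplier < 1) {
    stop("`ac_error_multiplier` must be >= 1", call. = FALSE)
  }
  if (is.null(cfg$novel_snp_table) &&
      cfg$n_novel_snps + 1L > cfg$n_v_genes) {
    stop("not enough V genes for the requested novel SNPs", call. = FALSE)
  }
  if (is.null(cfg$novel_snp_table) &&
      cfg$n_novel_snps + cfg$n_error_hotspots + 1L > cfg$n_v_genes) {
    stop("not enough V genes for disjoint SNP and hotspot genes", call. = FALSE)
  }
  if (cfg$retained_intron_len >= cfg$intron_len) {
    stop("`retained_intron_len` must be shorter than the intron", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @noRd
sample_non_stop_codons <- function(n) {
  paste(sample(non_stop_codons(), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic germline reference
#'
#' Produces both the database reference handed to the analysis (with a
#' duplicated gene pair and truncated alleles, to exercise
#' [prepare_reference()]) and the true full-length allele sequences used to
#' generate transcripts. Each analysis V gene carries a genomic model
#' (promoter, 5'UTR/L-PART1 exon ending at the GT donor, intron, L-PART2).
#' Intron prefixes are constructed so that a 7-base retention places an
#' in-frame TAA stop in the leader reading frame.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_reference` with elements `alleles` (the
#'   database [germline_alleles()] table), `genomic` (one row per analysis
#'   V gene), `truth_alleles` (true full-length sequences under collapsed
#'   analysis names), `v_genes`, `j_genes`, `v_weights`, `anchor_gene`,
#'   `splice_genes` and `cfg`.
#' @export
make_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  n_v <- cfg$n_v_genes
  fam <- ((seq_len(n_v) - 1L) %% 4L) + 1L
  pos <- seq_len(n_v) + 1L
  dup <- seq_len(n_v) > n_v - cfg$duplicated_gene_pairs
  # analysis names: duplicated pairs are known by their collapsed E name
  v_genes <- ifelse(dup,
                    sprintf("IGKV%dE-%d", fam, pos),
                    sprintf("IGKV%d-%d", fam, pos))
  db_base <- sprintf("IGKV%d-%d", fam, pos)
  db_twin <- sprintf("IGKV%dD-%d", fam, pos)

  n_two <- 1L + cfg$truncated_allele_count
  if (n_two > n_v) stop("not enough V genes for the truncated alleles", call. = FALSE)

  truth <- list()
  db <- list()
  genomic <- list()
  for (i in seq_len(n_v)) {
    v01 <- random_dna(cfg$v_len)
    truth[[length(truth) + 1L]] <- tibble(gene_name = v_genes[[i]],
                                          allele_id = "01", sequence = v01)
    has02 <- i <= n_two
    v02 <- NA_character_
    if (has02) {
      p <- sample(100:200, 1L)
      b <- substr(v01, p, p)
      v02 <- v01
      substr(v02, p, p) <- sample(setdiff(DNA_BASES, b), 1L)
      truth[[length(truth) + 1L]] <- tibble(gene_name = v_genes[[i]],
                                            allele_id = "02", sequence = v02)
    }
    # database entries: truncated 02s and duplicated twins are reference
    # artefacts; transcripts are always generated from the full truth
    db02 <- v02
    ext <- c(0L, 0L)
    if (has02 && i >= 2L && i <= 1L + cfg$truncated_allele_count) {
      if (i %% 2L == 0L) {
        db02 <- substr(v02, cfg$truncation_len + 1L, cfg$v_len)
      } else {
        db02 <- substr(v02, 1L, cfg$v_len - cfg$truncation_len)
      }
    }
    gene_db <- if (dup[[i]]) db_base[[i]] else v_genes[[i]]
    db[[length(db) + 1L]] <- tibble(gene_name = gene_db, allele_id = "01",
                                    sequence = v01)
    if (has02) {
      db[[length(db) + 1L]] <- tibble(gene_name = gene_db, allele_id = "02",
                                      sequence = db02)
    }
    if (dup[[i]]) {
      db[[length(db) + 1L]] <- tibble(gene_name = db_twin[[i]],
                                      allele_id = "01", sequence = v01)
    }

    utr5 <- random_dna(cfg$utr5_len)
    # leader frame: ATG + 8 non-stop codons + "C"; L-PART2 starts "AC" so
    # the canonical exon/L-PART2 junction codon is CAC (non-stop) while a
    # 7-base retention of the GTAAGTA intron prefix reads ...TGT AAG TAA
    leader1 <- paste0("ATG", sample_non_stop_codons(8L), "C")
    stopifnot(nchar(leader1) == cfg$leader1_len)
    lpart2 <- paste0("AC", sample_non_stop_codons(3L))
    stopifnot(nchar(lpart2) == cfg$lpart2_len)
    intron <- paste0("GTAAGTA", random_dna(cfg$intron_len - 9L), "AG")
    genomic[[length(genomic) + 1L]] <- tibble(
      gene_name = v_genes[[i]],
      promoter = random_dna(cfg$promoter_len),
      utr5_exon = paste0(utr5, leader1),
      intron = intron,
      lpart2 = lpart2,
      v_region = v01,
      leader_start_offset = cfg$utr5_len
    )
  }

  j_genes <- sprintf("IGKJ%d", seq_len(cfg$n_j_genes))
  anchor_gene <- j_genes[[cfg$anchor_gene_index]]
  for (j in seq_len(cfg$n_j_genes)) {
    j01 <- random_dna(cfg$j_len)
    truth[[length(truth) + 1L]] <- tibble(gene_name = j_genes[[j]],
                                          allele_id = "01", sequence = j01)
    db[[length(db) + 1L]] <- tibble(gene_name = j_genes[[j]], allele_id = "01",
                                    sequence = j01)
    if (j == cfg$anchor_gene_index) {
      j02 <- j01
      for (p in c(10L, 20L)) {
        b <- substr(j02, p, p)
        substr(j02, p, p) <- sample(setdiff(DNA_BASES, b), 1L)
      }
      truth[[length(truth) + 1L]] <- tibble(gene_name = anchor_gene,
                                            allele_id = "02", sequence = j02)
      db[[length(db) + 1L]] <- tibble(gene_name = anchor_gene,
                                      allele_id = "02", sequence = j02)
    }
  }

  v_weights <- rgamma(n_v, shape = 50)
  v_weights <- v_weights / sum(v_weights)
  names(v_weights) <- v_genes
  # alternative splicing sits in low-usage genes, as observed in cohorts
  splice_genes <- v_genes[order(v_weights)][seq_len(cfg$n_splice_genes)]

  dbt <- bind_rows(db)
  structure(list(
    alleles = germline_alleles(dbt$gene_name, dbt$allele_id, dbt$sequence),
    genomic = bind_rows(genomic),
    truth_alleles = bind_rows(truth),
    v_genes = v_genes,
    j_genes = j_genes,
    v_weights = v_weights,
    anchor_gene = anchor_gene,
    splice_genes = splice_genes,
    cfg = cfg
  ), class = "sim_reference")
}

#' Generate per-individual genotypes and truth tables
#'
#' Assigns every individual two chromosomal allele sets per gene, plants
#' novel SNPs at the configured zygosity, removes genes from one or both
#' chromosomes per the deletion tables, and forces the configured fraction
#' of individuals heterozygous at the anchor J gene (always including
#' single-deletion carriers). All truth tables are derived from the final
#' per-chromosome state, so they are mutually consistent by construction.
#'
#' @param cfg A [sim_config()].
#' @param reference A [make_reference()] result.
#' @return A list of class `sim_cohort`: `genotypes` (one row per
#'   individual x gene, columns `chrom1`/`chrom2` holding allele ids, `NA`
#'   = deleted) and `truth` (novel_snps, novel_carriers, deletions,
#'   hotspots, splice, anchor_het, genotype_sets, novel_sequences).
#' @export
make_cohort <- function(cfg, reference) {
  stopifnot(inherits(cfg, "sim_config"), inherits(reference, "sim_reference"))
  set.seed(cfg$seed + 1L)

  inds <- sprintf("S%03d", seq_len(cfg$n_individuals))
  v_genes <- reference$v_genes
  j_genes <- reference$j_genes
  truth_alleles <- reference$truth_alleles
  two_allele <- vapply(v_genes, function(g) {
    sum(truth_alleles$gene_name == g) > 1L
  }, logical(1))

  true_seq <- function(gene, allele) {
    truth_alleles$sequence[truth_alleles$gene_name == gene &
                             truth_alleles$allele_id == allele]
  }

  bias_gene <- if (cfg$bias_ratio != 1 && two_allele[[1L]]) v_genes[[1L]] else NA_character_
  eligible <- v_genes[-1L]

  # planted-variant role assignment (see sim_config docs)
  snp_tab <- cfg$novel_snp_table
  if (is.null(snp_tab)) {
    snp_genes <- sample(eligible, cfg$n_novel_snps)
    snp_tab <- tibble(gene_name = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      carrier_fraction = numeric(0), hom_fraction = numeric(0))
    if (length(snp_genes) > 0L) snp_tab <- bind_rows(lapply(snp_genes, function(g) {
      p <- sample(30:(cfg$v_len - 30L), 1L)
      ref_b <- substr(true_seq(g, "01"), p, p)
      tibble(gene_name = g, position = p, ref = ref_b,
             alt = sample(setdiff(DNA_BASES, ref_b), 1L),
             carrier_fraction = cfg$novel_carrier_fraction,
             hom_fraction = cfg$novel_hom_fraction)
    }))
  }
  check_genes(snp_tab$gene_name, v_genes, "novel_snp_table")

  hot_pool <- setdiff(eligible, snp_tab$gene_name)
  if (cfg$n_error_hotspots > length(hot_pool)) {
    stop("not enough SNP-free genes for the error hotspots", call. = FALSE)
  }
  hot_genes <- sample(hot_pool, cfg$n_error_hotspots)
  hotspots <- tibble(gene_name = character(0), position = integer(0),
                     ref = character(0), alt = character(0), rate = numeric(0))
  if (length(hot_genes) > 0L) hotspots <- bind_rows(lapply(hot_genes, function(g) {
    s <- true_seq(g, "01")
    a_pos <- which(strsplit(s, "")[[1L]] == "A")
    a_pos <- a_pos[a_pos > 5L & a_pos < cfg$v_len - 5L]
    p <- if (length(a_pos) > 0L) sample(a_pos, 1L) else sample(6:(cfg$v_len - 5L), 1L)
    ref_b <- substr(s, p, p)
    alt_b <- if (ref_b == "A") "C" else sample(setdiff(DNA_BASES, ref_b), 1L)
    tibble(gene_name = g, position = p, ref = ref_b, alt = alt_b,
           rate = cfg$hotspot_error_rate)
  }))

  dd_tab <- cfg$double_deletion_table
  if (is.null(dd_tab)) {
    plain <- setdiff(eligible, c(snp_tab$gene_name, hot_genes))
    dd_pool <- c(sample(plain), sample(snp_tab$gene_name))
    dd_genes <- dd_pool[seq_len(cfg$n_double_deletions)]
    # keep at least two carriers of every gene so the test frequency P
    # remains estimable in small cohorts
    n_carriers <- min(cfg$double_deletion_carriers, max(0L, length(inds) - 2L))
    dd_tab <- bind_rows(lapply(dd_genes, function(g) {
      tibble(gene_name = g, individual_id = sample(inds, n_carriers))
    }))
  }
  if (is.null(dd_tab) || nrow(dd_tab) == 0L) {
    dd_tab <- tibble(gene_name = character(0), individual_id = character(0))
  }
  check_genes(dd_tab$gene_name, v_genes, "double_deletion_table")

  # anchor heterozygotes (exact count), always covering single-deletion carriers
  n_het <- round(cfg$anchor_het_fraction * cfg$n_individuals)
  sd_tab <- cfg$single_deletion_table
  if (is.null(sd_tab)) {
    sd_pool <- setdiff(c(hot_genes, setdiff(eligible, c(snp_tab$gene_name, hot_genes))),
                       unique(dd_tab$gene_name))
    sd_genes <- sample(sd_pool, cfg$n_single_deletions)
    het_seed <- sample(inds, max(n_het, cfg$n_single_deletions))
    sd_tab <- tibble(gene_name = sd_genes,
                     individual_id = het_seed[seq_len(cfg$n_single_deletions)],
                     chrom = sample(1:2, cfg$n_single_deletions, replace = TRUE))
    het_inds <- het_seed[seq_len(n_het)]
    if (cfg$n_single_deletions > n_het) het_inds <- het_seed
  } else {
    check_genes(sd_tab$gene_name, v_genes, "single_deletion_table")
    het_inds <- unique(c(sd_tab$individual_id,
                         sample(inds, n_het)))[seq_len(max(n_het, length(unique(sd_tab$individual_id))))]
  }
  check_genes(sd_tab$gene_name, v_genes, "single_deletion_table")

  # baseline genotype draw
  geno <- expand.grid(individual_id = inds, gene_name = c(v_genes, j_genes),
                      stringsAsFactors = FALSE)
  geno <- as_tibble(geno)
  geno$segment <- ifelse(geno$gene_name %in% v_genes, "V", "J")
  draw_allele <- function(gene) {
    if (gene %in% v_genes && two_allele[[match(gene, v_genes)]]) {
      p01 <- if (!is.na(bias_gene) && gene == bias_gene) 0.5 else 0.65
      sample(c("01", "02"), 1L, prob = c(p01, 1 - p01))
    } else "01"
  }
  geno$chrom1 <- vapply(geno$gene_name, draw_allele, character(1),
                        USE.NAMES = FALSE)
  geno$chrom2 <- vapply(geno$gene_name, draw_allele, character(1),
                        USE.NAMES = FALSE)

  # anchor phase: chromosome 1 carries anchor allele 01 in heterozygotes
  anchor <- reference$anchor_gene
  geno$chrom1[geno$gene_name == anchor] <- "01"
  geno$chrom2[geno$gene_name == anchor] <-
    ifelse(geno$individual_id[geno$gene_name == anchor] %in% het_inds, "02", "01")

  # plant novel SNPs (carriers drawn among individuals not deleted for the gene)
  novel_seqs <- list()
  novel_truth <- list()
  for (r in seq_len(nrow(snp_tab))) {
    g <- snp_tab$gene_name[[r]]
    p <- snp_tab$position[[r]]
    alt <- snp_tab$alt[[r]]
    nid <- paste0("01_", snp_tab$ref[[r]], p, alt)
    s <- true_seq(g, "01")
    stopifnot(substr(s, p, p) == snp_tab$ref[[r]])
    substr(s, p, p) <- alt
    novel_seqs[[length(novel_seqs) + 1L]] <-
      tibble(gene_name = g, allele_id = nid, sequence = s)
    deleted_here <- dd_tab$individual_id[dd_tab$gene_name == g]
    pool <- setdiff(inds, deleted_here)
    carriers <- sample(pool, round(snp_tab$carrier_fraction[[r]] * cfg$n_individuals))
    for (ind in carriers) {
      i <- which(geno$individual_id == ind & geno$gene_name == g)
      hom <- runif(1) < snp_tab$hom_fraction[[r]]
      if (hom) {
        geno$chrom1[[i]] <- nid
        geno$chrom2[[i]] <- nid
      } else {
        side <- sample(1:2, 1L)
        geno$chrom1[[i]] <- if (side == 1L) nid else "01"
        geno$chrom2[[i]] <- if (side == 2L) nid else "01"
      }
      novel_truth[[length(novel_truth) + 1L]] <-
        tibble(individual_id = ind, gene_name = g, allele_id = nid,
               zygosity = if (hom) "hom" else "het")
    }
  }

  deletions <- list()
  for (r in seq_len(nrow(dd_tab))) {
    i <- which(geno$individual_id == dd_tab$individual_id[[r]] &
                 geno$gene_name == dd_tab$gene_name[[r]])
    geno$chrom1[[i]] <- NA_character_
    geno$chrom2[[i]] <- NA_character_
    deletions[[length(deletions) + 1L]] <-
      tibble(individual_id = dd_tab$individual_id[[r]],
             gene_name = dd_tab$gene_name[[r]], type = "double", chrom = NA_integer_)
  }
  for (r in seq_len(nrow(sd_tab))) {
    i <- which(geno$individual_id == sd_tab$individual_id[[r]] &
                 geno$gene_name == sd_tab$gene_name[[r]])
    if (sd_tab$chrom[[r]] == 1L) geno$chrom1[[i]] <- NA_character_
    else geno$chrom2[[i]] <- NA_character_
    deletions[[length(deletions) + 1L]] <-
      tibble(individual_id = sd_tab$individual_id[[r]],
             gene_name = sd_tab$gene_name[[r]], type = "single",
             chrom = as.integer(sd_tab$chrom[[r]]))
  }

  splice <- bind_rows(lapply(reference$splice_genes, function(g) {
    gm <- reference$genomic[reference$genomic$gene_name == g, ]
    retained <- paste0(gm$utr5_exon,
                       substr(gm$intron, 1L, cfg$retained_intron_len),
                       gm$lpart2)
    ptc <- first_stop_codon(retained, gm$leader_start_offset + 1L)
    tibble(gene_name = g, retained_len = cfg$retained_intron_len,
           retention_prob = cfg$upstream_retention_prob,
           has_ptc = !is.na(ptc), ptc_codon = ptc)
  }))

  sets <- geno
  sets$alleles <- vapply(seq_len(nrow(geno)), function(i) {
    paste(sort(unique(stats::na.omit(c(geno$chrom1[[i]], geno$chrom2[[i]])))),
          collapse = ",")
  }, character(1))

  structure(list(
    genotypes = geno,
    truth = list(
      novel_snps = snp_tab,
      novel_carriers = if (length(novel_truth)) bind_rows(novel_truth) else
        tibble(individual_id = character(0), gene_name = character(0),
               allele_id = character(0), zygosity = character(0)),
      deletions = if (length(deletions)) bind_rows(deletions) else
        tibble(individual_id = character(0), gene_name = character(0),
               type = character(0), chrom = integer(0)),
      hotspots = hotspots,
      splice = splice,
      anchor_het = tibble(individual_id = het_inds, gene_name = anchor),
      genotype_sets = sets[, c("individual_id", "gene_name", "segment", "alleles")],
      novel_sequences = if (length(novel_seqs)) bind_rows(novel_seqs) else
        tibble(gene_name = character(0), allele_id = character(0),
               sequence = character(0)),
      bias_gene = bias_gene
    )
  ), class = "sim_cohort")
}

#' @noRd
check_genes <- function(genes, known, what) {
  bad <- setdiff(genes, known)
  if (length(bad) > 0L) {
    stop("config error: ", what, " references unknown gene(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate an AIRR repertoire from a simulated cohort
#'
#' For each individual, draws transcripts by picking a chromosome, a V gene
#' (configured usage weights, restricted to genes present in the genotype)
#' and a J gene, taking both alleles from the same chromosome so that
#' anchored haplotype linkage is preserved. Transcripts of splice-flagged
#' genes retain an intron prefix with the configured probability.
#' Substitution errors are then applied with the MiSeq-like channel
#' structure described in [sim_config()].
#'
#' The returned table carries generator truth in its annotation columns
#' (`v_call`, `j_call`, `v_mutation_count`, `v_region_start`, `chrom`,
#' `is_retained`); re-annotating with [assign_calls()] overwrites the call
#' columns with inferred values.
#'
#' @param cfg A [sim_config()].
#' @param cohort A [make_cohort()] result.
#' @param reference A [make_reference()] result.
#' @return A rearrangement tibble, one row per transcript.
#' @export
make_repertoire <- function(cfg, cohort, reference) {
  stopifnot(inherits(cfg, "sim_config"), inherits(cohort, "sim_cohort"),
            inherits(reference, "sim_reference"))
  set.seed(cfg$seed + 2L)

  geno <- cohort$genotypes
  truth_alleles <- reference$truth_alleles
  all_seqs <- bind_rows(truth_alleles, cohort$truth$novel_sequences)
  seq_of <- setNames(all_seqs$sequence,
                     allele_name(all_seqs$gene_name, all_seqs$allele_id))
  bias_gene <- cohort$truth$bias_gene
  bias_p1 <- cfg$bias_ratio / (1 + cfg$bias_ratio)

  draws <- vector("list", cfg$n_individuals)
  inds <- unique(geno$individual_id)
  for (ii in seq_along(inds)) {
    ind <- inds[[ii]]
    gi <- geno[geno$individual_id == ind, ]
    vg <- gi[gi$segment == "V", ]
    present <- !is.na(vg$chrom1) | !is.na(vg$chrom2)
    vg <- vg[present, ]
    w <- reference$v_weights[vg$gene_name]
    n <- cfg$seqs_per_individual
    g_idx <- sample.int(nrow(vg), n, replace = TRUE, prob = w)
    # chromosome choice: 0.5/0.5 where both chromosomes carry the gene,
    # forced where one is deleted, biased at the bias gene in 01/02 hets
    p1 <- ifelse(is.na(vg$chrom1), 0, ifelse(is.na(vg$chrom2), 1, 0.5))
    if (!is.na(bias_gene)) {
      bi <- which(vg$gene_name == bias_gene)
      if (length(bi) == 1L && !is.na(vg$chrom1[[bi]]) && !is.na(vg$chrom2[[bi]]) &&
          vg$chrom1[[bi]] != vg$chrom2[[bi]]) {
        p1[[bi]] <- if (vg$chrom1[[bi]] == "01") bias_p1 else 1 - bias_p1
      }
    }
    chrom <- 1L + (runif(n) >= p1[g_idx])
    v_allele <- ifelse(chrom == 1L, vg$chrom1[g_idx], vg$chrom2[g_idx])
    jg <- gi[gi$segment == "J", ]
    j_idx <- sample.int(nrow(jg), n, replace = TRUE)
    j_allele <- ifelse(chrom == 1L, jg$chrom1[j_idx], jg$chrom2[j_idx])
    retained <- vg$gene_name[g_idx] %in% reference$splice_genes &
      runif(n) < cfg$upstream_retention_prob
    draws[[ii]] <- tibble(
      individual_id = ind,
      v_gene = vg$gene_name[g_idx], v_allele = v_allele,
      j_gene = jg$gene_name[j_idx], j_allele = j_allele,
      chrom = chrom, is_retained = retained
    )
  }
  reads <- bind_rows(draws)

  gm <- reference$genomic
  upstream_of <- setNames(paste0(gm$utr5_exon, gm$lpart2), gm$gene_name)
  retained_of <- setNames(paste0(gm$utr5_exon,
                                 substr(gm$intron, 1L, cfg$retained_intron_len),
                                 gm$lpart2), gm$gene_name)

  reads$v_call <- allele_name(reads$v_gene, reads$v_allele)
  reads$j_call <- allele_name(reads$j_gene, reads$j_allele)
  up <- ifelse(reads$is_retained, retained_of[reads$v_gene],
               upstream_of[reads$v_gene])
  reads$v_region_start <- nchar(up)
  template <- paste0(up, seq_of[reads$v_call], cfg$linker, seq_of[reads$j_call])

  mut <- apply_errors(template, reads$v_gene, reads$v_region_start, cfg,
                      cohort$truth$hotspots)
  reads$sequence <- mut$sequence
  reads$v_mutation_count <- mut$v_errors

  reads$sequence_id <- sprintf("%s_%06d", reads$individual_id,
                               stats::ave(seq_len(nrow(reads)), reads$individual_id,
                                          FUN = seq_along))
  reads[, c("sequence_id", "individual_id", "sequence", "v_call", "j_call",
            "v_mutation_count", "v_region_start", "chrom", "is_retained")]
}

# Substitution error engine. Works per distinct template so each channel is
# a single binomial draw over (reads x sites); a read hit twice at one
# position keeps the last substitution. Channels:
#   1. uniform errors at base_error_rate, random target;
#   2. extra A->C at base_error_rate * (ac_error_multiplier - 1) / 3;
#   3. extra neighbour-matching errors (X[b]X -> XbX) at repeat_hotspot_rate;
#   4. fixed per-gene hotspot positions at their configured rate.
#' @noRd
apply_errors <- function(template, v_gene, v_start, cfg, hotspots) {
  n_total <- length(template)
  out <- template
  v_err <- integer(n_total)
  if (n_total == 0L) return(list(sequence = out, v_errors = v_err))
  codes <- unname(DNA_CODE[DNA_BASES])

  key <- paste0(v_gene, "|", template)
  for (grp in split(seq_len(n_total), key)) {
    gene <- v_gene[[grp[[1L]]]]
    vs <- v_start[[grp[[1L]]]]
    s <- utf8ToInt(template[[grp[[1L]]]])
    L <- length(s)
    n <- length(grp)

    ev_i <- integer(0); ev_p <- integer(0); ev_b <- integer(0)

    if (cfg$base_error_rate > 0) {
      k <- rbinom(1L, n * L, cfg$base_error_rate)
      if (k > 0L) {
        cells <- sample.int(n * L, k)
        p <- (cells - 1L) %/% n + 1L
        tgt <- vapply(p, function(pp) sample(codes[codes != s[[pp]]], 1L),
                      integer(1))
        ev_i <- c(ev_i, (cells - 1L) %% n + 1L)
        ev_p <- c(ev_p, p)
        ev_b <- c(ev_b, tgt)
      }
    }
    if (cfg$ac_error_multiplier > 1 && cfg$base_error_rate > 0) {
      apos <- which(s == DNA_CODE[["A"]])
      if (length(apos) > 0L) {
        rate <- cfg$base_error_rate * (cfg$ac_error_multiplier - 1) / 3
        k <- rbinom(1L, n * length(apos), rate)
        if (k > 0L) {
          cells <- sample.int(n * length(apos), k)
          ev_i <- c(ev_i, (cells - 1L) %% n + 1L)
          ev_p <- c(ev_p, apos[(cells - 1L) %/% n + 1L])
          ev_b <- c(ev_b, rep(DNA_CODE[["C"]], k))
        }
      }
    }
    if (cfg$repeat_hotspot_rate > 0 && L >= 3L) {
      mid <- 2:(L - 1L)
      rpos <- mid[s[mid - 1L] == s[mid + 1L] & s[mid] != s[mid - 1L]]
      if (length(rpos) > 0L) {
        k <- rbinom(1L, n * length(rpos), cfg$repeat_hotspot_rate)
        if (k > 0L) {
          cells <- sample.int(n * length(rpos), k)
          p <- rpos[(cells - 1L) %/% n + 1L]
          ev_i <- c(ev_i, (cells - 1L) %% n + 1L)
          ev_p <- c(ev_p, p)
          ev_b <- c(ev_b, s[p - 1L])
        }
      }
    }
    if (!is.null(hotspots) && nrow(hotspots) > 0L) {
      hs <- hotspots[hotspots$gene_name == gene, ]
      for (r in seq_len(nrow(hs))) {
        p <- vs + hs$position[[r]]
        if (p > L) next
        k <- rbinom(1L, n, hs$rate[[r]])
        if (k > 0L) {
          ev_i <- c(ev_i, sample.int(n, k))
          ev_p <- c(ev_p, rep(p, k))
          ev_b <- c(ev_b, rep(DNA_CODE[[hs$alt[[r]]]], k))
        }
      }
    }

    if (length(ev_i) == 0L) next
    # last event at a (read, position) wins
    v_hi <- vs + min(cfg$v_len, L - vs)
    for (ri in unique(ev_i)) {
      sel <- which(ev_i == ri)
      chars <- s
      chars[ev_p[sel]] <- ev_b[sel]
      out[[grp[[ri]]]] <- intToUtf8(chars)
      changed <- which(chars != s)
      v_err[[grp[[ri]]]] <- sum(changed > vs & changed <= v_hi)
    }
  }
  list(sequence = out, v_errors = v_err)
}

#' Run the full simulation
#'
#' Convenience wrapper: [make_reference()], [make_cohort()],
#' [make_repertoire()].
#'
#' @param cfg A [sim_config()].
#' @return A list with `reference` (database alleles), `genomic`, `reads`,
#'   `truth`, plus the underlying `sim_reference` and `sim_cohort`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  ref <- make_reference(cfg)
  cohort <- make_cohort(cfg, ref)
  reads <- make_repertoire(cfg, cohort, ref)
  list(reference = ref$alleles, genomic = ref$genomic, reads = reads,
       truth = cohort$truth, sim_reference = ref, cohort = cohort)
}

#' Write simulation outputs to a directory
#'
#' Writes the database reference FASTA, the genomic-gene table, the AIRR
#' repertoire and the truth tables as plain-text files.
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(sim$reference, file.path(dir, "reference.fasta"))
  write.table(sim$genomic, file.path(dir, "genomic_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_airr(sim$reads, file.path(dir, "repertoire.tsv"))
  for (nm in c("novel_snps", "novel_carriers", "deletions", "hotspots",
               "splice", "anchor_het", "genotype_sets")) {
    write.table(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
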