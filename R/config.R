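#' Analysis configuration for a repertoire cohort
#'
#' Bundles the thresholds used throughout the inference pipeline. The
#' defaults are the study conditions of the analysis this package
#' implements: individuals contribute at least 2000 unique sequences;
#' the naive filter keeps sequences with fewer than 3 mismatches to their
#' assigned V germline; relative-usage floors are 0.001 for V genes and
#' 0.005 for J genes (there are fewer J genes, so their per-gene usage is
#' higher); the mismatch-frequency cutoff of 0.25 admits equal expression
#' of up to four variants of one gene; deletion calls use Benjamini-
#' Hochberg-adjusted significance 0.01; haplotype anchors require an
#' allele ratio of at least 30:70; and single-chromosome calls require a
#' Bayes factor above 1000.
#'
#' @param min_sequences_per_individual Minimum unique sequences for an
#'   individual to enter the analysis.
#' @param max_v_mutations Exclusive bound on V-REGION mismatches for the
#'   naive filter: sequences with `v_mutation_count < max_v_mutations`
#'   are kept (default 3, i.e. at most 2 mismatches).
#' @param v_usage_floor,j_usage_floor Relative-usage floors below which a
#'   gene's deletion test is undetermined.
#' @param mismatch_cutoff Per-individual mismatch frequency a true
#'   polymorphism must reach in at least one individual.
#' @param candidate_floor Frequency floor for generating candidates at
#'   all; defaults to `mismatch_cutoff / 2` so that borderline and
#'   artefact positions are classified and rejected with a reason rather
#'   than silently missed.
#' @param min_candidate_depth Minimum per-individual sequence depth at a
#'   position for that individual's mismatch frequency to be defined
#'   during candidate detection; a handful of stray sequences cannot
#'   define a frequency.
#' @param significance Adjusted p-value threshold for deletion calls.
#' @param het_min_ratio Minimum minor-allele share for an anchor gene to
#'   count as heterozygous (0.30 = a 30:70 ratio).
#' @param bayes_factor_threshold Bayes factor above which a chromosome
#'   assignment (or its converse) is accepted.
#' @param max_novel_per_gene Cap on novel-allele candidates retained per
#'   gene, ranked by support.
#' @param noise_floor Mismatch frequencies at or below this value are
#'   treated as background noise by the pattern classifier.
#' @param multimodal_gap Minimum gap separating sub-cutoff from
#'   supra-cutoff frequencies for a multimodal call.
#' @param leak_rate Cross-chromosome leak rate `eps` of the single-
#'   chromosome haplotype model (annotation noise; results are
#'   insensitive over 0.001-0.05).
#' @param upstream_ident,upstream_length_cov,upstream_cons_freq
#'   Upstream clustering identity, minimum overlap as a fraction of the
#'   shorter sequence, and consensus majority threshold.
#' @param upstream_min_cluster_freq,upstream_min_cluster_size Clusters
#'   below either bound are discarded.
#' @param upstream_len_class_min_freq Upstream length classes below this
#'   relative frequency are removed before clustering.
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config()
#' cfg$mismatch_cutoff
cohort_config <- function(min_sequences_per_individual = 2000L,
                          max_v_mutations = 3L,
                          v_usage_floor = 0.001,
                          j_usage_floor = 0.005,
                          mismatch_cutoff = 0.25,
                          candidate_floor = mismatch_cutoff / 2,
                          min_candidate_depth = 10L,
                          significance = 0.01,
                          het_min_ratio = 0.30,
                          bayes_factor_threshold = 1000,
                          max_novel_per_gene = 2L,
                          noise_floor = 0.05,
                          multimodal_gap = 0.15,
                          leak_rate = 0.01,
                          upstream_ident = 0.999,
                          upstream_length_cov = 0.5,
                          upstream_cons_freq = 0.6,
                          upstream_min_cluster_freq = 0.01,
                          upstream_min_cluster_size = 5L,
                          upstream_len_class_min_freq = 0.05) {
  cfg <- list(
    min_sequences_per_individual =
      assert_count(min_sequences_per_individual, "min_sequences_per_individual"),
    max_v_mutations = assert_count(max_v_mutations, "max_v_mutations"),
    v_usage_floor = assert_fraction(v_usage_floor, "v_usage_floor"),
    j_usage_floor = assert_fraction(j_usage_floor, "j_usage_floor"),
    mismatch_cutoff = assert_fraction(mismatch_cutoff, "mismatch_cutoff"),
    candidate_floor = assert_fraction(candidate_floor, "candidate_floor"),
    min_candidate_depth = assert_count(min_candidate_depth, "min_candidate_depth"),
    significance = assert_fraction(significance, "significance"),
    het_min_ratio = assert_fraction(het_min_ratio, "het_min_ratio"),
    bayes_factor_threshold = bayes_factor_threshold,
    max_novel_per_gene = assert_count(max_novel_per_gene, "max_novel_per_gene"),
    noise_floor = assert_fraction(noise_floor, "noise_floor"),
    multimodal_gap = assert_fraction(multimodal_gap, "multimodal_gap"),
    leak_rate = assert_fraction(leak_rate, "leak_rate"),
    upstream_ident = assert_fraction(upstream_ident, "upstream_ident"),
    upstream_length_cov = assert_fraction(upstream_length_cov, "upstream_length_cov"),
    upstream_cons_freq = assert_fraction(upstream_cons_freq, "upstream_cons_freq"),
    upstream_min_cluster_freq =
      assert_fraction(upstream_min_cluster_freq, "upstream_min_cluster_freq"),
    upstream_min_cluster_size =
      assert_count(upstream_min_cluster_size, "upstream_min_cluster_size"),
    upstream_len_class_min_freq =
      assert_fraction(upstream_len_class_min_freq, "upstream_len_class_min_freq")
  )
  if (!(is.numeric(bayes_factor_threshold) && bayes_factor_threshold > 0)) {
    stop("`bayes_factor_threshold` must be positive", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Read a cohort configuration from a YAML file
#'
#' Fields present in the YAML file override the [cohort_config()] defaults;
#' unknown fields are an error.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config` list.
#' @export
cohort_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(cohort_config, vals)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @noRd
as_cohort_config <- function(cfg) {
  if (is.null(cfg)) return(cohort_config())
  if (!inherits(cfg, "cohort_config")) {
    stop("`cfg` must be created by cohort_config()", call. = FALSE)
  }
  cfg
}
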