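#' Configuration for the synthetic tumor-cohort generator
#'
#' Bundles and validates every parameter of the synthetic data generator:
#' cohort composition, per-caller reporting behaviour, the planted
#' per-residue hotspot, the negative-binomial expression model with a
#' planted activation signature and a tumor-type batch effect, and the
#' cycloheximide-chase decay series.
#'
#' @param seed Integer global seed. Every generator stage derives its own
#'   deterministic substream from it, so stages are individually
#'   reproducible.
#' @param n_cases Number of tumor cases.
#' @param n_normals Number of normal-tissue cases, split evenly across
#'   tumor types.
#' @param tumor_types Named numeric vector of tumor-type proportions
#'   (must sum to 1).
#' @param protein_length_by_gene Named integer vector: protein length in
#'   codons for every mutated gene. The default carries the driver genes
#'   plus 35 generic passenger genes (`PSG01`..`PSG35`) so that the
#'   per-case probability of a driver-gene hit sits at realistic cohort
#'   levels rather than near 1.
#' @param hotspot_spec List with `gene`, `position` (1-based codon),
#'   `fraction` (share of that gene's events planted at the position),
#'   `ref_aa` (reference amino acid printed at the hotspot) and
#'   `alt_weights` (named weights over alternate amino acids drawn at the
#'   hotspot).
#' @param background_mutation_rate Poisson mean number of true somatic
#'   events per case.
#' @param spurious_rate Poisson mean number of spurious single-caller
#'   calls per case.
#' @param caller_concordance Probability that each of the four callers
#'   independently reports a true event.
#' @param ts_tv_ratio Odds of a substitution being a transition rather
#'   than a transversion.
#' @param n_genes Number of genes in the expression matrix.
#' @param activation_spec List with `genes` (signature-true genes
#'   upregulated under activation), `log2_effect` (log2 fold change) and
#'   `fraction` (fraction of tumors activated; all driver-gene mutant
#'   tumors are activated, then non-mutant tumors are added up to this
#'   fraction).
#' @param batch_spec List with `genes` (batch-affected genes, disjoint
#'   from the activation genes) and `offsets` (named per-tumor-type log2
#'   offsets applied to all samples of that type, tumor and normal).
#' @param nb_dispersion Negative-binomial dispersion alpha, with
#'   variance mu + alpha * mu^2.
#' @param baseline_means Optional vector of baseline expression means
#'   (length `n_genes`, all strictly positive). Drawn log-normally when
#'   `NULL`.
#' @param chase_spec List with `half_lives` (named true half-lives in
#'   minutes per construct), `timepoints` (minutes, at least three,
#'   starting at 0), `noise_sd` (sd of multiplicative log-normal noise)
#'   and `replicates`.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_cases = 200L,
                       n_normals = 24L,
                       tumor_types = c(LUSC = 0.5, LUAD = 0.5),
                       protein_length_by_gene = c(NFE2L2 = 605L,
                                                  KEAP1 = 624L,
                                                  TP53 = 393L,
                                                  STK11 = 433L,
                                                  EGFR = 1210L,
                                                  stats::setNames(
                                                    rep_len(c(350L, 420L,
                                                              510L, 640L,
                                                              780L), 35L),
                                                    sprintf("PSG%02d",
                                                            1:35))),
                       hotspot_spec = list(gene = "NFE2L2", position = 34L,
                                           fraction = 0.4, ref_aa = "R",
                                           alt_weights = c(G = 2, P = 1, Q = 1)),
                       background_mutation_rate = 8,
                       spurious_rate = 1,
                       caller_concordance = 0.9,
                       ts_tv_ratio = 2,
                       n_genes = 500L,
                       activation_spec = list(genes = c("AKR1B10", "AKR1B15",
                                                        "GPX2", "TXNRD1",
                                                        "GCLM", "GCLC"),
                                              log2_effect = 4,
                                              fraction = 0.4),
                       batch_spec = list(genes = sprintf("KRT%02d", 1:6),
                                         offsets = c(LUSC = 3, LUAD = 0)),
                       nb_dispersion = 0.05,
                       baseline_means = NULL,
                       chase_spec = list(half_lives = c(WT = 15, R34L = 22,
                                                        R34P = 31, R34Q = 40,
                                                        R34G = 49, E82G = 58),
                                         timepoints = c(0, 30, 60, 90, 120),
                                         noise_sd = 0.1,
                                         replicates = 3L)) {
  if (abs(sum(tumor_types) - 1) > 1e-9)
    stop("tumor_types proportions must sum to 1", call. = FALSE)
  if (is.null(names(tumor_types)) || anyDuplicated(names(tumor_types)))
    stop("tumor_types must be uniquely named", call. = FALSE)
  stop_if_not_positive(n_cases, "n_cases")
  stop_if_not_positive(n_normals, "n_normals")
  stop_if_not_positive(n_genes, "n_genes")
  stop_if_not_positive(protein_length_by_gene, "protein_length_by_gene")
  stop_if_not_positive(background_mutation_rate, "background_mutation_rate")
  stop_if_not_positive(spurious_rate, "spurious_rate", strict = FALSE)
  stop_if_not_positive(ts_tv_ratio, "ts_tv_ratio")
  stop_if_not_positive(nb_dispersion, "nb_dispersion")
  stop_if_not_scalar_prob(caller_concordance, "caller_concordance")
  stop_if_not_scalar_prob(hotspot_spec$fraction, "hotspot_spec$fraction")
  stop_if_not_scalar_prob(activation_spec$fraction, "activation_spec$fraction")

  if (!hotspot_spec$gene %in% names(protein_length_by_gene))
    stop("hotspot gene is not in protein_length_by_gene", call. = FALSE)
  if (hotspot_spec$position < 1 ||
      hotspot_spec$position > protein_length_by_gene[[hotspot_spec$gene]])
    stop("hotspot position exceeds the protein length of its gene",
         call. = FALSE)
  if (length(intersect(activation_spec$genes, batch_spec$genes)) > 0L)
    stop("activation genes and batch genes must be disjoint", call. = FALSE)
  if (length(activation_spec$genes) + length(batch_spec$genes) > n_genes)
    stop("n_genes is too small for the planted gene sets", call. = FALSE)
  if (!all(names(batch_spec$offsets) %in% names(tumor_types)))
    stop("batch offsets name unknown tumor types", call. = FALSE)
  if (!is.null(baseline_means)) {
    if (length(baseline_means) != n_genes)
      stop("baseline_means must have length n_genes", call. = FALSE)
    if (any(!is.finite(baseline_means) | baseline_means <= 0))
      stop("baseline_means must all be strictly positive", call. = FALSE)
  }
  stop_if_not_positive(chase_spec$half_lives, "chase_spec$half_lives")
  if (length(chase_spec$timepoints) < 3L)
    stop("chase_spec needs at least 3 timepoints (fit is underdetermined)",
         call. = FALSE)
  stop_if_not_positive(chase_spec$noise_sd, "chase_spec$noise_sd",
                       strict = FALSE)
  stop_if_not_positive(chase_spec$replicates, "chase_spec$replicates")

  structure(list(seed = as.integer(seed),
                 n_cases = as.integer(n_cases),
                 n_normals = as.integer(n_normals),
                 tumor_types = tumor_types,
                 protein_length_by_gene = protein_length_by_gene,
                 hotspot_spec = hotspot_spec,
                 background_mutation_rate = background_mutation_rate,
                 spurious_rate = spurious_rate,
                 caller_concordance = caller_concordance,
                 ts_tv_ratio = ts_tv_ratio,
                 n_genes = as.integer(n_genes),
                 activation_spec = activation_spec,
                 batch_spec = batch_spec,
                 nb_dispersion = nb_dispersion,
                 baseline_means = baseline_means,
                 chase_spec = chase_spec),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d tumor cases + %d normals over types: %s\n",
              x$n_cases, x$n_normals,
              paste(sprintf("%s (%.0f%%)", names(x$tumor_types),
                            100 * x$tumor_types), collapse = ", ")))
  cat(sprintf("  hotspot: %s codon %d, fraction %.2f\n",
              x$hotspot_spec$gene, x$hotspot_spec$position,
              x$hotspot_spec$fraction))
  cat(sprintf("  caller concordance %.2f, background rate %.1f events/case\n",
              x$caller_concordance, x$background_mutation_rate))
  cat(sprintf("  expression: %d genes, %d activation genes (+%g log2), %d batch genes\n",
              x$n_genes, length(x$activation_spec$genes),
              x$activation_spec$log2_effect, length(x$batch_spec$genes)))
  invisible(x)
}
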