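# Per-residue hotspot detection by Monte-Carlo permutation, with
# Benjamini-Hochberg adjustment, tumor-type-restricted enrichment and
# hotspot transversion-bias testing.

#' Monte-Carlo permutation p-value
#'
#' The add-one estimator p = (b + 1)/(m + 1), where `b` permutations
#' reached a statistic at least as extreme as observed out of `m`
#' permutations. Never smaller than 1/(m + 1) and never larger than 1.
#'
#' @param b Number of permutations at least as extreme as observed
#'   (vectorized).
#' @param m Number of permutations (>= 1).
#' @return Numeric vector of estimated p-values.
#' @export
montecarlo_pvalue <- function(b, m) {
  if (any(m < 1)) stop("m must be at least 1", call. = FALSE)
  if (any(b < 0) || any(b > m))
    stop("b must lie in [0, m]", call. = FALSE)
  (b + 1) / (m + 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR control: sort p ascending, take
#' q_(i) = min_\{j >= i\} p_(j) * n / j capped at 1, and return in the
#' input order. Equivalent to `p.adjust(method = "BH")`, reimplemented
#' here with explicit domain validation so Monte-Carlo p-values (which
#' are never 0) are the only admissible input.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
}

#' Per-codon nonsynonymous mutation counts for a gene
#'
#' @param consensus Consensus table from [merge_caller_calls()].
#' @param gene Gene symbol.
#' @param protein_length Protein length L in codons.
#' @return Integer vector of length L (event count per codon). Events
#'   with positions outside 1..L are excluded and counted in attribute
#'   `n_excluded`.
#' @export
position_counts <- function(consensus, gene, protein_length) {
  if (protein_length <= 0) stop("protein_length must be positive",
                                call. = FALSE)
  rows <- consensus[consensus$Hugo_Symbol == gene &
                      consensus$variant_class %in% NONSYNONYMOUS_CLASSES &
                      !is.na(consensus$protein_pos), , drop = FALSE]
  in_range <- rows$protein_pos >= 1L & rows$protein_pos <= protein_length
  if (any(!in_range))
    message(sum(!in_range), " event(s) outside codons 1..", protein_length,
            " excluded")
  counts <- tabulate(rows$protein_pos[in_range], nbins = protein_length)
  attr(counts, "n_excluded") <- sum(!in_range)
  counts
}

#' Per-residue positional hotspot enrichment
#'
#' Null model: the gene's n observed events are redistributed
#' independently and uniformly over its L codons in each permutation.
#' For each position with at least one observed event, `b` counts the
#' permutations in which that position's null count reached the observed
#' count; p = (b + 1)/(m + 1), Benjamini-Hochberg adjusted across the
#' tested positions. Only positions with observed events enter the BH
#' family. Results depend only on (seed, m, counts), not on internal
#' batching.
#'
#' @param counts Integer vector of per-codon event counts (from
#'   [position_counts()]).
#' @param m Number of permutations (default 1e5).
#' @param seed Integer seed.
#' @return Data frame with `protein_pos`, `observed`, `b`, `m`, `p_hat`,
#'   `q`, ordered by position.
#' @export
positional_enrichment <- function(counts, m = 100000L, seed = 1L) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  L <- length(counts)
  n <- sum(counts)
  if (n < 1) stop("need at least one observed event", call. = FALSE)
  tested <- which(counts > 0)
  obs <- counts[tested]

  set.seed(seed)
  b <- integer(length(tested))
  chunk <- max(1L, min(as.integer(m), as.integer(floor(5e6 / n))))
  done <- 0L
  while (done < m) {
    sz <- min(chunk, m - done)
    draws <- matrix(sample.int(L, n * sz, replace = TRUE), nrow = n)
    for (i in seq_along(tested))
      b[i] <- b[i] + sum(.colSums(draws == tested[i], n, sz) >= obs[i])
    done <- done + sz
  }
  p_hat <- montecarlo_pvalue(b, m)
  data.frame(protein_pos = tested, observed = obs, b = b,
             m = as.integer(m), p_hat = p_hat, q = bh_adjust(p_hat))
}

#' Tumor-type enrichment of the cases mutated at one position
#'
#' Null model: the k cases mutated at the position are drawn without
#' replacement from the pool of all cases mutated anywhere in the gene.
#' For each tumor type, `b` counts permutations where the type's draw
#' count reached its observed count; p = (b + 1)/(m + 1),
#' Benjamini-Hochberg adjusted across types.
#'
#' @param position_types Tumor types of the cases mutated at the
#'   position (one entry per case).
#' @param pool_types Tumor types of all gene-mutant cases (the sampling
#'   pool; must contain the position cases).
#' @param m Number of permutations.
#' @param seed Integer seed.
#' @return Data frame with `tumor_type`, `observed`, `b`, `m`, `p_hat`,
#'   `q`.
#' @export
tumor_type_enrichment <- function(position_types, pool_types,
                                  m = 100000L, seed = 1L) {
  k <- length(position_types)
  if (k < 1) stop("need at least one case at the position", call. = FALSE)
  if (k > length(pool_types))
    stop("position case count exceeds the gene-mutant pool", call. = FALSE)
  types <- sort(unique(pool_types))
  obs <- as.integer(table(factor(position_types, levels = types)))
  pool_int <- match(pool_types, types)
  n_pool <- length(pool_types)

  set.seed(seed)
  b <- integer(length(types))
  for (i in seq_len(m)) {
    cnt <- tabulate(pool_int[sample.int(n_pool, k)], nbins = length(types))
    b <- b + (cnt >= obs)
  }
  p_hat <- montecarlo_pvalue(b, m)
  data.frame(tumor_type = types, observed = obs, b = b, m = as.integer(m),
             p_hat = p_hat, q = bh_adjust(p_hat))
}

#' Transversion bias at hotspot positions
#'
#' One-sided Fisher's exact test for an excess of transversions among
#' substitution events at hotspot positions relative to the rest of the
#' gene.
#'
#' @param consensus Consensus table from [merge_caller_calls()].
#' @param gene Gene symbol.
#' @param hotspot_positions Integer vector of hotspot codon positions.
#' @return List with the 2x2 `table` (hotspot/other x
#'   transversion/transition) and one-sided `p_value`.
#' @export
hotspot_transversion_bias <- function(consensus, gene, hotspot_positions) {
  rows <- consensus[consensus$Hugo_Symbol == gene &
                      consensus$Reference_Allele %in% BASES &
                      consensus$Tumor_Seq_Allele2 %in% BASES &
                      consensus$Reference_Allele !=
                        consensus$Tumor_Seq_Allele2 &
                      !is.na(consensus$protein_pos), , drop = FALSE]
  cls <- classify_substitution(rows$Reference_Allele,
                               rows$Tumor_Seq_Allele2)
  at_hot <- rows$protein_pos %in% hotspot_positions
  tab <- matrix(c(sum(at_hot & cls == "transversion"),
                  sum(at_hot & cls == "transition"),
                  sum(!at_hot & cls == "transversion"),
                  sum(!at_hot & cls == "transition")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("hotspot", "other"),
                                c("transversion", "transition")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin in the transversion-bias table; p = 1",
            call. = FALSE)
    return(list(table = tab, p_value = 1))
  }
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(table = tab, p_value = p)
}
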