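# Cohort stratification: Ward clustering on the signature genes,
# G1/G2/G3 group designation and mutant-enrichment testing.

#' Ward clustering of samples on a signature submatrix
#'
#' Agglomerative clustering with Ward's minimum variance linkage on
#' Euclidean distances, cut into `k` clusters. Deterministic and
#' invariant to sample order up to cluster relabeling.
#'
#' @param x Matrix, signature genes x samples.
#' @param k Number of clusters (default 3).
#' @return Integer cluster assignment named by sample.
#' @export
ward_cluster <- function(x, k = 3L) {
  x <- as.matrix(x)
  if (ncol(x) < k)
    stop("fewer samples than clusters requested", call. = FALSE)
  stats::cutree(stats::hclust(stats::dist(t(x)), method = "ward.D2"), k = k)
}

#' Designate clusters as G1 (normal), G2 (active) and G3 (inactive)
#'
#' G1 is the cluster with the highest fraction of normal samples. Of the
#' remaining two, G2 is the cluster with the higher mean signature
#' expression and G3 the other; a tie sends the larger cluster to G3
#' with a warning.
#'
#' @param clusters Integer assignment over samples (3 clusters).
#' @param is_normal Logical vector over samples.
#' @param cluster_means Named numeric vector: mean signature expression
#'   per cluster id.
#' @return An object of class `"stratification"`: list with `groups`
#'   (character vector "G1"/"G2"/"G3" over samples), `assignment` (data
#'   frame `sample`, `cluster`, `group`) and `cluster_summary`.
#' @export
designate_groups <- function(clusters, is_normal, cluster_means) {
  ids <- sort(unique(clusters))
  if (length(ids) != 3L)
    stop("group designation expects exactly 3 clusters", call. = FALSE)
  if (is.null(names(cluster_means)))
    names(cluster_means) <- as.character(ids)
  norm_frac <- vapply(ids, function(cl) mean(is_normal[clusters == cl]),
                      numeric(1))
  g1 <- ids[which.max(norm_frac)]
  if (sum(norm_frac == max(norm_frac)) > 1L)
    warning("tie on normal fraction; smallest cluster id taken as G1",
            call. = FALSE)
  rest <- setdiff(ids, g1)
  mr <- cluster_means[as.character(rest)]
  if (mr[1] == mr[2]) {
    warning("tie on mean signature expression; larger cluster taken as G3",
            call. = FALSE)
    sizes <- vapply(rest, function(cl) sum(clusters == cl), numeric(1))
    g3 <- rest[which.max(sizes)]
    g2 <- setdiff(rest, g3)
  } else {
    g2 <- rest[which.max(mr)]
    g3 <- setdiff(rest, g2)
  }
  map <- c("G1", "G2", "G3")[match(clusters, c(g1, g2, g3))]
  samples <- names(clusters)
  if (is.null(samples)) samples <- as.character(seq_along(clusters))
  summary <- data.frame(cluster = ids,
                        group = c("G1", "G2", "G3")[match(ids,
                                                          c(g1, g2, g3))],
                        size = vapply(ids, function(cl)
                          sum(clusters == cl), integer(1)),
                        normal_fraction = norm_frac,
                        mean_expression =
                          unname(cluster_means[as.character(ids)]),
                        stringsAsFactors = FALSE)
  structure(list(groups = stats::setNames(map, samples),
                 assignment = data.frame(sample = samples,
                                         cluster = unname(clusters),
                                         group = map,
                                         stringsAsFactors = FALSE),
                 cluster_summary = summary),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat("Cohort stratification (Ward, k = 3)\n")
  print(x$cluster_summary, row.names = FALSE)
  invisible(x)
}

#' Mutant enrichment in G2 relative to G3
#'
#' One-sided Fisher's exact test on the 2x2 table (G2/G3 x
#' mutant/non-mutant), alternative: mutants over-represented in G2.
#' Accepts one logical flag vector or a named list of them (e.g. NRF2
#' mutants, KEAP1 mutants, R34 carriers).
#'
#' @param groups Character vector of group labels over samples
#'   (G1/G2/G3).
#' @param mutant Logical vector over samples, or a named list of such
#'   vectors.
#' @return For a single flag vector, a list with `table` and `p_value`;
#'   for a list input, a named list of such results.
#' @export
group_enrichment <- function(groups, mutant) {
  if (is.list(mutant))
    return(lapply(mutant, function(fl) group_enrichment(groups, fl)))
  stopifnot(length(groups) == length(mutant))
  g2 <- groups == "G2"
  g3 <- groups == "G3"
  if (!any(g2) || !any(g3))
    stop("both G2 and G3 must be non-empty", call. = FALSE)
  tab <- matrix(c(sum(g2 & mutant), sum(g2 & !mutant),
                  sum(g3 & mutant), sum(g3 & !mutant)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("G2", "G3"),
                                c("mutant", "non_mutant")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin in the enrichment table; p = 1", call. = FALSE)
    return(list(table = tab, p_value = 1))
  }
  list(table = tab,
       p_value = stats::fisher.test(tab,
                                    alternative = "greater")$p.value)
}

#' Stratify a cohort on a derived signature
#'
#' Convenience wrapper: Ward-clusters all samples on the signature
#' genes (k = 3), computes per-cluster mean signature expression (using
#' up-regulated signature genes when directions are available) and
#' designates G1/G2/G3.
#'
#' @param vst Transformed matrix over the whole cohort.
#' @param signature_genes Character vector of signature genes.
#' @param is_normal Logical vector over samples.
#' @param up_genes Optional subset of `signature_genes` with positive
#'   effect sign, used for the cluster means.
#' @return A `"stratification"` object (see [designate_groups()]).
#' @export
stratify_cohort <- function(vst, signature_genes, is_normal,
                            up_genes = NULL) {
  x <- as.matrix(vst)[signature_genes, , drop = FALSE]
  cl <- ward_cluster(x, k = 3L)
  mean_genes <- if (!is.null(up_genes) && length(up_genes) > 0L)
    intersect(up_genes, signature_genes) else signature_genes
  sample_means <- colMeans(as.matrix(vst)[mean_genes, , drop = FALSE])
  cluster_means <- vapply(sort(unique(cl)), function(ci)
    mean(sample_means[cl == ci]), numeric(1))
  names(cluster_means) <- as.character(sort(unique(cl)))
  designate_groups(cl, is_normal, cluster_means)
}
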