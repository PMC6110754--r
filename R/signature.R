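# Activation-signature derivation: variance-stabilizing transform,
# differential-expression filter, tumor-type-bias ranking, and
# sequential Ward clustering maximizing the machine-learning score
# MLS = L_Inter / L_Intra.

#' Variance-stabilizing transform of a count matrix
#'
#' Median-of-ratios size factors (geometric-mean reference computed over
#' the genes nonzero in every sample, size factors rescaled to geometric
#' mean 1) followed by log2(count / size_factor + 1). When no gene is
#' nonzero in all samples the transform falls back to total-count
#' scaling with a warning.
#'
#' @param counts Non-negative count matrix, genes x samples.
#' @return Transformed numeric matrix with attribute `size_factors`.
#' @export
vst_transform <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(colSums(counts) == 0))
    stop("every sample needs at least one nonzero gene", call. = FALSE)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    ref <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
    sf <- apply(counts[all_pos, , drop = FALSE] / ref, 2, stats::median)
  } else {
    warning("no gene is nonzero in all samples; ",
            "falling back to total-count size factors", call. = FALSE)
    sf <- colSums(counts)
  }
  sf <- sf / exp(mean(log(sf)))
  out <- log2(sweep(counts, 2, sf, "/") + 1)
  attr(out, "size_factors") <- sf
  out
}

#' Differential expression between tumor and normal samples
#'
#' Per-gene Welch two-sample t-test on transformed values, with
#' Benjamini-Hochberg adjustment across genes. A gene is selected when
#' its adjusted p-value is below `alpha` and the absolute group mean
#' difference is at least `lfc_min` (log2 units). This stage is a
#' pluggable interface: any externally computed table with the same
#' columns can be substituted downstream.
#'
#' @param vst Transformed matrix (genes x samples).
#' @param is_tumor Logical vector over samples (TRUE = tumor).
#' @param lfc_min Minimum absolute log2 mean difference (default 2.5).
#' @param alpha FDR threshold (default 0.05).
#' @return Data frame with `gene`, `lfc` (tumor minus normal), `p_value`,
#'   `q_value`, `direction` and logical `selected`, in input gene order.
#' @export
differential_expression <- function(vst, is_tumor, lfc_min = 2.5,
                                    alpha = 0.05) {
  vst <- as.matrix(vst)
  stopifnot(ncol(vst) == length(is_tumor))
  if (sum(is_tumor) < 2L || sum(!is_tumor) < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  xt <- vst[, is_tumor, drop = FALSE]
  xn <- vst[, !is_tumor, drop = FALSE]
  n1 <- ncol(xt); n2 <- ncol(xn)
  m1 <- rowMeans(xt); m2 <- rowMeans(xn)
  v1 <- apply(xt, 1, stats::var); v2 <- apply(xn, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # Degenerate genes: both groups constant. Equal means -> no evidence.
  degen <- se2 == 0
  p[degen] <- ifelse(lfc[degen] == 0, 1, 0)
  p[!is.finite(p)] <- 1
  q <- bh_adjust(p)
  genes <- rownames(vst)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_len(nrow(vst)))
  data.frame(gene = genes, lfc = lfc, p_value = p, q_value = q,
             direction = ifelse(lfc >= 0, "up", "down"),
             selected = q < alpha & abs(lfc) >= lfc_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank genes by absolute between-tumor-type expression difference
#'
#' d_r is the difference in mean transformed expression between the two
#' tumor types, computed over training tumors only. Genes are ranked by
#' increasing |d_r| (stable, ties broken by gene name), so the least
#' tumor-type-biased genes head the list.
#'
#' @param vst Transformed matrix restricted to training tumor samples.
#' @param genes Candidate genes (e.g. the selected genes of
#'   [differential_expression()]).
#' @param types Tumor-type labels of the training tumor samples; exactly
#'   two types, both present.
#' @return Data frame `gene`, `d_r`, `abs_d_r`, `rank`, ordered by rank.
#' @export
tumor_type_bias_rank <- function(vst, genes, types) {
  vst <- as.matrix(vst)
  stopifnot(ncol(vst) == length(types))
  lv <- sort(unique(types))
  if (length(lv) != 2L)
    stop("exactly two tumor types (both present) are required",
         call. = FALSE)
  missing <- setdiff(genes, rownames(vst))
  if (length(missing) > 0L)
    stop("genes absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- vst[genes, , drop = FALSE]
  d_r <- rowMeans(x[, types == lv[1], drop = FALSE]) -
    rowMeans(x[, types == lv[2], drop = FALSE])
  o <- order(abs(d_r), genes)
  data.frame(gene = genes[o], d_r = unname(d_r[o]),
             abs_d_r = unname(abs(d_r)[o]), rank = seq_along(o),
             stringsAsFactors = FALSE)
}

#' Machine-learning score of a clustering against known labels
#'
#' MLS = L_Inter / L_Intra. L_Inter is the Euclidean distance between
#' the normal-group centroid and the tumor-group centroid; L_Intra is
#' the mean over clusters of the mean pairwise Euclidean distance within
#' the cluster (singleton clusters are excluded). L_Intra = 0 yields the
#' sentinel `Inf`.
#'
#' @param x Matrix, genes x samples (the signature submatrix).
#' @param is_tumor Logical vector over samples (TRUE = tumor, FALSE =
#'   normal); both groups must be non-empty.
#' @param clusters Integer cluster assignment over samples.
#' @return List with `score`, `l_inter`, `l_intra`.
#' @export
mls_score <- function(x, is_tumor, clusters) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(is_tumor), ncol(x) == length(clusters))
  if (!any(is_tumor) || !any(!is_tumor))
    stop("both label groups must be non-empty", call. = FALSE)
  c_t <- rowMeans(x[, is_tumor, drop = FALSE])
  c_n <- rowMeans(x[, !is_tumor, drop = FALSE])
  l_inter <- sqrt(sum((c_t - c_n)^2))

  d <- as.matrix(stats::dist(t(x)))
  within <- vapply(unique(clusters), function(cl) {
    idx <- which(clusters == cl)
    if (length(idx) < 2L) return(NA_real_)
    mean(d[idx, idx][upper.tri(d[idx, idx])])
  }, numeric(1))
  within <- within[!is.na(within)]
  l_intra <- if (length(within) == 0L) 0 else mean(within)
  score <- if (l_intra == 0) Inf else l_inter / l_intra
  list(score = score, l_inter = l_inter, l_intra = l_intra)
}

#' Sequential signature selection by MLS maximization
#'
#' Starting from the top two ranked genes and adding one gene per
#' iteration, Ward-clusters the training samples (Euclidean distance,
#' Ward linkage, cut at 2 clusters) on the growing gene set and records
#' the MLS. The selected size is the smallest k attaining the maximal
#' MLS.
#'
#' @param vst Transformed matrix over the training samples.
#' @param ranked Ranked gene table from [tumor_type_bias_rank()].
#' @param is_tumor Logical vector over training samples.
#' @param k_max Largest gene-set size to explore (default
#'   min(200, number of ranked genes); truncated with a warning if it
#'   exceeds the list).
#' @return An object of class `"mls_trace"`: list with `trace` (data
#'   frame `k`, `mls`), `selected_k` and `genes` (the selected gene
#'   set, in rank order).
#' @export
sequential_signature_selection <- function(vst, ranked, is_tumor,
                                           k_max = min(200L, nrow(ranked))) {
  if (nrow(ranked) < 2L)
    stop("need at least two ranked genes", call. = FALSE)
  if (k_max > nrow(ranked)) {
    warning("k_max exceeds the ranked list; truncated to ", nrow(ranked),
            call. = FALSE)
    k_max <- nrow(ranked)
  }
  ks <- 2:k_max
  mls <- vapply(ks, function(k) {
    sub <- vst[ranked$gene[seq_len(k)], , drop = FALSE]
    cl <- stats::cutree(stats::hclust(stats::dist(t(sub)),
                                      method = "ward.D2"), k = 2)
    mls_score(sub, is_tumor, cl)$score
  }, numeric(1))
  selected_k <- ks[which.max(mls)]
  structure(list(trace = data.frame(k = ks, mls = mls),
                 selected_k = selected_k,
                 genes = ranked$gene[seq_len(selected_k)]),
            class = "mls_trace")
}

#' @export
print.mls_trace <- function(x, ...) {
  cat(sprintf("MLS trace over k = %d..%d; selected k = %d (MLS = %.3g)\n",
              min(x$trace$k), max(x$trace$k), x$selected_k,
              x$trace$mls[x$trace$k == x$selected_k]))
  cat("genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Pick a balanced training design from a sample sheet
#'
#' Selects `n_tumors` activated tumor cases and `n_normals` normal
#' cases, balanced across the two tumor types, mirroring a
#' 12-tumor / 12-normal training split.
#'
#' @param sample_sheet Sample sheet from [simulate_mutations()].
#' @param n_tumors,n_normals Training set sizes (defaults 12 and 12).
#' @return Data frame `case_id`, `role` ("tumor"/"normal"),
#'   `tumor_type`.
#' @export
training_design <- function(sample_sheet, n_tumors = 12L, n_normals = 12L) {
  types <- sort(unique(sample_sheet$tumor_type))
  if (length(types) != 2L)
    stop("the training design expects exactly two tumor types",
         call. = FALSE)
  pick <- function(rows, n_per_type, label) {
    sel <- do.call(rbind, lapply(types, function(tt) {
      cand <- rows[rows$tumor_type == tt, , drop = FALSE]
      if (nrow(cand) < n_per_type)
        stop("not enough ", label, " cases of type ", tt, call. = FALSE)
      cand[seq_len(n_per_type), , drop = FALSE]
    }))
    sel
  }
  tum <- pick(sample_sheet[sample_sheet$tissue == "tumor" &
                             sample_sheet$activated, , drop = FALSE],
              n_tumors %/% 2L, "activated tumor")
  nor <- pick(sample_sheet[sample_sheet$tissue == "normal", , drop = FALSE],
              n_normals %/% 2L, "normal")
  data.frame(case_id = c(tum$case_id, nor$case_id),
             role = rep(c("tumor", "normal"), c(nrow(tum), nrow(nor))),
             tumor_type = c(tum$tumor_type, nor$tumor_type),
             stringsAsFactors = FALSE)
}

#' Derive an activation signature from a labeled training set
#'
#' Runs the full derivation: variance-stabilizing transform of the count
#' matrix, tumor-vs-normal differential expression on the training
#' samples, |d_r| tumor-type-bias ranking of the selected genes over the
#' training tumors, and sequential Ward clustering maximizing the MLS.
#'
#' @param counts Count matrix (genes x samples).
#' @param design Training design from [training_design()].
#' @param lfc_min,alpha Differential-expression thresholds.
#' @param k_max Largest signature size to explore.
#' @param de_table Optional externally computed differential-expression
#'   table (columns `gene`, `lfc`, `selected`) replacing the built-in
#'   Welch test.
#' @return List with `signature` (selected genes with `d_r` and rank),
#'   `trace` (the [sequential_signature_selection()] result), `de` (the
#'   differential-expression table) and `vst` (the transformed matrix).
#' @export
derive_signature <- function(counts, design, lfc_min = 2.5, alpha = 0.05,
                             k_max = NULL, de_table = NULL) {
  vst <- vst_transform(counts)
  missing <- setdiff(design$case_id, colnames(vst))
  if (length(missing) > 0L)
    stop("design cases absent from the count matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  train <- vst[, design$case_id, drop = FALSE]
  is_tumor <- design$role == "tumor"
  de <- if (is.null(de_table))
    differential_expression(train, is_tumor, lfc_min, alpha) else de_table
  cand <- de$gene[de$selected]
  if (length(cand) < 2L)
    stop("fewer than two genes pass the differential-expression filter",
         call. = FALSE)
  ranked <- tumor_type_bias_rank(train[, is_tumor, drop = FALSE], cand,
                                 design$tumor_type[is_tumor])
  if (is.null(k_max)) k_max <- min(200L, nrow(ranked))
  trace <- sequential_signature_selection(train, ranked, is_tumor, k_max)
  sig <- ranked[ranked$gene %in% trace$genes, , drop = FALSE]
  sig$lfc <- de$lfc[match(sig$gene, de$gene)]
  list(signature = sig, trace = trace, de = de, vst = vst)
}
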