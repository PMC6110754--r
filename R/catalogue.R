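# Consensus mutation catalogue: multi-caller merging, substitution
# classification, protein-change parsing, burden and correlation
# summaries.

VARIANT_CLASS_MAP <- c(Missense_Mutation = "missense",
                       Nonsense_Mutation = "nonsense",
                       Frame_Shift_Del = "frameshift",
                       Frame_Shift_Ins = "frameshift",
                       In_Frame_Del = "inframe_indel",
                       In_Frame_Ins = "inframe_indel",
                       Splice_Site = "splice",
                       Silent = "silent")

NONSYNONYMOUS_CLASSES <- c("missense", "nonsense", "frameshift",
                           "inframe_indel", "splice")

#' Map MAF Variant_Classification strings to the internal vocabulary
#'
#' Unknown classifications map to `"other"`. "Non-synonymous" throughout
#' the package means every class except `silent` and `other`.
#'
#' @param x Character vector of MAF `Variant_Classification` values.
#' @return Character vector over
#'   \{missense, nonsense, frameshift, inframe_indel, splice, silent, other\}.
#' @export
map_variant_class <- function(x) {
  out <- unname(VARIANT_CLASS_MAP[x])
  out[is.na(out)] <- "other"
  out
}

#' Classify a nucleotide substitution as transition or transversion
#'
#' Transitions are purine-purine (A/G) or pyrimidine-pyrimidine (C/T)
#' exchanges; everything else is a transversion. The classification is
#' invariant under simultaneous complementation of both bases.
#'
#' @param ref,alt Character vectors of single bases in A/C/G/T.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @export
classify_substitution <- function(ref, alt) {
  if (length(ref) != length(alt))
    stop("ref and alt must have the same length", call. = FALSE)
  if (!all(ref %in% BASES) || !all(alt %in% BASES))
    stop("bases must be one of A, C, G, T", call. = FALSE)
  if (any(ref == alt))
    stop("ref and alt must differ", call. = FALSE)
  unname(ifelse(TRANSITION_PARTNER[ref] == alt, "transition",
                "transversion"))
}

#' Parse HGVS short protein-change strings
#'
#' Understands `"p.R34G"` (missense/silent), `"p.R34*"` (nonsense) and
#' `"p.E82fs"` (frameshift). Empty strings yield absent protein fields;
#' anything else is flagged malformed (all-NA row) and the count of
#' malformed strings is attached as attribute `n_malformed`.
#'
#' @param hgvsp Character vector of protein-change strings.
#' @return Data frame with columns `ref_aa`, `protein_pos`, `alt_aa`,
#'   `variant_class`.
#' @export
parse_protein_change <- function(hgvsp) {
  n <- length(hgvsp)
  out <- data.frame(ref_aa = rep(NA_character_, n),
                    protein_pos = rep(NA_integer_, n),
                    alt_aa = rep(NA_character_, n),
                    variant_class = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  hgvsp[is.na(hgvsp)] <- ""

  m_sub <- regmatches(hgvsp, regexec("^p\\.([A-Z])([0-9]+)([A-Z*])$", hgvsp))
  m_fs <- regmatches(hgvsp, regexec("^p\\.([A-Z])([0-9]+)fs$", hgvsp))
  malformed <- 0L
  for (i in seq_len(n)) {
    if (hgvsp[i] == "") next
    if (length(m_sub[[i]]) == 4L) {
      ref <- m_sub[[i]][2]; alt <- m_sub[[i]][4]
      out$ref_aa[i] <- ref
      out$protein_pos[i] <- as.integer(m_sub[[i]][3])
      out$alt_aa[i] <- alt
      out$variant_class[i] <- if (alt == "*") "nonsense"
        else if (alt == ref) "silent" else "missense"
    } else if (length(m_fs[[i]]) == 3L) {
      out$ref_aa[i] <- m_fs[[i]][2]
      out$protein_pos[i] <- as.integer(m_fs[[i]][3])
      out$alt_aa[i] <- "fs"
      out$variant_class[i] <- "frameshift"
    } else {
      malformed <- malformed + 1L
    }
  }
  if (malformed > 0L)
    message(malformed, " malformed protein-change string(s) excluded from ",
            "positional analyses")
  attr(out, "n_malformed") <- malformed
  out
}

#' Merge per-caller mutation tables into a consensus catalogue
#'
#' Records are keyed by (case, gene, chromosome, position, ref, alt);
#' the callers reporting each key are unioned and keys reported by fewer
#' than `min_callers` callers are dropped. Duplicate keys within one
#' caller's table are deduplicated with a warning. The returned table is
#' annotated with `case_id` (first 12 barcode characters), `n_callers`,
#' the internal `variant_class`, and parsed protein-change fields.
#'
#' @param calls Either a named list of MAF-style data frames (names are
#'   caller names, from MuSE, MuTect2, SomaticSniper, VarScan2), or a
#'   single data frame already carrying a semicolon-joined `callers`
#'   column.
#' @param min_callers Minimum number of reporting callers to retain a
#'   record (default 2).
#' @return Consensus data frame, one row per retained unique key.
#' @export
merge_caller_calls <- function(calls, min_callers = 2L) {
  if (is.data.frame(calls)) {
    if (!"callers" %in% names(calls))
      stop("aggregated input must carry a `callers` column", call. = FALSE)
    combined <- calls
    caller_sets <- strsplit(combined$callers, ";", fixed = TRUE)
    unknown <- setdiff(unique(unlist(caller_sets)), CALLER_SET)
    if (length(unknown) > 0L)
      stop("unknown caller name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  } else {
    unknown <- setdiff(names(calls), CALLER_SET)
    if (is.null(names(calls)) || length(unknown) > 0L)
      stop("caller tables must be named after known callers; unknown: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    tabs <- lapply(names(calls), function(cl) {
      tab <- calls[[cl]]
      dup <- duplicated(mutation_key(tab))
      if (any(dup)) {
        warning(sum(dup), " duplicate record(s) within the ", cl,
                " table; deduplicated", call. = FALSE)
        tab <- tab[!dup, , drop = FALSE]
      }
      tab$callers <- rep(cl, nrow(tab))
      tab
    })
    combined <- do.call(rbind, tabs)
    caller_sets <- as.list(combined$callers)
  }

  key <- mutation_key(combined)
  caller_by_key <- lapply(split(unlist(lapply(seq_along(caller_sets),
                                              function(i) caller_sets[[i]])),
                                rep(key, lengths(caller_sets))),
                          unique)
  first <- !duplicated(key)
  consensus <- combined[first, setdiff(names(combined), "callers"),
                        drop = FALSE]
  ckey <- key[first]
  sets <- caller_by_key[ckey]
  consensus$callers <- vapply(sets, function(s)
    paste(sort(s), collapse = ";"), character(1))
  consensus$n_callers <- lengths(sets)
  consensus <- consensus[consensus$n_callers >= min_callers, , drop = FALSE]

  consensus$case_id <- case_from_barcode(consensus$Tumor_Sample_Barcode)
  consensus$variant_class <-
    map_variant_class(consensus$Variant_Classification)
  parsed <- parse_protein_change(consensus$HGVSp_Short)
  consensus$ref_aa <- parsed$ref_aa
  consensus$protein_pos <- parsed$protein_pos
  consensus$alt_aa <- parsed$alt_aa
  consensus <- consensus[order(mutation_key(consensus)), , drop = FALSE]
  rownames(consensus) <- NULL
  consensus
}

#' Cases carrying a qualifying mutation in a gene
#'
#' @param consensus Consensus table from [merge_caller_calls()].
#' @param gene Gene symbol.
#' @param nonsynonymous_only Exclude silent and unclassified records
#'   (default TRUE).
#' @return Character vector of unique case ids.
#' @export
mutant_case_sets <- function(consensus, gene, nonsynonymous_only = TRUE) {
  rows <- consensus[consensus$Hugo_Symbol == gene, , drop = FALSE]
  if (nrow(rows) == 0L) {
    if (nrow(consensus) > 0L && !gene %in% consensus$Hugo_Symbol)
      warning("gene ", gene, " not present in the consensus table",
              call. = FALSE)
    return(character(0))
  }
  if (nonsynonymous_only)
    rows <- rows[rows$variant_class %in% NONSYNONYMOUS_CLASSES, ,
                 drop = FALSE]
  sort(unique(rows$case_id))
}

#' Overlap between two case sets against a finite universe
#'
#' Tests whether the observed overlap between two case sets is larger
#' than expected if both were random subsets of the universe. The exact
#' mode gives the hypergeometric upper tail P(X >= k); the Monte-Carlo
#' mode draws `m` random subset pairs and estimates p as (b + 1)/(m + 1).
#'
#' @param set_a,set_b Character vectors of case ids, or single integers
#'   giving set sizes (then `observed` must be supplied).
#' @param universe_size Number of cases in the universe.
#' @param observed Observed overlap; computed from the sets when they
#'   are given explicitly.
#' @param mode `"exact"` or `"montecarlo"`.
#' @param m Number of Monte-Carlo permutations.
#' @param seed Seed for the Monte-Carlo mode.
#' @return List with `n_universe`, `size_a`, `size_b`, `observed`,
#'   `expected`, `p_value`, `mode` (and `b`, `m` for Monte-Carlo).
#' @export
overlap_test <- function(set_a, set_b, universe_size, observed = NULL,
                         mode = c("exact", "montecarlo"), m = 10000L,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(set_a) || is.character(set_b)) {
    size_a <- length(unique(set_a))
    size_b <- length(unique(set_b))
    observed <- length(intersect(set_a, set_b))
  } else {
    size_a <- as.integer(set_a)
    size_b <- as.integer(set_b)
    if (is.null(observed))
      stop("observed overlap must be given when sets are passed as sizes",
           call. = FALSE)
  }
  n_u <- as.integer(universe_size)
  if (size_a > n_u || size_b > n_u)
    stop("set sizes cannot exceed the universe size", call. = FALSE)
  if (observed > min(size_a, size_b))
    stop("observed overlap exceeds the smaller set", call. = FALSE)

  expected <- size_a * size_b / n_u
  if (mode == "exact") {
    p <- stats::phyper(observed - 1L, size_a, n_u - size_a, size_b,
                       lower.tail = FALSE)
    res <- list(p_value = p)
  } else {
    set.seed(seed)
    b <- 0L
    for (i in seq_len(m)) {
      a <- sample.int(n_u, size_a)
      bb <- sample.int(n_u, size_b)
      if (length(intersect(a, bb)) >= observed) b <- b + 1L
    }
    res <- list(p_value = (b + 1) / (m + 1), b = b, m = as.integer(m))
  }
  c(list(n_universe = n_u, size_a = size_a, size_b = size_b,
         observed = as.integer(observed), expected = expected,
         mode = mode), res)
}

#' Per-case mutation burden
#'
#' Counts total events and transition/transversion substitution events
#' per case. Indels count toward the total only. Cases listed in
#' `case_ids` but absent from the table get zero rows.
#'
#' @param consensus Consensus table from [merge_caller_calls()].
#' @param case_ids Optional character vector of all case ids (e.g. the
#'   sample sheet's tumor cases).
#' @return Data frame with columns `case_id`, `n_total`, `n_transition`,
#'   `n_transversion`.
#' @export
case_burden <- function(consensus, case_ids = NULL) {
  if (is.null(case_ids)) case_ids <- sort(unique(consensus$case_id))
  is_sub <- consensus$Reference_Allele %in% BASES &
    consensus$Tumor_Seq_Allele2 %in% BASES &
    consensus$Reference_Allele != consensus$Tumor_Seq_Allele2
  ts <- rep(FALSE, nrow(consensus))
  ts[is_sub] <- classify_substitution(
    consensus$Reference_Allele[is_sub],
    consensus$Tumor_Seq_Allele2[is_sub]) == "transition"
  f <- factor(consensus$case_id, levels = case_ids)
  data.frame(case_id = case_ids,
             n_total = as.integer(table(f)),
             n_transition = as.integer(tapply(ts, f, sum, default = 0)),
             n_transversion = as.integer(tapply(is_sub & !ts, f, sum,
                                                default = 0)),
             stringsAsFactors = FALSE)
}

#' Compare mutation burden between activated and non-activated cases
#'
#' Two-sided Mann-Whitney U test per tumor type (exact for group sizes
#' up to 8 without ties, normal approximation with continuity and tie
#' correction otherwise), Benjamini-Hochberg adjusted across types.
#' Types lacking cases in either group are skipped with a warning.
#'
#' @param burden Burden table from [case_burden()].
#' @param activated Logical vector aligned with `burden` rows.
#' @param tumor_type Character vector aligned with `burden` rows.
#' @return Data frame with per-type group sizes, medians, `p_value` and
#'   BH-adjusted `q_value`.
#' @export
burden_comparison <- function(burden, activated, tumor_type) {
  stopifnot(nrow(burden) == length(activated),
            nrow(burden) == length(tumor_type))
  out <- lapply(sort(unique(tumor_type)), function(tt) {
    x <- burden$n_total[tumor_type == tt & activated]
    y <- burden$n_total[tumor_type == tt & !activated]
    if (length(x) == 0L || length(y) == 0L) {
      warning("tumor type ", tt, " lacks cases in one group; skipped",
              call. = FALSE)
      return(NULL)
    }
    p <- if (all(c(x, y) == c(x, y)[1])) 1 else {
      exact <- max(length(x), length(y)) <= 8L &&
        !anyDuplicated(c(x, y))
      suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                          correct = TRUE)$p.value)
    }
    data.frame(tumor_type = tt, n_active = length(x),
               n_inactive = length(y), median_active = stats::median(x),
               median_inactive = stats::median(y), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(out) && nrow(out) > 0L) out$q_value <- bh_adjust(out$p_value)
  out
}

#' Pearson correlation with a Fisher-transform p-value
#'
#' The two-sided p-value comes from z = atanh(r) compared against a
#' standard normal after scaling by sqrt(n - 3).
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List with `r`, `n`, `z`, `p_value`.
#' @export
pearson_fisher_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L)
    stop("need at least 4 paired observations for the Fisher transform",
         call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, n = n, z = NA_real_, p_value = NA_real_))
  }
  r <- stats::cor(x, y)
  z <- atanh(min(max(r, -1), 1))
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z) * sqrt(n - 3))
  list(r = r, n = n, z = z, p_value = p)
}

#' Correlate per-type activation frequency with substitution burden
#'
#' Computes Pearson correlations (with Fisher-transform p-values)
#' between the per-tumor-type activation fraction and the per-type
#' median transversion and transition burdens.
#'
#' @param activation_fraction Per-type fraction of activated cases.
#' @param median_tv,median_ts Per-type median transversion and
#'   transition counts, aligned with `activation_fraction`.
#' @return List with elements `transversion` and `transition`, each a
#'   [pearson_fisher_test()] result.
#' @export
activation_mutation_correlation <- function(activation_fraction,
                                            median_tv, median_ts) {
  list(transversion = pearson_fisher_test(activation_fraction, median_tv),
       transition = pearson_fisher_test(activation_fraction, median_ts))
}
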