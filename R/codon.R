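# Codon substitution-spectrum analysis: enumeration of all
# single-nucleotide codon neighbors under the standard genetic code and
# Monte-Carlo bias testing of observed variant spectra at a position.

#' Enumerate the nine single-nucleotide neighbors of a codon
#'
#' Every codon has exactly 3 positions x 3 alternative bases = 9
#' single-substitution neighbors. Each is translated with the standard
#' genetic code (translation table 1) and classified as synonymous
#' (amino acid unchanged), nonsense (stop gained) or missense.
#'
#' @param codon Three-letter codon over A/C/G/T (case-insensitive).
#' @return Data frame with 9 rows: `source_codon`, `offset` (changed
#'   position 1-3), `alt_base`, `alt_codon`, `source_aa`, `alt_aa`,
#'   `class`.
#' @export
single_substitution_variants <- function(codon) {
  codon <- toupper(codon)
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      !all(strsplit(codon, "")[[1]] %in% BASES))
    stop("codon must be three bases over A/C/G/T", call. = FALSE)
  code <- Biostrings::GENETIC_CODE
  src_aa <- unname(code[codon])
  bases <- strsplit(codon, "")[[1]]
  rows <- do.call(rbind, lapply(1:3, function(off) {
    do.call(rbind, lapply(setdiff(BASES, bases[off]), function(alt) {
      nb <- bases
      nb[off] <- alt
      alt_codon <- paste(nb, collapse = "")
      alt_aa <- unname(code[alt_codon])
      cls <- if (alt_aa == src_aa) "synonymous"
        else if (alt_aa == "*" && src_aa != "*") "nonsense"
        else "missense"
      data.frame(source_codon = codon, offset = off, alt_base = alt,
                 alt_codon = alt_codon, source_aa = src_aa,
                 alt_aa = alt_aa, class = cls, stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' Monte-Carlo bias test of an observed variant spectrum at a codon
#'
#' Null model: the n observed events are distributed over the codon's 9
#' single-nucleotide substitutions with equal probability (or with
#' transition substitutions weighted by `kappa`), then aggregated to
#' amino-acid outcomes. Per missense outcome, enrichment is the upper
#' tail (null count >= observed) and depletion the lower tail, both via
#' the (b + 1)/(m + 1) estimator and Benjamini-Hochberg adjusted across
#' the tested outcomes. Stop-gain outcomes are reported but not tested.
#'
#' @param observed Named integer vector of observed counts per alternate
#'   amino acid (one-letter; `"*"` allowed for stop). Outcomes not named
#'   count as 0.
#' @param codon Source codon.
#' @param m Number of permutations.
#' @param seed Integer seed.
#' @param kappa Optional transition/transversion weight for the null
#'   (`NULL` = unweighted).
#' @return Data frame per amino-acid outcome: `alt_aa`, `class`,
#'   `null_prob`, `observed`, `p_enrich`, `q_enrich`, `p_deplete`,
#'   `q_deplete` (NA for untested outcomes).
#' @export
variant_spectrum_bias <- function(observed, codon, m = 100000L, seed = 1L,
                                  kappa = NULL) {
  nb <- single_substitution_variants(codon)
  n <- sum(observed)
  if (n < 1) stop("need at least one observed event", call. = FALSE)
  bad <- setdiff(names(observed), nb$alt_aa)
  if (length(bad) > 0L)
    stop("observed variant(s) not reachable by single substitution: ",
         paste(bad, collapse = ", "), call. = FALSE)

  w <- rep(1, 9)
  if (!is.null(kappa)) {
    ref_base <- substr(nb$source_codon, nb$offset, nb$offset)
    w <- ifelse(TRANSITION_PARTNER[ref_base] == nb$alt_base, kappa, 1)
  }
  w <- w / sum(w)
  outcomes <- sort(unique(nb$alt_aa))
  prob <- vapply(outcomes, function(a) sum(w[nb$alt_aa == a]), numeric(1))
  obs <- vapply(outcomes, function(a)
    if (a %in% names(observed)) observed[[a]] else 0L, numeric(1))

  set.seed(seed)
  draws <- stats::rmultinom(m, size = n, prob = prob)
  b_enr <- rowSums(draws >= obs)
  b_dep <- rowSums(draws <= obs)
  p_enr <- montecarlo_pvalue(b_enr, m)
  p_dep <- montecarlo_pvalue(b_dep, m)

  cls <- nb$class[match(outcomes, nb$alt_aa)]
  tested <- cls == "missense"
  out <- data.frame(alt_aa = outcomes, class = cls, null_prob = unname(prob),
                    observed = unname(obs),
                    p_enrich = NA_real_, q_enrich = NA_real_,
                    p_deplete = NA_real_, q_deplete = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$p_enrich[tested] <- p_enr[tested]
  out$p_deplete[tested] <- p_dep[tested]
  out$q_enrich[tested] <- bh_adjust(out$p_enrich[tested])
  out$q_deplete[tested] <- bh_adjust(out$p_deplete[tested])
  out
}

#' Tabulate variants observed at one protein position
#'
#' Contingency counts of alternate amino acid (frameshifts pooled as
#' `"fs"`) by tumor type for the nonsynonymous records of a gene at a
#' position. Totals match [position_counts()] at that position.
#'
#' @param consensus Consensus table from [merge_caller_calls()].
#' @param gene Gene symbol.
#' @param position 1-based codon index.
#' @return Contingency table, variants x tumor types.
#' @export
tabulate_position_variants <- function(consensus, gene, position) {
  rows <- consensus[consensus$Hugo_Symbol == gene &
                      consensus$variant_class %in% NONSYNONYMOUS_CLASSES &
                      !is.na(consensus$protein_pos) &
                      consensus$protein_pos == position, , drop = FALSE]
  table(variant = rows$alt_aa, tumor_type = rows$tumor_type)
}
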