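# Shared fixtures and independent oracles.

# A small cohort configuration for fast tests; overrides are passed on.
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_cases = 60L, n_normals = 12L,
               background_mutation_rate = 6)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Minimal consensus-shaped data frame for functions that only need a few
# columns.
make_consensus <- function(case_id, gene, protein_pos,
                           ref = "C", alt = "A",
                           variant_class = "missense",
                           alt_aa = "G", tumor_type = "LUSC") {
  n <- length(case_id)
  if (n == 0L)
    return(data.frame(case_id = character(0),
                      Tumor_Sample_Barcode = character(0),
                      Hugo_Symbol = character(0),
                      tumor_type = character(0),
                      Reference_Allele = character(0),
                      Tumor_Seq_Allele2 = character(0),
                      protein_pos = integer(0),
                      alt_aa = character(0),
                      variant_class = character(0),
                      stringsAsFactors = FALSE))
  data.frame(case_id = case_id,
             Tumor_Sample_Barcode = paste0(case_id, "-01A"),
             Hugo_Symbol = rep_len(gene, n),
             tumor_type = rep_len(tumor_type, n),
             Reference_Allele = rep_len(ref, n),
             Tumor_Seq_Allele2 = rep_len(alt, n),
             protein_pos = rep_len(protein_pos, n),
             alt_aa = rep_len(alt_aa, n),
             variant_class = rep_len(variant_class, n),
             stringsAsFactors = FALSE)
}

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments (distinct values only).
exact_mw_p <- function(x, y) {
  vals <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(vals), nx)
  stats <- apply(idx, 2, function(i) {
    xx <- vals[i]
    sum(outer(xx, vals[-i], ">")) # U statistic
  })
  u_obs <- sum(outer(x, y, ">"))
  mu <- nx * length(y) / 2
  mean(abs(stats - mu) >= abs(u_obs - mu))
}

# Brute-force overlap tail probability: enumerate all subset pairs of
# sizes K and n from a universe of size N, count overlap >= k.
brute_overlap_p <- function(N, K, n, k) {
  subsets_a <- utils::combn(N, K, simplify = FALSE)
  subsets_b <- utils::combn(N, n, simplify = FALSE)
  hits <- 0L
  for (a in subsets_a)
    for (b in subsets_b)
      if (length(intersect(a, b)) >= k) hits <- hits + 1L
  hits / (length(subsets_a) * length(subsets_b))
}

# Codon neighbor enumeration through an independent route:
# Biostrings::translate on explicitly built neighbor codons.
oracle_neighbors <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  out <- NULL
  for (off in 1:3)
    for (alt in setdiff(c("A", "C", "G", "T"), bases[off])) {
      nb <- bases
      nb[off] <- alt
      alt_codon <- paste(nb, collapse = "")
      aas <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(c(codon, alt_codon)),
        no.init.codon = TRUE))
      cls <- if (aas[2] == aas[1]) "synonymous"
        else if (aas[2] == "*" && aas[1] != "*") "nonsense"
        else "missense"
      out <- rbind(out, data.frame(alt_codon = alt_codon,
                                   source_aa = aas[1], alt_aa = aas[2],
                                   class = cls, stringsAsFactors = FALSE))
    }
  out
}
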