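# Synthetic cohort generator: mutation tables, sample sheets, count
# matrices and chase series with the statistical structure the analysis
# stages assume. All stages draw from substreams of one global seed.

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

maf_columns <- c("Tumor_Sample_Barcode", "tumor_type", "Hugo_Symbol",
                 "Chromosome", "Start_Position", "Reference_Allele",
                 "Tumor_Seq_Allele2", "Variant_Classification",
                 "HGVSp_Short")

mutation_key <- function(df) {
  paste(case_from_barcode(df$Tumor_Sample_Barcode), df$Hugo_Symbol,
        df$Chromosome, df$Start_Position, df$Reference_Allele,
        df$Tumor_Seq_Allele2, sep = "|")
}

#' Simulate per-caller somatic mutation tables and a sample sheet
#'
#' Draws a Poisson number of true somatic events per tumor case. Events in
#' the hotspot gene land on the planted codon with the configured fraction
#' and uniformly elsewhere; every other gene is hit uniformly along its
#' protein. Each true event is reported by each of the four callers (MuSE,
#' MuTect2, SomaticSniper, VarScan2) independently with probability
#' `caller_concordance`; spurious events carrying exactly one caller flag
#' are added at `spurious_rate` per case. Substitutions are transitions
#' with odds `ts_tv_ratio` : 1. Tumor cases carrying a nonsynonymous event
#' in the hotspot gene or in KEAP1 are flagged activated, topped up with
#' random non-mutant tumors to reach `activation_spec$fraction`.
#'
#' @param config A [sim_config()] object.
#' @return A list with `per_caller` (named list of MAF-style data frames,
#'   one per caller), `truth` (the deduplicated true-event table with the
#'   drawn caller flags in a semicolon-joined `callers` column), and
#'   `sample_sheet` (case id, tumor type, tissue, activated flag).
#' @export
simulate_mutations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "mutations"))

  type_names <- names(config$tumor_types)
  tumor_type <- sample(type_names, config$n_cases, replace = TRUE,
                       prob = config$tumor_types)
  case_id <- sprintf("TCGA-%02d-%04d", match(tumor_type, type_names),
                     seq_len(config$n_cases))
  normal_type <- rep_len(type_names, config$n_normals)
  normal_id <- sprintf("TCGA-N%01d-%04d",
                       match(normal_type, type_names) %% 10L,
                       seq_len(config$n_normals))

  genes <- names(config$protein_length_by_gene)
  lens <- config$protein_length_by_gene
  hs <- config$hotspot_spec

  draw_events <- function(n_per_case, spurious) {
    idx <- rep.int(seq_along(n_per_case), n_per_case)
    n <- length(idx)
    if (n == 0L) return(NULL)
    gene <- sample(genes, n, replace = TRUE)
    pos <- vapply(gene, function(g) sample.int(lens[[g]], 1L), integer(1))
    at_hot <- gene == hs$gene & stats::runif(n) < hs$fraction
    pos[at_hot] <- hs$position

    cls <- sample(c("Missense_Mutation", "Silent", "Nonsense_Mutation",
                    "Frame_Shift_Del"), n, replace = TRUE,
                  prob = c(0.85, 0.05, 0.05, 0.05))
    cls[at_hot] <- "Missense_Mutation"

    ref <- sample(BASES, n, replace = TRUE)
    is_ts <- stats::runif(n) < config$ts_tv_ratio / (config$ts_tv_ratio + 1)
    alt <- ifelse(is_ts, TRANSITION_PARTNER[ref],
                  vapply(ref, function(b) {
                    sample(setdiff(BASES, c(b, TRANSITION_PARTNER[[b]])), 1L)
                  }, character(1)))
    is_fs <- cls == "Frame_Shift_Del"
    alt[is_fs] <- "-"

    ref_aa <- sample(AA1, n, replace = TRUE)
    ref_aa[at_hot] <- hs$ref_aa
    alt_aa <- vapply(ref_aa, function(a) sample(setdiff(AA1, a), 1L),
                     character(1))
    alt_aa[at_hot] <- sample(names(hs$alt_weights), sum(at_hot),
                             replace = TRUE, prob = hs$alt_weights)
    alt_aa[cls == "Silent"] <- ref_aa[cls == "Silent"]
    alt_aa[cls == "Nonsense_Mutation"] <- "*"
    hgvsp <- ifelse(is_fs, sprintf("p.%s%dfs", ref_aa, pos),
                    sprintf("p.%s%d%s", ref_aa, pos, alt_aa))

    data.frame(case_index = idx,
               Hugo_Symbol = gene,
               Chromosome = paste0("chr", match(gene, genes)),
               Start_Position = match(gene, genes) * 10000000L +
                 (pos - 1L) * 3L + sample.int(3L, n, replace = TRUE),
               Reference_Allele = ref,
               Tumor_Seq_Allele2 = alt,
               Variant_Classification = cls,
               HGVSp_Short = hgvsp,
               spurious = spurious,
               stringsAsFactors = FALSE)
  }

  n_true <- stats::rpois(config$n_cases, config$background_mutation_rate)
  truth <- draw_events(n_true, spurious = FALSE)
  if (is.null(truth))
    stop("no events drawn; raise background_mutation_rate", call. = FALSE)
  truth$Tumor_Sample_Barcode <- paste0(case_id[truth$case_index], "-01A")
  truth$tumor_type <- tumor_type[truth$case_index]
  truth <- truth[!duplicated(mutation_key(truth)), , drop = FALSE]

  # Independent per-caller reporting of every true event.
  flags <- matrix(stats::runif(nrow(truth) * 4L) < config$caller_concordance,
                  nrow = nrow(truth), ncol = 4L,
                  dimnames = list(NULL, CALLER_SET))
  truth$callers <- apply(flags, 1L, function(f)
    paste(CALLER_SET[f], collapse = ";"))

  n_spur <- stats::rpois(config$n_cases, config$spurious_rate)
  spur <- draw_events(n_spur, spurious = TRUE)
  if (!is.null(spur)) {
    spur$Tumor_Sample_Barcode <- paste0(case_id[spur$case_index], "-01A")
    spur$tumor_type <- tumor_type[spur$case_index]
    # Spurious calls never collide with true keys or each other, so the
    # >= 2-caller filter removes exactly the spurious set.
    keep <- !duplicated(mutation_key(spur)) &
      !(mutation_key(spur) %in% mutation_key(truth))
    spur <- spur[keep, , drop = FALSE]
    spur$caller <- sample(CALLER_SET, nrow(spur), replace = TRUE)
  }

  per_caller <- lapply(CALLER_SET, function(cl) {
    rows <- truth[flags[, cl], maf_columns, drop = FALSE]
    if (!is.null(spur) && nrow(spur) > 0L)
      rows <- rbind(rows, spur[spur$caller == cl, maf_columns, drop = FALSE])
    rownames(rows) <- NULL
    rows
  })
  names(per_caller) <- CALLER_SET

  # Activation: driver-gene mutant tumors, topped up to the target fraction.
  driver_genes <- intersect(c(hs$gene, "KEAP1"), genes)
  nonsyn <- !truth$Variant_Classification %in% c("Silent")
  mutant_cases <- unique(case_from_barcode(
    truth$Tumor_Sample_Barcode[nonsyn & truth$Hugo_Symbol %in% driver_genes]))
  target <- round(config$activation_spec$fraction * config$n_cases)
  activated <- case_id %in% mutant_cases
  deficit <- target - sum(activated)
  if (deficit > 0L) {
    pool <- which(!activated)
    activated[sample(pool, min(deficit, length(pool)))] <- TRUE
  }

  sample_sheet <- data.frame(
    case_id = c(case_id, normal_id),
    tumor_type = c(tumor_type, normal_type),
    tissue = rep(c("tumor", "normal"), c(config$n_cases, config$n_normals)),
    activated = c(activated, rep(FALSE, config$n_normals)),
    stringsAsFactors = FALSE)

  truth <- truth[order(mutation_key(truth)),
                 c(maf_columns, "callers"), drop = FALSE]
  rownames(truth) <- NULL
  list(per_caller = per_caller, truth = truth, sample_sheet = sample_sheet)
}

#' Simulate a negative-binomial RNA-seq count matrix
#'
#' Gene baselines are log-normal; signature-true genes gain
#' `activation_spec$log2_effect` log2 units in activated tumors; batch
#' genes gain the per-tumor-type offset in every sample (tumor and
#' normal) of that type. Counts are negative binomial with variance
#' mu + alpha * mu^2.
#'
#' @param sample_sheet Sample sheet as produced by [simulate_mutations()]
#'   (columns `case_id`, `tumor_type`, `tissue`, `activated`).
#' @param config A [sim_config()] object.
#' @return Integer matrix, genes in rows, samples (case ids) in columns.
#' @export
simulate_expression <- function(sample_sheet, config) {
  stopifnot(inherits(config, "sim_config"))
  req <- c("case_id", "tumor_type", "tissue", "activated")
  if (!all(req %in% names(sample_sheet)))
    stop("sample_sheet must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  set.seed(derive_seed(config$seed, "expression"))

  act <- config$activation_spec
  bat <- config$batch_spec
  fillers <- sprintf("GENE%04d",
                     seq_len(config$n_genes - length(act$genes) -
                               length(bat$genes)))
  genes <- c(act$genes, bat$genes, fillers)

  baseline <- config$baseline_means
  if (is.null(baseline))
    baseline <- stats::rlnorm(config$n_genes, meanlog = log(100), sdlog = 1)
  if (!any(baseline > 0))
    stop("all-zero baseline means are forbidden", call. = FALSE)

  n_s <- nrow(sample_sheet)
  log2_mu <- matrix(log2(baseline), nrow = config$n_genes, ncol = n_s)
  is_act <- sample_sheet$tissue == "tumor" & sample_sheet$activated
  log2_mu[genes %in% act$genes, is_act] <-
    log2_mu[genes %in% act$genes, is_act] + act$log2_effect
  for (tt in names(bat$offsets)) {
    cols <- sample_sheet$tumor_type == tt
    log2_mu[genes %in% bat$genes, cols] <-
      log2_mu[genes %in% bat$genes, cols] + bat$offsets[[tt]]
  }

  counts <- matrix(stats::rnbinom(config$n_genes * n_s,
                                  mu = 2^log2_mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = config$n_genes, ncol = n_s,
                   dimnames = list(genes, sample_sheet$case_id))
  counts
}

#' Simulate cycloheximide-chase decay series
#'
#' Intensities follow N0 * exp(-ln(2) * t / t_half) with multiplicative
#' log-normal noise, per construct and replicate.
#'
#' @param config A [sim_config()] object; see `chase_spec`.
#' @param n0 Intensity at time zero (arbitrary densitometry units).
#' @return Data frame with columns `construct`, `replicate`, `time_min`,
#'   `intensity`.
#' @export
simulate_chase <- function(config, n0 = 100) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "chase"))
  cs <- config$chase_spec
  grid <- expand.grid(time_min = cs$timepoints,
                      replicate = seq_len(cs$replicates),
                      construct = names(cs$half_lives),
                      stringsAsFactors = FALSE)
  t_half <- cs$half_lives[grid$construct]
  noise <- if (cs$noise_sd > 0)
    exp(stats::rnorm(nrow(grid), 0, cs$noise_sd)) else 1
  grid$intensity <- n0 * exp(-log(2) * grid$time_min / t_half) * noise
  grid[, c("construct", "replicate", "time_min", "intensity")]
}

#' Write the synthetic cohort to plain-text files
#'
#' Writes per-caller MAF-like TSVs, the sample sheet, the count matrix
#' and the chase series into a directory.
#'
#' @param config A [sim_config()] object.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the list of written file paths.
#' @export
write_cohort <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_mutations(config)
  counts <- simulate_expression(sim$sample_sheet, config)
  chase <- simulate_chase(config)
  paths <- c(
    vapply(names(sim$per_caller), function(cl) {
      p <- file.path(outdir, paste0(tolower(cl), ".maf.tsv"))
      utils::write.table(sim$per_caller[[cl]], p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      p
    }, character(1)),
    sample_sheet = {
      p <- file.path(outdir, "sample_sheet.tsv")
      utils::write.table(sim$sample_sheet, p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      p
    },
    counts = {
      p <- file.path(outdir, "counts.tsv")
      utils::write.table(data.frame(gene = rownames(counts), counts,
                                    check.names = FALSE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    },
    chase = {
      p <- file.path(outdir, "chase.tsv")
      utils::write.table(chase, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    })
  invisible(paths)
}
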