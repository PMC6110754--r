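# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

CALLER_SET <- c("MuSE", "MuTect2", "SomaticSniper", "VarScan2")

# One-letter amino acids (no stop).
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Deterministic per-stage substream seed derived from one global seed.
# Kept strictly below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483399)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

stop_if_not_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(!is.finite(x) | x <= 0) else any(!is.finite(x) | x < 0)
  if (!is.numeric(x) || length(x) == 0L || bad)
    stop(sprintf("`%s` must be %spositive and finite", name,
                 if (strict) "strictly " else "non-negative, "), call. = FALSE)
  invisible(x)
}

# TCGA-style participant identity: first 12 characters of the barcode.
case_from_barcode <- function(barcode) substr(barcode, 1L, 12L)
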