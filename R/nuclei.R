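# Single-nucleus QC filtering and integrative HTO + genotype demultiplex
# consolidation.
#
# QC keeps nuclei with 2000 <= n_features <= 10000 and pct_mito <= 5 (the
# removal rule is strict: > 10,000 or < 2000 features, or > 5% mitochondrial
# reads). Consolidation trusts a confident HTO singlet only when the
# genotype call agrees; HTO doublets/negatives fall back to the genotype
# assignment; everything else is discarded.

#' Nucleus quality-control filter
#'
#' @param records data.frame with `barcode`, `n_features`, `pct_mito`
#' @return list: `kept` (filtered records), `report` (counts per removal
#'   reason: features_low, features_high, mito_high)
#' @export
qc_filter <- function(records) {
  req <- c("barcode", "n_features", "pct_mito")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop_validation(sprintf("records missing columns: %s", paste(miss, collapse = ", ")))
  bad <- !is.finite(records$n_features) | !is.finite(records$pct_mito) |
    records$pct_mito < 0 | records$pct_mito > 100 | records$n_features < 0
  if (any(bad))
    stop_validation(sprintf("malformed record(s): %s",
                            paste(utils::head(records$barcode[bad], 3), collapse = ", ")))
  features_low <- records$n_features < 2000
  features_high <- records$n_features > 10000
  mito_high <- records$pct_mito > 5
  keep <- !(features_low | features_high | mito_high)
  list(kept = records[keep, , drop = FALSE],
       report = list(n_input = nrow(records), n_kept = sum(keep),
                     features_low = sum(features_low),
                     features_high = sum(features_high),
                     mito_high = sum(mito_high)))
}

HTO_SPECIAL <- c("Doublet", "Negative")
GENO_SPECIAL <- c("Doublet", "Unassigned")

#' Consolidate HTO and genotype sample assignments
#'
#' Decision rules, applied per nucleus:
#' \describe{
#'   \item{R1}{HTO singlet S, genotype S: assign S.}
#'   \item{R2}{HTO singlet S, genotype singlet S' != S: discard.}
#'   \item{R3}{HTO Doublet/Negative, genotype singlet S: assign S.}
#'   \item{R4}{HTO Doublet/Negative, genotype Doublet/Unassigned: discard.}
#'   \item{R5}{HTO singlet S, genotype Doublet/Unassigned: discard by
#'     default; with `trust_hto = TRUE` the HTO call S is kept.}
#' }
#'
#' @param records data.frame with `barcode`, `hto_call`, `genotype_call`
#' @param samples valid sample ids; defaults to all singlet calls observed
#' @param trust_hto keep the HTO singlet when the genotype is uninformative
#' @return data.frame: barcode, assigned_sample ("Discarded" or a sample id),
#'   rule_applied
#' @export
consolidate_assignments <- function(records, samples = NULL, trust_hto = FALSE) {
  if (is.null(samples))
    samples <- setdiff(unique(c(records$hto_call, records$genotype_call)),
                       c(HTO_SPECIAL, GENO_SPECIAL))
  bad_h <- setdiff(unique(records$hto_call), c(samples, HTO_SPECIAL))
  bad_g <- setdiff(unique(records$genotype_call), c(samples, GENO_SPECIAL))
  if (length(bad_h) || length(bad_g))
    stop_validation(sprintf("unknown call token(s): %s",
                            paste(c(bad_h, bad_g), collapse = ", ")))
  hto_singlet <- !(records$hto_call %in% HTO_SPECIAL)
  geno_singlet <- !(records$genotype_call %in% GENO_SPECIAL)
  assigned <- rep("Discarded", nrow(records))
  rule <- character(nrow(records))

  r1 <- hto_singlet & geno_singlet & records$hto_call == records$genotype_call
  r2 <- hto_singlet & geno_singlet & records$hto_call != records$genotype_call
  r3 <- !hto_singlet & geno_singlet
  r4 <- !hto_singlet & !geno_singlet
  r5 <- hto_singlet & !geno_singlet
  assigned[r1] <- records$hto_call[r1];      rule[r1] <- "R1"
  rule[r2] <- "R2"
  assigned[r3] <- records$genotype_call[r3]; rule[r3] <- "R3"
  rule[r4] <- "R4"
  rule[r5] <- "R5"
  if (trust_hto) assigned[r5] <- records$hto_call[r5]
  data.frame(barcode = records$barcode, assigned_sample = assigned,
             rule_applied = rule, row.names = NULL, stringsAsFactors = FALSE)
}
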