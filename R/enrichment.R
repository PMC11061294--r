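# Genomic-context enrichment of hit sets, stratified by Infinium probe
# design type with the Mantel-Haenszel common odds ratio, plus the
# stepwise-model context-proportion trend and Venn-partition accounting.

#' Cross-tabulate hits vs a genomic context, stratified by design type
#'
#' @param hits probe-id vector (subset of `universe`)
#' @param universe all analyzable probe ids for the assay
#' @param annotation probe annotation with `probe_id`, `design_type` and a
#'   0/1 column named by `context`
#' @param context annotation column to test
#' @return list of per-stratum counts `list(a, b, c, d, n)` named by design
#'   type (a = hit & context, b = hit & !context, c = non-hit & context,
#'   d = non-hit & !context)
#' @export
build_stratified_tables <- function(hits, universe, annotation, context) {
  extra <- setdiff(hits, universe)
  if (length(extra))
    stop_validation(sprintf("hits absent from universe: %s",
                            paste(utils::head(extra, 3), collapse = ", ")))
  ann <- annotation[match(universe, annotation$probe_id), ]
  if (anyNA(ann$probe_id))
    stop_validation("universe probes missing from annotation")
  if (!context %in% colnames(ann))
    stop_validation(sprintf("context '%s' not in annotation", context))
  is_hit <- universe %in% hits
  in_ctx <- ann[[context]] == 1
  tables <- list()
  for (s in sort(unique(ann$design_type))) {
    idx <- ann$design_type == s
    tables[[s]] <- list(
      a = sum(is_hit & in_ctx & idx), b = sum(is_hit & !in_ctx & idx),
      c = sum(!is_hit & in_ctx & idx), d = sum(!is_hit & !in_ctx & idx))
    tables[[s]]$n <- with(tables[[s]], a + b + c + d)
  }
  tables
}

#' Mantel-Haenszel common odds ratio across strata
#'
#' OR_MH = sum_s(a_s d_s / n_s) / sum_s(b_s c_s / n_s); the 95% CI uses the
#' Robins-Breslow-Greenland variance of log OR_MH, and the p-value comes
#' from the MH chi-square statistic (no continuity correction by default).
#' Empty strata are skipped.
#'
#' @param tables output of [build_stratified_tables()]
#' @param correct apply the 0.5 continuity correction in the chi-square
#' @return list: `or_mh`, `ci_low`, `ci_high`, `p`, `chisq`, `tables`
#' @export
mantel_haenszel <- function(tables, correct = FALSE) {
  tables <- Filter(function(t) t$n > 0, tables)
  if (!length(tables)) stop_validation("all strata are empty")
  # integer counts overflow in the variance product; work in doubles
  tables <- lapply(tables, function(t) lapply(t, as.numeric))
  R_s <- vapply(tables, function(t) t$a * t$d / t$n, 0)
  S_s <- vapply(tables, function(t) t$b * t$c / t$n, 0)
  R <- sum(R_s); S <- sum(S_s)
  or_mh <- if (S > 0) R / S else Inf

  # RBG variance of log(OR_MH)
  P_s <- vapply(tables, function(t) (t$a + t$d) / t$n, 0)
  Q_s <- vapply(tables, function(t) (t$b + t$c) / t$n, 0)
  var_log <- if (R > 0 && S > 0)
    sum(P_s * R_s) / (2 * R^2) + sum(P_s * S_s + Q_s * R_s) / (2 * R * S) +
      sum(Q_s * S_s) / (2 * S^2)
  else NA_real_
  if (is.finite(or_mh) && or_mh > 0 && is.finite(var_log)) {
    ci <- exp(log(or_mh) + c(-1, 1) * stats::qnorm(0.975) * sqrt(var_log))
  } else if (is.infinite(or_mh)) {
    # zero denominator: one-sided interval
    ci <- c(NA_real_, Inf)
  } else ci <- c(NA_real_, NA_real_)

  # MH chi-square on sum(a) vs its conditional expectation
  a_sum <- sum(vapply(tables, function(t) t$a, 0))
  e_sum <- sum(vapply(tables, function(t) (t$a + t$b) * (t$a + t$c) / t$n, 0))
  v_sum <- sum(vapply(tables, function(t)
    if (t$n > 1) (t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d) /
      (t$n^2 * (t$n - 1)) else 0, 0))
  if (v_sum > 0) {
    dev <- abs(a_sum - e_sum)
    if (correct) dev <- max(0, dev - 0.5)
    chisq <- dev^2 / v_sum
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  } else { chisq <- 0; p <- 1 }
  list(or_mh = or_mh, ci_low = ci[1], ci_high = ci[2], p = p, chisq = chisq,
       tables = tables)
}

#' Context enrichment of a hit set (tabulate + MH test)
#'
#' @inheritParams build_stratified_tables
#' @param correct passed to [mantel_haenszel()]
#' @return an [mantel_haenszel()] result with `context` attached
#' @export
context_enrichment <- function(hits, universe, annotation, context,
                               correct = FALSE) {
  res <- mantel_haenszel(build_stratified_tables(hits, universe, annotation,
                                                 context), correct = correct)
  res$context <- context
  res
}

#' Trend between stepwise adjustment depth and context hit proportion
#'
#' Spearman correlation between the number of cell-type covariates k and the
#' fraction of hits carrying a context flag, across the stepwise series.
#'
#' @param hit_sets named list of probe-id vectors, names coercible to k
#' @param annotation probe annotation
#' @param context annotation column
#' @return list: `rho`, `p`, `points` (k, proportion); flagged `undefined`
#'   when fewer than 3 non-empty sets exist
#' @export
context_trend <- function(hit_sets, annotation, context) {
  ks <- as.numeric(names(hit_sets))
  prop <- vapply(hit_sets, function(h) {
    if (!length(h)) return(NA_real_)
    flags <- annotation[[context]][match(h, annotation$probe_id)]
    mean(flags == 1)
  }, 0)
  ok <- !is.na(prop)
  if (sum(ok) < 3)
    return(list(rho = NA_real_, p = NA_real_, undefined = TRUE,
                points = data.frame(k = ks, proportion = prop)))
  ct <- suppressWarnings(stats::cor.test(ks[ok], prop[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, undefined = FALSE,
       points = data.frame(k = ks, proportion = prop))
}

#' Exact Venn-partition cardinalities for named sets
#'
#' @param sets named list of >= 2 id vectors
#' @return data.frame with one row per non-empty membership pattern
#'   (`pattern` like "A&B", `count`), plus attribute `n_union`
#' @export
sharing_sets <- function(sets) {
  if (length(sets) < 2) stop_validation("need >= 2 sets")
  universe <- Reduce(union, sets)
  if (!length(universe)) {
    out <- data.frame(pattern = character(), count = integer())
    attr(out, "n_union") <- 0L
    return(out)
  }
  member <- sapply(sets, function(s) universe %in% s)
  if (is.null(dim(member))) member <- matrix(member, nrow = 1,
                                             dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "n_union") <- length(universe)
  out
}

#' Per-context proportions within a hit set
#'
#' @param hits probe-id vector
#' @param annotation probe annotation
#' @param contexts context columns to summarize
#' @return data.frame: context, n_hits_with_flag, proportion
#' @export
context_hit_proportions <- function(hits, annotation, contexts) {
  idx <- match(hits, annotation$probe_id)
  do.call(rbind, lapply(contexts, function(ctx) {
    flags <- annotation[[ctx]][idx]
    data.frame(context = ctx, n_hits_with_flag = sum(flags == 1, na.rm = TRUE),
               proportion = if (length(hits)) mean(flags == 1, na.rm = TRUE) else NA_real_)
  }))
}
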