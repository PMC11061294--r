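# Constrained maximum-likelihood inference of 5mC and 5hmC from paired
# BS/oxBS beta values.
#
# Model: the BS assay reads m + h and the oxBS assay reads m. With binomial
# pseudo-counts n_bs, n_ox the log-likelihood is
#   L(m, h) = n_bs [b_bs log(m+h) + (1-b_bs) log(1-m-h)]
#           + n_ox [b_ox log(m)   + (1-b_ox) log(1-m)]
# maximized over m >= 0, h >= 0, m + h <= 1 (0 log 0 = 0 by convention).
# The solution is closed-form: when b_bs >= b_ox the unconstrained optimum
# m = b_ox, h = b_bs - b_ox is feasible; otherwise the constraint h = 0 is
# active and the two assays pool into a precision-weighted mean.

#' Infer 5mC and 5hmC from paired BS and oxBS beta matrices
#'
#' @param bs,ox probes x samples beta matrices with identical dimnames
#' @param n_bs,n_ox positive pseudo-counts (effective binomial depth) for
#'   the BS and oxBS assays; defaults treat the assays as equally precise
#' @return list with `m` (5mC), `h` (5hmC) and `boundary` (logical matrix;
#'   TRUE where the h >= 0 constraint was active). Missing inputs propagate
#'   to missing outputs.
#' @examples
#' est <- estimate_modifications(matrix(0.5), matrix(0.3))
#' est$m  # 0.3
#' est$h  # 0.2
#' @export
estimate_modifications <- function(bs, ox, n_bs = 100, n_ox = 100) {
  if (!is.matrix(bs)) bs <- as.matrix(bs)
  if (!is.matrix(ox)) ox <- as.matrix(ox)
  assert_same_index(bs, ox, "bs", "ox")
  assert_beta_matrix(bs, "bs"); assert_beta_matrix(ox, "ox")
  if (n_bs <= 0 || n_ox <= 0) stop_validation("pseudo-counts must be positive")

  interior <- bs >= ox
  m <- ifelse(interior, ox, (n_bs * bs + n_ox * ox) / (n_bs + n_ox))
  h <- ifelse(interior, bs - ox, 0)
  boundary <- !interior
  na <- is.na(bs) | is.na(ox)
  m[na] <- NA_real_; h[na] <- NA_real_; boundary[na] <- NA
  list(m = m, h = h, boundary = boundary)
}

#' Grid-search likelihood oracle for the paired BS/oxBS model
#'
#' Brute-force maximization of the binomial log-likelihood over (m, h) grids
#' on the constrained simplex, refined coarse-to-fine down to `step` (the
#' likelihood is concave in (m, h), so refining around the coarse maximum is
#' exact up to grid resolution). Used as an independent check of the
#' closed-form solution.
#'
#' @param beta_bs,beta_ox scalar beta values
#' @param n_bs,n_ox pseudo-counts
#' @param step final grid resolution
#' @return list with `m`, `h` at the grid maximum
#' @export
oxbs_grid_oracle <- function(beta_bs, beta_ox, n_bs = 100, n_ox = 100,
                             step = 1e-4) {
  # x is a scalar beta, y a vector of grid means; 0 log 0 = 0
  xlogy <- function(x, y) {
    if (x == 0) return(rep(0, length(y)))
    x * log(pmax(y, .Machine$double.xmin))
  }
  loglik <- function(m, h) {
    tot <- m + h
    n_bs * (xlogy(beta_bs, tot) + xlogy(1 - beta_bs, 1 - tot)) +
      n_ox * (xlogy(beta_ox, m) + xlogy(1 - beta_ox, 1 - m))
  }
  lo_m <- 0; hi_m <- 1; lo_h <- 0; hi_h <- 1
  s <- 1e-2
  repeat {
    gm <- seq(lo_m, hi_m, by = s)
    gh <- seq(lo_h, hi_h, by = s)
    pts <- expand.grid(m = gm, h = gh)
    pts <- pts[pts$m + pts$h <= 1 + 1e-12, ]
    ll <- loglik(pts$m, pts$h)
    best <- pts[which.max(ll), ]
    if (s <= step) return(list(m = best$m, h = best$h))
    lo_m <- max(0, best$m - 2 * s); hi_m <- min(1, best$m + 2 * s)
    lo_h <- max(0, best$h - 2 * s); hi_h <- min(1, best$h + 2 * s)
    s <- max(step, s / 10)
  }
}
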