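# Binomial assembly models: an n-mer built from independent draws of the
# subunit proteoform distribution has the n-fold self-convolution of that
# distribution as its mass distribution. Plus occupancy/independence tests
# for PTM-oligomerization coupling and dimer/monomer ratio quantification.

#' Weighted mean and variance of a mass distribution
#' @param md `mass_distribution` or data.frame with `mass`, `abundance`.
#' @return list with `mean`, `var`, `sd`.
#' @export
md_moments <- function(md) {
  w <- md$abundance / sum(md$abundance)
  mu <- sum(w * md$mass)
  v <- sum(w * (md$mass - mu)^2)
  list(mean = mu, var = v, sd = sqrt(v))
}

#' Predict an n-mer mass distribution by self-convolution
#'
#' Under independent subunit draws, the n-mer distribution is the n-fold
#' self-convolution of the subunit distribution, shifted by
#' `interface_delta` (mass gained or lost at the interface; the default 0
#' encodes assembly without additional interfacial ligands). Exact
#' identities: output mean `= n * input mean + interface_delta`; output
#' variance `= n * input variance`.
#'
#' @param md normalized subunit `mass_distribution`.
#' @param n oligomer order (integer >= 2).
#' @param interface_delta interface mass delta in Da.
#' @param round_digits masses are rounded to this many digits when
#'   aggregating convolution products (keeps exact ladders exact).
#' @return normalized `mass_distribution` of the n-mer.
#' @export
convolve_assembly <- function(md, n = 2, interface_delta = 0,
                              round_digits = 6) {
  if (abs(sum(md$abundance) - 1) > 1e-8) {
    stop("input distribution must be normalized (sum abundance = 1)",
         call. = FALSE)
  }
  if (n < 2 || n != round(n)) stop("order n must be an integer >= 2", call. = FALSE)
  m <- md$mass; w <- md$abundance
  out_m <- m; out_w <- w
  for (i in seq_len(n - 1L)) {
    mm <- round(outer(out_m, m, `+`), round_digits)
    ww <- outer(out_w, w)
    agg <- tapply(as.vector(ww), as.vector(mm), sum)
    out_m <- as.numeric(names(agg))
    out_w <- as.numeric(agg)
  }
  o <- order(out_m)
  mass_distribution(out_m[o] + interface_delta, out_w[o] / sum(out_w),
                    normalize = FALSE) -> res
  attr(res, "normalized") <- TRUE
  res
}

#' Compare a predicted assembly distribution with an observed one
#'
#' Reports the mean and s.d. differences (observed - predicted), a
#' normalized inner-product overlap on a common grid, and a verdict flag:
#' the distributions agree when `|Delta mean|` does not exceed the
#' combined uncertainty `sqrt(pred_se^2 + obs_se^2)`.
#'
#' @param predicted,observed `mass_distribution`s (or data.frames with
#'   `mass`, `abundance`).
#' @param pred_se,obs_se standard errors of the two mean masses (Da).
#' @param grid_res binning resolution for the overlap score (Da).
#' @return list with `dmean`, `dsd`, `overlap`, `combined_se`, `agree`.
#' @export
compare_assembly <- function(predicted, observed, pred_se = 0, obs_se = 0,
                             grid_res = 1) {
  mp <- md_moments(predicted); mo <- md_moments(observed)
  bin <- function(md) {
    idx <- round(md$mass / grid_res)
    tapply(md$abundance / sum(md$abundance), idx, sum)
  }
  bp <- bin(predicted); bo <- bin(observed)
  keys <- union(names(bp), names(bo))
  p <- ifelse(keys %in% names(bp), bp[keys], 0)
  q <- ifelse(keys %in% names(bo), bo[keys], 0)
  overlap <- sum(p * q) / sqrt(sum(p^2) * sum(q^2))
  dmean <- mo$mean - mp$mean
  comb <- sqrt(pred_se^2 + obs_se^2)
  list(dmean = dmean, dsd = mo$sd - mp$sd, overlap = overlap,
       combined_se = comb,
       agree = if (comb > 0) abs(dmean) <= comb else abs(dmean) < grid_res)
}

#' Expected modified-count fractions under independent site occupancy
#'
#' With per-site modification probability `p`, `sites` sites per monomer
#' and an oligomer of the given order, the number of modified sites is
#' Binomial(order x sites, p).
#'
#' @param p per-site modification probability.
#' @param sites sites per monomer.
#' @param order oligomer order.
#' @return named numeric vector of fractions for 0..order*sites modified
#'   sites (sums to 1).
#' @export
occupancy_expected <- function(p, sites = 1, order = 2) {
  stopifnot(p >= 0, p <= 1, sites >= 1, order >= 1)
  n <- order * sites
  setNames(dbinom(0:n, n, p), 0:n)
}

#' Test oligomer modification counts against independent assembly
#'
#' Goodness of fit of observed modified-count frequencies in the oligomer
#' against [occupancy_expected()] computed from the monomer modification
#' probability. Exact multinomial computation (total probability of all
#' outcomes no more probable than the observation) is used when the
#' outcome space is enumerable (`choose(n + k - 1, k - 1) <= max_exact`)
#' or when a zero-expected cell has nonzero observed count; otherwise the
#' asymptotic chi-square statistic is used.
#'
#' @param observed integer vector of observed counts for 0..order*sites
#'   modified sites.
#' @param p monomer per-site modification probability.
#' @param sites,order as in [occupancy_expected()].
#' @param method `"auto"`, `"exact"` or `"chisq"`.
#' @param max_exact enumeration budget for the exact branch.
#' @return list with `statistic` (chi-square; NA for exact), `p.value`,
#'   `method`, `expected` counts.
#' @export
independence_test <- function(observed, p, sites = 1, order = 2,
                              method = c("auto", "exact", "chisq"),
                              max_exact = 5e6) {
  method <- match.arg(method)
  probs <- occupancy_expected(p, sites, order)
  k <- length(probs)
  if (length(observed) != k) {
    stop("observed must have ", k, " cells (0..", k - 1L, " modified sites)",
         call. = FALSE)
  }
  n <- sum(observed)
  zero_issue <- any(probs == 0 & observed > 0)
  if (method == "auto") {
    method <- if (zero_issue || choose(n + k - 1, k - 1) <= max_exact)
      "exact" else "chisq"
  }
  expected <- n * probs
  if (method == "exact") {
    p_obs <- stats::dmultinom(observed, prob = probs)
    total <- .multinom_tail(n, probs, p_obs * (1 + 1e-9))
    return(list(statistic = NA_real_, p.value = min(1, total),
                method = "exact multinomial", expected = expected))
  }
  stat <- sum((observed - expected)^2 / expected)
  list(statistic = stat,
       p.value = pchisq(stat, df = k - 1L, lower.tail = FALSE),
       method = "chi-square", expected = expected)
}

# total probability of multinomial outcomes with probability <= cutoff;
# recursive enumeration over categories, vectorized in the last two
.multinom_tail <- function(n, probs, cutoff) {
  k <- length(probs)
  lp <- log(probs)
  lfac <- lgamma(seq_len(n + 1))  # lgamma(x+1) for x = 0..n
  lf <- function(x) lfac[x + 1L]
  xlp <- function(x, l) ifelse(x == 0, 0, x * l)  # 0 * log(0) = 0
  total <- 0
  rec <- function(prefix_lp, prefix_lfac, rem, idx) {
    if (idx == k - 1L) {
      x1 <- 0:rem
      x2 <- rem - x1
      lpx <- lgamma(n + 1) + prefix_lp + xlp(x1, lp[k - 1L]) +
        xlp(x2, lp[k]) - prefix_lfac - lf(x1) - lf(x2)
      pr <- exp(lpx)
      total <<- total + sum(pr[pr <= cutoff])
      return(invisible())
    }
    for (x in 0:rem) {
      rec(prefix_lp + xlp(x, lp[idx]), prefix_lfac + lf(x), rem - x, idx + 1L)
    }
  }
  if (k == 1L) return(if (exp(n * lp[1L]) <= cutoff) exp(n * lp[1L]) else 0)
  if (k == 2L) {
    x1 <- 0:n
    pr <- exp(lgamma(n + 1) + xlp(x1, lp[1L]) + xlp(n - x1, lp[2L]) -
                lf(x1) - lf(n - x1))
    return(sum(pr[pr <= cutoff]))
  }
  rec(0, 0, n, 1L)
  total
}

#' Quantify an oligomer/monomer abundance ratio
#'
#' For a mass distribution, the ratio of integrated abundance inside the
#' oligomer mass window to that inside the monomer window. For a fitted
#' mass-photometry mixture (see [mp_fit()]), the ratio of the component
#' weights whose means fall in the two windows.
#'
#' @param x `mass_distribution`, or an `mp_fit`.
#' @param monomer_window,oligomer_window numeric `c(lo, hi)` mass windows
#'   (Da for distributions, kDa for MP fits).
#' @return the ratio (0 when nothing lies in the oligomer window;
#'   `NA` when the monomer window is empty).
#' @export
ratio_quantify <- function(x, monomer_window, oligomer_window) {
  if (inherits(x, "mp_fit")) {
    comp <- x$components
    wm <- sum(comp$weight[comp$mean >= monomer_window[1L] &
                            comp$mean <= monomer_window[2L]])
    wo <- sum(comp$weight[comp$mean >= oligomer_window[1L] &
                            comp$mean <= oligomer_window[2L]])
    if (wm <= 0) return(NA_real_)
    return(wo / wm)
  }
  inwin <- function(win) sum(x$abundance[x$mass >= win[1L] & x$mass <= win[2L]])
  am <- inwin(monomer_window)
  if (am <= 0) return(NA_real_)
  inwin(oligomer_window) / am
}

#' Compare replicate ratios between two conditions
#'
#' @param a,b numeric vectors of replicate ratios.
#' @return list with per-condition `mean` and `sd` and a two-tailed
#'   Student's t-test (`statistic`, `p.value`).
#' @export
ratio_compare <- function(a, b) {
  tt <- t.test(a, b, var.equal = TRUE)
  list(mean = c(a = mean(a), b = mean(b)),
       sd = c(a = sd(a), b = sd(b)),
       statistic = unname(tt$statistic),
       p.value = tt$p.value)
}

#' Fit a k-component Gaussian mixture to mass-photometry events
#'
#' @param events numeric event masses (kDa), e.g. from
#'   [sample_mp_events()].
#' @param k number of components.
#' @return `mp_fit`: list with `components` (mean, sigma, weight; sorted
#'   by mean, weights sum to 1), `loglik`.
#' @importFrom mclust Mclust mclustBIC
#' @export
mp_fit <- function(events, k = 2) {
  ev <- as.numeric(events)
  if (length(ev) < 10 * k) stop("too few events for a ", k, "-component fit",
                                call. = FALSE)
  fit <- Mclust(ev, G = k, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  comp <- data.frame(mean = as.numeric(fit$parameters$mean),
                     sigma = sqrt(as.numeric(fit$parameters$variance$sigmasq)),
                     weight = as.numeric(fit$parameters$pro))
  comp <- comp[order(comp$mean), , drop = FALSE]
  comp$weight <- comp$weight / sum(comp$weight)
  rownames(comp) <- NULL
  structure(list(components = comp, loglik = fit$loglik), class = "mp_fit")
}
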