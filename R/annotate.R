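# Lattice annotation of zero-charge mass distributions: base-mass
# inference, P-series / antennary-fucose assignment, desialylation census,
# Gaussian envelope decomposition, dissociation-based adduct share, and
# off-lattice adduct labelling.

#' Infer the lattice base mass from a mass distribution
#'
#' Grid search over base-mass offsets within `window`, minimizing the
#' abundance-weighted squared distance of observed peak masses to the
#' nearest lattice point `base + k * spacing`. The search is translation
#' equivariant; with a single peak (or an otherwise flat objective) the
#' base is ambiguous up to the lattice spacing and an error is raised
#' naming that aliasing period.
#'
#' @param md `mass_distribution` (peaks taken via [md_peaks()]).
#' @param spacing lattice spacing in Da (e.g. 365.335 for the branch
#'   series).
#' @param window numeric `c(lo, hi)` for the base; defaults to one period
#'   below the lightest peak.
#' @param step search step in Da.
#' @param min_frac peaks below this fraction of the most abundant peak
#'   are ignored (residual reconstruction noise).
#' @param trim peaks farther than this (Da) from the aligned lattice are
#'   excluded from the refinement step.
#' @return list with `base`, `se` (profile-based error bar), `rss`,
#'   `n_used`.
#' @export
infer_base_mass <- function(md, spacing, window = NULL, step = 0.05,
                            min_frac = 0.02, trim = 15) {
  pk <- md_peaks(md, min_frac = min_frac)
  if (nrow(pk) < 3L) stop("need >= 3 lattice peaks to infer a base mass",
                          call. = FALSE)
  if (is.null(window)) window <- min(pk$mass) - c(spacing, 0)
  cand <- seq(window[1L], window[2L], by = step)
  w <- pk$abundance / sum(pk$abundance)
  rss <- vapply(cand, function(b) {
    r <- (pk$mass - b) %% spacing
    r <- pmin(r, spacing - r)
    sum(w * r^2)
  }, numeric(1))
  i <- which.min(rss)
  if (max(rss) - min(rss) < 1e-9 * max(rss, 1)) {
    stop("flat objective: base mass ambiguous up to the lattice spacing (",
         spacing, " Da)", call. = FALSE)
  }
  # refine: weighted mean of per-peak offsets at the selected alignment,
  # using only peaks that actually sit on the lattice (off-lattice peaks
  # -- adducts, stray reconstructions -- must not pull the base)
  k <- round((pk$mass - cand[i]) / spacing)
  r0 <- pk$mass - k * spacing - cand[i]
  keep <- abs(r0) <= trim
  if (!any(keep)) keep <- rep(TRUE, nrow(pk))
  base <- weighted.mean((pk$mass - k * spacing)[keep], w[keep])
  res <- (pk$mass - (base + k * spacing))[keep]
  se <- sqrt(sum(w[keep] * res^2) / max(1, sum(keep) - 1))
  list(base = base, se = se, rss = sum(w[keep] * res^2), n_used = sum(keep))
}

#' Assign lattice labels (P-series, aF-series) to mass peaks
#'
#' Each peak's mass offset from `base` is matched to glycan compositions
#' via [find_compositions()], optionally combined with adducts. The
#' primary label follows a fixed priority -- glycan-only before
#' adduct-bearing interpretations, then fewest residues -- and all
#' surviving candidates are reported so that degeneracies (Neu5Ac vs
#' 2xFuc, 2xbranch vs 5xFuc, PE vs 2xbranch) remain visible. The P index
#' is the branch count relative to the base (P1 = base peak); the aF
#' index counts antennary fucoses above the core.
#'
#' @param md `mass_distribution`.
#' @param base lattice base mass (Da), e.g. from [infer_base_mass()].
#' @param ranges named per-residue maxima for the glycan search.
#' @param adducts optional adduct table (see [adduct_table()]); when given,
#'   combinations up to `max_adducts` total adducts are considered.
#' @param tol assignment tolerance (Da).
#' @param max_adducts maximum total adduct count per peak.
#' @param gap peak-collapse gap passed to [md_peaks()].
#' @return `assignment_result`: list with `assignments` (one row per
#'   assigned peak: mass, abundance, label_P, label_aF, composition,
#'   adducts, error_Da, n_candidates), `candidates` (all candidate rows),
#'   `unassigned` (peak table).
#' @export
assign_lattice <- function(md, base, ranges, adducts = NULL, tol = 2,
                           max_adducts = 2L, gap = 4) {
  pk <- md_peaks(md, gap = gap)
  combos <- .adduct_combos(adducts, max_adducts)
  rows <- list(); cand_rows <- list(); unassigned <- list()
  for (i in seq_len(nrow(pk))) {
    delta <- pk$mass[i] - base
    cands <- .peak_candidates(delta, tol, ranges, combos)
    if (nrow(cands) == 0L) {
      unassigned[[length(unassigned) + 1L]] <- pk[i, ]
      next
    }
    best <- cands[1L, ]
    rows[[length(rows) + 1L]] <- data.frame(
      mass = pk$mass[i], abundance = pk$abundance[i],
      label_P = best$branch + 1L,
      label_aF = best$Fuc,
      composition = best$composition,
      adducts = best$adducts,
      error_Da = best$error_Da,
      n_candidates = nrow(cands),
      stringsAsFactors = FALSE
    )
    cands$peak_mass <- pk$mass[i]
    cand_rows[[length(cand_rows) + 1L]] <- cands
  }
  structure(list(
    assignments = if (length(rows)) do.call(rbind, rows) else NULL,
    candidates = if (length(cand_rows)) do.call(rbind, cand_rows) else NULL,
    unassigned = if (length(unassigned)) do.call(rbind, unassigned) else
      pk[0, , drop = FALSE]
  ), class = "assignment_result")
}

# adduct combination table: one row per combination, columns n_<name>,
# total count, total mass, label
.adduct_combos <- function(adducts, max_adducts) {
  if (is.null(adducts) || nrow(adducts) == 0L) {
    return(data.frame(adduct_mass = 0, n_adducts = 0L, adducts = "-",
                      stringsAsFactors = FALSE))
  }
  per <- lapply(seq_len(nrow(adducts)), function(i) 0:max_adducts)
  names(per) <- adducts$name
  g <- expand.grid(per, KEEP.OUT.ATTRS = FALSE)
  g <- g[rowSums(g) <= max_adducts, , drop = FALSE]
  lab <- apply(g, 1L, function(x) {
    nz <- x > 0
    if (!any(nz)) "-" else paste0(names(x)[nz], x[nz], collapse = " ")
  })
  data.frame(adduct_mass = as.numeric(as.matrix(g) %*% adducts$mass),
             n_adducts = as.integer(rowSums(g)), adducts = lab,
             stringsAsFactors = FALSE)
}

# Candidates for one peak delta: glycan-only before adduct-bearing, then
# fewest adducts. Within one adduct stratum, errors that differ by less
# than tie_eps are degenerate at instrument accuracy, so such near-ties
# resolve toward the fewest residues (the "tentative" primary label);
# only error differences above tie_eps are decisive.
.peak_candidates <- function(delta, tol, ranges, combos, tie_eps = 1) {
  out <- list()
  for (j in order(combos$n_adducts)) {
    d2 <- delta - combos$adduct_mass[j]
    if (d2 < -tol) next
    fc <- find_compositions(d2, tol, ranges, "average")
    if (nrow(fc) == 0L) next
    fc$adducts <- combos$adducts[j]
    fc$n_adducts <- combos$n_adducts[j]
    out[[length(out) + 1L]] <- fc
  }
  if (!length(out)) {
    fc <- find_compositions(delta, tol, ranges, "average")  # zero-row template
    fc$adducts <- character(0); fc$n_adducts <- integer(0)
    return(fc)
  }
  res <- do.call(rbind, out)
  for (col in c("branch", "Fuc", "Neu5Ac")) {
    if (is.null(res[[col]])) res[[col]] <- 0L
  }
  abs_err <- abs(res$error_Da)
  tied <- abs_err <= ave(abs_err, res$n_adducts, FUN = min) + tie_eps
  res[order(res$n_adducts, !tied, ifelse(tied, res$n_residues, 0L), abs_err), ,
      drop = FALSE]
}

#' Per-proteoform sialic acid census from a desialylation pair
#'
#' For each peak of the sialylated distribution, the matched desialylated
#' anchor is the one minimizing the residual of
#' `M_sial - M_desial - k * m(Neu5Ac)` over integer `k >= 0`; peaks whose
#' best residual exceeds `tol` are excluded and counted against coverage.
#'
#' @param sial_md,desial_md `mass_distribution`s of the sialylated and
#'   desialylated preparations.
#' @param tol residual tolerance (Da).
#' @param gap peak-collapse gap passed to [md_peaks()]; keep it below the
#'   smallest mass difference between distinct proteoforms (the 1.03 Da
#'   Neu5Ac vs 2xFuc near-degeneracy) for exact censuses of noise-free
#'   populations.
#' @param min_frac ignore peaks below this fraction of the most abundant
#'   peak in either distribution (suppresses rare species whose masses
#'   cross-match through adduct degeneracies).
#' @return list with `per_peak` (mass, abundance, k, anchor_mass,
#'   residual), `range` (min, max k), `mode` (abundance-weighted modal k),
#'   `coverage` (assigned abundance fraction).
#' @export
sialic_census <- function(sial_md, desial_md, tol = 2, gap = 4,
                          min_frac = 0) {
  sp <- md_peaks(sial_md, gap = gap, min_frac = min_frac)
  dp <- md_peaks(desial_md, gap = gap, min_frac = min_frac)
  m_neu <- residue_mass("Neu5Ac", "average")
  rows <- lapply(seq_len(nrow(sp)), function(i) {
    delta <- sp$mass[i] - dp$mass
    k <- as.integer(round(delta / m_neu))
    resid <- delta - k * m_neu
    ok <- k >= 0
    if (!any(ok)) return(NULL)
    j <- which(ok)[which.min(abs(resid[ok]))]
    data.frame(mass = sp$mass[i], abundance = sp$abundance[i],
               k = k[j], anchor_mass = dp$mass[j], residual = resid[j])
  })
  per <- do.call(rbind, rows)
  kept <- per[abs(per$residual) <= tol, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no sialylated peak matched an anchor", call. = FALSE)
  by_k <- tapply(kept$abundance, kept$k, sum)
  list(per_peak = kept,
       range = range(kept$k),
       mode = as.integer(names(by_k)[which.max(by_k)]),
       coverage = sum(kept$abundance) / sum(per$abundance))
}

#' Decompose a peak-series envelope into Gaussian components
#'
#' Nonlinear least squares of `k` Gaussians over the series index axis
#' (P1, P2, ...), initialized by a k-quantile split of the cumulative
#' abundance. Amplitudes are bounded below by zero. A second (or later)
#' component is flagged as present when its amplitude exceeds
#' `minor_frac` of the largest.
#'
#' @param abundance series abundances (index axis `seq_along(abundance)`).
#' @param k number of Gaussian components.
#' @param minor_frac presence threshold for minor components.
#' @return `envelope_fit`: list with `components` (mean, sigma,
#'   amplitude, present), `residual_norm`, `converged`, `fitted`.
#' @export
envelope_decompose <- function(abundance, k = 2, minor_frac = 0.1) {
  y <- as.numeric(abundance)
  x <- seq_along(y)
  if (length(y) < 2 * k + 1) stop("need >= 2k+1 points", call. = FALSE)
  cw <- cumsum(y) / sum(y)
  qs <- vapply((seq_len(k) - 0.5) / k, function(q) x[which.min(abs(cw - q))],
               numeric(1))
  start <- list(); lower <- c(); upper <- c()
  for (j in seq_len(k)) {
    start[[paste0("a", j)]] <- max(y[round(qs[j])], max(y) / (2 * k))
    start[[paste0("m", j)]] <- qs[j]
    start[[paste0("s", j)]] <- max(1, length(y) / (3 * k))
    lower <- c(lower, 0, min(x) - length(y), 0.3)
    upper <- c(upper, Inf, max(x) + length(y), length(y))
  }
  form <- paste0("y ~ ", paste0(sprintf("a%d * exp(-0.5 * ((x - m%d) / s%d)^2)",
                                        seq_len(k), seq_len(k), seq_len(k)),
                                collapse = " + "))
  # symmetric starts can give a singular gradient; retry with
  # deterministically perturbed component means
  fit <- NULL
  for (attempt in 0:3) {
    st <- start
    for (j in seq_len(k)) {
      st[[paste0("m", j)]] <- start[[paste0("m", j)]] +
        attempt * 0.37 * (j - (k + 1) / 2)
      st[[paste0("s", j)]] <- start[[paste0("s", j)]] * (1 + 0.2 * attempt * j)
    }
    fit <- try(minpack.lm::nlsLM(stats::as.formula(form),
                                 data = data.frame(x = x, y = y),
                                 start = st, lower = lower, upper = upper,
                                 control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (!inherits(fit, "try-error")) break
  }
  if (inherits(fit, "try-error")) {
    return(structure(list(components = NULL, residual_norm = NA_real_,
                          converged = FALSE, fitted = NULL),
                     class = "envelope_fit"))
  }
  cf <- coef(fit)
  comp <- data.frame(mean = cf[paste0("m", seq_len(k))],
                     sigma = cf[paste0("s", seq_len(k))],
                     amplitude = cf[paste0("a", seq_len(k))])
  comp <- comp[order(comp$mean), , drop = FALSE]
  comp$present <- comp$amplitude >= minor_frac * max(comp$amplitude)
  rownames(comp) <- NULL
  structure(list(components = comp,
                 residual_norm = sqrt(sum(resid(fit)^2)),
                 converged = TRUE,
                 fitted = stats::fitted(fit)),
            class = "envelope_fit")
}

#' Adduct-bound fraction from an intact/dissociated series pair
#'
#' Models the intact (complex) series as
#' `(1 - f) * S + f * shift(S, adduct)` where `S` is the adduct-free
#' (dissociated-subunit) series and the shift is the adduct mass rounded
#' to its nearest whole number of lattice steps. `f` is estimated by
#' bounded least squares; the confidence interval is a seeded residual
#' bootstrap (percentile). Both series are normalized first, so the
#' estimate is invariant to global intensity scaling.
#'
#' @param intact,dissociated abundance vectors aligned on the same
#'   P-index axis.
#' @param adduct mass of the adduct (Da).
#' @param spacing lattice spacing (Da); default the branch increment.
#' @param off_tol maximum |adduct - steps * spacing| (Da) still treated as
#'   lattice-compatible.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return list with `f`, `ci` (2.5/97.5 percentiles), `steps`,
#'   `fitted`, `residual`.
#' @export
adduct_share <- function(intact, dissociated, adduct,
                         spacing = residue_mass("branch", "average"),
                         off_tol = 40, n_boot = 200, seed = 1) {
  steps <- round(adduct / spacing)
  if (steps < 1 || abs(adduct - steps * spacing) > off_tol) {
    stop("adduct mass ", adduct, " Da is not close to a whole number of ",
         "lattice steps (", round(spacing, 2), " Da); the shifted-series ",
         "model cannot resolve it", call. = FALSE)
  }
  I <- intact / sum(intact)
  S <- dissociated / sum(dissociated)
  shift <- function(v, k) c(numeric(k), v)[seq_along(v)]
  D <- shift(S, steps) - S
  fit_f <- function(target) {
    f <- sum((target - S) * D) / sum(D^2)
    min(max(f, 0), 1)
  }
  f <- fit_f(I)
  fitted <- (1 - f) * S + f * shift(S, steps)
  r <- I - fitted
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      fit_f(fitted + sample(r, length(r), replace = TRUE))
    }, numeric(1))
  })
  list(f = f, ci = unname(quantile(boots, c(0.025, 0.975))), steps = steps,
       fitted = fitted, residual = r)
}

#' Label off-lattice residual masses with adducts
#'
#' For each peak, interpretations are ranked glycan-only first, then by
#' fewest adducts and smallest |error|; peaks with no interpretation
#' within `tol` are returned with their residual mass.
#'
#' @param md `mass_distribution`.
#' @param base lattice base mass (Da).
#' @param adducts adduct table (see [adduct_table()]).
#' @param ranges named per-residue maxima for the glycan part.
#' @param tol matching tolerance (Da).
#' @param max_adducts maximum total adducts per peak.
#' @return list with `labelled` (mass, abundance, composition, adducts,
#'   error_Da) and `unmatched` (mass, abundance, residual to the nearest
#'   glycan-only interpretation).
#' @export
annotate_adducts <- function(md, base, adducts = adduct_table(),
                             ranges = c(branch = 10, Fuc = 8), tol = 2,
                             max_adducts = 2L) {
  res <- assign_lattice(md, base, ranges, adducts = adducts, tol = tol,
                        max_adducts = max_adducts)
  lab <- res$assignments
  un <- res$unassigned
  if (nrow(un)) {
    lad <- enumerate_ladder(ranges, "average")
    un$residual <- vapply(un$mass - base, function(d) {
      d - lad$delta_Da[which.min(abs(lad$delta_Da - d))]
    }, numeric(1))
  }
  list(labelled = lab, unmatched = un)
}
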