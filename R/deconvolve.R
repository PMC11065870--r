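# Charge-state inference and lattice-constrained zero-charge mass
# reconstruction. Deliberately not a Bayesian charge-mass joint
# deconvolution: the analytical leverage for resolved glycoform fine
# structure is the repeat-unit lattice constraint, so reconstruction is
# histogram-based per assigned charge series with an optional lattice
# filter.

#' Centroid a profile spectrum
#'
#' Local maxima above a noise threshold are reduced to intensity-weighted
#' centroids over their half-height support. Peak intensity is the summed
#' profile intensity over the support (area proxy), so downstream
#' reconstruction conserves intensity.
#'
#' @param spec a `spectrum`.
#' @param min_snr apex threshold in units of the robust noise scale
#'   (`mad` of the intensity vector).
#' @param min_prominence minimum apex height as a fraction of the global
#'   maximum.
#' @param smooth_pts standard deviation, in grid points, of the Gaussian
#'   kernel applied before peak picking (0 disables). Light smoothing
#'   suppresses single-point noise spikes while leaving peak centroids
#'   unbiased.
#' @return `peak_list` data.frame with `mz`, `intensity`, `apex`, `fwhm`,
#'   sorted by m/z; zero rows for an all-noise/flat spectrum.
#' @export
centroid <- function(spec, min_snr = 3, min_prominence = 0.01,
                     smooth_pts = 2) {
  y <- spec$intensity
  mz <- spec$mz
  if (!length(y)) stop("empty spectrum", call. = FALSE)
  if (smooth_pts > 0 && length(y) > 8 * smooth_pts) {
    k <- dnorm(seq(-4 * smooth_pts, 4 * smooth_pts), 0, smooth_pts)
    k <- k / sum(k)
    ys <- as.numeric(stats::filter(y, k, sides = 2))
    # edge padding by replication (keeps flat baselines flat)
    na_head <- which(!is.na(ys))[1L]
    na_tail <- tail(which(!is.na(ys)), 1L)
    ys[seq_len(na_head - 1L)] <- ys[na_head]
    if (na_tail < length(ys)) ys[(na_tail + 1L):length(ys)] <- ys[na_tail]
    y <- ys
  }
  noise <- mad(y)
  thr <- max(min_snr * noise, min_prominence * max(y))
  n <- length(y)
  apex <- which(y > thr)
  apex <- apex[apex > 1L & apex < n]
  apex <- apex[y[apex] >= y[apex - 1L] & y[apex] > y[apex + 1L]]
  if (!length(apex)) {
    return(structure(data.frame(mz = numeric(0), intensity = numeric(0),
                                apex = numeric(0), fwhm = numeric(0)),
                     class = c("peak_list", "data.frame")))
  }
  half_support <- function(i) {
    h <- y[i] / 2
    l <- i
    while (l > 1L && y[l - 1L] >= h && y[l - 1L] <= y[l]) l <- l - 1L
    r <- i
    while (r < n && y[r + 1L] >= h && y[r + 1L] <= y[r]) r <- r + 1L
    c(l, r)
  }
  out <- lapply(apex, function(i) {
    s <- half_support(i)
    j <- s[1L]:s[2L]
    w <- y[j]
    c(mz = sum(mz[j] * w) / sum(w), intensity = sum(w), apex = y[i],
      fwhm = mz[s[2L]] - mz[s[1L]])
  })
  out <- as.data.frame(do.call(rbind, out))
  # merge apexes that collapsed to the same centroid (shoulder noise)
  out <- out[order(out$mz), , drop = FALSE]
  keep <- c(TRUE, diff(out$mz) > 1e-9)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("peak_list", "data.frame"))
}

#' Neutral mass of an m/z peak at charge z (positive mode)
#' @param mz m/z value(s).
#' @param z integer charge.
#' @return neutral mass in Da.
#' @export
neutral_mass <- function(mz, z) z * (mz - PROTON_MASS)

#' Infer charge states and species masses from a peak list
#'
#' Peaks are first clustered into envelope lobes (one lobe per charge
#' state per species; fine-structure peaks merge into their lobe).
#' Species are then found by hypothesis fitting: each candidate charge of
#' the strongest unclaimed lobe implies a neutral mass; every available
#' lobe is assigned its nearest charge under that mass, lobes within the
#' mass tolerance are kept, and the mass is refit iteratively. The
#' hypothesis with the highest residual-weighted explained intensity wins
#' (near-ties resolved toward consecutive charge states, which rejects
#' harmonic aliases), its lobes are claimed, and the search repeats on
#' the remainder, so overlapping envelopes (e.g. a complex and its dimer
#' of complexes) separate naturally. Lobes with no consistent charge are
#' returned as unassigned, not dropped.
#'
#' @param pl a `peak_list`.
#' @param z_range integer vector `c(zmin, zmax)` of candidate charges.
#' @param envelope_gap m/z gap separating lobes (must exceed the fine
#'   structure spacing and stay below the charge-state spacing).
#' @param min_frac peaks with integrated intensity below this fraction of
#'   the strongest peak are ignored when delimiting lobes (suppresses
#'   residual noise spikes, which have near-zero area).
#' @param sd_frac maximum relative standard deviation of member neutral
#'   masses for a chain to count as a consistent charge assignment.
#' @param series_min_frac series with summed intensity below this fraction
#'   of the strongest accepted series are discarded as residual noise.
#' @return `charge_assignment`: list with `series` (each with `mass`,
#'   `mass_sd`, and a `lobes` data.frame of z, m/z window and intensity)
#'   and `unassigned` (lobe table).
#' @export
infer_charges <- function(pl, z_range = c(15, 35), envelope_gap = 20,
                          min_frac = 0.03, sd_frac = 0.002,
                          series_min_frac = 0.02) {
  pl <- pl[pl$intensity >= min_frac * max(pl$intensity), , drop = FALSE]
  if (nrow(pl) < 2L) {
    return(structure(list(series = list(),
                          unassigned = .lobes(pl, envelope_gap)),
                     class = "charge_assignment"))
  }
  lobes <- .lobes(pl, envelope_gap)
  claimed <- rep(FALSE, nrow(lobes))
  series <- list()
  zmin <- z_range[1L]; zmax <- z_range[2L]

  # Evaluate one mass hypothesis: assign every available lobe its nearest
  # charge, keep lobes within the mass tolerance, refit the mass, iterate.
  # Score = residual-weighted explained intensity.
  evaluate <- function(M0, avail) {
    M <- M0
    sel <- logical(nrow(lobes)); z <- integer(nrow(lobes))
    for (it in 1:3) {
      z <- pmin(zmax, pmax(zmin, round(M / (lobes$mz - PROTON_MASS))))
      mass <- neutral_mass(lobes$mz, z)
      r <- mass - M
      sel <- avail & abs(r) <= sd_frac * M
      if (!any(sel)) return(NULL)
      # at most one lobe per charge state: keep the closest
      for (zz in unique(z[sel])) {
        i <- which(sel & z == zz)
        if (length(i) > 1L) sel[i[-which.min(abs(r[i]))]] <- FALSE
      }
      M <- weighted.mean(mass[sel], lobes$intensity[sel])
    }
    # an electrospray envelope occupies one contiguous charge run (we
    # allow a single vacant charge state); this also rejects harmonic
    # aliases, which select every other charge
    idx <- which(sel)
    idx <- idx[order(z[idx])]
    run_id <- integer(length(idx)); run <- 1L; miss <- 0L
    run_id[1L] <- run
    for (i in seq_along(idx)[-1L]) {
      gap <- z[idx[i]] - z[idx[i - 1L]]
      if (gap == 1L || (gap == 2L && miss == 0L)) {
        if (gap == 2L) miss <- 1L
      } else {
        run <- run + 1L; miss <- 0L
      }
      run_id[i] <- run
    }
    run_int <- tapply(lobes$intensity[idx], run_id, sum)
    best_run <- as.integer(names(run_int)[which.max(run_int)])
    keep <- idx[run_id == best_run]
    sel[] <- FALSE; sel[keep] <- TRUE
    if (sum(sel) < 2L) return(NULL)
    M <- weighted.mean(neutral_mass(lobes$mz[sel], z[sel]),
                       lobes$intensity[sel])
    r <- neutral_mass(lobes$mz, z) - M
    zs <- z[sel]
    if (length(unique(zs)) < 2L) return(NULL)
    consec <- sum(diff(sort(unique(zs))) == 1L)
    if (consec < 1L) return(NULL)  # an envelope has adjacent charge states
    score <- sum(lobes$intensity[sel] * (1 - (r[sel] / (sd_frac * M))^2))
    list(M = M, sel = which(sel), z = zs, score = score, consec = consec)
  }

  repeat {
    avail <- !claimed
    if (!any(avail)) break
    seed <- which(avail)[which.max(lobes$intensity[avail])]
    best <- NULL
    for (z0 in seq.int(zmin, zmax)) {
      h <- evaluate(neutral_mass(lobes$mz[seed], z0), avail)
      if (is.null(h) || !(seed %in% h$sel)) next
      if (is.null(best) || h$score > 1.02 * best$score ||
          (h$score > 0.98 * best$score && h$consec > best$consec)) {
        best <- h
      }
    }
    if (is.null(best)) {
      claimed[seed] <- TRUE  # unassignable seed: flag, do not retry
      lobes$unassignable[seed] <- TRUE
      next
    }
    claimed[best$sel] <- TRUE
    w <- lobes$intensity[best$sel]
    m <- neutral_mass(lobes$mz[best$sel], best$z)
    lob <- data.frame(z = best$z,
                      mz = lobes$mz[best$sel],
                      mz_lo = lobes$mz_lo[best$sel],
                      mz_hi = lobes$mz_hi[best$sel],
                      intensity = w,
                      mass = m)
    lob <- lob[order(lob$z), , drop = FALSE]
    series[[length(series) + 1L]] <-
      list(mass = weighted.mean(m, w),
           mass_sd = if (length(m) > 1L) sd(m) else 0,
           z = lob$z, lobes = lob,
           intensity = sum(w))
  }
  if (length(series) > 1L) {
    ints <- vapply(series, `[[`, 1, "intensity")
    series <- series[ints >= series_min_frac * max(ints)]
  }
  series <- series[order(vapply(series, `[[`, 1, "mass"))]
  un <- lobes[isTRUE_vec(lobes$unassignable), , drop = FALSE]
  structure(list(series = series, unassigned = un),
            class = "charge_assignment")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# Segment weighted point positions at the deep valleys of their weighted
# kernel density: a density minimum is a boundary when it falls below half
# of the smaller of its nearest flanking maxima. Robust to stray bridge
# points in the valleys (an isolated bridge becomes an isolated density
# bump with deep shoulders, which still cut). Falls back to gap
# clustering for < 3 points.
.segment_by_valleys <- function(pos, weight, bw, gap = 6 * bw) {
  if (length(pos) < 3L) return(cumsum(c(1, diff(pos) > gap)))
  d <- stats::density(pos, weights = weight / sum(weight), bw = bw, n = 8192,
                      from = min(pos) - 3 * bw, to = max(pos) + 3 * bw)
  y <- d$y; nn <- length(y)
  mins <- which(y[2:(nn - 1L)] <= y[1:(nn - 2L)] & y[2:(nn - 1L)] <= y[3:nn]) + 1L
  # recursive watershed: within a segment, split at the minimum with the
  # largest flank-to-valley ratio, provided both flanks rise to at least
  # twice the valley; recurse into both halves
  seg_cuts <- function(lo, hi) {
    mi <- mins[mins > lo & mins < hi]
    if (!length(mi)) return(integer(0))
    ratio <- vapply(mi, function(m) {
      min(max(y[lo:m]), max(y[m:hi])) / max(y[m], 1e-300)
    }, numeric(1))
    b <- which.max(ratio)
    if (ratio[b] <= 2) return(integer(0))
    m <- mi[b]
    c(seg_cuts(lo, m), m, seg_cuts(m, hi))
  }
  cuts <- d$x[seg_cuts(1L, nn)]
  findInterval(pos, sort(cuts)) + 1L
}

# Cluster a peak list into envelope lobes (one lobe per charge state per
# species; fine-structure peaks merge into their lobe).
.lobes <- function(pl, envelope_gap) {
  if (nrow(pl) == 0L) {
    return(data.frame(mz = numeric(0), mz_lo = numeric(0), mz_hi = numeric(0),
                      intensity = numeric(0), n_peaks = integer(0),
                      unassignable = logical(0)))
  }
  grp <- .segment_by_valleys(pl$mz, pl$intensity, bw = envelope_gap / 2,
                             gap = envelope_gap)
  out <- do.call(rbind, lapply(split(pl, grp), function(g) {
    data.frame(mz = weighted.mean(g$mz, g$intensity),
               mz_lo = min(g$mz) - max(g$fwhm, 0),
               mz_hi = max(g$mz) + max(g$fwhm, 0),
               intensity = sum(g$intensity),
               n_peaks = nrow(g))
  }))
  out$unassignable <- FALSE
  rownames(out) <- NULL
  out
}

#' Adjacent-peak spacing of glycoform fine structure within one charge state
#'
#' Returns the mean and s.d. of adjacent-peak Delta m/z, and the implied
#' neutral mass increment `z * mean`. Missing ladder teeth (gaps larger
#' than 1.5x the median gap) are split into their nearest integer number
#' of unit steps before averaging.
#'
#' @param pl `peak_list` restricted to the fine structure of one charge
#'   state (use the lobe windows from [infer_charges()]).
#' @param z the charge state.
#' @return list with `mean_dmz`, `sd_dmz`, `n`, `delta_mass`.
#' @export
fine_structure_interval <- function(pl, z) {
  mz <- sort(pl$mz)
  if (length(mz) < 3L) stop("need >= 3 fine-structure peaks", call. = FALSE)
  d <- diff(mz)
  med <- median(d)
  k <- ifelse(d > 1.5 * med, pmax(1, round(d / med)), 1)
  d <- rep(d / k, k)
  list(mean_dmz = mean(d),
       sd_dmz = if (length(d) > 1L) sd(d) else 0,
       n = length(d),
       delta_mass = z * mean(d))
}

#' Estimate the fine-structure repeat mass by Fourier transform
#'
#' The intensity profile of one charge state is resampled onto a uniform
#' m/z grid, mean-subtracted, and Fourier transformed (zero-padded with
#' parabolic interpolation of the power peak for sub-bin frequency
#' accuracy). The dominant non-zero frequency gives the m/z period; the
#' repeat mass is `period * z`. When no frequency dominates (peak power
#' below `power_ratio` x the median power) the result is `NA` with
#' `detected = FALSE`.
#'
#' @param spec `spectrum` segment spanning at least ~6 repeat periods of a
#'   single charge state.
#' @param z charge of the segment.
#' @param power_ratio detection threshold on peak/median spectral power.
#' @return list with `repeat_mass` (Da or NA), `period_mz`, `detected`.
#' @export
fourier_repeat <- function(spec, z, power_ratio = 3) {
  dx <- median(diff(spec$mz))
  grid <- seq(min(spec$mz), max(spec$mz), by = dx)
  y <- approx(spec$mz, spec$intensity, grid, rule = 2)$y
  y <- y - mean(y)
  nfft <- 2^ceiling(log2(16 * length(y)))
  p <- Mod(fft(c(y, numeric(nfft - length(y)))))^2
  half <- p[2:(nfft %/% 2)]
  imax <- which.max(half)
  # the maximum of a flat (noise) power spectrum over m independent bins
  # scales like median * log2(m); a genuine periodicity must beat that
  if (half[imax] < power_ratio * median(half) * log2(length(y))) {
    return(list(repeat_mass = NA_real_, period_mz = NA_real_, detected = FALSE))
  }
  # parabolic interpolation around the power maximum
  i <- imax + 1L   # index into p (1-based, p[1] is DC)
  delta <- 0
  if (i > 2L && i < nfft %/% 2) {
    a <- p[i - 1L]; b <- p[i]; c <- p[i + 1L]
    den <- a - 2 * b + c
    if (den != 0) delta <- 0.5 * (a - c) / den
  }
  freq <- (imax + delta) / (nfft * dx)
  period <- 1 / freq
  list(repeat_mass = period * z, period_mz = period, detected = TRUE)
}

#' Reconstruct the zero-charge mass distribution
#'
#' For every assigned charge series, peaks inside each lobe's m/z window
#' are mapped to neutral masses at that lobe's charge and accumulated on a
#' common mass grid; series contributions are summed. Total intensity is
#' conserved. With `repeat_filter`, a lattice of that spacing is anchored
#' at the most intense mass and every reconstructed peak is flagged
#' on/off lattice (off-lattice peaks -- e.g. phospho or lipid adducts --
#' keep their mass).
#'
#' @param pl full `peak_list`.
#' @param assignment a `charge_assignment` from [infer_charges()].
#' @param repeat_filter lattice spacing in Da, or `NULL` for no filter.
#' @param grid_res mass grid resolution (Da).
#' @param lattice_tol maximum |offset| from the lattice still flagged
#'   on-lattice (Da).
#' @param peak_gap gap (Da) separating reconstructed mass peaks when
#'   collapsing the histogram; keep it well below the finest expected
#'   proteoform spacing but above the per-charge mass scatter.
#' @param min_frac peaks below this fraction of the strongest peak are
#'   excluded from reconstruction (residual noise spikes).
#' @return a `mass_distribution`: data.frame `mass`, `abundance` on the
#'   grid, with a peak-level summary in `attr(, "peaks")` (columns `mass`,
#'   `abundance`, `on_lattice`, `lattice_offset`).
#' @export
zero_charge <- function(pl, assignment, repeat_filter = NULL, grid_res = 0.5,
                        lattice_tol = 10, peak_gap = 20, min_frac = 0.01) {
  series <- assignment$series
  if (!length(series)) stop("no assigned charge series", call. = FALSE)
  pl <- pl[pl$intensity >= min_frac * max(pl$intensity), , drop = FALSE]
  pts <- do.call(rbind, lapply(series, function(s) {
    do.call(rbind, lapply(seq_len(nrow(s$lobes)), function(i) {
      w <- s$lobes[i, ]
      sel <- pl$mz >= w$mz_lo & pl$mz <= w$mz_hi
      if (!any(sel)) return(NULL)
      data.frame(mass = neutral_mass(pl$mz[sel], w$z),
                 intensity = pl$intensity[sel])
    }))
  }))
  if (is.null(pts) || nrow(pts) == 0L) stop("no peaks inside series windows",
                                            call. = FALSE)
  lo <- floor(min(pts$mass)) - grid_res
  grid_idx <- round((pts$mass - lo) / grid_res)
  hist <- tapply(pts$intensity, grid_idx, sum)
  mass <- lo + as.numeric(names(hist)) * grid_res
  md <- data.frame(mass = mass, abundance = as.numeric(hist))
  md <- md[order(md$mass), , drop = FALSE]
  rownames(md) <- NULL

  # collapse into reconstructed mass peaks (valley segmentation of the
  # weighted neutral-mass points)
  o <- order(pts$mass)
  pts <- pts[o, , drop = FALSE]
  grp <- .segment_by_valleys(pts$mass, pts$intensity, bw = peak_gap / 4,
                             gap = peak_gap)
  pk <- do.call(rbind, lapply(split(pts, grp), function(g) {
    data.frame(mass = weighted.mean(g$mass, g$intensity),
               abundance = sum(g$intensity))
  }))
  rownames(pk) <- NULL
  if (!is.null(repeat_filter)) {
    anchor <- pk$mass[which.max(pk$abundance)]
    off <- (pk$mass - anchor) %% repeat_filter
    off <- pmin(off, repeat_filter - off)
    pk$lattice_offset <- off
    pk$on_lattice <- off <= lattice_tol
  } else {
    pk$lattice_offset <- NA_real_
    pk$on_lattice <- NA
  }
  structure(md, class = c("mass_distribution", "data.frame"),
            peaks = pk, grid_res = grid_res, normalized = FALSE,
            repeat_filter = repeat_filter)
}

#' Peak-level view of a mass distribution
#'
#' For distributions produced by [zero_charge()] this returns the stored
#' reconstructed peaks; for a plain `mass`/`abundance` data.frame (e.g. a
#' proteoform population cast to a distribution) adjacent masses within
#' `gap` are collapsed to abundance-weighted centroids.
#'
#' @param md `mass_distribution` or data.frame with `mass`, `abundance`.
#' @param gap collapse gap in Da.
#' @param min_frac drop peaks with abundance below this fraction of the
#'   most abundant peak.
#' @return data.frame `mass`, `abundance`, `on_lattice`, `lattice_offset`.
#' @export
md_peaks <- function(md, gap = 4, min_frac = 0) {
  pk <- attr(md, "peaks")
  if (!is.null(pk)) {
    if (!"on_lattice" %in% names(pk)) pk$on_lattice <- NA
    if (!"lattice_offset" %in% names(pk)) pk$lattice_offset <- NA_real_
    if (min_frac > 0) pk <- pk[pk$abundance >= min_frac * max(pk$abundance), ,
                               drop = FALSE]
    return(pk)
  }
  stopifnot(all(c("mass", "abundance") %in% names(md)))
  md <- md[order(md$mass), , drop = FALSE]
  grp <- cumsum(c(1, diff(md$mass) > gap))
  pk <- do.call(rbind, lapply(split(md[c("mass", "abundance")], grp), function(g) {
    data.frame(mass = weighted.mean(g$mass, g$abundance),
               abundance = sum(g$abundance))
  }))
  pk$on_lattice <- NA
  pk$lattice_offset <- NA_real_
  rownames(pk) <- NULL
  if (min_frac > 0) pk <- pk[pk$abundance >= min_frac * max(pk$abundance), ,
                             drop = FALSE]
  pk
}

#' Cast masses and abundances to a mass distribution
#' @param mass,abundance numeric vectors.
#' @param normalize divide abundances by their sum.
#' @return `mass_distribution` data.frame.
#' @export
mass_distribution <- function(mass, abundance, normalize = FALSE) {
  stopifnot(length(mass) == length(abundance), all(abundance >= 0))
  o <- order(mass)
  md <- data.frame(mass = mass[o], abundance = abundance[o])
  if (normalize) md$abundance <- md$abundance / sum(md$abundance)
  structure(md, class = c("mass_distribution", "data.frame"),
            normalized = normalize)
}
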