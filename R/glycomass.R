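#' @importFrom stats median sd setNames approx fft mad dnorm dbinom pchisq
#'   quantile rnorm rbinom weighted.mean var coef resid t.test rmultinom
#' @importFrom utils read.csv write.csv head tail
NULL

# Atomic masses. Average: IUPAC 2021 standard atomic weights (abridged to the
# precision conventional for intact-protein work). Monoisotopic: lightest
# isotope masses (CODATA/AME).
.ATOMIC_AVERAGE <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.973761998)
.ATOMIC_MONO <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069, P = 30.97376151)

#' Mass of a proton (Da), used for m/z conversion in positive mode
#' @export
PROTON_MASS <- 1.00728

# Lattice multiplicities of the glycan addition types on the ~73 Da unit grid:
# one Fuc spans 2 units, one Neu5Ac 4 units, one branch (HexNAc1Hex1) 5 units.
.LATTICE_UNITS <- c(Fuc = 2, Neu5Ac = 4, branch = 5)

#' Parse an elemental formula string
#'
#' @param formula character like `"C6H10O5"`; element symbols followed by
#'   optional counts.
#' @return named integer vector of element counts.
#' @keywords internal
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(ifelse(grepl("[0-9]+$", toks),
                         sub("^[A-Za-z]+", "", toks), "1"))
  tapply(n, el, sum)
}

#' Mass of an elemental formula
#'
#' @param formula formula string, e.g. `"C11H17NO8"`.
#' @param kind `"mono"` or `"average"`. No default: the two conventions
#'   differ by >0.5 Da for a residue and must be chosen explicitly.
#' @return mass in Da.
#' @export
formula_mass <- function(formula, kind) {
  kind <- match.arg(kind, c("mono", "average"))
  tab <- if (kind == "mono") .ATOMIC_MONO else .ATOMIC_AVERAGE
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(tab))
  if (length(unknown)) stop("unknown element(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  sum(tab[names(counts)] * counts)
}

#' Built-in monosaccharide residue table
#'
#' Residue (i.e. anhydro, as-incorporated) compositions for the glycan
#' building blocks of complex-type N-glycans, plus the named unit
#' `"branch"` (one HexNAc1Hex1 antenna extension, GlcNAc + Gal).
#'
#' @param extra optional data.frame with columns `name`, `formula` to append.
#' @return data.frame with columns `name`, `formula`, `mono`, `average`.
#' @examples
#' residue_table()
#' @export
residue_table <- function(extra = NULL) {
  tab <- data.frame(
    name = c("Hex", "HexNAc", "Fuc", "Neu5Ac", "branch"),
    formula = c("C6H10O5", "C8H13NO5", "C6H10O4", "C11H17NO8", "C14H23NO10"),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(all(c("name", "formula") %in% names(extra)))
    tab <- rbind(tab, extra[, c("name", "formula")])
  }
  tab$mono <- vapply(tab$formula, formula_mass, numeric(1), kind = "mono")
  tab$average <- vapply(tab$formula, formula_mass, numeric(1), kind = "average")
  if (any(tab$mono <= 0) || any(tab$average <= 0)) {
    stop("residue masses must be positive", call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' Mass of one residue
#'
#' @param name residue name present in `table`.
#' @param kind `"mono"` or `"average"` (required).
#' @param table a residue table, see [residue_table()].
#' @return mass in Da.
#' @examples
#' round(residue_mass("Fuc", "average"), 2)     # 146.14
#' round(residue_mass("branch", "average"), 2)  # 365.33
#' @export
residue_mass <- function(name, kind, table = residue_table()) {
  kind <- match.arg(kind, c("mono", "average"))
  i <- match(name, table$name)
  if (anyNA(i)) {
    stop("unknown residue name(s): ",
         paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  }
  unname(table[[kind]][i])
}

#' Validate a glycan composition
#'
#' A composition is a named vector of non-negative integer residue counts.
#' @param comp named numeric vector (possibly empty).
#' @return the composition as a named integer vector.
#' @keywords internal
as_composition <- function(comp) {
  if (is.null(comp) || length(comp) == 0L) return(setNames(integer(0), character(0)))
  if (is.null(names(comp)) || any(!nzchar(names(comp)))) {
    stop("composition counts must be named by residue", call. = FALSE)
  }
  if (any(comp < 0)) stop("negative residue count in composition", call. = FALSE)
  if (any(comp != round(comp))) stop("residue counts must be integers", call. = FALSE)
  storage.mode(comp) <- "integer"
  comp[comp > 0L]
}

#' Mass of a glycan composition
#'
#' Additive over residue counts; the empty composition has mass 0.
#'
#' @param comp named counts, e.g. `c(branch = 1, Neu5Ac = 1, Fuc = 1)`.
#' @inheritParams residue_mass
#' @return mass in Da.
#' @examples
#' round(composition_mass(c(branch = 2), "average"), 2)  # 730.67
#' @export
composition_mass <- function(comp, kind, table = residue_table()) {
  comp <- as_composition(comp)
  if (length(comp) == 0L) return(0)
  sum(residue_mass(names(comp), kind, table) * comp)
}

#' Format a composition as a compact label
#' @param comp named counts.
#' @return character like `"branch2 Fuc5"` (empty composition: `"-"`).
#' @export
format_composition <- function(comp) {
  comp <- as_composition(comp)
  if (length(comp) == 0L) return("-")
  paste0(names(comp), comp, collapse = " ")
}

#' Enumerate a combinatorial glycoform ladder
#'
#' All residue-count combinations within per-residue maxima, with delta
#' masses and lattice unit counts (2 units per Fuc, 4 per Neu5Ac, 5 per
#' branch), sorted by delta mass.
#'
#' @param ranges named integer vector of per-residue maximum counts, e.g.
#'   `c(Fuc = 6, Neu5Ac = 16, branch = 10)`. Empty ranges give the empty
#'   single-entry ladder.
#' @inheritParams residue_mass
#' @return data.frame with one count column per residue, plus `delta_Da`,
#'   `units` (NA where a residue has no lattice multiplicity) and
#'   `composition` label, sorted by `delta_Da`.
#' @export
enumerate_ladder <- function(ranges, kind, table = residue_table()) {
  kind <- match.arg(kind, c("mono", "average"))
  if (length(ranges) == 0L) {
    return(data.frame(delta_Da = 0, units = 0L, composition = "-",
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(ranges)) || any(!nzchar(names(ranges)))) {
    stop("ranges must be named by residue", call. = FALSE)
  }
  if (any(ranges < 0) || any(!is.finite(ranges))) {
    stop("ranges must be finite and non-negative", call. = FALSE)
  }
  grid <- expand.grid(lapply(ranges, function(k) 0:k),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  masses <- residue_mass(names(ranges), kind, table)
  grid$delta_Da <- as.numeric(as.matrix(grid[names(ranges)]) %*% masses)
  uw <- .LATTICE_UNITS[names(ranges)]
  names(uw) <- names(ranges)
  known <- !is.na(uw)
  grid$units <- if (any(known)) {
    as.integer(as.matrix(grid[, names(ranges)[known], drop = FALSE]) %*% uw[known])
  } else 0L
  if (any(!known)) {
    off <- rowSums(grid[, names(ranges)[!known], drop = FALSE] > 0) > 0
    grid$units[off] <- NA_integer_
  }
  grid$composition <- apply(grid[names(ranges)], 1L, function(x) {
    format_composition(setNames(as.integer(x), names(ranges)))
  })
  grid <- grid[order(grid$delta_Da, grid$units), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Collapse a mass ladder and estimate its repeat unit
#'
#' Masses closer than `merge_tol` are merged (single linkage on the sorted
#' axis) into intensity-agnostic centroids; the mean and standard deviation
#' of consecutive spacings of the collapsed ladder are returned. Vacancies
#' in a combinatorial ladder (missing teeth at the sparse extremes of the
#' unit lattice) produce spacings that are integer multiples of the unit;
#' with `split_vacancies = TRUE` (default) any gap larger than 1.5x the
#' median gap is divided into its nearest integer number of unit steps
#' before averaging.
#'
#' @param masses numeric vector of ladder masses (Da), or the data.frame
#'   returned by [enumerate_ladder()] (its `delta_Da` column is used).
#' @param merge_tol merge tolerance in Da (default 1.5, which collapses the
#'   1.02 Da Neu5Ac vs 2xFuc near-degeneracy).
#' @param split_vacancies handle missing teeth as described above.
#' @return list with `mean`, `sd`, `n_spacings`, and the `collapsed` masses.
#' @examples
#' lad <- enumerate_ladder(c(Fuc = 6, Neu5Ac = 16, branch = 10), "average")
#' repeat_unit(lad)$mean  # ~72.9
#' @export
repeat_unit <- function(masses, merge_tol = 1.5, split_vacancies = TRUE) {
  if (is.data.frame(masses)) masses <- masses$delta_Da
  m <- sort(unique(masses))
  if (length(m) < 3L) stop("need at least 3 distinct ladder masses", call. = FALSE)
  grp <- cumsum(c(1, diff(m) > merge_tol))
  collapsed <- as.numeric(tapply(m, grp, mean))
  if (length(collapsed) < 2L) {
    stop("fewer than 2 collapsed masses: ladder unresolved at this merge_tol",
         call. = FALSE)
  }
  d <- diff(collapsed)
  if (split_vacancies && length(d) >= 2L) {
    med <- median(d)
    k <- ifelse(d > 1.5 * med, pmax(1, round(d / med)), 1)
    d <- rep(d / k, k)
  }
  list(mean = mean(d),
       sd = if (length(d) > 1L) sd(d) else 0,
       n_spacings = length(d),
       collapsed = collapsed)
}

#' Find glycan compositions matching a mass difference
#'
#' Exhaustive search over a residue-count grid for compositions whose mass
#' lies within `tol` of `delta`. Deterministic ordering: smallest absolute
#' error, then fewest total residues, then lexicographic residue counts.
#'
#' @param delta target mass difference (Da).
#' @param tol tolerance in Da (> 0).
#' @param ranges named per-residue maximum counts.
#' @inheritParams residue_mass
#' @return data.frame of candidate compositions with `delta_Da` (candidate
#'   mass), `error_Da` (signed, candidate - target), `n_residues`,
#'   `composition`; zero rows when nothing matches.
#' @examples
#' find_compositions(291.26, 0.5, c(Fuc = 4, Neu5Ac = 2, branch = 2), "average")
#' @export
find_compositions <- function(delta, tol, ranges, kind, table = residue_table()) {
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  lad <- enumerate_ladder(ranges, kind, table)
  cnt_cols <- setdiff(names(lad), c("delta_Da", "units", "composition"))
  lad$error_Da <- lad$delta_Da - delta
  hit <- lad[abs(lad$error_Da) <= tol, , drop = FALSE]
  if (nrow(hit) == 0L) {
    out <- hit[, c(cnt_cols, "delta_Da", "error_Da", "composition"), drop = FALSE]
    out$n_residues <- integer(0)
    return(out[, c(cnt_cols, "delta_Da", "error_Da", "n_residues", "composition")])
  }
  hit$n_residues <- if (length(cnt_cols)) {
    as.integer(rowSums(hit[, cnt_cols, drop = FALSE]))
  } else 0L
  ord <- do.call(order, c(list(abs(hit$error_Da), hit$n_residues),
                          unname(hit[, cnt_cols, drop = FALSE])))
  hit <- hit[ord, c(cnt_cols, "delta_Da", "error_Da", "n_residues",
                    "composition"), drop = FALSE]
  rownames(hit) <- NULL
  hit
}

#' Group ladder entries indistinguishable within a mass tolerance
#'
#' Transitive (single-linkage) grouping of ladder entries by mass
#' proximity: entries whose masses chain together with consecutive gaps
#' `<= tol` share a group. Reports, per multi-member group, the member
#' compositions and the largest pairwise gap.
#'
#' @param ladder data.frame from [enumerate_ladder()].
#' @param tol grouping tolerance in Da (> 0); `tol = 0` puts every distinct
#'   mass in its own group.
#' @return list with `entries` (the ladder plus `group_id`) and `groups`
#'   (one row per group: `group_id`, `n`, `members`, `span_Da`).
#' @export
degeneracy_report <- function(ladder, tol) {
  if (!is.numeric(tol) || tol < 0) stop("tol must be >= 0", call. = FALSE)
  lad <- ladder[order(ladder$delta_Da), , drop = FALSE]
  lad$group_id <- cumsum(c(1, diff(lad$delta_Da) > tol))
  groups <- do.call(rbind, lapply(split(lad, lad$group_id), function(g) {
    data.frame(group_id = g$group_id[1L], n = nrow(g),
               members = paste(g$composition, collapse = " | "),
               span_Da = max(g$delta_Da) - min(g$delta_Da),
               stringsAsFactors = FALSE)
  }))
  rownames(lad) <- rownames(groups) <- NULL
  list(entries = lad, groups = groups)
}

#' Built-in adduct table
#'
#' Average mass shifts for the adduct classes seen on intact membrane
#' protein ions: phosphorylation and palmitoylation (PTMs), the weighted
#' average masses of the endogenous phospholipid classes PE, PS and PI,
#' and detergent monomers that survive as satellite adducts.
#'
#' @param extra optional data.frame with columns `name`, `mass`, `class`.
#' @return data.frame with columns `name`, `mass` (Da), `class`
#'   (`PTM`/`lipid`/`detergent`).
#' @export
adduct_table <- function(extra = NULL) {
  tab <- data.frame(
    name  = c("phospho", "palmitoyl", "PE", "PS", "PI", "OGNG", "LMNG", "GDN"),
    mass  = c(79.98, 238.41, 731, 796, 870, 568.7, 1005.2, 1165.3),
    class = c("PTM", "PTM", "lipid", "lipid", "lipid",
              "detergent", "detergent", "detergent"),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(all(c("name", "mass", "class") %in% names(extra)))
    tab <- rbind(tab, extra[, c("name", "mass", "class")])
  }
  if (any(tab$mass <= 0)) stop("adduct mass shifts must be positive", call. = FALSE)
  tab
}

#' Mass shift of one adduct
#' @param name adduct name in `table`.
#' @param table see [adduct_table()].
#' @return mass shift in Da.
#' @export
adduct_mass <- function(name, table = adduct_table()) {
  i <- match(name, table$name)
  if (anyNA(i)) stop("unknown adduct name(s): ",
                     paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  unname(table$mass[i])
}
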