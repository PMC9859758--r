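#' Approximate binodal boundary from a phase-separation grid
#'
#' For each tested protein concentration, finds the contiguous block of
#' phase-separated calls starting from the lowest tested salt (phase
#' separation occurs below the binodal in ionic strength) and places the
#' boundary at the arithmetic midpoint between the highest salt in that
#' block and the next tested salt. Columns that are separated at every salt
#' are censored `above_max`; columns with no separation at the lowest salt
#' are censored `below_min`. Non-monotonic columns (separation reappearing
#' at higher salt, possible with classification noise) use the lowest-salt
#' block with a warning. Concentrations with fewer than two tested salts
#' are skipped with a warning.
#'
#' @param grid A `data.frame` with columns `protein_uM`, `nacl_mM`,
#'   `separated` (logical or 0/1); no duplicate (conc, salt) pairs.
#' @return A `data.frame` of class `"binodal"` with columns `protein_uM`,
#'   `boundary_salt_mM` (`NA` when censored) and `censored` (`"none"`,
#'   `"above_max"`, `"below_min"`), one row per retained concentration,
#'   ordered by concentration.
#' @export
binodal_from_grid <- function(grid) {
  g <- validate_phase_grid(grid)
  out <- list()
  for (conc in sort(unique(g$protein_uM))) {
    col <- g[g$protein_uM == conc, , drop = FALSE]
    col <- col[order(col$nacl_mM), , drop = FALSE]
    if (nrow(col) < 2) {
      warning("skipping concentration ", conc, " uM: fewer than 2 tested salts")
      next
    }
    sep <- col$separated
    r <- which.min(c(sep, FALSE)) - 1L     # length of leading separated run
    if (r < length(sep) && any(sep[(r + 1L):length(sep)]))
      warning("non-monotonic phase calls at ", conc,
              " uM; using the lowest-salt separated block")
    if (!sep[1]) {
      row <- data.frame(protein_uM = conc, boundary_salt_mM = NA_real_,
                        censored = "below_min")
    } else {
      if (r >= nrow(col)) {
        row <- data.frame(protein_uM = conc, boundary_salt_mM = NA_real_,
                          censored = "above_max")
      } else {
        row <- data.frame(protein_uM = conc,
                          boundary_salt_mM = (col$nacl_mM[r] + col$nacl_mM[r + 1]) / 2,
                          censored = "none")
      }
    }
    out[[length(out) + 1L]] <- row
  }
  res <- if (length(out) == 0)
    data.frame(protein_uM = numeric(0), boundary_salt_mM = numeric(0),
               censored = character(0))
  else do.call(rbind, out)
  class(res) <- c("binodal", "data.frame")
  res
}

validate_phase_grid <- function(grid) {
  need <- c("protein_uM", "nacl_mM", "separated")
  miss <- setdiff(need, names(grid))
  if (length(miss) > 0) stop_invalid("phase grid lacks columns: ",
                                     paste(miss, collapse = ", "))
  if (anyDuplicated(grid[c("protein_uM", "nacl_mM")]) > 0)
    stop_invalid("duplicate (concentration, salt) pairs in phase grid")
  grid$separated <- as.logical(grid$separated)
  grid
}

#' Critical concentration bracket at a fixed salt
#'
#' Scanning upward in protein concentration at one salt concentration,
#' returns the bracketing pair around the onset of phase separation: the
#' highest soluble concentration below the first separated one, and that
#' first separated concentration. Columns without a transition are censored.
#' Non-monotonic behaviour (soluble calls above the first transition)
#' reports the first transition with a warning.
#'
#' @param grid A phase grid (see [binodal_from_grid()]).
#' @param salt Salt concentration, mM; must match tested values.
#' @return A list: `lower` and `upper` concentration (uM; `NA` when
#'   censored) and `censored` (`"none"`, `"all_soluble"`,
#'   `"all_separated"`).
#' @export
critical_concentration <- function(grid, salt) {
  g <- validate_phase_grid(grid)
  col <- g[abs(g$nacl_mM - salt) < 1e-9, , drop = FALSE]
  if (nrow(col) < 2) stop_invalid("need >= 2 tested concentrations at salt ", salt)
  col <- col[order(col$protein_uM), , drop = FALSE]
  sep <- col$separated
  first_sep <- which(sep)[1]
  if (is.na(first_sep))
    return(list(lower = NA_real_, upper = NA_real_, censored = "all_soluble"))
  if (first_sep == 1L)
    return(list(lower = NA_real_, upper = col$protein_uM[1],
                censored = "all_separated"))
  if (any(!sep[first_sep:length(sep)]))
    warning("non-monotonic phase calls in concentration at ", salt,
            " mM; reporting the first transition")
  list(lower = col$protein_uM[first_sep - 1L], upper = col$protein_uM[first_sep],
       censored = "none")
}

#' Per-concentration differences between two binodals
#'
#' Pairs two binodal boundary tables on their common concentrations and
#' reports the boundary-salt difference `b - a` at each; a pair involving a
#' censored boundary yields a censored (NA) difference.
#'
#' @param a,b `"binodal"` objects (see [binodal_from_grid()]).
#' @return A `data.frame` with columns `protein_uM`, `boundary_a`,
#'   `boundary_b`, `difference_mM`, `censored` (logical).
#' @export
compare_binodals <- function(a, b) {
  common <- intersect(a$protein_uM, b$protein_uM)
  if (length(common) == 0) stop_invalid("binodals share no concentrations")
  ia <- match(common, a$protein_uM); ib <- match(common, b$protein_uM)
  cens <- a$censored[ia] != "none" | b$censored[ib] != "none"
  data.frame(protein_uM = common,
             boundary_a = a$boundary_salt_mM[ia],
             boundary_b = b$boundary_salt_mM[ib],
             difference_mM = ifelse(cens, NA_real_,
                                    b$boundary_salt_mM[ib] - a$boundary_salt_mM[ia]),
             censored = cens)
}
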