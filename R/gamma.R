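# Global gamma index and gamma passing rates at the nine standard criteria.
# Dose difference is normalized to the reference maximum (global mode), the
# low-dose region below the threshold is excluded on the reference side, and
# the distance-to-agreement search interpolates the evaluated distribution on
# a fine sub-grid (see gammaMap for the numerical parameters).

#' The nine standard gamma criteria
#'
#' The full grid of \{1, 2, 3\}% dose tolerance by \{1, 2, 3\} mm
#' distance-to-agreement, in the conventional order.
#'
#' @return a data.frame with columns `doseTol` (%), `dta` (mm) and `label`
#'   (e.g. `"2%/2mm"`).
#' @export
gammaCriteria <- function() {
  g <- expand.grid(dta = c(1, 2, 3), doseTol = c(1, 2, 3))
  data.frame(doseTol = g$doseTol, dta = g$dta,
             label = sprintf("%d%%/%dmm", g$doseTol, g$dta))
}

#' 2D global gamma map
#'
#' For every reference pixel at or above `threshold` percent of the reference
#' maximum, computes the gamma index against the evaluated distribution:
#' the minimum over candidate positions within `searchMult * dta` of
#' `sqrt((dose diff / (doseTol% of max))^2 + (distance / dta)^2)`, with the
#' evaluated dose bilinearly interpolated at `stepFrac * dta` steps.
#' Reference pixels below the threshold are `NA` (outside the domain).
#'
#' @param reference,evaluated dose matrices on the same lattice (Gy).
#' @param doseTol dose tolerance, percent of the reference maximum.
#' @param dta distance to agreement, mm.
#' @param spacing pixel spacing, mm: one value or `c(row, col)`.
#' @param threshold low-dose threshold, percent of the reference maximum.
#' @param searchMult search radius in units of `dta`.
#' @param stepFrac interpolation step in units of `dta`.
#' @return matrix of gamma values (`NA` below threshold).
#' @export
gammaMap <- function(reference, evaluated, doseTol, dta, spacing = 1,
                     threshold = 10, searchMult = 3, stepFrac = 0.1) {
  if (doseTol <= 0 || dta <= 0)
    stop("dose tolerance and DTA must be strictly positive")
  spacing <- rep(as.numeric(spacing), length.out = 2L)
  if (!any(reference >= threshold / 100 * max(reference)))
    stop("degenerate input: no reference dose at or above the threshold")
  .gammaMapCpp(reference, evaluated, spacing[1], spacing[2],
               doseTol, dta, threshold, searchMult, stepFrac)
}

#' Gamma passing rate of a gamma map
#'
#' @param gamma a gamma-value field (`NA` outside the evaluation domain).
#' @return percent of in-domain points with gamma <= 1, in `[0, 100]`.
#' @export
gpr <- function(gamma) {
  ok <- !is.na(gamma)
  if (!any(ok)) stop("degenerate input: empty gamma field")
  100 * mean(gamma[ok] <= 1)
}

#' Gamma passing rates at the nine criteria
#'
#' Applies [gammaMap()] + [gpr()] for every criterion of [gammaCriteria()].
#'
#' @inheritParams gammaMap
#' @return named numeric vector of nine passing rates (%), names as in
#'   `gammaCriteria()$label`.
#' @export
gprVector <- function(reference, evaluated, spacing = 1, threshold = 10,
                      searchMult = 3, stepFrac = 0.1) {
  crit <- gammaCriteria()
  out <- vapply(seq_len(nrow(crit)), function(i) {
    gpr(gammaMap(reference, evaluated, crit$doseTol[i], crit$dta[i],
                 spacing = spacing, threshold = threshold,
                 searchMult = searchMult, stepFrac = stepFrac))
  }, numeric(1))
  names(out) <- crit$label
  out
}

# nine-entry GPR label sanity check: correct names, range, and monotone
# in both tolerances (loosening either never lowers the passing rate)
.checkGprLabel <- function(gpr, tol = 1e-9) {
  crit <- gammaCriteria()
  stopifnot(identical(names(gpr), crit$label), all(gpr >= -tol),
            all(gpr <= 100 + tol))
  m <- matrix(gpr, nrow = 3L) # rows: dta 1..3, cols: doseTol 1..3
  all(diff(m) >= -tol) && all(t(diff(t(m))) >= -tol)
}
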