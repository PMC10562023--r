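# MLC leaf-position map construction: stack the two banks into a 120-row
# matrix per plan, find the leaf pairs that never open anywhere in the
# dataset, and map each remaining leaf to its absolute displacement from the
# closed-state coordinate (closed = 0 by construction).

#' Stack a plan's leaf coordinates into a 120-row matrix
#'
#' Column `j` holds the 120 leaf-tip coordinates at control point `j`:
#' bank A leaves 1-60 in rows 1-60, bank B leaves 1-60 in rows 61-120. The
#' closed-state reference coordinate of each pair (the junction where the
#' opposing tips meet) is estimated as the tip midpoint averaged over the
#' control points at which the pair is closed, falling back to the midpoint
#' over all control points for pairs that never close.
#'
#' @param plan an [ArcPlan-class].
#' @param tol closure tolerance on the tip gap, mm.
#' @return a [LeafPositionMatrix-class].
#' @export
buildLeafMatrix <- function(plan, tol = .CLOSED_TOL_MM) {
  a <- bankA(plan); b <- bankB(plan)
  gap <- b - a
  mid <- (a + b) / 2
  ref <- vapply(seq_len(.N_LEAF_PAIRS), function(p) {
    closed <- gap[p, ] <= tol
    if (any(closed)) mean(mid[p, closed]) else mean(mid[p, ])
  }, numeric(1))
  new("LeafPositionMatrix", values = rbind(a, b), closedReference = ref,
      planId = planId(plan))
}

#' Leaf pairs closed at every control point of every plan
#'
#' A pair is reported only if its tip gap stays within `tol` of closed at
#' every control point of *every* supplied matrix; one open control point in
#' one plan keeps the pair.
#'
#' @param matrices a list of [LeafPositionMatrix-class] objects.
#' @param tol closure tolerance on the tip gap, mm.
#' @return sorted integer vector of pair indices (possibly empty).
#' @export
findAlwaysClosedPairs <- function(matrices, tol = .CLOSED_TOL_MM) {
  if (!length(matrices))
    stop("need at least one leaf-position matrix")
  closed <- rep(TRUE, .N_LEAF_PAIRS)
  for (m in matrices) {
    v <- mapValues(m)
    gap <- v[.N_LEAF_PAIRS + seq_len(.N_LEAF_PAIRS), , drop = FALSE] -
           v[seq_len(.N_LEAF_PAIRS), , drop = FALSE]
    closed <- closed & apply(gap <= tol, 1L, all)
  }
  which(closed)
}

#' Build the MLC leaf-position map
#'
#' Removes the rows of excluded (always-closed) pairs from both bank blocks,
#' maps every remaining cell to `|coordinate - closedReference|` (so a closed
#' leaf reads exactly 0), and right-pads the control-point axis with zeros to
#' the fixed width. Plans with more control points than the fixed width are
#' rejected rather than truncated, since dropping columns would discard leaf
#' motion.
#'
#' @param matrix a [LeafPositionMatrix-class].
#' @param excluded integer vector of excluded pair indices (subset of 1..60).
#' @param fixedShape output shape `c(rows, cols)`; rows must equal
#'   `120 - 2 * length(excluded)`.
#' @return an [MLPMap-class].
#' @export
buildMlpm <- function(matrix, excluded = integer(),
                      fixedShape = c(110L, 178L)) {
  excluded <- sort(as.integer(excluded))
  if (length(excluded) && (min(excluded) < 1L || max(excluded) > .N_LEAF_PAIRS))
    stop("excluded pair indices must lie in 1..60")
  keep <- setdiff(seq_len(.N_LEAF_PAIRS), excluded)
  nrows <- 2L * length(keep)
  if (nrows != fixedShape[1])
    stop(sprintf(paste0(
      "configuration error: %d retained rows but fixed shape expects %d ",
      "(wrong exclusion set for the configured input size)"),
      nrows, fixedShape[1]))
  ncp <- ncol(mapValues(matrix))
  if (ncp > fixedShape[2])
    stop(sprintf("plan has %d control points, more than the fixed width %d",
                 ncp, fixedShape[2]))
  v <- mapValues(matrix)
  ref <- closedReference(matrix)
  disp <- abs(sweep(v, 1L, c(ref, ref), "-"))
  out <- matrix(0, fixedShape[1], fixedShape[2])
  out[, seq_len(ncp)] <- disp[c(keep, .N_LEAF_PAIRS + keep), , drop = FALSE]
  new("MLPMap", values = out, excludedPairs = excluded,
      nControlPoints = as.integer(ncp), planId = planId(matrix))
}
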