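# independent plain-R gamma oracles, kept deliberately naive: no early
# termination, no shared code with the package kernel

# bilinear interpolation of a matrix at fractional (row, col) 0-based
# positions; NA outside
.oracleBilinear <- function(m, gy, gx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(gy))
  ok <- gy >= 0 & gy <= nr - 1 & gx >= 0 & gx <= nc - 1
  iy <- pmin(floor(gy[ok]), nr - 2); ix <- pmin(floor(gx[ok]), nc - 2)
  iy <- pmax(iy, 0); ix <- pmax(ix, 0)
  fy <- gy[ok] - iy; fx <- gx[ok] - ix
  out[ok] <- m[cbind(iy + 1, ix + 1)] * (1 - fy) * (1 - fx) +
    m[cbind(iy + 2, ix + 1)] * fy * (1 - fx) +
    m[cbind(iy + 1, ix + 2)] * (1 - fy) * fx +
    m[cbind(iy + 2, ix + 2)] * fy * fx
  out
}

# full fine-grid search with the same definition as the package engine
oracleGammaFine <- function(ref, ev, doseTol, dta, spacing = 1,
                            threshold = 10, searchMult = 3, stepFrac = 0.1) {
  dmax <- max(ref)
  tol <- doseTol / 100 * dmax
  thr <- threshold / 100 * dmax
  step <- stepFrac * dta
  nstep <- floor(searchMult * dta / step + 1e-9)
  offs <- expand.grid(du = (-nstep:nstep) * step, dv = (-nstep:nstep) * step)
  offs <- offs[offs$du^2 + offs$dv^2 <= (searchMult * dta)^2 + 1e-9, ]
  out <- matrix(NA_real_, nrow(ref), ncol(ref))
  for (r in seq_len(nrow(ref))) {
    for (cc in seq_len(ncol(ref))) {
      if (ref[r, cc] < thr) next
      gy <- ((r - 1) * spacing + offs$dv) / spacing
      gx <- ((cc - 1) * spacing + offs$du) / spacing
      dev <- .oracleBilinear(ev, gy, gx)
      g2 <- (offs$du^2 + offs$dv^2) / dta^2 + ((dev - ref[r, cc]) / tol)^2
      out[r, cc] <- sqrt(min(g2, na.rm = TRUE))
    }
  }
  out
}

# exhaustive search over the evaluated sample points only (no interpolation,
# no search-radius restriction)
oracleGammaExhaustive <- function(ref, ev, doseTol, dta, spacing = 1,
                                  threshold = 10) {
  dmax <- max(ref)
  tol <- doseTol / 100 * dmax
  thr <- threshold / 100 * dmax
  nr <- nrow(ref); nc <- ncol(ref)
  pos_y <- (seq_len(nr) - 1) * spacing
  pos_x <- (seq_len(nc) - 1) * spacing
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (ref[r, cc] < thr) next
      d2 <- outer((pos_y - pos_y[r])^2, rep(1, nc)) +
        outer(rep(1, nr), (pos_x - pos_x[cc])^2)
      g2 <- d2 / dta^2 + ((ev - ref[r, cc]) / tol)^2
      out[r, cc] <- sqrt(min(g2))
    }
  }
  out
}
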