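# Three-echo chemical-shift (Dixon) fat-water separation.
#
# Per-voxel model: S(TE) = (W + F c(TE)) exp(2 pi i psi TE) exp(-TE R2*),
# with c(TE) the multi-peak fat modulation, psi the field offset (Hz) and a
# single R2* shared by water and fat. Solved by variable projection: for a
# candidate (psi, R2*) the data are demodulated and the complex (W, F) pair
# solved linearly against the constant design [1, c(TE)]; (psi, R2*) are
# found on a coarse shared grid, disambiguated by region growing, then
# refined per voxel with a shrinking local grid (all steps vectorised
# across voxels).

# residual projector and pseudo-inverse for the constant design [1, c(TE)]
dixonDesign <- function(te, fatSpectrum, fieldStrength) {
  A <- cbind(1 + 0i, fatModulation(te, fatSpectrum, fieldStrength))
  AH <- Conj(t(A))
  P <- solve(AH %*% A, AH)          # 2 x nEcho pseudo-inverse
  R <- diag(length(te)) - A %*% P   # residual projector
  list(A = A, P = P, R = R)
}

# residual energy per voxel for per-voxel (psi, r2) candidate vectors;
# S is nVox x nEcho complex, te in ms, psi Hz, r2 1/s
dixonCost <- function(S, te, psi, r2, R) {
  E <- exp(outer(-2i * pi * psi, te / 1000) + outer(r2, te / 1000))
  Sd <- S * E
  rowSums(Mod(Sd %*% t(R))^2)
}

#' Separate water and fat from a three-echo Dixon acquisition
#'
#' Voxelwise least-squares estimation of water, fat, a shared R2* and the
#' field offset under the multi-peak fat model (see the package vignette for
#' the algorithm). Field-offset ambiguities (water/fat swaps) are resolved
#' by region growing from the highest-magnitude voxel, each voxel taking the
#' candidate cost minimum nearest its already-decided neighbours' field
#' offset; voxels with several candidates and no decided neighbour are
#' counted as unresolved.
#'
#' @param series a [DixonSeries-class]
#' @param psiRange field-offset search range, Hz
#' @param psiStep coarse grid spacing, Hz
#' @param r2Range shared R2* search range, 1/s
#' @param r2Step coarse grid spacing, 1/s
#' @param refineIter shrinking-grid refinement iterations
#' @return a [FatWaterResult-class]
#' @examples
#' ff <- matrix(30, 4, 4)
#' res <- separateFatWater(makeDixonVolume(ff, waterT2star = 25))
#' range(ffMap(res))
#' @export
separateFatWater <- function(series, psiRange = c(-150, 150), psiStep = 5,
                             r2Range = c(0, 300), r2Step = 25,
                             refineIter = 25) {
  stopIfNot(is(series, "DixonSeries"), "series must be a DixonSeries")
  te <- echoTimes(series)
  stopIfNot(length(te) >= 3, "fewer echoes than unknowns")
  dims <- dim(series@echoes[[1]])
  nVox <- prod(dims)
  S <- vapply(series@echoes, as.vector, complex(nVox))
  if (is.null(dim(S))) S <- matrix(S, nrow = nVox)
  des <- dixonDesign(te, series@fatSpectrum, series@fieldStrength)
  psiGrid <- seq(psiRange[1], psiRange[2], by = psiStep)
  r2Grid <- seq(r2Range[1], r2Range[2], by = r2Step)
  # coarse pass: per-voxel cost profile over psi (minimised over r2)
  costPsi <- matrix(Inf, nVox, length(psiGrid))
  bestR2 <- matrix(r2Grid[1], nVox, length(psiGrid))
  for (j in seq_along(psiGrid)) {
    for (r2 in r2Grid) {
      d <- exp(-2i * pi * psiGrid[j] * te / 1000 + r2 * te / 1000)
      B <- t(des$R %*% diag(d))
      cost <- rowSums(Mod(S %*% B)^2)
      upd <- cost < costPsi[, j]
      costPsi[upd, j] <- cost[upd]
      bestR2[upd, j] <- r2
    }
  }
  # candidate basins: local minima of each voxel's psi profile
  nP <- length(psiGrid)
  isMin <- costPsi <= cbind(Inf, costPsi[, -nP, drop = FALSE]) &
           costPsi <= cbind(costPsi[, -1, drop = FALSE], Inf)
  chosen <- integer(nVox)
  unresolved <- 0L
  mag <- rowSums(Mod(S))
  if (nP == 1L) {
    chosen[] <- 1L
  } else {
    # BFS region growing over the voxel lattice (preallocated queue)
    nb <- neighbourOffsets(dims)
    order0 <- which.max(mag)
    visited <- logical(nVox)
    queue <- integer(nVox)
    queue[1] <- order0
    head <- 1L; tail <- 1L
    visited[order0] <- TRUE
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      nbv <- nb(v)
      cand <- which(isMin[v, ])
      if (!length(cand)) cand <- which.min(costPsi[v, ])
      if (length(cand) > 1L) {
        decided <- nbv[chosen[nbv] > 0L]
        if (length(decided)) {
          ref <- mean(psiGrid[chosen[decided]])
          cand <- cand[order(abs(psiGrid[cand] - ref), costPsi[v, cand])]
        } else {
          if (v != order0) unresolved <- unresolved + 1L
          cand <- cand[order(costPsi[v, cand])]
        }
      }
      chosen[v] <- cand[1]
      nxt <- nbv[!visited[nbv]]
      if (length(nxt)) {
        visited[nxt] <- TRUE
        queue[tail + seq_along(nxt)] <- nxt
        tail <- tail + length(nxt)
      }
    }
  }
  psi <- psiGrid[chosen]
  r2 <- bestR2[cbind(seq_len(nVox), chosen)]
  # per-voxel shrinking-grid refinement of (psi, r2)
  dPsi <- psiStep / 2
  dR2 <- r2Step / 2
  cost0 <- dixonCost(S, te, psi, r2, des$R)
  for (it in seq_len(refineIter)) {
    improved <- FALSE
    for (off in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                     c(-1, -1), c(1, 1), c(-1, 1), c(1, -1))) {
      p2 <- psi + off[1] * dPsi
      r22 <- pmax(r2 + off[2] * dR2, 0)
      c2 <- dixonCost(S, te, p2, r22, des$R)
      upd <- c2 < cost0
      if (any(upd)) {
        psi[upd] <- p2[upd]; r2[upd] <- r22[upd]; cost0[upd] <- c2[upd]
        improved <- TRUE
      }
    }
    dPsi <- dPsi / 2; dR2 <- dR2 / 2
    if (dPsi < 1e-4 && dR2 < 1e-4) break
  }
  # final linear solve for complex water and fat
  E <- exp(outer(-2i * pi * psi, te / 1000) + outer(r2, te / 1000))
  X <- (S * E) %*% t(des$P)
  W <- Mod(X[, 1]); Fm <- Mod(X[, 2])
  tot <- W + Fm
  zero <- tot <= max(tot, 1e-300) * 1e-12
  ff <- numeric(nVox)
  ff[!zero] <- 100 * Fm[!zero] / tot[!zero]
  shape <- function(x) array(x, dims)
  new("FatWaterResult", water = shape(W), fat = shape(Fm),
      r2star = shape(r2), fieldMap = shape(psi), ff = shape(ff),
      zeroSignal = shape(zero), swapUnresolved = unresolved)
}

# face-neighbour index function for an array lattice (precomputed strides)
neighbourOffsets <- function(dims) {
  nd <- length(dims)
  strides <- cumprod(c(1L, dims[-nd]))
  function(v) {
    idx <- arrayInd(v, dims)[1, ]
    out <- integer(2L * nd)
    n <- 0L
    for (d in seq_len(nd)) {
      if (idx[d] > 1L) { n <- n + 1L; out[n] <- v - strides[d] }
      if (idx[d] < dims[d]) { n <- n + 1L; out[n] <- v + strides[d] }
    }
    out[seq_len(n)]
  }
}

#' Correct magnitude images for noise bias
#'
#' Quadrature (two-channel) noise-power correction of magnitude data:
#' `sqrt(max(M^2 - 2 sigma^2, 0))` per voxel, where `sigma` is the
#' per-channel Gaussian noise standard deviation. Values at or below the
#' noise floor return 0.
#'
#' @param magnitude non-negative magnitude values (vector or array)
#' @param noiseSd per-channel noise standard deviation (>= 0)
#' @return corrected magnitudes, same shape
#' @export
noiseBiasCorrect <- function(magnitude, noiseSd) {
  stopIfNot(all(magnitude >= 0), "magnitude values must be non-negative")
  stopIfNot(length(noiseSd) == 1 && noiseSd >= 0,
            "noiseSd must be a single non-negative number")
  out <- sqrt(pmax(magnitude^2 - 2 * noiseSd^2, 0))
  if (!is.null(dim(magnitude))) dim(out) <- dim(magnitude)
  out
}

#' Estimate the noise level from a background region
#'
#' Per-channel Gaussian noise standard deviation from the standard deviation
#' of background magnitude voxels, dividing out the Rayleigh correction
#' factor `sqrt(2 - pi/2)`.
#'
#' @param background magnitude values from a signal-free region
#' @return estimated per-channel noise standard deviation
#' @export
estimateNoiseSd <- function(background) {
  stopIfNot(length(background) >= 2, "need at least 2 background voxels")
  stats::sd(background) / sqrt(2 - pi / 2)
}

#' Summarise fat fraction over a mask
#'
#' Mean fat fraction over all masked voxels together with a per-slice
#' breakdown (slices along the last array dimension). Voxels flagged as
#' zero-signal (0/0 fat fraction) are excluded and counted.
#'
#' @param ff fat-fraction array, percent
#' @param mask integer/logical array of the same shape (non-zero = included)
#' @param zeroSignal optional logical array of excluded 0/0 voxels
#' @return list with `mean_ff`, `n_voxels`, `n_excluded`, `per_slice`
#'   (data.frame slice/mean_ff/n_voxels)
#' @export
summarizeFF <- function(ff, mask, zeroSignal = NULL) {
  ff <- as.array(ff); mask <- as.array(mask)
  stopIfNot(identical(dim(ff), dim(mask)), "mask does not match map geometry")
  sel <- mask != 0
  stopIfNot(any(sel), "empty mask")
  excl <- if (is.null(zeroSignal)) array(FALSE, dim(ff)) else as.array(zeroSignal)
  use <- sel & !excl
  stopIfNot(any(use), "mask selects only zero-signal voxels")
  nd <- length(dim(ff))
  sliceIdx <- if (nd >= 3) slice.index(ff, nd) else array(1L, dim(ff))
  slices <- sort(unique(sliceIdx[use]))
  per <- do.call(rbind, lapply(slices, function(s) {
    w <- use & sliceIdx == s
    data.frame(slice = s, mean_ff = mean(ff[w]), n_voxels = sum(w))
  }))
  list(mean_ff = mean(ff[use]), n_voxels = sum(use),
       n_excluded = sum(sel & excl), per_slice = per)
}
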