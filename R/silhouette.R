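#' Per-feature pairwise absolute distances
#'
#' For each feature dimension `f`, computes the absolute distance between
#' every pair of samples: `D[f, j, k] = |Z[j, f] - Z[k, f]|`. This tensor is
#' the shared intermediate of the vectorized target-position search; its
#' `F x N x N` size is the method's `O(F N^2)` memory footprint.
#'
#' @param batch a [FeatureBatch-class].
#' @return numeric array of dimension `F x N x N`, symmetric in the last two
#'   indices with zero diagonal.
#' @examples
#' fb <- FeatureBatch(matrix(c(0, 2, 1, 3), 4, 1), c(1, 1, 2, 2))
#' pairwiseAbsDistance(fb)[1, , ]
#' @export
pairwiseAbsDistance <- function(batch) {
  stopifnot(is(batch, "FeatureBatch"))
  Z <- featureMatrix(batch)
  stopifnotFinite(Z, "Z")
  N <- nrow(Z); F <- ncol(Z)
  D <- array(0, dim = c(F, N, N))
  for (f in seq_len(F)) {
    z <- Z[, f]
    D[f, , ] <- abs(outer(z, z, "-"))
  }
  D
}

# Eligibility of a label vector for class-count based checks.
classCounts <- function(y) {
  y <- as.integer(y)
  tab <- tabulate(y)
  tab[sort(unique(y))]
}

#' Is a batch eligible for the separability regularizer?
#'
#' A batch qualifies only when at least two distinct classes are present and
#' every present class has at least two samples; otherwise the silhouette is
#' ill-defined and callers fall back to cross-entropy only for that batch.
#'
#' @param y integer class labels.
#' @return `TRUE` or `FALSE`.
#' @examples
#' batchIsMsfsEligible(c(1, 1, 2, 2))  # TRUE
#' batchIsMsfsEligible(c(1, 1, 2))     # FALSE: singleton class
#' batchIsMsfsEligible(c(1, 1, 1, 1))  # FALSE: one class
#' @export
batchIsMsfsEligible <- function(y) {
  y <- as.integer(y)
  if (length(y) < 4L) return(FALSE)  # two classes x two samples minimum
  cls <- unique(y)
  length(cls) >= 2L && all(tabulate(y)[cls] >= 2L)
}

checkEligible <- function(y) {
  if (!batchIsMsfsEligible(y))
    stop("batch is not eligible: need >= 2 classes, each with >= 2 samples",
         call. = FALSE)
  invisible(TRUE)
}

#' One-dimensional silhouette scores
#'
#' For a single feature dimension, computes the per-sample silhouette
#' `s_i = (b_i - a_i) / max(a_i, b_i)` under the absolute distance, where
#' `a_i` is the mean distance to own-class members (excluding the sample
#' itself) and `b_i` is the minimum over other classes of the mean distance
#' to that class. When `max(a_i, b_i) = 0` (all relevant values coincide),
#' `s_i = 0` by convention.
#'
#' @param values numeric vector of length `N` (one feature dimension).
#' @param y integer class labels; every present class needs `>= 2` members
#'   and at least two classes must be present.
#' @return numeric vector of per-sample silhouettes, each in `[-1, 1]`.
#' @examples
#' silhouette1d(c(0, 0, 1, 1), c(1, 1, 2, 2))  # perfectly separated: all 1
#' silhouette1d(c(0, 2, 1, 3), c(1, 1, 2, 2))  # interleaved: (0, -.5, -.5, 0)
#' @export
silhouette1d <- function(values, y) {
  y <- as.integer(y)
  stopifnotFinite(values, "values")
  checkEligible(y)
  N <- length(values)
  stopifnot(length(y) == N)
  D <- abs(outer(values, values, "-"))
  cls <- sort(unique(y))
  nq <- tabulate(y)[cls]
  # sums of distances from each sample to each class
  ind <- vapply(cls, function(q) as.numeric(y == q), numeric(N))  # N x K
  S <- D %*% ind                                                  # N x K
  ownCol <- match(y, cls)
  a <- (S[cbind(seq_len(N), ownCol)]) / (nq[ownCol] - 1)
  Sbar <- sweep(S, 2L, nq, "/")
  Sbar[cbind(seq_len(N), ownCol)] <- Inf
  b <- apply(Sbar, 1L, min)
  denom <- pmax(a, b)
  s <- ifelse(denom == 0, 0, (b - a) / denom)
  as.numeric(s)
}

#' Relocation silhouettes for every sample, feature and candidate position
#'
#' For each sample `i`, feature `f` and candidate `j`, computes the
#' silhouette sample `i` would attain if its value in feature `f` were
#' relocated to the batch value `Z[j, f]`, with every other sample fixed:
#' `a[i,f,j]` is the mean distance from the candidate position to sample
#' `i`'s own class (excluding `i`), `b[i,f,j]` the minimum over other
#' classes of the mean distance from the candidate position to that class
#' (the candidate's coincident batch member contributes its zero
#' self-distance), and `s = (b - a) / max(a, b)` with the zero-denominator
#' convention `s = 0`.
#'
#' @param batch an eligible [FeatureBatch-class].
#' @return list with arrays `s`, `a`, `b`, each of dimension `N x F x N`
#'   indexed `[sample i, feature f, candidate j]`.
#' @export
relocatedSilhouette <- function(batch) {
  stopifnot(is(batch, "FeatureBatch"))
  Z <- featureMatrix(batch); y <- classLabels(batch)
  stopifnotFinite(Z, "Z")
  checkEligible(y)
  N <- nrow(Z); F <- ncol(Z)
  cls <- sort(unique(y))
  K <- length(cls)
  nq <- tabulate(y)[cls]
  ownCol <- match(y, cls)
  ind <- vapply(cls, function(q) as.numeric(y == q), numeric(N))  # N x K
  sArr <- array(0, dim = c(N, F, N))
  aArr <- array(0, dim = c(N, F, N))
  bArr <- array(0, dim = c(N, F, N))
  for (f in seq_len(F)) {
    z <- Z[, f]
    Df <- abs(outer(z, z, "-"))        # rows: candidate j, cols: sample k
    M <- Df %*% ind                    # M[j, q] = sum_{k in C_q} D[f, j, k]
    # a[j, i]: own-class mean from candidate j, excluding sample i itself
    A <- (M[, ownCol, drop = FALSE] - Df) /
      rep(nq[ownCol] - 1, each = N)
    # b[j, i]: min over classes other than y_i of class-mean distances
    Mbar <- sweep(M, 2L, nq, "/")      # N x K class means
    B <- matrix(0, N, N)
    for (qi in seq_len(K)) {
      others <- Mbar[, -qi, drop = FALSE]
      bq <- do.call(pmin, as.data.frame(others))
      B[, ownCol == qi] <- bq
    }
    denom <- pmax(A, B)
    S <- ifelse(denom == 0, 0, (B - A) / denom)
    sArr[, f, ] <- t(S)
    aArr[, f, ] <- t(A)
    bArr[, f, ] <- t(B)
  }
  list(s = sArr, a = aArr, b = bArr)
}

# Shared tie-break convention for candidate argmax: among candidates whose
# silhouette is within `tol` of the maximum, pick the candidate value
# closest to the sample's current value; remaining ties go to the lowest
# candidate index. The tolerance absorbs floating-point summation-order
# differences between the vectorized and brute-force paths.
SIL_TIE_TOL <- 1e-9

pickCandidate <- function(sVec, candValues, current, candIdx = seq_along(sVec)) {
  top <- which(sVec >= max(sVec) - SIL_TIE_TOL)
  if (length(top) > 1L) {
    d <- abs(candValues[top] - current)
    top <- top[d == min(d)]
  }
  candIdx[top[1L]]
}

#' Silhouette-optimized target positions (vectorized search)
#'
#' For every sample and feature dimension, selects among the existing batch
#' values of that feature the candidate position that maximizes the sample's
#' relocation silhouette, with all other samples fixed. The sample's own
#' position is always in the candidate set, so the selected silhouette never
#' falls below the current one. Ties are broken toward the candidate value
#' closest to the current value, then toward the lowest candidate index.
#'
#' @param batch an eligible [FeatureBatch-class].
#' @return numeric `N x F` target matrix; every entry is an existing batch
#'   value of its feature column.
#' @examples
#' fb <- FeatureBatch(matrix(c(0, 0.1, 5, 0.9), 4, 1), c(1, 1, 2, 2))
#' optPosSil(fb)  # sample 4 is pulled to its lone classmate at 5
#' @export
optPosSil <- function(batch) {
  rs <- relocatedSilhouette(batch)
  Z <- featureMatrix(batch)
  N <- nrow(Z); F <- ncol(Z)
  t <- matrix(0, N, F)
  for (f in seq_len(F)) {
    Sf <- rs$s[, f, ]                 # N x N: [sample i, candidate j]
    z <- Z[, f]
    for (i in seq_len(N)) {
      j <- pickCandidate(Sf[i, ], z, z[i])
      t[i, f] <- z[j]
    }
  }
  t
}

#' Brute-force target positions (independent oracle)
#'
#' A deliberately plain re-derivation of [optPosSil()] used as a testing
#' oracle: for each `(i, f)` and each candidate `j`, copies feature column
#' `f`, overwrites entry `i` with `Z[j, f]`, recomputes sample `i`'s
#' silhouette from the definitional formulas with all other entries fixed,
#' and returns the argmax candidate's value under the same tie-break
#' convention. Quadratic per candidate; intended for small batches.
#'
#' @param batch an eligible [FeatureBatch-class].
#' @return numeric `N x F` target matrix, elementwise equal to
#'   [optPosSil()].
#' @export
optPosBrute <- function(batch) {
  stopifnot(is(batch, "FeatureBatch"))
  Z <- featureMatrix(batch); y <- classLabels(batch)
  checkEligible(y)
  N <- nrow(Z); F <- ncol(Z)
  cls <- sort(unique(y))
  t <- matrix(0, N, F)
  for (f in seq_len(F)) {
    z0 <- Z[, f]
    for (i in seq_len(N)) {
      sVec <- numeric(N)
      for (j in seq_len(N)) {
        v <- z0
        v[i] <- z0[j]
        own <- which(y == y[i]); own <- own[own != i]
        a <- mean(abs(v[i] - v[own]))
        b <- Inf
        for (q in cls[cls != y[i]]) {
          b <- min(b, mean(abs(v[i] - v[y == q])))
        }
        m <- max(a, b)
        sVec[j] <- if (m == 0) 0 else (b - a) / m
      }
      j <- pickCandidate(sVec, z0, z0[i])
      t[i, f] <- z0[j]
    }
  }
  t
}

#' Random target positions within the batch range (ablation)
#'
#' Replaces the silhouette-optimized targets with values drawn independently
#' and uniformly from each feature's batch range `[min_j Z[j,f], max_j
#' Z[j,f]]`. Removes the separability criterion while keeping the loss form,
#' isolating the contribution of the silhouette search.
#'
#' @param batch a [FeatureBatch-class] (eligibility is not required).
#' @param seed integer seed, or an internal random stream.
#' @return numeric `N x F` target matrix.
#' @export
randPos <- function(batch, seed = 1L) {
  stopifnot(is(batch, "FeatureBatch"))
  Z <- featureMatrix(batch)
  N <- nrow(Z); F <- ncol(Z)
  draw <- function() {
    t <- matrix(0, N, F)
    for (f in seq_len(F)) {
      lo <- min(Z[, f]); hi <- max(Z[, f])
      t[, f] <- runif(N, lo, hi)
    }
    t
  }
  if (inherits(seed, "rngStream")) streamEval(seed, draw())
  else withSeed(seed, draw())
}

#' Subsampled-candidate target positions (fast approximation)
#'
#' Approximates [optPosSil()] by evaluating the relocation silhouette on at
#' most `m` candidate values per class (sampled without replacement per
#' feature), always augmented with the sample's own position. When `m` is at
#' least the largest class size the candidate set is complete and the result
#' equals the exact search elementwise.
#'
#' @param batch an eligible [FeatureBatch-class].
#' @param m candidates per class, `>= 1`.
#' @param seed integer seed, or an internal random stream.
#' @return numeric `N x F` target matrix; every entry is a batch value.
#' @export
optPosSilSubsampled <- function(batch, m, seed = 1L) {
  stopifnot(is(batch, "FeatureBatch"), m >= 1L)
  Z <- featureMatrix(batch); y <- classLabels(batch)
  checkEligible(y)
  N <- nrow(Z); F <- ncol(Z)
  cls <- sort(unique(y))
  nq <- tabulate(y)[cls]
  ownCol <- match(y, cls)
  ind <- vapply(cls, function(q) as.numeric(y == q), numeric(N))
  sampleCands <- function() {
    lapply(seq_len(F), function(f) {
      unlist(lapply(seq_along(cls), function(qi) {
        idx <- which(y == cls[qi])
        if (length(idx) <= m) idx else sample(idx, m)
      }))
    })
  }
  cands <- if (inherits(seed, "rngStream")) streamEval(seed, sampleCands())
           else withSeed(seed, sampleCands())
  t <- matrix(0, N, F)
  for (f in seq_len(F)) {
    z <- Z[, f]
    J <- sort(unique(cands[[f]]))
    # distances from candidate rows only: |J| x N
    DfJ <- abs(outer(z[J], z, "-"))
    M <- DfJ %*% ind                          # |J| x K sums
    Mbar <- sweep(M, 2L, nq, "/")
    for (i in seq_len(N)) {
      Ji <- if (i %in% J) J else sort(c(J, i))
      rows <- match(Ji, J)
      extra <- is.na(rows)
      aRow <- bRow <- numeric(length(Ji))
      for (kk in seq_along(Ji)) {
        if (!extra[kk]) {
          a <- (M[rows[kk], ownCol[i]] - DfJ[rows[kk], i]) / (nq[ownCol[i]] - 1)
          b <- min(Mbar[rows[kk], -ownCol[i]])
        } else {
          dRow <- abs(z[Ji[kk]] - z)
          sums <- as.numeric(dRow %*% ind)
          a <- (sums[ownCol[i]] - dRow[i]) / (nq[ownCol[i]] - 1)
          b <- min((sums / nq)[-ownCol[i]])
        }
        aRow[kk] <- a; bRow[kk] <- b
      }
      denom <- pmax(aRow, bRow)
      sVec <- ifelse(denom == 0, 0, (bRow - aRow) / denom)
      j <- pickCandidate(sVec, z[Ji], z[i], Ji)
      t[i, f] <- z[j]
    }
  }
  t
}

#' Most informative feature dimensions by current silhouette
#'
#' Ranks feature dimensions by the mean of their per-sample 1D silhouettes
#' at the current positions and returns the indices of the top `k`; the
#' position loss can then be restricted to these dimensions. Ties go to the
#' lowest feature index.
#'
#' @param batch an eligible [FeatureBatch-class].
#' @param k number of features to keep, `1 <= k <= F`.
#' @return integer vector of `k` feature indices, sorted increasingly.
#' @export
topkFeatureMask <- function(batch, k) {
  stopifnot(is(batch, "FeatureBatch"))
  Z <- featureMatrix(batch); y <- classLabels(batch)
  checkEligible(y)
  F <- ncol(Z)
  stopifnot(k >= 1L, k <= F)
  means <- vapply(seq_len(F), function(f) mean(silhouette1d(Z[, f], y)),
                  numeric(1))
  ord <- order(-means, seq_len(F))   # ties: lowest index first
  sort(ord[seq_len(k)])
}

#' Export a per-feature silhouette profile
#'
#' Writes a tab-delimited diagnostic table (feature index, mean silhouette
#' at current positions) for inspecting which dimensions of a feature layer
#' carry class structure.
#'
#' @param batch an eligible [FeatureBatch-class].
#' @param path output file path.
#' @return the profile `data.frame`, invisibly.
#' @export
exportSilhouetteProfile <- function(batch, path) {
  Z <- featureMatrix(batch); y <- classLabels(batch)
  checkEligible(y)
  prof <- data.frame(
    feature = seq_len(ncol(Z)),
    mean_silhouette = vapply(seq_len(ncol(Z)),
                             function(f) mean(silhouette1d(Z[, f], y)),
                             numeric(1)))
  utils::write.table(prof, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(prof)
}
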