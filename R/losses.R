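#' Cross-entropy loss
#'
#' Mean over samples of the negative natural-log softmax probability of the
#' true class, computed with log-sum-exp stabilization.
#'
#' @param logits numeric `N x K` matrix of unnormalized class scores.
#' @param y integer labels in `1..K`.
#' @return a single nonnegative number (nats).
#' @examples
#' ceLoss(matrix(0, 3, 4), c(1, 2, 3))  # uniform softmax: log(4)
#' @export
ceLoss <- function(logits, y) {
  logits <- as.matrix(logits)
  y <- as.integer(y)
  stopifnotFinite(logits, "logits")
  K <- ncol(logits)
  if (K < 2L) stop("need K >= 2 classes", call. = FALSE)
  if (any(y < 1L | y > K))
    stop("labels must lie in 1..K", call. = FALSE)
  if (length(y) != nrow(logits))
    stop("length(y) must equal nrow(logits)", call. = FALSE)
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  mean(lse - logits[cbind(seq_along(y), y)])
}

# Gradient of ceLoss w.r.t. logits: (softmax - onehot) / N.
ceGrad <- function(logits, y) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  p[cbind(seq_along(y), y)] <- p[cbind(seq_along(y), y)] - 1
  p / nrow(logits)
}

#' Mean squared position loss
#'
#' The feature-regression objective: `(1 / (N F)) * sum_(i,f) (Z[i,f] -
#' t[i,f])^2`. Targets are constants for gradient purposes — the loss pulls
#' features toward them, never the other way around.
#'
#' @param Z numeric `N x F` feature matrix.
#' @param targets numeric `N x F` target matrix.
#' @return a single nonnegative number.
#' @examples
#' positionLoss(matrix(c(1, 3), 1, 2), matrix(c(0, 1), 1, 2))  # 2.5
#' @export
positionLoss <- function(Z, targets) {
  Z <- as.matrix(Z); targets <- as.matrix(targets)
  if (!identical(dim(Z), dim(targets)))
    stop("features and targets must have identical dimensions", call. = FALSE)
  mean((Z - targets)^2)
}

#' Hard-gated composite objective
#'
#' Combines cross-entropy and the position loss behind a hard gate: the
#' total is `ce + omega * lpos` when `ce < lossMin` (strict inequality; a tie
#' at exactly `lossMin` keeps the gate closed), and `ce` otherwise. The gate
#' indicator is evaluated on the detached cross-entropy value of the current
#' batch and carries no gradient.
#'
#' @param ce nonnegative cross-entropy value.
#' @param lpos nonnegative position-loss value.
#' @param cfg a [GateConfig-class].
#' @return a `lossBreakdown` list with elements `ce`, `lpos`, `gateOpen`,
#'   `total`.
#' @examples
#' gatedTotalLoss(0.5, 0.3, GateConfig(1, 0.2))$total  # gate closed: 0.5
#' gatedTotalLoss(0.1, 0.3, GateConfig(1, 0.2))$total  # gate open: 0.4
#' @export
gatedTotalLoss <- function(ce, lpos, cfg) {
  stopifnot(is(cfg, "GateConfig"), is.finite(ce), ce >= 0,
            is.finite(lpos), lpos >= 0)
  gateOpen <- ce < lossMin(cfg)
  total <- if (gateOpen) ce + omega(cfg) * lpos else ce
  structure(list(ce = ce, lpos = lpos, gateOpen = gateOpen, total = total),
            class = "lossBreakdown")
}

#' @export
print.lossBreakdown <- function(x, ...) {
  cat(sprintf("loss: total %.4f = ce %.4f%s (gate %s, lpos %.4f)\n",
              x$total, x$ce,
              if (x$gateOpen) " + omega*lpos" else "",
              if (x$gateOpen) "open" else "closed", x$lpos))
  invisible(x)
}
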