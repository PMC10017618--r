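#' Loss configuration
#'
#' The compound training objective
#' `loss_total = w_tversky * loss_Tversky + w_ce * loss_CE` with the Tversky
#' false-positive weight `alpha = 0.1` and false-negative weight `beta = 0.9`
#' by default: false negatives are penalized nine times harder, raising
#' sensitivity on the dark cystic tumor interior while staying conservative
#' about false positives.
#'
#' @param alpha Tversky false-positive weight (>= 0).
#' @param beta Tversky false-negative weight (>= 0).
#' @param w_tversky,w_ce Convex combination weights; must sum to 1.
#' @param smooth Smoothing constant added to the Tversky numerator and
#'   denominator; keeps the index defined on empty masks.
#' @param per_image Compute the Tversky term per section and average over the
#'   batch (`TRUE`, default) rather than over all pixels of the batch pooled.
#'   The per-section form keeps the foreground gradient strong when most
#'   sections carry little or no tumor.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(alpha = 0.1, beta = 0.9, w_tversky = 0.5, w_ce = 0.5,
                        smooth = 1.0, per_image = TRUE) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (abs(w_tversky + w_ce - 1) > 1e-9) stop("w_tversky + w_ce must equal 1")
  if (smooth < 0) stop("smooth must be >= 0")
  structure(list(alpha = alpha, beta = beta, w_tversky = w_tversky,
                 w_ce = w_ce, smooth = smooth, per_image = isTRUE(per_image)),
            class = "loss_config")
}

check_pg <- function(p, g) {
  if (length(p) != length(g)) stop("p and g shapes differ")
  if (!is.null(dim(p)) && !is.null(dim(g)) && !identical(dim(p), dim(g)))
    stop("p and g shapes differ")
  if (any(p < -1e-9 | p > 1 + 1e-9)) stop("p must lie in [0,1]")
  if (!all(g %in% c(0, 1))) stop("g must be binary")
  invisible(TRUE)
}

#' Soft Tversky index
#'
#' `TI = (sum(p g) + s) / (sum(p g) + alpha sum(p (1-g)) + beta sum((1-p) g) + s)`.
#' With `alpha = beta = 0.5` this is exactly the soft Dice coefficient.
#'
#' @param p Predicted probabilities in \[0,1\].
#' @param g Binary targets, same shape.
#' @param alpha,beta False-positive / false-negative weights.
#' @param smooth Smoothing constant.
#' @return Scalar index in (0, 1\].
#' @export
tversky_index <- function(p, g, alpha = 0.1, beta = 0.9, smooth = 1.0) {
  check_pg(p, g)
  i <- sum(p * g)
  fp <- sum(p * (1 - g))
  fn <- sum((1 - p) * g)
  (i + smooth) / (i + alpha * fp + beta * fn + smooth)
}

#' Tversky loss: `1 - tversky_index`
#'
#' @inheritParams tversky_index
#' @param cfg A [loss_config()] supplying `alpha`, `beta`, `smooth`.
#' @return Scalar loss >= 0; 0 at a perfect hard prediction.
#' @export
tversky_loss <- function(p, g, cfg = loss_config()) {
  1 - tversky_index(p, g, cfg$alpha, cfg$beta, cfg$smooth)
}

#' Binary cross-entropy loss
#'
#' `-mean(g log p + (1-g) log(1-p))` with probabilities clamped to
#' `[eps, 1-eps]`, `eps = 1e-7`, so perfect predictions stay finite.
#'
#' @inheritParams tversky_index
#' @return Scalar loss >= 0.
#' @export
cross_entropy_loss <- function(p, g) {
  check_pg(p, g)
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(g * log(pc) + (1 - g) * log(1 - pc))
}

#' Compound segmentation loss
#'
#' `w_tversky * tversky_loss + w_ce * cross_entropy_loss`, the training
#' objective of the modified network (default weights 0.5 / 0.5).
#'
#' @inheritParams tversky_loss
#' @return Scalar loss.
#' @export
total_loss <- function(p, g, cfg = loss_config()) {
  cfg$w_tversky * tversky_loss(p, g, cfg) + cfg$w_ce * cross_entropy_loss(p, g)
}

# Gradient of total_loss with respect to p (same shape as p).
total_loss_grad <- function(p, g, cfg = loss_config()) {
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  dce <- -(g / pc - (1 - g) / (1 - pc)) / length(p)
  dce[(p < eps & g == 0) | (p > 1 - eps & g == 1)] <- 0  # inside the clamp
  cfg$w_tversky * (-tversky_index_grad(p, g, cfg)) + cfg$w_ce * dce
}

tversky_index_grad <- function(p, g, cfg) {
  i <- sum(p * g)
  fp <- sum(p * (1 - g))
  fn <- sum((1 - p) * g)
  s <- cfg$smooth
  den <- i + cfg$alpha * fp + cfg$beta * fn + s
  dden_dp <- g + cfg$alpha * (1 - g) - cfg$beta * g
  (g * den - (i + s) * dden_dp) / den^2
}

# Gradient of total_loss with respect to the sigmoid-head logits. The
# cross-entropy term is fused with the sigmoid ((p - g)/N), which stays
# finite and informative even when the sigmoid saturates; the Tversky term
# is chained through p(1-p), where it is genuinely flat.
total_loss_logit_grad <- function(p, g, cfg = loss_config()) {
  dce_logit <- (p - g) / length(p)
  dtv_logit <- -tversky_index_grad(p, g, cfg) * p * (1 - p)
  cfg$w_tversky * dtv_logit + cfg$w_ce * dce_logit
}

# Training-batch loss and logit gradient for (H, W, 1, B) arrays, honouring
# cfg$per_image for the Tversky term.
batch_loss_and_grad <- function(p, g, cfg) {
  ce <- cross_entropy_loss(p, g)
  if (!cfg$per_image) {
    tv <- tversky_loss(p, g, cfg)
    dl <- total_loss_logit_grad(p, g, cfg)
    return(list(tversky = tv, ce = ce, dlogits = array(dl, dim(p))))
  }
  B <- dim(p)[4]
  dl <- array(0, dim(p))
  tv <- 0
  for (b in seq_len(B)) {
    pb <- p[, , , b]; gb <- g[, , , b]
    tv <- tv + tversky_loss(pb, gb, cfg) / B
    dtv <- -tversky_index_grad(pb, gb, cfg) * pb * (1 - pb) / B
    dl[, , , b] <- cfg$w_tversky * dtv
  }
  dl <- dl + cfg$w_ce * (p - g) / length(p)
  list(tversky = tv, ce = ce, dlogits = dl)
}
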