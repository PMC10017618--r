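# Independent oracles and shared fixtures. Everything here is deliberately
# implemented with plain R loops / closed forms, separate from the package's
# compiled code paths.

# --- brute-force surface-distance / hd95 oracle ------------------------------

# boundary voxels by direct 6-neighbour inspection (border = background)
oracle_boundary <- function(m) {
  d <- dim(m)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (m[i, j, k] != 1) next
    nb <- c(
      if (i > 1) m[i - 1, j, k] else 0, if (i < d[1]) m[i + 1, j, k] else 0,
      if (j > 1) m[i, j - 1, k] else 0, if (j < d[2]) m[i, j + 1, k] else 0,
      if (k > 1) m[i, j, k - 1] else 0, if (k < d[3]) m[i, j, k + 1] else 0)
    if (any(nb == 0)) out <- rbind(out, c(i, j, k))
  }
  out
}

oracle_directed <- function(from, to, spacing) {
  apply(from, 1, function(a) {
    min(sqrt(colSums((t(to) * spacing - a * spacing)^2)))
  })
}

oracle_hd95 <- function(pred, gt, spacing, probs = 0.95) {
  bp <- oracle_boundary(pred); bg <- oracle_boundary(gt)
  if (is.null(bp) || is.null(bg)) return(NA_real_)
  d1 <- oracle_directed(bp, bg, spacing)
  d2 <- oracle_directed(bg, bp, spacing)
  unname(stats::quantile(c(d1, d2), probs, type = 7))
}

# --- closed-form loss oracles ------------------------------------------------

oracle_tversky <- function(p, g, alpha, beta, smooth = 0) {
  i <- sum(p * g)
  (i + smooth) / (i + alpha * sum(p * (1 - g)) + beta * sum((1 - p) * g) + smooth)
}

# soft Dice = (2 sum(pg) + 2s) / (sum(p) + sum(g) + 2s)
oracle_soft_dice <- function(p, g, smooth = 0) {
  (2 * sum(p * g) + 2 * smooth) / (sum(p) + sum(g) + 2 * smooth)
}

# --- random small masks ------------------------------------------------------

random_mask <- function(d = c(12, 12, 12), p = 0.2, min_fg = 1) {
  repeat {
    m <- array(as.numeric(stats::runif(prod(d)) < p), d)
    if (sum(m) >= min_fg) return(m)
  }
}

random_blob_mask <- function(d = c(16, 16, 16)) {
  ctr <- stats::runif(3, 0.3, 0.7) * d
  r <- stats::runif(1, 2, min(d) / 3)
  idx <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  v <- with(idx, (i - ctr[1])^2 + (j - ctr[2])^2 + (k - ctr[3])^2 <= r^2)
  m <- array(as.numeric(v), d)
  if (sum(m) == 0) m[round(ctr[1]), round(ctr[2]), round(ctr[3])] <- 1
  m
}

# --- desk-scale phantoms (small, for unit tests) -----------------------------

desk_phantom <- function(seed = 1, composition = "cystic", ...) {
  generate_phantom(phantom_spec(size = c(64, 64, 12), lobe_radius_mm = c(3, 8),
                                composition = composition, seed = seed, ...))
}

# --- shared end-to-end training runs (computed once per test session) --------

.acceptance_env <- new.env(parent = emptyenv())

acceptance_runs <- function() {
  if (!is.null(.acceptance_env$runs)) return(.acceptance_env$runs)
  seed <- 101L
  coh <- generate_cohort(30, seed = seed, size = c(64, 64, 12),
                         lobe_radius_mm = c(3, 8))
  cases <- preprocess_cases(coh$cases, preprocess_config(out_size = c(64, 64)))
  sp <- split_cases(coh$manifest$case_id, 0.8, 4L, seed = seed)
  pick <- function(ids) cases[match(ids, coh$manifest$case_id)]
  cfg_mod <- desk_profile(epochs = 15L, seed = seed)
  cfg_cls <- desk_profile(epochs = 15L, seed = seed, nonlocal_enabled = FALSE)
  run_mod <- train_unet(pick(sp$train), pick(sp$tuning), cfg_mod)
  run_cls <- train_unet(pick(sp$train), pick(sp$tuning), cfg_cls)
  test_cases <- pick(sp$test)
  ev_mod <- evaluate_dataset(run_mod$net, test_cases)
  ev_cls <- evaluate_dataset(run_cls$net, test_cases)
  shifted <- domain_shift(list(cases = cases[match(sp$test, coh$manifest$case_id)],
                               manifest = coh$manifest),
                          noise_scale = 2.5, intensity_gamma = 1.3, seed = seed)
  ev_shift <- evaluate_dataset(run_mod$net, shifted$cases)
  .acceptance_env$runs <- list(
    cohort = coh, split = sp, run_mod = run_mod, run_cls = run_cls,
    ev_mod = ev_mod, ev_cls = ev_cls, ev_shift = ev_shift)
  .acceptance_env$runs
}
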