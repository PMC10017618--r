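#' Training configuration
#'
#' The full-scale recipe: Adam, learning rate 1e-5, batches of 8 coronal
#' sections, 300 epochs, an 8:2 case-level train/test split with 10 training
#' cases held out as a tuning set that is evaluated after every epoch; the
#' checkpoint with the best tuning-set mean DSC is kept.
#'
#' @param split_ratio Training fraction of the case-level split (0 < r < 1).
#' @param tuning_n Cases drawn from the training group for per-epoch
#'   validation.
#' @param optimizer Only `"adam"` is implemented.
#' @param lr Learning rate.
#' @param batch_size Sections per gradient step.
#' @param epochs Training epochs (>= 1).
#' @param seed Master seed: initialization, split, data order, augmentation.
#' @param checkpoint_policy `"best_tuning_dsc"` or `"final"`.
#' @param network A [network_config()].
#' @param loss A [loss_config()].
#' @param augment An [augment_config()].
#' @param keep_empty_slices Keep background-only sections in training
#'   (real stacks contain them); set `FALSE` to drop them.
#' @param threshold Probability threshold for mask binarization.
#' @return A list of class `train_config`.
#' @export
train_config <- function(split_ratio = 0.8, tuning_n = 10L, optimizer = "adam",
                         lr = 1e-5, batch_size = 8L, epochs = 300L, seed = 1L,
                         checkpoint_policy = "best_tuning_dsc",
                         network = network_config(), loss = loss_config(),
                         augment = augment_config(),
                         keep_empty_slices = TRUE, threshold = 0.5) {
  if (split_ratio <= 0 || split_ratio >= 1) stop("split_ratio must be in (0,1)")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (optimizer != "adam") stop("only adam is implemented")
  if (!checkpoint_policy %in% c("best_tuning_dsc", "final"))
    stop("unknown checkpoint_policy")
  structure(list(split_ratio = split_ratio, tuning_n = as.integer(tuning_n),
                 optimizer = optimizer, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 checkpoint_policy = checkpoint_policy, network = network,
                 loss = loss, augment = augment,
                 keep_empty_slices = isTRUE(keep_empty_slices),
                 threshold = threshold),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' A scaled-down profile that trains end-to-end on one CPU in minutes:
#' 64 x 64 sections, a depth-3 U-Net with 8 base filters, 4 tuning cases and
#' a learning rate of 3e-3 suited to the short schedule. Used for tests and
#' worked examples; the architecture and objective are identical to the
#' full-scale configuration.
#'
#' @param epochs Training epochs (default 25).
#' @param seed Master seed.
#' @param nonlocal_enabled Insert the non-local bottleneck block.
#' @param lr Learning rate for the short desk schedule.
#' @param ... Overrides forwarded to [train_config()].
#' @return A `train_config`.
#' @export
desk_profile <- function(epochs = 25L, seed = 1L, nonlocal_enabled = TRUE,
                         lr = 3e-3, ...) {
  train_config(
    network = network_config(depth = 3L, base_filters = 8L,
                             nonlocal_enabled = nonlocal_enabled,
                             input_size = c(64, 64)),
    lr = lr, epochs = epochs, tuning_n = 4L, seed = seed, ...)
}

#' Case-level dataset split
#'
#' Splits case identifiers into training, tuning and internal-test groups.
#' The test group holds `floor((1 - ratio) * N)` cases; the tuning cases are
#' then drawn from the training group without replacement. All slices of a
#' case stay together. With `N = 264`, `ratio = 0.8`, `tuning_n = 10` this
#' reproduces the 202 / 10 / 52 partition.
#'
#' @param case_ids Vector of case identifiers.
#' @param ratio Training fraction.
#' @param tuning_n Tuning-set size; must leave a non-empty training set.
#' @param seed Seed making the partition deterministic.
#' @return `list(train = , tuning = , test = )` of disjoint id vectors whose
#'   union is the input.
#' @export
split_cases <- function(case_ids, ratio = 0.8, tuning_n = 10L, seed = 1L) {
  n <- length(case_ids)
  if (n < 3L) stop("need at least 3 cases to split")
  n_test <- floor((1 - ratio) * n + 1e-9)  # guard binary-fraction rounding
  with_seed(seed, {
    test <- sample(case_ids, n_test)
    train_full <- setdiff(case_ids, test)
    if (tuning_n >= length(train_full))
      stop("tuning_n must be smaller than the training group")
    tuning <- sample(train_full, tuning_n)
    list(train = setdiff(train_full, tuning), tuning = tuning, test = test)
  })
}

#' Preprocess every case of a dataset
#'
#' @param cases List of `list(vol, mask, ...)` case entries.
#' @param cfg A [preprocess_config()].
#' @return The list with `vol`/`mask` replaced by their preprocessed versions.
#' @export
preprocess_cases <- function(cases, cfg = preprocess_config()) {
  lapply(cases, function(cs) {
    res <- preprocess_case(cs$vol, cs$mask, cfg)
    cs$vol <- res$vol; cs$mask <- res$mask
    cs
  })
}

# one Adam step over an arbitrarily nested parameter list
adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.numeric(p)) {
      if (is.null(g)) g <- 0 * p
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    } else {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    }
  }
  walk(params, grads, state$m, state$v)
}

zero_like <- function(p) {
  if (is.numeric(p)) 0 * p else lapply(p, zero_like)
}

tuning_mean_dsc <- function(net, cases, threshold) {
  mean(vapply(cases, function(cs) {
    dice(predict_mask(net, cs$vol, threshold), cs$mask)
  }, numeric(1)))
}

#' Train a U-Net on preprocessed cases
#'
#' Iterates epochs of shuffled batches of augmented coronal sections,
#' minimizing the compound Tversky/cross-entropy objective with Adam. After
#' every epoch the tuning-set mean DSC is computed; the returned network is
#' the best-tuning-DSC checkpoint (under the default policy) and the
#' final-epoch weights are kept alongside. Fully reproducible given
#' `cfg$seed`.
#'
#' @param train_cases,tuning_cases Lists of preprocessed `list(vol, mask)`
#'   entries; slice size must match `cfg$network$input_size`.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return A list of class `train_result`: `net` (selected checkpoint),
#'   `final_net`, `history` (per-epoch losses and tuning DSC), `best_epoch`.
#' @export
train_unet <- function(train_cases, tuning_cases, cfg = desk_profile(),
                       verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(train_cases) == 0L) stop("empty training set")
  in_sz <- cfg$network$input_size
  for (cs in c(train_cases, tuning_cases))
    if (!all(dim(cs$vol$data)[1:2] == in_sz))
      stop("case slice size does not match network input size; preprocess first")
  with_seed(cfg$seed, {
    net <- build_unet(cfg$network, seed = sample.int(.Machine$integer.max, 1))
    slice_index <- do.call(rbind, lapply(seq_along(train_cases), function(i) {
      ks <- seq_len(dim(train_cases[[i]]$vol$data)[3])
      if (!cfg$keep_empty_slices) {
        keep <- vapply(ks, function(k) sum(train_cases[[i]]$mask$data[, , k]) > 0,
                       logical(1))
        ks <- ks[keep]
      }
      if (length(ks)) cbind(case = i, slice = ks) else NULL
    }))
    if (is.null(slice_index) || nrow(slice_index) == 0L)
      stop("no training slices")
    state <- list(m = zero_like(net$params), v = zero_like(net$params))
    t_adam <- 0L
    history <- data.frame(epoch = integer(), loss_total = numeric(),
                          loss_tversky = numeric(), loss_ce = numeric(),
                          tuning_dsc = numeric())
    best <- list(dsc = -Inf, params = net$params, epoch = 0L)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(nrow(slice_index))
      ep_tv <- ep_ce <- ep_tot <- 0; nb <- 0L
      for (s in seq(1L, length(ord), by = cfg$batch_size)) {
        rows <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
        B <- length(rows)
        x <- array(0, c(in_sz[1], in_sz[2], 1L, B))
        g <- array(0, c(in_sz[1], in_sz[2], 1L, B))
        for (b in seq_len(B)) {
          ci <- slice_index[rows[b], 1]; k <- slice_index[rows[b], 2]
          aug <- augment_pair(train_cases[[ci]]$vol$data[, , k],
                              train_cases[[ci]]$mask$data[, , k], cfg$augment)
          x[, , 1L, b] <- aug$image
          g[, , 1L, b] <- aug$mask
        }
        fw <- unet_forward(net, x, need_cache = TRUE)
        p <- fw$prob
        lg <- batch_loss_and_grad(p, g, cfg$loss)
        ltv <- lg$tversky
        lce <- lg$ce
        grads <- unet_backward(net, fw$cache, lg$dlogits)
        t_adam <- t_adam + 1L
        upd <- adam_step(net$params, grads, state, cfg$lr, t_adam)
        net$params <- upd$p; state$m <- upd$m; state$v <- upd$v
        ep_tv <- ep_tv + ltv; ep_ce <- ep_ce + lce
        ep_tot <- ep_tot + cfg$loss$w_tversky * ltv + cfg$loss$w_ce * lce
        nb <- nb + 1L
      }
      tdsc <- if (length(tuning_cases))
        tuning_mean_dsc(net, tuning_cases, cfg$threshold) else NA_real_
      history <- rbind(history, data.frame(
        epoch = ep, loss_total = ep_tot / nb, loss_tversky = ep_tv / nb,
        loss_ce = ep_ce / nb, tuning_dsc = tdsc))
      if (!is.na(tdsc) && tdsc > best$dsc)
        best <- list(dsc = tdsc, params = net$params, epoch = ep)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f (tversky %.4f, ce %.4f)  tuning DSC %.4f",
                        ep, ep_tot / nb, ep_tv / nb, ep_ce / nb, tdsc))
    }
    final_net <- net
    sel <- net
    if (cfg$checkpoint_policy == "best_tuning_dsc" && best$epoch > 0L)
      sel$params <- best$params
    structure(list(net = sel, final_net = final_net, history = history,
                   best_epoch = if (best$epoch > 0L) best$epoch else cfg$epochs),
              class = "train_result")
  })
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint stores the network configuration together with the weights,
#' so it can be reloaded without external context.
#'
#' @param net A `unet`.
#' @param path File path (`.rds`).
#' @return `save_checkpoint` the path invisibly; `load_checkpoint` a `unet`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "unet"))
  saveRDS(list(format = "cranioseg-checkpoint-1", cfg = unclass(net$cfg),
               params = net$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cranioseg-checkpoint-1"))
    stop("not a cranioseg checkpoint")
  cfg <- do.call(network_config, obj$cfg[setdiff(names(obj$cfg), NULL)])
  structure(list(cfg = cfg, params = obj$params), class = "unet")
}

#' Evaluate a network on a set of cases
#'
#' Predicts every case, computes the per-case metric row (including the
#' per-case wall-clock prediction time) and a summary with the mean and
#' t-based 95% confidence interval of each metric, NA values dropped.
#'
#' @param net A trained `unet`.
#' @param cases List of preprocessed `list(vol, mask, meta)` entries.
#' @param threshold Binarization threshold.
#' @return `list(records = per-case data.frame, summary = data.frame)`.
#' @export
evaluate_dataset <- function(net, cases, threshold = 0.5) {
  if (length(cases) == 0L) stop("no cases to evaluate")
  records <- do.call(rbind, lapply(cases, function(cs) {
    t0 <- proc.time()[["elapsed"]]
    pred <- predict_mask(net, cs$vol, threshold)
    dt <- proc.time()[["elapsed"]] - t0
    id <- if (!is.null(cs$meta)) cs$meta$case_id else "case"
    evaluate_case(pred, cs$mask, cs$vol$spacing, case_id = id,
                  seconds_elapsed = dt)
  }))
  num_cols <- setdiff(names(records), "case_id")
  summary <- do.call(rbind, lapply(num_cols, function(cn) {
    v <- records[[cn]]; v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0L) return(data.frame(metric = cn, mean = NA_real_,
                                   ci_lo = NA_real_, ci_hi = NA_real_, n = 0L))
    m <- mean(v)
    half <- if (n > 1L) stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n) else 0
    data.frame(metric = cn, mean = m, ci_lo = m - half, ci_hi = m + half, n = n)
  }))
  list(records = records, summary = summary)
}

#' Paired comparison of two networks on the same cases
#'
#' Evaluates both networks on the identical case list and reports per-case
#' metric deltas (`modified - baseline`) plus a sign summary per metric.
#'
#' @param baseline,modified Trained `unet` objects.
#' @param cases Preprocessed cases, as in [evaluate_dataset()].
#' @param threshold Binarization threshold.
#' @return `list(baseline = , modified = , deltas = , sign_summary = )`.
#' @export
compare_models <- function(baseline, modified, cases, threshold = 0.5) {
  ev_a <- evaluate_dataset(baseline, cases, threshold)
  ev_b <- evaluate_dataset(modified, cases, threshold)
  if (!identical(ev_a$records$case_id, ev_b$records$case_id))
    stop("case sets differ between the two evaluations")
  mcols <- c("dsc", "jaccard", "tpr", "fpr", "hd95_mm", "pred_volume_ml")
  deltas <- data.frame(case_id = ev_a$records$case_id)
  for (cn in mcols) deltas[[cn]] <- ev_b$records[[cn]] - ev_a$records[[cn]]
  sign_summary <- do.call(rbind, lapply(mcols, function(cn) {
    d <- deltas[[cn]]; d <- d[!is.na(d)]
    data.frame(metric = cn, mean_delta = mean(d),
               n_improved = sum(d > 0), n_worse = sum(d < 0),
               n_tied = sum(d == 0))
  }))
  list(baseline = ev_a, modified = ev_b, deltas = deltas,
       sign_summary = sign_summary)
}
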