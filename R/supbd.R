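# Supervised training of the super-resolution localizer: pixelwise MSE
# against blurred reference center maps, Adam with a step learning-rate
# schedule, early stopping on the validation loss with best-of-last-five
# checkpoint selection.

#' Supervised training configuration
#'
#' @param minibatch Minibatch size (default 16).
#' @param lr Initial learning rate (default 1e-3), reduced by
#'   `lr_decay` every `decay_every` epochs.
#' @param lr_decay Multiplicative decay factor (default 0.1).
#' @param decay_every Epochs between decays (default 5).
#' @param patience Early-stop patience in epochs without validation
#'   improvement (default 5).
#' @param val_frac Validation fraction of the dataset (default 0.3).
#' @param max_epochs Hard epoch cap (default 50).
#' @param peak_weight Extra weight on reference-blob pixels: the pixelwise
#'   squared error is multiplied by `1 + peak_weight * ref`. The default 0
#'   is the plain pixelwise MSE; scaled-down trainings use a positive value
#'   to counteract the extreme foreground/background imbalance of sparse
#'   center maps at small sample counts.
#' @param seed Optional seed controlling the split and shuffling.
#' @return A `sup_train_config`.
#' @export
sup_train_config <- function(minibatch = 16L, lr = 1e-3, lr_decay = 0.1,
                             decay_every = 5L, patience = 5L,
                             val_frac = 0.3, max_epochs = 50L,
                             peak_weight = 0, seed = NULL) {
  structure(list(minibatch = as.integer(minibatch), lr = lr,
                 lr_decay = lr_decay, decay_every = as.integer(decay_every),
                 patience = as.integer(patience), val_frac = val_frac,
                 max_epochs = as.integer(max_epochs),
                 peak_weight = peak_weight, seed = seed),
            class = "sup_train_config")
}

mse_loss <- function(out, ref, pw = 0) {
  if (pw <= 0) return(mean((out - ref)^2))
  mean((1 + pw * ref) * (out - ref)^2)
}

#' Train the supervised localizer
#'
#' @param net An `ulm_net` from [build_supbd()].
#' @param dataset An `ulm_dataset` from [build_training_set()] (or any list
#'   with `inputs` and `refs`).
#' @param config A [sup_train_config()].
#' @param verbose Print per-epoch losses.
#' @return List of class `supbd_fit`: `net` (best checkpoint), `history`
#'   tibble (`epoch`, `train_loss`, `val_loss`, `lr`), `best_epoch`.
#' @export
train_supbd <- function(net, dataset, config = sup_train_config(),
                        verbose = FALSE) {
  n <- length(dataset$inputs)
  if (n < 2) stop("empty or degenerate dataset")
  if (!is.null(config$seed)) set.seed(config$seed)
  n_val <- max(1L, round(config$val_frac * n))
  perm <- sample.int(n)
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  state <- adam_state()
  t_step <- 0L
  history <- list()
  ckpts <- list()
  best_val <- Inf
  best_epoch <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$lr * config$lr_decay^((epoch - 1L) %/% config$decay_every)
    order_ep <- sample(tr_idx)
    batches <- split(order_ep, ceiling(seq_along(order_ep) /
                                         config$minibatch))
    tl <- 0
    for (bt in batches) {
      acc <- NULL
      bl <- 0
      for (i in bt) {
        fw <- nn_forward(net, dataset$inputs[[i]], keep_cache = TRUE)
        ref <- dataset$refs[[i]]
        pw <- config$peak_weight
        bl <- bl + mse_loss(fw$out, ref, pw)
        dout <- 2 * (1 + pw * ref) * (fw$out - ref) / length(ref)
        acc <- grad_axpy(acc, nn_backward(net, fw$cache, dout),
                         1 / length(bt))
      }
      t_step <- t_step + 1L
      net$params <- adam_step(net$params, acc, state, lr, t_step)
      tl <- tl + bl / length(bt)
    }
    tl <- tl / length(batches)
    vl <- mean(vapply(val_idx, function(i)
      mse_loss(nn_forward(net, dataset$inputs[[i]])$out,
               dataset$refs[[i]], config$peak_weight), numeric(1)))
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = tl,
                                       val_loss = vl, lr = lr)
    ckpts[[1 + (epoch - 1L) %% 5L]] <- list(epoch = epoch,
                                            params = net$params, val = vl)
    if (verbose)
      message(sprintf("epoch %d: train %.3e val %.3e (lr %.1e)",
                      epoch, tl, vl, lr))
    if (vl < best_val) { best_val <- vl; best_epoch <- epoch }
    if (epoch - best_epoch >= config$patience) break
  }
  # best of the stored (last five) checkpoints by validation loss
  vals <- vapply(ckpts, function(ck) ck$val, numeric(1))
  best <- ckpts[[which.min(vals)]]
  net$params <- best$params
  structure(list(net = net, history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, best_val = best$val),
            class = "supbd_fit")
}

#' @export
print.supbd_fit <- function(x, ...) {
  cat(sprintf("<supbd_fit> %d epochs, best epoch %d (val loss %.3e)\n",
              nrow(x$history), x$best_epoch, x$best_val))
  invisible(x)
}

#' Run the localizer on a frame
#'
#' @param net `ulm_net` or `supbd_fit`.
#' @param frame Native-resolution matrix.
#' @return Super-resolution center-likelihood matrix in (0, 1).
#' @export
supbd_infer <- function(net, frame) {
  if (inherits(net, "supbd_fit")) net <- net$net
  nn_forward(net, frame)$out
}

#' Extract centers from a network likelihood map
#'
#' Thresholds the map at `min_peak`, labels 8-connected clusters, and
#' reduces each to its intensity-weighted centroid on the super-resolution
#' grid.
#'
#' @param map Likelihood matrix in (0, 1) at super resolution.
#' @param grid An [grid_spec()].
#' @param min_peak Peak threshold (default 0.5).
#' @param frame Frame index stored in the output.
#' @return Detection tibble (`frame`, `depth_um`, `lateral_um`, `weight`).
#' @export
net_extract_centers <- function(map, grid = grid_spec(), min_peak = 0.5,
                                frame = NA_integer_) {
  centers_from_map(map, grid$superres_pixel, min_peak, frame)
}

#' Layer audit of a localizer network
#'
#' @param net An `ulm_net`.
#' @return Tibble with one row per convolution layer: `layer`,
#'   `kernel`, `c_in`, `c_out`.
#' @export
supbd_layer_audit <- function(net) {
  pm <- net$params
  rows <- list(tibble::tibble(layer = "h1c", kernel = pm$h1c$k,
                              c_in = pm$h1c$cin, c_out = pm$h1c$cout),
               tibble::tibble(layer = "h2c", kernel = pm$h2c$k,
                              c_in = pm$h2c$cin, c_out = pm$h2c$cout))
  for (nm in names(pm$res)) {
    for (cv in c("c1", "c2")) {
      ly <- pm$res[[nm]][[cv]]
      rows[[length(rows) + 1L]] <-
        tibble::tibble(layer = paste0(nm, ".", cv), kernel = ly$k,
                       c_in = ly$cin, c_out = ly$cout)
    }
  }
  rows[[length(rows) + 1L]] <-
    tibble::tibble(layer = "upc", kernel = pm$upc$k, c_in = pm$upc$cin,
                   c_out = pm$upc$cout)
  rows[[length(rows) + 1L]] <-
    tibble::tibble(layer = "outc", kernel = pm$outc$k, c_in = pm$outc$cin,
                   c_out = pm$outc$cout)
  dplyr::bind_rows(rows)
}
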