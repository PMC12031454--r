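#' Training configuration
#'
#' Optimization settings shared by both networks: Adam at the configured
#' learning rate, seeded shuffling, and a hard iteration cap. One iteration
#' processes one batch; gradients are averaged over the batch.
#'
#' @param learning_rate Positive real (default 1e-4).
#' @param batch_size Positive integer (default 4).
#' @param max_iterations Positive integer (default 1000).
#' @param seed Integer seed for shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L,
                         max_iterations = 1000L, seed = 1L) {
  if (learning_rate <= 0 || batch_size < 1L || max_iterations < 1L) {
    stop("learning_rate, batch_size and max_iterations must be positive")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "train_config")
}

forward_any <- function(model, xnorm, tape) {
  if (inherits(model, "mangrovenet")) forward_mangrovenet(model, xnorm, tape)
  else forward_attcloudnet(model, xnorm, tape)
}

loss_node <- function(model, out, mask, tape) {
  if (inherits(model, "mangrovenet")) {
    t <- as_mask_values(mask)
    if (!all(t %in% c(0L, 1L))) stop("extent truth values must be 0 or 1")
    ag_bce(out, t, tape)
  } else {
    ag_filtered_jaccard(out, as_mask_values(mask), tape)
  }
}

#' Train a segmentation model
#'
#' Runs seeded mini-batch Adam on paired tile/mask data. MangroveNet models
#' are trained with binary cross-entropy against 0/1 extent masks;
#' AttCloudNet+ models with the filtered Jaccard loss against integer class
#' masks. Tiles are 8-bit arrays (values 0..255) and are normalized to [0, 1]
#' by division by 255 before the forward pass. The per-iteration batch-mean
#' loss history is recorded; with a fixed seed, repeated runs on the same
#' platform are bit-reproducible.
#'
#' @param model A `mangrovenet` or `attcloudnet` model.
#' @param tiles Non-empty list of (H, W, C) arrays or `multispectral_raster`s.
#' @param masks List of matching `segmentation_mask`s or integer matrices.
#' @param tc A [train_config()].
#' @param validation Optional list(tiles=, masks=) evaluated every
#'   `val_every` iterations; the parameters with the lowest validation loss
#'   are restored at the end.
#' @param val_every Validation cadence in iterations (default 50).
#' @return List with `model` (trained) and `history` (numeric vector of
#'   per-iteration losses).
#' @export
train_model <- function(model, tiles, masks, tc = train_config(),
                        validation = NULL, val_every = 50L) {
  if (length(tiles) == 0L) stop("training dataset is empty")
  if (length(tiles) != length(masks)) stop("tiles and masks differ in length")
  xs <- lapply(tiles, normalize_tile)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(tc$seed)
  n <- length(xs)
  order_pool <- integer(0)
  history <- numeric(tc$max_iterations)
  best <- NULL
  best_loss <- Inf
  for (it in seq_len(tc$max_iterations)) {
    while (length(order_pool) < tc$batch_size) {
      order_pool <- c(order_pool, sample.int(n))
    }
    batch <- order_pool[seq_len(tc$batch_size)]
    order_pool <- order_pool[-seq_len(tc$batch_size)]
    total <- 0
    acc <- list()
    for (j in batch) {
      tape <- ag_tape()
      out <- forward_any(model, xs[[j]], tape)
      l <- loss_node(model, out, masks[[j]], tape)
      ag_backward(tape, l)
      total <- total + l$value
      g <- collect_grads(tape)
      for (nm in names(g)) {
        acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
      }
    }
    loss <- total / length(batch)
    if (!is.finite(loss)) {
      stop("training aborted: non-finite loss at iteration ", it)
    }
    history[it] <- loss
    acc <- lapply(acc, function(g) g / length(batch))
    adam_step(model$store, acc, tc$learning_rate)
    if (!is.null(validation) && (it %% val_every == 0L || it == tc$max_iterations)) {
      vl <- evaluate_loss(model, validation$tiles, validation$masks)
      if (vl < best_loss) {
        best_loss <- vl
        best <- store_to_list(model$store)
      }
    }
  }
  if (!is.null(best)) {
    restored <- store_from_list(best)
    model$store$params <- restored$params
    model$store$m <- restored$m
    model$store$v <- restored$v
    model$store$t <- restored$t
  }
  list(model = model, history = history)
}

#' Mean loss of a model over a dataset
#'
#' @inheritParams train_model
#' @return Scalar mean loss.
#' @export
evaluate_loss <- function(model, tiles, masks) {
  losses <- vapply(seq_along(tiles), function(j) {
    tape <- ag_tape()
    out <- forward_any(model, normalize_tile(tiles[[j]]), tape)
    loss_node(model, out, masks[[j]], tape)$value
  }, numeric(1L))
  mean(losses)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file embedding the model class, its config, the
#' attention flag, and all parameters and optimizer state.
#'
#' @param model A model object.
#' @param path File path.
#' @return `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(class = class(model), cfg = model$cfg,
              attention = isTRUE(model$attention),
              store = store_to_list(model$store))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- list(cfg = obj$cfg, store = store_from_list(obj$store))
  if (obj$class[1L] == "attcloudnet") model$attention <- obj$attention
  structure(model, class = obj$class)
}
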