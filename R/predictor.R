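# ---------------------------------------------------------------------------
# Embedding-based prediction of future central nodes.  Every node of every
# daily network becomes a labelled example (1 = top-k by the chosen
# centrality in its own day's network); the classifier is a three-hidden-
# layer multilayer perceptron (32 units each, ReLU, dropout 0.5, softmax
# output) trained with Adam, class upsampling and early stopping, evaluated
# by rolling 1/5/10-day prediction.  No neural-network package is available
# in the target environment, so forward/backward passes are implemented
# directly with matrix algebra.
# ---------------------------------------------------------------------------

#' Build the labelled dataset from daily networks
#'
#' @param daily_graphs list of igraphs aligned with stream days (names are
#'   day indices, as from \code{\link{build_daily_networks}}).
#' @param stream the \code{misinfo_stream} supplying embeddings.
#' @param measure centrality measure used for labelling.
#' @param k top-k cutoff for the positive class (default 100).
#' @return data.frame (class \code{labeled_dataset}) with columns id, day,
#'   label; embedding matrix in attribute \code{"x"} (one row per example).
#' @export
build_dataset <- function(daily_graphs, stream, measure = "degree",
                          k = 100L) {
  fn <- measure_fun(measure)
  days <- if (!is.null(names(daily_graphs))) as.integer(names(daily_graphs))
  else seq_along(daily_graphs) - 1L
  rows <- list()
  for (i in seq_along(daily_graphs)) {
    g <- daily_graphs[[i]]
    if (igraph::vcount(g) < 1) next  # skipped: empty day
    v <- fn(g)
    pos <- top_k(v, k)
    ids <- names(v)
    rows[[length(rows) + 1L]] <- data.frame(
      id = ids, day = days[i], label = as.integer(ids %in% pos),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no non-empty days")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "x") <- stream$embeddings[out$id, , drop = FALSE]
  attr(out, "measure") <- measure
  class(out) <- c("labeled_dataset", "data.frame")
  out
}

#' Balance a dataset by upsampling the minority class
#'
#' All original examples are retained; minority-class rows are resampled
#' with replacement (seeded) until both classes have equal counts.
#'
#' @param dataset a \code{labeled_dataset}.
#' @param seed integer seed.
#' @return a \code{labeled_dataset} with equal class counts.
#' @export
balance_upsample <- function(dataset, seed = 1L) {
  y <- dataset$label
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("single-class dataset cannot be balanced")
  if (n1 == n0) return(dataset)
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  set.seed(as.integer(seed))
  extra <- sample(which(y == minority), need, replace = TRUE)
  idx <- c(seq_along(y), extra)
  out <- dataset[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "x") <- attr(dataset, "x")[idx, , drop = FALSE]
  attr(out, "measure") <- attr(dataset, "measure")
  class(out) <- class(dataset)
  out
}

#' MLP hyperparameters
#'
#' The layout is fixed to three 32-unit ReLU layers, each followed by
#' dropout 0.5, and a 2-way softmax output.
#'
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss (default 10).
#' @param val_frac held-out validation fraction (default 0.1).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param dropout dropout rate after each hidden layer.
#' @param hidden hidden-layer widths.
#' @param seed integer seed for weight init, dropout and the split.
#' @return list of class \code{mlp_config}.
#' @export
mlp_config <- function(epochs = 100L, patience = 10L, val_frac = 0.1,
                       batch_size = 32L, lr = 1e-3, dropout = 0.5,
                       hidden = c(32L, 32L, 32L), seed = 1L) {
  structure(list(epochs = epochs, patience = patience, val_frac = val_frac,
                 batch_size = batch_size, lr = lr, dropout = dropout,
                 hidden = hidden, seed = as.integer(seed)),
            class = "mlp_config")
}

relu <- function(z) pmax(z, 0)

mlp_forward <- function(params, x, dropout = 0, training = FALSE) {
  a <- x
  masks <- list()
  L <- length(params$W)
  for (l in seq_len(L - 1L)) {
    z <- a %*% params$W[[l]] + rep(1, nrow(a)) %*% t(params$b[[l]])
    a <- relu(z)
    if (training && dropout > 0) {
      mask <- matrix(runif(length(a)) >= dropout, nrow(a), ncol(a))
      a <- a * mask / (1 - dropout)  # inverted dropout
      masks[[l]] <- mask
    }
  }
  z <- a %*% params$W[[L]] + rep(1, nrow(a)) %*% t(params$b[[L]])
  zs <- z - apply(z, 1, max)
  ez <- exp(zs)
  probs <- ez / rowSums(ez)
  list(probs = probs, masks = masks)
}

# forward keeping activations, then backprop of mean cross-entropy
mlp_grad <- function(params, x, y01, dropout, rng_masks = TRUE) {
  L <- length(params$W)
  acts <- list(x)
  masks <- list()
  a <- x
  for (l in seq_len(L - 1L)) {
    z <- a %*% params$W[[l]] + rep(1, nrow(a)) %*% t(params$b[[l]])
    a <- relu(z)
    if (dropout > 0) {
      mask <- matrix(runif(length(a)) >= dropout, nrow(a), ncol(a))
      a <- a * mask / (1 - dropout)
      masks[[l]] <- mask
    }
    acts[[l + 1L]] <- a
  }
  z <- a %*% params$W[[L]] + rep(1, nrow(a)) %*% t(params$b[[L]])
  zs <- z - apply(z, 1, max)
  ez <- exp(zs)
  probs <- ez / rowSums(ez)
  n <- nrow(x)
  Y <- cbind(1 - y01, y01)
  delta <- (probs - Y) / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- t(acts[[l]]) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(params$W[[l]])
      if (dropout > 0) delta <- delta * masks[[l - 1L]] / (1 - dropout)
      delta <- delta * (acts[[l]] > 0)
    }
  }
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), y01 + 1L)], 1e-12)))
  list(gW = gW, gb = gb, loss = loss)
}

mlp_loss <- function(params, x, y01) {
  p <- mlp_forward(params, x)$probs
  -mean(log(pmax(p[cbind(seq_len(nrow(x)), y01 + 1L)], 1e-12)))
}

#' Train the centrality-prediction MLP
#'
#' He-initialised weights, Adam updates on minibatches, inverted dropout,
#' and early stopping on the loss of a held-out validation split: training
#' stops when validation loss has not improved for \code{patience} epochs
#' and the best-validation weights are restored.
#'
#' @param dataset a balanced \code{labeled_dataset} with >= 20 examples, or
#'   a plain label vector if \code{x} is given.
#' @param config an \code{\link{mlp_config}}.
#' @param x optional feature matrix overriding the dataset attribute.
#' @return object of class \code{mlp_model}; use \code{predict} with
#'   \code{type = "prob"} (class-1 probability) or \code{"class"}.
#' @export
train_predictor <- function(dataset, config = mlp_config(), x = NULL) {
  if (is.null(x)) x <- attr(dataset, "x")
  y <- if (is.data.frame(dataset)) dataset$label else as.integer(dataset)
  if (length(y) < 20) stop("need at least 20 examples")
  if (is.null(x) || nrow(x) != length(y))
    stop("feature matrix does not match labels")
  set.seed(config$seed)
  d <- ncol(x)
  sizes <- c(d, config$hidden, 2L)
  L <- length(sizes) - 1L
  params <- list(W = vector("list", L), b = vector("list", L))
  for (l in seq_len(L)) {
    params$W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                            sizes[l], sizes[l + 1L])
    params$b[[l]] <- rep(0, sizes[l + 1L])
  }
  n <- length(y)
  n_val <- max(2L, round(config$val_frac * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  xtr <- x[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  xva <- x[val_idx, , drop = FALSE]; yva <- y[val_idx]
  mW <- lapply(params$W, function(w) w * 0); vW <- mW
  mb <- lapply(params$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(loss = Inf, params = params)
  stall <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(seq_along(ytr))
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      g <- mlp_grad(params, xtr[idx, , drop = FALSE], ytr[idx],
                    config$dropout)
      step <- step + 1L
      for (l in seq_len(L)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$gW[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$gW[[l]]^2
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$gb[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$gb[[l]]^2
        mhW <- mW[[l]] / (1 - b1^step); vhW <- vW[[l]] / (1 - b2^step)
        mhb <- mb[[l]] / (1 - b1^step); vhb <- vb[[l]] / (1 - b2^step)
        params$W[[l]] <- params$W[[l]] - config$lr * mhW / (sqrt(vhW) + eps)
        params$b[[l]] <- params$b[[l]] - config$lr * mhb / (sqrt(vhb) + eps)
      }
    }
    vloss <- mlp_loss(params, xva, yva)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  structure(list(params = best$params, config = config, dim = d,
                 val_loss = best$loss, epochs_run = epoch),
            class = "mlp_model")
}

#' @export
predict.mlp_model <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (ncol(x) != object$dim) stop("feature dimension mismatch")
  p <- mlp_forward(object$params, x)$probs[, 2]
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUROC with midrank tie handling.
#'
#' @param scores numeric class-1 scores.
#' @param labels 0/1 labels (both classes present).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined for single-class labels")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rolling evaluation of the centrality predictor
#'
#' Evaluation blocks are consecutive \code{horizon}-day windows; for each
#' block, an MLP is trained on the balanced labelled examples of all days
#' strictly before the block and scored on the block's nodes from their
#' embeddings alone.  Accuracy (at threshold 0.5, natural class
#' distribution), balanced accuracy and AUROC are aggregated over blocks
#' and over \code{n_seeds} training repetitions.  Blocks with a single
#' class are excluded from AUROC (logged in the per-block table).
#'
#' @param daily_graphs daily networks aligned with the stream.
#' @param stream the \code{misinfo_stream}.
#' @param measure centrality measure for labelling.
#' @param horizon block length in days (1, 5 or 10 in the reference setup).
#' @param k top-k cutoff (default 100).
#' @param n_seeds training repetitions (default 5).
#' @param config an \code{\link{mlp_config}}; its seed is offset per
#'   repetition.
#' @param min_train_days evaluation starts once at least this many days of
#'   training data exist (default \code{horizon}; the reference protocol
#'   used a 10-day warm-up for 1-day prediction).
#' @return object of class \code{eval_report}: accuracy/balanced
#'   accuracy/AUROC mean and sd, per-block table, settings.
#' @export
rolling_evaluate <- function(daily_graphs, stream, measure = "degree",
                             horizon = 1L, k = 100L, n_seeds = 5L,
                             config = mlp_config(),
                             min_train_days = horizon) {
  dataset <- build_dataset(daily_graphs, stream, measure, k)
  days <- sort(unique(dataset$day))
  if (length(days) < horizon + 2)
    stop("need at least horizon + 2 days of graphs")
  x_all <- attr(dataset, "x")
  starts <- seq(max(horizon, min_train_days), max(days), by = horizon)
  rows <- list()
  for (s in seq_len(n_seeds)) {
    seed_s <- config$seed + 1000L * (s - 1L)
    for (b0 in starts) {
      block_days <- b0:min(b0 + horizon - 1L, max(days))
      tr <- which(dataset$day < b0)
      te <- which(dataset$day %in% block_days)
      if (!length(te) || !length(tr)) next
      ytr <- dataset$label[tr]
      if (length(unique(ytr)) < 2 || length(tr) < 20) next
      sub <- dataset[tr, , drop = FALSE]
      attr(sub, "x") <- x_all[tr, , drop = FALSE]
      class(sub) <- class(dataset)
      bal <- balance_upsample(sub, seed = seed_s)
      cfg <- config; cfg$seed <- seed_s
      model <- train_predictor(bal, cfg)
      p <- predict(model, x_all[te, , drop = FALSE])
      yte <- dataset$label[te]
      acc <- mean((p >= 0.5) == yte)
      bacc <- if (length(unique(yte)) == 2)
        (mean(p[yte == 1] >= 0.5) + mean(p[yte == 0] < 0.5)) / 2
      else NA_real_
      auc <- if (length(unique(yte)) == 2) auroc(p, yte) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, block_start = b0, n_test = length(te),
        accuracy = acc, balanced_accuracy = bacc, auroc = auc)
    }
  }
  if (!length(rows)) stop("no evaluable blocks")
  per_block <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE)
                       else 0)
  structure(list(
    measure = measure, horizon = horizon, k = k, n_seeds = n_seeds,
    accuracy = agg(per_block$accuracy),
    balanced_accuracy = agg(per_block$balanced_accuracy),
    auroc = agg(per_block$auroc),
    per_block = per_block
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("eval_report[%s, horizon=%d]: accuracy %.3f +/- %.3f, ",
           "AUROC %.3f +/- %.3f (%d blocks x %d seeds)\n"),
    x$measure, x$horizon, x$accuracy["mean"], x$accuracy["sd"],
    x$auroc["mean"], x$auroc["sd"],
    length(unique(x$per_block$block_start)), x$n_seeds))
  invisible(x)
}
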