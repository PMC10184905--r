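# Multilayer perceptron regression, implemented with base R matrix
# arithmetic. Architecture per hidden layer: dense -> batch normalization ->
# ReLU -> dropout; linear output; mean-squared-error loss with L2 weight
# penalty; Adam optimizer with early stopping on validation loss.

.row_bcast <- function(M, v) M * matrix(v, nrow(M), length(v), byrow = TRUE)

.mlp_init <- function(d_in, hidden, batch_norm) {
  theta <- list()
  state <- list()
  d <- d_in
  for (l in seq_along(hidden)) {
    dl <- hidden[l]
    theta[[paste0("W", l)]] <- matrix(stats::rnorm(d * dl, sd = sqrt(2 / d)),
                                      d, dl)
    if (batch_norm) {
      theta[[paste0("g", l)]] <- rep(1, dl)
      theta[[paste0("be", l)]] <- rep(0, dl)
      state[[paste0("rm", l)]] <- rep(0, dl)
      state[[paste0("rv", l)]] <- rep(1, dl)
    } else {
      theta[[paste0("b", l)]] <- rep(0, dl)
    }
    d <- dl
  }
  theta$W_out <- matrix(stats::rnorm(d, sd = sqrt(1 / d)), d, 1)
  theta$b_out <- 0
  list(theta = theta, state = state, hidden = hidden,
       batch_norm = batch_norm)
}

.bn_eps <- 1e-5

# Forward + backward over one minibatch (training mode). Returns loss,
# gradient list and updated running statistics.
.mlp_grad <- function(net, X, y, dropout, l2, bn_momentum = 0.99) {
  th <- net$theta
  L <- length(net$hidden)
  m <- nrow(X)
  cache <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    W <- th[[paste0("W", l)]]
    Z <- H %*% W
    if (net$batch_norm) {
      mu <- colMeans(Z)
      Zc <- sweep(Z, 2, mu)
      v <- colMeans(Zc^2)
      invstd <- 1 / sqrt(v + .bn_eps)
      Zhat <- .row_bcast(Zc, invstd)
      U <- .row_bcast(Zhat, th[[paste0("g", l)]])
      U <- sweep(U, 2, th[[paste0("be", l)]], "+")
      net$state[[paste0("rm", l)]] <-
        bn_momentum * net$state[[paste0("rm", l)]] + (1 - bn_momentum) * mu
      net$state[[paste0("rv", l)]] <-
        bn_momentum * net$state[[paste0("rv", l)]] + (1 - bn_momentum) * v
    } else {
      U <- sweep(Z, 2, th[[paste0("b", l)]], "+")
      Zhat <- invstd <- NULL
    }
    A <- pmax(U, 0)
    if (dropout > 0) {
      keep <- 1 - dropout
      mask <- matrix((stats::runif(length(A)) < keep) / keep,
                     nrow(A), ncol(A))
      Hn <- A * mask
    } else {
      mask <- NULL
      Hn <- A
    }
    cache[[l]] <- list(X = H, Zhat = Zhat, invstd = invstd, U = U,
                       mask = mask)
    H <- Hn
  }
  yhat <- H %*% th$W_out + th$b_out
  err <- yhat - y
  loss <- mean(err^2)
  grads <- list()
  d_yhat <- 2 * err / m
  grads$W_out <- crossprod(H, d_yhat) + 2 * l2 * th$W_out
  grads$b_out <- sum(d_yhat)
  dH <- d_yhat %*% t(th$W_out)
  for (l in rev(seq_len(L))) {
    cc <- cache[[l]]
    dA <- if (is.null(cc$mask)) dH else dH * cc$mask
    dU <- dA * (cc$U > 0)
    if (net$batch_norm) {
      grads[[paste0("g", l)]] <- colSums(dU * cc$Zhat)
      grads[[paste0("be", l)]] <- colSums(dU)
      dZhat <- .row_bcast(dU, th[[paste0("g", l)]])
      s1 <- colSums(dZhat)
      s2 <- colSums(dZhat * cc$Zhat)
      dZ <- .row_bcast(dZhat - matrix(s1 / m, m, length(s1), byrow = TRUE) -
                         .row_bcast(cc$Zhat, s2 / m), cc$invstd)
    } else {
      grads[[paste0("b", l)]] <- colSums(dU)
      dZ <- dU
    }
    grads[[paste0("W", l)]] <- crossprod(cc$X, dZ) +
      2 * l2 * th[[paste0("W", l)]]
    if (l > 1) dH <- dZ %*% t(th[[paste0("W", l)]])
  }
  list(loss = loss, grads = grads, state = net$state)
}

# Replace batch-norm running statistics with exact population statistics
# of the training inputs under the current weights ("precise" batch norm):
# propagate the full training set layer by layer without dropout, using the
# exact per-layer mean/variance for normalization as they are computed.
# This removes the lag of momentum-averaged statistics and matches the
# dropout-free inference pass.
.mlp_recalibrate_bn <- function(net, X) {
  if (!net$batch_norm) return(net)
  th <- net$theta
  H <- X
  for (l in seq_along(net$hidden)) {
    Z <- H %*% th[[paste0("W", l)]]
    mu <- colMeans(Z)
    Zc <- sweep(Z, 2, mu)
    v <- colMeans(Zc^2)
    net$state[[paste0("rm", l)]] <- mu
    net$state[[paste0("rv", l)]] <- v
    Zhat <- .row_bcast(Zc, 1 / sqrt(v + .bn_eps))
    U <- sweep(.row_bcast(Zhat, th[[paste0("g", l)]]), 2,
               th[[paste0("be", l)]], "+")
    H <- pmax(U, 0)
  }
  net
}

# Inference-mode forward pass (running batch-norm statistics, no dropout).
.mlp_forward <- function(net, X) {
  th <- net$theta
  H <- X
  for (l in seq_along(net$hidden)) {
    Z <- H %*% th[[paste0("W", l)]]
    if (net$batch_norm) {
      invstd <- 1 / sqrt(net$state[[paste0("rv", l)]] + .bn_eps)
      Zhat <- .row_bcast(sweep(Z, 2, net$state[[paste0("rm", l)]]), invstd)
      U <- sweep(.row_bcast(Zhat, th[[paste0("g", l)]]), 2,
                 th[[paste0("be", l)]], "+")
    } else {
      U <- sweep(Z, 2, th[[paste0("b", l)]], "+")
    }
    H <- pmax(U, 0)
  }
  as.numeric(H %*% th$W_out + th$b_out)
}

#' Split a feature table into train/validation/test sets
#'
#' Random row-level split, deterministic given the seed; set sizes are
#' within one row of the exact fractions.
#'
#' @param table data.frame.
#' @param fractions length-3 vector summing to 1 (train, validation, test).
#' @param seed RNG seed.
#' @return list with elements `train`, `val`, `test` and attribute
#'   `indices`.
#' @examples
#' s <- split_dataset(data.frame(x = 1:100), seed = 1)
#' sapply(s, nrow)   # 70 15 15
#' @export
split_dataset <- function(table, fractions = c(0.7, 0.15, 0.15), seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3)
  n <- nrow(table)
  if (n < 3) stop("need at least 3 rows to split")
  set.seed(seed)
  idx <- sample.int(n)
  cuts <- diff(round(cumsum(c(0, fractions)) * n))
  grp <- rep(1:3, times = cuts)
  out <- list(train = table[idx[grp == 1], , drop = FALSE],
              val = table[idx[grp == 2], , drop = FALSE],
              test = table[idx[grp == 3], , drop = FALSE])
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  attr(out, "indices") <- split(idx, grp)
  out
}

.design_matrix <- function(data, features) {
  cols <- lapply(features, function(f) {
    v <- data[[f]]
    if (f == "species") as.numeric(v == "heterotroph") else as.numeric(v)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- features
  X
}

#' Fit the colony-fitness neural network
#'
#' Trains the regression from colony features to fitness: input
#' standardization, three hidden layers of 512 ReLU units with batch
#' normalization and dropout 0.5, L2 weight penalty 1e-4, linear output,
#' mean-squared-error loss, Adam optimizer, early stopping on validation
#' loss. Species is encoded as a binary indicator feature. The target is
#' standardized internally and predictions are returned on the original
#' scale.
#'
#' @param train,val training and validation data.frames.
#' @param target name of the target column (default `"fitness"`).
#' @param features feature column names; default: every column except the
#'   target and the bookkeeping columns `founder_id`/`sim`.
#' @param hidden hidden layer widths.
#' @param dropout dropout rate after each hidden layer.
#' @param l2 L2 weight-penalty coefficient.
#' @param batch_norm use batch normalization.
#' @param lr Adam learning rate; @param batch_size minibatch size.
#' @param epochs maximum epochs; @param patience early-stopping patience
#'   (epochs without validation improvement).
#' @param seed RNG seed (weight init, shuffling, dropout).
#' @param verbose print per-epoch losses.
#' @return Object of class `fitness_model`: the trained network, input and
#'   target normalization statistics, feature names, and a training
#'   `history` data.frame (epoch, train and validation loss).
#' @export
fit_fitness_model <- function(train, val, target = "fitness",
                              features = NULL,
                              hidden = c(512, 512, 512), dropout = 0.5,
                              l2 = 1e-4, batch_norm = TRUE, lr = 1e-3,
                              batch_size = 256, epochs = 150,
                              patience = 20, seed = 1, verbose = FALSE) {
  if (is.null(features)) {
    features <- setdiff(names(train), c(target, "founder_id", "sim"))
  }
  X <- .design_matrix(train, features)
  if (any(!is.finite(X))) stop("non-finite feature values in training data")
  y <- as.numeric(train[[target]])
  Xv <- .design_matrix(val, features)
  yv <- as.numeric(val[[target]])

  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_sd[x_sd == 0 | !is.finite(x_sd)] <- 1
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  Xs <- .row_bcast(sweep(X, 2, x_mean), 1 / x_sd)
  Xvs <- .row_bcast(sweep(Xv, 2, x_mean), 1 / x_sd)
  ys <- (y - y_mean) / y_sd
  yvs <- (yv - y_mean) / y_sd

  set.seed(seed)
  net <- .mlp_init(ncol(Xs), hidden, batch_norm)
  adam_m <- lapply(net$theta, function(p) p * 0)
  adam_v <- lapply(net$theta, function(p) p * 0)
  step <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(Xs)
  best <- list(val = Inf, theta = net$theta, state = net$state, epoch = 0)
  wait <- 0
  hist_tr <- hist_val <- numeric(0)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      b <- ord[start:min(start + batch_size - 1, n)]
      if (length(b) < 2 && batch_norm) next    # batch stats need >= 2 rows
      g <- .mlp_grad(net, Xs[b, , drop = FALSE],
                     matrix(ys[b], ncol = 1), dropout, l2)
      net$state <- g$state
      step <- step + 1
      for (nm in names(net$theta)) {
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g$grads[[nm]]
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g$grads[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1^step)
        vhat <- adam_v[[nm]] / (1 - b2^step)
        net$theta[[nm]] <- net$theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + g$loss; nb <- nb + 1
    }
    if (!is.finite(ep_loss)) {
      stop("training failure: non-finite loss at epoch ", ep,
           " (lr = ", lr, ", batch = ", batch_size, ")")
    }
    net <- .mlp_recalibrate_bn(net, Xs)
    val_loss <- mean((.mlp_forward(net, Xvs) - yvs)^2)
    hist_tr <- c(hist_tr, ep_loss / max(nb, 1))
    hist_val <- c(hist_val, val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                      ep_loss / max(nb, 1), val_loss))
    }
    if (val_loss < best$val - 1e-7) {
      best <- list(val = val_loss, theta = net$theta, state = net$state,
                   epoch = ep)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  net$theta <- best$theta
  net$state <- best$state
  net <- .mlp_recalibrate_bn(net, Xs)
  structure(list(
    net = net, features = features, target = target,
    x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd,
    history = data.frame(epoch = seq_along(hist_tr), train_loss = hist_tr,
                         val_loss = hist_val),
    best_epoch = best$epoch, best_val_loss = best$val,
    spec = list(hidden = hidden, dropout = dropout, l2 = l2,
                batch_norm = batch_norm, lr = lr, batch_size = batch_size,
                epochs = epochs, patience = patience, seed = seed)
  ), class = "fitness_model")
}

#' @export
#' @method predict fitness_model
predict.fitness_model <- function(object, newdata, ...) {
  X <- .design_matrix(newdata, object$features)
  Xs <- .row_bcast(sweep(X, 2, object$x_mean), 1 / object$x_sd)
  .mlp_forward(object$net, Xs) * object$y_sd + object$y_mean
}

#' @export
#' @method print fitness_model
print.fitness_model <- function(x, ...) {
  cat(sprintf("<fitness_model> %s -> %s\n",
              paste(x$spec$hidden, collapse = "x"), x$target))
  cat(sprintf("  %d features; dropout %.2g, L2 %.2g, batch norm %s\n",
              length(x$features), x$spec$dropout, x$spec$l2,
              x$spec$batch_norm))
  cat(sprintf("  best val MSE %.4g (standardized) at epoch %d of %d run\n",
              x$best_val_loss, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' @export
#' @method summary fitness_model
summary.fitness_model <- function(object, ...) {
  print(object)
  cat("  features:", paste(object$features, collapse = ", "), "\n")
  invisible(object)
}

#' @export
#' @method plot fitness_model
plot.fitness_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, lwd = 2, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "MSE (standardized)", log = "y",
                    ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  graphics::legend("topright", c("train", "validation"), lwd = 2,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`. Undefined (NA) for a constant observed
#' vector.
#'
#' @param obs observed values; @param pred predicted values.
#' @return R-squared.
#' @examples
#' r_squared(1:5, c(1.1, 1.9, 3.2, 3.8, 5.1))
#' @export
r_squared <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

#' Evaluate model R-squared on a data split
#'
#' @param model a `fitness_model`.
#' @param data data.frame to evaluate on (normally the held-out test set).
#' @param per_species also report R-squared within each species.
#' @return Named numeric vector: `overall`, plus one entry per species if
#'   requested.
#' @export
evaluate_r2 <- function(model, data, per_species = FALSE) {
  obs <- as.numeric(data[[model$target]])
  pred <- predict(model, data)
  out <- c(overall = r_squared(obs, pred))
  if (per_species) {
    for (sp in sort(unique(data$species))) {
      k <- data$species == sp
      out[sp] <- r_squared(obs[k], pred[k])
    }
  }
  out
}

#' Permutation feature importance
#'
#' Mean drop in test-set R-squared when one feature column is randomly
#' shuffled, averaged over `n_repeats` shuffles; a model-agnostic measure
#' of how much the model relies on each feature.
#'
#' @param model a `fitness_model`.
#' @param data evaluation data.frame.
#' @param n_repeats shuffles per feature.
#' @param seed RNG seed.
#' @return Named numeric vector of importance scores (R-squared drop), in
#'   feature order.
#' @export
permutation_importance <- function(model, data, n_repeats = 5, seed = 1) {
  set.seed(seed)
  base <- evaluate_r2(model, data)[["overall"]]
  obs <- as.numeric(data[[model$target]])
  out <- stats::setNames(numeric(length(model$features)), model$features)
  for (f in model$features) {
    drops <- numeric(n_repeats)
    for (k in seq_len(n_repeats)) {
      shuf <- data
      shuf[[f]] <- sample(shuf[[f]])
      drops[k] <- base - r_squared(obs, predict(model, shuf))
    }
    out[f] <- mean(drops)
  }
  out
}
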