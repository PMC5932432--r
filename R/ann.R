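# Feed-forward fusion network: maps each pixel's vector of per-scale matched
# filter responses to a single vessel score in (0, 1). Two hidden layers plus
# a one-neuron output layer; logistic activations throughout by default.

#' Define the fusion network architecture
#'
#' @param n_inputs input dimension (number of scales in the response stack).
#' @param hidden integer pair: neurons in the first and second hidden layer.
#' @param activation_hidden,activation_output activation names
#'   (`"logistic"` or `"tanh"` for hidden; output is `"logistic"`).
#' @return an object of class `network_architecture`.
#' @examples
#' network_architecture(11, c(3, 8))
#' @export
network_architecture <- function(n_inputs, hidden = c(3L, 8L),
                                 activation_hidden = "logistic",
                                 activation_output = "logistic") {
  stopifnot(length(n_inputs) == 1L, n_inputs >= 1L,
            length(hidden) == 2L, all(hidden >= 1L))
  activation_hidden <- match.arg(activation_hidden, c("logistic", "tanh"))
  activation_output <- match.arg(activation_output, "logistic")
  structure(
    list(n_inputs = as.integer(n_inputs), hidden_sizes = as.integer(hidden),
         activation_hidden = activation_hidden,
         activation_output = activation_output),
    class = "network_architecture"
  )
}

logistic <- function(z) 1 / (1 + exp(-z))

act_fun <- function(name) {
  switch(name,
    logistic = list(f = logistic, df = function(a) a * (1 - a)),
    tanh = list(f = tanh, df = function(a) 1 - a^2),
    stop("unknown activation: ", name))
}

# Run expr with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Initialize a fusion network
#'
#' Weights are drawn i.i.d. uniform on `[-r, r]` with `r` equal to
#' `sqrt(6 / (fan_in + fan_out))` (Glorot); biases start at zero. The
#' same `(architecture, seed)` pair always yields the identical model.
#'
#' @param arch a [network_architecture()].
#' @param seed integer RNG seed, recorded in the model.
#' @return an object of class `network_model`.
#' @export
init_network <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "network_architecture"))
  sizes <- c(arch$n_inputs, arch$hidden_sizes, 1L)
  with_seed(seed, {
    weights <- vector("list", 3L)
    biases <- vector("list", 3L)
    for (l in 1:3) {
      fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
      r <- sqrt(6 / (fan_in + fan_out))
      weights[[l]] <- matrix(stats::runif(fan_out * fan_in, -r, r),
                             fan_out, fan_in)
      biases[[l]] <- rep(0, fan_out)
    }
    structure(
      list(architecture = arch, weights = weights, biases = biases,
           input_norm = list(center = rep(0, arch$n_inputs),
                             scale = rep(1, arch$n_inputs)),
           seed = as.integer(seed), history = NULL, cfg = NULL),
      class = "network_model"
    )
  })
}

#' @export
print.network_model <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("Fusion network %d-%d-%d-1 (%s hidden, %s output), seed %d\n",
              a$n_inputs, a$hidden_sizes[1L], a$hidden_sizes[2L],
              a$activation_hidden, a$activation_output, x$seed))
  invisible(x)
}

# Forward pass for a feature matrix X (n_samples x n_inputs); returns the
# layer activations (needed by backprop) with out = A3 (n_samples x 1).
forward_pass <- function(model, X) {
  g <- act_fun(model$architecture$activation_hidden)$f
  h <- act_fun(model$architecture$activation_output)$f
  Xs <- sweep(sweep(X, 2L, model$input_norm$center, "-"),
              2L, model$input_norm$scale, "/")
  A1 <- g(sweep(Xs %*% t(model$weights[[1L]]), 2L, model$biases[[1L]], "+"))
  A2 <- g(sweep(A1 %*% t(model$weights[[2L]]), 2L, model$biases[[2L]], "+"))
  A3 <- h(sweep(A2 %*% t(model$weights[[3L]]), 2L, model$biases[[3L]], "+"))
  list(Xs = Xs, A1 = A1, A2 = A2, out = A3)
}

#' Score feature vectors with a fusion network
#'
#' @param model a `network_model`.
#' @param features a length-`n_inputs` vector or a matrix with `n_inputs`
#'   columns (one row per pixel).
#' @return detection score(s) in `(0, 1)`.
#' @export
forward <- function(model, features) {
  stopifnot(inherits(model, "network_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != model$architecture$n_inputs) {
    stop("feature dimension ", ncol(features), " != network inputs ",
         model$architecture$n_inputs)
  }
  as.vector(forward_pass(model, features)$out)
}

#' Training configuration for the fusion network
#'
#' @param optimizer `"sgd"` (mini-batch gradient descent with momentum,
#'   default) or `"lm"` (full-batch Levenberg-Marquardt via
#'   \pkg{minpack.lm}).
#' @param learning_rate,momentum SGD hyperparameters.
#' @param epochs training epochs (LM: maximum iterations).
#' @param batch_size mini-batch size.
#' @param seed RNG seed covering sampling, initialization and shuffling.
#' @param class_balance background-to-vessel pixel sampling ratio.
#' @param validation_fraction fraction of samples held out; when positive,
#'   training stops early once validation A_z has not improved for
#'   `patience` epochs.
#' @param patience early-stopping patience in epochs.
#' @param input_norm z-score features with constants frozen into the model
#'   (default `TRUE`).
#' @param max_samples optional cap on the total number of training pixels
#'   (seeded subsample after the class-balanced draw).
#' @return an object of class `training_config`.
#' @export
training_config <- function(optimizer = c("sgd", "lm"), learning_rate = 0.5,
                            momentum = 0.9, epochs = 200L, batch_size = 1024L,
                            seed = 1L, class_balance = 1,
                            validation_fraction = 0, patience = 20L,
                            input_norm = TRUE, max_samples = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(epochs >= 1L, batch_size >= 1L, class_balance > 0,
            validation_fraction >= 0, validation_fraction < 1)
  structure(
    list(loss = "mse", optimizer = optimizer,
         learning_rate = learning_rate, momentum = momentum,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         seed = as.integer(seed), class_balance = class_balance,
         validation_fraction = validation_fraction,
         patience = as.integer(patience), input_norm = input_norm,
         max_samples = if (is.null(max_samples)) NULL else as.integer(max_samples)),
    class = "training_config"
  )
}

pack_params <- function(model) {
  unlist(c(lapply(model$weights, as.vector), model$biases))
}

unpack_params <- function(model, par) {
  i <- 0L
  for (l in 1:3) {
    n <- length(model$weights[[l]])
    model$weights[[l]][] <- par[i + seq_len(n)]; i <- i + n
  }
  for (l in 1:3) {
    n <- length(model$biases[[l]])
    model$biases[[l]] <- par[i + seq_len(n)]; i <- i + n
  }
  model
}

#' Fit the fusion network on a feature matrix
#'
#' Low-level trainer: minimizes mean squared error between network scores
#' and `{0, 1}` labels. [train_network()] builds the pixel sample from
#' response stacks and delegates here.
#'
#' @param X numeric matrix, one row per sample.
#' @param y numeric 0/1 label vector.
#' @param arch a [network_architecture()]; its `n_inputs` must match
#'   `ncol(X)`.
#' @param cfg a [training_config()].
#' @return a trained `network_model`; `$history` holds the per-epoch loss
#'   and, when a validation split is used, validation A_z.
#' @export
fit_mlp <- function(X, y, arch, cfg = training_config()) {
  stopifnot(inherits(arch, "network_architecture"),
            inherits(cfg, "training_config"))
  if (ncol(X) != arch$n_inputs) stop("ncol(X) != arch$n_inputs")
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  model <- init_network(arch, cfg$seed)
  if (isTRUE(cfg$input_norm)) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    model$input_norm <- list(center = ctr, scale = scl)
  }
  model$cfg <- cfg
  if (cfg$optimizer == "lm") {
    return(fit_mlp_lm(model, X, y, cfg))
  }
  dg <- act_fun(arch$activation_hidden)$df
  dh <- act_fun(arch$activation_output)$df
  with_seed(cfg$seed + 1L, {
    n <- nrow(X)
    val_idx <- integer(0)
    if (cfg$validation_fraction > 0) {
      val_idx <- sample.int(n, max(1L, round(cfg$validation_fraction * n)))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    vW <- lapply(model$weights, function(w) w * 0)
    vb <- lapply(model$biases, function(b) b * 0)
    loss_hist <- numeric(0); val_hist <- numeric(0)
    best_val <- -Inf; best_model <- model; since_best <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(length(ytr))
      starts <- seq(1L, length(ytr), by = cfg$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, length(ytr))]
        Xb <- Xtr[idx, , drop = FALSE]; yb <- ytr[idx]
        fp <- forward_pass(model, Xb)
        err <- fp$out - yb
        batch_losses[bi] <- mean(err^2)
        d3 <- (2 / length(yb)) * err * dh(fp$out)
        gW3 <- t(d3) %*% fp$A2; gb3 <- colSums(d3)
        d2 <- (d3 %*% model$weights[[3L]]) * dg(fp$A2)
        gW2 <- t(d2) %*% fp$A1; gb2 <- colSums(d2)
        d1 <- (d2 %*% model$weights[[2L]]) * dg(fp$A1)
        gW1 <- t(d1) %*% fp$Xs; gb1 <- colSums(d1)
        gW <- list(gW1, gW2, gW3); gb <- list(gb1, gb2, gb3)
        for (l in 1:3) {
          vW[[l]] <- cfg$momentum * vW[[l]] - cfg$learning_rate * gW[[l]]
          vb[[l]] <- cfg$momentum * vb[[l]] - cfg$learning_rate * gb[[l]]
          model$weights[[l]] <- model$weights[[l]] + vW[[l]]
          model$biases[[l]] <- model$biases[[l]] + vb[[l]]
        }
      }
      epoch_loss <- mean(batch_losses)
      if (!is.finite(epoch_loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      loss_hist <- c(loss_hist, epoch_loss)
      if (length(val_idx)) {
        sc <- as.vector(forward_pass(model, X[val_idx, , drop = FALSE])$out)
        va <- tryCatch(auc(roc(sc, y[val_idx] == 1)), error = function(e) NA_real_)
        val_hist <- c(val_hist, va)
        if (is.finite(va) && va > best_val + 1e-6) {
          best_val <- va; best_model <- model; since_best <- 0L
        } else {
          since_best <- since_best + 1L
          if (since_best >= cfg$patience) { model <- best_model; break }
        }
      }
    }
    model$history <- list(loss = loss_hist,
                          validation_auc = if (length(val_idx)) val_hist else NULL)
    model
  })
}

# Full-batch Levenberg-Marquardt through minpack.lm; residuals are the
# per-sample score errors.
fit_mlp_lm <- function(model, X, y, cfg) {
  if (!requireNamespace("minpack.lm", quietly = TRUE)) {
    stop("optimizer \"lm\" requires the minpack.lm package")
  }
  par0 <- pack_params(model)
  resid_fun <- function(par) {
    as.vector(forward_pass(unpack_params(model, par), X)$out) - y
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = cfg$epochs))
  model <- unpack_params(model, fit$par)
  model$history <- list(loss = fit$rsstrace / length(y), validation_auc = NULL)
  model
}

# Build the balanced pixel sample from response stacks + masks.
sample_training_pixels <- function(stacks, masks, cfg) {
  stopifnot(length(stacks) == length(masks), length(stacks) >= 1L)
  with_seed(cfg$seed + 2L, {
    Xs <- list(); ys <- list()
    for (i in seq_along(stacks)) {
      f <- stack_features(stacks[[i]])
      g <- as.vector(as_binary(masks[[i]], "mask"))
      if (length(g) != nrow(f)) stop("stack/mask shape mismatch at image ", i)
      vi <- which(g); bi <- which(!g)
      if (length(vi) && length(bi)) {
        nb <- min(length(bi), max(1L, round(cfg$class_balance * length(vi))))
        bi <- sample(bi, nb)
      }
      idx <- c(vi, bi)
      Xs[[i]] <- f[idx, , drop = FALSE]
      ys[[i]] <- as.numeric(g[idx])
    }
    X <- do.call(rbind, Xs); y <- unlist(ys)
    if (length(unique(y)) < 2L) {
      stop("training sample contains a single class; need vessel and background pixels")
    }
    if (!is.null(cfg$max_samples) && nrow(X) > cfg$max_samples) {
      keep <- sample.int(nrow(X), cfg$max_samples)
      X <- X[keep, , drop = FALSE]; y <- y[keep]
    }
    list(X = X, y = y)
  })
}

#' Train the fusion network on response stacks
#'
#' Builds a pixel sample (all vessel pixels plus `class_balance` times as
#' many uniformly drawn background pixels per image, seeded), z-scores each
#' scale with constants frozen into the model, and fits the network by
#' minimizing mean squared error against the `{0, 1}` ground-truth labels.
#'
#' @param stacks list of `response_stack` objects (one per training image).
#' @param masks list of matching ground-truth masks.
#' @param arch a [network_architecture()]; defaults to the 3-8 two-hidden-
#'   layer design with `n_inputs` taken from the stacks.
#' @param cfg a [training_config()].
#' @return a trained `network_model` with `$history`.
#' @export
train_network <- function(stacks, masks, arch = NULL, cfg = training_config()) {
  if (inherits(stacks, "response_stack")) stacks <- list(stacks)
  if (is.matrix(masks) || is.logical(masks)) masks <- list(masks)
  m <- length(stacks[[1L]]$sigmas)
  if (is.null(arch)) arch <- network_architecture(m)
  if (arch$n_inputs != m) stop("arch$n_inputs != number of scales in stacks")
  s <- sample_training_pixels(stacks, masks, cfg)
  fit_mlp(s$X, s$y, arch, cfg)
}

#' Apply the fusion network to a response stack
#'
#' @param model a trained `network_model`.
#' @param stack a `response_stack` whose depth equals the model's input
#'   dimension.
#' @return detection-response matrix with values in `(0, 1)`, same shape as
#'   the input image.
#' @export
predict_image <- function(model, stack) {
  stopifnot(inherits(model, "network_model"), inherits(stack, "response_stack"))
  if (length(stack$sigmas) != model$architecture$n_inputs) {
    stop("stack depth ", length(stack$sigmas), " != network inputs ",
         model$architecture$n_inputs)
  }
  sc <- forward(model, stack_features(stack))
  matrix(sc, nrow(stack$responses[[1L]]), ncol(stack$responses[[1L]]))
}

#' Exhaustive two-hidden-layer architecture search
#'
#' Trains one model for every hidden-size pair `(n1, n2)` in
#' `[1..grid_max] x [1..grid_max]` and scores each by pooled training-set
#' A_z of its detection response. Ties are broken toward the smaller total
#' neuron count, then the smaller first hidden layer. Cells whose training
#' fails are recorded as `NA`.
#'
#' @param stacks,masks training data as in [train_network()].
#' @param grid_max upper bound of both hidden sizes (10 reproduces the
#'   published search grid).
#' @param cfg a [training_config()] shared by every cell.
#' @return list with `best` (integer pair), `best_model`, and `table`
#'   (`grid_max x grid_max` A_z matrix, rows = first hidden layer).
#' @export
architecture_search <- function(stacks, masks, grid_max = 10L,
                                cfg = training_config()) {
  stopifnot(grid_max >= 1L)
  if (inherits(stacks, "response_stack")) stacks <- list(stacks)
  if (is.matrix(masks) || is.logical(masks)) masks <- list(masks)
  m <- length(stacks[[1L]]$sigmas)
  tab <- matrix(NA_real_, grid_max, grid_max,
                dimnames = list(n_1st = seq_len(grid_max),
                                n_2nd = seq_len(grid_max)))
  models <- vector("list", grid_max * grid_max)
  s <- sample_training_pixels(stacks, masks, cfg)
  for (n1 in seq_len(grid_max)) {
    for (n2 in seq_len(grid_max)) {
      arch <- network_architecture(m, c(n1, n2))
      res <- tryCatch({
        mod <- fit_mlp(s$X, s$y, arch, cfg)
        responses <- lapply(stacks, function(st) predict_image(mod, st))
        list(az = dataset_auc(responses, masks), model = mod)
      }, error = function(e) NULL)
      if (!is.null(res)) {
        tab[n1, n2] <- res$az
        models[[(n1 - 1L) * grid_max + n2]] <- res$model
      }
    }
  }
  if (all(is.na(tab))) stop("every architecture-search cell failed")
  best_az <- max(tab, na.rm = TRUE)
  cand <- which(tab == best_az, arr.ind = TRUE)
  ord <- order(cand[, 1L] + cand[, 2L], cand[, 1L])
  best <- as.integer(cand[ord[1L], ])
  list(best = best,
       best_model = models[[(best[1L] - 1L) * grid_max + best[2L]]],
       table = tab)
}

#' Serialize a fusion network to a portable text file
#'
#' Writes architecture, weights, biases, input normalization, seed and
#' training configuration as JSON with 17 significant digits, so
#' [read_model()] restores the model bit-exactly.
#'
#' @param model a `network_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "network_model"))
  payload <- list(
    format = "mgmf-network-model-1",
    architecture = unclass(model$architecture),
    weights = model$weights, biases = model$biases,
    input_norm = model$input_norm, seed = model$seed,
    cfg = if (is.null(model$cfg)) NULL else unclass(model$cfg)
  )
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' Read a fusion network written by [write_model()]
#'
#' @param path file path.
#' @return a `network_model`.
#' @export
read_model <- function(path) {
  p <- jsonlite::fromJSON(path)
  if (!identical(p$format, "mgmf-network-model-1")) {
    stop("not an mgmf network model file: ", path)
  }
  arch <- network_architecture(p$architecture$n_inputs,
                               p$architecture$hidden_sizes,
                               p$architecture$activation_hidden,
                               p$architecture$activation_output)
  cfg <- NULL
  if (!is.null(p$cfg)) {
    cfg <- training_config(
      optimizer = p$cfg$optimizer, learning_rate = p$cfg$learning_rate,
      momentum = p$cfg$momentum, epochs = p$cfg$epochs,
      batch_size = p$cfg$batch_size, seed = p$cfg$seed,
      class_balance = p$cfg$class_balance,
      validation_fraction = p$cfg$validation_fraction,
      patience = p$cfg$patience, input_norm = p$cfg$input_norm,
      max_samples = p$cfg$max_samples)
  }
  structure(
    list(architecture = arch,
         weights = lapply(p$weights, function(w) {
           if (is.null(dim(w))) matrix(w, nrow = 1L) else w
         }),
         biases = lapply(p$biases, as.numeric),
         input_norm = list(center = as.numeric(p$input_norm$center),
                           scale = as.numeric(p$input_norm$scale)),
         seed = as.integer(p$seed), history = NULL, cfg = cfg),
    class = "network_model"
  )
}
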