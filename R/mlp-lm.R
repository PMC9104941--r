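#' Split a dataset into train/validation/test
#'
#' Largest-remainder rounding of `n * fractions` fixes the split sizes
#' (e.g. 33 examples at 70/15/15 gives 23/5/5); examples are shuffled
#' within each label group and interleaved so both classes appear in every
#' split where possible. Deterministic for a fixed seed.
#'
#' @param n Number of examples, or a vector of labels of length n.
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `validation`, `test`
#'   forming a partition of `1:n`.
#' @export
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 42) {
  labels <- if (length(n) > 1) n else rep(0, n)
  n <- length(labels)
  stopifnot(n >= 7, abs(sum(fractions) - 1) < 1e-9, all(fractions > 0))
  sizes <- largest_remainder(n, fractions)
  if (any(sizes == 0)) stop("a split would receive 0 examples")
  set.seed(as.integer(seed))
  # shuffle within label groups, then interleave groups proportionally so
  # consecutive blocks (the splits) are label-balanced
  order_out <- integer(0)
  groups <- lapply(split(seq_len(n), labels), sample)
  ranks <- unlist(lapply(groups, function(g) (seq_along(g) - 0.5) / length(g)))
  order_out <- unname(unlist(groups))[order(ranks)]
  list(train = sort(order_out[seq_len(sizes[1])]),
       validation = sort(order_out[sizes[1] + seq_len(sizes[2])]),
       test = sort(order_out[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  sizes <- floor(exact)
  short <- n - sum(sizes)
  if (short > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Initialize the arrhythmia MLP
#'
#' Three sigmoid layers of 8, 16 and 1 units on a 7-dimensional feature
#' vector (five RR statistics, age, gender). Weights are drawn from
#' Normal(0, 1/fan_in); biases start at zero. 225 parameters in total for
#' the default sizes.
#'
#' @param input_dim Input dimension (default 7).
#' @param layer_sizes Units per layer (default `c(8, 16, 1)`).
#' @param seed Integer seed.
#' @return An object of class `mlp_model`: list of weight matrices `W`
#'   (unit x input) and bias vectors `b` per layer.
#' @export
init_network <- function(input_dim = 7, layer_sizes = c(8, 16, 1),
                         seed = 42) {
  stopifnot(input_dim >= 1, all(layer_sizes >= 1))
  set.seed(as.integer(seed))
  dims <- c(input_dim, layer_sizes)
  W <- list(); b <- list()
  for (l in seq_along(layer_sizes)) {
    W[[l]] <- matrix(rnorm(dims[l + 1] * dims[l], 0, 1 / sqrt(dims[l])),
                     nrow = dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  structure(list(W = W, b = b, layer_sizes = layer_sizes,
                 input_dim = input_dim, init_seed = seed,
                 scaler = NULL),
            class = "mlp_model")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_n_params <- function(model) {
  sum(vapply(seq_along(model$W),
             function(l) length(model$W[[l]]) + length(model$b[[l]]),
             numeric(1)))
}

mlp_get_params <- function(model) {
  unlist(lapply(seq_along(model$W),
                function(l) c(as.numeric(model$W[[l]]), model$b[[l]])))
}

mlp_set_params <- function(model, theta) {
  pos <- 0
  for (l in seq_along(model$W)) {
    nw <- length(model$W[[l]])
    model$W[[l]][] <- theta[pos + seq_len(nw)]
    pos <- pos + nw
    nb <- length(model$b[[l]])
    model$b[[l]] <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  model
}

mlp_forward <- function(model, x) {
  a <- list()
  h <- as.numeric(x)
  for (l in seq_along(model$W)) {
    h <- sigmoid(as.numeric(model$W[[l]] %*% h + model$b[[l]]))
    a[[l]] <- h
  }
  list(output = h[1], activations = a)
}

#' Residuals and Jacobian of the network on a dataset
#'
#' Residuals `r_i = f(x_i) - y_i` and the Jacobian `J[i, ] = d r_i /
#' d theta` computed by per-example backpropagation; `theta` is the flat
#' parameter vector in layer order (weights column-major, then biases).
#' Exposed because Levenberg-Marquardt and its diagnostics (gradient
#' checks, step-limit analysis) operate directly on `(J, r)`.
#'
#' @param model An [init_network()] model.
#' @param x Feature matrix (rows = examples).
#' @param y Numeric targets in `[0, 1]`.
#' @return List with vector `r` and matrix `J` (n x p).
#' @export
mlp_residuals <- function(model, x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(nrow(x) == length(y), ncol(x) == model$input_dim)
  n <- nrow(x)
  p <- mlp_n_params(model)
  J <- matrix(0, n, p)
  r <- numeric(n)
  L <- length(model$W)
  for (i in seq_len(n)) {
    fw <- mlp_forward(model, x[i, ])
    r[i] <- fw$output - y[i]
    # backprop d(output)/d(theta)
    delta <- list()
    aL <- fw$activations[[L]]
    delta[[L]] <- aL * (1 - aL)            # output layer (length 1)
    for (l in seq(L - 1, 1)) {
      al <- fw$activations[[l]]
      delta[[l]] <- as.numeric(t(model$W[[l + 1]]) %*% delta[[l + 1]]) *
        al * (1 - al)
    }
    pos <- 0
    for (l in seq_len(L)) {
      inp <- if (l == 1) as.numeric(x[i, ]) else fw$activations[[l - 1]]
      gW <- outer(delta[[l]], inp)         # same shape as W[[l]]
      nw <- length(gW)
      J[i, pos + seq_len(nw)] <- as.numeric(gW)
      pos <- pos + nw
      nb <- length(delta[[l]])
      J[i, pos + seq_len(nb)] <- delta[[l]]
      pos <- pos + nb
    }
  }
  list(r = r, J = J)
}

#' One Levenberg-Marquardt step
#'
#' Solves `(J'J + mu I) delta = -J' r`. As `mu -> 0` the step approaches
#' the Gauss-Newton step; as `mu -> Inf` it approaches scaled gradient
#' descent `-J'r / mu`.
#'
#' @param J Jacobian matrix (n x p).
#' @param r Residual vector (length n).
#' @param mu Damping parameter (> 0).
#' @return Parameter increment vector (length p).
#' @export
lm_step <- function(J, r, mu) {
  stopifnot(mu > 0)
  g <- as.numeric(crossprod(J, r))
  A <- crossprod(J) + diag(mu, ncol(J))
  -solve(A, g)
}

#' Train the MLP with Levenberg-Marquardt
#'
#' Per epoch the damped normal equations give a candidate step; the step
#' is accepted only if training MSE decreases, otherwise `mu` is
#' multiplied by `mu_factor` and the step recomputed. On acceptance `mu`
#' is divided by `mu_factor`. Early stopping keeps the parameters with the
#' best validation MSE (ties keep the earlier epoch) and stops after
#' `patience` epochs without improvement. If `mu` exceeds `1e10` while
#' searching, training stops with `stop_reason = "convergence_failure"`.
#'
#' @param model An [init_network()] model.
#' @param x_train,y_train Training features and 0/1 targets.
#' @param x_val,y_val Optional validation split (defaults to the training
#'   split).
#' @param max_epochs Maximum epochs (default 10).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param mu0 Initial damping (default 1e-3).
#' @param mu_factor Damping multiplier (default 10).
#' @return List with the trained `model` (best-validation parameters) and
#'   `history` data.frame (epoch, train_mse, val_mse, gradient_norm, mu,
#'   accepted) plus attributes `best_epoch` and `stop_reason`.
#' @export
train_lm <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                     max_epochs = 10, patience = 10, mu0 = 1e-3,
                     mu_factor = 10) {
  if (is.null(x_val)) { x_val <- x_train; y_val <- y_train }
  if (is.null(dim(x_train))) x_train <- matrix(x_train, nrow = 1)
  stopifnot(nrow(x_train) >= 1, all(is.finite(x_train)),
            all(is.finite(y_train)))
  if (length(unique(y_train)) < 2)
    stop("training split contains a single class; cannot train a classifier")
  mse <- function(m, x, y) {
    pred <- apply(x, 1, function(row) mlp_forward(m, row)$output)
    mean((pred - y)^2)
  }
  mu <- mu0
  history <- data.frame()
  best_val <- Inf; best_model <- model; best_epoch <- 0
  stop_reason <- "max_epochs"
  since_best <- 0
  for (epoch in seq_len(max_epochs)) {
    jr <- mlp_residuals(model, x_train, y_train)
    cur_mse <- mean(jr$r^2)
    grad <- as.numeric(crossprod(jr$J, jr$r))
    accepted <- FALSE
    while (!accepted) {
      delta <- tryCatch(lm_step(jr$J, jr$r, mu), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- mlp_set_params(model, mlp_get_params(model) + delta)
        cand_mse <- mse(cand, x_train, y_train)
        if (is.finite(cand_mse) && cand_mse < cur_mse) {
          model <- cand
          mu <- mu / mu_factor
          accepted <- TRUE
          break
        }
      }
      mu <- mu * mu_factor
      if (mu > 1e10) break
    }
    train_mse <- mse(model, x_train, y_train)
    val_mse <- mse(model, x_val, y_val)
    history <- rbind(history, data.frame(
      epoch = epoch, train_mse = train_mse, val_mse = val_mse,
      gradient_norm = sqrt(sum(grad^2)), mu = mu, accepted = accepted))
    if (!accepted) { stop_reason <- "convergence_failure"; break }
    if (val_mse < best_val) {
      best_val <- val_mse; best_model <- model; best_epoch <- epoch
      since_best <- 0
    } else {
      since_best <- since_best + 1
      if (since_best >= patience) { stop_reason <- "early_stop"; break }
    }
  }
  best_model$scaler <- model$scaler
  attr(history, "best_epoch") <- best_epoch
  attr(history, "stop_reason") <- stop_reason
  list(model = best_model, history = history)
}

#' Predict arrhythmia probability
#'
#' @param object A trained `mlp_model`.
#' @param x Feature vector or matrix (already scaled as in training; if
#'   the model carries a scaler it is applied to raw features).
#' @param threshold Decision threshold (default 0.5).
#' @param ... Unused.
#' @return Data frame with `probability` and `label`
#'   (`"arrhythmia"`/`"normal"`).
#' @export
predict.mlp_model <- function(object, x, threshold = 0.5, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != object$input_dim) stop("feature dimension mismatch")
  if (!is.null(object$scaler)) x <- apply_scaler(object$scaler, x)
  prob <- apply(x, 1, function(row) mlp_forward(object, row)$output)
  data.frame(probability = prob,
             label = ifelse(prob >= threshold, "arrhythmia", "normal"))
}

#' Confusion counts and accuracy
#'
#' @param labels True 0/1 (or `"normal"`/`"arrhythmia"`) labels.
#' @param predictions Predicted labels, same coding.
#' @return List with `tn`, `fp`, `fn`, `tp`, `accuracy`.
#' @export
confusion_and_accuracy <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  stopifnot(length(labels) >= 1)
  to01 <- function(v) {
    if (is.character(v) || is.factor(v)) as.numeric(v == "arrhythmia")
    else as.numeric(v)
  }
  y <- to01(labels); p <- to01(predictions)
  tp <- sum(y == 1 & p == 1); tn <- sum(y == 0 & p == 0)
  fp <- sum(y == 0 & p == 1); fn <- sum(y == 1 & p == 0)
  list(tn = tn, fp = fp, fn = fn, tp = tp,
       accuracy = (tn + tp) / length(y))
}

#' Serialize / restore an MLP model as JSON
#'
#' @param model A trained `mlp_model`.
#' @param path Output file.
#' @export
write_mlp_json <- function(model, path) {
  obj <- list(input_dim = model$input_dim, layer_sizes = model$layer_sizes,
              init_seed = model$init_seed,
              params = mlp_get_params(model),
              scaler = if (is.null(model$scaler)) NULL else
                list(min = as.numeric(model$scaler$min),
                     range = as.numeric(model$scaler$range)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp_json
#' @return `read_mlp_json` returns the restored `mlp_model`.
#' @export
read_mlp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- init_network(obj$input_dim, obj$layer_sizes, obj$init_seed)
  m <- mlp_set_params(m, obj$params)
  if (!is.null(obj$scaler))
    m$scaler <- structure(list(min = obj$scaler$min,
                               range = obj$scaler$range),
                          class = "feature_scaler")
  m
}
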