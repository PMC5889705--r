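#' Training configuration for the backpropagation classifier
#'
#' @param max_iterations Maximum number of full-batch gradient iterations.
#' @param target_rms Stop once the training RMS error falls to this level
#'   (default 0.04); the first of `target_rms` / `max_iterations` wins.
#' @param hidden_dim Width of the single hidden layer.
#' @param learning_rate Gradient-descent step size (default 0.20).
#' @param update `"pattern"` (default): one weight update per training
#'   sample, in a seeded shuffled order, the classic online
#'   backpropagation regime whose RMS typically reaches the 0.04 stopping
#'   level within a few tens of iterations; `"batch"`: one full-batch
#'   update per iteration (much slower to converge at the same rate).
#' @param seed Integer seed for the weight initialization (and the
#'   per-pattern presentation order).
#' @return A list of class `train_config`.
#' @export
train_config <- function(max_iterations = 500L, target_rms = 0.04,
                         hidden_dim = 8L, learning_rate = 0.20,
                         update = c("pattern", "batch"), seed = 1L) {
  if (max_iterations < 1L) stop("max_iterations must be >= 1", call. = FALSE)
  if (target_rms <= 0) stop("target_rms must be > 0", call. = FALSE)
  structure(list(max_iterations = as.integer(max_iterations),
                 target_rms = target_rms, hidden_dim = as.integer(hidden_dim),
                 learning_rate = learning_rate, update = match.arg(update),
                 seed = as.integer(seed)),
            class = "train_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Extract and normalize training features from a stack
#'
#' Pulls the feature vector of every sampled cell out of the stack, scales
#' each feature to `[0, 1]` by min-max constants computed from the training
#' rows only (required for the logistic-activation network), and one-hot
#' encodes the class labels.
#'
#' @param stack A `scene_stack` (see [stack_scene()]).
#' @param samples Reference sample data frame with `row`, `col`,
#'   `true_class` columns (see [sample_reference()]).
#' @param classes Class levels in code order; defaults to the classes
#'   present, sorted.
#' @return List with `X` (n x p normalized features), `Y` (n x q one-hot
#'   targets), `mins`, `maxs` (per-feature constants), `classes`.
#' @export
normalize_features <- function(stack, samples, classes = NULL) {
  stopifnot(inherits(stack, "scene_stack"))
  d <- dim(stack$bands[[1]]$values)
  if (any(samples$row < 1 | samples$row > d[1] |
          samples$col < 1 | samples$col > d[2])) {
    stop("sample indices fall outside the stack grid", call. = FALSE)
  }
  idx <- cbind(samples$row, samples$col)
  X <- sapply(stack$bands, function(g) g$values[idx])
  if (!is.matrix(X)) X <- matrix(X, nrow = nrow(samples))
  colnames(X) <- names(stack$bands)
  bad <- which(rowSums(is.na(X)) > 0)
  if (length(bad)) {
    stop("data error: sampled nodata cells at rows ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  mins <- apply(X, 2, min); maxs <- apply(X, 2, max)
  degenerate <- names(which(maxs - mins <= 0))
  if (length(degenerate)) {
    stop("data error: constant feature(s): ",
         paste(degenerate, collapse = ", "), call. = FALSE)
  }
  Xn <- sweep(sweep(X, 2, mins), 2, maxs - mins, "/")
  if (is.null(classes)) classes <- sort(unique(samples$true_class))
  ki <- match(samples$true_class, classes)
  if (anyNA(ki)) stop("sample classes not in `classes`", call. = FALSE)
  Y <- matrix(0, nrow(Xn), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_len(nrow(Y)), ki)] <- 1
  list(X = Xn, Y = Y, mins = mins, maxs = maxs, classes = classes)
}

#' Train a one-hidden-layer backpropagation network
#'
#' Gradient descent on the squared error of logistic activations in both
#' the hidden and the output layer -- the classic BPNN, monitored by the
#' root-mean-square (RMS) error over all output units. Weights are
#' initialized uniform(-0.5, 0.5) from the config seed. One "iteration" is
#' a pass over the training set: in the default `"pattern"` mode the
#' weights are updated after every sample (seeded shuffled order, restored
#' each iteration), in `"batch"` mode once per pass. Training stops at the
#' first of `target_rms` or `max_iterations`; the per-iteration RMS trace
#' (evaluated on the whole set after each pass) is recorded on the model,
#' with the pre-training RMS as its first entry.
#'
#' @param X Numeric feature matrix (rows = training samples), expected to
#'   be normalized to `[0, 1]` (see [normalize_features()]).
#' @param Y One-hot target matrix with the same number of rows.
#' @param config A [train_config()].
#' @return An object of class `bpnn`.
#' @export
train_bpnn <- function(X, Y, config = train_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) == 0L) stop("data error: empty training set", call. = FALSE)
  if (nrow(X) != nrow(Y)) stop("X and Y must have equal rows", call. = FALSE)
  if (any(Y != 0 & Y != 1) || any(rowSums(Y) != 1)) {
    stop("Y must be one-hot", call. = FALSE)
  }
  d <- ncol(X); h <- config$hidden_dim; q <- ncol(Y); n <- nrow(X)
  init <- withr::with_seed(config$seed, {
    list(W1 = matrix(stats::runif(d * h, -0.5, 0.5), d, h),
         b1 = stats::runif(h, -0.5, 0.5),
         W2 = matrix(stats::runif(h * q, -0.5, 0.5), h, q),
         b2 = stats::runif(q, -0.5, 0.5))
  })
  W1 <- init$W1; b1 <- init$b1; W2 <- init$W2; b2 <- init$b2
  lr <- config$learning_rate
  rms_now <- function() {
    A1 <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
    A2 <- sigmoid(sweep(A1 %*% W2, 2, b2, "+"))
    sqrt(mean((A2 - Y)^2))
  }
  trace <- rms_now()
  orders <- withr::with_seed(config$seed, {
    lapply(seq_len(config$max_iterations), function(i) sample.int(n))
  })
  for (it in seq_len(config$max_iterations)) {
    if (trace[it] <= config$target_rms) break
    if (config$update == "pattern") {
      ord <- orders[[it]]
      for (i in ord) {
        x <- X[i, ]
        a1 <- sigmoid(drop(crossprod(W1, x)) + b1)
        a2 <- sigmoid(drop(crossprod(W2, a1)) + b2)
        d2 <- (a2 - Y[i, ]) * a2 * (1 - a2)
        d1 <- drop(W2 %*% d2) * a1 * (1 - a1)
        W2 <- W2 - lr * tcrossprod(a1, d2); b2 <- b2 - lr * d2
        W1 <- W1 - lr * tcrossprod(x, d1); b1 <- b1 - lr * d1
      }
    } else {
      A1 <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
      A2 <- sigmoid(sweep(A1 %*% W2, 2, b2, "+"))
      D2 <- (A2 - Y) * A2 * (1 - A2)
      D1 <- (D2 %*% t(W2)) * A1 * (1 - A1)
      W2 <- W2 - lr * crossprod(A1, D2) / n
      b2 <- b2 - lr * colMeans(D2)
      W1 <- W1 - lr * crossprod(X, D1) / n
      b1 <- b1 - lr * colMeans(D1)
    }
    trace[it + 1L] <- rms_now()
  }
  structure(list(
    input_dim = d, hidden_dim = h, output_dim = q,
    W1 = W1, b1 = b1, W2 = W2, b2 = b2,
    activation = "logistic", learning_rate = lr,
    feature_names = colnames(X), classes = colnames(Y),
    feature_mins = NULL, feature_maxs = NULL,
    training_trace = trace, config = config, seed = config$seed),
    class = "bpnn")
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("<bpnn> %d-%d-%d network, logistic activations, lr %.3g\n",
              x$input_dim, x$hidden_dim, x$output_dim, x$learning_rate))
  tr <- x$training_trace
  cat(sprintf("  trained %d iterations, RMS %.4f -> %.4f\n",
              length(tr), tr[1], tr[length(tr)]))
  if (!is.null(x$classes)) {
    cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  }
  invisible(x)
}

# forward pass on an already-normalized feature matrix
forward_bpnn <- function(model, Xn) {
  A1 <- sigmoid(sweep(Xn %*% model$W1, 2, model$b1, "+"))
  sigmoid(sweep(A1 %*% model$W2, 2, model$b2, "+"))
}

#' Predict class activations for raw feature rows
#'
#' Applies the model's stored min-max normalization (when present) and runs
#' the forward pass.
#'
#' @param object A `bpnn` model.
#' @param newdata Numeric matrix of raw feature rows.
#' @param type `"activation"` (raw output-unit activations), `"prob"`
#'   (activations normalized to sum to one) or `"class"`.
#' @param ... Unused.
#' @return Matrix of activations/probabilities, or a character vector of
#'   classes.
#' @export
predict.bpnn <- function(object, newdata,
                         type = c("activation", "prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object$input_dim) {
    stop("feature dimension mismatch: model expects ", object$input_dim,
         call. = FALSE)
  }
  if (!is.null(object$feature_mins)) {
    X <- sweep(sweep(X, 2, object$feature_mins), 2,
               object$feature_maxs - object$feature_mins, "/")
  }
  A <- forward_bpnn(object, X)
  colnames(A) <- object$classes
  if (type == "activation") return(A)
  P <- A / rowSums(A)
  if (type == "prob") return(P)
  cls <- max.col(A, ties.method = "first")
  if (!is.null(object$classes)) object$classes[cls] else cls
}

#' Fit the classifier on a stack and reference sample
#'
#' Convenience wrapper: normalizes features from the training sample,
#' trains the network, and stores the normalization constants and class
#' order on the model so it can be applied to whole scenes.
#'
#' @param stack A `scene_stack`.
#' @param samples Training sample (`row`, `col`, `true_class`).
#' @param config A [train_config()].
#' @param classes Optional class order; defaults to the stratifying grid's.
#' @return A `bpnn` model ready for [predict_map()].
#' @export
fit_bpnn <- function(stack, samples, config = train_config(),
                     classes = NULL) {
  nf <- normalize_features(stack, samples, classes = classes)
  model <- train_bpnn(nf$X, nf$Y, config)
  model$feature_mins <- nf$mins
  model$feature_maxs <- nf$maxs
  model$classes <- nf$classes
  model
}

#' Classify every cell of a scene
#'
#' Runs the trained network over the stack, producing a categorical class
#' map (argmax of the four output activations, ties broken by the lowest
#' class index) and a probability map holding the winning class's share of
#' the activation total. Nodata cells propagate to both outputs.
#'
#' @param model A `bpnn` with stored normalization constants (from
#'   [fit_bpnn()]).
#' @param stack A `scene_stack` with features matching the model.
#' @return List with `class` (categorical [grid]) and `probability`
#'   (continuous [grid] of winning shares in `(0, 1]`).
#' @export
predict_map <- function(model, stack) {
  stopifnot(inherits(model, "bpnn"), inherits(stack, "scene_stack"))
  Xall <- feature_matrix(stack)
  if (ncol(Xall) != model$input_dim) {
    stop("feature dimension mismatch: model expects ", model$input_dim,
         " features, stack has ", ncol(Xall), call. = FALSE)
  }
  if (is.null(model$feature_mins)) {
    stop("model lacks normalization constants; fit with fit_bpnn()",
         call. = FALSE)
  }
  d <- dim(stack$bands[[1]]$values)
  ok <- rowSums(is.na(Xall)) == 0
  cls <- rep(NA_real_, nrow(Xall))
  prob <- rep(NA_real_, nrow(Xall))
  if (any(ok)) {
    A <- predict(model, Xall[ok, , drop = FALSE], type = "activation")
    win <- max.col(A, ties.method = "first")
    share <- A[cbind(seq_len(nrow(A)), win)] / rowSums(A)
    cls[ok] <- win
    prob[ok] <- share
  }
  list(class = grid(matrix(cls, d[1], d[2]),
                    cell_size = stack$bands[[1]]$cell_size,
                    kind = "categorical", levels = model$classes),
       probability = grid(matrix(prob, d[1], d[2]),
                          cell_size = stack$bands[[1]]$cell_size))
}
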