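# Extreme learning machine.
#
# Single-hidden-layer feedforward network: the input weights and biases
# are drawn once from a seeded Uniform[-1, 1] and never trained; the
# output weights are the minimum-norm least-squares solution (SVD
# pseudoinverse) mapping the random hidden representation onto one-hot
# class targets.  Features are z-scored with training statistics before
# the random projection so the sigmoid operates away from saturation.

sigmoid <- function(z) 1 / (1 + exp(-z))

# Moore-Penrose pseudoinverse via SVD with relative cutoff.
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric, logical(1))])
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

#' Train an extreme learning machine
#'
#' @param x Feature matrix or data frame (`n x d`, numeric columns).
#' @param y Class labels (factor or coercible; at least two classes
#'   present).
#' @param hidden Number of hidden nodes `l` (default 60).
#' @param activation Hidden activation; `"sigmoid"` (logistic) is the
#'   only built-in.
#' @param seed Integer seed for the random input layer.
#' @return An object of class `elm` holding the scaler, input weights
#'   `W` (`d x l`), biases `b`, output weights `beta` (`l x c`), class
#'   levels, and the training call parameters.
#' @export
elm_train <- function(x, y, hidden = 60L, activation = "sigmoid",
                      seed = 1L) {
  X <- as_feature_matrix(x)
  if (anyNA(X)) stop_invalid("features contain missing values; impute or drop first")
  y <- factor(y)
  if (nrow(X) < 2) stop_invalid("need at least 2 training samples")
  if (nlevels(y) < 2) stop_invalid("training labels contain a single class")
  if (activation != "sigmoid") stop_invalid("unsupported activation")
  d <- ncol(X)
  l <- as.integer(hidden)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  Wb <- with_rng(seed, stats::runif(d * l + l, -1, 1))
  W <- matrix(Wb[seq_len(d * l)], nrow = d, ncol = l)
  b <- Wb[d * l + seq_len(l)]
  H <- sigmoid(sweep(Xs %*% W, 2, b, "+"))
  Tmat <- vapply(levels(y), function(lv) as.numeric(y == lv),
                 numeric(length(y)))
  beta <- pinv(H) %*% Tmat
  structure(
    list(W = W, b = b, beta = beta, activation = activation,
         hidden = l, seed = seed, levels = levels(y),
         center = center, scale = scale_, d = d,
         n_train = nrow(X)),
    class = "elm"
  )
}

#' Predict from an extreme learning machine
#'
#' Scores are the output-layer activations `g(XW + b) beta`; the label
#' is the argmax over classes with ties broken toward the lower class
#' index.
#'
#' @param object An `elm` model.
#' @param newdata Feature matrix or data frame with the training
#'   feature dimension.
#' @param type `"class"` (factor of labels, default) or `"scores"`
#'   (numeric matrix, one column per class).
#' @param ... Unused.
#' @return Factor of predicted labels or score matrix.
#' @export
predict.elm <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  if (ncol(X) != object$d) stop_invalid("feature dimension mismatch")
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  H <- sigmoid(sweep(Xs %*% object$W, 2, object$b, "+"))
  scores <- H %*% object$beta
  colnames(scores) <- object$levels
  if (type == "scores") return(scores)
  idx <- apply(scores, 1, which.max)   # which.max: first (lowest) index wins ties
  factor(object$levels[idx], levels = object$levels)
}

#' @export
print.elm <- function(x, ...) {
  cat("<elm>", x$d, "features ->", x$hidden, "hidden ->",
      length(x$levels), "classes | seed", x$seed, "\n")
  invisible(x)
}

#' @rdname elm_train
#' @param x An `elm` model (for `tidy`/`glance`).
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.elm <- function(x, ...) {
  tibble::tibble(
    hidden_node = rep(seq_len(x$hidden), times = length(x$levels)),
    class = rep(x$levels, each = x$hidden),
    beta = as.vector(x$beta)
  )
}

#' @rdname elm_train
#' @exportS3Method generics::glance
glance.elm <- function(x, ...) {
  tibble::tibble(n_features = x$d, hidden = x$hidden,
                 n_classes = length(x$levels), n_train = x$n_train,
                 seed = x$seed, activation = x$activation)
}

#' Serialize / restore an ELM model as JSON
#'
#' The JSON container stores the seed, dimensions, activation, scaler
#' and the solved output weights; [elm_from_json()] rebuilds the random
#' input layer from the seed and restores `beta` bit-exactly.
#'
#' @param model An `elm` model.
#' @param path File path to write to / read from.
#' @return `elm_to_json()` returns `path` invisibly; `elm_from_json()`
#'   returns the restored `elm` model.
#' @export
elm_to_json <- function(model, path) {
  payload <- list(
    seed = model$seed, d = model$d, hidden = model$hidden,
    activation = model$activation, levels = model$levels,
    center = model$center, scale = model$scale,
    beta = model$beta, n_train = model$n_train
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname elm_to_json
#' @export
elm_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.integer(p$d); l <- as.integer(p$hidden)
  Wb <- with_rng(as.integer(p$seed), stats::runif(d * l + l, -1, 1))
  structure(
    list(W = matrix(Wb[seq_len(d * l)], d, l), b = Wb[d * l + seq_len(l)],
         beta = matrix(as.numeric(p$beta), nrow = l),
         activation = p$activation, hidden = l, seed = as.integer(p$seed),
         levels = p$levels, center = as.numeric(p$center),
         scale = as.numeric(p$scale), d = d,
         n_train = as.integer(p$n_train)),
    class = "elm"
  )
}
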