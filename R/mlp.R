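# Multilayer-perceptron classifier for the seven-feature vectors.
#
# Single hidden layer (default 25 units, ReLU) with a softmax 3-class
# output, trained by full-batch Adam on the cross-entropy loss after
# z-score standardization of the inputs. Written as a classic fitting
# function: formula + data in, classed object with methods out.

#' Fit the conjunctival-pallor MLP classifier
#'
#' Trains a single-hidden-layer perceptron (ReLU hidden units, softmax
#' output) on labeled feature vectors. Inputs are z-score standardized
#' using statistics fitted on the training data; the scaler is stored in
#' the model and re-applied at prediction time. Training is full-batch
#' Adam on the multinomial cross-entropy, run to convergence (gradient
#' infinity-norm below `tol`) or `max_iter` iterations. The same seed
#' yields an identical model.
#'
#' @param x A formula such as `label ~ .`, or a numeric matrix/data frame
#'   of features.
#' @param data Data frame holding the variables when `x` is a formula.
#' @param y Factor (or character) of class labels when `x` is a matrix.
#' @param hidden_units Hidden-layer width.
#' @param max_iter Iteration limit.
#' @param learning_rate Adam step size.
#' @param tol Convergence tolerance on the gradient infinity-norm.
#' @param seed Integer seed for weight initialization.
#' @param ... Passed between methods.
#' @return An object of class `pallor_mlp` with components `weights`,
#'   `scaler`, `classes`, `feature_names`, `loss` (per-iteration trace),
#'   `iterations`, `converged` and `call`.
#' @examples
#' set.seed(1)
#' n <- 60
#' df <- data.frame(
#'   f1 = c(rnorm(n, 0), rnorm(n, 4), rnorm(n, 8)),
#'   f2 = c(rnorm(n, 2), rnorm(n, -2), rnorm(n, 6)),
#'   label = rep(c("anemic", "moderate", "normal"), each = n)
#' )
#' fit <- pallor_mlp(label ~ ., df, seed = 7)
#' table(predict(fit, df), df$label)
#' @export
pallor_mlp <- function(x, ...) UseMethod("pallor_mlp")

#' @rdname pallor_mlp
#' @export
pallor_mlp.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- pallor_mlp.default(X, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname pallor_mlp
#' @export
pallor_mlp.default <- function(x, y, hidden_units = 25L, max_iter = 1000L,
                               learning_rate = 0.01, tol = 1e-6,
                               seed = 1L, ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X)))
    stop("feature matrix must be finite", call. = FALSE)
  # a factor's declared levels are a contract: every level must be trained
  classes <- if (is.factor(y)) sort(levels(y))
             else sort(unique(as.character(y)))
  y <- factor(as.character(y), levels = classes)
  counts <- table(y)
  if (any(counts == 0L))
    stop("class absent from training data: ",
         paste(names(counts)[counts == 0L], collapse = ", "),
         call. = FALSE)
  if (nlevels(y) < 2L)
    stop("training data must contain at least two classes", call. = FALSE)
  n <- nrow(X); p <- ncol(X); k <- nlevels(y)
  if (n != length(y)) stop("x and y lengths differ", call. = FALSE)

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Y <- diag(k)[as.integer(y), , drop = FALSE]

  h <- as.integer(hidden_units)
  W <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(p * h, sd = sqrt(2 / p)), p, h),
    b1 = numeric(h),
    W2 = matrix(stats::rnorm(h * k, sd = sqrt(2 / h)), h, k),
    b2 = numeric(k)
  ))

  adam <- lapply(W, function(w) list(m = 0 * w, v = 0 * w))
  b1 <- 0.9; b2m <- 0.999; eps <- 1e-8
  loss_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A1 <- sweep(Z %*% W$W1, 2, W$b1, "+")
    H <- pmax(A1, 0)
    S <- sweep(H %*% W$W2, 2, W$b2, "+")
    S <- sweep(S, 1, apply(S, 1, max))
    E <- exp(S)
    P <- E / rowSums(E)
    loss_trace[it] <- -mean(log(pmax(P[cbind(seq_len(n),
                                             as.integer(y))], 1e-300)))
    G <- (P - Y) / n
    grads <- list(
      W1 = crossprod(Z, (G %*% t(W$W2)) * (A1 > 0)),
      b1 = colSums((G %*% t(W$W2)) * (A1 > 0)),
      W2 = crossprod(H, G),
      b2 = colSums(G)
    )
    gmax <- max(vapply(grads, function(g) max(abs(g)), numeric(1)))
    if (gmax < tol) { converged <- TRUE; break }
    for (nm in names(W)) {
      adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * grads[[nm]]
      adam[[nm]]$v <- b2m * adam[[nm]]$v + (1 - b2m) * grads[[nm]]^2
      mhat <- adam[[nm]]$m / (1 - b1^it)
      vhat <- adam[[nm]]$v / (1 - b2m^it)
      W[[nm]] <- W[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }

  structure(list(
    weights = W,
    scaler = list(mean = mu, sd = sdv),
    classes = classes,
    feature_names = colnames(X),
    loss = loss_trace,
    iterations = it,
    converged = converged,
    hidden_units = h,
    seed = as.integer(seed),
    call = match.call()
  ), class = "pallor_mlp")
}

#' Predict classes or probabilities from a fitted pallor MLP
#'
#' Probabilities are the softmax outputs and sum to one; the predicted
#' label is the argmax, exact ties going to the lexicographically first
#' class.
#'
#' @param object A `pallor_mlp` fit.
#' @param newdata Data frame or numeric matrix of feature vectors (a bare
#'   numeric vector is taken as one observation).
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... Unused.
#' @return Factor of labels, or an `n x k` probability matrix.
#' @export
predict.pallor_mlp <- function(object, newdata,
                               type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) {
    newdata <- matrix(as.numeric(newdata), nrow = 1,
                      dimnames = list(NULL, object$feature_names))
  }
  X <- as.matrix(as.data.frame(newdata)[,
    if (!is.null(object$feature_names) &&
        all(object$feature_names %in% colnames(newdata)))
      object$feature_names else seq_along(object$scaler$mean),
    drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X)))
    stop("feature matrix must be finite", call. = FALSE)
  Z <- sweep(sweep(X, 2, object$scaler$mean), 2, object$scaler$sd, "/")
  H <- pmax(sweep(Z %*% object$weights$W1, 2, object$weights$b1, "+"), 0)
  S <- sweep(H %*% object$weights$W2, 2, object$weights$b2, "+")
  S <- sweep(S, 1, apply(S, 1, max))
  E <- exp(S)
  P <- E / rowSums(E)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.pallor_mlp <- function(x, ...) {
  cat("Conjunctival-pallor MLP classifier\n")
  cat(sprintf("  %d -> %d (ReLU) -> %d (softmax)\n",
              length(x$scaler$mean), x$hidden_units, length(x$classes)))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  %d iteration(s), final cross-entropy %.6f%s\n",
              x$iterations, x$loss[length(x$loss)],
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' @export
summary.pallor_mlp <- function(object, ...) {
  print(object)
  cat("  feature standardization (train-set mean / sd):\n")
  tab <- rbind(mean = object$scaler$mean, sd = object$scaler$sd)
  colnames(tab) <- object$feature_names
  print(round(tab, 4))
  invisible(object)
}

#' @export
coef.pallor_mlp <- function(object, ...) object$weights

#' Save / load a fitted model with a JSON sidecar
#'
#' The model is serialized as an RDS artifact next to a human-readable
#' JSON sidecar recording the class order, feature names, scaler and
#' training configuration.
#'
#' @param model A `pallor_mlp` fit.
#' @param path Destination `.rds` path; the sidecar is `<path>.json`.
#' @return `path` (save) or the restored model (load), invisibly/visibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "pallor_mlp"))
    stop("`model` must be a pallor_mlp fit", call. = FALSE)
  saveRDS(model, path)
  sidecar <- list(
    format = "pallor_mlp/1",
    classes = model$classes,
    feature_names = model$feature_names,
    hidden_units = model$hidden_units,
    iterations = model$iterations,
    seed = model$seed,
    scaler = list(mean = unname(model$scaler$mean),
                  sd = unname(model$scaler$sd))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pallor_mlp"))
    stop("not a pallor_mlp artifact: ", path, call. = FALSE)
  model
}
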