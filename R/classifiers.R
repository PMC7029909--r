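#' Classifier specification
#'
#' The five algorithms of the lameness bench with their fixed
#' hyperparameters: random forest (250 trees, minimum leaf size 1,
#' sqrt(n_features) candidates per split), RBF-kernel SVM, a single-hidden-
#' layer neural network (100 rectified-linear units, learning rate 1e-4),
#' AdaBoost (100 depth-1 decision-tree learners, learning rate 1) and KNN
#' (K = 5, Euclidean, no normalisation). Hyperparameters are fixed at
#' construction.
#'
#' @param algorithm One of `"rf"`, `"nn"`, `"svm"`, `"ada"`, `"knn"`.
#' @param seed Integer seed controlling every stochastic element of training.
#' @return A `classifier_spec` object.
#' @examples
#' classifier_spec("rf", seed = 1)
#' @export
classifier_spec <- function(algorithm = c("rf", "nn", "svm", "ada", "knn"), seed = 1L) {
  algorithm <- match.arg(algorithm)
  hp <- switch(algorithm,
    rf  = list(n_trees = 250L, min_leaf = 1L),
    svm = list(kernel = "radial"),
    nn  = list(hidden = 100L, activation = "relu", learning_rate = 1e-4,
               max_epochs = 500L, patience = 20L),
    ada = list(n_learners = 100L, max_depth = 1L, learning_rate = 1),
    knn = list(k = 5L, metric = "euclidean", normalize = FALSE)
  )
  structure(list(algorithm = algorithm, hyperparameters = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s (seed %d)\n", x$algorithm, x$seed))
  str(x$hyperparameters, give.attr = FALSE)
  invisible(x)
}

# Fit one classifier on a numeric feature matrix and logical labels.
# Uses the current RNG stream; callers seed it for reproducibility.
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"), is.matrix(X), is.logical(y))
  hp <- spec$hyperparameters
  model <- switch(spec$algorithm,
    rf = randomForest::randomForest(
      x = X, y = factor(y, levels = c(FALSE, TRUE)),
      ntree = hp$n_trees, nodesize = hp$min_leaf,
      mtry = max(1L, floor(sqrt(ncol(X))))),
    svm = suppressWarnings(e1071::svm(
      x = X, y = factor(y, levels = c(FALSE, TRUE)), kernel = hp$kernel)),
    nn = fit_mlp(X, y, hidden = hp$hidden, lr = hp$learning_rate,
                 max_epochs = hp$max_epochs, patience = hp$patience),
    ada = fit_adaboost(X, y, n_learners = hp$n_learners, lr = hp$learning_rate),
    knn = list(train = X, labels = y, k = hp$k)
  )
  structure(list(spec = spec, model = model), class = "ovi_classifier")
}

# Logical lame/non-lame predictions for new windows.
predict_classifier <- function(fit, X) {
  stopifnot(inherits(fit, "ovi_classifier"), is.matrix(X))
  m <- fit$model
  switch(fit$spec$algorithm,
    rf = as.logical(predict(m, X)),
    svm = as.logical(predict(m, X)),
    nn = predict_mlp(m, X),
    ada = predict_adaboost(m, X),
    knn = as.logical(class::knn(m$train, X, factor(m$labels), k = m$k))
  )
}

# --- single-hidden-layer ReLU network, Adam, full batch -----------------
# Inputs are standardised on the training fold; logistic output with
# cross-entropy loss; training stops when the loss plateaus.
fit_mlp <- function(X, y, hidden, lr, max_epochs, patience) {
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  n <- nrow(Xs); p <- ncol(Xs)
  yv <- as.numeric(y)
  W1 <- matrix(rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
  b1 <- numeric(hidden)
  w2 <- matrix(rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
  b2 <- 0
  adam <- function() list(m = 0, v = 0)
  st <- list(W1 = adam(), b1 = adam(), w2 = adam(), b2 = adam())
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- function(s, g, t) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    upd <- lr * (s$m / (1 - beta1^t)) / (sqrt(s$v / (1 - beta2^t)) + eps)
    list(state = s, update = upd)
  }
  best <- Inf; stall <- 0L
  for (t in seq_len(max_epochs)) {
    Z <- sweep(Xs %*% W1, 2, b1, "+")
    A <- pmax(Z, 0)
    logit <- drop(A %*% w2) + b2
    prob <- 1 / (1 + exp(-logit))
    loss <- -mean(yv * log(prob + 1e-12) + (1 - yv) * log(1 - prob + 1e-12))
    if (loss < best - 1e-5) { best <- loss; stall <- 0L } else stall <- stall + 1L
    if (stall >= patience) break
    dl <- matrix((prob - yv) / n, n, 1)
    gw2 <- crossprod(A, dl); gb2 <- sum(dl)
    dA <- dl %*% t(w2)
    dZ <- dA * (Z > 0)
    gW1 <- crossprod(Xs, dZ); gb1 <- colSums(dZ)
    r <- step(st$W1, gW1, t); st$W1 <- r$state; W1 <- W1 - r$update
    r <- step(st$b1, gb1, t); st$b1 <- r$state; b1 <- b1 - r$update
    r <- step(st$w2, gw2, t); st$w2 <- r$state; w2 <- w2 - r$update
    r <- step(st$b2, gb2, t); st$b2 <- r$state; b2 <- b2 - r$update
  }
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2, mu = mu, sg = sg)
}

predict_mlp <- function(m, X) {
  Xs <- sweep(sweep(X, 2, m$mu), 2, m$sg, "/")
  A <- pmax(sweep(Xs %*% m$W1, 2, m$b1, "+"), 0)
  drop(A %*% m$w2) + m$b2 > 0
}

# --- AdaBoost (discrete SAMME) over depth-1 rpart stumps ----------------
fit_adaboost <- function(X, y, n_learners, lr) {
  n <- nrow(X)
  df <- data.frame(.y = factor(y, levels = c(FALSE, TRUE)), X, check.names = FALSE)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, minbucket = 1,
                               cp = -1, xval = 0, maxsurrogate = 0,
                               usesurrogate = 0)
  for (m in seq_len(n_learners)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class") == "TRUE"
    err <- sum(w * (pred != y))
    if (err <= 0) { stumps[[m]] <- fit; alphas[m] <- 10; break }
    if (err >= 0.5) {
      if (m == 1) { stumps[[m]] <- fit; alphas[m] <- 0 }
      break
    }
    alpha <- lr * log((1 - err) / err)
    stumps[[m]] <- fit; alphas[m] <- alpha
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(m, X) {
  df <- data.frame(X, check.names = FALSE)
  score <- numeric(nrow(X))
  for (j in seq_along(m$stumps)) {
    pj <- predict(m$stumps[[j]], df, type = "class") == "TRUE"
    score <- score + m$alphas[j] * ifelse(pj, 1, -1)
  }
  score > 0
}
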