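# Individual learners behind a uniform fit/predict-probability interface.
#
# SVM, random forest and ridge logistic regression are delegated to e1071,
# ranger and glmnet. Multinomial naive Bayes and the single-hidden-layer MLP
# are implemented here: the installed naive Bayes is the Gaussian variant,
# which is the wrong likelihood for sparse TF-IDF counts, and quasi-Newton
# MLP trainers keep a quadratic-in-weights workspace that does not scale to
# wide text features, so the MLP is trained full-batch with Adam.

.POSITIVE <- "cohesion"
.NEGATIVE <- "non_cohesion"
.CLASSIFIER_NAMES <- c("logistic_regression", "mlp", "naive_bayes",
                       "random_forest", "svm")

as_label_factor <- function(y) {
  factor(as.character(y), levels = c(.NEGATIVE, .POSITIVE))
}

# ---- multinomial naive Bayes (Laplace alpha = 1) --------------------------

nb_multinomial_fit <- function(X, y, alpha = 1) {
  y <- as_label_factor(y)
  classes <- levels(y)
  p <- ncol(X)
  log_theta <- matrix(0, 2L, p)
  log_prior <- numeric(2L)
  for (c in 1:2) {
    rows <- which(y == classes[c])
    fs <- Matrix::colSums(X[rows, , drop = FALSE])
    log_theta[c, ] <- log(fs + alpha) - log(sum(fs) + alpha * p)
    log_prior[c] <- log(length(rows) / length(y))
  }
  list(log_theta = log_theta, log_prior = log_prior, classes = classes)
}

nb_multinomial_prob <- function(fit, X) {
  ll <- as.matrix(X %*% t(fit$log_theta))
  ll <- sweep(ll, 2L, fit$log_prior, "+")
  m <- pmax(ll[, 1], ll[, 2])
  e1 <- exp(ll[, 1] - m); e2 <- exp(ll[, 2] - m)
  as.numeric(e2 / (e1 + e2))  # P(positive class)
}

# ---- single-hidden-layer MLP, full-batch Adam -----------------------------

mlp_fit <- function(X, y, hidden = 100L, maxit = 500L, lr = 0.01,
                    decay = 1e-4, tol = 1e-6, seed = 1L) {
  X <- as.matrix(X)
  y01 <- as.numeric(as_label_factor(y) == .POSITIVE)
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  r1 <- sqrt(6 / (p + hidden)); r2 <- sqrt(6 / (hidden + 1))
  par <- list(
    W1 = matrix(stats::runif(p * hidden, -r1, r1), p, hidden),
    b1 = numeric(hidden),
    w2 = stats::runif(hidden, -r2, r2),
    b2 = 0
  )
  m <- lapply(par, function(z) z * 0)
  v <- lapply(par, function(z) z * 0)
  b1t <- 1; b2t <- 1
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  prev_loss <- Inf
  for (it in seq_len(maxit)) {
    A <- sweep(X %*% par$W1, 2L, par$b1, "+")
    Z <- tanh(A)
    s <- as.numeric(Z %*% par$w2) + par$b2
    prob <- 1 / (1 + exp(-s))
    prob_c <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
    loss <- -mean(y01 * log(prob_c) + (1 - y01) * log(1 - prob_c)) +
      decay * (sum(par$W1^2) + sum(par$w2^2)) / 2
    if (abs(prev_loss - loss) < tol * max(1, abs(prev_loss))) break
    prev_loss <- loss
    dout <- (prob - y01) / n
    grad <- list(
      W1 = NULL, b1 = NULL,
      w2 = as.numeric(crossprod(Z, dout)) + decay * par$w2,
      b2 = sum(dout)
    )
    dZ <- outer(dout, par$w2) * (1 - Z^2)
    grad$W1 <- crossprod(X, dZ) + decay * par$W1
    grad$b1 <- colSums(dZ)
    b1t <- b1t * beta1; b2t <- b2t * beta2
    for (k in names(par)) {
      m[[k]] <- beta1 * m[[k]] + (1 - beta1) * grad[[k]]
      v[[k]] <- beta2 * v[[k]] + (1 - beta2) * grad[[k]]^2
      par[[k]] <- par[[k]] - lr * (m[[k]] / (1 - b1t)) /
        (sqrt(v[[k]] / (1 - b2t)) + eps)
    }
  }
  list(par = par, hidden = hidden)
}

mlp_prob <- function(fit, X) {
  X <- as.matrix(X)
  Z <- tanh(sweep(X %*% fit$par$W1, 2L, fit$par$b1, "+"))
  s <- as.numeric(Z %*% fit$par$w2) + fit$par$b2
  1 / (1 + exp(-s))
}

# ---- uniform interface ----------------------------------------------------

fit_learner <- function(name, X, y, seed) {
  y <- as_label_factor(y)
  fit <- switch(
    name,
    logistic_regression = {
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = 1 / nrow(X), standardize = FALSE)
    },
    mlp = mlp_fit(X, y, seed = seed),
    naive_bayes = nb_multinomial_fit(X, y),
    random_forest = ranger::ranger(
      x = as.matrix(X), y = y, probability = TRUE, num.trees = 300L,
      seed = seed, num.threads = 1L
    ),
    svm = {
      set.seed(seed)
      e1071::svm(x = as.matrix(X), y = y, kernel = "linear", cost = 1,
                 probability = TRUE, scale = FALSE)
    },
    stop("unknown classifier: ", name, call. = FALSE)
  )
  structure(list(name = name, fit = fit), class = "osg_learner")
}

# positive-class probability for each row of X
predict_prob <- function(learner, X) {
  stopifnot(inherits(learner, "osg_learner"))
  if (nrow(X) == 0L) return(numeric(0))
  switch(
    learner$name,
    logistic_regression =
      as.numeric(stats::predict(learner$fit, newx = X, type = "response")),
    mlp = mlp_prob(learner$fit, X),
    naive_bayes = nb_multinomial_prob(learner$fit, X),
    random_forest = {
      pr <- stats::predict(learner$fit, data = as.matrix(X),
                           num.threads = 1L)$predictions
      as.numeric(pr[, .POSITIVE])
    },
    svm = {
      pr <- stats::predict(learner$fit, newdata = as.matrix(X),
                           probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, .POSITIVE])
    }
  )
}

# positive-class F1 of predicted vs gold labels
f1_binary <- function(pred, gold, positive = .POSITIVE) {
  tp <- sum(pred == positive & gold == positive)
  fp <- sum(pred == positive & gold != positive)
  fn <- sum(pred != positive & gold == positive)
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}
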