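#' @name train_classifier
#' @title Train one of the eight benchmark classifiers
#'
#' @description
#' Trains a binary classifier on a data.frame of categorical predictors and
#' returns a model object whose [predict()] method yields scores in
#' `[0, 1]`. The eight classifiers of the benchmark are gradient-boosted
#' trees (`"xgboost"`), adaptive boosting of decision stumps (`"adaboost"`),
#' k-nearest neighbors (`"knn"`), logistic regression (`"lr"`), categorical
#' naive Bayes (`"nb"`), random forest (`"rf"`), a linear squared-hinge
#' support-vector machine with CV-tuned cost (`"svm"`), and a single-hidden-
#' layer feed-forward neural network (`"bpnn"`).
#'
#' Several of these are compact in-package implementations (trees, boosting,
#' naive Bayes, SVM, neural network) because no corresponding R package is
#' available in the supported environment; KNN is backed by \pkg{FNN} and
#' logistic regression by \code{stats::glm.fit}. All hyperparameters are
#' frozen defaults (see [classifier_defaults()]); none are taken from the
#' benchmark data beyond the documented CV tuning of the SVM cost.
#'
#' @param name Classifier name (one of [classifier_names()] or a descriptive
#'   alias such as `"gradient-boosted trees"`).
#' @param X Data.frame of categorical predictors.
#' @param y 0/1 outcome (both classes required).
#' @param params Optional list overriding entries of
#'   `classifier_defaults()[[name]]`.
#' @param seed Seed for any stochastic component (bagging, initial weights).
#' @return An object of class `ml_model`.
NULL

#' @rdname train_classifier
#' @export
classifier_names <- function() {
  c("xgboost", "adaboost", "knn", "lr", "nb", "rf", "svm", "bpnn")
}

#' @rdname train_classifier
#' @export
classifier_defaults <- function() {
  list(
    xgboost  = list(rounds = 150, eta = 0.1, max_depth = 2, lambda = 1),
    adaboost = list(rounds = 100),
    knn      = list(k = 5),
    lr       = list(),
    nb       = list(laplace = 1),
    rf       = list(n_trees = 100, max_depth = 6, min_node = 5),
    svm      = list(cost_grid = c(0.01, 0.1, 1, 10), folds = 5),
    bpnn     = list(hidden = 8, decay = 1e-3, maxit = 200)
  )
}

classifier_alias <- c(
  "gradient-boosted trees"      = "xgboost",
  "adaptive boosting"           = "adaboost",
  "k-nearest neighbors"         = "knn",
  "logistic regression"         = "lr",
  "naive bayes"                 = "nb",
  "random forest"               = "rf",
  "support-vector machine"      = "svm",
  "feed-forward neural network" = "bpnn"
)

#' @rdname train_classifier
#' @export
train_classifier <- function(name, X, y, params = NULL, seed = 1) {
  nm <- tolower(name)
  if (nm %in% names(classifier_alias)) nm <- classifier_alias[[nm]]
  if (!nm %in% classifier_names()) {
    stop("unknown classifier name: ", name, call. = FALSE)
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  p <- utils::modifyList(classifier_defaults()[[nm]],
                         if (is.null(params)) list() else params)
  recipe <- onehot_recipe(X)
  M <- apply_onehot(X, recipe)
  set.seed(seed)
  fit <- switch(nm,
    lr   = fit_lr(M, y),
    knn  = list(M = M, y = y, k = p$k),
    nb   = fit_nb(X, y, recipe, p$laplace),
    rf   = fit_rf(M, y, p),
    xgboost  = fit_gbt(M, y, p),
    adaboost = fit_ada(M, y, p),
    svm  = fit_svm(M, y, p),
    bpnn = fit_bpnn(M, y, p)
  )
  structure(list(name = nm, fit = fit, recipe = recipe,
                 features = names(X)), class = "ml_model")
}

#' @rdname train_classifier
#' @param object An `ml_model`.
#' @param newdata Data.frame with the training feature columns.
#' @param ... Unused.
#' @export
predict.ml_model <- function(object, newdata, ...) {
  M <- apply_onehot(newdata[, object$features, drop = FALSE], object$recipe)
  f <- object$fit
  switch(object$name,
    lr   = as.numeric(stats::plogis(cbind(1, M) %*% f$beta)),
    knn  = {
      nn <- FNN::get.knnx(f$M, M, k = f$k)$nn.index
      rowMeans(matrix(f$y[nn], nrow = nrow(M)))
    },
    nb   = predict_nb(f, newdata[, object$features, drop = FALSE]),
    rf   = {
      preds <- vapply(f$trees, function(tr) predict_tree(tr, M),
                      numeric(nrow(M)))
      rowMeans(matrix(preds, nrow = nrow(M)))
    },
    xgboost = {
      s <- rep(f$base, nrow(M))
      for (tr in f$trees) s <- s + f$eta * predict_tree(tr, M)
      as.numeric(stats::plogis(s))
    },
    adaboost = {
      s <- numeric(nrow(M))
      for (st in f$stumps) {
        h <- ifelse(M[, st$j] == 1, st$polarity, -st$polarity)
        s <- s + st$alpha * h
      }
      as.numeric(stats::plogis(2 * s))
    },
    svm  = {
      dec <- as.numeric(M %*% f$w + f$b)
      as.numeric(stats::plogis(f$platt[1] + f$platt[2] * dec))
    },
    bpnn = predict_bpnn(f, M)
  )
}

#' @export
print.ml_model <- function(x, ...) {
  cat("ml_model:", x$name, "on", length(x$features), "factor(s)\n")
  invisible(x)
}

## ---- one-hot encoding --------------------------------------------------

onehot_recipe <- function(X) {
  lapply(X, function(col) levels(droplevels(factor(col))))
}

apply_onehot <- function(X, recipe) {
  cols <- list()
  for (nm in names(recipe)) {
    v <- as.character(X[[nm]])
    for (lev in recipe[[nm]]) {
      cols[[paste0(nm, "=", lev)]] <- as.numeric(v == lev)
    }
  }
  do.call(cbind, cols)
}

## ---- logistic regression ----------------------------------------------

fit_lr <- function(M, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, M), y, family = stats::binomial()))
  list(beta = ifelse(is.na(fit$coefficients), 0, fit$coefficients))
}

## ---- categorical naive Bayes ------------------------------------------

fit_nb <- function(X, y, recipe, laplace) {
  prior <- c(p0 = mean(y == 0), p1 = mean(y == 1))
  tabs <- lapply(names(recipe), function(nm) {
    lev <- recipe[[nm]]
    v <- factor(as.character(X[[nm]]), levels = lev)
    t0 <- table(v[y == 0]) + laplace
    t1 <- table(v[y == 1]) + laplace
    cbind(p0 = as.numeric(t0 / sum(t0)), p1 = as.numeric(t1 / sum(t1)))
  })
  names(tabs) <- names(recipe)
  list(prior = prior, tabs = tabs, recipe = recipe)
}

predict_nb <- function(f, X) {
  l0 <- rep(log(f$prior["p0"]), nrow(X))
  l1 <- rep(log(f$prior["p1"]), nrow(X))
  for (nm in names(f$tabs)) {
    lev <- f$recipe[[nm]]
    idx <- match(as.character(X[[nm]]), lev)
    # unseen level: uniform contribution (cancels out)
    known <- !is.na(idx)
    l0[known] <- l0[known] + log(f$tabs[[nm]][idx[known], "p0"])
    l1[known] <- l1[known] + log(f$tabs[[nm]][idx[known], "p1"])
  }
  1 / (1 + exp(l0 - l1))
}

## ---- CART on binary (one-hot) features ---------------------------------
# Nodes are lists: leaf -> list(value); split -> list(j, left, right) where
# left is the x[, j] == 0 branch. `type` selects the split criterion:
# "gini" (classification on 0/1 target) or "xgb" (second-order gain on
# gradient/hessian pairs with L2 leaf regularization lambda).

fit_cart <- function(M, target, h = NULL, depth, min_node, mtry,
                     type = c("gini", "xgb"), lambda = 1) {
  type <- match.arg(type)
  grow <- function(rows, d) {
    nr <- length(rows)
    leaf_value <- if (type == "gini") mean(target[rows])
      else -sum(target[rows]) / (sum(h[rows]) + lambda)
    if (d >= depth || nr < 2 * min_node) return(list(value = leaf_value))
    js <- if (mtry < ncol(M)) sample.int(ncol(M), mtry) else seq_len(ncol(M))
    Msub <- M[rows, js, drop = FALSE]
    n1 <- colSums(Msub)
    ok <- n1 >= min_node & (nr - n1) >= min_node
    if (!any(ok)) return(list(value = leaf_value))
    if (type == "gini") {
      s1 <- colSums(Msub * target[rows])
      s0 <- sum(target[rows]) - s1
      n0 <- nr - n1
      gini <- function(s, n) ifelse(n > 0, s * (1 - s / n), 0)
      score <- gini(s1, n1) + gini(s0, n0)       # lower is better
      score[!ok] <- Inf
      jbest <- which.min(score)
      base <- gini(sum(target[rows]), nr)
      if (score[jbest] >= base - 1e-12) return(list(value = leaf_value))
    } else {
      G1 <- colSums(Msub * target[rows]); H1 <- colSums(Msub * h[rows])
      G <- sum(target[rows]); H <- sum(h[rows])
      gain <- G1^2 / (H1 + lambda) + (G - G1)^2 / (H - H1 + lambda) -
        G^2 / (H + lambda)
      gain[!ok] <- -Inf
      jbest <- which.max(gain)
      if (gain[jbest] <= 1e-12) return(list(value = leaf_value))
    }
    j <- js[jbest]
    go_right <- M[rows, j] == 1
    list(j = j,
         left = grow(rows[!go_right], d + 1L),
         right = grow(rows[go_right], d + 1L))
  }
  grow(seq_len(nrow(M)), 0L)
}

predict_tree <- function(node, M) {
  out <- numeric(nrow(M))
  walk <- function(nd, rows) {
    if (!length(rows)) return(invisible())
    if (!is.null(nd$value)) { out[rows] <<- nd$value; return(invisible()) }
    right <- M[rows, nd$j] == 1
    walk(nd$left, rows[!right])
    walk(nd$right, rows[right])
  }
  walk(node, seq_len(nrow(M)))
  out
}

## ---- random forest ------------------------------------------------------

fit_rf <- function(M, y, p) {
  n <- nrow(M)
  mtry <- max(1L, floor(sqrt(ncol(M))))
  trees <- lapply(seq_len(p$n_trees), function(t) {
    idx <- sample.int(n, n, replace = TRUE)
    fit_cart(M[idx, , drop = FALSE], y[idx], depth = p$max_depth,
             min_node = p$min_node, mtry = mtry, type = "gini")
  })
  list(trees = trees)
}

## ---- gradient-boosted trees (logistic loss, second-order) ---------------

fit_gbt <- function(M, y, p) {
  base <- stats::qlogis(mean(y) * 0.998 + 0.001)
  s <- rep(base, nrow(M))
  trees <- vector("list", p$rounds)
  for (r in seq_len(p$rounds)) {
    prob <- stats::plogis(s)
    g <- prob - y
    hh <- pmax(prob * (1 - prob), 1e-6)
    tr <- fit_cart(M, g, h = hh, depth = p$max_depth, min_node = 1,
                   mtry = ncol(M), type = "xgb", lambda = p$lambda)
    trees[[r]] <- tr
    s <- s + p$eta * predict_tree(tr, M)
  }
  list(trees = trees, base = base, eta = p$eta)
}

## ---- AdaBoost with decision stumps --------------------------------------

fit_ada <- function(M, y, p) {
  yy <- 2 * y - 1
  n <- nrow(M)
  w <- rep(1 / n, n)
  stumps <- list()
  for (r in seq_len(p$rounds)) {
    wpos <- w * (yy == 1)
    wneg <- w * (yy == -1)
    a <- as.numeric(crossprod(M, wpos))   # x=1, y=+1
    b <- as.numeric(crossprod(M, wneg))   # x=1, y=-1
    cpos <- sum(wpos) - a                 # x=0, y=+1
    d <- sum(wneg) - b                    # x=0, y=-1
    err_plus <- b + cpos      # predict +1 when x=1
    err_minus <- a + d        # predict +1 when x=0
    jp <- which.min(err_plus); jm <- which.min(err_minus)
    if (err_plus[jp] <= err_minus[jm]) {
      j <- jp; pol <- 1; err <- err_plus[jp]
    } else {
      j <- jm; pol <- -1; err <- err_minus[jm]
    }
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    hvec <- ifelse(M[, j] == 1, pol, -pol)
    stumps[[length(stumps) + 1L]] <- list(j = j, polarity = pol,
                                          alpha = alpha)
    w <- w * exp(-alpha * hvec * yy)
    w <- w / sum(w)
  }
  list(stumps = stumps)
}

## ---- linear squared-hinge SVM with Platt scaling ------------------------

fit_svm <- function(M, y, p) {
  yy <- 2 * y - 1
  train_one <- function(Mtr, yytr, cost) {
    pdim <- ncol(Mtr)
    obj <- function(th) {
      w <- th[-1]; b <- th[1]
      m <- 1 - yytr * (Mtr %*% w + b)
      0.5 * sum(w^2) + cost * sum(pmax(m, 0)^2)
    }
    grd <- function(th) {
      w <- th[-1]; b <- th[1]
      m <- as.numeric(1 - yytr * (Mtr %*% w + b))
      act <- m > 0
      gm <- -2 * cost * (m * yytr) * act
      c(sum(gm), w + as.numeric(crossprod(Mtr, gm)))
    }
    res <- stats::optim(rep(0, pdim + 1), obj, grd, method = "BFGS",
                        control = list(maxit = 200))
    list(b = res$par[1], w = res$par[-1])
  }
  cost <- p$cost_grid[1]
  if (length(p$cost_grid) > 1) {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(p$folds), length(idx)))
    }
    cv_auc <- vapply(p$cost_grid, function(cc) {
      sc <- numeric(length(y))
      for (f in seq_len(p$folds)) {
        tr <- fold != f
        m <- train_one(M[tr, , drop = FALSE], yy[tr], cc)
        sc[!tr] <- M[!tr, , drop = FALSE] %*% m$w + m$b
      }
      auc_rank(sc, y)
    }, 0)
    cost <- p$cost_grid[which.max(cv_auc)]
  }
  m <- train_one(M, yy, cost)
  dec <- as.numeric(M %*% m$w + m$b)
  platt <- tryCatch({
    pf <- suppressWarnings(stats::glm.fit(cbind(1, dec), y,
                                          family = stats::binomial()))
    co <- pf$coefficients
    if (any(is.na(co))) c(0, 1) else co
  }, error = function(e) c(0, 1))
  list(w = m$w, b = m$b, cost = cost, platt = platt)
}

## ---- single-hidden-layer neural network ---------------------------------

fit_bpnn <- function(M, y, p) {
  pdim <- ncol(M); h <- p$hidden
  npar <- pdim * h + h + h + 1
  unpack <- function(th) {
    W1 <- matrix(th[seq_len(pdim * h)], pdim, h)
    b1 <- th[pdim * h + seq_len(h)]
    W2 <- th[pdim * h + h + seq_len(h)]
    b2 <- th[npar]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  obj <- function(th) {
    pr <- unpack(th)
    Z <- tanh(sweep(M %*% pr$W1, 2, pr$b1, "+"))
    f <- as.numeric(Z %*% pr$W2 + pr$b2)
    pp <- stats::plogis(f)
    eps <- 1e-12
    -sum(y * log(pp + eps) + (1 - y) * log(1 - pp + eps)) +
      p$decay * (sum(pr$W1^2) + sum(pr$W2^2))
  }
  grd <- function(th) {
    pr <- unpack(th)
    A <- sweep(M %*% pr$W1, 2, pr$b1, "+")
    Z <- tanh(A)
    f <- as.numeric(Z %*% pr$W2 + pr$b2)
    delta <- stats::plogis(f) - y                 # d(negLL)/df
    gW2 <- as.numeric(crossprod(Z, delta)) + 2 * p$decay * pr$W2
    gb2 <- sum(delta)
    dZ <- outer(delta, pr$W2) * (1 - Z^2)
    gW1 <- crossprod(M, dZ) + 2 * p$decay * pr$W1
    gb1 <- colSums(dZ)
    c(as.numeric(gW1), gb1, gW2, gb2)
  }
  th0 <- stats::rnorm(npar, 0, 0.3)
  res <- stats::optim(th0, obj, grd, method = "BFGS",
                      control = list(maxit = p$maxit))
  c(unpack(res$par), list(hidden = h))
}

predict_bpnn <- function(f, M) {
  Z <- tanh(sweep(M %*% f$W1, 2, f$b1, "+"))
  as.numeric(stats::plogis(Z %*% f$W2 + f$b2))
}
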