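# Suitability learners behind a single pluggable contract:
#   fit(env, y, weights)  -> opaque fit object
#   predict(fit, env)     -> continuous suitability in [0, 1]
# Members violating the contract (predictions outside [0, 1]) are
# rejected at fitting time.
#
# The shipped set spans the families commonly combined in ensemble
# niche modelling: a quadratic logistic GLM, a spline-basis GAM
# (mgcv), a ridge-regularised logistic model (glmnet), a Gaussian
# class-conditional density-ratio model (a Maxent-flavoured
# presence/background contrast) and gradient-boosted decision stumps
# (a boosted-regression-tree analogue, implemented here because no
# boosting package is available in the supported dependency set).

#' Define a suitability learner
#'
#' @param name learner identifier.
#' @param fit function `(env, y, weights)` returning a fit object.
#' @param predict function `(fit, env)` returning suitabilities in
#'   `[0, 1]`.
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "learner_spec")
}

quad_formula <- function(vars) {
  stats::as.formula(paste(
    "y ~", paste(c(vars, sprintf("I(%s^2)", vars)), collapse = " + ")))
}

learner_glm <- function() {
  learner_spec(
    "glm",
    fit = function(env, y, weights) {
      d <- cbind(env, y = y)
      d$.w <- weights   # looked up in `data`, not the formula env
      # quasibinomial: identical fit, silences non-integer-weight warnings
      stats::glm(quad_formula(names(env)), data = d,
                 family = stats::quasibinomial(), weights = .w)
    },
    predict = function(fit, env)
      as.numeric(stats::predict(fit, newdata = env, type = "response")))
}

learner_gam <- function(k = 4) {
  learner_spec(
    "gam",
    fit = function(env, y, weights) {
      d <- cbind(env, y = y)
      d$.w <- weights
      form <- stats::as.formula(paste(
        "y ~", paste(sprintf("s(%s, k = %d)", names(env), k),
                     collapse = " + ")))
      mgcv::gam(form, data = d, family = stats::quasibinomial(),
                weights = .w)
    },
    predict = function(fit, env)
      as.numeric(stats::predict(fit, newdata = env, type = "response")))
}

learner_glmnet <- function(alpha = 0, nfolds = 5) {
  learner_spec(
    "glmnet",
    fit = function(env, y, weights) {
      x <- as_num_matrix(env)
      cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                              weights = weights, nfolds = nfolds)
      list(cv = cv, vars = colnames(x))
    },
    predict = function(fit, env) {
      x <- as_num_matrix(env[, fit$vars, drop = FALSE])
      as.numeric(stats::predict(fit$cv, newx = x, s = "lambda.min",
                                type = "response"))
    })
}

# Gaussian class-conditional density ratio with neutral prevalence:
# suitability = f(presence) / (f(presence) + f(background)).
learner_densratio <- function() {
  wstats <- function(x, w) {
    mu <- sum(w * x) / sum(w)
    v <- sum(w * (x - mu)^2) / sum(w)
    c(mu, sqrt(max(v, 1e-12)))
  }
  learner_spec(
    "densratio",
    fit = function(env, y, weights) {
      x <- as_num_matrix(env)
      p1 <- apply(x[y == 1, , drop = FALSE], 2, wstats,
                  w = weights[y == 1])
      p0 <- apply(x[y == 0, , drop = FALSE], 2, wstats,
                  w = weights[y == 0])
      list(p1 = p1, p0 = p0, vars = colnames(x))
    },
    predict = function(fit, env) {
      x <- as_num_matrix(env[, fit$vars, drop = FALSE])
      ll <- function(par) {
        s <- 0
        for (j in seq_len(ncol(x)))
          s <- s + stats::dnorm(x[, j], par[1, j], par[2, j], log = TRUE)
        s
      }
      d1 <- ll(fit$p1); d0 <- ll(fit$p0)
      1 / (1 + exp(d0 - d1))
    })
}

# Gradient-boosted stumps for the logistic loss.
brt_fit_stumps <- function(x, y, w, n_trees, shrinkage, n_splits) {
  n <- nrow(x); k <- ncol(x)
  w <- w / sum(w)
  splits <- lapply(seq_len(k), function(j)
    unique(stats::quantile(x[, j], probs = seq(0.05, 0.95,
                                               length.out = n_splits),
                           names = FALSE)))
  p0 <- sum(w * y)
  f0 <- stats::qlogis(min(max(p0, 1e-6), 1 - 1e-6))
  f <- rep(f0, n)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    p <- stats::plogis(f)
    r <- y - p
    best <- NULL; best_sse <- Inf
    for (j in seq_len(k)) {
      for (s in splits[[j]]) {
        left <- x[, j] <= s
        wl <- sum(w[left]); wr <- sum(w[!left])
        if (wl < 1e-9 || wr < 1e-9) next
        ml <- sum(w[left] * r[left]) / wl
        mr <- sum(w[!left] * r[!left]) / wr
        sse <- sum(w * (r - ifelse(left, ml, mr))^2)
        if (sse < best_sse) {
          best_sse <- sse
          best <- list(var = j, split = s, left = ml, right = mr)
        }
      }
    }
    if (is.null(best)) break
    pred <- ifelse(x[, best$var] <= best$split, best$left, best$right)
    f <- f + shrinkage * pred
    trees[[t]] <- best
  }
  list(f0 = f0, trees = Filter(Negate(is.null), trees),
       shrinkage = shrinkage)
}

brt_predict_stumps <- function(fit, x) {
  f <- rep(fit$f0, nrow(x))
  for (tr in fit$trees)
    f <- f + fit$shrinkage *
      ifelse(x[, tr$var] <= tr$split, tr$left, tr$right)
  stats::plogis(f)
}

learner_brt <- function(n_trees = 60, shrinkage = 0.1, n_splits = 12) {
  learner_spec(
    "brt",
    fit = function(env, y, weights) {
      x <- as_num_matrix(env)
      list(fit = brt_fit_stumps(x, y, weights, n_trees, shrinkage,
                                n_splits),
           vars = colnames(x))
    },
    predict = function(fit, env)
      brt_predict_stumps(fit$fit,
                         as_num_matrix(env[, fit$vars, drop = FALSE])))
}

#' The default suitability learner set
#'
#' @return named list of [learner_spec()] objects: `glm`, `gam`,
#'   `glmnet`, `densratio`, `brt`.
#' @export
default_learners <- function() {
  l <- list(learner_glm(), learner_gam(), learner_glmnet(),
            learner_densratio(), learner_brt())
  names(l) <- vapply(l, `[[`, character(1), "name")
  l
}
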