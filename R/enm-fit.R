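# Fitting, evaluating, ensembling and projecting suitability models.

#' AUC and maximised TSS of continuous suitability scores
#'
#' AUC is the rank (Mann-Whitney) statistic over presence vs
#' pseudo-absence scores; ties contribute one half.  TSS
#' (sensitivity + specificity - 1) is maximised over all candidate
#' thresholds (the unique scores plus the extremes) and the maximising
#' threshold is reported.  The AUC band follows the conventional
#' interpretation scale: > 0.9 excellent, > 0.8 good, > 0.7 fair,
#' > 0.6 poor, > 0.5 fail, otherwise no better than random.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 presence labels (both classes required).
#' @return object of class `eval_scores`: `auc`, `tss`,
#'   `tss_threshold`, `auc_band`, `sensitivity`, `specificity`.
#' @export
eval_scores <- function(scores, labels) {
  y <- as.integer(labels)
  stop_if(length(unique(y)) < 2, "evaluation dataset has a single class")
  stop_if(length(scores) != length(y), "scores/labels length mismatch")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # sweep thresholds via the sorted-score representation
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord] == 1)
  fp <- cumsum(y[ord] == 0)
  sens <- tp / n1
  spec <- 1 - fp / n0
  tssv <- sens + spec - 1
  # valid cut points: after the last of each tied score block
  s_sorted <- scores[ord]
  last_of_block <- c(s_sorted[-length(s_sorted)] != s_sorted[-1], TRUE)
  cand <- which(last_of_block)
  best <- cand[which.max(tssv[cand])]
  tss <- tssv[best]
  if (tss < 0) {  # predicting nothing can never be beaten below 0
    tss <- 0
    thr <- Inf; se <- 0; sp <- 1
  } else {
    thr <- s_sorted[best]; se <- sens[best]; sp <- spec[best]
  }
  band <- if (auc > 0.9) "excellent" else if (auc > 0.8) "good"
          else if (auc > 0.7) "fair" else if (auc > 0.6) "poor"
          else if (auc > 0.5) "fail" else "no-better-than-random"
  structure(list(auc = auc, tss = tss, tss_threshold = thr,
                 sensitivity = se, specificity = sp, auc_band = band),
            class = "eval_scores")
}

#' @exportS3Method base::print
print.eval_scores <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%s); TSS = %.3f at threshold %.3g\n",
              x$auc, x$auc_band, x$tss, x$tss_threshold))
  invisible(x)
}

predict_suitability <- function(model, env) {
  if (inherits(model, "ensemble_model")) {
    preds <- vapply(model$members,
                    function(m) m$spec$predict(m$fit, env),
                    numeric(nrow(env)))
    if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
    as.numeric(preds %*% model$weights / sum(model$weights))
  } else if (inherits(model, "suit_model")) {
    model$spec$predict(model$fit, env)
  } else stop("not a suitability model or ensemble", call. = FALSE)
}

#' Evaluate a model or ensemble on a presence/pseudo-absence dataset
#'
#' @param model a fitted member (`suit_model`) or [build_ensemble()]
#'   ensemble.
#' @param pa a [make_pa_dataset()] (both classes required).
#' @return an [eval_scores()] object.
#' @export
evaluate_model <- function(model, pa) {
  stopifnot(inherits(pa, "pa_dataset"))
  eval_scores(predict_suitability(model, pa$env), pa$y)
}

#' Fit the member models of an ensemble
#'
#' Fits every learner on every inner train slice of the split plan
#' (one member per learner x repeat), applies the prevalence-balanced
#' case weights, scores each member on its inner test slice, and
#' rejects members whose predictions leave `[0, 1]` or whose fit
#' fails; failures are logged, not fatal, provided at least one member
#' survives.
#'
#' @param pa a [make_pa_dataset()].
#' @param plan a [split_dataset()] plan for `pa`.
#' @param learners list of [learner_spec()]s (default
#'   [default_learners()]).
#' @param seed RNG seed (member fits get derived sub-seeds).
#' @return object of class `member_set`: list `members` of
#'   `suit_model`s (each with `spec`, `fit`, `repeat_id`, `scores` on
#'   the inner test), plus a character `log` of rejections.
#' @export
fit_members <- function(pa, plan, learners = default_learners(),
                        seed = NULL) {
  stopifnot(inherits(pa, "pa_dataset"), inherits(plan, "split_plan"))
  stop_if(length(learners) < 1, "need at least one learner")
  members <- list(); log <- character(0)
  for (r in seq_along(plan$repeats)) {
    tr <- pa_subset(pa, plan$repeats[[r]]$train)
    te <- pa_subset(pa, plan$repeats[[r]]$test)
    for (ls in learners) {
      tag <- sprintf("%s/rep%d", ls$name, r)
      res <- try(with_seed(
        if (is.null(seed)) NULL else derive_seed(seed + 131 * r, "enm"),
        {
          fit <- ls$fit(tr$env, tr$y, tr$weights)
          pred <- ls$predict(fit, te$env)
          if (any(!is.finite(pred)) || any(pred < 0) || any(pred > 1))
            stop("predictions outside [0, 1]")
          list(fit = fit, scores = eval_scores(pred, te$y))
        }), silent = TRUE)
      if (inherits(res, "try-error")) {
        log <- c(log, sprintf("rejected %s: %s", tag,
                              trimws(attr(res, "condition")$message %||%
                                       as.character(res))))
      } else {
        members[[length(members) + 1L]] <-
          structure(list(spec = ls, fit = res$fit, repeat_id = r,
                         scores = res$scores, tag = tag),
                    class = "suit_model")
      }
    }
  }
  stop_if(length(members) == 0,
          paste("all member fits failed:", paste(log, collapse = "; ")))
  if (length(log)) warning(length(log), " member(s) rejected; see $log")
  structure(list(members = members, log = log,
                 range_label = pa$range_label),
            class = "member_set")
}

#' @exportS3Method base::print
print.member_set <- function(x, ...) {
  tss <- vapply(x$members, function(m) m$scores$tss, numeric(1))
  cat(sprintf("member_set (%s): %d members, inner-test TSS %.2f-%.2f\n",
              x$range_label, length(x$members), min(tss), max(tss)))
  if (length(x$log)) cat("  rejections:", length(x$log), "\n")
  invisible(x)
}

#' Build a TSS-weighted ensemble from fitted members
#'
#' The ensemble prediction is \eqn{\sum_i w_i p_i / \sum_i w_i} with
#' \eqn{w_i = \max(TSS_i, 0)}: better-performing members contribute
#' more, members no better than random contribute nothing.
#'
#' @param member_set a [fit_members()] result.
#' @return object of class `ensemble_model`.
#' @export
build_ensemble <- function(member_set) {
  stopifnot(inherits(member_set, "member_set"))
  w <- vapply(member_set$members, function(m) max(m$scores$tss, 0),
              numeric(1))
  stop_if(all(w <= 0), "no member with positive TSS")
  structure(list(members = member_set$members, weights = w,
                 weighting = "max(TSS, 0)",
                 range_label = member_set$range_label),
            class = "ensemble_model")
}

#' @exportS3Method base::print
print.ensemble_model <- function(x, ...) {
  cat(sprintf("TSS-weighted ensemble (%s): %d members, %d with weight > 0\n",
              x$range_label, length(x$members), sum(x$weights > 0)))
  invisible(x)
}

#' Project a model or ensemble onto an environmental raster stack
#'
#' @param model `suit_model` or `ensemble_model`.
#' @param stack an [env_stack()] carrying all model variables.
#' @return suitability matrix with the stack's dimensions; cells with
#'   any missing layer value stay `NA`.
#' @export
project_suitability <- function(model, stack) {
  stopifnot(inherits(stack, "env_stack"))
  df <- stack_as_df(stack)
  ok <- stats::complete.cases(df)
  out <- rep(NA_real_, nrow(df))
  if (any(ok))
    out[ok] <- predict_suitability(model, df[ok, , drop = FALSE])
  matrix(out, stack$nrow, stack$ncol)
}

#' Clamping (extrapolation) masks for a model transfer
#'
#' A target cell/point is clamped for a variable when its value falls
#' outside the closed calibration interval `[min, max]` of that
#' variable in the training data; predictions there are extrapolations
#' and therefore uncertain.
#'
#' @param training_env data frame of calibration environmental values.
#' @param target_env data frame or [env_stack()] of projection values
#'   (must carry all training variables).
#' @return list with `per_variable` (logical matrix or data frame of
#'   clamped indicators), `combined` (union over variables),
#'   `fractions` (per-variable clamped fractions) and
#'   `fraction_combined`.
#' @export
clamping_mask <- function(training_env, target_env) {
  tr <- as.data.frame(training_env)
  is_stack <- inherits(target_env, "env_stack")
  tg <- if (is_stack) stack_as_df(target_env) else as.data.frame(target_env)
  missing <- setdiff(names(tr), names(tg))
  stop_if(length(missing) > 0,
          "target lacks variables: ", paste(missing, collapse = ", "))
  per <- lapply(names(tr), function(v)
    tg[[v]] < min(tr[[v]]) | tg[[v]] > max(tr[[v]]))
  names(per) <- names(tr)
  pm <- do.call(cbind, per)
  comb <- rowSums(pm, na.rm = TRUE) > 0
  fr <- colMeans(pm, na.rm = TRUE)
  if (is_stack) {
    comb <- matrix(comb, target_env$nrow, target_env$ncol)
    per <- lapply(per, matrix, nrow = target_env$nrow,
                  ncol = target_env$ncol)
  }
  list(per_variable = per, combined = comb, fractions = fr,
       fraction_combined = mean(comb, na.rm = TRUE))
}
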