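# Sparse partial least squares discriminant analysis (sPLS-DA), implemented
# from first principles: per component the dominant singular pair of the
# deflated X'Y cross-product is found by power iteration, the x-weight
# vector is soft-thresholded to keep the keepX largest-magnitude entries and
# renormalized, and X (and Y) are deflated by regression on the component
# score. Prediction is by maximum indicator value ("max.dist"). Tuning
# follows the two-stage protocol: the number of components is selected first
# by leave-one-out accuracy on dense fits, then keepX is grid-searched
# component by component.

# keep the `keep` largest-|u| entries, soft-shrunk by the largest discarded
# magnitude (ties broken by order, so the non-zero count never exceeds keep)
.soft_keep <- function(u, keep) {
  p <- length(u)
  if (keep >= p) return(u)
  ord <- order(abs(u), decreasing = TRUE)
  drop <- ord[(keep + 1L):p]
  lambda <- max(abs(u[drop]))
  out <- sign(u) * pmax(abs(u) - lambda, 0)
  out[drop] <- 0
  out
}

# core NIPALS-style sPLS2 on a pre-centered/scaled X and centered Y
.fit_core <- function(Xs, Yc, ncomp, keepX, tol = 1e-9, max_iter = 500L) {
  p <- ncol(Xs); q <- ncol(Yc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, q, ncomp); TT <- matrix(0, nrow(Xs), ncomp)
  ssy <- numeric(ncomp)
  Xh <- Xs; Yh <- Yc
  h_eff <- 0L
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Yh)                    # p x q
    if (max(abs(M)) < 1e-12) break
    v <- colSums(M * M)
    v <- if (all(v == 0)) rep(1 / sqrt(q), q) else v / sqrt(sum(v^2))
    u <- numeric(p)
    for (it in seq_len(max_iter)) {
      u_new <- .soft_keep(drop(M %*% v), keepX[h])
      nu <- sqrt(sum(u_new^2))
      if (nu == 0) { u_new <- drop(M %*% v); nu <- sqrt(sum(u_new^2)) }
      u_new <- u_new / nu
      v_new <- drop(crossprod(M, u_new))
      v_new <- v_new / sqrt(sum(v_new^2))
      if (sum((u_new - u)^2) < tol^2) { u <- u_new; v <- v_new; break }
      u <- u_new; v <- v_new
    }
    if (u[which.max(abs(u))] < 0) u <- -u    # reproducible sign
    t_h <- drop(Xh %*% u)
    nt <- sum(t_h^2)
    if (nt < 1e-12) break
    c_h <- drop(crossprod(Yh, t_h)) / nt
    p_h <- drop(crossprod(Xh, t_h)) / nt
    Xh <- Xh - tcrossprod(t_h, p_h)
    Yh <- Yh - tcrossprod(t_h, c_h)
    W[, h] <- u; P[, h] <- p_h; C[, h] <- c_h; TT[, h] <- t_h
    ssy[h] <- nt * sum(c_h^2)
    h_eff <- h
  }
  list(W = W[, seq_len(h_eff), drop = FALSE],
       P = P[, seq_len(h_eff), drop = FALSE],
       C = C[, seq_len(h_eff), drop = FALSE],
       scores = TT[, seq_len(h_eff), drop = FALSE],
       ssy = ssy[seq_len(h_eff)], ncomp = h_eff)
}

#' Fit a sparse PLS-DA model
#'
#' @param X sample x feature matrix (library-size-normalized counts; columns
#'   must be named). Zero-variance features are dropped with a warning.
#' @param y class labels (2 or more classes).
#' @param ncomp number of components.
#' @param keepX integer vector (recycled to `ncomp`) of non-zero x-weights
#'   per component; `Inf`/`NULL` keeps all features (dense PLS-DA). Values
#'   above the feature count are clipped with a warning.
#' @param scale unit-variance scale X columns (default TRUE; X is always
#'   centered).
#' @return object of class `splsda_model`.
#' @export
fit_splsda <- function(X, y, ncomp = 2L, keepX = NULL, scale = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stopf("X must have feature (column) names")
  y <- as.factor(y)
  if (nlevels(y) < 2L) stopf("need at least two classes")
  if (nrow(X) < 4L) stopf("need at least 4 samples")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    warnf("dropping %d zero-variance feature(s)", sum(sds == 0))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  p <- ncol(X)
  if (is.null(keepX)) keepX <- rep(p, ncomp)
  keepX[!is.finite(keepX)] <- p
  keepX <- as.integer(rep_len(keepX, ncomp))
  if (any(keepX > p)) {
    warnf("keepX clipped to the feature count (%d)", p)
    keepX[keepX > p] <- p
  }
  ctr <- colMeans(X)
  scl <- if (scale) sds else rep(1, p)
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  ym <- colMeans(Y)
  core <- .fit_core(Xs, sweep(Y, 2L, ym), ncomp, keepX)
  rownames(core$W) <- rownames(core$P) <- colnames(Xs)
  rownames(core$C) <- levels(y)
  structure(c(core, list(features = colnames(Xs), center = ctr, scale = scl,
                         y_means = ym, levels = levels(y), y = y,
                         keepX = keepX[seq_len(core$ncomp)],
                         selected = apply(core$W, 2L, function(w)
                           colnames(Xs)[w != 0], simplify = FALSE))),
            class = "splsda_model")
}

#' @export
print.splsda_model <- function(x, ...) {
  cat(sprintf("<splsda_model> %d comps, %d features, classes: %s; keepX: %s\n",
              x$ncomp, length(x$features), paste(x$levels, collapse = "/"),
              paste(x$keepX, collapse = ",")))
  invisible(x)
}

#' Predict classes from a sparse PLS-DA model
#'
#' Projects new samples onto the model scores and predicts the
#' class-indicator values; the class with the maximum predicted indicator
#' wins ("max.dist"). Continuous per-class values are returned for ROC
#' analysis.
#'
#' @param object an `splsda_model`.
#' @param newdata sample x feature matrix; must contain all model features
#'   (by name; order free).
#' @param ncomp use only the first `ncomp` components (default: all).
#' @param ... unused.
#' @return list: `class` (labels), `scores` (component scores),
#'   `predicted` (per-class continuous values).
#' @export
predict.splsda_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss))
    stopf("newdata lacks model feature(s): %s",
          paste(head(miss, 5L), collapse = ", "))
  ncomp <- min(ncomp, object$ncomp)
  Xs <- sweep(sweep(newdata[, object$features, drop = FALSE], 2L,
                    object$center), 2L, object$scale, "/")
  W <- object$W[, seq_len(ncomp), drop = FALSE]
  P <- object$P[, seq_len(ncomp), drop = FALSE]
  C <- object$C[, seq_len(ncomp), drop = FALSE]
  # scores via sequential deflation-consistent projection W (P'W)^-1
  Wstar <- W %*% solve(crossprod(P, W))
  TTnew <- Xs %*% Wstar
  pred <- TTnew %*% t(C)
  pred <- sweep(pred, 2L, object$y_means, "+")
  colnames(pred) <- object$levels
  cls <- object$levels[max.col(pred, ties.method = "first")]
  list(class = cls, scores = TTnew, predicted = pred)
}

#' VIP (variable importance in projection) scores
#'
#' VIP_j = sqrt(p * sum_h SS_h w_jh^2 / sum_h SS_h), with SS_h the variance
#' of the class indicators explained by component h. For dense fits
#' mean(VIP^2) = 1.
#'
#' @param model an `splsda_model`.
#' @return data.frame `feature`, `vip`, sorted descending.
#' @export
vip <- function(model) {
  stopifnot(is(model, "splsda_model"))
  w2 <- model$W^2
  num <- drop(w2 %*% model$ssy)
  v <- sqrt(length(model$features) * num / sum(model$ssy))
  out <- data.frame(feature = model$features, vip = v,
                    stringsAsFactors = FALSE)
  out[order(-out$vip), ]
}

# leave-one-out accuracy of one (ncomp, keepX) configuration; returns the
# pooled predictions as well
.loo_eval <- function(X, y, ncomp, keepX, scale = TRUE, max_ncomp = ncomp) {
  n <- nrow(X)
  y <- as.factor(y)
  pred_class <- matrix(NA_character_, n, max_ncomp)
  pred_val <- array(NA_real_, c(n, nlevels(y), max_ncomp),
                    dimnames = list(NULL, levels(y), NULL))
  skipped <- 0L
  for (i in seq_len(n)) {
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < nlevels(y)) {
      warnf("LOO fold %d lost a class; skipped", i)
      skipped <- skipped + 1L
      next
    }
    fit <- suppressWarnings(fit_splsda(X[-i, , drop = FALSE], y[-i],
                                       ncomp = ncomp, keepX = keepX,
                                       scale = scale))
    for (h in seq_len(min(max_ncomp, fit$ncomp))) {
      pr <- predict(fit, X[i, , drop = FALSE], ncomp = h)
      pred_class[i, h] <- pr$class
      pred_val[i, , h] <- pr$predicted
    }
    if (fit$ncomp < max_ncomp) {  # carry the deepest model forward
      for (h in seq(fit$ncomp + 1L, max_ncomp)) {
        pred_class[i, h] <- pred_class[i, fit$ncomp]
        pred_val[i, , h] <- pred_val[i, , fit$ncomp]
      }
    }
  }
  acc <- vapply(seq_len(max_ncomp), function(h)
    mean(pred_class[, h] == as.character(y), na.rm = TRUE), 0)
  list(accuracy = acc, pred_class = pred_class, pred_val = pred_val,
       skipped = skipped)
}

# macro one-vs-rest AUC from pooled continuous predictions
.macro_auc <- function(y, pred_val) {
  y <- as.factor(y)
  lev <- levels(y)
  ok <- !is.na(pred_val[, 1])
  if (length(lev) == 2L) {
    r <- pROC::roc(response = y[ok] == lev[2L], predictor = pred_val[ok, 2L],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    return(as.numeric(pROC::auc(r)))
  }
  mean(vapply(lev, function(l) {
    r <- pROC::roc(response = y[ok] == l, predictor = pred_val[ok, l],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(r))
  }, 0))
}

#' Tune and evaluate a sparse PLS-DA classifier by leave-one-out CV
#'
#' Stage 1 selects the number of components (dense fits, candidates
#' `h_grid`) by LOO accuracy, ties going to the smaller model. Stage 2
#' grid-searches keepX component by component (earlier components fixed),
#' ties going to the sparser model. The chosen configuration's pooled LOO
#' predictions give the reported accuracy and (macro one-vs-rest) AUC.
#'
#' @param X sample x feature matrix (named columns).
#' @param y class labels.
#' @param h_grid candidate component numbers (default 1:10).
#' @param keepX_grid candidate per-component keepX values (default
#'   5/10/25/50/100/all, intersected with the feature count).
#' @param scale unit-variance scale features.
#' @param seed accepted for interface stability; the procedure is
#'   deterministic.
#' @return list of class `cv_report`: `best_ncomp`, `best_keepX`,
#'   `accuracy`, `auc`, `stage1` (per-H accuracies), `stage2` (grid trace),
#'   `predictions` (per-fold), `model` (final fit on all samples).
#' @export
tune_and_evaluate <- function(X, y, h_grid = 1:10,
                              keepX_grid = c(5L, 10L, 25L, 50L, 100L, Inf),
                              scale = TRUE, seed = 1L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nrow(X) < 5L) stopf("need >= 5 samples for LOO tuning")
  p <- ncol(X)
  h_grid <- sort(unique(pmin(h_grid, nrow(X) - 2L)))
  keepX_grid <- sort(unique(pmin(keepX_grid, p)))

  # stage 1: one dense LOO sweep at max H gives every smaller H for free
  hmax <- max(h_grid)
  sweep1 <- .loo_eval(X, y, ncomp = hmax, keepX = rep(p, hmax),
                      scale = scale, max_ncomp = hmax)
  stage1 <- data.frame(ncomp = h_grid, accuracy = sweep1$accuracy[h_grid])
  best_h <- stage1$ncomp[which.max(stage1$accuracy)]  # ties -> smaller H

  # stage 2: sequential keepX search
  chosen <- integer(0)
  stage2 <- list()
  for (h in seq_len(best_h)) {
    accs <- vapply(keepX_grid, function(kx) {
      .loo_eval(X, y, ncomp = h, keepX = c(chosen, kx),
                scale = scale)$accuracy[h]
    }, 0)
    stage2[[h]] <- data.frame(comp = h, keepX = keepX_grid, accuracy = accs)
    chosen <- c(chosen, keepX_grid[which.max(accs)])  # ties -> smaller keepX
  }

  final <- .loo_eval(X, y, ncomp = best_h, keepX = chosen, scale = scale)
  model <- suppressWarnings(fit_splsda(X, y, ncomp = best_h, keepX = chosen,
                                       scale = scale))
  structure(list(
    best_ncomp = best_h, best_keepX = chosen,
    accuracy = final$accuracy[best_h],
    auc = .macro_auc(y, final$pred_val[, , best_h, drop = FALSE][, , 1]),
    stage1 = stage1, stage2 = do.call(rbind, stage2),
    predictions = data.frame(sample = rownames(X) %||% seq_len(nrow(X)),
                             truth = as.character(y),
                             predicted = final$pred_class[, best_h]),
    model = model), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> ncomp = %d, keepX = %s; LOO accuracy = %.3f, AUC = %.3f\n",
              x$best_ncomp, paste(x$best_keepX, collapse = ","),
              x$accuracy, x$auc))
  invisible(x)
}
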