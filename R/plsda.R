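#' Fit a two-class PLS discriminant analysis model
#'
#' Autoscales the predictor matrix (training mean 0, SD 1 per analyte; constant
#' analytes dropped with a warning), encodes the classes as a single centered
#' 0/1 response (greater = 1), and extracts latent variables by the classical
#' iterative (NIPALS) algorithm with deflation. The classification threshold is
#' the midpoint of the calibration class means of the predicted response.
#' LV1 is oriented so the greater-decliner class mean score is negative.
#'
#' @param X numeric matrix (samples x analytes) or [proteomic_matrix],
#'   log-scale values expected.
#' @param classes per-sample labels with levels greater/lesser.
#' @param n_lv number of latent variables (default 2).
#' @param tol,max_iter NIPALS convergence tolerance and iteration cap per LV.
#' @return An object of class `plsda_model`: weights, loadings (`x_loadings`),
#'   `y_loadings`, `x_scores`, projection matrix, regression vector `beta`,
#'   scaling parameters, `threshold`, `x_variance_explained`, and flags.
#' @export
fit_plsda <- function(X, classes, n_lv = 2, tol = 1e-10, max_iter = 500) {
  if (inherits(X, "proteomic_matrix")) X <- X$values
  X <- as.matrix(X)
  classes <- check_binary_classes(classes)
  if (any(table(classes) < 2)) stop("each class needs n >= 2 samples")
  if (nrow(X) != length(classes)) stop("X rows must match classes")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))

  ctr <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning("dropping constant analytes: ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  ctr <- ctr[keep]
  sdv <- sdv[keep]
  n <- nrow(X); p <- ncol(X)
  if (p == 0) stop("no non-constant analytes")
  n_lv <- min(n_lv, n - 1, p)
  if (n_lv < 1) stop("cannot extract any latent variable")

  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, sdv, "/")
  y <- as.numeric(classes == "greater")
  y_mean <- mean(y)
  yc <- y - y_mean

  E <- Xs
  f <- yc
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  ssq_x <- sum(Xs^2)
  a_used <- 0
  for (a in seq_len(n_lv)) {
    u <- f
    w_old <- rep(0, p)
    tt <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      tt <- E %*% w
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
      u <- f              # single response: u stays the centered response
    }
    if (is.null(tt) || nw < tol || sum(tt^2) < tol) {
      break               # residual carries no covariance with the response
    }
    pa <- crossprod(E, tt)[, 1] / sum(tt^2)
    qa <- sum(f * tt) / sum(tt^2)
    W[, a] <- w
    P[, a] <- pa
    Tm[, a] <- tt
    q[a] <- qa
    E <- E - tcrossprod(tt, pa)
    f <- f - tt * qa
    a_used <- a
  }
  if (a_used == 0) stop("NIPALS could not extract a latent variable")
  if (a_used < n_lv) {
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    Tm <- Tm[, seq_len(a_used), drop = FALSE]
    q <- q[seq_len(a_used)]
    n_lv <- a_used
  }

  proj <- W %*% solve(crossprod(P, W))   # X-score generator: scores = Xs %*% proj
  beta <- proj %*% q

  model <- structure(list(
    weights = W, x_loadings = P, y_loadings = q, x_scores = Tm,
    proj = proj, beta = beta,
    analytes = colnames(X), center = ctr, scale_sd = sdv,
    dropped = names(keep)[!keep],
    y_mean = y_mean, class_levels = c("greater", "lesser"),
    n_lv = n_lv, ssq_x = ssq_x, orthogonalized = FALSE,
    classes = classes
  ), class = "plsda_model")

  model <- orient_lv1(model)
  fitted <- predict(model, X)$response
  model$threshold <- (mean(fitted[classes == "greater"]) +
                      mean(fitted[classes == "lesser"])) / 2
  model$x_variance_explained <-
    colSums(model$x_scores^2) * colSums(model$x_loadings^2) / model$ssq_x
  model
}

# flip LV1 so the greater-class mean score is negative (prediction-invariant)
orient_lv1 <- function(model) {
  g <- model$classes == "greater"
  if (mean(model$x_scores[g, 1]) > mean(model$x_scores[!g, 1])) {
    model$weights[, 1] <- -model$weights[, 1]
    model$x_loadings[, 1] <- -model$x_loadings[, 1]
    model$x_scores[, 1] <- -model$x_scores[, 1]
    model$y_loadings[1] <- -model$y_loadings[1]
    model$proj <- model$weights %*% solve(crossprod(model$x_loadings,
                                                    model$weights))
  }
  model
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf(
    "plsda_model: %d analytes, %d LV%s%s; X variance explained: %s\n",
    length(x$analytes), x$n_lv, if (x$n_lv > 1) "s" else "",
    if (x$orthogonalized) " (orthogonalized)" else "",
    paste(sprintf("%.1f%%", 100 * x$x_variance_explained), collapse = ", ")
  ))
  invisible(x)
}

#' Concentrate the predictive covariance on LV1
#'
#' Rotates the latent space of a fitted model so that all response-predictive
#' covariance lies on LV1 and the remaining latent variables carry
#' response-orthogonal variation (their scores are exactly uncorrelated with
#' the centered class response). Predicted responses are unchanged.
#' Idempotent: an already-orthogonalized model is returned as is.
#'
#' @param model a fitted [fit_plsda()] model.
#' @return The rotated `plsda_model` with `orthogonalized = TRUE`.
#' @export
orthogonalize <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  if (model$orthogonalized) return(model)
  A <- model$n_lv
  model$orthogonalized <- TRUE
  if (A == 1) return(model)

  d <- colSums(model$x_scores^2)
  v <- sqrt(d) * model$y_loadings        # response direction in normalized scores
  if (sqrt(sum(v^2)) < 1e-12) return(model)   # nothing predictive to rotate
  r1 <- v / sqrt(sum(v^2))
  Q <- qr.Q(qr(cbind(r1, diag(A))))[, seq_len(A), drop = FALSE]
  if (sum(Q[, 1] * r1) < 0) Q[, 1] <- -Q[, 1]
  M <- diag(1 / sqrt(d), A) %*% Q        # score transform: T_new = T M
  Minv <- solve(M)

  model$x_scores <- model$x_scores %*% M
  model$x_loadings <- t(Minv %*% t(model$x_loadings))
  model$y_loadings <- drop(Minv %*% model$y_loadings)
  model$proj <- model$proj %*% M
  model$weights <- model$proj            # rotated score generator
  model <- orient_lv1(model)
  model$x_variance_explained <-
    colSums(model$x_scores^2) * colSums(model$x_loadings^2) / model$ssq_x
  model
}

#' Predict classes for new samples
#'
#' Applies the training scaling parameters only (no test-set statistics),
#' computes predicted responses and LV scores, and assigns `greater` when the
#' response strictly exceeds the decision threshold (ties go to the larger
#' calibration class, `lesser`).
#'
#' @param object a `plsda_model`.
#' @param newdata matrix or [proteomic_matrix] containing the model's analytes
#'   (extra columns ignored, order free).
#' @param ... unused.
#' @return A list with `response`, `class` (factor greater/lesser) and
#'   `scores` (samples x LVs).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  if (inherits(newdata, "proteomic_matrix")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$analytes)) {
      stop("unnamed newdata must have exactly the model's analytes")
    }
    colnames(newdata) <- object$analytes
  }
  missing <- setdiff(object$analytes, colnames(newdata))
  if (length(missing)) {
    stop("newdata lacks model analytes: ", paste(missing, collapse = ", "))
  }
  Xn <- newdata[, object$analytes, drop = FALSE]
  Xs <- sweep(sweep(Xn, 2, object$center, "-"), 2, object$scale_sd, "/")
  response <- drop(object$y_mean + Xs %*% object$beta)
  scores <- Xs %*% object$proj
  thr <- if (is.null(object$threshold)) 0.5 else object$threshold
  cls <- factor(ifelse(response > thr, "greater", "lesser"),
                levels = c("greater", "lesser"))
  list(response = response, class = cls, scores = scores)
}

#' Serialize / restore a PLSDA model as JSON
#'
#' @param model a `plsda_model`.
#' @param path output file.
#' @return `write_plsda` invisibly returns `path`; `read_plsda` the model.
#' @export
write_plsda <- function(model, path) {
  stopifnot(inherits(model, "plsda_model"))
  out <- unclass(model)
  out$classes <- as.character(out$classes)
  for (nm in c("weights", "x_loadings", "x_scores", "proj", "beta")) {
    out[[nm]] <- as.data.frame(out[[nm]])
  }
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plsda
#' @export
read_plsda <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("weights", "x_loadings", "x_scores", "proj", "beta")) {
    raw[[nm]] <- as.matrix(raw[[nm]])
  }
  raw$classes <- factor(raw$classes, levels = c("greater", "lesser"))
  names(raw$center) <- raw$analytes
  names(raw$scale_sd) <- raw$analytes
  structure(raw, class = "plsda_model")
}
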