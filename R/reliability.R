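#' Train the edge-reliability logistic regression
#'
#' Fits `Pr(true interaction | X) = 1 / (1 + exp(-b0 - b1*C - b2*rho -
#' b3*loc))` on labeled positive/negative edge features. Following the
#' published protocol, the positive set is first truncated to the negative
#' set's size (its leading rows, mirroring the "first 2000 interactions"
#' balancing rule), the balanced data are split into stratified folds, one
#' maximum-likelihood logistic fit is run per fold (training on the
#' complementary folds), and the final coefficient vector is the mean of the
#' per-fold coefficients. Per-fold coefficients are retained for inspection,
#' and a median average is available since a single unstable fold can
#' dominate the mean.
#'
#' @param pos_features,neg_features feature data.frames from
#'   [build_edge_features()] (columns `C`, `rho`, `loc`) for the positive
#'   and negative edge sets
#' @param folds number of cross-validation folds (default 10)
#' @param balance truncate the positive set to the negative set's size
#'   (default `TRUE`)
#' @param seed integer seed for the stratified fold assignment
#' @param average `"mean"` (default, per the published procedure) or
#'   `"median"` of the per-fold coefficients
#' @param ridge nonnegative ridge penalty; 0 (default) fits plain maximum
#'   likelihood, a positive value uses an L2 penalty (via glmnet) which is
#'   useful when clean synthetic data are linearly separable
#' @return object of class `reliability_model`: list with `beta` (named
#'   4-vector: intercept, C, rho, loc), `fold_betas` (folds x 4 matrix),
#'   `average`, `ridge`, `seed`
#' @export
train_reliability <- function(pos_features, neg_features, folds = 10L,
                              balance = TRUE, seed = 1L,
                              average = c("mean", "median"), ridge = 0) {
  average <- match.arg(average)
  fcols <- c("C", "rho", "loc")
  pos <- as.data.frame(pos_features)[, fcols, drop = FALSE]
  neg <- as.data.frame(neg_features)[, fcols, drop = FALSE]
  if (balance && nrow(pos) > nrow(neg))
    pos <- pos[seq_len(nrow(neg)), , drop = FALSE]
  X <- as.matrix(rbind(pos, neg))
  if (any(!is.finite(X))) stop("non-finite feature values")
  y <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg)))
  if (min(nrow(pos), nrow(neg)) < folds)
    stop("each class needs at least `folds` examples")
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_betas <- matrix(NA_real_, nrow = folds, ncol = 4L,
                       dimnames = list(paste0("fold", seq_len(folds)),
                                       c("(Intercept)", fcols)))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fold_betas[f, ] <- fit_logistic(X[tr, , drop = FALSE], y[tr], ridge)
  }
  beta <- switch(average,
                 mean = colMeans(fold_betas),
                 median = apply(fold_betas, 2L, stats::median))
  structure(list(beta = beta, fold_betas = fold_betas, average = average,
                 ridge = ridge, seed = seed, balanced = balance),
            class = "reliability_model")
}

fit_logistic <- function(X, y, ridge = 0) {
  if (ridge > 0) {
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop("ridge > 0 requires the glmnet package")
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = ridge, standardize = FALSE)
    as.numeric(stats::coef(fit))
  } else {
    df <- data.frame(y = y, X)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df, family = stats::binomial(),
                 control = stats::glm.control(maxit = 100L)))
    as.numeric(stats::coef(fit))
  }
}

#' @export
print.reliability_model <- function(x, ...) {
  cat("Edge reliability model (", x$average, " of ",
      nrow(x$fold_betas), " fold fits", if (x$ridge > 0)
        paste0(", ridge = ", x$ridge), ")\n", sep = "")
  print(round(x$beta, 6))
  invisible(x)
}

#' Predict edge reliability from features
#'
#' @param model a [train_reliability()] fit
#' @param X numeric length-3 vector `(C, rho, loc)` or a matrix/data.frame
#'   with those three columns
#' @return probability (or vector of probabilities) in `(0, 1)`
#' @export
predict_reliability <- function(model, X) {
  b <- model$beta
  if (is.data.frame(X)) X <- as.matrix(X[, c("C", "rho", "loc")])
  if (is.null(dim(X))) {
    if (length(X) != 3L) stop("feature vector must have length 3")
    X <- matrix(X, nrow = 1L)
  }
  if (any(!is.finite(X))) stop("non-finite feature values")
  eta <- b[1L] + drop(X %*% b[-1L])
  stats::plogis(eta)
}

#' Re-weight a network with predicted edge reliabilities
#'
#' Returns a copy of `net` whose edge weights are the model's predicted
#' probabilities of true interaction; the node set is unchanged.
#'
#' @param net a [ppi_network]
#' @param model a [reliability model][train_reliability]
#' @param features feature data.frame from [build_edge_features()] covering
#'   every edge of `net`
#' @return a [ppi_network] with weights in `(0, 1)`
#' @export
weight_network <- function(net, model, features) {
  key_net <- edge_keys(net$edges)
  key_feat <- paste(pmin(features$from, features$to),
                    pmax(features$from, features$to), sep = "\t")
  idx <- match(key_net, key_feat)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1L]
    stop("no feature row for edge ", net$edges$from[miss], " -- ",
         net$edges$to[miss])
  }
  w <- predict_reliability(model,
                           features[idx, c("C", "rho", "loc"), drop = FALSE])
  edges <- net$edges
  edges$weight <- as.numeric(w)
  ppi_network(edges, nodes = net$nodes)
}

#' Serialize a reliability model to a key-value text file
#' @param model a `reliability_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_reliability_model <- function(model, path) {
  fb <- model$fold_betas
  lines <- c(
    paste0("average=", model$average),
    paste0("ridge=", formatC(model$ridge, digits = 15, format = "g")),
    paste0("seed=", model$seed),
    paste0("beta=", paste(formatC(model$beta, digits = 15, format = "g"),
                          collapse = ",")),
    vapply(seq_len(nrow(fb)), function(i)
      paste0("fold", i, "=",
             paste(formatC(fb[i, ], digits = 15, format = "g"),
                   collapse = ",")), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a reliability model written by [write_reliability_model()]
#' @param path input path
#' @return a `reliability_model`
#' @export
read_reliability_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  getnum <- function(k) as.numeric(strsplit(vals[keys == k], ",")[[1L]])
  fold_keys <- grep("^fold[0-9]+$", keys, value = TRUE)
  fb <- t(vapply(fold_keys, getnum, numeric(4L)))
  colnames(fb) <- c("(Intercept)", "C", "rho", "loc")
  beta <- getnum("beta")
  names(beta) <- colnames(fb)
  structure(list(beta = beta, fold_betas = fb,
                 average = vals[keys == "average"],
                 ridge = getnum("ridge"), seed = as.integer(vals[keys == "seed"]),
                 balanced = NA),
            class = "reliability_model")
}
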