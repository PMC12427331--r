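#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 * sum p (1 - p))` with `Z = X - 2p` column-centred at the
#' observed allele frequencies `p`.  Monomorphic columns centre to zero and
#' contribute nothing.  Under equilibrium the mean diagonal is close to 1.
#'
#' @param dosages numeric matrix of mean-imputed dosages (individuals x
#'   SNPs), e.g. the `mean` matrix from [impute_and_discretize()].
#' @return A symmetric n x n matrix with sample ids as dimnames and the
#'   scaling denominator in attribute `denom`.
#' @export
compute_grm <- function(dosages) {
  if (!is.matrix(dosages)) abort("`dosages` must be a matrix")
  p <- colMeans(dosages) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) abort("all SNPs monomorphic; GRM undefined")
  Z <- sweep(dosages, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(dosages), rownames(dosages))
  attr(G, "denom") <- denom
  G
}

# Profiled REML log-likelihood over lambda = sigma_e^2 / sigma_g^2, using a
# single spectral decomposition of the training kinship (intercept-only
# fixed effects).
reml_loglik <- function(log_lambda, d, Uy, UX, n) {
  lambda <- exp(log_lambda)
  Dl <- d + lambda
  XtWX <- sum(UX^2 / Dl)
  beta <- sum(UX * Uy / Dl) / XtWX
  r <- Uy - UX * beta
  yPy <- sum(r^2 / Dl)
  sg2 <- yPy / (n - 1)
  -0.5 * ((n - 1) * log(sg2) + sum(log(Dl)) + log(XtWX) + (n - 1))
}

#' Fit a GBLUP model
#'
#' Mixed model `y = mu + g + e`, `g ~ N(0, sigma_g^2 G)`,
#' `e ~ N(0, sigma_e^2 I)`.  With `method = "reml"` the variance ratio
#' `lambda = sigma_e^2 / sigma_g^2` maximises the restricted likelihood
#' via one spectral decomposition of the training kinship and a 1-D search
#' over `log(lambda)`; with `method = "fixed_h2"` it is set to
#' `(1 - h2) / h2`.
#'
#' @param G kinship matrix covering (at least) the training individuals,
#'   from [compute_grm()].
#' @param y named numeric vector of training phenotypes; names select the
#'   training rows of `G`.
#' @param method `"reml"` or `"fixed_h2"`.
#' @param h2 heritability used when `method = "fixed_h2"`.
#' @param jitter ridge added to the training kinship for numerical
#'   positive-definiteness.
#' @return A `gblup_model`: variance components `sigma_g2`, `sigma_e2`,
#'   `lambda`, heritability estimate `h2`, GLS mean `mu`, training ids,
#'   and the precomputed BLUP weights `alpha = (G + lambda I)^{-1} (y -
#'   mu)`.
#' @export
fit_gblup <- function(G, y, method = c("reml", "fixed_h2"), h2 = NULL,
                      jitter = 1e-8) {
  method <- match.arg(method)
  ids <- names(y)
  if (is.null(ids)) abort("`y` must be named with individual ids")
  if (!all(ids %in% rownames(G))) abort("training ids missing from G")
  Gt <- G[ids, ids]
  n <- length(y)
  eg <- eigen(Gt + diag(jitter, n), symmetric = TRUE)
  if (min(eg$values) < -1e-6) {
    abort("training kinship not positive semi-definite after jitter")
  }
  d <- pmax(eg$values, 1e-10)
  Uy <- crossprod(eg$vectors, y)[, 1]
  UX <- crossprod(eg$vectors, rep(1, n))[, 1]
  if (method == "reml") {
    opt <- optimize(reml_loglik, c(-12, 12), d = d, Uy = Uy, UX = UX,
                    n = n, maximum = TRUE)
    lambda <- exp(opt$maximum)
  } else {
    check_scalar(h2, "h2", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
    lambda <- (1 - h2) / h2
  }
  Dl <- d + lambda
  mu <- sum(UX * Uy / Dl) / sum(UX^2 / Dl)
  r <- Uy - UX * mu
  sg2 <- sum(r^2 / Dl) / (n - 1)
  alpha <- eg$vectors %*% (r / Dl)
  structure(list(
    sigma_g2 = sg2, sigma_e2 = lambda * sg2, lambda = lambda,
    h2 = 1 / (1 + lambda), mu = mu,
    alpha = stats::setNames(alpha[, 1], ids),
    train_ids = ids, method = method
  ), class = "gblup_model")
}

#' @export
print.gblup_model <- function(x, ...) {
  cat(sprintf(
    "<gblup_model> n=%d (%s): sigma_g2=%.4f sigma_e2=%.4f h2=%.3f\n",
    length(x$train_ids), x$method, x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

#' Predict genomic values with a fitted GBLUP model
#'
#' `yhat = mu + G_cross alpha` with `alpha = (G_train + lambda I)^{-1}
#' (y_train - mu)`.
#'
#' @param object a `gblup_model`.
#' @param G the kinship matrix (or a cross-kinship block test x train).
#' @param ids ids of the individuals to predict; defaults to every row of
#'   `G`.
#' @param ... unused.
#' @return Named numeric vector of predictions.
#' @export
predict.gblup_model <- function(object, G, ids = NULL, ...) {
  ids <- ids %||% rownames(G)
  if (!all(ids %in% rownames(G))) abort("prediction ids missing from G")
  if (!all(object$train_ids %in% colnames(G))) {
    abort("training ids missing from G columns")
  }
  Gc <- G[ids, object$train_ids, drop = FALSE]
  stats::setNames(as.numeric(Gc %*% object$alpha) + object$mu, ids)
}

#' @export
tidy.gblup_model <- function(x, ...) {
  tibble::tibble(id = x$train_ids, blup_weight = unname(x$alpha))
}

#' @export
glance.gblup_model <- function(x, ...) {
  tibble::tibble(sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
                 lambda = x$lambda, h2 = x$h2, mu = x$mu,
                 n_train = length(x$train_ids), method = x$method)
}

#' Fit a Lasso baseline with validation-based penalty selection
#'
#' L1-penalised least squares on mean-imputed dosages (coordinate descent
#' via glmnet); the penalty is chosen to maximise the coefficient of
#' determination on the validation split only.
#'
#' @param X_train,y_train training dosage matrix and phenotypes.
#' @param X_val,y_val validation dosage matrix and phenotypes.
#' @param penalties decreasing penalty grid; defaults to glmnet's
#'   data-driven path.
#' @return A `lasso_model`: sparse `coefficients`, `intercept`, selected
#'   `penalty`, validation scores per grid point.
#' @export
fit_lasso <- function(X_train, y_train, X_val, y_val, penalties = NULL) {
  if (!is.null(penalties) && !length(penalties)) abort("empty penalty grid")
  fit <- glmnet::glmnet(X_train, y_train, alpha = 1, lambda = penalties,
                        standardize = TRUE, thresh = 1e-10)
  pv <- predict(fit, newx = X_val)
  scores <- apply(pv, 2, function(p) {
    tryCatch(compute_metrics(y_val, p)$r2, error = function(e) -Inf)
  })
  best <- which.max(ifelse(is.finite(scores), scores, -Inf))
  lam <- fit$lambda[best]
  cf <- coef(fit, s = lam)
  structure(list(
    coefficients = stats::setNames(as.numeric(cf[-1]), rownames(cf)[-1]),
    intercept = cf[1],
    penalty = lam,
    validation = tibble::tibble(penalty = fit$lambda, val_r2 = scores),
    glmnet_fit = fit
  ), class = "lasso_model")
}

#' @export
predict.lasso_model <- function(object, X, ...) {
  stats::setNames(
    as.numeric(X %*% object$coefficients + object$intercept), rownames(X))
}

#' @export
tidy.lasso_model <- function(x, ...) {
  cf <- x$coefficients
  tibble::tibble(term = names(cf), estimate = unname(cf))[cf != 0, ]
}

#' @export
glance.lasso_model <- function(x, ...) {
  tibble::tibble(penalty = x$penalty,
                 n_nonzero = sum(x$coefficients != 0),
                 intercept = x$intercept)
}
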