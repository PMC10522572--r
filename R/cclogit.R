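# Conditional logistic regression for 1:m matched sets, fitted by
# Newton-Raphson on the exact conditional likelihood. With exactly one case
# per set no ties arise, so the Breslow and exact likelihoods coincide:
#
#   L(beta) = prod_s exp(x_case(s) . beta) / sum_{j in s} exp(x_j . beta)
#
# Gradient  = sum_s (x_case(s) - E_beta[x | s])
# Hessian   = -sum_s Cov_beta[x | s],
# where the expectation weights are softmax(x_j . beta) within the set.

#' Conditional logistic regression for matched case-control sets
#'
#' Fits the conditional (matched-set) logistic likelihood by Newton-Raphson
#' with step-halving, starting from `beta = 0`. Each stratum must contain
#' exactly one case and at least two members; strata whose members all share
#' identical covariate rows are non-informative (they contribute a constant
#' to the likelihood) and are counted but do not affect the estimate.
#'
#' Standard errors come from the inverse of the observed information at the
#' optimum; odds ratios and 95 percent Wald confidence intervals use the
#' normal quantile 1.959964.
#'
#' @param formula Model formula, `case ~ x1 + x2 + ...`. The response must be
#'   a logical/0-1 case indicator. No intercept is fitted (it cancels from
#'   the conditional likelihood).
#' @param data Data frame holding the response, regressors and set variable.
#' @param set Name of the column identifying matched sets (character scalar),
#'   or a vector of set identifiers of length `nrow(data)`.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param max_iter Maximum Newton iterations.
#' @param max_halvings Maximum step-halvings per iteration.
#' @return An object of class `"cclogit"`: list with elements `coefficients`,
#'   `se`, `vcov`, `loglik`, `loglik_null`, `iterations`, `converged`,
#'   `flag` (`"ok"` or `"suspect_separation"`), `n_sets`, `n_informative`,
#'   `n_obs`, `terms`, `call`.
#' @examples
#' d <- data.frame(y = rep(c(1, 0, 0), 4), x = rnorm(12),
#'                 s = rep(1:4, each = 3))
#' fit <- cclogit(y ~ x, d, set = "s")
#' summary(fit)
#' @export
cclogit <- function(formula, data, set, tol = 1e-8, max_iter = 50L,
                    max_halvings = 10L) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  case <- as.logical(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (length(set) == 1L && is.character(set)) set <- data[[set]]
  if (length(set) != nrow(X)) stop("'set' must match the rows of 'data'")
  set <- factor(set, levels = unique(set))

  fit <- cclogit_fit(X, case, set, tol = tol, max_iter = max_iter,
                     max_halvings = max_halvings)
  fit$call <- cl
  fit$terms <- colnames(X)
  fit
}

#' @rdname cclogit
#' @param X Numeric design matrix (no intercept column).
#' @param case Logical case indicator, exactly one `TRUE` per set.
#' @export
cclogit_fit <- function(X, case, set, tol = 1e-8, max_iter = 50L,
                        max_halvings = 10L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in design matrix")
  set <- factor(set, levels = unique(set))
  n_case <- tapply(case, set, sum)
  if (any(n_case != 1L)) stop("every matched set must contain exactly one case")
  size <- tabulate(set)
  if (any(size < 2L)) stop("every matched set must have at least 2 members")

  # informative = at least two distinct covariate rows within the set
  key <- apply(X, 1L, paste, collapse = "\r")
  informative <- tapply(key, set, function(k) length(unique(k)) > 1L)
  n_inf <- sum(informative)
  if (n_inf == 0L) stop("no informative sets")

  p <- ncol(X)
  beta <- numeric(p)
  d <- ccl_loglik(X, case, set, beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(d$grad)) < tol) { converged <- TRUE; break }
    info <- -d$hess
    step <- tryCatch(solve(info, d$grad), error = function(e) {
      sv <- svd(info)
      bad <- sv$d < max(sv$d) * 1e-10
      if (any(bad)) {
        cols <- colnames(X)[apply(abs(sv$v[, bad, drop = FALSE]) > 0.3, 1, any)]
        stop("singular information matrix; collinear columns: ",
             paste(cols, collapse = ", "), call. = FALSE)
      }
      stop(e)
    })
    h <- 0L
    repeat {
      cand <- beta + step
      dc <- ccl_loglik(X, case, set, cand)
      if (is.finite(dc$loglik) && dc$loglik >= d$loglik - 1e-12) break
      h <- h + 1L
      if (h > max_halvings) break
      step <- step / 2
    }
    beta <- beta + step
    d <- ccl_loglik(X, case, set, beta)
    if (max(abs(d$grad)) < tol) { converged <- TRUE; break }
  }
  if (max(abs(d$grad)) < tol) converged <- TRUE

  vcov <- solve(-d$hess)
  se <- sqrt(diag(vcov))
  flag <- if (any(abs(beta) > 15)) "suspect_separation" else "ok"
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(p))
  names(beta) <- names(se) <- rownames(vcov) <- colnames(vcov) <- nms
  structure(list(
    coefficients = beta, se = se, vcov = vcov,
    loglik = d$loglik,
    loglik_null = ccl_loglik(X, case, set, numeric(p))$loglik,
    iterations = iter, converged = converged, flag = flag,
    n_sets = nlevels(set), n_informative = n_inf, n_obs = nrow(X),
    terms = nms
  ), class = "cclogit")
}

#' Conditional log-likelihood, gradient and Hessian
#'
#' Evaluates the matched-set conditional log-likelihood at `beta`, with its
#' analytic gradient and Hessian. Softmax weights are computed with set-wise
#' maximum subtraction for overflow safety.
#'
#' @inheritParams cclogit_fit
#' @param beta Numeric coefficient vector.
#' @return List with `loglik` (scalar), `grad` (length p), `hess` (p x p,
#'   negative semidefinite).
#' @export
ccl_loglik <- function(X, case, set, beta) {
  set <- factor(set, levels = unique(set))
  eta <- drop(X %*% beta)
  mx <- vapply(split(eta, set), max, 0)
  w <- exp(eta - mx[as.integer(set)])
  W <- vapply(split(w, set), sum, 0)
  pi <- w / W[as.integer(set)]
  loglik <- sum(eta[case]) - sum(mx + log(W))
  Xbar <- rowsum(X * pi, set, reorder = TRUE)
  grad <- colSums(X[case, , drop = FALSE]) - colSums(Xbar)
  hess <- -(crossprod(X, X * pi) - crossprod(Xbar))
  list(loglik = loglik, grad = grad, hess = hess)
}

z975 <- 1.959964

#' Wald odds-ratio table for a conditional logistic fit
#'
#' @param fit A [cclogit] object.
#' @return Data frame with one row per term: `term`, `beta`, `se`, `OR`,
#'   `lo95`, `hi95`, `p` (two-sided Wald), `significant` (p <= 0.05).
#' @export
wald_table <- function(fit) {
  b <- fit$coefficients
  se <- fit$se
  z <- b / se
  data.frame(
    term = names(b),
    beta = unname(b),
    se = unname(se),
    OR = exp(unname(b)),
    lo95 = exp(unname(b) - z975 * se),
    hi95 = exp(unname(b) + z975 * se),
    p = 2 * stats::pnorm(-abs(unname(z))),
    significant = 2 * stats::pnorm(-abs(unname(z))) <= 0.05,
    row.names = NULL
  )
}

#' @export
print.cclogit <- function(x, digits = 4, ...) {
  cat("Conditional logistic regression (matched sets)\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("%d sets (%d informative), %d observations\n",
              x$n_sets, x$n_informative, x$n_obs))
  cat(sprintf("log-likelihood %.4f after %d iteration(s)%s\n", x$loglik,
              x$iterations,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.cclogit <- function(object, ...) {
  out <- list(fit = object, table = wald_table(object))
  class(out) <- "summary.cclogit"
  out
}

#' @export
print.summary.cclogit <- function(x, digits = 3, ...) {
  f <- x$fit
  cat(sprintf(
    "Conditional logistic regression: %d sets (%d informative), %d obs\n",
    f$n_sets, f$n_informative, f$n_obs))
  cat(sprintf("log-likelihood %.4f (null %.4f), converged: %s%s\n\n",
              f$loglik, f$loglik_null, f$converged,
              if (f$flag != "ok") paste0(" [", f$flag, "]") else ""))
  tab <- x$table
  tab$p <- format.pval(tab$p, digits = digits)
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cclogit <- function(object, ...) object$coefficients

#' @export
vcov.cclogit <- function(object, ...) object$vcov

#' @export
logLik.cclogit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' @export
nobs.cclogit <- function(object, ...) object$n_obs

#' @export
confint.cclogit <- function(object, parm, level = 0.95, ...) {
  b <- object$coefficients
  if (missing(parm)) parm <- names(b)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(b[parm] - z * object$se[parm], b[parm] + z * object$se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' @export
#' @rdname cclogit
#' @param object,newdata,type Standard `predict` arguments; `type = "lp"`
#'   returns the linear predictor, `type = "prob"` the within-set softmax
#'   probability of being the case.
#' @param newset Set identifiers for `newdata` (required for `type = "prob"`).
predict.cclogit <- function(object, newdata, newset = NULL,
                            type = c("lp", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$terms, drop = FALSE])
  eta <- drop(X %*% object$coefficients)
  if (type == "lp") return(eta)
  if (is.null(newset)) stop("'newset' is required for type = \"prob\"")
  set <- factor(newset, levels = unique(newset))
  mx <- vapply(split(eta, set), max, 0)
  w <- exp(eta - mx[as.integer(set)])
  W <- vapply(split(w, set), sum, 0)
  w / W[as.integer(set)]
}
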