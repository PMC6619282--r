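## ---------------------------------------------------------------------------
## Semiparametric proportional hazards core: Breslow partial likelihood on
## counting-process data (start, stop], Newton-Raphson with step halving,
## Breslow baseline, Schoenfeld and martingale residuals.  The internal
## cox_prep/cox_newton pair avoids all formula overhead so the EM algorithm
## can refit thousands of times cheaply.
## ---------------------------------------------------------------------------

## Precompute everything that does not depend on the coefficients.
## A row is at risk at event time e iff start < e <= stop.
cox_prep <- function(start, stop, status, X, cluster = NULL) {
  n <- length(stop)
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (any(start >= stop)) stop_domain("need start < stop in all rows")
  if (any(!is.finite(X))) stop_domain("covariates must be finite")
  status <- as.integer(status)
  ev_rows <- which(status == 1L)
  if (!length(ev_rows)) stop_domain("no events in the data")
  e <- sort(unique(stop[ev_rows]))
  d <- as.integer(table(factor(stop[ev_rows], levels = e)))
  ord_stop <- order(stop)
  ord_start <- order(start)
  ## position of the first sorted element >= e_k, for suffix sums
  idx_stop <- n - findInterval(e, stop[ord_stop], left.open = TRUE) # count stop >= e
  idx_start <- n - findInterval(e, start[ord_start], left.open = TRUE)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  const_cols <- apply(abs(Xc), 2, max) < 1e-12
  est <- which(!const_cols)
  ## second-moment columns of the estimable covariates (upper triangle),
  ## fixed across Newton iterations
  pe <- length(est)
  Xe <- Xc[, est, drop = FALSE]
  XX <- matrix(0, n, pe * (pe + 1L) / 2L)
  cnt <- 0L
  for (j in seq_len(pe)) for (l in j:pe) {
    cnt <- cnt + 1L
    XX[, cnt] <- Xe[, j] * Xe[, l]
  }
  ## row -> index of last event time <= stop / <= start (0 if none)
  pos_stop <- findInterval(stop, e)
  pos_start <- findInterval(start, e)
  ## map each event row to its event-time index
  ev_time_idx <- match(stop[ev_rows], e)
  list(n = n, p = p, X = X, Xc = Xc, xbar = xbar,
       start = start, stop = stop, status = status,
       e = e, d = d, K = length(e), ev_rows = ev_rows,
       ev_time_idx = ev_time_idx,
       ord_stop = ord_stop, ord_start = ord_start,
       rev_ord_stop = rev(ord_stop), rev_ord_start = rev(ord_start),
       idx_stop = idx_stop, idx_start = idx_start,
       pos_stop = pos_stop, pos_start = pos_start,
       cluster = cluster,
       const_cols = const_cols, est = est, Xe = Xe, XX = XX,
       ev_sum_Xe = colSums(Xe[ev_rows, , drop = FALSE]))
}

## suffix sums of the columns of V over the risk sets at each event time:
## out[k, j] = sum_{rows at risk at e_k} V[row, j]
.risk_sums <- function(prep, V) {
  V <- as.matrix(V)
  nc <- ncol(V)
  out <- matrix(0, prep$K, nc)
  ok_stop <- prep$idx_stop >= 1L
  ok_start <- prep$idx_start >= 1L
  for (j in seq_len(nc)) {
    cs <- cumsum(V[prep$rev_ord_stop, j])
    col <- numeric(prep$K)
    col[ok_stop] <- cs[prep$idx_stop[ok_stop]]
    cs <- cumsum(V[prep$rev_ord_start, j])
    col[ok_start] <- col[ok_start] - cs[prep$idx_start[ok_start]]
    out[, j] <- col
  }
  out
}

## Newton-Raphson maximization of the Breslow log partial likelihood with a
## fixed-coefficient offset.  Returns coefficients, variance, baseline hazard
## increments and the full (profile) log likelihood.
cox_newton <- function(prep, offset = NULL, init = NULL,
                       max_iter = 50L, tol = 1e-9, compute_var = TRUE) {
  p <- prep$p
  n <- prep$n
  if (is.null(offset)) offset <- numeric(n)
  est <- prep$est
  pe <- length(est)
  beta <- if (is.null(init)) numeric(p) else init
  beta[prep$const_cols] <- 0
  pl <- function(beta) {
    eta <- offset + drop(prep$Xc %*% beta)
    w <- exp(eta)
    S0 <- drop(.risk_sums(prep, w))
    list(eta = eta, w = w, S0 = S0,
         ll = sum(eta[prep$ev_rows]) - sum(prep$d * log(S0)))
  }
  ## risk-set moments S1 (means) and the information matrix at the current w
  moments <- function(cur) {
    M <- .risk_sums(prep, cur$w * cbind(prep$Xe, prep$XX))
    S1 <- M[, seq_len(pe), drop = FALSE] / cur$S0
    I <- matrix(0, pe, pe)
    cnt <- 0L
    for (j in seq_len(pe)) for (l in j:pe) {
      cnt <- cnt + 1L
      I[j, l] <- I[l, j] <-
        sum(prep$d * (M[, pe + cnt] / cur$S0 - S1[, j] * S1[, l]))
    }
    list(S1 = S1, I = I)
  }
  cur <- pl(beta)
  flag <- NULL
  iter <- 0L
  mom <- NULL
  if (pe) {
    repeat {
      iter <- iter + 1L
      mom <- moments(cur)
      U <- prep$ev_sum_Xe - colSums(prep$d * mom$S1)
      step <- tryCatch(solve(mom$I, U), error = function(e) NULL)
      if (is.null(step)) { flag <- "singular information"; break }
      new_beta <- beta
      new_beta[est] <- beta[est] + step
      nxt <- pl(new_beta)
      halvings <- 0L
      while (!is.finite(nxt$ll) || nxt$ll < cur$ll - 1e-12) {
        halvings <- halvings + 1L
        if (halvings > 20L) break
        step <- step / 2
        new_beta[est] <- beta[est] + step
        nxt <- pl(new_beta)
      }
      done <- abs(nxt$ll - cur$ll) < tol * (abs(cur$ll) + 0.1)
      beta <- new_beta
      cur <- nxt
      if (done) break
      if (iter >= max_iter) { flag <- "not converged"; break }
      if (max(abs(beta[est])) > 20) { flag <- "monotone likelihood"; break }
    }
  }
  vcov <- matrix(NA_real_, p, p)
  imat <- matrix(0, p, p)
  schoen_mean <- NULL
  if (pe && compute_var) {
    mom <- moments(cur)
    imat[est, est] <- mom$I
    vcov[est, est] <- tryCatch(solve(mom$I),
                               error = function(e) matrix(NA_real_, pe, pe))
    schoen_mean <- matrix(0, prep$K, p)
    schoen_mean[, est] <- mom$S1
  } else if (compute_var) {
    schoen_mean <- matrix(0, prep$K, p)
  }
  ## Breslow baseline on the original covariate scale:
  ## S0 was computed with centered covariates, rescale by exp(xbar' beta)
  haz <- prep$d / (cur$S0 * exp(sum(prep$xbar * beta)))
  list(beta = stats::setNames(beta, colnames(prep$X)),
       loglik = cur$ll, imat = imat, vcov = vcov,
       hazard = haz, S0c = cur$S0, schoen_mean = schoen_mean,
       iter = iter, flag = flag, offset = offset)
}

## per-row conditional cumulative hazard exp(offset + X beta) * Lambda0(start, stop]
.row_cumhaz <- function(prep, nr, with_offset = TRUE) {
  cum <- cumsum(nr$hazard)
  base <- c(0, cum)[prep$pos_stop + 1L] - c(0, cum)[prep$pos_start + 1L]
  eta <- drop(prep$X %*% nr$beta)
  if (with_offset) eta <- eta + nr$offset
  exp(eta) * base
}

## full semiparametric log likelihood (partial + baseline jump terms):
## sum_events [eta + log dLambda0] - sum_rows cumhaz
.full_loglik <- function(prep, nr) {
  eta <- drop(prep$X %*% nr$beta) + nr$offset
  sum(eta[prep$ev_rows]) + sum(prep$d * log(nr$hazard)) -
    sum(.row_cumhaz(prep, nr))
}

#' Fit a proportional hazards model by Breslow partial likelihood
#'
#' Newton-Raphson fit of a Cox proportional hazards (or intensity) model on
#' counting-process data with optional offsets entering the linear predictor
#' with fixed coefficient 1.  Ties are handled by the Breslow approximation;
#' a row is at risk at `t` iff `start < t <= stop`.
#'
#' @param formula a formula with a `survival::Surv` response, either
#'   `Surv(time, status)` or `Surv(start, stop, status)`, and covariates on
#'   the right-hand side.  A `cluster(id)` term identifies clusters (used by
#'   heterogeneity diagnostics); if absent, a `cluster_id` column in `data`
#'   is used when present.
#' @param data a data frame.
#' @param offset optional numeric vector of offsets (one per row).
#' @param init optional initial coefficients.
#' @return an object of class `"cox_fit"` with components `coefficients`,
#'   `loglik` (Breslow partial log likelihood), `loglik_full` (including the
#'   baseline jump terms), `baseline` (`data.frame` of event times and
#'   Breslow hazard increments), `var`, `n_events`, and a `flag` that is
#'   non-`NULL` for monotone-likelihood or non-converged fits.
#' @examples
#' d <- data.frame(time = c(1, 2, 3, 4), status = c(1, 1, 1, 0),
#'                 x = c(1, 0, 1, 0))
#' f <- fit_cox(survival::Surv(time, status) ~ x, d)
#' coef(f)
#' @export
fit_cox <- function(formula, data, offset = NULL, init = NULL) {
  pd <- .parse_surv_formula(formula, data)
  prep <- cox_prep(pd$start, pd$stop, pd$status, pd$X, pd$cluster)
  nr <- cox_newton(prep, offset = offset, init = init)
  .as_cox_fit(prep, nr, call = match.call(), terms = pd$term_labels)
}

.as_cox_fit <- function(prep, nr, call = NULL, terms = NULL) {
  mart <- prep$status - .row_cumhaz(prep, nr)
  fit <- list(coefficients = nr$beta,
              loglik = nr$loglik,
              loglik_full = .full_loglik(prep, nr),
              var = nr$vcov, imat = nr$imat,
              baseline = data.frame(time = prep$e, hazard = nr$hazard),
              n_events = sum(prep$d),
              martingale = mart,
              flag = nr$flag, iter = nr$iter,
              prep = prep, newton = nr,
              call = call, term_labels = terms)
  class(fit) <- "cox_fit"
  fit
}

.parse_surv_formula <- function(formula, data) {
  tf <- stats::terms(formula, specials = "cluster", data = data)
  mf <- stats::model.frame(tf, data = data)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y)) stop_domain("response must be a survival::Surv object")
  ym <- unclass(y)
  if (ncol(ym) == 2L) {
    start <- rep(0, nrow(ym)); stop <- ym[, 1]; status <- ym[, 2]
  } else {
    start <- ym[, 1]; stop <- ym[, 2]; status <- ym[, 3]
  }
  cl_id <- attr(tf, "specials")$cluster
  cluster <- NULL
  drop_terms <- integer(0)
  if (!is.null(cl_id)) {
    cluster <- mf[[cl_id]]
    drop_terms <- which(attr(tf, "term.labels") %in%
                          colnames(attr(tf, "factors"))[cl_id] |
                        grepl("^cluster\\(", attr(tf, "term.labels")))
  } else if (!is.null(data$cluster_id)) {
    cluster <- data$cluster_id[as.integer(rownames(mf))]
  }
  tl <- attr(tf, "term.labels")
  if (length(drop_terms)) tl <- tl[-drop_terms]
  X <- if (length(tl)) {
    f2 <- stats::reformulate(tl)
    stats::model.matrix(f2, data = mf)[, -1, drop = FALSE]
  } else {
    matrix(0, nrow(mf), 1, dimnames = list(NULL, "(none)"))
  }
  list(start = start, stop = stop, status = status, X = X,
       cluster = cluster, term_labels = tl)
}

#' Breslow cumulative baseline hazard
#'
#' Evaluates the step-function estimate of the cumulative baseline hazard of
#' a fitted model at arbitrary times.
#'
#' @param fit a [fit_cox()] or [fit_frailty()] object.
#' @param t nonnegative evaluation times.
#' @return the cumulative baseline hazard at `t`.
#' @export
breslow_cumhaz <- function(fit, t) {
  if (any(t < 0)) stop_domain("'t' must be >= 0")
  bl <- fit$baseline
  cum <- cumsum(bl$hazard)
  c(0, cum)[findInterval(t, bl$time) + 1L]
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik, df = sum(!object$prep$const_cols), class = "logLik")
}

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' Residuals of a proportional hazards fit
#'
#' @param object a [fit_cox()] object.
#' @param kind `"martingale"` (one per data row), `"schoenfeld"` (one row per
#'   event, covariate minus risk-set weighted mean) or `"scaled_schoenfeld"`
#'   (`n_events * V %*% s + beta`, the standard construction behind the
#'   proportional hazards test).
#' @param ... unused.
#' @return a vector (martingale) or matrix with one row per event, ordered by
#'   event time, with the event times as an attribute.
#' @export
residuals.cox_fit <- function(object,
                              kind = c("martingale", "schoenfeld",
                                       "scaled_schoenfeld"), ...) {
  kind <- match.arg(kind)
  if (kind == "martingale") return(object$martingale)
  prep <- object$prep
  ord <- order(prep$stop[prep$ev_rows])
  rows <- prep$ev_rows[ord]
  tidx <- prep$ev_time_idx[ord]
  s <- prep$Xc[rows, , drop = FALSE] - object$newton$schoen_mean[tidx, , drop = FALSE]
  colnames(s) <- names(object$coefficients)
  if (kind == "scaled_schoenfeld") {
    s <- object$n_events * s %*% object$var
    s <- sweep(s, 2, object$coefficients, "+")
    colnames(s) <- names(object$coefficients)
  }
  attr(s, "time") <- prep$stop[rows]
  s
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Proportional hazards fit (Breslow partial likelihood)\n")
  if (!is.null(x$flag)) cat("  [flag:", x$flag, "]\n")
  print(.coef_table(x))
  cat(sprintf("Partial log likelihood: %.4f on %d events\n",
              x$loglik, x$n_events))
  invisible(x)
}

.coef_table <- function(x) {
  se <- sqrt(diag(as.matrix(x$var)))
  z <- x$coefficients / se
  data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
             se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
             check.names = FALSE, row.names = names(x$coefficients))
}

#' @export
summary.cox_fit <- function(object, ...) {
  out <- list(coefficients = .coef_table(object),
              loglik = object$loglik, n_events = object$n_events,
              flag = object$flag)
  class(out) <- "summary.cox_fit"
  out
}

#' @export
print.summary.cox_fit <- function(x, ...) {
  print(x$coefficients)
  cat(sprintf("Events: %d;  partial log likelihood %.4f\n", x$n_events, x$loglik))
  invisible(x)
}
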