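# Phenome scan: Firth-penalized logistic regression for binary traits,
# linear regression for quantitative traits, BH-FDR across the scan.

firth_parts <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  w <- p * (1 - p)
  XW <- X * w
  info <- crossprod(X, XW)
  cinfo <- chol(info)  # fails if information is not positive definite
  # hat diagonal of W^{1/2} X (X'WX)^{-1} X' W^{1/2}
  h <- rowSums((X * sqrt(w)) * t(backsolve(cinfo, forwardsolve(t(cinfo), t(X * sqrt(w))))))
  loglik <- sum(y * log(p) + (1 - y) * log(1 - p)) + sum(log(diag(cinfo)))
  score <- drop(crossprod(X, y - p + h * (0.5 - p)))
  list(p = p, info = info, h = h, loglik = loglik, score = score)
}

firth_fit <- function(X, y, free = seq_len(ncol(X)), tol = 1e-8, maxit = 50) {
  beta <- numeric(ncol(X))
  trace <- numeric(0)
  parts <- firth_parts(X, y, beta)
  for (it in seq_len(maxit)) {
    g <- parts$score[free]
    trace[it] <- max(abs(g))
    if (max(abs(g)) < tol) {
      return(list(beta = beta, loglik = parts$loglik, info = parts$info,
                  iter = it - 1L, converged = TRUE, trace = trace))
    }
    step <- solve(parts$info[free, free, drop = FALSE], g)
    # step-halving keeps the penalized log-likelihood increasing
    for (half in 0:20) {
      cand <- beta
      cand[free] <- beta[free] + step / 2^half
      cand_parts <- tryCatch(firth_parts(X, y, cand), error = function(e) NULL)
      if (!is.null(cand_parts) && cand_parts$loglik > parts$loglik - 1e-12) {
        beta <- cand
        parts <- cand_parts
        break
      }
      if (half == 20) break  # no improving step; let convergence check decide
    }
  }
  if (max(abs(parts$score[free])) >= tol) {
    stop(sprintf("Firth fit did not converge in %d iterations; score-norm trace: %s",
                 maxit, paste(signif(trace, 3), collapse = ", ")))
  }
  list(beta = beta, loglik = parts$loglik, info = parts$info,
       iter = maxit, converged = TRUE, trace = trace)
}

#' Firth-penalized logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' `l(beta) + 0.5 * log det I(beta)`, where `I` is the Fisher information.
#' The penalty keeps estimates finite under complete separation and reduces
#' the small-sample bias that plain maximum likelihood suffers with rare
#' outcomes, which is why it is the model of choice for scanning imbalanced
#' binary phenotypes. Newton iterations use the Firth-modified score with
#' step-halving; convergence requires the score norm to fall below `tol`.
#'
#' P-values are penalized likelihood-ratio tests: the tested coefficient is
#' fixed at zero, the remaining coefficients are re-maximized (penalty still
#' computed from the full-model information), and twice the penalized
#' log-likelihood difference is referred to chi-square on 1 df.
#'
#' @param y binary outcome vector (0/1).
#' @param X design matrix (including an intercept column); must be full
#'   rank.
#' @param test columns (names or indices) for which penalized
#'   likelihood-ratio p-values are computed; defaults to all non-intercept
#'   columns.
#' @param tol convergence tolerance on the score norm (default 1e-8).
#' @param maxit maximum Newton iterations (default 50); non-convergence is
#'   an error that reports the score-norm trace.
#' @return A list of class `firth_fit`: `coefficients`, `se`, `vcov`,
#'   `loglik` (penalized), `p_plrt` (named), `iter`, `converged`.
#' @export
firth_logistic <- function(y, X, test = NULL, tol = 1e-8, maxit = 50) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  fit <- firth_fit(X, y, tol = tol, maxit = maxit)
  vc <- solve(fit$info)
  se <- sqrt(diag(vc))
  if (is.null(test)) {
    test <- setdiff(colnames(X), "(Intercept)")
  } else if (is.numeric(test)) {
    test <- colnames(X)[test]
  }
  p <- setNames(rep(NA_real_, length(test)), test)
  for (nm in test) {
    j <- match(nm, colnames(X))
    fit0 <- firth_fit(X, y, free = setdiff(seq_len(ncol(X)), j),
                      tol = tol, maxit = maxit)
    p[nm] <- pchisq(2 * (fit$loglik - fit0$loglik), df = 1, lower.tail = FALSE)
  }
  out <- list(coefficients = setNames(fit$beta, colnames(X)),
              se = setNames(se, colnames(X)), vcov = vc,
              loglik = fit$loglik, p_plrt = p,
              iter = fit$iter, converged = fit$converged)
  class(out) <- "firth_fit"
  out
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth-penalized logistic regression\n")
  tab <- data.frame(beta = x$coefficients, se = x$se,
                    p_plrt = x$p_plrt[names(x$coefficients)])
  print(tab)
  invisible(x)
}

#' Scan phenotypes for association with carrier status
#'
#' Rule-based model dispatch per phenotype: columns whose non-missing values
#' lie in `{0, 1}` are tested with Firth-penalized logistic regression
#' ([firth_logistic()], penalized likelihood-ratio p for the exposure);
#' all other numeric columns with linear least squares. Each phenotype is
#' analysed on its complete cases (exposure, covariates and phenotype all
#' observed). Benjamini-Hochberg q-values are computed jointly across every
#' tested phenotype, and the significant set is `q < fdr_level`. Phenotypes
#' with fewer than two distinct values are skipped with a warning.
#'
#' @param phenotypes data frame of numeric phenotype columns (a `sample_id`
#'   column, if present, is ignored).
#' @param exposure logical or numeric exposure per sample (e.g. ePAR
#'   carrier status).
#' @param covariates optional data frame or matrix of covariates.
#' @param fdr_level false-discovery-rate threshold (default 0.05).
#' @return Data frame of class `phenome_scan`: `phenotype`, `kind`,
#'   `model`, `beta`, `se`, `p_value`, `q_value`, `n_used`, `significant`.
#' @export
phenome_scan <- function(phenotypes, exposure, covariates = NULL,
                         fdr_level = 0.05) {
  stopifnot(is.data.frame(phenotypes))
  phenotypes <- phenotypes[, setdiff(names(phenotypes), "sample_id"), drop = FALSE]
  if (!ncol(phenotypes)) stop("no phenotypes to test")
  exposure <- as.numeric(exposure)
  if (length(exposure) != nrow(phenotypes)) {
    stop("exposure must be defined for every sample")
  }
  if (anyNA(exposure)) stop("exposure must be defined for every sample")
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)

  rows <- list()
  for (nm in names(phenotypes)) {
    yv <- phenotypes[[nm]]
    cc <- !is.na(yv) & if (is.null(covm)) TRUE else complete.cases(covm)
    y <- yv[cc]
    if (length(unique(y)) < 2) {
      warning(sprintf("phenotype '%s' has fewer than two distinct values; skipped", nm))
      next
    }
    Xc <- cbind(`(Intercept)` = 1, exposure = exposure[cc],
                if (!is.null(covm)) covm[cc, , drop = FALSE])
    if (all(y %in% c(0, 1))) {
      fit <- firth_logistic(y, Xc, test = "exposure")
      rows[[nm]] <- data.frame(phenotype = nm, kind = "binary",
                               model = "FIRTH_LOGISTIC",
                               beta = unname(fit$coefficients["exposure"]),
                               se = unname(fit$se["exposure"]),
                               p_value = unname(fit$p_plrt["exposure"]),
                               n_used = length(y))
    } else {
      df <- data.frame(.y = y, Xc[, -1, drop = FALSE], check.names = TRUE)
      fit <- lm(.y ~ ., data = df)
      sm <- summary(fit)$coefficients
      k <- match("exposure", rownames(sm))
      rows[[nm]] <- data.frame(phenotype = nm, kind = "quantitative",
                               model = "LINEAR",
                               beta = sm[k, "Estimate"], se = sm[k, "Std. Error"],
                               p_value = sm[k, "Pr(>|t|)"], n_used = length(y))
    }
  }
  if (!length(rows)) stop("no testable phenotypes")
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < fdr_level
  class(res) <- c("phenome_scan", class(res))
  res
}
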