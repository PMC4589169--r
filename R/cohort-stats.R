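#' Pooled-variance two-sample t test
#'
#' Works either from raw samples (`x`, `y`) or directly from printed summary
#' statistics (means, SDs, group sizes), which is how published demographic
#' tables are re-checked. Equal variances are assumed;
#' `df = n1 + n2 - 2`.
#'
#' @param x,y raw samples, or `NULL` when summaries are supplied.
#' @param mean1,sd1,n1,mean2,sd2,n2 summary statistics.
#' @return list with `t`, `df`, `p` (two-tailed).
#' @export
pooled_t <- function(x = NULL, y = NULL,
                     mean1, sd1, n1, mean2, sd2, n2) {
  if (!is.null(x) || !is.null(y)) {
    stopifnot(is.numeric(x), is.numeric(y))
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  if (sd1 <= 0 && sd2 <= 0 && mean1 == mean2) {
    return(list(t = 0, df = n1 + n2 - 2, p = 1))
  }
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be nonnegative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Mann-Whitney U test with midrank ties
#'
#' Reports `U = min(U1, U2)` (so complete separation gives exactly 0) with
#' `U1 + U2 = n1 * n2`. The p-value is exact — full enumeration of rank
#' subsets, valid under ties — when the number of group assignments is small
#' enough (`choose(n1 + n2, n1) <= 2e5`), otherwise a tie-corrected normal
#' approximation is used; the `p_method` field records which.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `U1`, `U2`, `p` (two-tailed), `p_method`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be nonempty")
  r <- rank(c(x, y))  # midranks
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  N <- n1 + n2
  if (choose(N, n1) <= 2e5) {
    combos <- utils::combn(N, n1)
    Us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    Umin <- pmin(Us, n1 * n2 - Us)
    p <- min(1, mean(Umin <= U + 1e-9) )
    p_method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U1 - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    p_method <- "normal_tie_corrected"
  }
  list(U = U, U1 = U1, U2 = U2, p = p, p_method = p_method)
}

# midrank transform
.midrank <- function(v) rank(v, ties.method = "average")

# residuals of v on covariate columns (with intercept); rank-deficiency safe
.resid_on <- function(v, covs) {
  X <- cbind(1, covs)
  qr.resid(qr(X), v)
}

#' Partial correlation with covariate control
#'
#' Pearson variant: correlation of the residuals of `x` and `y` after
#' ordinary least squares on the covariates. Spearman variant: the same
#' procedure after midrank-transforming `x`, `y` and every covariate (the
#' conventional SPSS-style partial rank correlation). Significance uses
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k` covariates;
#' one-tailed p-values are available for directional hypotheses.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data.frame of covariates, or
#'   `NULL` for a simple correlation.
#' @param method `"pearson"` or `"spearman"`.
#' @param alternative `"two.sided"`, `"greater"` (positive association) or
#'   `"less"`.
#' @return object of class `correlation_result`: `estimate`, `method`,
#'   `controlled`, `n`, `df`, `statistic`, `p.value`, `alternative`.
#' @export
partial_corr <- function(x, y, covariates = NULL,
                         method = c("pearson", "spearman"),
                         alternative = c("two.sided", "greater", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (is.null(covariates)) {
    covs <- NULL
  } else {
    covs <- as.matrix(as.data.frame(covariates))
  }
  dat <- cbind(x = x, y = y, covs)
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  n <- nrow(dat)
  k <- if (is.null(covs)) 0L else ncol(covs)
  if (n <= k + 2) stop("need n > number of covariates + 2")
  m <- dat
  if (method == "spearman") {
    m <- apply(dat, 2, .midrank)
  }
  if (stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0) {
    stop("constant input (after ranking/adjustment): correlation undefined")
  }
  if (k > 0) {
    rx <- .resid_on(m[, 1], m[, -(1:2), drop = FALSE])
    ry <- .resid_on(m[, 2], m[, -(1:2), drop = FALSE])
  } else {
    rx <- m[, 1] - mean(m[, 1])
    ry <- m[, 2] - mean(m[, 2])
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant input (after ranking/adjustment): correlation undefined")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(tstat), df),
    greater = stats::pt(tstat, df, lower.tail = FALSE),
    less = stats::pt(tstat, df)
  )
  mlab <- if (k > 0) paste0("partial_", method) else method
  structure(
    list(estimate = r, method = mlab,
         controlled = if (is.null(covs)) character(0) else colnames(covs),
         n = n, df = df, statistic = tstat, p.value = p,
         alternative = alternative),
    class = "correlation_result"
  )
}

#' Route a two-group comparison to a parametric or nonparametric test
#'
#' Both groups are screened with the Shapiro-Wilk test; the comparison is
#' routed to the parametric t test only when neither group rejects normality
#' at `alpha`. Groups too small to test (n < 3) force the nonparametric
#' route and are flagged.
#'
#' @param x,y per-group samples.
#' @param alpha normality screening level.
#' @return list with `route` ("parametric"/"nonparametric"), `shapiro_p`
#'   (length 2, NA when not testable), `flag`.
#' @export
route_test <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  pvals <- vapply(list(x, y), function(s) {
    if (length(s) < 3 || length(s) > 5000 || stats::sd(s) == 0) {
      return(NA_real_)
    }
    stats::shapiro.test(s)$p.value
  }, numeric(1))
  if (any(is.na(pvals))) {
    return(list(route = "nonparametric", shapiro_p = pvals,
                flag = "group not testable for normality (n < 3 or constant)"))
  }
  route <- if (all(pvals > alpha)) "parametric" else "nonparametric"
  list(route = route, shapiro_p = pvals, flag = NA_character_)
}

#' Pearson chi-square test for a 2x2 table (no continuity correction)
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @return list with `chisq`, `df` (= 1), `p`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(dim(tab) != 2L) || any(tab < 0)) {
    stop("need a 2x2 table of nonnegative counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal: chi-square undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Forward stepwise linear regression with removal
#'
#' SPSS-style stepwise selection: at each step the candidate with the
#' smallest entry p-value below `entry_p` joins the model; after each entry,
#' any included predictor whose p-value has risen above `removal_p` is
#' dropped (worst first); iteration stops when nothing changes. Reports
#' standardized coefficients, model R-squared and F, and — for candidates
#' left out — the standardized beta and p they would have if entered into
#' the final model.
#'
#' @param data data.frame holding the response and candidates (complete-case
#'   rows are used; listwise deletion).
#' @param response name of the dependent variable.
#' @param candidates character vector of candidate predictor names.
#' @param entry_p,removal_p entry and removal thresholds (entry < removal).
#' @param max_steps safety cap on selection iterations.
#' @return object of class `stepwise_model`: `selected` (in entry order),
#'   `coefficients` (term, beta_std, p per selected predictor),
#'   `excluded` (same columns for non-selected candidates), `r_squared`,
#'   `f_statistic`, `f_df` (c(df1, df2)), `model_p`, `n`.
#' @export
stepwise_forward <- function(data, response, candidates,
                             entry_p = 0.05, removal_p = 0.10,
                             max_steps = 50L) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(candidates %in% names(data)), entry_p < removal_p)
  dat <- data[stats::complete.cases(data[c(response, candidates)]),
              c(response, candidates), drop = FALSE]
  n <- nrow(dat)
  if (n <= length(candidates) + 2) {
    stop("too few complete cases for the candidate set")
  }
  X <- scale(as.matrix(dat[candidates]))
  if (any(!is.finite(X))) stop("constant candidate predictor")
  if (length(candidates) > 1L) {
    kap <- kappa(X, exact = TRUE)
    if (kap > 1e8) {
      cm <- abs(stats::cor(dat[candidates]))
      diag(cm) <- 0
      worst <- sort(which(cm == max(cm), arr.ind = TRUE)[1, ])
      stop("collinear candidates (condition number ", format(kap, digits = 3),
           "): ", candidates[worst[1]], " and ", candidates[worst[2]])
    }
  }

  coef_p <- function(vars) {
    f <- stats::reformulate(vars, response)
    fit <- stats::lm(f, data = dat)
    s <- summary(fit)$coefficients[-1, , drop = FALSE]
    list(fit = fit,
         p = stats::setNames(s[, 4], rownames(s)),
         est = stats::setNames(s[, 1], rownames(s)))
  }

  selected <- character(0)
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      entry <- vapply(pool, function(v) {
        coef_p(c(selected, v))$p[[v]]
      }, numeric(1))
      if (min(entry) < entry_p) {
        selected <- c(selected, pool[which.min(entry)])
        changed <- TRUE
      }
    }
    if (length(selected)) {
      repeat {
        pv <- coef_p(selected)$p
        if (max(pv) <= removal_p) break
        drop <- names(pv)[which.max(pv)]
        selected <- setdiff(selected, drop)
        changed <- TRUE
        if (!length(selected)) break
      }
    }
    if (!changed) break
  }

  sd_y <- stats::sd(dat[[response]])
  std_beta <- function(est, vars) {
    unname(est[vars]) * vapply(vars, function(v) stats::sd(dat[[v]]),
                               numeric(1)) / sd_y
  }
  if (length(selected)) {
    fin <- coef_p(selected)
    sm <- summary(fin$fit)
    coefs <- data.frame(
      term = selected,
      beta_std = std_beta(fin$est, selected),
      p = unname(fin$p[selected]),
      row.names = NULL
    )
    r2 <- sm$r.squared
    fstat <- unname(sm$fstatistic[1])
    fdf <- unname(sm$fstatistic[2:3])
    model_p <- stats::pf(fstat, fdf[1], fdf[2], lower.tail = FALSE)
  } else {
    coefs <- data.frame(term = character(0), beta_std = numeric(0),
                        p = numeric(0))
    r2 <- 0
    fstat <- NA_real_
    fdf <- c(NA_real_, NA_real_)
    model_p <- NA_real_
  }
  pool <- setdiff(candidates, selected)
  excluded <- do.call(rbind, lapply(pool, function(v) {
    cp <- coef_p(c(selected, v))
    data.frame(term = v, beta_std = std_beta(cp$est, v),
               p = unname(cp$p[[v]]), row.names = NULL)
  }))
  if (is.null(excluded)) {
    excluded <- data.frame(term = character(0), beta_std = numeric(0),
                           p = numeric(0))
  }
  structure(
    list(response = response, candidates = candidates, selected = selected,
         coefficients = coefs, excluded = excluded, r_squared = r2,
         f_statistic = fstat, f_df = fdf, model_p = model_p, n = n),
    class = "stepwise_model"
  )
}
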