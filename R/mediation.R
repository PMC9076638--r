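# Bayesian moderated mediation with exGaussian residuals.
#
# Outcome model:  Y = i1 + c1*X + c2*W + c3*X*W + b1*M + b2*M*W (+ g*C) + e1
# Mediator model: M = i2 + a1*X + a2*W + a3*X*W + e2
# e ~ exGaussian(0, sigma, beta_exg) with identity links on mu, sigma and
# beta. Uniform priors on all parameters; posterior sampled with an adaptive
# random-walk Metropolis scheme (adaptation restricted to warmup).

# exGaussian log density: convolution of Normal(mu, sigma) and
# Exponential(mean beta). Numerically stable via pnorm on the log scale.
dexgauss <- function(x, mu = 0, sigma = 1, beta = 1, log = FALSE) {
  stopifnot(sigma > 0, beta > 0)
  z <- x - mu
  ll <- -log(beta) + (sigma^2 / (2 * beta^2)) - z / beta +
    pnorm(z / sigma - sigma / beta, log.p = TRUE)
  if (log) ll else exp(ll)
}

# Design matrices of the two models given centered data.
mediation_design <- function(data, x, m, w, covariate = NULL) {
  X <- data[[x]]; W <- data[[w]]; M <- data[[m]]
  out <- cbind(1, X, W, X * W, M, M * W)
  colnames(out) <- c("i1", "c1", "c2", "c3", "b1", "b2")
  if (!is.null(covariate)) {
    out <- cbind(out, data[[covariate]])
    colnames(out)[ncol(out)] <- "g1"
  }
  med <- cbind(1, X, W, X * W)
  colnames(med) <- c("i2", "a1", "a2", "a3")
  list(outcome = out, mediator = med)
}

# Adaptive random-walk Metropolis for one exGaussian regression
# y = D %*% coef + exGaussian(0, sigma, beta). All parameters (coefficients
# plus log sigma, log beta) move in one joint block whose proposal
# covariance adapts to the empirical posterior covariance during warmup
# (Haario-style) and is frozen afterwards; the intercept and the
# exponential mean are strongly correlated (mu + beta ridge), which the
# joint proposal follows.
rwm_exgauss <- function(y, D, iter, warmup, prior_coef = 50,
                        prior_scale = 50, init = NULL) {
  n <- length(y); k <- ncol(D); d <- k + 2
  ls <- function(th) {
    coef <- th[seq_len(k)]
    sigma <- exp(th[k + 1]); beta <- exp(th[k + 2])
    if (any(abs(coef) > prior_coef) || sigma > prior_scale ||
        beta > prior_scale) return(-Inf)
    mu <- drop(D %*% coef)
    # Jacobian of the log-scale parametrization keeps the prior uniform on
    # (0, prior_scale] for sigma and beta
    sum(dexgauss(y, mu, sigma, beta, log = TRUE)) + th[k + 1] + th[k + 2]
  }
  if (is.null(init)) {
    fit <- stats::lm.fit(D, y)
    res <- fit$residuals
    b0 <- max(sd(res) / 2, 1e-3)
    init <- c(fit$coefficients - c(b0, rep(0, k - 1)),
              log(max(sd(res) / 2, 1e-3)), log(b0))
  }
  th <- init
  cur <- ls(th)
  if (!is.finite(cur)) { th <- c(rep(0, k), 0, 0); cur <- ls(th) }
  draws <- matrix(NA_real_, iter - warmup, d)
  hist <- matrix(NA_real_, iter, d)
  # start from the OLS covariance shape, diagonal for the log scales
  XtX <- crossprod(D)
  S0 <- diag(d) * 0.01
  prec <- tryCatch(solve(XtX / n), error = function(e) diag(k))
  S0[seq_len(k), seq_len(k)] <- prec / n
  Rch <- chol(S0 + diag(1e-8, d))
  lambda <- 1
  acc <- 0; acc_r <- 0
  ridge_sc <- max(exp(init[k + 2]) / 4, 1e-3)   # fixed => symmetric move
  ind <- NULL   # independence-proposal approximation (mean, chol, logdet)
  lq <- function(x) {
    z <- backsolve(ind$R, x - ind$m, transpose = TRUE)
    -0.5 * sum(z^2) - ind$logdet
  }
  for (it in seq_len(iter)) {
    if (!is.null(ind) && runif(1) < 0.5) {
      # independence move from the adapted Gaussian approximation
      prop <- ind$m + drop(rnorm(d) %*% ind$R)
      lp <- ls(prop)
      if (log(runif(1)) < (lp - lq(prop)) - (cur - lq(th))) {
        th <- prop; cur <- lp
      }
    }
    prop <- th + sqrt(lambda) * drop(rnorm(d) %*% Rch)
    lp <- ls(prop)
    if (log(runif(1)) < lp - cur) { th <- prop; cur <- lp; acc <- acc + 1 }
    # ridge move: shift mass between intercept and exponential mean along
    # i1 + beta = const (symmetric in (i1, beta) coordinates, hence the
    # Jacobian correction removing the log-scale term)
    dlt <- rnorm(1, 0, ridge_sc)
    bnew <- exp(th[k + 2]) - dlt
    if (bnew > 0) {
      prop <- th
      prop[1] <- th[1] + dlt
      prop[k + 2] <- log(bnew)
      lp <- ls(prop)
      if (log(runif(1)) < (lp - prop[k + 2]) - (cur - th[k + 2])) {
        th <- prop; cur <- lp; acc_r <- acc_r + 1
      }
    }
    hist[it, ] <- th
    if (it <= warmup && it %% 100 == 0) {
      lambda <- lambda * exp(acc / 100 - 0.3)
      ridge_sc <- ridge_sc * exp(acc_r / 100 - 0.35)
      acc <- 0; acc_r <- 0
    }
    # Haario-style adaptive covariance with diminishing adaptation: the
    # empirical covariance of the whole history stabilizes as 1/t
    if (it >= 200 && (it %% 100 == 0 && it <= warmup ||
                      it %% 500 == 0 && it > warmup)) {
      win <- hist[seq(max(100, floor(it / 2)), it), , drop = FALSE]
      emp <- stats::cov(win)
      Rch <- tryCatch(chol(2.38^2 / d * emp + diag(1e-8, d)),
                      error = function(e) Rch)
      Rind <- tryCatch(chol(1.5 * emp + diag(1e-8, d)),
                       error = function(e) NULL)
      if (!is.null(Rind))
        ind <- list(m = colMeans(win), R = Rind,
                    logdet = sum(log(diag(Rind))))
    }
    if (it > warmup) draws[it - warmup, ] <- th
  }
  draws[, k + 1] <- exp(draws[, k + 1])
  draws[, k + 2] <- exp(draws[, k + 2])
  colnames(draws) <- c(colnames(D), "sigma", "beta_exg")
  draws
}

# Split R-hat (Gelman et al.): chains x iterations matrix -> scalar.
split_rhat <- function(mat) {
  m <- ncol(mat)               # chains
  n2 <- floor(nrow(mat) / 2)
  halves <- cbind(mat[seq_len(n2), , drop = FALSE],
                  mat[n2 + seq_len(n2), , drop = FALSE])
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  B <- n2 * var(means)
  Wv <- mean(vars)
  if (Wv == 0) return(1)
  sqrt(((n2 - 1) / n2 * Wv + B / n2) / Wv)
}

# Effective sample size from pooled chain autocorrelations (Geyer initial
# positive sequence, simplified).
ess_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (var(as.vector(mat)) == 0) return(n * m)
  rho_sum <- 0
  for (ch in seq_len(m)) {
    x <- mat[, ch]
    if (var(x) == 0) next
    ac <- drop(stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf)[-1]
    s <- 0
    for (l in seq(1, length(ac) - 1, by = 2)) {
      pair <- ac[l] + ac[l + 1]
      if (is.na(pair) || pair <= 0) break
      s <- s + pair
    }
    rho_sum <- rho_sum + s
  }
  (n * m) / (1 + 2 * rho_sum / m)
}

#' Fit the Bayesian moderated mediation model
#'
#' Jointly estimates the exGaussian outcome model
#' `Y = i1 + c1 X + c2 W + c3 XW + b1 M + b2 MW (+ g1 C) + e1` and mediator
#' model `M = i2 + a1 X + a2 W + a3 XW + e2` by MCMC (adaptive random-walk
#' Metropolis; uniform priors, identity links on mu, sigma and beta).
#' Convergence is gated on split R-hat < 1.01 and ESS > 400 per
#' coefficient; a fit failing the gates is flagged, never silently
#' accepted.
#'
#' @param data Data frame with the model columns.
#' @param outcome,x,m,w Column names of outcome `Y`, independent `X`,
#'   mediator `M`, moderator `W`.
#' @param covariate Optional centered covariate for the outcome model (e.g.
#'   transition mode coded ±0.5).
#' @param chains,iter,warmup MCMC layout. Defaults 4 chains of 10000
#'   iterations, first 1000 discarded.
#' @param prior_coef,prior_scale Half-width of the uniform prior on
#'   coefficients; upper bound of the uniform prior on sigma and beta.
#'   Defaults 50 (recorded in the result).
#' @param center Center `x`, `m`, `w` (and the covariate) before fitting
#'   (default `TRUE`). With `center = FALSE` non-centered predictors are an
#'   error: the model contract requires centered inputs.
#' @param seed Integer seed.
#' @return A `mediation_fit`: draws matrices (`chains*draws` x parameter)
#'   for both models, per-parameter diagnostics, convergence flag, data and
#'   settings. Derived path draws come from [conditional_effects()].
#' @export
fit_mediation <- function(data, outcome = "Y", x = "X", m = "M", w = "W",
                          covariate = NULL, chains = 4, iter = 10000,
                          warmup = 1000, prior_coef = 50, prior_scale = 50,
                          center = TRUE, seed = 1) {
  if (nrow(data) < 20) stop_invalid("need n >= 20 observations")
  vars <- c(outcome, x, m, w, covariate)
  stopifnot(all(vars %in% names(data)))
  data <- data[complete.cases(data[vars]), vars]
  preds <- c(x, m, w, covariate)
  if (center) {
    for (v in preds) data[[v]] <- data[[v]] - mean(data[[v]])
  } else if (any(abs(vapply(preds, function(v) mean(data[[v]]),
                            numeric(1))) > 1e-6)) {
    stop_invalid(paste("predictors must be centered before fitting;",
                       "center them (or leave `center = TRUE`)"))
  }
  des <- mediation_design(data, x, m, w, covariate)
  y <- data[[outcome]]; mv <- data[[m]]

  run_model <- function(yv, D, label) {
    ch <- lapply(seq_len(chains), function(cc) {
      with_seed(derive_seed(seed, "mediation", label, cc), {
        init <- NULL
        if (cc > 1) {
          fit <- stats::lm.fit(D, yv)
          init <- c(fit$coefficients + rnorm(ncol(D), 0, 0.05),
                    log(max(sd(fit$residuals) / 2, 1e-3)) + rnorm(1, 0, 0.1),
                    log(max(sd(fit$residuals) / 2, 1e-3)) + rnorm(1, 0, 0.1))
        }
        rwm_exgauss(yv, D, iter, warmup, prior_coef, prior_scale, init)
      })
    })
    draws <- do.call(rbind, ch)
    diag <- purrr::map_dfr(colnames(draws), function(p) {
      mat <- vapply(ch, function(d) d[, p], numeric(nrow(ch[[1]])))
      tibble::tibble(model = label, parameter = p,
                     rhat = split_rhat(mat), ess = ess_basic(mat))
    })
    list(draws = draws, diag = diag, chains = ch)
  }

  out_fit <- run_model(y, des$outcome, "outcome")
  med_fit <- run_model(mv, des$mediator, "mediator")
  diagnostics <- dplyr::bind_rows(out_fit$diag, med_fit$diag)
  converged <- all(diagnostics$rhat < 1.01) && all(diagnostics$ess > 400)
  if (!converged)
    warning("mediation fit flagged non-converged (R-hat/ESS gates)")

  # Bayesian R2 per model: var(linpred) / (var(linpred) + residual var)
  bayes_r2 <- function(draws, D) {
    k <- ncol(D)
    lp_var <- apply(draws[, seq_len(k), drop = FALSE] %*% t(D), 1, var)
    res_var <- draws[, "sigma"]^2 + draws[, "beta_exg"]^2
    mean(lp_var / (lp_var + res_var))
  }

  structure(list(
    outcome_draws = out_fit$draws, mediator_draws = med_fit$draws,
    diagnostics = diagnostics, converged = converged,
    r2 = c(outcome = bayes_r2(out_fit$draws, des$outcome),
           mediator = bayes_r2(med_fit$draws, des$mediator)),
    data = data, vars = list(outcome = outcome, x = x, m = m, w = w,
                             covariate = covariate),
    settings = list(chains = chains, iter = iter, warmup = warmup,
                    prior_coef = prior_coef, prior_scale = prior_scale,
                    seed = seed)),
    class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("<mediation_fit> %d draws x %d chains%s\n",
              nrow(x$outcome_draws) / x$settings$chains, x$settings$chains,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(tidy.mediation_fit(x))
  invisible(x)
}

#' Total effect model (no mediator)
#'
#' Fits the reduced exGaussian model `Y = i + tau1 X + tau2 W + tau3 XW
#' (+ g1 C) + e` whose X path gives the total effect
#' `tau(W) = tau1 + tau3 W`.
#'
#' @inheritParams fit_mediation
#' @return List with `draws`, `diagnostics`, `converged`.
#' @export
total_effect <- function(data, outcome = "Y", x = "X", w = "W",
                         covariate = NULL, chains = 4, iter = 10000,
                         warmup = 1000, prior_coef = 50, prior_scale = 50,
                         center = TRUE, seed = 1) {
  vars <- c(outcome, x, w, covariate)
  stopifnot(all(vars %in% names(data)))
  data <- data[complete.cases(data[vars]), vars]
  preds <- c(x, w, covariate)
  if (center) for (v in preds) data[[v]] <- data[[v]] - mean(data[[v]])
  D <- cbind(1, data[[x]], data[[w]], data[[x]] * data[[w]])
  colnames(D) <- c("i", "tau1", "tau2", "tau3")
  if (!is.null(covariate)) {
    D <- cbind(D, data[[covariate]]); colnames(D)[ncol(D)] <- "g1"
  }
  ch <- lapply(seq_len(chains), function(cc) {
    with_seed(derive_seed(seed, "total", cc),
              rwm_exgauss(data[[outcome]], D, iter, warmup,
                          prior_coef, prior_scale))
  })
  draws <- do.call(rbind, ch)
  diag <- purrr::map_dfr(colnames(draws), function(p) {
    mat <- vapply(ch, function(d) d[, p], numeric(nrow(ch[[1]])))
    tibble::tibble(parameter = p, rhat = split_rhat(mat),
                   ess = ess_basic(mat))
  })
  list(draws = draws, diagnostics = diag,
       converged = all(diag$rhat < 1.01) && all(diag$ess > 400))
}

#' Conditional path and effect draws at moderator quintile levels
#'
#' Evaluates the moderated paths at the lowest/highest sample quintile
#' boundaries (20th/80th percentile) of the moderator:
#' `alpha(W) = a1 + a3 W`, `beta(W) = b1 + b2 W`,
#' `tau'(W) = c1 + c3 W`, `indirect(W) = alpha(W) * beta(W)`; the direct
#' effect is additionally reported at mediator quintile levels (it varies
#' with M only through the `b2 M W` term's derivative structure, so it is
#' constant in M; M levels are carried for the conditional outcome
#' simulations).
#'
#' @param fit A `mediation_fit`.
#' @param w_levels,m_levels Moderator / mediator evaluation levels; default
#'   the 20th and 80th percentiles of the fitted (centered) sample.
#' @return Tibble of draws: `w_level`, `draw`, `alpha`, `beta`,
#'   `tau_prime`, `indirect`.
#' @export
conditional_effects <- function(fit, w_levels = NULL, m_levels = NULL) {
  stopifnot(inherits(fit, "mediation_fit"))
  if (!fit$converged)
    warning("conditional effects from a non-converged fit")
  Wd <- fit$data[[fit$vars$w]]
  if (length(unique(Wd)) < 2) stop_invalid("moderator is constant")
  if (is.null(w_levels)) {
    w_levels <- unname(quantile(Wd, c(0.2, 0.8)))
    if (length(unique(Wd)) == 2) w_levels <- sort(unique(Wd))
  }
  if (is.null(m_levels))
    m_levels <- unname(quantile(fit$data[[fit$vars$m]], c(0.2, 0.8)))
  od <- fit$outcome_draws; md <- fit$mediator_draws
  purrr::map_dfr(w_levels, function(wl) {
    tibble::tibble(
      w_level = wl, draw = seq_len(nrow(od)),
      alpha = md[, "a1"] + md[, "a3"] * wl,
      beta = od[, "b1"] + od[, "b2"] * wl,
      tau_prime = od[, "c1"] + od[, "c3"] * wl,
      indirect = (md[, "a1"] + md[, "a3"] * wl) *
        (od[, "b1"] + od[, "b2"] * wl))
  })
}

#' Probability of direction
#'
#' Share of the posterior on its dominant side of zero, in percent
#' (50-100).
#'
#' @param draws Posterior draws (>= 1000 recommended; fewer are accepted
#'   with reduced resolution).
#' @return pd in `[50, 100]`.
#' @export
pd <- function(draws) {
  if (!length(draws)) stop_invalid("no draws")
  if (all(draws == 0)) {
    warning("all draws exactly zero; pd = 50")
    return(50)
  }
  100 * max(mean(draws > 0), mean(draws < 0))
}

#' Convert probability of direction to a two-sided p-value
#'
#' `p = 2 * (1 - pd / 100)`.
#'
#' @param pd_percent pd in `[50, 100]`.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
pd_to_p <- function(pd_percent) {
  if (any(pd_percent < 50 | pd_percent > 100))
    stop_invalid("pd must lie in [50, 100]")
  2 * (1 - pd_percent / 100)
}

#' Highest density interval
#'
#' Shortest interval containing the stated posterior mass (89% by default).
#'
#' @param draws Posterior draws.
#' @param mass Probability mass in (0, 1). Default 0.89.
#' @return Named numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.89) {
  if (mass <= 0 || mass >= 1) stop_invalid("`mass` must be in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[seq_len(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Tidy posterior summaries of a mediation fit
#'
#' @param x A `mediation_fit`.
#' @param hdi_mass HDI mass. Default 0.89.
#' @param ... Unused.
#' @return Tibble: `model`, `parameter`, `mean`, `median`, `hdi89_lo`,
#'   `hdi89_hi`, `pd`, `p_equiv`, `rhat`, `ess`.
#' @method tidy mediation_fit
#' @export
tidy.mediation_fit <- function(x, hdi_mass = 0.89, ...) {
  summ <- function(draws, label) {
    purrr::map_dfr(colnames(draws), function(p) {
      d <- draws[, p]
      h <- hdi(d, hdi_mass)
      pdv <- if (p %in% c("sigma", "beta_exg")) NA_real_ else pd(d)
      tibble::tibble(model = label, parameter = p, mean = mean(d),
                     median = median(d), hdi89_lo = h[["lower"]],
                     hdi89_hi = h[["upper"]], pd = pdv,
                     p_equiv = ifelse(is.na(pdv), NA_real_, pd_to_p(pdv)))
    })
  }
  dplyr::left_join(
    dplyr::bind_rows(summ(x$outcome_draws, "outcome"),
                     summ(x$mediator_draws, "mediator")),
    x$diagnostics, by = c("model", "parameter"))
}

#' One-row fit summary
#'
#' @param x A `mediation_fit`.
#' @param ... Unused.
#' @return Tibble with convergence flag, worst R-hat, smallest ESS,
#'   Bayesian R2 of both models, n, chains, draws.
#' @method glance mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(
    converged = x$converged, max_rhat = max(x$diagnostics$rhat),
    min_ess = min(x$diagnostics$ess), r2_outcome = x$r2[["outcome"]],
    r2_mediator = x$r2[["mediator"]], n = nrow(x$data),
    chains = x$settings$chains,
    draws = nrow(x$outcome_draws))
}
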