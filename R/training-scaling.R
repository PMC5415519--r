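#' Build nested training subsets along one variability axis
#'
#' Constructs the training-data scaling experiment: nested subsets of an
#' annotated call library that vary the amount of training data along one
#' of three variability axes -- calls within a recording
#' (`"within_recording"`), recordings within a site (`"among_recording"`),
#' or sites (`"among_site"`) -- while holding the other two axes at fixed
#' target levels. Subsets are nested (each level's calls are a subset of
#' the next level's) via a single seeded random ordering of sites,
#' recordings within site, and calls within recording. When the library
#' has fewer units than targeted, the achieved counts fall short of the
#' targets and a warning is issued.
#'
#' @param library_annotations annotation data frame (the call library),
#'   with `recording_id` and `site_id`.
#' @param axis one of `"within_recording"`, `"among_recording"`,
#'   `"among_site"`.
#' @param levels increasing vector of target counts along `axis`.
#' @param held named list of the constants for the other axes:
#'   `calls_per_recording`, `recordings_per_site`, `n_sites` (entries for
#'   the varied axis are ignored).
#' @param seed RNG seed.
#' @return List of `"training_subset"` objects, each with `axis`,
#'   `target`, `achieved` (mean achieved count per grouping),
#'   `total_calls`, and `annotations` (the subset rows).
#' @export
build_training_subsets <- function(library_annotations, axis, levels,
                                   held = list(calls_per_recording = 12,
                                               recordings_per_site = 15,
                                               n_sites = 28),
                                   seed = 1L) {
  axis <- match.arg(axis, c("within_recording", "among_recording",
                            "among_site"))
  lib <- library_annotations
  if (nrow(lib) == 0L) stop("empty call library")
  if (is.unsorted(levels, strictly = TRUE))
    stop("levels must be strictly increasing")
  set.seed(as.integer(seed))

  # one random ordering shared by all levels => nesting by construction
  sites <- sample(unique(lib$site_id))
  rec_order <- lapply(stats::setNames(sites, sites), function(s)
    sample(unique(lib$recording_id[lib$site_id == s])))
  call_order <- lapply(rec_order, function(recs)
    lapply(stats::setNames(recs, recs), function(r)
      sample(which(lib$recording_id == r))))

  n_sites_max <- length(sites)
  take <- function(n_sites_t, n_rec_t, n_calls_t) {
    used_sites <- sites[seq_len(min(n_sites_t, n_sites_max))]
    rows <- integer(0)
    rec_counts <- integer(0)
    call_counts <- integer(0)
    for (s in used_sites) {
      recs <- rec_order[[s]][seq_len(min(n_rec_t, length(rec_order[[s]])))]
      rec_counts <- c(rec_counts, length(recs))
      for (r in recs) {
        calls <- call_order[[s]][[r]]
        calls <- calls[seq_len(min(n_calls_t, length(calls)))]
        call_counts <- c(call_counts, length(calls))
        rows <- c(rows, calls)
      }
    }
    list(rows = rows, n_sites = length(used_sites),
         mean_recs = mean(rec_counts), mean_calls = mean(call_counts))
  }

  max_level <- switch(axis,
    within_recording = max(vapply(unlist(call_order, recursive = FALSE),
                                  length, 0L)),
    among_recording = max(vapply(rec_order, length, 0L)),
    among_site = n_sites_max)
  if (max(levels) > max_level)
    warning("library cannot supply the largest target level along '",
            axis, "' (max available: ", max_level,
            "); achieved counts will fall short")

  out <- lapply(levels, function(lv) {
    tgt <- list(calls_per_recording = held$calls_per_recording,
                recordings_per_site = held$recordings_per_site,
                n_sites = held$n_sites)
    tgt[[switch(axis, within_recording = "calls_per_recording",
                among_recording = "recordings_per_site",
                among_site = "n_sites")]] <- lv
    sel <- take(tgt$n_sites, tgt$recordings_per_site,
                tgt$calls_per_recording)
    achieved <- switch(axis,
      within_recording = sel$mean_calls,
      among_recording = sel$mean_recs,
      among_site = sel$n_sites)
    structure(list(axis = axis, target = lv, achieved = achieved,
                   n_sites = sel$n_sites,
                   mean_recordings_per_site = sel$mean_recs,
                   mean_calls_per_recording = sel$mean_calls,
                   total_calls = length(sel$rows),
                   annotations = lib[sel$rows, , drop = FALSE]),
              class = "training_subset")
  })
  out
}

#' @export
print.training_subset <- function(x, ...) {
  cat(sprintf(
    "Training subset [%s]: target %g, achieved %.1f, %d total calls (%d sites, %.1f rec/site, %.1f calls/rec)\n",
    x$axis, x$target, x$achieved, x$total_calls, x$n_sites,
    x$mean_recordings_per_site, x$mean_calls_per_recording))
  invisible(x)
}

#' Fit a beta regression by maximum likelihood
#'
#' Beta regression for responses in (0, 1) -- here, conditional precision
#' or sensitivity of a recognizer -- with a logit link for the mean and a
#' constant precision parameter `phi` (mean/precision parameterization:
#' `y ~ Beta(mu * phi, (1 - mu) * phi)`). Responses exactly at 0 or 1 are
#' shrunk with the standard `(y * (n - 1) + 0.5) / n` transform before
#' fitting. Estimation is by direct maximization of the log-likelihood
#' (BFGS on coefficients and `log(phi)`); standard errors come from the
#' inverse observed information.
#'
#' @param y response vector; values must be in \[0, 1\] (boundary values
#'   are shrunk as above).
#' @param X design matrix (defaults to intercept only); must be full
#'   rank.
#' @return Object of class `"beta_reg_fit"`: `coefficients`, `se`, `phi`,
#'   `loglik`, `K` (number of parameters, coefficients + phi), `n`,
#'   `pseudo_r2` (squared correlation between linear predictor and
#'   `logit(y)`), `aicc`, `fitted`, `y`.
#' @export
fit_beta_regression <- function(y, X = matrix(1, length(y), 1,
                                              dimnames = list(NULL,
                                                              "(Intercept)"))) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("X must have one row per response")
  if (any(!is.finite(y)) || any(y < 0 | y > 1))
    stop("responses must lie in [0, 1]")
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  if (any(y <= 0 | y >= 1))
    y <- (y * (n - 1) + 0.5) / n  # boundary shrinkage
  p <- ncol(X)
  K <- p + 1L
  if (n <= K + 1L)
    stop("too few observations (n must exceed K + 1 for AICc)")

  logit_y <- stats::qlogis(y)
  beta0 <- stats::lm.fit(X, logit_y)$coefficients
  theta0 <- c(beta0, log_phi = log(5))

  nll <- function(theta) {
    mu <- stats::plogis(drop(X %*% theta[seq_len(p)]))
    phi <- exp(theta[p + 1L])
    mu <- pmin(1 - 1e-10, pmax(1e-10, mu))
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  opt <- stats::optim(theta0, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("beta regression did not converge (optim code ",
         opt$convergence, "): ", paste(opt$message, collapse = " "))
  coefs <- opt$par[seq_len(p)]
  names(coefs) <- colnames(X)
  phi <- exp(opt$par[p + 1L])
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, p) else sqrt(pmax(0, diag(vc)[seq_len(p)]))
  names(se) <- colnames(X)
  eta <- drop(X %*% coefs)
  pr2 <- if (p > 1L || stats::sd(eta) > 0)
    suppressWarnings(stats::cor(eta, logit_y)^2) else NA_real_
  if (is.na(pr2)) pr2 <- 0
  ll <- -opt$value
  fit <- structure(list(coefficients = coefs, se = se, phi = phi,
                        loglik = ll, K = K, n = n, pseudo_r2 = pr2,
                        fitted = stats::plogis(eta), y = y,
                        linear_predictor = eta),
                   class = "beta_reg_fit")
  fit$aicc <- aicc(fit)
  fit
}

#' Formula interface for [fit_beta_regression()]
#'
#' @param formula model formula for the mean (logit link).
#' @param data data frame containing the response and covariates.
#' @return A `"beta_reg_fit"` (see [fit_beta_regression()]).
#' @export
beta_regression <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  fit <- fit_beta_regression(y, X)
  fit$formula <- formula
  fit
}

#' @export
print.beta_reg_fit <- function(x, ...) {
  cat("Beta regression (logit link), ML fit\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se)
  print(round(tab, 5))
  cat(sprintf("phi %.3f, logLik %.3f, K %d, n %d, pseudo-R2 %.4f, AICc %.2f\n",
              x$phi, x$loglik, x$K, x$n, x$pseudo_r2, x$aicc))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K + 1) / (n - K - 1)`.
#'
#' @param fit a `"beta_reg_fit"`, or a log-likelihood value when `K` and
#'   `n` are given explicitly.
#' @param K number of estimated parameters.
#' @param n number of observations (must exceed `K + 1`).
#' @return AICc value.
#' @export
aicc <- function(fit, K = NULL, n = NULL) {
  if (inherits(fit, "beta_reg_fit")) {
    ll <- fit$loglik; K <- fit$K; n <- fit$n
  } else {
    ll <- as.numeric(fit)
    if (is.null(K) || is.null(n)) stop("supply K and n with a raw loglik")
  }
  if (n <= K + 1) stop("AICc undefined: n must exceed K + 1")
  -2 * ll + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' AICc model selection table
#'
#' Ranks a set of beta-regression fits of the same response by AICc and
#' computes Akaike weights `exp(-delta/2) / sum(exp(-delta/2))` and
#' evidence ratios (best model's weight divided by each model's weight).
#'
#' @param fits list of `"beta_reg_fit"` objects fitted to the same
#'   responses (equal `n` enforced).
#' @param labels model names (defaults to list names or `M1, M2, ...`).
#' @return Data frame of class `"model_selection_table"`, sorted by
#'   ascending AICc, with columns `model`, `K`, `aicc`, `delta_aicc`,
#'   `weight`, `evidence_ratio`, `loglik`, `pseudo_r2`.
#' @export
rank_models <- function(fits, labels = NULL) {
  if (length(fits) < 2L) stop("need at least 2 fits to rank")
  if (is.null(labels)) {
    labels <- names(fits)
    if (is.null(labels)) labels <- paste0("M", seq_along(fits))
  }
  ns <- vapply(fits, function(f) f$n, 0)
  if (length(unique(ns)) != 1L)
    stop("fits have different numbers of observations")
  aiccs <- vapply(fits, function(f) f$aicc, 0)
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = labels,
                    K = vapply(fits, function(f) f$K, 0L),
                    aicc = aiccs, delta_aicc = delta, weight = w,
                    evidence_ratio = max(w) / w,
                    loglik = vapply(fits, function(f) f$loglik, 0),
                    pseudo_r2 = vapply(fits, function(f) f$pseudo_r2, 0))
  out <- out[order(out$aicc), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("model_selection_table", "data.frame")
  out
}
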