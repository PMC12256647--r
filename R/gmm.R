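#' Derive a glia-exclusion size cutoff from GABA+ soma areas
#'
#' GABAergic interneurons are the smallest neurons in the tissue, so the
#' lower tail of the GABA+ soma-area distribution bounds the neuronal size
#' range from below: the cutoff is the `percentile`-th percentile of GABA+
#' areas (default 1, i.e. the area above which 99% of GABA+ cells lie).
#' Cells below it are treated as glia.  Uses the linear-interpolation
#' quantile convention (type 7).
#'
#' @param gaba_positive_areas Soma areas (um^2) of GABA+ cells.
#' @param percentile Lower percentile in the open interval (0, 100).
#' @return The cutoff in um^2.
#' @export
derive_glia_cutoff <- function(gaba_positive_areas, percentile = 1) {
  if (!length(gaba_positive_areas)) {
    stop("no GABA+ areas supplied")
  }
  if (percentile <= 0 || percentile >= 100) {
    stop("'percentile' must lie strictly between 0 and 100")
  }
  stats::quantile(gaba_positive_areas, percentile / 100, type = 7,
                  names = FALSE)
}

#' Exclude presumed-glial cells below a size cutoff
#'
#' Retains cells with `area_um2 >= cutoff` (cells strictly smaller are
#' classified as glia and dropped).  The number excluded is reported via
#' `message()`; if everything is excluded a warning is also raised.
#'
#' @param dataset A `soma_dataset` (or any data frame with `area_um2`).
#' @param cutoff Size cutoff in um^2 (default 40).
#' @return The filtered dataset.
#' @export
exclude_small_cells <- function(dataset, cutoff = 40) {
  stopifnot(is.data.frame(dataset), "area_um2" %in% names(dataset),
            cutoff > 0)
  keep <- dataset$area_um2 >= cutoff
  message(sum(!keep), " of ", nrow(dataset),
          " cells excluded as presumed glia (area < ", cutoff, " um^2)")
  if (nrow(dataset) > 0 && !any(keep)) {
    warning("all cells fell below the glia cutoff of ", cutoff, " um^2")
  }
  dataset[keep, , drop = FALSE]
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Expectation-maximization for a `K`-component univariate normal mixture
#' with either unequal (default) or equal component variances.  One
#' deterministic initialization (quantile-spread means, pooled SD, uniform
#' weights) plus `n_restarts` seeded random restarts are run and the best
#' converged log-likelihood kept.  Components are reported sorted by
#' ascending mean; fits where a component SD collapses below
#' `1e-6 * sd(x)` are discarded and, if no initialization survives, an
#' error is raised.
#'
#' @param x Observations (e.g. soma areas in um^2).
#' @param K Number of components (`length(x) >= 5 * K` required).
#' @param variance_model `"unequal"` (free per-component variances) or
#'   `"equal"` (one shared variance).
#' @param seed Integer seed for the random restarts.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per initialization.
#' @param n_restarts Number of random restarts beyond the deterministic
#'   initialization.
#' @return An object of class `gmm_fit`: list with `K`, `variance_model`,
#'   `weights`, `means`, `sds`, `loglik`, `bic`, `n`, `n_params`,
#'   `converged`, `n_iter`, `loglik_trace`, `posterior` (n x K),
#'   `classification`.
#' @export
fit_gmm <- function(x, K, variance_model = c("unequal", "equal"),
                    seed = NULL, tol = 1e-8, max_iter = 1000L,
                    n_restarts = 5L) {
  variance_model <- match.arg(variance_model)
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(K >= 1)
  if (n < 5 * K) {
    stop("need at least 5 observations per component (n = ", n,
         ", K = ", K, ")")
  }
  sd_x <- stats::sd(x)
  if (sd_x == 0) {
    stop("degenerate data: all observations are identical")
  }

  inits <- vector("list", n_restarts + 1L)
  inits[[1]] <- list(mu = stats::quantile(x, (seq_len(K) - 0.5) / K,
                                          names = FALSE),
                     sd = rep(sd_x, K),
                     w = rep(1 / K, K))
  for (r in seq_len(n_restarts)) {
    if (!is.null(seed)) set.seed(as.integer(seed) + r)
    mu <- sample(x, K)
    # jitter duplicated starting means so components start distinct
    mu <- mu + (duplicated(mu)) * stats::runif(K, -0.1, 0.1) * sd_x
    inits[[r + 1L]] <- list(mu = sort(mu), sd = rep(sd_x, K),
                            w = rep(1 / K, K))
  }

  best <- NULL
  for (init in inits) {
    fit <- em_univariate(x, init$mu, init$sd, init$w, variance_model,
                         tol, max_iter, sd_floor = 1e-6 * sd_x)
    if (is.null(fit)) next  # component collapse
    if (is.null(best) ||
        (fit$converged && !best$converged) ||
        (fit$converged == best$converged && fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("EM failed: every initialization collapsed a component")
  }

  ord <- order(best$mu)
  mu <- best$mu[ord]; sdv <- best$sd[ord]; w <- best$w[ord]
  post <- gmm_posterior(x, w, mu, sdv)
  n_params <- if (variance_model == "unequal") 3L * K - 1L else 2L * K
  structure(
    list(K = K, variance_model = variance_model,
         weights = w, means = mu, sds = sdv,
         loglik = best$loglik,
         bic = 2 * best$loglik - n_params * log(n),
         n = n, n_params = n_params,
         converged = best$converged, n_iter = best$n_iter,
         loglik_trace = best$trace,
         posterior = post,
         classification = max.col(post, ties.method = "first")),
    class = "gmm_fit"
  )
}

# One EM run; returns NULL on component collapse.
em_univariate <- function(x, mu, sdv, w, variance_model, tol, max_iter,
                          sd_floor) {
  n <- length(x)
  K <- length(mu)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(K), function(k) {
      log(w[k]) + stats::dnorm(x, mu[k], sdv[k], log = TRUE)
    }, numeric(n))
    m <- do.call(pmax, as.data.frame(logd))
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    post <- exp(logd - lse)
    nk <- colSums(post)
    if (any(nk < 1e-10)) return(NULL)
    w <- nk / n
    mu <- colSums(post * x) / nk
    dev2 <- (matrix(x, n, K) - matrix(mu, n, K, byrow = TRUE))^2
    if (variance_model == "unequal") {
      sdv <- sqrt(colSums(post * dev2) / nk)
    } else {
      sdv <- rep(sqrt(sum(post * dev2) / n), K)
    }
    if (any(sdv < sd_floor)) return(NULL)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sd = sdv, w = w, loglik = trace[length(trace)],
       converged = converged, n_iter = iter, trace = trace)
}

# Posterior responsibilities for given parameters (n x K, rows sum to 1).
gmm_posterior <- function(x, w, mu, sdv) {
  n <- length(x)
  K <- length(mu)
  logd <- vapply(seq_len(K), function(k) {
    log(w[k]) + stats::dnorm(x, mu[k], sdv[k], log = TRUE)
  }, numeric(n))
  logd <- matrix(logd, n, K)
  m <- do.call(pmax, as.data.frame(logd))
  exp(logd - (m + log(rowSums(exp(logd - m)))))
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: K = %d (%s variances), n = %d\n",
              x$K, x$variance_model, x$n))
  cat(sprintf("  logLik = %.3f, BIC = %.3f, converged: %s (%d iter)\n",
              x$loglik, x$bic, x$converged, x$n_iter))
  comp <- data.frame(weight = round(x$weights, 4),
                     mean = round(x$means, 2),
                     sd = round(x$sds, 2))
  print(comp, row.names = paste0("  comp", seq_len(x$K)))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits every `K` in `K_range` and selects the converged fit with the
#' highest BIC, using the `2 logL - p log n` convention (so the best model
#' maximizes BIC; `p = 3K - 1` for unequal variances, `2K` for equal).
#'
#' @inheritParams fit_gmm
#' @param K_range Candidate component counts (default 1..9).
#' @return A list with `best` (the maximum-BIC `gmm_fit`) and `bic_table`
#'   (data frame: `K`, `loglik`, `bic`, `converged`).
#' @export
select_by_bic <- function(x, K_range = 1:9,
                          variance_model = c("unequal", "equal"),
                          seed = NULL, tol = 1e-8, max_iter = 1000L,
                          n_restarts = 5L) {
  variance_model <- match.arg(variance_model)
  stopifnot(length(K_range) >= 1)
  fits <- vector("list", length(K_range))
  rows <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    fit <- tryCatch(
      fit_gmm(x, K, variance_model = variance_model, seed = seed,
              tol = tol, max_iter = max_iter, n_restarts = n_restarts),
      error = function(e) NULL)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      K = K,
      loglik = if (is.null(fit)) NA_real_ else fit$loglik,
      bic = if (is.null(fit)) NA_real_ else fit$bic,
      converged = !is.null(fit) && fit$converged)
  }
  bic_table <- do.call(rbind, rows)
  ok <- which(bic_table$converged)
  if (!length(ok)) {
    stop("no candidate K converged; cannot select a model")
  }
  best <- fits[[ok[which.max(bic_table$bic[ok])]]]
  list(best = best, bic_table = bic_table)
}

#' Classify observations under a fitted mixture
#'
#' Maximum-posterior assignment of each observation to a component; exact
#' posterior ties are broken toward the lower-mean component (components
#' are stored in ascending-mean order).
#'
#' @param fit A `gmm_fit`.
#' @param areas Observations to classify (defaults are not stored in the
#'   fit; pass the data explicitly).
#' @return A list with `label` (component index per observation) and
#'   `posterior` (n x K matrix, rows summing to 1).
#' @export
classify_cells <- function(fit, areas) {
  stopifnot(inherits(fit, "gmm_fit"))
  post <- gmm_posterior(as.numeric(areas), fit$weights, fit$means,
                        fit$sds)
  list(label = max.col(post, ties.method = "first"), posterior = post)
}
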