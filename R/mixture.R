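#' Moments of a lognormal distribution
#'
#' Converts between the log-space parameters of a lognormal distribution and
#' its distribution mean and standard deviation. Component estimates are
#' reported as "mean +/- sigma" on the radial-index scale, so lognormal fits
#' performed in log space must be moment-matched back.
#'
#' @param mu_log,sigma_log Log-space mean and standard deviation
#'   (`sigma_log >= 0`).
#' @return `lognormal_moments()`: named vector `c(mean, sd)`.
#' @examples
#' lognormal_moments(0, 0)        # point mass at 1
#' moment_match(0.18, 0.31)       # log-space parameters of an ILC-like peak
#' @export
lognormal_moments <- function(mu_log, sigma_log) {
  if (any(sigma_log < 0)) stop("`sigma_log` must be >= 0", call. = FALSE)
  m <- exp(mu_log + sigma_log^2 / 2)
  s <- m * sqrt(exp(sigma_log^2) - 1)
  c(mean = unname(m), sd = unname(s))
}

#' @rdname lognormal_moments
#' @param mean,sd Distribution mean (`> 0`) and standard deviation (`>= 0`).
#' @return `moment_match()`: named vector `c(mu_log, sigma_log)` such that
#'   `lognormal_moments(mu_log, sigma_log)` reproduces `(mean, sd)`.
#' @export
moment_match <- function(mean, sd) {
  if (any(mean <= 0)) stop("`mean` must be positive", call. = FALSE)
  if (any(sd < 0)) stop("`sd` must be >= 0", call. = FALSE)
  s2 <- log1p((sd / mean)^2)
  c(mu_log = unname(log(mean) - s2 / 2), sigma_log = unname(sqrt(s2)))
}

#' Construct a mixture fit from known components
#'
#' Builds a `mixture_fit` object directly from component parameters, e.g. to
#' evaluate [responsibilities()] for a hypothesized decomposition or to seed
#' model-based predictions. [em_fit()] returns objects of the same class.
#'
#' @param weights Positive component weights; normalized to sum to 1.
#' @param locations Component means on the observation scale.
#' @param dispersions Component standard deviations (positive).
#' @param family `"gaussian"`, `"lognormal"`, or a character vector with one
#'   family per component (aligned with `locations`).
#' @return A `mixture_fit` object.
#' @export
mixture_fit <- function(weights, locations, dispersions,
                        family = "gaussian") {
  k <- length(weights)
  fam <- .component_families(family, k)
  stopifnot(length(locations) == k, length(dispersions) == k,
            all(weights > 0), all(dispersions > 0))
  ord <- order(locations)
  weights <- weights[ord] / sum(weights)
  locations <- locations[ord]
  dispersions <- dispersions[ord]
  fam <- fam[ord]
  if (any(fam == "lognormal" & locations <= 0)) {
    stop("lognormal components require positive locations", call. = FALSE)
  }
  mu_log <- rep(NA_real_, k)
  sigma_log <- rep(NA_real_, k)
  for (j in which(fam == "lognormal")) {
    lp <- moment_match(locations[j], dispersions[j])
    mu_log[j] <- lp[["mu_log"]]
    sigma_log[j] <- lp[["sigma_log"]]
  }
  components <- data.frame(
    component = seq_len(k), weight = weights, location = locations,
    dispersion = dispersions, family = fam, mu_log = mu_log,
    sigma_log = sigma_log
  )
  structure(
    list(components = components, k = k,
         family = if (length(unique(fam)) == 1) fam[1] else "mixed",
         log_likelihood = NA_real_, loglik_trace = numeric(0),
         n_iterations = 0L, converged = NA, collapsed = FALSE,
         n = NA_integer_, seed = NA_integer_),
    class = "mixture_fit"
  )
}

.component_families <- function(family, k) {
  if (!is.character(family) || !length(family) %in% c(1L, k) ||
      !all(family %in% c("gaussian", "lognormal"))) {
    stop("`family` must be \"gaussian\", \"lognormal\", or a vector of ",
         "these with one entry per component", call. = FALSE)
  }
  rep_len(family, k)
}

# n x k matrix of log(weight_j * f_j(x)); x on the observation scale
.component_logdens <- function(fit, x) {
  comp <- fit$components
  ld <- vapply(seq_len(fit$k), function(j) {
    if (comp$family[j] == "lognormal") {
      stats::dlnorm(x, comp$mu_log[j], comp$sigma_log[j], log = TRUE)
    } else {
      stats::dnorm(x, comp$location[j], comp$dispersion[j], log = TRUE)
    }
  }, numeric(length(x)))
  if (is.null(dim(ld))) ld <- matrix(ld, nrow = length(x))
  sweep(ld, 2, log(comp$weight), "+")
}

#' Log-likelihood of samples under a mixture fit
#'
#' @param object A `mixture_fit`.
#' @param samples Numeric vector on the observation scale.
#' @param ... Unused.
#' @export
logLik.mixture_fit <- function(object, samples, ...) {
  ld <- .component_logdens(object, samples)
  m <- apply(ld, 1, max)
  sum(m + log(rowSums(exp(ld - m))))
}

#' Posterior component memberships
#'
#' E-step exposure: the posterior probability that each sample belongs to
#' each mixture component. Rows sum to 1.
#'
#' @param fit A `mixture_fit`.
#' @param samples Numeric vector; must be positive for lognormal fits.
#' @return Numeric matrix, `length(samples)` rows by `fit$k` columns.
#' @export
responsibilities <- function(fit, samples) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (any(fit$components$family == "lognormal") && any(samples <= 0)) {
    stop("lognormal components require positive samples", call. = FALSE)
  }
  ld <- .component_logdens(fit, samples)
  m <- apply(ld, 1, max)
  r <- exp(ld - m)
  r / rowSums(r)
}

.init_em <- function(y, k, init, init_locations, seed) {
  n <- length(y)
  if (init == "manual") {
    if (is.null(init_locations) || length(init_locations) != k) {
      stop("`init_locations` of length k required for init = \"manual\"",
           call. = FALSE)
    }
    mu <- sort(init_locations)
    sd0 <- rep(max(stats::sd(y) / k, 1e-3), k)
    return(list(w = rep(1 / k, k), mu = mu, sd = sd0))
  }
  if (init == "kmeans") {
    if (!is.null(seed)) set.seed(seed)
    km <- stats::kmeans(y, centers = k, nstart = 10L)
    ord <- order(km$centers)
    mu <- as.numeric(km$centers[ord])
    sd0 <- vapply(ord, function(j) {
      v <- stats::sd(y[km$cluster == j])
      if (!is.finite(v) || v < 1e-3) 1e-3 else v
    }, numeric(1))
    w <- as.numeric(table(factor(km$cluster, levels = ord)) / n)
    return(list(w = w, mu = mu, sd = sd0))
  }
  # quantile: split the sorted sample into k equal groups
  ys <- sort(y)
  grp <- if (k == 1) rep(1L, n) else cut(seq_len(n), breaks = k,
                                         labels = FALSE)
  mu <- tapply(ys, grp, mean)
  sd0 <- tapply(ys, grp, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-3) 1e-3 else s
  })
  list(w = rep(1 / k, k), mu = as.numeric(mu), sd = as.numeric(sd0))
}

#' Fit a 1-D Gaussian or lognormal mixture by expectation-maximization
#'
#' Decomposes a one-dimensional sample (radial indices of same-age labelled
#' cells) into `k` components. A pure lognormal mixture is fitted as a
#' Gaussian mixture on log-transformed samples -- exactly equivalent -- and
#' component moments are transformed back to the observation scale with
#' [lognormal_moments()], so lognormal components are reported as
#' distribution mean and standard deviation ("mean +/- sigma"). Mixed
#' per-component families are fitted by EM on the observation scale, with
#' the lognormal components' M-step performed on responsibility-weighted
#' log moments.
#'
#' The log-likelihood is non-decreasing across iterations and is recorded in
#' `loglik_trace`. Component variances are floored at `var_floor` to prevent
#' collapse onto single points; a fit that hits the floor is flagged
#' `collapsed`. Components are returned sorted by ascending location.
#'
#' @param samples Numeric vector, `length(samples) >= 10 * k`. When any
#'   component is lognormal, samples must be non-negative; exact zeros are
#'   nudged to half the smallest positive sample with a warning.
#' @param k Number of components (>= 1).
#' @param family `"gaussian"` (default), `"lognormal"`, or a character
#'   vector with one family per component (in ascending-location order of
#'   the initialization).
#' @param init Initialization: `"quantile"` (default; equal split of the
#'   sorted sample), `"kmeans"`, or `"manual"` (supply `init_locations`).
#' @param init_locations Starting component locations (observation scale)
#'   for `init = "manual"`.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @param seed Integer seed; fixes the k-means initialization so identical
#'   seeds give bit-identical fits.
#' @param var_floor Lower bound on component variances (in the fitting
#'   space, i.e. log space for lognormal components).
#' @return A `mixture_fit` with elements `components` (data frame: `weight`,
#'   `location`, `dispersion`, `family`, `mu_log`, `sigma_log`), `k`,
#'   `family`, `log_likelihood` (observation scale), `loglik_trace`,
#'   `n_iterations`, `converged`, `collapsed`, `n`, `seed`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(200, 0.2, 0.05), rnorm(200, 1.2, 0.1))
#' em_fit(x, k = 2)$components
#' @export
em_fit <- function(samples, k, family = "gaussian",
                   init = c("quantile", "kmeans", "manual"),
                   init_locations = NULL, tol = 1e-8, max_iter = 2000L,
                   seed = NULL, var_floor = 1e-6) {
  init <- match.arg(init)
  stopifnot(k >= 1, tol > 0, max_iter >= 1)
  fam <- .component_families(family, k)
  x <- as.numeric(samples)
  if (anyNA(x)) stop("`samples` must not contain NA", call. = FALSE)
  n <- length(x)
  if (n < 10 * k) {
    stop("need at least 10 samples per component (n >= 10 * k)",
         call. = FALSE)
  }
  if (length(unique(x)) < k) {
    stop("degenerate fit: fewer distinct sample values than components",
         call. = FALSE)
  }
  any_ln <- any(fam == "lognormal")
  if (any_ln) {
    if (any(x < 0)) {
      stop("lognormal components require non-negative samples",
           call. = FALSE)
    }
    if (any(x == 0)) {
      nudge <- min(x[x > 0]) / 2
      warning(sum(x == 0), " zero sample(s) nudged to ", signif(nudge, 3),
              " for the lognormal fit")
      x[x == 0] <- nudge
    }
  }
  pure_ln <- all(fam == "lognormal")

  if (pure_ln) {
    # exact path: Gaussian EM on log-transformed samples, with the Jacobian
    # term linking the log-space likelihood to the observation scale
    y <- log(x)
    jac <- -sum(y)
    init_y <- if (!is.null(init_locations)) log(init_locations) else NULL
    st <- .init_em(y, k, init, init_y, seed)
    res <- .em_gaussian(y, st, tol, max_iter, var_floor)
    mom <- lognormal_moments(res$mu, res$sd)
    fit <- mixture_fit(res$w, mom[seq_len(k)], mom[k + seq_len(k)],
                       family = "lognormal")
    trace <- res$trace + jac
  } else if (!any_ln) {
    st <- .init_em(x, k, init, init_locations, seed)
    res <- .em_gaussian(x, st, tol, max_iter, var_floor)
    fit <- mixture_fit(res$w, res$mu, res$sd, family = "gaussian")
    trace <- res$trace
  } else {
    st <- .init_em(x, k, init, init_locations, seed)
    res <- .em_mixed(x, st, fam, tol, max_iter, var_floor)
    fit <- mixture_fit(res$w, res$mu, res$sd, family = res$fam)
    trace <- res$trace
  }
  if (res$collapsed) {
    warning("variance floor reached: fit flagged as collapsed")
  }
  fit$log_likelihood <- trace[length(trace)]
  fit$loglik_trace <- trace
  fit$n_iterations <- res$n_iterations
  fit$converged <- res$converged
  fit$collapsed <- res$collapsed
  fit$n <- n
  fit$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  fit
}

# standard Gaussian EM on y; st holds the initial state
.em_gaussian <- function(y, st, tol, max_iter, var_floor) {
  n <- length(y)
  k <- length(st$w)
  w <- st$w; mu <- st$mu; sd_ <- st$sd
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    ld <- vapply(seq_len(k),
                 function(j) stats::dnorm(y, mu[j], sd_[j], log = TRUE) +
                   log(w[j]),
                 numeric(n))
    if (is.null(dim(ld))) ld <- matrix(ld, nrow = n)
    m <- apply(ld, 1, max)
    lse <- m + log(rowSums(exp(ld - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_prev <- ll
    r <- exp(ld - lse)               # n x k responsibilities
    nk <- colSums(r)
    nk[nk < .Machine$double.xmin] <- .Machine$double.xmin
    w <- nk / n
    mu <- colSums(r * y) / nk
    v <- vapply(seq_len(k),
                function(j) sum(r[, j] * (y - mu[j])^2) / nk[j],
                numeric(1))
    sd_ <- sqrt(pmax(v, var_floor))
  }
  list(w = w, mu = mu, sd = sd_, trace = trace, n_iterations = it,
       converged = converged,
       collapsed = any(sd_^2 <= var_floor * (1 + 1e-12)))
}

# EM with per-component families on the observation scale; lognormal
# components are updated through responsibility-weighted log moments
.em_mixed <- function(x, st, fam, tol, max_iter, var_floor) {
  n <- length(x)
  k <- length(st$w)
  lx <- log(x)
  w <- st$w; mu <- st$mu; sd_ <- st$sd
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  collapsed <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    ld <- vapply(seq_len(k), function(j) {
      if (fam[j] == "lognormal") {
        lp <- moment_match(mu[j], sd_[j])
        stats::dlnorm(x, lp[["mu_log"]], lp[["sigma_log"]], log = TRUE) +
          log(w[j])
      } else {
        stats::dnorm(x, mu[j], sd_[j], log = TRUE) + log(w[j])
      }
    }, numeric(n))
    if (is.null(dim(ld))) ld <- matrix(ld, nrow = n)
    m <- apply(ld, 1, max)
    lse <- m + log(rowSums(exp(ld - m)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_prev <- ll
    r <- exp(ld - lse)
    nk <- colSums(r)
    nk[nk < .Machine$double.xmin] <- .Machine$double.xmin
    w <- nk / n
    collapsed <- FALSE
    for (j in seq_len(k)) {
      if (fam[j] == "lognormal") {
        ml <- sum(r[, j] * lx) / nk[j]
        vl <- max(sum(r[, j] * (lx - ml)^2) / nk[j], var_floor)
        collapsed <- collapsed || vl <= var_floor * (1 + 1e-12)
        mo <- lognormal_moments(ml, sqrt(vl))
        mu[j] <- mo[["mean"]]
        sd_[j] <- mo[["sd"]]
      } else {
        mu[j] <- sum(r[, j] * x) / nk[j]
        v <- max(sum(r[, j] * (x - mu[j])^2) / nk[j], var_floor)
        collapsed <- collapsed || v <= var_floor * (1 + 1e-12)
        sd_[j] <- sqrt(v)
      }
    }
  }
  list(w = w, mu = mu, sd = sd_, fam = fam, trace = trace,
       n_iterations = it, converged = converged, collapsed = collapsed)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%d-component %s mixture (n = %s, logLik = %.3f, %s in %d iterations)\n",
              x$k, x$family,
              ifelse(is.na(x$n), "?", x$n),
              x$log_likelihood,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$n_iterations))
  comp <- x$components
  for (j in seq_len(x$k)) {
    cat(sprintf("  peak %d: weight %.3f, %.3f +/- %.3f\n",
                j, comp$weight[j], comp$location[j], comp$dispersion[j]))
  }
  invisible(x)
}

#' BIC of a fitted mixture
#'
#' Reported for model comparison; the number of components is always
#' user-supplied and never auto-selected.
#'
#' @param object A `mixture_fit` returned by [em_fit()].
#' @param ... Unused.
#' @export
BIC.mixture_fit <- function(object, ...) {
  if (is.na(object$n)) stop("fit carries no sample size", call. = FALSE)
  p <- 3 * object$k - 1
  -2 * object$log_likelihood + p * log(object$n)
}
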