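#' Gaussian-process hyperparameters
#'
#' Hyperparameters of the Tanimoto-kernel GP surrogate. All variances are on
#' the standardized label scale ([fit_gp()] standardizes potencies to zero
#' mean and unit SD internally, so an amplitude of 1 and a noise variance of
#' 0.1 are sensible starting points for any pool).
#'
#' @param amplitude Kernel scale (signal variance), > 0.
#' @param noise_variance Observation noise variance, floored at the 1e-6
#'   jitter level.
#' @param mean_constant Constant prior mean in standardized label space.
#' @param fit_iterations Maximum marginal-likelihood ascent iterations when
#'   optimizing.
#' @param learning_rate Step size of the ascent.
#' @return An object of class `gp_hyperparams`.
#' @export
gp_hyperparams <- function(amplitude = 1, noise_variance = 0.1,
                           mean_constant = 0, fit_iterations = 200L,
                           learning_rate = 0.1) {
  amplitude <- check_number(amplitude, "amplitude", min = 0, strict = TRUE)
  noise_variance <- check_number(noise_variance, "noise_variance", min = 1e-6)
  mean_constant <- check_number(mean_constant, "mean_constant")
  fit_iterations <- check_count(fit_iterations, "fit_iterations", min = 1)
  learning_rate <- check_number(learning_rate, "learning_rate", min = 0, strict = TRUE)
  structure(list(amplitude = amplitude, noise_variance = noise_variance,
                 mean_constant = mean_constant, fit_iterations = fit_iterations,
                 learning_rate = learning_rate),
            class = "gp_hyperparams")
}

#' Tanimoto kernel matrix
#'
#' `K[i, j] = amplitude * tanimoto(X[i, ], Y[j, ])`. With `X = Y` the matrix
#' is symmetric positive semidefinite up to numerical jitter, with a constant
#' diagonal equal to the amplitude.
#'
#' @param X,Y Binary 0/1 fingerprint matrices with equal numbers of columns.
#' @param amplitude Kernel scale.
#' @return An `nrow(X)` by `nrow(Y)` covariance matrix.
#' @export
kernel_matrix <- function(X, Y = X, amplitude = 1) {
  amplitude <- check_number(amplitude, "amplitude", min = 0)
  amplitude * tanimoto_matrix(X, Y)
}

# Cholesky with jitter escalation: 1e-6 then 1e-4 extra on the diagonal,
# then a hard error.
chol_with_jitter <- function(K) {
  for (jitter in c(0, 1e-6, 1e-4)) {
    L <- tryCatch(t(chol(K + diag(jitter, nrow(K)))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  abort("Kernel matrix is singular even after jitter escalation to 1e-4.")
}

# Log marginal likelihood and its gradients at (log amp, log noise, mean).
# S is the unscaled Tanimoto matrix, y the standardized labels.
gp_lml_grad <- function(S, y, log_amp, log_noise, m) {
  n <- length(y)
  amp <- exp(log_amp); noise <- exp(log_noise)
  L <- chol_with_jitter(amp * S + diag(noise, n))
  r <- y - m
  alpha <- backsolve(t(L), forwardsolve(L, r))
  lml <- -0.5 * sum(r * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(t(L))
  A <- tcrossprod(alpha) - Kinv
  list(lml = lml,
       g_log_amp = 0.5 * amp * sum(A * S),
       g_log_noise = 0.5 * noise * sum(diag(A)),
       g_mean = sum(alpha))
}

#' Fit a Tanimoto-kernel Gaussian process
#'
#' Fits GP regression with covariance `amplitude * tanimoto + noise * I` on
#' binary fingerprints. Labels are standardized internally to zero mean and
#' unit SD over the training set; predictions are returned on the original pK
#' scale. With `hyper = "optimize"` (the default) the amplitude, noise
#' variance and constant mean maximize the log marginal likelihood by
#' adaptive-moment (Adam) gradient ascent in log-variance space from fixed
#' initial values, so the fit is fully reproducible; ascent stops early once
#' the marginal likelihood changes by less than 1e-8 per training point.
#'
#' @param fingerprints Binary 0/1 training matrix, one row per compound.
#' @param labels Numeric potencies in pK units, one per row.
#' @param hyper Either `"optimize"` or a fixed [gp_hyperparams()] object.
#' @param init Initial hyperparameters for optimization (also supplies
#'   `fit_iterations` and `learning_rate`).
#' @param fix Character vector of hyperparameter names (`"amplitude"`,
#'   `"noise_variance"`, `"mean_constant"`) to hold at their initial values
#'   during optimization.
#' @param similarity Optional precomputed `tanimoto_matrix()` of the training
#'   rows, to avoid recomputation in tight loops.
#' @param standardize Standardize labels internally (default). Disable only
#'   when labels are already on a standardized scale and fits with different
#'   training subsets must share one prior (hyperparameters then apply to the
#'   raw label scale).
#' @return An object of class `tanimoto_gp`; use [predict.tanimoto_gp()] for
#'   posterior means and variances, [tidy()] and [glance()] for summaries.
#' @examples
#' fp <- matrix(rbinom(80, 1, 0.3), nrow = 8)
#' fit <- fit_gp(fp, rnorm(8), hyper = gp_hyperparams())
#' predict(fit, fp[1:2, ])
#' @export
fit_gp <- function(fingerprints, labels, hyper = "optimize",
                   init = gp_hyperparams(), fix = character(),
                   similarity = NULL, standardize = TRUE) {
  fingerprints <- check_fingerprints(fingerprints)
  if (!is.numeric(labels) || length(labels) != nrow(fingerprints)) {
    abort("`labels` must be numeric with one value per fingerprint row.")
  }
  if (any(!is.finite(labels))) abort("All labels must be finite.")
  if (length(labels) < 1) abort("At least one training point is required.")

  if (standardize) {
    mu_y <- mean(labels)
    sd_y <- if (length(labels) > 1) sd(labels) else 0
    if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  } else {
    mu_y <- 0
    sd_y <- 1
  }
  y <- (labels - mu_y) / sd_y

  S <- similarity %||% tanimoto_matrix(fingerprints)

  if (identical(hyper, "optimize")) {
    hp <- optimize_gp_hyper(S, y, init, fix)
  } else if (inherits(hyper, "gp_hyperparams")) {
    hp <- hyper
    hp$iterations_run <- 0L
  } else {
    abort("`hyper` must be \"optimize\" or a gp_hyperparams object.")
  }

  n <- length(y)
  L <- chol_with_jitter(hp$amplitude * S + diag(hp$noise_variance, n))
  r <- y - hp$mean_constant
  alpha <- backsolve(t(L), forwardsolve(L, r))
  lml <- -0.5 * sum(r * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)

  structure(
    list(fingerprints = fingerprints, L = L, alpha = alpha, hyper = hp,
         mu_y = mu_y, sd_y = sd_y, n_train = n, log_marginal_likelihood = lml),
    class = "tanimoto_gp")
}

optimize_gp_hyper <- function(S, y, init, fix) {
  bad <- setdiff(fix, c("amplitude", "noise_variance", "mean_constant"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown hyperparameter(s) in `fix`: %s.", paste(bad, collapse = ", ")))
  }
  theta <- c(log(init$amplitude), log(init$noise_variance), init$mean_constant)
  free <- !(c("amplitude", "noise_variance", "mean_constant") %in% fix)
  lr <- init$learning_rate
  m_t <- v_t <- numeric(3)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  prev_lml <- -Inf
  iters <- 0L
  for (t in seq_len(init$fit_iterations)) {
    gr <- gp_lml_grad(S, y, theta[1], theta[2], theta[3])
    g <- c(gr$g_log_amp, gr$g_log_noise, gr$g_mean) * free
    m_t <- b1 * m_t + (1 - b1) * g
    v_t <- b2 * v_t + (1 - b2) * g^2
    step <- lr * (m_t / (1 - b1^t)) / (sqrt(v_t / (1 - b2^t)) + eps)
    theta <- theta + step
    # keep noise at or above the jitter floor
    theta[2] <- max(theta[2], log(1e-6))
    iters <- t
    if (abs(gr$lml - prev_lml) < 1e-8 * length(y)) break
    prev_lml <- gr$lml
  }
  hp <- gp_hyperparams(amplitude = exp(theta[1]),
                       noise_variance = max(exp(theta[2]), 1e-6),
                       mean_constant = theta[3],
                       fit_iterations = init$fit_iterations,
                       learning_rate = lr)
  hp$iterations_run <- iters
  hp
}

#' Posterior prediction from a fitted Tanimoto GP
#'
#' Returns the latent posterior mean and variance at each query compound,
#' de-standardized to pK units. The variance is that of the latent function
#' (the observation noise `noise_variance` is not added) and is clipped at
#' zero; acquisition rankings are identical either way, and users who want
#' predictive-observation variance can add `noise_variance * sd_y^2`.
#' A query with an all-zero kernel row against the training set falls back to
#' the prior: mean equal to the prior mean constant and variance equal to the
#' amplitude (both de-standardized).
#'
#' @param object A fitted `tanimoto_gp`.
#' @param fingerprints Binary query matrix with the training fingerprint
#'   length.
#' @param cross_similarity Optional precomputed Tanimoto matrix between
#'   training rows and query rows (n_train by n_query).
#' @param ... Unused.
#' @return A tibble with columns `mean` (pK units) and `variance`
#'   (pK squared units), one row per query compound.
#' @export
predict.tanimoto_gp <- function(object, fingerprints, cross_similarity = NULL, ...) {
  if (is.null(cross_similarity)) {
    fingerprints <- check_fingerprints(fingerprints)
    if (ncol(fingerprints) != ncol(object$fingerprints)) {
      abort(sprintf("Query fingerprint length %d does not match training length %d.",
                    ncol(fingerprints), ncol(object$fingerprints)))
    }
    cross_similarity <- tanimoto_matrix(object$fingerprints, fingerprints)
  }
  hp <- object$hyper
  k_star <- hp$amplitude * cross_similarity
  mean_std <- hp$mean_constant + drop(crossprod(k_star, object$alpha))
  v <- forwardsolve(object$L, k_star)
  var_std <- pmax(hp$amplitude - colSums(v^2), 0)
  tibble::tibble(mean = mean_std * object$sd_y + object$mu_y,
                 variance = var_std * object$sd_y^2)
}

#' @export
print.tanimoto_gp <- function(x, ...) {
  cat(sprintf("Tanimoto-kernel GP: %d training compounds, log marginal likelihood %.3f\n",
              x$n_train, x$log_marginal_likelihood))
  cat(sprintf("  amplitude %.4f, noise variance %.4f, mean constant %.4f (standardized scale)\n",
              x$hyper$amplitude, x$hyper$noise_variance, x$hyper$mean_constant))
  invisible(x)
}

#' Tidy a fitted Tanimoto GP
#'
#' @param x A fitted `tanimoto_gp`.
#' @param ... Unused.
#' @return `tidy()`: a tibble of hyperparameters (term, estimate) on the
#'   standardized label scale. `glance()`: a one-row model summary.
#' @method tidy tanimoto_gp
#' @export
tidy.tanimoto_gp <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "noise_variance", "mean_constant"),
    estimate = c(x$hyper$amplitude, x$hyper$noise_variance, x$hyper$mean_constant))
}

#' @rdname tidy.tanimoto_gp
#' @method glance tanimoto_gp
#' @export
glance.tanimoto_gp <- function(x, ...) {
  tibble::tibble(n_train = x$n_train,
                 log_marginal_likelihood = x$log_marginal_likelihood,
                 amplitude = x$hyper$amplitude,
                 noise_variance = x$hyper$noise_variance,
                 mean_constant = x$hyper$mean_constant,
                 iterations = x$hyper$iterations_run %||% NA_integer_)
}
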