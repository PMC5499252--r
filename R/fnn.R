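# Two-layer feed-forward network (sigmoid hidden units, linear output)
# with a class-cost-weighted mean-squared-error objective, trained by
# Moller's scaled conjugate gradient: conjugate search directions, a
# finite-difference Hessian-vector estimate along the direction, and
# Levenberg-style scaling instead of a line search.

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialise network weights
#'
#' Fan-in-scaled symmetric uniform initialisation in the Nguyen-Widrow
#' style: hidden-unit input vectors are drawn uniformly, rescaled to a
#' common magnitude `0.7 * N_H^(1/N_I)`, and hidden biases spread
#' uniformly over the same range so the sigmoids start active across the
#' input region.
#'
#' @param sizes Integer triple `(N_I, N_H, N_O)`; `N_O` must be 1 for
#'   the binary task.
#' @param seed RNG seed.
#' @param no_bias Omit both bias vectors (the textbook equations without
#'   intercept terms).
#' @return Object of class `fnn_weights`: list `w1` (N_I x N_H), `b1`,
#'   `w2` (N_H x N_O), `b2`, `sizes`, `no_bias`.
#' @export
init_weights <- function(sizes, seed = 1L, no_bias = FALSE) {
  stopifnot(length(sizes) == 3L, all(sizes >= 1L))
  set.seed(seed)
  ni <- sizes[1]; nh <- sizes[2]; no <- sizes[3]
  w1 <- matrix(stats::runif(ni * nh, -0.5, 0.5), ni, nh)
  beta <- 0.7 * nh^(1 / ni)
  nrm <- sqrt(colSums(w1^2))
  w1 <- sweep(w1, 2L, ifelse(nrm > 0, beta / nrm, 1), `*`)
  b1 <- if (nh > 1L) beta * seq(-1, 1, length.out = nh) *
          sign(stats::runif(nh) - 0.5) else stats::runif(1, -beta, beta)
  w2 <- matrix(stats::runif(nh * no, -0.5, 0.5) / sqrt(nh), nh, no)
  b2 <- stats::runif(no, -0.1, 0.1)
  if (no_bias) { b1 <- numeric(nh); b2 <- numeric(no) }
  structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2,
                 sizes = as.integer(sizes), no_bias = isTRUE(no_bias)),
            class = "fnn_weights")
}

#' Forward pass through the network
#'
#' Hidden activations `y = sigmoid(x' w1 + b1)`, output
#' `O = y' w2 + b2` (linear output unit).
#'
#' @param weights An `fnn_weights` object.
#' @param x Input vector of length `N_I`, or a samples x `N_I` matrix.
#' @return List with `hidden` (samples x N_H) and `output`
#'   (samples x N_O).
#' @export
forward_pass <- function(weights, x) {
  stopifnot(inherits(weights, "fnn_weights"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != weights$sizes[1])
    stop(sprintf("input has %d features but the network expects %d",
                 ncol(x), weights$sizes[1]), call. = FALSE)
  h <- .sigmoid(sweep(x %*% weights$w1, 2L, weights$b1, `+`))
  o <- sweep(h %*% weights$w2, 2L, weights$b2, `+`)
  list(hidden = h, output = o)
}

# Per-sample cost factors from class costs.  `class_costs` is NULL
# (all 1), or a named pair c(HC = ..., AD = ...) applied via the 0/1
# targets, or a full per-sample vector.
.sample_costs <- function(targets, class_costs) {
  n <- length(targets)
  if (is.null(class_costs)) return(rep(1, n))
  if (length(class_costs) == n && is.null(names(class_costs)))
    return(as.numeric(class_costs))
  if (!all(c("HC", "AD") %in% names(class_costs)))
    stop("class_costs must be named c(HC=, AD=) or one weight per sample",
         call. = FALSE)
  ifelse(targets >= 0.5, class_costs[["AD"]], class_costs[["HC"]])
}

#' Cost-weighted mean-squared-error loss
#'
#' `sum_i c_i (O_i - T_i)^2 / sum_i c_i`: the cost-weighted mean of the
#' squared output-target differences.  With all costs equal to 1 this is
#' the plain MSE; unbalanced cohorts use costs inversely proportional to
#' class frequency so both classes pull equally on the fit.
#'
#' @param weights An `fnn_weights` object.
#' @param X Samples x N_I input matrix.
#' @param targets Numeric 0/1 targets (HC = 0, AD = 1), one per row.
#' @param class_costs `NULL`, a named pair `c(HC=, AD=)`, or one
#'   positive weight per sample.
#' @return Scalar loss.
#' @export
mse_loss <- function(weights, X, targets, class_costs = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (nrow(X) != length(targets))
    stop(sprintf("%d samples but %d targets", nrow(X), length(targets)),
         call. = FALSE)
  cst <- .sample_costs(targets, class_costs)
  if (any(cst <= 0)) stop("costs must be positive", call. = FALSE)
  o <- forward_pass(weights, X)$output[, 1L]
  sum(cst * (o - targets)^2) / sum(cst)
}

#' Analytic gradient of [mse_loss()]
#'
#' Exact backpropagated gradient with the same shapes as the weights.
#'
#' @inheritParams mse_loss
#' @return List `w1`, `b1`, `w2`, `b2` of gradient arrays.
#' @export
fnn_gradient <- function(weights, X, targets, class_costs = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (nrow(X) != length(targets))
    stop(sprintf("%d samples but %d targets", nrow(X), length(targets)),
         call. = FALSE)
  cst <- .sample_costs(targets, class_costs)
  fp <- forward_pass(weights, X)
  h <- fp$hidden
  d_o <- matrix(2 * cst * (fp$output[, 1L] - targets) / sum(cst), ncol = 1L)
  g_w2 <- t(h) %*% d_o
  g_b2 <- colSums(d_o)
  d_h <- (d_o %*% t(weights$w2)) * h * (1 - h)
  g_w1 <- t(X) %*% d_h
  g_b1 <- colSums(d_h)
  if (weights$no_bias) { g_b1 <- numeric(length(g_b1)); g_b2 <- numeric(length(g_b2)) }
  list(w1 = g_w1, b1 = g_b1, w2 = g_w2, b2 = g_b2)
}

.flatten <- function(w) c(w$w1, w$b1, w$w2, w$b2)

.unflatten <- function(v, template) {
  s <- template$sizes
  n1 <- s[1] * s[2]; n2 <- s[2]; n3 <- s[2] * s[3]; n4 <- s[3]
  template$w1 <- matrix(v[seq_len(n1)], s[1], s[2])
  template$b1 <- v[n1 + seq_len(n2)]
  template$w2 <- matrix(v[n1 + n2 + seq_len(n3)], s[2], s[3])
  template$b2 <- v[n1 + n2 + n3 + seq_len(n4)]
  template
}

#' Training configuration for [train_scg()]
#'
#' @param max_iterations Iteration cap (>= 0; 0 returns the initial
#'   weights untouched).
#' @param mse_goal Stop once the loss falls to or below this value.
#' @param sigma Scale of the finite-difference step used for the
#'   Hessian-vector estimate (Moller's sigma, default 5e-5).
#' @param lambda_init Initial Levenberg scale (Moller's lambda_1).
#' @param seed Seed for the weight initialisation.
#' @param class_costs See [mse_loss()]; `"balanced"` resolves to costs
#'   inversely proportional to the class frequencies in the training
#'   targets.
#' @param no_bias Train the literal no-intercept network.
#' @return List of class `scg_config`.
#' @export
scg_config <- function(max_iterations = 500L, mse_goal = 1e-6,
                       sigma = 5e-5, lambda_init = 1e-6, seed = 1L,
                       class_costs = NULL, no_bias = FALSE) {
  stopifnot(max_iterations >= 0L, mse_goal >= 0, sigma > 0, lambda_init > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 mse_goal = mse_goal, sigma = sigma,
                 lambda_init = lambda_init, seed = as.integer(seed),
                 class_costs = class_costs, no_bias = isTRUE(no_bias)),
            class = "scg_config")
}

#' Train the network by scaled conjugate gradient
#'
#' Moller's SCG: conjugate directions with the curvature along each
#' direction estimated by a one-sided finite difference of the gradient,
#' and a Levenberg-style lambda that grows when the quadratic model
#' predicts poorly and shrinks when it predicts well.  No line search is
#' performed.  The loss trace over accepted iterates is non-increasing;
#' everything is deterministic given the seed.
#'
#' @param X Samples x N_I input matrix.
#' @param targets Numeric 0/1 targets.
#' @param sizes `(N_I, N_H, N_O)` layer sizes (default hidden size 10).
#' @param config An [scg_config()] list.
#' @param weights Optional starting `fnn_weights` (otherwise seeded
#'   [init_weights()]).
#' @return List with `weights` (trained `fnn_weights`), `trace`
#'   (accepted-iterate losses, first entry the initial loss),
#'   `iterations`, `converged`.
#' @export
train_scg <- function(X, targets, sizes = c(ncol(X), 10L, 1L),
                      config = scg_config(), weights = NULL) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  stopifnot(nrow(X) >= 1L, length(targets) == nrow(X))
  if (sizes[3] != 1L)
    stop("one output unit is required for the binary task", call. = FALSE)
  cc <- config$class_costs
  if (identical(cc, "balanced")) {
    n <- length(targets); na <- sum(targets >= 0.5); nh <- n - na
    if (na == 0L || nh == 0L)
      stop("balanced class costs need both classes in the training targets",
           call. = FALSE)
    cc <- c(HC = n / (2 * nh), AD = n / (2 * na))
  }
  if (is.null(weights))
    weights <- init_weights(sizes, seed = config$seed, no_bias = config$no_bias)
  tmpl <- weights

  fval <- function(v) mse_loss(.unflatten(v, tmpl), X, targets, cc)
  gval <- function(v) .flatten(fnn_gradient(.unflatten(v, tmpl), X, targets, cc))

  w <- .flatten(weights)
  f_w <- fval(w)
  trace <- f_w
  if (config$max_iterations == 0L)
    return(list(weights = .unflatten(w, tmpl), trace = trace,
                iterations = 0L, converged = f_w <= config$mse_goal))

  r <- -gval(w)                    # negative gradient
  p <- r
  lambda <- config$lambda_init
  success <- TRUE
  N <- length(w)
  theta <- 0; kappa <- 0; mu <- 0
  for (k in seq_len(config$max_iterations)) {
    if (!is.finite(f_w))
      stop("non-finite loss at SCG iteration ", k, call. = FALSE)
    if (success) {                 # curvature along the new direction
      kappa <- sum(p^2)
      if (kappa < 1e-300) break
      mu <- sum(p * r)
      if (mu <= 0) {               # not a descent direction: restart
        p <- r
        mu <- sum(p * r)
        kappa <- sum(p^2)
        if (kappa < 1e-300) break
      }
      sigma_k <- config$sigma / sqrt(kappa)
      s <- (gval(w + sigma_k * p) + r) / sigma_k
      theta <- sum(p * s)
    }
    delta <- theta + lambda * kappa
    if (delta <= 0) {              # force positive definiteness
      delta <- lambda * kappa
      lambda <- lambda - theta / kappa
    }
    alpha <- mu / delta
    f_new <- fval(w + alpha * p)
    Delta <- 2 * delta * (f_w - f_new) / mu^2
    if (Delta >= 0) {              # accept the step
      w <- w + alpha * p
      r_old <- r
      r <- -gval(w)
      success <- TRUE
      f_w <- f_new
      trace <- c(trace, f_w)
      if (f_w <= config$mse_goal) break
      if (k %% N == 0L) {
        p <- r                     # periodic restart along steepest descent
      } else {
        beta <- (sum(r^2) - sum(r * r_old)) / mu
        p <- r + beta * p
      }
      if (Delta >= 0.75) lambda <- max(lambda / 2, 1e-15)
    } else {
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- min(lambda * 4, 1e100)
    if (sum(r^2) < 1e-24) break
  }
  list(weights = .unflatten(w, tmpl), trace = trace,
       iterations = length(trace) - 1L, converged = f_w <= config$mse_goal)
}

#' Threshold network outputs into class labels
#'
#' @param weights Trained `fnn_weights`.
#' @param X Samples x N_I matrix (or vector).
#' @param threshold Decision threshold on the linear output (default
#'   0.5 for 0/1 targets); outputs at or above it are labelled AD.
#' @return Character vector of "AD"/"HC" labels.
#' @export
fnn_classify <- function(weights, X, threshold = 0.5) {
  o <- forward_pass(weights, X)$output[, 1L]
  ifelse(o >= threshold, "AD", "HC")
}

#' @export
print.fnn_weights <- function(x, ...) {
  cat(sprintf("Feed-forward network %d-%d-%d (sigmoid hidden, linear output%s)\n",
              x$sizes[1], x$sizes[2], x$sizes[3],
              if (x$no_bias) ", no biases" else ""))
  invisible(x)
}
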