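#' Scaled conjugate gradient minimizer
#'
#' Full-batch scaled conjugate gradient (SCG) descent after Moller (1993),
#' the algorithm behind the classic neural-network "trainscg" routine. It
#' avoids a line search by a scaled second-order step with a Levenberg-style
#' trust parameter, and only accepts steps that lower the objective, so the
#' recorded cost trajectory is non-increasing.
#'
#' @param fn function of a parameter vector returning
#'   `list(cost = <scalar>, grad = <vector>)`.
#' @param theta0 numeric initial parameter vector.
#' @param max_iter maximum number of SCG iterations ("epochs").
#' @param grad_tol stop when the gradient infinity-norm falls below this.
#' @return list with `par` (the minimizer found), `cost` (its objective
#'   value), `trajectory` (objective value of the current iterate after
#'   every iteration, length `<= max_iter`), and `iterations`.
#' @examples
#' quad <- function(w) list(cost = sum((w - 3)^2), grad = 2 * (w - 3))
#' fit <- scg_optimize(quad, c(0, 0), max_iter = 50)
#' fit$par
#' @export
scg_optimize <- function(fn, theta0, max_iter = 100L, grad_tol = 1e-8) {
  w <- as.numeric(theta0)
  ev <- fn(w)
  if (!is.finite(ev$cost)) stop("non-finite cost at the initial point", call. = FALSE)
  E <- ev$cost
  g <- as.numeric(ev$grad)
  r <- -g
  p <- r
  sigma0 <- 5e-5
  lambda <- 5e-7
  lambda_bar <- 0
  success <- TRUE
  delta <- 0
  norm_p2 <- sum(p * p)
  traj <- numeric(max_iter)
  k <- 0L
  while (k < max_iter) {
    k <- k + 1L
    if (success) {
      norm_p2 <- sum(p * p)
      if (norm_p2 < .Machine$double.eps) {
        traj[k] <- E
        break
      }
      sigma <- sigma0 / sqrt(norm_p2)
      g_plus <- fn(w + sigma * p)$grad
      s <- (g_plus - g) / sigma
      delta <- sum(p * s)
    }
    # scale the curvature estimate; force positive definiteness
    delta <- delta + (lambda - lambda_bar) * norm_p2
    if (delta <= 0) {
      lambda_bar <- 2 * (lambda - delta / norm_p2)
      delta <- -delta + lambda * norm_p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    E_new <- fn(w + alpha * p)$cost
    cmp <- 2 * delta * (E - E_new) / (mu * mu)
    if (is.finite(cmp) && cmp >= 0) {
      # accept the step
      w <- w + alpha * p
      ev <- fn(w)
      E <- ev$cost
      g_new <- as.numeric(ev$grad)
      r_new <- -g_new
      lambda_bar <- 0
      success <- TRUE
      if (k %% length(w) == 0L) {
        p <- r_new # periodic restart along steepest descent
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      g <- g_new
      if (cmp >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (!is.finite(cmp) || cmp < 0.25) {
      lambda <- lambda + delta * (1 - ifelse(is.finite(cmp), cmp, 0)) / norm_p2
    }
    if (!is.finite(lambda) || lambda > 1e100) lambda <- 1e100
    traj[k] <- E
    if (max(abs(g)) < grad_tol) break
  }
  list(par = w, cost = E, trajectory = traj[seq_len(k)], iterations = k)
}

# Plain full-batch gradient descent with a fixed learning rate.
gd_optimize <- function(fn, theta0, max_iter = 100L, lr = 0.1) {
  w <- as.numeric(theta0)
  traj <- numeric(max_iter)
  E <- NA_real_
  for (k in seq_len(max_iter)) {
    ev <- fn(w)
    if (!is.finite(ev$cost)) {
      stop(sprintf("optimization diverged (non-finite cost) at epoch %d", k),
           call. = FALSE)
    }
    E <- ev$cost
    w <- w - lr * as.numeric(ev$grad)
    traj[k] <- E
  }
  list(par = w, cost = fn(w)$cost, trajectory = traj, iterations = max_iter)
}

run_optimizer <- function(fn, theta0, optimizer = c("scg", "gd"),
                          max_iter = 100L, lr = 0.1) {
  optimizer <- match.arg(optimizer)
  if (optimizer == "scg") {
    scg_optimize(fn, theta0, max_iter = max_iter)
  } else {
    gd_optimize(fn, theta0, max_iter = max_iter, lr = lr)
  }
}
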