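# No-U-Turn sampler (NUTS) with dual-averaging step-size adaptation and
# diagonal mass-matrix estimation during warmup. This is the slice-sampling
# formulation of NUTS (dynamic binary tree doubling, stopped at a U-turn or
# a divergence), which is the sampler used for all Bayesian inference in
# this package. Kept generic: it only sees a log-density-with-gradient
# callback on an unconstrained parameter vector.

# lp_grad(theta) -> list(lp = scalar log density, grad = gradient vector)
nuts_sample <- function(lp_grad, init, n_warmup = 500, n_samples = 500,
                        target_accept = 0.9, seed = 1, max_treedepth = 10,
                        adapt_mass = TRUE) {
  stopifnot(n_warmup > 0, n_samples > 0, target_accept > 0, target_accept < 1)
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  d <- length(init)
  theta <- as.numeric(init)
  cur <- lp_grad(theta)
  if (!is.finite(cur$lp)) stop("initial point has non-finite log density")
  inv_mass <- rep(1, d)

  eps <- find_initial_eps(lp_grad, theta, cur, inv_mass)
  mu <- log(10 * eps)
  log_eps_bar <- 0
  H_bar <- 0
  adapt_iter <- 0L
  gamma <- 0.05; t0 <- 10; kappa <- 0.75

  total <- n_warmup + n_samples
  draws <- matrix(NA_real_, n_samples, d)
  n_div <- 0L
  accept_sum <- 0
  depth_sum <- 0L
  # Stan-like warmup schedule: initial step-size phase, doubling
  # mass-estimation windows, terminal step-size phase
  win_ends <- integer(0)
  if (adapt_mass && n_warmup >= 60L) {
    t_init <- max(10L, floor(0.15 * n_warmup))
    t_term <- max(10L, floor(0.10 * n_warmup))
    pos <- t_init
    wlen <- 25L
    while (pos + wlen < n_warmup - t_term) {
      pos <- pos + wlen
      win_ends <- c(win_ends, pos)
      wlen <- 2L * wlen
    }
    if (length(win_ends)) win_ends[length(win_ends)] <- n_warmup - t_term
    win_start <- c(t_init, win_ends[-length(win_ends)]) + 1L
  }
  win_buf <- list()

  for (it in seq_len(total)) {
    warmup <- it <= n_warmup
    r0 <- stats::rnorm(d) / sqrt(inv_mass)       # momentum ~ N(0, mass)
    joint0 <- cur$lp - 0.5 * sum(r0^2 * inv_mass)
    log_u <- joint0 + log(stats::runif(1))       # slice variable

    st <- list(theta_m = theta, r_m = r0, grad_m = cur$grad,
               theta_p = theta, r_p = r0, grad_p = cur$grad,
               theta_new = theta, lp_new = cur$lp, grad_new = cur$grad,
               n = 1L, s = TRUE, alpha = 0, n_alpha = 0L, div = FALSE)
    depth <- 0L
    while (st$s && depth < max_treedepth) {
      dir <- if (stats::runif(1) < 0.5) -1 else 1
      if (dir == -1) {
        sub <- build_tree(lp_grad, st$theta_m, st$r_m, st$grad_m, log_u,
                          joint0, dir, depth, eps, inv_mass)
        st$theta_m <- sub$theta_m; st$r_m <- sub$r_m; st$grad_m <- sub$grad_m
      } else {
        sub <- build_tree(lp_grad, st$theta_p, st$r_p, st$grad_p, log_u,
                          joint0, dir, depth, eps, inv_mass)
        st$theta_p <- sub$theta_p; st$r_p <- sub$r_p; st$grad_p <- sub$grad_p
      }
      if (sub$s && stats::runif(1) < sub$n / max(st$n, 1L)) {
        st$theta_new <- sub$theta_new
        st$lp_new <- sub$lp_new
        st$grad_new <- sub$grad_new
      }
      st$n <- st$n + sub$n
      st$alpha <- st$alpha + sub$alpha
      st$n_alpha <- st$n_alpha + sub$n_alpha
      st$div <- st$div || sub$div
      st$s <- sub$s && uturn_ok(st$theta_m, st$theta_p, st$r_m, st$r_p,
                                inv_mass)
      depth <- depth + 1L
    }
    theta <- st$theta_new
    cur <- list(lp = st$lp_new, grad = st$grad_new)
    a_frac <- if (st$n_alpha > 0L) st$alpha / st$n_alpha else 0
    if (st$div && !warmup) n_div <- n_div + 1L

    if (warmup) {
      adapt_iter <- adapt_iter + 1L
      m <- adapt_iter
      H_bar <- (1 - 1 / (m + t0)) * H_bar +
        (target_accept - a_frac) / (m + t0)
      log_eps <- mu - sqrt(m) / gamma * H_bar
      w <- m^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (length(win_ends) && it > win_start[1] - 1L && it <= max(win_ends)) {
        win_buf[[length(win_buf) + 1L]] <- theta
        if (it %in% win_ends) {
          B <- do.call(rbind, win_buf)
          v <- apply(B, 2, stats::var)
          n_w <- nrow(B)
          # regularize towards unit metric as Stan does
          inv_mass_new <- (n_w / (n_w + 5)) * v + (5 / (n_w + 5)) * 1e-3
          inv_mass_new[!is.finite(inv_mass_new) | inv_mass_new <= 0] <- 1
          inv_mass <- inv_mass_new
          win_buf <- list()
          # restart dual averaging around the current step size
          mu <- log(10 * eps)
          H_bar <- 0
          log_eps_bar <- log(eps)
          adapt_iter <- 0L
        }
      }
      if (it == n_warmup) eps <- exp(log_eps_bar)
    } else {
      draws[it - n_warmup, ] <- theta
      accept_sum <- accept_sum + a_frac
      depth_sum <- depth_sum + depth
    }
  }

  list(draws = draws, step_size = eps, inv_mass = inv_mass,
       n_divergent = n_div, mean_accept = accept_sum / n_samples,
       mean_treedepth = depth_sum / n_samples)
}

leapfrog <- function(lp_grad, theta, r, grad, eps, inv_mass) {
  r1 <- r + 0.5 * eps * grad
  theta1 <- theta + eps * inv_mass * r1
  new <- lp_grad(theta1)
  r1 <- r1 + 0.5 * eps * new$grad
  list(theta = theta1, r = r1, lp = new$lp, grad = new$grad)
}

uturn_ok <- function(theta_m, theta_p, r_m, r_p, inv_mass) {
  dt <- theta_p - theta_m
  sum(dt * (inv_mass * r_m)) >= 0 && sum(dt * (inv_mass * r_p)) >= 0
}

build_tree <- function(lp_grad, theta, r, grad, log_u, joint0, dir, depth,
                       eps, inv_mass) {
  if (depth == 0L) {
    step <- leapfrog(lp_grad, theta, r, grad, dir * eps, inv_mass)
    joint <- if (is.finite(step$lp))
      step$lp - 0.5 * sum(step$r^2 * inv_mass) else -Inf
    div <- !is.finite(joint) || (log_u - joint) > 1000
    n <- if (!div && log_u <= joint) 1L else 0L
    alpha <- if (is.finite(joint)) min(1, exp(joint - joint0)) else 0
    return(list(theta_m = step$theta, r_m = step$r, grad_m = step$grad,
                theta_p = step$theta, r_p = step$r, grad_p = step$grad,
                theta_new = step$theta, lp_new = step$lp,
                grad_new = step$grad, n = n, s = !div,
                alpha = min(1, alpha), n_alpha = 1L, div = div))
  }
  first <- build_tree(lp_grad, theta, r, grad, log_u, joint0, dir,
                      depth - 1L, eps, inv_mass)
  out <- first
  if (first$s) {
    if (dir == -1) {
      second <- build_tree(lp_grad, first$theta_m, first$r_m, first$grad_m,
                           log_u, joint0, dir, depth - 1L, eps, inv_mass)
      out$theta_m <- second$theta_m; out$r_m <- second$r_m
      out$grad_m <- second$grad_m
    } else {
      second <- build_tree(lp_grad, first$theta_p, first$r_p, first$grad_p,
                           log_u, joint0, dir, depth - 1L, eps, inv_mass)
      out$theta_p <- second$theta_p; out$r_p <- second$r_p
      out$grad_p <- second$grad_p
    }
    tot <- first$n + second$n
    if (tot > 0L && stats::runif(1) < second$n / tot) {
      out$theta_new <- second$theta_new
      out$lp_new <- second$lp_new
      out$grad_new <- second$grad_new
    }
    out$n <- tot
    out$alpha <- first$alpha + second$alpha
    out$n_alpha <- first$n_alpha + second$n_alpha
    out$div <- first$div || second$div
    out$s <- second$s && uturn_ok(out$theta_m, out$theta_p, out$r_m, out$r_p,
                                  inv_mass)
  }
  out
}

# heuristic of Hoffman & Gelman: double/halve eps to cross 50% acceptance
find_initial_eps <- function(lp_grad, theta, cur, inv_mass) {
  d <- length(theta)
  eps <- 1
  r0 <- stats::rnorm(d) / sqrt(inv_mass)
  joint0 <- cur$lp - 0.5 * sum(r0^2 * inv_mass)
  step <- leapfrog(lp_grad, theta, r0, cur$grad, eps, inv_mass)
  joint1 <- if (is.finite(step$lp))
    step$lp - 0.5 * sum(step$r^2 * inv_mass) else -Inf
  a <- if ((joint1 - joint0) > log(0.5)) 1 else -1
  for (k in 1:50) {
    eps <- eps * 2^a
    step <- leapfrog(lp_grad, theta, r0, cur$grad, eps, inv_mass)
    joint1 <- if (is.finite(step$lp))
      step$lp - 0.5 * sum(step$r^2 * inv_mass) else -Inf
    if (a * (joint1 - joint0) <= a * log(0.5)) break
  }
  max(eps, 1e-8)
}
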