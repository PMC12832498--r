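#' Structural confidence map
#'
#' `C(i) = exp(-(y(i) - hx(i))^2 / sigma_conf^2)`: per-pixel agreement between
#' the observation and the forward-modeled iterate. Values lie in (0, 1] and
#' equal 1 exactly where the residual is zero.
#'
#' @param y observation.
#' @param hx forward-model prediction, same shape.
#' @param sigma_conf positive robustness scale (intensity units).
#' @return matrix of confidences in (0, 1].
#' @export
confidence_map <- function(y, hx, sigma_conf) {
  if (!is.numeric(sigma_conf) || length(sigma_conf) != 1L || sigma_conf <= 0) {
    stop("sigma_conf must be a positive scalar", call. = FALSE)
  }
  if (!all(dim(y) == dim(hx))) stop("y and hx must have the same shape", call. = FALSE)
  exp(-(y - hx)^2 / sigma_conf^2)
}

#' Reliable/uncertain partition and spatial weights
#'
#' Pixels with confidence `>= tau` form the reliable region and get unit
#' weight; the rest get weight `gamma` in (0, 1]. When an uncertainty map is
#' supplied, weights are reweighted multiplicatively as
#' `omega * (1 + delta * Sigma)` (literal convention; set
#' `uncertainty_mode = "inverse"` for `omega / (1 + delta * Sigma)`, which
#' down-weights uncertain pixels instead).
#'
#' @param C confidence map.
#' @param tau threshold in \[0, 1\] (values above 1 mark every pixel uncertain).
#' @param gamma uncertain-region weight in (0, 1\].
#' @param sigma_map optional uncertainty map (nonnegative matrix).
#' @param delta nonnegative reweighting gain.
#' @param uncertainty_mode `"literal"` or `"inverse"`.
#' @return `list(reliable = <logical matrix>, tau = , omega = <matrix > 0>)`.
#' @export
partition_and_weights <- function(C, tau, gamma, sigma_map = NULL, delta = 0,
                                  uncertainty_mode = c("literal", "inverse")) {
  uncertainty_mode <- match.arg(uncertainty_mode)
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]", call. = FALSE)
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  reliable <- C >= tau
  omega <- ifelse(reliable, 1, gamma)
  if (!is.null(sigma_map) && delta > 0) {
    omega <- switch(uncertainty_mode,
                    literal = omega * (1 + delta * sigma_map),
                    inverse = omega / (1 + delta * sigma_map))
  }
  list(reliable = reliable, tau = tau, omega = omega)
}

#' Confidence-weighted data fidelity
#'
#' `sum_i omega_i (y_i - hx_i)^2`; reduces to the plain sum of squared errors
#' when all weights are one.
#'
#' @param y observation.
#' @param hx forward-model prediction.
#' @param omega positive weight matrix.
#' @return nonnegative scalar.
#' @export
weighted_fidelity <- function(y, hx, omega) {
  if (!all(dim(y) == dim(hx))) stop("y and hx must have the same shape", call. = FALSE)
  sum(omega * (y - hx)^2)
}

#' Build the pixel-similarity graph
#'
#' Connects each pixel to its `k` nearest neighbors in feature space, keeps
#' edges whose feature distance is at most `eps`, assigns affinity weights
#' `exp(-dist^2 / beta)`, symmetrizes by union, drops weights below 1e-4, and
#' prunes to a maximum degree of `k` (strongest edges kept, deterministic
#' tie-breaks: feature distance, then spatial distance, then index). Exact
#' neighbor search is used up to 4096 pixels; larger images use a spatial
#' grid-bucketed approximate search (candidates restricted to nearby buckets,
#' which is where structurally similar pixels overwhelmingly live).
#'
#' @param features `h x w x d` feature array (or `n x d` matrix plus `dims`).
#' @param eps distance threshold (`> 0`).
#' @param beta affinity bandwidth (`> 0`), on squared-distance scale.
#' @param k neighbor budget (`>= 1`, `< n`).
#' @param dims image dimensions when `features` is a plain matrix.
#' @return object of class `pixel_graph`: `list(n, h, w, edges =
#'   data.frame(i, j, w, d2), eps, beta, k)` with `i < j`, each undirected
#'   edge stored once.
#' @export
build_graph <- function(features, eps, beta, k, dims = NULL) {
  if (eps <= 0 || beta <= 0) stop("eps and beta must be positive", call. = FALSE)
  if (length(dim(features)) == 3L) {
    dims <- dim(features)[1:2]
    fmat <- matrix(features, nrow = prod(dims), ncol = dim(features)[3L])
  } else {
    stopifnot(!is.null(dims))
    fmat <- as.matrix(features)
  }
  n <- nrow(fmat)
  if (k >= n) stop("k must be smaller than the number of pixels", call. = FALSE)
  h <- dims[1L]; w <- dims[2L]
  px_row <- ((seq_len(n) - 1L) %% h) + 1L
  px_col <- ((seq_len(n) - 1L) %/% h) + 1L

  # pick the k nearest of `cand` to pixel i given squared distances d2;
  # ties broken by spatial distance, then index, for determinism
  select_k <- function(i, cand, d2) {
    if (length(cand) > k) {
      thr <- sort.int(d2, partial = k)[k]
      keep <- d2 <= thr
      cand <- cand[keep]; d2 <- d2[keep]
      if (length(cand) > k) {
        sp <- (px_row[cand] - px_row[i])^2 + (px_col[cand] - px_col[i])^2
        ord <- order(d2, sp, cand)[seq_len(k)]
        cand <- cand[ord]; d2 <- d2[ord]
      }
    }
    sel <- d2 <= eps^2
    if (!any(sel)) return(NULL)
    cbind(i = i, j = cand[sel], d2 = d2[sel])
  }

  collect <- function(i, cand) {
    cand <- cand[cand != i]
    d2 <- colSums((t(fmat[cand, , drop = FALSE]) - fmat[i, ])^2)
    select_k(i, cand, d2)
  }

  if (n <= 4096L) {
    # exact search, blocked: full squared-distance rows via matrix algebra
    sq <- rowSums(fmat^2)
    rows <- vector("list", n)
    bs_rows <- 256L
    for (start in seq(1L, n, by = bs_rows)) {
      ii <- start:min(start + bs_rows - 1L, n)
      D2 <- outer(sq[ii], sq, "+") - 2 * tcrossprod(fmat[ii, , drop = FALSE], fmat)
      for (m_ in seq_along(ii)) {
        i <- ii[m_]
        d2 <- pmax(D2[m_, ], 0)
        rows[[i]] <- select_k(i, seq_len(n)[-i], d2[-i])
      }
    }
  } else {
    # grid-bucketed approximate search: candidates from the 5x5 bucket patch
    bs <- 8L
    bi <- (px_row - 1L) %/% bs
    bj <- (px_col - 1L) %/% bs
    nb_i <- max(bi) + 1L
    key <- bi + bj * nb_i
    buckets <- split(seq_len(n), key)
    rows <- lapply(seq_len(n), function(i) {
      cand <- unlist(lapply(-2:2, function(dj) {
        lapply(-2:2, function(di) {
          kk <- as.character((bi[i] + di) + (bj[i] + dj) * nb_i)
          buckets[[kk]]
        })
      }), use.names = FALSE)
      collect(i, cand)
    })
  }
  ed <- do.call(rbind, rows)
  if (is.null(ed) || nrow(ed) == 0L) {
    edges <- data.frame(i = integer(0), j = integer(0),
                        w = numeric(0), d2 = numeric(0))
  } else {
    # symmetrize by union, store each undirected edge once with i < j
    a <- pmin(ed[, "i"], ed[, "j"]); b <- pmax(ed[, "i"], ed[, "j"])
    keep <- !duplicated(cbind(a, b))
    a <- a[keep]; b <- b[keep]; d2 <- ed[keep, "d2"]
    wgt <- exp(-d2 / beta)
    ok <- wgt >= 1e-4
    edges <- data.frame(i = a[ok], j = b[ok], w = wgt[ok], d2 = d2[ok])
    edges <- prune_degree(edges, n, k)
  }
  structure(list(n = n, h = h, w = w, edges = edges,
                 eps = eps, beta = beta, k = as.integer(k)),
            class = "pixel_graph")
}

# Enforce max degree <= k: visit edges strongest-first (ties: smaller d2,
# then i, then j) and keep an edge only while both endpoints have budget.
prune_degree <- function(edges, n, k) {
  if (nrow(edges) == 0L) return(edges)
  deg <- tabulate(c(edges$i, edges$j), nbins = n)
  if (max(deg) <= k) return(edges)
  ord <- order(-edges$w, edges$d2, edges$i, edges$j)
  used <- integer(n)
  keep <- logical(nrow(edges))
  for (e in ord) {
    i <- edges$i[e]; j <- edges$j[e]
    if (used[i] < k && used[j] < k) {
      keep[e] <- TRUE
      used[i] <- used[i] + 1L
      used[j] <- used[j] + 1L
    }
  }
  edges[keep, , drop = FALSE]
}

#' Weighted graph Laplacian
#'
#' Sparse Laplacian `L = D - W` of a [build_graph()] result, with `W` the
#' symmetric affinity matrix. The quadratic form `x' L x` equals the graph
#' penalty with each undirected edge counted once.
#'
#' @param graph a `pixel_graph`.
#' @return a sparse `Matrix::dgCMatrix`.
#' @export
graph_laplacian <- function(graph) {
  n <- graph$n
  e <- graph$edges
  if (nrow(e) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  }
  W <- Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                            x = c(e$w, e$w), dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(W)) - W
}

#' Graph smoothness penalty
#'
#' `sum_{(i,j) in E} w_ij (x_i - x_j)^2`, each undirected edge counted once;
#' zero on constant images and equal to the Laplacian quadratic form
#' `x' L x`.
#'
#' @param x image matrix over the graph's pixels (column-major indexing).
#' @param graph a `pixel_graph`.
#' @return nonnegative scalar.
#' @export
graph_penalty <- function(x, graph) {
  if (length(x) != graph$n) stop("image size does not match graph", call. = FALSE)
  e <- graph$edges
  if (nrow(e) == 0L) return(0)
  xv <- as.vector(x)
  sum(e$w * (xv[e$i] - xv[e$j])^2)
}

#' Adaptive objective and its gradient
#'
#' `J(x) = sum_i omega_i (y_i - H(x)_i)^2 + lambda * sum_E w_ij (x_i - x_j)^2`
#' with gradient `-2 H'(omega * (y - Hx)) + 2 lambda L x`, where `H'` is the
#' exact adjoint of the blur path (including boundary folding).
#'
#' @param x current iterate.
#' @param y observation.
#' @param forward `list(H = , Ht = )` as from the blur operator of a spec.
#' @param graph a `pixel_graph` (or `NULL` for no regularizer).
#' @param omega weight matrix.
#' @param lambda nonnegative regularization weight.
#' @param L optional precomputed Laplacian for `graph`.
#' @return `list(J, grad, residual_energy, fidelity, penalty)`.
#' @export
objective_and_gradient <- function(x, y, forward, graph, omega, lambda,
                                   L = NULL) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  r <- y - forward$H(x)
  fid <- sum(omega * r^2)
  grad <- -2 * forward$Ht(omega * r, x)
  pen <- 0
  if (!is.null(graph) && lambda > 0 && nrow(graph$edges) > 0L) {
    if (is.null(L)) L <- graph_laplacian(graph)
    pen <- graph_penalty(x, graph)
    grad <- grad + matrix(2 * lambda * as.vector(L %*% as.vector(x)),
                          nrow(x), ncol(x))
  }
  list(J = fid + lambda * pen, grad = grad,
       residual_energy = sum(r^2), fidelity = fid, penalty = pen)
}

#' Optimizer schedules
#'
#' All schedule quantities have exact closed forms in the iteration index:
#' step size `eta_t = eta0 / (1 + rho t)`; confidence threshold
#' `tau_t = tau0 * kappa^floor(t/K)` (relaxed at every restructure);
#' uncertain-region weight `gamma_t = min(1, gamma0 + t * dgamma)` (linear
#' ramp toward full inclusion); sharpening coefficient
#' `zeta_t = zeta0 / (1 + t)`; graph thresholds `eps_t = eps0 * eps_decay^
#' floor(t/K)` and bandwidth `beta_t = beta0 * beta_decay^floor(t/K)`
#' (tightened per restructure); termination margin `xi_t = xi0 / (1 + t)`;
#' regularization weight `lambda_t` constant.
#'
#' `eps0` and `beta0` may be left `NA`, in which case [run_psgo()] calibrates
#' them from the feature-distance distribution at the first restructure.
#' `sigma_conf = NA` means "estimate robustly from the current residual"
#' (1.4826 x its median absolute deviation, refreshed at each restructure).
#'
#' @param eta0 initial step size (`> 0`).
#' @param rho step decay rate (`>= 0`).
#' @param tau0 initial confidence threshold in \[0, 1\].
#' @param kappa threshold relaxation factor in (0, 1).
#' @param K restructure interval (iterations, `>= 1`).
#' @param gamma0 initial uncertain-region weight (small positive).
#' @param dgamma per-iteration ramp of `gamma_t`.
#' @param zeta0 initial sharpening coefficient.
#' @param eps0,eps_decay graph distance threshold start and per-restructure decay.
#' @param beta0,beta_decay affinity bandwidth start and per-restructure decay.
#' @param xi0 initial residual-energy improvement margin.
#' @param lambda graph regularization weight (constant).
#' @param delta uncertainty reweighting gain.
#' @param k graph neighbor budget.
#' @param T maximum iterations.
#' @param sigma_conf confidence scale, or `NA` for the robust estimate.
#' @param uncertainty_mode `"literal"` (up-weight uncertain pixels, the stated
#'   reweighting rule) or `"inverse"`.
#' @param momentum if `TRUE`, use a momentum-averaged step direction instead
#'   of the plain gradient (optional mode; the closed-form schedule remains
#'   the default).
#' @return an object of class `psgo_schedules`.
#' @export
psgo_schedules <- function(eta0 = 0.4, rho = 0.05, tau0 = 0.8, kappa = 0.9,
                           K = 5L, gamma0 = 0.01, dgamma = 0.02, zeta0 = 0.05,
                           eps0 = NA_real_, eps_decay = 0.95,
                           beta0 = NA_real_, beta_decay = 0.95,
                           xi0 = 1e-4, lambda = 0.2, delta = 0.5, k = 16L,
                           T = 60L, sigma_conf = NA_real_,
                           uncertainty_mode = c("literal", "inverse"),
                           momentum = FALSE) {
  uncertainty_mode <- match.arg(uncertainty_mode)
  stopifnot(eta0 > 0, rho >= 0, tau0 >= 0, tau0 <= 1,
            kappa > 0, kappa < 1, K >= 1, gamma0 > 0, dgamma >= 0,
            zeta0 >= 0, xi0 >= 0, lambda >= 0, delta >= 0, k >= 1)
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  structure(list(eta0 = eta0, rho = rho, tau0 = tau0, kappa = kappa,
                 K = as.integer(K), gamma0 = gamma0, dgamma = dgamma,
                 zeta0 = zeta0, eps0 = eps0, eps_decay = eps_decay,
                 beta0 = beta0, beta_decay = beta_decay, xi0 = xi0,
                 lambda = lambda, delta = delta, k = as.integer(k),
                 T = as.integer(T), sigma_conf = sigma_conf,
                 uncertainty_mode = uncertainty_mode, momentum = momentum),
            class = "psgo_schedules")
}

#' Evaluate all schedules at iteration t
#'
#' @param t iteration index (`>= 0`).
#' @param sched a [psgo_schedules()].
#' @return `list(eta, tau, gamma, zeta, eps, beta, xi, lambda)`.
#' @export
schedules_eval <- function(t, sched) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  s <- floor(t / sched$K)
  list(eta = sched$eta0 / (1 + sched$rho * t),
       tau = sched$tau0 * sched$kappa^s,
       gamma = min(1, sched$gamma0 + t * sched$dgamma),
       zeta = sched$zeta0 / (1 + t),
       eps = sched$eps0 * sched$eps_decay^s,
       beta = sched$beta0 * sched$beta_decay^s,
       xi = sched$xi0 / (1 + t),
       lambda = sched$lambda)
}

# Unsharp residual: x minus a Gaussian-blurred copy (sigma = 1).
sharpen_residual <- function(x) {
  x - convolve_image(x, gaussian_kernel(1), "reflect")
}

# Robust residual scale for the confidence map: 1.4826 * MAD, floored.
robust_sigma <- function(r, floor_at = 1e-3) {
  max(1.4826 * stats::median(abs(r - stats::median(r))), floor_at)
}

new_psgo_state <- function(x0) {
  list(t = 0L, x = x0, C = NULL, reliable = NULL, omega = NULL,
       graph = NULL, L = NULL, sigma_conf = NULL,
       ring = list(x0), J_hist = numeric(0), res_hist = numeric(0),
       velocity = NULL)
}

#' Restructure the optimizer state
#'
#' Performed every `K` iterations (including at initialization): features of
#' the current iterate are re-encoded, the pixel graph is rebuilt with the
#' tightened `eps_t`/`beta_t`, the confidence scale is re-estimated from the
#' current residual (1.4826 x MAD), and the confidence map, partition and
#' weights are refreshed (including uncertainty reweighting when enough
#' iterates have accumulated).
#'
#' @param state optimizer state (see [run_psgo()]).
#' @param problem `list(y = , forward = , params = )`.
#' @param sched a [psgo_schedules()] (with calibrated `eps0`/`beta0`).
#' @param lenient if `TRUE`, calling off-schedule is a no-op instead of an
#'   error.
#' @return updated state.
#' @export
restructure <- function(state, problem, sched, lenient = FALSE) {
  if (state$t %% sched$K != 0L) {
    if (lenient) return(state)
    stop(sprintf("restructure called at t = %d, not a multiple of K = %d",
                 state$t, sched$K), call. = FALSE)
  }
  sv <- schedules_eval(state$t, sched)
  f <- encode_features(state$x, problem$params)
  state$graph <- build_graph(f, eps = sv$eps, beta = sv$beta, k = sched$k)
  state$L <- graph_laplacian(state$graph)
  r <- problem$y - problem$forward$H(state$x)
  state$sigma_conf <- if (is.na(sched$sigma_conf)) robust_sigma(r)
                      else sched$sigma_conf
  state$C <- confidence_map(problem$y, problem$forward$H(state$x),
                            state$sigma_conf)
  sigma_map <- if (length(state$ring) >= 2L) {
    uncertainty_correct(state$x, state$ring, beta = 0)$sigma
  } else NULL
  pw <- partition_and_weights(state$C, sv$tau, sv$gamma, sigma_map,
                              sched$delta, sched$uncertainty_mode)
  state$reliable <- pw$reliable
  state$omega <- pw$omega
  state
}

#' One optimizer iteration
#'
#' Gradient step on the adaptive objective with backtracking line search
#' (step halved at most 8 times until the objective does not increase; the
#' step is skipped entirely if no trial succeeds), followed by the decaying
#' unsharp sharpening correction `zeta_t * (x - gauss_blur(x, 1))`, clipping
#' to \[0, 1\], and history bookkeeping.
#'
#' @param state optimizer state.
#' @param problem `list(y = , forward = , params = )`.
#' @param sched a [psgo_schedules()].
#' @return updated state with `t` advanced and histories appended; attributes
#'   of the appended trace row are stored in `state$last_step`.
#' @export
psgo_iterate <- function(state, problem, sched) {
  sv <- schedules_eval(state$t, sched)
  og <- objective_and_gradient(state$x, problem$y, problem$forward,
                               state$graph, state$omega, sv$lambda,
                               L = state$L)
  if (any(!is.finite(og$grad))) {
    stop(sprintf("non-finite gradient at iteration %d", state$t), call. = FALSE)
  }
  direction <- og$grad
  if (isTRUE(sched$momentum)) {
    state$velocity <- if (is.null(state$velocity)) direction
                      else 0.9 * state$velocity + direction
    direction <- state$velocity
  }
  sharp <- sv$zeta * sharpen_residual(state$x)
  eta <- sv$eta
  accepted <- FALSE
  backtracks <- 0L
  x_new <- state$x
  J_new <- og$J
  res_new <- og$residual_energy
  for (trial in 0:8) {
    cand <- clip01(state$x - eta * direction + sharp)
    oc <- objective_and_gradient(cand, problem$y, problem$forward,
                                 state$graph, state$omega, sv$lambda,
                                 L = state$L)
    if (oc$J <= og$J) {
      accepted <- TRUE
      x_new <- cand; J_new <- oc$J; res_new <- oc$residual_energy
      break
    }
    eta <- eta / 2
    backtracks <- backtracks + 1L
  }
  state$last_step <- list(t = state$t, J_pre = og$J, J = J_new,
                          residual_energy = res_new,
                          reliable_fraction = mean(state$reliable),
                          eta = if (accepted) eta else 0,
                          tau = sv$tau, backtracks = backtracks,
                          skipped = !accepted)
  state$x <- x_new
  state$J_hist <- c(state$J_hist, J_new)
  state$res_hist <- c(state$res_hist, res_new)
  state$ring <- c(state$ring, list(x_new))
  if (length(state$ring) > 6L) state$ring <- state$ring[-1L]
  state$t <- state$t + 1L
  state
}

#' Run the progressive structure-guided optimizer
#'
#' Full reconstruction loop: starting from `x0` (default: the observation),
#' the optimizer alternates confidence-weighted gradient steps on the
#' adaptive objective with periodic restructuring (every `K` iterations the
#' pixel graph, confidence map, threshold and weights are rebuilt from the
#' current iterate). Iteration stops at `T` or as soon as the residual-energy
#' improvement falls below `xi_t` for 3 consecutive iterations.
#'
#' @param y observed degraded image.
#' @param spec the [degradation_spec()] describing the forward model (its
#'   blur path and boundary rule define `H`).
#' @param config a [psgo_schedules()].
#' @param x0 optional initial iterate (defaults to `y`).
#' @param params optional [encoder_params()] used for graph features
#'   (default: `encoder_params(init_seed = seed)`).
#' @param seed integer seed (controls encoder initialization only; the loop
#'   itself is deterministic).
#' @param estimate_outliers_every if positive, re-estimate a sparse outlier
#'   field from the current residual every that-many restructures and subtract
#'   it from the working observation (robustness to impulse noise); 0 disables.
#' @param outlier_lambda soft-threshold penalty for the outlier step.
#' @return object of class `psgo_result`: `list(x_hat, trace, converged_at,
#'   sigma_conf, config)`. `trace` is a data frame with columns `t`, `J`,
#'   `residual_energy`, `reliable_fraction`, `eta`, `tau`, plus diagnostics
#'   `J_pre`, `backtracks`, `skipped`.
#' @export
run_psgo <- function(y, spec, config = psgo_schedules(), x0 = NULL,
                     params = NULL, seed = 0L,
                     estimate_outliers_every = 0L, outlier_lambda = 0.1) {
  assert_image(y)
  stopifnot(inherits(config, "psgo_schedules"))
  forward <- spec_operator(spec)
  if (is.null(params)) params <- encoder_params(init_seed = derive_seed(seed, 7L))
  if (is.null(x0)) x0 <- y
  stopifnot(all(dim(x0) == dim(y)))

  sched <- config
  y_work <- y
  problem <- list(y = y_work, forward = forward, params = params)
  state <- new_psgo_state(x0)

  # calibrate graph thresholds from the feature-distance distribution when
  # the config leaves them open
  if (is.na(sched$eps0) || is.na(sched$beta0)) {
    f0 <- encode_features(x0, params)
    cal <- calibrate_graph_scales(f0, sched$k)
    if (is.na(sched$eps0)) sched$eps0 <- cal$eps0
    if (is.na(sched$beta0)) sched$beta0 <- cal$beta0
  }

  trace <- vector("list", sched$T)
  strikes <- 0L
  converged_at <- NA_integer_
  restructures <- 0L
  for (t in seq_len(sched$T) - 1L) {
    if (t %% sched$K == 0L) {
      state <- restructure(state, problem, sched)
      restructures <- restructures + 1L
      if (estimate_outliers_every > 0L &&
          restructures %% estimate_outliers_every == 0L) {
        o <- estimate_outliers(y, forward$H(state$x), outlier_lambda)
        problem$y <- y - o$values
      }
    }
    res_prev <- sum((problem$y - forward$H(state$x))^2)
    state <- psgo_iterate(state, problem, sched)
    trace[[t + 1L]] <- as.data.frame(state$last_step)
    xi_t <- schedules_eval(t, sched)$xi
    if (res_prev - state$last_step$residual_energy < xi_t) {
      strikes <- strikes + 1L
    } else {
      strikes <- 0L
    }
    if (strikes >= 3L) {
      converged_at <- t + 1L
      break
    }
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1L))])
  trace <- trace[, c("t", "J", "residual_energy", "reliable_fraction",
                     "eta", "tau", "J_pre", "backtracks", "skipped")]
  structure(list(x_hat = state$x, trace = trace, converged_at = converged_at,
                 sigma_conf = state$sigma_conf, config = sched),
            class = "psgo_result")
}

# Pick eps0/beta0 from a subsample of pairwise feature distances so that the
# initial graph keeps most k-NN edges; both then tighten per restructure.
calibrate_graph_scales <- function(features, k) {
  dm <- dim(features)
  fmat <- matrix(features, nrow = dm[1L] * dm[2L], ncol = dm[3L])
  n <- nrow(fmat)
  idx <- unique(as.integer(round(seq(1L, n, length.out = min(n, 256L)))))
  d2 <- numeric(0)
  for (i in idx) {
    di <- colSums((t(fmat) - fmat[i, ])^2)
    di <- sort(di[-i], partial = min(k, n - 1L))[seq_len(min(k, n - 1L))]
    d2 <- c(d2, di)
  }
  med <- stats::median(d2)
  list(eps0 = sqrt(max(stats::quantile(d2, 0.95), 1e-8)),
       beta0 = max(med, 1e-8))
}

#' @export
print.psgo_result <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf("psgo_result: %d iterations%s\n", n,
              if (!is.na(x$converged_at))
                sprintf(" (converged at %d)", x$converged_at) else ""))
  cat(sprintf("  final J = %.6g, residual energy = %.6g\n",
              x$trace$J[n], x$trace$residual_energy[n]))
  invisible(x)
}
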