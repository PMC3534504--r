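#' Solve the augmented two-point boundary value problem
#'
#' Solves the augmented system for given rate parameters `p` and initial
#' species values `y0` under the two-way boundary conditions `y(0) = y0` and
#' `u(T) = 0`, using Hermite-Simpson collocation (4th order) on a uniform
#' mesh and a damped Newton iteration. The initial guess is the forward
#' solution under `x = S_x` with `u = 0`, which is exact in the
#' zero-residual limit; on Newton failure the mesh is doubled up to
#' `max_nodes` before giving up. The reconstructed input is attached via the
#' closed-form elimination.
#'
#' @param system an [augmented_system()].
#' @param p parameter vector (finite).
#' @param y0 initial species values (length `n`).
#' @param options list of solver options: `n_mesh` (mesh intervals, default
#'   96), `bvp_tol` (Newton residual tolerance, default 1e-9),
#'   `boundary_tol` (reported check on `|u(T)|`, default 1e-8), `max_newton`
#'   (default 30), `max_nodes` (default 1537), `init` (an
#'   `augmented_trajectory` or a `2n x (n_mesh+1)` state matrix used as
#'   starting guess).
#' @return An object of class `augmented_trajectory`: list with `times`
#'   (mesh nodes), `y` (`n x K`), `u` (`n x K`), `x` (`m x K`), the node
#'   derivatives `f` used for dense output, `bvp_residual` (max collocation
#'   residual), and bookkeeping fields.
#' @export
solve_augmented_bvp <- function(system, p, y0, options = list()) {
  stopifnot(inherits(system, "augmented_system"))
  model <- system$model
  if (!all(is.finite(p)) || length(p) != model$r)
    stop("p must be ", model$r, " finite values")
  if (!all(is.finite(y0)) || length(y0) != model$n)
    stop("y0 must be ", model$n, " finite values")
  o <- modifyList(list(n_mesh = 96L, bvp_tol = 1e-9, boundary_tol = 1e-8,
                       max_newton = 30L, max_nodes = 1537L, init = NULL),
                  options)
  n <- model$n; d <- 2L * n
  Tend <- system$T
  n_mesh <- as.integer(o$n_mesh)
  Zinit <- o$init
  last_res <- Inf

  repeat {
    times <- seq(0, Tend, length.out = n_mesh + 1)
    sol <- bvp_newton(system, p, y0, times, Zinit, o)
    if (sol$converged) {
      traj <- structure(
        list(times = times, y = sol$Z[seq_len(n), , drop = FALSE],
             u = sol$Z[n + seq_len(n), , drop = FALSE],
             x = sol$X, f = sol$F_nodes,
             bvp_residual = sol$resnorm, n_newton = sol$iter,
             n_mesh = n_mesh, system = system, p = p, y0 = y0),
        class = "augmented_trajectory")
      if (max(abs(traj$u[, ncol(traj$u)])) > o$boundary_tol)
        warning("terminal adjoint exceeds boundary_tol")
      return(traj)
    }
    last_res <- sol$resnorm
    if (2L * n_mesh + 1L > o$max_nodes) break
    Zinit <- sol$Z            # refine: double the mesh, reuse current iterate
    n_mesh <- 2L * n_mesh
  }
  stop(structure(class = c("bvp_convergence_error", "error", "condition"),
                 list(message = paste0(
                        "augmented BVP did not converge after mesh refinement ",
                        "(last max residual ", format(last_res), "); ",
                        "consider damping the priors or increasing max_nodes"),
                      call = sys.call(-1), residual = last_res)))
}

## One Newton solve on a fixed mesh. Returns Z, reconstructed X, node
## derivatives, residual norm, convergence flag.
bvp_newton <- function(system, p, y0, times, Zinit, o) {
  model <- system$model
  n <- model$n; d <- 2L * n
  K <- length(times); N <- K - 1L
  h <- diff(times)
  tmid <- (times[-K] + times[-1]) / 2
  pg_n <- prior_grid(system, times)
  pg_m <- prior_grid(system, tmid)

  Z <- bvp_initial_guess(system, p, y0, times, pg_n, Zinit)

  hN <- matrix(rep(h, each = d), d, N)
  ## sparse pattern (triplets ordered: bc0, A-blocks, B-blocks, bcT)
  i_in <- rep(seq_len(d), times = d)
  j_in <- rep(seq_len(d), each = d)
  kk <- rep(seq_len(N), each = d * d)
  rows_blk <- n + (kk - 1L) * d + rep(i_in, N)
  colsA <- (kk - 1L) * d + rep(j_in, N)
  colsB <- kk * d + rep(j_in, N)
  ii <- c(seq_len(n), rows_blk, rows_blk, n + N * d + seq_len(n))
  jj <- c(seq_len(n), colsA, colsB, N * d + n + seq_len(n))
  Id <- diag(d)

  resid <- function(Z) {
    Fn <- aug_rhs_mat(system, Z, p, pg_n)
    Zl <- Z[, -K, drop = FALSE]; Zr <- Z[, -1, drop = FALSE]
    Fl <- Fn[, -K, drop = FALSE]; Fr <- Fn[, -1, drop = FALSE]
    Zm <- (Zl + Zr) / 2 + hN / 8 * (Fl - Fr)
    Fm <- aug_rhs_mat(system, Zm, p, pg_m)
    r_coll <- Zr - Zl - hN / 6 * (Fl + 4 * Fm + Fr)
    r <- c(Z[seq_len(n), 1] - y0, as.numeric(r_coll), Z[n + seq_len(n), K])
    list(r = r, Fn = Fn, Fm = Fm, Zm = Zm)
  }

  rs <- resid(Z)
  resnorm <- max(abs(rs$r))
  iter <- 0L
  converged <- resnorm < o$bvp_tol
  while (!converged && iter < o$max_newton) {
    iter <- iter + 1L
    Jn <- fd_rhs_jac(system, Z, p, pg_n, rs$Fn)
    Jm <- fd_rhs_jac(system, rs$Zm, p, pg_m, rs$Fm)
    Jl <- Jn[, , -K, drop = FALSE]; Jr <- Jn[, , -1, drop = FALSE]
    hh <- rep(h, each = 1)
    ## M1 = I/2 + h/8 Jl ; M2 = I/2 - h/8 Jr ; P = Jm %*% M
    A <- array(0.0, c(d, d, N)); B <- A
    h8 <- rep(h / 8, each = 1)
    for (a in seq_len(d)) for (b in seq_len(d)) {
      P1 <- 0; P2 <- 0
      for (l in seq_len(d)) {
        M1 <- (if (l == b) 0.5 else 0) + (h / 8) * Jl[l, b, ]
        M2 <- (if (l == b) 0.5 else 0) - (h / 8) * Jr[l, b, ]
        P1 <- P1 + Jm[a, l, ] * M1
        P2 <- P2 + Jm[a, l, ] * M2
      }
      A[a, b, ] <- -(Id[a, b]) - (h / 6) * (Jl[a, b, ] + 4 * P1)
      B[a, b, ] <-  (Id[a, b]) - (h / 6) * (Jr[a, b, ] + 4 * P2)
    }
    M <- Matrix::sparseMatrix(i = ii, j = jj,
                              x = c(rep(1, n), as.numeric(A), as.numeric(B), rep(1, n)),
                              dims = c(d * K, d * K))
    delta <- tryCatch(as.numeric(Matrix::solve(M, -rs$r)),
                      error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) break
    dZ <- matrix(delta, d, K)
    step <- 1
    improved <- FALSE
    for (half in 1:8) {
      Znew <- Z + step * dZ
      rs_new <- tryCatch(resid(Znew), error = function(e) NULL)
      if (!is.null(rs_new) && all(is.finite(rs_new$r)) &&
          max(abs(rs_new$r)) < resnorm * (1 - 1e-4 * step) + 1e-14) {
        Z <- Znew; rs <- rs_new; resnorm <- max(abs(rs$r))
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    converged <- resnorm < o$bvp_tol
  }

  X <- eliminate_input_mat(system, Z[seq_len(n), , drop = FALSE],
                           Z[n + seq_len(n), , drop = FALSE], p, pg_n)
  list(Z = Z, X = X, F_nodes = rs$Fn, resnorm = resnorm, iter = iter,
       converged = converged)
}

## Forward RK4 under x = S_x with u = 0, or reuse/interpolate a given guess.
bvp_initial_guess <- function(system, p, y0, times, pg_n, Zinit) {
  model <- system$model
  n <- model$n; d <- 2L * n; K <- length(times)
  if (!is.null(Zinit)) {
    told <- NULL
    if (inherits(Zinit, "augmented_trajectory")) {
      told <- Zinit$times
      Zinit <- rbind(Zinit$y, Zinit$u)
    }
    if (is.matrix(Zinit) && nrow(Zinit) == d) {
      if (ncol(Zinit) == K && is.null(told)) return(Zinit)
      if (is.null(told)) told <- seq(times[1], times[K], length.out = ncol(Zinit))
      if (length(told) == K && max(abs(told - times)) < 1e-12) return(Zinit)
      Z <- matrix(0.0, d, K)
      for (i in seq_len(d)) Z[i, ] <- approx(told, Zinit[i, ], xout = times, rule = 2)$y
      return(Z)
    }
  }
  xs <- list(node = pg_n$Sx,
             mid = prior_grid(system, (times[-K] + times[-1]) / 2)$Sx)
  Y <- rk4_solve(model, y0, p, times, xs = xs)
  rbind(Y, matrix(0.0, n, K))
}

## Forward-difference Jacobian of the augmented rhs w.r.t. the state,
## vectorized over grid columns. F0 is the rhs at Z.
fd_rhs_jac <- function(system, Z, p, pg, F0) {
  d <- nrow(Z); K <- ncol(Z)
  J <- array(0.0, c(d, d, K))
  for (j in seq_len(d)) {
    eps <- 1e-7 * (1 + max(abs(Z[j, ])))
    Zp <- Z
    Zp[j, ] <- Z[j, ] + eps
    J[, j, ] <- (aug_rhs_mat(system, Zp, p, pg) - F0) / eps
  }
  J
}

#' @export
print.augmented_trajectory <- function(x, ...) {
  K <- ncol(x$y)
  cat("augmented trajectory on [", x$times[1], ", ", x$times[K], "], ",
      x$n_mesh, " mesh intervals\n", sep = "")
  cat("  max collocation residual: ", format(x$bvp_residual),
      "; |u(T)| = ", format(max(abs(x$u[, K]))), "\n", sep = "")
  invisible(x)
}

## Cubic Hermite dense output from node values V (d x K) and derivatives
## D (d x K) on nodes `times`; query times tq inside [times[1], times[K]].
hermite_interp <- function(times, V, D, tq) {
  K <- length(times)
  idx <- pmin(pmax(findInterval(tq, times), 1L), K - 1L)
  h <- times[idx + 1] - times[idx]
  s <- (tq - times[idx]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  Vq <- matrix(0.0, nrow(V), length(tq))
  for (i in seq_len(nrow(V)))
    Vq[i, ] <- h00 * V[i, idx] + (h * h10) * D[i, idx] +
      h01 * V[i, idx + 1] + (h * h11) * D[i, idx + 1]
  Vq
}

#' Evaluate a solved augmented trajectory at arbitrary times
#'
#' Dense output by cubic Hermite interpolation between collocation nodes;
#' the reconstructed input is re-derived from the interpolated `(y, u)`
#' through the closed-form elimination.
#'
#' @param object an `augmented_trajectory`.
#' @param times query times inside the trajectory span.
#' @param ... unused.
#' @return list with matrices `y` (`n x length(times)`), `u` and `x`.
#' @export
predict.augmented_trajectory <- function(object, times, ...) {
  if (any(times < object$times[1] - 1e-12) ||
      any(times > object$times[length(object$times)] + 1e-12))
    stop("requested time outside the trajectory span")
  n <- nrow(object$y)
  Z <- rbind(object$y, object$u)
  Zq <- hermite_interp(object$times, Z, object$f, times)
  Y <- Zq[seq_len(n), , drop = FALSE]
  U <- Zq[n + seq_len(n), , drop = FALSE]
  pg <- prior_grid(object$system, times)
  X <- eliminate_input_mat(object$system, Y, U, object$p, pg)
  list(y = Y, u = U, x = X)
}
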