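#' Solve a bounded-variable linear program
#'
#' Two-phase primal simplex for problems of the form
#' maximize (or minimize) \code{obj \%*\% x} subject to \code{A \%*\% x == b}
#' and \code{lb <= x <= ub}. All variable bounds must be finite; equality
#' constraints are the only row type (flux-balance problems need nothing
#' else). Written for the dense, small-to-medium problems produced by
#' knockout simulation; deterministic given its inputs.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A constraint matrix (m x n), dense or \code{Matrix} sparse.
#' @param b right-hand side, length m.
#' @param lb,ub finite variable bounds, length n.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter iteration cap across both phases.
#' @return list with \code{status} ("optimal", "infeasible" or "unbounded"),
#'   \code{objective} and the primal solution \code{x}. For an unbounded
#'   problem \code{unbounded_var} names the offending column.
#' @export
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  obj <- as.numeric(obj)
  lb <- as.numeric(lb)
  ub <- as.numeric(ub)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  ub <- pmax(ub, lb)
  if (is.null(max_iter)) max_iter <- 200L + 60L * (n + m)
  sense <- if (maximize) 1 else -1
  cc <- sense * as.numeric(obj)

  # augment with one artificial column per row
  big <- max(1, max(abs(b)), max(abs(lb)), max(abs(ub)))
  Aall <- cbind(A, diag(m))
  lb_all <- c(lb, rep(0, m))
  ub_all <- c(ub, rep(big * (n + 1) * 10, m))   # generous but finite
  nt <- n + m

  # start structural variables at the bound nearer zero
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_upper <- abs(lb) > abs(ub)
  res <- b - as.vector(A %*% x)
  art_sign <- ifelse(res < 0, -1, 1)
  Aall[, (n + 1):nt] <- diag(art_sign, m)

  basis <- (n + 1):nt
  xB <- abs(res)
  status_nb <- logical(nt)              # TRUE = nonbasic at upper bound
  status_nb[seq_len(n)] <- at_upper
  in_basis <- logical(nt)
  in_basis[basis] <- TRUE
  Binv <- diag(art_sign, m)             # inverse of the artificial basis

  phase <- 1L
  c1 <- c(rep(0, n), rep(-1, m))        # phase-1: maximize -sum(artificials)
  cvec <- c1
  allowed <- rep(TRUE, nt)
  iter <- 0L
  bland_after <- 1000L
  converged <- FALSE

  refactor <- function() {
    Bmat <- Aall[, basis, drop = FALSE]
    Binv <<- tryCatch(solve(Bmat), error = function(e) Binv)
    nb <- which(!in_basis)
    xn <- ifelse(status_nb[nb], ub_all[nb], lb_all[nb])
    xB <<- as.vector(Binv %*% (b - Aall[, nb, drop = FALSE] %*% xn))
  }

  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    if (iter %% 200L == 0L) refactor()

    cB <- cvec[basis]
    y <- as.vector(crossprod(Binv, cB))        # y = Binv' cB
    nb <- which(!in_basis & allowed)
    if (length(nb) == 0L) break
    d <- cvec[nb] - as.vector(y %*% Aall[, nb, drop = FALSE])
    improving <- (d > tol & !status_nb[nb]) | (d < -tol & status_nb[nb])
    if (!any(improving)) {
      if (phase == 1L) {
        if (sum(xB[basis > n]) > 1e-7 * big)
          return(list(status = "infeasible", objective = NA_real_, x = NULL))
        # enter phase 2: lock artificials at zero
        ub_all[(n + 1):nt] <- 0
        xB[basis > n] <- 0
        allowed[(n + 1):nt] <- FALSE
        cvec <- c(cc, rep(0, m))
        phase <- 2L
        iter <- 0L
        next
      }
      converged <- TRUE
      break  # phase-2 optimal
    }
    cand <- nb[improving]
    dj <- d[improving]
    j <- if (iter > bland_after) cand[1L] else cand[which.max(abs(dj))]
    dirj <- if (status_nb[j]) -1 else 1        # move off its current bound
    w <- as.vector(Binv %*% Aall[, j])

    # ratio test: xB - t * dirj * w stays within basic bounds
    g <- dirj * w
    t_basic <- rep(Inf, m)
    pos <- g > tol
    neg <- g < -tol
    t_basic[pos] <- (xB[pos] - lb_all[basis[pos]]) / g[pos]
    t_basic[neg] <- (ub_all[basis[neg]] - xB[neg]) / (-g[neg])
    t_flip <- ub_all[j] - lb_all[j]
    t_min <- min(t_basic, t_flip)
    if (!is.finite(t_min))
      return(list(status = "unbounded", objective = NA_real_, x = NULL,
                  unbounded_var = j))
    t_min <- max(t_min, 0)

    if (t_flip <= t_min + tol && t_flip <= min(t_basic)) {
      # bound flip, basis unchanged
      xB <- xB - t_flip * g
      status_nb[j] <- !status_nb[j]
      next
    }
    r_cand <- which(t_basic <= t_min + tol)
    r <- if (iter > bland_after) r_cand[which.min(basis[r_cand])] else
      r_cand[which.max(abs(w[r_cand]))]
    leave <- basis[r]
    leave_at_upper <- g[r] < 0

    xj_start <- if (status_nb[j]) ub_all[j] else lb_all[j]
    xB <- xB - t_min * g
    xB[r] <- xj_start + dirj * t_min
    basis[r] <- j
    in_basis[j] <- TRUE
    in_basis[leave] <- FALSE
    status_nb[leave] <- leave_at_upper

    piv <- w[r]
    Binv[r, ] <- Binv[r, ] / piv
    other <- setdiff(seq_len(m), r)
    if (length(other))
      Binv[other, ] <- Binv[other, ] - outer(w[other], Binv[r, ])
  }

  if (!converged)
    stop("lp_solve: iteration limit reached without convergence")

  xfull <- ifelse(status_nb, ub_all, lb_all)
  xfull[basis] <- xB
  x <- xfull[seq_len(n)]
  # clamp tiny bound violations from accumulated arithmetic
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal",
       objective = sum(obj * x),
       x = x)
}
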