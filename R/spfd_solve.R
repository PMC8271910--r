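#' Solve the SPFD forward problem for a dipole source
#'
#' Computes the scalar potential induced at every grid node by a 1-voxel
#' dipole in the volume conductor, i.e. solves `A phi = b` where `A` is
#' the pure-Neumann SPFD operator of [spfd_system()] and `b` injects
#' `+I`/`-I` at the source nodes. Because the operator has a constant null
#' space, the solution is gauge-fixed to zero mean over conducting nodes.
#'
#' Three solver back-ends are available:
#' \describe{
#'   \item{`"multigrid"`}{(default) stationary iteration whose error
#'     correction is a geometric multigrid V-cycle — factor-2 node-grid
#'     coarsening with trilinear transfer operators and Galerkin coarse
#'     matrices — smoothed by successive over-relaxation (SOR); iterates
#'     until the relative residual `||b - A phi|| / ||b||` drops below
#'     `tol`. The method of choice for large volumes.}
#'   \item{`"sor"`}{plain SOR sweeps; robust, slow on large grids.}
#'   \item{`"direct"`}{sparse Cholesky on the conducting subsystem (one
#'     reference node pinned); exact to machine precision and the cheapest
#'     option when many right-hand sides share one conductor, since the
#'     factorization (see [spfd_factor()]) is reused.}
#' }
#'
#' @param system An [spfd_system()].
#' @param source A [dipole_source()], or a list of them solved by
#'   superposition, or a bare numeric right-hand-side vector.
#' @param method `"multigrid"`, `"sor"` or `"direct"`.
#' @param tol Relative residual tolerance (default `1e-6`).
#' @param max_iter Iteration cap (V-cycles or SOR sweeps).
#' @param levels Maximum multigrid depth (default 6; capped automatically
#'   when the grid is too small to coarsen that far).
#' @param omega SOR relaxation factor (default 1.5).
#' @param factor Optional pre-computed [spfd_factor()] (direct method).
#' @return An object of class `potential_field`: node potential array
#'   `phi` (volts, zero at air nodes), `residual`, `iterations`, plus the
#'   grid geometry.
#' @export
solve_spfd <- function(system, source,
                       method = c("multigrid", "sor", "direct"),
                       tol = 1e-6, max_iter = 10000, levels = 6,
                       omega = 1.5, factor = NULL) {
  method <- match.arg(method)
  b <- source_to_rhs(system, source)
  idx <- which(system$conducting)
  bs <- b[idx]
  bnorm <- sqrt(sum(bs^2))
  if (bnorm == 0) abort("right-hand side is zero")

  if (method == "direct") {
    factor <- factor %||% spfd_factor(system)
    x <- factor_solve(factor, bs)
    Asub <- factor$Asub
    res <- relres(Asub, x, bs, bnorm)
    iters <- 1L
  } else if (method == "sor") {
    Asub <- system$A[idx, idx]
    sm <- sor_operator(Asub, omega)
    x <- numeric(length(idx))
    iters <- 0L
    repeat {
      r <- bs - as.vector(Asub %*% x)
      rel <- sqrt(sum(r^2)) / bnorm
      if (rel < tol) break
      if (iters >= max_iter) {
        abort(sprintf("SOR failed to converge: relative residual %.3e after %d sweeps",
                      rel, iters))
      }
      x <- x + as.vector(Matrix::solve(sm, r))
      iters <- iters + 1L
    }
    res <- rel
  } else {
    hier <- mg_hierarchy(system, levels = levels, omega = omega)
    x <- numeric(length(idx))
    Asub <- hier$A[[1]]
    iters <- 0L
    repeat {
      r <- bs - as.vector(Asub %*% x)
      rel <- sqrt(sum(r^2)) / bnorm
      if (rel < tol) break
      if (iters >= max_iter) {
        abort(sprintf("multigrid failed to converge: relative residual %.3e after %d cycles",
                      rel, iters))
      }
      x <- x + mg_vcycle(hier, 1L, r)
      x <- x - mean(x)
      iters <- iters + 1L
    }
    res <- rel
  }

  phi <- numeric(prod(system$nd))
  phi[idx] <- x - mean(x)
  structure(list(phi = array(phi, system$nd), residual = res,
                 iterations = iters, method = method, nd = system$nd,
                 pitch_mm = system$pitch_mm, origin_mm = system$origin_mm,
                 conducting = system$conducting),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("<potential_field> %d x %d x %d nodes, %s, residual %.2e (%d iterations)\n",
              x$nd[1], x$nd[2], x$nd[3], x$method, x$residual, x$iterations))
  invisible(x)
}

source_to_rhs <- function(system, source) {
  if (is.numeric(source)) {
    if (length(source) != prod(system$nd)) {
      abort("numeric right-hand side has the wrong length")
    }
    return(source)
  }
  if (inherits(source, "dipole_source")) source <- list(source)
  Reduce(`+`, lapply(source, function(s) spfd_rhs(system, s)))
}

relres <- function(A, x, b, bnorm) {
  sqrt(sum((b - as.vector(A %*% x))^2)) / bnorm
}

#' Factorize the conducting SPFD subsystem for repeated solves
#'
#' Pins one reference node (removing the constant null space), extracts the
#' conducting submatrix and computes its sparse Cholesky factorization.
#' Building a lead field matrix or running a dipole study solves the same
#' conductor for hundreds of right-hand sides, so the factorization is
#' done once and each solve reduces to two triangular backsolves.
#'
#' @param system An [spfd_system()].
#' @return An object of class `spfd_factor`.
#' @export
spfd_factor <- function(system) {
  idx <- which(system$conducting)
  Asub <- system$A[idx, idx]
  n <- length(idx)
  keep <- seq_len(n)[-1]            # pin the first conducting node at 0
  Ak <- Matrix::forceSymmetric(Asub[keep, keep])
  ch <- tryCatch(Matrix::Cholesky(Ak, LDL = FALSE),
                 error = function(e) NULL)
  structure(list(idx = idx, keep = keep, Asub = Asub, Ak = Ak, chol = ch),
            class = "spfd_factor")
}

# solve on the conducting subset given a subset RHS; returns gauge-free x
factor_solve <- function(factor, bs) {
  bk <- bs[factor$keep]
  xk <- if (!is.null(factor$chol)) {
    as.vector(Matrix::solve(factor$chol, bk))
  } else {
    as.vector(Matrix::solve(factor$Ak, bk))
  }
  x <- numeric(length(bs))
  x[factor$keep] <- xk
  x
}

# --- SOR smoother -----------------------------------------------------------

# lower-triangular SOR operator M = D/omega + L (strictly lower part of A)
sor_operator <- function(Asub, omega) {
  M <- Matrix::tril(Asub, -1) + Matrix::Diagonal(x = Matrix::diag(Asub) / omega)
  methods::as(M, "triangularMatrix")
}

# --- geometric multigrid ----------------------------------------------------

# 1-D trilinear prolongation from the coarse node line (every 2nd node)
prolong_1d <- function(m) {
  mc <- (m - 1L) %/% 2L + 1L
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (f in seq_len(m)) {
    if (f %% 2L == 1L) {
      i <- c(i, f); j <- c(j, (f + 1L) %/% 2L); x <- c(x, 1)
    } else {
      c1 <- f %/% 2L; c2 <- c1 + 1L
      if (c2 <= mc) {
        i <- c(i, f, f); j <- c(j, c1, c2); x <- c(x, 0.5, 0.5)
      } else {
        i <- c(i, f); j <- c(j, c1); x <- c(x, 1)
      }
    }
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(m, mc))
}

# Build the multigrid hierarchy on the conducting subset: trilinear
# prolongation restricted to conducting nodes, Galerkin coarse operators,
# coarse nodes with empty rows dropped, dense pseudo-inverse at the bottom.
mg_hierarchy <- function(system, levels = 6, omega = 1.5, nu = 2) {
  idx <- which(system$conducting)
  A1 <- system$A[idx, idx]
  nd <- system$nd
  A <- list(A1); P <- list(); M <- list(sor_operator(A1, omega))
  sel <- Matrix::sparseMatrix(i = seq_along(idx), j = idx, x = 1,
                              dims = c(length(idx), prod(nd)))
  cur_rows <- sel   # maps full fine-node space -> current level rows
  l <- 1L
  while (l < levels && min(nd) >= 3L) {
    Pfull <- Matrix::kronecker(prolong_1d(nd[3]),
             Matrix::kronecker(prolong_1d(nd[2]), prolong_1d(nd[1])))
    Psub <- cur_rows %*% Pfull
    Ac <- Matrix::crossprod(Psub, A[[l]] %*% Psub)
    dAc <- Matrix::diag(Ac)
    keep <- which(dAc > 0)
    if (length(keep) < 2) break
    Ac <- Ac[keep, keep]
    Psub <- Psub[, keep]
    ndc <- (nd - 1L) %/% 2L + 1L
    A[[l + 1L]] <- Ac
    P[[l]] <- Psub
    M[[l + 1L]] <- sor_operator(Ac, omega)
    # row map into the coarse full-node space for the next coarsening
    cur_rows <- Matrix::sparseMatrix(i = seq_along(keep), j = keep, x = 1,
                                     dims = c(length(keep), prod(ndc)))
    nd <- ndc
    l <- l + 1L
  }
  coarse_pinv <- pinv(as.matrix(A[[l]]))
  list(A = A, P = P, M = M, depth = l, nu = nu, coarse_pinv = coarse_pinv)
}

mg_smooth <- function(A, M, x, b, nu) {
  for (i in seq_len(nu)) {
    x <- x + as.vector(Matrix::solve(M, b - as.vector(A %*% x)))
  }
  x
}

mg_vcycle <- function(h, l, b) {
  if (l == h$depth) {
    return(as.vector(h$coarse_pinv %*% b))
  }
  x <- mg_smooth(h$A[[l]], h$M[[l]], numeric(length(b)), b, h$nu)
  r <- b - as.vector(h$A[[l]] %*% x)
  xc <- mg_vcycle(h, l + 1L, as.vector(Matrix::crossprod(h$P[[l]], r)))
  x <- x + as.vector(h$P[[l]] %*% xc)
  mg_smooth(h$A[[l]], h$M[[l]], x, b, h$nu)
}

# --- electrode sampling -----------------------------------------------------

#' Sample a potential field at the surface electrodes
#'
#' Returns the M-vector of node potentials at the electrode positions
#' (M = 9 for the standard 12-lead configuration: V1-V6, RA, LA, LL).
#' Positions in mm are snapped to the nearest grid node, which must be
#' conducting (an electrode cannot sit in air).
#'
#' @param field A `potential_field` from [solve_spfd()].
#' @param electrodes An electrode set: tibble with columns `role`, `x_mm`,
#'   `y_mm`, `z_mm` (see [electrode_set()]).
#' @return Named numeric vector of potentials (V), one per electrode.
#' @export
electrode_potentials <- function(field, electrodes) {
  nodes <- electrode_nodes(electrodes, field$nd, field$pitch_mm,
                           field$origin_mm)
  lin <- node_lin(nodes, field$nd)
  bad <- !field$conducting[lin]
  if (any(bad)) {
    abort(sprintf("electrode(s) %s sit at non-conducting nodes",
                  paste(electrodes$role[bad], collapse = ", ")))
  }
  setNames(as.vector(field$phi)[lin], electrodes$role)
}

# snap mm positions to nearest node indices (1-based), clamped to the grid
electrode_nodes <- function(electrodes, nd, pitch_mm, origin_mm) {
  req <- c("role", "x_mm", "y_mm", "z_mm")
  if (!all(req %in% names(electrodes))) {
    abort("electrode set needs columns role, x_mm, y_mm, z_mm")
  }
  xyz <- as.matrix(electrodes[, c("x_mm", "y_mm", "z_mm")])
  nodes <- round(sweep(xyz, 2, origin_mm) / pitch_mm) + 1
  nodes <- pmin(pmax(nodes, 1), matrix(nd, nrow(nodes), 3, byrow = TRUE))
  storage.mode(nodes) <- "integer"
  nodes
}
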