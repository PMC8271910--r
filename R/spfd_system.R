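#' Edge conductances of the scalar-potential finite-difference grid
#'
#' The SPFD discretization places the unknown scalar potential at voxel
#' corners (nodes) and turns the conductive medium into a resistor network:
#' every grid edge carries a conductance derived from the conductivity of
#' the (up to four) voxels sharing that edge. With cubic voxels the edge
#' conductance is `mean(sigma) * pitch` (effective cross-section
#' `pitch^2` over length `pitch`); the arithmetic mean over the adjacent
#' voxels is the standard SPFD construction. Edges bordered only by air
#' carry zero conductance and drop out of the network.
#'
#' @param sigma 3-D array of voxel conductivities (S/m), e.g. from
#'   [assign_conductivity()].
#' @param pitch_mm Voxel pitch in mm.
#' @return An object of class `edge_field`: list of arrays `Sx`, `Sy`,
#'   `Sz` (conductances in siemens of the edges along each axis; `Sx` has
#'   dim `(nx, ny+1, nz+1)` and so on) plus `pitch_mm`.
#' @export
edge_conductances <- function(sigma, pitch_mm) {
  if (length(dim(sigma)) != 3) abort("`sigma` must be a 3-D array")
  if (any(sigma < 0)) abort("conductivities must be >= 0")
  pitch_m <- pitch_mm / 1000
  structure(list(Sx = edge_axis_mean(sigma, 1) * pitch_m,
                 Sy = edge_axis_mean(sigma, 2) * pitch_m,
                 Sz = edge_axis_mean(sigma, 3) * pitch_m,
                 pitch_mm = pitch_mm),
            class = "edge_field")
}

# mean conductivity of the <=4 voxels around each edge running along `axis`;
# voxels outside the grid do not enter the average.
edge_axis_mean <- function(sigma, axis) {
  perm <- switch(axis, c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  sp <- aperm(sigma, perm)
  d <- dim(sp)
  pad <- array(NA_real_, dim = d + c(0, 2, 2))
  pad[, 2:(d[2] + 1), 2:(d[3] + 1)] <- sp
  j1 <- 1:(d[2] + 1); j2 <- 2:(d[2] + 2)
  k1 <- 1:(d[3] + 1); k2 <- 2:(d[3] + 2)
  acc <- array(0, dim = c(d[1], d[2] + 1, d[3] + 1))
  cnt <- array(0L, dim = dim(acc))
  for (jj in list(j1, j2)) for (kk in list(k1, k2)) {
    v <- pad[, jj, kk, drop = FALSE]
    ok <- !is.na(v)
    v[!ok] <- 0
    acc <- acc + v
    cnt <- cnt + ok
  }
  out <- acc / pmax(cnt, 1L)
  # undo the axis permutation
  aperm(out, order(perm))
}

node_dims <- function(vox_dims) as.integer(vox_dims) + 1L

node_lin <- function(ijk, nd) {
  ijk[, 1] + nd[1] * (ijk[, 2] - 1 + nd[2] * (ijk[, 3] - 1))
}

#' Assemble the SPFD linear system
#'
#' Applies Kirchhoff's current law at every node of the resistor network:
#' row `n` reads `sum(S_n) * phi_0 - sum(S_n * phi_n) = b_n`, giving a
#' symmetric 7-point-stencil sparse system whose rows sum to zero (the
#' discrete pure-Neumann Poisson operator: no current crosses the body
#' surface). Nodes surrounded entirely by air have empty rows and are
#' excluded from the unknown set.
#'
#' @param edges An `edge_field` from [edge_conductances()], or a
#'   [voxel_model()] (conductivities are assigned automatically).
#' @param origin_mm World origin of the node grid; taken from the model
#'   when one is passed.
#' @return An object of class `spfd_system`: sparse matrix `A`
#'   (all-nodes-square, `dgCMatrix`), node grid dims `nd`, `pitch_mm`,
#'   `origin_mm` and the logical `conducting` node mask.
#' @export
spfd_system <- function(edges, origin_mm = c(0, 0, 0)) {
  if (inherits(edges, "voxel_model")) {
    origin_mm <- edges$origin_mm
    edges <- edge_conductances(assign_conductivity(edges), edges$pitch_mm)
  }
  if (!inherits(edges, "edge_field")) {
    abort("`edges` must be an edge_field or a voxel_model")
  }
  nd <- dim(edges$Sx) + c(1L, 0L, 0L)
  N <- prod(nd)

  tri <- function(S, axis) {
    d <- dim(S)
    p <- which(S > 0)
    if (length(p) == 0) {
      return(list(from = integer(0), to = integer(0), s = numeric(0)))
    }
    ijk <- arrayInd(p, d)
    step <- c(0L, 0L, 0L); step[axis] <- 1L
    list(from = node_lin(ijk, nd),
         to = node_lin(sweep(ijk, 2, step, "+"), nd),
         s = S[p])
  }
  tx <- tri(edges$Sx, 1); ty <- tri(edges$Sy, 2); tz <- tri(edges$Sz, 3)
  from <- c(tx$from, ty$from, tz$from)
  to <- c(tx$to, ty$to, tz$to)
  s <- c(tx$s, ty$s, tz$s)

  adj <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = c(s, s),
                              dims = c(N, N))
  deg <- Matrix::rowSums(adj)
  A <- Matrix::Diagonal(x = deg) - adj
  structure(list(A = methods::as(A, "CsparseMatrix"), nd = nd,
                 pitch_mm = edges$pitch_mm,
                 origin_mm = vec3(origin_mm, "origin_mm"),
                 conducting = deg > 0),
            class = "spfd_system")
}

#' @export
print.spfd_system <- function(x, ...) {
  cat(sprintf("<spfd_system> %d x %d x %d nodes (%d conducting), pitch %g mm\n",
              x$nd[1], x$nd[2], x$nd[3], sum(x$conducting), x$pitch_mm))
  invisible(x)
}

#' Define a 1-voxel-length dipole current source
#'
#' The cardiac current source is modelled as a single electric dipole one
#' voxel edge long: a current `current_A` injected at the anode node and
#' extracted at the grid-adjacent cathode node along one of the six axis
#' directions. Oblique sources are obtained by superposing the three
#' positive-axis dipoles sharing an anode (the system is linear).
#'
#' @param anode Integer 3-vector: 1-based node index of the anode.
#' @param axis One of `"+x","-x","+y","-y","+z","-z"`; the cathode is the
#'   neighbouring node in that direction.
#' @param current_A Injected current in amperes (`> 0`). Its magnitude
#'   cancels in the lead-field normalisation.
#' @return An object of class `dipole_source`.
#' @export
dipole_source <- function(anode, axis = "+x", current_A = 1) {
  axis <- match.arg(axis, c("+x", "-x", "+y", "-y", "+z", "-z"))
  if (current_A <= 0) abort("`current_A` must be positive")
  anode <- as.integer(vec3(anode, "anode"))
  step <- switch(axis,
                 "+x" = c(1L, 0L, 0L), "-x" = c(-1L, 0L, 0L),
                 "+y" = c(0L, 1L, 0L), "-y" = c(0L, -1L, 0L),
                 "+z" = c(0L, 0L, 1L), "-z" = c(0L, 0L, -1L))
  structure(list(anode = anode, cathode = anode + step, axis = axis,
                 current_A = current_A),
            class = "dipole_source")
}

# right-hand side: +I at anode, -I at cathode (current conservation:
# sum(b) == 0); errors if either node sits in a non-conducting region.
spfd_rhs <- function(system, source) {
  nd <- system$nd
  an <- source$anode; ca <- source$cathode
  if (any(an < 1 | an > nd) || any(ca < 1 | ca > nd)) {
    abort("source nodes fall outside the node grid")
  }
  ia <- node_lin(matrix(an, 1), nd)
  ic <- node_lin(matrix(ca, 1), nd)
  if (!system$conducting[ia] || !system$conducting[ic]) {
    abort("source in non-conducting region")
  }
  b <- numeric(prod(nd))
  b[ia] <- source$current_A
  b[ic] <- -source$current_A
  b
}
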