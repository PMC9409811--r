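# Shared finite-volume machinery on the axisymmetric (r,z) tensor grid.
#
# Cells are annular rings; fluxes cross radial faces (between i and i+1)
# and axial faces (between j and j+1). Face conductances use the
# two-sided resistance A / (dP/cP + dN/cN), which reduces to a
# harmonic-mean interface coefficient on a uniform grid. Cells can be
# unknowns (tissue), Dirichlet ("fixed": electrode equipotential or
# grounded region) or blocked (insulated shaft: zero flux). Dirichlet
# cells carry no internal resistance, so a tissue-fixed face uses the
# tissue half-resistance only, placing the Dirichlet value at the cell
# interface. All geometry is converted to SI (m) here.

MM <- 1e-3

# type: 0 unknown, 1 fixed, 2 blocked; fixed_value: value at fixed cells.
# boundary: "dirichlet" adds faces from boundary-adjacent cells to the
# outer box boundary at boundary_value; "plates" adds Dirichlet faces on
# the two z boundaries only (boundary_value is length 2: bottom, top);
# "insulated" adds none. The r = 0 axis is always a natural no-flux
# boundary (zero face area).
assemble_faces <- function(grid, coef, type, fixed_value = NULL,
                           boundary = c("dirichlet", "insulated",
                                        "plates"),
                           boundary_value = 0) {
  boundary <- match.arg(boundary)
  nr <- length(grid$rc); nz <- length(grid$zc)
  N <- nr * nz
  rf <- grid$rf * MM; zf <- grid$zf * MM
  rc <- grid$rc * MM; zc <- grid$zc * MM
  dz <- diff(zf)
  ring <- pi * diff(rf^2)                     # annulus areas, m^2
  id <- matrix(seq_len(N), nr, nz)

  faces <- list()
  add_faces <- function(p, n, A, dP, dN) {
    tp <- type[p]; tn <- type[n]
    keep <- !(tp == 2L | tn == 2L) & !(tp == 1L & tn == 1L)
    p <- p[keep]; n <- n[keep]; A <- A[keep]; dP <- dP[keep]; dN <- dN[keep]
    tp <- type[p]; tn <- type[n]
    # orient so that a fixed cell, if any, is on the n side
    swap <- tp == 1L
    tmp <- p[swap]; p[swap] <- n[swap]; n[swap] <- tmp
    tmp <- dP[swap]; dP[swap] <- dN[swap]; dN[swap] <- tmp
    fixedN <- type[n] == 1L
    rP <- dP / coef[p]
    rN <- ifelse(fixedN, 0, dN / coef[n])
    G <- A / (rP + rN)
    list(p = p, n = n, G = G,
         fracP = rP / (rP + rN),
         fixedN = fixedN,
         val = ifelse(fixedN, fixed_value[n], NA_real_))
  }

  if (nr > 1L) {
    i <- seq_len(nr - 1L)
    P <- as.vector(id[i, , drop = FALSE])
    Nn <- as.vector(id[i + 1L, , drop = FALSE])
    A <- as.vector(outer(2 * pi * rf[i + 1L], dz))
    dP <- rep(rf[i + 1L] - rc[i], nz)
    dN <- rep(rc[i + 1L] - rf[i + 1L], nz)
    faces$radial <- add_faces(P, Nn, A, dP, dN)
  }
  if (nz > 1L) {
    j <- seq_len(nz - 1L)
    P <- as.vector(id[, j, drop = FALSE])
    Nn <- as.vector(id[, j + 1L, drop = FALSE])
    A <- rep(ring, nz - 1L)
    dP <- rep(zf[j + 1L] - zc[j], each = nr)
    dN <- rep(zc[j + 1L] - zf[j + 1L], each = nr)
    faces$axial <- add_faces(P, Nn, A, dP, dN)
  }

  bface <- NULL
  if (boundary == "dirichlet") {
    p <- c(id[nr, ], id[, 1L], id[, nz])
    A <- c(2 * pi * rf[nr + 1L] * dz, ring, ring)
    d <- c(rep(rf[nr + 1L] - rc[nr], nz),
           rep(zc[1L] - zf[1L], nr),
           rep(zf[nz + 1L] - zc[nz], nr))
    val <- rep(boundary_value[1], length(p))
    keep <- type[p] == 0L
    bface <- list(p = p[keep], G = (A * coef[p] / d)[keep],
                  val = val[keep])
  } else if (boundary == "plates") {
    p <- c(id[, 1L], id[, nz])
    A <- c(ring, ring)
    d <- c(rep(zc[1L] - zf[1L], nr),
           rep(zf[nz + 1L] - zc[nz], nr))
    val <- c(rep(boundary_value[1], nr), rep(boundary_value[2], nr))
    keep <- type[p] == 0L
    bface <- list(p = p[keep], G = (A * coef[p] / d)[keep],
                  val = val[keep])
  }
  list(faces = faces, bfaces = bface, n_cells = N)
}

# Assemble the SPD system  L phi = b  over unknown cells from face lists.
# Returns compact index map, sparse matrix and RHS contributions from
# fixed cells and Dirichlet boundaries.
fv_system <- function(asm, type) {
  unknown <- which(type == 0L)
  comp <- integer(asm$n_cells)
  comp[unknown] <- seq_along(unknown)
  nU <- length(unknown)
  diag_acc <- numeric(nU)
  ii <- list(); jj <- list(); xx <- list()
  b <- numeric(nU)
  for (f in asm$faces) {
    if (is.null(f) || !length(f$p)) next
    cp <- comp[f$p]
    interior <- !f$fixedN
    # interior faces: both p and n unknown
    cn <- comp[f$n]
    pi_ <- cp[interior]; ni_ <- cn[interior]; Gi <- f$G[interior]
    ii[[length(ii) + 1L]] <- c(pi_, ni_)
    jj[[length(jj) + 1L]] <- c(ni_, pi_)
    xx[[length(xx) + 1L]] <- c(-Gi, -Gi)
    dacc <- numeric(nU)
    dacc <- dacc + tab_sum(pi_, Gi, nU) + tab_sum(ni_, Gi, nU)
    # fixed faces: contribute to diagonal and RHS of p
    pf <- cp[f$fixedN]; Gf <- f$G[f$fixedN]; vf <- f$val[f$fixedN]
    dacc <- dacc + tab_sum(pf, Gf, nU)
    b <- b + tab_sum(pf, Gf * vf, nU)
    diag_acc <- diag_acc + dacc
  }
  if (!is.null(asm$bfaces) && length(asm$bfaces$p)) {
    bp <- comp[asm$bfaces$p]
    diag_acc <- diag_acc + tab_sum(bp, asm$bfaces$G, nU)
    b <- b + tab_sum(bp, asm$bfaces$G * asm$bfaces$val, nU)
  }
  ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)
  L <- Matrix::sparseMatrix(i = c(ii, seq_len(nU)),
                            j = c(jj, seq_len(nU)),
                            x = c(xx, diag_acc),
                            dims = c(nU, nU))
  list(L = Matrix::forceSymmetric(L), b = b, unknown = unknown,
       comp = comp)
}

# scatter-add x into bins (fast alternative to tapply for large vectors)
tab_sum <- function(bin, x, n) {
  out <- numeric(n)
  if (length(bin)) {
    s <- rowsum(x, bin)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  out
}

# Per-cell dissipation (W) of a potential-like field over the faces, and
# flux bookkeeping at fixed cells / Dirichlet boundaries.
fv_dissipation <- function(asm, phi_full, fixed_value, type) {
  W <- numeric(asm$n_cells)
  flux_fixed <- numeric(asm$n_cells)   # current into domain from fixed cells
  flux_bc <- 0
  for (f in asm$faces) {
    if (is.null(f) || !length(f$p)) next
    phiN <- ifelse(f$fixedN, f$val, phi_full[f$n])
    dphi <- phi_full[f$p] - phiN
    w <- f$G * dphi^2
    W <- W + tab_sum(f$p, w * f$fracP, asm$n_cells)
    int <- !f$fixedN
    W <- W + tab_sum(f$n[int], (w * (1 - f$fracP))[int], asm$n_cells)
    # current leaving fixed cells into tissue
    fx <- f$fixedN
    flux_fixed <- flux_fixed +
      tab_sum(f$n[fx], (f$G * (phiN - phi_full[f$p]))[fx], asm$n_cells)
  }
  if (!is.null(asm$bfaces) && length(asm$bfaces$p)) {
    dphi <- phi_full[asm$bfaces$p] - asm$bfaces$val
    W <- W + tab_sum(asm$bfaces$p, asm$bfaces$G * dphi^2, asm$n_cells)
    flux_bc <- sum(asm$bfaces$G * dphi)
  }
  list(W = W, flux_fixed = flux_fixed, flux_bc = flux_bc)
}
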