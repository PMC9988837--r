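# Synthetic quasi-landmark template: a smooth, bilaterally symmetric open
# surface standing in for the dense anthropometric mask that real registered
# facial scans are in correspondence with.

#' Build a synthetic face-like landmark template
#'
#' Constructs a smooth convex height field over a rectangular grid that is
#' bilaterally symmetric about the plane `x = 0`, together with a consistent
#' triangulation (counter-clockwise winding seen from `+z`, so vertex normals
#' point outward along `+z`) and an involutive bilateral landmark pairing.
#' The template plays the role of the dense quasi-landmark mask to which all
#' cohort configurations are in correspondence.
#'
#' `L` must factor as `nr x nc` with `nc` odd and both factors at least 3, so
#' the grid has a self-paired midline column. Among admissible factorizations
#' the most nearly square one is used.
#'
#' @param L Number of landmarks (grid vertices). Default 7160, the density of
#'   the dense facial mask the synthetic template emulates.
#' @param extent Physical width of the grid, in template units (think mm for a
#'   face-sized object). Default 100.
#' @return An object of class `face_template`: list with `coordinates`
#'   (`L x 3`), `triangles` (integer `F x 3`, 1-based), `pairing` (integer
#'   involution of length `L`), `grid` (`nr`, `nc`), `extent`.
#' @examples
#' tpl <- make_template(L = 9, extent = 1)
#' nrow(tpl$triangles)  # 8
#' @export
make_template <- function(L = 7160, extent = 100) {
  stopifnot_scalar(L, "L", positive = TRUE)
  stopifnot_scalar(extent, "extent", positive = TRUE)
  L <- as.integer(L)
  if (L < 9L) stop("L must be >= 9; got ", L)
  fac <- grid_factorization(L)
  if (is.null(fac)) {
    stop("L = ", L, " admits no nr x nc grid with nc odd and nr, nc >= 3; ",
         "nearest valid L is ", nearest_valid_L(L))
  }
  nr <- fac[1L]; nc <- fac[2L]

  xs <- seq(-extent / 2, extent / 2, length.out = nc)
  # force exact symmetry of the x positions about 0
  xs <- (xs - rev(xs)) / 2
  ys <- seq(-extent / 2, extent / 2, length.out = nr) * (nr / nc)
  grid <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  x <- xs[grid$c]
  y <- ys[grid$r]
  # smooth convex dome: face-like open surface, symmetric in x by construction
  sigma <- extent / 2.5
  z <- (extent / 4) * exp(-(x^2 + y^2) / (2 * sigma^2))
  coords <- cbind(x = x, y = y, z = z)

  # landmark index of grid cell (r, c), column-major
  idx <- function(r, c) (c - 1L) * nr + r
  pairing <- idx(grid$r, nc + 1L - grid$c)

  tri <- vector("list", 2L * (nr - 1L) * (nc - 1L))
  k <- 0L
  for (c in seq_len(nc - 1L)) {
    for (r in seq_len(nr - 1L)) {
      v00 <- idx(r, c); v10 <- idx(r + 1L, c)
      v01 <- idx(r, c + 1L); v11 <- idx(r + 1L, c + 1L)
      # CCW from +z (x right, y up): normals point along +z
      k <- k + 1L; tri[[k]] <- c(v00, v01, v11)
      k <- k + 1L; tri[[k]] <- c(v00, v11, v10)
    }
  }
  triangles <- do.call(rbind, tri)
  storage.mode(triangles) <- "integer"

  structure(list(coordinates = coords, triangles = triangles,
                 pairing = as.integer(pairing),
                 grid = c(nr = nr, nc = nc), extent = extent),
            class = "face_template")
}

# Most nearly square nr x nc factorization with nc odd, nr >= 3, nc >= 3.
grid_factorization <- function(L) {
  best <- NULL
  for (nc in seq(3L, L %/% 3L, by = 2L)) {
    if (L %% nc == 0L) {
      nr <- L %/% nc
      if (nr >= 3L) {
        if (is.null(best) || abs(nr - nc) < abs(best[1L] - best[2L]))
          best <- c(nr, nc)
      }
    }
  }
  best
}

nearest_valid_L <- function(L) {
  for (d in seq_len(1000L)) {
    for (cand in c(L - d, L + d)) {
      if (cand >= 9L && !is.null(grid_factorization(cand))) return(cand)
    }
  }
  L
}

#' @export
print.face_template <- function(x, ...) {
  cat("Synthetic landmark template\n")
  cat("  landmarks   :", nrow(x$coordinates),
      sprintf("(%d x %d grid)\n", x$grid[["nr"]], x$grid[["nc"]]))
  cat("  triangles   :", nrow(x$triangles), "\n")
  cat("  extent      :", x$extent, "template units\n")
  cat("  self-paired :", sum(x$pairing == seq_len(nrow(x$coordinates))),
      "midline landmarks\n")
  invisible(x)
}

#' Validate a landmark template
#'
#' Checks the structural invariants of a `face_template`: the pairing is an
#' involution, triangle indices are in range, and reflecting `x` then applying
#' the pairing reproduces the reference coordinates (bilateral symmetry).
#'
#' @param template A `face_template`.
#' @param tol Symmetry tolerance in template units.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_template <- function(template, tol = 1e-12) {
  L <- nrow(template$coordinates)
  p <- template$pairing
  if (!all(p[p] == seq_len(L))) stop("symmetry pairing is not an involution")
  if (any(template$triangles < 1L) || any(template$triangles > L))
    stop("triangle vertex index out of range")
  refl <- template$coordinates
  refl[, 1L] <- -refl[, 1L]
  if (max(abs(refl[p, , drop = FALSE] - template$coordinates)) > tol)
    stop("template is not bilaterally symmetric under its pairing")
  invisible(TRUE)
}
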