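# Crystallographic and rigid-body geometry: fractional/orthogonal
# conversions, symmetry-operator algebra, least-squares superposition and
# Shrake-Rupley solvent-accessible surface areas.

#' Unit cell constructor
#'
#' @param a,b,c cell edge lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @return An object of class `xc_cell`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  vals <- c(a = unname(a), b = unname(b), c = unname(c),
            alpha = unname(alpha), beta = unname(beta),
            gamma = unname(gamma))
  if (!all(is.finite(vals)) || any(vals[1:3] <= 0)) {
    stop("cell edges must be finite and positive")
  }
  if (any(vals[4:6] <= 0 | vals[4:6] >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  structure(as.list(vals), class = "xc_cell")
}

#' Fractional-to-orthogonal matrix for a unit cell
#'
#' Standard crystallographic orthogonalization with the a axis along x and
#' b in the xy plane.
#'
#' @param cell an `xc_cell`.
#' @return A 3x3 matrix M such that orth = M %*% frac.
#' @export
frac_to_orth_matrix <- function(cell) {
  al <- cell$alpha * pi / 180
  be <- cell$beta * pi / 180
  ga <- cell$gamma * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(
    cell$a, cell$b * cos(ga), cell$c * cos(be),
    0, cell$b * sin(ga), cell$c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0, cell$c * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname frac_to_orth_matrix
#' @export
orth_to_frac_matrix <- function(cell) solve(frac_to_orth_matrix(cell))

# ---- symmetry operators ----------------------------------------------------

#' Parse a symmetry operator in xyz notation
#'
#' Accepts strings such as `"-x,y+1/2,-z"` and returns the fractional-space
#' rotation matrix and translation vector.
#'
#' @param s operator string, three comma-separated terms.
#' @return list with elements `R` (3x3) and `t` (length-3).
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(s)), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3L) stop("malformed symmetry operator: ", s)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # split into signed terms
    expr <- gsub("-", "+-", expr, fixed = TRUE)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[nzchar(terms)]
    for (term in terms) {
      sign <- 1
      if (startsWith(term, "-")) {
        sign <- -1
        term <- substring(term, 2)
      }
      if (term %in% c("x", "y", "z")) {
        R[i, match(term, c("x", "y", "z"))] <-
          R[i, match(term, c("x", "y", "z"))] + sign
      } else if (grepl("^[0-9]+/[0-9]+$", term)) {
        fr <- as.numeric(strsplit(term, "/", fixed = TRUE)[[1]])
        t[i] <- t[i] + sign * fr[1] / fr[2]
      } else if (grepl("^[0-9.]+$", term)) {
        t[i] <- t[i] + sign * as.numeric(term)
      } else {
        stop("cannot parse symmetry term '", term, "' in: ", s)
      }
    }
  }
  list(R = R, t = t)
}

#' Render a symmetry operator back to xyz notation
#' @param op list with `R` and `t` as from [parse_symop()].
#' @return character scalar.
#' @export
symop_to_string <- function(op) {
  ax <- c("x", "y", "z")
  out <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      v <- op$R[i, j]
      if (v == 0) next
      s <- paste0(s, if (v > 0 && nzchar(s)) "+" else if (v < 0) "-" else "",
                  ax[j])
    }
    tv <- op$t[i]
    if (abs(tv) > 1e-9) {
      fr <- .as_fraction(tv)
      s <- paste0(s, if (tv > 0) "+" else "-", fr)
    }
    out[i] <- s
  }
  paste(out, collapse = ",")
}

.as_fraction <- function(x) {
  x <- abs(x)
  for (den in c(2L, 3L, 4L, 6L)) {
    num <- x * den
    if (abs(num - round(num)) < 1e-9) {
      return(paste0(round(num), "/", den))
    }
  }
  format(x)
}

# Built-in generator tables for the space groups the toolkit emits and the
# common primitive groups; anything else must carry explicit operator
# records in the file.
.sg_table <- list(
  "P 1" = c("x,y,z"),
  "P 1 21 1" = c("x,y,z", "-x,y+1/2,-z"),
  "P 21 21 21" = c("x,y,z", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2",
                   "-x+1/2,-y,z+1/2"),
  "P 21 21 2" = c("x,y,z", "-x,-y,z", "x+1/2,-y+1/2,-z", "-x+1/2,y+1/2,-z"),
  "P 1 2 1" = c("x,y,z", "-x,y,-z"),
  "C 1 2 1" = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P 2 2 2" = c("x,y,z", "-x,-y,z", "-x,y,-z", "x,-y,-z"),
  "P 4" = c("x,y,z", "-x,-y,z", "-y,x,z", "y,-x,z")
)

#' Symmetry operators for a space-group symbol
#'
#' @param symbol Hermann-Mauguin symbol, e.g. `"P 21 21 21"`. The short
#'   monoclinic forms `"P 21"` and `"C 2"` are accepted as aliases.
#' @return list of operators (each with `R`, `t`), identity first.
#' @export
space_group_ops <- function(symbol) {
  key <- toupper(trimws(symbol))
  key <- switch(key, "P 21" = "P 1 21 1", "P 2" = "P 1 2 1",
                "C 2" = "C 1 2 1", key)
  hit <- match(key, toupper(names(.sg_table)))
  if (is.na(hit)) {
    stop("unknown space group symbol '", symbol,
         "'; supply explicit symmetry operator records")
  }
  lapply(.sg_table[[hit]], parse_symop)
}

.is_identity_op <- function(op) {
  all(abs(op$R - diag(3)) < 1e-9) && all(abs(op$t) < 1e-9)
}

# ---- superposition ---------------------------------------------------------

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum ||R p_i + t - q_i||^2` over paired coordinate rows.
#'
#' @param P,Q n x 3 coordinate matrices (P is moved onto Q).
#' @return list with `R` (3x3 rotation), `t` (length-3), `rmsd`, and
#'   `residuals` (per-row distances after superposition).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L) {
    stop("P and Q must be n x 3 matrices with equal n")
  }
  if (nrow(P) < 3L) stop("at least 3 paired points are required")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.vector(R %*% cp)
  moved <- sweep(P %*% t(R), 2, t, "+")
  res <- sqrt(rowSums((moved - Q)^2))
  list(R = R, t = t, rmsd = sqrt(mean(res^2)), residuals = res)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param R 3x3 rotation.
#' @param t length-3 translation.
#' @return n x 3 matrix.
#' @export
apply_transform <- function(xyz, R, t) {
  sweep(as.matrix(xyz) %*% t(R), 2, t, "+")
}

# ---- solvent-accessible surface area ---------------------------------------

# Deterministic quasi-uniform sphere sampling (golden-spiral / Fibonacci).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.20, D = 1.20, F = 1.47, CL = 1.75, BR = 1.85,
                I = 1.98, FE = 1.40, ZN = 1.39, MG = 1.73, CA = 1.74,
                "NA" = 2.27, K = 2.75, MN = 1.40)
.vdw_default <- 1.70

.atom_radii <- function(elements) {
  r <- .vdw_radii[toupper(elements)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples points on each atom's solvent-expanded sphere and counts the
#' fraction not buried inside any neighbouring sphere. Deterministic
#' (fixed golden-spiral point set).
#'
#' @param xyz n x 3 heavy-atom coordinates.
#' @param elements length-n element symbols (for van der Waals radii).
#' @param probe probe radius in Angstrom.
#' @param n_points sphere sample points per atom.
#' @return total SASA in A^2.
#' @export
sasa <- function(xyz, elements, probe = 1.44, n_points = 960) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n == 0L) return(0)
  if (!all(is.finite(xyz))) stop("non-finite coordinates in SASA input")
  radii <- .atom_radii(elements) + probe
  pts <- .sphere_points(n_points)
  total <- 0
  # neighbour prune: atoms whose spheres can overlap
  max_r <- max(radii)
  for (i in seq_len(n)) {
    ri <- radii[i]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ri + radii)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      total <- total + 4 * pi * ri^2
      next
    }
    sp <- sweep(pts * ri, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- rowSums(sweep(sp[free, , drop = FALSE], 2, xyz[j, ])^2)
      keep <- dj2 >= radii[j]^2
      free[free] <- keep
    }
    total <- total + 4 * pi * ri^2 * sum(free) / n_points
  }
  total
}
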