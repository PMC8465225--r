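#' Labelled monomer-coordinate configuration
#'
#' A `polymer_config` is an ordered set of 3D monomer-center coordinates with
#' a monomer radius and a shape label. Lengths are in monomer-radius units of
#' the default generator convention (unit-radius monomers, diameter 2), except
#' where a generator documents otherwise (`ring()` and `parabola()` follow the
#' unit-diameter convention of their respective reference constructions and
#' record `r_mono = 0.5`).
#'
#' @param coords Numeric matrix `N x 3` of monomer-center coordinates.
#' @param shape Shape label: one of `"SR"`, `"Ring"`, `"Pa"`, `"DS"`, `"SS"`,
#'   `"SAW"` (or any other descriptive string).
#' @param r_mono Monomer radius. Default 1.
#' @param rg Optional nominal radius of gyration of the construction (closed
#'   form where one exists). Defaults to [rg_of()] of the coordinates.
#' @return An object of class `polymer_config`.
#' @export
configuration <- function(coords, shape, r_mono = 1, rg = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3 || nrow(coords) < 1) {
    stop("coords must be a numeric N x 3 matrix with N >= 1")
  }
  dimnames(coords) <- NULL
  structure(
    list(
      coords = coords,
      N = nrow(coords),
      r_mono = r_mono,
      shape = shape,
      rg = if (is.null(rg)) rg_of(coords) else rg
    ),
    class = "polymer_config"
  )
}

#' @export
print.polymer_config <- function(x, ...) {
  cat(sprintf(
    "Polymer configuration '%s': N = %d monomers (r_mono = %g)\n  Rg = %.4f\n",
    x$shape, x$N, x$r_mono, x$rg
  ))
  invisible(x)
}

#' Radius of gyration of a set of monomer coordinates
#'
#' Root-mean-square distance of the monomer centers from their center of
#' mass, with all monomer masses equal to one:
#' \deqn{R_g = \left[\frac{1}{N}\sum_{i=1}^{N} r_i^2\right]^{1/2}.}
#'
#' @param config A [configuration()] object or a numeric `N x 3` (or `N x 2`)
#'   coordinate matrix.
#' @return The radius of gyration.
#' @examples
#' rg_of(rbind(c(0, 0, 0), c(2, 0, 0)))  # 1
#' @export
rg_of <- function(config) {
  coords <- if (inherits(config, "polymer_config")) config$coords else as.matrix(config)
  if (!is.numeric(coords) || nrow(coords) < 1) {
    stop("need at least one monomer coordinate")
  }
  centered <- sweep(coords, 2, colMeans(coords))
  sqrt(mean(rowSums(centered^2)))
}

#' Straight rope-like configuration
#'
#' The maximally extended, essentially 1D configuration of a stiff, strongly
#' charged chain: `N` touching unit-radius monomers on a line, centers spaced
#' by one diameter (2 units). Its radius of gyration has the closed form
#' \eqn{R_g = \sqrt{(N^2 - 1)/3}}.
#'
#' @param N Number of monomers (>= 1).
#' @return A `polymer_config` with shape `"SR"`.
#' @examples
#' straight_rope(20)$rg  # 11.53
#' @export
straight_rope <- function(N) {
  N <- check_count(N)
  coords <- cbind(2 * (seq_len(N) - 1), 0, 0)
  configuration(coords, "SR", r_mono = 1, rg = sqrt((N^2 - 1) / 3))
}

#' Ring configuration
#'
#' `N` monomer centers equally spaced on a circle of radius `R`. The default
#' (`convention = "table"`) uses \eqn{R = N/(2\pi)}, the closed ring of `N`
#' unit-diameter monomers (so `r_mono = 0.5`); all centers are equidistant
#' from the centroid, hence \eqn{R_g = R} exactly. The alternative
#' `"perimeter"` convention divides the circumference by one diameter of a
#' unit-radius monomer, giving \eqn{R = N/\pi} and `r_mono = 1`.
#'
#' Note that on a closed ring neighboring centers sit on a chord, slightly
#' shorter than the arc: neighbor spacing is \eqn{(N/\pi)\sin(\pi/N)} diameters
#' (0.4% under one diameter at N = 20).
#'
#' @param N Number of monomers (>= 3).
#' @param convention `"table"` (default, \eqn{R = N/(2\pi)}) or
#'   `"perimeter"` (\eqn{R = N/\pi}).
#' @return A `polymer_config` with shape `"Ring"`.
#' @examples
#' ring(50)$rg  # 7.96, i.e. 50/(2*pi)
#' @export
ring <- function(N, convention = c("table", "perimeter")) {
  convention <- match.arg(convention)
  N <- check_count(N)
  if (N < 3) {
    stop("a ring needs at least 3 monomers")
  }
  R <- switch(convention, table = N / (2 * pi), perimeter = N / pi)
  theta <- 2 * pi * (seq_len(N) - 1) / N
  coords <- cbind(R * cos(theta), R * sin(theta), 0)
  configuration(coords, "Ring",
                r_mono = switch(convention, table = 0.5, perimeter = 1),
                rg = R)
}

#' Shell capacities of the dense-sphere construction
#'
#' Maximum number of unit-radius monomers on concentric shells of radius
#' 0, 2, 4, ... about a central monomer while keeping spherical symmetry:
#' 1, 7, 19, 37, 61, ... (capacity of shell k is \eqn{3k(k-1) + 1}).
#'
#' @param k Shell index (1-based; vectorized).
#' @return Integer capacities.
#' @examples
#' shell_capacity(1:4)  # 1 7 19 37
#' @export
shell_capacity <- function(k) {
  if (any(k < 1)) stop("shell index k must be >= 1")
  3 * k * (k - 1) + 1
}

# Occupancy of the concentric shells for N monomers: radii 2*(k-1) and
# counts, outermost shell partially filled.
shell_occupancy <- function(N) {
  k <- 1
  placed <- 0
  radii <- numeric(0)
  counts <- integer(0)
  while (placed < N) {
    cap <- shell_capacity(k)
    take <- min(cap, N - placed)
    radii <- c(radii, 2 * (k - 1))
    counts <- c(counts, take)
    placed <- placed + take
    k <- k + 1
  }
  data.frame(shell = seq_along(radii), radius = radii, count = counts,
             capacity = shell_capacity(seq_along(radii)))
}

#' Radius of gyration of the dense-sphere shell construction
#'
#' Closed-form accounting of the shell filling (distances taken to the sphere
#' center): \eqn{R_g = [\,(n_1 r_1^2 + n_2 r_2^2 + \dots)/N\,]^{1/2}} with
#' shell radii 0, 2, 4, ... and counts from [shell_capacity()], the outermost
#' shell partially filled.
#'
#' @param N Number of monomers (>= 1; vectorized).
#' @return The dense-sphere radius of gyration.
#' @examples
#' dense_sphere_rg(40)  # 4.47
#' @export
dense_sphere_rg <- function(N) {
  vapply(N, function(n) {
    occ <- shell_occupancy(check_count(n))
    sqrt(sum(occ$count * occ$radius^2) / n)
  }, numeric(1))
}

#' Dense-sphere configuration
#'
#' The fully 3D, maximally compact idealized configuration: monomers fill
#' concentric shells at radii 0, 2, 4, 6, ... with capacities 1, 7, 19, 37,
#' ... until `N` monomers are placed (partial outermost shell). The nominal
#' `rg` is the shell closed form [dense_sphere_rg()] (distances to the sphere
#' center); the returned coordinates place each shell's monomers
#' quasi-uniformly on its sphere (icosahedral directions for small shells, a
#' Fibonacci lattice otherwise) for XYZ export, so [rg_of()] of the
#' coordinates differs only by the small centroid offset of the discrete
#' placement.
#'
#' @param N Number of monomers (>= 1).
#' @return A `polymer_config` with shape `"DS"`.
#' @examples
#' dense_sphere(40)
#' @export
dense_sphere <- function(N) {
  N <- check_count(N)
  occ <- shell_occupancy(N)
  coords <- do.call(rbind, lapply(seq_len(nrow(occ)), function(i) {
    shell_points(occ$count[i], occ$capacity[i]) * occ$radius[i]
  }))
  configuration(coords, "DS", r_mono = 1, rg = dense_sphere_rg(N))
}

#' Sparse-sphere configuration
#'
#' A radially dilated dense sphere: the same shell occupancy, with all shell
#' radii scaled so the envelope radius grows from the compact-sphere estimate
#' \eqn{R = N^{1/3}} to \eqn{R + r} (one monomer radius larger, `r = 1`).
#' Consequently \eqn{R_g(\mathrm{SS}) = R_g(\mathrm{DS}) \cdot (N^{1/3} + 1)/N^{1/3}}
#' and the sparse sphere is always larger than the dense sphere at the same
#' `N`. Only this single dilation variant is implemented; "degrees of
#' sparsity" beyond it are not modelled.
#'
#' @param N Number of monomers (>= 1).
#' @return A `polymer_config` with shape `"SS"`.
#' @examples
#' sparse_sphere(20)$rg
#' @export
sparse_sphere <- function(N) {
  N <- check_count(N)
  scale <- (N^(1 / 3) + 1) / N^(1 / 3)
  ds <- dense_sphere(N)
  configuration(ds$coords * scale, "SS", r_mono = 1, rg = ds$rg * scale)
}

#' Sparse-sphere radius of gyration
#'
#' Closed form of the dilated-shell construction of [sparse_sphere()].
#'
#' @param N Number of monomers (>= 1; vectorized).
#' @return The sparse-sphere radius of gyration.
#' @export
sparse_sphere_rg <- function(N) {
  dense_sphere_rg(N) * (N^(1 / 3) + 1) / N^(1 / 3)
}

#' Parabola (horseshoe) configuration
#'
#' A planar, symmetric configuration of `N` monomer centers at equal
#' arc-length steps along \eqn{y = x^2}: one center at the apex when `N` is
#' odd, and mirror pairs at \eqn{\pm x}. The default step is one unit arc
#' length (unit-length monomers, `r_mono = 0.5`), the convention of the
#' reference construction for this shape; `step = 2` gives touching
#' unit-radius monomers instead. Arc-length positions are inverted via the
#' closed-form arc length of the parabola,
#' \eqn{s(x) = x\sqrt{1 + 4x^2}/2 + \sinh^{-1}(2x)/4}.
#'
#' @param N Number of monomers (>= 2).
#' @param step Arc-length spacing between consecutive centers. Default 1.
#' @return A `polymer_config` with shape `"Pa"`.
#' @examples
#' parabola(20)$rg
#' @export
parabola <- function(N, step = 1) {
  N <- check_count(N)
  if (N < 2) {
    stop("a parabola configuration needs at least 2 monomers")
  }
  if (step <= 0) stop("step must be positive")
  half <- if (N %% 2 == 1) {
    step * seq_len((N - 1) / 2)
  } else {
    step * (seq_len(N / 2) - 0.5)
  }
  x_half <- vapply(half, parabola_x_at_arc, numeric(1))
  x <- sort(c(-x_half, if (N %% 2 == 1) 0, x_half))
  configuration(cbind(x, x^2, 0), "Pa", r_mono = step / 2)
}

# Invert s(x) = x*sqrt(1+4x^2)/2 + asinh(2x)/4 for x >= 0.
parabola_x_at_arc <- function(s) {
  if (s == 0) return(0)
  arc <- function(x) x * sqrt(1 + 4 * x^2) / 2 + asinh(2 * x) / 4
  stats::uniroot(function(x) arc(x) - s, c(0, s + 1), tol = 1e-12)$root
}

#' Self-avoiding random walk configuration
#'
#' An off-lattice pearl-necklace chain of `N` touching unit-radius monomers:
#' each bond has length one diameter (2 units) in a direction drawn uniformly
#' on the sphere, and a placement overlapping any previously placed monomer
#' (center distance < 2) is rejected. After `max_tries` rejected directions
#' for one step the whole walk restarts, up to `max_restarts` times (dead
#' ends are rare off-lattice for chains up to a few hundred monomers).
#'
#' Over an ensemble of walks the mean radius of gyration scales as
#' \eqn{N^{\nu}} with \eqn{\nu \approx 0.59}, the self-avoiding-walk
#' exponent.
#'
#' @param N Number of monomers (>= 1).
#' @param seed Optional integer seed; a fixed seed makes the walk
#'   bit-reproducible.
#' @param max_tries Direction attempts per step before restarting. Default 100.
#' @param max_restarts Walk restarts before giving up. Default 1000.
#' @return A `polymer_config` with shape `"SAW"`.
#' @examples
#' saw_walk(40, seed = 1)$rg
#' @export
saw_walk <- function(N, seed = NULL, max_tries = 100, max_restarts = 1000) {
  N <- check_count(N)
  if (!is.null(seed)) set.seed(seed)
  min_sq <- 4 * (1 - 1e-9)  # non-overlap: center distance >= one diameter
  for (restart in seq_len(max_restarts)) {
    coords <- matrix(0, nrow = N, ncol = 3)
    i <- 2
    failed <- FALSE
    while (i <= N) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        u <- random_unit_vector()
        cand <- coords[i - 1, ] + 2 * u
        if (i > 2) {
          prev <- coords[seq_len(i - 2), , drop = FALSE]
          d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
            (prev[, 3] - cand[3])^2
          if (min(d2) < min_sq) next
        }
        coords[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        failed <- TRUE
        break
      }
      i <- i + 1
    }
    if (!failed) {
      return(configuration(coords, "SAW", r_mono = 1))
    }
  }
  stop("self-avoiding walk generation failed after max_restarts restarts")
}

random_unit_vector <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  rho <- sqrt(1 - z^2)
  c(rho * cos(phi), rho * sin(phi), z)
}

# Quasi-uniform directions on the unit sphere for one shell: the first
# `count` of a `capacity`-point layout, so partial shells inherit the full
# shell's spacing. Icosahedral vertices (min pairwise angle 63.4 deg) for up
# to 12 points, Fibonacci lattice otherwise.
shell_points <- function(count, capacity) {
  if (capacity == 1) {
    return(matrix(0, nrow = count, ncol = 3))
  }
  pts <- if (capacity <= 12) {
    icosahedron_vertices()
  } else {
    fibonacci_sphere(capacity)
  }
  pts[seq_len(count), , drop = FALSE]
}

icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1)
  )
  v / sqrt(1 + phi^2)
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  theta <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(theta), rho * sin(theta), z)
}

#' Write a configuration as a standard XYZ file
#'
#' Standard XYZ layout: atom count, comment line, then one `element x y z`
#' row per monomer. The element symbol is fixed to `"C"`; the comment line
#' records the shape, `N`, monomer radius and nominal Rg.
#'
#' @param config A [configuration()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(config, path) {
  stopifnot(inherits(config, "polymer_config"))
  lines <- c(
    as.character(config$N),
    sprintf("shape=%s N=%d r_mono=%g Rg=%.6f",
            config$shape, config$N, config$r_mono, config$rg),
    sprintf("C %.6f %.6f %.6f",
            config$coords[, 1], config$coords[, 2], config$coords[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

check_count <- function(N) {
  if (length(N) != 1 || !is.finite(N) || N < 1 || N != round(N)) {
    stop("N must be a single integer >= 1")
  }
  as.integer(N)
}
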