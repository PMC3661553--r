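DINUCS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          paste0))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_z <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Rodrigues rotation about unit axis u by angle a (degrees)
rot_axis <- function(u, a) {
  a <- deg2rad(a)
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Load and validate a dinucleotide step-parameter table
#'
#' The packaged default (`"electrophoretic"`) carries the gel-mobility-derived
#' wedge-model angles (twist, wedge magnitude and direction per dinucleotide
#' step), a uniform 3.4 A rise and dinucleotide stacking energies; see the
#' file header of `inst/extdata/step_params_electrophoretic.tsv` for
#' provenance. Custom tables use the same tab-delimited schema.
#'
#' Validation requires all 16 dinucleotides, numeric values, and stacking
#' energies symmetric under reverse complement
#' (E(XY) = E(complement(Y)complement(X))).
#'
#' @param config `"electrophoretic"` (packaged default), a file path to a
#'   table in the packaged schema, or a data.frame with columns
#'   `dinucleotide`, `twist`, `wedge`, `direction`, `rise`, `stacking`.
#' @return data.frame with one row per dinucleotide (rownames = dinucleotide)
#'   and columns `twist`, `wedge`, `direction` (degrees), `rise` (Angstrom),
#'   `stacking` (kcal/mol).
#' @export
load_step_table <- function(config = "electrophoretic") {
  tab <- if (is.data.frame(config)) {
    config
  } else if (identical(config, "electrophoretic")) {
    read.delim(system.file("extdata", "step_params_electrophoretic.tsv",
                           package = "islandscape", mustWork = TRUE),
               comment.char = "#")
  } else {
    read.delim(config, comment.char = "#")
  }
  need <- c("dinucleotide", "twist", "wedge", "direction", "rise", "stacking")
  if (!all(need %in% names(tab))) {
    stop("step table must have columns: ", paste(need, collapse = ", "))
  }
  tab$dinucleotide <- toupper(tab$dinucleotide)
  missing <- setdiff(DINUCS, tab$dinucleotide)
  if (length(missing)) {
    stop("step table is missing dinucleotides: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$dinucleotide)) stop("duplicated dinucleotide entries")
  num <- c("twist", "wedge", "direction", "rise", "stacking")
  if (!all(vapply(tab[num], is.numeric, logical(1))) ||
      anyNA(tab[num])) {
    stop("step table values must all be numeric and non-missing")
  }
  rownames(tab) <- tab$dinucleotide
  tab <- tab[DINUCS, num]
  rc <- vapply(DINUCS, function(d) revcomp(d), character(1))
  if (any(abs(tab[DINUCS, "stacking"] - tab[rc, "stacking"]) > 1e-6)) {
    stop("stacking energies are not reverse-complement symmetric")
  }
  tab
}

# per-step parameter rows for a sequence (n-1 rows)
step_params <- function(seq, table) {
  assert_acgt(seq, "sequence")
  L <- nchar(seq)
  if (L < 2) stop("sequence must have at least 2 bases")
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  steps <- paste0(b[-L], b[-1])
  table[steps, , drop = FALSE]
}

#' Build base-pair reference frames along a wedge-model trajectory
#'
#' Propagates one orthonormal triad per base pair: x = base-pair long axis,
#' y = pseudo-dyad, z = local helical direction. The step rotation applies the
#' dinucleotide twist about z with the wedge bend (magnitude `wedge` about the
#' in-plane axis at azimuth `direction`, measured in the mid-step frame)
#' inserted at the half-twist point:
#' `S = Rz(twist/2) %*% Rwedge(direction, wedge) %*% Rz(twist/2)`. Measuring
#' `direction` in the mid-step frame is forced by the parameter table itself:
#' the reverse-complement step carries the opposite direction sign, so
#' self-complementary steps (AT, CG, GC, TA) must have a dyad-symmetric wedge
#' axis, which only holds at the half-twist point.
#'
#' The origin then advances by `rise` along a local helical direction chosen
#' by `translation`:
#' * `"endstep"` (default): along the z axis of the *new* frame — the
#'   propagation convention of classical wedge-model trajectory builders;
#' * `"midstep"`: along the mean of the flanking z axes — the modern
#'   base-pair-step convention, which makes the trajectories of a sequence
#'   and of its reverse complement exactly congruent (one physical duplex).
#'   Under `"endstep"` that congruence holds only approximately (each
#'   segment deviates by about `rise * wedge` in radians).
#'
#' With zero wedge both conventions coincide and give a straight helix with
#' spacing `rise`. The first frame is the identity at the coordinate origin.
#'
#' @param seq DNA sequence (character string, >= 2 bases, A/C/G/T).
#' @param table step-parameter table from [load_step_table()].
#' @param translation `"endstep"` or `"midstep"` (see Details).
#' @return object of class `frame_chain`: list with `origins` (L x 3 matrix,
#'   Angstrom) and `triads` (3 x 3 x L array, columns x/y/z).
#' @export
build_frames <- function(seq, table, translation = c("endstep", "midstep")) {
  translation <- match.arg(translation)
  par <- step_params(seq, table)
  L <- nrow(par) + 1L
  origins <- matrix(0, L, 3)
  triads <- array(0, c(3, 3, L))
  R <- diag(3)
  triads[, , 1] <- R
  O <- c(0, 0, 0)
  for (i in seq_len(L - 1L)) {
    t <- par$twist[i]; w <- par$wedge[i]; d <- par$direction[i]
    S <- rot_z(t / 2)
    if (w != 0) {
      S <- S %*% rot_axis(c(cos(deg2rad(d)), sin(deg2rad(d)), 0), w)
    }
    S <- S %*% rot_z(t / 2)
    z_old <- R[, 3]
    R <- R %*% S
    zdir <- if (translation == "endstep") {
      R[, 3]
    } else {
      zm <- z_old + R[, 3]
      zm / sqrt(sum(zm^2))
    }
    O <- O + par$rise[i] * zdir
    origins[i + 1L, ] <- O
    triads[, , i + 1L] <- R
  }
  structure(list(origins = origins, triads = triads), class = "frame_chain")
}

#' Default pseudo-atom offsets (fiber B-DNA)
#'
#' Local-frame offsets, in Angstrom, of the two conformational-chain
#' pseudo-atoms from the frame origin (which models the local helical axis):
#' * `carbon`: midpoint of the base-pair long axis (C6 of the pyrimidine to
#'   C8 of the purine). In the standard base-pair reference frame this
#'   midpoint nearly coincides with the base-pair origin, which in fiber
#'   B-DNA is displaced from the helix axis along the pseudo-dyad by the
#'   x-displacement of about -0.71 A.
#' * `phosphorus`: midpoint of the two phosphorus atoms of a base pair. By
#'   dyad symmetry it lies on the pseudo-dyad, at r cos(phi) with the fiber
#'   B-DNA phosphate cylindrical coordinates (r = 8.91 A, phi = 95.2 deg),
#'   i.e. about -0.81 A.
#'
#' In this package's triad convention the pseudo-dyad is the local y axis,
#' so both offsets lie on y; dyad-invariant offsets keep the chains of a
#' sequence and of its reverse complement congruent (one physical duplex).
#'
#' @return named list of numeric length-3 vectors.
#' @export
chain_offsets <- function() {
  list(carbon = c(0, -0.71, 0),
       phosphorus = c(0, round(8.91 * cos(deg2rad(95.2)), 3), 0))
}

#' Place a conformational chain along a frame chain
#'
#' Vertex n is `O_n + R_n %*% offset`; the chain is then translated so its
#' first vertex sits at the coordinate origin. `offset = c(0, 0, 0)` yields
#' the chain of frame origins (the helical-axis polyline).
#'
#' @param frames a [build_frames()] result.
#' @param kind `"carbon"` or `"phosphorus"`; selects the default offset.
#' @param offset numeric length-3 local-frame offset in Angstrom, overriding
#'   the [chain_offsets()] default for `kind`.
#' @return object of class `conformational_chain`: list with `kind` and
#'   `vertices` (L x 3 matrix).
#' @export
place_chain <- function(frames, kind = c("carbon", "phosphorus"),
                        offset = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(frames, "frame_chain"))
  if (is.null(offset)) offset <- chain_offsets()[[kind]]
  stopifnot(is.numeric(offset), length(offset) == 3)
  L <- nrow(frames$origins)
  V <- frames$origins
  if (any(offset != 0)) {
    for (i in seq_len(L)) {
      V[i, ] <- V[i, ] + as.vector(frames$triads[, , i] %*% offset)
    }
  }
  V <- sweep(V, 2, V[1, ])
  structure(list(kind = kind, vertices = V), class = "conformational_chain")
}

#' Global chain metrics: contour length, end-to-end length, curvature
#'
#' RL (real length) is the summed length of the segments joining consecutive
#' vertices; SL (straightened length) is the distance between the two chain
#' endpoints; their difference RL - SL measures the global curvature of the
#' fragment (0 for a straight chain).
#'
#' @param chain a [place_chain()] result, or an L x 3 vertex matrix.
#' @return named list `RL`, `SL`, `curvature` (Angstrom).
#' @export
global_metrics <- function(chain) {
  V <- if (inherits(chain, "conformational_chain")) chain$vertices else chain
  stopifnot(is.matrix(V), ncol(V) == 3)
  if (nrow(V) < 2) stop("chain needs at least 2 vertices")
  d <- diff(V)
  RL <- sum(sqrt(rowSums(d^2)))
  SL <- sqrt(sum((V[nrow(V), ] - V[1, ])^2))
  list(RL = RL, SL = SL, curvature = RL - SL)
}

#' Local chain angles: bending (theta) and torsion (phi)
#'
#' theta_n is the deflection between consecutive segment directions
#' (V_{n+1}-V_n) and (V_{n+2}-V_{n+1}): 0 for a straight continuation, up to
#' 180 for a full back-fold. phi_n measures the local unflatness of the chain
#' at the vertex quadruple (V_n, ..., V_{n+3}): the signed angle between the
#' plane through (V_n, V_{n+1}, V_{n+2}) and the plane through (V_{n+1},
#' V_{n+2}, V_{n+3}), with the sign given by the right-hand rule about the
#' shared segment. Any coplanar quadruple — cis or trans — gives phi = 0, so
#' phi lies in \[-90, 90\] (it folds the conventional torsion dihedral delta
#' to `atan2(sin(delta), |cos(delta)|)`).
#'
#' @param chain a [place_chain()] result, or an L x 3 vertex matrix.
#' @return list with numeric vectors `theta` (length L-2, degrees in
#'   \[0, 180\]) and `phi` (length L-3, degrees in \[-90, 90\]).
#' @export
local_angles <- function(chain) {
  V <- if (inherits(chain, "conformational_chain")) chain$vertices else chain
  stopifnot(is.matrix(V), ncol(V) == 3)
  L <- nrow(V)
  if (L < 3) stop("chain needs at least 3 vertices for theta")
  seg <- diff(V)
  len <- sqrt(rowSums(seg^2))
  u <- seg / len
  dots <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  theta <- rad2deg(acos(pmin(1, pmax(-1, dots))))
  phi <- numeric(0)
  if (L >= 4) {
    b1 <- seg[1:(L - 3), , drop = FALSE]
    b2 <- seg[2:(L - 2), , drop = FALSE]
    b3 <- seg[3:(L - 1), , drop = FALSE]
    cross <- function(a, b) {
      cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
            a[, 3] * b[, 1] - a[, 1] * b[, 3],
            a[, 1] * b[, 2] - a[, 2] * b[, 1])
    }
    n1 <- cross(b1, b2)
    n2 <- cross(b2, b3)
    b2n <- sqrt(rowSums(b2^2))
    x <- rowSums(n1 * n2)
    y <- rowSums(cross(n1, n2) * (b2 / b2n))
    phi <- rad2deg(atan2(y, abs(x)))
    phi[abs(x) < 1e-12 & abs(y) < 1e-12] <- 0
  }
  list(theta = theta, phi = phi)
}

#' Sliding-window profiles: cumulative twist, stacking energy, curvature
#'
#' A window of size S covers S consecutive dinucleotide steps (vertices
#' i..i+S of the chain). With the default `"steps"` convention a fragment of
#' L bp yields L - S windows (e.g. 300 - 22 = 278 values). Per window:
#' * `omega_cum`: sum of the per-step twist angles, each measured as the
#'   acute line-line angle between the long (x) axes of adjacent base pairs;
#' * `stacking`: sum of the dinucleotide stacking energies over the steps;
#' * `curvature`: RL - SL of the sub-chain.
#'
#' @param seq the sequence the frames were built from.
#' @param frames a [build_frames()] result for `seq`.
#' @param chain a [place_chain()] result for `frames`.
#' @param S window size in steps (>= 2).
#' @param table step-parameter table (for stacking energies).
#' @param convention `"steps"` (L - S windows, the printed count) or
#'   `"basepairs"` (a window of S base pairs = S - 1 steps, L - S + 1
#'   windows).
#' @return data.frame with `start` (first base of the window), `omega_cum`
#'   (degrees), `stacking` (kcal/mol), `curvature` (Angstrom).
#' @export
windowed_profiles <- function(seq, frames, chain, S = 22,
                              table = load_step_table(),
                              convention = c("steps", "basepairs")) {
  convention <- match.arg(convention)
  stopifnot(inherits(frames, "frame_chain"),
            inherits(chain, "conformational_chain"))
  L <- nchar(seq)
  stopifnot(nrow(chain$vertices) == L, dim(frames$triads)[3] == L)
  n_steps <- if (convention == "steps") as.integer(S) else as.integer(S) - 1L
  if (n_steps < 2) stop("window size too small")
  if (n_steps > L - 1L) stop("window size exceeds the fragment")
  par <- step_params(seq, table)
  # per-step acute angle between adjacent long axes
  xs <- t(frames$triads[, 1, ])
  dots <- abs(rowSums(xs[-L, , drop = FALSE] * xs[-1, , drop = FALSE]))
  omega_step <- rad2deg(acos(pmin(1, dots)))
  cw <- c(0, cumsum(omega_step))
  ce <- c(0, cumsum(par$stacking))
  starts <- seq_len(L - 1L - n_steps + 1L)
  if (convention == "steps") starts <- starts[seq_len(L - as.integer(S))]
  data.frame(
    start = starts,
    omega_cum = cw[starts + n_steps] - cw[starts],
    stacking = ce[starts + n_steps] - ce[starts],
    curvature = vapply(starts, function(i) {
      global_metrics(chain$vertices[i:(i + n_steps), , drop = FALSE])$curvature
    }, numeric(1)))
}

#' Histogram with fixed interval width
#'
#' Bins values into left-closed, right-open intervals of width `i`, anchored
#' at the data minimum by default. Counts always sum to the input size.
#'
#' @param values numeric vector (non-empty).
#' @param i interval width (> 0).
#' @param anchor left edge of the first bin (default `min(values)`).
#' @return data.frame with `bin_start`, `bin_end`, `count`.
#' @export
metric_histogram <- function(values, i, anchor = NULL) {
  if (!length(values)) stop("empty input")
  stopifnot(is.numeric(values), i > 0)
  if (is.null(anchor)) anchor <- min(values)
  idx <- floor((values - anchor) / i)
  if (any(idx < 0)) stop("anchor must not exceed the data minimum")
  tab <- table(idx)
  bin <- as.integer(names(tab))
  data.frame(bin_start = anchor + bin * i,
             bin_end = anchor + (bin + 1) * i,
             count = as.integer(tab))
}
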