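# Synthetic helical-filament generator. Amyloid filaments stack identical
# rungs along a helical axis with a rise of ~4.8 A (the cross-beta sheet
# spacing) and a small per-rung twist; the crossover distance -- the axial
# length over which the filament rotates 180 degrees -- relates the two:
# crossover = 180 * rise / |twist|. Tau filaments are left-handed (negative
# twist). These fixtures give every comparison stage a ground truth without
# any deposited coordinates: rungs are exact rigid copies (optionally with
# seeded Gaussian noise), so inter-rung RMSDs, recovered rise/twist, and
# localized perturbations are all known by construction.

#' Helical parameters
#'
#' Rise (Angstrom per rung), signed twist (degrees per rung; negative =
#' left-handed) and crossover distance (Angstrom, the 180-degree repeat),
#' kept mutually consistent: `crossover = 180 * rise / |twist|`.
#'
#' @param rise axial translation per rung, Angstrom, > 0.
#' @param twist signed rotation per rung, degrees, non-zero.
#' @param crossover optional crossover distance; if supplied it must agree
#'   with `180 * rise / |twist|` to 1e-6 relative.
#' @return an object of class `helical_params`.
#' @export
helical_params <- function(rise, twist, crossover = NULL) {
  if (!is.numeric(rise) || rise <= 0) stop("helical_params: rise must be > 0")
  if (!is.numeric(twist) || twist == 0)
    stop("helical_params: twist must be non-zero")
  implied <- 180 * rise / abs(twist)
  if (!is.null(crossover) &&
      abs(crossover - implied) > 1e-6 * max(1, abs(implied)))
    stop("helical_params: crossover ", crossover,
         " inconsistent with rise/twist (implies ", implied, ")")
  structure(list(rise = rise, twist = twist, crossover = implied),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf(
    "<helical_params> rise %.4f A, twist %+.4f deg/rung (%s-handed), crossover %.1f A\n",
    x$rise, x$twist, if (x$twist < 0) "left" else "right", x$crossover))
  invisible(x)
}

#' Convert a crossover distance to a per-rung twist
#'
#' The crossover is the axial distance over which the filament rotates
#' half a turn, so `|twist| = 180 * rise / crossover` degrees per rung.
#' Left-handed filaments (tau) get a negative sign.
#'
#' @param crossover crossover distance, Angstrom, > 0.
#' @param rise rise per rung, Angstrom, > 0.
#' @param handedness `"left"` (default, negative twist) or `"right"`.
#' @return signed twist in degrees per rung.
#' @export
crossover_to_twist <- function(crossover, rise,
                               handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  if (!is.numeric(crossover) || crossover <= 0)
    stop("crossover_to_twist: crossover must be > 0")
  if (!is.numeric(rise) || rise <= 0)
    stop("crossover_to_twist: rise must be > 0")
  tw <- 180 * rise / crossover
  if (handedness == "left") -tw else tw
}

#' Default synthetic rung: a planar serpentine CA trace
#'
#' A 100-residue CA-only chain meandering in the z = 0 plane: straight
#' strands of consecutive CA positions 3.8 A apart (the trans CA-CA
#' distance), folded back every 20 residues with a 4.8 A inter-strand
#' offset, echoing the packing scale of an amyloid cross-beta core. Purely
#' geometric -- no stereochemistry -- which is all the comparison machinery
#' sees. Residue numbering starts at 273 by default (the modelled core of
#' 4R tau depositions); identities cycle through a fixed arbitrary set.
#'
#' @param n_res number of residues.
#' @param first_resno first residue number.
#' @param strand_len residues per strand before a turn.
#' @param ca_spacing CA-CA distance along a strand, Angstrom.
#' @param strand_gap perpendicular offset between strands, Angstrom.
#' @param chain_id chain identifier.
#' @return a [residue_chain] with CA coordinates only.
#' @export
serpentine_rung <- function(n_res = 100, first_resno = 273, strand_len = 20,
                            ca_spacing = 3.8, strand_gap = 4.8,
                            chain_id = "A") {
  i <- seq_len(n_res) - 1L
  strand <- i %/% strand_len
  pos <- i %% strand_len
  x <- ifelse(strand %% 2 == 0, pos, strand_len - 1 - pos) * ca_spacing
  y <- strand * strand_gap
  ca <- cbind(x, y, 0)
  aa <- rep(strsplit("GKVQIINKKLDLSNVQSKCGS", "")[[1]],
            length.out = n_res)
  residue_chain(chain_id, first_resno + i, aa, list(CA = ca))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

#' Build an idealized helical filament from a single rung
#'
#' Rung k (0-based) is the input rung rotated by `k * twist` degrees about
#' the z-axis through the rung's CA centroid and translated by `k * rise`
#' Angstrom along z. Chains are labelled consecutively (A, B, C, ...).
#' Rungs are exact rigid copies unless `noise_sd > 0`, in which case seeded
#' isotropic Gaussian noise is added to every coordinate.
#'
#' @param rung a [residue_chain].
#' @param params a [helical_params].
#' @param n_rungs number of rungs, >= 1; 1 returns the input unchanged.
#' @param noise_sd per-coordinate Gaussian noise, Angstrom (default 0).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param id label for the structure.
#' @return a [fold_structure] with `n_rungs` chains.
#' @export
build_filament <- function(rung, params, n_rungs, noise_sd = 0, seed = 1L,
                           id = "synthetic_filament") {
  stopifnot(inherits(rung, "residue_chain"),
            inherits(params, "helical_params"))
  n_rungs <- as.integer(n_rungs)
  if (n_rungs < 1L) stop("build_filament: n_rungs must be >= 1")
  ctr <- colMeans(rung$xyz$CA)
  ctr[3] <- 0
  labels <- make_chain_labels(n_rungs)
  noise <- NULL
  if (noise_sd > 0) {
    noise <- with_seed(seed, lapply(seq_len(n_rungs), function(k) {
      lapply(rung$xyz, function(m)
        matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m), 3))
    }))
  }
  chains <- lapply(seq_len(n_rungs), function(k) {
    R <- rot_z((k - 1L) * params$twist)
    shift <- c(0, 0, (k - 1L) * params$rise)
    xyz <- lapply(rung$xyz, function(m) {
      out <- sweep(sweep(m, 2, ctr) %*% t(R), 2, ctr + shift, `+`)
      out
    })
    if (!is.null(noise))
      xyz <- Map(`+`, xyz, noise[[k]])
    residue_chain(labels[k], rung$resno, rung$aa, xyz)
  })
  fold_structure(id, chains,
                 source = list(params = params, n_rungs = n_rungs,
                               noise_sd = noise_sd))
}

make_chain_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)]
  else c(LETTERS, as.vector(outer(LETTERS, LETTERS,
                                  function(a, b) paste0(a, b))))[seq_len(n)]
}

# run expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Apply a smooth localized deformation to a residue range
#'
#' Residues inside `res_range` are displaced along a single random unit
#' direction (drawn from the seeded generator) by a cosine-tapered bump:
#' zero at the range ends, exactly `amplitude` Angstrom at the peak
#' (the taper is renormalised so its maximum over the sampled residues is
#' 1). Residues outside the range are bit-identical to the input. Ground
#' truth for heat-map localization tests.
#'
#' @param chain a [residue_chain].
#' @param res_range length-2 vector of residue numbers (inclusive).
#' @param amplitude peak displacement, Angstrom, >= 0.
#' @param seed RNG seed for the displacement direction.
#' @return a deformed [residue_chain]; deterministic for fixed seed.
#' @export
perturb_region <- function(chain, res_range, amplitude, seed = 1L) {
  stopifnot(inherits(chain, "residue_chain"))
  if (amplitude < 0) stop("perturb_region: amplitude must be >= 0")
  sel <- which(chain$resno >= res_range[1] & chain$resno <= res_range[2])
  if (length(sel) == 0L) {
    warning("perturb_region: empty residue range; chain unchanged")
    return(chain)
  }
  if (amplitude == 0) return(chain)
  dir <- with_seed(seed, {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  })
  frac <- if (length(sel) == 1L) 0.5 else
    (seq_along(sel) - 1) / (length(sel) - 1)
  taper <- sin(pi * frac)^2
  taper <- taper / max(taper)
  xyz <- lapply(chain$xyz, function(m) {
    m[sel, ] <- m[sel, , drop = FALSE] +
      outer(amplitude * taper, dir)
    m
  })
  residue_chain(chain$chain_id, chain$resno, chain$aa, xyz)
}

#' Recover helical parameters from a built filament
#'
#' The helical axis is the first principal component of all CA coordinates,
#' oriented along increasing rung order. Rise is the mean axial spacing of
#' consecutive rung CA centroids; twist is the mean rotation angle of the
#' optimal adjacent-rung superposition, signed by the sense of the rotation
#' about the axis (negative = left-handed).
#'
#' @param structure a [fold_structure] with >= 2 rungs of identical residue
#'   composition.
#' @return a [helical_params].
#' @export
estimate_helical_params <- function(structure) {
  stopifnot(inherits(structure, "fold_structure"))
  chains <- structure$chains
  if (length(chains) < 2L)
    stop("estimate_helical_params: need >= 2 rungs")
  resno0 <- chains[[1]]$resno
  for (ch in chains)
    if (!identical(ch$resno, resno0))
      stop("estimate_helical_params: rungs differ in residue composition")
  cents <- t(vapply(chains, function(ch) colMeans(ch$xyz$CA), numeric(3)))
  axis <- helical_axis(cents)
  proj <- as.vector(sweep(cents, 2, colMeans(cents)) %*% axis)
  if (stats::cor(proj, seq_along(proj)) < 0) { axis <- -axis; proj <- -proj }
  rise <- mean(diff(proj))
  angles <- numeric(length(chains) - 1L)
  for (k in seq_len(length(chains) - 1L)) {
    fit <- kabsch_superpose(chains[[k + 1L]]$xyz$CA, chains[[k]]$xyz$CA)
    R <- fit$R
    ct <- (sum(diag(R)) - 1) / 2
    ct <- min(1, max(-1, ct))
    ang <- acos(ct) * 180 / pi
    # rotation axis from the skew-symmetric part; sign along helical axis.
    # points are rows (p %*% R), so the matrix acting on column vectors is
    # t(R); take its axis.
    Rc <- t(R)
    v <- c(Rc[3, 2] - Rc[2, 3], Rc[1, 3] - Rc[3, 1], Rc[2, 1] - Rc[1, 2])
    s <- sum(v * axis)
    angles[k] <- if (s < 0) -ang else ang
  }
  twist <- mean(angles)
  if (abs(twist) < 1e-12)
    stop("estimate_helical_params: no measurable twist between rungs")
  helical_params(rise = rise, twist = twist)
}
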