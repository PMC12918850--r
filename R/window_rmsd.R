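# Core fold-comparison method: backbone RMSD between two filament folds
# over all contiguous sliding windows of increasing length, each window
# independently optimally superposed. Per-window superposition is essential:
# two folds can share a motif whose relative orientation is globally rotated,
# and only an independent rigid fit of each window reveals it. The mean over
# all admissible windows is the localized RMSD; the full matrix renders as a
# triangular heat-map, and localized RMSDs rank a query against a library.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of two paired point sets. Returns the proper
#' rotation (determinant +1; reflections are excluded so mirror-image folds
#' never score as similar), the translation, and the minimal RMSD. The
#' fitted coordinates are `Y %*% R + t` (points as rows). The minimum is
#' well defined even for degenerate (collinear or coincident) point sets,
#' where the rotation itself may not be unique.
#'
#' @param X,Y n x 3 coordinate matrices in paired row order, n >= 1.
#' @return list with elements `R` (3 x 3 rotation), `t` (length-3
#'   translation), `rmsd` (Angstrom), `fitted` (transformed `Y`).
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n == 0L) stop("kabsch_superpose: no points")
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L)
    stop("kabsch_superpose: X and Y must be equal-size n x 3 matrices")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Yc, Xc)              # 3x3 covariance, Y -> X
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  fitted <- Yc %*% R
  rmsd <- sqrt(sum((Xc - fitted)^2) / n)
  tvec <- cx - as.vector(cy %*% R)
  list(R = R, t = tvec, rmsd = rmsd,
       fitted = sweep(fitted, 2, cx, `+`))
}

# gather paired coordinates for pair rows `idx` of a correspondence,
# stacking the selected backbone atoms; rows where either side lacks the
# atom are dropped pairwise so the sets stay in register.
paired_coords <- function(chainA, chainB, corr, idx, atom_set) {
  Xs <- list(); Ys <- list()
  for (el in atom_set) {
    ma <- chainA$xyz[[el]]; mb <- chainB$xyz[[el]]
    if (is.null(ma) || is.null(mb)) next
    xa <- ma[corr$pairs[idx, 1], , drop = FALSE]
    xb <- mb[corr$pairs[idx, 2], , drop = FALSE]
    ok <- stats::complete.cases(xa) & stats::complete.cases(xb)
    Xs[[el]] <- xa[ok, , drop = FALSE]
    Ys[[el]] <- xb[ok, , drop = FALSE]
  }
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys))
}

#' All-window superposed RMSD matrix
#'
#' For every contiguous window of at least `min_window` aligned residues
#' lying wholly inside one correspondence segment, computes the backbone
#' RMSD after an independent optimal superposition of just that window's
#' paired atoms. Windows never span segment boundaries, so splicing gaps
#' and chain breaks bound them.
#'
#' @param chainA,chainB [residue_chain] objects.
#' @param corr a [residue_correspondence] between them; defaults to
#'   [correspond_by_numbering].
#' @param min_window smallest window length in residues (>= 3; 3 is the
#'   smallest window with a non-trivial rigid fit).
#' @param atom_set backbone atoms to compare; default `"CA"`.
#' @return an object of class `window_rmsd_matrix`: a data frame of windows
#'   (`start` pair index, `length`, `start_res`, `end_res`, `rmsd`) with
#'   attributes `min_window`, `atom_set`, `idA`, `idB`.
#' @export
window_rmsd_matrix <- function(chainA, chainB,
                               corr = correspond_by_numbering(chainA, chainB),
                               min_window = 3, atom_set = "CA") {
  stopifnot(inherits(corr, "residue_correspondence"))
  min_window <- as.integer(min_window)
  if (min_window < 3L) stop("window_rmsd_matrix: min_window must be >= 3")
  atom_set <- match.arg(atom_set, BACKBONE_ATOMS, several.ok = TRUE)
  rows <- list()
  for (seg in seq_len(max(corr$segment))) {
    sidx <- which(corr$segment == seg)
    L <- length(sidx)
    if (L < min_window) next
    for (start in seq_len(L - min_window + 1L)) {
      for (len in min_window:(L - start + 1L)) {
        idx <- sidx[start:(start + len - 1L)]
        pc <- paired_coords(chainA, chainB, corr, idx, atom_set)
        r <- kabsch_superpose(pc$X, pc$Y)$rmsd
        rows[[length(rows) + 1L]] <- c(idx[1], len, corr$resnoA[idx[1]],
                                       corr$resnoA[idx[len]], r)
      }
    }
  }
  if (length(rows) == 0L) {
    warning("window_rmsd_matrix: no segment reaches min_window = ",
            min_window, "; empty matrix")
    m <- data.frame(start = integer(), length = integer(),
                    start_res = integer(), end_res = integer(),
                    rmsd = numeric())
  } else {
    m <- as.data.frame(do.call(rbind, rows))
    names(m) <- c("start", "length", "start_res", "end_res", "rmsd")
  }
  structure(m, min_window = min_window, atom_set = atom_set,
            idA = chainA$chain_id, idB = chainB$chain_id,
            class = c("window_rmsd_matrix", "data.frame"))
}

#' Localized RMSD
#'
#' The summary statistic of the fold comparison: the unweighted arithmetic
#' mean of the per-window superposed RMSDs over all admissible windows.
#'
#' @param matrix a [window_rmsd_matrix].
#' @return mean RMSD in Angstrom.
#' @export
localized_rmsd <- function(matrix) {
  stopifnot(inherits(matrix, "window_rmsd_matrix"))
  if (nrow(matrix) == 0L) stop("localized_rmsd: no admissible windows")
  mean(matrix$rmsd)
}

#' RMSD over one named residue range
#'
#' Single-window RMSD after optimal superposition of exactly the closed
#' residue range `[start_res, end_res]` (canonical numbering of chain A),
#' which must be fully paired in the correspondence.
#'
#' @param chainA,chainB [residue_chain] objects.
#' @param corr a [residue_correspondence]; defaults to numbering mode.
#' @param start_res,end_res residue numbers bounding the range (inclusive).
#' @param atom_set backbone atoms to compare; default `"CA"`.
#' @return RMSD in Angstrom.
#' @export
region_rmsd <- function(chainA, chainB,
                        corr = correspond_by_numbering(chainA, chainB),
                        start_res, end_res, atom_set = "CA") {
  atom_set <- match.arg(atom_set, BACKBONE_ATOMS, several.ok = TRUE)
  want <- seq(start_res, end_res)
  idx <- match(want, corr$resnoA)
  if (anyNA(idx))
    stop("region_rmsd: residues not paired in correspondence: ",
         paste(want[is.na(idx)], collapse = ", "))
  pc <- paired_coords(chainA, chainB, corr, idx, atom_set)
  kabsch_superpose(pc$X, pc$Y)$rmsd
}

#' Rank a fold library against a query fold
#'
#' Computes the localized RMSD of the query rung against every member of a
#' fold library and orders members ascending (most similar first). Members
#' sharing no admissible window with the query are reported as incomparable
#' (`NA` score, ranked last), never silently dropped. Ties break by label.
#'
#' @param query a [residue_chain].
#' @param library named list of [residue_chain] objects (names are labels).
#' @param min_window,atom_set as in [window_rmsd_matrix].
#' @param mode `"numbering"` (default) or `"sequence"` correspondence.
#' @return data frame with columns `label`, `localized_rmsd`, `n_windows`,
#'   `comparable`, ordered by rank.
#' @export
rank_folds <- function(query, library, min_window = 3, atom_set = "CA",
                       mode = c("numbering", "sequence")) {
  mode <- match.arg(mode)
  if (length(library) == 0L) stop("rank_folds: empty library")
  labels <- names(library)
  if (is.null(labels) || any(labels == ""))
    stop("rank_folds: library members must be named")
  score_one <- function(member) {
    corr <- tryCatch(
      if (mode == "numbering") correspond_by_numbering(query, member)
      else correspond_by_sequence(query, member),
      error = function(e) NULL)
    if (is.null(corr)) return(c(NA_real_, 0))
    m <- withCallingHandlers(
      window_rmsd_matrix(query, member, corr, min_window, atom_set),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(m) == 0L) return(c(NA_real_, 0))
    c(localized_rmsd(m), nrow(m))
  }
  sc <- t(vapply(library, score_one, numeric(2)))
  out <- data.frame(label = labels, localized_rmsd = sc[, 1],
                    n_windows = as.integer(sc[, 2]),
                    comparable = !is.na(sc[, 1]),
                    stringsAsFactors = FALSE)
  out <- out[order(!out$comparable, out$localized_rmsd, out$label), ]
  rownames(out) <- NULL
  out
}

#' Export a window-RMSD matrix as TSV
#'
#' Columns `start_res`, `end_res`, `length`, `rmsd_A`.
#'
#' @param matrix a [window_rmsd_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmsd_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "window_rmsd_matrix"))
  df <- data.frame(start_res = matrix$start_res, end_res = matrix$end_res,
                   length = matrix$length, rmsd_A = matrix$rmsd)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise a fold comparison as JSON
#'
#' Writes the localized RMSD, optional per-motif region RMSDs, and the
#' comparison parameters.
#'
#' @param matrix a [window_rmsd_matrix].
#' @param path output path.
#' @param motifs optional named list of `c(start_res, end_res)` ranges whose
#'   single-window RMSDs are included (computed from the matrix when the
#'   exact window is present).
#' @return the summary list, invisibly.
#' @export
write_comparison_summary <- function(matrix, path, motifs = NULL) {
  stopifnot(inherits(matrix, "window_rmsd_matrix"))
  summ <- list(
    fold_a = attr(matrix, "idA"), fold_b = attr(matrix, "idB"),
    localized_rmsd = if (nrow(matrix)) mean(matrix$rmsd) else NA,
    n_windows = nrow(matrix),
    min_window = attr(matrix, "min_window"),
    atom_set = attr(matrix, "atom_set"))
  if (!is.null(motifs)) {
    summ$motifs <- lapply(motifs, function(rg) {
      hit <- matrix$start_res == rg[1] & matrix$end_res == rg[2]
      if (any(hit)) matrix$rmsd[which(hit)[1]] else NA
    })
  }
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(summ)
}

#' Render a triangular window-RMSD heat-map
#'
#' Horizontal axis: window start residue number; vertical axis: window
#' length in residues; colour: RMSD in Angstrom on a fixed viridis scale
#' from 0 to the matrix maximum (or `max_rmsd` if given), with a colour
#' bar. Unfilled cells are transparent. Writes both PNG and SVG next to
#' `out_path` (extension replaced).
#'
#' @param matrix a non-empty [window_rmsd_matrix].
#' @param out_path output path; `.png` and `.svg` siblings are written.
#' @param max_rmsd optional fixed colour-scale maximum (Angstrom).
#' @return character vector of the files written, invisibly.
#' @export
render_heatmap <- function(matrix, out_path, max_rmsd = NULL) {
  stopifnot(inherits(matrix, "window_rmsd_matrix"))
  if (nrow(matrix) == 0L)
    stop("render_heatmap: empty matrix, nothing to render")
  top <- if (is.null(max_rmsd)) max(matrix$rmsd, 1e-6) else max_rmsd
  df <- as.data.frame(matrix)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = start_res, y = length, fill = rmsd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(
      name = "RMSD (Å)", limits = c(0, top), oob = scales_squish) +
    ggplot2::labs(
      x = "window start (residue number)", y = "window length (residues)",
      title = sprintf("%s vs %s (atoms %s, min window %d)",
                      attr(matrix, "idA"), attr(matrix, "idB"),
                      paste(attr(matrix, "atom_set"), collapse = "+"),
                      attr(matrix, "min_window"))) +
    ggplot2::theme_minimal()
  base <- tools::file_path_sans_ext(out_path)
  files <- paste0(base, c(".png", ".svg"))
  ok <- tryCatch({
    ggplot2::ggsave(files[1], p, width = 7, height = 4.5, dpi = 150)
    ggplot2::ggsave(files[2], p, width = 7, height = 4.5,
                    device = grDevices::svg)
    TRUE
  }, error = function(e) stop("render_heatmap: cannot write '", out_path,
                              "': ", conditionMessage(e), call. = FALSE))
  invisible(files)
}

# clamp out-of-range values to the scale limits (avoids a hard scales dep)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}
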