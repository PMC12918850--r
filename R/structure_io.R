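# Coordinate I/O for filament models: read deposited PDB/mmCIF files,
# extract single protofilament rungs as ordered backbone chains, and write
# structures back out (needed to emit synthetic filaments).

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a residue chain
#'
#' A `residue_chain` is one protofilament rung: an ordered run of residues
#' with canonical residue numbering (2N4R tau numbering for tau
#' depositions), one-letter amino-acid identities, and backbone coordinates
#' in Angstrom. The CA coordinate is mandatory for every residue; N, C and
#' O may be absent (`NA` rows).
#'
#' @param chain_id single character chain identifier.
#' @param resno integer vector of residue numbers, strictly increasing.
#' @param aa character vector of one-letter amino-acid codes.
#' @param xyz named list of n x 3 numeric matrices, one per backbone atom
#'   name in `c("N", "CA", "C", "O")`. `CA` is required and must be finite
#'   everywhere; other atoms may be missing entirely or contain `NA` rows.
#' @return an object of class `residue_chain`.
#' @export
residue_chain <- function(chain_id, resno, aa, xyz) {
  stopifnot(is.character(chain_id), length(chain_id) == 1L)
  resno <- as.integer(resno)
  n <- length(resno)
  if (n == 0L) stop("residue_chain: chain '", chain_id, "' has no residues")
  if (any(diff(resno) <= 0L))
    stop("residue_chain: residue numbers must be strictly increasing")
  if (length(aa) != n) stop("residue_chain: aa/resno length mismatch")
  if (!is.list(xyz) || is.null(xyz$CA))
    stop("residue_chain: xyz must be a list with a CA matrix")
  xyz <- xyz[intersect(BACKBONE_ATOMS, names(xyz))]
  xyz <- lapply(xyz, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (nrow(m) != n || ncol(m) != 3L)
      stop("residue_chain: coordinate matrix must be n x 3")
    dimnames(m) <- NULL
    m
  })
  if (anyNA(xyz$CA) || any(!is.finite(xyz$CA)))
    stop("residue_chain: every residue needs a finite CA coordinate")
  structure(
    list(chain_id = chain_id, resno = resno, aa = as.character(aa), xyz = xyz),
    class = "residue_chain"
  )
}

#' @export
print.residue_chain <- function(x, ...) {
  cat(sprintf("<residue_chain> chain %s: %d residues (%d-%d), atoms: %s\n",
              x$chain_id, length(x$resno), min(x$resno), max(x$resno),
              paste(names(x$xyz), collapse = ",")))
  invisible(x)
}

#' @export
length.residue_chain <- function(x) length(x$resno)

#' Construct a fold structure
#'
#' A `fold_structure` holds one filament model: an identifier, an ordered
#' set of chains (rungs), and a record of where it came from. Chain ids
#' must be unique and at least one chain is required.
#'
#' @param id character label for the fold.
#' @param chains list of [residue_chain] objects.
#' @param source optional list recording `path` and `format`.
#' @return an object of class `fold_structure`.
#' @export
fold_structure <- function(id, chains, source = NULL) {
  if (length(chains) == 0L) stop("fold_structure: at least one chain required")
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(ids)) stop("fold_structure: chain ids must be unique")
  names(chains) <- ids
  structure(list(id = id, chains = chains, source = source),
            class = "fold_structure")
}

#' @export
print.fold_structure <- function(x, ...) {
  cat(sprintf("<fold_structure> %s: %d chain(s) [%s]\n", x$id,
              length(x$chains), paste(names(x$chains), collapse = ",")))
  invisible(x)
}

#' Read a filament coordinate file
#'
#' Reads a PDB or mmCIF file and returns all polymer chains with their
#' backbone atoms (N, CA, C, O). Heteroatoms and non-backbone atoms are
#' ignored. Residue numbers are taken verbatim from the file; deposited tau
#' models use canonical 2N4R numbering and no renumbering is ever applied.
#' Altloc records keep only the highest-occupancy conformer; insertion
#' codes are rejected (never present in filament depositions). A chain
#' without any CA atom is dropped with a warning.
#'
#' @param path path to the coordinate file.
#' @param format one of `"auto"`, `"pdb"`, `"mmcif"`. `"auto"` resolves by
#'   file extension (`.cif`/`.mmcif` vs anything else).
#' @param id label for the returned structure; defaults to the file stem.
#' @return a [fold_structure].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  obj <- withCallingHandlers(
    tryCatch(
      if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE,
                                             rm.alt = FALSE)
      else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
      error = function(e) stop("read_structure: cannot parse '", path,
                               "' as ", format, ": ", conditionMessage(e),
                               call. = FALSE)
    ),
    warning = function(w) {
      if (grepl("beta version|helix/sheet", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  atom <- obj$atom
  atom <- atom[atom$type == "ATOM" & atom$elety %in% BACKBONE_ATOMS, ,
               drop = FALSE]
  if (nrow(atom) == 0L)
    stop("read_structure: no polymer backbone atoms in ", path)
  ins <- atom$insert
  if (!is.null(ins) && any(!is.na(ins) & ins != ""))
    stop("read_structure: insertion codes are not supported")
  # altlocs: keep the highest-occupancy conformer per (chain, resno, atom)
  alt <- atom$alt
  if (!is.null(alt) && any(!is.na(alt) & alt != "")) {
    occ <- atom$o
    occ[is.na(occ)] <- 1
    key <- paste(atom$chain, atom$resno, atom$elety)
    keep <- unlist(lapply(split(seq_len(nrow(atom)), key), function(i) {
      i[which.max(occ[i])]
    }), use.names = FALSE)
    atom <- atom[sort(keep), , drop = FALSE]
  }
  chains <- list()
  for (ch in unique(atom$chain)) {
    a <- atom[atom$chain == ch, , drop = FALSE]
    resno <- sort(unique(a$resno))
    xyz <- lapply(BACKBONE_ATOMS, function(el) {
      m <- matrix(NA_real_, length(resno), 3L)
      b <- a[a$elety == el, , drop = FALSE]
      idx <- match(b$resno, resno)
      m[idx, ] <- cbind(b$x, b$y, b$z)
      m
    })
    names(xyz) <- BACKBONE_ATOMS
    if (all(is.na(xyz$CA))) {
      warning("read_structure: chain '", ch, "' has no CA atoms; omitted")
      next
    }
    if (anyNA(xyz$CA)) {
      # residues without CA cannot anchor a comparison; drop those rows
      ok <- !is.na(xyz$CA[, 1])
      resno <- resno[ok]
      xyz <- lapply(xyz, function(m) m[ok, , drop = FALSE])
    }
    aa <- a$resid[a$elety == "CA"][match(resno, a$resno[a$elety == "CA"])]
    aa1 <- suppressWarnings(bio3d::aa321(aa))
    aa1[is.na(aa1)] <- "X"
    xyz <- xyz[vapply(xyz, function(m) !all(is.na(m)), logical(1))]
    chains[[length(chains) + 1L]] <-
      residue_chain(ch, resno, aa1, xyz)
  }
  if (length(chains) == 0L)
    stop("read_structure: no usable chains in ", path)
  fold_structure(id, chains, source = list(path = path, format = format))
}

#' Select a single protofilament rung
#'
#' Filament fold comparisons operate on one rung of one protofilament.
#' With `chain = "auto"` the rung least affected by end effects is chosen:
#' the chain whose CA centroid projection onto the principal (helical) axis
#' of all CA atoms lies closest to the median projection. The principal
#' axis is the first principal component of all CA coordinates.
#'
#' @param structure a [fold_structure].
#' @param chain a chain id, or `"auto"` (default) for the central rung.
#' @return a [residue_chain].
#' @export
select_rung <- function(structure, chain = "auto") {
  stopifnot(inherits(structure, "fold_structure"))
  chains <- structure$chains
  if (!identical(chain, "auto")) {
    if (!chain %in% names(chains))
      stop("select_rung: chain '", chain, "' not found; available: ",
           paste(names(chains), collapse = ", "))
    return(chains[[chain]])
  }
  if (length(chains) == 1L) return(chains[[1L]])
  cents <- t(vapply(chains, function(ch) colMeans(ch$xyz$CA), numeric(3)))
  axis <- helical_axis(cents)
  ctr <- colMeans(cents)
  proj <- as.vector(sweep(cents, 2, ctr) %*% axis)
  med <- stats::median(proj)
  chains[[which.min(abs(proj - med))]]
}

# principal (helical) axis: first principal component of the per-rung CA
# centroids. The centroids trace the stacking direction, whereas a single
# rung's own extent can exceed the stack height and mislead an all-atom PC.
helical_axis <- function(cents) {
  svd(sweep(cents, 2, colMeans(cents)))$v[, 1]
}

#' Write a filament coordinate file
#'
#' Writes a [fold_structure] as PDB or mmCIF. Round-tripping through
#' [read_structure] reproduces residue numbering, chain ids and amino-acid
#' identities exactly, and coordinates to within 1e-3 Angstrom (the format's
#' printed precision).
#'
#' @param structure a [fold_structure].
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("pdb", "mmcif")) {
  stopifnot(inherits(structure, "fold_structure"))
  format <- match.arg(format)
  rows <- flatten_atoms(structure)
  ok <- tryCatch({
    if (format == "pdb") {
      bio3d::write.pdb(file = path,
                       xyz = as.vector(t(as.matrix(rows[, c("x", "y", "z")]))),
                       resno = rows$resno, resid = rows$resid,
                       eleno = seq_len(nrow(rows)), elety = rows$elety,
                       chain = rows$chain, o = rep(1, nrow(rows)),
                       b = rep(0, nrow(rows)))
    } else {
      write_mmcif(structure$id, rows, path)
    }
    TRUE
  }, error = function(e) {
    stop("write_structure: cannot write '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

# one row per atom, chains in order
flatten_atoms <- function(structure) {
  do.call(rbind, lapply(structure$chains, function(ch) {
    aa3 <- suppressWarnings(bio3d::aa123(ch$aa))
    aa3[is.na(aa3)] <- "UNK"
    do.call(rbind, lapply(names(ch$xyz), function(el) {
      m <- ch$xyz[[el]]
      ok <- stats::complete.cases(m)
      if (!any(ok)) return(NULL)
      data.frame(chain = ch$chain_id, resno = ch$resno[ok], resid = aa3[ok],
                 elety = el, x = m[ok, 1], y = m[ok, 2], z = m[ok, 3],
                 stringsAsFactors = FALSE)
    }))
  })) |> sort_atom_rows()
}

sort_atom_rows <- function(rows) {
  atom_rank <- match(rows$elety, BACKBONE_ATOMS)
  rows[order(match(rows$chain, unique(rows$chain)), rows$resno, atom_rank), ,
       drop = FALSE]
}

# minimal mmCIF atom_site writer (coordinates to 0.001 A)
write_mmcif <- function(id, rows, path) {
  elem <- substr(rows$elety, 1, 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_", id)),
    "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"), con)
  lines <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
    seq_len(nrow(rows)), elem, rows$elety, rows$resid, rows$chain,
    rows$resno, rows$x, rows$y, rows$z, rows$resno, rows$resid,
    rows$chain, rows$elety)
  writeLines(lines, con)
  writeLines("#", con)
  invisible(path)
}
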