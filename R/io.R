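# Readers and writers: the native tabular configuration format (CSV +
# JSON sidecar), PDB (atoms via bio3d, CRYST1 box parsed directly since
# bio3d discards it), and GRO (fixed-width, nm converted to Angstrom on
# read).  Trajectory containers DCD/XTC are not supported; multi-model
# PDB or multi-frame CSV carry multiple frames.

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   F = 18.998, NA. = 22.990, MG = 24.305, P = 30.974,
                   S = 32.06, CL = 35.45, K = 39.098, CA = 40.078,
                   FE = 55.845, ZN = 65.38, BR = 79.904, I = 126.904)

# Minimal element -> mass lookup from an atom/element name.
mass_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", trimws(name)))
  two <- substr(nm, 1, 2)
  two[two == "NA"] <- "NA."
  one <- substr(nm, 1, 1)
  m <- ATOMIC_MASSES[two]
  m[is.na(m)] <- ATOMIC_MASSES[one[is.na(m)]]
  if (any(is.na(m)))
    stop("cannot infer atomic mass for atom name(s): ",
         paste(unique(name[is.na(m)]), collapse = ", "))
  unname(m)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a trajectory to the tabular configuration format
#'
#' One CSV row per atom (`frame, molecule_id, atom_index, x, y, z,
#' mass`) plus a JSON sidecar (same path with `.json` extension)
#' holding the box, optional seed/spec provenance, and any head/tail
#' axis conventions.
#'
#' @param traj a [trajectory()] or [configuration()].
#' @param path output CSV path.
#' @param seed optional integer recorded in the sidecar.
#' @param spec optional [generator_spec()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_configuration_csv <- function(traj, path, seed = NULL, spec = NULL) {
  traj <- trajectory(traj)
  rows <- list()
  head_tail <- list()
  for (f in seq_along(traj)) {
    for (m in traj[[f]]$molecules) {
      n <- nrow(m$xyz)
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, molecule_id = m$id, atom_index = seq_len(n),
        x = m$xyz[, 1], y = m$xyz[, 2], z = m$xyz[, 3], mass = m$masses)
      if (f == 1 && !is.null(m$head))
        head_tail[[m$id]] <- c(m$head, m$tail)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  meta <- list(box = as.numeric(unclass(traj[[1]]$box)),
               frames = length(traj), units = "angstrom")
  if (!is.null(seed)) meta$seed <- seed
  if (length(head_tail)) meta$head_tail <- head_tail
  if (!is.null(spec)) {
    s <- unclass(spec)
    s$box <- as.numeric(unclass(s$box))
    meta$generator_spec <- s
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a tabular-configuration CSV (with its JSON sidecar)
#'
#' @param path CSV path written by [write_configuration_csv()]; the
#'   sidecar `<path>.json` must exist (it carries the box).
#' @return a [trajectory()].
#' @export
read_configuration_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing JSON sidecar ", sp, " (carries the periodic box)")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$box)) stop("sidecar ", sp, " has no box entry")
  b <- as_box(meta$box)
  d <- utils::read.csv(path)
  need <- c("frame", "molecule_id", "atom_index", "x", "y", "z", "mass")
  if (!all(need %in% names(d)))
    stop("configuration CSV must have columns ",
         paste(need, collapse = ", "))
  frames <- lapply(sort(unique(d$frame)), function(f) {
    df <- d[d$frame == f, ]
    ids <- unique(df$molecule_id)
    mols <- lapply(ids, function(id) {
      dm <- df[df$molecule_id == id, ]
      dm <- dm[order(dm$atom_index), ]
      ht <- meta$head_tail[[as.character(id)]]
      molecule(id, cbind(dm$x, dm$y, dm$z), masses = dm$mass,
               head = if (!is.null(ht)) ht[1] else NULL,
               tail = if (!is.null(ht)) ht[2] else NULL)
    })
    configuration(mols, b, frame_index = f)
  })
  trajectory(frames)
}

#' Write a trajectory to PDB with a CRYST1 box record
#'
#' Minimal writer: CRYST1 with the orthorhombic cell, one MODEL per
#' frame, carbon-like atoms.  Molecule identity is carried by the
#' residue number; `resname` labels the dye species for selection on
#' re-read.
#'
#' @param traj a [trajectory()] or [configuration()].
#' @param path output PDB path.
#' @param resname 1-3 character residue name (default `"ICG"`).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(traj, path, resname = "ICG") {
  traj <- trajectory(traj)
  b <- unclass(traj[[1]]$box)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    b[1], b[2], b[3], 90, 90, 90), con)
  for (f in seq_along(traj)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    for (mi in seq_along(traj[[f]]$molecules)) {
      m <- traj[[f]]$molecules[[mi]]
      for (a in seq_len(nrow(m$xyz))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d  C%-2d %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, a, substr(resname, 1, 3), mi,
          m$xyz[a, 1], m$xyz[a, 2], m$xyz[a, 3], 1, 0), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Parse the CRYST1 record of a PDB file; error if absent or triclinic.
read_pdb_box <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- lines[startsWith(lines, "CRYST1")]
  if (length(cl) == 0)
    stop("PDB file ", path, " has no CRYST1 record: the periodic cell ",
         "is missing")
  v <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                    substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                    substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
  if (any(abs(v[4:6] - 90) > 1e-3))
    stop("triclinic cells are unsupported (angles ",
         paste(v[4:6], collapse = ", "), "); only orthorhombic boxes")
  box(v[1], v[2], v[3])
}

read_structure_pdb <- function(path, selection = NULL) {
  b <- read_pdb_box(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- if (is.null(selection)) rep(TRUE, nrow(at))
          else trimws(at$resid) == selection
  if (!any(keep))
    stop("selection '", selection, "' matches no atoms in ", path,
         " (residue names present: ",
         paste(unique(trimws(at$resid)), collapse = ", "), ")")
  ele <- at$elesy
  names_for_mass <- ifelse(is.na(ele) | trimws(ele) == "",
                           at$elety, trimws(ele))
  masses <- mass_from_name(names_for_mass[keep])
  molkey <- paste(at$chain, at$resno, sep = ":")[keep]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  atom_sel <- which(keep)
  frames <- lapply(seq_len(nrow(xyz)), function(f) {
    coords <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)[atom_sel, , drop = FALSE]
    ids <- unique(molkey)
    mols <- lapply(seq_along(ids), function(i) {
      rowsel <- molkey == ids[i]
      molecule(paste0("M", i), coords[rowsel, , drop = FALSE],
               masses = masses[rowsel])
    })
    configuration(mols, b, frame_index = f)
  })
  trajectory(frames)
}

read_structure_gro <- function(path, selection = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("truncated GRO file: ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stop("cannot parse atom count from GRO file ", path)
  if (length(lines) < nat + 3) stop("GRO file shorter than its atom count")
  al <- lines[3:(2 + nat)]
  resno <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  atomname <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28)) * 10
  y <- as.numeric(substr(al, 29, 36)) * 10
  z <- as.numeric(substr(al, 37, 44)) * 10
  bv <- as.numeric(strsplit(trimws(lines[nat + 3]), "\\s+")[[1]])
  if (length(bv) >= 9 && any(abs(bv[4:9]) > 1e-9))
    stop("triclinic GRO cells are unsupported; only orthorhombic boxes")
  b <- box(bv[1] * 10, bv[2] * 10, bv[3] * 10)
  keep <- if (is.null(selection)) rep(TRUE, nat) else resname == selection
  if (!any(keep))
    stop("selection '", selection, "' matches no atoms in ", path,
         " (residue names present: ",
         paste(unique(resname), collapse = ", "), ")")
  masses <- mass_from_name(atomname[keep])
  molkey <- resno[keep]
  ids <- unique(molkey)
  coords <- cbind(x, y, z)[keep, , drop = FALSE]
  mols <- lapply(seq_along(ids), function(i) {
    rowsel <- molkey == ids[i]
    molecule(paste0("M", i), coords[rowsel, , drop = FALSE],
             masses = masses[rowsel])
  })
  trajectory(configuration(mols, b))
}

#' Read molecular configurations from a structure file
#'
#' Dispatches on the file extension: `.pdb` (atoms via bio3d, CRYST1
#' box required; multi-model files yield multi-frame trajectories),
#' `.gro` (fixed-width, nm converted to Angstrom), or `.csv` (the
#' native tabular format with JSON sidecar).
#'
#' @param path structure file.
#' @param selection optional residue-name filter for the dye species
#'   (e.g. `"ICG"`); ignored for CSV input.
#' @param expect_n optional molecule-count assertion, to catch topology
#'   or selection mistakes.
#' @return a [trajectory()].
#' @export
read_structure <- function(path, selection = NULL, expect_n = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  traj <- switch(ext,
    pdb = read_structure_pdb(path, selection),
    gro = read_structure_gro(path, selection),
    csv = read_configuration_csv(path),
    stop("unsupported structure format '.", ext,
         "': use PDB, GRO or the tabular CSV format"))
  if (!is.null(expect_n)) {
    got <- length(traj[[1]]$molecules)
    if (got != expect_n)
      stop("expected ", expect_n, " molecules but selection yields ", got)
  }
  traj
}

#' Read a trajectory: structure plus optional trajectory file
#'
#' @param structure_path PDB, GRO or CSV file (see [read_structure()]).
#' @param trajectory_path optional separate trajectory container.
#'   Binary containers (DCD, XTC) are not supported; supply frames as a
#'   multi-model PDB or multi-frame CSV instead.
#' @inheritParams read_structure
#' @return a [trajectory()].
#' @export
read_trajectory <- function(structure_path, trajectory_path = NULL,
                            selection = NULL, expect_n = NULL) {
  if (!is.null(trajectory_path)) {
    ext <- tolower(tools::file_ext(trajectory_path))
    if (ext %in% c("dcd", "xtc"))
      stop("binary trajectory containers (.", ext, ") are unsupported; ",
           "supply frames as a multi-model PDB or multi-frame CSV")
    stop("unsupported trajectory format '.", ext, "'")
  }
  read_structure(structure_path, selection, expect_n)
}
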