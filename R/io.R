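# Readers and writers: extended XYZ (multi-frame), a PDB subset
# (ATOM/HETATM/CRYST1/CONECT), and the YAML/JSON topology sidecar that
# carries what neither format does (charges, LJ parameters, bonds, groups).

#' Read a topology sidecar (YAML or JSON)
#'
#' The sidecar supplies per-atom `charges`, `lj_epsilon`, `lj_rmin` (or
#' `lj_sigma`, converted as `rmin = 2^(1/6) sigma`), `masses`, a `bonds`
#' list of 1-based pairs, a `box` (3x3 row-major or 3 edge lengths), and
#' named `groups`.
#'
#' @param path file path; extension decides the parser (.json vs YAML).
#' @return named list of topology fields.
#' @export
read_topology <- function(path) {
  top <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(top$lj_sigma) && is.null(top$lj_rmin))
    top$lj_rmin <- 2^(1 / 6) * as.numeric(top$lj_sigma)
  if (!is.null(top$box)) top$box <- as_box(top$box)
  if (!is.null(top$bonds)) {
    top$bonds <- matrix(as.integer(unlist(top$bonds)), ncol = 2L,
                        byrow = is.list(top$bonds))
  }
  top
}

as_box <- function(b) {
  b <- as.numeric(unlist(b))
  if (length(b) == 3L) return(diag(b))
  if (length(b) == 9L) return(matrix(b, 3L, 3L, byrow = TRUE))
  stop("box must be 3 edge lengths or 9 lattice-vector components")
}

apply_topology <- function(config, top) {
  if (is.null(top)) return(config)
  n <- n_atoms(config)
  grab <- function(x) if (is.null(x)) NULL else as.numeric(x)
  configuration(
    positions = config$positions, elements = config$elements,
    masses = grab(top$masses) %||% config$masses,
    charges = grab(top$charges) %||% config$charges,
    lj_epsilon = grab(top$lj_epsilon) %||% config$lj_epsilon,
    lj_rmin = grab(top$lj_rmin) %||% config$lj_rmin,
    bonds = if (!is.null(top$bonds)) rbind(config$bonds, top$bonds) else config$bonds,
    box = config$box %||% top$box,
    groups = if (!is.null(top$groups)) lapply(top$groups, as.integer) else config$groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a (multi-frame, extended) XYZ file
#'
#' Per-frame comment lines may carry `Lattice="ax ay az bx by bz cx cy cz"`
#' (extended-XYZ convention, row-major lattice vectors). A topology sidecar
#' supplies charges, LJ parameters, bonds, masses, groups and — when the
#' file has no Lattice — the box.
#'
#' @param path XYZ file path.
#' @param topology path to a sidecar file, or a list from
#'   [read_topology()], or NULL.
#' @return An `fk_traj` (possibly single-frame).
#' @export
read_xyz <- function(path, topology = NULL) {
  if (is.character(topology)) topology <- read_topology(topology)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  frames <- list()
  pos <- 1L
  n_ref <- NA_integer_
  while (pos <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[pos]))
      stop(sprintf("malformed atom count at line %d of %s", pos, path))
    n <- as.integer(lines[pos])
    if (!is.na(n_ref) && n != n_ref)
      stop(sprintf("inconsistent atom count (%d vs %d) at line %d", n, n_ref, pos))
    n_ref <- n
    if (pos + 1L + n > length(lines))
      stop(sprintf("truncated frame starting at line %d", pos))
    comment <- lines[pos + 1L]
    box <- parse_lattice(comment)
    block <- lines[pos + 1L + seq_len(n)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(toks) < 4L)
    if (length(bad))
      stop(sprintf("malformed atom record at line %d", pos + 1L + bad[1L]))
    el <- vapply(toks, `[[`, "", 1L)
    xyz <- matrix(as.numeric(vapply(toks, function(t) t[2:4], character(3L))),
                  ncol = 3L, byrow = TRUE)
    cfg <- configuration(xyz, el, box = box)
    frames[[length(frames) + 1L]] <- apply_topology(cfg, topology)
    pos <- pos + 2L + n
  }
  if (!length(frames)) stop(sprintf("no frames in %s", path))
  trajectory(frames)
}

parse_lattice <- function(comment) {
  m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (!length(m)) return(NULL)
  v <- as.numeric(strsplit(trimws(gsub('Lattice="|"', "", m)), "\\s+")[[1L]])
  if (length(v) != 9L) stop("Lattice= must contain 9 numbers")
  matrix(v, 3L, 3L, byrow = TRUE)
}

#' Write a trajectory or configuration as extended XYZ
#'
#' @param x an `fk_config` or `fk_traj`.
#' @param path output path.
#' @param digits coordinate precision (default 12 significant digits, ample
#'   for 1e-9 Angstrom round trips).
#' @export
write_xyz <- function(x, path, digits = 12L) {
  frames <- if (inherits(x, "fk_traj")) x$frames else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    comment <- if (is.null(f$box)) "" else
      sprintf('Lattice="%s"', paste(format(t(f$box), digits = 15L,
                                           scientific = FALSE, trim = TRUE),
                                    collapse = " "))
    writeLines(as.character(n_atoms(f)), con)
    writeLines(comment, con)
    writeLines(sprintf("%s %.*g %.*g %.*g", f$elements,
                       digits, f$positions[, 1L],
                       digits, f$positions[, 2L],
                       digits, f$positions[, 3L]), con)
  }
  invisible(path)
}

#' Read a PDB subset (ATOM/HETATM, CRYST1, CONECT)
#'
#' Only those record types are honoured. CRYST1 cell parameters are
#' converted to lattice vectors (a along x, b in the xy plane); CONECT
#' records are merged into the bond list. A sidecar box is used only when
#' the file has no CRYST1.
#'
#' @param path PDB file path.
#' @param topology sidecar path or list, as in [read_xyz()].
#' @return An `fk_config`.
#' @export
read_pdb_subset <- function(path, topology = NULL) {
  if (is.character(topology)) topology <- read_topology(topology)
  lines <- readLines(path)
  rec <- substr(lines, 1L, 6L)
  at <- lines[trimws(rec) %in% c("ATOM", "HETATM")]
  if (!length(at)) stop(sprintf("no ATOM/HETATM records in %s", path))
  xyz <- cbind(as.numeric(substr(at, 31L, 38L)),
               as.numeric(substr(at, 39L, 46L)),
               as.numeric(substr(at, 47L, 54L)))
  if (any(is.na(xyz))) stop("missing or unparsable coordinates in ATOM record")
  serial <- as.integer(substr(at, 7L, 11L))
  el <- trimws(substr(at, 77L, 78L))
  # fall back on the first letter of the atom name when columns 77-78 are blank
  blank <- el == ""
  el[blank] <- gsub("[^A-Za-z].*", "", trimws(substr(at[blank], 13L, 16L)))
  box <- NULL
  cry <- lines[trimws(rec) == "CRYST1"]
  if (length(cry)) {
    p <- as.numeric(c(substr(cry[1L], 7L, 15L), substr(cry[1L], 16L, 24L),
                      substr(cry[1L], 25L, 33L), substr(cry[1L], 34L, 40L),
                      substr(cry[1L], 41L, 47L), substr(cry[1L], 48L, 54L)))
    box <- cell_to_lattice(p[1L], p[2L], p[3L], p[4L], p[5L], p[6L])
  }
  bonds <- matrix(integer(0), ncol = 2L)
  con <- lines[trimws(rec) == "CONECT"]
  idx_of <- match(seq_len(max(serial)), serial)
  for (cl in con) {
    f <- as.integer(strsplit(trimws(substr(cl, 7L, nchar(cl))), "\\s+")[[1L]])
    f <- idx_of[f]
    if (length(f) >= 2L && !any(is.na(f)))
      bonds <- rbind(bonds, cbind(f[1L], f[-1L]))
  }
  cfg <- configuration(xyz, el, bonds = bonds, box = box)
  apply_topology(cfg, topology)
}

cell_to_lattice <- function(a, b, c, alpha, beta, gamma) {
  ar <- alpha * pi / 180; br <- beta * pi / 180; gr <- gamma * pi / 180
  bx <- b * cos(gr); by <- b * sin(gr)
  cx <- c * cos(br)
  cy <- c * (cos(ar) - cos(br) * cos(gr)) / sin(gr)
  cz <- sqrt(pmax(c^2 - cx^2 - cy^2, 0))
  rbind(c(a, 0, 0), c(bx, by, 0), c(cx, cy, cz))
}
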