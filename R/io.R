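#' Read and write the plain-text trajectory fixture format
#'
#' The package's native trajectory format is a self-describing text file:
#' a header (`MEMTRAJ 1`, units, box lengths and periodicity, species table,
#' particle table) followed by one `FRAME <time>` block per frame with one
#' `x y theta` line per particle in particle-table order. Numbers are
#' written with 17 significant digits so a save/load round trip is
#' bit-exact.
#'
#' @param traj A `mem_trajectory`.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `mem_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  a <- traj_arrays(wrap_trajectory(traj))
  sp <- trajectory_species_table(traj)
  sp <- sp[sp$species %in% unique(a$species), , drop = FALSE]
  num <- function(v) sprintf("%.17g", v)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(...), con)
  wl("MEMTRAJ 1")
  wl("UNITS length=nm time=us angle=rad")
  wl("BOX", paste(num(a$box$lengths), collapse = " "))
  wl("PERIODIC", paste(a$box$periodic, collapse = " "))
  wl("SPECIES", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    row <- vapply(sp[i, ], function(z) ifelse(is.na(z), "NA", as.character(z)), "")
    wl(paste(row, collapse = " "))
  }
  np <- nrow(a$x)
  wl("PARTICLES", np)
  for (i in seq_len(np)) wl(a$ids[i], a$species[i])
  wl("FRAMES", ncol(a$x))
  for (f in seq_len(ncol(a$x))) {
    wl("FRAME", num(a$times[f]))
    th <- ifelse(is.na(a$theta[, f]), "NA", num(a$theta[, f]))
    writeLines(paste(num(a$x[, f]), num(a$y[, f]), th), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  i <- 1L
  fail <- function(msg) abort(sprintf("Parse error at line %d of %s: %s", i, path, msg))
  expect_tok <- function(key) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!identical(tok[1], key)) fail(paste0("expected '", key, "'"))
    tok[-1]
  }
  hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
  if (!identical(hdr, c("MEMTRAJ", "1"))) fail("not a MEMTRAJ v1 file")
  i <- i + 1L # UNITS line, informational
  expect_tok("UNITS")
  i <- i + 1L
  lens <- as.numeric(expect_tok("BOX"))
  i <- i + 1L
  per <- as.logical(expect_tok("PERIODIC"))
  i <- i + 1L
  box <- box_spec(lens, per)
  nsp <- as.integer(expect_tok("SPECIES"))
  sp_rows <- lapply(seq_len(nsp), function(k) {
    tok <- strsplit(trimws(lines[i + k]), "\\s+")[[1]]
    if (length(tok) != 6) {
      i <<- i + k
      fail("species row must have 6 fields")
    }
    tok[tok == "NA"] <- NA
    tok
  })
  i <- i + nsp + 1L
  sp <- species_registry()
  if (nsp > 0) {
    m <- do.call(rbind, sp_rows)
    file_sp <- tibble(species = m[, 1], role = m[, 2], tail_1 = m[, 3],
                      tail_2 = m[, 4], sat_1 = m[, 5], sat_2 = m[, 6])
    sp <- bind_rows(file_sp, sp[!sp$species %in% file_sp$species, ])
  }
  np <- as.integer(expect_tok("PARTICLES"))
  ptok <- strsplit(trimws(lines[i + seq_len(np)]), "\\s+")
  ids <- vapply(ptok, function(t) as.integer(t[1]), 1L)
  pspecies <- vapply(ptok, function(t) t[2], "")
  i <- i + np + 1L
  nf <- as.integer(expect_tok("FRAMES"))
  i <- i + 1L
  times <- numeric(nf)
  X <- matrix(NA_real_, np, nf); Y <- X; TH <- X
  for (f in seq_len(nf)) {
    times[f] <- as.numeric(expect_tok("FRAME"))
    if (is.na(times[f])) fail("FRAME time not numeric")
    block <- lines[i + seq_len(np)]
    if (anyNA(block)) fail("truncated frame block")
    ctok <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(ctok) != 3)
    if (length(bad)) {
      i <- i + bad[1]
      fail("coordinate row must have 3 fields (x y theta)")
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(ctok))), ncol = 3, byrow = TRUE)
    X[, f] <- m[, 1]; Y[, f] <- m[, 2]; TH[, f] <- m[, 3]
    if (anyNA(X[, f]) || anyNA(Y[, f])) fail("non-numeric coordinate")
    i <- i + np + 1L
  }
  a <- list(ids = ids, species = pspecies,
            role = {
              r <- species_role(pspecies, sp)
              r[is.na(r)] <- "unknown"
              r
            },
            times = times, x = X, y = Y, theta = TH, box = box)
  out <- arrays_to_traj(a, species_table = sp, validate = FALSE)
  validate_trajectory(out)
  out
}

#' Load a trajectory from native or standard MD formats
#'
#' @param path Path to a MEMTRAJ fixture file, or to a PDB topology when
#'   `format = "pdb_dcd"`.
#' @param format `"auto"` (by extension), `"memtraj"`, or `"pdb_dcd"`.
#' @param dcd Path to the DCD coordinate file (required for `"pdb_dcd"`).
#' @param box A [box_spec()] for formats that do not carry one (PDB/DCD
#'   coordinates are converted from Angstrom to nm).
#' @param dt Frame spacing in us for formats without a time axis.
#' @param species_map Named character vector mapping residue names to
#'   registry species for PDB input; unmapped residues keep their residue
#'   name with role `"unknown"`.
#' @return A `mem_trajectory`.
#' @export
load_trajectory <- function(path, format = c("auto", "memtraj", "pdb_dcd"),
                            dcd = NULL, box = NULL, dt = 1,
                            species_map = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb_dcd" else "memtraj"
  }
  if (format == "memtraj") return(read_trajectory(path))
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("Reading PDB/DCD requires the bio3d package.")
  }
  if (is.null(dcd)) abort("`dcd` path is required for pdb_dcd input.")
  if (is.null(box)) abort("`box` must be supplied for pdb_dcd input.")
  pdb <- bio3d::read.pdb(path)
  coords <- bio3d::read.dcd(dcd, verbose = FALSE)
  nat <- nrow(pdb$atom)
  resnames <- pdb$atom$resid
  species <- if (is.null(species_map)) resnames else {
    out <- unname(species_map[resnames])
    out[is.na(out)] <- resnames[is.na(out)]
    out
  }
  reg <- species_registry()
  role <- species_role(species, reg)
  role[is.na(role)] <- "unknown"
  nf <- nrow(coords)
  xi <- seq(1, 3 * nat, by = 3)
  df <- tibble(
    frame = rep(seq_len(nf) - 1L, each = nat),
    time = rep((seq_len(nf) - 1) * dt, each = nat),
    id = rep(seq_len(nat), nf),
    species = rep(species, nf),
    role = rep(role, nf),
    x = as.vector(t(coords[, xi, drop = FALSE])) / 10,
    y = as.vector(t(coords[, xi + 1, drop = FALSE])) / 10,
    theta = NA_real_
  )
  df$x <- wrap_coord(df$x, box$lengths[1])
  df$y <- wrap_coord(df$y, box$lengths[2])
  as_trajectory(df, box)
}
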