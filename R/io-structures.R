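#' Read a molecular structure (GRO or PDB)
#'
#' Parses a GRO fixed-column file or the ATOM/HETATM records of a PDB
#' file into a [MolecularSystem] plus a [Frame].  PDB coordinates (and
#' CRYST1 box lengths) are converted from Angstrom to nm; GRO files are
#' already in nm.  Species classes are inferred from residue names via
#' `speciesMap`.
#'
#' @param path file path.
#' @param format "gro" or "pdb"; guessed from the file extension when
#'   missing.
#' @param speciesMap residue-name to species dictionary, see
#'   [defaultSpeciesMap()].
#' @param headgroupTable headgroup atom table, see
#'   [defaultHeadgroupTable()].
#' @return list with elements `system` ([MolecularSystem]) and `frame`
#'   ([Frame]).
#' @export
readStructure <- function(path, format = c("auto", "gro", "pdb"),
                          speciesMap = defaultSpeciesMap(),
                          headgroupTable = defaultHeadgroupTable()) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gro", "pdb")) ext else
      stop("cannot guess format of '", path, "'; pass format=")
  }
  switch(format,
         gro = readGRO(path, speciesMap, headgroupTable),
         pdb = readPDB(path, speciesMap, headgroupTable))
}

## Parse one GRO frame starting at `lines[at]`.  Returns the parsed block
## and the index one past it, or NULL at end of input.
parseGROBlock <- function(lines, at, path) {
  if (at > length(lines)) return(NULL)
  title <- lines[at]
  nLine <- lines[at + 1L]
  nat <- suppressWarnings(as.integer(trimws(nLine)))
  if (is.na(nat))
    stop("malformed GRO atom-count line ", at + 1L, " in ", path, ": '",
         nLine, "'")
  last <- at + 1L + nat
  if (last + 1L > length(lines) + 1L || last > length(lines))
    stop("GRO file ", path, " truncated: expected ", nat,
         " atom lines plus box after line ", at + 1L)
  atomLines <- lines[(at + 2L):(at + 1L + nat)]
  boxLine <- if (last + 1L <= length(lines)) lines[last + 1L] else
    stop("missing box line in GRO file ", path, " after line ", last)
  resid <- suppressWarnings(as.integer(substr(atomLines, 1L, 5L)))
  resname <- trimws(substr(atomLines, 6L, 10L))
  name <- trimws(substr(atomLines, 11L, 15L))
  x <- suppressWarnings(as.numeric(substr(atomLines, 21L, 28L)))
  y <- suppressWarnings(as.numeric(substr(atomLines, 29L, 36L)))
  z <- suppressWarnings(as.numeric(substr(atomLines, 37L, 44L)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed fixed columns at line ", at + 1L + bad[1L], " of ",
         path, ": '", atomLines[bad[1L]], "'")
  box <- suppressWarnings(as.numeric(strsplit(trimws(boxLine), "\\s+")[[1L]]))
  if (length(box) < 3L || any(is.na(box[1:3])))
    stop("malformed box line ", last + 1L, " in ", path, ": '", boxLine, "'")
  ## GRO titles in this package's trajectory dialect carry "t= <ns>"
  tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1L]]
  time <- if (length(tm) == 2L) as.numeric(tm[2L]) else 0
  list(resid = resid, resname = resname, name = name,
       coords = unname(cbind(x, y, z)), box = box[1:3], time = time,
       nextAt = last + 2L)
}

#' Read a GRO file
#'
#' @inheritParams readStructure
#' @return list with `system` and `frame`.
#' @export
readGRO <- function(path, speciesMap = defaultSpeciesMap(),
                    headgroupTable = defaultHeadgroupTable()) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  blk <- parseGROBlock(lines, 1L, path)
  if (is.null(blk)) stop("empty GRO file: ", path)
  system <- buildSystem(blk$name, blk$resname, blk$resid,
                        speciesMap = speciesMap,
                        headgroupTable = headgroupTable)
  frame <- new("Frame", time = blk$time, coords = blk$coords, box = blk$box)
  list(system = system, frame = frame)
}

#' Read a PDB file (ATOM/HETATM subset)
#'
#' Delegates parsing to `bio3d::read.pdb()`; coordinates are converted
#' from Angstrom to nm.  The box is taken from CRYST1 when present,
#' otherwise from the coordinate extent (with a warning).
#'
#' @inheritParams readStructure
#' @return list with `system` and `frame`.
#' @export
readPDB <- function(path, speciesMap = defaultSpeciesMap(),
                    headgroupTable = defaultHeadgroupTable()) {
  stopifnot(file.exists(path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  system <- buildSystem(at$elety, at$resid, at$resno, chain,
                        speciesMap = speciesMap,
                        headgroupTable = headgroupTable)
  xyz <- unname(cbind(at$x, at$y, at$z)) * ANGSTROM_TO_NM
  box <- NULL
  cryst <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cryst)) {
    abc <- suppressWarnings(as.numeric(c(
      substr(cryst[1L], 7L, 15L), substr(cryst[1L], 16L, 24L),
      substr(cryst[1L], 25L, 33L))))
    if (all(is.finite(abc)) && all(abc > 0))
      box <- abc * ANGSTROM_TO_NM
  }
  if (is.null(box)) {
    warning("no CRYST1 record in ", path, "; box set from coordinate extent")
    box <- apply(xyz, 2L, function(v) max(diff(range(v)), 1))
  }
  frame <- new("Frame", time = 0, coords = xyz, box = unname(box))
  list(system = system, frame = frame)
}

#' Write a system + frame as a GRO file
#'
#' Fixed-column GRO with 3-decimal coordinates (the format's precision).
#' The title embeds the frame time as "t= <ns>", the dialect understood
#' by [readTrajectory()].
#'
#' @param system a [MolecularSystem].
#' @param frame a [Frame] with matching atom count.
#' @param path output path.
#' @param append append as an additional trajectory frame.
#' @return invisibly, `path`.
#' @export
writeGRO <- function(system, frame, path, append = FALSE) {
  stopifnot(nAtoms(system) == nAtoms(frame))
  at <- system@atoms
  n <- nrow(at)
  lines <- c(
    sprintf("poremetrics t= %.6f", frame@time),
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            at$resid %% 100000L, substr(at$resname, 1L, 5L),
            substr(at$name, 1L, 5L), seq_len(n) %% 100000L,
            frame@coords[, 1L], frame@coords[, 2L], frame@coords[, 3L]),
    sprintf("%10.5f%10.5f%10.5f", frame@box[1L], frame@box[2L],
            frame@box[3L]))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a concatenated-GRO trajectory
#'
#' The portable trajectory dialect: GRO frames concatenated in one file,
#' frame times embedded in the title lines.  Frames are returned in file
#' order; the atom count must be constant.
#'
#' @param path file path.
#' @return list of [Frame] objects (empty list for an empty file).
#' @export
readTrajectory <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  frames <- list()
  at <- 1L
  nat0 <- NA_integer_
  k <- 0L
  while (at <= length(lines)) {
    if (!nzchar(trimws(lines[at])) && at == length(lines)) break
    blk <- parseGROBlock(lines, at, path)
    k <- k + 1L
    if (is.na(nat0)) nat0 <- nrow(blk$coords)
    else if (nrow(blk$coords) != nat0)
      stop("atom count changed from ", nat0, " to ", nrow(blk$coords),
           " at frame index ", k - 1L, " in ", path)
    frames[[k]] <- new("Frame", time = blk$time, coords = blk$coords,
                       box = blk$box)
    at <- blk$nextAt
  }
  frames
}

#' Write a trajectory as concatenated GRO frames
#'
#' @param system a [MolecularSystem].
#' @param frames list of [Frame] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeTrajectory <- function(system, frames, path) {
  if (file.exists(path)) file.remove(path)
  for (fr in frames) writeGRO(system, fr, path, append = TRUE)
  invisible(path)
}
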