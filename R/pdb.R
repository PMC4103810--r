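#' @title Multi-model PDB input/output
#' @description Minimal fixed-column PDB reader/writer for structure
#'   ensembles: MODEL/ENDMDL records delimit frames and the atom order must
#'   be identical across models (validated on read). Only ATOM/HETATM
#'   records are interpreted.
#' @name pdb_io
NULL

#' Read a (multi-model) PDB file into a trajectory
#'
#' @param path PDB file path.
#' @return A [trajectory()]; single-model files yield one frame.
#' @export
read_pdb_trajectory <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  frames <- list(); cur <- NULL
  meta <- NULL; first_key <- NULL
  flush <- function(cur) {
    if (is.null(cur) || !length(cur$x)) return(NULL)
    cur
  }
  cur <- list(x = numeric(0), y = numeric(0), z = numeric(0), key = character(0),
              atoms = NULL)
  rows <- list()
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      if (length(cur$x)) { frames[[length(frames) + 1L]] <- cur; cur <- list(x = numeric(0), y = numeric(0), z = numeric(0), key = character(0), atoms = NULL); rows <- list() }
    } else if (r == "ENDMDL") {
      frames[[length(frames) + 1L]] <- cur
      cur <- list(x = numeric(0), y = numeric(0), z = numeric(0), key = character(0), atoms = NULL)
      rows <- list()
    } else if (r %in% c("ATOM  ", "HETATM")) {
      ln <- lines[i]
      if (nchar(ln) < 54)
        stop(sprintf("malformed ATOM record at line %d: too short", i), call. = FALSE)
      x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
      if (anyNA(c(x, y, z)))
        stop(sprintf("malformed coordinates at line %d", i), call. = FALSE)
      atom_name <- trimws(substr(ln, 13, 16))
      res_name <- trimws(substr(ln, 18, 20))
      chain <- trimws(substr(ln, 22, 22))
      res_i <- suppressWarnings(as.integer(substr(ln, 23, 26)))
      if (is.na(res_i))
        stop(sprintf("malformed residue number at line %d", i), call. = FALSE)
      element <- if (nchar(ln) >= 78) trimws(substr(ln, 77, 78)) else ""
      cur$x <- c(cur$x, x); cur$y <- c(cur$y, y); cur$z <- c(cur$z, z)
      cur$key <- c(cur$key, paste(chain, res_i, atom_name))
      rows[[length(rows) + 1L]] <- data.frame(
        residue_index = res_i, residue_name = res_name, atom_name = atom_name,
        element = element, chain = chain, stringsAsFactors = FALSE)
      cur$atoms <- rows
    }
  }
  if (length(cur$x)) frames[[length(frames) + 1L]] <- cur
  if (!length(frames)) stop("no ATOM records found in ", path, call. = FALSE)
  key0 <- frames[[1]]$key
  for (f in seq_along(frames)) {
    if (!identical(frames[[f]]$key, key0))
      stop(sprintf("model %d atom order/count differs from model 1", f),
           call. = FALSE)
  }
  atoms <- do.call(rbind, frames[[1]]$atoms)
  arr <- array(0, dim = c(length(key0), 3, length(frames)))
  for (f in seq_along(frames))
    arr[, , f] <- cbind(frames[[f]]$x, frames[[f]]$y, frames[[f]]$z)
  trajectory(arr, atoms)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pip_trajectory"))
  a <- traj$atoms
  el <- .element_of(a)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    X <- traj$coords[, , f]
    for (i in seq_len(nrow(a))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, a$atom_name[i], a$residue_name[i] %||% "GLY",
        a$chain[i] %||% "A", a$residue_index[i],
        X[i, 1], X[i, 2], X[i, 3], 1, 0, el[i]), con)
    }
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
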