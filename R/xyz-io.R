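# Extended-XYZ reader/writer.  The comment line carries key=value fields;
# `Lattice="L 0 0 0 L 0 0 0 L"` encodes the cubic box and `energy=<kcal/mol>`
# an optional label.  Multi-frame files are plain concatenations.

.xyz_comment <- function(cfg, energy = NULL, extra = character()) {
  parts <- character()
  if (!is.null(cfg$box_edge)) {
    L <- cfg$box_edge
    parts <- c(parts, sprintf('Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g"',
                              L, L, L))
  }
  if (!is.null(energy)) parts <- c(parts, sprintf("energy=%.10g", energy))
  paste(c(parts, extra), collapse = " ")
}

#' Write configurations to an extended-XYZ file
#'
#' @param cfgs an `mbw_config` or a list of them (multi-frame file).
#' @param path output file path.
#' @param energies optional numeric vector of per-frame energies (kcal/mol),
#'   stored as `energy=` in the comment line.
#' @param comments optional extra per-frame comment strings.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cfgs, path, energies = NULL, comments = NULL) {
  if (inherits(cfgs, "mbw_config")) cfgs <- list(cfgs)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(cfgs)) {
    cfg <- cfgs[[k]]
    writeLines(as.character(nrow(cfg$coords)), con)
    writeLines(.xyz_comment(cfg, if (is.null(energies)) NULL else energies[k],
                            if (is.null(comments)) character()
                            else comments[k]), con)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f", cfg$elements,
                       cfg$coords[, 1], cfg$coords[, 2], cfg$coords[, 3]), con)
  }
  invisible(path)
}

#' Read configurations from an extended-XYZ file
#'
#' The molecule partition is inferred from the O,H,H atom ordering; a
#' `Lattice=` field (cubic) sets the box edge; an `energy=` field is returned
#' as an attribute.
#'
#' @param path input file path.
#' @param multi if `TRUE` return a list of configurations (all frames);
#'   otherwise return the first frame only.
#' @return an `mbw_config`, or a list of them when `multi = TRUE`.  Each has
#'   an `energy` attribute when the file provides one.
#' @export
read_xyz <- function(path, multi = FALSE) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0L)
      stop(sprintf("line %d: malformed atom count '%s'", i, lines[i]))
    if (i + 1L + nat > length(lines))
      stop(sprintf("line %d: truncated frame (%d atoms declared)", i, nat))
    comment <- lines[i + 1L]
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(atom_lines), "[[:space:]]+")
    elements <- vapply(toks, `[`, "", 1L)
    coords <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (nat %% 3L != 0L)
      stop(sprintf("line %d: %d atoms is not a whole number of O,H,H waters",
                   i, nat))
    patt <- rep(c("O", "H", "H"), nat %/% 3L)
    bad <- which(elements != patt)
    if (length(bad))
      stop(sprintf("line %d: atom %d is '%s', expected '%s' (O,H,H order)",
                   i + 1L + bad[1L], bad[1L], elements[bad[1L]],
                   patt[bad[1L]]))
    box <- NULL
    m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1L]]
    if (length(m) == 2L) {
      lat <- as.numeric(strsplit(trimws(m[2L]), "[[:space:]]+")[[1L]])
      if (length(lat) != 9L) stop("malformed Lattice field")
      box <- lat[1L]
    }
    cfg <- configuration(coords, elements, box_edge = box)
    e <- regmatches(comment, regexec("energy=([-+0-9.eE]+)", comment))[[1L]]
    if (length(e) == 2L) attr(cfg, "energy") <- as.numeric(e[2L])
    frames[[length(frames) + 1L]] <- cfg
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("no frames in ", path)
  if (multi) frames else frames[[1L]]
}
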