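# Reading and writing macromolecular models. Parsing of PDB and mmCIF goes
# through bio3d; the mmCIF writer is a minimal atom_site loop (bio3d has no
# mmCIF writer). Alternate locations are resolved to the highest-occupancy
# conformer; secondary structure is consumed from HELIX/SHEET records (or the
# mmCIF equivalents) and never computed.

guessFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) "mmcif" else if (ext %in% c("pdb", "ent")) "pdb"
  else stop("cannot infer format from extension '", ext, "'; pass format explicitly")
}

#' Read a macromolecular model
#'
#' Parses a PDB or mmCIF coordinate file into a \code{StructureModel}. All
#' ATOM and HETATM records are kept with author chain/residue numbering;
#' alternate locations are resolved to the highest-occupancy conformer (ties
#' broken by file order, dropped altlocs are reported via a message).
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by extension).
#' @return a \code{StructureModel}.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guessFormat(path)
  pdb <- tryCatch(
    switch(format,
           pdb = bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
           mmcif = suppressWarnings(bio3d::read.cif(path, verbose = FALSE,
                                                    rm.alt = FALSE))),
    error = function(e) stop("parse error reading ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  atoms <- data.frame(
    chain = as.character(a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", as.character(a$insert)),
    resid = as.character(a$resid),
    elety = as.character(a$elety),
    elesy = if (!is.null(a$elesy) && !all(is.na(a$elesy)))
      ifelse(is.na(a$elesy) | a$elesy == "", elementFromName(a$elety), toupper(a$elesy))
    else elementFromName(a$elety),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    alt = ifelse(is.na(a$alt) | a$alt == "", "", as.character(a$alt)),
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "

  # resolve altlocs: keep the highest-occupancy conformer per atom site
  if (any(atoms$alt != "")) {
    siteKey <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
    ord <- order(siteKey, -atoms$o, seq_len(nrow(atoms)))
    keep <- ord[!duplicated(siteKey[ord])]
    dropped <- nrow(atoms) - length(keep)
    if (dropped > 0)
      message("readStructure: dropped ", dropped, " alternate-location atom(s)")
    atoms <- atoms[sort(keep), ]
  }
  atoms$alt <- NULL

  atoms$ss <- "unassigned"
  assignSS <- function(tab, label) {
    if (is.null(tab) || length(tab$start) == 0) return()
    for (i in seq_along(tab$start)) {
      sel <- atoms$chain == tab$chain[i] &
        atoms$resno >= as.integer(tab$start[i]) &
        atoms$resno <= as.integer(tab$end[i])
      atoms$ss[sel] <<- label
    }
  }
  hadSS <- (!is.null(pdb$helix) && length(pdb$helix$start)) ||
    (!is.null(pdb$sheet) && length(pdb$sheet$start))
  if (hadSS) {
    atoms$ss <- "coil"
    assignSS(pdb$helix, "helix")
    assignSS(pdb$sheet, "strand")
  }
  newStructureModel(atoms, title = basename(path))
}

#' Write a macromolecular model
#'
#' Emits PDB or mmCIF; the output re-parses (via \code{readStructure}) to an
#' equivalent model: same atom count, names, numbering and coordinates to
#' 1e-3 Angstrom.
#'
#' @param model a non-empty \code{StructureModel}.
#' @param path output file path.
#' @param format "pdb" or "mmcif" (default by extension).
#' @export
writeStructure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (nAtoms(model) == 0) stop("refusing to write an empty model")
  if (format == "auto") format <- guessFormat(path)
  a <- model@atoms
  if (format == "pdb") {
    ok <- tryCatch({
      bio3d::write.pdb(file = path,
                       xyz = as.vector(t(coords(model))),
                       resno = a$resno, resid = a$resid, chain = a$chain,
                       insert = ifelse(a$insert == "", NA, a$insert),
                       elety = a$elety, o = a$o, b = a$b, elesy = a$elesy)
      TRUE
    }, error = function(e) stop("I/O error writing ", path, ": ",
                                conditionMessage(e), call. = FALSE))
    invisible(ok)
  } else {
    writeMmcif(model, path)
  }
  invisible(path)
}

writeMmcif <- function(model, path) {
  a <- model@atoms
  isAA <- a$resid %in% names(AA_3TO1)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("I/O error opening ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  ttl <- if (nzchar(model@title)) gsub("[^A-Za-z0-9_.-]", "_", model@title) else "model"
  writeLines(c(paste0("data_", ttl), "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.label_entity_id",
               "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
               "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  lines <- sprintf("%-6s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
                   ifelse(isAA, "ATOM", "HETATM"), seq_len(nrow(a)),
                   a$elesy, a$elety, a$resid, a$chain, a$resno,
                   ifelse(a$insert == "", "?", a$insert),
                   a$x, a$y, a$z, a$o, a$b, a$resno, a$resid, a$chain, a$elety)
  writeLines(lines, con)
  writeLines("#", con)
  invisible(path)
}
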