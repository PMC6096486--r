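# Restraint-set serialization. Atoms are addressed portably by
# chain / residue number / insertion code / atom name, so a restraint file
# written against one copy of a model applies to another.

atomAddress <- function(model, idx) {
  a <- model@atoms
  data.frame(chain = a$chain[idx], resno = a$resno[idx],
             insert = a$insert[idx], atom = a$elety[idx],
             stringsAsFactors = FALSE)
}

atomFromAddress <- function(model, chain, resno, insert, atom) {
  a <- model@atoms
  insert <- ifelse(is.na(insert) | insert == ".", "", insert)
  hit <- which(a$chain == chain & a$resno == resno &
                 a$insert == insert & a$elety == atom)
  if (length(hit) != 1)
    stop("cannot resolve atom ", chain, "/", resno, insert, "/", atom)
  hit
}

#' Write a restraint set to JSON
#' @param set a \code{RestraintSet}
#' @param model the \code{StructureModel} the indices refer to
#' @param path output file
#' @export
writeRestraints <- function(set, model, path) {
  d <- set@dihedrals
  dih <- lapply(seq_len(nrow(d)), function(r) {
    list(atoms = lapply(c(d$i1[r], d$i2[r], d$i3[r], d$i4[r]),
                        function(i) as.list(atomAddress(model, i))),
         kind = d$kind[r], target = d$target[r], cutoff = d$cutoff[r],
         k = d$k[r], enabled = d$enabled[r], temporary = d$temporary[r])
  })
  l <- set@linear
  lin <- lapply(seq_len(nrow(l)), function(r) {
    entry <- list(kind = l$kind[r],
                  atom = as.list(atomAddress(model, l$i[r])),
                  r0 = l$r0[r], k = l$k[r], fmax = l$fmax[r],
                  enabled = l$enabled[r])
    if (!is.na(l$j[r])) entry$partner <- as.list(atomAddress(model, l$j[r]))
    else entry$target <- c(l$tx[r], l$ty[r], l$tz[r])
    entry
  })
  jsonlite::write_json(list(dihedrals = dih, linear = lin), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a restraint set from JSON
#' @param model the \code{StructureModel} to resolve atom addresses against
#' @param path JSON file written by \code{writeRestraints}
#' @return a \code{RestraintSet}
#' @export
readRestraints <- function(model, path) {
  doc <- jsonlite::read_json(path)
  set <- restraintSet()
  d <- emptyDihedralDf()
  for (entry in doc$dihedrals) {
    idx <- vapply(entry$atoms, function(ad)
      atomFromAddress(model, ad$chain, ad$resno, ad$insert %||% "", ad$atom),
      integer(1))
    keys <- atomResidueKeys(model)
    resKey <- if (entry$kind == "phi" || startsWith(entry$kind, "chi"))
      keys[idx[2]] else if (entry$kind == "psi") keys[idx[1]] else keys[idx[4]]
    d <- rbind(d, data.frame(i1 = idx[1], i2 = idx[2], i3 = idx[3], i4 = idx[4],
                             kind = entry$kind, resKey = resKey,
                             target = entry$target, cutoff = entry$cutoff,
                             k = entry$k, enabled = isTRUE(entry$enabled),
                             temporary = isTRUE(entry$temporary),
                             bundle = NA_integer_, createdFrame = 0L,
                             stringsAsFactors = FALSE))
  }
  l <- emptyLinearDf()
  for (entry in doc$linear) {
    i <- atomFromAddress(model, entry$atom$chain, entry$atom$resno,
                         entry$atom$insert %||% "", entry$atom$atom)
    if (!is.null(entry$partner)) {
      j <- atomFromAddress(model, entry$partner$chain, entry$partner$resno,
                           entry$partner$insert %||% "", entry$partner$atom)
      tx <- ty <- tz <- NA_real_
    } else {
      j <- NA_integer_
      tx <- entry$target[[1]]; ty <- entry$target[[2]]; tz <- entry$target[[3]]
    }
    l <- rbind(l, data.frame(kind = entry$kind, i = i, j = j,
                             tx = tx, ty = ty, tz = tz, r0 = entry$r0,
                             k = entry$k, fmax = entry$fmax,
                             enabled = isTRUE(entry$enabled),
                             bundle = NA_integer_, stringsAsFactors = FALSE))
  }
  set@dihedrals <- d
  set@linear <- l
  validObject(set)
  set
}
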