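#' Default residue/atom-name to bead-kind mapping
#'
#' The package writes (and expects) a small fixed vocabulary: residue PRT
#' with atom BB for protomer beads, residue LIP with atoms HD/T1/T2 for
#' lipid head and tail beads, residue HOH atom O for water, residue STE
#' atom X for analysis sites. Users reading foreign bead PDBs can supply
#' their own table; `elety = "*"` matches any atom name within the
#' residue.
#'
#' @return data.frame with columns resid, elety, kind.
#' @export
defaultBeadMapping <- function() {
  data.frame(
    resid = c("PRT", "LIP", "LIP", "LIP", "HOH", "STE"),
    elety = c("*", "HD", "T1", "T2", "*", "*"),
    kind = c("protomer_bead", "lipid_head", "lipid_tail", "lipid_tail",
             "water", "site"),
    stringsAsFactors = FALSE
  )
}

leafletFromCode <- c("none", "loop_side", "nc_side")

#' Read a bead structure from PDB
#'
#' Coordinates are converted from Angstrom to nm. The box is taken from
#' the CRYST1 record unless `box` overrides it; a PDB with neither is
#' rejected. One chain per protomer, assigned 0-based in file order.
#' Leaflet tags are carried in the B-factor column (0 none, 1 loop side,
#' 2 NC side), the package's own round-trip convention.
#'
#' @param path PDB file.
#' @param box optional numeric(3) box override, nm.
#' @param mapping bead-kind mapping table, see [defaultBeadMapping()].
#' @return a [BeadSystem-class].
#' @export
readStructurePDB <- function(path, box = NULL,
                             mapping = defaultBeadMapping()) {
  lines <- readLines(path, warn = FALSE)
  atomLines <- grep("^(ATOM|HETATM)", lines)
  bad <- atomLines[nchar(lines[atomLines]) < 54]
  if (length(bad))
    rwStop("rw_format_error",
           sprintf("unparsable ATOM record at line %d", bad[1]))
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (is.null(box)) {
    if (!length(cr))
      rwStop("rw_format_error",
             "no CRYST1 record and no explicit box override")
    abc <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15),
                                         substr(cr[1], 16, 24),
                                         substr(cr[1], 25, 33))))
    if (any(!is.finite(abc)) || any(abc <= 0))
      rwStop("rw_format_error", "malformed CRYST1 record")
    box <- abc / 10
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    rwStop("rw_format_error", conditionMessage(e)))
  at <- pdb$atom
  kind <- rep(NA_character_, nrow(at))
  for (r in seq_len(nrow(mapping))) {
    hit <- at$resid == mapping$resid[r] &
      (mapping$elety[r] == "*" | trimws(at$elety) == mapping$elety[r])
    kind[hit & is.na(kind)] <- mapping$kind[r]
  }
  if (anyNA(kind)) {
    i <- which(is.na(kind))[1]
    rwStop("rw_classification_error",
           sprintf("no bead-kind mapping for residue %s atom %s",
                   at$resid[i], trimws(at$elety[i])))
  }
  chain <- ifelse(is.na(at$chain), " ", at$chain)
  molKey <- paste(chain, at$resno)
  molecule <- as.integer(factor(molKey, levels = unique(molKey))) - 1L
  protomer <- rep(NA_integer_, nrow(at))
  isProt <- kind == "protomer_bead"
  if (any(isProt)) {
    pc <- chain[isProt]
    protomer[isProt] <- as.integer(factor(pc, levels = unique(pc))) - 1L
  }
  b <- ifelse(is.na(at$b), 0, round(at$b))
  b[!b %in% 0:2] <- 0
  BeadSystem(
    coords = cbind(at$x, at$y, at$z) / 10, kind = kind, box = box,
    beadId = seq_len(nrow(at)), protomer = protomer, molecule = molecule,
    leaflet = leafletFromCode[b + 1L]
  )
}

#' Write a bead structure to PDB
#'
#' Inverse of [readStructurePDB()]: nm to Angstrom, CRYST1 from the box,
#' chains A, B, ... per protomer, leaflet tag encoded in the B-factor
#' column. Round trips preserve coordinates to PDB precision (1e-3
#' Angstrom) and all labels.
#'
#' @param x a [BeadSystem-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStructurePDB <- function(x, path) {
  kindToRes <- c(protomer_bead = "PRT", lipid_head = "LIP",
                 lipid_tail = "LIP", water = "HOH", site = "STE")
  kindToAtom <- c(protomer_bead = "BB", lipid_head = "HD",
                  lipid_tail = "T", water = "O", site = "X")
  elety <- kindToAtom[x@kind]
  # number tail beads T1, T2, ... within each molecule
  isTail <- x@kind == "lipid_tail"
  if (any(isTail)) {
    tailNo <- stats::ave(rep(1, sum(isTail)), x@molecule[isTail],
                         FUN = cumsum)
    elety[isTail] <- paste0("T", tailNo)
  }
  chain <- rep("x", length(x@beadId))
  isProt <- x@kind == "protomer_bead"
  if (any(isProt)) {
    pidx <- x@protomer[isProt]
    if (max(pidx) > 25)
      rwStop("rw_format_error", "more than 26 protomer chains in PDB output")
    chain[isProt] <- LETTERS[pidx + 1L]
  }
  chain[x@kind == "water"] <- "w"
  chain[x@kind == "site"] <- "s"
  bCode <- match(x@leaflet, leafletFromCode) - 1L
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
    x@box[1] * 10, x@box[2] * 10, x@box[3] * 10), path)
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = as.numeric(t(x@coords * 10)),
    resno = (x@molecule %% 10000L) + 1L,
    resid = kindToRes[x@kind],
    eleno = x@beadId %% 100000L, elety = elety, chain = chain,
    b = bCode, o = rep(1, length(x@beadId)),
    append = TRUE, end = TRUE, verbose = FALSE
  )
  invisible(path)
}
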