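#' Structure models
#'
#' A `structure_model` holds receptor atoms (ordered by chain then residue
#' number), an optional bound ligand, and an optional generic-numbering map
#' (e.g. residue 108 -> "3x32") used to compare residues across structures.
#'
#' @param atoms data frame with columns `chain`, `resno`, `resname`, `atom`
#'   (atom name), `element`, `x`, `y`, `z`, and logical `ligand`.
#' @param numbering named integer vector: names are generic labels, values
#'   are residue numbers present among the receptor atoms.
#' @param source free-text origin.
#' @return a `structure_model`.
#' @export
structure_model <- function(atoms, numbering = NULL, source = "") {
  need <- c("chain", "resno", "resname", "atom", "element",
            "x", "y", "z", "ligand")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  rec <- atoms[!atoms$ligand, , drop = FALSE]
  rec <- rec[order(rec$chain, rec$resno), , drop = FALSE]
  lig <- atoms[atoms$ligand, , drop = FALSE]
  atoms <- rbind(rec, lig)
  rownames(atoms) <- NULL
  if (!is.null(numbering)) {
    numbering <- setNames(as.integer(numbering), names(numbering))
    bad <- !numbering %in% rec$resno
    if (any(bad))
      stop("numbering map refers to residues absent from the structure: ",
           paste(names(numbering)[bad], collapse = ", "))
    ca <- rec[rec$atom == "CA", ]
    noca <- !numbering %in% ca$resno
    if (any(noca))
      stop("no CA atom resolvable for mapped residue(s): ",
           paste(names(numbering)[noca], collapse = ", "))
  }
  structure(list(atoms = atoms, numbering = numbering, source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  rec <- x$atoms[!x$atoms$ligand, ]
  cat("structure_model:", length(unique(paste(rec$chain, rec$resno))),
      "residues,", nrow(rec), "receptor atoms,",
      sum(x$atoms$ligand), "ligand atoms")
  if (!is.null(x$numbering))
    cat(",", length(x$numbering), "numbered residues")
  cat("\n")
  invisible(x)
}

receptor_atoms <- function(model) model$atoms[!model$atoms$ligand, , drop = FALSE]
ligand_atoms   <- function(model) model$atoms[model$atoms$ligand, , drop = FALSE]

#' Resolve a generic residue label to a residue number
#'
#' @param model a `structure_model` with a numbering map.
#' @param label generic label such as `"3x32"`.
#' @return integer residue number.
#' @export
resolve_label <- function(model, label) {
  if (is.null(model$numbering)) stop("structure has no numbering map")
  if (!label %in% names(model$numbering))
    stop("label not present in numbering map: ", label)
  unname(model$numbering[[label]])
}

guess_element <- function(elety, elesy) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | !nzchar(el)
  if (any(miss)) {
    nm <- gsub("[^A-Za-z].*$", "", trimws(elety[miss]))
    two <- toupper(substr(nm, 1, 2))
    el2 <- toupper(substr(nm, 1, 1))
    known2 <- c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")
    el[miss] <- ifelse(two %in% known2, two, el2)
  }
  # normalize e.g. "CL" -> "Cl"
  paste0(substr(el, 1, 1), tolower(substr(el, 2, 5)))
}

#' Read a receptor(-ligand) structure from PDB or mmCIF
#'
#' @param path PDB or mmCIF file.
#' @param ligand residue name identifying the bound ligand; `NULL` for an
#'   apo structure. An absent named ligand is an error.
#' @param numbering optional numbering table: a named vector
#'   (label -> residue number) or a two-column data frame / TSV file path
#'   with columns `resno`, `label`. Entries absent from the file are dropped
#'   with a warning.
#' @param format `"auto"`, `"pdb"` or `"cif"`.
#' @return a `structure_model`.
#' @export
read_structure <- function(path, ligand = NULL, numbering = NULL,
                           format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- if (format == "cif") bio3d::read.cif(path) else
    suppressWarnings(bio3d::read.pdb(path))
  at <- pdb$atom
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    resname = trimws(at$resid),
    atom = trimws(at$elety),
    element = guess_element(at$elety, at$elesy),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  atoms$ligand <- FALSE
  if (!is.null(ligand)) {
    atoms$ligand <- atoms$resname == ligand
    if (!any(atoms$ligand))
      stop("ligand not found: no residue named '", ligand, "' in ", path)
  }
  # drop waters from the receptor side
  atoms <- atoms[!(atoms$resname %in% c("HOH", "WAT") & !atoms$ligand), ]
  nmap <- NULL
  if (!is.null(numbering)) {
    if (is.character(numbering) && length(numbering) == 1 &&
        file.exists(numbering))
      numbering <- read.delim(numbering, stringsAsFactors = FALSE)
    if (is.data.frame(numbering)) {
      stopifnot(all(c("resno", "label") %in% names(numbering)))
      nmap <- setNames(as.integer(numbering$resno), numbering$label)
    } else {
      nmap <- setNames(as.integer(numbering), names(numbering))
    }
    present <- nmap %in% atoms$resno[!atoms$ligand]
    if (!all(present)) {
      warning("dropping numbering entries absent from the file: ",
              paste(names(nmap)[!present], collapse = ", "))
      nmap <- nmap[present]
    }
    if (!length(nmap)) nmap <- NULL
  }
  structure_model(atoms, numbering = nmap, source = path)
}

#' Write a structure model to a PDB file
#'
#' Receptor atoms are written as ATOM records, ligand atoms as HETATM.
#'
#' @param model a `structure_model`.
#' @param path output PDB path.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$ligand, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   elety = a$atom, elesy = toupper(a$element),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}
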