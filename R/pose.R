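# Quantitative comparison of predicted and experimental receptor-ligand
# complexes: Kabsch superposition, symmetry-aware ligand RMSD, contact
# sets and recovery, residue displacement, polar contacts.

xyz_mat <- function(df) as.matrix(df[, c("x", "y", "z")])

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Least-squares (Kabsch) superposition on CA atoms
#'
#' Residues are matched across the two structures by (chain, residue
#' number). The rigid transform minimizing the CA least-squares deviation
#' over the selection is computed by SVD and applied to the whole model,
#' ligand included.
#'
#' @param model,reference `structure_model`s.
#' @param selection `"all"` or an integer vector of residue numbers
#'   restricting the fit (e.g. a binding site).
#' @return a `superposition` list: `rotation` (3x3, acts on coordinate
#'   rows), `translation`, `ca_rmsd`, `n_pairs`, and `model` (the
#'   transformed model).
#' @export
superpose <- function(model, reference, selection = "all") {
  ca_m <- receptor_atoms(model); ca_m <- ca_m[ca_m$atom == "CA", ]
  ca_r <- receptor_atoms(reference); ca_r <- ca_r[ca_r$atom == "CA", ]
  key_m <- paste(ca_m$chain, ca_m$resno)
  key_r <- paste(ca_r$chain, ca_r$resno)
  common <- intersect(key_m, key_r)
  if (!identical(selection, "all"))
    common <- common[ca_m$resno[match(common, key_m)] %in% selection]
  if (length(common) < 3)
    stop("need at least 3 matched CA pairs for superposition (got ",
         length(common), ")")
  Y <- xyz_mat(ca_m[match(common, key_m), ])
  X <- xyz_mat(ca_r[match(common, key_r), ])
  cy <- colMeans(Y); cx <- colMeans(X)
  H <- crossprod(sweep(Y, 2, cy), sweep(X, 2, cx))
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)   # rows transform: y' = (y-cy) R + cx
  Yt <- sweep(Y, 2, cy) %*% R
  ca_rmsd <- rmsd_xyz(sweep(Yt, 2, -cx), X)
  out_model <- transform_model(model, R, cy, cx)
  structure(list(rotation = R, translation = cx - cy, center = cy,
                 ca_rmsd = ca_rmsd, n_pairs = length(common),
                 model = out_model),
            class = "superposition")
}

transform_model <- function(model, R, center, target) {
  xyz <- xyz_mat(model$atoms)
  xyz <- sweep(sweep(xyz, 2, center) %*% R, 2, -target)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: CA RMSD %.3f A over %d pairs\n",
              x$ca_rmsd, x$n_pairs))
  invisible(x)
}

infer_bonds <- function(atoms, cutoff = 1.85) {
  xyz <- xyz_mat(atoms)
  n <- nrow(xyz)
  out <- NULL
  if (n >= 2) {
    d <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    if (nrow(idx)) out <- cbind(idx[, 1], idx[, 2])
  }
  out
}

ligand_df <- function(x) {
  if (is(x, "structure_model")) ligand_atoms(x)
  else if (is.data.frame(x)) x
  else stop("expected a structure_model or an atom data frame")
}

# All color-preserving automorphisms of the bond graph.
graph_automorphisms <- function(elements, bonds) {
  n <- length(elements)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(bonds) && nrow(bonds) > 0)
    g <- igraph::add_edges(g, as.vector(t(bonds)))
  col <- as.integer(factor(elements))
  maps <- igraph::isomorphisms(g, g, method = "vf2",
                               vertex.color1 = col, vertex.color2 = col)
  lapply(maps, as.integer)
}

#' Heavy-atom ligand RMSD, optionally symmetry-corrected
#'
#' Atoms are assumed to correspond by position in the two inputs (same
#' molecule, same atom order). With `symmetry_aware = TRUE` the RMSD is
#' minimized over all automorphisms of the bond graph (graph symmetries
#' such as a flipped para-substituted ring), so it is never larger than
#' the naive value. No superposition is applied here: poses must already
#' be in a common frame (see [superpose()]).
#'
#' @param model_ligand,reference_ligand `structure_model`s (their ligand
#'   atoms are used) or atom data frames with `element`, `x`, `y`, `z`.
#' @param symmetry_aware minimize over bond-graph automorphisms
#'   (default TRUE).
#' @param bonds optional 2-column atom-index bond matrix; inferred from
#'   interatomic distances (<= 1.85 A) when absent.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(model_ligand, reference_ligand,
                        symmetry_aware = TRUE, bonds = NULL) {
  a <- ligand_df(model_ligand); b <- ligand_df(reference_ligand)
  a <- a[toupper(a$element) != "H", , drop = FALSE]
  b <- b[toupper(b$element) != "H", , drop = FALSE]
  if (nrow(a) != nrow(b))
    stop("ligand atom count mismatch: ", nrow(a), " vs ", nrow(b))
  if (!identical(sort(toupper(a$element)), sort(toupper(b$element))))
    stop("ligand element composition mismatch")
  A <- xyz_mat(a); B <- xyz_mat(b)
  naive <- rmsd_xyz(A, B)
  if (!symmetry_aware) return(naive)
  if (is.null(bonds)) bonds <- infer_bonds(b)
  maps <- graph_automorphisms(toupper(b$element), bonds)
  best <- naive
  for (p in maps) {
    if (!identical(toupper(a$element), toupper(b$element[p]))) next
    best <- min(best, rmsd_xyz(A, B[p, , drop = FALSE]))
  }
  best
}

#' Receptor heavy atoms in contact with the ligand
#'
#' A receptor heavy atom is a contact iff its minimum distance to any
#' ligand heavy atom is `<= cutoff`. Hydrogens are excluded on both sides.
#'
#' @param structure a `structure_model` with a ligand.
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @return a `contact_set` data frame (`chain`, `resno`, `atom`) with
#'   attribute `"cutoff"`.
#' @export
contact_set <- function(structure, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  lig <- ligand_atoms(structure)
  lig <- lig[toupper(lig$element) != "H", , drop = FALSE]
  if (!nrow(lig)) stop("structure has no ligand")
  rec <- receptor_atoms(structure)
  rec <- rec[toupper(rec$element) != "H", , drop = FALSE]
  L <- xyz_mat(lig); R <- xyz_mat(rec)
  # min distance of each receptor atom to the ligand
  mind <- vapply(seq_len(nrow(R)), function(i) {
    sqrt(min(colSums((t(L) - R[i, ])^2)))
  }, numeric(1))
  out <- rec[mind <= cutoff, c("chain", "resno", "atom"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_set", "data.frame")
  out
}

contact_keys <- function(cs) paste(cs$chain, cs$resno, cs$atom)

#' Fraction of reference contacts captured by a model (LC)
#'
#' `LC = 100 * |model intersect reference| / |reference|`, i.e. the
#' percentage of experimental receptor-ligand contacts recovered by the
#' model pose. A symmetric (Jaccard) variant is available.
#'
#' @param model,reference `contact_set`s built with the same cutoff and
#'   atom-identifier scheme.
#' @param symmetric use `100 * |intersection| / |union|` instead.
#' @return percentage in `[0, 100]`.
#' @export
contact_recovery <- function(model, reference, symmetric = FALSE) {
  cm <- attr(model, "cutoff"); cr <- attr(reference, "cutoff")
  if (!is.null(cm) && !is.null(cr) && cm != cr)
    stop("contact sets built with different cutoffs")
  km <- contact_keys(model); kr <- contact_keys(reference)
  if (!length(kr)) stop("reference contact set is empty: LC undefined")
  inter <- length(intersect(km, kr))
  if (symmetric) 100 * inter / length(union(km, kr))
  else 100 * inter / length(kr)
}

#' Per-residue CA displacement between superposed structures
#'
#' @param model,reference `structure_model`s already in a common frame,
#'   both carrying numbering maps resolving the requested labels.
#' @param labels generic residue labels (e.g. `"2x66"`).
#' @return named numeric vector of CA distances in Angstrom.
#' @export
residue_displacement <- function(model, reference, labels) {
  vapply(setNames(labels, labels), function(lab) {
    rm_ <- resolve_label(model, lab)
    rr <- resolve_label(reference, lab)
    am <- receptor_atoms(model)
    ar <- receptor_atoms(reference)
    pm <- am[am$resno == rm_ & am$atom == "CA", ][1, ]
    pr <- ar[ar$resno == rr & ar$atom == "CA", ][1, ]
    sqrt(sum((c(pm$x, pm$y, pm$z) - c(pr$x, pr$y, pr$z))^2))
  }, numeric(1))
}

#' Polar contacts between receptor and ligand
#'
#' Donor/acceptor pairs are nitrogen and oxygen heavy atoms. A pair is
#' reported when the heavy-atom distance is `<= dist_cutoff`; when
#' hydrogen positions exist on the donor side the D-H...A angle must also
#' be `>= angle_min`. In heavy-atom-only mode the angle is `NA` and
#' element-type donor/acceptor tables (N, O on both sides) are used.
#'
#' @param structure a `structure_model` with a ligand.
#' @param dist_cutoff donor-acceptor distance cutoff in Angstrom
#'   (default 3.5).
#' @param angle_min minimum D-H...A angle in degrees (default 120), used
#'   only when hydrogens are present.
#' @param residue_labels optional restriction to receptor residues with
#'   these generic labels.
#' @return data frame: `rec_resno`, `rec_atom`, `lig_atom`, `distance`,
#'   `angle`, `label`.
#' @export
polar_contacts <- function(structure, dist_cutoff = 3.5, angle_min = 120,
                           residue_labels = NULL) {
  rec <- receptor_atoms(structure)
  lig <- ligand_atoms(structure)
  recH <- rec[toupper(rec$element) == "H", , drop = FALSE]
  rec_pol <- rec[toupper(rec$element) %in% c("N", "O"), , drop = FALSE]
  lig_pol <- lig[toupper(lig$element) %in% c("N", "O"), , drop = FALSE]
  if (!is.null(residue_labels)) {
    resnos <- vapply(residue_labels, function(l) resolve_label(structure, l),
                     integer(1))
    rec_pol <- rec_pol[rec_pol$resno %in% resnos, , drop = FALSE]
  }
  out <- data.frame(rec_resno = integer(), rec_atom = character(),
                    lig_atom = character(), distance = numeric(),
                    angle = numeric(), label = character(),
                    stringsAsFactors = FALSE)
  if (!nrow(rec_pol) || !nrow(lig_pol)) return(out)
  lab_of <- function(resno) {
    if (is.null(structure$numbering)) return(NA_character_)
    hit <- names(structure$numbering)[structure$numbering == resno]
    if (length(hit)) hit[1] else NA_character_
  }
  for (i in seq_len(nrow(rec_pol))) {
    D <- c(rec_pol$x[i], rec_pol$y[i], rec_pol$z[i])
    for (j in seq_len(nrow(lig_pol))) {
      A <- c(lig_pol$x[j], lig_pol$y[j], lig_pol$z[j])
      dda <- sqrt(sum((D - A)^2))
      if (dda > dist_cutoff || dda <= 0) next
      ang <- NA_real_
      if (nrow(recH)) {
        # hydrogens covalently bound to this donor
        hd <- sqrt((recH$x - D[1])^2 + (recH$y - D[2])^2 +
                     (recH$z - D[3])^2)
        hs <- which(hd < 1.25 & recH$resno == rec_pol$resno[i])
        if (length(hs)) {
          angs <- vapply(hs, function(k) {
            H <- c(recH$x[k], recH$y[k], recH$z[k])
            v1 <- D - H; v2 <- A - H
            acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) *
              180 / pi
          }, numeric(1))
          ang <- max(angs)
          if (ang < angle_min) next
        }
      }
      out <- rbind(out, data.frame(
        rec_resno = rec_pol$resno[i], rec_atom = rec_pol$atom[i],
        lig_atom = lig_pol$atom[j], distance = dda, angle = ang,
        label = lab_of(rec_pol$resno[i]), stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
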