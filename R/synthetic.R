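# Synthetic-data generators: a mock screening library with planted
# actives, toy receptor-ligand complexes of known geometry, and simulated
# plate / concentration-response tables. Everything the pipeline consumes
# can be produced here, so all stages are testable without downloads.
# All generators are pure functions of (config, seed), and truth labels
# are returned separately, never written into the tables the pipeline
# reads.

#' Fragment grammar for synthetic molecules
#'
#' A curated set of chemically valid, chain-appendable SMILES fragments
#' (each ends in an atom that accepts a further single bond), so that
#' concatenation yields parsable molecules with meaningful fingerprints
#' and substructures.
#'
#' @return character vector of fragment SMILES.
#' @export
synth_fragments <- function() {
  c("c1ccccc1", "c1ccncc1", "c1ccoc1", "c1cc[nH]c1", "c1ccc(F)cc1",
    "c1ccc(Cl)cc1", "c1ccc(C)cc1", "c1ccc(OC)cc1", "c1cnccc1",
    "C1CCCCC1", "C1CCOCC1", "C1CCNCC1", "C1CCCC1",
    "CC(=O)N", "C(=O)N", "C(=O)OC", "CS(=O)(=O)N", "C(=O)",
    "CC", "CCC", "CCO", "CCN", "CN(C)C", "COC", "CNC",
    "CC(C)", "CC(O)", "C(F)(F)", "CC#N", "OC")
}

# Scaffold shared by planted actives; kept out of the decoy fragment pool
# so actives form a distinct, substructure-searchable chemotype.
ACTIVE_SCAFFOLD <- "c1ccsc1C(=O)N"

#' Generate a synthetic docking screen with planted actives
#'
#' Molecules are assembled from the fragment grammar; planted actives
#' share the thiophene-carboxamide scaffold. Dock scores are standard
#' normal with actives shifted by `-score_advantage` (lower is better).
#' Truth labels are returned separately from the library.
#'
#' @param n_molecules library size.
#' @param n_actives number of planted actives.
#' @param score_advantage score shift of actives, in standard deviations.
#' @param seed integer seed.
#' @param heavy_tails draw scores from a t(5) distribution instead of the
#'   normal.
#' @return list with `library` (a `screen_library` with dock records) and
#'   `truth` (data frame `id`, `active`).
#' @export
make_screen <- function(n_molecules = 10000, n_actives = 100,
                        score_advantage = 2, seed = 1,
                        heavy_tails = FALSE) {
  stopifnot(n_actives <= n_molecules, score_advantage >= 0)
  set.seed(seed)
  frags <- synth_fragments()
  decoy_frags <- frags[!grepl("s", frags, fixed = TRUE)]
  n_dec <- n_molecules - n_actives
  dec_smi <- paste0(sample(decoy_frags, n_dec, TRUE),
                    sample(decoy_frags, n_dec, TRUE),
                    sample(decoy_frags, n_dec, TRUE))
  act_smi <- if (n_actives > 0)
    paste0(ACTIVE_SCAFFOLD, sample(decoy_frags, n_actives, TRUE),
           sample(decoy_frags, n_actives, TRUE)) else character(0)
  smi <- c(act_smi, dec_smi)
  active <- c(rep(TRUE, n_actives), rep(FALSE, n_dec))
  perm <- sample.int(n_molecules)
  smi <- smi[perm]; active <- active[perm]
  ids <- sprintf("M%06d", seq_len(n_molecules))
  base <- if (heavy_tails) stats::rt(n_molecules, df = 5)
  else rnorm(n_molecules)
  score <- base - score_advantage * active
  frac <- matrix(stats::runif(3 * n_molecules), ncol = 3)
  frac <- frac / rowSums(frac)
  records <- data.frame(molecule_id = ids, score_total = score,
                        electrostatic = score * frac[, 1],
                        van_der_waals = score * frac[, 2],
                        ligand_desolvation = score * frac[, 3],
                        stringsAsFactors = FALSE)
  lib <- screen_library(ids, smi, records = records,
                        provenance = "synthetic screen")
  list(library = lib, truth = data.frame(id = ids, active = active,
                                         stringsAsFactors = FALSE))
}

rotation_matrix <- function(axis, degrees) {
  u <- axis / sqrt(sum(axis^2))
  th <- degrees * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a toy receptor pocket with reference and perturbed ligand
#'
#' The reference complex has exactly `planted_contacts` pocket atoms
#' inside the contact shell (minimum distance to the ligand in
#' (2.8, cutoff]) and all other pocket atoms clearly outside
#' (> cutoff + 0.5). The perturbed complex applies the requested rigid
#' motion to the ligand (rotation about its centroid around a random
#' axis, then translation along a random direction); the receptor is
#' unchanged. Truth metrics follow from the construction.
#'
#' @param n_pocket_atoms pocket size (each atom its own residue).
#' @param planted_contacts atoms placed inside the cutoff shell.
#' @param rotation_deg ligand rotation in degrees.
#' @param translation_ang ligand translation in Angstrom.
#' @param cutoff contact cutoff used in the construction (default 4).
#' @param seed integer seed.
#' @return list with `reference` and `perturbed` (`structure_model`s) and
#'   `truth` (`ligand_rmsd`, `contact_count`, `cutoff`).
#' @export
make_toy_complex <- function(n_pocket_atoms = 40, planted_contacts = 7,
                             rotation_deg = 0, translation_ang = 0,
                             cutoff = 4, seed = 1) {
  stopifnot(planted_contacts <= n_pocket_atoms)
  set.seed(seed)
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  lig_xyz <- rbind(cbind(1.4 * cos(ang), 1.4 * sin(ang), 0),
                   c(0, 0, 1.3), c(0, 0, -1.3))
  lig_el <- c(rep("C", 6), "N", "O")
  nl <- nrow(lig_xyz)

  rand_dir <- function() { v <- rnorm(3); v / sqrt(sum(v^2)) }
  min_dist <- function(p) sqrt(min(colSums((t(lig_xyz) - p)^2)))
  place <- function(lo, hi) {
    repeat {
      anchor <- lig_xyz[sample.int(nl, 1), ]
      p <- anchor + rand_dir() * runif(1, max(lo, 2.9), hi)
      d <- min_dist(p)
      if (d > lo && d <= hi) return(p)
    }
  }
  pocket <- matrix(NA_real_, n_pocket_atoms, 3)
  for (i in seq_len(planted_contacts))
    pocket[i, ] <- place(2.8, cutoff - 0.05)
  for (i in seq_len(n_pocket_atoms - planted_contacts)) {
    repeat {
      p <- rand_dir() * runif(1, cutoff + 2, cutoff + 10)
      if (min_dist(p) > cutoff + 0.5) break
    }
    pocket[planted_contacts + i, ] <- p
  }

  cen <- colMeans(lig_xyz)
  R <- rotation_matrix(rand_dir(), rotation_deg)
  lig2 <- sweep(sweep(lig_xyz, 2, cen) %*% t(R), 2, -cen) +
    matrix(rand_dir() * translation_ang, nl, 3, byrow = TRUE)
  truth_rmsd <- sqrt(mean(rowSums((lig2 - lig_xyz)^2)))

  mk <- function(lxyz) {
    atoms <- data.frame(
      chain = "A",
      resno = c(seq_len(n_pocket_atoms), rep(900L, nl)),
      resname = c(rep("POC", n_pocket_atoms), rep("LIG", nl)),
      atom = c(rep("CA", n_pocket_atoms),
               paste0(lig_el, seq_len(nl))),
      element = c(rep("C", n_pocket_atoms), lig_el),
      x = c(pocket[, 1], lxyz[, 1]),
      y = c(pocket[, 2], lxyz[, 2]),
      z = c(pocket[, 3], lxyz[, 3]),
      ligand = c(rep(FALSE, n_pocket_atoms), rep(TRUE, nl)),
      stringsAsFactors = FALSE)
    structure_model(atoms,
                    numbering = setNames(seq_len(n_pocket_atoms),
                                         paste0("x", seq_len(n_pocket_atoms))),
                    source = "synthetic toy complex")
  }
  list(reference = mk(lig_xyz), perturbed = mk(lig2),
       truth = list(ligand_rmsd = truth_rmsd,
                    contact_count = planted_contacts, cutoff = cutoff))
}

#' Simulate primary-screen plates and concentration-response tables
#'
#' Plate signals and CRC points are drawn from the 4PL model with additive
#' normal noise, anchored to buffer (raw 100) and reference (raw 1100)
#' wells. Second-step (EC80 addition) responses encode the two-addition
#' design: agonists are desensitized, antagonists suppress the reference
#' response, inactives leave it intact.
#'
#' @param truth data frame with columns `compound_id`,
#'   `class` (`"agonist"`, `"antagonist"`, `"inactive"`), and for agonists
#'   `ec50` (molar), `top`, `hill` (`bottom` fixed at 0).
#' @param sigma response noise SD in percent points (default 5).
#' @param replicates technical replicates (default 3).
#' @param seed integer seed.
#' @param concentrations CRC concentrations in molar.
#' @param test_conc primary-screen test concentration (default 10 uM).
#' @param ec80_percent expected EC80-addition response, percent of
#'   reference max.
#' @return list with `plates` (one row per compound: raw signals),
#'   `crc` (long table: `compound_id`, `concentration_M`, `replicate`,
#'   `raw_signal`, `buffer_response`, `reference_response`) and the input
#'   `truth`.
#' @export
make_pharm_data <- function(truth, sigma = 5, replicates = 3, seed = 1,
                            concentrations = 10^seq(-9, -4.5,
                                                    length.out = 8),
                            test_conc = 1e-5, ec80_percent = 80) {
  stopifnot(all(c("compound_id", "class") %in% names(truth)))
  set.seed(seed)
  buffer <- 100; reference <- 1100
  to_raw <- function(pct) buffer + pct / 100 * (reference - buffer)
  n <- nrow(truth)
  step1_pct <- numeric(n); step2_pct <- numeric(n)
  for (i in seq_len(n)) {
    cl <- truth$class[i]
    if (cl == "agonist") {
      step1_pct[i] <- fpl(log10(test_conc), 0, truth$top[i],
                          log10(truth$ec50[i]), truth$hill[i])
      step2_pct[i] <- 0.05 * ec80_percent    # desensitized
    } else if (cl == "antagonist") {
      step1_pct[i] <- 0
      step2_pct[i] <- 0.05 * ec80_percent    # reference suppressed
    } else {
      step1_pct[i] <- 0
      step2_pct[i] <- ec80_percent           # full EC80 response
    }
  }
  noise <- function(m) rnorm(m, 0, sigma / sqrt(replicates))
  plates <- data.frame(
    compound_id = truth$compound_id,
    step1_response = to_raw(step1_pct + noise(n)),
    step2_response = to_raw(step2_pct + noise(n)),
    buffer_response = buffer,
    reference_response = reference,
    stringsAsFactors = FALSE)

  ago <- truth[truth$class == "agonist" & !is.na(truth$ec50), ,
               drop = FALSE]
  crc <- NULL
  if (nrow(ago)) {
    grid <- expand.grid(k = seq_len(nrow(ago)),
                        concentration_M = concentrations,
                        replicate = seq_len(replicates))
    mu <- fpl(log10(grid$concentration_M), 0, ago$top[grid$k],
              log10(ago$ec50[grid$k]), ago$hill[grid$k])
    crc <- data.frame(
      compound_id = ago$compound_id[grid$k],
      concentration_M = grid$concentration_M,
      replicate = grid$replicate,
      raw_signal = to_raw(mu + rnorm(nrow(grid), 0, sigma)),
      buffer_response = buffer,
      reference_response = reference,
      stringsAsFactors = FALSE)
    crc <- crc[order(crc$compound_id, crc$concentration_M,
                     crc$replicate), ]
    rownames(crc) <- NULL
  }
  list(plates = plates, crc = crc, truth = truth)
}

#' Synthetic stand-in for the campaign's primary screen
#'
#' A fully synthetic 68-compound primary screen whose planted truth
#' encodes the published summary of the campaign this pipeline emulates:
#' 14 compounds respond above the 25% agonist threshold at 10 uM, of
#' which 5 are potent full agonists (EC50 0.16-3.6 uM, Emax >= 70%) and 9
#' are weak agonists whose maximal response stays below the 50% CRC
#' follow-up criterion. The remaining 54 are inactive. This is generated
#' data, not the campaign's supplementary table.
#'
#' @param seed integer seed.
#' @param sigma response noise SD in percent points (default 0:
#'   deterministic truth recovery).
#' @return [make_pharm_data()] output.
#' @export
synthetic_primary_screen <- function(seed = 1, sigma = 0) {
  ids <- sprintf("C%02d", 1:68)
  class <- rep("inactive", 68)
  set.seed(seed + 1000)
  slots <- sample.int(68, 14)
  potent <- slots[1:5]; weak <- slots[6:14]
  class[slots] <- "agonist"
  ec50 <- rep(NA_real_, 68); top <- rep(NA_real_, 68)
  hill <- rep(NA_real_, 68)
  ec50[potent] <- c(160e-9, 320e-9, 540e-9, 1.8e-6, 3.6e-6)
  top[potent] <- c(100, 95, 122, 80, 70)
  hill[potent] <- 1
  ec50[weak] <- runif(9, 1e-6, 3e-6)
  top[weak] <- runif(9, 36, 46)
  hill[weak] <- 1
  truth <- data.frame(compound_id = ids, class = class, ec50 = ec50,
                      top = top, hill = hill, stringsAsFactors = FALSE)
  make_pharm_data(truth, sigma = sigma, seed = seed)
}
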