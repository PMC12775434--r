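# Physicochemical properties and the lead-like / interference filters.

lib_smiles <- function(x) {
  if (is(x, "screen_library")) setNames(x$molecules$smiles, x$molecules$id)
  else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- sprintf("MOL%05d", seq_along(x))
    x
  } else stop("expected a screen_library or a character vector of SMILES")
}

# One SDFset for a set of SMILES (2D connection tables only, no conformers).
smiles_sdfset <- function(smiles) {
  smiles <- lib_smiles(smiles)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e)
                    stop("unparsable structure among inputs: ",
                         conditionMessage(e)))
  if (length(sdf) != length(smiles))
    stop("unparsable structure among inputs (",
         length(smiles) - length(sdf), " record(s) failed)")
  sdf
}

net_charge_from_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    br <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    ch <- 0L
    for (b in br) {
      for (x in regmatches(b, gregexpr("[+-][0-9]*", b))[[1]]) {
        sgn <- if (substr(x, 1, 1) == "+") 1L else -1L
        d <- substring(x, 2)
        ch <- ch + sgn * (if (nzchar(d)) as.integer(d) else 1L)
      }
    }
    ch
  }, integer(1), USE.NAMES = FALSE)
}

# Strict rotatable-bond definition: non-ring single bond between two
# non-terminal atoms, excluding bonds adjacent to triple bonds.
ROTOR_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Compute the property vector used by the lead-like filter
#'
#' Properties: molecular weight (Da), cLogP (OpenBabel atomic-contribution
#' logP), hydrogen-bond donors and acceptors, rotatable bonds, and net
#' formal charge.
#'
#' @param x a `screen_library` or character vector of SMILES.
#' @return data frame with one row per molecule: `id`, `mw`, `clogp`,
#'   `hbd`, `hba`, `rotatable_bonds`, `net_charge`.
#' @export
compute_properties <- function(x) {
  smiles <- lib_smiles(x)
  if (!length(smiles))
    return(data.frame(id = character(), mw = numeric(), clogp = numeric(),
                      hbd = integer(), hba = integer(),
                      rotatable_bonds = integer(), net_charge = integer()))
  sdf <- smiles_sdfset(smiles)
  pr <- ChemmineR::propOB(sdf)
  rot <- ChemmineR::smartsSearchOB(sdf, ROTOR_SMARTS, uniqueMatches = TRUE)
  out <- data.frame(
    id = names(smiles),
    mw = as.numeric(pr$MW),
    clogp = as.numeric(pr$logP),
    hbd = as.integer(pr$HBD),
    hba = as.integer(pr$HBA1),
    rotatable_bonds = as.integer(rot),
    net_charge = net_charge_from_smiles(unname(smiles)),
    stringsAsFactors = FALSE)
  bad <- !is.finite(out$mw) | out$mw <= 0
  if (any(bad))
    stop("could not compute property 'mw' for: ",
         paste(out$id[bad], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Lead-like property filter
#'
#' Retains molecules with `clogp <= max_clogp` and `mw <= max_mw`
#' (boundaries inclusive).
#'
#' @param library a `screen_library`.
#' @param max_clogp cLogP ceiling (default 3.5).
#' @param max_mw molecular-weight ceiling in Da (default 350).
#' @param properties optional precomputed [compute_properties()] table.
#' @return the filtered library (a subset of the input).
#' @export
leadlike_filter <- function(library, max_clogp = 3.5, max_mw = 350,
                            properties = NULL) {
  if (!length(library)) return(library)
  if (is.null(properties)) properties <- compute_properties(library)
  props <- properties[match(library$molecules$id, properties$id), ]
  keep <- props$clogp <= max_clogp & props$mw <= max_mw
  library$molecules <- library$molecules[keep, , drop = FALSE]
  if (!is.null(library$records))
    library$records <- library$records[
      library$records$molecule_id %in% library$molecules$id, , drop = FALSE]
  library
}

#' Bundled interference (PAINS-family) substructure patterns
#'
#' A small curated subset of well-known assay-interference motifs shipped
#' as a versioned plain-text file; the filter accepts any SMARTS table with
#' columns `id` and `smarts`.
#'
#' @return data frame with columns `id`, `smarts`.
#' @export
pains_patterns <- function() {
  path <- system.file("extdata", "pains_subset_v1.tsv",
                      package = "screenfunnel")
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Interference substructure filter
#'
#' Removes every molecule matching at least one pattern. Removals are
#' logged on the `"removed"` attribute together with the matched pattern.
#'
#' @param library a `screen_library`.
#' @param patterns data frame with columns `id`, `smarts`
#'   (default: [pains_patterns()]); an empty table is the identity.
#' @return the filtered library.
#' @export
interference_filter <- function(library, patterns = pains_patterns()) {
  if (!is.null(patterns) && nrow(patterns) > 0)
    stopifnot(all(c("id", "smarts") %in% names(patterns)))
  if (!length(library) || is.null(patterns) || nrow(patterns) == 0) {
    attr(library, "removed") <-
      data.frame(id = character(), pattern = character())
    return(library)
  }
  sdf <- smiles_sdfset(library)
  hit_pattern <- rep(NA_character_, length(library))
  for (k in seq_len(nrow(patterns))) {
    counts <- tryCatch(
      ChemmineR::smartsSearchOB(sdf, patterns$smarts[k],
                                 uniqueMatches = TRUE),
      error = function(e)
        stop("invalid interference pattern '", patterns$id[k], "': ",
             conditionMessage(e)))
    new_hit <- counts > 0 & is.na(hit_pattern)
    hit_pattern[new_hit] <- patterns$id[k]
  }
  removed <- data.frame(id = library$molecules$id[!is.na(hit_pattern)],
                        pattern = hit_pattern[!is.na(hit_pattern)],
                        stringsAsFactors = FALSE)
  keep <- is.na(hit_pattern)
  library$molecules <- library$molecules[keep, , drop = FALSE]
  if (!is.null(library$records))
    library$records <- library$records[
      library$records$molecule_id %in% library$molecules$id, , drop = FALSE]
  attr(library, "removed") <- removed
  library
}
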