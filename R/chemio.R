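#' @importFrom methods as is new
#' @importFrom stats median optim quantile rnorm runif sd setNames
#' @importFrom utils read.csv read.delim write.csv head
NULL

#' Canonicalize SMILES strings
#'
#' Computes OpenBabel canonical SMILES for each input. Invalid records give
#' `NA` rather than an error, so callers can count rejections exactly.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) ""
    )
    out <- trimws(sub("\t.*$", "", out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

new_screen_library <- function(molecules, records = NULL, provenance = "") {
  stopifnot(is.data.frame(molecules),
            all(c("id", "smiles", "cansmi") %in% names(molecules)))
  if (anyDuplicated(molecules$id))
    stop("molecule ids must be unique within a library")
  if (!is.null(records)) {
    stopifnot(all(c("molecule_id", "score_total") %in% names(records)))
    missing <- setdiff(records$molecule_id, molecules$id)
    if (length(missing))
      stop("score records refer to unknown molecule ids: ",
           paste(head(missing, 5), collapse = ", "))
    if (any(!is.finite(records$score_total)))
      stop("score_total must be finite for every record")
  }
  structure(list(molecules = molecules, records = records,
                 provenance = provenance),
            class = "screen_library")
}

#' Assemble a screen library from molecules and optional dock scores
#'
#' @param id,smiles parallel vectors of molecule identifiers and SMILES.
#' @param cansmi optional precomputed canonical SMILES (computed lazily by
#'   downstream functions when absent).
#' @param records optional data frame of dock records with columns
#'   `molecule_id`, `score_total` and optional component columns
#'   `electrostatic`, `van_der_waals`, `ligand_desolvation`.
#' @param provenance free-text origin note.
#' @return a `screen_library` object.
#' @export
screen_library <- function(id, smiles, cansmi = NA_character_,
                           records = NULL, provenance = "") {
  new_screen_library(
    data.frame(id = as.character(id), smiles = as.character(smiles),
               cansmi = rep_len(as.character(cansmi),
                                length(id)), stringsAsFactors = FALSE),
    records = records, provenance = provenance)
}

#' @export
print.screen_library <- function(x, ...) {
  cat("screen_library:", nrow(x$molecules), "molecules")
  if (!is.null(x$records)) cat(";", nrow(x$records), "dock records")
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.screen_library <- function(x) nrow(x$molecules)

#' Ensure canonical SMILES are populated on a library
#'
#' @param library a `screen_library`.
#' @return the library with the `cansmi` column filled in.
#' @export
ensure_canonical <- function(library) {
  m <- library$molecules
  todo <- is.na(m$cansmi)
  if (any(todo)) m$cansmi[todo] <- canonical_smiles(m$smiles[todo])
  library$molecules <- m
  library
}

#' Read molecules from a SMILES list, SDF or mol2 file
#'
#' One `Molecule` per valid record. Invalid records are counted and reported
#' via a message and the `"rejections"` attribute, never silently dropped.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"smiles"`, `"sdf"` or `"mol2"`.
#' @param provenance free-text origin note stored on the library.
#' @return a `screen_library`; attribute `"rejections"` is a data frame of
#'   rejected records (index and reason).
#' @export
read_molecules <- function(path, format = c("auto", "smiles", "sdf", "mol2"),
                           provenance = path) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read molecule file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = , ism = , txt = "smiles",
                     sdf = , mol = "sdf", mol2 = "mol2",
                     "smiles")
  }
  if (format == "mol2") {
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    ChemmineOB::convertFormatFile("MOL2", "SDF", path, tmp)
    path <- tmp
    format <- "sdf"
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      warning("empty molecule file: returning empty library")
      return(screen_library(character(), character(), provenance = provenance))
    }
    parts <- strsplit(trimws(lines), "[ \t]+")
    smi <- vapply(parts, `[`, character(1), 1L)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("MOL%05d", i)
    }, character(1))
    can <- canonical_smiles(smi)
    bad <- is.na(can)
    rejections <- data.frame(index = which(bad), id = ids[bad],
                             reason = rep_len("unparsable SMILES",
                                              sum(bad)),
                             stringsAsFactors = FALSE)
    if (any(bad))
      message(sum(bad), " record(s) rejected while reading ", path)
    lib <- screen_library(ids[!bad], smi[!bad], can[!bad],
                          provenance = provenance)
  } else {
    sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
    ok <- ChemmineR::validSDF(sdfs)
    ids <- ChemmineR::sdfid(sdfs)
    ids[!nzchar(ids) | is.na(ids)] <-
      sprintf("MOL%05d", which(!nzchar(ids) | is.na(ids)))
    smi <- rep(NA_character_, length(sdfs))
    if (any(ok)) {
      smi[ok] <- vapply(which(ok), function(i) {
        out <- tryCatch(as.character(
          ChemmineR::sdf2smiles(sdfs[i])), error = function(e) NA_character_)
        if (length(out) != 1) NA_character_ else out
      }, character(1))
    }
    bad <- !ok | is.na(smi)
    rejections <- data.frame(index = which(bad), id = ids[bad],
                             reason = rep_len("invalid SDF record",
                                              sum(bad)),
                             stringsAsFactors = FALSE)
    if (any(bad))
      message(sum(bad), " record(s) rejected while reading ", path)
    if (!any(!bad)) {
      warning("no valid records: returning empty library")
      lib <- screen_library(character(), character(), provenance = provenance)
    } else {
      lib <- screen_library(ids[!bad], smi[!bad],
                            canonical_smiles(smi[!bad]),
                            provenance = provenance)
    }
  }
  attr(lib, "rejections") <- rejections
  lib
}

#' Read a dock score table (CSV/TSV)
#'
#' Required columns: `molecule_id`, `score_total`. Optional component
#' columns: `electrostatic`, `van_der_waals`, `ligand_desolvation`.
#'
#' @param path CSV or TSV file.
#' @return data frame of dock records.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("cannot read score table: ", path)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("molecule_id", "score_total")
  if (!all(need %in% names(df)))
    stop("score table must contain columns: ", paste(need, collapse = ", "))
  df$molecule_id <- as.character(df$molecule_id)
  if (any(!is.finite(df$score_total)))
    stop("score_total must be finite for every record")
  keep <- c(need, intersect(c("electrostatic", "van_der_waals",
                              "ligand_desolvation"), names(df)))
  df[keep]
}

#' Attach dock records to a library
#'
#' @param library a `screen_library`.
#' @param scores data frame as returned by [read_scores()].
#' @return the library with records attached.
#' @export
attach_scores <- function(library, scores) {
  new_screen_library(library$molecules, records = scores,
                     provenance = library$provenance)
}

#' Write a ranked shortlist to CSV
#'
#' Columns `id, smiles, score_total, cluster_size, max_tc_to_known, flags`
#' in rank order.
#'
#' @param shortlist data frame as returned by [build_shortlist()].
#' @param path output file.
#' @param allow_empty write a header-only file when the shortlist is empty.
#' @export
write_shortlist <- function(shortlist, path, allow_empty = FALSE) {
  cols <- c("id", "smiles", "score_total", "cluster_size",
            "max_tc_to_known", "flags")
  if (nrow(shortlist) == 0 && !allow_empty)
    stop("refusing to write an empty shortlist (set allow_empty = TRUE)")
  out <- as.data.frame(shortlist)[, cols, drop = FALSE]
  ok <- tryCatch({ write.csv(out, path, row.names = FALSE); TRUE },
                 error = function(e) stop("cannot write shortlist: ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Read a shortlist written by [write_shortlist()]
#' @param path CSV file.
#' @return data frame in rank order.
#' @export
read_shortlist <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(id = "character"))
  df
}
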