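# Analog expansion: build a SMARTS scaffold pattern from a hit core and
# search a library for molecules containing it.

# Tokenize a SMILES string into atom and syntax tokens with character
# positions. Handles bracket atoms, two-letter halogens, the aromatic
# organic subset, ring-closure digits and branches.
smiles_tokens <- function(s) {
  chars <- strsplit(s, "")[[1]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced bracket in SMILES: ", s)
      toks[[length(toks) + 1L]] <- list(
        token = paste(chars[i:j], collapse = ""), start = i, end = j,
        atom = TRUE, aromatic = grepl("^\\[[a-z]", paste(chars[i:j],
                                                         collapse = "")))
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in%
                 c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      toks[[length(toks) + 1L]] <- list(token = paste0(ch, chars[i + 1L]),
                                        start = i, end = i + 1L,
                                        atom = TRUE, aromatic = FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      toks[[length(toks) + 1L]] <- list(token = ch, start = i, end = i,
                                        atom = TRUE, aromatic = FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      toks[[length(toks) + 1L]] <- list(token = ch, start = i, end = i,
                                        atom = TRUE, aromatic = TRUE)
      i <- i + 1L
    } else {
      toks[[length(toks) + 1L]] <- list(token = ch, start = i, end = i,
                                        atom = FALSE, aromatic = FALSE)
      i <- i + 1L
    }
  }
  toks
}

#' Build a SMARTS scaffold pattern from a core molecule
#'
#' Non-variable atoms keep their element, aromaticity and ring topology
#' (the core SMILES is used as the SMARTS backbone). Two generalization
#' levels are applied at the variable sites: a terminal connected group of
#' variable atoms (attached to the fixed part by a single bond and written
#' contiguously in the input SMILES) is collapsed to a single
#' any-aromatic-ring-atom (`[a;R]`) attachment, so analogs carrying any
#' aromatic ring at that position match regardless of ring size; other
#' variable atoms are generalized in place (`a` for aromatic, `*`
#' otherwise). The constructed pattern is validated to match the core
#' itself.
#'
#' @param core core SMILES.
#' @param variable_atoms integer atom indices (in input SMILES atom order)
#'   to generalize; must be non-empty.
#' @param collapse_terminal collapse terminal variable groups to `[a;R]`
#'   (default TRUE).
#' @return a `scaffold_pattern`: list with `pattern` (SMARTS), `core`,
#'   `variable_sites`.
#' @export
build_pattern <- function(core, variable_atoms, collapse_terminal = TRUE) {
  if (!length(variable_atoms)) stop("at least one variable site required")
  toks <- smiles_tokens(core)
  atom_tok <- which(vapply(toks, `[[`, logical(1), "atom"))
  n_atoms <- length(atom_tok)
  if (any(variable_atoms < 1 | variable_atoms > n_atoms))
    stop("variable atom index out of range (core has ", n_atoms, " atoms)")
  graphs <- mol_graphs(setNames(core, "core"))
  g <- graphs[[1]]
  if (length(g$elem) != n_atoms)
    stop("tokenizer/parser atom count mismatch for core SMILES")

  edges <- do.call(rbind, lapply(seq_along(g$adj), function(i) {
    nb <- g$adj[[i]]; if (length(nb)) cbind(i, nb) else NULL
  }))
  ig <- igraph::graph_from_edgelist(unique(t(apply(edges, 1, sort))),
                                    directed = FALSE)
  if (igraph::vcount(ig) < n_atoms)
    ig <- igraph::add_vertices(ig, n_atoms - igraph::vcount(ig))
  sub <- igraph::induced_subgraph(ig, variable_atoms)
  comps <- igraph::components(sub)
  comp_sets <- split(variable_atoms, comps$membership)

  s <- core
  # process edits right-to-left so character positions stay valid
  edits <- list()
  for (cs in comp_sets) {
    cs <- sort(cs)
    external <- unique(unlist(lapply(cs, function(i)
      setdiff(g$adj[[i]], cs))))
    span <- range(unlist(lapply(atom_tok[cs], function(k)
      c(toks[[k]]$start, toks[[k]]$end))))
    fixed_inside <- any(vapply(setdiff(seq_len(n_atoms), cs), function(i) {
      st <- toks[[atom_tok[i]]]$start
      st >= span[1] && st <= span[2]
    }, logical(1)))
    if (collapse_terminal && length(external) == 1 && !fixed_inside) {
      # extend span over trailing ring-closure digits
      e <- span[2]
      nchar_s <- nchar(core)
      while (e < nchar_s && substr(core, e + 1, e + 1) %in%
               c(as.character(0:9), "%")) e <- e + 1
      # aromatic-ring groups collapse to an any-aromatic-ring atom;
      # aliphatic groups to an unconstrained attachment
      group_aromatic <- any(vapply(cs, function(i)
        toks[[atom_tok[i]]]$aromatic, logical(1)))
      edits[[length(edits) + 1L]] <- list(start = span[1], end = e,
                                          repl = if (group_aromatic)
                                            "[a;R]" else "*")
    } else {
      for (i in cs) {
        tk <- toks[[atom_tok[i]]]
        repl <- if (tk$aromatic) "a" else "*"
        edits[[length(edits) + 1L]] <- list(start = tk$start, end = tk$end,
                                            repl = repl)
      }
    }
  }
  ord <- order(vapply(edits, `[[`, numeric(1), "start"), decreasing = TRUE)
  for (e in edits[ord])
    s <- paste0(substr(s, 1, e$start - 1), e$repl,
                substring(s, e$end + 1))

  pat <- structure(list(pattern = s, core = core,
                        variable_sites = sort(unique(variable_atoms))),
                   class = "scaffold_pattern")
  hits <- tryCatch(substructure_search(
    screen_library("core", core), pat),
    error = function(e) stop("constructed pattern is not a valid SMARTS ",
                             "(disconnected core after generalization?): ",
                             s))
  if (!length(hits))
    stop("constructed pattern does not match the core itself: ", s)
  pat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scaffold_pattern <- function(x, ...) {
  cat("scaffold_pattern:", x$pattern, "\n  core:", x$core,
      "\n  variable sites:", paste(x$variable_sites, collapse = ","), "\n")
  invisible(x)
}

#' Substructure search over a library
#'
#' Returns the ids of all molecules containing at least one embedding of
#' the pattern, in library order.
#'
#' @param library a `screen_library`.
#' @param pattern a `scaffold_pattern` or SMARTS string.
#' @return character vector of molecule ids.
#' @export
substructure_search <- function(library, pattern) {
  smarts <- if (is(pattern, "scaffold_pattern")) pattern$pattern
  else as.character(pattern)
  if (!length(library)) return(character(0))
  sdf <- smiles_sdfset(library)
  counts <- ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE)
  library$molecules$id[counts > 0]
}
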