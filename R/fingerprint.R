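# Morgan (circular, ECFP-style) fingerprints over the molecular graph.
#
# Implemented natively so that bit length and radius match the pipeline's
# defaults (2048 bits, radius 2) and fingerprinting stays fast at library
# scale. Atom-order invariance follows from using only graph-invariant
# initial atom codes and sorted neighbor lists in the iterative hashing.

ATOMIC_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                    P = 15, S = 16, Cl = 17, Br = 35, I = 53)

# 31-bit multiplicative mixing; exact integer arithmetic in doubles.
h_mix <- function(h, x) (h * 31 + x) %% 2147483647

# Connection tables for a set of SMILES: elements, adjacency, bond orders,
# ring membership. Indices follow the input atom order of each SMILES.
mol_graphs <- function(smiles) {
  smiles <- lib_smiles(smiles)
  sdf <- smiles_sdfset(smiles)
  lapply(seq_along(sdf), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    elem <- sub("_.*$", "", rownames(ab))
    n <- length(elem)
    adj <- vector("list", n); bord <- vector("list", n)
    for (k in seq_len(n)) { adj[[k]] <- integer(0); bord[[k]] <- integer(0) }
    bb <- tryCatch(ChemmineR::bondblock(sdf[[i]]), error = function(e) NULL)
    inring <- rep(FALSE, n)
    if (!is.null(bb) && length(dim(bb)) == 2 && nrow(bb) > 0 &&
        ncol(bb) >= 3) {
      a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
      bo <- as.integer(bb[, 3])
      for (k in seq_along(a1)) {
        adj[[a1[k]]] <- c(adj[[a1[k]]], a2[k])
        adj[[a2[k]]] <- c(adj[[a2[k]]], a1[k])
        bord[[a1[k]]] <- c(bord[[a1[k]]], bo[k])
        bord[[a2[k]]] <- c(bord[[a2[k]]], bo[k])
      }
      g <- igraph::graph_from_edgelist(cbind(a1, a2), directed = FALSE)
      if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
      ring_edges <- setdiff(seq_along(a1), igraph::bridges(g))
      inring[unique(c(a1[ring_edges], a2[ring_edges]))] <- TRUE
    }
    list(elem = elem, adj = adj, bord = bord, inring = inring,
         degree = lengths(adj))
  })
}

morgan_bits_one <- function(g, radius, nbits) {
  n <- length(g$elem)
  z <- ATOMIC_NUMBERS[g$elem]
  z[is.na(z)] <- 0
  sumbo <- vapply(g$bord, sum, numeric(1))
  cur <- numeric(n)
  for (i in seq_len(n)) {
    h <- h_mix(5381, z[i])
    h <- h_mix(h, g$degree[i])
    h <- h_mix(h, sumbo[i])
    h <- h_mix(h, as.integer(g$inring[i]))
    cur[i] <- h
  }
  feats <- cur
  if (radius > 0) for (r in seq_len(radius)) {
    nxt <- numeric(n)
    for (i in seq_len(n)) {
      h <- h_mix(5381, r)
      h <- h_mix(h, cur[i])
      nb <- g$adj[[i]]
      if (length(nb)) {
        bo <- g$bord[[i]]
        hv <- cur[nb]
        o <- order(bo, hv)
        for (k in o) { h <- h_mix(h, bo[k]); h <- h_mix(h, hv[k]) }
      }
      nxt[i] <- h
    }
    cur <- nxt
    feats <- c(feats, cur)
  }
  sort(unique(as.integer(feats %% nbits) + 1L))
}

#' Morgan fingerprints for a set of molecules
#'
#' Circular substructure fingerprints (ECFP-style) hashed to a fixed bit
#' length. Deterministic for a given structure and invariant to atom input
#' order.
#'
#' @param x a `screen_library` or character vector of SMILES.
#' @param radius neighborhood radius (default 2, the ECFP4 equivalent).
#' @param nbits fingerprint length (default 2048).
#' @return an `fp_set`: list with `bits` (per-molecule sorted bit indices),
#'   `ids`, `radius`, `nbits`.
#' @export
morgan_fp <- function(x, radius = 2, nbits = 2048) {
  stopifnot(radius >= 0, nbits > 0)
  smiles <- lib_smiles(x)
  # canonicalize first: kekule assignments from the parser depend on the
  # written atom order, and the fingerprint must not
  can <- canonical_smiles(unname(smiles))
  bad <- is.na(can)
  if (any(bad))
    stop("unparsable structure for: ",
         paste(names(smiles)[bad], collapse = ", "))
  graphs <- if (length(smiles))
    mol_graphs(setNames(can, names(smiles))) else list()
  bits <- lapply(graphs, morgan_bits_one, radius = radius, nbits = nbits)
  structure(list(bits = bits, ids = names(smiles),
                 radius = radius, nbits = nbits),
            class = "fp_set")
}

#' @export
print.fp_set <- function(x, ...) {
  cat("fp_set:", length(x$bits), "fingerprints (radius", x$radius,
      ", ", x$nbits, "bits)\n")
  invisible(x)
}

#' @export
`[.fp_set` <- function(x, i) {
  structure(list(bits = x$bits[i], ids = x$ids[i],
                 radius = x$radius, nbits = x$nbits), class = "fp_set")
}

fp_bits <- function(x) {
  if (is(x, "fp_set")) {
    if (length(x$bits) != 1) stop("expected a single fingerprint")
    x$bits[[1]]
  } else if (is.numeric(x)) as.integer(sort(unique(x)))
  else stop("not a fingerprint")
}

fp_params <- function(x) {
  if (is(x, "fp_set")) c(x$radius, x$nbits) else c(NA_real_, NA_real_)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a intersect b| / |a union b|`. Two empty bit sets have similarity 0.
#'
#' @param a,b single fingerprints (length-1 `fp_set` subsets) or integer
#'   vectors of set bit indices. `fp_set` inputs must share radius and bit
#'   length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  pa <- fp_params(a); pb <- fp_params(b)
  if (!anyNA(c(pa, pb)) && !identical(pa, pb))
    stop("fingerprints have mismatched radius/nbits")
  ba <- fp_bits(a); bb <- fp_bits(b)
  u <- length(ba) + length(bb) - (i <- length(intersect(ba, bb)))
  if (u == 0) return(0)
  i / u
}

# Max Tanimoto of each query fingerprint against a reference fp_set.
tc_max <- function(query, refs) {
  if (!length(refs$bits)) return(rep(NA_real_, length(query$bits)))
  nbits <- query$nbits
  m <- matrix(0, nrow = nbits, ncol = length(refs$bits))
  for (j in seq_along(refs$bits)) m[refs$bits[[j]], j] <- 1
  pc_ref <- lengths(refs$bits)
  vapply(query$bits, function(bits) {
    if (!length(bits)) return(0)
    inter <- colSums(m[bits, , drop = FALSE])
    max(inter / (pc_ref + length(bits) - inter))
  }, numeric(1))
}
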