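# Independent oracles used to check the package's implementations, kept
# deliberately naive (enumeration / all-pairs / brute force).

# Brute-force leader clustering on raw bit sets, processed best score
# first with lexicographic-id tie break.
oracle_leader_cluster <- function(bits, scores, ids, cutoff) {
  ord <- order(scores, ids)
  reps <- integer(0)
  assign <- integer(length(scores))
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      r <- reps[k]
      u <- union(bits[[i]], bits[[r]])
      tcv <- if (length(u)) length(intersect(bits[[i]], bits[[r]])) /
        length(u) else 0
      if (tcv > cutoff) { assign[i] <- k; placed <- TRUE; break }
    }
    if (!placed) { reps <- c(reps, i); assign[i] <- length(reps) }
  }
  list(rep_idx = reps, assign = assign)
}

# O(n^2) all-pairs contact scan.
oracle_contacts <- function(model, cutoff) {
  at <- model$atoms
  rec <- at[!at$ligand & toupper(at$element) != "H", ]
  lig <- at[at$ligand & toupper(at$element) != "H", ]
  keys <- character(0)
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((rec$x[i] - lig$x[j])^2 + (rec$y[i] - lig$y[j])^2 +
                  (rec$z[i] - lig$z[j])^2)
      if (d <= cutoff) {
        keys <- c(keys, paste(rec$chain[i], rec$resno[i], rec$atom[i]))
        break
      }
    }
  }
  sort(unique(keys))
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# Brute-force symmetry-corrected RMSD: minimum over all element- and
# adjacency-preserving atom permutations.
oracle_sym_rmsd <- function(A, B, elements, bonds) {
  n <- nrow(A)
  adj <- matrix(FALSE, n, n)
  if (!is.null(bonds) && nrow(bonds))
    for (k in seq_len(nrow(bonds))) {
      adj[bonds[k, 1], bonds[k, 2]] <- TRUE
      adj[bonds[k, 2], bonds[k, 1]] <- TRUE
    }
  best <- Inf
  for (p in all_perms(n)) {
    p <- as.integer(p)
    if (!identical(elements, elements[p])) next
    if (!identical(adj, adj[p, p])) next
    best <- min(best, sqrt(mean(rowSums((A - B[p, , drop = FALSE])^2))))
  }
  best
}

# A small diverse SMILES fixture set.
fixture_smiles <- function() c(
  s01 = "c1ccccc1CCO",        s02 = "c1ccccc1CCN",
  s03 = "c1ccncc1CCO",        s04 = "CC(=O)Nc1ccccc1",
  s05 = "CC(=O)Nc1ccncc1",    s06 = "C1CCCCC1CO",
  s07 = "C1CCCCC1CN",         s08 = "c1ccoc1C(=O)N",
  s09 = "c1ccsc1C(=O)N",      s10 = "CCCCCCO",
  s11 = "CCCCCCN",            s12 = "c1ccccc1c1ccccc1",
  s13 = "OCCOCCO",            s14 = "CN(C)CCc1ccccc1",
  s15 = "CC(C)Cc1ccc(C)cc1",  s16 = "c1cc[nH]c1CCO",
  s17 = "ClCCCl",             s18 = "c1ccc(F)cc1CO",
  s19 = "CC(O)CC(O)C",        s20 = "c1ccccc1OC")
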