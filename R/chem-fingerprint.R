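# Morgan-style circular fingerprints.
#
# An ECFP-type scheme: per-atom initial invariants (element, formal charge,
# heavy-atom degree, implicit hydrogen count, ring membership) are refined for
# two iterations by hashing the sorted (bond order, neighbour identifier)
# lists, and every identifier from radii 0..2 is folded into a fixed-length
# bit vector. Deterministic by construction; computed on the canonical
# aromatic form so every spelling of a molecule yields identical bits.

FP_NBITS <- 2048L

# default valences used to derive implicit hydrogen counts
.cg_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                 I = 1, B = 3, Si = 4)

# deterministic polynomial hash of an integer vector into [0, 2^31 - 2]
cg_hash_ints <- function(v) {
  m <- 2147483647
  h <- 17
  for (x in v) h <- (h * 31 + (x %% m)) %% m
  h
}

# molecular graph from one SDF component: list(elem, charge, degree, hcount,
# ring, bonds = 2-col matrix + order)
cg_molgraph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- gsub("_.*$", "", rownames(ab))
  n <- length(elem)
  chg_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge <- ifelse(chg_code == 0, 0, 4 - chg_code)  # MDL old-style codes
  charge[chg_code == 4] <- 0                         # radical flag, not charge
  bonds <- matrix(numeric(0), ncol = 3)
  # atom-only molecules yield a 1x2 placeholder block; require real bond rows
  if (!is.null(bb) && is.matrix(bb) && ncol(bb) >= 3 && nrow(bb) > 0) {
    bonds <- cbind(bb[, 1], bb[, 2], bb[, 3])
  }
  degree <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  bondsum <- rep(0, n)
  if (nrow(bonds)) {
    ord <- ifelse(bonds[, 3] == 4, 1.5, bonds[, 3])  # aromatic SDF bonds
    for (k in seq_len(nrow(bonds))) {
      bondsum[bonds[k, 1]] <- bondsum[bonds[k, 1]] + ord[k]
      bondsum[bonds[k, 2]] <- bondsum[bonds[k, 2]] + ord[k]
    }
  }
  defv <- .cg_valence[elem]
  defv[is.na(defv)] <- 0
  hcount <- pmax(0, round(defv + charge - bondsum))
  ring <- rep(FALSE, n)
  if (nrow(bonds) >= 3) {
    g <- igraph::graph_from_edgelist(cbind(bonds[, 1], bonds[, 2]),
                                     directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    in_cycle <- setdiff(seq_len(nrow(bonds)), as.integer(br))
    ring[unique(c(bonds[in_cycle, 1], bonds[in_cycle, 2]))] <- TRUE
  }
  list(elem = elem, charge = charge, degree = degree, hcount = hcount,
       ring = ring, bonds = bonds)
}

cg_ecfp_bits <- function(graph, radius = 2L, nbits = FP_NBITS) {
  n <- length(graph$elem)
  if (n == 0L) return(integer(0))
  elem_code <- vapply(graph$elem, function(e) {
    cg_hash_ints(utf8ToInt(e))
  }, numeric(1))
  ids <- vapply(seq_len(n), function(i) {
    cg_hash_ints(c(elem_code[i], graph$charge[i], graph$degree[i],
                   graph$hcount[i], as.integer(graph$ring[i])))
  }, numeric(1))
  all_ids <- ids
  nbr <- vector("list", n)
  if (nrow(graph$bonds)) {
    for (k in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds[k, 1]; b <- graph$bonds[k, 2]; o <- graph$bonds[k, 3]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  for (r in seq_len(radius)) {
    new_ids <- ids
    for (i in seq_len(n)) {
      if (is.null(nbr[[i]])) next
      pairs <- cbind(nbr[[i]][, 2], ids[nbr[[i]][, 1]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      new_ids[i] <- cg_hash_ints(c(r, ids[i], as.vector(t(pairs))))
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  sort(unique(as.integer(all_ids %% nbits)))
}

new_fingerprint <- function(on_bits, nbits = FP_NBITS) {
  bits <- integer(nbits)
  bits[on_bits + 1L] <- 1L
  structure(bits, class = "cg_fingerprint")
}

#' @export
print.cg_fingerprint <- function(x, ...) {
  cat(sprintf("<circular fingerprint: %d bits, %d set>\n",
              length(x), sum(x)))
  invisible(x)
}

# batched fingerprints for a vector of SMILES; returns a named list keyed by
# position; errors if any SMILES is invalid
cg_fingerprints <- function(smiles) {
  canon <- canonicalize_smiles(smiles)
  if (anyNA(canon)) {
    stop("invalid SMILES: ", paste(smiles[is.na(canon)], collapse = ", "),
         call. = FALSE)
  }
  cache <- cg_cache_get_env("fingerprint")
  res <- vector("list", length(smiles))
  need <- unique(canon[vapply(canon, function(s) is.null(cache[[s]]), logical(1))])
  if (length(need)) {
    nm <- paste0("m", seq_along(need))
    sdfset <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(need, nm)))
    kept <- ChemmineR::sdfid(sdfset)
    for (j in seq_along(need)) {
      k <- match(nm[j], kept)
      if (is.na(k)) stop("SMILES->SDF conversion failed for: ", need[j],
                         call. = FALSE)
      graph <- cg_molgraph(sdfset[[k]])
      cache[[need[j]]] <- new_fingerprint(cg_ecfp_bits(graph))
    }
  }
  for (i in seq_along(canon)) res[[i]] <- cache[[canon[i]]]
  res
}

#' Morgan-style circular fingerprint
#'
#' Radius-2 circular substructure fingerprint folded to 2048 bits, in the
#' spirit of the extended-connectivity (ECFP4/Morgan) family: atom
#' environments up to two bonds away are hashed from element, formal charge,
#' degree, implicit-hydrogen and ring-membership invariants. The molecule is
#' canonicalized before hashing, so all spellings of one molecule map to the
#' same bit vector. The hashing scheme is deterministic but its bit positions
#' are this package's own, not those of any external toolkit.
#'
#' @param smiles a single valid SMILES string.
#' @param nbits fingerprint length in bits (default 2048).
#' @return an integer 0/1 vector of class `cg_fingerprint`.
#' @export
morgan_fingerprint <- function(smiles, nbits = FP_NBITS) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (nbits != FP_NBITS) {
    canon <- canonicalize_smiles(smiles)
    if (is.na(canon)) stop("invalid SMILES: ", smiles, call. = FALSE)
    nm <- c(m1 = canon)
    sdfset <- suppressWarnings(ChemmineR::smiles2sdf(nm))
    return(new_fingerprint(cg_ecfp_bits(cg_molgraph(sdfset[[1]]), nbits = nbits),
                           nbits = nbits))
  }
  cg_fingerprints(smiles)[[1]]
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection-over-union of the on-bit sets:
#' \deqn{T(a,b) = \sum_i a_i b_i / \sum_j (a_j + b_j - a_j b_j).}
#' Two all-zero fingerprints share no evidence of structure and are assigned
#' similarity 0 (the 0/0 case).
#'
#' @param a,b fingerprints from [morgan_fingerprint()] (or any equal-length
#'   0/1 vectors).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ", call. = FALSE)
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0) return(0)
  inter / union
}

#' Tanimoto similarity between SMILES strings
#'
#' Convenience wrapper: fingerprints `x` once and compares it to every
#' element of `y`.
#'
#' @param x a single valid SMILES string.
#' @param y character vector of valid SMILES strings.
#' @return numeric vector of similarities in `[0, 1]`.
#' @export
tanimoto_smiles <- function(x, y) {
  fx <- morgan_fingerprint(x)
  fys <- cg_fingerprints(y)
  vapply(fys, function(fy) tanimoto(fx, fy), numeric(1))
}
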