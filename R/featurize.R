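#' Fingerprint configuration
#'
#' Configuration for hashed circular (Morgan-style) fingerprints. The default
#' radius of 4 corresponds to diameter-8 atom environments (the "ECFP8"
#' convention) hashed to 4096 bits.
#'
#' @param radius Neighborhood radius (number of hashing iterations); radius 4
#'   covers atom environments of diameter 8.
#' @param n_bits Fingerprint length.
#' @param use_chirality If `TRUE`, tetrahedral parity (as perceived from the
#'   SMILES `@`/`@@` annotations) joins the atom invariants, so enantiomers
#'   receive different fingerprints.
#' @return An object of class `fingerprint_config`.
#' @export
fingerprint_config <- function(radius = 4L, n_bits = 4096L, use_chirality = FALSE) {
  radius <- check_count(radius, "radius", min = 0)
  n_bits <- check_count(n_bits, "n_bits", min = 1)
  structure(list(radius = radius, n_bits = n_bits,
                 use_chirality = isTRUE(use_chirality)),
            class = "fingerprint_config")
}

#' Tanimoto similarity between binary fingerprints
#'
#' `tanimoto()` computes the similarity of two binary vectors,
#' `|u AND v| / (|u| + |v| - |u AND v|)`. Two all-zero vectors are identical
#' and score 1 by convention (this keeps the kernel diagonal constant;
#' all-zero fingerprints are separately flagged upstream).
#' `tanimoto_matrix()` computes all pairwise similarities between the rows of
#' two 0/1 matrices in one linear-algebra pass.
#'
#' @param u,v Binary 0/1 vectors of equal length.
#' @param X,Y Binary 0/1 matrices with equal numbers of columns; `Y` defaults
#'   to `X`.
#' @return `tanimoto()`: a single similarity in \[0, 1\].
#'   `tanimoto_matrix()`: an `nrow(X)` by `nrow(Y)` similarity matrix.
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))  # |int| 2 / |union| 4 = 0.5
#' @export
tanimoto <- function(u, v) {
  if (length(u) != length(v)) {
    abort(sprintf("Fingerprint lengths differ: %d vs %d.", length(u), length(v)))
  }
  both <- sum(u * v)
  denom <- sum(u) + sum(v) - both
  if (denom == 0) return(1)
  both / denom
}

#' @rdname tanimoto
#' @export
tanimoto_matrix <- function(X, Y = X) {
  X <- check_fingerprints(X)
  Y <- check_fingerprints(Y)
  if (ncol(X) != ncol(Y)) {
    abort(sprintf("Fingerprint lengths differ: %d vs %d.", ncol(X), ncol(Y)))
  }
  common <- X %*% t(Y)
  denom <- outer(rowSums(X), rowSums(Y), "+") - common
  out <- common / denom
  out[denom == 0] <- 1  # identical empty sets
  out
}

#' Featurize SMILES as hashed circular fingerprints
#'
#' Parses SMILES through OpenBabel (via ChemmineR/ChemmineOB) and computes
#' Morgan-style hashed circular fingerprints on the molecular graph: each
#' heavy atom starts from an invariant code (element, heavy degree, implicit
#' hydrogen count, formal charge, aromaticity, and tetrahedral parity when
#' `use_chirality` is set), the codes are iteratively re-hashed together with
#' the sorted (bond class, neighbor code) list for `radius` rounds, and every
#' intermediate code sets one bit of the `n_bits`-long fingerprint. Bonds in
#' perceived aromatic rings are normalized to a single aromatic bond class so
#' that equivalent kekulized and aromatic SMILES of the same molecule map to
#' the same fingerprint. Exact bit positions are implementation-defined, as
#' with any hashed fingerprint.
#'
#' @param smiles Character vector of SMILES strings.
#' @param config A [fingerprint_config()].
#' @return A binary matrix with `length(smiles)` rows and `config$n_bits`
#'   columns; row i depends only on `smiles[i]` and the configuration.
#' @export
featurize_smiles <- function(smiles, config = fingerprint_config()) {
  if (!is.character(smiles) || length(smiles) == 0) {
    abort("`smiles` must be a non-empty character vector.")
  }
  for (pkg in c("ChemmineR", "ChemmineOB")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort(sprintf("Package '%s' is required for SMILES featurization.", pkg))
    }
  }
  if (!inherits(config, "fingerprint_config")) {
    abort("`config` must be created with fingerprint_config().")
  }
  names(smiles) <- sprintf("m%06d", seq_along(smiles))
  # OpenBabel drops unparseable entries from a batch, so fall back to
  # per-molecule parsing when the batch comes back short
  mols <- vector("list", length(smiles))
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  if (!is.null(sdf) && length(sdf) == length(smiles) &&
      all(suppressWarnings(ChemmineR::validSDF(sdf)))) {
    mols <- lapply(seq_along(smiles), function(i) sdf[[i]])
  } else {
    for (i in seq_along(smiles)) {
      one <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles[i])),
                      error = function(e) NULL)
      if (!is.null(one) && length(one) == 1 &&
          all(suppressWarnings(ChemmineR::validSDF(one)))) {
        mols[[i]] <- one[[1]]
      }
    }
  }
  out <- matrix(0, nrow = length(smiles), ncol = config$n_bits)
  for (i in seq_along(smiles)) {
    mol <- mols[[i]]
    graph <- if (!is.null(mol)) tryCatch(mol_graph(mol), error = function(e) NULL)
    if (is.null(graph) || graph$n == 0) {
      abort(sprintf("Unparseable SMILES '%s' at position %d.", smiles[i], i))
    }
    bits <- morgan_bits(graph, config)
    out[i, bits] <- 1
  }
  out
}

# MDL molfile old-style charge codes -> formal charge
.charge_codes <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)

# Extract a plain molecular graph (elements, charges, parities, bonds with
# aromatic perception, implicit H counts) from a ChemmineR SDF object.
mol_graph <- function(mol) {
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  n <- nrow(ab)
  elements <- sub("_.*$", "", rownames(ab))
  charge <- integer(n)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(ab[, "C6"])
    charge <- unname(ifelse(code %in% names(.charge_codes), .charge_codes[code], 0L))
  }
  parity <- if ("C7" %in% colnames(ab)) as.integer(ab[, "C7"]) else integer(n)

  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- matrix(integer(0), ncol = 3)
  } else {
    bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }

  # aromatic bond perception: bonds whose endpoints are consecutive members of
  # a ring that ChemmineR flags aromatic get bond class 4 (order 1.5)
  aromatic_atom <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    rings <- tryCatch(
      suppressWarnings(ChemmineR::rings(mol, type = "all", arom = TRUE)),
      error = function(e) NULL)
    if (!is.null(rings) && length(rings$RINGS) > 0 && any(rings$AROMATIC)) {
      for (ring in rings$RINGS[rings$AROMATIC]) {
        idx <- as.integer(sub("^.*_", "", ring))
        aromatic_atom[idx] <- TRUE
        pairs <- cbind(idx, c(idx[-1], idx[1]))
        for (r in seq_len(nrow(pairs))) {
          hit <- (bonds[, 1] == pairs[r, 1] & bonds[, 2] == pairs[r, 2]) |
                 (bonds[, 1] == pairs[r, 2] & bonds[, 2] == pairs[r, 1])
          bonds[hit, 3] <- 4L
        }
      }
    }
  }

  # implicit hydrogens from default valences (aromatic bonds count 1.5)
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1, B = 3)
  order_sum <- numeric(n)
  degree <- integer(n)
  if (nrow(bonds) > 0) {
    bo <- ifelse(bonds[, 3] == 4L, 1.5, bonds[, 3])
    for (r in seq_len(nrow(bonds))) {
      for (a in bonds[r, 1:2]) {
        order_sum[a] <- order_sum[a] + bo[r]
        degree[a] <- degree[a] + 1L
      }
    }
  }
  val <- unname(valence[elements])
  val[is.na(val)] <- 0
  n_h <- pmax(0, round(val + charge - order_sum))

  list(n = n, elements = elements, charge = charge, parity = parity,
       degree = degree, n_h = as.integer(n_h), aromatic = aromatic_atom,
       bonds = bonds)
}

# Deterministic integer hash of an integer vector into [0, 2^31 - 2].
hash_ints <- function(v) {
  h <- 17
  m <- 2147483629  # prime below 2^31; h * 31 + v stays exactly representable
  for (x in v) {
    h <- (h * 31 + (x %% m)) %% m
  }
  h
}

.element_symbols <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
                      "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
                      "Se", "Br", "I", "Sn", "Zn", "Fe", "Cu", "Mn", "Co", "Ni")

# Morgan-style iterative neighborhood hashing; returns 1-based bit indices.
morgan_bits <- function(graph, config) {
  elem_num <- match(graph$elements, .element_symbols)
  elem_num[is.na(elem_num)] <- 0L
  parity <- if (config$use_chirality) graph$parity else integer(graph$n)
  codes <- vapply(seq_len(graph$n), function(a) {
    hash_ints(c(elem_num[a], graph$degree[a], graph$n_h[a], graph$charge[a] + 4L,
                as.integer(graph$aromatic[a]), parity[a]))
  }, numeric(1))

  nbrs <- vector("list", graph$n)
  if (nrow(graph$bonds) > 0) {
    for (r in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds[r, 1]; b <- graph$bonds[r, 2]; o <- graph$bonds[r, 3]
      nbrs[[a]] <- rbind(nbrs[[a]], c(o, b))
      nbrs[[b]] <- rbind(nbrs[[b]], c(o, a))
    }
  }

  all_codes <- codes
  for (iter in seq_len(config$radius)) {
    codes <- vapply(seq_len(graph$n), function(a) {
      nb <- nbrs[[a]]
      if (is.null(nb)) return(hash_ints(c(iter, codes[a])))
      pairs <- cbind(nb[, 1], codes[nb[, 2]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      hash_ints(c(iter, codes[a], as.vector(t(pairs))))
    }, numeric(1))
    all_codes <- c(all_codes, codes)
  }
  unique(as.integer(all_codes %% config$n_bits) + 1L)
}
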