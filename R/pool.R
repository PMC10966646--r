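#' Construct a compound pool
#'
#' A compound pool is the central data container of the package: a tibble with
#' one row per compound, carrying a unique `id`, a true potency in pK units
#' (pKi or pIC50; higher is more potent), an optional `cluster_id` recording
#' which congeneric series a synthetic compound belongs to, an optional
#' `smiles` column, and a `fingerprint` matrix column of binary (0/1)
#' substructure fingerprints.
#'
#' @param ids Character vector of unique compound identifiers.
#' @param potency Numeric vector of potencies in pK units, one per compound.
#' @param fingerprints Binary 0/1 matrix with one row per compound, or `NULL`
#'   if fingerprints are to be attached later (e.g. via [featurize_smiles()]).
#' @param cluster_id Optional integer vector of cluster memberships.
#' @param smiles Optional character vector of SMILES strings.
#'
#' @return A tibble of class `compound_pool` with columns `id`, `potency`,
#'   optionally `cluster_id` and `smiles`, and a matrix column `fingerprint`
#'   when fingerprints are supplied.
#'
#' @examples
#' fp <- matrix(c(1, 0, 1, 1, 1, 0), nrow = 3)
#' compound_pool(c("a", "b", "c"), c(6.2, 7.1, 5.9), fp)
#' @export
compound_pool <- function(ids, potency, fingerprints = NULL, cluster_id = NULL,
                          smiles = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("Compound ids must be unique; duplicated: %s.",
                  paste(head(dup, 5), collapse = ", ")))
  }
  if (!is.numeric(potency) || length(potency) != length(ids)) {
    abort("`potency` must be a numeric vector with one value per id.")
  }
  if (any(!is.finite(potency))) {
    abort(sprintf("Non-finite potency at row(s): %s.",
                  paste(head(which(!is.finite(potency)), 5), collapse = ", ")))
  }
  out <- tibble::tibble(id = ids, potency = as.numeric(potency))
  if (!is.null(cluster_id)) {
    if (length(cluster_id) != length(ids)) {
      abort("`cluster_id` must have one value per id.")
    }
    out$cluster_id <- as.integer(cluster_id)
  }
  if (!is.null(smiles)) {
    if (length(smiles) != length(ids)) {
      abort("`smiles` must have one value per id.")
    }
    out$smiles <- as.character(smiles)
  }
  if (!is.null(fingerprints)) {
    fingerprints <- check_fingerprints(fingerprints, n = length(ids))
    rownames(fingerprints) <- ids
    out$fingerprint <- fingerprints
  }
  class(out) <- c("compound_pool", class(out))
  out
}

check_fingerprints <- function(fp, n = NULL) {
  if (!is.matrix(fp)) fp <- as.matrix(fp)
  storage.mode(fp) <- "numeric"
  if (!is.null(n) && nrow(fp) != n) {
    abort(sprintf("Fingerprint matrix has %d rows but the pool has %d compounds.",
                  nrow(fp), n))
  }
  if (any(!(fp == 0 | fp == 1))) {
    abort("Fingerprint entries must all be 0 or 1.")
  }
  if (!is.null(n) && any(rowSums(fp) == 0)) {
    warn(sprintf("%d compound(s) have an all-zero fingerprint; Tanimoto similarity to them is degenerate.",
                 sum(rowSums(fp) == 0)))
  }
  fp
}

#' Population standard deviation of a pool's potencies
#'
#' Recomputed from the `potency` column on every call, so it is always
#' consistent with the pool. This is the sigma that the label-noise experiment
#' scales its Gaussian noise by (see [add_label_noise()]).
#'
#' @param pool A [compound_pool()].
#' @return A single non-negative number in pK units.
#' @export
potency_sd <- function(pool) {
  p <- pool$potency
  sqrt(mean((p - mean(p))^2))
}

pool_fingerprints <- function(pool) {
  if (!"fingerprint" %in% names(pool)) {
    abort("This pool has no fingerprints; attach them (e.g. with featurize_smiles()) first.")
  }
  fp <- pool$fingerprint
  if (!is.matrix(fp)) fp <- as.matrix(fp)
  fp
}

#' Convert a relative binding free energy to pKi
#'
#' Relative binding free energies (ddG, in kJ/mol, relative to a reference
#' compound with known absolute binding free energy `dg_ref`) are converted to
#' the more interpretable pKi scale via `pKi = -(dg_ref + ddg) * 1000 /
#' (R * T * ln 10)` with the gas constant R = 8.314 J/(mol K). The mapping is
#' affine and strictly decreasing in `ddg`: more negative total free energy
#' means tighter binding and higher pKi.
#'
#' @param ddg Numeric vector of relative binding free energies in kJ/mol.
#' @param dg_ref Absolute binding free energy of the reference compound in
#'   kJ/mol. Defaults to -47.778, the reference value for the TYK2 congeneric
#'   library this conversion is typically applied to.
#' @param temperature Absolute temperature in kelvin; defaults to the standard
#'   298.15 K (the temperature is a convention, not a property of the data).
#'
#' @return Numeric vector of pKi values.
#'
#' @examples
#' ddg_to_pki(0)                      # the reference compound itself
#' ddg_to_pki(47.778, dg_ref = -47.778)  # total free energy zero -> pKi 0
#' @export
ddg_to_pki <- function(ddg, dg_ref = -47.778, temperature = 298.15) {
  if (any(!is.finite(ddg))) {
    abort(sprintf("Non-finite ddG at position(s): %s.",
                  paste(head(which(!is.finite(ddg)), 5), collapse = ", ")))
  }
  check_number(dg_ref, "dg_ref")
  check_number(temperature, "temperature", min = 0, strict = TRUE)
  R <- 8.314 # J/(mol K)
  -(dg_ref + ddg) * 1000 / (R * temperature * log(10))
}

#' Read a compound pool from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row, an `id` column and
#' the named potency column. Fingerprints may be supplied alongside as a dense
#' 0/1 matrix file with one row per compound (same order as the CSV) and one
#' column per bit, in bit-index order, without a header. If no fingerprint
#' file is given and a `smiles` column is present, the SMILES are kept so the
#' caller can featurize with [featurize_smiles()].
#'
#' @param path Path to the pool CSV.
#' @param potency_column Name of the potency column (e.g. `"pKi"`, `"pIC50"`,
#'   `"ddG_kJmol"`).
#' @param conversion Optional conversion applied to the potency column; the
#'   only recognized value is `"ddg_to_pki"`, which applies [ddg_to_pki()]
#'   row-wise with its default reference free energy and temperature.
#' @param fingerprint_path Optional path to the dense fingerprint matrix file.
#'
#' @return A [compound_pool()].
#' @seealso [write_pool_csv()]
#' @export
read_pool_csv <- function(path, potency_column = "pKi", conversion = NULL,
                          fingerprint_path = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"id" %in% names(raw)) abort(sprintf("'%s' has no `id` column.", path))
  if (!potency_column %in% names(raw)) {
    abort(sprintf("'%s' has no `%s` column (columns: %s).", path, potency_column,
                  paste(names(raw), collapse = ", ")))
  }
  if (anyDuplicated(raw$id)) {
    row <- which(duplicated(raw$id))[1]
    abort(sprintf("Duplicate id '%s' at data row %d of '%s'.", raw$id[row], row, path))
  }
  potency <- suppressWarnings(as.numeric(raw[[potency_column]]))
  if (any(is.na(potency))) {
    row <- which(is.na(potency))[1]
    abort(sprintf("Non-numeric %s value '%s' at data row %d of '%s'.",
                  potency_column, raw[[potency_column]][row], row, path))
  }
  if (!is.null(conversion)) {
    if (!identical(conversion, "ddg_to_pki")) {
      abort(sprintf("Unknown conversion '%s'; the only supported value is \"ddg_to_pki\".",
                    conversion))
    }
    potency <- ddg_to_pki(potency)
  }
  cluster_id <- if ("cluster_id" %in% names(raw)) as.integer(raw$cluster_id)
  smiles <- if ("smiles" %in% names(raw)) raw$smiles
  fingerprints <- NULL
  if (!is.null(fingerprint_path)) {
    fingerprints <- as.matrix(utils::read.table(fingerprint_path, header = FALSE,
                                                sep = ",", colClasses = "numeric"))
    dimnames(fingerprints) <- NULL
  }
  compound_pool(raw$id, potency, fingerprints = fingerprints,
                cluster_id = cluster_id, smiles = smiles)
}

#' Write a compound pool to CSV
#'
#' Writes the tabular part of the pool (id, potency as a `pKi` column,
#' cluster_id and smiles when present) as a comma-separated file with a header
#' row, and optionally the fingerprint matrix as a dense 0/1 comma-separated
#' file with one row per compound in the same order and one column per bit in
#' bit-index order. Potencies are written with full round-trip precision, so
#' writing and re-reading a pool reproduces it exactly.
#'
#' @param pool A [compound_pool()].
#' @param path Output CSV path.
#' @param fingerprint_path Optional output path for the fingerprint matrix.
#' @return `path`, invisibly.
#' @export
write_pool_csv <- function(pool, path, fingerprint_path = NULL) {
  tab <- tibble::tibble(id = pool$id, pKi = pool$potency)
  if ("cluster_id" %in% names(pool)) tab$cluster_id <- pool$cluster_id
  if ("smiles" %in% names(pool)) tab$smiles <- pool$smiles
  readr::write_csv(tab, path, progress = FALSE)
  if (!is.null(fingerprint_path)) {
    fp <- pool_fingerprints(pool)
    utils::write.table(fp, fingerprint_path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
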