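# The 20 standard amino acids; the atom-type alphabet is closed over these.
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

is_hydrogen_name <- function(elety, elesy = NULL) {
  h <- rep(FALSE, length(elety))
  if (!is.null(elesy)) {
    sy <- toupper(trimws(elesy))
    h <- h | (!is.na(sy) & sy %in% c("H", "D"))
  }
  # strip leading digits ("1HB2"); heavy amino-acid atoms never start with H/D
  stripped <- sub("^[0-9]+", "", toupper(trimws(elety)))
  h | substr(stripped, 1, 1) %in% c("H", "D")
}

#' Construct a structure model
#'
#' A `structure_model` holds the heavy atoms of a single protein chain with
#' gap-free sequential residue numbering (0-based, in order of appearance),
#' the unit consumed by every distance statistic in the package.
#'
#' @param identifier Free-text model identifier.
#' @param atoms A data.frame with columns `residue_name` (3-letter code),
#'   `atom_name`, `residue_index` (0-based integer), `chain_id`, `x`, `y`, `z`.
#' @return An object of class `structure_model` with elements `identifier`,
#'   `atoms`, `n_residues`.
#' @export
structure_model <- function(identifier, atoms) {
  need <- c("residue_name", "atom_name", "residue_index", "chain_id",
            "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (nrow(atoms) > 0) {
    if (length(unique(atoms$chain_id)) != 1L)
      stop("all atoms of a structure_model must share one chain_id")
    if (any(atoms$residue_index < 0) || is.unsorted(atoms$residue_index))
      stop("residue_index must be non-negative and non-decreasing")
  }
  rownames(atoms) <- NULL
  structure(list(
    identifier = identifier,
    atoms = atoms,
    n_residues = length(unique(atoms$residue_index))
  ), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, %d residues, chain %s\n",
              x$identifier, nrow(x$atoms), x$n_residues,
              if (nrow(x$atoms)) x$atoms$chain_id[1] else "?"))
  invisible(x)
}

coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Parse one chain of a PDB file into a structure model
#'
#' Reads ATOM records of the requested chain, keeping heavy atoms of the 20
#' standard residues only. Hydrogens/deuteriums, HETATM records and
#' nonstandard residues (e.g. MSE) are dropped; alternate locations are
#' resolved to the highest-occupancy copy (ties: first encountered); only the
#' first MODEL block is read. Residues are renumbered sequentially 0..n-1 in
#' order of appearance, so numbering gaps and insertion codes cannot inflate
#' sequence separation.
#'
#' @param path Path to a PDB file.
#' @param chain_id Single chain identifier; `NULL` selects the first protein
#'   chain in the file.
#' @return A [structure_model()].
#' @export
parse_pdb_chain <- function(path, chain_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% STANDARD_AA, , drop = FALSE]
  at <- at[!is_hydrogen_name(at$elety, at$elesy), , drop = FALSE]

  if (is.null(chain_id)) {
    if (nrow(at) == 0) stop("empty chain: no standard-residue heavy atoms in ",
                            path)
    chain_id <- at$chain[1]
  } else {
    if (!any(pdb$atom$chain %in% chain_id))
      stop("chain not found: '", chain_id, "' in ", path)
  }
  at <- at[at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0)
    stop("empty chain: no standard-residue heavy atoms for chain '",
         chain_id, "' in ", path)

  # altloc resolution: one atom per (residue, atom name), highest occupancy,
  # ties broken by file order
  ins <- at$insert
  ins[is.na(ins)] <- ""
  res_uid <- paste(at$resno, ins, sep = "_")
  occ <- at$o
  occ[is.na(occ)] <- 1
  ord <- order(res_uid, at$elety, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  res_uid <- res_uid[ord]
  dup <- duplicated(paste(res_uid, at$elety, sep = "|"))
  at <- at[!dup, , drop = FALSE]
  res_uid <- res_uid[!dup]
  # restore file order before renumbering by order of appearance
  ord2 <- order(at$eleno)
  at <- at[ord2, , drop = FALSE]
  res_uid <- res_uid[ord2]

  ridx <- match(res_uid, unique(res_uid)) - 1L
  atoms <- data.frame(
    residue_name = at$resid,
    atom_name = trimws(at$elety),
    residue_index = ridx,
    chain_id = chain_id,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  ident <- paste0(sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path),
                      ignore.case = TRUE), "_", chain_id)
  structure_model(ident, atoms)
}

#' Restrict a model to an atom selection
#'
#' @param model A [structure_model()].
#' @param selection `"all_heavy"` (identity) or `"ca_only"` (one CA per
#'   residue; residues lacking a CA are dropped with a warning).
#' @return A [structure_model()].
#' @export
select_atoms <- function(model, selection = c("all_heavy", "ca_only")) {
  selection <- match.arg(selection)
  if (nrow(model$atoms) == 0) stop("empty model")
  if (selection == "all_heavy") return(model)
  at <- model$atoms[model$atoms$atom_name == "CA", , drop = FALSE]
  at <- at[!duplicated(at$residue_index), , drop = FALSE]
  lost <- setdiff(unique(model$atoms$residue_index), at$residue_index)
  if (length(lost) > 0)
    warning(sprintf("%s: %d residue(s) lack a CA atom and were omitted",
                    model$identifier, length(lost)))
  structure_model(model$identifier, at)
}

pair_side <- function(residue_name, atom_name) {
  paste0(residue_name, ":", atom_name)
}

#' Canonical pair-type key
#'
#' Builds the order-independent identifier of an (residue, atom) x
#' (residue, atom) distance distribution: the two sides are sorted
#' lexicographically so `pair_type_key(a, b) == pair_type_key(b, a)`.
#'
#' @param side1,side2 Character vectors of `"RES:ATOM"` labels
#'   (e.g. `"CYS:CA"`).
#' @return Character vector of keys `"RES:ATOM|RES:ATOM"`.
#' @export
pair_type_key <- function(side1, side2) {
  paste(pmin(side1, side2), pmax(side1, side2), sep = "|")
}

#' Enumerate qualifying atom pairs of a model
#'
#' Yields every unordered heavy-atom pair whose residues are at least
#' `min_separation` positions apart in the chain and whose Euclidean distance
#' is strictly below `cutoff`. Pairs within the same residue or between
#' near-neighbour residues (i, i+1 .. i+min_separation-1) never appear. With
#' the default `min_separation = 4`, distances between residues i and i+1,
#' i+2, i+3 are excluded.
#'
#' @param model A [structure_model()].
#' @param min_separation Minimum residue-index separation (>= 1).
#' @param cutoff Distance cutoff in Angstrom (strict upper bound).
#' @return A data.frame with columns `key` (canonical pair-type key) and
#'   `distance`; zero rows when no pair qualifies.
#' @export
qualifying_pairs <- function(model, min_separation = 4, cutoff = 15.0) {
  stopifnot(min_separation >= 1, cutoff > 0)
  at <- model$atoms
  n <- nrow(at)
  empty <- data.frame(key = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  dm <- as.matrix(stats::dist(coords(model)))
  sep <- abs(outer(at$residue_index, at$residue_index, "-"))
  keep <- upper.tri(dm) & sep >= min_separation & dm < cutoff
  ij <- which(keep, arr.ind = TRUE)
  if (nrow(ij) == 0) return(empty)
  side <- pair_side(at$residue_name, at$atom_name)
  data.frame(
    key = pair_type_key(side[ij[, 1]], side[ij[, 2]]),
    distance = dm[ij],
    stringsAsFactors = FALSE
  )
}
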