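# Structure container: an ordered atom table plus residue bookkeeping.
# Atoms live in a data.frame (one row per atom) rather than nested objects;
# this keeps geometry operations vectorised.

#' Residue keys
#'
#' A residue key is the compact string `<chain><resno><icode>` (insertion code
#' omitted when blank), e.g. `"A105"`. It identifies a residue uniquely within
#' a structure and names its fragment file in a fragment library.
#'
#' @param chain chain identifiers.
#' @param resno residue sequence numbers.
#' @param icode insertion codes (`""` or `" "` for none).
#' @return character vector of keys.
#' @export
res_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  sprintf("%s%d%s", chain, as.integer(resno), icode)
}

atom_res_keys <- function(atoms) res_key(atoms$chain, atoms$resno, atoms$icode)

#' Construct an atom table
#'
#' @param serial integer atom serial numbers (unique).
#' @param name atom names (PDB convention, at most 4 characters).
#' @param element element symbols.
#' @param resname 3-letter residue names.
#' @param chain chain identifiers.
#' @param resno residue numbers.
#' @param x,y,z coordinates in Angstrom.
#' @param icode insertion codes.
#' @param hetero logical, HETATM records.
#' @return a data.frame with one row per atom.
#' @export
atom_table <- function(serial, name, element, resname, chain, resno,
                       x, y, z, icode = "", hetero = FALSE) {
  data.frame(
    serial = as.integer(serial), name = as.character(name),
    element = as.character(element), resname = as.character(resname),
    chain = as.character(chain), resno = as.integer(resno),
    icode = rep_len(as.character(icode), length(serial)),
    hetero = rep_len(as.logical(hetero), length(serial)),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
}

#' Structure model
#'
#' The central container of the pipeline: an ordered atom table, the residue
#' order (assembly order), the net formal charge in elementary charges, the
#' set of frozen atom serials (coordinates held fixed by the backend), and
#' per-residue annotations (formal charges, substrate residues). Water
#' residues are recognised by residue name.
#'
#' @param atoms an atom table (see [atom_table()]).
#' @param residue_order residue keys in assembly order; defaults to first
#'   appearance order in `atoms`.
#' @param frozen integer serials of atoms whose coordinates are fixed.
#' @param residue_charges named numeric vector of per-residue formal charges
#'   (elementary charges); residues absent from the vector are neutral. The
#'   model's `net_charge` is their sum.
#' @param substrate_residues residue keys flagged as substrate.
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms, residue_order = NULL, frozen = integer(),
                            residue_charges = numeric(),
                            substrate_residues = character()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  if (any(!nzchar(trimws(atoms$element)))) {
    stop("every atom must carry a non-empty element symbol")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinate")
  }
  if (anyDuplicated(atoms$serial)) {
    stop("duplicate atom serial: ",
         paste(unique(atoms$serial[duplicated(atoms$serial)]), collapse = ", "))
  }
  keys <- atom_res_keys(atoms)
  if (is.null(residue_order)) residue_order <- unique(keys)
  if (!all(keys %in% residue_order)) {
    stop("atom residue_key absent from residue_order: ",
         paste(setdiff(unique(keys), residue_order), collapse = ", "))
  }
  frozen <- sort(unique(as.integer(frozen)))
  if (!all(frozen %in% atoms$serial)) {
    stop("frozen serial not present in structure: ",
         paste(setdiff(frozen, atoms$serial), collapse = ", "))
  }
  residue_charges <- residue_charges[names(residue_charges) %in% residue_order]
  water <- residue_order %in% unique(keys[atoms$resname %in% .WATER_RESNAMES])
  structure(
    list(
      atoms = atoms,
      residue_order = residue_order,
      net_charge = as.integer(round(sum(residue_charges))),
      frozen = frozen,
      residue_charges = residue_charges,
      substrate_residues = intersect(substrate_residues, residue_order),
      water_residues = residue_order[water]
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %d atoms, %d residues (%d water, %d substrate), charge %+d, %d frozen\n",
    nrow(x$atoms), length(x$residue_order), length(x$water_residues),
    length(x$substrate_residues), x$net_charge, length(x$frozen)))
  invisible(x)
}

#' Number of atoms in a model
#' @param model a `structure_model`.
#' @return integer count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Extract / replace the coordinate matrix
#'
#' @param model a `structure_model`.
#' @return `coords()` returns an `n x 3` numeric matrix in atom order.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' @rdname coords
#' @param value an `n x 3` matrix of replacement coordinates.
#' @export
`coords<-` <- function(model, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(model$atoms), ncol(value) == 3)
  model$atoms$x <- value[, 1]
  model$atoms$y <- value[, 2]
  model$atoms$z <- value[, 3]
  model
}

#' Set per-residue formal charges
#'
#' Annotates formal charges (net charge is recomputed as their sum). Charges
#' are input annotations: protonation-state assignment is upstream of this
#' package.
#'
#' @param model a `structure_model`.
#' @param charges named numeric vector, names are residue keys.
#' @return the updated model.
#' @export
set_residue_charges <- function(model, charges) {
  bad <- setdiff(names(charges), model$residue_order)
  if (length(bad)) stop("unknown residue key(s): ", paste(bad, collapse = ", "))
  merged <- model$residue_charges
  merged[names(charges)] <- charges
  merged <- merged[merged != 0 | names(merged) %in% names(charges)]
  model$residue_charges <- merged
  model$net_charge <- as.integer(round(sum(merged)))
  model
}

#' Atom rows of one residue
#' @param model a `structure_model`.
#' @param key a residue key.
#' @return data.frame subset of the atom table (file order preserved).
#' @export
residue_atoms <- function(model, key) {
  model$atoms[atom_res_keys(model$atoms) == key, , drop = FALSE]
}

# Positions of one atom by serial (3-vector).
atom_position <- function(model, serial) {
  i <- match(serial, model$atoms$serial)
  if (is.na(i)) stop("no atom with serial ", serial)
  c(model$atoms$x[i], model$atoms$y[i], model$atoms$z[i])
}

#' Subset a model to a set of residues
#'
#' Keeps the listed residues (in the model's order) with their annotations;
#' frozen atoms and charges outside the subset are dropped.
#'
#' @param model a `structure_model`.
#' @param keys residue keys to keep.
#' @return the reduced `structure_model`.
#' @export
subset_residues <- function(model, keys) {
  keys <- model$residue_order[model$residue_order %in% keys]
  if (!length(keys)) stop("empty residue selection")
  keep <- atom_res_keys(model$atoms) %in% keys
  atoms <- model$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  structure_model(
    atoms,
    residue_order = keys,
    frozen = intersect(model$frozen, atoms$serial),
    residue_charges = model$residue_charges[names(model$residue_charges) %in% keys],
    substrate_residues = intersect(model$substrate_residues, keys)
  )
}
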