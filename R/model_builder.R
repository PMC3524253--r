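# Truncated active-site model construction: radius selection around a center
# residue, single-gap fill, capping of chain breaks, reaction-endpoint
# preparation and surface side-chain freezing.

#' Selection specification for model truncation
#'
#' @param center_residue residue key of the selection center (typically the
#'   catalytic nucleophile residue, e.g. the active-site serine).
#' @param radius inclusion radius in Angstrom (> 0). A residue is included
#'   when any of its atoms lies within `radius` of any atom of the center
#'   residue (the most inclusive reading of a residue-radius criterion).
#' @param include_waters include crystal waters satisfying the radius
#'   criterion.
#' @param fill_single_gaps include a residue when both its backbone
#'   neighbours are selected (see [fill_single_gaps()]).
#' @return object of class `selection_spec`.
#' @export
selection_spec <- function(center_residue, radius, include_waters = TRUE,
                           fill_single_gaps = TRUE) {
  stopifnot(is.numeric(radius), radius > 0)
  structure(list(center_residue = center_residue, radius = radius,
                 include_waters = include_waters,
                 fill_single_gaps = fill_single_gaps),
            class = "selection_spec")
}

#' Reaction coordinate definition
#'
#' The reaction coordinate is the distance between the nucleophile oxygen
#' (e.g. the serine O-gamma) and the substrate electrophile carbon (the
#' carbonyl carbon attacked in the reaction). It is fixed per interpolation
#' frame during constrained optimization.
#'
#' @param nucleophile_atom serial of the nucleophile atom.
#' @param electrophile_atom serial of the electrophile atom.
#' @param es_distance nucleophile-electrophile distance in the
#'   enzyme-substrate complex, Angstrom (default 3.5).
#' @param ti_distance distance in the tetrahedral intermediate, Angstrom
#'   (default 1.5, a formed C-O bond).
#' @return object of class `reaction_coordinate`.
#' @export
reaction_coordinate <- function(nucleophile_atom, electrophile_atom,
                                es_distance = 3.5, ti_distance = 1.5) {
  if (!(es_distance > ti_distance && ti_distance > 0)) {
    stop("require es_distance > ti_distance > 0")
  }
  structure(list(nucleophile_atom = as.integer(nucleophile_atom),
                 electrophile_atom = as.integer(electrophile_atom),
                 es_distance = es_distance, ti_distance = ti_distance),
            class = "reaction_coordinate")
}

#' Reaction endpoint pair
#'
#' The two optimized reaction end points (enzyme-substrate complex and
#' tetrahedral intermediate) used by the linear interpolation. Both models
#' must have identical atom count and ordering -- the interpolation
#' precondition.
#'
#' @param es,ti `structure_model`s of the two end points.
#' @param rc a [reaction_coordinate()].
#' @param freeze_list residue keys whose side chains are held fixed in every
#'   frame (surface residues prone to spurious rearrangement in variants).
#' @return object of class `endpoint_pair`.
#' @export
endpoint_pair <- function(es, ti, rc, freeze_list = character()) {
  if (n_atoms(es) != n_atoms(ti)) {
    stop("ES and TI atom counts differ: ", n_atoms(es), " vs ", n_atoms(ti))
  }
  if (!identical(es$atoms$name, ti$atoms$name) ||
      !identical(atom_res_keys(es$atoms), atom_res_keys(ti$atoms))) {
    stop("ES and TI atom ordering differs; interpolation requires identical ordering")
  }
  bad <- setdiff(freeze_list, intersect(es$residue_order, ti$residue_order))
  if (length(bad)) stop("freeze_list residue(s) absent: ", paste(bad, collapse = ", "))
  structure(list(es = es, ti = ti, rc = rc, freeze_list = freeze_list),
            class = "endpoint_pair")
}

#' Select the truncated model region around a center residue
#'
#' A residue enters the model iff any of its atoms lies within `spec$radius`
#' of any atom of the center residue. Waters obey the same criterion and are
#' dropped entirely when `include_waters` is `FALSE`. Single backbone gaps
#' are filled when requested. The original residue order is preserved.
#'
#' @param full the full `structure_model`.
#' @param spec a [selection_spec()].
#' @return the truncated `structure_model`.
#' @export
select_model_region <- function(full, spec) {
  if (!spec$center_residue %in% full$residue_order) {
    stop("center residue not present: ", spec$center_residue)
  }
  keys <- atom_res_keys(full$atoms)
  xyz <- coords(full)
  center <- xyz[keys == spec$center_residue, , drop = FALSE]
  # squared min distance of every atom to the center residue's atoms
  d2 <- apply(xyz, 1, function(p) {
    min(colSums((t(center) - p)^2))
  })
  hit <- unique(keys[d2 <= spec$radius^2])
  selected <- full$residue_order[full$residue_order %in% hit]
  if (!spec$include_waters) {
    selected <- setdiff(selected, full$water_residues)
  }
  if (isTRUE(spec$fill_single_gaps)) {
    selected <- fill_single_gaps(selected, full)
  }
  if (!length(selected)) stop("empty selection at radius ", spec$radius)
  subset_residues(full, selected)
}

#' Fill single-residue backbone gaps in a selection
#'
#' When the backbone chain of a selection is interrupted by exactly one
#' residue, that residue is included as well; gaps of two or more residues
#' are left untouched. Idempotent. Only polymer (non-HETATM) residues are
#' considered; waters and ligands carry arbitrary numbering.
#'
#' @param selection character vector of selected residue keys.
#' @param full the full `structure_model` the selection came from.
#' @return selected residue keys in the full model's order, gaps filled.
#' @export
fill_single_gaps <- function(selection, full) {
  keys <- atom_res_keys(full$atoms)
  first <- !duplicated(keys)
  info <- data.frame(key = keys[first], chain = full$atoms$chain[first],
                     resno = full$atoms$resno[first],
                     hetero = full$atoms$hetero[first],
                     stringsAsFactors = FALSE)
  added <- character(0)
  for (ch in unique(info$chain)) {
    poly <- info[info$chain == ch & !info$hetero, , drop = FALSE]
    sel_no <- poly$resno[poly$key %in% selection]
    gap1 <- poly$resno[!poly$key %in% selection &
                       (poly$resno - 1) %in% sel_no &
                       (poly$resno + 1) %in% sel_no]
    added <- c(added, poly$key[poly$resno %in% gap1])
  }
  out <- union(selection, added)
  full$residue_order[full$residue_order %in% out]
}

# sp2-completion direction for a -CHO cap when the removed neighbour is not
# available: opposite the bisector of the two remaining bonds at C.
.cap_direction <- function(c_pos, ca_pos, o_pos) {
  u1 <- (ca_pos - c_pos) / sqrt(sum((ca_pos - c_pos)^2))
  u2 <- (o_pos - c_pos) / sqrt(sum((o_pos - c_pos)^2))
  d <- -(u1 + u2)
  d / sqrt(sum(d^2))
}

#' Cap chain-break termini of a truncated model
#'
#' Chain breaks introduced by truncation are closed off chemically: every
#' break N-terminus is annotated neutral (charge bookkeeping
#' only, no atoms added), and every break C-terminus is modeled as an
#' aldehyde (-CHO) by adding one hydrogen at the carbonyl carbon, 1.09 A
#' along the direction of the removed C-N bond. When the full structure is
#' supplied that direction is the actual position of the removed residue's
#' N; otherwise the sp2-completion direction at C is used. Cap hydrogens are
#' named `"HC"`; the operation is idempotent. Native chain termini (no break)
#' are left untouched.
#'
#' @param model the truncated `structure_model`.
#' @param full optional full structure the model was selected from; enables
#'   capping of the selection's outer termini and exact cap directions.
#' @return the capped `structure_model`.
#' @export
cap_termini <- function(model, full = NULL) {
  keys <- atom_res_keys(model$atoms)
  first <- !duplicated(keys)
  info <- data.frame(key = keys[first], chain = model$atoms$chain[first],
                     resno = model$atoms$resno[first],
                     hetero = model$atoms$hetero[first],
                     stringsAsFactors = FALSE)
  full_info <- NULL
  if (!is.null(full)) {
    fk <- atom_res_keys(full$atoms)
    ff <- !duplicated(fk)
    full_info <- data.frame(key = fk[ff], chain = full$atoms$chain[ff],
                            resno = full$atoms$resno[ff],
                            hetero = full$atoms$hetero[ff],
                            stringsAsFactors = FALSE)
  }
  c_caps <- character(0)   # residue keys needing a -CHO cap
  n_neutral <- character(0)
  for (ch in unique(info$chain)) {
    poly <- info[info$chain == ch & !info$hetero, , drop = FALSE]
    if (nrow(poly) < 1) next
    gaps_after <- poly$key[which(diff(poly$resno) > 1)]
    gaps_before <- poly$key[which(diff(poly$resno) > 1) + 1]
    c_caps <- c(c_caps, gaps_after)
    n_neutral <- c(n_neutral, gaps_before)
    if (!is.null(full_info)) {
      fpoly <- full_info[full_info$chain == ch & !full_info$hetero, , drop = FALSE]
      if (nrow(fpoly)) {
        if (min(fpoly$resno) < min(poly$resno)) n_neutral <- c(n_neutral, poly$key[which.min(poly$resno)])
        if (max(fpoly$resno) > max(poly$resno)) c_caps <- c(c_caps, poly$key[which.max(poly$resno)])
      }
    }
  }
  out_atoms <- NULL
  for (k in model$residue_order) {
    rows <- model$atoms[keys == k, , drop = FALSE]
    if (k %in% c_caps && !"HC" %in% rows$name) {
      need <- c("C", "O", "CA")
      if (!all(need %in% rows$name)) {
        stop("cannot cap residue ", k, ": missing backbone atom(s) ",
             paste(setdiff(need, rows$name), collapse = ", "))
      }
      cpos <- unlist(rows[rows$name == "C", c("x", "y", "z")])
      opos <- unlist(rows[rows$name == "O", c("x", "y", "z")])
      capos <- unlist(rows[rows$name == "CA", c("x", "y", "z")])
      dir <- NULL
      if (!is.null(full)) {
        # position of the removed next residue's N, if present in full
        fk <- atom_res_keys(full$atoms)
        nxt <- full$atoms[full$atoms$chain == rows$chain[1] &
                          full$atoms$resno == rows$resno[1] + 1 &
                          full$atoms$name == "N", , drop = FALSE]
        if (nrow(nxt) == 1) {
          v <- c(nxt$x, nxt$y, nxt$z) - cpos
          dir <- v / sqrt(sum(v^2))
        }
      }
      if (is.null(dir)) dir <- .cap_direction(cpos, capos, opos)
      hpos <- cpos + 1.09 * dir
      cap <- rows[rows$name == "C", , drop = FALSE]
      cap$serial <- NA_integer_
      cap$name <- "HC"
      cap$element <- "H"
      cap$x <- hpos[1]; cap$y <- hpos[2]; cap$z <- hpos[3]
      rows <- rbind(rows, cap)
    }
    out_atoms <- rbind(out_atoms, rows)
  }
  rownames(out_atoms) <- NULL
  # renumber, remapping the frozen set through old serials
  old_serial <- out_atoms$serial
  out_atoms$serial <- seq_len(nrow(out_atoms))
  frozen <- out_atoms$serial[old_serial %in% model$frozen & !is.na(old_serial)]
  m <- structure_model(out_atoms, residue_order = model$residue_order,
                       frozen = frozen,
                       residue_charges = model$residue_charges,
                       substrate_residues = model$substrate_residues)
  # break N-termini are annotated neutral: charge bookkeeping only, no atoms
  # added (side-chain charges of those residues are untouched)
  m$neutral_n_termini <- sort(unique(c(model$neutral_n_termini, n_neutral)))
  m
}

#' Build the ES end point from an optimized TI model
#'
#' The enzyme-substrate (ES) complex is modeled on the optimized tetrahedral
#' intermediate (TI): the covalently bound tetrahedral substrate is replaced
#' by externally modeled planar substrate coordinates, rigid-shifted along
#' the nucleophile-electrophile axis so their distance equals
#' `rc$es_distance` (default 3.5 A), and the catalytic proton is transferred
#' back onto the nucleophile oxygen, 0.97 A along the direction towards the
#' electrophile. Atom count and ordering are identical to the TI, as the
#' interpolation requires. The planar substrate coordinates are an input
#' (molecular modelling of the unbound substrate pose is upstream).
#'
#' @param ti optimized TI `structure_model` with substrate residues
#'   annotated.
#' @param substrate_planar_coords numeric matrix (n_substrate_atoms x 3) of
#'   planar substrate coordinates, in the TI's substrate atom order.
#' @param proton serial of the catalytic proton to transfer.
#' @param rc a [reaction_coordinate()].
#' @return the ES `structure_model`.
#' @export
build_es_from_ti <- function(ti, substrate_planar_coords, proton, rc) {
  if (!length(ti$substrate_residues)) stop("TI model has no substrate residues annotated")
  keys <- atom_res_keys(ti$atoms)
  sub_idx <- which(keys %in% ti$substrate_residues)
  substrate_planar_coords <- as.matrix(substrate_planar_coords)
  if (nrow(substrate_planar_coords) != length(sub_idx)) {
    stop(sprintf("substrate atom count mismatch: TI has %d, coordinates supply %d",
                 length(sub_idx), nrow(substrate_planar_coords)))
  }
  es <- ti
  xyz <- coords(es)
  xyz[sub_idx, ] <- substrate_planar_coords
  og <- atom_position(ti, rc$nucleophile_atom)
  iC <- match(rc$electrophile_atom, ti$atoms$serial)
  if (is.na(iC) || !(iC %in% sub_idx)) stop("electrophile atom not found among substrate atoms")
  c20 <- xyz[iC, ]
  u <- (c20 - og) / sqrt(sum((c20 - og)^2))
  shift <- (og + rc$es_distance * u) - c20
  xyz[sub_idx, ] <- sweep(xyz[sub_idx, , drop = FALSE], 2, shift, `+`)
  iH <- match(proton, ti$atoms$serial)
  if (is.na(iH)) stop("proton serial not found: ", proton)
  u2 <- (xyz[iC, ] - og) / sqrt(sum((xyz[iC, ] - og)^2))
  xyz[iH, ] <- og + 0.97 * u2
  coords(es) <- xyz
  es
}

#' Freeze the side chains of selected residues
#'
#' Adds every side-chain atom (all atoms outside the backbone set N, CA, C,
#' O, amide/alpha hydrogens, OXT) of the listed residues to the model's
#' frozen set. Used for surface residues whose spurious rearrangement under
#' a bulky active-site mutation would otherwise distort the barrier profile.
#' The freeze state propagates into backend input rendering as per-coordinate
#' optimization flags.
#'
#' @param model a `structure_model`.
#' @param residues residue keys to freeze.
#' @return the model with an extended frozen set.
#' @export
freeze_surface_sidechains <- function(model, residues) {
  bad <- setdiff(residues, model$residue_order)
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
  keys <- atom_res_keys(model$atoms)
  sel <- keys %in% residues & !model$atoms$name %in% .BACKBONE_NAMES
  model$frozen <- sort(unique(c(model$frozen, model$atoms$serial[sel])))
  model
}

#' Reaction-coordinate distance of a model
#'
#' @param model a `structure_model`.
#' @param rc a [reaction_coordinate()].
#' @return the nucleophile-electrophile distance, Angstrom.
#' @export
rc_distance <- function(model, rc) {
  sqrt(sum((atom_position(model, rc$electrophile_atom) -
            atom_position(model, rc$nucleophile_atom))^2))
}
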