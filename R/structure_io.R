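# PDB v3.3 fixed-column reading/writing and the per-residue fragment library.
#
# The fragment library is the substitution mechanism for variant assembly:
# every residue (plus each water and the substrate) is one single-residue PDB
# fragment; swapping the fragment at a position for a mutated side-chain
# fragment and concatenating in library order yields the variant structure.

.guess_element <- function(name) {
  a <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(a, 1, 2)
  ifelse(two %in% names(.ATOMIC_MASSES) & !substr(a, 1, 1) %in% c("H", "C", "N", "O", "S", "P"),
         two, substr(a, 1, 1))
}

.pdb_lines <- function(path_or_text) {
  if (length(path_or_text) == 1 && !grepl("\n", path_or_text, fixed = TRUE) &&
      file.exists(path_or_text)) {
    readLines(path_or_text, warn = FALSE)
  } else {
    strsplit(paste(path_or_text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
}

#' Read a PDB structure
#'
#' Parses fixed-column PDB v3.3 ATOM/HETATM records into a
#' [structure_model()]. Waters (by residue name) are flagged; the net charge
#' defaults to 0 until annotated with [set_residue_charges()]. Alternate
#' locations other than blank or `'A'` are rejected: collapsing altLocs is an
#' upstream curation step, not something to guess here.
#'
#' @param path_or_text path to a PDB file, or PDB text (single string or
#'   character vector of lines).
#' @return a `structure_model` with atoms in file order and residues in
#'   first-appearance order.
#' @export
read_pdb <- function(path_or_text) {
  lines <- .pdb_lines(path_or_text)
  rec <- substr(lines, 1, 6)
  sel <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  if (!length(sel)) stop("no ATOM/HETATM records found")
  ln <- lines[sel]
  num <- function(s, i, j, what) {
    v <- suppressWarnings(as.numeric(substr(s, i, j)))
    bad <- which(is.na(v) | !nzchar(trimws(substr(s, i, j))))
    if (length(bad)) {
      stop(sprintf("malformed %s field in PDB record at line %d", what,
                   sel[bad[1]]))
    }
    v
  }
  altloc <- substr(ln, 17, 17)
  badalt <- which(!altloc %in% c(" ", "", "A"))
  if (length(badalt)) {
    stop(sprintf("unsupported alternate location '%s' at line %d (only blank or 'A')",
                 altloc[badalt[1]], sel[badalt[1]]))
  }
  serial <- as.integer(num(ln, 7, 11, "serial"))
  name <- trimws(substr(ln, 13, 16))
  resname <- trimws(substr(ln, 18, 20))
  chain <- substr(ln, 22, 22)
  chain[chain %in% c(" ", "")] <- "A"
  resno <- as.integer(num(ln, 23, 26, "residue number"))
  icode <- sub(" ", "", substr(ln, 27, 27), fixed = TRUE)
  x <- num(ln, 31, 38, "x")
  y <- num(ln, 39, 46, "y")
  z <- num(ln, 47, 54, "z")
  element <- trimws(substr(ln, 77, 78))
  element[!nzchar(element)] <- .guess_element(name[!nzchar(element)])
  if (anyDuplicated(serial)) {
    stop("duplicate atom serial: ",
         paste(unique(serial[duplicated(serial)]), collapse = ", "))
  }
  atoms <- atom_table(serial, name, element, resname, chain, resno, x, y, z,
                      icode = icode, hetero = trimws(rec[sel]) == "HETATM")
  structure_model(atoms)
}

.format_atom_name <- function(name, element) {
  # Standard PDB justification: names of 1-3 characters start in column 14
  # unless the element symbol has two letters.
  wide <- nchar(name) >= 4 | nchar(trimws(element)) >= 2
  ifelse(wide, formatC(name, width = -4), sprintf(" %-3s", name))
}

#' Write a structure as PDB text
#'
#' Emits fixed-column PDB v3.3 ATOM/HETATM records (coordinates to 3
#' decimals), a TER record at each chain change and a terminal END.
#' [read_pdb()] composed with `write_pdb()` is the identity on atoms and
#' coordinates at 3-decimal precision. The frozen-atom set deliberately does
#' not appear: freeze state belongs to backend input rendering, not to the
#' structure exchange format.
#'
#' @param model a `structure_model`.
#' @param path optional file path; when given the text is also written there.
#' @return the PDB text as a single string (invisibly when `path` is given).
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model$atoms
  if (any(nchar(a$name) > 4)) {
    stop("atom name longer than 4 characters: ",
         paste(unique(a$name[nchar(a$name) > 4]), collapse = ", "))
  }
  lines <- sprintf(
    "%-6s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$hetero, "HETATM", "ATOM"), a$serial,
    .format_atom_name(a$name, a$element), a$resname, a$chain, a$resno,
    ifelse(nzchar(a$icode), a$icode, " "), a$x, a$y, a$z, 1, 0,
    toupper(a$element))
  ter <- which(a$chain[-1] != a$chain[-nrow(a)])
  out <- character(0)
  prev <- 0
  for (t in c(ter, nrow(a))) {
    out <- c(out, lines[(prev + 1):t], if (t %in% ter) "TER")
    prev <- t
  }
  txt <- paste(c(out, "END", ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' Fragment record
#'
#' One residue (amino acid, water, or substrate) stored as an independent
#' unit: its atoms, formal charge and role flags. Fragment records are the
#' unit of substitution in variant assembly.
#'
#' @param atoms atom table rows of this residue (non-empty).
#' @param residue_key the residue key the fragment occupies.
#' @param residue_name 3-letter residue name.
#' @param formal_charge integer in -2..2, elementary charges.
#' @param is_water,is_substrate role flags.
#' @return object of class `fragment_record`.
#' @export
fragment_record <- function(atoms, residue_key, residue_name,
                            formal_charge = 0L, is_water = FALSE,
                            is_substrate = FALSE) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0) {
    stop("fragment must contain at least one atom (residue ", residue_key, ")")
  }
  if (formal_charge < -2 || formal_charge > 2) {
    stop("formal_charge out of range [-2, 2]: ", formal_charge)
  }
  rownames(atoms) <- NULL
  structure(
    list(residue_key = residue_key, residue_name = residue_name,
         atoms = atoms, formal_charge = as.integer(formal_charge),
         is_water = is_water, is_substrate = is_substrate),
    class = "fragment_record"
  )
}

#' Fragment library
#'
#' Ordered collection of fragment records; the order defines assembly order.
#'
#' @param records list of [fragment_record()] objects with unique residue keys.
#' @param provenance free-text provenance note.
#' @return object of class `fragment_library`.
#' @export
fragment_library <- function(records, provenance = "") {
  keys <- vapply(records, `[[`, "", "residue_key")
  if (anyDuplicated(keys)) {
    stop("duplicate residue keys in fragment library: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  structure(list(records = records, provenance = provenance),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library> %d fragments\n", length(x$records)))
  invisible(x)
}

#' Split a structure into a fragment library
#'
#' Partitions the model into one fragment per residue (in residue order);
#' waters and the substrate become fragments of their own. Concatenating the
#' fragment atoms in order reproduces the model's atoms exactly.
#'
#' @param model a `structure_model`.
#' @param substrate_residues residue keys to flag as substrate (defaults to
#'   the model's own annotation).
#' @param charges named numeric vector of per-residue formal charges; keys
#'   must exist in the model. Defaults to the model's annotation.
#' @return a `fragment_library`.
#' @export
split_fragments <- function(model,
                            substrate_residues = model$substrate_residues,
                            charges = model$residue_charges) {
  bad <- setdiff(names(charges), model$residue_order)
  if (length(bad)) stop("charge key(s) not in model: ", paste(bad, collapse = ", "))
  keys <- atom_res_keys(model$atoms)
  recs <- lapply(model$residue_order, function(k) {
    rows <- model$atoms[keys == k, , drop = FALSE]
    if (nrow(rows) == 0) stop("residue with zero atoms: ", k)
    fragment_record(
      rows, residue_key = k, residue_name = rows$resname[1],
      formal_charge = if (k %in% names(charges)) charges[[k]] else 0L,
      is_water = k %in% model$water_residues,
      is_substrate = k %in% substrate_residues
    )
  })
  fragment_library(recs, provenance = sprintf(
    "split_fragments of %d-residue model", length(model$residue_order)))
}

#' Assemble a (variant) structure from a fragment library
#'
#' Concatenates fragment atoms in library order, with substituted records
#' replacing the wild-type record at their position. Atom serials are
#' renumbered 1-based consecutively (substituted fragments typically come
#' from modelling tools with arbitrary serials) and the net charge is the sum
#' of assembled fragment charges. Any number of positions may be substituted
#' at once, so combination mutants assemble the same way as single mutants.
#'
#' @param library a `fragment_library` (the wild type).
#' @param substitutions named list of `fragment_record`s; names are the
#'   residue keys being replaced. Each record's own `residue_key` must match
#'   the position it replaces.
#' @return a `structure_model` of the assembled (variant) structure.
#' @export
assemble_variant <- function(library, substitutions = list()) {
  keys <- vapply(library$records, `[[`, "", "residue_key")
  missing <- setdiff(names(substitutions), keys)
  if (length(missing)) {
    stop("substitution position(s) absent from library: ",
         paste(missing, collapse = ", "))
  }
  recs <- library$records
  names(recs) <- keys
  for (k in names(substitutions)) {
    sub <- substitutions[[k]]
    stopifnot(inherits(sub, "fragment_record"))
    if (!identical(sub$residue_key, k)) {
      stop(sprintf("substituting fragment carries residue_key '%s' but replaces position '%s'",
                   sub$residue_key, k))
    }
    recs[[k]] <- sub
  }
  atoms <- do.call(rbind, lapply(recs, `[[`, "atoms"))
  rownames(atoms) <- NULL
  atoms$serial <- seq_len(nrow(atoms))
  chg <- vapply(recs, `[[`, 0L, "formal_charge")
  names(chg) <- keys
  structure_model(
    atoms, residue_order = keys,
    residue_charges = chg[chg != 0],
    substrate_residues = keys[vapply(recs, `[[`, FALSE, "is_substrate")]
  )
}

# ---- fragment library directory layout ------------------------------------
# One PDB per residue named <residue_key><resname>.pdb carrying its formal
# charge on a REMARK line, plus a JSON manifest with the assembly order.

.fragment_pdb_text <- function(rec) {
  m <- structure_model(rec$atoms)
  paste0(sprintf("REMARK   6 FORMAL_CHARGE %d\n", rec$formal_charge),
         write_pdb(m))
}

#' Write a fragment library to a directory
#'
#' @param library a `fragment_library`.
#' @param dir target directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_fragment_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (rec in library$records) {
    f <- sprintf("%s%s.pdb", rec$residue_key, rec$residue_name)
    cat(.fragment_pdb_text(rec), file = file.path(dir, f))
    files <- c(files, f)
  }
  manifest <- list(
    provenance = library$provenance,
    records = lapply(seq_along(library$records), function(i) {
      rec <- library$records[[i]]
      list(residue_key = rec$residue_key, file = files[i],
           residue_name = rec$residue_name,
           formal_charge = rec$formal_charge,
           is_water = rec$is_water, is_substrate = rec$is_substrate)
    })
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mpath)
}

#' Read a fragment library from a directory
#'
#' @param dir directory written by [write_fragment_library()].
#' @return a `fragment_library`.
#' @export
read_fragment_library <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  recs <- lapply(manifest$records, function(e) {
    txt <- readLines(file.path(dir, e$file), warn = FALSE)
    chg_line <- grep("^REMARK +6 FORMAL_CHARGE ", txt, value = TRUE)
    chg <- if (length(chg_line)) {
      as.integer(sub("^REMARK +6 FORMAL_CHARGE +(-?[0-9]+).*$", "\\1", chg_line[1]))
    } else e$formal_charge
    m <- read_pdb(txt)
    fragment_record(m$atoms, residue_key = e$residue_key,
                    residue_name = e$residue_name, formal_charge = chg,
                    is_water = isTRUE(e$is_water),
                    is_substrate = isTRUE(e$is_substrate))
  })
  fragment_library(recs, provenance = manifest$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
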