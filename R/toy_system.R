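# Deterministic synthetic fixture: a small polypeptide-like chain with a
# catalytic nucleophile, a pseudo-substrate and matched surrogate-surface
# parameters whose analytic barrier is known exactly. Every stage of the
# pipeline is exercised on this system with no structure download and no
# external quantum engine.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

#' Generate the seeded toy enzyme-substrate system
#'
#' Builds a deterministic toy system emulating the geometry of the screening
#' problem: a short polypeptide-like chain whose middle residue carries a
#' nucleophile oxygen (`OG`) and catalytic proton (`HG`), a four-atom
#' pseudo-substrate whose carbonyl-like carbon (`C20`) sits `ti_distance`
#' from the nucleophile in the tetrahedral-intermediate state, and optional
#' single-atom crystal waters. The matching surrogate surface has harmonic
#' bonds referenced to the TI geometry (chain and substrate internal bonds
#' only -- no bond across the reaction coordinate) plus a double-well term
#' along the nucleophile-electrophile distance with wells at `ti_distance`
#' and `es_distance` and an exactly known barrier `A` at their midpoint.
#'
#' The ES end point is built from the TI exactly as in the real workflow
#' ([build_es_from_ti()]): the substrate is rotated by
#' `substrate_rotation_deg` about the electrophile (standing in for the
#' externally modeled planar pose), rigid-shifted to `es_distance`, and the
#' proton is transferred back onto the nucleophile. Because the rotation
#' pivots on the electrophile, that atom's displacement between the end
#' points is exactly `es_distance - ti_distance`.
#'
#' The same seed yields byte-identical structures (and PDB text).
#'
#' @param seed integer RNG seed (applies to small coordinate jitter only).
#' @param n_residues chain length (>= 3), default 8.
#' @param es_distance,ti_distance reaction-coordinate distances of the two
#'   end points, Angstrom (defaults 3.5 and 1.5).
#' @param barrier analytic barrier height `A` of the double-well term,
#'   kcal/mol (default 10).
#' @param substrate_rotation_deg rigid rotation of the substrate in the ES
#'   pose, degrees (default 25; set 0 for a pure translation of the
#'   substrate).
#' @param n_waters number of single-atom waters appended (default 2).
#' @return list with `full` (the TI-state `structure_model`), `endpoints`
#'   (an [endpoint_pair()]), `params` (a [surrogate_params()] with barrier
#'   `A`), `rc` (the [reaction_coordinate()]), `proton` (serial of `HG`).
#' @export
make_toy_system <- function(seed, n_residues = 8L, es_distance = 3.5,
                            ti_distance = 1.5, barrier = 10,
                            substrate_rotation_deg = 25, n_waters = 2L) {
  stopifnot(n_residues >= 3)
  .with_seed(seed, {
    mid <- as.integer(ceiling(n_residues / 2))
    rows <- list()
    serial <- 0L
    add <- function(name, element, resname, resno, pos, hetero = FALSE) {
      serial <<- serial + 1L
      rows[[length(rows) + 1]] <<- atom_table(
        serial, name, element, resname, "A", resno,
        pos[1], pos[2], pos[3], hetero = hetero)
      serial
    }
    jitter3 <- function() stats::rnorm(3, 0, 0.05)
    for (i in seq_len(n_residues)) {
      b <- c(3.0 * i, 1.2 * sin(0.8 * i), 1.2 * cos(0.8 * i))
      resname <- if (i == mid) "SER" else "GLY"
      add("N", "N", resname, i, b + c(0, 0, 0) + jitter3())
      ca <- add("CA", "C", resname, i, b + c(1.2, 0.5, 0.1) + jitter3())
      add("C", "C", resname, i, b + c(2.3, -0.2, 0.4) + jitter3())
      add("O", "O", resname, i, b + c(2.5, -1.4, 0.3) + jitter3())
      if (i == mid) {
        og <- add("OG", "O", resname, i,
                  b + c(1.2, 1.9, 0.6) + jitter3())
      }
    }
    og_pos <- {
      a <- do.call(rbind, rows)
      unlist(a[a$serial == og, c("x", "y", "z")])
    }
    u <- c(0.15, 0.90, 0.45)
    u <- u / sqrt(sum(u^2))
    c20_pos <- og_pos + ti_distance * u
    v1 <- c(0.8, -0.3, 0.52); v1 <- v1 - sum(v1 * u) * u; v1 <- v1 / sqrt(sum(v1^2))
    v2 <- c(u[2] * v1[3] - u[3] * v1[2],
            u[3] * v1[1] - u[1] * v1[3],
            u[1] * v1[2] - u[2] * v1[1])
    sub_resno <- 900L
    c20 <- add("C20", "C", "SUB", sub_resno, c20_pos, hetero = TRUE)
    o2_pos <- c20_pos + 1.23 * (0.7 * u + 0.71 * v1)
    add("O2", "O", "SUB", sub_resno, o2_pos, hetero = TRUE)
    c21_pos <- c20_pos + 1.52 * (0.5 * u - 0.6 * v1 + 0.62 * v2)
    add("C21", "C", "SUB", sub_resno, c21_pos, hetero = TRUE)
    n2_pos <- c21_pos + 1.45 * (0.3 * u + 0.2 * v1 - 0.93 * v2)
    add("N2", "N", "SUB", sub_resno, n2_pos, hetero = TRUE)
    # catalytic proton: sits on the substrate oxyanion in the TI state
    hg <- add("HG", "H", "SUB", sub_resno, o2_pos + 0.97 * v1, hetero = TRUE)
    for (w in seq_len(n_waters)) {
      add("O", "O", "HOH", 950L + w,
          c(3.0 * (w + 1), -3.5, 2.5) + jitter3(), hetero = TRUE)
    }
    atoms <- do.call(rbind, rows)
    rownames(atoms) <- NULL
    full <- structure_model(atoms,
                            substrate_residues = res_key("A", sub_resno))
    rc <- reaction_coordinate(og, c20, es_distance = es_distance,
                              ti_distance = ti_distance)
    # harmonic reference topology from the TI geometry; no bond across the
    # reaction coordinate and none to the transferable proton
    pair_rows <- list()
    dist_between <- function(s1, s2) {
      sqrt(sum((atom_position(full, s1) - atom_position(full, s2))^2))
    }
    bond <- function(s1, s2) {
      pair_rows[[length(pair_rows) + 1]] <<- data.frame(
        i = s1, j = s2, r0 = dist_between(s1, s2), k = 300)
    }
    serial_of <- function(resno, name) {
      s <- atoms$serial[atoms$resno == resno & atoms$name == name &
                        atoms$resname != "HOH"]
      stopifnot(length(s) == 1)
      s
    }
    for (i in seq_len(n_residues)) {
      bond(serial_of(i, "N"), serial_of(i, "CA"))
      bond(serial_of(i, "CA"), serial_of(i, "C"))
      bond(serial_of(i, "C"), serial_of(i, "O"))
      if (i < n_residues) bond(serial_of(i, "C"), serial_of(i + 1, "N"))
      if (i == mid) bond(serial_of(i, "CA"), og)
    }
    s_sub <- function(name) atoms$serial[atoms$resno == sub_resno & atoms$name == name]
    bond(c20, s_sub("O2"))
    bond(c20, s_sub("C21"))
    bond(s_sub("C21"), s_sub("N2"))
    params <- surrogate_params(
      bonds = do.call(rbind, pair_rows),
      well = list(i = og, j = c20, d1 = ti_distance, d2 = es_distance,
                  A = barrier))
    # ES end point: substrate rotated about the electrophile (external
    # planar pose stand-in), then positioned by the standard construction
    keys <- atom_res_keys(full$atoms)
    sub_idx <- which(keys == res_key("A", sub_resno))
    sub_xyz <- coords(full)[sub_idx, , drop = FALSE]
    R <- .rotation_about_axis(v2, substrate_rotation_deg)
    planar <- sweep(sweep(sub_xyz, 2, c20_pos) %*% t(R), 2, c20_pos, `+`)
    es <- build_es_from_ti(full, planar, proton = hg, rc = rc)
    list(full = full,
         endpoints = endpoint_pair(es, full, rc),
         params = params, rc = rc, proton = hg)
  })
}
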