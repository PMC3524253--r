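# Adiabatic mapping: linear interpolation between the reaction end points,
# per-frame reaction-coordinate constraints, independent constrained
# optimization of every frame, and profile assembly.

#' Interpolation frame
#'
#' @param index frame index, 0-based: 0 is the ES end point,
#'   `n_divisions + 1` the TI end point, 1..`n_divisions` are interior.
#' @param structure the frame's `structure_model`.
#' @param constrained whether the reaction-coordinate constraint applies
#'   (interior frames only; all constraints on the reaction-coordinate pair
#'   are discarded in the first and last frame).
#' @param rc_atoms integer pair of reaction-coordinate serials.
#' @return object of class `mapping_frame`.
#' @export
mapping_frame <- function(index, structure, constrained, rc_atoms) {
  structure(list(index = as.integer(index), structure = structure,
                 constrained = constrained,
                 rc_atoms = as.integer(rc_atoms),
                 energies = list(), status = "pending"),
            class = "mapping_frame")
}

#' Linearly interpolate frames between ES and TI
#'
#' Divides the displacement of every atom between the two end points by
#' `n_divisions` and adds it incrementally: interior frame `i` places every
#' atom at `r_ES + i * (r_TI - r_ES) / n_divisions`, so per-frame
#' displacement of each atom is constant along the path. The result has
#' `n_divisions + 2` frames: frame 0 is the ES end point and frame
#' `n_divisions + 1` the TI end point, both unconstrained; frame
#' `n_divisions` coincides geometrically with the TI but carries the
#' constraint. An atom whose end point positions differ by 2.2 A therefore
#' translates by 0.22 A between consecutive frames at the default 10
#' divisions.
#'
#' @param endpoints an [endpoint_pair()].
#' @param n_divisions number of divisions of the path (>= 2), default 10.
#' @return list of `mapping_frame`s, indices 0..`n_divisions + 1`.
#' @export
interpolate_path <- function(endpoints, n_divisions = 10L) {
  stopifnot(n_divisions >= 2)
  es <- endpoints$es
  ti <- endpoints$ti
  if (n_atoms(es) != n_atoms(ti)) stop("ES/TI atom count mismatch")
  rc_atoms <- c(endpoints$rc$nucleophile_atom, endpoints$rc$electrophile_atom)
  r0 <- coords(es)
  dr <- (coords(ti) - r0) / n_divisions
  frames <- vector("list", n_divisions + 2)
  frames[[1]] <- mapping_frame(0, es, FALSE, rc_atoms)
  for (i in seq_len(n_divisions)) {
    m <- es
    coords(m) <- r0 + i * dr
    frames[[i + 1]] <- mapping_frame(i, m, TRUE, rc_atoms)
  }
  frames[[n_divisions + 2]] <- mapping_frame(n_divisions + 1, ti, FALSE, rc_atoms)
  frames
}

#' Apply the reaction-coordinate constraint to a frame
#'
#' Fixing both reaction-coordinate atoms' Cartesian coordinates fixes their
#' distance; per-coordinate freeze flags are the native constraint mechanism
#' of the target engine. Interior frames gain the two atoms in their frozen
#' set; end point frames are left untouched (any residue freeze list still
#' applies there). Idempotent.
#'
#' @param frame a `mapping_frame`.
#' @param rc a [reaction_coordinate()].
#' @return the frame, with the constraint materialized in its structure's
#'   frozen set.
#' @export
constrain_frame <- function(frame, rc) {
  pair <- c(rc$nucleophile_atom, rc$electrophile_atom)
  if (!all(pair %in% frame$structure$atoms$serial)) {
    stop("reaction-coordinate atom(s) missing from frame structure")
  }
  if (frame$constrained) {
    frame$structure$frozen <- sort(unique(c(frame$structure$frozen, pair)))
    frame$rc_atoms <- as.integer(pair)
  }
  frame
}

#' Energy profile
#'
#' @param frames ordered list of `mapping_frame`s (all sharing one atom
#'   count).
#' @param reference_channel energy channel used for barrier analysis.
#' @param label configuration tag, e.g. `"PM6//M(C15, G0.5)"`.
#' @param opt_config the optimization `backend_config` (kept for
#'   convergence-ordering reports).
#' @return object of class `energy_profile`.
#' @export
energy_profile <- function(frames, reference_channel = "conventional_sp",
                           label = "", opt_config = NULL) {
  idx <- vapply(frames, `[[`, 0L, "index")
  stopifnot(!is.unsorted(idx))
  counts <- vapply(frames, function(f) n_atoms(f$structure), 0L)
  if (length(unique(counts)) != 1) stop("frames differ in atom count")
  structure(list(frames = frames, reference_channel = reference_channel,
                 label = label, opt_config = opt_config),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("<energy_profile> %s: %d frames\n", x$label, length(x$frames)))
  invisible(x)
}

#' Frame energies of one channel
#'
#' @param profile an `energy_profile`.
#' @param channel channel name; defaults to the profile's reference channel.
#' @return numeric vector (NA where a frame lacks the channel or failed),
#'   named by frame index.
#' @export
profile_energies <- function(profile, channel = profile$reference_channel) {
  e <- vapply(profile$frames, function(f) {
    for (rec in f$energies) {
      if (identical(rec$channel, channel)) return(rec$heat_of_formation)
    }
    NA_real_
  }, 0)
  names(e) <- vapply(profile$frames, `[[`, 0L, "index")
  e
}

#' Configuration label for a profile
#' @param sp_config,opt_config single-point and optimization configurations.
#' @return string `"<sp method>//M(C<cutoff>, G<gcc>)"`.
#' @export
profile_label <- function(sp_config, opt_config) {
  sprintf("%s//M(C%g, G%s)", sp_config$method, opt_config$nddo_cutoff,
          .fmt_gcc(opt_config$gradient_convergence))
}

# gcc printed with one decimal when that loses nothing (G5.0, G0.5), full
# precision otherwise (G0.05)
.fmt_gcc <- function(x) {
  s <- sprintf("%.1f", x)
  if (abs(as.numeric(s) - x) < 1e-12) s else format(x)
}

#' Run the adiabatic mapping over a set of frames
#'
#' Each frame is optimized independently under its constraints (no
#' cross-frame state, so frames may run in any order or in parallel), then
#' re-evaluated as a single point with the second configuration; both energy
#' channels are stored on the frame. A failed frame optimization marks the
#' frame `"failed"` and the profile is still returned with the gap flagged.
#'
#' @param frames list of `mapping_frame`s from [interpolate_path()], already
#'   constrained as desired (e.g. via [constrain_frame()]).
#' @param opt_config optimization configuration (`single_point` must be
#'   `FALSE`).
#' @param sp_config single-point configuration (`single_point` must be
#'   `TRUE`).
#' @param backend energy backend closure `(xyz) -> list(energy, gradient)`.
#' @param max_iter per-frame optimizer iteration cap.
#' @return an `energy_profile` labelled
#'   `"<sp method>//M(C<cutoff>, G<gcc>)"`.
#' @export
run_mapping <- function(frames, opt_config, sp_config, backend,
                        max_iter = 2000L) {
  stopifnot(!opt_config$single_point, sp_config$single_point)
  out <- lapply(frames, function(f) {
    frozen <- f$structure$frozen
    if (f$constrained) frozen <- sort(unique(c(frozen, f$rc_atoms)))
    res <- optimize_geometry(f$structure, opt_config, backend,
                             frozen = frozen, max_iter = max_iter)
    if (is.null(res$final_structure)) {
      f$status <- "failed"
      return(f)
    }
    f$structure <- res$final_structure
    sp <- backend(coords(res$final_structure))
    f$energies <- list(res$energy,
                       energy_record(energy_channel(sp_config), sp$energy))
    f$status <- if (isTRUE(res$converged)) "optimized" else "failed"
    f
  })
  out <- out[order(vapply(out, `[[`, 0L, "index"))]
  n_failed <- sum(vapply(out, `[[`, "", "status") == "failed")
  if (n_failed > 0) {
    warning(n_failed, " frame(s) failed to optimize; profile has gaps")
  }
  energy_profile(out, reference_channel = energy_channel(sp_config),
                 label = profile_label(sp_config, opt_config),
                 opt_config = opt_config)
}

#' Generate self-contained per-frame job inputs
#'
#' Writes one engine input file per (frame, configuration) pair plus a JSON
#' manifest mapping files to frame indices and configuration tags. Frames
#' are independent, so the generated jobs can be dispatched trivially in
#' parallel; re-running the generation is byte-identical.
#'
#' @param frames list of `mapping_frame`s.
#' @param configs list of `backend_config`s (or a single one).
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest as a data.frame (`file`, `frame_index`,
#'   `config`).
#' @export
generate_jobs <- function(frames, configs, dir) {
  if (inherits(configs, "backend_config")) configs <- list(configs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cfg in configs) {
    tag <- sprintf("C%g_G%g", cfg$nddo_cutoff, cfg$gradient_convergence)
    for (f in frames) {
      frozen <- f$structure$frozen
      if (f$constrained) frozen <- sort(unique(c(frozen, f$rc_atoms)))
      file <- sprintf("frame_%02d__%s.mop", f$index, tag)
      txt <- render_input(f$structure, cfg, constraints = frozen,
                          title = sprintf("frame %d (%s)", f$index, tag))
      cat(txt, file = file.path(dir, file))
      rows[[length(rows) + 1]] <- data.frame(
        file = file, frame_index = f$index, config = tag,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(dir, "jobs.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read a job manifest
#' @param dir directory written by [generate_jobs()].
#' @return data.frame with `file`, `frame_index`, `config`.
#' @export
read_job_manifest <- function(dir) {
  df <- jsonlite::fromJSON(file.path(dir, "jobs.json"))
  df$frame_index <- as.integer(df$frame_index)
  df
}

#' Write an energy profile as CSV
#'
#' One row per frame: index, reaction-coordinate distance, constraint state,
#' status, and one column per energy channel present.
#'
#' @param profile an `energy_profile`.
#' @param path output CSV path.
#' @param rc optional [reaction_coordinate()] for the distance column.
#' @return invisibly, the written data.frame.
#' @export
write_profile_csv <- function(profile, path, rc = NULL) {
  channels <- unique(unlist(lapply(profile$frames, function(f) {
    vapply(f$energies, `[[`, "", "channel")
  })))
  df <- data.frame(
    frame = vapply(profile$frames, `[[`, 0L, "index"),
    rc_distance = vapply(profile$frames, function(f) {
      if (is.null(rc)) NA_real_ else rc_distance(f$structure, rc)
    }, 0),
    constrained = vapply(profile$frames, `[[`, FALSE, "constrained"),
    status = vapply(profile$frames, `[[`, "", "status"),
    stringsAsFactors = FALSE)
  for (ch in channels) df[[ch]] <- unname(profile_energies(profile, ch))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read an energy profile CSV
#' @param path CSV written by [write_profile_csv()].
#' @return data.frame.
#' @export
read_profile_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
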