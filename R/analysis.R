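# Profile analytics: barrier extraction, configuration-convergence report,
# localized-orbital drift report, and Kabsch superposition RMSD.

#' Extract the reaction barrier from an energy profile
#'
#' The barrier is defined by locating the highest point on the profile and
#' subtracting the energy of the lowest point before it -- not the energy of
#' frame 0, since a profile may dip below its initial state when a lower
#' local minimum becomes accessible along the path. Ties at the maximum are
#' broken towards the lowest index; failed frames (missing energies) are
#' skipped with their gap ignored.
#'
#' @param profile an `energy_profile`, or a numeric vector of frame energies
#'   (kcal/mol), or a data.frame from [read_profile_csv()].
#' @param channel energy channel (profile/data.frame input only).
#' @return object of class `barrier_estimate`: `barrier` (kcal/mol),
#'   `max_frame`, `reference_frame` (frame indices), `channel`.
#' @export
extract_barrier <- function(profile, channel = NULL) {
  if (inherits(profile, "energy_profile")) {
    if (is.null(channel)) channel <- profile$reference_channel
    e <- profile_energies(profile, channel)
    idx <- as.integer(names(e))
  } else if (is.data.frame(profile)) {
    if (is.null(channel)) channel <- "conventional_sp"
    if (!channel %in% names(profile)) stop("channel column absent: ", channel)
    e <- profile[[channel]]
    idx <- profile$frame
  } else {
    e <- as.numeric(profile)
    idx <- seq_along(e) - 1L
    if (is.null(channel)) channel <- "energy"
  }
  ok <- is.finite(e)
  e <- e[ok]
  idx <- idx[ok]
  if (length(e) < 2) stop("need at least 2 frames with energies in channel ", channel)
  imax <- which.max(e)            # which.max already breaks ties low
  iref <- if (imax == 1) 1L else which.min(e[seq_len(imax - 1)])
  structure(list(barrier = unname(e[imax] - e[iref]),
                 max_frame = unname(idx[imax]),
                 reference_frame = unname(idx[iref]),
                 channel = channel),
            class = "barrier_estimate")
}

#' @export
print.barrier_estimate <- function(x, ...) {
  cat(sprintf("<barrier_estimate> %.2f kcal/mol (frame %d relative to frame %d, %s)\n",
              x$barrier, x$max_frame, x$reference_frame, x$channel))
  invisible(x)
}

#' Configuration-convergence report over several profiles
#'
#' Tabulates the extracted barrier per configuration, computes frame-wise
#' energy deltas between consecutive configurations (ordered from loosest to
#' strictest: increasing NDDO cutoff, decreasing gradient criterion), and
#' flags whether the barrier decreases monotonically along that ordering --
#' the expected signature of convergence towards a lower bound with stricter
#' settings.
#'
#' @param profiles list of `energy_profile`s sharing frame indexing.
#' @param channel energy channel used throughout.
#' @return list with `table` (data.frame: label, cutoff, gcc, barrier,
#'   max_frame), `deltas` (named list of frame-wise energy differences
#'   between consecutive configurations), `monotone_decreasing` flag.
#' @export
convergence_report <- function(profiles, channel = NULL) {
  stopifnot(length(profiles) >= 1)
  nf <- vapply(profiles, function(p) length(p$frames), 0L)
  if (length(unique(nf)) != 1) stop("profiles have mismatched frame counts")
  ord_key <- vapply(profiles, function(p) {
    cfg <- p$opt_config
    if (is.null(cfg)) return(0)
    cfg$nddo_cutoff * 1e3 - cfg$gradient_convergence
  }, 0)
  profiles <- profiles[order(ord_key)]
  rows <- lapply(profiles, function(p) {
    ch <- if (is.null(channel)) p$reference_channel else channel
    b <- extract_barrier(p, ch)
    data.frame(
      label = p$label,
      cutoff = if (is.null(p$opt_config)) NA_real_ else p$opt_config$nddo_cutoff,
      gcc = if (is.null(p$opt_config)) NA_real_ else p$opt_config$gradient_convergence,
      barrier = b$barrier, max_frame = b$max_frame,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  deltas <- list()
  if (length(profiles) > 1) {
    for (i in seq_len(length(profiles) - 1)) {
      ch <- if (is.null(channel)) profiles[[i]]$reference_channel else channel
      deltas[[sprintf("%s -> %s", tab$label[i], tab$label[i + 1])]] <-
        profile_energies(profiles[[i + 1]], ch) - profile_energies(profiles[[i]], ch)
    }
  }
  list(table = tab,
       deltas = deltas,
       monotone_decreasing = all(diff(tab$barrier) <= 1e-9))
}

#' Localized-orbital drift report
#'
#' Per-frame differences between the energy channels of a profile. The
#' localized-orbital optimization energy can drift from the conventional
#' energy through accumulated orbital-truncation error (loss of
#' orthogonality, growing with the number of SCF cycles); this report makes
#' the drift visible frame by frame and, when SCF cycle counts are present,
#' reports the correlation of |drift| with cycle count.
#'
#' @param profile an `energy_profile` carrying at least two channels on some
#'   frames.
#' @param channel_a,channel_b the two channels compared (difference is
#'   `a - b`).
#' @return object of class `drift_report`: data.frame `frames` (frame,
#'   difference, scf_cycles) over frames where both channels are present,
#'   and `scf_correlation` (Pearson, or NA).
#' @export
drift_report <- function(profile, channel_a = "mozyme",
                         channel_b = "conventional_sp") {
  ea <- profile_energies(profile, channel_a)
  eb <- profile_energies(profile, channel_b)
  scf <- vapply(profile$frames, function(f) {
    for (rec in f$energies) {
      if (identical(rec$channel, channel_a) && !is.na(rec$scf_cycles)) {
        return(as.integer(rec$scf_cycles))
      }
    }
    NA_integer_
  }, 0L)
  ok <- is.finite(ea) & is.finite(eb)
  df <- data.frame(frame = as.integer(names(ea))[ok],
                   difference = (ea - eb)[ok],
                   scf_cycles = scf[ok])
  rownames(df) <- NULL
  corr <- NA_real_
  use <- !is.na(df$scf_cycles)
  if (sum(use) >= 3 && stats::sd(df$scf_cycles[use]) > 0 &&
      stats::sd(abs(df$difference[use])) > 0) {
    corr <- stats::cor(abs(df$difference[use]), df$scf_cycles[use])
  }
  structure(list(frames = df, scf_correlation = corr,
                 channels = c(channel_a, channel_b)),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("<drift_report> %s - %s over %d frames; max |drift| %.3f kcal/mol\n",
              x$channels[1], x$channels[2], nrow(x$frames),
              if (nrow(x$frames)) max(abs(x$frames$difference)) else NA))
  invisible(x)
}

# ---- Kabsch superposition --------------------------------------------------

.default_atom_map <- function(a, b, include_hydrogens) {
  ka <- paste(atom_res_keys(a$atoms), a$atoms$name)
  kb <- paste(atom_res_keys(b$atoms), b$atoms$name)
  if (!include_hydrogens) {
    ha <- toupper(a$atoms$element) == "H"
    hb <- toupper(b$atoms$element) == "H"
  } else {
    ha <- hb <- FALSE
  }
  common <- intersect(ka[!ha], kb[!hb])
  cbind(match(common, ka), match(common, kb))
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Minimal root-mean-square deviation over all rigid rotations and
#' translations, via singular value decomposition of the cross-covariance
#' matrix with the proper-rotation (determinant +1) correction. By default
#' atoms are paired by identical (residue key, atom name) with hydrogens
#' excluded -- heavy-atom geometry comparison of e.g. alternative
#' transition-state models.
#'
#' @param a,b `structure_model`s, or plain `n x 3` coordinate matrices.
#' @param atom_map optional 2-column integer matrix of row indices pairing
#'   atoms of `a` with atoms of `b`.
#' @param include_hydrogens pair hydrogens too (default mapping only).
#' @return the minimal RMSD, Angstrom.
#' @export
kabsch_rmsd <- function(a, b, atom_map = NULL, include_hydrogens = FALSE) {
  A <- if (inherits(a, "structure_model")) coords(a) else as.matrix(a)
  B <- if (inherits(b, "structure_model")) coords(b) else as.matrix(b)
  if (is.null(atom_map)) {
    if (inherits(a, "structure_model") && inherits(b, "structure_model")) {
      atom_map <- .default_atom_map(a, b, include_hydrogens)
    } else {
      if (nrow(A) != nrow(B)) stop("coordinate sets differ in size; supply atom_map")
      atom_map <- cbind(seq_len(nrow(A)), seq_len(nrow(B)))
    }
  }
  P <- A[atom_map[, 1], , drop = FALSE]
  Q <- B[atom_map[, 2], , drop = FALSE]
  n <- nrow(P)
  if (n < 3) stop("need at least 3 mapped atoms for superposition")
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  if (qr(Pc)$rank < 2 || qr(Qc)$rank < 2) {
    stop("mapped atoms are collinear; superposition is underdetermined")
  }
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diff <- Qc - Pc %*% t(R)
  sqrt(sum(diff^2) / n)
}
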