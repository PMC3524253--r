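test_that("interpolation is exactly linear with constant per-frame steps", {
  # end points whose electrophile carbon positions differ by 2.2 A: ten
  # divisions translate that atom 0.22 A per frame
  toy <- make_toy_system(3, es_distance = 3.7, ti_distance = 1.5,
                         substrate_rotation_deg = 0)
  frames <- interpolate_path(toy$endpoints, 10)
  expect_length(frames, 12)
  expect_equal(vapply(frames, `[[`, 0L, "index"), 0:11)
  expect_false(frames[[1]]$constrained)
  expect_false(frames[[12]]$constrained)
  expect_true(all(vapply(frames[2:11], `[[`, FALSE, "constrained")))
  iC <- which(toy$full$atoms$serial == toy$rc$electrophile_atom)
  pos <- t(vapply(frames, function(f) coords(f$structure)[iC, ], numeric(3)))
  expect_equal(sqrt(sum((pos[1, ] - pos[12, ])^2)), 2.2, tolerance = 1e-9)
  steps <- sqrt(rowSums(diff(pos[1:11, ])^2))
  expect_equal(steps, rep(0.22, 10), tolerance = 1e-9)
  # every atom of every interior frame sits on the closed-form convex
  # combination to machine precision
  r_es <- coords(toy$endpoints$es)
  r_ti <- coords(toy$endpoints$ti)
  for (i in 1:10) {
    expected <- r_es + i * (r_ti - r_es) / 10
    expect_equal(coords(frames[[i + 1]]$structure), expected,
                 tolerance = 1e-14)
  }
  # frame n_divisions coincides geometrically with the TI but is constrained
  expect_equal(coords(frames[[11]]$structure), r_ti, tolerance = 1e-14)
  expect_true(frames[[11]]$constrained)
  # es = ti degenerate path: all frames identical
  same <- endpoint_pair(toy$endpoints$ti, toy$endpoints$ti, toy$rc)
  for (f in interpolate_path(same, 5)) {
    expect_identical(coords(f$structure), r_ti)
  }
})

test_that("the reaction-coordinate constraint freezes exactly the atom pair", {
  toy <- make_toy_system(4)
  frames <- interpolate_path(toy$endpoints, 4)
  pair <- sort(c(toy$rc$nucleophile_atom, toy$rc$electrophile_atom))
  interior <- constrain_frame(frames[[3]], toy$rc)
  expect_equal(interior$structure$frozen, pair)
  # idempotent
  expect_equal(constrain_frame(interior, toy$rc)$structure$frozen, pair)
  # end point frames are unaffected by the rc constraint
  endp <- constrain_frame(frames[[1]], toy$rc)
  expect_length(endp$structure$frozen, 0)
  # a residue freeze list still applies on end points and stacks on interior
  keys <- res_key(toy$full$atoms$chain, toy$full$atoms$resno,
                  toy$full$atoms$icode)
  ser_res <- unique(keys[toy$full$atoms$name == "OG"])
  frames2 <- interpolate_path(toy$endpoints, 4)
  frames2 <- lapply(frames2, function(f) {
    f$structure <- freeze_surface_sidechains(f$structure, ser_res)
    constrain_frame(f, toy$rc)
  })
  expect_gt(length(frames2[[1]]$structure$frozen), 0)
  expect_true(all(pair %in% frames2[[3]]$structure$frozen))
})

test_that("mapping runs frames independently and locates the barrier top", {
  toy <- make_toy_system(6)
  be <- surrogate_backend(toy$params, toy$full)
  frames <- interpolate_path(toy$endpoints, 10)
  opt <- backend_config(gradient_convergence = 0.5)
  sp <- backend_config(localized_orbitals = FALSE, single_point = TRUE)
  prof <- run_mapping(frames, opt, sp, be)
  expect_s3_class(prof, "energy_profile")
  expect_equal(prof$label, "PM6//M(C15, G0.5)")
  e <- profile_energies(prof, "conventional_sp")
  expect_length(e, 12)
  # profile maximum at the interior frame nearest the analytic barrier top
  # (reaction coordinate midpoint), and both channels recorded
  expect_equal(as.integer(names(which.max(e))), 5L)
  expect_false(any(is.na(profile_energies(prof, "mozyme"))))
  # frozen rc atoms are bit-identical through each interior optimization
  pair_idx <- which(toy$full$atoms$serial %in%
                    c(toy$rc$nucleophile_atom, toy$rc$electrophile_atom))
  for (i in 2:11) {
    expect_identical(coords(prof$frames[[i]]$structure)[pair_idx, ],
                     coords(frames[[i]]$structure)[pair_idx, ])
  }
  # permuting frame execution order changes nothing (no cross-frame state)
  perm <- sample(seq_along(frames))
  prof2 <- run_mapping(frames[perm], opt, sp, be)
  e2 <- profile_energies(prof2, "conventional_sp")
  expect_equal(e2[order(as.integer(names(e2)))], e[order(as.integer(names(e)))])
  # all frames at one geometry: flat profile
  flat_frames <- lapply(frames, function(f) {
    f$structure <- toy$endpoints$ti
    f
  })
  flat <- profile_energies(run_mapping(flat_frames, opt, sp, be))
  expect_equal(unname(diff(range(flat))), 0, tolerance = 1e-8)
})

test_that("job generation is complete, byte-identical and manifest-consistent", {
  toy <- make_toy_system(8)
  frames <- interpolate_path(toy$endpoints, 10)
  configs <- list(backend_config(nddo_cutoff = 9, gradient_convergence = 5,
                                 charge = 0L),
                  backend_config(nddo_cutoff = 12, gradient_convergence = 1,
                                 charge = 0L),
                  backend_config(nddo_cutoff = 15,
                                 gradient_convergence = 0.5, charge = 0L))
  d1 <- withr::local_tempdir()
  man <- generate_jobs(frames, configs, d1)
  expect_equal(nrow(man), 36)          # 12 frames x 3 configurations
  expect_true(all(file.exists(file.path(d1, man$file))))
  d2 <- withr::local_tempdir()
  generate_jobs(frames, configs, d2)
  for (f in man$file) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_identical(readLines(file.path(d1, "jobs.json")),
                   readLines(file.path(d2, "jobs.json")))
  # manifest round trip reconstructs the frame -> file map
  back <- read_job_manifest(d1)
  expect_equal(back$file, man$file)
  expect_equal(back$frame_index, man$frame_index)
  # single config: 12 files
  d3 <- withr::local_tempdir()
  expect_equal(nrow(generate_jobs(frames, configs[[3]], d3)), 12)
})

test_that("profile CSV round trip preserves energies and barrier", {
  toy <- make_toy_system(10)
  be <- surrogate_backend(toy$params, toy$full)
  prof <- run_mapping(interpolate_path(toy$endpoints, 4),
                      backend_config(gradient_convergence = 0.1),
                      backend_config(localized_orbitals = FALSE,
                                     single_point = TRUE), be)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, f, rc = toy$rc)
  df <- read_profile_csv(f)
  expect_equal(df$frame, 0:5)
  expect_equal(df$conventional_sp, unname(profile_energies(prof)))
  expect_equal(df$rc_distance[1], 3.5, tolerance = 1e-6)
  b1 <- extract_barrier(prof)
  b2 <- extract_barrier(df, "conventional_sp")
  expect_equal(b2$barrier, b1$barrier, tolerance = 1e-9)
})
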