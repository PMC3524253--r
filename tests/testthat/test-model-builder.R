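test_that("radius selection matches a brute-force all-pairs oracle", {
  toy <- make_toy_system(13, n_residues = 10)
  full <- toy$full
  center <- "A5"
  keys <- res_key(full$atoms$chain, full$atoms$resno, full$atoms$icode)
  xyz <- coords(full)
  for (radius in c(4, 7, 11)) {
    sel <- select_model_region(full, selection_spec(center, radius,
                                                    fill_single_gaps = FALSE))
    # oracle: explicit double loop over every atom pair
    cidx <- which(keys == center)
    expected <- character(0)
    for (k in unique(keys)) {
      hit <- FALSE
      for (i in which(keys == k)) {
        for (j in cidx) {
          if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= radius) hit <- TRUE
        }
      }
      if (hit) expected <- c(expected, k)
    }
    expect_setequal(sel$residue_order, expected)
  }
  # monotonicity: larger radius is a superset
  s8 <- select_model_region(full, selection_spec(center, 8))
  s12 <- select_model_region(full, selection_spec(center, 12))
  expect_true(all(s8$residue_order %in% s12$residue_order))
  # radius beyond the model diameter selects everything
  sall <- select_model_region(full, selection_spec(center, 1e3))
  expect_equal(sall$residue_order, full$residue_order)
  expect_error(select_model_region(full, selection_spec("Z1", 8)), "Z1")
})

test_that("single-residue backbone gaps are filled; wider gaps are not", {
  full <- chain_model(10)
  expect_equal(fill_single_gaps(c("A5", "A7"), full), c("A5", "A6", "A7"))
  expect_equal(fill_single_gaps(c("A5", "A8"), full), c("A5", "A8"))
  once <- fill_single_gaps(c("A2", "A4", "A6"), full)
  expect_equal(fill_single_gaps(once, full), once)  # idempotent
  expect_equal(once, c("A2", "A3", "A4", "A5", "A6"))
})

test_that("chain-break C-termini gain exactly one aldehyde cap hydrogen", {
  toy <- make_toy_system(17, n_residues = 9, n_waters = 0)
  full <- toy$full
  # an intact model with native termini is unchanged
  intact <- cap_termini(full)
  expect_equal(n_atoms(intact), n_atoms(full))
  # remove residue 5: one internal cut -> one cap at A4, neutral N at A6
  sel <- subset_residues(full, setdiff(full$residue_order, "A5"))
  capped <- cap_termini(sel, full = full)
  expect_equal(n_atoms(capped), n_atoms(sel) + 1)
  kc <- res_key(capped$atoms$chain, capped$atoms$resno, capped$atoms$icode)
  expect_equal(capped$atoms$name[kc == "A4"],
               c(sel$atoms$name[res_key(sel$atoms$chain, sel$atoms$resno,
                                        sel$atoms$icode) == "A4"], "HC"))
  expect_equal(capped$neutral_n_termini, "A6")
  # cap H sits 1.09 A from the carbonyl carbon, towards the removed N
  cpos <- unlist(capped$atoms[kc == "A4" & capped$atoms$name == "C",
                              c("x", "y", "z")])
  hpos <- unlist(capped$atoms[kc == "A4" & capped$atoms$name == "HC",
                              c("x", "y", "z")])
  expect_equal(sqrt(sum((hpos - cpos)^2)), 1.09, tolerance = 1e-9)
  npos <- unlist(full$atoms[full$atoms$resno == 5 & full$atoms$name == "N",
                            c("x", "y", "z")])
  u <- (npos - cpos) / sqrt(sum((npos - cpos)^2))
  expect_equal(as.numeric(hpos), as.numeric(cpos + 1.09 * u), tolerance = 1e-9)
  # idempotent
  expect_equal(n_atoms(cap_termini(capped, full = full)), n_atoms(capped))
})

test_that("ES construction hits the target distance and preserves ordering", {
  toy <- make_toy_system(19)
  es <- toy$endpoints$es
  ti <- toy$endpoints$ti
  expect_equal(rc_distance(es, toy$rc), 3.5, tolerance = 1e-9)
  expect_identical(es$atoms$name, ti$atoms$name)
  expect_identical(es$atoms$serial, ti$atoms$serial)
  # non-substrate atoms are untouched
  keys <- res_key(ti$atoms$chain, ti$atoms$resno, ti$atoms$icode)
  prot <- !keys %in% ti$substrate_residues
  expect_identical(coords(es)[prot, ], coords(ti)[prot, ])
  # proton transferred onto the nucleophile at 0.97 A
  og <- coords(ti)[ti$atoms$serial == toy$rc$nucleophile_atom, ]
  h <- coords(es)[es$atoms$serial == toy$proton, ]
  expect_equal(sqrt(sum((h - og)^2)), 0.97, tolerance = 1e-9)
  # degenerate case: planar pose = TI pose at the TI distance leaves the
  # substrate in place except the proton move
  keys_ti <- keys[keys %in% ti$substrate_residues]
  sub_xyz <- coords(ti)[keys %in% ti$substrate_residues, , drop = FALSE]
  rc0 <- reaction_coordinate(toy$rc$nucleophile_atom,
                             toy$rc$electrophile_atom,
                             es_distance = toy$rc$ti_distance + 1e-9,
                             ti_distance = toy$rc$ti_distance / 2)
  same <- build_es_from_ti(ti, sub_xyz, toy$proton, rc0)
  moved <- abs(coords(same) - coords(ti)) > 1e-6
  expect_equal(unique(which(rowSums(moved) > 0)),
               which(ti$atoms$serial == toy$proton))
  # atom-count mismatch is an error
  expect_error(build_es_from_ti(ti, sub_xyz[-1, ], toy$proton, toy$rc),
               "mismatch")
})

test_that("surface side-chain freezing freezes exactly the side chains", {
  toy <- make_toy_system(23, n_residues = 7)
  m <- toy$full
  frozen <- freeze_surface_sidechains(m, c("A2", "A6"))
  keys <- res_key(m$atoms$chain, m$atoms$resno, m$atoms$icode)
  # toy GLY residues have pure-backbone atoms, so only SER's OG would count;
  # A2/A4 are glycine-like: nothing beyond backbone => nothing frozen
  expect_length(frozen$frozen, 0)
  mid_key <- m$residue_order[vapply(m$residue_order, function(k) {
    any(m$atoms$name[keys == k] == "OG")
  }, FALSE)]
  frozen2 <- freeze_surface_sidechains(m, mid_key)
  expect_equal(frozen2$frozen,
               m$atoms$serial[keys == mid_key & m$atoms$name == "OG"])
  expect_identical(freeze_surface_sidechains(m, character())$frozen, m$frozen)
  expect_error(freeze_surface_sidechains(m, "B99"), "B99")
  # freeze survives into backend input rendering as 0-flags
  txt <- render_input(frozen2, backend_config(), constraints = frozen2$frozen)
  ln <- strsplit(txt, "\n")[[1]]
  geom <- ln[seq(4, length.out = n_atoms(m))]
  frozen_row <- which(m$atoms$serial %in% frozen2$frozen)
  expect_true(all(grepl(" 0 .* 0 .* 0$|0$", geom[frozen_row])))
  flags <- vapply(strsplit(trimws(geom), "\\s+"), function(tok) {
    paste(tok[c(3, 5, 7)], collapse = "")
  }, "")
  expect_equal(flags[frozen_row], rep("000", length(frozen_row)))
  expect_true(all(flags[-frozen_row] == "111"))
})
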