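# toy complexes, hydrogen-bond detection, desolvation and the interaction
# index with its calibration

test_that("planted hydrogen bonds are detected exactly, decoys never", {
  s0 <- generate_toy_complex(complex_sim_config(0, n_decoy_atoms = 50,
                                                seed = 2))
  expect_equal(detect_interface_hbonds(s0)$h, 0)

  s <- generate_toy_complex(complex_sim_config(12, n_decoy_atoms = 200,
                                               seed = 3))
  hb <- detect_interface_hbonds(s)
  expect_equal(hb$h, 12)
  expect_equal(hb$h, brute_force_hbonds(s))
  # every reported bond crosses the interface
  expect_true(all(s$atoms$role[hb$bonds$donor] !=
                    s$atoms$role[hb$bonds$acceptor]))
})

test_that("separating the chains abolishes all bonds", {
  s <- generate_toy_complex(complex_sim_config(5, seed = 4))
  s$atoms$x[s$atoms$chain == "B"] <- s$atoms$x[s$atoms$chain == "B"] + 100
  expect_equal(detect_interface_hbonds(s)$h, 0)
})

test_that("bond count is symmetric in the chain role assignment", {
  s <- generate_toy_complex(complex_sim_config(7, n_decoy_atoms = 60,
                                               seed = 5))
  swapped <- complex_structure(s$atoms[, setdiff(names(s$atoms), "role")],
                               mhc_chain = "B", kir_chain = "A")
  expect_equal(detect_interface_hbonds(swapped)$h,
               detect_interface_hbonds(s)$h)
})

test_that("jitter beyond the planting margin is refused", {
  expect_error(complex_sim_config(3, jitter = 0.4), "jitter")
})

test_that("PDB round trip preserves detector and desolvation results", {
  s <- generate_toy_complex(complex_sim_config(6, n_decoy_atoms = 40,
                                               seed = 6))
  f <- tempfile(fileext = ".pdb")
  write_complex_pdb(s, f)
  s2 <- read_complex_pdb(f, "A", "B")
  expect_equal(detect_interface_hbonds(s2)$h, 6)
  expect_equal(as.numeric(desolvation_energy(s2)),
               as.numeric(desolvation_energy(s)), tolerance = 1e-4)
})

test_that("desolvation equals the hand sum on a two-atom toy and is additive", {
  tab <- contact_energy_table()
  atoms <- data.frame(chain = c("A", "B"), resno = 1:2,
                      resname = "ALA", atom = c("CB", "CB"),
                      element = "C", x = c(0, 4), y = 0, z = 0)
  s <- complex_structure(atoms, "A", "B")
  expect_equal(as.numeric(desolvation_energy(s)),
               tab["C_aliph", "C_aliph"])

  # duplicating the KIR-side atom doubles the sum exactly
  atoms2 <- rbind(atoms, data.frame(chain = "B", resno = 3, resname = "ALA",
                                    atom = "CB", element = "C",
                                    x = 4, y = 0.5, z = 0))
  s2 <- complex_structure(atoms2, "A", "B")
  expect_equal(as.numeric(desolvation_energy(s2)),
               2 * tab["C_aliph", "C_aliph"])

  # out-of-radius atoms contribute nothing
  atoms3 <- atoms; atoms3$x[2] <- 7
  expect_equal(as.numeric(desolvation_energy(
    complex_structure(atoms3, "A", "B"))), 0)

  # untypable atoms are excluded with a warning
  atoms4 <- rbind(atoms, data.frame(chain = "B", resno = 4, resname = "LIG",
                                    atom = "FE", element = "FE",
                                    x = 4, y = -0.5, z = 0))
  expect_warning(dg4 <- desolvation_energy(
    complex_structure(atoms4, "A", "B")), "untypable")
  expect_equal(as.numeric(dg4), tab["C_aliph", "C_aliph"])
})

test_that("h, dG and I are invariant under rigid motion of the complex", {
  s <- generate_toy_complex(complex_sim_config(9, n_decoy_atoms = 80,
                                               seed = 7))
  h0 <- detect_interface_hbonds(s)$h
  dg0 <- as.numeric(desolvation_energy(s))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s2 <- s
  s2$atoms$x <- xyz[, 1] + 13.7
  s2$atoms$y <- xyz[, 2] - 8.1
  s2$atoms$z <- xyz[, 3] + 2.2
  expect_equal(detect_interface_hbonds(s2)$h, h0)
  expect_equal(as.numeric(desolvation_energy(s2)), dg0, tolerance = 1e-9)
})

test_that("the interaction index follows I = k h / ln|dG| with guarded domain", {
  expect_equal(interaction_index(10, exp(1), k = 5)$I, 50)
  expect_equal(interaction_index(0, -20)$I, 0)
  expect_identical(interaction_index(4, 0.5)$call, "indeterminate")
  expect_true(is.na(interaction_index(4, 0.5)$I))
  expect_identical(interaction_index(4, -1)$call, "indeterminate")
  # sign convention: only the magnitude of dG enters
  expect_equal(interaction_index(6, -exp(2), k = 5)$I,
               interaction_index(6, exp(2), k = 5)$I)
  # monotone in h at fixed dG, k
  Is <- vapply(0:8, function(h) interaction_index(h, 50, k = 5)$I, 0)
  expect_true(all(diff(Is) >= 0))
  # k rescales linearly
  expect_equal(interaction_index(7, 30, k = 10)$I,
               2 * interaction_index(7, 30, k = 5)$I)
})

test_that("calibration separates classes and handles edge cases", {
  set.seed(8)
  pos <- rnorm(50, 5000, 100); neg <- rnorm(50, 1300, 100)
  cal <- calibrate_and_classify(c(pos, neg),
                                rep(c("positive", "negative"), each = 50))
  expect_equal(cal$error_rate, 0)
  expect_equal(cal$fp_rate, 0)
  expect_equal(cal$fn_rate, 0)
  expect_true(all(cal$calls[1:50] == "interacting"))

  # two scores, one per class: threshold at the midpoint
  cal2 <- calibrate_and_classify(c(10, 2), c("positive", "negative"))
  expect_equal(cal2$threshold, 6)

  expect_error(calibrate_and_classify(1:3, rep("positive", 3)),
               "each class")
  expect_error(calibrate_and_classify(1:2, c("positive", "maybe")),
               "labels")
})
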