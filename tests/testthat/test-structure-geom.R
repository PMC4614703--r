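make_simple_model <- function(residues, ligands, chain = "A", ...) {
  load_structure(write_synthetic_structure(residues, ligands, chain, ...),
                 chain)
}

test_that("synthetic PDB fixtures round-trip through the loader", {
  res <- data.frame(resno = 1:3, x = c(0, 3.125, -7.5), y = c(0, 1, 2),
                    z = c(0, -1.875, 4))
  lig <- data.frame(resid = c("FMN", "SF4"), x = c(10, 20), y = 0, z = 0)
  s <- make_simple_model(res, lig)
  prot <- s$atoms[s$atoms$type == "ATOM", ]
  expect_equal(nrow(prot), 3)
  expect_equal(prot$x, res$x, tolerance = 1e-3)
  expect_equal(prot$z, res$z, tolerance = 1e-3)
  expect_equal(sum(s$atoms$type == "HETATM"), 2)
})

test_that("alternate locations collapse to the highest-occupancy conformer", {
  res <- data.frame(resno = 1:2, x = c(0, 5), y = 0, z = 0)
  lig <- data.frame(resid = "FMN", x = 0, y = 0, z = 0)
  s <- make_simple_model(res, lig, altloc_duplicates = TRUE)
  prot <- s$atoms[s$atoms$type == "ATOM", ]
  expect_equal(nrow(prot), 2)                 # one CA per residue survives
  expect_equal(sort(prot$x), c(0, 5), tolerance = 1e-3) # occupancy-0.6 conformer
})

test_that("a missing chain errors naming the available chains", {
  res <- data.frame(resno = 1, x = 0, y = 0, z = 0)
  lig <- data.frame(resid = "FMN", x = 1, y = 0, z = 0)
  p <- write_synthetic_structure(res, lig, chain = "B")
  expect_error(load_structure(p, "Z"), "available chains: .*B")
})

test_that("minimum ligand distances follow exact constructed geometry", {
  res <- data.frame(resno = 7, x = 0, y = 0, z = 0)
  lig <- data.frame(resid = c("FMN", "FMN"), x = c(3, 6), y = c(4, 8), z = 0)
  s <- make_simple_model(res, lig)
  expect_equal(min_distance_to_ligand(s, 7, ligand_selector("FMN")), 5)

  # ligand atom coincident with the CA gives distance zero
  s0 <- make_simple_model(res, data.frame(resid = "SF4", x = 0, y = 0, z = 0))
  expect_equal(min_distance_to_ligand(s0, 7, ligand_selector("SF4")), 0)

  expect_error(min_distance_to_ligand(s, 99, ligand_selector("FMN")),
               "no CA atom")
  expect_error(min_distance_to_ligand(s, 7, ligand_selector("HEM")),
               "no ligand atoms")
})

test_that("distances agree with a brute-force oracle on random structures", {
  for (seed in 1:20) {
    spec <- random_structure_spec(n_residues = sample(2:10, 1),
                                  n_ligand_atoms = sample(2:40, 1),
                                  seed = seed)
    s <- make_simple_model(spec$residues, spec$ligands)
    prof <- distance_profile(s, copy_policy = "all")
    expect_equal(prof$residue, sort(spec$residues$resno))
    for (i in seq_len(nrow(spec$residues))) {
      p <- as.numeric(spec$residues[i, c("x", "y", "z")])
      for (lname in c("FMN", "SF4")) {
        pts <- spec$ligands[spec$ligands$resid == lname, c("x", "y", "z")]
        if (nrow(pts) == 0) next
        got <- min_distance_to_ligand(s, spec$residues$resno[i],
                                      ligand_selector(lname),
                                      copy_policy = "all")
        expect_equal(got, oracle_min_distance(p, pts), tolerance = 1e-9)
      }
    }
  }
})

test_that("distances are invariant under rigid-body transforms", {
  spec <- random_structure_spec(n_residues = 6, n_ligand_atoms = 8, seed = 11)
  s1 <- make_simple_model(spec$residues, spec$ligands)
  d1 <- distance_profile(s1, copy_policy = "all")
  # rotate about z by 30 degrees then translate; re-rounded to PDB precision
  th <- pi / 6
  rot <- function(df) {
    x <- df$x * cos(th) - df$y * sin(th) + 5.5
    y <- df$x * sin(th) + df$y * cos(th) - 2.25
    df$x <- round(x, 3); df$y <- round(y, 3); df$z <- round(df$z + 7.125, 3)
    df
  }
  s2 <- make_simple_model(rot(spec$residues), rot(spec$ligands))
  d2 <- distance_profile(s2, copy_policy = "all")
  # 1e-3 A coordinate quantisation bounds the distance perturbation
  expect_equal(d1$d_fmn, d2$d_fmn, tolerance = 1e-2)
  expect_equal(d1$d_fes, d2$d_fes, tolerance = 1e-2)
})

test_that("adding a ligand atom never increases any minimum distance", {
  spec <- random_structure_spec(n_residues = 8, n_ligand_atoms = 6, seed = 5)
  s1 <- make_simple_model(spec$residues, spec$ligands)
  d1 <- distance_profile(s1, copy_policy = "all")
  extra <- rbind(spec$ligands,
                 data.frame(resid = c("FMN", "SF4"), x = c(1, -4),
                            y = c(2, 0), z = c(-3, 2)))
  s2 <- make_simple_model(spec$residues, extra)
  d2 <- distance_profile(s2, copy_policy = "all")
  expect_true(all(d2$d_fmn <= d1$d_fmn + 1e-9))
  expect_true(all(d2$d_fes <= d1$d_fes + 1e-9))
})

test_that("identical selectors give identical profiles", {
  spec <- random_structure_spec(n_residues = 4, n_ligand_atoms = 5,
                                ligand_names = "FMN", seed = 2)
  s <- make_simple_model(spec$residues, spec$ligands)
  prof <- distance_profile(s, sel_fmn = ligand_selector("FMN"),
                           sel_fes = ligand_selector("FMN"))
  expect_equal(prof$d_fmn, prof$d_fes)
})

test_that("a cofactor copy on another chain cannot shadow the local copy", {
  # the local FeS copy is nearest the chain overall; a second copy on a
  # foreign chain sits closer to residue 2 but must be ignored by default
  res <- data.frame(resno = 1:2, x = c(0, 20), y = 0, z = 0)
  lig <- data.frame(resid = c("SF4", "SF4"), x = c(2, 24), y = 0, z = 0,
                    resno = c(900L, 901L), chain = c("A", "Q"))
  s <- make_simple_model(res, lig)
  expect_equal(min_distance_to_ligand(s, 2, ligand_selector("SF4")), 18)
  expect_equal(min_distance_to_ligand(s, 2, ligand_selector("SF4"),
                                      copy_policy = "all"), 4)
  # chain-restricted selector pins the copy explicitly
  expect_equal(min_distance_to_ligand(s, 2, ligand_selector("SF4", chain = "Q")), 4)
})
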