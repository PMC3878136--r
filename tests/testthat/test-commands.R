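# Run configuration, audit/family/synth commands and the CLI wrapper.

test_that("run configurations round-trip losslessly through their file format", {
  cfg <- run_config(tol_d = 0.35, tol_ang = 9, max_da = 3.2, host_only = TRUE,
                    seed = 42L)
  path <- tempfile(fileext = ".cfg")
  write_run_config(cfg, path)
  expect_identical(read_run_config(path), cfg)
  expect_error(run_config(tol_d = -1), "positive")
})

test_that("audit reports cell metrics and the hydrate hydrogen bond", {
  out <- tempfile()
  dir.create(out)
  f1 <- file.path(out, "hydrate.cif")
  syn <- build_crystal(motif_spec("hydrate_channel", seed = 3),
                       structure_id = "hyd")
  write_cif(syn$contents, f1)
  rep <- audit_structures(f1, run_config())
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$volume, cell_volume(syn$contents$cell), tolerance = 1e-4)
  expect_equal(rep$n_molecules, 2L)
  hb <- attr(rep, "reports")[["hyd"]]$hydrogen_bonds
  expect_true(any(hb$donor == "O1W" & hb$acceptor == "O1"))
  # a cell-only CIF still audits its volume (triclinic published cell)
  cellcif <- c("data_cellonly",
               "_cell_length_a 4.1302", "_cell_length_b 12.9513",
               "_cell_length_c 13.0829", "_cell_angle_alpha 62.708",
               "_cell_angle_beta 86.495", "_cell_angle_gamma 86.546",
               "_symmetry_equiv_pos_as_xyz 'x, y, z'",
               "loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y",
               "_atom_site_fract_z", "C1 C 0.25 0.25 0.25")
  f2 <- file.path(out, "cellonly.cif")
  writeLines(cellcif, f2)
  rep2 <- audit_structures(f2)
  expect_equal(rep2$volume, 620.35, tolerance = 0.1 / 620)
  # empty file errors with the file named
  f3 <- file.path(out, "empty.cif")
  file.create(f3)
  expect_error(audit_structures(f3), "empty.cif")
  # stated-volume cross-check warns above 0.5 percent
  bad <- sub("_cell_length_a 4.1302",
             c("_cell_volume 700.0\n_cell_length_a 4.1302"), cellcif)
  f4 <- file.path(out, "badvol.cif")
  writeLines(bad, f4)
  expect_warning(audit_structures(f4), "0.5%")
})

test_that("family reports detect isostructural and dimer-only families", {
  out <- tempfile()
  p <- build_motif_pair("isostructural_pair", seed = 2, noise = 0.02)
  rep <- family_report(p$structures, run_config(), out_dir = out)
  expect_equal(nrow(rep$scs), 1L)
  expect_equal(rep$scs$dimensionality, 3L)
  expect_true(file.exists(file.path(out, "sc_table.csv")))
  expect_true(file.exists(file.path(out, "relationships.dot")))
  csv <- utils::read.csv(file.path(out, "sc_table.csv"))
  expect_equal(csv$dimensionality, 3L)
  # deterministic rerun: byte-identical outputs
  out2 <- tempfile()
  family_report(p$structures, run_config(), out_dir = out2)
  for (fn in c("sc_table.csv", "sc_report.json", "relationships.dot",
               "relationships.json")) {
    expect_identical(readLines(file.path(out, fn)),
                     readLines(file.path(out2, fn)), label = fn)
  }
  expect_error(family_report(p$structures[1]), ">= 2 inputs")
})

test_that("synthetic generation writes CIF plus ground truth deterministically", {
  out <- tempfile()
  spec <- motif_spec("translation_stack", seed = 7, noise = 0.02)
  paths <- generate_crystal(spec, out_dir = out)
  expect_true(file.exists(paths$cif))
  expect_true(file.exists(paths$truth))
  truth <- jsonlite::fromJSON(paths$truth)
  expect_equal(truth$dimensionality, 1L)
  first <- readLines(paths$cif)
  generate_crystal(spec, out_dir = out)
  expect_identical(readLines(paths$cif), first)
})

test_that("the command-line wrapper runs and signals errors by exit code", {
  cli <- system.file("exec", "packmotif", package = "packmotif")
  if (!nzchar(cli)) cli <- file.path(find.package("packmotif"), "exec", "packmotif")
  expect_true(file.exists(cli))
  out <- tempfile()
  st <- system2("Rscript", c(cli, "synth", "--kind", "inversion_dimer",
                             "--seed", "5", "--out", out))
  expect_equal(st, 0L)
  expect_length(list.files(out, pattern = "\\.cif$"), 1L)
  expect_equal(system2("Rscript", c(cli, "audit"), stdout = FALSE,
                       stderr = FALSE), 2L)
  expect_equal(system2("Rscript", c(cli, "synth", "--kind", "no_such",
                                    "--out", out),
                       stdout = FALSE, stderr = FALSE), 4L)
})
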