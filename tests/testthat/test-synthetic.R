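test_that("default archetypes encode the documented ordinal guild relations", {
  arch <- default_archetypes()
  expect_setequal(names(arch), JAW_GUILDS)
  mu <- sapply(arch, archetype_character_means)

  # symphysis-length bands for the key guilds
  expect_gt(mu["MSL.ML", "Pierce II"], 0.42)
  expect_lt(mu["MSL.ML", "Pierce II"], 0.55)
  expect_gt(mu["MSL.ML", "Crunch"], 0.42)
  expect_lt(mu["MSL.ML", "Crunch"], 0.50)
  expect_gt(mu["MSL.ML", "Generalist"], 0.20)
  expect_lt(mu["MSL.ML", "Generalist"], 0.30)

  # opening speed: smash-feeders fastest, durophages slowest
  expect_lt(mu["oMA", "Smash"], mu["oMA", "Pierce II"])
  expect_lt(mu["oMA", "Pierce II"], mu["oMA", "Crunch"])

  # macrophagous guilds transmit more force and have shorter symphyses
  for (mac in c("Cut", "Generalist", "Crunch")) {
    for (pk in c("Pierce II", "Smash")) {
      expect_gt(mu["aMA", mac], mu["aMA", pk])
      expect_lt(mu["MSL.ML", mac], mu["MSL.ML", pk])
    }
  }

  # tooth index and size extremes
  expect_equal(names(which.max(mu["TI", ])), "Pierce I")
  expect_equal(names(which.min(mu["TI", ])), "Smash")
  size <- sapply(arch, function(a) a$mean[["logML"]])
  expect_equal(names(which.min(size)), "Pierce I")
  expect_equal(names(which.max(size)), "Generalist")

  # ratio means are anatomically plausible
  expect_true(all(mu > 0 & mu < 1))
})

test_that("identical seed and configuration give a byte-identical table", {
  cfg <- simulation_config(seed = 77)
  t1 <- simulate_assemblage(cfg)
  t2 <- simulate_assemblage(cfg)
  expect_identical(t1, t2)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_specimen_table(t1, p1); write_specimen_table(t2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_identical(t1$provenance, "synthetic:77")
})

test_that("zero noise pins every specimen at its archetype mean and zero effect collapses all guilds", {
  cfg <- simulation_config(noise_scale = 0, seed = 1,
                           design = balanced_design(2))
  tab <- simulate_assemblage(cfg)
  cm <- character_matrix(tab)
  arch <- default_archetypes()
  for (g in JAW_GUILDS) {
    rows <- cm[tab$records$guild == g, , drop = FALSE]
    expect_equal(unname(rows[1, ]),
                 unname(archetype_character_means(arch[[g]])),
                 tolerance = 1e-9)
    expect_equal(max(apply(rows, 2, sd)), 0)
  }

  null_cfg <- simulation_config(noise_scale = 0, effect_scale = 0,
                                seed = 1, design = balanced_design(2))
  null_cm <- character_matrix(simulate_assemblage(null_cfg))
  expect_lt(max(apply(null_cm, 2, sd)), 1e-12)
})

test_that("back-solved measurements are internally consistent with the lever geometry", {
  tab <- simulate_assemblage(simulation_config(seed = 19))
  df <- tab$records
  cm <- character_matrix(tab, characters = c(JAW_CHARACTERS, "ltMA"))
  # characters recomputed from measurements obey the defining ratios
  expect_equal(unname(cm[, "oMA"]), df$RPL / (df$ML - df$RPL),
               tolerance = 1e-9)
  expect_equal(unname(cm[, "aMA"]), df$ILc / (df$ML - df$RPL),
               tolerance = 1e-9)
  expect_equal(unname(cm[, "pMA"]),
               df$ILc / (df$ML - df$RPL - df$TRL), tolerance = 1e-9)
  expect_equal(unname(cm[, "TI"]), df$LCH / df$ML, tolerance = 1e-9)
  # largest tooth stays within the tooth row
  expect_true(all(df$DLT <= df$TRL))
  expect_true(all(cm[, "pMA"] >= cm[, "ltMA"] & cm[, "ltMA"] >= cm[, "aMA"]))
})

test_that("guild sample means converge to archetype means at the Monte-Carlo rate", {
  arch <- default_archetypes()
  design <- balanced_design(500)
  tab <- simulate_assemblage(simulation_config(design = design,
                                               seed = 101))
  cm <- character_matrix(tab)
  checked <- c("MSL.ML", "aMA", "TI", "RPL.ML")
  for (g in c("Pierce I", "Crunch")) {
    mu <- archetype_character_means(arch[[g]])
    rows <- cm[tab$records$guild == g, checked]
    se <- apply(rows, 2, sd) / sqrt(nrow(rows))
    expect_true(all(abs(colMeans(rows) - mu[checked]) <= 3 * se + 1e-4))
  }
})

test_that("configuration validation catches inconsistent designs", {
  expect_error(simulation_config(design = data.frame(
    clade = "Pliosauridae", guild = "Chomp", time_bin = "OCF", n = 10L),
    seed = 1), "without an archetype")
  expect_error(simulation_config(design = data.frame(
    clade = "Pliosauridae", guild = "Cut", time_bin = "OCF", n = 2L),
    seed = 1), "at least 4")
  expect_error(simulation_config(effect_scale = -1, seed = 1))
})
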