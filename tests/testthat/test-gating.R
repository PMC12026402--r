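test_that("constructed cascade yields the forced survivor counts", {
  fx <- cascadeFixture()
  rep <- runCascade(features = fx$features, singlet = fx$singletOracle,
                    cnn = fx$cnnOracle, cfg = fx$cfg)
  expect_equal(rep@gates$gate,
               c("stable_flow", "unsaturated", "viable", "nucleated",
                 "lymphocytes", "cd41_dump", "singlet", "focus", "cnn"))
  expect_equal(rep@gates$surviving, c(90L, 80L, 70L, 60L, 45L, 35L, 25L,
                                      15L, 5L))
  expect_equal(rep@terminalIds, 96:100)
  # attrition is monotone and fractions re-multiply to the terminal fraction
  expect_true(all(diff(rep@gates$surviving) <= 0))
  expect_equal(prod(rep@gates$fraction), 5 / 100, tolerance = 1e-12)
})

test_that("independent gates (saturation, focus) commute on the fixture", {
  fx <- cascadeFixture()
  base <- runCascade(features = fx$features, singlet = fx$singletOracle,
                     cnn = fx$cnnOracle, cfg = fx$cfg)
  perm <- runCascade(features = fx$features, singlet = fx$singletOracle,
                     cnn = fx$cnnOracle, cfg = fx$cfg,
                     gates = c("stable_flow", "focus", "viable", "nucleated",
                               "lymphocytes", "cd41_dump", "singlet",
                               "unsaturated", "cnn"))
  expect_setequal(perm@terminalIds, base@terminalIds)
})

test_that("empty input and disabled gates degenerate gracefully", {
  fx <- cascadeFixture()
  empty <- runCascade(features = fx$features[0, ], cfg = fx$cfg,
                      gates = c("unsaturated", "focus"))
  expect_equal(empty@gates$surviving, c(0L, 0L))
  expect_length(empty@terminalIds, 0L)
  none <- runCascade(features = fx$features, cfg = fx$cfg,
                     gates = character(0))
  expect_setequal(none@terminalIds, fx$features$object_id)
})

test_that("saturation gate is strict at the 4030 boundary", {
  f <- data.frame(object_id = 1:3,
                  raw_max_pixel_cd41 = c(4029, 4030, 0),
                  raw_max_pixel_bf = c(4029, 100, 0))
  expect_equal(gateUnsaturated(f, gateConfig()), c(1L, 3L))
})

test_that("explicit stable-flow window keeps exactly the in-window events", {
  f <- data.frame(object_id = 1:5, time_s = c(5, 10, 15, 20, 25))
  ids <- gateStableFlow(f, gateConfig(stable_flow = c(10, 20)))
  expect_equal(ids, 2:4)
})

test_that("evenly spread event times are fully retained in auto mode", {
  f <- data.frame(object_id = 1:200, time_s = seq(0, 100, length.out = 200))
  expect_equal(gateStableFlow(f, gateConfig()), 1:200)
})

test_that("auto stable-flow gate excludes the injected unstable burst", {
  fx <- fxGallery()
  kept <- gateStableFlow(fx$features, gateConfig())
  unstable <- fx$truth$object_id[fx$truth$is_unstable]
  expect_gt(length(unstable), 10L)
  expect_gte(mean(!(unstable %in% kept)), 0.9)
})

test_that("viability/DNA gate removes dead and anucleate events (auto)", {
  fx <- fxGallery()
  ids <- gateLiveNucleated(fx$features, gateConfig())
  tr <- fx$truth
  expect_equal(sum(ids %in% tr$object_id[tr$class == "dead"]), 0L)
  expect_equal(sum(ids %in% tr$object_id[tr$class == "anucleate"]), 0L)
  mk <- tr$object_id[tr$class == "mk"]
  expect_gte(mean(mk %in% ids), 0.95)
})

test_that("all-MK population passes the viability/DNA gate untouched", {
  gen <- generateEventSet(syntheticConfig(n_events = 60L,
                                          class_mixture = c(mk = 1),
                                          defocus_fraction = 0,
                                          saturated_fraction = 0, seed = 2L))
  ft <- computeFeatures(gen$events)
  expect_equal(gateLiveNucleated(ft, gateConfig()), ft$object_id)
  # and the unimodal CD45 guard removes nothing either
  expect_equal(gateExcludeLymphocytes(ft, gateConfig()), ft$object_id)
})

test_that("lymphocyte exclusion removes lymphocytes, spares MKs", {
  gen <- generateEventSet(syntheticConfig(
    n_events = 500L, seed = 1L,
    class_mixture = c(mk = 0.5, micro_mk = 0.1, lymphocyte = 0.3,
                      platelet_adherent = 0.1),
    defocus_fraction = 0, saturated_fraction = 0, flow_instability = 0))
  ft <- computeFeatures(gen$events)
  ids <- gateExcludeLymphocytes(ft, gateConfig())
  tr <- gen$truth
  lymph <- tr$object_id[tr$class == "lymphocyte"]
  mks <- tr$object_id[tr$class %in% c("mk", "micro_mk")]
  expect_gte(mean(!(lymph %in% ids)), 0.9)
  expect_lte(mean(!(mks %in% ids)), 0.1)
  # an impossible explicit region removes nothing
  all <- gateExcludeLymphocytes(ft, gateConfig(cd45_min = Inf, ssc_max = 0))
  expect_setequal(all, ft$object_id)
})

test_that("CD41+/dump- gate keeps MKs and removes dump-positive events", {
  fx <- fxGallery()
  tr <- fx$truth
  live <- tr$object_id[tr$is_viable & tr$is_nucleated]
  f2 <- fx$features[fx$features$object_id %in% live, ]
  ids <- gateCD41Dump(f2, gateConfig())
  mks <- intersect(tr$object_id[tr$class %in% c("mk", "micro_mk")], live)
  lymph <- intersect(tr$object_id[tr$class == "lymphocyte"], live)
  expect_gte(mean(mks %in% ids), 0.95)
  expect_lte(mean(lymph %in% ids), 0.1)
  # identity gate with trivial thresholds
  expect_setequal(gateCD41Dump(f2, gateConfig(cd41_min = -1, dump_max = Inf)),
                  f2$object_id)
})

test_that("focus gate removes defocused events at the default threshold", {
  fx <- fxGallery()
  ids <- gateFocus(fx$features, gateConfig())
  tr <- fx$truth
  blurred <- tr$object_id[!tr$is_in_focus]
  sharp <- tr$object_id[tr$is_in_focus]
  expect_gt(length(blurred), 10L)
  expect_gte(mean(!(blurred %in% ids)), 0.9)
  expect_gte(mean(sharp %in% ids), 0.95)
  # threshold 0 keeps every non-constant image
  expect_setequal(gateFocus(fx$features,
                            gateConfig(focus_min_gradient_rms = 0)),
                  fx$features$object_id)
})

test_that("degenerate intensity columns demand explicit thresholds", {
  f <- data.frame(object_id = 1:5, intensity_viability = rep(3, 5),
                  intensity_dna = rep(3, 5))
  expect_error(gateLiveNucleated(f, gateConfig()), "explicit threshold")
  expect_equal(gateLiveNucleated(f, gateConfig(viability_max = 10,
                                               dna_min = 1)), 1:5)
})

test_that("missing classifiers raise errors when their stage is enabled", {
  fx <- cascadeFixture()
  expect_error(runCascade(features = fx$features, cfg = fx$cfg,
                          gates = "singlet"), "singlet")
  expect_error(runCascade(features = fx$features, cfg = fx$cfg,
                          gates = "cnn"), "CNN")
})

test_that("gating report serializes to JSON with counts intact", {
  fx <- cascadeFixture()
  rep <- runCascade(features = fx$features, singlet = fx$singletOracle,
                    cnn = fx$cnnOracle, cfg = fx$cfg)
  path <- withr::local_tempfile(fileext = ".json")
  writeGatingReport(rep, path, meta = list(seed = 1L))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$gates$surviving, rep@gates$surviving)
  expect_equal(back$terminal_ids, rep@terminalIds)
  expect_equal(back$seed, 1L)
})
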