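# End-to-end wiring and the command-line dispatcher. Subcommands mirror the
# workflow order: simulate -> features -> gate -> train-cnn -> classify ->
# evaluate. Every artifact carries a provenance header (seed, package
# version, config hash) and reruns with the same seed are byte-identical.

provenance <- function(seed, cfg = NULL) {
  list(seed = seed,
       version = as.character(utils::packageVersion("mkflow")),
       config_hash = if (is.null(cfg)) NA_character_ else
         sprintf("%08x", sum(utf8ToInt(paste(deparse(cfg), collapse = "")) *
                             (seq_len(nchar(paste(deparse(cfg),
                                                  collapse = ""))) %% 251))))
}

#' Run the full synthetic-benchmark pipeline
#'
#' Generates a labeled gallery, computes features, fits the singlet LDA on
#' synthetic truth populations, trains the CNN on a stratified split of the
#' gallery's CD41+/CD41- events, runs the gating cascade with both
#' classifiers, and evaluates the CNN on the held-out test split.
#'
#' @param outDir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param nEvents gallery size.
#' @param cnnSpec a [cnnModelSpec()]; its seed is overridden by `seed`.
#' @param gateCfg a [gateConfig()].
#' @param writeArtifacts write gallery/feature/report files under `outDir`.
#' @return list with `report` ([GatingReport-class]), `metrics`
#'   ([MetricsReport-class]), `model`, `singlet`, `split`, `features`,
#'   `truth`.
#' @export
runPipeline <- function(outDir = tempfile("mkflow"), seed = 1L,
                        nEvents = 500L, cnnSpec = cnnModelSpec(),
                        gateCfg = gateConfig(), writeArtifacts = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  scfg <- syntheticConfig(n_events = as.integer(nEvents), seed = seed)
  gen <- generateEventSet(scfg)
  features <- computeFeatures(gen$events)

  # singlet truth populations: the historical tally of 28 tagged singlets
  # and 52 tagged doublets
  sCfg <- syntheticConfig(n_events = 28L,
                          class_mixture = c(mk = 1), seed = seed + 101L,
                          defocus_fraction = 0, saturated_fraction = 0,
                          flow_instability = 0)
  dCfg <- syntheticConfig(n_events = 52L,
                          class_mixture = c(doublet = 1), seed = seed + 102L,
                          defocus_fraction = 0, saturated_fraction = 0,
                          flow_instability = 0)
  singlet <- fitSingletClassifier(generateEventSet(sCfg)$events,
                                  generateEventSet(dCfg)$events)

  truth <- makeTruthSet(gen$events, size = cnnSpec$input_size)
  split <- splitTruthSet(truth, seed = seed + 7L)
  cnnSpec$seed <- seed
  model <- trainCNN(subsetTruthSet(truth, split$train),
                    subsetTruthSet(truth, split$validation), cnnSpec)
  report <- runCascade(gen$events, features = features, singlet = singlet,
                       cnn = model, cfg = gateCfg)
  test <- subsetTruthSet(truth, split$test)
  pred <- predictCNN(model, test)
  metrics <- metricsReport(confusionMatrix(as.character(test$labels),
                                           pred$label, "cd41_pos"))
  if (writeArtifacts) {
    saveEventSet(gen$events, file.path(outDir, "gallery"))
    write.csv(gen$truth, file.path(outDir, "truth.csv"), row.names = FALSE)
    write.csv(features, file.path(outDir, "features.csv"), row.names = FALSE)
    exportFeaturesFCS(features, file.path(outDir, "features.fcs"))
    writeGatingReport(report, file.path(outDir, "gating_report.json"),
                      meta = provenance(seed, scfg))
    writeMetricsReport(metrics, file.path(outDir, "metrics.json"))
    writeSingletClassifier(singlet, file.path(outDir, "singlet.json"))
    writeCnnModel(model, file.path(outDir, "cnn_model.json"))
    write.csv(data.frame(object_id = report@terminalIds,
                         diameter_um = report@terminalDiameters[
                           seq_along(report@terminalIds)]),
              file.path(outDir, "terminal_diameters.csv"), row.names = FALSE)
  }
  list(report = report, metrics = metrics, model = model, singlet = singlet,
       split = split, features = features, truth = gen$truth,
       events = gen$events)
}

cliArg <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}

#' Command-line dispatcher
#'
#' Entry point behind the `mkflow` executable script
#' (`system.file("cli", "mkflow.R", package = "mkflow")`). Subcommands:
#' `simulate`, `features`, `gate`, `train-cnn`, `classify`, `evaluate`,
#' `pipeline`. Run with no arguments for usage.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 = success, 2 = usage/input error).
#' @export
mkflowMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mkflow <command> [options]",
    "  simulate  --out DIR [--seed N] [--n N]",
    "  features  --gallery DIR --out CSV [--fcs FCS]",
    "  gate      --gallery DIR --report JSON [--seed N]",
    "  train-cnn --gallery DIR --out MODEL.json [--seed N]",
    "  classify  --gallery DIR --model MODEL.json --out CSV",
    "  evaluate  --pred CSV --truth CSV --out JSON",
    "  pipeline  --out DIR [--seed N] [--n N]", sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(2L)) }
  cmd <- args[1L]
  seed <- as.integer(cliArg(args, "--seed", "1"))
  status <- tryCatch({
    switch(cmd,
      simulate = {
        out <- cliArg(args, "--out")
        if (is.null(out)) stop("simulate: --out is required")
        n <- as.integer(cliArg(args, "--n", "500"))
        gen <- generateEventSet(syntheticConfig(n_events = n, seed = seed))
        saveEventSet(gen$events, out)
        tr <- gen$truth
        tr$seed <- seed
        write.csv(tr, file.path(out, "truth.csv"), row.names = FALSE)
        message("wrote ", n, " events to ", out)
      },
      features = {
        g <- cliArg(args, "--gallery"); out <- cliArg(args, "--out")
        if (is.null(g) || !dir.exists(g))
          stop("features: gallery path not found: ", g)
        ft <- computeFeatures(loadEventSet(g))
        write.csv(ft, out, row.names = FALSE)
        fcs <- cliArg(args, "--fcs")
        if (!is.null(fcs)) exportFeaturesFCS(ft, fcs)
        message("wrote features for ", nrow(ft), " events")
      },
      gate = {
        g <- cliArg(args, "--gallery"); rep <- cliArg(args, "--report")
        if (is.null(g) || !dir.exists(g))
          stop("gate: gallery path not found: ", g)
        events <- loadEventSet(g)
        r <- runCascade(events, cfg = gateConfig(),
                        gates = c("stable_flow", "unsaturated", "viable",
                                  "nucleated", "lymphocytes", "cd41_dump",
                                  "focus"))
        writeGatingReport(r, rep, meta = provenance(seed))
        message("terminal population: ", length(r@terminalIds), " events")
      },
      `train-cnn` = {
        g <- cliArg(args, "--gallery"); out <- cliArg(args, "--out")
        if (is.null(g) || !dir.exists(g))
          stop("train-cnn: gallery path not found: ", g)
        events <- loadEventSet(g)
        truth <- makeTruthSet(events)
        split <- splitTruthSet(truth, seed = seed)
        model <- trainCNN(subsetTruthSet(truth, split$train),
                          subsetTruthSet(truth, split$validation),
                          cnnModelSpec(seed = seed))
        writeCnnModel(model, out)
        message("trained ", nrow(model@history), " epochs")
      },
      classify = {
        g <- cliArg(args, "--gallery"); mp <- cliArg(args, "--model")
        out <- cliArg(args, "--out")
        if (is.null(g) || !dir.exists(g))
          stop("classify: gallery path not found: ", g)
        model <- readCnnModel(mp)
        events <- loadEventSet(g)
        crops <- extractCrops(events, size = model@weights$in_size)
        pred <- predictCNN(model, crops$x)
        pred$object_id <- crops$object_id
        write.csv(pred, out, row.names = FALSE)
        message("classified ", nrow(pred), " events")
      },
      evaluate = {
        predPath <- cliArg(args, "--pred"); truthPath <- cliArg(args, "--truth")
        out <- cliArg(args, "--out")
        pred <- read.csv(predPath); tr <- read.csv(truthPath)
        m <- merge(tr, pred, by = "object_id")
        cls <- ifelse(m$class %in% c("mk", "micro_mk"), "cd41_pos",
                      "cd41_neg")
        keep <- m$class %in% c("mk", "micro_mk", "platelet_adherent")
        rep <- metricsReport(confusionMatrix(cls[keep], m$label[keep],
                                             "cd41_pos"))
        writeMetricsReport(rep, out)
        message("accuracy: ", rep@accuracy, "%")
      },
      pipeline = {
        out <- cliArg(args, "--out")
        if (is.null(out)) stop("pipeline: --out is required")
        n <- as.integer(cliArg(args, "--n", "400"))
        res <- runPipeline(out, seed = seed, nEvents = n)
        message("terminal MKs: ", length(res$report@terminalIds),
                "; CNN test accuracy: ", res$metrics@accuracy, "%")
      },
      { message(usage); return(invisible(2L)) })
    0L
  }, error = function(e) {
    message("mkflow ", cmd, ": ", conditionMessage(e))
    2L
  })
  invisible(status)
}
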