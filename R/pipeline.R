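# Pipeline entry points. Three stages -- simulate, fit, impacts -- each
# consuming the previous stage's files from the run directory, so stages
# are independently testable and a run is fully reproducible from its
# config and seed. Every output carries the config hash and seed.

#' Default run configuration
#'
#' @param outdir output directory.
#' @param seed run seed (recorded in all outputs).
#' @return nested named list; override entries and pass to the `run*`
#'   stages or write as YAML for the command-line wrapper.
#' @export
defaultRunConfig <- function(outdir = "treelim_run", seed = 1) {
  list(
    outdir = outdir,
    seed = seed,
    synthetic = list(nlat = 50, nlon = 50, corLength = 5,
                     baSeasCor = 0.6, landFraction = 0.8),
    fit = list(nChains = 4, nIter = 2000, warmupFraction = 0.5,
               trainFraction = 0.2, nKeepPerChain = 10),
    experiments = c("relative_impacts", "fire_increment",
                    "fire_without_humans", "biome_table", "histogram")
  )
}

#' Read a run configuration from YAML
#' @param path YAML file path.
#' @return config list merged over [defaultRunConfig()].
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultRunConfig()
  merge2 <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]])) {
        merge2(a[[nm]], b[[nm]])
      } else b[[nm]]
    }
    a
  }
  merge2(base, cfg)
}

.configHash <- function(config) .fnv1a(yaml::as.yaml(config))

.runLog <- function(config, stage, lines) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$outdir, "run.log")
  msg <- sprintf("[%s] %s", stage, lines)
  message(paste(msg, collapse = "\n"))
  cat(msg, file = path, sep = "\n", append = TRUE)
}

.provAttrs <- function(config) {
  list(seed = config$seed, config_hash = .configHash(config))
}

#' Write a DriverSet as one NetCDF file per variable
#' @param drivers a [DriverSet-class].
#' @param dir output directory.
#' @param attributes provenance attributes for each file.
#' @return `dir`, invisibly.
#' @export
writeDrivers <- function(drivers, dir, attributes = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(drivers@fields)) {
    writeGridNetCDF(drivers@fields[[nm]], file.path(dir,
                                                    paste0(nm, ".nc")),
                    attributes = attributes)
  }
  invisible(dir)
}

#' Read a DriverSet written by [writeDrivers()]
#' @param dir directory of per-variable NetCDF files.
#' @param scaling scaling constants (default as in [driverSet()]).
#' @return a [DriverSet-class].
#' @export
readDrivers <- function(dir, scaling = list(mtwm_c = c(10, 45),
                                            wind_ms = c(0, 12),
                                            pop_density = c(0, 1000))) {
  fields <- lapply(.DRIVER_NAMES, function(nm) {
    readGridNetCDF(file.path(dir, paste0(nm, ".nc")), nm)
  })
  names(fields) <- .DRIVER_NAMES
  driverSet(fields, scaling = scaling)
}

#' Stage 1: generate and write the synthetic inputs
#'
#' Writes driver fields, forward-simulated observations, the biome-code
#' map and the grouping table into the run directory.
#'
#' @param config run configuration (see [defaultRunConfig()]).
#' @return the run directory, invisibly.
#' @export
runSimulate <- function(config = defaultRunConfig()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- config$synthetic
  scfg <- syntheticConfig(nlat = sc$nlat, nlon = sc$nlon,
                          seed = config$seed, corLength = sc$corLength,
                          baSeasCor = sc$baSeasCor,
                          landFraction = sc$landFraction)
  drivers <- generateDrivers(scfg)
  obs <- simulateObservations(drivers, scfg@trueParams,
                              seed = config$seed + 1)
  biomes <- generateBiomeMap(drivers)
  attrs <- .provAttrs(config)
  writeDrivers(drivers, file.path(config$outdir, "drivers"), attrs)
  writeGridNetCDF(obs@field, file.path(config$outdir,
                                       "observations.nc"), attrs)
  writeGridNetCDF(biomes@codes, file.path(config$outdir, "biomes.nc"),
                  attrs)
  utils::write.csv(biomes@groups,
                   file.path(config$outdir, "biome_groups.csv"),
                   row.names = FALSE)
  .runLog(config, "simulate",
          c(sprintf("seed=%d hash=%s", config$seed, attrs$config_hash),
            sprintf("grid %dx%d, %d land cells", sc$nlat, sc$nlon,
                    sum(drivers@fields[[1]]@mask))))
  invisible(config$outdir)
}

#' Stage 2: fit the model to the simulated observations
#'
#' Splits cells into train/validation, runs the MCMC, and writes the
#' ensemble table (member by parameter, with log-likelihood and
#' provenance), the split-Rhat report, the validation predictive-coverage
#' report and the run log. Non-convergence is reported as a warning, not
#' a failure.
#'
#' @param config run configuration.
#' @param rhatWarn warn if any split-Rhat exceeds this (default 1.1).
#' @return the fitted [PosteriorEnsemble-class], invisibly.
#' @export
runFit <- function(config = defaultRunConfig(), rhatWarn = 1.1) {
  drivers <- readDrivers(file.path(config$outdir, "drivers"))
  obsField <- readGridNetCDF(file.path(config$outdir, "observations.nc"),
                             "tree_cover_obs")
  obs <- observationSet(obsField)
  fc <- config$fit
  cc <- chainConfig(nChains = fc$nChains, nIter = fc$nIter,
                    warmupFraction = fc$warmupFraction,
                    trainFraction = fc$trainFraction,
                    nKeepPerChain = fc$nKeepPerChain, seed = config$seed)
  split <- splitTrain(obs, fraction = cc@trainFraction,
                      seed = config$seed)
  ens <- samplePosterior(split$train, drivers, config = cc,
                         provenance = "synthetic")
  rh <- rhat(ens)
  if (any(rh > rhatWarn)) {
    warning(sprintf("split-Rhat > %.2f for: %s", rhatWarn,
                    paste(names(rh)[rh > rhatWarn], collapse = ", ")))
  }
  pc <- predictiveInterval(drivers, ens, obs = split$validation,
                           seed = config$seed + 2)
  tab <- data.frame(ens@members, logLik = ens@logLik,
                    provenance = ens@provenance, check.names = FALSE)
  utils::write.table(tab, file.path(config$outdir, "ensemble.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(parameter = names(rh), rhat = rh),
                     file.path(config$outdir, "rhat.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(sprintf("validation_coverage_10_90 %.4f", pc$coverage),
             file.path(config$outdir, "validation_coverage.txt"))
  .runLog(config, "fit",
          c(sprintf("seed=%d hash=%s", config$seed,
                    .configHash(config)),
            sprintf("members=%d max_rhat=%.3f mean_acceptance=%.2f",
                    nMembers(ens), max(rh), mean(ens@acceptance)),
            sprintf("validation 10-90%% coverage=%.3f", pc$coverage)))
  invisible(ens)
}

.readEnsemble <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  pcols <- setdiff(names(tab), c("logLik", "provenance"))
  new("PosteriorEnsemble",
      members = as.matrix(tab[, pcols, drop = FALSE]),
      logLik = tab$logLik, provenance = as.character(tab$provenance),
      weights = NULL, chains = array(numeric(), c(0, 0, 0)),
      acceptance = numeric())
}

#' Stage 3: impact experiments from a fitted ensemble
#'
#' Computes the experiments requested in `config$experiments`: per-control
#' relative-impact quantile maps, the +1% burnt-area experiment, the
#' fire-without-humans counterfactual, the biome impact table and the
#' tree-cover histogram. An empty experiment list is a logged no-op.
#'
#' @param config run configuration.
#' @return invisibly, a list of computed results.
#' @export
runImpacts <- function(config = defaultRunConfig()) {
  exps <- config$experiments
  if (!length(exps)) {
    .runLog(config, "impacts", "no experiments requested; nothing to do")
    return(invisible(list()))
  }
  drivers <- readDrivers(file.path(config$outdir, "drivers"))
  ensPath <- file.path(config$outdir, "ensemble.tsv")
  if (!file.exists(ensPath)) .stopf("no ensemble at %s; run the fit first",
                                    ensPath)
  ens <- .readEnsemble(ensPath)
  spec <- defaultControlSpec()
  attrs <- .provAttrs(config)
  out <- list()
  if ("relative_impacts" %in% exps) {
    for (ctrl in names(spec@controls)) {
      d <- impactDistribution(drivers, ens, spec, ctrl, "relative")
      for (lv in c(0.1, 0.9)) {
        f <- impactQuantileField(d, lv)
        f@name <- sprintf("relative_impact_%s_q%02d", ctrl,
                          as.integer(round(lv * 100)))
        writeGridNetCDF(f, file.path(config$outdir,
                                     paste0(f@name, ".nc")), attrs)
      }
      out$relative[[ctrl]] <- d
    }
  }
  if ("fire_increment" %in% exps) {
    d <- fireIncrementExperiment(drivers, ens, spec)
    f <- impactQuantileField(d, 0.9)
    f@name <- "fire_increment_loss_q90"
    writeGridNetCDF(f, file.path(config$outdir, paste0(f@name, ".nc")),
                    attrs)
    out$fire_increment <- d
  }
  if ("fire_without_humans" %in% exps) {
    out$fire_without_humans <- fireWithoutHumans(drivers, ens, spec)
  }
  if ("biome_table" %in% exps) {
    codes <- readGridNetCDF(file.path(config$outdir, "biomes.nc"),
                            "biome_code")
    groups <- utils::read.csv(file.path(config$outdir,
                                        "biome_groups.csv"))
    biomes <- biomeMap(codes, groups)
    tab <- aggregateByBiome(drivers, ens, spec,
                            targets = c("MAP", "S", "LU", "burnt_area",
                                        "seasonality", "heat", "wind"),
                            biomes = biomes)
    utils::write.csv(tab, file.path(config$outdir, "biome_impacts.csv"),
                     row.names = FALSE)
    out$biome_table <- tab
  }
  if ("histogram" %in% exps) {
    prep <- .prepareDrivers(drivers, spec)
    tcm <- vapply(seq_len(nMembers(ens)), function(m) {
      .treeCoverVec(prep, memberParams(ens, m, spec), spec)
    }, numeric(nrow(prep$X)))
    hist <- treeCoverHistogram(tcm)
    utils::write.csv(hist, file.path(config$outdir,
                                     "tree_cover_histogram.csv"),
                     row.names = FALSE)
    out$histogram <- hist
  }
  .runLog(config, "impacts",
          sprintf("seed=%d hash=%s experiments=%s", config$seed,
                  attrs$config_hash, paste(exps, collapse = ",")))
  invisible(out)
}
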