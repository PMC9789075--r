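#' Read and write imaging volumes
#'
#' Volumes are stored as NIfTI with a JSON sidecar carrying the metadata
#' that NIfTI headers cannot: echo times and provenance for an
#' \linkS4class{EchoSeries}, fit bounds for a \linkS4class{T2Map}.
#' Label masks are stored as uint8. Round trips preserve float32 data
#' exactly.
#'
#' @param object the object to write.
#' @param path file path; the sidecar uses \code{<path>.json}.
#' @return \code{read*} return the reconstructed object; \code{write*}
#'   return \code{path} invisibly.
#' @name accelT2-io
NULL

sidecarPath <- function(path) paste0(path, ".json")

#' @rdname accelT2-io
#' @export
writeEchoSeries <- function(object, path) {
  stopifnot(is(object, "EchoSeries"))
  RNifti::writeNifti(object@data, path)
  jsonlite::write_json(list(type = "EchoSeries",
                            echo_times = object@echoTimes),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname accelT2-io
#' @export
readEchoSeries <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp))
    stop("missing sidecar JSON for EchoSeries: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  dat <- array(as.numeric(RNifti::readNifti(path)), dim(RNifti::readNifti(path)))
  if (length(dim(dat)) != 4L)
    stop("expected a 4-D (y, x, z, echo) NIfTI volume")
  new("EchoSeries", data = dat, echoTimes = as.numeric(meta$echo_times))
}

#' @rdname accelT2-io
#' @export
writeT2Map <- function(object, path) {
  stopifnot(is(object, "T2Map"))
  d <- dim(object@t2)
  stack <- array(0, c(d, 4L))
  t2 <- object@t2; t2[is.na(t2)] <- -1
  amp <- object@amplitude; amp[is.na(amp)] <- -1
  stack[, , , 1] <- t2; stack[, , , 2] <- amp
  stack[, , , 3] <- object@valid; stack[, , , 4] <- object@atBound
  RNifti::writeNifti(stack, path)
  jsonlite::write_json(list(type = "T2Map", bounds = object@bounds,
                            layout = c("t2", "amplitude", "valid", "atBound"),
                            na_sentinel = -1),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname accelT2-io
#' @export
readT2Map <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp)) stop("missing sidecar JSON for T2Map: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  dat <- array(as.numeric(img), dim(img))
  if (length(dim(dat)) != 4L || dim(dat)[4] != 4L)
    stop("expected a 4-volume T2Map NIfTI stack")
  t2 <- dat[, , , 1]; amp <- dat[, , , 2]
  t2[t2 == meta$na_sentinel] <- NA; amp[amp == meta$na_sentinel] <- NA
  new("T2Map", t2 = t2, amplitude = amp, valid = dat[, , , 3] > 0.5,
      atBound = dat[, , , 4] > 0.5, bounds = as.numeric(meta$bounds))
}

#' @rdname accelT2-io
#' @export
writeRoiMask <- function(object, path) {
  stopifnot(is(object, "RoiMask"))
  RNifti::writeNifti(object@labels, path, datatype = "uint8")
  invisible(path)
}

#' @rdname accelT2-io
#' @export
readRoiMask <- function(path) {
  img <- RNifti::readNifti(path)
  lab <- array(as.integer(img), dim(img))
  if (length(dim(lab)) != 3L) stop("expected a 3-D label volume")
  new("RoiMask", labels = lab)
}

#' Pipeline run configuration
#'
#' Describes an end-to-end experiment: phantom generation, retrospective
#' undersampling at each requested acceleration, ground-truth and
#' zero-fill fitting, optional network training and prediction, and the
#' metric reports. Every stage derives its seed deterministically from
#' the global seed.
#'
#' @param anatomy "knee", "hip" or "spine".
#' @param grid phantom grid c(n_y, n_x, n_z).
#' @param accelerations acceleration factors to evaluate.
#' @param n_test number of evaluation phantoms.
#' @param n_train,n_val phantoms for training; 0 disables training.
#' @param train_accelerations subset of \code{accelerations} at which a
#'   network is trained (default: the first).
#' @param variant model variant for training.
#' @param max_epochs,patience training schedule.
#' @param loss_weights \linkS4class{LossWeights} for training.
#' @param noise_sigma phantom Rician noise level.
#' @param seed global seed.
#' @param out_dir output directory.
#' @return list of class "runConfig".
#' @export
runConfig <- function(anatomy = "knee", grid = c(32L, 32L, 8L),
                      accelerations = c(2, 4), n_test = 4L, n_train = 0L,
                      n_val = 0L, train_accelerations = NULL,
                      variant = "reduced", max_epochs = 10L, patience = 10L,
                      loss_weights = lossWeights(1, 100, 1, 0),
                      noise_sigma = 0.02, seed = 1L, out_dir = tempfile()) {
  if (is.null(train_accelerations)) train_accelerations <- accelerations[1]
  structure(list(anatomy = anatomy, grid = as.integer(grid),
                 accelerations = accelerations, n_test = as.integer(n_test),
                 n_train = as.integer(n_train), n_val = as.integer(n_val),
                 train_accelerations = train_accelerations,
                 variant = variant, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 loss_weights = loss_weights, noise_sigma = noise_sigma,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "runConfig")
}

#' Write or read a pipeline configuration as YAML
#'
#' @param config a \code{\link{runConfig}}.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  lw <- config$loss_weights
  cfg <- unclass(config)
  cfg$loss_weights <- list(l1 = lw@l1, l1_roi = lw@l1Roi, ssim = lw@ssim,
                           feature = lw@feature)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  lw <- cfg$loss_weights
  cfg$loss_weights <- lossWeights(lw$l1, lw$l1_roi, lw$ssim, lw$feature)
  do.call(runConfig, cfg)
}

#' Run the end-to-end pipeline
#'
#' Executes phantom generation, undersampling at each requested
#' acceleration with the zero-fill fitting baseline, optional network
#' training and prediction, and writes per-scan metric and texture
#' reports plus a manifest recording the package version, seeds,
#' realised accelerations and the MD5 of every artefact.
#'
#' @param config a \code{\link{runConfig}}.
#' @param verbose print stage progress.
#' @return the manifest, invisibly; artefacts are under
#'   \code{config$out_dir}.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  od <- config$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  preset <- anatomyPreset(config$anatomy)
  manifest <- list(package = "AccelT2",
                   version = as.character(utils::packageVersion("AccelT2")),
                   seed = config$seed, anatomy = config$anatomy,
                   accelerations = config$accelerations,
                   realized_R = list(), files = list())

  say("generating %d test phantoms", config$n_test)
  phantoms <- stage("phantom", lapply(seq_len(config$n_test), function(i) {
    cfg <- phantomConfig(grid = config$grid, anatomy = config$anatomy,
                         noise_sigma = config$noise_sigma,
                         seed = deriveSeed(config$seed, i))
    generatePhantom(cfg)
  }))
  for (i in seq_along(phantoms)) {
    writeEchoSeries(phantoms[[i]]@echoes,
                    file.path(od, sprintf("phantom%02d_echoes.nii", i)))
    writeRoiMask(phantoms[[i]]@roi,
                 file.path(od, sprintf("phantom%02d_roi.nii", i)))
  }

  say("fitting ground-truth maps")
  gt <- stage("fit", lapply(phantoms, function(ph) fitT2(ph@echoes)))
  for (i in seq_along(gt))
    writeT2Map(gt[[i]], file.path(od, sprintf("phantom%02d_t2gt.nii", i)))

  trained <- list()
  if (config$n_train > 0) {
    say("training at R = %s", paste(config$train_accelerations, collapse = ","))
    trained <- stage("train", {
      tr_ph <- lapply(seq_len(config$n_train), function(i)
        generatePhantom(phantomConfig(grid = config$grid,
                                      anatomy = config$anatomy,
                                      noise_sigma = config$noise_sigma,
                                      seed = deriveSeed(config$seed, 1000L + i))))
      va_ph <- lapply(seq_len(max(config$n_val, 1L)), function(i)
        generatePhantom(phantomConfig(grid = config$grid,
                                      anatomy = config$anatomy,
                                      noise_sigma = config$noise_sigma,
                                      seed = deriveSeed(config$seed, 2000L + i))))
      out <- list()
      for (Rv in config$train_accelerations) {
        plan <- samplingPlan(Rv, config$grid[c(1, 3)],
                             seed = deriveSeed(config$seed, 31L))
        ts <- buildTrainingSet(tr_ph, plan, preset)
        vs <- buildTrainingSet(va_ph, plan, preset)
        model <- buildModel(modelConfig(config$variant),
                            seed = deriveSeed(config$seed, 57L))
        tc <- trainConfig(max_epochs = config$max_epochs,
                          patience = config$patience,
                          aug_translate = 3, aug_rotate = 5,
                          seed = deriveSeed(config$seed, 77L))
        fit <- trainModel(model, ts, vs, tc, preset, config$loss_weights)
        write.csv(fit$history,
                  file.path(od, sprintf("training_R%g.csv", Rv)),
                  row.names = FALSE)
        out[[as.character(Rv)]] <- fit$model
      }
      out
    })
  }

  say("evaluating accelerations")
  summary_rows <- list()
  for (Rv in config$accelerations) {
    rows <- list()
    for (i in seq_along(phantoms)) {
      plan <- samplingPlan(Rv, config$grid[c(1, 3)],
                           seed = deriveSeed(config$seed, 500L + i))
      und <- stage("undersample", undersampleVolume(phantoms[[i]]@echoes, plan))
      manifest$realized_R[[sprintf("R%g_phantom%02d", Rv, i)]] <-
        und$mask@realizedR
      zf <- stage("fit", fitT2(und$echoes))
      ref <- gt[[i]]@t2; ref[is.na(ref)] <- 0
      zfm <- zf@t2; zfm[is.na(zfm)] <- 0
      rep_zf <- metricReport(ref, zfm, phantoms[[i]]@roi@labels)
      rep_zf$method <- "zero_fill"; rep_zf$phantom <- i; rep_zf$R <- Rv
      rows[[length(rows) + 1L]] <- rep_zf
      key <- as.character(Rv)
      if (length(trained) && key %in% names(trained)) {
        scaled <- scaleSignals(und$echoes, preset)
        pred <- stage("predict", predictMap(trained[[key]], scaled))
        rep_dl <- metricReport(ref, pred, phantoms[[i]]@roi@labels)
        rep_dl$method <- "network"; rep_dl$phantom <- i; rep_dl$R <- Rv
        rows[[length(rows) + 1L]] <- rep_dl
      }
    }
    tab <- do.call(rbind, rows)
    write.csv(tab, file.path(od, sprintf("metrics_R%g.csv", Rv)),
              row.names = FALSE)
    summary_rows[[length(summary_rows) + 1L]] <- tab
  }
  all_tab <- do.call(rbind, summary_rows)
  write.csv(all_tab, file.path(od, "metrics_all.csv"), row.names = FALSE)

  files <- list.files(od, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(files)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
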