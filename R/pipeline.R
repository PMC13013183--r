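#' End-to-end run configuration
#'
#' A single validated configuration object covering simulation, sensor
#' layout, architecture, training and evaluation, serializable to YAML
#' with [write_config()] / [read_config()] (round-trip identity).
#'
#' @param seed Global seed; every stage derives its substream from it.
#' @param n Training sample size (an equally sized validation set is
#'   simulated independently, and `test_n` subjects for evaluation).
#' @param m Number of sensor intervals.
#' @param tau,censor_mean,censor_cap Generator settings, see
#'   [sim_config()].
#' @param branch,dense_nodes,cnn_filters,pool_size,latent_p Architecture,
#'   see [network_spec()].
#' @param learning_rate,batch_size,max_epochs,patience Training, see
#'   [train_config()].
#' @param test_n Independent test-set size for the Brier-score report.
#' @return A list of class `svo_run_config`.
#' @export
run_config <- function(seed = 1L, n = 500L, m = 50L, tau = 100,
                       censor_mean = 50, censor_cap = 99,
                       branch = "fnn", dense_nodes = 64L,
                       cnn_filters = 16L, pool_size = 4L, latent_p = 10L,
                       learning_rate = 1e-3, batch_size = 500L,
                       max_epochs = 200L, patience = 10L, test_n = 200L) {
  stopifnot(branch %in% c("fnn", "cnn"))
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 m = as.integer(m), tau = as.numeric(tau),
                 censor_mean = as.numeric(censor_mean),
                 censor_cap = as.numeric(censor_cap),
                 branch = branch, dense_nodes = as.integer(dense_nodes),
                 cnn_filters = as.integer(cnn_filters),
                 pool_size = as.integer(pool_size),
                 latent_p = as.integer(latent_p),
                 learning_rate = as.numeric(learning_rate),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 test_n = as.integer(test_n)),
            class = "svo_run_config")
}

#' @rdname run_config
#' @param config A `svo_run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint is a self-describing versioned list holding the
#' architecture spec, all parameters, the time grid and the covariate
#' schema.
#'
#' @param fit A fitted [survonet()] model.
#' @param path Destination file.
#' @export
save_checkpoint <- function(fit, path) {
  ck <- list(format = "survonet-checkpoint", version = 1L,
             spec = fit$spec, params = fit$net$params, grid = fit$grid,
             channels = channel_names(fit$records_train),
             invariant = invariant_names(fit$records_train))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a list with `net` (usable with
#'   [operator_forward()] and [predict_survival()]) and `grid`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "survonet-checkpoint"))
    stop("not a survonet checkpoint: ", path)
  list(net = structure(list(spec = ck$spec, params = ck$params),
                       class = "svo_net"),
       grid = ck$grid, channels = ck$channels, invariant = ck$invariant)
}

#' Run the full simulate / fit / predict / evaluate pipeline
#'
#' Simulates training, validation and test data under the configured
#' generator, fits the operator network, and writes a reproducible
#' artifact directory: `data.csv` (training data, long format),
#' `truth.csv` (true survival on the grid per training subject),
#' `model.ckpt`, `train_log.csv`, `curves.csv` (predicted survival for
#' every test subject), `report.json` and `config.yaml`.  A failure in
#' stage X leaves a `FAILED_X` marker file.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(out_dir, paste0("FAILED_", name)))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  grid <- time_grid(config$tau, config$m)
  sim_tr <- sim_config(n = config$n, tau = config$tau,
                       censor_mean = config$censor_mean,
                       censor_cap = config$censor_cap,
                       seed = subject_seed(config$seed, 1L))
  sim_va <- sim_tr; sim_va$seed <- subject_seed(config$seed, 2L)
  sim_te <- sim_tr; sim_te$n <- config$test_n
  sim_te$seed <- subject_seed(config$seed, 3L)

  dat <- stage("simulate", {
    dtr <- simulate_survdata(sim_tr, grid)
    dva <- simulate_survdata(sim_va, grid, keep_truth = FALSE)
    dte <- simulate_survdata(sim_te, grid, keep_truth = FALSE)
    write_long_format(dtr$records, file.path(out_dir, "data.csv"), grid)
    truth <- do.call(rbind, lapply(seq_along(dtr$records), function(i)
      data.frame(id = dtr$records[[i]]$id, t = grid$points,
                 surv = truepath_surv_at(dtr$truth[[i]], grid$points))))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    list(tr = dtr, va = dva, te = dte)
  })

  fit <- stage("train", {
    f <- survonet(dat$tr$records, grid, validation = dat$va$records,
                  branch = config$branch, dense_nodes = config$dense_nodes,
                  cnn_filters = config$cnn_filters,
                  pool_size = config$pool_size, latent_p = config$latent_p,
                  learning_rate = config$learning_rate,
                  batch_size = config$batch_size,
                  max_epochs = config$max_epochs,
                  patience = config$patience,
                  seed = subject_seed(config$seed, 4L))
    save_checkpoint(f, file.path(out_dir, "model.ckpt"))
    utils::write.csv(f$log, file.path(out_dir, "train_log.csv"),
                     row.names = FALSE)
    f
  })

  stage("predict", {
    S <- predict(fit, dat$te$records)
    curves <- do.call(rbind, lapply(seq_len(nrow(S)), function(i)
      data.frame(id = rownames(S)[i], t = attr(S, "times"), s_hat = S[i, ])))
    utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                     row.names = FALSE)
  })

  report <- stage("evaluate", {
    y_te <- vapply(dat$te$records, `[[`, numeric(1), "y")
    d_te <- vapply(dat$te$records, `[[`, numeric(1), "delta")
    y_tr <- vapply(dat$tr$records, `[[`, numeric(1), "y")
    d_tr <- vapply(dat$tr$records, `[[`, numeric(1), "delta")
    G <- kaplan_meier(y_tr, 1 - d_tr)
    mesh <- sort(unique(y_te))
    S <- predict(fit, dat$te$records, times = mesh)
    bs <- vapply(seq_along(mesh), function(j)
      brier_score(mesh[j], S[, j], y_te, d_te, G), numeric(1))
    rep <- list(package_version = as.character(utils::packageVersion("survonet")),
                seed = config$seed, n_train = config$n, m = config$m,
                censor_rate_train = mean(d_tr == 0),
                epochs_run = nrow(fit$log),
                best_epoch = fit$best_epoch,
                best_val_loss = fit$best_val_loss,
                test_ibs = integrated_brier(mesh, bs))
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep
  })
  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(report)
}
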