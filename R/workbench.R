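# Evaluation workbench: error metrics comparing a reconstruction with the
# forward-simulation ground truth, and the end-to-end pipeline
# (simulate -> extract profiles -> train -> evaluate) with a mode-count
# sweep.

#' Normalized L2 displacement error
#'
#' Per time step, `e(t) = 100 * ||U_pred - U_true||_2 / ||U_true||_2` with
#' displacements `U = X - X0`. Times where the true displacement norm is
#' zero are excluded with a warning.
#'
#' @param X_pred,X_true lists of n x 3 deformed position matrices (or T x 3n
#'   matrices).
#' @param X0 rest positions (n x 3).
#' @param eval_idx optional indices of the times entering the mean/SD
#'   summary (default: all).
#' @return list with `per_time` (percent), `mean`, `sd`.
#' @export
displacement_error <- function(X_pred, X_true, X0, eval_idx = NULL) {
  as_rows <- function(X) {
    if (is.list(X)) t(sapply(X, function(m) as.numeric(t(m)))) else as.matrix(X)
  }
  P <- as_rows(X_pred); Tr <- as_rows(X_true)
  stop_if_not(all(dim(P) == dim(Tr)), "prediction/truth dimensions differ")
  x0 <- as.numeric(t(X0))
  Up <- sweep(P, 2, x0, "-")
  Ut <- sweep(Tr, 2, x0, "-")
  nt <- sqrt(rowSums(Ut^2))
  ok <- nt > 0
  if (!all(ok)) warning("excluding ", sum(!ok), " time(s) with zero true displacement")
  e <- rep(NA_real_, nrow(P))
  e[ok] <- 100 * sqrt(rowSums((Up[ok, , drop = FALSE] - Ut[ok, , drop = FALSE])^2)) / nt[ok]
  idx <- if (is.null(eval_idx)) which(ok) else intersect(eval_idx, which(ok))
  list(per_time = e, mean = mean(e[idx]), sd = stats::sd(e[idx]))
}

#' Scalar error suite for aerodynamic and acoustic quantities
#'
#' Time-mean relative errors (percent) with SDs for the flow rate and the
#' mean intraglottal pressure, signed relative errors of the peak and mean
#' flow rate, and SPL / acoustic-power differences.
#'
#' @param pred,truth lists with aligned elements `Q` (vector), `P_sec`
#'   (T x n_sections matrix), and optionally `spl`, `power_db`.
#' @param eval_idx indices used for the mean/SD statistics (default: all).
#' @return list of error entries (percent unless suffixed `_db`).
#' @export
scalar_error_suite <- function(pred, truth, eval_idx = NULL) {
  stop_if_not(length(pred$Q) == length(truth$Q), "misaligned flow series")
  idx <- if (is.null(eval_idx)) seq_along(pred$Q) else eval_idx
  rel <- function(p, t) 100 * abs(p - t) / pmax(abs(t), .Machine$double.eps)
  q_err <- rel(pred$Q, truth$Q)
  out <- list(flow_rate_err_mean = mean(q_err[idx]),
              flow_rate_err_sd = stats::sd(q_err[idx]),
              peak_flow_err = 100 * (max(pred$Q) - max(truth$Q)) / max(truth$Q),
              mean_flow_err = 100 * (mean(pred$Q) - mean(truth$Q)) / mean(truth$Q))
  if (!is.null(pred$P_sec) && !is.null(truth$P_sec)) {
    # mean intraglottal pressure per time (sections up to separation carry
    # the Bernoulli pressure; downstream sections are zero gage)
    mp_p <- rowMeans(pred$P_sec)
    mp_t <- rowMeans(truth$P_sec)
    p_err <- rel(mp_p, mp_t)
    out$pressure_err_mean <- mean(p_err[idx])
    out$pressure_err_sd <- stats::sd(p_err[idx])
  }
  if (!is.null(pred$spl) && !is.null(truth$spl)) {
    out$spl_err <- 100 * (pred$spl - truth$spl) / truth$spl
    out$spl_delta_db <- pred$spl - truth$spl
  }
  if (!is.null(pred$power_db) && !is.null(truth$power_db)) {
    out$power_err <- 100 * (pred$power_db - truth$power_db) / truth$power_db
    out$power_delta_db <- pred$power_db - truth$power_db
  }
  out
}

#' Default configuration of the whole pipeline
#'
#' One nested list collecting the defaults of every stage; serializable to
#' YAML with [write_config()]. The material constants put the fundamental
#' eigenfrequency of the default fold in the canine phonation range and the
#' cover layer softer than the body.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    geometry = list(span = 10e-3, depth = 8e-3, thickness = 6e-3,
                    half_gap = 0.2e-3, bulge_y = 0.1e-3, bulge_z = 1.0e-3,
                    cover_thickness = 1.5e-3, element_size = 1.0e-3),
    material = list(
      cover = list(density = 1040, E_t = 2e3, E_l = 20e3, nu_t = 0.3,
                   nu_lt = 0.3, G_l = 6e3),
      body = list(density = 1040, E_t = 6e3, E_l = 40e3, nu_t = 0.3,
                  nu_lt = 0.3, G_l = 12e3)),
    damping = list(alpha = 60.0, beta = 6.0e-5),
    flow = list(P_sub = 1000, rho_air = 1.1, n_sections = 100,
                area_floor = 1e-8, tau_gap = 1e-6, tau_area = 5e-8),
    contact = list(k_c1 = 5e5, k_c2 = 1e6),
    sim = list(dt = 1e-5, duration = 0.2, seed = 1),
    observation = list(n_profiles = 20, n_stations = 64),
    network = list(hidden = 64, fc_layers = 4, fc_width = 64),
    train = list(epochs = 20000, lr = 1e-2, lr_min = 5e-5, W_e = 1e4,
                 W_d = 1e-5, auto_balance = TRUE, patience = 1000,
                 rel_tol = 1e-4, converge_patience = 20000, seed = 1),
    acoustics = list(r = 1, d = 0.12, fs = 48000, cutoff = 20000,
                     c_sound = 343)
  )
}

# instantiate typed parameter objects from the nested config
config_objects <- function(cfg) {
  list(
    geometry = do.call(geometry_params, cfg$geometry),
    materials = list(cover = do.call(material, cfg$material$cover),
                     body = do.call(material, cfg$material$body)),
    flow = do.call(flow_params, cfg$flow),
    contact = do.call(contact_params, cfg$contact),
    acoustics = do.call(acoustic_config,
                        c(cfg$acoustics, list(rho_air = cfg$flow$rho_air)))
  )
}

#' Run the full synthetic-data experiment
#'
#' Generates ground truth with the forward FSI simulator on the packaged
#' two-layer fold, extracts time-labeled 2D profiles over one steady cycle,
#' trains the physics-informed network, reconstructs all fields, and
#' evaluates the error metrics (16 evaluation times per cycle by default,
#' matching the reported statistics convention).
#'
#' @param cfg nested configuration (see [default_config()]).
#' @param n_modes number of eigenmodes given to the network.
#' @param seed master seed (forward-simulation and training seeds derive
#'   from it).
#' @param n_eval evaluation time points per cycle for the statistics.
#' @param shared optional list with precomputed `mesh`, `basis`, `sim`,
#'   `training` to reuse across mode counts (see [mode_sweep()]).
#' @param verbose print training progress.
#' @return list with the evaluation report and all intermediate artifacts.
#' @export
run_pipeline <- function(cfg = default_config(), n_modes = 100, seed = 1,
                         n_eval = 16, shared = NULL, verbose = FALSE) {
  ob <- config_objects(cfg)
  if (is.null(shared)) {
    mesh <- build_vocal_fold_mesh(ob$geometry)
    sys <- assemble_mass_stiffness(mesh, ob$materials)
    basis_full <- solve_eigenmodes(sys, n_modes = max(n_modes, cfg$sim$basis_modes %||% n_modes),
                                   alpha = cfg$damping$alpha, beta = cfg$damping$beta)
    simcfg <- sim_config(dt = cfg$sim$dt, duration = cfg$sim$duration,
                         seed = seed)
    sim <- fsi_simulate(mesh, basis_full, ob$flow, ob$contact, simcfg,
                        n_stations = cfg$observation$n_stations)
    training <- extract_training_set(sim, n_profiles = cfg$observation$n_profiles,
                                     n_stations = cfg$observation$n_stations)
  } else {
    mesh <- shared$mesh; basis_full <- shared$basis
    sim <- shared$sim; training <- shared$training
  }
  stop_if_not(n_modes <= basis_full$n_modes,
              "requested %d modes but the basis holds %d", n_modes, basis_full$n_modes)
  basis <- truncate_basis(basis_full, n_modes)
  net_cfg <- network_config(hidden = cfg$network$hidden,
                            fc_layers = cfg$network$fc_layers,
                            fc_width = cfg$network$fc_width,
                            n_modes = n_modes)
  tr_cfg <- train_config(epochs = cfg$train$epochs, lr = cfg$train$lr,
                         lr_min = cfg$train$lr_min, W_e = cfg$train$W_e,
                         W_d = cfg$train$W_d,
                         auto_balance = isTRUE(cfg$train$auto_balance),
                         patience = cfg$train$patience %||% 1000,
                         rel_tol = cfg$train$rel_tol %||% 1e-4,
                         converge_patience = cfg$train$converge_patience %||% 6000,
                         balance_ratio = cfg$train$balance_ratio %||% 1,
                         seed = seed + 1000)
  ck <- train_pinn(training$profiles, mesh, basis, ob$flow, ob$contact,
                   net_cfg, tr_cfg, verbose = verbose)
  rec <- reconstruct_and_postprocess(ck, mesh, basis, ob$flow, ob$contact)
  # ground-truth fields at the observation times (full basis)
  T_ <- length(training$truth$Q)
  X_true <- lapply(seq_len(T_), function(i)
    reconstruct_displacement(basis_full, training$truth$b[i, ], mesh$nodes))
  eval_idx <- unique(round(seq(1, T_, length.out = n_eval)))
  de <- displacement_error(rec$X, X_true, mesh$nodes, eval_idx = eval_idx)
  fs_cycle <- 1 / (training$profiles$times[2] - training$profiles$times[1])
  ac <- ob$acoustics
  n_tile <- max(8, ceiling(0.25 * training$truth$f0))
  p_true <- acoustic_pressure(tile_cycle(training$truth$Q, n_tile), fs_cycle, ac)
  p_pred <- acoustic_pressure(tile_cycle(rec$Q, n_tile), fs_cycle, ac)
  truth_sc <- list(Q = training$truth$Q, P_sec = training$truth$P_sec,
                   spl = compute_spl(p_true$p, ac),
                   power_db = acoustic_power(p_true$p, ac)$dB)
  pred_sc <- list(Q = rec$Q, P_sec = rec$P_sec,
                  spl = compute_spl(p_pred$p, ac),
                  power_db = acoustic_power(p_pred$p, ac)$dB)
  errors <- scalar_error_suite(pred_sc, truth_sc, eval_idx = eval_idx)
  report <- c(list(disp_err_mean = de$mean, disp_err_sd = de$sd,
                   f0_hz = training$truth$f0, n_modes = n_modes),
              errors)
  list(report = report, disp = de, checkpoint = ck, reconstruction = rec,
       truth = training$truth, profiles = training$profiles,
       mesh = mesh, basis = basis_full, sim = sim, training = training,
       spl = list(pred = pred_sc$spl, truth = truth_sc$spl),
       power_db = list(pred = pred_sc$power_db, truth = truth_sc$power_db))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Truncate a modal basis to its lowest modes
#'
#' @param basis a `vf_modal_basis`.
#' @param n_modes number of lowest modes to keep.
#' @return a `vf_modal_basis` with `n_modes` columns.
#' @export
truncate_basis <- function(basis, n_modes) {
  stop_if_not(n_modes <= basis$n_modes, "cannot truncate to more modes than available")
  modal_basis(basis$modes[, seq_len(n_modes), drop = FALSE],
              basis$omega[seq_len(n_modes)], alpha = basis$alpha,
              beta = basis$beta, free_dofs = basis$free_dofs,
              n_nodes = basis$n_nodes)
}

#' Sweep the number of eigenmodes given to the network
#'
#' Re-trains and re-evaluates the pipeline for each mode count on a shared
#' forward-simulation ground truth; rows that fail to train are reported
#' with `NA` errors and the sweep continues.
#'
#' @param cfg nested configuration.
#' @param counts integer vector of mode counts.
#' @param seed master seed.
#' @param n_eval evaluation times per cycle.
#' @param verbose print progress.
#' @return list with `table` (data frame: n_modes, disp_err_mean,
#'   disp_err_sd) and `runs` (per-count pipeline outputs).
#' @export
mode_sweep <- function(cfg = default_config(), counts = c(20, 100), seed = 1,
                       n_eval = 16, verbose = FALSE) {
  ob <- config_objects(cfg)
  mesh <- build_vocal_fold_mesh(ob$geometry)
  sys <- assemble_mass_stiffness(mesh, ob$materials)
  basis <- solve_eigenmodes(sys, n_modes = max(counts),
                            alpha = cfg$damping$alpha, beta = cfg$damping$beta)
  simcfg <- sim_config(dt = cfg$sim$dt, duration = cfg$sim$duration, seed = seed)
  sim <- fsi_simulate(mesh, basis, ob$flow, ob$contact, simcfg,
                      n_stations = cfg$observation$n_stations)
  training <- extract_training_set(sim, n_profiles = cfg$observation$n_profiles,
                                   n_stations = cfg$observation$n_stations)
  shared <- list(mesh = mesh, basis = basis, sim = sim, training = training)
  runs <- vector("list", length(counts))
  tab <- data.frame(n_modes = counts, disp_err_mean = NA_real_,
                    disp_err_sd = NA_real_)
  for (i in seq_along(counts)) {
    res <- tryCatch(run_pipeline(cfg, n_modes = counts[i], seed = seed,
                                 n_eval = n_eval, shared = shared,
                                 verbose = verbose),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("mode count ", counts[i], " failed: ", conditionMessage(res))
      next
    }
    runs[[i]] <- res
    tab$disp_err_mean[i] <- res$report$disp_err_mean
    tab$disp_err_sd[i] <- res$report$disp_err_sd
  }
  list(table = tab, runs = runs, shared = shared)
}
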