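# Training loop: full-batch (single-sequence) optimization of the LSTM
# encoder-decoder + MLP against the combined physics/data loss, with Adam
# and a reduce-on-plateau learning-rate schedule.

#' Training hyperparameters
#'
#' @param epochs maximum number of epochs.
#' @param lr initial learning rate.
#' @param lr_min floor of the learning-rate schedule.
#' @param lr_factor multiplicative decay on plateau.
#' @param patience epochs without sufficient improvement before the rate is
#'   reduced.
#' @param W_e,W_d equation / data loss weights.
#' @param auto_balance if `TRUE`, rescale the weights once at epoch 0 so
#'   both weighted loss terms start at comparable magnitude (each weight
#'   becomes `1 / L(0)` for its own initial loss, ignoring `W_e`/`W_d`).
#' @param balance_ratio extra multiplier on the balanced data weight;
#'   values above 1 emphasize the observation mismatch relative to the
#'   equation residual.
#' @param clip_norm global gradient-norm clipping threshold (stabilizes the
#'   high-learning-rate phase of training through the stiff physics terms);
#'   `Inf` disables clipping.
#' @param seed RNG seed for parameter initialization.
#' @param rel_tol relative improvement of the best loss that counts as
#'   progress for the plateau detector and the convergence stop.
#' @param converge_patience epochs without progress before training stops
#'   early.
#' @return object of class `vf_train_config`.
#' @export
train_config <- function(epochs = 5000, lr = 1e-2, lr_min = 5e-5,
                         lr_factor = 0.5, patience = 250,
                         W_e = 1e4, W_d = 1e-5, auto_balance = FALSE,
                         balance_ratio = 1, clip_norm = 1.0,
                         seed = 1L, rel_tol = 1e-3, converge_patience = 2000) {
  stop_if_not(lr_min > 0 && lr_min <= lr, "need 0 < lr_min <= lr")
  stop_if_not(W_e >= 0 && W_d >= 0, "loss weights must be non-negative")
  structure(list(epochs = as.integer(epochs), lr = lr, lr_min = lr_min,
                 lr_factor = lr_factor, patience = as.integer(patience),
                 W_e = W_e, W_d = W_d, auto_balance = auto_balance,
                 balance_ratio = balance_ratio, clip_norm = clip_norm,
                 seed = as.integer(seed), rel_tol = rel_tol,
                 converge_patience = as.integer(converge_patience)),
            class = "vf_train_config")
}

# feature/coefficient scaling shared by training and inference. The output
# scale is per mode: a characteristic amplitude b_ref (one rest gap carried
# by a mass-orthonormal mode of the fold's mass) rolled off as (omega_1 /
# omega_j)^2, the static-response scaling, so the network expresses every
# mode as an O(1) quantity. This is a reparameterization only; the losses
# are unchanged.
make_scaling <- function(mesh, basis, so) {
  L_ref <- mesh$params$half_gap
  vol <- sum(tet_volumes(mesh$nodes, mesh$tets))
  b_ref <- L_ref * sqrt(1040 * vol)
  b_scale <- b_ref * (basis$omega[1] / basis$omega)^2
  edge_rest <- station_forward(so, numeric(basis$n_modes), mode = "eval")$profile
  list(L_ref = L_ref, b_scale = b_scale, edge_rest = edge_rest)
}

profile_features <- function(edges, scaling) {
  sweep(edges, 2, scaling$edge_rest, "-") / scaling$L_ref
}

#' Train the physics-informed network on an observed profile sequence
#'
#' The observed 2D profiles are nondimensionalized (deviation from the rest
#' profile in units of the rest half-gap) and fed to the LSTM
#' encoder-decoder; the predicted modal coefficient sequence is pushed
#' through the differentiable flow/contact/projection physics to form
#' `L_f = W_e L_e + W_d L_d`; gradients flow end-to-end back to every
#' network parameter. Full-batch Adam with reduce-on-plateau scheduling;
#' the returned checkpoint holds the parameters with the best `L_f`.
#'
#' @param profiles observed `vf_profile_sequence` (one vibration cycle,
#'   uniformly sampled).
#' @param mesh,basis the structural model.
#' @param flow,contact physics parameters.
#' @param net_cfg a [network_config()]; its `n_modes` must match `basis`.
#' @param tr_cfg a [train_config()].
#' @param verbose print progress every 500 epochs.
#' @return object of class `vf_checkpoint`: best parameters, configs,
#'   scaling, loss `history` data frame, and the station operator.
#' @export
train_pinn <- function(profiles, mesh, basis, flow = flow_params(),
                       contact = contact_params(),
                       net_cfg = network_config(n_modes = basis$n_modes),
                       tr_cfg = train_config(), verbose = FALSE) {
  stop_if_not(net_cfg$n_modes == basis$n_modes,
              "network output dim (%d) must equal the modal basis size (%d)",
              net_cfg$n_modes, basis$n_modes)
  tsp <- diff(profiles$times)
  stop_if_not(max(abs(tsp - tsp[1])) < 1e-9 * tsp[1] + 1e-15,
              "profile times must be uniformly spaced (resample first)")
  dt <- tsp[1]
  so <- station_operator(mesh, basis, flow, contact,
                         n_stations = length(profiles$stations))
  stop_if_not(max(abs(so$stations - profiles$stations)) < 1e-12,
              "station mismatch between profiles and mesh span")
  scaling <- make_scaling(mesh, basis, so)
  X <- profile_features(profiles$edges, scaling)
  params <- network_init(net_cfg, n_features = ncol(X), seed = tr_cfg$seed)
  cdamp <- modal_damping(basis)
  W_e <- tr_cfg$W_e; W_d <- tr_cfg$W_d

  eval_loss <- function(params, W_e, W_d) {
    out <- network_forward(params, X)
    b <- sweep(out$Y, 2, scaling$b_scale, "*")
    pl <- pinn_loss(so, b, profiles$edges, dt, basis$omega, cdamp,
                    W_e = W_e, W_d = W_d, L_ref = scaling$L_ref)
    list(net = out, pl = pl)
  }
  if (tr_cfg$auto_balance) {
    # equalize the two weighted terms at epoch 0 (both start at 1)
    probe <- eval_loss(params, 1, 1)$pl
    W_e <- 1 / max(probe$L_e, .Machine$double.xmin)
    W_d <- tr_cfg$balance_ratio / max(probe$L_d, .Machine$double.xmin)
  }
  opt <- adam_init(params)
  lr <- tr_cfg$lr
  hist <- matrix(0, tr_cfg$epochs, 4)
  best <- list(L_f = Inf, params = params, epoch = 0L)
  since_improve <- 0L; since_converge <- 0L
  for (ep in seq_len(tr_cfg$epochs)) {
    ev <- eval_loss(params, W_e, W_d)
    pl <- ev$pl
    if (!is.finite(pl$L_f)) {
      stop("non-finite loss at epoch ", ep,
           "; lower the learning rate or increase the smoothing widths")
    }
    hist[ep, ] <- c(pl$L_d, pl$L_e, pl$L_f, lr)
    improved <- pl$L_f < best$L_f * (1 - tr_cfg$rel_tol)
    if (pl$L_f < best$L_f) {
      best <- list(L_f = pl$L_f, L_e = pl$L_e, L_d = pl$L_d,
                   params = params, epoch = ep)
    }
    if (improved) { since_improve <- 0L; since_converge <- 0L }
    else { since_improve <- since_improve + 1L; since_converge <- since_converge + 1L }
    if (since_converge >= tr_cfg$converge_patience) break
    if (since_improve >= tr_cfg$patience && lr > tr_cfg$lr_min) {
      lr <- max(lr * tr_cfg$lr_factor, tr_cfg$lr_min)
      since_improve <- 0L
    }
    dY <- sweep(pl$grad_b, 2, scaling$b_scale, "*")
    grads <- network_backward(params, ev$net$cache, dY)
    if (is.finite(tr_cfg$clip_norm)) {
      gn <- sqrt(par_sumsq(grads))
      if (gn > tr_cfg$clip_norm) {
        sc <- tr_cfg$clip_norm / gn
        grads <- par_map(grads, function(g) g * sc)
      }
    }
    stp <- adam_step(opt, params, grads, lr)
    opt <- stp$state; params <- stp$params
    if (verbose && ep %% 500 == 0) {
      message(sprintf("epoch %6d  L_d=%.3e  L_e=%.3e  L_f=%.3e  lr=%.2e",
                      ep, pl$L_d, pl$L_e, pl$L_f, lr))
    }
  }
  n_ep <- if (exists("ep")) ep else 0L
  history <- data.frame(epoch = seq_len(n_ep), L_d = hist[seq_len(n_ep), 1],
                        L_e = hist[seq_len(n_ep), 2], L_f = hist[seq_len(n_ep), 3],
                        lr = hist[seq_len(n_ep), 4])
  structure(list(params = best$params, best_L_f = best$L_f,
                 best_epoch = best$epoch,
                 net_cfg = net_cfg, tr_cfg = tr_cfg,
                 W_e = W_e, W_d = W_d,
                 scaling = scaling, history = history,
                 profiles = profiles, dt = dt),
            class = "vf_checkpoint")
}

#' Predict the modal coefficient sequence from a trained checkpoint
#'
#' @param checkpoint a `vf_checkpoint` from [train_pinn()].
#' @param profiles a `vf_profile_sequence` (defaults to the training one).
#' @return T x J matrix of modal coefficients (dimensional).
#' @export
predict_modal <- function(checkpoint, profiles = checkpoint$profiles) {
  X <- profile_features(profiles$edges, checkpoint$scaling)
  sweep(network_forward(checkpoint$params, X)$Y, 2, checkpoint$scaling$b_scale, "*")
}

#' Reconstruct full physical fields from a trained checkpoint
#'
#' Evaluation-mode pipeline (exact max/min, no smoothing): 3D shapes,
#' glottal flow rate, intraglottal pressures, and projected profiles at the
#' observation times.
#'
#' @param checkpoint a `vf_checkpoint`.
#' @param mesh,basis the structural model used in training.
#' @param flow,contact physics parameters.
#' @param profiles profile sequence to condition on (defaults to training).
#' @return list with `b`, `X` (list of n x 3 matrices), `Q`, `A_min`,
#'   `P_sec`, `profiles_pred` (a `vf_profile_sequence`), `times`.
#' @export
reconstruct_and_postprocess <- function(checkpoint, mesh, basis,
                                        flow = flow_params(),
                                        contact = contact_params(),
                                        profiles = checkpoint$profiles) {
  b <- predict_modal(checkpoint, profiles)
  so <- station_operator(mesh, basis, flow, contact,
                         n_stations = length(profiles$stations))
  T_ <- nrow(b)
  Q <- numeric(T_); A_min <- numeric(T_)
  P_sec <- matrix(0, T_, flow$n_sections)
  edges <- matrix(0, T_, length(profiles$stations))
  Xlist <- vector("list", T_)
  for (i in seq_len(T_)) {
    st <- station_forward(so, b[i, ], mode = "eval")
    Q[i] <- st$Q; A_min[i] <- st$A_min; P_sec[i, ] <- st$P_sec
    edges[i, ] <- st$profile
    Xlist[[i]] <- reconstruct_displacement(basis, b[i, ], mesh$nodes)
  }
  list(b = b, X = Xlist, Q = Q, A_min = A_min, P_sec = P_sec,
       y_sec = so$y_sec,
       profiles_pred = profile_sequence(profiles$times, profiles$stations,
                                        edges, view = profiles$view),
       times = profiles$times)
}
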