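#' Train the registration network
#'
#' Minimises the semi-supervised loss
#' L = -NCC(V o T, V_f) - NCC(V o Psi, V_f) + delta * smoothness(phi)
#' with Adam (batch size 1), logging per-epoch mean training loss and, when
#' validation cases are given, validation Dice; the best-validation parameters
#' are kept.  A single seed controls weight updates' data order; two runs with
#' the same seed produce identical histories.
#'
#' @param model a \code{prost_model} from \code{\link{init_registration_model}}.
#' @param train_cases list of \code{registration_case} with ground truth.
#' @param val_cases optional list of validation cases.
#' @param epochs number of epochs (default from the model config).
#' @param lr Adam learning rate (default from the config: 1e-5 at full scale,
#'   1e-3 for the tiny preset).  A vector is treated as a per-epoch schedule
#'   (recycled to \code{epochs}), e.g. \code{rep(c(3e-3, 1e-3), c(40, 20))}.
#' @param delta smoothness weight (default from the config, 0.01).
#' @param seed seed for data order.
#' @param clip_norm clip the global gradient norm to this value before each
#'   Adam step (default 1; \code{Inf} disables).  Guards against the pose
#'   regression throwing the atlas outside the sampling grid early in training,
#'   where the image term becomes flat and unrecoverable.
#' @param affine_only train (and run) only the affine stage?
#' @param freeze optional regular expression; parameters whose names match are
#'   excluded from updates (e.g. \code{"^aff_"} to train the local module
#'   against a fixed affine stage).
#' @param verbose log per-epoch records to stderr?
#' @param log_csv optional path for a per-epoch CSV log.
#' @return the model with trained parameters and a \code{history} data.frame.
#' @export
train_registration <- function(model, train_cases, val_cases = NULL,
                               epochs = NULL, lr = NULL, delta = NULL,
                               seed = 1, clip_norm = 1, affine_only = FALSE,
                               freeze = NULL, verbose = TRUE, log_csv = NULL) {
  stopifnot(inherits(model, "prost_model"))
  if (length(train_cases) == 0) stop("empty training dataset")
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (is.null(lr)) lr <- cfg$lr
  lr_vec <- rep_len(lr, epochs)
  if (!is.null(delta)) model$config$delta <- delta
  adam <- new.env(parent = emptyenv())
  adam$m <- list(); adam$v <- list(); adam$t <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- vector("list", epochs)
  best <- list(dice = -Inf, params = model$params)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(train_cases))
      losses <- numeric(length(ord))
      for (ii in seq_along(ord)) {
        case <- train_cases[[ord[ii]]]
        ids <- forward_pass(model, case, affine_only = affine_only)
        lv <- tp_val(ids$tape, ids$loss)
        if (!is.finite(lv))
          stop(sprintf("non-finite loss at epoch %d, case %d: %g", ep, ord[ii], lv))
        losses[ii] <- lv
        grads <- tp_backward(ids$tape, ids$loss)
        if (is.finite(clip_norm)) {
          gn <- sqrt(sum(vapply(ls(ids$pe), function(nm) {
            g <- grads[[ids$pe[[nm]]]]
            if (is.null(g)) 0 else sum(g^2)
          }, numeric(1))))
          if (gn > clip_norm) {
            sc <- clip_norm / gn
            for (nm in ls(ids$pe)) {
              id <- ids$pe[[nm]]
              if (!is.null(grads[[id]])) grads[[id]] <- grads[[id]] * sc
            }
          }
        }
        adam$t <- adam$t + 1
        corr <- sqrt(1 - b2^adam$t) / (1 - b1^adam$t)
        for (nm in ls(ids$pe)) {
          g <- grads[[ids$pe[[nm]]]]
          if (is.null(g)) next
          if (!is.null(freeze) && grepl(freeze, nm)) next
          if (is.null(adam$m[[nm]])) {
            adam$m[[nm]] <- g * 0; adam$v[[nm]] <- g * 0
          }
          adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * g
          adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * g^2
          model$params[[nm]] <- model$params[[nm]] -
            lr_vec[ep] * corr * adam$m[[nm]] / (sqrt(adam$v[[nm]]) + eps)
        }
      }
      vd <- NA_real_
      if (!is.null(val_cases)) {
        vd <- mean(vapply(val_cases, function(cs) {
          r <- register_case(model, cs, affine_only = affine_only)
          dice(r$warped_labels, cs$target$labels)
        }, numeric(1)))
        if (vd > best$dice) best <- list(dice = vd, params = model$params)
      }
      hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses), val_dice = vd)
      if (verbose)
        message(sprintf("[%s] epoch %d/%d  loss %.4f  val dice %s",
                        format(Sys.time(), "%H:%M:%S"), ep, epochs,
                        mean(losses), ifelse(is.na(vd), "-", sprintf("%.4f", vd))))
    }
  })
  if (!is.null(val_cases) && is.finite(best$dice)) model$params <- best$params
  model$history <- do.call(rbind, hist)
  if (!is.null(log_csv)) utils::write.csv(model$history, log_csv, row.names = FALSE)
  model
}

#' Save / load a trained model
#'
#' The checkpoint is a JSON sidecar of the full configuration plus an RDS of
#' the parameter arrays.
#'
#' @param model a \code{prost_model}.
#' @param path base path; writes \code{<path>.rds} and \code{<path>.json}.
#' @export
save_model <- function(model, path) {
  saveRDS(list(params = model$params, history = model$history), paste0(path, ".rds"))
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg$volume_dim <- as.integer(cfg$volume_dim)
  cfg$input_px <- as.integer(cfg$input_px)
  cfg$k_samples <- as.integer(cfg$k_samples)
  cfg$affine <- as.list(cfg$affine); cfg$local <- as.list(cfg$local)
  cfg$local$decoder_features <- as.integer(cfg$local$decoder_features)
  class(cfg) <- "reg_config"
  blob <- readRDS(paste0(path, ".rds"))
  m <- init_registration_model(cfg, seed = 1)
  m$params <- blob$params
  m$history <- blob$history
  m
}
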