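#' Training configuration
#'
#' Per-example (batch size one) Adam training over a fixed number of
#' epochs, with a piecewise-linear learning-rate schedule: the rate rises
#' linearly from 0 to `peak_lr` over the first `warmup_frac` of all
#' training examples, then decays linearly back to 0. The default peak
#' of 1e-5 is the published fine-tuning rate for a large transformer
#' backbone; when training a fresh head alone on a frozen or mock
#' backbone, pass a larger value (1e-2 is a reasonable desk-scale
#' choice).
#'
#' @param peak_lr Peak learning rate (default 1e-5).
#' @param warmup_frac Fraction of total examples spent ramping up
#'   (default 0.30; must lie strictly inside (0, 1)).
#' @param epochs Number of passes over the data (default 3).
#' @param batch_size Examples per update (the reference protocol uses 1).
#' @param seed Seed governing shuffling and weight initialization.
#' @param freeze_backbone If `TRUE`, backbone state is left untouched
#'   during training. Backbones without trainable state (the mock, most
#'   adapters) are frozen de facto regardless.
#' @param hidden Hidden width for heads initialized by the trainer.
#' @return A `train_config` list.
#' @export
train_config <- function(peak_lr = 1e-5, warmup_frac = 0.30, epochs = 3L,
                         batch_size = 1L, seed = 1L,
                         freeze_backbone = FALSE, hidden = 32L) {
  abort_if(warmup_frac <= 0 || warmup_frac >= 1,
           "warmup_frac must lie strictly between 0 and 1")
  abort_if(epochs < 1, "epochs must be >= 1")
  structure(list(peak_lr = peak_lr, warmup_frac = warmup_frac,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 freeze_backbone = freeze_backbone,
                 hidden = as.integer(hidden)),
            class = "train_config")
}

#' Learning rate at a given step
#'
#' Piecewise-linear warmup/decay: 0 at step 0, `peak_lr` exactly at
#' `warmup_frac * total_steps`, 0 at `total_steps`, linear in between.
#' Total steps are counted across all epochs (the warmup fraction is a
#' fraction of all training examples seen during the run).
#'
#' @param step Step index, 0..`total_steps`.
#' @param total_steps Total number of update steps in the run.
#' @param config A [train_config()].
#' @return Learning rate at `step`.
#' @export
lr_at <- function(step, total_steps, config = train_config()) {
  abort_if(any(step < 0 | step > total_steps),
           "step outside 0..%d", total_steps)
  peak_step <- config$warmup_frac * total_steps
  ifelse(step <= peak_step,
         config$peak_lr * step / peak_step,
         config$peak_lr * (total_steps - step) / (total_steps - peak_step))
}

# one Adam update; state holds m, v, t
adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# forward + gradients of the squared error for one example
head_grads <- function(head, e_wt_sel, e_mt_sel, target) {
  p <- head$params
  spec <- head$spec
  f <- switch(spec$merge,
              concatenation = c(e_wt_sel, e_mt_sel),
              outer_product = as.vector(outer(e_wt_sel, e_mt_sel)),
              linear = p$w_wt * e_wt_sel + p$w_mt * e_mt_sel)
  z <- as.vector(p$W1 %*% f) + p$b1
  h <- tanh(z)
  y <- sum(p$W2 * h) + p$b2
  dy <- 2 * (y - target)
  dz <- dy * p$W2 * (1 - h^2)
  df <- as.vector(crossprod(p$W1, dz))
  grads <- list(W1 = outer(dz, f), b1 = dz, W2 = dy * h, b2 = dy)
  if (spec$merge == "linear") {
    if (spec$antisymmetric) {
      # tied w_mt = -w_wt, biases pinned at zero
      grads$w_wt <- df * e_wt_sel - df * e_mt_sel
      grads$b1 <- grads$b1 * 0
      grads$b2 <- 0
    } else {
      grads$w_wt <- df * e_wt_sel
      grads$w_mt <- df * e_mt_sel
    }
  }
  list(loss = (y - target)^2, pred = y, grads = grads)
}

# re-impose structural constraints after an update
enforce_ties <- function(head) {
  if (isTRUE(head$spec$antisymmetric)) {
    head$params$w_mt <- -head$params$w_wt
    head$params$b1 <- head$params$b1 * 0
    head$params$b2 <- 0
  }
  head
}

#' Train a regression head
#'
#' End-to-end per-example training with mean-squared-error loss, Adam
#' updates and the warmup/decay schedule of [lr_at()]. Data order is
#' reshuffled once per epoch under the run seed; the full run is bitwise
#' reproducible for a fixed seed and data order. Aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param spec A [head_spec()] (or an initialized `protstab_head` to
#'   continue training).
#' @param dataset Data frame of pairs with columns `wt_seq`, `mt_seq`,
#'   `position`, `ddg`.
#' @param backbone A `protstab_backbone`.
#' @param config A [train_config()].
#' @return List with `model` (trained head) and `trace` (data frame:
#'   epoch, step, lr, loss).
#' @export
train_head <- function(spec, dataset, backbone,
                       config = train_config()) {
  abort_if(nrow(dataset) == 0, "empty training dataset")
  need <- c("wt_seq", "mt_seq", "position", "ddg")
  miss <- setdiff(need, names(dataset))
  abort_if(length(miss) > 0, "dataset lacks column(s): %s",
           paste(miss, collapse = ", "))
  abort_if(any(!is.finite(dataset$ddg)), "non-finite training targets")

  head <- if (inherits(spec, "protstab_head")) spec
  else init_head(spec, backbone$width, seed = config$seed)
  cache <- embedding_cache()
  n <- nrow(dataset)
  total <- config$epochs * n
  state <- list(m = list(), v = list(), t = 0)
  trace <- vector("list", total)

  with_seed(config$seed, {
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      order_ep <- sample.int(n)
      for (i in order_ep) {
        step <- step + 1L
        lr <- lr_at(step, total, config)
        e_wt <- select_source(head$spec,
                              embed_cached(dataset$wt_seq[i], backbone,
                                           cache),
                              dataset$position[i])
        e_mt <- select_source(head$spec,
                              embed_cached(dataset$mt_seq[i], backbone,
                                           cache),
                              dataset$position[i])
        g <- head_grads(head, e_wt, e_mt, dataset$ddg[i])
        abort_if(!is.finite(g$loss),
                 "non-finite loss at epoch %d step %d (target %g)",
                 epoch, step, dataset$ddg[i])
        upd <- adam_update(head$params, g$grads, state, lr)
        head$params <- upd$params
        head <- enforce_ties(head)
        state <- upd$state
        trace[[step]] <- c(epoch = epoch, step = step, lr = lr,
                           loss = g$loss)
      }
    }
  })
  head$trained <- TRUE
  list(model = head,
       trace = as.data.frame(do.call(rbind, trace)))
}

#' Train the five-head ensemble
#'
#' Trains the five admissible heads as five independent runs with
#' distinct seeds derived from the run seed, then assembles them into an
#' ensemble whose prediction is the member mean.
#'
#' @param dataset Training pairs (see [train_head()]).
#' @param backbone A `protstab_backbone`.
#' @param config A [train_config()].
#' @param antisymmetric Antisymmetric tying for the linear-merge members.
#' @return List with `ensemble` (a `protstab_ensemble`) and `traces`
#'   (per-member loss traces).
#' @export
train_ensemble <- function(dataset, backbone, config = train_config(),
                           antisymmetric = FALSE) {
  specs <- five_head_specs(hidden = config$hidden,
                           antisymmetric = antisymmetric)
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  for (k in seq_along(specs)) {
    cfg <- config
    cfg$seed <- config$seed + k
    fits[[k]] <- train_head(specs[[k]], dataset, backbone, cfg)
  }
  list(ensemble = build_ensemble(lapply(fits, `[[`, "model")),
       traces = lapply(fits, `[[`, "trace"))
}

#' Predict ddG for a table of pairs
#'
#' Vectorized convenience over [predict_head()] / [predict_ensemble()],
#' with embedding reuse across rows.
#'
#' @param model A trained `protstab_head` or `protstab_ensemble`.
#' @param pairs Data frame with `wt_seq`, `mt_seq`, `position`.
#' @param backbone A `protstab_backbone`.
#' @param allow_untrained Permit untrained heads (structural tests).
#' @return Numeric vector of predictions.
#' @export
predict_pairs <- function(model, pairs, backbone,
                          allow_untrained = FALSE) {
  cache <- embedding_cache()
  fun <- if (inherits(model, "protstab_ensemble")) predict_ensemble
  else predict_head
  vapply(seq_len(nrow(pairs)), function(i)
    fun(model, list(wt_seq = pairs$wt_seq[i], mt_seq = pairs$mt_seq[i],
                    position = pairs$position[i]),
        backbone, allow_untrained = allow_untrained, cache = cache),
    0)
}
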