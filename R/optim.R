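# ---------------------------------------------------------------------------
# Adam optimizer and the reduce-on-plateau learning-rate schedule.
# ---------------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(state = state, params = params)
}

#' Reduce-on-plateau learning-rate schedule
#'
#' Starts at `initial_lr`; whenever the monitored metric (validation Dice,
#' to be maximized) fails to improve for `patience` consecutive updates,
#' the learning rate is multiplied by `factor` and the stagnation counter
#' resets. The resulting trace is a non-increasing step function with
#' steps of exactly `factor`.
#'
#' @param initial_lr starting learning rate (default 0.001).
#' @param factor multiplicative decay (default 0.1).
#' @param patience stagnant updates tolerated before decaying (default 10).
#' @return a list of class `lr_schedule` with fields `lr`, `best`, `bad`.
#' @export
lr_schedule <- function(initial_lr = 1e-3, factor = 0.1, patience = 10L) {
  if (initial_lr <= 0) stop("initial_lr must be > 0")
  if (factor <= 0 || factor >= 1) stop("factor must lie in (0, 1)")
  structure(list(lr = initial_lr, factor = factor,
                 patience = as.integer(patience),
                 best = -Inf, bad = 0L, n_decays = 0L),
            class = "lr_schedule")
}

#' Advance the schedule with a new metric value
#'
#' @param sched an [lr_schedule()].
#' @param metric the monitored value (higher is better).
#' @return the updated schedule.
#' @export
lr_schedule_step <- function(sched, metric) {
  if (is.finite(metric) && metric > sched$best) {
    sched$best <- metric
    sched$bad <- 0L
  } else {
    sched$bad <- sched$bad + 1L
    if (sched$bad >= sched$patience) {
      sched$lr <- sched$lr * sched$factor
      sched$n_decays <- sched$n_decays + 1L
      sched$bad <- 0L
    }
  }
  sched
}
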