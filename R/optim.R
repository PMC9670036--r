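# Adam optimizer over a named list of parameter matrices, plus the two
# learning-rate schedules used in the package: step decay for the
# graph-transformer and cosine annealing for contrastive pre-training.

adam_state <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(params, function(p) array(0, dim(p))),
    v = lapply(params, function(p) array(0, dim(p)))
  )
}

adam_step <- function(opt, params, grads, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    mhat <- opt$m[[nm]] / c1
    vhat <- opt$v[[nm]] / c2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}

# Piecewise-constant decay: lr_i applies from decay_steps[i] onward (step is
# 0-based, matching "decayed at step 30 and 100").
lr_step_decay <- function(step, initial_lr, decay_steps, decay_factors) {
  lr <- initial_lr
  for (i in seq_along(decay_steps)) {
    if (step >= decay_steps[i]) lr <- initial_lr * decay_factors[i]
  }
  lr
}

lr_cosine <- function(step, total_steps, initial_lr, min_lr = 0) {
  min_lr + 0.5 * (initial_lr - min_lr) * (1 + cos(pi * min(step, total_steps) / total_steps))
}
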