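# Desk-scale GRPO training: a per-prompt categorical policy over eight
# templated completions, scored by the real reward suite. Every reward
# component is exercised by the template set and exactly one completion per
# prompt attains the maximum total of 5.75.

#' Build the planted toy completion task
#'
#' Each prompt carries a ground-truth label and eight fixed completions
#' spanning the reward landscape: ideal; correct with moderate and low
#' confidence; incorrect with low and high confidence; correct but missing
#' the score block; invalid label; free text with no tags. Rewards are
#' precomputed with [total_reward()].
#'
#' @param truths Ground-truth labels, one prompt each (default three
#'   prompts, mixed labels).
#' @return A `toy_task` list with per-prompt completions and reward
#'   vectors.
#' @export
toy_task <- function(truths = c("approved", "unapproved", "approved")) {
  abort_if(!all(truths %in% APPROVAL_LABELS), "truths must be approval labels")
  prompts <- lapply(seq_along(truths), function(j) {
    t <- truths[j]
    o <- setdiff(APPROVAL_LABELS, t)
    comps <- c(
      ideal          = render_response("candidate tracks the approved neighbors", t, 0.9),
      correct_mid    = render_response("likely, with reservations", t, 0.5),
      correct_low    = render_response("weak evidence either way", t, 0.2),
      wrong_low      = render_response("hard to call", o, 0.2),
      wrong_high     = render_response("confidently mistaken", o, 0.9),
      missing_score  = sprintf("<think>no confidence given</think>\n<label>%s</label>", t),
      invalid_label  = render_response("hedging", "maybe", 0.9),
      no_tags        = "the molecule looks fine to me.")
    rew <- vapply(comps, function(r) total_reward(r, t)$total, numeric(1))
    list(truth = t, completions = comps, rewards = unname(rew))
  })
  structure(list(prompts = prompts,
                 max_reward = max(vapply(prompts, function(p) max(p$rewards), 0))),
            class = "toy_task")
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# temperature / top-k / top-p truncated sampling distribution
truncated_sampler <- function(p, temperature, top_k, top_p) {
  if (temperature != 1) p <- softmax(log(pmax(p, 1e-300)) / temperature)
  ord <- order(p, decreasing = TRUE)
  keep <- ord[seq_len(min(top_k, length(p)))]
  ck <- cumsum(p[keep])
  n_keep <- which(ck >= top_p)[1]
  if (is.na(n_keep)) n_keep <- length(keep)
  keep <- keep[seq_len(n_keep)]
  q <- numeric(length(p))
  q[keep] <- p[keep] / sum(p[keep])
  q
}

#' Train the toy categorical policy with GRPO
#'
#' One categorical distribution per prompt is optimized with the GRPO loss:
#' per step, K completions are sampled per prompt from the
#' temperature/top-k/top-p truncated snapshot policy, scored by the reward
#' suite, advantaged against the group mean, and the clipped surrogate plus
#' KL penalty to the snapshot is ascended by AdamW (decoupled weight decay,
#' linear warmup, cosine decay, global gradient clipping). With the default
#' `inner_iterations = 2` the clipping and KL terms are active.
#'
#' The default learning rate here is 0.05: the categorical toy policy has a
#' few dozen logits, not billions of transformer weights, and converges on
#' the planted task within the configured steps at this scale.
#'
#' @param task A [toy_task()].
#' @param cfg A [grpo_config()]; `steps`, `seed`, `group_size` and the
#'   optimizer block are honored.
#' @param learning_rate Overrides `cfg$learning_rate` (default 0.05).
#' @param eval_every When > 0, evaluate the greedy policy on the task's
#'   prompts every `eval_every` steps and return a checkpoint table
#'   (`step`, `auc`, `f1`, `format_adherence`, ...) for
#'   [select_checkpoint()].
#' @return List with `trace` (per-step `data.frame`: `step`, `mean_reward`,
#'   `ema_reward`, `kl_step`, `kl_ref`, `loss`, `p_best`), final `logits`,
#'   `final_ema`, `max_reward`, `checkpoints` (or `NULL`), and the
#'   effective config.
#' @export
toy_grpo_train <- function(task, cfg = grpo_config(), learning_rate = 0.05,
                           eval_every = 0L) {
  abort_if(!inherits(task, "toy_task"), "`task` must come from toy_task()")
  cfg$learning_rate <- learning_rate
  J <- length(task$prompts)
  n_act <- length(task$prompts[[1]]$completions)
  degenerate <- all(vapply(task$prompts, function(p) length(unique(p$rewards)) == 1L, logical(1)))
  if (degenerate) warning("degenerate task: all completions share one reward; training is a no-op")
  set.seed(cfg$seed)
  theta <- matrix(0, nrow = J, ncol = n_act)
  p_ref <- t(apply(theta, 1, softmax))          # frozen initial reference, for drift reporting
  m <- v <- matrix(0, nrow = J, ncol = n_act)
  best_idx <- vapply(task$prompts, function(p) which.max(p$rewards), integer(1))
  ema <- NA_real_
  trace <- vector("list", cfg$steps)
  checkpoints <- list()
  truths <- vapply(task$prompts, `[[`, "", "truth")
  adam_t <- 0L
  for (step in seq_len(cfg$steps)) {
    warm <- min(1, step / max(1L, cfg$warmup_steps))
    prog <- max(0, (step - cfg$warmup_steps) / max(1L, cfg$steps - cfg$warmup_steps))
    lr <- cfg$learning_rate * warm * 0.5 * (1 + cos(pi * min(1, prog)))
    p_old <- t(apply(theta, 1, softmax))        # snapshot pi_theta_old
    samples <- vector("list", J)
    rewards_step <- numeric(0)
    for (j in seq_len(J)) {
      q <- truncated_sampler(p_old[j, ], cfg$temperature, cfg$top_k, cfg$top_p)
      a <- sample.int(n_act, cfg$group_size, replace = TRUE, prob = q)
      samples[[j]] <- a
      rewards_step <- c(rewards_step, task$prompts[[j]]$rewards[a])
    }
    kl_step <- 0
    loss_val <- NA_real_
    for (it in seq_len(cfg$inner_iterations)) {
      grad <- matrix(0, nrow = J, ncol = n_act)
      surrogate <- 0
      kl_sum <- 0
      for (j in seq_len(J)) {
        p_new <- softmax(theta[j, ])
        a <- samples[[j]]
        A <- advantages(task$prompts[[j]]$rewards[a])
        r <- p_new[a] / p_old[j, a]
        L <- clipped_objective(r, A, cfg$clip_eps)
        surrogate <- surrogate + sum(L)
        unclipped_active <- (r * A) <= (pmin(pmax(r, 1 - cfg$clip_eps), 1 + cfg$clip_eps) * A + 1e-15)
        for (k in seq_along(a)) {
          if (!unclipped_active[k]) next
          e <- numeric(n_act); e[a[k]] <- 1
          grad[j, ] <- grad[j, ] - A[k] * r[k] * (e - p_new)   # d(-L)/dtheta
        }
        grad[j, ] <- grad[j, ] + cfg$kl_weight * (p_new - p_old[j, ])  # d KL(p_old||p)/dtheta
        kl_sum <- kl_sum + kl_categorical(p_old[j, ], p_new)
      }
      loss_val <- -surrogate + cfg$kl_weight * kl_sum
      kl_step <- kl_sum
      gn <- sqrt(sum(grad^2))
      if (gn > cfg$grad_clip_norm) grad <- grad * (cfg$grad_clip_norm / gn)
      adam_t <- adam_t + 1L
      m <- cfg$adam_beta1 * m + (1 - cfg$adam_beta1) * grad
      v <- cfg$adam_beta2 * v + (1 - cfg$adam_beta2) * grad^2
      mh <- m / (1 - cfg$adam_beta1^adam_t)
      vh <- v / (1 - cfg$adam_beta2^adam_t)
      theta <- theta - lr * (mh / (sqrt(vh) + 1e-8) + cfg$weight_decay * theta)
    }
    mean_reward <- mean(rewards_step)
    ema <- if (is.na(ema)) mean_reward else 0.9 * ema + 0.1 * mean_reward
    p_now <- t(apply(theta, 1, softmax))
    trace[[step]] <- data.frame(
      step = step, mean_reward = mean_reward, ema_reward = ema,
      kl_step = kl_step,
      kl_ref = sum(vapply(seq_len(J), function(j) kl_categorical(p_ref[j, ], p_now[j, ]), 0)),
      loss = loss_val,
      p_best = mean(p_now[cbind(seq_len(J), best_idx)]))
    if (eval_every > 0L && step %% eval_every == 0L) {
      greedy <- vapply(seq_len(J), function(j) {
        task$prompts[[j]]$completions[which.max(theta[j, ])]
      }, character(1))
      rep <- evaluate_responses(truths, greedy)
      checkpoints[[length(checkpoints) + 1L]] <- data.frame(
        step = step, auc = rep$auc, f1 = rep$f1, accuracy = rep$accuracy,
        recall = rep$recall, precision = rep$precision,
        specificity = rep$specificity, format_adherence = rep$format_adherence)
    }
  }
  trace <- do.call(rbind, trace)
  list(trace = trace, logits = theta, final_ema = ema,
       max_reward = task$max_reward,
       checkpoints = if (length(checkpoints)) do.call(rbind, checkpoints) else NULL,
       config = cfg)
}
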