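# Group-relative policy optimization: group-mean baseline, advantages,
# clipped probability-ratio surrogate and KL penalty to the pre-update
# policy snapshot, composed into the scalar loss
#   L(theta) = - sum_j sum_k L_jk(theta) + beta * sum_j D_KL(pi_old || pi).

#' GRPO configuration
#'
#' Defaults mirror the reference training recipe: group size 4, learning
#' rate 5e-6, Adam moments (0.9, 0.99), weight decay 0.1, 100 warmup steps,
#' cosine schedule, gradient-clip norm 0.1, sampling with temperature 1,
#' top-p 0.9 and top-k 9. The clip width and KL weight are not printed in
#' that recipe; the conventional 0.2 and 0.04 are used and exposed here.
#'
#' @param clip_eps Clipping half-width, in (0, 1).
#' @param kl_weight KL-penalty coefficient beta, >= 0.
#' @param group_size Completions sampled per prompt (K).
#' @param steps Optimization steps.
#' @param learning_rate Adam learning rate.
#' @param adam_beta1,adam_beta2 Adam moment decays.
#' @param weight_decay Decoupled weight decay.
#' @param warmup_steps Linear warmup length.
#' @param grad_clip_norm Global gradient-norm clip.
#' @param temperature,top_p,top_k Sampling controls for the policy sampler.
#' @param inner_iterations Gradient updates per sampled batch; values > 1
#'   activate the clipping and KL terms.
#' @param seed Integer seed.
#' @return A `grpo_config` list.
#' @export
grpo_config <- function(clip_eps = 0.2, kl_weight = 0.04, group_size = 4L,
                        steps = 2000L, learning_rate = 5e-6,
                        adam_beta1 = 0.9, adam_beta2 = 0.99,
                        weight_decay = 0.1, warmup_steps = 100L,
                        grad_clip_norm = 0.1, temperature = 1,
                        top_p = 0.9, top_k = 9L, inner_iterations = 2L,
                        seed = 1L) {
  cfg <- list(clip_eps = clip_eps, kl_weight = kl_weight, group_size = as.integer(group_size),
              steps = as.integer(steps), learning_rate = learning_rate,
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              weight_decay = weight_decay, warmup_steps = as.integer(warmup_steps),
              grad_clip_norm = grad_clip_norm, temperature = temperature,
              top_p = top_p, top_k = as.integer(top_k),
              inner_iterations = as.integer(inner_iterations), seed = as.integer(seed))
  abort_if(!(cfg$clip_eps > 0 && cfg$clip_eps < 1), "`clip_eps` must lie in (0, 1)")
  abort_if(cfg$kl_weight < 0, "`kl_weight` must be >= 0")
  abort_if(cfg$group_size < 1, "`group_size` must be >= 1")
  class(cfg) <- "grpo_config"
  cfg
}

#' Group baseline (mean reward)
#'
#' @param rewards Numeric vector of the K rewards of one group.
#' @return Scalar mean.
#' @export
group_baseline <- function(rewards) {
  abort_if(!length(rewards), "empty reward group")
  mean(rewards)
}

#' Group-relative advantages
#'
#' `A_jk = R_jk - mean(R_j)`; sums to zero within each group.
#'
#' @param rewards Numeric vector of the K rewards of one group.
#' @return Numeric vector of advantages.
#' @export
advantages <- function(rewards) {
  rewards - group_baseline(rewards)
}

#' Probability ratio of new to old policy
#'
#' @param logp_new,logp_old Log-probabilities of the completion under the
#'   current and snapshot policies.
#' @return `exp(logp_new - logp_old)`, positive.
#' @export
prob_ratio <- function(logp_new, logp_old) {
  abort_if(any(!is.finite(logp_new)) || any(!is.finite(logp_old)),
           "log-probabilities must be finite")
  exp(logp_new - logp_old)
}

#' Clipped surrogate objective for one completion
#'
#' `min(r * A, clip(r, 1 - eps, 1 + eps) * A)`.
#'
#' @param r Probability ratio (> 0).
#' @param advantage Advantage A.
#' @param clip_eps Clipping half-width.
#' @return Scalar objective value.
#' @export
clipped_objective <- function(r, advantage, clip_eps = 0.2) {
  abort_if(any(r <= 0), "probability ratio must be positive")
  pmin(r * advantage, pmin(pmax(r, 1 - clip_eps), 1 + clip_eps) * advantage)
}

#' KL divergence between categorical distributions
#'
#' `D_KL(p_old || p_new) = sum p_old * log(p_old / p_new)`, requiring
#' `p_new > 0` wherever `p_old > 0`.
#'
#' @param p_old,p_new Probability vectors over the same support.
#' @return Non-negative scalar.
#' @export
kl_categorical <- function(p_old, p_new) {
  abort_if(length(p_old) != length(p_new), "distributions must share a support")
  abort_if(any(p_old < 0) || any(p_new < 0) ||
           abs(sum(p_old) - 1) > 1e-8 || abs(sum(p_new) - 1) > 1e-8,
           "inputs must be probability distributions")
  nz <- p_old > 0
  abort_if(any(p_new[nz] == 0), "p_new must be positive wherever p_old is")
  sum(p_old[nz] * log(p_old[nz] / p_new[nz]))
}

#' GRPO loss over a batch of groups
#'
#' Composes the clipped surrogates and KL penalties into the training loss
#' `-sum_j sum_k L_jk + beta * sum_j D_KL`. Advantages are recomputed from
#' the group rewards.
#'
#' @param groups List of groups; each a list with numeric `rewards`,
#'   `logp_new`, `logp_old` of equal length K.
#' @param cfg A [grpo_config()].
#' @param kl_terms Numeric vector, one KL divergence per group (computed by
#'   the policy owner; see [kl_categorical()]).
#' @return List with `surrogate_sum`, `kl_sum`, `total`, and per-group
#'   detail.
#' @export
grpo_loss <- function(groups, cfg = grpo_config(), kl_terms = numeric(length(groups))) {
  abort_if(!length(groups), "`groups` must be non-empty")
  abort_if(length(kl_terms) != length(groups), "`kl_terms` must align with `groups`")
  surrogate <- 0
  detail <- vector("list", length(groups))
  for (j in seq_along(groups)) {
    g <- groups[[j]]
    abort_if(length(g$rewards) != length(g$logp_new) ||
             length(g$rewards) != length(g$logp_old),
             "group ", j, ": rewards and log-probabilities are misaligned")
    A <- advantages(g$rewards)
    r <- prob_ratio(g$logp_new, g$logp_old)
    L <- clipped_objective(r, A, cfg$clip_eps)
    surrogate <- surrogate + sum(L)
    detail[[j]] <- data.frame(advantage = A, ratio = r, objective = L)
  }
  kl_sum <- sum(kl_terms)
  abort_if(kl_sum < -1e-12, "KL terms must be non-negative")
  list(surrogate_sum = surrogate, kl_sum = kl_sum,
       total = -surrogate + cfg$kl_weight * kl_sum, detail = detail)
}
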