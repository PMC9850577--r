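# Similarity-gated rewards and REINFORCE fine-tuning.

test_that("task configurations carry the published thresholds", {
  qed <- task_reward_config("qed")
  expect_equal(qed$direction, "increase")
  expect_equal(qed$delta, 0.75); expect_equal(qed$epsilon, 0.3)
  drd2 <- task_reward_config("drd2")
  expect_equal(drd2$delta, 0); expect_equal(drd2$epsilon, 0.3)
  expect_equal(task_reward_config("plogp04")$epsilon, 0.3)
  p6 <- task_reward_config("plogp06")
  expect_equal(p6$direction, "improvement"); expect_equal(p6$epsilon, 0.5)
  ab <- task_reward_config("abcg2")
  expect_equal(ab$direction, "decrease")
  expect_equal(ab$delta, 4.989); expect_equal(ab$epsilon, 0.4)
  expect_equal(ab$aux_min, 6.235)
  expect_error(task_reward_config("nope"))
  # config invariants
  expect_error(make_reward_config("decrease", delta = 0, epsilon = 0.3),
               "delta")
  expect_error(make_reward_config("increase", delta = 1, epsilon = 0.3),
               "delta")
  expect_error(make_reward_config("increase", delta = 0, epsilon = 1.5),
               "epsilon")
})

test_that("reward kernel reproduces the piecewise definitions", {
  inc <- make_reward_config("increase", delta = 0.75, epsilon = 0.3)
  expect_equal(reward_kernel(0.90, 0.50, inc), 0.6)      # (0.90-0.75)/0.25
  expect_equal(reward_kernel(0.90, 0.30, inc), 0)        # T == epsilon: gated
  expect_equal(reward_kernel(0.90, 0.29, inc), 0)
  expect_equal(reward_kernel(0.75, 0.50, inc), 0)        # numerator zero
  expect_equal(reward_kernel(0.60, 0.50, inc), 0)        # clipped at zero

  dec <- make_reward_config("decrease", delta = 4.989, epsilon = 0.4)
  expect_equal(reward_kernel(4.989, 0.5, dec), 0)
  expect_equal(reward_kernel(0, 0.5, dec), 1.0)
  expect_equal(reward_kernel(2, 0.5, dec), (4.989 - 2) / 4.989)

  imp <- make_reward_config("improvement", delta = 0, epsilon = 0.3)
  # gains over the source can exceed 1 for unbounded properties
  expect_equal(reward_kernel(3, 0.4, imp, phi_source = 1), 2.0)
  expect_equal(reward_kernel(0.5, 0.4, imp, phi_source = 1), 0)
  expect_error(reward_kernel(1, 0.5, imp), "phi_source")

  aux <- make_reward_config("decrease", delta = 4.989, epsilon = 0.4,
                            aux_min = 6.235,
                            aux_oracle = make_oracle("function",
                                                     fn = function(s) 7))
  expect_equal(reward_kernel(2, 0.5, aux, aux = 7), (4.989 - 2) / 4.989)
  expect_equal(reward_kernel(2, 0.5, aux, aux = 6.235), 0)  # strict >
  expect_equal(reward_kernel(2, 0.5, aux, aux = 5), 0)
})

test_that("reward gates invalid outputs and sub-threshold similarity", {
  or <- heavy_oracle()
  cfg <- make_reward_config("increase", delta = 0, epsilon = 0.3,
                            oracle = or)
  # identical molecule: similarity 1 > epsilon, reward = phi
  expect_equal(reward("CCCCCC", "CCCCCC", cfg), heavy_atom_score("CCCCCC"))
  # invalid generated text scores 0, not an error
  expect_equal(reward(c("C(C", "xyz"), "CCCCCC", cfg), c(0, 0))
  # structurally unrelated molecule is gated out
  expect_equal(reward("OCOCOCOCO", "CCCCCC", cfg), 0)
  expect_error(reward("CCO", "C(C", cfg), "invalid source")

  # randomized strict-gate property: reward is 0 whenever T <= epsilon
  set.seed(12)
  pool <- syn_small()$negatives_pool
  for (i in 1:1000) {
    x <- sample(pool, 1); y <- sample(pool, 1)
    eps <- runif(1)
    cfg2 <- make_reward_config("increase", delta = 0, epsilon = eps,
                               oracle = or)
    r <- reward(y, x, cfg2)
    s <- tanimoto_smiles(x, y)
    if (s <= eps) expect_identical(r, 0)
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("a REINFORCE step updates only the decoder, in the right direction", {
  m <- fit_small()
  or <- heavy_oracle()
  cfg <- make_reward_config("increase", delta = 0, epsilon = 0.3,
                            oracle = or)
  src <- syn_small()$pairs$source[1:6]
  enc_before <- m$params[contragen:::ENCODER_PARAM_NAMES]
  step <- reinforce_step(m, src, cfg, lr = 0.05, seed = 17)
  expect_identical(step$model$params[contragen:::ENCODER_PARAM_NAMES],
                   enc_before)
  # zero rewards everywhere -> parameters unchanged
  zero <- make_reward_config("increase", delta = 0, epsilon = 0.3,
                             oracle = make_oracle("function",
                                                  fn = function(s) 0 * nchar(s)))
  step0 <- reinforce_step(m, src, zero, lr = 0.05, seed = 17)
  expect_identical(step0$model$params, m$params)
  expect_equal(step0$mean_reward, 0)
})

test_that("policy gradient raises the probability of the rewarded sequence", {
  # enumerable toy decoder: sources are the single atom "C"; only the exact
  # sequence "C" earns reward 1
  vocab <- build_vocab(c("C", "N", "O"))
  m <- contragen_init(vocab, contragen_config(latent_dim = 2L,
                                              hidden_size = 6L,
                                              embed_size = 4L, max_len = 3L,
                                              seed = 6L))
  m$params$b_lv[] <- -8  # near-deterministic latents
  target_canon <- canonicalize_smiles("C")
  or <- make_oracle("function",
                    fn = function(s) {
                      as.numeric(canonicalize_smiles(s) == target_canon)
                    })
  cfg <- make_reward_config("increase", delta = 0, epsilon = 0, oracle = or)
  prob_C <- function(model) {
    g <- encode_latent(model, "C")
    # probability of emitting token "C" then <eos> from the latent mean
    p <- exp(-decode_nll(model, g$mean, "C"))
    as.numeric(p)
  }
  p0 <- prob_C(m)
  step <- reinforce_step(m, rep("C", 64L), cfg, lr = 0.1, seed = 23)
  expect_gt(prob_C(step$model), p0)
})

test_that("RL training is seeded and logs a reward history", {
  m <- fit_small()
  or <- heavy_oracle()
  cfg <- make_reward_config("increase", delta = 0, epsilon = 0.3,
                            oracle = or)
  src <- unique(syn_small()$pairs$source)
  expect_identical(train_rl_phase(m, src, cfg, epochs = 0L), m)
  r1 <- train_rl_phase(m, src, cfg, epochs = 2L, batch_size = 18L,
                       learning_rate = 2e-3, seed = 9L)
  r2 <- train_rl_phase(m, src, cfg, epochs = 2L, batch_size = 18L,
                       learning_rate = 2e-3, seed = 9L)
  expect_identical(r1$rl_history, r2$rl_history)
  expect_identical(r1$params, r2$params)
  expect_equal(nrow(r1$rl_history), 2L)
  expect_true(all(is.finite(r1$rl_history$mean_reward)))
})
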