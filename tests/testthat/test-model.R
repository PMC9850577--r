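# The sequence VAE: encoding, latent sampling, decoding, generation.

tiny_model <- function(seed = 3L) {
  vocab <- build_vocab(c("CCO", "CCCO", "CCN", "CCOC", "CCCCC"))
  contragen_init(vocab, contragen_config(latent_dim = 4L, hidden_size = 8L,
                                         embed_size = 6L, seed = seed))
}

test_that("encoding is deterministic with strictly positive variance", {
  m <- tiny_model()
  g1 <- encode_latent(m, c("CCO", "CCCO"))
  g2 <- encode_latent(m, c("CCO", "CCCO"))
  expect_identical(g1, g2)
  expect_true(all(g1$variance > 0))
  expect_true(all(is.finite(g1$mean)))
  # different sequences get distinct means under random initialization
  expect_gt(sum(abs(g1$mean[1, ] - g1$mean[2, ])), 1e-8)
  expect_error(encode_latent(m, ""), "empty")
})

test_that("latent sampling is reparameterized and distributionally correct", {
  m <- tiny_model()
  g <- encode_latent(m, "CCO")
  expect_identical(sample_latent(g, seed = 11), sample_latent(g, seed = 11))
  # degenerate variance collapses the sample onto the mean
  g0 <- structure(list(mean = g$mean, variance = g$variance * 1e-20),
                  class = "cg_latent")
  expect_equal(as.numeric(sample_latent(g0, seed = 1)), as.numeric(g$mean),
               tolerance = 1e-6)
  # Monte-Carlo mean within 4 standard errors, per coordinate
  n <- 10000L
  gg <- structure(list(mean = g$mean[rep(1, n), ],
                       variance = g$variance[rep(1, n), ]),
                  class = "cg_latent")
  draws <- sample_latent(gg, seed = 42)
  se <- sqrt(as.numeric(g$variance)) / sqrt(n)
  expect_true(all(abs(colMeans(draws) - as.numeric(g$mean)) < 4 * se))
  # Kolmogorov-Smirnov agreement with N(mean, variance) at alpha = 0.01
  for (j in 1:2) {
    p <- stats::ks.test(draws[, j], "pnorm", mean = g$mean[1, j],
                        sd = sqrt(g$variance[1, j]))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("teacher-forced NLL has the uniform-decoder closed form", {
  m <- tiny_model()
  # zero the output head: logits identically 0 -> uniform over V tokens
  m$params$W_out[] <- 0
  m$params$b_out[] <- 0
  V <- length(m$vocab)
  z <- numeric(m$config$latent_dim)
  for (s in c("CCO", "CCCCC")) {
    L <- length(tokenize_smiles(s)) + 1L  # tokens + <eos> predictions
    expect_equal(as.numeric(decode_nll(m, z, s)), L * log(V),
                 tolerance = 1e-9)
  }
  # NLL is non-negative in general
  m2 <- tiny_model(seed = 9)
  expect_true(all(decode_nll(m2, matrix(rnorm(8), 2, 4),
                             c("CCO", "CCOC")) >= 0))
  expect_error(decode_nll(m2, numeric(3), "CCO"), "dimension")
})

test_that("generation is seeded, bounded, and flags validity consistently", {
  m <- tiny_model()
  z <- matrix(rnorm(5 * 4), 5, 4)
  g1 <- generate_smiles(m, z, seed = 21)
  g2 <- generate_smiles(m, z, seed = 21)
  expect_identical(g1, g2)
  expect_true(all(nchar(g1) <= m$config$max_len * 4))
  expect_identical(attr(g1, "valid"), smiles_is_valid(as.character(g1)))
  expect_error(generate_smiles(m, matrix(0, 1, 7)), "dimension")
})

test_that("a model overfit on one molecule reproduces it", {
  triplets <- data.frame(source = "CCO", target = "CCO",
                         negative = "CSCSCSCSCS", stringsAsFactors = FALSE)
  vocab <- build_vocab(c("CCO", "CSCSCSCSCS"))
  m <- contragen_init(vocab, contragen_config(latent_dim = 4L,
                                              hidden_size = 16L,
                                              embed_size = 8L, seed = 2L))
  m <- train_metric_phase(m, triplets[rep(1, 16), ], epochs = 150L,
                          batch_size = 16L, seed = 4L)
  out <- translate_smiles(m, "CCO", k = 40L, seed = 8L)
  expect_gt(mean(as.character(out) == "CCO"), 0.9)
})

test_that("translate returns k seeded outputs for a valid source", {
  m <- fit_small()
  src <- syn_small()$pairs$source[1]
  out <- translate_smiles(m, src, k = 20L, seed = 13)
  expect_length(as.character(out), 20L)
  expect_identical(as.character(translate_smiles(m, src, k = 1L, seed = 5)),
                   as.character(translate_smiles(m, src, k = 1L, seed = 5)))
  expect_identical(attr(out, "valid"), smiles_is_valid(as.character(out)))
  expect_error(translate_smiles(m, "C(C"), "invalid")
})

test_that("checkpoints round-trip with identical behaviour", {
  m <- fit_small()
  path <- tempfile(fileext = ".rds")
  save_contragen(m, path)
  m2 <- load_contragen(path)
  probe <- c("CCO", syn_small()$pairs$source[2])
  g1 <- encode_latent(m, probe); g2 <- encode_latent(m2, probe)
  expect_equal(g1$mean, g2$mean, tolerance = 1e-6)
  expect_equal(g1$variance, g2$variance, tolerance = 1e-6)
  z <- matrix(0.1, 2, m$config$latent_dim)
  expect_equal(decode_nll(m, z, probe), decode_nll(m2, z, probe),
               tolerance = 1e-6)
})

test_that("model methods expose the usual fitted-object interface", {
  m <- fit_small()
  expect_output(print(m), "sequence VAE|generator")
  s <- summary(m)
  expect_s3_class(s, "summary.contragen")
  expect_gt(s$n_parameters, 1000)
  expect_named(coef(m), c(contragen:::ENCODER_PARAM_NAMES,
                          contragen:::DECODER_PARAM_NAMES),
               ignore.order = TRUE)
  lat <- predict(m, c("CCO", "CCN"), type = "latent")
  expect_equal(dim(lat), c(2L, m$config$latent_dim))
  tr <- predict(m, "CCO", type = "translate", k = 3L, seed = 1)
  expect_length(as.character(tr[["CCO"]]), 3L)
  sim <- simulate(m, nsim = 4L, seed = 2, newdata = c("CCO"))
  expect_s3_class(sim[[1]], "cg_genset")
  expect_length(sim[[1]]$outputs, 4L)
  path <- tempfile(fileext = ".png")
  grDevices::png(path); plot(m); grDevices::dev.off()
  expect_true(file.exists(path))
})
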